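# End-to-end orchestration: normalize -> extract -> select -> train ->
# evaluate, across conditions (normalization on/off, selection on/off) and
# independent seeded runs, with config validation and provenance echo.

# Full default configuration; unknown keys are rejected against this schema.
.default_config <- function() list(
  seed = 0L,
  runs = 1L,
  normalize = list(enabled = TRUE, compare = FALSE, template = 1L),
  backbone = list(name = "stub", input_size = c(64L, 64L),
                  feature_dim = 64L, seed = 0L),
  selection = list(enabled = FALSE, compare = FALSE, swarm = 20L,
                   iters = 100L, k = 5L, w_start = 0.9, w_end = 0.4,
                   c1 = 2.0, c2 = 2.0, v_max = 6.0),
  split = list(train_fraction = 0.8, folds = 10L, stratified = TRUE),
  classifier = list(kind = "xgboost", params = list()),
  out = NULL,
  verbose = FALSE
)

# Merge user values over defaults, rejecting unknown keys; `where` names
# the offending key path in errors.
.merge_config <- function(defaults, user, where = "config") {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop(where, " must be a mapping", call. = FALSE)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown configuration key: ", where, "$", unknown[1], call. = FALSE)
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) &&
        k != "params") {
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]],
                                     paste0(where, "$", k))
    } else defaults[k] <- list(user[[k]])  # [k]<- keeps explicit NULLs
  }
  defaults
}

#' Parse and validate a pipeline configuration
#'
#' Accepts a YAML/JSON file path or a named list; fills every omitted key
#' with its documented default and rejects unknown keys by name. The
#' validated config is what [run_pipeline()] executes and echoes to the
#' output directory for provenance.
#'
#' @param source file path (YAML or JSON) or named list; `NULL` gives the
#'   full default config.
#' @return validated configuration list of class `pipeline_config`.
#' @export
parse_pipeline_config <- function(source = NULL) {
  user <- if (is.null(source)) list()
    else if (is.character(source)) {
      if (!file.exists(source))
        stop("config file not found: ", source, call. = FALSE)
      if (grepl("\\.json$", source)) jsonlite::read_json(source, simplifyVector = TRUE)
      else yaml::read_yaml(source)
    } else if (is.list(source)) source
    else stop("config must be a file path or a list", call. = FALSE)
  cfg <- .merge_config(.default_config(), user)
  if (cfg$runs < 1L) stop("runs must be >= 1", call. = FALSE)
  if (!cfg$classifier$kind %in% c("xgboost", "random_forest", "ann"))
    stop("unknown configuration value: classifier$kind = ",
         cfg$classifier$kind, call. = FALSE)
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Write a config echo next to run outputs
#'
#' @param cfg a validated [parse_pipeline_config()] result.
#' @param dir output directory.
#' @return the echo path, invisibly.
#' @export
write_config_echo <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "config_echo.yaml")
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# Run a stage with tagged diagnostics.
.stage <- function(name, expr, verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e)
    stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
  if (verbose)
    message(sprintf("[%s] done in %.2fs", name,
                    proc.time()[["elapsed"]] - t0))
  out
}

#' Run the full diagnosis pipeline
#'
#' Executes stain normalization (optional), backbone feature extraction,
#' BPSO feature selection (optional) and classifier training/evaluation
#' over `runs` independent seeded runs. When `normalize$compare` or
#' `selection$compare` is set, both conditions of that stage are run and
#' the report includes the comparison: per-condition mean accuracies, the
#' before/after-selection accuracy delta, and the with/without-
#' normalization table.
#'
#' Each run re-splits the data with its own seed and re-seeds the
#' classifier and selection, so run-to-run spread reflects both sampling
#' and algorithmic stochasticity.
#'
#' @param images list of RGB arrays, or `NULL` if `manifest` is given.
#' @param labels 0/1 labels matching `images`.
#' @param config anything [parse_pipeline_config()] accepts.
#' @param manifest optional path of a `path,label` manifest CSV read via
#'   [read_image_manifest()].
#' @param backbone optional backbone-contract object overriding the
#'   `backbone` config block (a real pretrained network wrapper plugs in
#'   here); by default a [stub_backbone()] per the config.
#' @return object of class `cad_report`: `per_run` data frame, `summary`
#'   per-condition aggregate, `selection_delta`, `normalization_table`,
#'   `config`.
#' @export
run_pipeline <- function(images = NULL, labels = NULL, config = NULL,
                         manifest = NULL, backbone = NULL) {
  cfg <- parse_pipeline_config(config)
  if (!is.null(manifest)) {
    loaded <- .stage("load", read_image_manifest(manifest), cfg$verbose)
    images <- loaded$images; labels <- loaded$labels
  }
  if (is.null(images) || is.null(labels))
    stop("either images+labels or a manifest is required", call. = FALSE)
  labels <- as.integer(labels)
  if (is.null(backbone)) {
    if (cfg$backbone$name != "stub")
      stop("backbone '", cfg$backbone$name, "' requires a pretrained ",
           "network wrapper; pass it via the backbone argument",
           call. = FALSE)
    backbone <- stub_backbone(
      backbone_spec("stub", cfg$backbone$input_size, cfg$backbone$feature_dim),
      seed = cfg$backbone$seed)
  }

  norm_conditions <- if (isTRUE(cfg$normalize$compare)) c(TRUE, FALSE)
    else isTRUE(cfg$normalize$enabled)
  sel_conditions <- if (isTRUE(cfg$selection$compare)) c(FALSE, TRUE)
    else isTRUE(cfg$selection$enabled)

  rows <- list()
  for (norm_on in norm_conditions) {
    imgs <- if (norm_on) .stage("normalize", {
      template <- images[[cfg$normalize$template]]
      lapply(images, reinhard_normalize, target = template)
    }, cfg$verbose) else images
    imgs <- .stage("resize",
                   lapply(imgs, resize_for_backbone,
                          spec = list(input_size = backbone$input_size)),
                   cfg$verbose)
    data <- .stage("extract",
                   extract_features(imgs, backbone, labels), cfg$verbose)

    for (sel_on in sel_conditions) {
      for (r in seq_len(cfg$runs)) {
        run_seed <- cfg$seed + r - 1L
        plan <- split_plan(cfg$split$train_fraction, cfg$split$folds,
                           cfg$split$stratified, seed = run_seed)
        sp <- split_data(data, plan)
        std <- standardize_features(sp$train, sp$test)
        train <- std$train; test <- std$test
        n_sel <- ncol(train$x)
        if (sel_on) {
          bcfg <- bpso_config(cfg$selection$swarm, cfg$selection$iters,
                              cfg$selection$w_start, cfg$selection$w_end,
                              cfg$selection$c1, cfg$selection$c2,
                              cfg$selection$v_max, cfg$selection$k,
                              seed = run_seed)
          sel <- .stage("select", bpso_select(train, bcfg), cfg$verbose)
          train <- train[seq_len(nrow(train$x)), sel$selected]
          test <- test[seq_len(nrow(test$x)), sel$selected]
          n_sel <- sel$n_selected
        }
        model <- .stage("train",
                        train_classifier(train, cfg$classifier$kind,
                                         cfg$classifier$params,
                                         seed = run_seed), cfg$verbose)
        counts <- .stage("evaluate", evaluate(model, test), cfg$verbose)
        met <- compute_metrics(counts)
        rows[[length(rows) + 1L]] <- data.frame(
          normalize = norm_on, selection = sel_on, run = r, seed = run_seed,
          accuracy = met$accuracy, sensitivity = met$sensitivity,
          precision = met$precision, TP = counts$TP, TN = counts$TN,
          FP = counts$FP, FN = counts$FN, n_features = n_sel)
      }
    }
  }
  per_run <- do.call(rbind, rows)

  agg <- stats::aggregate(accuracy ~ normalize + selection, per_run, mean)
  names(agg)[names(agg) == "accuracy"] <- "mean_accuracy"
  agg$sd_accuracy <- stats::aggregate(accuracy ~ normalize + selection,
                                      per_run, stats::sd)$accuracy

  selection_delta <- NULL
  if (length(sel_conditions) == 2L) {
    on <- agg[agg$selection, ]; off <- agg[!agg$selection, ]
    selection_delta <- merge(off[, c("normalize", "mean_accuracy")],
                             on[, c("normalize", "mean_accuracy")],
                             by = "normalize",
                             suffixes = c("_all", "_selected"))
    selection_delta$delta <- selection_delta$mean_accuracy_selected -
      selection_delta$mean_accuracy_all
  }
  normalization_table <- NULL
  if (length(norm_conditions) == 2L) {
    on <- agg[agg$normalize, ]; off <- agg[!agg$normalize, ]
    normalization_table <- merge(
      off[, c("selection", "mean_accuracy")],
      on[, c("selection", "mean_accuracy")],
      by = "selection", suffixes = c("_raw", "_normalized"))
  }

  report <- structure(list(per_run = per_run, summary = agg,
                           selection_delta = selection_delta,
                           normalization_table = normalization_table,
                           config = cfg),
                      class = "cad_report")
  if (!is.null(cfg$out)) {
    dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
    write_config_echo(cfg, cfg$out)
    utils::write.csv(per_run, file.path(cfg$out, "per_run.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(summary = agg,
                              selection_delta = selection_delta,
                              normalization_table = normalization_table),
                         file.path(cfg$out, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  report
}

#' @export
print.cad_report <- function(x, ...) {
  cat("CAD pipeline report:", nrow(x$per_run), "evaluations\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  normalize=%-5s selection=%-5s mean accuracy %.1f%% (sd %.1f)\n",
                s$normalize[i], s$selection[i], s$mean_accuracy[i],
                ifelse(is.na(s$sd_accuracy[i]), 0, s$sd_accuracy[i])))
  if (!is.null(x$selection_delta))
    cat(sprintf("  selection delta (normalize=%s): %+.1f percentage points\n",
                x$selection_delta$normalize, x$selection_delta$delta))
  invisible(x)
}

#' @export
summary.cad_report <- function(object, ...) {
  print(object)
  if (!is.null(object$normalization_table)) {
    cat("normalization comparison:\n")
    print(object$normalization_table)
  }
  invisible(object)
}
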