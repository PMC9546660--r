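# Binary particle swarm optimization for wrapper feature selection.
#
# Each particle carries a binary position (a feature mask) and a real-valued
# velocity. Velocities follow the canonical PSO update — inertia plus
# cognitive attraction to the particle's personal best and social attraction
# to the swarm's global best — and positions are resampled through a sigmoid
# transfer of the velocity: coordinate d becomes 1 with probability
# S(v_d) = 1 / (1 + exp(-v_d)). The fitness is the error rate of a
# k-nearest-neighbour classifier on the masked feature columns (lower is
# better), so the swarm searches mask space for subsets that classify well.

#' BPSO configuration
#'
#' Hyperparameters of the binary particle swarm search and its kNN
#' error-rate fitness. The inertia weight decays linearly from `w_start` to
#' `w_end` over the iterations (favouring exploration early, exploitation
#' late); velocities are clamped to `[-v_max, v_max]` so the sigmoid never
#' saturates to a frozen position.
#'
#' @param swarm_size number of particles (>= 2).
#' @param max_iter number of iterations T (>= 1).
#' @param w_start,w_end inertia weight schedule endpoints.
#' @param c1,c2 cognitive and social acceleration coefficients.
#' @param v_max componentwise velocity clamp (> 0).
#' @param knn_k neighbours for the fitness classifier (>= 1).
#' @param holdout_fraction fraction of the data held out (stratified) for
#'   the internal fitness estimate; fixed once per run so the fitness is
#'   deterministic within a run.
#' @param seed integer seed for the run's RNG stream.
#' @return list of class `bpso_config`.
#' @export
bpso_config <- function(swarm_size = 20L, max_iter = 100L,
                        w_start = 0.9, w_end = 0.4,
                        c1 = 2.0, c2 = 2.0, v_max = 6.0,
                        knn_k = 5L, holdout_fraction = 0.2, seed = 0L) {
  cfg <- list(swarm_size = as.integer(swarm_size),
              max_iter = as.integer(max_iter),
              w_start = w_start, w_end = w_end, c1 = c1, c2 = c2,
              v_max = v_max, knn_k = as.integer(knn_k),
              holdout_fraction = holdout_fraction, seed = as.integer(seed))
  if (cfg$swarm_size < 2L) stop("swarm_size must be >= 2", call. = FALSE)
  if (cfg$max_iter < 1L) stop("max_iter must be >= 1", call. = FALSE)
  if (cfg$v_max <= 0) stop("v_max must be > 0", call. = FALSE)
  if (cfg$knn_k < 1L) stop("knn_k must be >= 1", call. = FALSE)
  if (cfg$holdout_fraction <= 0 || cfg$holdout_fraction >= 1)
    stop("holdout_fraction must be in (0, 1)", call. = FALSE)
  structure(cfg, class = "bpso_config")
}

#' Sigmoid transfer function
#'
#' Logistic map `S(v) = 1 / (1 + exp(-v))` turning a real velocity into the
#' probability that the corresponding position bit is set.
#'
#' @param v numeric vector of velocities.
#' @return values in (0, 1).
#' @export
sigmoid_transfer <- function(v) 1 / (1 + exp(-v))

#' Initialize a swarm
#'
#' Positions are independent fair coin flips; velocities are uniform in
#' `[-v_max, v_max]`; each particle's personal best starts at its initial
#' position. All-zero positions are repaired by setting one random
#' coordinate (the fitness is undefined on an empty mask). Draws come from
#' the current RNG stream; [bpso_select()] seeds it.
#'
#' @param D number of features (>= 1).
#' @param cfg a [bpso_config()].
#' @return list of particles, each with `position`, `velocity`,
#'   `pbest_position`, `pbest_fitness` (`NA` until evaluated).
#' @export
init_swarm <- function(D, cfg) {
  if (!is.numeric(D) || D < 1L) stop("D must be >= 1", call. = FALSE)
  D <- as.integer(D)
  lapply(seq_len(cfg$swarm_size), function(i) {
    pos <- repair_empty_mask(as.integer(stats::runif(D) < 0.5))
    list(position = pos,
         velocity = stats::runif(D, -cfg$v_max, cfg$v_max),
         pbest_position = pos,
         pbest_fitness = NA_real_)
  })
}

#' Set one random coordinate of an all-zero mask
#'
#' The kNN fitness is undefined on an empty feature set, so an all-zero
#' position is repaired by switching on a single uniformly chosen bit.
#' Non-empty masks pass through unchanged.
#'
#' @param mask binary integer vector.
#' @return binary vector with at least one 1.
#' @export
repair_empty_mask <- function(mask) {
  if (any(mask == 1L)) return(mask)
  mask[sample.int(length(mask), 1L)] <- 1L
  mask
}

#' Velocity update
#'
#' `v' = w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)`, with `r1`, `r2`
#' fresh uniform(0,1) draws per coordinate, then componentwise clamping to
#' `[-v_max, v_max]`.
#'
#' @param p particle (see [init_swarm()]).
#' @param gbest binary global-best position.
#' @param cfg a [bpso_config()].
#' @param w inertia weight for this iteration (defaults to `cfg$w_start`).
#' @param r1,r2 optional uniform draws (length D), exposed so the update
#'   can be replayed; fresh draws by default.
#' @return clamped velocity vector.
#' @export
update_velocity <- function(p, gbest, cfg, w = cfg$w_start,
                            r1 = stats::runif(length(p$position)),
                            r2 = stats::runif(length(p$position))) {
  D <- length(p$position)
  if (length(gbest) != D || length(p$velocity) != D)
    stop("dimension mismatch in velocity update", call. = FALSE)
  v <- w * p$velocity +
    cfg$c1 * r1 * (p$pbest_position - p$position) +
    cfg$c2 * r2 * (gbest - p$position)
  pmin(pmax(v, -cfg$v_max), cfg$v_max)
}

#' Position update by sigmoid sampling
#'
#' Each coordinate is set to 1 with probability `S(v_d)` using a fresh
#' uniform draw, else 0 — positions are resampled from the velocity, not
#' flipped from the current value. An all-zero outcome is repaired via
#' [repair_empty_mask()] unless `repair = FALSE`.
#'
#' @param p particle whose `velocity` was updated this iteration.
#' @param repair apply the empty-mask repair rule.
#' @return binary position vector.
#' @export
update_position <- function(p, repair = TRUE) {
  pos <- as.integer(stats::runif(length(p$velocity)) <
                      sigmoid_transfer(p$velocity))
  if (repair) pos <- repair_empty_mask(pos)
  pos
}

#' kNN error-rate fitness of a feature mask
#'
#' Misclassification rate of a k-nearest-neighbour classifier (Euclidean
#' metric, `k = cfg$knn_k`) restricted to the masked feature columns,
#' estimated on a fixed stratified internal holdout. Lower is better; 0
#' means the holdout is classified perfectly with the selected features.
#'
#' @param mask binary vector selecting >= 1 column of `data$x`.
#' @param data a [feature_dataset()].
#' @param cfg a [bpso_config()].
#' @param holdout list with integer `train` and `val` row indices; by
#'   default a stratified split at `1 - holdout_fraction` drawn from the
#'   current RNG stream.
#' @return error rate in \[0, 1\].
#' @export
knn_fitness <- function(mask, data, cfg,
                        holdout = stratified_holdout(
                          data$labels, 1 - cfg$holdout_fraction)) {
  keep <- which(mask == 1L)
  if (!length(keep)) stop("empty mask has undefined fitness", call. = FALSE)
  xtr <- data$x[holdout$train, keep, drop = FALSE]
  xva <- data$x[holdout$val, keep, drop = FALSE]
  k <- min(cfg$knn_k, nrow(xtr))
  pred <- class::knn(xtr, xva, cl = factor(data$labels[holdout$train]), k = k)
  mean(pred != factor(data$labels[holdout$val]))
}

#' Personal- and global-best bookkeeping
#'
#' A particle's personal best is replaced only on strict improvement
#' (`F(x) < F(pbest)`); the global best likewise. Ties keep the incumbent.
#'
#' @param swarm list of particles with current `position`.
#' @param fitnesses fitness of each particle's current position.
#' @param gbest list with `position` and `fitness` of the incumbent global
#'   best.
#' @return list with updated `swarm` and `gbest`.
#' @export
update_pbest_gbest <- function(swarm, fitnesses, gbest) {
  for (i in seq_along(swarm)) {
    if (is.na(swarm[[i]]$pbest_fitness) ||
        fitnesses[i] < swarm[[i]]$pbest_fitness) {
      swarm[[i]]$pbest_fitness <- fitnesses[i]
      swarm[[i]]$pbest_position <- swarm[[i]]$position
    }
    if (swarm[[i]]$pbest_fitness < gbest$fitness) {
      gbest$fitness <- swarm[[i]]$pbest_fitness
      gbest$position <- swarm[[i]]$pbest_position
    }
  }
  list(swarm = swarm, gbest = gbest)
}

#' BPSO feature selection
#'
#' Runs the full binary particle swarm search: seeded initialization, then
#' `max_iter` rounds of velocity update (with linearly decaying inertia),
#' sigmoid position resampling, kNN fitness evaluation on a fixed internal
#' holdout, and strict personal-/global-best bookkeeping. Returns the best
#' mask found and the best-so-far fitness trace. Fitness values are
#' memoized within the run (the fitness is deterministic given the fixed
#' holdout, so caching changes no result).
#'
#' @param data a [feature_dataset()] with both classes present.
#' @param cfg a [bpso_config()].
#' @return object of class `bpso_selection`: `mask` (binary vector),
#'   `selected` (column indices), `fitness` (gbest error rate),
#'   `history` (best-so-far per iteration, element 1 = after
#'   initialization), `n_selected`, `n_evaluations`, `holdout` (the fixed
#'   internal train/validation indices, so the fitness of any mask can be
#'   re-evaluated exactly), `config`.
#' @export
bpso_select <- function(data, cfg = bpso_config()) {
  stopifnot(inherits(data, "feature_dataset"))
  if (length(unique(data$labels)) < 2L)
    stop("both classes must be present for wrapper selection", call. = FALSE)
  D <- ncol(data$x)
  with_seed(cfg$seed, {
    holdout <- stratified_holdout(data$labels, 1 - cfg$holdout_fraction)
    cache <- new.env(parent = emptyenv())
    n_eval <- 0L
    fit <- function(mask) {
      key <- paste(mask, collapse = "")
      if (!is.null(cache[[key]])) return(cache[[key]])
      n_eval <<- n_eval + 1L
      cache[[key]] <- knn_fitness(mask, data, cfg, holdout)
    }
    swarm <- init_swarm(D, cfg)
    f0 <- vapply(swarm, function(p) fit(p$position), numeric(1))
    gbest <- list(position = NULL, fitness = Inf)
    st <- update_pbest_gbest(swarm, f0, gbest)
    swarm <- st$swarm; gbest <- st$gbest
    history <- numeric(cfg$max_iter + 1L)
    history[1L] <- gbest$fitness
    for (t in seq_len(cfg$max_iter)) {
      w_t <- if (cfg$max_iter == 1L) cfg$w_start else
        cfg$w_start - (cfg$w_start - cfg$w_end) * (t - 1) / (cfg$max_iter - 1)
      for (i in seq_along(swarm)) {
        swarm[[i]]$velocity <- update_velocity(swarm[[i]], gbest$position,
                                               cfg, w = w_t)
        swarm[[i]]$position <- update_position(swarm[[i]])
      }
      ft <- vapply(swarm, function(p) fit(p$position), numeric(1))
      st <- update_pbest_gbest(swarm, ft, gbest)
      swarm <- st$swarm; gbest <- st$gbest
      history[t + 1L] <- gbest$fitness
    }
    structure(list(mask = gbest$position,
                   selected = which(gbest$position == 1L),
                   fitness = gbest$fitness,
                   history = history,
                   n_selected = sum(gbest$position),
                   n_evaluations = n_eval,
                   holdout = holdout,
                   config = cfg),
              class = "bpso_selection")
  })
}

#' Multi-seed BPSO batch
#'
#' Runs [bpso_select()] once per seed and collects the per-run best-so-far
#' histories plus their mean curve (the convention used for reporting
#' convergence averaged over independent runs).
#'
#' @param data a [feature_dataset()].
#' @param cfg a [bpso_config()]; its `seed` field is overridden per run.
#' @param seeds integer vector of run seeds.
#' @return list with `runs` (list of `bpso_selection`), `history` (matrix,
#'   one column per run), `mean_history`, `selection_frequency` (per-feature
#'   fraction of runs selecting it), `majority_mask`.
#' @export
bpso_select_runs <- function(data, cfg = bpso_config(), seeds = 0:19) {
  runs <- lapply(seeds, function(s) {
    cfg$seed <- as.integer(s)
    bpso_select(data, cfg)
  })
  hist <- vapply(runs, `[[`, numeric(cfg$max_iter + 1L), "history")
  freq <- rowMeans(vapply(runs, `[[`, numeric(ncol(data$x)), "mask"))
  list(runs = runs, history = hist, mean_history = rowMeans(hist),
       selection_frequency = freq,
       majority_mask = as.integer(freq > 0.5))
}

#' @export
print.bpso_selection <- function(x, ...) {
  cat("BPSO feature selection\n")
  cat(sprintf("  selected %d / %d features; gbest kNN error %.4f\n",
              x$n_selected, length(x$mask), x$fitness))
  cat(sprintf("  %d iterations, %d distinct fitness evaluations\n",
              length(x$history) - 1L, x$n_evaluations))
  invisible(x)
}

#' @export
summary.bpso_selection <- function(object, ...) {
  cat("BPSO feature selection (swarm ", object$config$swarm_size,
      ", T ", object$config$max_iter, ", k ", object$config$knn_k,
      ", seed ", object$config$seed, ")\n", sep = "")
  cat("  gbest error rate:", format(object$fitness, digits = 4), "\n")
  cat("  selected columns:", paste(object$selected, collapse = " "), "\n")
  cat("  best-so-far trace:",
      paste(format(object$history[unique(round(seq(1, length(object$history),
                                                   length.out = 6)))],
                   digits = 3), collapse = " -> "), "\n")
  invisible(object)
}

#' Plot the best-so-far convergence curve
#'
#' @param x a `bpso_selection`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bpso_selection <- function(x, ...) {
  graphics::plot(seq_along(x$history) - 1L, x$history, type = "s",
                 xlab = "iteration", ylab = "best-so-far kNN error rate",
                 main = "BPSO convergence", ...)
  invisible(x)
}
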