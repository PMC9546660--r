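# Feature extraction through a pluggable backbone contract.
#
# A backbone is any object with fields name, input_size (h, w), feature_dim
# and an extract function mapping one RGB array (already resized to
# input_size) to a fixed-length finite numeric vector. Real pretrained
# convolutional networks satisfy the contract through a thin wrapper; the
# deterministic stub backbone below satisfies it without any weights, so
# the whole pipeline is testable offline.

# Input geometries of the four standard architectures.
.BACKBONE_GEOMETRY <- list(
  vgg16       = list(input_size = c(224L, 224L), feature_dim = 4096L),
  alexnet     = list(input_size = c(227L, 227L), feature_dim = 4096L),
  resnet50    = list(input_size = c(224L, 224L), feature_dim = 2048L),
  inceptionv3 = list(input_size = c(299L, 299L), feature_dim = 2048L)
)

#' Backbone geometry specification
#'
#' Returns the input geometry and nominal feature width for one of the four
#' standard architectures (`vgg16`, `alexnet`, `resnet50`, `inceptionv3`),
#' or a custom spec for arbitrary name/size/dimension. `feature_dim` for the
#' named architectures is the penultimate (pre-classification) layer width,
#' flattened and global-average-pooled where applicable.
#'
#' @param name backbone identifier.
#' @param input_size optional `(height, width)` override.
#' @param feature_dim optional feature-length override.
#' @return list of class `backbone_spec` with `name`, `input_size`,
#'   `feature_dim`.
#' @export
backbone_spec <- function(name, input_size = NULL, feature_dim = NULL) {
  geom <- .BACKBONE_GEOMETRY[[tolower(name)]]
  if (is.null(geom) && (is.null(input_size) || is.null(feature_dim)))
    stop("unknown backbone '", name,
         "'; give input_size and feature_dim explicitly", call. = FALSE)
  spec <- list(
    name = tolower(name),
    input_size = as.integer(if (is.null(input_size)) geom$input_size else input_size),
    feature_dim = as.integer(if (is.null(feature_dim)) geom$feature_dim else feature_dim)
  )
  if (length(spec$input_size) != 2L || any(spec$input_size < 1L))
    stop("input_size must be two positive integers", call. = FALSE)
  if (spec$feature_dim < 1L) stop("feature_dim must be >= 1", call. = FALSE)
  structure(spec, class = "backbone_spec")
}

#' Resize an image to a backbone's input geometry
#'
#' Bilinear resize to exactly `spec$input_size`; the aspect ratio is not
#' preserved, matching the usual practice of stretching patches to the
#' network's fixed input resolution.
#'
#' @param img H x W x 3 RGB array.
#' @param spec a [backbone_spec()].
#' @return RGB array of dimension `input_size[1]` x `input_size[2]` x 3.
#' @export
resize_for_backbone <- function(img, spec) {
  validate_rgb_image(img)
  h <- spec$input_size[1]; w <- spec$input_size[2]
  if (all(dim(img)[1:2] == c(h, w))) return(img)
  out <- from_ebimage(EBImage::resize(as_ebimage(img), w = w, h = h,
                                      filter = "bilinear"))
  pmin(pmax(out, 0), 255)
}

#' Deterministic stub backbone
#'
#' A backbone-contract extractor that needs no pretrained weights: it
#' computes fixed image statistics (per-channel 16-bin intensity histograms
#' and 4 x 4 block means, 96 numbers in all) and projects them through a
#' seeded random Gaussian matrix to `feature_dim` outputs. The statistics
#' respond to both colour distribution and coarse spatial structure, so
#' visually distinct classes remain separable in stub-feature space, and
#' the projection is frozen at construction, so extraction is fully
#' deterministic.
#'
#' @param spec a [backbone_spec()]; only `feature_dim` and `input_size`
#'   are used. Defaults to a 64-dimensional stub at 64 x 64 input.
#' @param seed integer seed for the projection matrix.
#' @return a list of class `backbone` with `name`, `input_size`,
#'   `feature_dim` and `extract(img)`.
#' @export
stub_backbone <- function(spec = backbone_spec("stub", c(64L, 64L), 64L),
                          seed = 0L) {
  n_stats <- 96L
  proj <- with_seed(seed,
    matrix(stats::rnorm(spec$feature_dim * n_stats, 0, 1 / sqrt(n_stats)),
           nrow = spec$feature_dim))
  extract <- function(img) {
    validate_rgb_image(img)
    px <- matrix(img, ncol = 3L) / 255
    hists <- vapply(1:3, function(ch) {
      idx <- findInterval(px[, ch], seq(0, 1, length.out = 17L),
                          rightmost.closed = TRUE, all.inside = TRUE)
      tabulate(idx, nbins = 16L) / nrow(px)
    }, numeric(16L))
    blocks <- vapply(1:3, function(ch) {
      m <- img[, , ch] / 255
      ri <- ceiling(4 * seq_len(nrow(m)) / nrow(m))
      ci <- ceiling(4 * seq_len(ncol(m)) / ncol(m))
      as.vector(tapply(m, list(ri[row(m)], ci[col(m)]), mean))
    }, numeric(16L))
    as.numeric(proj %*% c(hists, blocks))
  }
  structure(list(name = paste0("stub", seed), input_size = spec$input_size,
                 feature_dim = spec$feature_dim, extract = extract),
            class = "backbone")
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `expr`, and restores the caller's RNG state,
#' so seeded components do not perturb each other's streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  expr
}

#' Extract a feature dataset from a list of images
#'
#' Applies the backbone's extractor to each image; row i of the matrix is
#' the feature vector of image i. All vectors must have the backbone's
#' advertised length and be finite, otherwise a contract violation is
#' raised.
#'
#' @param images list of RGB arrays, each already resized to
#'   `backbone$input_size` (checked).
#' @param backbone a backbone-contract object (for example
#'   [stub_backbone()]).
#' @param labels binary labels (0 = NEOR, 1 = OSCC), one per image.
#' @param sample_ids optional identifiers; defaults to `img_1 ...`.
#' @return a [feature_dataset()].
#' @export
extract_features <- function(images, backbone, labels,
                             sample_ids = NULL) {
  if (!length(images)) stop("no images", call. = FALSE)
  rows <- lapply(images, function(img) {
    if (!all(dim(img)[1:2] == backbone$input_size))
      stop("image not resized to backbone input size ",
           paste(backbone$input_size, collapse = "x"), call. = FALSE)
    v <- backbone$extract(img)
    if (length(v) != backbone$feature_dim || any(!is.finite(v)))
      stop("backbone contract violation: expected ", backbone$feature_dim,
           " finite values, got ", length(v), call. = FALSE)
    v
  })
  x <- do.call(rbind, rows)
  colnames(x) <- paste0("f", seq_len(ncol(x)) - 1L)
  feature_dataset(x, labels, sample_ids = sample_ids)
}

#' Feature dataset container
#'
#' An n_samples x n_features numeric matrix with binary labels
#' (0 = NEOR, 1 = OSCC) and sample identifiers.
#'
#' @param x numeric matrix, one row per sample.
#' @param labels vector of 0/1 labels, length `nrow(x)`.
#' @param sample_ids optional identifiers.
#' @param informative optional integer indices of planted informative
#'   columns (synthetic fixtures record them here).
#' @return list of class `feature_dataset` with `x`, `labels`,
#'   `sample_ids`, `informative`.
#' @export
feature_dataset <- function(x, labels, sample_ids = NULL, informative = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("feature matrix must be numeric and finite", call. = FALSE)
  labels <- as.integer(labels)
  if (length(labels) != nrow(x))
    stop("row count (", nrow(x), ") != label count (", length(labels), ")",
         call. = FALSE)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be binary 0/1", call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- paste0("img_", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)) - 1L)
  structure(list(x = x, labels = labels, sample_ids = as.character(sample_ids),
                 informative = informative),
            class = "feature_dataset")
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat("feature_dataset:", nrow(x$x), "samples x", ncol(x$x), "features;",
      sum(x$labels == 0L), "NEOR /", sum(x$labels == 1L), "OSCC\n")
  if (!is.null(x$informative))
    cat("  planted informative columns:",
        paste(x$informative, collapse = ", "), "\n")
  invisible(x)
}

#' Subset rows (and optionally columns) of a feature dataset
#'
#' @param d a [feature_dataset()].
#' @param i row indices.
#' @param j optional column indices (all columns if missing).
#' @return a [feature_dataset()] (planted-index metadata is dropped, since
#'   column indices change meaning under subsetting).
#' @export
`[.feature_dataset` <- function(d, i, j) {
  if (missing(j)) j <- seq_len(ncol(d$x))
  feature_dataset(d$x[i, j, drop = FALSE], d$labels[i], d$sample_ids[i])
}

#' Standardize feature columns using training statistics
#'
#' Centres and scales every column to zero mean and unit variance using the
#' statistics of `train`; the same affine map is applied to `test`. Columns
#' with zero training variance are centred only. The wrapper selection's
#' kNN fitness is scale-sensitive, so this precedes selection and
#' classification.
#'
#' @param train training [feature_dataset()].
#' @param test optional second dataset mapped with the training statistics.
#' @return the standardized `train`, or `list(train=, test=)` when `test`
#'   is given.
#' @export
standardize_features <- function(train, test = NULL) {
  m <- colMeans(train$x)
  s <- apply(train$x, 2L, stats::sd)
  s[!is.finite(s) | s == 0] <- 1
  tr <- feature_dataset(scale(train$x, center = m, scale = s),
                        train$labels, train$sample_ids, train$informative)
  if (is.null(test)) return(tr)
  te <- feature_dataset(scale(test$x, center = m, scale = s),
                        test$labels, test$sample_ids, test$informative)
  list(train = tr, test = te)
}

#' Write a feature dataset as delimited text
#'
#' CSV dialect: header `sample_id,label,f0,...,fD`.
#'
#' @param data a [feature_dataset()].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(data, path) {
  d <- data.frame(sample_id = data$sample_ids, label = data$labels,
                  data$x, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature dataset written by [write_features()]
#'
#' @param path CSV path with columns `sample_id`, `label`, then features.
#' @return a [feature_dataset()].
#' @export
read_features <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("sample_id", "label") %in% names(d)))
    stop("feature file must have sample_id and label columns", call. = FALSE)
  x <- as.matrix(d[, setdiff(names(d), c("sample_id", "label")), drop = FALSE])
  feature_dataset(x, d$label, sample_ids = d$sample_id)
}
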