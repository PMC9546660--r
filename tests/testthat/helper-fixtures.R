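# Shared fixtures, generated in code.

# Small random RGB image with integer intensities.
random_rgb <- function(h = 16, w = 16, seed = 1) {
  with_seed(seed, array(sample(0:255, h * w * 3, replace = TRUE),
                        dim = c(h, w, 3)))
}

# Constant-colour image.
flat_rgb <- function(rgb, h = 8, w = 8) {
  array(rep(rgb, each = h * w), dim = c(h, w, 3))
}

# Independent transcription of the Reinhard forward chain for a single
# constant-gray pixel, used as the oracle for hand-derived values. Kept as
# explicit scalar arithmetic, separate from the package's vectorised path.
oracle_gray_lab <- function(g) {
  r <- g / 255
  L <- 0.3811 * r + 0.5783 * r + 0.0402 * r
  M <- 0.1967 * r + 0.7244 * r + 0.0782 * r
  S <- 0.0241 * r + 0.1288 * r + 0.8444 * r
  lg <- log10(c(L, M, S) + 1 / 255)
  c(l = (lg[1] + lg[2] + lg[3]) / sqrt(3),
    alpha = (lg[1] + lg[2] - 2 * lg[3]) / sqrt(6),
    beta = (lg[1] - lg[2]) / sqrt(2))
}

# Tiny separable feature dataset: one informative column, rest noise.
tiny_separable <- function(n = 24, noise_cols = 3, seed = 5) {
  with_seed(seed, {
    labels <- rep(c(0L, 1L), each = n / 2)
    x <- cbind(stats::rnorm(n, mean = 6 * labels, sd = 0.5),
               matrix(stats::rnorm(n * noise_cols), n, noise_cols))
    feature_dataset(x, labels, informative = 1L)
  })
}

# Simple stratified index split, written independently of the package's
# splitting code (draws from the current RNG stream).
stratified_split_for_tests <- function(labels, train_fraction) {
  train <- integer(0)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    train <- c(train, sample(idx, floor(train_fraction * length(idx))))
  }
  list(train = sort(train), val = setdiff(seq_along(labels), train))
}

# Exhaustive minimum of the kNN fitness over all non-empty masks of D
# features, evaluated on the same fixed holdout.
exhaustive_best_fitness <- function(data, cfg, holdout) {
  D <- ncol(data$x)
  best <- Inf
  for (code in seq_len(2^D - 1)) {
    mask <- as.integer(intToBits(code)[1:D])
    f <- knn_fitness(mask, data, cfg, holdout)
    if (f < best) best <- f
  }
  best
}
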