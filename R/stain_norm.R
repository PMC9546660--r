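# Reinhard colour-transfer stain normalization.
#
# The transfer works in the decorrelated l-alpha-beta colour space: RGB is
# mapped to LMS cone responses by a fixed 3x3 matrix, compressed with a
# base-10 logarithm, and rotated into (l, alpha, beta) by a fixed orthogonal
# transform. Channel statistics are then transferred independently: the
# source image's per-channel mean/std are replaced by the template's. The
# logarithmic compression makes channel distributions roughly symmetric and
# the rotation decorrelates them, which is what makes the channel-wise
# transfer legitimate.

# Fixed transform chain (Reinhard et al. colour-transfer matrices).
.RGB2LMS <- matrix(c(
  0.3811, 0.5783, 0.0402,
  0.1967, 0.7244, 0.0782,
  0.0241, 0.1288, 0.8444), nrow = 3, byrow = TRUE)

.LMS2RGB <- matrix(c(
   4.4679, -3.5873,  0.1193,
  -1.2186,  2.3809, -0.1624,
   0.0497, -0.2439,  1.2045), nrow = 3, byrow = TRUE)

.LMS2LAB <- diag(c(1 / sqrt(3), 1 / sqrt(6), 1 / sqrt(2))) %*%
  matrix(c(1, 1, 1, 1, 1, -2, 1, -1, 0), nrow = 3, byrow = TRUE)

.LAB2LMS <- matrix(c(1, 1, 1, 1, 1, -1, 1, -2, 0), nrow = 3, byrow = TRUE) %*%
  diag(c(sqrt(3) / 3, sqrt(6) / 6, sqrt(2) / 2))

# Offset added to LMS values (RGB scaled to [0,1]) before the log, so that
# black pixels have a finite image; subtracted again in the inverse.
.LOG_EPS <- 1 / 255

# n x 3 pixel matrix from H x W x 3 array and back.
.flatten <- function(img) matrix(img, ncol = 3L)
.unflatten <- function(px, d) array(px, dim = d)

#' Convert an RGB image to the l-alpha-beta colour space
#'
#' Applies the fixed RGB-to-LMS matrix, a base-10 logarithm (after an offset
#' of 1/255 so zero intensities stay finite), and the orthogonal
#' l-alpha-beta rotation. The l channel carries luminance; alpha and beta
#' carry yellow-blue and red-green opponents, so achromatic pixels map to
#' alpha = beta = 0 up to the small chromatic bias of the LMS matrix.
#'
#' @param img H x W x 3 numeric array, intensities in \[0, 255\].
#' @return H x W x 3 numeric array of finite l-alpha-beta values.
#' @seealso [lab_to_rgb()], [reinhard_normalize()]
#' @export
rgb_to_lab <- function(img) {
  validate_rgb_image(img)
  lms <- .flatten(img / 255) %*% t(.RGB2LMS)
  lab <- log10(lms + .LOG_EPS) %*% t(.LMS2LAB)
  .unflatten(lab, dim(img))
}

#' Convert an l-alpha-beta image back to RGB
#'
#' Exact inverse of [rgb_to_lab()] up to the final clipping to \[0, 255\]
#' and rounding to integer intensity levels.
#'
#' @param lab H x W x 3 numeric array of finite l-alpha-beta values.
#' @return H x W x 3 array of integers in \[0, 255\].
#' @export
lab_to_rgb <- function(lab) {
  if (!is.array(lab) || length(dim(lab)) != 3L || dim(lab)[3] != 3L)
    stop("lab must be an H x W x 3 array", call. = FALSE)
  if (anyNA(lab) || any(!is.finite(lab)))
    stop("lab contains non-finite values", call. = FALSE)
  lms <- 10^(.flatten(lab) %*% t(.LAB2LMS)) - .LOG_EPS
  rgb <- lms %*% t(.LMS2RGB) * 255
  .unflatten(round(pmin(pmax(rgb, 0), 255)), dim(lab))
}

#' Global per-channel mean and standard deviation
#'
#' Computes the per-channel mean and population standard deviation (divide
#' by N) over all pixels of one image. These are the global statistics that
#' the Reinhard transfer matches between source and template.
#'
#' @param img H x W x 3 numeric array (any colour space).
#' @return list with `mean` and `std`, each a named 3-vector.
#' @export
channel_stats <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("img must be an H x W x 3 array", call. = FALSE)
  if (prod(dim(img)[1:2]) < 1L) stop("img is empty", call. = FALSE)
  px <- .flatten(img)
  m <- colMeans(px)
  s <- sqrt(colMeans(px^2) - m^2)
  s[s < 0] <- 0  # guard tiny negative from float cancellation
  ch <- c("l", "alpha", "beta")
  list(mean = stats::setNames(m, ch), std = stats::setNames(s, ch))
}

#' Reinhard stain normalization against a template image
#'
#' Maps the colour distribution of `source` onto that of `target`: both are
#' converted to l-alpha-beta space, each source channel is recentred and
#' rescaled so its global mean and standard deviation equal the template's
#' (`out = mu_t + (in - mu_s) * sd_t / sd_s`), and the result is converted
#' back to RGB with clipping. Structure (relative intensity variation) is
#' preserved; the colour palette is exchanged for the template's.
#'
#' @param source H x W x 3 RGB array to normalize.
#' @param target template RGB array whose stain appearance is adopted.
#' @param details if `TRUE`, also return the transferred l-alpha-beta array
#'   (before conversion/clipping) and the channel statistics involved.
#' @return the normalized RGB array, or, with `details = TRUE`, a list with
#'   elements `rgb`, `lab`, `source_stats`, `target_stats`.
#' @export
reinhard_normalize <- function(source, target, details = FALSE) {
  validate_rgb_image(source, "source")
  validate_rgb_image(target, "target")
  src <- rgb_to_lab(source)
  tgt <- rgb_to_lab(target)
  ss <- channel_stats(src)
  ts <- channel_stats(tgt)
  if (any(ss$std <= 0))
    stop("degenerate source: zero variance in l-alpha-beta channel(s) ",
         paste(names(ss$std)[ss$std <= 0], collapse = ", "),
         "; scaling is undefined", call. = FALSE)
  px <- sweep(.flatten(src), 2L, ss$mean, "-")
  px <- sweep(px, 2L, ts$std / ss$std, "*")
  px <- sweep(px, 2L, ts$mean, "+")
  lab <- .unflatten(px, dim(source))
  out <- lab_to_rgb(lab)
  if (!details) return(out)
  list(rgb = out, lab = lab, source_stats = ss, target_stats = ts)
}

#' Per-channel probability density diagnostics
#'
#' Normalized per-channel histograms of an RGB image over \[0, 255\], used
#' to compare colour distributions before and after stain normalization.
#' Densities integrate to 1 over the intensity range.
#'
#' @param img H x W x 3 RGB array.
#' @param n_bins number of equal-width bins (>= 2).
#' @return list with `bin_edges` (length `n_bins + 1`) and `density`, an
#'   `n_bins` x 3 matrix with columns R, G, B.
#' @export
channel_pdf <- function(img, n_bins = 32L) {
  validate_rgb_image(img)
  if (!is.numeric(n_bins) || length(n_bins) != 1L || n_bins < 2)
    stop("n_bins must be a single integer >= 2", call. = FALSE)
  n_bins <- as.integer(n_bins)
  edges <- seq(0, 255, length.out = n_bins + 1L)
  width <- 255 / n_bins
  px <- .flatten(img)
  dens <- vapply(1:3, function(ch) {
    idx <- findInterval(px[, ch], edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    tabulate(idx, nbins = n_bins) / (nrow(px) * width)
  }, numeric(n_bins))
  colnames(dens) <- c("R", "G", "B")
  list(bin_edges = edges, density = dens)
}

#' Write channel PDFs as a delimited table
#'
#' One row per bin: left bin edge and the three channel densities.
#'
#' @param pdf result of [channel_pdf()].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_channel_pdf <- function(pdf, path) {
  d <- data.frame(bin_edge = pdf$bin_edges[-length(pdf$bin_edges)],
                  density_R = pdf$density[, "R"],
                  density_G = pdf$density[, "G"],
                  density_B = pdf$density[, "B"])
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
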