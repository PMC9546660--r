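# Synthetic fixtures: stained-tissue-like images and feature matrices with
# planted structure. Every pipeline stage is testable against these without
# any external download. The images emulate the two features of H&E
# histopathology that the pipeline exercises: a class-dependent density of
# dark "nuclei" blobs on an eosin-toned background (the classification
# signal) and a per-image global colour cast (the lab-to-lab staining
# variation that stain normalization is meant to remove).

#' Specification for synthetic stained-tissue images
#'
#' Defaults approximate an H&E appearance: pink cytoplasm-like background
#' and purple nuclei. The carcinoma-like class (label 1) has denser,
#' larger nuclei — a crude but detectable analogue of the hypercellularity
#' that separates carcinoma from normal epithelium. `color_jitter` adds a
#' per-image global channel shift (uniform in `[-jitter, +jitter]` per
#' channel) plus a brightness scale, simulating staining variation across
#' labs; set it to 0 for colour-stable images.
#'
#' @param n_per_class images per class.
#' @param image_size `(H, W)` in pixels.
#' @param class0_palette,class1_palette list with `background` and
#'   `nucleus` RGB triplets in \[0, 255\].
#' @param nuclei_range0,nuclei_range1 integer `(min, max)` nuclei counts
#'   per class.
#' @param nucleus_radius0,nucleus_radius1 mean blob radius (pixels).
#' @param color_jitter per-image channel shift magnitude (intensity
#'   levels).
#' @param seed integer seed.
#' @return list of class `image_fixture_spec`.
#' @export
image_fixture_spec <- function(n_per_class = 20L, image_size = c(64L, 64L),
                               class0_palette = list(
                                 background = c(235, 170, 205),
                                 nucleus = c(110, 70, 160)),
                               class1_palette = list(
                                 background = c(225, 150, 190),
                                 nucleus = c(80, 45, 130)),
                               nuclei_range0 = c(4L, 8L),
                               nuclei_range1 = c(18L, 28L),
                               nucleus_radius0 = 3.0,
                               nucleus_radius1 = 4.5,
                               color_jitter = 25,
                               seed = 0L) {
  spec <- list(n_per_class = as.integer(n_per_class),
               image_size = as.integer(image_size),
               class0_palette = class0_palette,
               class1_palette = class1_palette,
               nuclei_range0 = as.integer(nuclei_range0),
               nuclei_range1 = as.integer(nuclei_range1),
               nucleus_radius0 = nucleus_radius0,
               nucleus_radius1 = nucleus_radius1,
               color_jitter = color_jitter, seed = as.integer(seed))
  if (any(spec$image_size < 8L)) stop("image_size too small", call. = FALSE)
  if (spec$n_per_class < 1L) stop("n_per_class must be >= 1", call. = FALSE)
  if (spec$color_jitter < 0) stop("color_jitter must be >= 0", call. = FALSE)
  structure(spec, class = "image_fixture_spec")
}

# One image: background + Gaussian-profile blobs + jitter + pixel noise.
.render_tissue <- function(h, w, palette, n_nuclei, radius, jitter) {
  img <- array(rep(palette$background, each = h * w), dim = c(h, w, 3L))
  rowg <- matrix(seq_len(h), h, w)
  colg <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (i in seq_len(n_nuclei)) {
    cy <- stats::runif(1, 1, h); cx <- stats::runif(1, 1, w)
    r <- radius * stats::runif(1, 0.7, 1.3)
    # blob opacity falls off as a Gaussian of distance from the centre
    alpha <- exp(-((rowg - cy)^2 + (colg - cx)^2) / (2 * r^2))
    for (ch in 1:3)
      img[, , ch] <- img[, , ch] * (1 - alpha) + palette$nucleus[ch] * alpha
  }
  shift <- stats::runif(3, -jitter, jitter)
  scale <- stats::runif(1, 1 - jitter / 255, 1 + jitter / 255)
  for (ch in 1:3) img[, , ch] <- img[, , ch] * scale + shift[ch]
  img <- img + array(stats::rnorm(h * w * 3, 0, 2), dim = dim(img))
  round(pmin(pmax(img, 0), 255))
}

#' Generate a two-class synthetic image fixture
#'
#' Deterministic given `spec$seed`. Returns the images in memory plus a
#' manifest data frame; [write_image_fixture()] writes them to disk with a
#' `path,label` manifest CSV.
#'
#' @param spec an [image_fixture_spec()].
#' @return list with `images` (list of H x W x 3 arrays), `labels`
#'   (0 = NEOR-like, 1 = OSCC-like) and `manifest` (data frame with
#'   `sample_id`, `label`).
#' @export
make_image_fixture <- function(spec = image_fixture_spec()) {
  stopifnot(inherits(spec, "image_fixture_spec"))
  h <- spec$image_size[1]; w <- spec$image_size[2]
  with_seed(spec$seed, {
    images <- list(); labels <- integer(0)
    for (cl in 0:1) {
      pal <- if (cl == 0L) spec$class0_palette else spec$class1_palette
      nr <- if (cl == 0L) spec$nuclei_range0 else spec$nuclei_range1
      rad <- if (cl == 0L) spec$nucleus_radius0 else spec$nucleus_radius1
      for (i in seq_len(spec$n_per_class)) {
        n_nuc <- sample(seq(nr[1], nr[2]), 1L)
        images[[length(images) + 1L]] <-
          .render_tissue(h, w, pal, n_nuc, rad, spec$color_jitter)
        labels <- c(labels, cl)
      }
    }
    manifest <- data.frame(
      sample_id = sprintf("synth_%s_%03d",
                          ifelse(labels == 0L, "neor", "oscc"),
                          stats::ave(labels, labels, FUN = seq_along)),
      label = labels, stringsAsFactors = FALSE)
    list(images = images, labels = labels, manifest = manifest)
  })
}

#' Write an image fixture to disk
#'
#' PNG files plus a `path,label` manifest CSV, the on-disk dialect the
#' pipeline reads.
#'
#' @param fixture result of [make_image_fixture()].
#' @param dir output directory (created if needed).
#' @return path of the manifest CSV, invisibly.
#' @export
write_image_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(fixture$manifest$sample_id, ".png"))
  for (i in seq_along(fixture$images)) write_image(fixture$images[[i]], paths[i])
  manifest <- data.frame(path = paths, label = fixture$labels)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a `path,label` manifest into images and labels
#'
#' @param manifest_path CSV with columns `path` (image file) and `label`
#'   (0/1). Relative paths are resolved against the manifest's directory.
#' @return list with `images`, `labels`, `manifest`.
#' @export
read_image_manifest <- function(manifest_path) {
  m <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(m)))
    stop("manifest must have path and label columns", call. = FALSE)
  paths <- ifelse(file.exists(m$path), m$path,
                  file.path(dirname(manifest_path), m$path))
  list(images = lapply(paths, read_image), labels = as.integer(m$label),
       manifest = m)
}

#' Specification for synthetic feature matrices with planted signal
#'
#' Informative columns are drawn from class-shifted normal distributions
#' (mean shift = `class_separation * noise_sd` between classes); noise
#' columns are class-independent. The planted column indices are recorded
#' in the resulting dataset so recovery can be scored.
#'
#' @param n_samples total rows (>= 4).
#' @param n_informative planted signal columns (>= 1).
#' @param n_noise pure-noise columns.
#' @param class_separation effect size (class mean difference in units of
#'   `noise_sd`).
#' @param noise_sd standard deviation of every column.
#' @param label_balance fraction of samples in class 1.
#' @param seed integer seed.
#' @return list of class `feature_fixture_spec`.
#' @export
feature_fixture_spec <- function(n_samples = 200L, n_informative = 2L,
                                 n_noise = 50L, class_separation = 3,
                                 noise_sd = 1, label_balance = 0.5,
                                 seed = 0L) {
  spec <- list(n_samples = as.integer(n_samples),
               n_informative = as.integer(n_informative),
               n_noise = as.integer(n_noise),
               class_separation = class_separation, noise_sd = noise_sd,
               label_balance = label_balance, seed = as.integer(seed))
  if (spec$n_samples < 4L) stop("n_samples must be >= 4", call. = FALSE)
  if (spec$n_informative < 1L) stop("n_informative must be >= 1", call. = FALSE)
  if (spec$label_balance <= 0 || spec$label_balance >= 1)
    stop("label_balance must be in (0, 1)", call. = FALSE)
  structure(spec, class = "feature_fixture_spec")
}

#' Generate a synthetic feature dataset with planted informative columns
#'
#' The informative columns occupy the first `n_informative` positions;
#' their indices are recorded in the dataset's `informative` field.
#' Deterministic given `spec$seed`.
#'
#' @param spec a [feature_fixture_spec()].
#' @return a [feature_dataset()] with planted-index metadata.
#' @export
make_feature_fixture <- function(spec = feature_fixture_spec()) {
  stopifnot(inherits(spec, "feature_fixture_spec"))
  with_seed(spec$seed, {
    n1 <- round(spec$n_samples * spec$label_balance)
    labels <- sample(rep(c(0L, 1L), c(spec$n_samples - n1, n1)))
    D <- spec$n_informative + spec$n_noise
    x <- matrix(stats::rnorm(spec$n_samples * D, 0, spec$noise_sd),
                spec$n_samples, D)
    shift <- spec$class_separation * spec$noise_sd
    for (j in seq_len(spec$n_informative))
      x[labels == 1L, j] <- x[labels == 1L, j] + shift
    colnames(x) <- paste0("f", seq_len(D) - 1L)
    feature_dataset(x, labels, informative = seq_len(spec$n_informative))
  })
}
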