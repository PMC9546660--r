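# Reinhard colour transfer: forward/inverse chain, channel statistics,
# mean/std transfer, PDF diagnostics.

test_that("rgb_to_lab rejects malformed input and handles achromatic images", {
  expect_error(rgb_to_lab(matrix(1, 4, 4)), "H x W x 3")
  expect_error(rgb_to_lab(array(0, dim = c(4, 4, 4))), "three channels")
  expect_error(rgb_to_lab(array(300, dim = c(4, 4, 3))), "\\[0, 255\\]")

  # achromatic input carries (almost) no chromatic opponent signal
  lab <- rgb_to_lab(flat_rgb(c(128, 128, 128)))
  expect_lt(max(abs(lab[, , 2:3])), 0.01)
})

test_that("constant-gray images match the scalar oracle and white has maximal l", {
  grays <- c(0, 64, 128, 192, 255)
  l_values <- vapply(grays, function(g) {
    lab <- rgb_to_lab(flat_rgb(c(g, g, g), 2, 2))
    expected <- oracle_gray_lab(g)
    expect_equal(unname(lab[1, 1, ]), unname(expected), tolerance = 1e-12)
    lab[1, 1, 1]
  }, numeric(1))
  expect_identical(which.max(l_values), length(grays))
  expect_true(all(diff(l_values) > 0))  # l increases with gray level
})

test_that("rgb <-> lab round trip is identity within quantization tolerance", {
  for (seed in 1:5) {
    img <- random_rgb(12, 17, seed = seed)
    expect_lte(max(abs(lab_to_rgb(rgb_to_lab(img)) - img)), 2)
  }
})

test_that("lab_to_rgb maps the zero image to one fixed gray and clips extremes", {
  # scalar oracle for the inverse chain at (0,0,0)
  lms <- 10^0 - 1 / 255
  inv <- matrix(c(4.4679, -3.5873, 0.1193,
                  -1.2186, 2.3809, -0.1624,
                  0.0497, -0.2439, 1.2045), 3, 3, byrow = TRUE)
  expected <- round(pmin(pmax(as.numeric(inv %*% rep(lms, 3)) * 255, 0), 255))

  out <- lab_to_rgb(array(0, dim = c(5, 4, 3)))
  for (ch in 1:3) {
    expect_true(all(out[, , ch] == expected[ch]))
  }

  extreme <- array(c(50, -50, 30), dim = c(3, 3, 3))
  out2 <- lab_to_rgb(extreme)
  expect_gte(min(out2), 0)
  expect_lte(max(out2), 255)

  expect_error(lab_to_rgb(array(Inf, dim = c(2, 2, 3))), "non-finite")
})

test_that("channel_stats matches a brute-force two-pass oracle", {
  img <- flat_rgb(c(10, 200, 77))
  st <- channel_stats(img)
  expect_equal(unname(st$mean), c(10, 200, 77))
  expect_equal(unname(st$std), c(0, 0, 0))

  two_px <- array(c(0, 2, 0, 2, 0, 2), dim = c(2, 1, 3))
  st2 <- channel_stats(two_px)
  expect_equal(unname(st2$mean), c(1, 1, 1))
  expect_equal(unname(st2$std), c(1, 1, 1))

  lab <- rgb_to_lab(random_rgb(9, 13, seed = 7))
  st3 <- channel_stats(lab)
  for (ch in 1:3) {
    v <- as.numeric(lab[, , ch])
    m <- sum(v) / length(v)                  # two-pass oracle
    s <- sqrt(sum((v - m)^2) / length(v))
    expect_equal(unname(st3$mean[ch]), m, tolerance = 1e-9)
    expect_equal(unname(st3$std[ch]), s, tolerance = 1e-9)
  }
})

test_that("reinhard_normalize transfers channel statistics onto the target", {
  fx <- make_image_fixture(image_fixture_spec(n_per_class = 2, seed = 11))
  source <- fx$images[[1]]  # pink-toned
  target <- fx$images[[4]]  # denser purple-toned

  res <- reinhard_normalize(source, target, details = TRUE)
  st <- channel_stats(res$lab)
  expect_lt(max(abs(st$mean - res$target_stats$mean) /
                  abs(res$target_stats$mean)), 1e-3)
  expect_lt(max(abs(st$std - res$target_stats$std) /
                  res$target_stats$std), 1e-3)
})

test_that("identity transfer leaves the image essentially unchanged", {
  img <- random_rgb(20, 20, seed = 3)
  expect_lte(max(abs(reinhard_normalize(img, img) - img)), 2)
})

test_that("degenerate sources are refused", {
  flat <- flat_rgb(c(120, 90, 180))
  img <- random_rgb(8, 8, seed = 2)
  expect_error(reinhard_normalize(flat, img), "degenerate source")
  expect_error(reinhard_normalize(img, "nope"), "target")
})

test_that("channel_pdf is a normalized density and matches direct counting", {
  img <- flat_rgb(c(100, 100, 100), 10, 10)
  pdf <- channel_pdf(img, n_bins = 8)
  width <- diff(pdf$bin_edges)[1]
  for (ch in 1:3) {
    expect_equal(sum(pdf$density[, ch] * width), 1, tolerance = 1e-6)
    expect_equal(sum(pdf$density[, ch] > 0), 1)  # one bin holds all mass
  }

  img2 <- random_rgb(40, 40, seed = 9)
  pdf2 <- channel_pdf(img2, n_bins = 16)
  w2 <- diff(pdf2$bin_edges)[1]
  expect_true(all(pdf2$density >= 0))
  for (ch in 1:3) {
    expect_equal(sum(pdf2$density[, ch] * w2), 1, tolerance = 1e-6)
    # counting oracle per bin
    v <- as.numeric(img2[, , ch])
    counts <- vapply(seq_len(16), function(b) {
      lo <- pdf2$bin_edges[b]; hi <- pdf2$bin_edges[b + 1]
      if (b == 16) sum(v >= lo & v <= hi) else sum(v >= lo & v < hi)
    }, numeric(1))
    expect_equal(pdf2$density[, ch], counts / (length(v) * w2))
    # uniform sampling: all bins near the uniform density 1/256
    expect_lt(max(abs(pdf2$density[, ch] - 1 / 256)) / (1 / 256), 0.35)
  }

  expect_error(channel_pdf(img, n_bins = 1), "n_bins")
})

test_that("channel_pdf table export round-trips", {
  pdf <- channel_pdf(random_rgb(8, 8, seed = 4), n_bins = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_channel_pdf(pdf, path)
  d <- read.csv(path)
  expect_equal(nrow(d), 8)
  expect_equal(d$density_G, unname(pdf$density[, "G"]))
})
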