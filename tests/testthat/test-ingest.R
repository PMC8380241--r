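test_that("gating features match analytic geometry", {
  # uniform disc of radius 10 px on a flat background
  mk <- function(fg) {
    m <- matrix(30000L, 64, 64)
    d <- sqrt((row(m) - 32.5)^2 + (col(m) - 32.5)^2)
    m[fg(d, row(m), col(m))] <- 10000L
    m
  }
  disc <- mk(function(d, i, j) d <= 10)
  f <- compute_gating_features(disc, pixel_size = 0.33)
  expect_equal(f$brightfield_area, pi * 10^2 * 0.33^2,
               tolerance = 2 * 21 * 0.33^2 / (pi * 100 * 0.1089))  # +-1 px ring
  expect_equal(f$aspect_ratio, 1.0, tolerance = 0.02)

  # 2:1 ellipse -> aspect ratio 0.5 (smoothing/discretisation bias shrinks
  # with object size; allow a few percent)
  ell <- matrix(30000L, 64, 64)
  d2 <- ((col(ell) - 32.5) / 26)^2 + ((row(ell) - 32.5) / 13)^2
  ell[d2 <= 1] <- 10000L
  f2 <- compute_gating_features(ell)
  expect_lt(abs(f2$aspect_ratio - 0.5), 0.025)

  expect_error(compute_gating_features(matrix(500L, 64, 64)), "no object")
})

test_that("gate_single_cells applies the published inclusive gates", {
  mkrec <- function(area, ar, g)
    list(features = list(brightfield_area = area, aspect_ratio = ar,
                         gradient_rms = g))
  recs <- list(mkrec(300, 0.9, 60),    # inside all gates
               mkrec(150, 0.9, 60),    # below area gate
               mkrec(200, 0.75, 55),   # exactly on the lower boundaries
               mkrec(500, 1.0, 80),    # exactly on the upper boundaries
               mkrec(300, 0.7, 60),    # aspect ratio fail
               mkrec(300, 0.9, 85))    # focus fail
  g <- gate_single_cells(recs)
  expect_equal(length(g$kept), 3L)
  expect_equal(length(g$rejected), 3L)
  expect_identical(c(g$kept, g$rejected)[order(c(1, 3, 4, 2, 5, 6))], recs)

  # idempotence: gating the kept set changes nothing
  g2 <- gate_single_cells(g$kept)
  expect_identical(g2$kept, g$kept)
  expect_equal(length(g2$rejected), 0L)
})

test_that("normalize_channel maps to the full 16-bit range", {
  m <- matrix(c(100, 200, 300), 1)
  out <- normalize_channel(m)
  expect_identical(as.integer(out), c(0L, 32768L, 65535L))

  # idempotence up to quantisation
  full <- matrix(as.integer(seq(0, 65535, length.out = 64)), 8, 8)
  expect_equal(max(abs(normalize_channel(full) - full)), 0)

  expect_warning(out0 <- normalize_channel(matrix(7, 3, 3)), "constant")
  expect_true(all(out0 == 0L))

  # rank order preserved on random data (ties preserved)
  set.seed(8)
  r <- matrix(sample(0:1000, 100, replace = TRUE), 10, 10)
  nr <- normalize_channel(r)
  expect_identical(order(r, seq_along(r)), order(nr, seq_along(nr)))
  expect_identical(outer(c(r), c(r), `==`), outer(c(nr), c(nr), `==`))
})

test_that("crop_pad centres, pads and crops to 64", {
  m <- matrix(1, 50, 60)
  out <- crop_pad(m, 64L)
  expect_equal(dim(out), c(64L, 64L))
  expect_true(all(out[1:7, ] == 0) && all(out[58:64, ] == 0))
  expect_true(all(out[, 1:2] == 0) && all(out[, 63:64] == 0))
  expect_true(all(out[8:57, 3:62] == 1))

  m64 <- matrix(rnorm(64 * 64), 64, 64)
  expect_identical(crop_pad(m64), m64)

  # centre-crop equals the independent slice-index oracle
  m2 <- matrix(seq_len(80 * 70), 80, 70)
  out2 <- crop_pad(m2, 64L)
  expect_identical(out2, m2[9:72, 4:67])
})

test_that("TIFF round trip is bit-identical and malformed inputs error", {
  tmp <- withr::local_tempdir()
  set.seed(21)
  labels <- sample(PHENOTYPE_CLASSES[c(1, 3, 4, 9)], 20, replace = TRUE)
  recs <- make_test_records(labels, seed0 = 400)
  for (r in seq_along(recs))
    recs[[r]]$features <- compute_gating_features(recs[[r]]$image)
  manifest <- write_dataset(recs, tmp)
  back <- read_dataset(manifest)
  expect_equal(length(back), 20L)
  for (i in seq_along(recs)) {
    expect_identical(back[[i]]$image, recs[[i]]$image)
    expect_identical(back[[i]]$label, recs[[i]]$label)
    expect_equal(back[[i]]$features$brightfield_area,
                 recs[[i]]$features$brightfield_area, tolerance = 1e-9)
  }

  # single-page TIFF -> format error naming the file
  write_tiff16(list(recs[[1]]$image[, , 1]), file.path(tmp, "cell_000001.tif"))
  expect_error(read_dataset(manifest), "2-page")

  # unknown label -> validation error naming the row
  write_tiff16(list(recs[[1]]$image[, , 1], recs[[1]]$image[, , 2]),
               file.path(tmp, "cell_000001.tif"))
  df <- read.csv(manifest, stringsAsFactors = FALSE)
  df$label[5] <- "binucleated_cell"
  write.csv(df, manifest, row.names = FALSE)
  expect_error(read_dataset(manifest), "row 5.*binucleated_cell")

  expect_error(read_tiff16(file.path(tmp, "nope.tif")), "not found")
  writeBin(as.raw(1:10), file.path(tmp, "junk.tif"))
  expect_error(read_tiff16(file.path(tmp, "junk.tif")), "TIFF")
})

test_that("standardize_image rescales and reshapes to 64x64x2", {
  set.seed(4)
  raw <- list(matrix(sample(100:1000, 50 * 70, TRUE), 50, 70),
              matrix(sample(100:1000, 50 * 70, TRUE), 50, 70))
  out <- standardize_image(raw, 64L)
  expect_equal(dim(out), c(64L, 64L, 2L))
  expect_equal(max(out), 65535L)
})
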