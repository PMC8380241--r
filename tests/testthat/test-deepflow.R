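test_that("lr_at_epoch matches the closed-form schedule exactly", {
  cfg <- train_config()
  expect_identical(lr_at_epoch(1, cfg), 5e-3)
  expect_identical(lr_at_epoch(6, cfg), 5e-3 * 0.9)
  expect_identical(lr_at_epoch(30, cfg), 5e-3 * 0.9^5)
  for (e in 1:30)
    expect_identical(lr_at_epoch(e, cfg), 5e-3 * 0.9^floor((e - 1) / 5))
  expect_error(lr_at_epoch(0, cfg), ">= 1")
})

test_that("augment preserves shape, identity and oracle labels", {
  sp <- cell_spec("binucleate_mn", n_micronuclei = 1,
                  mn_diameter_ratios = 0.22)
  img <- render_cell(sp, lab_profile(), seed = 31)
  storage.mode(img) <- "double"

  ident <- list(flip_x = FALSE, flip_y = FALSE, angle = 0, tx = 0, ty = 0,
                scale = 1.0)
  expect_equal(augment(img, params = ident), img, tolerance = 1e-12)

  # pure x-reflection keeps the blob-count label
  refl <- modifyList(ident, list(flip_x = TRUE))
  out <- augment(img, params = refl)
  expect_equal(dim(out), dim(img))
  expect_identical(blob_phenotype(out), blob_phenotype(img))

  # max upscale still returns the contracted 64x64 shape
  big <- augment(img, params = modifyList(ident, list(scale = 1.10)))
  expect_equal(dim(big), c(64L, 64L, 2L))

  # seeded draws are reproducible
  a1 <- augment(img, seed = 5)
  a2 <- augment(img, seed = 5)
  expect_identical(a1, a2)
})

test_that("untrained network emits valid softmax distributions", {
  m <- build_network(network_config(seed = 2))
  set.seed(6)
  X <- array(sample(0:65535, 64 * 64 * 2 * 7, TRUE), c(64, 64, 2, 7))
  pr <- predict(m, X)
  P <- attr(pr, "prob")
  expect_equal(dim(P), c(7L, 9L))
  expect_true(all(P >= 0))
  expect_equal(rowSums(P), rep(1, 7), tolerance = 1e-5)
  # order-preserving over the batch
  pr_sub <- predict(m, X[, , , c(3, 5), drop = FALSE])
  expect_equal(attr(pr_sub, "prob")[1, ], P[3, ], tolerance = 1e-5)
  # 16-bit extremes do not produce NaN
  Xex <- array(0L, c(64, 64, 2, 2)); Xex[, , , 2] <- 65535L
  expect_false(any(is.na(attr(predict(m, Xex), "prob"))))

  # doubling widths strictly increases the parameter count
  m2 <- build_network(network_config(block_widths = c(64L, 128L, 256L),
                                     seed = 2))
  expect_gt(n_parameters(m2), n_parameters(m))
})

test_that("training is seed-deterministic and weighting by ones is a no-op", {
  cfg <- network_config(n_classes = 2, block_widths = c(4L, 8L),
                        n_blocks_per_scale = 1L, stem_width = 4L,
                        img = 16L, seed = 3)
  set.seed(12)
  X <- array(runif(16 * 16 * 2 * 40) * 65535, c(16, 16, 2, 40))
  y <- rep(c("a", "b"), 20)
  tc <- train_config(epochs = 2, batch_size = 16, augmentation = NULL,
                     seed = 9)
  m1 <- train_network(build_network(cfg, c("a", "b")), X, y, tc)
  m2 <- train_network(build_network(cfg, c("a", "b")), X, y, tc)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)

  tc_w <- modifyList(tc, list(class_weights = c(1, 1)))
  class(tc_w) <- "train_config"
  m3 <- train_network(build_network(cfg, c("a", "b")), X, y, tc_w)
  expect_identical(m3$history$loss, m1$history$loss)

  expect_error(train_network(build_network(cfg, c("a", "b")),
                             X, rep("c", 40), tc), "outside")
  expect_error(train_network(build_network(cfg, c("a", "b")),
                             X[, , , 0, drop = FALSE], character(0), tc),
               "empty")
})

test_that("network separates mono from binucleate cells", {
  # separable-data sanity oracle, scaled down from the 500/class, 10-epoch
  # design for runtime: 150/class, 6 epochs is already cleanly separable
  labels <- rep(c("mononucleate", "binucleate"), each = 150)
  recs <- make_test_records(labels, seed0 = 1000)
  sp <- split_train_test(labels = labels, fraction = 0.6, seed = 3)
  m <- build_network(network_config(n_classes = 2, seed = 5),
                     label_encoding = c("mononucleate", "binucleate"))
  m <- train_network(m, recs[sp$train], labels[sp$train],
                     train_config(epochs = 6, seed = 9))
  pr <- predict(m, recs[sp$test])
  expect_gte(mean(pr$label == labels[sp$test]), 0.95)
  expect_true(all(pr$confidence >= 0.5 & pr$confidence <= 1))
  # argmax stable across repeated calls
  pr2 <- predict(m, recs[sp$test])
  expect_identical(pr$label, pr2$label)
  # training loss fell over the run (weak monotonicity sanity)
  expect_lt(tail(m$history$loss, 1), m$history$loss[1])

  # checkpoint round trip preserves behaviour
  tmp <- withr::local_tempfile(fileext = ".rds")
  save_model(m, tmp)
  m_back <- load_model(tmp)
  expect_identical(predict(m_back, recs[sp$test])$label, pr$label)
})

test_that("merge_polynucleated collapses tri/tetra classes idempotently", {
  labs <- c("trinucleate_mn", "binucleate_mn", "tetranucleate",
            "mononucleate", "other", "tetranucleate_mn")
  out <- merge_polynucleated(labs)
  expect_identical(as.character(out),
                   c("polynucleated", "binucleate_mn", "polynucleated",
                     "mononucleate", "other", "polynucleated"))
  expect_identical(as.character(merge_polynucleated(out)),
                   as.character(out))
  expect_equal(length(attr(out, "taxonomy")), 6L)
})

test_that("inverse-frequency class weights normalise to mean one", {
  labs <- c(rep("mononucleate", 80), rep("binucleate", 20))
  w <- class_weights_inverse(labs, c("mononucleate", "binucleate"))
  expect_equal(mean(w), 1)
  expect_equal(w[2] / w[1], 4)
})
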