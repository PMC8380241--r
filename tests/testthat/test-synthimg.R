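test_that("render_cell is deterministic and validates MN size ratios", {
  sp <- cell_spec("binucleate_mn", n_micronuclei = 1,
                  mn_diameter_ratios = 0.25)
  lab <- lab_profile()
  a <- render_cell(sp, lab, seed = 42)
  b <- render_cell(sp, lab, seed = 42)
  expect_identical(a, b)
  expect_equal(dim(a), c(64L, 64L, 2L))
  expect_true(all(a >= 0 & a <= 65535))
  expect_false(identical(a, render_cell(sp, lab, seed = 43)))

  # the 1/3 upper bound and 1/16 lower bound are enforced
  expect_error(cell_spec("binucleate_mn", n_micronuclei = 1,
                         mn_diameter_ratios = 0.40), "1/3")
  expect_error(cell_spec("mononucleate_mn", n_micronuclei = 1,
                         mn_diameter_ratios = 0.05), "1/3")
  sp_bad <- cell_spec("binucleate_mn", n_micronuclei = 1,
                      mn_diameter_ratios = 0.25)
  sp_bad$mn_diameter_ratios <- 0.40   # bypass the constructor
  expect_error(render_cell(sp_bad, lab, seed = 1), "1/16")

  # phenotype/count consistency
  expect_error(cell_spec("binucleate", n_micronuclei = 1), "inconsistent")
  expect_error(cell_spec("trinucleate_mn", n_micronuclei = 0), "inconsistent")
})

test_that("blob-count oracle recovers the rendered geometry", {
  # bi + 1 MN at ratio 0.25: two large and one small component, sizes in
  # the admissible band relative to the parent nuclei
  sp <- cell_spec("binucleate_mn", n_micronuclei = 1,
                  mn_diameter_ratios = 0.25)
  img <- render_cell(sp, lab_profile(), seed = 7)
  blobs <- blob_oracle(img[, , 1])
  blobs <- blobs[blobs$size >= 3, ]
  ref <- blobs$diameter[1]
  n_nuc <- sum(blobs$diameter > ref / 3)
  n_small <- sum(blobs$diameter <= ref / 3 & blobs$diameter >= ref / 16)
  expect_equal(n_nuc, 2L)
  expect_equal(n_small, 1L)
  # measured MN ratio respects the scoring band
  mn_d <- blobs$diameter[blobs$diameter <= ref / 3][1]
  expect_gt(mn_d / ref, 1 / 16)
  expect_lt(mn_d / ref, 1 / 3)
})

test_that("rendered phenotypes are recoverable by the oracle at default noise", {
  # spec invariant: >= 99% of non-unscorable cells, default lab profile
  classes <- setdiff(PHENOTYPE_CLASSES, "other")
  n <- 0; ok <- 0
  for (cl in classes) {
    for (i in 1:30) {
      sp <- mnflow:::withr_seed(i * 53 + match(cl, classes) * 7,
                                random_cell_spec(cl))
      img <- render_cell(sp, lab_profile(), seed = i * 17 + match(cl, classes))
      n <- n + 1
      ok <- ok + identical(blob_phenotype(img), cl)
    }
  }
  expect_gte(ok / n, 0.99)
})

test_that("sample_population draws labels from the class frequencies", {
  one_hot <- setNames(as.numeric(PHENOTYPE_CLASSES == "binucleate"),
                      PHENOTYPE_CLASSES)
  pop <- population_spec(one_hot, 100L, seed = 3)
  recs <- sample_population(pop, render = FALSE)
  expect_equal(length(recs), 100L)
  expect_true(all(vapply(recs, function(r) r$label, "") == "binucleate"))

  # multinomial tolerance oracle: uniform, n = 9000, 3 sd of 1000
  pop9 <- population_spec(rep(1 / 9, 9), 9000L, seed = 11)
  labs <- vapply(sample_population(pop9, render = FALSE),
                 function(r) r$label, "")
  counts <- table(factor(labs, levels = PHENOTYPE_CLASSES))
  sd_mult <- sqrt(9000 * (1 / 9) * (8 / 9))     # ~29.8
  expect_true(all(abs(counts - 1000) <= 3 * sd_mult))

  # same seed -> identical label sequence
  labs2 <- vapply(sample_population(pop9, render = FALSE),
                  function(r) r$label, "")
  expect_identical(labs, labs2)

  expect_error(population_spec(rep(1 / 9, 9), 0L), "n_cells")
  expect_error(population_spec(rep(1, 9), 10L))   # does not sum to 1
})

test_that("simulate_experiment follows the induction curve", {
  # flat-curve limit: no induction when fold = 1
  flat <- simulate_experiment(dose_response_spec(max_fold_induction = 1,
                                                 noise_model = 0, seed = 5))
  curve <- attr(flat, "curve")
  expect_equal(curve$fold, 1)
  agg <- tapply(flat$response, flat$concentration, mean)
  # every concentration's mean stays within 3 binomial sd of background
  nb <- tapply(flat$n_binucleated, flat$concentration, sum)
  tol <- 3 * sqrt(0.01 * 0.99 / nb)
  expect_true(all(abs(agg - 0.01) < tol))
  expect_true(is.na(attr(flat, "true_bmd")))   # benchmark unreachable

  # law-of-large-numbers check at n = 50,000, zero replicate noise
  big <- simulate_experiment(dose_response_spec(n_scored_per_sample = 50000L,
                                                noise_model = 0, seed = 9))
  cv <- attr(big, "curve")
  for (x in unique(big$concentration)) {
    rows <- big$concentration == x
    expected <- induction_curve(x, cv$f0, cv$fold, cv$b, cv$d)
    nb <- sum(big$n_binucleated[rows])
    emp <- sum(big$response[rows] * big$n_binucleated[rows]) / nb
    expect_lt(abs(emp - expected), 3 * sqrt(expected * (1 - expected) / nb))
  }

  # ground-truth BMD equals independent root-finding on the curve
  dr <- simulate_experiment(dose_response_spec(seed = 1), ces = 0.5)
  cv <- attr(dr, "curve")
  root <- uniroot(function(x)
    induction_curve(x, cv$f0, cv$fold, cv$b, cv$d) - 1.5 * cv$f0,
    c(1e-6, 100), tol = 1e-12)$root
  expect_equal(attr(dr, "true_bmd"), root, tolerance = 1e-8)

  expect_error(dose_response_spec(concentrations = c(1, 2)), "vehicle")
})

test_that("unscorable kinds render distinct morphologies", {
  kinds <- c("debris", "doublet", "out_of_focus", "mitotic", "dead")
  feats <- lapply(kinds, function(k) {
    sp <- cell_spec("other", unscorable_kind = k)
    img <- render_cell(sp, lab_profile(), seed = 99)
    tryCatch(compute_gating_features(img),
             error = function(e) list(brightfield_area = 0,
                                      aspect_ratio = NA, gradient_rms = NA))
  })
  names(feats) <- kinds
  # debris and dead cells are far smaller than intact cells
  expect_lt(feats$debris$brightfield_area, 100)
  expect_lt(feats$dead$brightfield_area, 150)
  # doublets are elongated
  expect_lt(feats$doublet$aspect_ratio, 0.75)
  # defocused cells fail the focus gate
  expect_lt(feats$out_of_focus$gradient_rms, 55)
})
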