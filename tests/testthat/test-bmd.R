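test_that("model_response implements the two EFSA family forms", {
  p <- list(a = 2, b = 1, c = 3, d = 1)
  for (fam in c("exponential", "hill")) {
    expect_equal(model_response(0, p, fam), 2)                  # y(0) = a
    expect_equal(model_response(1e9, p, fam), 6, tolerance = 1e-6) # -> a*c
    expect_equal(model_response(0.5, list(a = 2, b = 1, c = 1, d = 1), fam),
                 2)                                             # flat at c=1
  }
  expect_equal(model_response(1, p, "hill"), 2 * (1 + 2 * 0.5))  # = 4
  expect_equal(model_response(1, p, "exponential"),
               2 * (3 - 2 * exp(-1)))
  expect_error(model_response(-1, p, "hill"), ">= 0")
})

test_that("compute_bmd inverts both families in closed form", {
  # frozen closed-form examples, cross-checked by a root-finding oracle
  p_hill <- list(a = 2, b = 1, c = 3, d = 1)
  expect_equal(compute_bmd(p_hill, "hill", 0.5), 1 / 3, tolerance = 1e-10)
  p_exp <- list(a = 1, b = 1, c = 3, d = 1)
  expect_equal(compute_bmd(p_exp, "exponential", 0.5), log(4 / 3),
               tolerance = 1e-10)
  for (fam in c("hill", "exponential")) {
    root <- uniroot(function(x)
      model_response(x, if (fam == "hill") p_hill else p_exp, fam) -
        (if (fam == "hill") 2 else 1) * 1.5,
      c(1e-9, 50), tol = 1e-12)$root
    expect_equal(compute_bmd(if (fam == "hill") p_hill else p_exp, fam, 0.5),
                 root, tolerance = 1e-8)
  }
  # inverse property on random admissible parameter draws
  set.seed(14)
  for (i in 1:25) {
    p <- list(a = runif(1, 0.001, 5), b = runif(1, 0.1, 10),
              c = runif(1, 1.6, 30), d = runif(1, 0.3, 5))
    fam <- sample(c("hill", "exponential"), 1)
    bmd <- compute_bmd(p, fam, 0.5)
    expect_equal(model_response(bmd, p, fam) / (p$a * 1.5), 1,
                 tolerance = 1e-8)
  }
  expect_error(compute_bmd(list(a = 1, b = 1, c = 1, d = 1), "hill", 0.5),
               "unreachable")
  expect_error(compute_bmd(list(a = 1, b = 1, c = 1.4, d = 1),
                           "exponential", 0.5), "unreachable")
})

simulate_ln <- function(seed, b = 1, n = 3, sd = 0.1,
                        concs = c(0, 0.8, 1.2, 1.6), f0 = 0.005,
                        fold = 8, d = 2) {
  set.seed(seed)
  x <- rep(concs, each = n)
  m <- induction_curve(x, f0, fold, b, d)
  data.frame(concentration = x, response = m * exp(rnorm(length(x), 0, sd)))
}

test_that("single-level fit recovers the generating curve", {
  d <- simulate_ln(1, sd = 0.08, concs = c(0, 0.25, 0.5, 1, 1.5, 2), n = 3)
  for (fam in c("hill", "exponential")) {
    f <- fit_covariate_model(d, bmd_config(fam))
    expect_s3_class(f, "bmd_fit")
    expect_equal(f$params$a, 0.005, tolerance = 0.15)
    # fitted BMD close to the generator's closed-form truth
    true_bmd <- 1 * ((0.5 / 7) / (1 - 0.5 / 7))^(1 / 2)
    expect_equal(f$params$bmd, true_bmd, tolerance = 0.35)
  }
  # exponential and Hill agree on the BMD at low noise (model robustness)
  fh <- fit_covariate_model(d, bmd_config("hill"))
  fe <- fit_covariate_model(d, bmd_config("exponential"))
  expect_lt(abs(fh$params$bmd - fe$params$bmd) / fh$params$bmd, 0.15)

  expect_error(fit_covariate_model(
    data.frame(concentration = c(0, 1), response = c(1, 2))), "3 distinct")
  expect_error(fit_covariate_model(
    data.frame(concentration = rep(c(0, 1, 2), 2),
               response = c(0.1, 0.2, 0.3, 0, 0.1, 0.2))), "positive")
})

test_that("single covariate level reduces to the plain fit", {
  d <- simulate_ln(21)
  plain <- fit_covariate_model(d, bmd_config("hill"))
  with_cov <- fit_covariate_model(cbind(d, covariate = "only"),
                                  bmd_config("hill"))
  expect_equal(plain$loglik, with_cov$loglik, tolerance = 1e-6)
  expect_equal(plain$params$bmd, with_cov$params$bmd, tolerance = 1e-4)
})

test_that("covariate ladder rejects potency for identical curves and
           detects a true 2x difference", {
  # identical curves: level-specific b rejected, one shared BMD
  d <- rbind(cbind(simulate_ln(2), covariate = "human"),
             cbind(simulate_ln(3), covariate = "network"))
  f <- fit_covariate_model(d, bmd_config("hill"))
  expect_true(f$covariate_rejected_for_potency)
  expect_equal(f$params$bmd[1], f$params$bmd[2])
  # nesting: every richer candidate fits at least as well as the shared
  # model, and the accepted model at least as well as the shared model
  expect_true(all(f$ladder$loglik >= f$ladder$loglik[1] - 1e-6))
  expect_gte(f$loglik, f$ladder$loglik[1] - 1e-6)

  # 2x potency difference at n = 6: detected and recovered
  d2 <- rbind(cbind(simulate_ln(4, b = 1, n = 6), covariate = "A"),
              cbind(simulate_ln(5, b = 2, n = 6), covariate = "B"))
  f2 <- fit_covariate_model(d2, bmd_config("hill"))
  expect_false(f2$covariate_rejected_for_potency)
  ratio <- f2$params$bmd[f2$params$level == "B"] /
    f2$params$bmd[f2$params$level == "A"]
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
})

test_that("profile-likelihood interval brackets the estimate and tightens
           with information", {
  d <- simulate_ln(8, sd = 0.08, concs = c(0, 0.25, 0.5, 1, 1.5, 2), n = 3)
  f <- fit_covariate_model(d, bmd_config("hill"))
  ci <- bmd_confidence_interval(f)
  expect_true(ci$bmdl <= f$params$bmd && f$params$bmd <= ci$bmdu)

  # noise -> 0 limit: interval collapses onto the true BMD
  d_tiny <- simulate_ln(9, sd = 0.004, concs = c(0, 0.25, 0.5, 1, 1.5, 2),
                        n = 3)
  f_tiny <- fit_covariate_model(d_tiny, bmd_config("hill"))
  ci_tiny <- bmd_confidence_interval(f_tiny)
  expect_lt(ci_tiny$bmdu / ci_tiny$bmdl, 1.25)
  true_bmd <- ((0.5 / 7) / (1 - 0.5 / 7))^(1 / 2)
  expect_equal(ci_tiny$bmd, true_bmd, tolerance = 0.05)

  # width monotonicity on a seeded noise ladder: the interval widens and
  # the lower bound falls further below the estimate as noise grows (the
  # raw BMDL is not monotone because the point estimate itself drifts
  # when the same residual pattern is amplified)
  lad <- t(vapply(c(0.05, 0.15, 0.45), function(s) {
    ds <- simulate_ln(10, sd = s, concs = c(0, 0.25, 0.5, 1, 1.5, 2), n = 3)
    ci <- bmd_confidence_interval(fit_covariate_model(ds, bmd_config("hill")))
    c(width = log(ci$bmdu / ci$bmdl), rel = ci$bmdl / ci$bmd)
  }, numeric(2)))
  expect_true(all(diff(lad[, "width"]) > 0))
  expect_true(all(diff(lad[, "rel"]) < 0))
})
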