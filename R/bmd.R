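#' Benchmark-dose analysis configuration
#'
#' @param model_family `"exponential"` or `"hill"` (the two continuous-data
#'   families recommended for toxicity dose-response assessment).
#' @param ces critical effect size: the benchmark response is a `ces`
#'   fractional increase over the fitted background (0.5 = 50%).
#' @param ci_level two-sided profile-likelihood confidence level.
#' @param acceptance_alpha likelihood-ratio p-value below which a
#'   covariate-dependent parameter is accepted.
#' @param ladder order in which level-specific parameters are tested;
#'   `c` and `d` are always held shared across covariate levels.
#' @return object of class `bmd_config`.
#' @export
bmd_config <- function(model_family = c("exponential", "hill"), ces = 0.50,
                       ci_level = 0.90, acceptance_alpha = 0.05,
                       ladder = c("var", "a", "b")) {
  model_family <- match.arg(model_family)
  stopifnot(ces > 0, ci_level > 0, ci_level < 1, acceptance_alpha > 0,
            identical(sort(ladder), sort(c("var", "a", "b"))))
  structure(list(model_family = model_family, ces = ces,
                 ci_level = ci_level, acceptance_alpha = acceptance_alpha,
                 ladder = ladder),
            class = "bmd_config")
}

#' Continuous dose-response model families
#'
#' Four-parameter members of the exponential and Hill families:
#' exponential `y = a (c - (c - 1) exp(-(x/b)^d))` and Hill
#' `y = a (1 + (c - 1) x^d / (b^d + x^d))`, with background `a > 0`,
#' potency `b > 0` (concentration units), maximum fold-change `c >= 1`
#' and log-steepness `d > 0`. Both satisfy `y(0) = a` and
#' `y -> a c` as `x -> Inf`.
#'
#' @param x concentration(s), >= 0.
#' @param p parameter list/vector with `a`, `b`, `c`, `d`.
#' @param family `"exponential"` or `"hill"`.
#' @return expected response at `x`.
#' @export
model_response <- function(x, p, family = c("exponential", "hill")) {
  family <- match.arg(family)
  a <- p[["a"]]; b <- p[["b"]]; cc <- p[["c"]]; d <- p[["d"]]
  if (any(x < 0)) stop("concentrations must be >= 0")
  stopifnot(a > 0, b > 0, cc >= 1, d > 0)
  if (family == "exponential") {
    a * (cc - (cc - 1) * exp(-(x / b)^d))
  } else {
    a * (1 + (cc - 1) * x^d / (b^d + x^d))
  }
}

#' Benchmark dose of a fitted curve
#'
#' The concentration producing a `ces` fractional increase over background:
#' the unique positive root of `y(BMD) = a (1 + ces)`, in closed form for
#' both families. Unreachable benchmarks (plateau `a c <= a (1 + ces)`,
#' i.e. `c <= 1 + ces`) raise an error.
#'
#' @inheritParams model_response
#' @param ces critical effect size.
#' @return the benchmark dose (same units as `b`).
#' @export
compute_bmd <- function(p, family = c("exponential", "hill"), ces = 0.5) {
  family <- match.arg(family)
  a <- p[["a"]]; b <- p[["b"]]; cc <- p[["c"]]; d <- p[["d"]]
  stopifnot(a > 0, b > 0, d > 0)
  if (cc <= 1 + ces)
    stop("benchmark unreachable: maximum fold-change c = ", cc,
         " cannot produce a ", 100 * ces, "% increase over background")
  b * .bmd_gain(cc, d, family, ces)
}

# BMD / b as a function of (c, d): the family-specific inversion
.bmd_gain <- function(cc, d, family, ces) {
  if (family == "hill") {
    h <- ces / (cc - 1)            # in (0,1) because cc > 1 + ces
    (h / (1 - h))^(1 / d)
  } else {
    (-log((cc - 1 - ces) / (cc - 1)))^(1 / d)
  }
}

# ---- covariate maximum-likelihood machinery ------------------------------
# theta layout: [log a (1|L), log BMD (1|L), log(c - 1 - ces), log d]
# potency is parameterised through the BMD itself (b = BMD / gain(c,d)),
# which makes profile-likelihood intervals a coordinate profile and
# guarantees c > 1 + ces throughout.

.theta_index <- function(struct, L) {
  na <- if (struct$a) L else 1L
  nb <- if (struct$b) L else 1L
  list(a = seq_len(na), bmd = na + seq_len(nb), c = na + nb + 1L,
       d = na + nb + 2L, len = na + nb + 2L)
}

.unpack_theta <- function(theta, struct, L, ces) {
  ix <- .theta_index(struct, L)
  a <- exp(theta[ix$a]); if (!struct$a) a <- rep(a, L)
  bmd <- exp(theta[ix$bmd]); if (!struct$b) bmd <- rep(bmd, L)
  cc <- 1 + ces + exp(theta[ix$c])
  d <- exp(theta[ix$d])
  list(a = a, bmd = bmd, c = cc, d = d)
}

.bmd_nll <- function(theta, dat, struct, family, ces) {
  out <- tryCatch(.bmd_nll_impl(theta, dat, struct, family, ces),
                  error = function(e) 1e10)
  if (length(out) != 1L || is.na(out) || !is.finite(out)) 1e10 else out
}

.bmd_nll_impl <- function(theta, dat, struct, family, ces) {
  L <- nlevels(dat$level)
  pp <- .unpack_theta(theta, struct, L, ces)
  if (!all(is.finite(c(pp$a, pp$bmd, pp$c, pp$d)))) return(1e10)
  gain <- .bmd_gain(pp$c, pp$d, family, ces)
  if (!is.finite(gain) || gain <= 0) return(1e10)
  nll <- 0
  rss <- numeric(L); nl <- numeric(L)
  for (l in seq_len(L)) {
    rows <- dat$level == levels(dat$level)[l]
    b <- pp$bmd[l] / gain
    m <- model_response(dat$concentration[rows],
                        list(a = pp$a[l], b = b, c = pp$c, d = pp$d), family)
    r <- dat$logr[rows] - log(m)
    rss[l] <- sum(r^2); nl[l] <- sum(rows)
  }
  if (struct$var) {
    if (any(rss <= 0)) return(1e10)
    nll <- sum(nl / 2 * (log(2 * pi) + 1 + log(rss / nl)))
  } else {
    if (sum(rss) <= 0) return(1e10)
    N <- sum(nl)
    nll <- N / 2 * (log(2 * pi) + 1 + log(sum(rss) / N))
  }
  if (!is.finite(nll)) return(1e10)
  nll
}

.bmd_fit_once <- function(dat, struct, family, ces, starts) {
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      optim(st, .bmd_nll, dat = dat, struct = struct, family = family,
            ces = ces, method = "BFGS",
            control = list(maxit = 600, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("BMD model fit failed to converge from any start")
  # polish with Nelder-Mead in case BFGS stalled on a kink
  pol <- tryCatch(optim(best$par, .bmd_nll, dat = dat, struct = struct,
                        family = family, ces = ces,
                        control = list(maxit = 2000, reltol = 1e-12)),
                  error = function(e) best)
  if (pol$value < best$value) best <- pol
  best
}

.bmd_starts <- function(dat, struct, family, ces) {
  L <- nlevels(dat$level)
  xpos <- sort(unique(dat$concentration[dat$concentration > 0]))
  gm <- tapply(dat$logr, list(dat$level, dat$concentration), mean)
  a0 <- exp(gm[, 1]); a0[!is.finite(a0)] <- exp(min(dat$logr))
  top <- apply(exp(gm), 1, max, na.rm = TRUE)
  c0 <- max(max(top / a0, na.rm = TRUE), 1 + ces + 0.3)
  c0 <- min(c0, 100)
  la0 <- if (struct$a) log(a0) else log(mean(a0))
  combos <- list(c(1, stats::median(xpos)), c(2, stats::median(xpos)),
                 c(0.5, max(xpos) / 2), c(4, stats::median(xpos)),
                 c(2, max(xpos)))
  lapply(combos, function(co) {
    d0 <- co[1]; b0 <- co[2]
    bmd0 <- b0 * .bmd_gain(c0, d0, family, ces)
    lb0 <- if (struct$b) rep(log(bmd0), L) else log(bmd0)
    c(la0, lb0, log(c0 - 1 - ces), log(d0))
  })
}

#' Fit a covariate dose-response model and estimate the BMD
#'
#' Maximum-likelihood fit of the chosen model family to log responses
#' (lognormal error). With a covariate, fitting starts from the fully
#' shared model and walks a nested acceptance ladder (by default
#' within-group variance, then background `a`, then potency `b`), making a
#' parameter level-specific only when the likelihood-ratio test improves
#' the fit at `cfg$acceptance_alpha`; maximum response `c` and
#' log-steepness `d` are always shared. If level-specific potency is
#' rejected, all covariate levels share a single BMD
#' (`covariate_rejected_for_potency = TRUE`).
#'
#' @param data data.frame with columns `concentration`, `response` (> 0)
#'   and optionally `covariate` (factor/character; e.g. scoring method).
#' @param cfg a [bmd_config()].
#' @return object of class `bmd_fit` with per-level parameter estimates,
#'   BMDs, the accepted covariate structure, and the log-likelihood ladder.
#' @export
fit_covariate_model <- function(data, cfg = bmd_config()) {
  stopifnot(inherits(cfg, "bmd_config"),
            all(c("concentration", "response") %in% names(data)))
  if (any(!is.finite(data$response)) || any(data$response <= 0))
    stop("responses must be positive (apply a pseudo-count upstream)")
  if (length(unique(data$concentration)) < 3)
    stop("need at least 3 distinct concentrations")
  level <- if ("covariate" %in% names(data)) factor(data$covariate)
           else factor(rep("all", nrow(data)))
  for (l in levels(level)) {
    if (!any(data$concentration[level == l] == 0))
      stop("covariate level '", l, "' has no zero-concentration control")
  }
  dat <- data.frame(concentration = data$concentration,
                    logr = log(data$response), level = level)
  L <- nlevels(level)
  fam <- cfg$model_family; ces <- cfg$ces

  fit_struct <- function(struct, warm = NULL) {
    starts <- .bmd_starts(dat, struct, fam, ces)
    # a warm start from the nested accepted model is nearly always in the
    # right basin; keep two cold starts as insurance
    if (!is.null(warm)) starts <- c(list(warm), starts[1:2])
    .bmd_fit_once(dat, struct, fam, ces, starts)
  }
  # grow a warm start when a parameter becomes level-specific
  expand_warm <- function(par, from, to) {
    ixf <- .theta_index(from, L); ixt <- .theta_index(to, L)
    out <- numeric(ixt$len)
    out[ixt$a] <- if (length(ixt$a) == length(ixf$a)) par[ixf$a]
                  else rep(par[ixf$a], L)
    out[ixt$bmd] <- if (length(ixt$bmd) == length(ixf$bmd)) par[ixf$bmd]
                    else rep(par[ixf$bmd], L)
    out[ixt$c] <- par[ixf$c]; out[ixt$d] <- par[ixf$d]
    out
  }

  struct <- list(var = FALSE, a = FALSE, b = FALSE)
  fit <- fit_struct(struct)
  ladder <- data.frame(step = "shared", loglik = -fit$value, df = 0,
                       p = NA_real_, accepted = TRUE,
                       stringsAsFactors = FALSE)
  if (L > 1) {
    for (par_name in cfg$ladder) {
      cand <- struct; cand[[par_name]] <- TRUE
      warm <- expand_warm(fit$par, struct, cand)
      cfit <- fit_struct(cand, warm)
      # var adds L-1 variance parameters; a/b add L-1 mean parameters
      df <- L - 1L
      lrt <- 2 * (fit$value - cfit$value)
      p <- pchisq(max(lrt, 0), df, lower.tail = FALSE)
      acc <- is.finite(p) && p < cfg$acceptance_alpha
      ladder <- rbind(ladder, data.frame(step = par_name,
                                         loglik = -cfit$value, df = df,
                                         p = p, accepted = acc,
                                         stringsAsFactors = FALSE))
      if (acc) { struct <- cand; fit <- cfit }
    }
  }

  pp <- .unpack_theta(fit$par, struct, L, ces)
  gain <- .bmd_gain(pp$c, pp$d, fam, ces)
  # per-level residual variances under the accepted structure
  rssl <- vapply(seq_len(L), function(l) {
    rows <- dat$level == levels(level)[l]
    m <- model_response(dat$concentration[rows],
                        list(a = pp$a[l], b = pp$bmd[l] / gain, c = pp$c,
                             d = pp$d), fam)
    sum((dat$logr[rows] - log(m))^2)
  }, numeric(1))
  nl <- as.numeric(table(dat$level))
  varl <- if (struct$var) rssl / nl else rep(sum(rssl) / sum(nl), L)

  params <- data.frame(level = levels(level), a = pp$a, b = pp$bmd / gain,
                       c = pp$c, d = pp$d, var = varl, bmd = pp$bmd,
                       row.names = NULL, stringsAsFactors = FALSE)
  structure(list(params = params, loglik = -fit$value, ladder = ladder,
                 structure = struct,
                 covariate_rejected_for_potency = (L > 1) && !struct$b,
                 theta = fit$par, dat = dat, cfg = cfg, n_levels = L),
            class = "bmd_fit")
}

#' Profile-likelihood confidence interval for the BMD
#'
#' Two-sided interval at `cfg$ci_level` from the profile deviance. The BMD
#' is a model parameter here (potency is parameterised through it), so
#' profiling fixes it and re-optimises everything else. By default the
#' deviance cutoff uses the F-calibrated form
#' `N log(1 + F(level; 1, N - p) / (N - p))`, which is exact for Gaussian
#' regression with profiled variance and noticeably better calibrated than
#' the asymptotic chi-square(1) cutoff at the small replicate counts of a
#' typical dose-response design. A profile that never crosses the cutoff
#' yields an infinite (or zero) bound, flagged in `unbounded`.
#'
#' @param fit a [fit_covariate_model()] result.
#' @param cutoff_method `"f"` (small-sample calibrated, default) or
#'   `"chisq"` (asymptotic).
#' @return data.frame per covariate level: bmd, bmdl, bmdu, unbounded.
#' @export
bmd_confidence_interval <- function(fit, cutoff_method = c("f", "chisq")) {
  stopifnot(inherits(fit, "bmd_fit"))
  cutoff_method <- match.arg(cutoff_method)
  cfg <- fit$cfg; struct <- fit$structure; dat <- fit$dat
  L <- fit$n_levels; ces <- cfg$ces; fam <- cfg$model_family
  N <- nrow(dat); p <- length(fit$theta)
  cutoff <- if (cutoff_method == "f" && N - p > 0) {
    N * log(1 + qf(cfg$ci_level, 1, N - p) / (N - p))
  } else {
    qchisq(cfg$ci_level, 1)
  }
  ix <- .theta_index(struct, L)
  nll_min <- -fit$loglik

  profile_nll <- function(coord, log_bmd) {
    free <- setdiff(seq_len(ix$len), coord)
    obj <- function(th_free) {
      th <- numeric(ix$len)
      th[free] <- th_free; th[coord] <- log_bmd
      .bmd_nll(th, dat, struct, fam, ces)
    }
    st <- fit$theta[free]
    o <- tryCatch(optim(st, obj, method = "BFGS",
                        control = list(maxit = 400, reltol = 1e-11)),
                  error = function(e) list(value = Inf))
    if (!is.finite(o$value))  # fall back on the simplex if BFGS breaks down
      o <- tryCatch(optim(st, obj, control = list(maxit = 1500)),
                    error = function(e) list(value = Inf))
    o$value
  }

  one_bound <- function(coord, lb_hat, dir) {
    dev <- function(lb) 2 * (profile_nll(coord, lb) - nll_min)
    step <- 0.25 * dir
    prev <- lb_hat; cur <- lb_hat + step
    for (i in seq_len(60)) {
      d <- dev(cur)
      if (!is.finite(d)) return(list(bound = NA_real_, unbounded = TRUE))
      if (d >= cutoff) {
        r <- uniroot(function(lb) dev(lb) - cutoff, c(min(prev, cur),
                                                      max(prev, cur)),
                     tol = 1e-3)
        return(list(bound = exp(r$root), unbounded = FALSE))
      }
      prev <- cur; cur <- cur + step
    }
    list(bound = if (dir > 0) Inf else 0, unbounded = TRUE)
  }

  n_bmd_par <- length(ix$bmd)
  out <- NULL
  bounds <- vector("list", n_bmd_par)
  for (k in seq_len(n_bmd_par)) {
    coord <- ix$bmd[k]
    lb_hat <- fit$theta[coord]
    lo <- one_bound(coord, lb_hat, -1)
    hi <- one_bound(coord, lb_hat, +1)
    bounds[[k]] <- list(lo = lo, hi = hi)
  }
  for (l in seq_len(L)) {
    k <- if (struct$b) l else 1L
    bmd_l <- fit$params$bmd[l]
    out <- rbind(out, data.frame(
      level = fit$params$level[l], bmd = bmd_l,
      bmdl = bounds[[k]]$lo$bound, bmdu = bounds[[k]]$hi$bound,
      unbounded = bounds[[k]]$lo$unbounded || bounds[[k]]$hi$unbounded,
      stringsAsFactors = FALSE))
  }
  out
}

#' @export
print.bmd_fit <- function(x, ...) {
  cat(sprintf("<bmd_fit> %s family, CES %.0f%%, logLik %.3f\n",
              x$cfg$model_family, 100 * x$cfg$ces, x$loglik))
  if (x$n_levels > 1)
    cat(sprintf("covariate rejected for potency: %s\n",
                x$covariate_rejected_for_potency))
  print(x$params, ...)
  invisible(x)
}
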