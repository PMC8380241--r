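#' Tabulate phenotype labels into per-sample class counts
#'
#' @param labels scored labels for one sample.
#' @return named integer vector over [PHENOTYPE_CLASSES] with attribute
#'   `n_scored`.
#' @export
tabulate_counts <- function(labels) {
  assert_phenotype(labels)
  counts <- table(factor(labels, levels = PHENOTYPE_CLASSES))
  out <- as.integer(counts)
  names(out) <- PHENOTYPE_CLASSES
  attr(out, "n_scored") <- length(labels)
  out
}

#' Binucleated-cell micronucleus frequency
#'
#' The CBMN assay's core DNA-damage readout: micronucleated binucleates per
#' total binucleate scored,
#' `N(binucleate_mn) / (N(binucleate) + N(binucleate_mn))`.
#' With no binucleated cells at all the frequency is undefined and `NA` is
#' returned (never silently 0).
#'
#' @param counts named counts including `binucleate` and `binucleate_mn`
#'   (e.g. from [tabulate_counts()]).
#' @return frequency in `[0, 1]`, or `NA_real_` when undefined.
#' @export
mn_frequency <- function(counts) {
  bn <- as.numeric(counts[["binucleate"]])
  bnmn <- as.numeric(counts[["binucleate_mn"]])
  if (is.na(bn) || is.na(bnmn)) stop("counts must include binucleate and binucleate_mn")
  denom <- bn + bnmn
  if (denom == 0) return(NA_real_)
  bnmn / denom
}

# ---- Gauss quadrature helpers (Golub-Welsch on the Jacobi matrix) --------

.gauss_hermite <- function(n) {
  # physicists' Hermite: int exp(-x^2) f(x) dx = sum w_i f(x_i)
  b <- sqrt(seq_len(n - 1) / 2)
  J <- diag(0, n); J[cbind(1:(n - 1), 2:n)] <- b; J[cbind(2:n, 1:(n - 1))] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

.gauss_legendre <- function(n, lo = -1, hi = 1) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- diag(0, n); J[cbind(1:(n - 1), 2:n)] <- b; J[cbind(2:n, 1:(n - 1))] <- b
  e <- eigen(J, symmetric = TRUE)
  x <- e$values; w <- 2 * e$vectors[1, ]^2
  list(x = (hi - lo) / 2 * x + (hi + lo) / 2, w = (hi - lo) / 2 * w)
}

#' Joint lower tail of the many-to-one Dunnett t statistics
#'
#' Computes `P(T_1 <= t, ..., T_m <= t)` under the global null for the
#' one-sided many-to-one comparison design: `m` treatment groups of sizes
#' `nj` compared against one control of size `n0`, pooled-variance t
#' statistics with `df` degrees of freedom. Evaluated by conditioning on
#' the control mean (Gauss-Hermite) and the pooled standard deviation
#' (Gauss-Legendre on the chi distribution).
#'
#' @param t scalar threshold.
#' @param nj integer vector of treatment group sizes.
#' @param n0 control group size.
#' @param df residual degrees of freedom.
#' @return joint probability.
#' @keywords internal
dunnett_prob <- function(t, nj, n0, df) {
  gh <- .gauss_hermite(40L)
  z0 <- sqrt(2) * gh$x; wz <- gh$w / sqrt(pi)
  ulim <- sqrt(qchisq(c(1e-10, 1 - 1e-10), df) / df)
  gl <- .gauss_legendre(64L, ulim[1], ulim[2])
  u <- gl$x
  # density of U = S/sigma: f(u) = 2 (df/2)^(df/2)/Gamma(df/2) u^(df-1)
  #   exp(-df u^2/2)  (so that df U^2 ~ chi-square_df)
  wu <- gl$w * 2 * exp((df / 2) * log(df / 2) - lgamma(df / 2) +
                         (df - 1) * log(u) - df * u^2 / 2)
  cj <- sqrt(1 / nj + 1 / n0)
  acc <- 0
  for (iu in seq_along(u)) {
    inner <- rep(1, length(z0))
    for (j in seq_along(nj)) {
      inner <- inner * pnorm(sqrt(nj[j]) * (t * u[iu] * cj[j]) +
                               sqrt(nj[j] / n0) * z0)
    }
    acc <- acc + wu[iu] * sum(wz * inner)
  }
  min(max(acc, 0), 1)
}

#' One-sided Dunnett many-to-one test against control
#'
#' @param y response values (already transformed).
#' @param group factor; its first level is the control.
#' @return data.frame per treatment level: estimate (difference of means),
#'   statistic, p_adjusted (single-step Dunnett, one-sided increase).
#' @export
dunnett_test <- function(y, group) {
  group <- droplevels(as.factor(group))
  lv <- levels(group)
  if (length(lv) < 2) stop("need a control and at least one treatment group")
  ns <- tapply(y, group, length)
  ms <- tapply(y, group, mean)
  vs <- tapply(y, group, stats::var)
  df <- sum(ns) - length(lv)
  s2 <- sum((ns - 1) * vs) / df
  n0 <- ns[1]; nj <- ns[-1]
  tstat <- (ms[-1] - ms[1]) / sqrt(s2 * (1 / nj + 1 / n0))
  padj <- vapply(tstat, function(tt)
    1 - dunnett_prob(tt, nj = nj, n0 = n0, df = df), numeric(1))
  data.frame(group = lv[-1], estimate = as.numeric(ms[-1] - ms[1]),
             statistic = as.numeric(tstat), p_adjusted = as.numeric(padj),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One-sided Dunn rank test against control
#'
#' Non-parametric many-to-one comparison on pooled ranks with tie
#' correction; multiplicity controlled by the Sidak family correction.
#'
#' @param y response values.
#' @param group factor; first level is the control.
#' @return data.frame per treatment level: statistic (z), p_adjusted.
#' @export
dunn_test <- function(y, group) {
  group <- droplevels(as.factor(group))
  lv <- levels(group)
  N <- length(y)
  rk <- rank(y)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  v <- N * (N + 1) / 12 - tie_corr
  ns <- tapply(rk, group, length)
  mr <- tapply(rk, group, mean)
  n0 <- ns[1]; m <- length(lv) - 1L
  z <- (mr[-1] - mr[1]) / sqrt(v * (1 / ns[-1] + 1 / n0))
  p1 <- pnorm(z, lower.tail = FALSE)
  padj <- 1 - (1 - p1)^m
  data.frame(group = lv[-1], statistic = as.numeric(z),
             p_adjusted = as.numeric(pmin(padj, 1)), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Dose-response significance framework
#'
#' Implements the decision framework used for micronucleus responses:
#' frequencies are log10 transformed (zeros replaced by a half-minimum
#' pseudo-count first), normality is checked by Shapiro-Wilk on pooled
#' within-group-centred residuals and variance homogeneity by Bartlett's
#' test; if both pretests pass (p > 0.05) concentrations are compared to
#' the vehicle control by a one-sided (increase) single-step Dunnett test,
#' otherwise by the non-parametric one-sided Dunn test with Sidak
#' correction. Significance is flagged at p < 0.05 / 0.01 / 0.001.
#'
#' @param data data.frame with columns `concentration` (0 = vehicle
#'   control) and `response` (binucleated-cell MN frequency); an optional
#'   `n_binucleated` column scales the zero-replacement pseudo-count.
#' @param alpha pretest significance level for routing.
#' @return object of class `significance_result`: data.frame of
#'   per-concentration decisions with fields `branch`, `normality_p`,
#'   `variance_homogeneity_p` as attributes.
#' @export
significance_pipeline <- function(data, alpha = 0.05) {
  stopifnot(all(c("concentration", "response") %in% names(data)))
  data <- data[!is.na(data$response), ]
  if (!any(data$concentration == 0))
    stop("data must include the vehicle control (concentration 0)")
  if (length(unique(data$concentration)) < 2)
    stop("need at least one non-control concentration")
  reps <- table(data$concentration)
  if (any(reps < 2))
    stop("every concentration needs >= 2 replicates (single replicate in: ",
         paste(names(reps)[reps < 2], collapse = ", "), ")")
  f <- data$response
  if (any(f < 0 | f > 1)) stop("responses must be frequencies in [0, 1]")
  zero <- f == 0
  if (any(zero)) {
    repl <- if (!is.null(data$n_binucleated))
      0.5 / pmax(data$n_binucleated[zero], 1)
    else rep(0.5 * min(f[f > 0], 1), sum(zero))
    f[zero] <- repl
  }
  y <- log10(f)
  grp <- factor(data$concentration)  # levels sorted numerically: control first
  resid <- y - ave(y, grp)
  normality_p <- tryCatch(shapiro.test(resid)$p.value, error = function(e) 0)
  bartlett_p <- tryCatch(bartlett.test(y, grp)$p.value, error = function(e) 0)
  branch <- if (normality_p > alpha && bartlett_p > alpha) "Dunnett" else "Dunn"
  res <- if (branch == "Dunnett") dunnett_test(y, grp) else dunn_test(y, grp)
  res$concentration <- as.numeric(res$group)
  res$significance <- cut(res$p_adjusted, c(-Inf, 0.001, 0.01, 0.05, Inf),
                          labels = c("***", "**", "*", ""))
  res$significance <- as.character(res$significance)
  structure(res[, c("concentration", "statistic", "p_adjusted",
                    "significance")],
            branch = branch, normality_p = normality_p,
            variance_homogeneity_p = bartlett_p,
            class = c("significance_result", "data.frame"))
}

#' @export
print.significance_result <- function(x, ...) {
  cat(sprintf("Branch: %s (Shapiro-Wilk p = %.3f, Bartlett p = %.3f)\n",
              attr(x, "branch"), attr(x, "normality_p"),
              attr(x, "variance_homogeneity_p")))
  print.data.frame(x, ...)
  invisible(x)
}
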