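# Statistical battery: min-max scaling, normality-gated group comparison,
# partial Spearman correlation with covariates, segmented regression with a
# Davies pseudo-score test, bootstrap mediation, Benjamini-Hochberg FDR.

#' Min-max normalization to [0, 1]
#'
#' Affine rescaling `(x - min) / (max - min)`. A constant vector maps to all
#' zeros with a warning.
#'
#' @param x Numeric vector of finite values.
#' @return Numeric vector in `[0, 1]`.
#' @export
minmax_normalize <- function(x) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("values must be finite")
  r <- range(x)
  if (r[1] == r[2]) {
    warning("constant input: min-max normalization returns all zeros")
    return(rep(0, length(x)))
  }
  (x - r[1]) / (r[2] - r[1])
}

#' Choose a group-comparison test via a Shapiro-Wilk gate
#'
#' The Mann-Whitney U test is selected whenever the Shapiro-Wilk test
#' rejects normality (p < `alpha`) in either group; otherwise the
#' independent t-test.
#'
#' @param x,y Numeric samples, n >= 3 each.
#' @param alpha Normality rejection level. Default 0.05.
#' @return `"t_test"` or `"mann_whitney"`.
#' @export
normality_gate <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) >= 3, length(y) >= 3)
  p_of <- function(v) {
    if (length(unique(v)) < 3) return(0)  # degenerate: treat as non-normal
    tryCatch(stats::shapiro.test(v)$p.value, error = function(e) 0)
  }
  if (p_of(x) < alpha || p_of(y) < alpha) "mann_whitney" else "t_test"
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. `U` is the number of (x, y) pairs with x ranked
#' below y minus ties/2, the same convention as `wilcox.test`'s `W` for the
#' first sample. For small tie-free samples (both n <= 25) the p-value is by
#' exact enumeration; otherwise the normal approximation with tie-corrected
#' variance and continuity correction is used. `z` is always reported from
#' the normal approximation.
#'
#' @param x,y Numeric samples, n >= 1 each.
#' @return A list with `U`, `z`, `p`, `method`.
#' @export
mann_whitney <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  mu <- n1 * n2 / 2
  sig2 <- n1 * n2 / 12 *
    ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
  z <- if (sig2 > 0) (U - mu - sign(U - mu) * 0.5) / sqrt(sig2) else 0
  has_ties <- any(ties > 1)
  if (!has_ties && n1 <= 25 && n2 <= 25) {
    p <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    method <- "exact"
  } else {
    p <- if (sig2 > 0) 2 * stats::pnorm(-abs(z)) else 1
    method <- "normal_approx"
  }
  list(U = U, z = z, p = min(p, 1), method = method)
}

#' Partial Spearman correlation with covariates
#'
#' Both variables are rank-transformed (average ranks for ties) and
#' residualized on the covariates (with intercept) by least squares; the
#' Pearson correlation of the residuals is the partial Spearman rho.
#' Significance uses a t reference with `n - 2 - k` degrees of freedom and
#' the 95% CI a Fisher z interval with sd `1 / sqrt(n - 3 - k)`, where `k`
#' is the number of covariates.
#'
#' @param x,y Numeric vectors.
#' @param covars Optional data frame / matrix of covariates.
#' @param n_min Minimum complete-case n. Default 10.
#' @return A list with `rho`, `ci95`, `p`, `n`, `covariates`; `NA` rho (with
#'   a message) when either variable has zero variance.
#' @export
partial_spearman <- function(x, y, covars = NULL, n_min = 10) {
  keep <- is.finite(x) & is.finite(y)
  if (!is.null(covars)) {
    covars <- as.data.frame(covars)
    keep <- keep & stats::complete.cases(covars)
  }
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < n_min) stop(sprintf("need at least %d complete cases, have %d",
                              n_min, n))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    message("zero-variance variable: correlation undefined")
    return(list(rho = NA_real_, ci95 = c(NA_real_, NA_real_), p = NA_real_,
                n = n, covariates = colnames(covars)))
  }
  rx <- rank(x); ry <- rank(y)
  k <- 0L
  if (!is.null(covars) && ncol(covars) > 0) {
    cc <- as.matrix(covars[keep, , drop = FALSE])
    X <- cbind(1, cc)
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      bad <- colnames(cc)[qx$pivot[seq(qx$rank + 1, ncol(X))] - 1L]
      stop("rank-deficient covariates: ", paste(bad, collapse = ", "))
    }
    rx <- stats::lm.fit(X, rx)$residuals
    ry <- stats::lm.fit(X, ry)$residuals
    k <- ncol(cc)
  }
  rho <- stats::cor(rx, ry)
  df <- n - 2 - k
  tstat <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df)
  ci <- if (n - 3 - k > 0) {
    zse <- 1 / sqrt(n - 3 - k)
    tanh(atanh(min(max(rho, -1 + 1e-15), 1 - 1e-15)) + c(-1, 1) * 1.96 * zse)
  } else c(NA_real_, NA_real_)
  list(rho = rho, ci95 = ci, p = p, n = n,
       covariates = if (k) colnames(covars) else character(0))
}

hinge <- function(x, psi) pmax(0, x - psi)

# residual sum of squares of y ~ [1, x, (x-psi)+, covars]
seg_rss <- function(x, y, C, psi) {
  X <- cbind(1, x, hinge(x, psi), C)
  sum(stats::lm.fit(X, y)$residuals^2)
}

#' Segmented (piecewise linear) regression with covariates
#'
#' Fits `y = b0 + b1 x + b2 (x - psi)+ + covariate terms`, estimating the
#' breakpoint `psi` by profiling the residual sum of squares over a quantile
#' grid of `x` followed by local golden-section refinement. The slope below
#' the breakpoint is `b1` and the combined slope above it `b1 + b2`. The
#' breakpoint CI comes from the linearization (delta-method) standard error
#' `se(gamma) / |b2|`, where `gamma` is the coefficient of the indicator
#' term `-(x > psi)` in the locally linearized model. The Davies pseudo-score
#' test supplies the p-value guarding against the breakpoint being an
#' artifact of the search.
#'
#' @param x Primary predictor.
#' @param y Response.
#' @param covars Optional covariate data frame (e.g. age, gender, BMI).
#' @param grid_n Number of profiling grid points between the 10th and 90th
#'   percentile of `x`. Default 50.
#' @return An object of class `segmented_fit`: `breakpoint`,
#'   `breakpoint_ci95`, `slope_below`, `slope_above_combined`,
#'   `slope_above_ci95`, `p_below`, `p_above`, `covariate_betas`, `r2`,
#'   `f_stat`, `f_p`, `davies_p`, `supported`, `n`.
#' @export
segmented_fit <- function(x, y, covars = NULL, grid_n = 50) {
  keep <- is.finite(x) & is.finite(y)
  if (!is.null(covars)) {
    covars <- as.data.frame(covars)
    keep <- keep & stats::complete.cases(covars)
  }
  x <- x[keep]; y <- y[keep]
  C <- if (!is.null(covars) && ncol(covars) > 0)
    as.matrix(covars[keep, , drop = FALSE]) else NULL
  n <- length(x)
  if (n < 15) stop("segmented regression needs n >= 15")

  qs <- stats::quantile(x, c(0.1, 0.9), names = FALSE)
  grid <- unique(seq(qs[1], qs[2], length.out = grid_n))
  rss <- vapply(grid, function(p) seg_rss(x, y, C, p), 0)
  j <- which.min(rss)
  lo <- grid[max(1, j - 1)]; hi <- grid[min(length(grid), j + 1)]
  psi <- if (lo < hi)
    stats::optimize(function(p) seg_rss(x, y, C, p), c(lo, hi))$minimum
  else grid[j]

  dat <- data.frame(y = y, x = x, u = hinge(x, psi))
  if (!is.null(C)) dat <- cbind(dat, as.data.frame(C))
  fit <- stats::lm(y ~ ., data = dat)
  sm <- summary(fit)
  cf <- sm$coefficients
  b1 <- cf["x", "Estimate"]; b2 <- cf["u", "Estimate"]
  V <- stats::vcov(fit)
  se_comb <- sqrt(V["x", "x"] + V["u", "u"] + 2 * V["x", "u"])
  comb <- b1 + b2
  df_res <- fit$df.residual
  p_comb <- 2 * stats::pt(-abs(comb / se_comb), df_res)
  # linearization SE for psi: refit with the indicator term V = -(x > psi)
  datV <- cbind(dat, v = -(x > psi))
  fitV <- stats::lm(y ~ ., data = datV)
  se_g <- tryCatch(summary(fitV)$coefficients["v", "Std. Error"],
                   error = function(e) NA_real_)
  se_psi <- if (is.finite(se_g) && abs(b2) > 1e-12) se_g / abs(b2)
            else NA_real_
  ci_psi <- psi + c(-1, 1) * 1.96 * se_psi
  ci_psi <- pmin(pmax(ci_psi, min(x)), max(x))

  dp <- davies_test(x, y, covars = if (is.null(C)) NULL else
                      as.data.frame(C))
  cov_betas <- if (!is.null(C))
    cf[setdiff(rownames(cf), c("(Intercept)", "x", "u")), "Estimate"]
  else numeric(0)

  structure(list(
    breakpoint = psi, breakpoint_ci95 = ci_psi,
    slope_below = b1, p_below = cf["x", "Pr(>|t|)"],
    slope_above_combined = comb,
    slope_above_ci95 = comb + c(-1, 1) * 1.96 * se_comb,
    p_above = p_comb,
    covariate_betas = cov_betas,
    r2 = sm$r.squared,
    f_stat = sm$fstatistic[["value"]],
    f_df = c(sm$fstatistic[["numdf"]], sm$fstatistic[["dendf"]]),
    f_p = stats::pf(sm$fstatistic[["value"]], sm$fstatistic[["numdf"]],
                    sm$fstatistic[["dendf"]], lower.tail = FALSE),
    davies_p = dp, supported = dp < 0.05, n = n, fit = fit),
    class = "segmented_fit")
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat(sprintf(
    paste0("<segmented_fit> n = %d\n",
           "  breakpoint psi = %.2f  (95%% CI [%.2f, %.2f])%s\n",
           "  slope below = %.4f (p = %.3f); combined slope above = %.4f ",
           "(95%% CI [%.4f, %.4f], p = %.3f)\n",
           "  R2 = %.3f, F(%d, %d) = %.2f (p = %.3f), Davies p = %.3f\n"),
    x$n, x$breakpoint, x$breakpoint_ci95[1], x$breakpoint_ci95[2],
    if (x$supported) "" else "  [breakpoint unsupported]",
    x$slope_below, x$p_below, x$slope_above_combined,
    x$slope_above_ci95[1], x$slope_above_ci95[2], x$p_above,
    x$r2, x$f_df[1], x$f_df[2], x$f_stat, x$f_p, x$davies_p))
  invisible(x)
}

#' Davies pseudo-score test for a breakpoint
#'
#' Tests the null of a purely linear relationship against a hinge
#' alternative whose breakpoint is unidentified under the null. The hinge
#' t-statistic is evaluated at `k_grid` candidate breakpoints spanning the
#' 10th-90th percentile of `x`; the p-value is the Davies upper bound for
#' the supremum of the correlated statistics,
#' `2 * P(T > M) + V * f_T(M)`, where `M` is the largest absolute
#' statistic, `V` the total variation of the statistic across the grid and
#' `f_T` the density of the per-point t reference distribution. The bound
#' is conservative by construction.
#'
#' @param x,y Predictor and response.
#' @param covars Optional covariate data frame.
#' @param k_grid Number of candidate breakpoints. Default 10.
#' @return A p-value in (0, 1].
#' @export
davies_test <- function(x, y, covars = NULL, k_grid = 10) {
  keep <- is.finite(x) & is.finite(y)
  if (!is.null(covars)) {
    covars <- as.data.frame(covars)
    keep <- keep & stats::complete.cases(covars)
  }
  x <- x[keep]; y <- y[keep]
  C <- if (!is.null(covars) && ncol(covars) > 0)
    as.matrix(covars[keep, , drop = FALSE]) else NULL
  n <- length(x)
  qs <- stats::quantile(x, c(0.1, 0.9), names = FALSE)
  grid <- unique(seq(qs[1], qs[2], length.out = k_grid))
  grid <- grid[vapply(grid, function(p)
    sum(x > p) >= 2 && sum(x <= p) >= 2, TRUE)]
  if (length(grid) < 2) return(1)
  tstat <- vapply(grid, function(p) {
    X <- cbind(1, x, hinge(x, p), C)
    f <- stats::lm.fit(X, y)
    dfr <- n - ncol(X)
    s2 <- sum(f$residuals^2) / dfr
    R <- qr.R(f$qr)
    XtXinv <- chol2inv(R)
    se <- sqrt(s2 * XtXinv[3, 3])
    f$coefficients[3] / se
  }, 0)
  tstat <- tstat[is.finite(tstat)]
  if (length(tstat) < 2) return(1)
  M <- max(abs(tstat))
  Vtot <- sum(abs(diff(tstat)))
  dfr <- n - 3 - if (is.null(C)) 0 else ncol(C)
  # two-sided Davies bound; the upcrossing correction uses the t density,
  # matching the t reference of the per-breakpoint score statistics
  p <- 2 * stats::pt(-M, dfr) + Vtot * stats::dt(M, dfr)
  min(max(p, .Machine$double.xmin), 1)
}

#' Bootstrap mediation analysis
#'
#' OLS path analysis on z-scored complete cases: path `a` (x -> m given
#' covariates), paths `b` and direct `c'` (m and x -> y), total `c`
#' (x -> y). The indirect effect is `a * b`; confidence intervals are
#' percentile bootstrap over case resampling. For linear models the identity
#' `total = direct + indirect` holds exactly for the point estimates.
#'
#' @param x Predictor.
#' @param m Mediator.
#' @param y Outcome.
#' @param covars Optional covariate data frame.
#' @param n_boot Bootstrap resamples. Default 5000.
#' @param seed Integer seed for the resampling.
#' @param ci_type `"percentile"` (default) or `"bc"` (bias-corrected).
#' @return An object of class `mediation_result` with `indirect`,
#'   `indirect_ci95`, `direct`, `direct_ci95`, `path_a`, `path_b`, `total`,
#'   `n`, `n_boot`, `seed`, `n_degenerate_redrawn`.
#' @export
mediation_bootstrap <- function(x, m, y, covars = NULL, n_boot = 5000,
                                seed = 1, ci_type = c("percentile", "bc")) {
  ci_type <- match.arg(ci_type)
  keep <- is.finite(x) & is.finite(m) & is.finite(y)
  if (!is.null(covars)) {
    covars <- as.data.frame(covars)
    keep <- keep & stats::complete.cases(covars)
  }
  x <- x[keep]; m <- m[keep]; y <- y[keep]
  n <- length(x)
  if (n < 20) stop("mediation needs n >= 20 complete cases")
  zs <- function(v) (v - mean(v)) / stats::sd(v)
  x <- zs(x); m <- zs(m); y <- zs(y)
  C <- if (!is.null(covars) && ncol(covars) > 0)
    scale(as.matrix(covars[keep, , drop = FALSE])) else NULL

  paths <- function(xi, mi, yi, Ci) {
    Xa <- cbind(1, xi, Ci)
    a <- stats::lm.fit(Xa, mi)$coefficients[2]
    Xb <- cbind(1, mi, xi, Ci)
    fb <- stats::lm.fit(Xb, yi)$coefficients
    b <- fb[2]; cprime <- fb[3]
    tot <- stats::lm.fit(Xa, yi)$coefficients[2]
    c(a = unname(a), b = unname(b), direct = unname(cprime),
      total = unname(tot), indirect = unname(a * b))
  }
  pt_est <- paths(x, m, y, C)

  old <- local_seed(seed); on.exit(restore_seed(old))
  boot <- matrix(NA_real_, n_boot, 2,
                 dimnames = list(NULL, c("indirect", "direct")))
  n_redrawn <- 0L
  for (bi in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::sd(x[idx]) > 0 && stats::sd(m[idx]) > 0 &&
          stats::sd(y[idx]) > 0) break
      n_redrawn <- n_redrawn + 1L
    }
    pb <- paths(x[idx], m[idx], y[idx],
                if (is.null(C)) NULL else C[idx, , drop = FALSE])
    boot[bi, ] <- pb[c("indirect", "direct")]
  }
  ci <- function(v, est) {
    if (ci_type == "percentile")
      stats::quantile(v, c(0.025, 0.975), names = FALSE)
    else {
      z0 <- stats::qnorm(mean(v < est))
      a <- stats::pnorm(2 * z0 + stats::qnorm(c(0.025, 0.975)))
      stats::quantile(v, a, names = FALSE)
    }
  }
  structure(list(
    indirect = pt_est[["indirect"]],
    indirect_ci95 = ci(boot[, "indirect"], pt_est[["indirect"]]),
    direct = pt_est[["direct"]],
    direct_ci95 = ci(boot[, "direct"], pt_est[["direct"]]),
    path_a = pt_est[["a"]], path_b = pt_est[["b"]],
    total = pt_est[["total"]], n = n, n_boot = n_boot, seed = seed,
    n_degenerate_redrawn = n_redrawn),
    class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(
    paste0("<mediation_result> n = %d, %d resamples (seed %d)\n",
           "  indirect = %.3f [%.3f, %.3f]; direct = %.3f [%.3f, %.3f]; ",
           "total = %.3f\n"),
    x$n, x$n_boot, x$seed, x$indirect, x$indirect_ci95[1],
    x$indirect_ci95[2], x$direct, x$direct_ci95[1], x$direct_ci95[2],
    x$total))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone in the raw p ranks and capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
fdr_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
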