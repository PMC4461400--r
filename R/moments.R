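#' Bootstrap moment summary of a per-cell expression distribution
#'
#' Computes mean, variance, CV and Fano factor of a vector of per-cell
#' measurements, with 95% confidence intervals taken as the 2.5% and 97.5%
#' quantiles of `B` resampled-with-replacement statistics (percentile
#' bootstrap).
#'
#' @param values numeric vector of per-cell measurements (length >= 2).
#' @param B number of bootstrap replicates (>= 100).
#' @param seed integer seed.
#' @param clone_id identifier carried into the summary.
#' @return A one-row data.frame (class `moment_summary`) with columns
#'   `clone_id`, `n`, `mean`, `variance`, `cv`, `fano`, matching `_lo` / `_hi`
#'   CI columns, and `degenerate` (`TRUE` when the mean is zero and CV/Fano
#'   are undefined).
#' @export
bootstrap_moments <- function(values, B = 1000, seed = 1L,
                              clone_id = "clone") {
  n <- length(values)
  if (n < 2) stop("need at least 2 values")
  if (B < 100) stop("B must be >= 100")
  degenerate <- mean(values) == 0
  stat <- function(x) {
    m <- mean(x); v <- stats::var(x)
    c(mean = m, variance = v,
      cv = if (m > 0) sqrt(v) / m else NA_real_,
      fano = if (m > 0) v / m else NA_real_)
  }
  pt <- stat(values)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  boot <- matrix(NA_real_, B, 4)
  for (i in seq_len(B))
    boot[i, ] <- stat(values[sample.int(n, n, replace = TRUE)])
  q <- apply(boot, 2, stats::quantile, probs = c(0.025, 0.975), na.rm = TRUE)
  out <- data.frame(clone_id = clone_id, n = n,
                    mean = pt[1], variance = pt[2], cv = pt[3], fano = pt[4],
                    mean_lo = q[1, 1], mean_hi = q[2, 1],
                    variance_lo = q[1, 2], variance_hi = q[2, 2],
                    cv_lo = q[1, 3], cv_hi = q[2, 3],
                    fano_lo = q[1, 4], fano_hi = q[2, 4],
                    degenerate = degenerate, row.names = NULL)
  class(out) <- c("moment_summary", "data.frame")
  out
}

#' Moment summaries for every clone in a cohort
#'
#' @param counts_df tidy counts table (`clone_id`, `cell_id`, `count`), a list
#'   of `count_distribution`s, or a flow-event table with a `gfp` column when
#'   `channel = "gfp"`.
#' @param B bootstrap replicates per clone; `B = 0` skips CIs (fast path).
#' @param seed integer seed (per-clone seeds are spawned deterministically).
#' @param channel `"count"` (default) or the name of a column to summarize.
#' @return data.frame of per-clone moment summaries.
#' @export
cohort_moments <- function(counts_df, B = 0, seed = 1L, channel = "count") {
  if (is.data.frame(counts_df)) {
    stopifnot(all(c("clone_id", channel) %in% names(counts_df)))
    values <- split(counts_df[[channel]], counts_df$clone_id)
  } else {
    dists <- as_count_list(counts_df)
    values <- lapply(dists, `[[`, "counts")
    names(values) <- vapply(dists, `[[`, character(1), "clone_id")
  }
  ids <- names(values)
  if (B > 0) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(seed)
    seeds <- sample.int(.Machine$integer.max - 1L, length(ids))
    rows <- mapply(function(v, id, s) bootstrap_moments(v, B, s, id),
                   values, ids, seeds, SIMPLIFY = FALSE)
  } else {
    rows <- mapply(function(v, id) {
      m <- mean(v); va <- stats::var(v)
      data.frame(clone_id = id, n = length(v), mean = m, variance = va,
                 cv = if (m > 0) sqrt(va) / m else NA_real_,
                 fano = if (m > 0) va / m else NA_real_,
                 degenerate = m == 0)
    }, values, ids, SIMPLIFY = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Log-log linear regression with Spearman correlation
#'
#' Ordinary least squares of `log10(y)` on `log10(x)`, the workhorse for
#' power-law scaling analyses (variance vs mean, CV vs burst frequency,
#' kinetics vs chromatin accessibility). The Spearman rank correlation is
#' computed on the untransformed values with average-rank ties; its p-value
#' uses the t approximation (exact for n < 10 when there are no ties). The
#' slope p-value is the two-sided t-test against slope zero.
#'
#' @param x,y strictly positive numeric vectors of equal length >= 3.
#' @return A `loglog_fit` object: list with `slope`, `intercept`, `slope_se`,
#'   `slope_ci` (95%), `r_squared`, `spearman_rs`, `p_slope`, `p_spearman`,
#'   `n`, `df`, and the underlying `lm` fit.
#' @examples
#' fit <- loglog_regression(1:10, (1:10)^2)
#' fit$slope # 2
#' @export
loglog_regression <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 points")
  bad <- which(!(x > 0) | !(y > 0))
  if (length(bad))
    stop("non-positive values at indices: ", paste(bad, collapse = ", "))
  lx <- log10(x); ly <- log10(y)
  if (stats::var(lx) == 0) stop("x has zero variance on the log scale")
  fit <- stats::lm(ly ~ lx)
  # exact power laws are legitimate inputs; silence the perfect-fit notice
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  slope <- co[2, 1]; se <- co[2, 2]
  r2 <- if (stats::var(ly) == 0) 0 else sm$r.squared
  df <- fit$df.residual
  tcrit <- stats::qt(0.975, df)
  sp <- spearman_test(x, y)
  structure(list(
    slope = slope, intercept = co[1, 1], slope_se = se,
    slope_ci = c(slope - tcrit * se, slope + tcrit * se),
    r_squared = r2,
    spearman_rs = sp$rs, p_slope = co[2, 4], p_spearman = sp$p,
    n = length(x), df = df, lm_fit = fit),
    class = "loglog_fit")
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf(
    "log-log OLS: slope %.3f +/- %.3f (95%% CI %.3f..%.3f), R2 = %.3f\n",
    x$slope, x$slope_se, x$slope_ci[1], x$slope_ci[2], x$r_squared))
  cat(sprintf("  Spearman rs = %.3f, p_slope = %.3g, p_spearman = %.3g, n = %d\n",
              x$spearman_rs, x$p_slope, x$p_spearman, x$n))
  invisible(x)
}

# Spearman correlation with average-rank ties; exact permutation p (via
# cor.test's AS89 path) for n < 10 without ties, t approximation otherwise.
spearman_test <- function(x, y) {
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rs = NA_real_, p = NA_real_))
  rs <- stats::cor(rank(x), rank(y))
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n < 10 && !ties) {
    ct <- stats::cor.test(x, y, method = "spearman", exact = TRUE)
    return(list(rs = unname(ct$estimate), p = ct$p.value))
  }
  if (abs(rs) >= 1) return(list(rs = rs, p = 0))
  tstat <- rs * sqrt((n - 2) / (1 - rs^2))
  list(rs = rs, p = 2 * stats::pt(-abs(tstat), n - 2))
}

#' Test a fitted log-log slope against a null value
#'
#' Two-sided t-test of the regression slope against `null_slope`, used e.g.
#' to test the observed variance-mean scaling exponent against the Poisson
#' null of 1.
#'
#' @param fit a `loglog_fit`.
#' @param null_slope slope under the null hypothesis.
#' @return Two-sided p-value.
#' @export
slope_test <- function(fit, null_slope) {
  stopifnot(inherits(fit, "loglog_fit"))
  if (fit$df < 1) stop("no residual degrees of freedom")
  if (fit$slope_se == 0 || fit$r_squared >= 1 - 1e-12) {
    if (isTRUE(all.equal(fit$slope, null_slope))) return(1)
    stop("degenerate fit: zero residual variance with slope != null")
  }
  tstat <- (fit$slope - null_slope) / fit$slope_se
  2 * stats::pt(-abs(tstat), fit$df)
}

#' F-test comparing a subset's log-log trend with the full set's
#'
#' Nested-model F-test on the pooled data: the full model allows a separate
#' intercept and slope for the subset (group indicator and group-by-log10(x)
#' interaction); the reduced model fits a common line. A non-significant p
#' indicates the subset's scaling trend is statistically indistinguishable
#' from the full set's.
#'
#' @param x_sub,y_sub subset data (strictly positive).
#' @param x_full,y_full full-set data (strictly positive).
#' @return List with `p`, `f_statistic`, `identical` (`TRUE`, with `p = 1`,
#'   when subset and full set are the same data).
#' @export
compare_regressions_ftest <- function(x_sub, y_sub, x_full, y_full) {
  if (length(x_sub) == length(x_full) &&
      all(sort(x_sub) == sort(x_full)) && all(sort(y_sub) == sort(y_full)))
    return(list(p = 1, f_statistic = 0, identical = TRUE))
  lx <- log10(c(x_sub, x_full)); ly <- log10(c(y_sub, y_full))
  if (any(!is.finite(lx)) || any(!is.finite(ly)))
    stop("all values must be strictly positive")
  g <- factor(rep(c("subset", "full"), c(length(x_sub), length(x_full))))
  full_model <- stats::lm(ly ~ lx * g)
  reduced <- stats::lm(ly ~ lx)
  a <- stats::anova(reduced, full_model)
  list(p = a[2, "Pr(>F)"], f_statistic = a[2, "F"], identical = FALSE)
}

#' Poisson reference scaling lines
#'
#' For a Poisson process, variance equals the mean (log-log slope 1) and the
#' CV is the inverse square root of the mean (log-log slope -1/2). Used as
#' the null reference overlay for scaling plots and tests.
#'
#' @param means strictly positive vector of mean expression values.
#' @return List with `variance_line` and `cv_line` evaluated at `means`.
#' @export
poisson_reference <- function(means) {
  if (any(means <= 0)) stop("means must be strictly positive")
  list(variance_line = means, cv_line = 1 / sqrt(means))
}
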