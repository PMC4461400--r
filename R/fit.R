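#' Negative log-likelihood of burst parameters given per-cell counts
#'
#' Evaluates `-sum(log p(n_i))` under the stationary telegraph law with
#' `alpha = f`, `beta = lam / b`, `lam` fixed (time measured in units of the
#' mRNA degradation rate, `delta = 1`). Evaluation is in log space throughout;
#' repeated counts are tabulated so the pmf is computed once per unique copy
#' number.
#'
#' @param b burst size (> 0).
#' @param f burst frequency / normalized On rate (> 0).
#' @param lam fixed transcription rate in degradation units (> 0).
#' @param counts a `count_distribution` or integer vector.
#' @return The negative log-likelihood (finite for valid parameters).
#' @export
neg_log_likelihood <- function(b, f, lam, counts) {
  if (inherits(counts, "count_distribution")) counts <- counts$counts
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (b <= 0 || f <= 0 || lam <= 0) stop("b, f and lam must be positive")
  nll <- bp_nll_cpp(as.integer(counts), f, lam / b, lam)
  if (!is.finite(nll)) {
    # quadrature fallback for any pmf value the series path could not produce
    params <- telegraph_from_bursts(b, f, lam)
    nll <- -sum(tabulate_counts(counts)$weight *
                  telegraph_log_pmf(tabulate_counts(counts)$n, params))
  }
  nll
}

tabulate_counts <- function(counts) {
  tab <- table(counts)
  list(n = as.integer(names(tab)), weight = as.vector(tab))
}

# log10-parameter bounds for the optimizer
.fit_bounds <- list(log10_b = c(-2, 4), log10_f = c(-3, 3))

#' Fit burst size and burst frequency to a count distribution by ML
#'
#' Minimizes the negative log-likelihood over `(log10 b, log10 f)` with the
#' transcription rate `lam` held fixed and time measured in degradation-rate
#' units. Initialization is by method of moments (in the bursty regime
#' `CV^2 ~ (1/f)(1 + 1/b)` and `Fano ~ 1 + b`), plus jittered restarts; the
#' reported optimum is the best across all starts. 95% profile-likelihood
#' confidence intervals are attached via [profile_ci()] unless disabled.
#'
#' @param counts a `count_distribution` or integer vector.
#' @param delta measured mRNA degradation rate; enters only through the units
#'   of the reported burst frequency (`k_on = f * delta`), not the fit itself.
#' @param lam fixed transcription rate in degradation units.
#' @param n_starts number of optimizer starts (method-of-moments start plus
#'   `n_starts - 1` jittered restarts).
#' @param compute_ci compute profile-likelihood CIs (default `TRUE`).
#' @param seed seed for the jittered restarts.
#' @return A `burst_fit` object: list with `clone_id`, `burst_size_hat`,
#'   `burst_freq_hat`, `lam`, `delta`, `nll`, `converged`, `boundary`,
#'   `ci_b`, `ci_f`, `n_cells`.
#' @export
fit_clone <- function(counts, delta = 1, lam = 1000, n_starts = 5,
                      compute_ci = TRUE, seed = 1L) {
  clone_id <- if (inherits(counts, "count_distribution")) counts$clone_id
              else "clone"
  if (inherits(counts, "count_distribution")) counts <- counts$counts
  if (any(counts != round(counts)) || any(counts < 0))
    stop("counts must be non-negative integers")
  counts <- as.integer(counts)
  n <- length(counts)
  if (n < 30) warning("fewer than 30 cells; estimates will be unstable")
  if (all(counts == 0)) {
    return(structure(list(
      clone_id = clone_id, burst_size_hat = 10^.fit_bounds$log10_b[1],
      burst_freq_hat = 10^.fit_bounds$log10_f[1], lam = lam, delta = delta,
      nll = 0, converged = FALSE, boundary = TRUE,
      ci_b = c(NA_real_, NA_real_), ci_f = c(NA_real_, NA_real_),
      n_cells = n), class = "burst_fit"))
  }

  mu <- mean(counts); v <- stats::var(counts)
  fano <- v / mu; cv2 <- v / mu^2
  b0 <- max(fano - 1, 0.1)
  f0 <- max((1 + 1 / b0) / cv2, 1e-3)
  start0 <- c(clamp(log10(b0), .fit_bounds$log10_b),
              clamp(log10(f0), .fit_bounds$log10_f))

  obj <- function(theta) {
    if (theta[1] < .fit_bounds$log10_b[1] || theta[1] > .fit_bounds$log10_b[2] ||
        theta[2] < .fit_bounds$log10_f[1] || theta[2] > .fit_bounds$log10_f[2])
      return(1e10 + 1e6 * sum(pmax(0, abs(theta) - 4)^2))
    neg_log_likelihood(10^theta[1], 10^theta[2], lam, counts)
  }

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  starts <- list(start0)
  for (i in seq_len(n_starts - 1))
    starts[[i + 1]] <- c(
      clamp(start0[1] + stats::rnorm(1, 0, 0.5), .fit_bounds$log10_b),
      clamp(start0[2] + stats::rnorm(1, 0, 0.5), .fit_bounds$log10_f))

  best <- NULL
  start_nll <- vapply(starts, obj, numeric(1))
  for (s in starts) {
    fit <- stats::optim(s, obj, method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  theta <- best$par
  boundary <-
    min(abs(theta[1] - .fit_bounds$log10_b),
        abs(theta[2] - .fit_bounds$log10_f)) < 1e-3
  res <- structure(list(
    clone_id = clone_id,
    burst_size_hat = 10^theta[1],
    burst_freq_hat = 10^theta[2],
    lam = lam, delta = delta,
    nll = best$value,
    converged = best$value <= min(start_nll) + 1e-6 && is.finite(best$value),
    boundary = boundary,
    ci_b = c(NA_real_, NA_real_), ci_f = c(NA_real_, NA_real_),
    n_cells = n), class = "burst_fit")
  if (compute_ci && res$converged) {
    ci <- profile_ci(res, counts)
    res$ci_b <- ci$ci_b
    res$ci_f <- ci$ci_f
    res$ci_open <- ci$open
  }
  res
}

clamp <- function(x, bounds) pmin(pmax(x, bounds[1]), bounds[2])

#' @export
print.burst_fit <- function(x, ...) {
  cat(sprintf("Burst-parameter fit '%s' (%d cells)\n", x$clone_id, x$n_cells))
  cat(sprintf("  burst size  b = %.3g  [%.3g, %.3g]\n", x$burst_size_hat,
              x$ci_b[1], x$ci_b[2]))
  cat(sprintf("  burst freq  f = %.3g  [%.3g, %.3g]\n", x$burst_freq_hat,
              x$ci_f[1], x$ci_f[2]))
  cat(sprintf("  NLL = %.4f, converged = %s, boundary = %s\n", x$nll,
              x$converged, x$boundary))
  invisible(x)
}

#' Profile-likelihood confidence intervals for fitted burst parameters
#'
#' For each parameter in turn, the other is re-optimized at every profile
#' point and the CI endpoints are located where the profile negative
#' log-likelihood rises `llr_offset` units above the optimum. The default
#' offset, 1.92, is half the 0.95 quantile of the chi-square distribution with
#' one degree of freedom, giving asymptotic 95% intervals. Brackets are
#' expanded geometrically; an endpoint that never reaches the offset within
#' the parameter bounds is returned at the bound and flagged open.
#'
#' @param fit a converged `burst_fit`.
#' @param counts the counts the fit was computed from.
#' @param llr_offset log-likelihood-ratio offset defining the interval.
#' @param tol tolerance on the achieved `|delta NLL - llr_offset|`.
#' @return List with `ci_b`, `ci_f` (each `c(lower, upper)`) and `open`, a
#'   logical vector flagging open-ended endpoints.
#' @export
profile_ci <- function(fit, counts, llr_offset = 1.92, tol = 1e-3) {
  stopifnot(inherits(fit, "burst_fit"))
  if (!fit$converged) stop("profile_ci requires a converged fit")
  if (inherits(counts, "count_distribution")) counts <- counts$counts
  lam <- fit$lam
  theta_hat <- c(log10(fit$burst_size_hat), log10(fit$burst_freq_hat))
  nll_hat <- fit$nll
  open <- c(b_lo = FALSE, b_hi = FALSE, f_lo = FALSE, f_hi = FALSE)

  prof <- function(which, value) {
    # re-optimize the nuisance parameter at a fixed profile point
    bounds <- if (which == 1) .fit_bounds$log10_f else .fit_bounds$log10_b
    f1 <- function(other) {
      th <- if (which == 1) c(value, other) else c(other, value)
      neg_log_likelihood(10^th[1], 10^th[2], lam, counts)
    }
    stats::optimize(f1, bounds, tol = 1e-5)$objective
  }

  one_side <- function(which, dir) {
    bound <- if (which == 1) .fit_bounds$log10_b else .fit_bounds$log10_f
    limit <- if (dir < 0) bound[1] else bound[2]
    g <- function(v) prof(which, v) - nll_hat - llr_offset
    step <- 0.25
    lo <- theta_hat[which]
    repeat {
      hi <- lo + dir * step
      if ((dir < 0 && hi <= limit) || (dir > 0 && hi >= limit)) {
        if (g(limit) < 0) return(list(v = limit, open = TRUE))
        hi <- limit
        break
      }
      if (g(hi) > 0) break
      lo <- hi
      step <- step * 2
    }
    r <- stats::uniroot(g, sort(c(lo, hi)), tol = 1e-5)
    # tighten until the achieved offset matches to tolerance
    if (abs(r$f.root) > tol)
      r <- stats::uniroot(g, sort(c(lo, hi)), tol = 1e-7)
    list(v = r$root, open = FALSE)
  }

  b_lo <- one_side(1, -1); b_hi <- one_side(1, +1)
  f_lo <- one_side(2, -1); f_hi <- one_side(2, +1)
  open[] <- c(b_lo$open, b_hi$open, f_lo$open, f_hi$open)
  list(ci_b = c(10^b_lo$v, 10^b_hi$v),
       ci_f = c(10^f_lo$v, 10^f_hi$v),
       open = open)
}

#' Fit every clone in a cohort and summarize the kinetics cross-correlations
#'
#' Batch driver: fits each clone's counts by maximum likelihood, joins the
#' per-clone sample moments, and computes the four cross-regressions relating
#' fitted kinetics to expression moments (burst size vs mean, burst frequency
#' vs mean, burst size vs CV, burst frequency vs CV), each as a
#' log-log regression. Per-clone failures are recorded in the `error` column
#' and the batch continues.
#'
#' @param counts_df data.frame with columns `clone_id`, `cell_id`, `count`
#'   (the counts-table layout), or a list of `count_distribution`s.
#' @param delta measured degradation rate.
#' @param lam fixed transcription rate in degradation units.
#' @param compute_ci compute per-clone profile CIs (slower).
#' @param seed seed forwarded to the per-clone optimizer restarts.
#' @return List with `fits` (one row per clone: estimates, CIs, flags, sample
#'   moments) and `regressions` (named list of [loglog_regression()] results).
#' @export
fit_cohort <- function(counts_df, delta = 1, lam = 1000, compute_ci = FALSE,
                       seed = 1L) {
  dists <- as_count_list(counts_df)
  if (length(dists) < 1) stop("at least one clone required")
  rows <- lapply(dists, function(d) {
    fit <- tryCatch(
      fit_clone(d, delta = delta, lam = lam, compute_ci = compute_ci,
                seed = seed),
      error = function(e) e)
    if (inherits(fit, "error"))
      return(data.frame(clone_id = d$clone_id, burst_size_hat = NA,
                        burst_freq_hat = NA, nll = NA, converged = FALSE,
                        boundary = NA, ci_b_lo = NA, ci_b_hi = NA,
                        ci_f_lo = NA, ci_f_hi = NA, n_cells = length(d$counts),
                        mean = mean(d$counts), cv = NA,
                        error = conditionMessage(fit)))
    mu <- mean(d$counts)
    data.frame(clone_id = d$clone_id, burst_size_hat = fit$burst_size_hat,
               burst_freq_hat = fit$burst_freq_hat, nll = fit$nll,
               converged = fit$converged, boundary = fit$boundary,
               ci_b_lo = fit$ci_b[1], ci_b_hi = fit$ci_b[2],
               ci_f_lo = fit$ci_f[1], ci_f_hi = fit$ci_f[2],
               n_cells = length(d$counts), mean = mu,
               cv = stats::sd(d$counts) / mu, error = NA_character_)
  })
  fits <- do.call(rbind, rows)
  ok <- fits$converged & !is.na(fits$burst_size_hat) & fits$mean > 0 &
    is.finite(fits$cv) & fits$cv > 0
  regressions <- NULL
  if (sum(ok) >= 3) {
    f <- fits[ok, ]
    regressions <- list(
      b_vs_mean  = loglog_regression(f$burst_size_hat, f$mean),
      f_vs_mean  = loglog_regression(f$burst_freq_hat, f$mean),
      b_vs_cv    = loglog_regression(f$burst_size_hat, f$cv),
      f_vs_cv    = loglog_regression(f$burst_freq_hat, f$cv),
      cv_vs_f    = loglog_regression(f$burst_freq_hat, f$cv))
  }
  list(fits = fits, regressions = regressions)
}

# accept either the tidy counts table or a list of count_distribution objects
as_count_list <- function(counts) {
  if (inherits(counts, "count_distribution")) return(list(counts))
  if (is.data.frame(counts)) {
    stopifnot(all(c("clone_id", "count") %in% names(counts)))
    by_clone <- split(counts$count, counts$clone_id)
    return(mapply(count_distribution, names(by_clone), by_clone,
                  SIMPLIFY = FALSE, USE.NAMES = FALSE))
  }
  stopifnot(all(vapply(counts, inherits, logical(1), "count_distribution")))
  counts
}

#' Estimate the mRNA degradation rate from a qPCR decay time course
#'
#' After transcription is blocked, target abundance relative to a stable
#' reference transcript decays exponentially. Per timepoint the relative
#' abundance is `2^-(Ct_target - Ct_reference)` (triplicates averaged on the
#' Ct scale), normalized to the `t = 0` value; ordinary least squares of
#' `ln(abundance)` on time gives `delta = -slope` and
#' `half-life = ln(2) / delta`.
#'
#' @param timecourse data.frame with columns `time`, `series` (`"treated"` or
#'   `"untreated"`), `target` (`"target"` or `"reference"`), `replicate`, `Ct`.
#' @param series which series to fit (default `"treated"`).
#' @return List with `delta`, `half_life`, `slope_se`, `r_squared`, `flagged`
#'   (`TRUE` when the estimated decay is non-positive, in which case
#'   `half_life` is `NA`).
#' @export
estimate_degradation_rate <- function(timecourse, series = "treated") {
  tc <- timecourse[timecourse$series == series, ]
  if (!all(c("time", "target", "Ct") %in% names(tc)))
    stop("timecourse must have columns time, series, target, replicate, Ct")
  times <- sort(unique(tc$time))
  if (length(times) < 3) stop("need at least 3 timepoints")
  if (!any(tc$target == "reference")) stop("reference series required")
  dct <- vapply(times, function(t) {
    mean(tc$Ct[tc$time == t & tc$target == "target"]) -
      mean(tc$Ct[tc$time == t & tc$target == "reference"])
  }, numeric(1))
  rel <- 2^(-(dct - dct[1])) # relative abundance normalized to t = 0
  fit <- stats::lm(log(rel) ~ times)
  sm <- suppressWarnings(summary(fit)) # noise-free series fit exactly
  delta <- -unname(stats::coef(fit)[2])
  flagged <- delta <= 0
  list(delta = delta,
       half_life = if (flagged) NA_real_ else log(2) / delta,
       slope_se = sm$coefficients[2, 2],
       r_squared = sm$r.squared,
       flagged = flagged)
}
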