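#' Kinetic parameters of the two-state (telegraph) transcription model
#'
#' The telegraph model describes a promoter switching stochastically between a
#' silent Off state and a productive On state. mRNA is transcribed at rate
#' `k_m` only while On and degrades first-order at rate `delta`. The
#' constructor validates the rates and precomputes the derived quantities used
#' throughout the package:
#' \describe{
#'   \item{`alpha`}{`k_on / delta` — Off-to-On rate in degradation units; also
#'     the burst frequency / normalized On rate `f`.}
#'   \item{`beta`}{`k_off / delta` — On-to-Off rate in degradation units.}
#'   \item{`lam`}{`k_m / delta` — transcription rate in degradation units.}
#'   \item{`burst_size`}{`b = k_m / k_off` — mean transcripts per On episode.}
#'   \item{`burst_freq`}{`f = k_on / delta` — bursts per mRNA lifetime.}
#' }
#' All derived quantities are dimensionless, so rescaling every rate by a
#' common factor (a change of time unit) leaves them unchanged.
#'
#' @param k_on promoter Off-to-On rate (per unit time), >= 0.
#' @param k_off promoter On-to-Off rate (per unit time), >= 0.
#' @param k_m transcription rate while On (transcripts per unit time), >= 0.
#' @param delta mRNA degradation rate (per unit time), > 0.
#' @return An object of class `telegraph_params`.
#' @examples
#' tp <- telegraph_params(k_on = 0.5, k_off = 100, k_m = 1000, delta = 1)
#' tp$burst_size # 10
#' tp$burst_freq # 0.5
#' @export
telegraph_params <- function(k_on, k_off, k_m, delta) {
  rates <- c(k_on = k_on, k_off = k_off, k_m = k_m, delta = delta)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates must be finite and non-negative")
  if (delta <= 0) stop("delta must be strictly positive")
  structure(
    list(
      k_on = k_on, k_off = k_off, k_m = k_m, delta = delta,
      alpha = k_on / delta, beta = k_off / delta, lam = k_m / delta,
      burst_size = if (k_off > 0) k_m / k_off else Inf,
      burst_freq = k_on / delta,
      burst_period = if (k_on > 0) delta / k_on else Inf
    ),
    class = "telegraph_params"
  )
}

#' Construct telegraph parameters from burst size and burst frequency
#'
#' The effective parameterization used for fitting: with `delta = 1` defining
#' the time unit and the transcription rate `lam` fixed, burst size `b` sets
#' `k_off = lam / b` and burst frequency `f` sets `k_on = f`.
#'
#' @param b burst size (transcripts per burst), > 0.
#' @param f burst frequency (per mRNA lifetime), > 0.
#' @param lam transcription rate in degradation units, > 0.
#' @param delta degradation rate; defaults to 1 (the internal time unit).
#' @return A `telegraph_params` object.
#' @export
telegraph_from_bursts <- function(b, f, lam, delta = 1) {
  if (b <= 0 || f <= 0 || lam <= 0) stop("b, f and lam must be positive")
  telegraph_params(k_on = f * delta, k_off = lam * delta / b,
                   k_m = lam * delta, delta = delta)
}

#' @export
print.telegraph_params <- function(x, ...) {
  cat("Telegraph model parameters\n")
  cat(sprintf("  k_on = %g, k_off = %g, k_m = %g, delta = %g\n",
              x$k_on, x$k_off, x$k_m, x$delta))
  cat(sprintf("  burst size b = %g, burst frequency f = %g, lam = %g\n",
              x$burst_size, x$burst_freq, x$lam))
  invisible(x)
}

#' Log stationary pmf of the telegraph model at given copy numbers
#'
#' Evaluates the exact stationary law (the beta-Poisson mixture) at the
#' requested mRNA copy numbers. The primary path is a log-space evaluation of
#' the confluent-hypergeometric closed form via an all-positive term
#' recurrence (Kummer-transformed, so no cancellation); if that path ever
#' fails to converge the value is recomputed by adaptive quadrature of the
#' beta-Poisson integral.
#'
#' @param n vector of non-negative integer copy numbers.
#' @param params a `telegraph_params` object.
#' @return Numeric vector of log probabilities.
#' @export
telegraph_log_pmf <- function(n, params) {
  stopifnot(inherits(params, "telegraph_params"))
  if (any(n < 0) || any(n != round(n))) stop("n must be non-negative integers")
  lp <- bp_log_pmf_cpp(as.integer(n), params$alpha, params$beta, params$lam)
  bad <- is.na(lp)
  if (any(bad)) lp[bad] <- vapply(n[bad], bp_log_pmf_quad,
                                  numeric(1), params = params)
  lp
}

# quadrature fallback: log integral of dpois(n, lam*x) dbeta(x, alpha, beta),
# computed with the integrand scaled by its maximum for stability
bp_log_pmf_quad <- function(n, params) {
  a <- params$alpha; b <- params$beta; lam <- params$lam
  f_log <- function(x) stats::dpois(n, lam * x, log = TRUE) +
    stats::dbeta(x, a, b, log = TRUE)
  opt <- stats::optimize(f_log, c(1e-12, 1 - 1e-12), maximum = TRUE)
  m <- opt$objective
  val <- stats::integrate(function(x) exp(f_log(x) - m), 0, 1,
                          rel.tol = 1e-10, subdivisions = 500L)$value
  m + log(val)
}

#' Stationary distribution of mRNA copy number under the telegraph model
#'
#' Returns the stationary pmf over `n = 0..N`, with the truncation point `N`
#' chosen so that the omitted upper tail has mass below `tail_tol`. The
#' truncated vector is renormalized to sum to one.
#'
#' @param params a `telegraph_params` object.
#' @param tail_tol maximum tail mass omitted by truncation (0 < tail_tol < 1).
#' @param n_max optional hard cap on the support size.
#' @return Numeric vector of probabilities named by copy number, with
#'   attributes `N` (truncation point) and `tail_mass` (mass beyond `N`).
#' @examples
#' tp <- telegraph_params(1, 1, 10, 1)
#' p <- stationary_pmf(tp)
#' p[["0"]] # (1 - exp(-10)) / 10
#' @export
stationary_pmf <- function(params, tail_tol = 1e-10, n_max = 100000L) {
  stopifnot(inherits(params, "telegraph_params"))
  if (!is.finite(tail_tol) || tail_tol <= 0 || tail_tol >= 1)
    stop("tail_tol must lie in (0, 1)")
  mom <- analytic_moments(params, allow_degenerate = TRUE)
  # initial guess well beyond the bulk, then extend until the tail is covered
  N <- max(10, ceiling(mom$mean + 10 * sqrt(max(mom$variance, 1))))
  repeat {
    lp <- telegraph_log_pmf(0:N, params)
    p <- exp(lp)
    tail_mass <- 1 - sum(p)
    if (tail_mass < tail_tol || N >= n_max) break
    N <- min(n_max, ceiling(N * 1.5) + 10)
  }
  if (tail_mass >= tail_tol)
    warning("support cap reached before tail tolerance; tail mass = ",
            format(tail_mass))
  out <- p / sum(p)
  names(out) <- 0:N
  attr(out, "N") <- N
  attr(out, "tail_mass") <- max(tail_mass, 0)
  out
}

#' Analytic stationary moments of the telegraph model
#'
#' Closed-form mean, variance, coefficient of variation and Fano factor of the
#' stationary beta-Poisson law: with `a = k_on/delta`, `b = k_off/delta`,
#' `lam = k_m/delta`,
#' `mean = lam a/(a+b)` and
#' `variance = mean + lam^2 a b / ((a+b)^2 (a+b+1))`.
#'
#' @param params a `telegraph_params` object.
#' @param allow_degenerate if `TRUE`, a zero-mean distribution returns
#'   `CV = NA` instead of erroring (internal use).
#' @return A list with `mean`, `variance`, `cv`, `fano`.
#' @export
analytic_moments <- function(params, allow_degenerate = FALSE) {
  stopifnot(inherits(params, "telegraph_params"))
  a <- params$alpha; b <- params$beta; lam <- params$lam
  if (a + b <= 0) stop("k_on + k_off must be positive")
  mean <- lam * a / (a + b)
  variance <- mean + lam^2 * a * b / ((a + b)^2 * (a + b + 1))
  if (mean == 0) {
    if (!allow_degenerate)
      stop("degenerate distribution: mean is zero, CV undefined")
    cv <- NA_real_; fano <- NA_real_
  } else {
    cv <- sqrt(variance) / mean
    fano <- variance / mean
  }
  list(mean = mean, variance = variance, cv = cv, fano = fano)
}

#' Sample per-cell mRNA counts from the stationary telegraph law
#'
#' Draws each cell independently via the mixture representation:
#' `x ~ Beta(alpha, beta)`, `n ~ Poisson(lam * x)`. With `k_off = 0` the
#' promoter is permanently On and counts are exactly Poisson(`lam`).
#'
#' @param params a `telegraph_params` object.
#' @param n_cells number of cells to draw (>= 1).
#' @param seed integer seed; identical seeds give identical draws.
#' @param clone_id identifier recorded in the result.
#' @return A `count_distribution`: list with `clone_id` and integer `counts`.
#' @export
sample_stationary <- function(params, n_cells, seed, clone_id = "clone") {
  stopifnot(inherits(params, "telegraph_params"))
  if (n_cells < 1) stop("n_cells must be >= 1")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  if (params$beta == 0) {
    counts <- stats::rpois(n_cells, params$lam)
  } else if (params$alpha == 0 || params$lam == 0) {
    counts <- integer(n_cells)
  } else {
    x <- stats::rbeta(n_cells, params$alpha, params$beta)
    counts <- stats::rpois(n_cells, params$lam * x)
  }
  count_distribution(clone_id, counts)
}

#' Per-clone mRNA count distribution
#'
#' @param clone_id identifier.
#' @param counts vector of non-negative integer per-cell copy numbers.
#' @return A `count_distribution` object.
#' @export
count_distribution <- function(clone_id, counts) {
  if (length(counts) < 1) stop("counts must have length >= 1")
  if (any(counts < 0) || any(counts != round(counts)) || any(!is.finite(counts)))
    stop("counts must be non-negative integers")
  structure(list(clone_id = as.character(clone_id),
                 counts = as.integer(counts)),
            class = "count_distribution")
}

#' @export
print.count_distribution <- function(x, ...) {
  cat(sprintf("Count distribution '%s': %d cells, mean %.2f, CV %.2f\n",
              x$clone_id, length(x$counts), mean(x$counts),
              stats::sd(x$counts) / mean(x$counts)))
  invisible(x)
}

#' Exact stochastic simulation of the telegraph model
#'
#' Gillespie (direct-method) simulation of the reactions Off->On (`k_on`),
#' On->Off (`k_off`), On -> On + mRNA (`k_m`), mRNA decay (`delta * m`), and —
#' when a protein stage is supplied — translation (`k_p * m`) and protein
#' decay (`delta_p * p`). Cells start Off and empty; `t_end` should be much
#' larger than the relaxation time (guidance: `t_end >= 10 / min(delta,
#' k_on + k_off)`, and `10 / delta_p` when a long-lived protein is simulated).
#'
#' @param params a `telegraph_params` object.
#' @param t_end simulation end time (> 0).
#' @param n_replicates number of independent cells.
#' @param seed integer seed.
#' @param protein optional list with `k_p` (translation rate per mRNA) and
#'   `delta_p` (protein degradation rate).
#' @return A data.frame with one row per replicate: `state` (0 = Off,
#'   1 = On), `mrna`, `protein`, and `on_frac`, the fraction of simulated time
#'   spent in the On state.
#' @export
gillespie_simulate <- function(params, t_end, n_replicates, seed,
                               protein = NULL) {
  stopifnot(inherits(params, "telegraph_params"))
  if (t_end <= 0) stop("t_end must be positive")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  with_protein <- !is.null(protein)
  if (with_protein && (is.null(protein$k_p) || is.null(protein$delta_p)))
    stop("protein stage requires k_p and delta_p")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  m <- ssa_telegraph_cpp(params$k_on, params$k_off, params$k_m, params$delta,
                         t_end, as.integer(n_replicates), with_protein,
                         if (with_protein) protein$k_p else 0,
                         if (with_protein) protein$delta_p else 0)
  as.data.frame(m)
}

# RNG bookkeeping: generation functions set their own seed but must not
# disturb the caller's random stream.
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
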