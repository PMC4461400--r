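#' Configuration for a synthetic clone cohort
#'
#' Defines the study conditions emulated by the generator: a set of clonal
#' integration positions whose burst size `b` and burst frequency `f` are
#' drawn independently (the orthogonal-control structure), per-cell counts
#' from the stationary telegraph law at a shared fixed transcription rate, a
#' buffered long-lived protein readout, chromatin inaccessibility at three
#' promoter sites coupled log-linearly to burst frequency, and triplicate
#' qPCR noise.
#'
#' Defaults: `log10 b ~ Normal(0.9, 0.4)` and `log10 f ~ Normal(-0.4, 0.283)`
#' (a 2:1 log-variance ratio), both truncated at +/- 2 sd, `lam_fixed = 1000`
#' in degradation-rate units, 200 clones x 600 cells. This calibration places
#' the cohort in the bursty regime (mean << lam) and yields a variance-mean
#' log-log slope of about `1 + sd_b^2/(sd_b^2 + sd_f^2) ~ 1.67` and a CV vs
#' burst-frequency slope near -1/2.
#'
#' @param n_clones number of clones.
#' @param cells_per_clone cells sampled per clone.
#' @param log10_burst_size_dist list describing the log10 burst-size law:
#'   either `list(family = "normal", location, scale, trunc_sd)` or
#'   `list(family = "uniform", min, max)`.
#' @param log10_burst_freq_dist same shape, for log10 burst frequency.
#' @param lam_fixed shared transcription rate in degradation units.
#' @param protein translation-stage parameters: `k_p`, `delta_p`,
#'   `scale` (fluorescence units per protein), `autofluor_meanlog`,
#'   `autofluor_sdlog`, and `fast_approx` (use the temporal-averaging
#'   approximation instead of the SSA).
#' @param chromatin per-site coupling `list(site = list(a0, a1, sigma_eps))`
#'   for sites `Nuc-1`, `HSS`, `Nuc-0`: `log10 I = a0 + a1 * log10 f + eps`.
#' @param qpcr qPCR noise model: `ct_sd` (triplicate Ct sd),
#'   `target_untreated_ct`, `ref_untreated_ct`, `ref_resistant` (DNase-
#'   resistant fraction at the reference locus).
#' @param flow scatter-channel lognormal parameters (independent of GFP).
#' @param seed cohort-level integer seed; per-clone streams are spawned from
#'   it deterministically.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(
    n_clones = 200,
    cells_per_clone = 600,
    log10_burst_size_dist = list(family = "normal", location = 0.9,
                                 scale = 0.4, trunc_sd = 2),
    log10_burst_freq_dist = list(family = "normal", location = -0.4,
                                 scale = 0.283, trunc_sd = 2),
    lam_fixed = 1000,
    protein = list(k_p = 0.2, delta_p = 0.02, scale = 1,
                   autofluor_meanlog = log(50), autofluor_sdlog = 0.4,
                   fast_approx = FALSE),
    chromatin = list(
      `Nuc-1` = list(a0 = -0.80, a1 = -0.63, sigma_eps = 0.15),
      `HSS`   = list(a0 = -0.95, a1 = -0.30, sigma_eps = 0.25),
      `Nuc-0` = list(a0 = -0.70, a1 = -0.20, sigma_eps = 0.30)),
    qpcr = list(ct_sd = 0.1, target_untreated_ct = 22,
                ref_untreated_ct = 20, ref_resistant = 0.8),
    flow = list(fsc_meanlog = 11, fsc_sdlog = 0.15,
                ssc_meanlog = 10.5, ssc_sdlog = 0.2),
    seed = 1L) {
  if (n_clones < 1 || cells_per_clone < 1)
    stop("n_clones and cells_per_clone must be >= 1")
  if (lam_fixed <= 0) stop("lam_fixed must be positive")
  for (d in list(log10_burst_size_dist, log10_burst_freq_dist)) {
    if (identical(d$family, "normal") && (is.null(d$scale) || d$scale < 0))
      stop("normal distribution needs a non-negative scale")
    if (identical(d$family, "uniform") && d$min > d$max)
      stop("uniform distribution needs min <= max")
  }
  structure(list(n_clones = as.integer(n_clones),
                 cells_per_clone = as.integer(cells_per_clone),
                 log10_burst_size_dist = log10_burst_size_dist,
                 log10_burst_freq_dist = log10_burst_freq_dist,
                 lam_fixed = lam_fixed, protein = protein,
                 chromatin = chromatin, qpcr = qpcr, flow = flow,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# draw n values from a log10-scale distribution spec; truncation uses the
# inverse-CDF so the number of RNG draws is deterministic
draw_log10_dist <- function(dist, n) {
  if (identical(dist$family, "uniform"))
    return(stats::runif(n, dist$min, dist$max))
  if (!identical(dist$family, "normal"))
    stop("unknown distribution family: ", dist$family)
  if (dist$scale == 0) return(rep(dist$location, n))
  t <- if (is.null(dist$trunc_sd)) Inf else dist$trunc_sd
  u <- stats::runif(n, stats::pnorm(-t), stats::pnorm(t))
  dist$location + dist$scale * stats::qnorm(u)
}

#' Generate a synthetic clone cohort
#'
#' Draws per-clone burst size and burst frequency independently from the
#' configured distributions, then samples per-cell mRNA counts from the
#' stationary telegraph law with `lam = lam_fixed`, `k_off = lam / b`,
#' `k_on = f` (time in degradation units, `delta = 1`). The truth table
#' records, per clone, the drawn kinetics, the exact analytic stationary
#' moments, the true chromatin inaccessibility at each promoter site
#' (`log10 I = a0 + a1 log10 f + Normal(0, sigma_eps)`, clamped into (0, 1]),
#' and the per-clone RNG seed so any clone can be regenerated independently
#' of evaluation order.
#'
#' @param config a [cohort_config()].
#' @return List with `truth` (data.frame of per-clone ground truth), `counts`
#'   (list of `count_distribution`), `counts_df` (tidy table with `clone_id`,
#'   `cell_id`, `count`), and the `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(config$seed)
  n <- config$n_clones
  lam <- config$lam_fixed
  log10_b <- draw_log10_dist(config$log10_burst_size_dist, n)
  log10_f <- draw_log10_dist(config$log10_burst_freq_dist, n)
  b <- 10^log10_b; f <- 10^log10_f
  if (any(b <= 0)) stop("configuration produced non-positive burst size")
  clone_seeds <- sample.int(.Machine$integer.max - 1L, n)
  ids <- sprintf("clone%03d", seq_len(n))

  sites <- names(config$chromatin)
  inacc <- sapply(sites, function(s) {
    cc <- config$chromatin[[s]]
    li <- cc$a0 + cc$a1 * log10_f + stats::rnorm(n, 0, cc$sigma_eps)
    pmin(10^li, 1)
  })
  colnames(inacc) <- paste0("I_", gsub("-", "", sites))

  moments <- t(vapply(seq_len(n), function(i) {
    m <- analytic_moments(telegraph_from_bursts(b[i], f[i], lam))
    c(m$mean, m$variance, m$cv)
  }, numeric(3)))

  truth <- data.frame(clone_id = ids, b = b, f = f, k_off = lam / b,
                      alpha = f, lam = lam,
                      mean = moments[, 1], variance = moments[, 2],
                      cv = moments[, 3],
                      inacc,
                      protein_scale = config$protein$scale,
                      clone_seed = clone_seeds,
                      stringsAsFactors = FALSE)

  counts <- lapply(seq_len(n), function(i)
    sample_stationary(telegraph_from_bursts(b[i], f[i], lam),
                      config$cells_per_clone, seed = clone_seeds[i],
                      clone_id = ids[i]))
  counts_df <- do.call(rbind, lapply(counts, function(d)
    data.frame(clone_id = d$clone_id,
               cell_id = seq_along(d$counts),
               count = d$counts)))
  list(truth = truth, counts = counts, counts_df = counts_df, config = config)
}

#' Generate a synthetic flow-cytometry readout for one clone
#'
#' Simulates per-event (per-cell) protein copy number via the exact SSA with
#' a translation stage (`delta_p << delta` emulates a long-lived fluorescent
#' reporter, so protein temporally averages the mRNA fluctuations), then
#' reports `GFP = scale * protein + autofluorescence` with lognormal
#' autofluorescence, and forward/side scatter drawn from lognormals
#' independent of GFP. With `config$protein$fast_approx = TRUE` the protein
#' level is instead approximated as `(k_p/delta_p)` times the average of
#' `K = delta/delta_p` independent stationary mRNA draws (the temporal-
#' averaging approximation).
#'
#' @param clone_params a `telegraph_params` for the clone.
#' @param config a [cohort_config()] providing the protein and flow settings.
#' @param n_events number of events (cells) to simulate.
#' @param seed integer seed.
#' @return data.frame with columns `FSC`, `SSC`, `GFP`.
#' @export
generate_protein_readout <- function(clone_params, config, n_events, seed) {
  stopifnot(inherits(clone_params, "telegraph_params"),
            inherits(config, "cohort_config"))
  pr <- config$protein
  if (is.null(pr) || is.null(pr$k_p) || is.null(pr$delta_p))
    stop("protein configuration (k_p, delta_p) required")
  if (n_events < 1) stop("n_events must be >= 1")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  if (isTRUE(pr$fast_approx)) {
    K <- max(1, round(clone_params$delta / pr$delta_p))
    mdraws <- matrix(sample_stationary(clone_params, n_events * K,
                                       seed = seed + 1L)$counts,
                     nrow = n_events)
    protein <- (pr$k_p / pr$delta_p) * rowMeans(mdraws)
  } else {
    t_end <- 10 / min(clone_params$delta, pr$delta_p,
                      clone_params$k_on + clone_params$k_off)
    sim <- gillespie_simulate(clone_params, t_end, n_events, seed = seed + 1L,
                              protein = list(k_p = pr$k_p,
                                             delta_p = pr$delta_p))
    protein <- sim$protein
  }
  autofluor <- stats::rlnorm(n_events, pr$autofluor_meanlog, pr$autofluor_sdlog)
  data.frame(
    FSC = stats::rlnorm(n_events, config$flow$fsc_meanlog,
                        config$flow$fsc_sdlog),
    SSC = stats::rlnorm(n_events, config$flow$ssc_meanlog,
                        config$flow$ssc_sdlog),
    GFP = pr$scale * protein + autofluor)
}

#' Generate a synthetic DNase-qPCR chromatin panel
#'
#' Builds triplicate Ct values (DNase-treated and untreated, target sites and
#' reference locus) consistent with each clone's true inaccessibility as
#' recorded in the cohort truth table: the DNase-resistant fraction at a
#' target site is `R = I * r0` where `r0` is the resistant fraction at the
#' reference locus, and `Ct_treated = Ct_untreated - log2(R)`. Triplicate Ct
#' noise is added with sd `config$qpcr$ct_sd`, so
#' [inaccessibility_from_ct()] inverts the construction up to that noise.
#'
#' @param truth cohort truth table from [generate_cohort()].
#' @param config a [cohort_config()].
#' @param seed integer seed (defaults to a stream spawned from the config
#'   seed).
#' @param n_replicates qPCR replicates per condition (default 3).
#' @return data.frame with columns `clone_id`, `site`, `condition`
#'   (`"treated"`/`"untreated"`), `replicate`, `Ct`.
#' @export
generate_chromatin_panel <- function(truth, config,
                                     seed = config$seed + 101L,
                                     n_replicates = 3) {
  stopifnot(inherits(config, "cohort_config"))
  q <- config$qpcr
  if (q$ref_resistant <= 0) stop("reference resistant fraction must be > 0")
  sites <- names(config$chromatin)
  icols <- paste0("I_", gsub("-", "", sites))
  if (!all(icols %in% names(truth)))
    stop("truth table lacks inaccessibility columns for all sites")
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  rows <- list()
  for (i in seq_len(nrow(truth))) {
    for (s in seq_along(sites)) {
      I <- truth[[icols[s]]][i]
      R_target <- I * q$ref_resistant
      dct <- -log2(R_target)
      rows[[length(rows) + 1]] <- data.frame(
        clone_id = truth$clone_id[i], site = sites[s],
        condition = rep(c("untreated", "treated"), each = n_replicates),
        replicate = rep(seq_len(n_replicates), 2),
        Ct = c(q$target_untreated_ct +
                 stats::rnorm(n_replicates, 0, q$ct_sd),
               q$target_untreated_ct + dct +
                 stats::rnorm(n_replicates, 0, q$ct_sd)))
    }
    dct_ref <- -log2(q$ref_resistant)
    rows[[length(rows) + 1]] <- data.frame(
      clone_id = truth$clone_id[i], site = "reference",
      condition = rep(c("untreated", "treated"), each = n_replicates),
      replicate = rep(seq_len(n_replicates), 2),
      Ct = c(q$ref_untreated_ct + stats::rnorm(n_replicates, 0, q$ct_sd),
             q$ref_untreated_ct + dct_ref +
               stats::rnorm(n_replicates, 0, q$ct_sd)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a synthetic transcription-shutoff decay time course
#'
#' Emulates the RT-qPCR time course used for half-life estimation: after
#' transcription is blocked, target abundance relative to a stable reference
#' transcript decays as `exp(-delta * t)`, so the treated-series
#' `Ct_target - Ct_reference` grows by `delta * t / ln(2)`; the untreated
#' series stays flat. Triplicate Gaussian Ct noise with sd
#' `config$qpcr$ct_sd` is added to every well.
#'
#' @param delta true degradation rate (per unit time).
#' @param timepoints numeric vector of sampling times (>= 3 values, must
#'   include 0, all non-negative).
#' @param config a [cohort_config()] (for the qPCR noise model).
#' @param seed integer seed.
#' @param n_replicates replicates per well (default 3).
#' @return data.frame with columns `time`, `series`, `target`, `replicate`,
#'   `Ct`.
#' @export
generate_decay_timecourse <- function(delta, timepoints, config,
                                      seed = config$seed + 202L,
                                      n_replicates = 3) {
  stopifnot(inherits(config, "cohort_config"))
  if (any(timepoints < 0)) stop("timepoints must be non-negative")
  if (length(timepoints) < 3 || !any(timepoints == 0))
    stop("need >= 3 timepoints including 0")
  q <- config$qpcr
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  rows <- list()
  for (t in sort(timepoints)) {
    for (series in c("treated", "untreated")) {
      shift <- if (series == "treated") delta * t / log(2) else 0
      rows[[length(rows) + 1]] <- data.frame(
        time = t, series = series,
        target = rep(c("target", "reference"), each = n_replicates),
        replicate = rep(seq_len(n_replicates), 2),
        Ct = c(q$target_untreated_ct + shift +
                 stats::rnorm(n_replicates, 0, q$ct_sd),
               q$ref_untreated_ct + stats::rnorm(n_replicates, 0, q$ct_sd)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
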