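# shared fixtures: small, seeded synthetic inputs built in code

small_cohort_config <- function(n_clones = 30, cells_per_clone = 200,
                                seed = 42, ...) {
  cohort_config(n_clones = n_clones, cells_per_clone = cells_per_clone,
                seed = seed, ...)
}

# log-uniform kinetic draws matching the recovery-study layout
uniform_kinetics_config <- function(n_clones = 25, cells_per_clone = 600,
                                    b_range = c(2, 50), f_range = c(0.1, 2),
                                    seed = 1) {
  cohort_config(
    n_clones = n_clones, cells_per_clone = cells_per_clone,
    log10_burst_size_dist = list(family = "uniform",
                                 min = log10(b_range[1]),
                                 max = log10(b_range[2])),
    log10_burst_freq_dist = list(family = "uniform",
                                 min = log10(f_range[1]),
                                 max = log10(f_range[2])),
    seed = seed)
}

# total-variation distance between an empirical count vector and a pmf
tv_distance <- function(counts, pmf) {
  h <- tabulate(counts + 1, nbins = length(pmf)) / length(counts)
  0.5 * sum(abs(h - pmf)) + 0.5 * (1 - sum(h))
}

# chi-square goodness-of-fit of counts against a discrete pmf, pooling
# low-expectation tail bins
gof_pvalue <- function(counts, pmf) {
  n <- length(counts)
  expected <- pmf * n
  keep <- which(expected >= 5)
  if (length(keep) < 2) return(NA_real_)
  cut <- max(keep)
  obs <- tabulate(counts + 1, nbins = length(pmf))
  o <- c(obs[seq_len(cut)], sum(obs) - sum(obs[seq_len(cut)]) + n - sum(obs))
  e <- c(expected[seq_len(cut)], n - sum(expected[seq_len(cut)]))
  suppressWarnings(stats::chisq.test(o, p = e / sum(e))$p.value)
}

# flow events with GFP statistically independent of scatter
independent_flow_events <- function(n_clones = 12, n_events = 400,
                                    seed = 99) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_clones), function(i) {
    data.frame(clone_id = sprintf("c%02d", i),
               FSC = rlnorm(n_events, 11, 0.15),
               SSC = rlnorm(n_events, 10.5, 0.2),
               GFP = rlnorm(n_events, 3 + 0.3 * i, 0.3 + 0.05 * i))
  }))
}
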