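test_that("cohort generation is deterministic and records exact truth", {
  cfg <- small_cohort_config(n_clones = 10, cells_per_clone = 50)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$counts_df, c2$counts_df)

  # truth moments equal the analytic stationary moments exactly
  for (i in c(1, 5, 10)) {
    m <- analytic_moments(telegraph_from_bursts(c1$truth$b[i], c1$truth$f[i],
                                                cfg$lam_fixed))
    expect_identical(c1$truth$mean[i], m$mean)
    expect_identical(c1$truth$variance[i], m$variance)
  }

  # any clone can be regenerated from its recorded per-clone seed
  i <- 7
  d <- sample_stationary(
    telegraph_from_bursts(c1$truth$b[i], c1$truth$f[i], cfg$lam_fixed),
    cfg$cells_per_clone, seed = c1$truth$clone_seed[i],
    clone_id = c1$truth$clone_id[i])
  expect_identical(d$counts, c1$counts[[i]]$counts)
})

test_that("zero-scale distributions give identical clone kinetics", {
  cfg <- cohort_config(
    n_clones = 5, cells_per_clone = 20,
    log10_burst_size_dist = list(family = "normal", location = 1,
                                 scale = 0, trunc_sd = 2),
    log10_burst_freq_dist = list(family = "normal", location = -0.3,
                                 scale = 0, trunc_sd = 2),
    seed = 3)
  coh <- generate_cohort(cfg)
  expect_equal(length(unique(coh$truth$mean)), 1)
  expect_equal(length(unique(coh$truth$cv)), 1)
  expect_equal(unique(coh$truth$b), 10)
})

test_that("default cohort has the calibrated scaling and orthogonality", {
  coh <- generate_cohort(cohort_config(seed = 1))
  mom <- cohort_moments(coh$counts)

  # variance-mean log-log slope in the bursty-regime band
  fit <- loglog_regression(mom$mean, mom$variance)
  expect_gt(fit$slope, 1.5)
  expect_lt(fit$slope, 1.8)

  # burst size and burst frequency drawn independently
  expect_lt(abs(cor(coh$truth$b, coh$truth$f, method = "spearman")), 0.1)

  # noise-structure fidelity: log CV vs log true f slope near -1/2
  cvfit <- loglog_regression(coh$truth$f, mom$cv)
  expect_lt(abs(cvfit$slope + 0.5), 0.1)

  # CV-mean slope magnitude stays small (mean and noise decoupled)
  cm <- loglog_regression(mom$mean, mom$cv)
  expect_lt(abs(cm$slope), 0.3)
})

test_that("protein readout: autofluorescence-only null and RNA-GFP coupling", {
  cfg <- small_cohort_config(seed = 8)

  # silent clone: GFP indistinguishable from pure autofluorescence
  silent <- telegraph_params(1, 1, 0, 1)
  ev <- generate_protein_readout(silent, cfg, n_events = 400, seed = 21)
  set.seed(22)
  af <- rlnorm(400, cfg$protein$autofluor_meanlog, cfg$protein$autofluor_sdlog)
  expect_gt(ks.test(ev$GFP, af)$p.value, 0.01)

  # missing protein config errors
  cfg_np <- cfg; cfg_np$protein <- NULL
  expect_error(generate_protein_readout(silent, cfg_np, 10, 1), "protein")

  # clone-level log GFP mean and variance track RNA mean and variance
  coh <- generate_cohort(small_cohort_config(n_clones = 16,
                                             cells_per_clone = 400, seed = 4))
  gfp <- lapply(seq_len(16), function(i) {
    tp <- telegraph_from_bursts(coh$truth$b[i], coh$truth$f[i],
                                cfg$lam_fixed)
    generate_protein_readout(tp, cfg, n_events = 300, seed = 100 + i)$GFP
  })
  rna_mom <- cohort_moments(coh$counts)
  lg_mean <- log10(vapply(gfp, mean, numeric(1)))
  lg_var <- log10(vapply(gfp, var, numeric(1)))
  expect_gt(cor(lg_mean, log10(rna_mom$mean)), 0.8)
  expect_gt(cor(lg_var, log10(rna_mom$variance)), 0.8)
})

test_that("long-lived reporter buffers noise: GFP CV below mRNA CV", {
  cfg <- small_cohort_config(seed = 10) # delta_p = delta / 50
  coh <- generate_cohort(small_cohort_config(n_clones = 8,
                                             cells_per_clone = 600, seed = 5))
  for (i in seq_len(8)) {
    tp <- telegraph_from_bursts(coh$truth$b[i], coh$truth$f[i],
                                cfg$lam_fixed)
    g <- generate_protein_readout(tp, cfg, n_events = 150, seed = 200 + i)$GFP
    rna <- coh$counts[[i]]$counts
    expect_lt(sd(g) / mean(g), sd(rna) / mean(rna))
  }
})

test_that("fast protein approximation also preserves the RNA-GFP coupling", {
  cfg <- small_cohort_config(seed = 12)
  cfg$protein$fast_approx <- TRUE
  tp <- telegraph_from_bursts(10, 0.5, cfg$lam_fixed)
  ev <- generate_protein_readout(tp, cfg, n_events = 300, seed = 31)
  # temporal averaging over K = delta/delta_p draws shrinks relative noise
  rna <- sample_stationary(tp, 2000, seed = 32)$counts
  expect_lt(sd(ev$GFP) / mean(ev$GFP), sd(rna) / mean(rna))
})

test_that("chromatin panel inverts exactly without noise, approximately with", {
  # noise-free: recovered I is exactly affine in log10 f
  cfg0 <- small_cohort_config(n_clones = 15, cells_per_clone = 20, seed = 6)
  for (s in names(cfg0$chromatin)) cfg0$chromatin[[s]]$sigma_eps <- 0
  cfg0$qpcr$ct_sd <- 0
  coh0 <- generate_cohort(cfg0)
  panel0 <- generate_chromatin_panel(coh0$truth, cfg0)
  prof0 <- chromatin_profiles(panel0)
  nuc1 <- prof0[prof0$site == "Nuc-1", ]
  nuc1 <- nuc1[match(coh0$truth$clone_id, nuc1$clone_id), ]
  unclamped <- nuc1$I < 1
  fit <- lm(log10(nuc1$I[unclamped]) ~ log10(coh0$truth$f[unclamped]))
  expect_equal(unname(coef(fit)[2]), cfg0$chromatin$`Nuc-1`$a1,
               tolerance = 1e-9)
  expect_lt(max(abs(residuals(fit))), 1e-9)

  # with triplicate noise: round trip recovers I within propagated sd
  cfg1 <- small_cohort_config(n_clones = 40, cells_per_clone = 20, seed = 7)
  coh1 <- generate_cohort(cfg1)
  panel1 <- generate_chromatin_panel(coh1$truth, cfg1)
  prof1 <- chromatin_profiles(panel1)
  nuc1 <- prof1[prof1$site == "Nuc-1", ]
  nuc1 <- nuc1[match(coh1$truth$clone_id, nuc1$clone_id), ]
  ok <- !nuc1$clamped
  z <- abs(nuc1$I[ok] - coh1$truth$I_Nuc1[ok]) / nuc1$sd[ok]
  expect_gte(mean(z < 2.6), 0.95)
})

test_that("chromatin coupling makes the noisier clone less accessible", {
  # matched-mean, contrasting-CV pairs selected as in the clone workflow:
  # cluster each cohort on (mean, CV), take the maximal-CV-gap pair per
  # cluster, and ask whether the higher-noise member has higher Nuc-1
  # inaccessibility in its recorded truth
  hits <- 0; total <- 0
  for (k in 1:8) {
    cfg <- cohort_config(n_clones = 200, cells_per_clone = 200,
                         seed = 900 + k)
    coh <- generate_cohort(cfg)
    mom <- cohort_moments(coh$counts)
    labels <- cluster_clone_distributions(mom, k = 4)
    pairs <- suppressWarnings(select_noise_pairs(mom, labels,
                                                 mean_tol = 0.1))
    tr <- coh$truth
    for (i in seq_len(nrow(pairs))) {
      hi <- tr[tr$clone_id == pairs$high_noise[i], ]
      lo <- tr[tr$clone_id == pairs$low_noise[i], ]
      total <- total + 1
      if (hi$I_Nuc1 > lo$I_Nuc1) hits <- hits + 1
    }
  }
  expect_gt(total, 20)
  expect_gt(hits / total, 0.9)
})

test_that("decay time course recovers the degradation rate", {
  cfg <- small_cohort_config(seed = 13)

  # noise-free, delta = ln 2 per hour: delta Ct grows exactly 1 per hour
  cfg0 <- cfg; cfg0$qpcr$ct_sd <- 0
  tc <- generate_decay_timecourse(log(2), 0:4, cfg0)
  dct <- vapply(0:4, function(t) {
    tr <- tc[tc$series == "treated" & tc$time == t, ]
    mean(tr$Ct[tr$target == "target"]) - mean(tr$Ct[tr$target == "reference"])
  }, numeric(1))
  expect_equal(diff(dct), rep(1, 4), tolerance = 1e-12)
  est <- estimate_degradation_rate(tc)
  expect_equal(est$delta, log(2), tolerance = 1e-12)
  expect_equal(est$half_life, 1, tolerance = 1e-12)

  # untreated series: decay indistinguishable from zero
  est_u <- estimate_degradation_rate(tc, series = "untreated")
  expect_lt(abs(est_u$delta), 1e-12)

  # sd = 0.2 triplicates, 6 timepoints over 4 half-lives: delta within 10%
  cfg2 <- cfg; cfg2$qpcr$ct_sd <- 0.2
  tc2 <- generate_decay_timecourse(log(2), seq(0, 4, length.out = 6), cfg2,
                                   seed = 77)
  est2 <- estimate_degradation_rate(tc2)
  expect_lt(abs(est2$delta - log(2)) / log(2), 0.1)

  expect_error(generate_decay_timecourse(1, c(-1, 0, 1), cfg), "non-negative")
  expect_error(generate_decay_timecourse(1, c(1, 2, 3), cfg), "including 0")
})

test_that("generated tables pass their readers' validation", {
  cfg <- small_cohort_config(n_clones = 4, cells_per_clone = 25, seed = 14)
  coh <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  counts <- read_counts_tsv(file.path(dir, "counts.tsv"))
  expect_equal(nrow(counts), 100)
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  expect_equal(manifest$seed, 14)

  panel <- generate_chromatin_panel(coh$truth, cfg)
  qf <- tempfile(fileext = ".csv")
  write_qpcr_csv(panel, qf)
  expect_silent(read_qpcr_csv(qf))

  tp <- telegraph_from_bursts(coh$truth$b[1], coh$truth$f[1], cfg$lam_fixed)
  ev <- generate_protein_readout(tp, cfg, 50, seed = 15)
  ff <- tempfile(fileext = ".csv")
  write_flow_csv(ev, ff)
  expect_silent(read_flow_csv(ff))

  pf <- tempfile(fileext = ".yaml")
  write_params_yaml(tp, pf)
  tp2 <- read_params_yaml(pf)
  expect_equal(tp2$burst_size, tp$burst_size)
})
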