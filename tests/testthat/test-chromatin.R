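test_that("inaccessibility from Ct: worked examples and invariances", {
  tt <- c(23, 23, 23); tu <- c(22, 22, 22)
  rt <- c(21, 21, 21); ru <- c(21, 21, 21)
  # target dCt = 1, reference dCt = 0: I = 2^-1
  r <- inaccessibility_from_ct(tt, tu, rt, ru)
  expect_equal(r$I, 0.5)
  expect_false(r$clamped)

  # equal dCt at target and reference: fully protected relative to reference
  r1 <- inaccessibility_from_ct(c(24, 24), c(22, 22), c(23, 23), c(21, 21))
  expect_equal(r1$I, 1)

  # more resistant than the reference: clamped to 1 with a flag
  r2 <- inaccessibility_from_ct(c(22.5, 22.5), c(22, 22), c(22, 22),
                                c(21, 21))
  expect_equal(r2$I, 1)
  expect_true(r2$clamped)

  # global Ct shift cancels
  sh <- 3.7
  r3 <- inaccessibility_from_ct(tt + sh, tu + sh, rt + sh, ru + sh)
  expect_equal(r3$I, r$I, tolerance = 1e-12)

  # propagated sd grows with replicate scatter
  set.seed(60)
  rn <- inaccessibility_from_ct(tt + rnorm(3, 0, 0.2), tu + rnorm(3, 0, 0.2),
                                rt + rnorm(3, 0, 0.2), ru + rnorm(3, 0, 0.2))
  expect_gt(rn$sd, 0)
  expect_error(inaccessibility_from_ct(c(-1, 2), tu, rt, ru), "positive")
  expect_warning(inaccessibility_from_ct(23, c(22, 22), c(21, 21),
                                         c(21, 21)),
                 "replicates")
})

test_that("profile extraction requires complete clone/site series", {
  cfg <- small_cohort_config(n_clones = 3, cells_per_clone = 20, seed = 61)
  coh <- generate_cohort(cfg)
  panel <- generate_chromatin_panel(coh$truth, cfg)
  prof <- chromatin_profiles(panel)
  expect_setequal(unique(prof$site), c("Nuc-1", "HSS", "Nuc-0"))
  expect_equal(nrow(prof), 9)
  expect_true(all(prof$I >= 0 & prof$I <= 1))

  broken <- panel[!(panel$site == "reference" &
                      panel$condition == "untreated" &
                      panel$clone_id == "clone001"), ]
  expect_error(chromatin_profiles(broken), "untreated reference")
})

test_that("noise-pair inaccessibility ratios behave and fail loudly", {
  prof <- data.frame(clone_id = rep(c("a", "b"), each = 1),
                     site = "Nuc-1", I = c(0.6, 0.6), sd = c(0.05, 0.05),
                     clamped = FALSE)
  pairs <- data.frame(cluster = 1, high_noise = "a", low_noise = "b")
  rr <- noise_pair_ratio(prof, pairs, "Nuc-1")
  expect_equal(rr$ratio, 1)

  pairs2 <- data.frame(cluster = 1, high_noise = "a", low_noise = "missing")
  rr2 <- noise_pair_ratio(prof, pairs2, "Nuc-1")
  expect_true(is.na(rr2$ratio))
  expect_match(rr2$error, "missing")
  expect_error(noise_pair_ratio(prof, pairs, "HSS"), "site")
})

test_that("high-noise clones carry more Nuc-1 inaccessibility than their pairs", {
  cfg <- cohort_config(n_clones = 60, cells_per_clone = 300, seed = 62)
  coh <- generate_cohort(cfg)
  mom <- cohort_moments(coh$counts)
  labels <- cluster_clone_distributions(mom, k = 4)
  pairs <- select_noise_pairs(mom, labels, mean_tol = 0.1)
  expect_gt(nrow(pairs), 1)
  panel <- generate_chromatin_panel(coh$truth, cfg)
  prof <- chromatin_profiles(panel)
  rr <- noise_pair_ratio(prof, pairs, "Nuc-1")
  expect_gt(median(rr$ratio, na.rm = TRUE), 1)
})

test_that("kinetics-accessibility regression: delegation and site ordering", {
  cfg <- cohort_config(n_clones = 40, cells_per_clone = 300, seed = 63)
  coh <- generate_cohort(cfg)
  panel <- generate_chromatin_panel(coh$truth, cfg)
  prof <- chromatin_profiles(panel)
  fits <- fit_cohort(coh$counts_df, delta = 1, lam = 1000)$fits

  reg <- kinetics_accessibility_regression(prof, fits, "Nuc-1")
  # delegation: identical to calling loglog_regression directly
  m <- merge(prof[prof$site == "Nuc-1", c("clone_id", "I")],
             fits[, c("clone_id", "burst_freq_hat")], by = "clone_id")
  direct <- loglog_regression(m$I, m$burst_freq_hat)
  expect_equal(reg$fit$slope, direct$slope, tolerance = 1e-12)
  expect_equal(reg$fit$r_squared, direct$r_squared, tolerance = 1e-12)

  # full chain recovers a negative slope whose 95% CI excludes zero
  expect_lt(reg$fit$slope, 0)
  expect_lt(reg$fit$slope_ci[2], 0)

  # Nuc-1 is the best predictor of burst frequency among the three sites
  r2 <- vapply(c("Nuc-1", "HSS", "Nuc-0"), function(s)
    kinetics_accessibility_regression(prof, fits, s)$fit$r_squared,
    numeric(1))
  expect_gt(r2["Nuc-1"], r2["HSS"])
  expect_gt(r2["Nuc-1"], r2["Nuc-0"])

  # burst size stays unexplained by Nuc-1 accessibility
  regb <- kinetics_accessibility_regression(prof, fits, "Nuc-1",
                                            param = "burst_size")
  expect_lt(regb$fit$r_squared, reg$fit$r_squared / 2)

  expect_error(kinetics_accessibility_regression(prof, fits, "TSS"), "site")
})

test_that("decoupled chromatin shows no kinetics association", {
  ps <- numeric(20)
  for (k in seq_len(20)) {
    cfg <- cohort_config(n_clones = 30, cells_per_clone = 20, seed = 500 + k)
    cfg$chromatin$`Nuc-1`$a1 <- 0 # coupling disabled
    coh <- generate_cohort(cfg)
    prof <- chromatin_profiles(generate_chromatin_panel(coh$truth, cfg))
    truth_as_fits <- data.frame(clone_id = coh$truth$clone_id,
                                burst_freq_hat = coh$truth$f,
                                burst_size_hat = coh$truth$b)
    ps[k] <- kinetics_accessibility_regression(prof, truth_as_fits,
                                               "Nuc-1")$fit$p_slope
  }
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("chromatin PCA: closed-form two-variable case and conventions", {
  set.seed(64)
  n <- 200
  f <- 10^rnorm(n, -0.4, 0.3)
  I <- 10^(-0.8 - 0.63 * log10(f) + rnorm(n, 0, 0.15))
  prof <- data.frame(clone_id = sprintf("c%03d", 1:n), site = "Nuc-1",
                     I = pmin(I, 1), sd = 0, clamped = FALSE)
  fits <- data.frame(clone_id = prof$clone_id, burst_freq_hat = f)
  pca <- chromatin_pca(prof, fits)

  # two standardized variables with correlation r: PC1 explains (1+|r|)/2
  r <- cor(log10(pmin(I, 1)), log10(f))
  expect_equal(pca$explained[1], (1 + abs(r)) / 2, tolerance = 1e-10)
  expect_equal(sum(pca$explained), 1, tolerance = 1e-12)
  # perfectly anti-correlated pair loads with equal magnitude on PC1
  expect_equal(abs(pca$loadings[1, 1]), abs(pca$loadings[2, 1]),
               tolerance = 1e-10)

  # row order invariance
  perm <- sample(n)
  pca2 <- chromatin_pca(prof[perm, ], fits)
  expect_equal(pca2$explained, pca$explained, tolerance = 1e-12)
  expect_equal(pca2$loadings, pca$loadings, tolerance = 1e-10)

  # constant column rejected by name
  prof_const <- prof; prof_const$I <- 0.5
  expect_error(chromatin_pca(prof_const, fits), "log10_I_Nuc-1")
})

test_that("PCA axes recover the coupling geometry on the default cohort", {
  cfg <- cohort_config(n_clones = 80, cells_per_clone = 20, seed = 65)
  coh <- generate_cohort(cfg)
  prof <- chromatin_profiles(generate_chromatin_panel(coh$truth, cfg))
  truth_as_fits <- data.frame(clone_id = coh$truth$clone_id,
                              burst_freq_hat = coh$truth$f)
  pca <- chromatin_pca(prof, truth_as_fits)
  # burst frequency and Nuc-1 inaccessibility load with opposite signs
  l <- pca$loadings
  expect_lt(l["log10_I_Nuc-1", 1] * l["log10_f", 1], 0)
  expect_equal(sum(pca$explained), 1, tolerance = 1e-12)
})
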