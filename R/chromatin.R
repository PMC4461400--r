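#' Chromatin inaccessibility from DNase-qPCR Ct values
#'
#' The DNase-resistant fraction of an amplicon is `R = 2^(-dCt)` with
#' `dCt = mean(treated Ct) - mean(untreated Ct)` (triplicates averaged on the
#' Ct scale). Inaccessibility is the target's resistant fraction normalized
#' to a reference locus assumed fully protected: `I = R_target / R_reference`,
#' clamped into [0, 1] with a flag when qPCR noise pushes it outside.
#' Uncertainty is propagated to `I` from the replicate Ct standard deviations
#' by the delta method. Adding a common constant to every Ct leaves `I`
#' unchanged.
#'
#' @param target_treated,target_untreated Ct replicate vectors at the target
#'   site.
#' @param ref_treated,ref_untreated Ct replicate vectors at the reference
#'   locus.
#' @return List with `I`, `sd`, `clamped`, `R_target`, `R_reference`.
#' @export
inaccessibility_from_ct <- function(target_treated, target_untreated,
                                    ref_treated, ref_untreated) {
  for (v in list(target_treated, target_untreated, ref_treated,
                 ref_untreated)) {
    if (length(v) < 2) warning("fewer than 2 replicates in a Ct series")
    if (any(!is.finite(v)) || any(v <= 0))
      stop("Ct values must be positive and finite")
  }
  dct_t <- mean(target_treated) - mean(target_untreated)
  dct_r <- mean(ref_treated) - mean(ref_untreated)
  R_t <- 2^(-dct_t)
  R_r <- 2^(-dct_r)
  if (R_r == 0) stop("reference resistant fraction is zero")
  I_raw <- R_t / R_r
  clamped <- I_raw > 1 || I_raw < 0
  I <- min(max(I_raw, 0), 1)
  # var of each dCt: se^2 of treated mean + se^2 of untreated mean
  vdct <- function(tr, un)
    stats::var(tr) / length(tr) + stats::var(un) / length(un)
  sd_log2 <- sqrt(vdct(target_treated, target_untreated) +
                    vdct(ref_treated, ref_untreated))
  list(I = I, sd = I_raw * log(2) * sd_log2, clamped = clamped,
       R_target = R_t, R_reference = R_r)
}

#' Per-clone chromatin inaccessibility profiles from a qPCR table
#'
#' Applies [inaccessibility_from_ct()] to every (clone, site) combination in
#' a long-format qPCR table, normalizing each site to the clone's reference-
#' locus measurements.
#'
#' @param qpcr data.frame with columns `clone_id`, `site`, `condition`
#'   (`"treated"`/`"untreated"`), `replicate`, `Ct`; the reference locus rows
#'   have `site == "reference"`.
#' @return data.frame with columns `clone_id`, `site`, `I`, `sd`, `clamped`.
#' @export
chromatin_profiles <- function(qpcr) {
  need <- c("clone_id", "site", "condition", "Ct")
  if (!all(need %in% names(qpcr)))
    stop("qpcr table must have columns ", paste(need, collapse = ", "))
  rows <- list()
  for (id in unique(qpcr$clone_id)) {
    q <- qpcr[qpcr$clone_id == id, ]
    ref <- q[q$site == "reference", ]
    if (!nrow(ref)) stop("no reference-locus rows for clone ", id)
    rt <- ref$Ct[ref$condition == "treated"]
    ru <- ref$Ct[ref$condition == "untreated"]
    if (!length(ru)) stop("missing untreated reference series for clone ", id)
    for (s in setdiff(unique(q$site), "reference")) {
      tt <- q$Ct[q$site == s & q$condition == "treated"]
      tu <- q$Ct[q$site == s & q$condition == "untreated"]
      if (!length(tu)) stop("missing untreated series for clone ", id,
                            " site ", s)
      r <- inaccessibility_from_ct(tt, tu, rt, ru)
      rows[[length(rows) + 1]] <- data.frame(
        clone_id = id, site = s, I = r$I, sd = r$sd, clamped = r$clamped)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Inaccessibility ratios within matched-mean noise pairs
#'
#' For each (high-noise, low-noise) clone pair, the ratio of chromatin
#' inaccessibility `I_high / I_low` at the requested site, with first-order
#' propagated uncertainty. Whether the ratios exceed 1 is an observation on
#' the data, not enforced.
#'
#' @param profiles table from [chromatin_profiles()].
#' @param pairs pair table from [select_noise_pairs()].
#' @param site promoter site name.
#' @return data.frame with `cluster`, `high_noise`, `low_noise`, `ratio`,
#'   `ratio_sd`, and `error` for pairs that could not be resolved.
#' @export
noise_pair_ratio <- function(profiles, pairs, site) {
  p <- profiles[profiles$site == site, ]
  if (!nrow(p)) stop("site not present in profiles: ", site)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    hi <- p[p$clone_id == pairs$high_noise[i], ]
    lo <- p[p$clone_id == pairs$low_noise[i], ]
    if (!nrow(hi) || !nrow(lo))
      return(data.frame(cluster = pairs$cluster[i],
                        high_noise = pairs$high_noise[i],
                        low_noise = pairs$low_noise[i],
                        ratio = NA_real_, ratio_sd = NA_real_,
                        error = paste("pair", pairs$high_noise[i], "/",
                                      pairs$low_noise[i],
                                      "not resolvable in profiles")))
    if (lo$I == 0)
      return(data.frame(cluster = pairs$cluster[i],
                        high_noise = pairs$high_noise[i],
                        low_noise = pairs$low_noise[i],
                        ratio = NA_real_, ratio_sd = NA_real_,
                        error = "zero denominator"))
    ratio <- hi$I / lo$I
    rsd <- ratio * sqrt((hi$sd / hi$I)^2 + (lo$sd / lo$I)^2)
    data.frame(cluster = pairs$cluster[i], high_noise = pairs$high_noise[i],
               low_noise = pairs$low_noise[i], ratio = ratio, ratio_sd = rsd,
               error = NA_character_)
  })
  do.call(rbind, rows)
}

#' Regress fitted burst kinetics on chromatin inaccessibility
#'
#' Log-log regression of a fitted kinetic parameter (burst frequency by
#' default, burst size for the expected-null comparison) on chromatin
#' inaccessibility at one promoter site. Both orientations are returned
#' (`fit`: parameter on I, the headline orientation; `fit_reversed`: I on
#' parameter).
#'
#' @param profiles table from [chromatin_profiles()].
#' @param fits fit table (the `fits` element of [fit_cohort()]).
#' @param site promoter site name.
#' @param param `"burst_freq"` or `"burst_size"`.
#' @return List with `site`, `param`, `fit` (a `loglog_fit` of the parameter
#'   on I), `fit_reversed`, and `n`.
#' @export
kinetics_accessibility_regression <- function(profiles, fits, site,
                                              param = c("burst_freq",
                                                        "burst_size")) {
  param <- match.arg(param)
  p <- profiles[profiles$site == site, ]
  if (!nrow(p)) stop("site not present in profiles: ", site)
  col <- if (param == "burst_freq") "burst_freq_hat" else "burst_size_hat"
  m <- merge(p[, c("clone_id", "I")], fits[, c("clone_id", col)],
             by = "clone_id")
  m <- m[is.finite(m$I) & m$I > 0 & is.finite(m[[col]]) & m[[col]] > 0, ]
  if (nrow(m) < 3) stop("need at least 3 clones with both I and fits")
  list(site = site, param = param,
       fit = loglog_regression(m$I, m[[col]]),
       fit_reversed = loglog_regression(m[[col]], m$I),
       n = nrow(m))
}

#' PCA of chromatin inaccessibility and burst frequency
#'
#' Principal components of the standardized columns (log10 inaccessibility
#' at each site, log10 fitted burst frequency), computed by singular value
#' decomposition of the column-standardized matrix (i.e., on the correlation
#' scale). Sign convention: within each component the largest-magnitude
#' loading is made positive, so output is deterministic and invariant to row
#' order.
#'
#' @param profiles table from [chromatin_profiles()].
#' @param fits fit table with `clone_id` and `burst_freq_hat`.
#' @return List with `loadings` (variables x components), `explained`
#'   (variance fractions, summing to 1), `scores`, `f_axis` (the burst-
#'   frequency row of the loadings), `n`.
#' @export
chromatin_pca <- function(profiles, fits) {
  sites <- unique(profiles$site)
  wide <- NULL
  for (s in sites) {
    p <- profiles[profiles$site == s, c("clone_id", "I")]
    names(p)[2] <- paste0("log10_I_", s)
    p[[2]] <- log10(p[[2]])
    wide <- if (is.null(wide)) p else merge(wide, p, by = "clone_id")
  }
  wide <- merge(wide, data.frame(clone_id = fits$clone_id,
                                 log10_f = log10(fits$burst_freq_hat)),
                by = "clone_id")
  x <- as.matrix(wide[, -1])
  x <- x[apply(is.finite(x), 1, all), , drop = FALSE]
  if (nrow(x) < 3 || ncol(x) < 2) stop("need >= 3 clones and >= 2 variables")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  xs <- scale(x)
  sv <- svd(xs)
  loadings <- sv$v
  rownames(loadings) <- colnames(x)
  colnames(loadings) <- paste0("PC", seq_len(ncol(loadings)))
  # deterministic sign: largest-magnitude loading per component positive
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  ev <- sv$d^2 / sum(sv$d^2)
  scores <- xs %*% loadings
  list(loadings = loadings, explained = ev, scores = scores,
       f_axis = loadings["log10_f", ], n = nrow(x))
}
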