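#' Gate specification for density-mode scatter gating
#'
#' @param retain_fraction fraction of events to keep from the highest-density
#'   region of forward/side-scatter space (0 < fraction <= 1).
#' @param min_cells minimum number of retained events; the gate is enlarged
#'   (up to keeping everything) to meet it.
#' @param grid_size kernel-density evaluation grid per axis.
#' @return A `gate_spec` list.
#' @export
gate_spec <- function(retain_fraction = 0.2, min_cells = 4000,
                      grid_size = 128L) {
  if (retain_fraction <= 0 || retain_fraction > 1)
    stop("retain_fraction must lie in (0, 1]")
  if (min_cells < 1) stop("min_cells must be >= 1")
  structure(list(retain_fraction = retain_fraction,
                 min_cells = as.integer(min_cells),
                 grid_size = as.integer(grid_size)),
            class = "gate_spec")
}

#' Gate flow events on the density mode of forward/side scatter
#'
#' Estimates a 2D Gaussian kernel density on (FSC, SSC) (Silverman bandwidth
#' per axis, evaluated on a regular grid), interpolates the density at every
#' event, and keeps the events of highest density — the smallest
#' highest-density region containing `retain_fraction` of the events. If that
#' region holds fewer than `min_cells`, the fraction is enlarged until the
#' floor is met or all events are kept (flagged in the report). Gates are
#' nested: a larger `retain_fraction` always yields a superset.
#'
#' @param events data.frame with positive columns `FSC`, `SSC`, `GFP`.
#' @param gate a [gate_spec()].
#' @return List with `events` (the retained subset), `kept` (logical vector
#'   over the input), and `report` (requested and achieved fraction, flags).
#' @export
density_mode_gate <- function(events, gate = gate_spec()) {
  stopifnot(inherits(gate, "gate_spec"))
  if (!all(c("FSC", "SSC", "GFP") %in% names(events)))
    stop("events must have columns FSC, SSC, GFP")
  n <- nrow(events)
  if (n < 1) stop("events must be non-empty")
  report <- list(requested_fraction = gate$retain_fraction,
                 achieved_fraction = 1, n_input = n,
                 degenerate_kde = FALSE, below_min_cells = FALSE,
                 fraction_enlarged = FALSE)
  if (n == 1 || stats::sd(events$FSC) == 0 || stats::sd(events$SSC) == 0) {
    report$degenerate_kde <- TRUE
    return(list(events = events, kept = rep(TRUE, n), report = report))
  }
  if (n < gate$min_cells) {
    report$below_min_cells <- TRUE
    warning("fewer events than min_cells; keeping all events")
    return(list(events = events, kept = rep(TRUE, n), report = report))
  }
  dens <- event_density(events$FSC, events$SSC, gate$grid_size)
  frac <- gate$retain_fraction
  n_keep <- max(ceiling(frac * n), gate$min_cells)
  if (n_keep > ceiling(frac * n)) report$fraction_enlarged <- TRUE
  n_keep <- min(n_keep, n)
  # highest-density events; stable order tie-break for determinism
  ord <- order(dens, seq_len(n), decreasing = TRUE)
  kept <- logical(n)
  kept[ord[seq_len(n_keep)]] <- TRUE
  report$achieved_fraction <- n_keep / n
  list(events = events[kept, , drop = FALSE], kept = kept, report = report)
}

# per-event 2D KDE via bilinear interpolation of MASS::kde2d on a grid;
# bandwidth = Silverman's rule per axis
event_density <- function(x, y, grid_size) {
  hx <- stats::bw.nrd0(x); hy <- stats::bw.nrd0(y)
  k <- MASS::kde2d(x, y, h = c(4 * hx, 4 * hy), n = grid_size,
                   lims = c(range(x), range(y)))
  ix <- findInterval(x, k$x, rightmost.closed = TRUE, all.inside = TRUE)
  iy <- findInterval(y, k$y, rightmost.closed = TRUE, all.inside = TRUE)
  wx <- (x - k$x[ix]) / diff(k$x[1:2])
  wy <- (y - k$y[iy]) / diff(k$y[1:2])
  (1 - wx) * (1 - wy) * k$z[cbind(ix, iy)] +
    wx * (1 - wy) * k$z[cbind(ix + 1, iy)] +
    (1 - wx) * wy * k$z[cbind(ix, iy + 1)] +
    wx * wy * k$z[cbind(ix + 1, iy + 1)]
}

#' Scan the scaling slope across gate sizes
#'
#' For each retained fraction, gates every clone's events on the scatter
#' density mode, computes per-clone GFP mean and variance, and fits the
#' log-log variance-vs-mean regression. Used to show that the scaling slope
#' is invariant to gate size when expression is independent of cell scatter.
#'
#' @param events data.frame with columns `clone_id`, `FSC`, `SSC`, `GFP`.
#' @param fractions vector of retain fractions in (0, 1].
#' @param min_cells per-clone retained-event floor (small default so the scan
#'   works on modest synthetic cohorts).
#' @return data.frame with one row per fraction: `fraction`, `slope`,
#'   `slope_se`, `slope_lo`, `slope_hi`, `n_clones`.
#' @export
gate_robustness_scan <- function(events, fractions, min_cells = 10) {
  if (length(fractions) < 1) stop("fractions must be non-empty")
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]")
  ids <- unique(events$clone_id)
  if (length(ids) < 2) stop("need at least 2 clones")
  rows <- lapply(fractions, function(fr) {
    mom <- do.call(rbind, lapply(ids, function(id) {
      ev <- events[events$clone_id == id, ]
      g <- density_mode_gate(ev, gate_spec(retain_fraction = fr,
                                           min_cells = min_cells))
      data.frame(mean = mean(g$events$GFP), variance = stats::var(g$events$GFP))
    }))
    fit <- loglog_regression(mom$mean, mom$variance)
    data.frame(fraction = fr, slope = fit$slope, slope_se = fit$slope_se,
               slope_lo = fit$slope_ci[1], slope_hi = fit$slope_ci[2],
               n_clones = length(ids))
  })
  do.call(rbind, rows)
}

#' Cluster clone expression distributions on (mean, noise)
#'
#' Agglomerative hierarchical clustering (Ward linkage, Euclidean distance)
#' of clones on standardized `(log10 mean, log10 CV)`, the two axes along
#' which expression distributions vary. Deterministic.
#'
#' @param summaries per-clone moment table with columns `clone_id`, `mean`,
#'   `cv` (e.g. from [cohort_moments()]).
#' @param k number of clusters (1 <= k <= number of clones).
#' @return Integer cluster labels named by `clone_id`.
#' @export
cluster_clone_distributions <- function(summaries, k) {
  n <- nrow(summaries)
  if (k < 1 || k > n) stop("need n >= k >= 1")
  feats <- scale(cbind(log10(summaries$mean), log10(summaries$cv)))
  feats[is.nan(feats)] <- 0 # zero-variance feature: no contribution
  hc <- stats::hclust(stats::dist(feats), method = "ward.D2")
  labels <- stats::cutree(hc, k = k)
  names(labels) <- summaries$clone_id
  labels
}

#' Select matched-mean, contrasting-noise clone pairs per cluster
#'
#' Within each cluster, among all clone pairs whose log10 means differ by at
#' most `mean_tol`, returns the pair maximizing the log10 CV gap. Ties are
#' broken lexicographically on clone ids; clusters without an admissible pair
#' are skipped with a warning.
#'
#' @param summaries per-clone moment table (`clone_id`, `mean`, `cv`).
#' @param labels cluster labels named by `clone_id`.
#' @param mean_tol maximum |difference in log10 mean| within a pair.
#' @return data.frame with columns `cluster`, `high_noise`, `low_noise`,
#'   `dlog10_mean`, `dlog10_cv`.
#' @export
select_noise_pairs <- function(summaries, labels, mean_tol = 0.1) {
  stopifnot(all(summaries$clone_id %in% names(labels)))
  out <- list()
  for (cl in sort(unique(labels))) {
    ids <- names(labels)[labels == cl]
    s <- summaries[summaries$clone_id %in% ids, ]
    s <- s[order(s$clone_id), ]
    if (nrow(s) < 2) {
      warning("cluster ", cl, " has no admissible pair; skipped")
      next
    }
    best <- NULL
    for (i in seq_len(nrow(s) - 1)) for (j in (i + 1):nrow(s)) {
      dm <- abs(log10(s$mean[i]) - log10(s$mean[j]))
      if (dm > mean_tol) next
      dcv <- abs(log10(s$cv[i]) - log10(s$cv[j]))
      if (is.null(best) || dcv > best$dcv + 1e-15) # first-found wins ties
        best <- list(i = i, j = j, dm = dm, dcv = dcv)
    }
    if (is.null(best)) {
      warning("cluster ", cl, " has no admissible pair; skipped")
      next
    }
    hi <- if (s$cv[best$i] >= s$cv[best$j]) best$i else best$j
    lo <- if (hi == best$i) best$j else best$i
    out[[length(out) + 1]] <- data.frame(
      cluster = cl, high_noise = s$clone_id[hi], low_noise = s$clone_id[lo],
      dlog10_mean = best$dm, dlog10_cv = best$dcv)
  }
  if (!length(out))
    return(data.frame(cluster = integer(), high_noise = character(),
                      low_noise = character(), dlog10_mean = numeric(),
                      dlog10_cv = numeric()))
  do.call(rbind, out)
}

#' Infer multiplicity of infection from the fraction of positive cells
#'
#' Under Poisson infection statistics the fraction of infected cells is
#' `1 - exp(-MOI)`, so `MOI = -ln(1 - fraction_positive)`. A well with 5%
#' positive cells corresponds to an MOI of about 0.05, the low-MOI regime
#' ensuring at most one integration per infected cell.
#'
#' @param fraction_positive observed fraction of positive cells, in [0, 1).
#' @return The multiplicity of infection (infectious units per cell).
#' @examples
#' infer_moi(0.05) # ~0.0513
#' @export
infer_moi <- function(fraction_positive) {
  if (any(fraction_positive < 0)) stop("fraction_positive must be >= 0")
  if (any(fraction_positive >= 1)) stop("fraction_positive must be < 1")
  -log(1 - fraction_positive)
}
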