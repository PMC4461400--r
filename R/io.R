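#' Read and write the package's table formats
#'
#' Counts tables are TSV with columns `clone_id`, `cell_id`, `count`; flow
#' event tables are CSV with columns `FSC`, `SSC`, `GFP` (plus optional
#' `clone_id`); qPCR tables are CSV with columns `clone_id`, `site`,
#' `condition`, `replicate`, `Ct`. All readers validate their input.
#'
#' @param path file path.
#' @return `read_counts_tsv` returns the validated counts data.frame.
#' @name burstfit_io
NULL

#' @rdname burstfit_io
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("clone_id", "cell_id", "count")
  if (!all(need %in% names(df)))
    stop("counts TSV must have columns ", paste(need, collapse = ", "))
  if (any(df$count < 0) || any(df$count != round(df$count)))
    stop("counts must be non-negative integers")
  df$count <- as.integer(df$count)
  df
}

#' @rdname burstfit_io
#' @param counts_df counts table to write.
#' @export
write_counts_tsv <- function(counts_df, path) {
  utils::write.table(counts_df[, c("clone_id", "cell_id", "count")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname burstfit_io
#' @export
read_flow_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("FSC", "SSC", "GFP")
  if (!all(need %in% names(df)))
    stop("flow CSV must have columns ", paste(need, collapse = ", "))
  if (nrow(df) < 1) stop("flow table is empty")
  if (any(df$FSC <= 0) || any(df$SSC <= 0) || any(df$GFP <= 0))
    stop("flow channels must be positive")
  df
}

#' @rdname burstfit_io
#' @param events flow event table to write.
#' @export
write_flow_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname burstfit_io
#' @export
read_qpcr_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("clone_id", "site", "condition", "replicate", "Ct")
  if (!all(need %in% names(df)))
    stop("qPCR CSV must have columns ", paste(need, collapse = ", "))
  if (any(!df$condition %in% c("treated", "untreated")))
    stop("condition must be 'treated' or 'untreated'")
  if (any(!is.finite(df$Ct)) || any(df$Ct <= 0))
    stop("Ct values must be positive and finite")
  df
}

#' @rdname burstfit_io
#' @param qpcr qPCR table to write.
#' @export
write_qpcr_csv <- function(qpcr, path) {
  utils::write.csv(qpcr, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write telegraph parameters as YAML
#'
#' Parameters are serialized as a YAML record keyed `k_on`, `k_off`, `k_m`,
#' `delta`.
#'
#' @param params a `telegraph_params` object.
#' @param path file path.
#' @return `read_params_yaml` returns a `telegraph_params` object.
#' @export
write_params_yaml <- function(params, path) {
  stopifnot(inherits(params, "telegraph_params"))
  yaml::write_yaml(list(k_on = params$k_on, k_off = params$k_off,
                        k_m = params$k_m, delta = params$delta), path)
  invisible(path)
}

#' @rdname write_params_yaml
#' @export
read_params_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  telegraph_params(y$k_on, y$k_off, y$k_m, y$delta)
}

#' Write a generated cohort to a directory
#'
#' Writes the counts TSV, truth TSV and a manifest YAML echoing the full
#' configuration and seed.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_counts_tsv(cohort$counts_df, file.path(dir, "counts.tsv"))
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- cohort$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Write fit results as TSV and a JSON report
#'
#' @param cohort_fit result of [fit_cohort()].
#' @param tsv_path path for the per-clone fits TSV.
#' @param json_path optional path for a JSON report including the
#'   cross-regressions.
#' @return `tsv_path`, invisibly.
#' @export
write_fits <- function(cohort_fit, tsv_path, json_path = NULL) {
  utils::write.table(cohort_fit$fits, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path)) {
    regs <- lapply(cohort_fit$regressions, function(r)
      r[c("slope", "intercept", "slope_se", "slope_ci", "r_squared",
          "spearman_rs", "p_slope", "p_spearman", "n")])
    jsonlite::write_json(regs, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(tsv_path)
}
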