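# Sweep-table file format: a CSV whose first column is time (s) and whose
# remaining columns are sweeps named by stimulus amplitude in pA, plus a
# JSON sidecar (<file>.json) carrying cell id, clamp mode, units, sampling
# rate, protocol and provenance.

#' Write a sweep set to CSV + JSON sidecar
#'
#' @param sweepset a [sweep_set()].
#' @param path CSV path; the sidecar is written to `<path>.json`.
#' @param extra named list merged into the sidecar (e.g. condition,
#'   internal-solution flag, generator seed).
#' @return `path`, invisibly.
#' @export
write_sweep_set <- function(sweepset, path, extra = list()) {
  stopifnot(inherits(sweepset, "sweep_set"))
  p <- sweepset$protocol
  df <- data.frame(time = protocol_time(p), sweepset$sweeps,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- c(list(cell_id = sweepset$cell_id,
                 clamp = if (sweepset$units == "mV") "current" else "voltage",
                 units = sweepset$units,
                 sampling_rate = p$sampling_rate,
                 protocol = list(step_amplitudes = p$step_amplitudes,
                                 step_duration = p$step_duration,
                                 baseline_pre = p$baseline_pre,
                                 baseline_post = p$baseline_post)),
            extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a sweep set from CSV + JSON sidecar
#'
#' Validates that the sidecar amplitudes match the CSV headers and that
#' the sampling rate matches the row count.
#'
#' @param path CSV path written by [write_sweep_set()].
#' @return A [sweep_set()].
#' @export
read_sweep_set <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pr <- meta$protocol
  protocol <- stim_protocol(pr$step_amplitudes, pr$step_duration,
                            pr$baseline_pre, pr$baseline_post,
                            meta$sampling_rate)
  want <- format_amp(pr$step_amplitudes)
  have <- setdiff(names(df), "time")
  if (!identical(sort(want), sort(have)))
    stop("sidecar amplitudes do not match CSV columns in ", path)
  n_expect <- sum(unlist(protocol_samples(protocol)))
  if (nrow(df) != n_expect)
    stop("sampling_rate x duration (", n_expect, ") does not match row ",
         "count (", nrow(df), ") in ", path)
  sweep_set(protocol, as.matrix(df[, want, drop = FALSE]),
            units = meta$units, cell_id = meta$cell_id)
}

#' Write a features table as TSV
#' @param features data frame from [extract_features_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_features_tsv <- function(features, path) {
  utils::write.table(features, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a features TSV
#' @param path path written by [write_features_tsv()].
#' @return data frame.
#' @export
read_features_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
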