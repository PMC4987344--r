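#' Average IPSC trials into a measurement
#'
#' Pointwise mean across trials with the baseline (mean over the 100 ms
#' pre-stimulus window) subtracted. Currents are outward-positive.
#'
#' @param trials samples x trials numeric matrix, or a list of equal-length
#'   trial vectors.
#' @param time time base in seconds, 0 = stimulus onset.
#' @param condition condition label carried on the measurement.
#' @param baseline_s length of the pre-stimulus baseline window, s.
#' @param response_window window (s) in which the peak is sought.
#' @return An `ipsc_measurement`: list with `time`, `trace`
#'   (baseline-subtracted mean, pA), `baseline` (pA), `peak` (pA),
#'   `n_trials` and `condition`.
#' @export
average_trials <- function(trials, time, condition = "baseline",
                           baseline_s = 0.1, response_window = c(0, 0.5)) {
  if (is.list(trials) && !is.matrix(trials)) {
    if (length(unique(lengths(trials))) != 1)
      stop("trials have mismatched time bases")
    trials <- do.call(cbind, trials)
  }
  stopifnot(is.matrix(trials), nrow(trials) == length(time))
  avg <- rowMeans(trials)
  base_idx <- which(time >= -baseline_s & time < 0)
  if (!length(base_idx)) stop("no pre-stimulus baseline window in time base")
  baseline <- mean(avg[base_idx])
  trace <- avg - baseline
  resp <- which(time >= response_window[1] & time <= response_window[2])
  structure(list(time = time, trace = trace, baseline = baseline,
                 peak = max(trace[resp]), n_trials = ncol(trials),
                 condition = condition),
            class = "ipsc_measurement")
}

#' IPSC charge (area under the outward current)
#'
#' Trapezoidal integral of the outward (positive) part of the
#' baseline-subtracted current over the response window.
#'
#' @param measurement an `ipsc_measurement` (or a list with `time` and
#'   baseline-subtracted `trace`).
#' @param window integration window in seconds relative to stimulus onset.
#' @return Charge in pA*s (non-negative).
#' @export
charge <- function(measurement, window = c(0, 0.5)) {
  time <- measurement$time
  if (window[1] < time[1] - 1e-9 || window[2] > time[length(time)] + 1e-9)
    stop("integration window lies outside the trace")
  idx <- which(time >= window[1] & time <= window[2])
  y <- pmax(measurement$trace[idx], 0)
  t <- time[idx]
  sum(diff(t) * (y[-1] + y[-length(y)]) / 2)
}

#' Inclusion filter for averaged IPSCs
#'
#' Retains measurements whose peak amplitude reaches the minimum; smaller
#' IPSCs are not distinguishable from noise. Never adds measurements and is
#' order-independent.
#'
#' @param measurements list of `ipsc_measurement` objects.
#' @param min_amplitude minimum peak amplitude in pA (default 10).
#' @return Filtered list.
#' @export
include_filter <- function(measurements, min_amplitude = 10) {
  keep <- vapply(measurements, function(m) m$peak >= min_amplitude,
                 logical(1))
  measurements[keep]
}

#' Somatic/distal/residual decomposition of pyramidal-cell inhibition
#'
#' Decomposes the baseline inhibitory charge into the proximal (somatic)
#' contribution blocked by somatic gabazine, the distal (L1B dendritic)
#' contribution additionally blocked when gabazine is applied at both
#' sites, and the residual ("other") charge surviving the double block,
#' which is subtracted from the somatic and distal estimates:
#' `other = Q_both/Q_base`, `somatic = (Q_base - Q_soma)/Q_base`,
#' `distal = (Q_soma - Q_both)/Q_base` (all x100). The three percentages
#' sum to 100 by construction.
#'
#' @param q_base,q_soma,q_both charges (pA*s) at baseline, during somatic
#'   GZ and during simultaneous somatic + L1B GZ, from the same cell.
#' @return An `inhibition_decomposition`: list with `somatic_percent`,
#'   `distal_percent`, `other_percent` and `ordering_ok`.
#' @export
decompose <- function(q_base, q_soma, q_both) {
  stopifnot(is.finite(q_base), is.finite(q_soma), is.finite(q_both))
  if (q_base <= 0) stop("baseline charge must be positive")
  ordering_ok <- q_soma <= q_base && q_both <= q_soma
  if (!ordering_ok)
    warning("non-physical charge ordering (expected Q_both <= Q_soma <= ",
            "Q_base); percentages returned as computed")
  structure(list(somatic_percent = 100 * (q_base - q_soma) / q_base,
                 distal_percent = 100 * (q_soma - q_both) / q_base,
                 other_percent = 100 * q_both / q_base,
                 ordering_ok = ordering_ok),
            class = "inhibition_decomposition")
}

#' Measure and decompose a simulated gabazine experiment
#'
#' Averages the trials of each condition, computes charges and applies the
#' three-condition decomposition.
#'
#' @param experiment result of [simulate_ipsc_experiment()].
#' @param window integration window, s.
#' @return list with the per-condition `measurements`, `charges` and the
#'   `decomposition`.
#' @export
measure_ipsc_experiment <- function(experiment, window = c(0, 0.5)) {
  ms <- lapply(names(experiment$conditions), function(cond)
    average_trials(experiment$conditions[[cond]], experiment$time,
                   condition = cond))
  names(ms) <- names(experiment$conditions)
  qs <- vapply(ms, charge, numeric(1), window = window)
  dec <- if (all(c("baseline", "GZ-soma", "GZ-both") %in% names(qs)))
    decompose(qs[["baseline"]], qs[["GZ-soma"]], qs[["GZ-both"]])
  else NULL
  list(measurements = ms, charges = qs, decomposition = dec)
}

#' Paired within-slice comparison of IPSC strength
#'
#' Compares the inhibitory charge received by putative PV cells with that
#' of other interneuron classes recorded in the same slice: per-group
#' means, mean paired difference, and a Wilcoxon signed-rank test.
#'
#' @param paired_charges data frame or matrix with two columns: pPV charge
#'   and other-class charge per slice pair (pA*s).
#' @return list with `mean_ppv`, `mean_other`, `mean_difference`, `n` and
#'   `test` (a `test_result` from [run_test()]).
#' @export
compare_within_slice <- function(paired_charges) {
  m <- as.matrix(paired_charges)
  if (nrow(m) < 1) stop("at least one pair is required")
  stopifnot(ncol(m) == 2)
  res <- run_test("WSR", list(x = m[, 1], y = m[, 2]))
  list(mean_ppv = mean(m[, 1]), mean_other = mean(m[, 2]),
       mean_difference = mean(m[, 1] - m[, 2]), n = nrow(m), test = res)
}
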