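#' Current-step stimulus protocols
#'
#' A stimulus protocol describes a family of square current steps delivered
#' from rest: an ordered set of step amplitudes (pA), a common step duration,
#' and pre/post baseline periods, all sampled at a fixed rate.
#'
#' Two standard protocols are provided. The subthreshold protocol steps from
#' -50 to +50 pA in 10 pA increments (1 s steps) and supports input
#' resistance, membrane time constant and sag measurements. The
#' suprathreshold protocol steps from 0 to 1000 pA in 100 pA increments
#' (1 s steps) and supports rheobase, spike width, maximum firing rate and
#' interspike-interval measurements.
#'
#' @param step_amplitudes numeric vector of step amplitudes in pA.
#' @param step_duration step duration in seconds.
#' @param baseline_pre,baseline_post baseline durations in seconds before and
#'   after the step.
#' @param sampling_rate sampling rate in Hz.
#' @return An object of class `stim_protocol`.
#' @export
stim_protocol <- function(step_amplitudes, step_duration = 1,
                          baseline_pre = 0.2, baseline_post = 0.2,
                          sampling_rate = 10000) {
  stopifnot(is.numeric(step_amplitudes), length(step_amplitudes) >= 1,
            !anyDuplicated(step_amplitudes),
            step_duration > 0, baseline_pre >= 0, baseline_post >= 0,
            sampling_rate > 0)
  structure(list(step_amplitudes = as.numeric(step_amplitudes),
                 step_duration = step_duration,
                 baseline_pre = baseline_pre,
                 baseline_post = baseline_post,
                 sampling_rate = sampling_rate),
            class = "stim_protocol")
}

#' @rdname stim_protocol
#' @export
protocol_subthreshold <- function(sampling_rate = 10000) {
  stim_protocol(seq(-50, 50, by = 10), step_duration = 1,
                sampling_rate = sampling_rate)
}

#' @rdname stim_protocol
#' @export
protocol_suprathreshold <- function(sampling_rate = 10000) {
  stim_protocol(seq(0, 1000, by = 100), step_duration = 1,
                sampling_rate = sampling_rate)
}

# sample counts for the three protocol segments
protocol_samples <- function(protocol) {
  fs <- protocol$sampling_rate
  list(pre = round(protocol$baseline_pre * fs),
       step = round(protocol$step_duration * fs),
       post = round(protocol$baseline_post * fs))
}

# index vector of the step period within a sweep
step_index <- function(protocol) {
  ns <- protocol_samples(protocol)
  seq(ns$pre + 1L, ns$pre + ns$step)
}

protocol_time <- function(protocol) {
  ns <- protocol_samples(protocol)
  n <- ns$pre + ns$step + ns$post
  (seq_len(n) - 1) / protocol$sampling_rate
}

#' Construct a sweep set
#'
#' A sweep set is one cell's recording under a step protocol: a shared time
#' base and one sampled trace per stimulus amplitude.
#'
#' @param protocol a [stim_protocol()].
#' @param sweeps numeric matrix, samples in rows, one column per amplitude;
#'   column order follows `protocol$step_amplitudes`.
#' @param units trace units, `"mV"` (current clamp) or `"pA"` (voltage clamp).
#' @param cell_id cell identifier.
#' @param spike_times optional list (per sweep) of ground-truth spike times in
#'   seconds, carried by the synthetic generator.
#' @return An object of class `sweep_set`.
#' @export
sweep_set <- function(protocol, sweeps, units = "mV", cell_id = "cell",
                      spike_times = NULL) {
  stopifnot(inherits(protocol, "stim_protocol"), is.matrix(sweeps))
  ns <- protocol_samples(protocol)
  if (nrow(sweeps) != ns$pre + ns$step + ns$post)
    stop("sweep length does not match the protocol time base")
  if (ncol(sweeps) != length(protocol$step_amplitudes))
    stop("one sweep per protocol amplitude is required")
  colnames(sweeps) <- format_amp(protocol$step_amplitudes)
  structure(list(protocol = protocol, sweeps = sweeps, units = units,
                 cell_id = cell_id, spike_times = spike_times),
            class = "sweep_set")
}

format_amp <- function(a) sub("\\.0+$", "", format(a, trim = TRUE, scientific = FALSE))

#' Look up the sweep recorded at a given stimulus amplitude
#' @param x a [sweep_set()].
#' @param amplitude stimulus amplitude in pA.
#' @return numeric trace, or `NULL` if the amplitude is absent.
#' @export
sweep_at <- function(x, amplitude) {
  stopifnot(inherits(x, "sweep_set"))
  i <- match(amplitude, x$protocol$step_amplitudes)
  if (is.na(i)) return(NULL)
  x$sweeps[, i]
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> cell %s: %d sweeps x %d samples (%s), %g Hz\n",
              x$cell_id, ncol(x$sweeps), nrow(x$sweeps), x$units,
              x$protocol$sampling_rate))
  invisible(x)
}
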