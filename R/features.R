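#' Detect spikes in a voltage trace
#'
#' Identifies one spike per suprathreshold excursion: contiguous runs of
#' samples at or above the detection threshold are reduced to the sample of
#' their maximum, and events closer than the merge window are collapsed into
#' one. A derivative-based policy (`"dvdt"`) is available as an option; the
#' default fixed-voltage policy is adequate for stamped spike waveforms.
#'
#' @param trace numeric voltage trace (mV).
#' @param sampling_rate Hz.
#' @param threshold detection threshold in mV (default 0).
#' @param merge_window_ms events closer than this are merged (default 1 ms).
#' @param policy `"voltage"` (default) or `"dvdt"` (threshold applied to
#'   dV/dt in mV/ms).
#' @return A `spike_train`: list with `times` (s, strictly increasing),
#'   `index` (sample of each spike peak) and the detection parameters.
#' @export
detect_spikes <- function(trace, sampling_rate, threshold = 0,
                          merge_window_ms = 1, policy = c("voltage", "dvdt")) {
  policy <- match.arg(policy)
  if (any(!is.finite(trace))) stop("trace contains non-finite samples")
  x <- if (policy == "dvdt") c(0, diff(trace)) * sampling_rate / 1000 else trace
  above <- x >= threshold
  idx <- integer(0)
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    idx <- vapply(runs, function(k) {
      span <- starts[k]:ends[k]
      span[which.max(trace[span])]
    }, integer(1))
    # merge events closer than the merge window, keeping the taller peak
    if (length(idx) > 1) {
      min_gap <- merge_window_ms / 1000 * sampling_rate
      keep <- idx[1]
      for (i in idx[-1]) {
        if (i - keep[length(keep)] < min_gap) {
          if (trace[i] > trace[keep[length(keep)]]) keep[length(keep)] <- i
        } else keep <- c(keep, i)
      }
      idx <- keep
    }
  }
  structure(list(times = (idx - 1) / sampling_rate, index = idx,
                 threshold = threshold, merge_window_ms = merge_window_ms,
                 policy = policy, sampling_rate = sampling_rate),
            class = "spike_train")
}

# spikes restricted to the step period of a sweep
step_spikes <- function(trace, protocol, ...) {
  st <- detect_spikes(trace, protocol$sampling_rate, ...)
  keep <- st$index %in% step_index(protocol)
  st$times <- st$times[keep]
  st$index <- st$index[keep]
  st
}

# steady-state voltage deflection of one sweep: mean over the last
# `steady_ms` of the step minus the pre-step baseline mean
sweep_deflection <- function(trace, protocol, steady_ms = 100) {
  ns <- protocol_samples(protocol)
  fs <- protocol$sampling_rate
  k <- round(steady_ms / 1000 * fs)
  late <- seq(ns$pre + ns$step - k + 1L, ns$pre + ns$step)
  base <- if (ns$pre > 0) mean(trace[seq_len(ns$pre)]) else trace[1]
  mean(trace[late]) - base
}

#' Input resistance from subthreshold steps
#'
#' Ordinary least-squares slope of the steady-state voltage deflection
#' against injected current over steps between -50 and +50 pA. The
#' steady-state value of each sweep is the mean over the last 100 ms of the
#' step minus the pre-step baseline; sweeps containing spikes are excluded
#' from the fit.
#'
#' @param sweepset subthreshold [sweep_set()].
#' @param amp_range amplitudes (pA) admitted to the fit.
#' @param steady_ms length of the steady-state window, ms.
#' @return Input resistance in MOhm.
#' @export
input_resistance <- function(sweepset, amp_range = c(-50, 50),
                             steady_ms = 100) {
  stopifnot(inherits(sweepset, "sweep_set"))
  p <- sweepset$protocol
  amps <- p$step_amplitudes
  use <- which(amps >= amp_range[1] & amps <= amp_range[2])
  use <- use[vapply(use, function(j)
    length(detect_spikes(sweepset$sweeps[, j],
                         p$sampling_rate)$index) == 0, logical(1))]
  if (length(unique(amps[use])) < 3)
    stop("input resistance needs >= 3 spike-free amplitudes in ",
         amp_range[1], "..", amp_range[2], " pA")
  dv <- vapply(use, function(j)
    sweep_deflection(sweepset$sweeps[, j], p, steady_ms), numeric(1))
  fit <- stats::lm(dv ~ amps[use])
  unname(stats::coef(fit)[2]) * 1000   # mV/pA = GOhm -> MOhm
}

#' Membrane time constant from the -50 pA step
#'
#' Least-squares monoexponential fit of the falling phase of the voltage
#' response to a -50 pA step. The fit window runs from step onset to the
#' trough of a lightly smoothed copy of the trace (which ends the falling
#' phase when a sag relaxation is present), capped at five initial
#' time-constant guesses.
#'
#' @param sweepset subthreshold [sweep_set()] containing a -50 pA sweep.
#' @return Time constant in ms.
#' @export
time_constant <- function(sweepset) {
  tr <- sweep_at(sweepset, -50)
  if (is.null(tr)) stop("no -50 pA sweep present")
  p <- sweepset$protocol
  fs <- p$sampling_rate
  if (length(detect_spikes(tr, fs)$index))
    stop("spikes present in the -50 pA sweep; time constant unreliable")
  ns <- protocol_samples(p)
  base <- mean(tr[seq_len(ns$pre)])
  stepi <- step_index(p)
  sm <- smooth_boxcar(tr[stepi], round(0.002 * fs))
  i_tr <- which.min(sm)
  v_tr <- sm[i_tr]
  # initial guess: time to cover 63.2% of the drop
  drop <- base + 0.632 * (v_tr - base)
  i63 <- which(sm <= drop)[1]
  if (is.na(i63)) stop("no falling phase found on the -50 pA sweep")
  tau0 <- max(i63 / fs * 1000, 0.5)
  i_end <- min(i_tr, max(round(5 * tau0 / 1000 * fs), 80L))
  i_end <- max(i_end, 80L)   # never fit fewer than 8 ms of trace
  t_ms <- (seq_len(i_end) - 1) / fs * 1000
  y <- tr[stepi[seq_len(i_end)]]
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a + b * exp(-t_ms / tau),
                      start = list(a = v_tr, b = base - v_tr, tau = tau0),
                      lower = c(-Inf, -Inf, 0.1), upper = c(Inf, Inf, 500),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      cond <- simpleError(paste0("time-constant fit failed: ",
                                 conditionMessage(e)))
      cond$residuals <- y - mean(y)
      class(cond) <- c("tau_fit_failure", class(cond))
      stop(cond)
    })
  unname(stats::coef(fit)["tau"])
}

#' Sag amplitude from the -50 pA step
#'
#' Difference between the steady voltage over the last 100 ms of the step
#' and the onset value within the first 50 ms. The onset value is the
#' extremum (most hyperpolarised point) of a boxcar-smoothed copy of the
#' trace, so the measure is positive when the early hyperpolarisation
#' exceeds the late steady state, i.e. when the trace relaxes back toward
#' baseline.
#'
#' @param sweepset subthreshold [sweep_set()] containing a -50 pA sweep.
#' @param onset_ms onset search window, ms (default 50).
#' @param steady_ms steady-state window at the end of the step, ms.
#' @param smooth_ms boxcar width used to locate the onset extremum, ms.
#' @return Sag in mV.
#' @export
sag <- function(sweepset, onset_ms = 50, steady_ms = 100, smooth_ms = 10) {
  tr <- sweep_at(sweepset, -50)
  if (is.null(tr)) stop("no -50 pA sweep present")
  p <- sweepset$protocol
  fs <- p$sampling_rate
  if (length(detect_spikes(tr, fs)$index))
    stop("spikes present in the -50 pA sweep; sag unreliable")
  ns <- protocol_samples(p)
  if (ns$step / fs * 1000 < onset_ms + steady_ms)
    stop("step shorter than ", onset_ms + steady_ms, " ms")
  stepi <- step_index(p)
  k_on <- round(onset_ms / 1000 * fs)
  sm <- smooth_boxcar(tr[stepi[seq_len(k_on)]], round(smooth_ms / 1000 * fs))
  onset <- min(sm)
  k_st <- round(steady_ms / 1000 * fs)
  steady <- mean(tr[stepi[seq(length(stepi) - k_st + 1L, length(stepi))]])
  steady - onset
}

# centred moving average with partial windows at the edges (never falls
# back to raw samples, so the noise suppression is uniform)
smooth_boxcar <- function(x, k) {
  if (k <= 1) return(x)
  n <- length(x)
  h <- k %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Rheobase: minimum step current eliciting a spike
#'
#' Smallest amplitude whose sweep contains at least one spike during the
#' step. When a subthreshold sweep set is also supplied its sweeps are
#' pooled, so cells that reach threshold within the fine-grained
#' -50..+50 pA series resolve to a 10 pA grid rather than the coarse
#' 100 pA grid.
#'
#' @param suprathreshold suprathreshold [sweep_set()].
#' @param subthreshold optional subthreshold [sweep_set()] pooled into the
#'   search.
#' @return Rheobase in pA, or `NA` (with a message attribute) when no sweep
#'   spikes; the no-spike condition is flagged, not an error.
#' @export
rheobase <- function(suprathreshold, subthreshold = NULL) {
  stopifnot(inherits(suprathreshold, "sweep_set"))
  cand <- spiking_amplitudes(suprathreshold)
  if (!is.null(subthreshold)) cand <- c(cand, spiking_amplitudes(subthreshold))
  if (!length(cand)) return(structure(NA_real_, reason = "no sweep spiked"))
  min(cand)
}

spiking_amplitudes <- function(sweepset) {
  p <- sweepset$protocol
  amps <- p$step_amplitudes
  amps[vapply(seq_along(amps), function(j)
    length(step_spikes(sweepset$sweeps[, j], p)$index) > 0, logical(1))]
}

#' Spike width at half height
#'
#' Mean full width at half height over the spikes of the rheobase sweep.
#' The half-height level of each spike is the midpoint between the spike
#' peak and the voltage at the detection-threshold crossing (0 mV under the
#' default policy); crossing times on each flank are linearly interpolated
#' between samples.
#'
#' @param sweepset [sweep_set()] containing the rheobase sweep.
#' @param rheobase_amp amplitude (pA) of the rheobase sweep.
#' @return Width in ms, or `NA` if the sweep has no spikes.
#' @export
spike_width <- function(sweepset, rheobase_amp) {
  tr <- sweep_at(sweepset, rheobase_amp)
  if (is.null(tr)) stop("no sweep at ", rheobase_amp, " pA")
  p <- sweepset$protocol
  fs <- p$sampling_rate
  st <- step_spikes(tr, p)
  if (!length(st$index)) return(NA_real_)
  widths <- vapply(st$index, function(i)
    fwhm_at(tr, i, level = (tr[i] + st$threshold) / 2, fs), numeric(1))
  mean(widths, na.rm = TRUE)
}

# interpolated full width of the peak at `i` at the given level (ms)
fwhm_at <- function(tr, i, level, fs) {
  n <- length(tr)
  li <- i
  while (li > 1 && tr[li] > level) li <- li - 1L
  ri <- i
  while (ri < n && tr[ri] > level) ri <- ri + 1L
  if (tr[li] > level || tr[ri] > level) return(NA_real_)
  tl <- li + (level - tr[li]) / (tr[li + 1L] - tr[li])
  tr_ <- ri - 1L + (tr[ri - 1L] - level) / (tr[ri - 1L] - tr[ri])
  (tr_ - tl) / fs * 1000
}

#' Maximum firing rate over the suprathreshold series
#'
#' Maximum over sweeps of the spike count during the step divided by the
#' step duration.
#'
#' @param sweepset suprathreshold [sweep_set()].
#' @return Rate in Hz, or `NA` if no sweep spikes.
#' @export
max_firing_rate <- function(sweepset) {
  stopifnot(inherits(sweepset, "sweep_set"))
  p <- sweepset$protocol
  counts <- vapply(seq_len(ncol(sweepset$sweeps)), function(j)
    length(step_spikes(sweepset$sweeps[, j], p)$index), numeric(1))
  if (max(counts) == 0) return(NA_real_)
  max(counts) / p$step_duration
}

#' Interspike-interval statistics at rheobase + 100 pA
#'
#' Adaptation ratio (last interspike interval divided by the first) and
#' coefficient of variation of the interspike interval (sample standard
#' deviation over mean) computed on the sweep 100 pA above rheobase. When
#' that amplitude is not present, the smallest available amplitude above it
#' (or the highest sweep) is used and the deviation is flagged.
#'
#' @param sweepset suprathreshold [sweep_set()].
#' @param rheobase_amp rheobase in pA.
#' @return List with `adaptation_ratio`, `cv_isi`, `amplitude_used`,
#'   `flagged` (TRUE when a substitute amplitude was used) and `valid`
#'   (FALSE when fewer than 2 ISIs exist).
#' @export
isi_stats <- function(sweepset, rheobase_amp) {
  stopifnot(inherits(sweepset, "sweep_set"))
  p <- sweepset$protocol
  target <- rheobase_amp + 100
  amps <- p$step_amplitudes
  # candidate sweeps at/above the target (highest available as fallback);
  # walk upward until one carries >= 3 spikes -- a pausing cell may fire
  # too few spikes just above rheobase
  cand <- sort(amps[amps >= target])
  if (!length(cand)) cand <- max(amps)
  use <- cand[1]
  st <- step_spikes(sweep_at(sweepset, use), p)
  for (a in cand[-1]) {
    if (length(st$times) >= 3) break
    use <- a
    st <- step_spikes(sweep_at(sweepset, use), p)
  }
  flagged <- use != target
  if (length(st$times) < 3)
    return(list(adaptation_ratio = NA_real_, cv_isi = NA_real_,
                amplitude_used = use, flagged = flagged, valid = FALSE))
  isi <- diff(st$times)
  list(adaptation_ratio = isi[length(isi)] / isi[1],
       cv_isi = stats::sd(isi) / mean(isi),
       amplitude_used = use, flagged = flagged, valid = TRUE)
}

#' Extract the eight intrinsic properties of one cell
#'
#' Computes input resistance, membrane time constant and sag from the
#' subthreshold sweep set, and rheobase, spike width, maximum firing rate,
#' adaptation ratio and CV of the interspike interval from the
#' suprathreshold set. Features whose protocol or spikes are missing (for
#' example recordings made with a sodium-channel blocker in the pipette)
#' are flagged invalid rather than raising; per-feature failures propagate
#' as flags and never abort the vector.
#'
#' @param subthreshold subthreshold [sweep_set()] (required).
#' @param suprathreshold suprathreshold [sweep_set()] or `NULL`.
#' @return An `intrinsic_features` object: one-row data frame with columns
#'   `r_in`, `tau_m`, `sag`, `rheobase`, `spike_width`, `max_rate`, `ar`,
#'   `cv_isi` plus logical `*_valid` flags and the cell id.
#' @export
extract_features <- function(subthreshold, suprathreshold = NULL) {
  stopifnot(inherits(subthreshold, "sweep_set"))
  grab <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  r_in <- grab(input_resistance(subthreshold))
  tau_m <- grab(time_constant(subthreshold))
  sg <- grab(sag(subthreshold))
  rheo <- sw <- mfr <- ar <- cv <- NA_real_
  if (!is.null(suprathreshold)) {
    rheo <- grab(as.numeric(rheobase(suprathreshold, subthreshold)))
    if (is.finite(rheo)) {
      src <- if (rheo %in% suprathreshold$protocol$step_amplitudes)
        suprathreshold else subthreshold
      sw <- grab(spike_width(src, rheo))
      ist <- grab(isi_stats(suprathreshold, rheo))
      if (is.list(ist)) { ar <- ist$adaptation_ratio; cv <- ist$cv_isi }
    }
    mfr <- grab(max_firing_rate(suprathreshold))
  }
  out <- data.frame(cell_id = subthreshold$cell_id,
                    r_in = r_in, tau_m = tau_m, sag = sg, rheobase = rheo,
                    spike_width = sw, max_rate = mfr, ar = ar, cv_isi = cv,
                    stringsAsFactors = FALSE)
  for (f in feature_names())
    out[[paste0(f, "_valid")]] <- is.finite(out[[f]])
  class(out) <- c("intrinsic_features", "data.frame")
  out
}

#' Names of the eight intrinsic features
#' @return character vector in canonical order.
#' @export
feature_names <- function() {
  c("r_in", "tau_m", "sag", "rheobase", "spike_width", "max_rate",
    "ar", "cv_isi")
}

#' Subset of features measurable without spikes
#' @return character vector: input resistance, time constant, sag.
#' @export
subthreshold_features <- function() c("r_in", "tau_m", "sag")
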