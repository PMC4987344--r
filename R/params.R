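#' Membrane model parameters
#'
#' Parameters of the single-compartment adaptive leaky integrate-and-fire
#' model used by the synthetic generator. The model carries one Ih-like sag
#' state (conductance `sag_conductance` with reversal `sag_reversal` and
#' activation time constant `sag_time_constant`), one spike-triggered
#' adaptation current (`adaptation_increment`, `adaptation_time_constant`),
#' and a slow rectified Ornstein-Uhlenbeck modulation of the spike
#' threshold (`stutter_amplitude`, `stutter_time_constant`) that
#' intermittently gates excitability off, producing stuttering firing
#' while leaving subthreshold responses and the rheobase untouched. Spike shape is not part of the dynamics; a stylised waveform of
#' width `spike_shape_halfwidth` is stamped at each spike time so that spike
#' width extraction is exercised.
#'
#' @param membrane_capacitance pF.
#' @param leak_conductance nS.
#' @param resting_potential mV.
#' @param spike_threshold mV; must exceed `reset_potential`.
#' @param reset_potential mV.
#' @param refractory_period ms.
#' @param sag_conductance nS (0 disables the sag mechanism).
#' @param sag_time_constant ms.
#' @param sag_reversal mV; must differ from `resting_potential`.
#' @param adaptation_increment pA per spike (0 disables adaptation).
#' @param adaptation_time_constant ms.
#' @param stutter_amplitude scale (mV) of the rectified slow threshold
#'   modulation (0 disables stuttering).
#' @param stutter_time_constant ms.
#' @param noise_sd stationary subthreshold voltage noise, mV.
#' @param spike_shape_halfwidth ms, full width at half height of the stamped
#'   spike waveform as measured by the extraction convention.
#' @return An object of class `neuron_params`.
#' @export
neuron_params <- function(membrane_capacitance, leak_conductance,
                          resting_potential = -65, spike_threshold = -40,
                          reset_potential = -65, refractory_period = 2,
                          sag_conductance = 0, sag_time_constant = 40,
                          sag_reversal = -30,
                          adaptation_increment = 0,
                          adaptation_time_constant = 120,
                          stutter_amplitude = 0, stutter_time_constant = 250,
                          noise_sd = 0, spike_shape_halfwidth = 0.5) {
  p <- list(membrane_capacitance = membrane_capacitance,
            leak_conductance = leak_conductance,
            resting_potential = resting_potential,
            spike_threshold = spike_threshold,
            reset_potential = reset_potential,
            refractory_period = refractory_period,
            sag_conductance = sag_conductance,
            sag_time_constant = sag_time_constant,
            sag_reversal = sag_reversal,
            adaptation_increment = adaptation_increment,
            adaptation_time_constant = adaptation_time_constant,
            stutter_amplitude = stutter_amplitude,
            stutter_time_constant = stutter_time_constant,
            noise_sd = noise_sd,
            spike_shape_halfwidth = spike_shape_halfwidth)
  validate_neuron_params(p)
  structure(p, class = "neuron_params")
}

validate_neuron_params <- function(p) {
  nonneg <- c("membrane_capacitance", "leak_conductance", "refractory_period",
              "sag_conductance", "sag_time_constant",
              "adaptation_increment", "adaptation_time_constant",
              "stutter_amplitude", "stutter_time_constant", "noise_sd",
              "spike_shape_halfwidth")
  for (f in nonneg)
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || !is.finite(p[[f]]) ||
        p[[f]] < 0)
      stop(sprintf("'%s' must be a single non-negative number", f))
  if (p$membrane_capacitance <= 0 || p$leak_conductance <= 0)
    stop("capacitance and leak conductance must be positive")
  if (p$reset_potential >= p$spike_threshold)
    stop("reset_potential must be below spike_threshold")
  if (p$sag_conductance > 0 && p$sag_reversal == p$resting_potential)
    stop("sag_reversal must differ from resting_potential")
  invisible(p)
}

# parameter vector in the layout expected by the C++ integrator
params_vector <- function(p) {
  c(p$membrane_capacitance, p$leak_conductance, p$resting_potential,
    p$spike_threshold, p$reset_potential, p$refractory_period,
    p$sag_conductance, p$sag_time_constant, p$sag_reversal,
    p$adaptation_increment, p$adaptation_time_constant,
    p$stutter_amplitude, p$stutter_time_constant, p$noise_sd)
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("<neuron_params>\n")
  for (f in names(x)) cat(sprintf("  %-26s %g\n", f, x[[f]]))
  invisible(x)
}
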