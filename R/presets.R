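# Preset registry for the synthetic interneuron generator.
#
# Each preset is parameterised by physiological "knobs" (steady-state input
# resistance, sag depth, membrane time constant, continuous threshold
# current, spike half-width, refractory period, adaptation increment, noise
# and stutter settings) from which the mechanistic model parameters are
# derived in closed form. Knob centres are calibrated so that the feature
# EXTRACTION pipeline, run on simulated populations, reproduces the
# published population means for each identified interneuron class; the
# per-knob lognormal jitter is set from the published standard errors
# (SD ~ SE * sqrt(n)). Achieved values are documented in the methods
# vignette.

preset_registry <- function() {
  list(
    "RS-SST" = list(
      class = "SST", phenotype = "RS",
      knobs = list(rss = 183.2, sagr = 27.41, tau_ms = 15.71, rheo_cont = 206.9,
                   hw = 1.149, tref = 5.458, b = 41.53, tauw = 300, taus = 40,
                   noise = 0.18, stut_amp = 13.91, stut_tau = 300),
      cv = c(rss = 0.62, sagr = 0.75, tau_ms = 0.38, rheo_cont = 0.55,
             hw = 0.40, tref = 0.45, b = 0.70, noise = 0.45, stut_amp = 0.3)),
    "GIN-RS" = list(
      class = "GIN", phenotype = "RS",
      knobs = list(rss = 217, sagr = 37.06, tau_ms = 19.44, rheo_cont = 156.5,
                   hw = 1.804, tref = 7.157, b = 58.2, tauw = 300, taus = 40,
                   noise = 0.14, stut_amp = 0.05, stut_tau = 300),
      cv = c(rss = 0.65, sagr = 0.90, tau_ms = 0.42, rheo_cont = 0.38,
             hw = 0.22, tref = 0.30, b = 0.65, noise = 0.40, stut_amp = 0.3)),
    "FS-SST-tonic" = list(
      class = "SST", phenotype = "FS-tonic",
      knobs = list(rss = 116.5, sagr = 14.1, tau_ms = 6.988, rheo_cont = 341.3,
                   hw = 0.423, tref = 2.419, b = 8.602, tauw = 120, taus = 40,
                   noise = 0.15, stut_amp = 4.024, stut_tau = 400),
      cv = c(rss = 0.34, sagr = 0.55, tau_ms = 0.32, rheo_cont = 0.28,
             hw = 0.16, tref = 0.28, b = 0.70, noise = 0.50, stut_amp = 0.3)),
    "FS-SST-stutter" = list(
      class = "SST", phenotype = "FS-stutter",
      knobs = list(rss = 116.5, sagr = 14.1, tau_ms = 6.988, rheo_cont = 337.7,
                   hw = 0.4184, tref = 2.73, b = 0.09283, tauw = 120, taus = 40,
                   noise = 0.15, stut_amp = 25, stut_tau = 400),
      cv = c(rss = 0.34, sagr = 0.55, tau_ms = 0.32, rheo_cont = 0.28,
             hw = 0.16, tref = 0.28, b = 0.70, noise = 0.50,
             stut_amp = 0.3)),
    "FS-PV-stutter" = list(
      class = "PV", phenotype = "FS-stutter",
      knobs = list(rss = 76.3, sagr = 0.3438, tau_ms = 4.827, rheo_cont = 429.9,
                   hw = 0.4036, tref = 2.426, b = 0.0001, tauw = 120, taus = 40,
                   noise = 0.12, stut_amp = 25, stut_tau = 400),
      cv = c(rss = 0.34, sagr = 0.25, tau_ms = 0.26, rheo_cont = 0.26,
             hw = 0.16, tref = 0.30, b = 0.70, noise = 0.50,
             stut_amp = 0.3)),
    "FS-PV-tonic" = list(
      class = "PV", phenotype = "FS-tonic",
      knobs = list(rss = 76.3, sagr = 0.3438, tau_ms = 4.827, rheo_cont = 430.6,
                   hw = 0.4036, tref = 2.767, b = 0.04185, tauw = 120, taus = 40,
                   noise = 0.12, stut_amp = 7.527, stut_tau = 400),
      cv = c(rss = 0.34, sagr = 0.25, tau_ms = 0.26, rheo_cont = 0.26,
             hw = 0.16, tref = 0.30, b = 0.70, noise = 0.50, stut_amp = 0.3)),
    "G42-APC" = list(
      class = "G42", phenotype = "adapting",
      knobs = list(rss = 468.7, sagr = 135, tau_ms = 28.68, rheo_cont = 74.61,
                   hw = 1.003, tref = 9.444, b = 46.46, tauw = 300, taus = 80,
                   noise = 0.15, stut_amp = 0.7448, stut_tau = 300),
      cv = c(rss = 0.33, sagr = 0.60, tau_ms = 0.35, rheo_cont = 0.60,
             hw = 0.20, tref = 0.35, b = 0.70, noise = 0.40, stut_amp = 0.3)),
    "G42-Neo" = list(
      class = "G42-Neo", phenotype = "FS-tonic",
      knobs = list(rss = 64.51, sagr = 1.976, tau_ms = 4.413, rheo_cont = 532.4,
                   hw = 0.3661, tref = 1.106, b = 1.853, tauw = 120, taus = 40,
                   noise = 0.12, stut_amp = 6.613, stut_tau = 400),
      cv = c(rss = 0.12, sagr = 0.90, tau_ms = 0.22, rheo_cont = 0.12,
             hw = 0.35, tref = 0.15, b = 0.45, noise = 0.50, stut_amp = 0.3)),
    "PC" = list(
      class = "PC", phenotype = "RS",
      knobs = list(rss = 184.3, sagr = 42.09, tau_ms = 22.84, rheo_cont = 156.4,
                   hw = 1.202, tref = 12, b = 31.79, tauw = 300, taus = 60,
                   noise = 0.15, stut_amp = 0.1711, stut_tau = 300),
      cv = c(rss = 0.30, sagr = 0.50, tau_ms = 0.30, rheo_cont = 0.30,
             hw = 0.15, tref = 0.25, b = 0.50, noise = 0.40, stut_amp = 0.3))
  )
}

# map physiological knobs to mechanistic model parameters
params_from_knobs <- function(k, EL = -65, Eh = -30) {
  r0 <- k$rss + k$sagr                     # MOhm, instantaneous resistance
  gl <- 1000 / r0                          # nS
  gs <- 1000 / k$rss - gl
  neuron_params(
    membrane_capacitance = k$tau_ms * gl,  # pF
    leak_conductance = gl,
    resting_potential = EL,
    # threshold capped below the stamped spike peak
    spike_threshold = min(EL + max(k$rheo_cont * k$rss / 1000, 2), -20),
    reset_potential = EL,
    refractory_period = k$tref,
    sag_conductance = gs,
    sag_time_constant = k$taus,
    sag_reversal = Eh,
    adaptation_increment = k$b,
    adaptation_time_constant = k$tauw,
    stutter_amplitude = k$stut_amp,
    stutter_time_constant = k$stut_tau,
    noise_sd = k$noise,
    spike_shape_halfwidth = k$hw)
}

#' Model parameters for a named interneuron preset
#'
#' Returns the calibrated centre parameters of one of the identified
#' interneuron classes. `FS-SST-tonic` / `FS-SST-stutter` and
#' `FS-PV-stutter` / `FS-PV-tonic` share subthreshold calibration and
#' differ in their firing-irregularity mechanism.
#'
#' @param name one of `preset_names()`.
#' @return A [neuron_params()] object.
#' @export
make_preset <- function(name) {
  reg <- preset_registry()
  if (!name %in% names(reg))
    stop("unknown preset '", name, "'; valid presets: ",
         paste(names(reg), collapse = ", "))
  params_from_knobs(reg[[name]]$knobs)
}

#' @rdname make_preset
#' @export
preset_names <- function() names(preset_registry())

# Mean-preserving truncated-lognormal jitter of the knob centres.
#
# Deviates are truncated at +/- 2 SD: real cells occupy a physiological
# range, and untruncated lognormal tails produce singleton outlier
# clusters that no recorded cohort shows and that derail a k = 2 Ward
# cut. The normalisation keeps each knob's population mean at its centre.
rnorm_trunc2 <- function() {
  z <- stats::rnorm(1)
  while (abs(z) > 2) z <- stats::rnorm(1)
  z
}

# E[exp(a * Z)] for Z standard normal truncated at +/- 2
exp_mean_trunc2 <- function(a) {
  exp(a^2 / 2) * (stats::pnorm(2 - a) - stats::pnorm(-2 - a)) /
    (stats::pnorm(2) - stats::pnorm(-2))
}

jitter_knobs <- function(k, cv, variability_scale) {
  for (f in names(cv)) {
    s <- sqrt(log(1 + cv[[f]]^2)) * variability_scale
    if (s > 0 && k[[f]] > 0)
      k[[f]] <- k[[f]] * exp(s * rnorm_trunc2()) / exp_mean_trunc2(s)
  }
  k
}

#' Simulate a population of cells from a preset
#'
#' Draws per-cell parameters by mean-preserving lognormal jitter of the
#' preset knobs (jitter magnitudes calibrated to the published population
#' standard errors), then runs the subthreshold and suprathreshold step
#' protocols on every cell. Reproducible for a fixed seed.
#'
#' @param preset_name one of `preset_names()`, or a vector of length `n`
#'   giving a preset per cell.
#' @param n number of cells.
#' @param variability_scale multiplies the per-knob lognormal jitter; 0
#'   yields `n` identical copies of the preset centre.
#' @param seed integer seed.
#' @param protocols which protocols to run: `"both"` (default), `"sub"`, or
#'   `"supra"`.
#' @return List of cells; each cell is a list with `record` (cell id,
#'   preset, class label, phenotype), `params`, and sweep sets `sub` and/or
#'   `supra`.
#' @export
simulate_population <- function(preset_name, n, variability_scale = 1,
                                seed = 1, protocols = c("both", "sub", "supra")) {
  protocols <- match.arg(protocols)
  stopifnot(n >= 1, variability_scale >= 0)
  reg <- preset_registry()
  presets <- if (length(preset_name) == 1) rep(preset_name, n) else preset_name
  stopifnot(length(presets) == n, all(presets %in% names(reg)))
  set.seed(seed)
  sub_p <- protocol_subthreshold()
  sup_p <- protocol_suprathreshold()
  lapply(seq_len(n), function(i) {
    entry <- reg[[presets[i]]]
    k <- jitter_knobs(entry$knobs, entry$cv, variability_scale)
    par <- params_from_knobs(k)
    id <- sprintf("%s_%03d", presets[i], i)
    cell <- list(record = list(cell_id = id, preset = presets[i],
                               class = entry$class,
                               phenotype = entry$phenotype),
                 params = par)
    if (protocols %in% c("both", "sub"))
      cell$sub <- simulate_membrane(par, sub_p, cell_id = id)
    if (protocols %in% c("both", "supra"))
      cell$supra <- simulate_membrane(par, sup_p, cell_id = id)
    cell
  })
}

#' Simulate the mixed fast-spiking cohort
#'
#' The classification cohort: fast-spiking cells of the SST line (a
#' tonic/stuttering mix) together with fast-spiking PV-line cells
#' (predominantly stuttering). Defaults follow the recorded composition:
#' 14 SST-like FS cells of which 3 stutter, and 11 PV-like FS cells of
#' which 3 are tonic.
#'
#' @param seed integer seed.
#' @param n_sst,n_pv cells per line.
#' @param sst_stutter number of stuttering cells among the SST group.
#' @param pv_tonic number of tonic cells among the PV group.
#' @param variability_scale passed to [simulate_population()].
#' @return List of cells as in [simulate_population()].
#' @export
simulate_fs_cohort <- function(seed = 1, n_sst = 14, n_pv = 11,
                               sst_stutter = 3, pv_tonic = 3,
                               variability_scale = 1) {
  stopifnot(sst_stutter <= n_sst, pv_tonic <= n_pv)
  presets <- c(rep("FS-SST-tonic", n_sst - sst_stutter),
               rep("FS-SST-stutter", sst_stutter),
               rep("FS-PV-stutter", n_pv - pv_tonic),
               rep("FS-PV-tonic", pv_tonic))
  simulate_population(presets, length(presets), seed = seed,
                      variability_scale = variability_scale)
}

#' Extract features for a list of simulated cells
#'
#' @param cells list of cells from [simulate_population()].
#' @return Data frame: one row per cell with class labels and the eight
#'   features plus validity flags.
#' @export
extract_features_table <- function(cells) {
  rows <- lapply(cells, function(cell) {
    feats <- extract_features(cell$sub, cell$supra)
    cbind(data.frame(preset = cell$record$preset, class = cell$record$class,
                     phenotype = cell$record$phenotype,
                     stringsAsFactors = FALSE),
          feats)
  })
  do.call(rbind, rows)
}
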