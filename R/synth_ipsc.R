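# Synthetic light-evoked IPSC experiments.
#
# A scenario describes the compound inhibitory input to one recorded cell
# as two separable components -- somatic (proximal) and dendritic (distal,
# L1B) -- each a train of peak-normalised difference-of-exponential events
# triggered within the 20 ms light window. Local gabazine (GZ) application
# suppresses the targeted component to `residual_fraction`; applying GZ at
# both sites suppresses both. Currents are outward-positive (recorded at
# 0 mV).

#' Synaptic component description
#' @param amplitude event peak amplitude, pA (outward positive).
#' @param rise,decay kinetics in ms (`rise < decay`).
#' @param count number of events in the light window.
#' @return list describing the component.
#' @export
synapse_component <- function(amplitude, rise, decay, count) {
  stopifnot(amplitude >= 0, rise > 0, decay > rise, count >= 1)
  list(amplitude = amplitude, rise = rise, decay = decay,
       count = as.integer(count))
}

#' IPSC experiment scenario
#'
#' @param somatic,dendritic [synapse_component()] descriptions.
#' @param residual_fraction fraction of a component surviving full local
#'   block (0..1).
#' @param trial_noise_sd per-sample trial noise, pA.
#' @param n_trials trials per condition.
#' @param dendritic_delay_ms extra conduction/filtering delay of the distal
#'   component, ms.
#' @return object of class `synapse_scenario`.
#' @export
synapse_scenario <- function(somatic, dendritic, residual_fraction,
                             trial_noise_sd = 2, n_trials = 10,
                             dendritic_delay_ms = 1.5) {
  stopifnot(residual_fraction >= 0, residual_fraction <= 1,
            trial_noise_sd >= 0)
  if (n_trials < 1) stop("n_trials must be >= 1")
  structure(list(somatic = somatic, dendritic = dendritic,
                 residual_fraction = residual_fraction,
                 trial_noise_sd = trial_noise_sd,
                 n_trials = as.integer(n_trials),
                 dendritic_delay_ms = dendritic_delay_ms,
                 light_window_ms = 20),
            class = "synapse_scenario")
}

#' Analytic expected charge of a scenario component
#' @param component a [synapse_component()].
#' @return charge in pA*s.
#' @export
component_charge <- function(component) {
  component$count *
    doe_event_charge(component$amplitude, component$rise, component$decay)
}

# condition -> per-component survival factors
condition_block_map <- function(residual) {
  list("baseline" = c(somatic = 1, dendritic = 1),
       "GZ-soma" = c(somatic = residual, dendritic = 1),
       "GZ-L1B" = c(somatic = 1, dendritic = residual),
       "GZ-both" = c(somatic = residual, dendritic = residual))
}

#' Simulate a light-evoked IPSC experiment
#'
#' Generates per-trial current traces for the four pharmacological
#' conditions. Each trial is the sum of the active components' event
#' waveforms (events evenly spread over the light window, the dendritic
#' component delayed) plus white trial noise. Deterministic under a fixed
#' seed.
#'
#' @param scenario a [synapse_scenario()].
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @param conditions which conditions to simulate.
#' @param pre_s,post_s pre-stimulus and post-onset durations, s.
#' @param sampling_rate Hz.
#' @return list with `time` (s, 0 = light onset) and `conditions`, a named
#'   list of samples x trials matrices (pA).
#' @export
simulate_ipsc_experiment <- function(scenario, seed = NULL,
                                     conditions = names(condition_block_map(0)),
                                     pre_s = 0.1, post_s = 0.6,
                                     sampling_rate = 10000) {
  stopifnot(inherits(scenario, "synapse_scenario"))
  if (!is.null(seed)) set.seed(seed)
  dt <- 1000 / sampling_rate                      # ms
  n <- round((pre_s + post_s) * sampling_rate)
  t0 <- -pre_s * 1000
  time <- (t0 + (seq_len(n) - 1) * dt) / 1000
  ev_times <- function(comp, delay = 0)
    (seq_len(comp$count) - 0.5) / comp$count * scenario$light_window_ms + delay
  tmpl <- function(comp, delay = 0) {
    if (comp$amplitude == 0) return(numeric(n))
    doe_events_cpp(n, t0, dt, ev_times(comp, delay), comp$amplitude,
                   comp$rise, comp$decay)
  }
  som <- tmpl(scenario$somatic)
  den <- tmpl(scenario$dendritic, scenario$dendritic_delay_ms)
  blocks <- condition_block_map(scenario$residual_fraction)
  out <- lapply(conditions, function(cond) {
    f <- blocks[[cond]]
    if (is.null(f)) stop("unknown condition '", cond, "'")
    clean <- f["somatic"] * som + f["dendritic"] * den
    trials <- matrix(clean, n, scenario$n_trials)
    if (scenario$trial_noise_sd > 0)
      trials <- trials + matrix(stats::rnorm(n * scenario$n_trials,
                                             0, scenario$trial_noise_sd),
                                n, scenario$n_trials)
    trials
  })
  names(out) <- conditions
  list(time = time, conditions = out, scenario = scenario)
}

#' Default pyramidal-cell inhibition scenario
#'
#' Compound SST-mediated inhibition of an L3 pyramidal cell recorded with a
#' caesium internal: total baseline charge ~40.6 pA*s split between a
#' proximal somatic component (~56%) and a distal dendritic component
#' (~44%), with 12% of either component surviving full local block.
#'
#' @param total_charge total baseline charge, pA*s.
#' @param dendritic_fraction fraction of the total charge carried by the
#'   distal component.
#' @param residual_fraction fraction surviving full block.
#' @param trial_noise_sd,n_trials trial structure.
#' @return a [synapse_scenario()].
#' @export
default_pc_scenario <- function(total_charge = 40.6,
                                dendritic_fraction = 0.443,
                                residual_fraction = 0.12,
                                trial_noise_sd = 2, n_trials = 10) {
  q_som <- total_charge * (1 - dendritic_fraction)
  q_den <- total_charge * dendritic_fraction
  som <- synapse_component(
    amplitude = q_som / 4 / doe_event_charge(1, 1, 15),
    rise = 1, decay = 15, count = 4)
  den <- synapse_component(
    amplitude = q_den / 5 / doe_event_charge(1, 3, 25),
    rise = 3, decay = 25, count = 5)
  synapse_scenario(som, den, residual_fraction,
                   trial_noise_sd = trial_noise_sd, n_trials = n_trials)
}

#' Simulate a cohort of pyramidal-cell gabazine experiments
#'
#' Draws per-cell scenarios around the default pyramidal-cell scenario
#' (lognormal jitter of the overall strength; normal jitter of the
#' dendritic split and the block residual) and simulates every condition
#' for each cell.
#'
#' @param n number of cells.
#' @param seed integer seed.
#' @param scenario centre scenario, by default [default_pc_scenario()].
#' @param scale_cv lognormal coefficient of variation of the per-cell
#'   overall strength.
#' @param split_sd standard deviation of the per-cell dendritic fraction.
#' @param residual_sd standard deviation of the per-cell residual fraction.
#' @return list of experiments (as from [simulate_ipsc_experiment()]), each
#'   carrying its ground-truth scenario.
#' @export
simulate_pc_cohort <- function(n = 6, seed = 1, scenario = NULL,
                               scale_cv = 0.55, split_sd = 0.08,
                               residual_sd = 0.03) {
  set.seed(seed)
  base_total <- 40.6
  base_split <- 0.443
  base_resid <- 0.12
  if (!is.null(scenario)) {
    base_total <- component_charge(scenario$somatic) +
      component_charge(scenario$dendritic)
    base_split <- component_charge(scenario$dendritic) / base_total
    base_resid <- scenario$residual_fraction
  }
  s <- sqrt(log(1 + scale_cv^2))
  lapply(seq_len(n), function(i) {
    tot <- base_total * exp(stats::rnorm(1, 0, s) - s^2 / 2)
    spl <- min(0.9, max(0.1, stats::rnorm(1, base_split, split_sd)))
    res <- min(0.4, max(0.02, stats::rnorm(1, base_resid, residual_sd)))
    sc <- default_pc_scenario(total_charge = tot, dendritic_fraction = spl,
                              residual_fraction = res)
    simulate_ipsc_experiment(sc)
  })
}
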