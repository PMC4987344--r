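test_that("spike detection finds one spike per excursion and none when flat", {
  expect_length(detect_spikes(rep(-65, 1000), 10000)$times, 0)
  idx <- c(1500, 3000, 5200)
  v <- template_spike_trace(10000, idx)
  st <- detect_spikes(v, 10000)
  expect_equal(st$index, idx)
  expect_error(detect_spikes(c(0, NA, 0), 10000), "non-finite")
})

test_that("spike detection merges crossings within the merge window", {
  # two peaks 0.5 ms apart collapse into one detected spike
  v <- template_spike_trace(4000, c(2000, 2005), sigma_ms = 0.1)
  expect_length(detect_spikes(v, 10000)$index, 1)
  v2 <- template_spike_trace(4000, c(2000, 2030), sigma_ms = 0.1)
  expect_length(detect_spikes(v2, 10000)$index, 2)
})

test_that("input resistance of ideal ohmic sweeps is exact", {
  ss <- ohmic_sweep_set(r_mohm = 100)
  expect_equal(input_resistance(ss), 100, tolerance = 1e-10)
})

test_that("input resistance equals the normal-equations OLS oracle", {
  set.seed(42)
  ss <- ohmic_sweep_set(r_mohm = 150, noise_sd = 0.3)
  p <- ss$protocol
  amps <- p$step_amplitudes
  dv <- vapply(seq_along(amps), function(j)
    apcephys:::sweep_deflection(ss$sweeps[, j], p), numeric(1))
  X <- cbind(1, amps)
  beta <- solve(t(X) %*% X, t(X) %*% dv)
  expect_equal(input_resistance(ss), beta[2] * 1000, tolerance = 1e-9)
})

test_that("input resistance is unbiased on noisy ohmic sweeps", {
  set.seed(7)
  est <- replicate(40, input_resistance(ohmic_sweep_set(150, noise_sd = 0.2)))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 150), 3 * se + 0.05)
})

test_that("input resistance requires at least three spike-free amplitudes", {
  pr <- stim_protocol(c(-50, 0), step_duration = 0.3, baseline_pre = 0.05,
                      baseline_post = 0.05)
  ss <- ohmic_sweep_set(100, protocol = pr)
  expect_error(input_resistance(ss), ">= 3")
})

test_that("time constant is recovered on traces of the exact model class", {
  ss <- rc_sweep_set(r_mohm = 100, tau_ms = 10)
  expect_equal(time_constant(ss), 10, tolerance = 0.01)
  # generator ground truth: tau = C/gL
  p <- neuron_params(membrane_capacitance = 80, leak_conductance = 10)
  sim <- simulate_membrane(p, fast_sub_protocol(), seed = 2)
  expect_equal(time_constant(sim), 8, tolerance = 0.01)
})

test_that("sag is at the noise floor for passive cells and grows with the sag conductance", {
  p0 <- neuron_params(membrane_capacitance = 50, leak_conductance = 10)
  pr <- fast_sub_protocol()
  expect_lt(abs(sag(simulate_membrane(p0, pr, seed = 3))), 0.05)
  sags <- vapply(c(0.5, 1.5, 3), function(gs) {
    p <- neuron_params(membrane_capacitance = 50, leak_conductance = 10,
                       sag_conductance = gs, sag_time_constant = 40)
    sag(simulate_membrane(p, pr, seed = 3))
  }, numeric(1))
  expect_true(all(diff(sags) > 0))
  expect_gt(sags[1], 0.05)
})

test_that("sag matches the closed-form two-exponential steady-state difference", {
  # steady state: R_ss = 1/(gL + gs_eff); early extremum ~ R0 = 1/gL.
  # with taus >> tau_m and a long step, sag ~ |I| (R0 - Rss)
  gl <- 10; gs <- 1
  p <- neuron_params(membrane_capacitance = 30, leak_conductance = gl,
                     sag_conductance = gs, sag_time_constant = 120,
                     sag_reversal = -30)
  pr <- stim_protocol(c(-50, -40, -30), step_duration = 1,
                      baseline_pre = 0.1, baseline_post = 0.1)
  s <- sag(simulate_membrane(p, pr, seed = 4))
  # effective sag conductance at the -50 pA operating point: the linearised
  # activation carries (Eh - V)/(Eh - EL) ~ 1 + dV/(Eh - EL)
  dv <- -50 / (gl + gs)              # operating deflection, mV (pA/nS)
  gs_eff <- gs * (1 + dv / 35)
  expected <- 50 * (1 / gl - 1 / (gl + gs_eff))  # pA * GOhm = mV
  expect_equal(s, expected, tolerance = 0.15)
})

test_that("sag errors when the step is too short for its windows", {
  pr <- stim_protocol(seq(-50, 50, 10), step_duration = 0.1,
                      baseline_pre = 0.02, baseline_post = 0.02)
  ss <- ohmic_sweep_set(100, protocol = pr)
  expect_error(sag(ss), "shorter")
})

test_that("rheobase is the smallest amplitude with a spike and is flagged when absent", {
  spikes <- list(NULL, NULL, NULL, c(0.1), c(0.05, 0.2), c(0.05, 0.1, 0.2),
                 NULL, NULL, NULL, NULL, NULL)
  spikes[7:11] <- lapply(7:11, function(i) seq(0.05, 0.9, by = 0.05))
  ss <- spiking_sweep_set(spikes)
  expect_equal(rheobase(ss), 300)
  empty <- spiking_sweep_set(vector("list", 11))
  r <- rheobase(empty)
  expect_true(is.na(r))
  expect_equal(attr(r, "reason"), "no sweep spiked")
})

test_that("noiseless integrate-and-fire rheobase matches the analytic threshold current", {
  # continuous rheobase = gL*(Vth-EL) = 10 nS * 25 mV = 250 pA -> grid 300
  p <- neuron_params(membrane_capacitance = 60, leak_conductance = 10,
                     spike_threshold = -40)
  sup <- simulate_membrane(p, protocol_suprathreshold(), seed = 5)
  expect_equal(as.numeric(rheobase(sup)), 300)
})

test_that("spike width matches closed-form widths of known waveforms", {
  fs <- 10000
  # triangular spike: rises from -65 to +30 over 1 ms, falls over 1 ms.
  # half level is (30+0)/2 = 15 mV; crossing offsets are where the flanks
  # pass 15 mV: fraction (30-15)/(30-(-65)) of 1 ms on each side
  pr <- stim_protocol(100, step_duration = 0.3, baseline_pre = 0.05,
                      baseline_post = 0.05, sampling_rate = fs)
  ns <- apcephys:::protocol_samples(pr)
  n <- ns$pre + ns$step + ns$post
  v <- rep(-65, n)
  apex <- ns$pre + 1500
  ramp <- seq(-65, 30, length.out = 11)   # 1 ms flanks at 10 kHz
  v[(apex - 10):apex] <- ramp
  v[apex:(apex + 10)] <- rev(ramp)
  ss <- sweep_set(pr, matrix(v, ncol = 1), cell_id = "tri")
  expected <- 2 * (30 - 15) / (30 + 65) * 1   # ms
  expect_equal(spike_width(ss, 100), expected, tolerance = 0.02)

  # Gaussian spike of scale sigma: width at the 15 mV half level is
  # 2*sigma*sqrt(2*log(A/(level - base)))
  sigma <- 0.4
  v2 <- template_spike_trace(n, apex, amplitude = 95, sigma_ms = sigma,
                             fs = fs)
  ss2 <- sweep_set(pr, matrix(v2, ncol = 1), cell_id = "gauss")
  expected2 <- 2 * sigma * sqrt(2 * log(95 / (15 + 65)))
  # linear interpolation between 0.1 ms samples bounds the accuracy
  expect_equal(spike_width(ss2, 100), expected2, tolerance = 0.03)
})

test_that("stamped spike widths reproduce the configured half-width", {
  for (hw in c(0.4, 1.0, 1.8)) {
    p <- neuron_params(membrane_capacitance = 60, leak_conductance = 10,
                       spike_threshold = -40, spike_shape_halfwidth = hw)
    sup <- simulate_membrane(p, stim_protocol(c(300, 400), 1, 0.05, 0.05),
                             seed = 6)
    expect_equal(spike_width(sup, 300), hw, tolerance = 0.05)
  }
})

test_that("max firing rate equals the brute-force per-sweep count maximum", {
  spikes <- lapply(seq(0, 1000, 100), function(a)
    if (a < 300) NULL else seq(0.05, 0.95, length.out = a / 20))
  ss <- spiking_sweep_set(spikes)
  counts <- vapply(seq_len(ncol(ss$sweeps)), function(j)
    length(apcephys:::step_spikes(ss$sweeps[, j], ss$protocol)$index),
    numeric(1))
  expect_equal(max_firing_rate(ss), max(counts) / 1)
  expect_equal(max_firing_rate(ss), 50)
  expect_true(is.na(max_firing_rate(spiking_sweep_set(vector("list", 11)))))
})

test_that("ISI statistics follow their arithmetic definitions", {
  # periodic train at rheobase+100: AR = 1, CV = 0
  spikes <- list(NULL, c(0.1), seq(0.1, 0.9, by = 0.01))
  ss <- spiking_sweep_set(spikes, amps = c(0, 100, 200))
  out <- isi_stats(ss, 100)
  expect_true(out$valid)
  expect_equal(out$adaptation_ratio, 1, tolerance = 1e-6)
  expect_equal(out$cv_isi, 0, tolerance = 1e-6)

  # hand-computed: ISIs 10, 12, 15, 20 ms
  st <- cumsum(c(0.1, 0.010, 0.012, 0.015, 0.020))
  ss2 <- spiking_sweep_set(list(NULL, c(0.1), st), amps = c(0, 100, 200))
  out2 <- isi_stats(ss2, 100)
  isi <- c(10, 12, 15, 20)
  expect_equal(out2$adaptation_ratio, 2, tolerance = 1e-6)
  expect_equal(out2$cv_isi, sd(isi) / mean(isi), tolerance = 1e-6)

  # fewer than 2 ISIs -> invalid, not an error
  ss3 <- spiking_sweep_set(list(NULL, c(0.1), c(0.1, 0.2)),
                           amps = c(0, 100, 200))
  expect_false(isi_stats(ss3, 100)$valid)
})

test_that("the substitute amplitude is flagged when rheobase+100 is unavailable", {
  spikes <- lapply(1:11, function(i) seq(0.05, 0.9, 0.05))
  ss <- spiking_sweep_set(spikes)
  out <- isi_stats(ss, 1000)  # 1100 pA not in protocol
  expect_true(out$flagged)
  expect_equal(out$amplitude_used, 1000)
})

test_that("feature extraction flags unavailable features instead of failing", {
  cell <- simulate_population("FS-SST-tonic", 1, variability_scale = 0,
                              seed = 8)[[1]]
  f_passive <- extract_features(cell$sub)          # QX-314-style recording
  expect_true(all(unlist(f_passive[paste0(subthreshold_features(),
                                          "_valid")])))
  expect_false(any(unlist(f_passive[paste0(setdiff(feature_names(),
                                                   subthreshold_features()),
                                           "_valid")])))
  f_full <- extract_features(cell$sub, cell$supra)
  expect_true(all(unlist(f_full[paste0(feature_names(), "_valid")])))
})

test_that("feature extraction is deterministic and window-local", {
  cell <- simulate_population("FS-PV-tonic", 1, variability_scale = 0,
                              seed = 9)[[1]]
  f1 <- extract_features(cell$sub, cell$supra)
  f2 <- extract_features(cell$sub, cell$supra)
  expect_identical(f1, f2)

  # appending trailing baseline outside all analysis windows changes nothing
  p <- cell$sub$protocol
  longer <- stim_protocol(p$step_amplitudes, p$step_duration,
                          p$baseline_pre, p$baseline_post + 0.1,
                          p$sampling_rate)
  extra <- matrix(rep(cell$sub$sweeps[nrow(cell$sub$sweeps), ],
                      each = round(0.1 * p$sampling_rate)),
                  nrow = round(0.1 * p$sampling_rate))
  ss_long <- sweep_set(longer, rbind(cell$sub$sweeps, extra),
                       cell_id = "padded")
  expect_equal(input_resistance(ss_long), input_resistance(cell$sub))
  expect_equal(sag(ss_long), sag(cell$sub))
  expect_equal(time_constant(ss_long), time_constant(cell$sub))
})
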