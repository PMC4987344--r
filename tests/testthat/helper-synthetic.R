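# Shared fixture builders; everything is generated in code.

# short protocols keep unit tests fast; windows (50/100 ms) still fit
fast_sub_protocol <- function() {
  stim_protocol(seq(-50, 50, by = 10), step_duration = 0.3,
                baseline_pre = 0.05, baseline_post = 0.05)
}

# ideal ohmic sweep set: instantaneous deflection amp * R, no dynamics
ohmic_sweep_set <- function(r_mohm = 100, protocol = fast_sub_protocol(),
                            noise_sd = 0, el = -65) {
  ns <- apcephys:::protocol_samples(protocol)
  n <- ns$pre + ns$step + ns$post
  sweeps <- vapply(protocol$step_amplitudes, function(a) {
    v <- rep(el, n)
    v[apcephys:::step_index(protocol)] <- el + a * r_mohm / 1000
    if (noise_sd > 0) v <- v + rnorm(n, 0, noise_sd)
    v
  }, numeric(n))
  sweep_set(protocol, sweeps, cell_id = "ohmic")
}

# single-exponential charging responses with time constant tau_ms
rc_sweep_set <- function(r_mohm = 100, tau_ms = 10,
                         protocol = fast_sub_protocol(), el = -65) {
  ns <- apcephys:::protocol_samples(protocol)
  n <- ns$pre + ns$step + ns$post
  fs <- protocol$sampling_rate
  stepi <- apcephys:::step_index(protocol)
  sweeps <- vapply(protocol$step_amplitudes, function(a) {
    v <- rep(el, n)
    tt <- (seq_along(stepi) - 1) / fs * 1000
    v[stepi] <- el + a * r_mohm / 1000 * (1 - exp(-tt / tau_ms))
    # relaxation after the step
    posti <- seq(max(stepi) + 1L, n)
    t2 <- (seq_along(posti) - 1) / fs * 1000
    v[posti] <- el + (v[max(stepi)] - el) * exp(-t2 / tau_ms)
    v
  }, numeric(n))
  sweep_set(protocol, sweeps, cell_id = "rc")
}

# trace with Gaussian spike templates at given sample indices
template_spike_trace <- function(n, peak_idx, amplitude = 95, sigma_ms = 0.2,
                                 fs = 10000, base = -65) {
  v <- rep(base, n)
  k <- ceiling(5 * sigma_ms / 1000 * fs)
  for (i0 in peak_idx) {
    w <- max(1, i0 - k):min(n, i0 + k)
    v[w] <- pmax(v[w], base + amplitude *
                   exp(-((w - i0) / fs * 1000)^2 / (2 * sigma_ms^2)))
  }
  v
}

# suprathreshold-style sweep set with spikes stamped at chosen times
spiking_sweep_set <- function(spike_times_by_amp,
                              amps = seq(0, 1000, by = 100),
                              step_duration = 1, fs = 10000,
                              sigma_ms = 0.2) {
  protocol <- stim_protocol(amps, step_duration = step_duration,
                            baseline_pre = 0.05, baseline_post = 0.05,
                            sampling_rate = fs)
  ns <- apcephys:::protocol_samples(protocol)
  n <- ns$pre + ns$step + ns$post
  sweeps <- vapply(seq_along(amps), function(j) {
    st <- spike_times_by_amp[[j]]
    if (is.null(st) || !length(st)) return(rep(-65, n))
    idx <- ns$pre + round(st * fs)
    template_spike_trace(n, idx, sigma_ms = sigma_ms, fs = fs)
  }, numeric(n))
  sweep_set(protocol, sweeps, cell_id = "stamped")
}

# independent brute-force Ward agglomeration: recompute the within-cluster
# variance increase from raw coordinates at every step
ward_oracle <- function(X) {
  clusters <- lapply(seq_len(nrow(X)), identity)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- NULL
    best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      ci <- clusters[[j]]; cj <- clusters[[i]]
      mi <- colMeans(X[ci, , drop = FALSE])
      mj <- colMeans(X[cj, , drop = FALSE])
      d <- length(ci) * length(cj) / (length(ci) + length(cj)) *
        sum((mi - mj)^2)
      if (d < best_d - 1e-12) { best_d <- d; best <- c(j, i) }
    }
    heights <- c(heights, sqrt(2 * best_d))
    clusters <- c(clusters[-best],
                  list(c(clusters[[best[1]]], clusters[[best[2]]])))
  }
  heights
}

# exhaustive Mann-Whitney permutation p-value (two-sided)
mwu_exact_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  u_of <- function(ix) {
    xs <- pooled[ix]; ys <- pooled[-ix]
    sum(outer(xs, ys, ">")) # U statistic for x
  }
  obs <- u_of(seq_len(nx))
  all_u <- apply(utils::combn(nx + ny, nx), 2, u_of)
  mu <- nx * ny / 2
  mean(abs(all_u - mu) >= abs(obs - mu) - 1e-9)
}

# exhaustive Wilcoxon signed-rank p-value over all sign assignments
wsr_exact_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  n <- length(d)
  signs <- expand.grid(rep(list(c(0, 1)), n))
  all_v <- as.matrix(signs) %*% r
  mu <- sum(r) / 2
  mean(abs(all_v - mu) >= abs(obs - mu) - 1e-9)
}
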