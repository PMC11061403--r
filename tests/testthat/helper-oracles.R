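# Independent oracles used across the suite.

# A stable alpha-peaked gain set used as the canonical test point.
test_gains <- function() ctm_gains_default()

# Excitatory field amplitude obtained by solving the four-population linear
# system directly (matrix form), with an arbitrary loop-gain factorization:
# any split that reproduces the loop products must give the same field, so
# this doubles as a factorization-invariance check. Independent of the
# closed-form implementation under test.
transfer_matrix_oracle <- function(g, k, omega) {
  L <- 1 / ((1 - 1i * omega / g$alpha) * (1 - 1i * omega / g$beta))
  E <- exp(1i * omega * g$t0 / 2)
  # deliberately skewed factorization of the loop gains
  g_es <- 0.7 * sqrt(g$g_ese)
  g_se <- if (g_es > 0) g$g_ese / g_es else 0
  g_sr <- -abs(g$g_srs)^0.6
  g_rs <- if (g_sr != 0) g$g_srs / g_sr else 0
  g_re <- if (g_es * g_sr != 0) g$g_esre / (g_es * g_sr) else 0
  g_sn <- if (g_es > 0) g$amplitude / g_es else g$amplitude
  d_e <- k^2 * g$r_e^2 + (1 - 1i * omega / g$gamma_e)^2
  D <- diag(c(d_e, 1, 1, 1) + 0i)
  J <- matrix(0i, 4, 4)           # population order: e, i, r, s
  J[1, 1] <- g$g_ee * L;  J[1, 2] <- g$g_ei * L;  J[1, 4] <- g_es * L * E
  J[2, 1] <- g$g_ee * L;  J[2, 2] <- g$g_ei * L;  J[2, 4] <- g_es * L * E
  J[3, 1] <- g_re * L * E;                        J[3, 4] <- g_rs * L
  J[4, 1] <- g_se * L * E; J[4, 3] <- g_sr * L
  b <- c(0, 0, 0, g_sn * L)
  phi <- solve(D - J, b)
  phi[1]
}

# Closed-form zero-gain spectrum: amplitude^2 |L|^4 summed over the same
# spatial-mode set the implementation documents (modes whose filtered weight
# falls below 1e-14 of the spacing are dropped).
zero_gain_spectrum_oracle <- function(g, freqs, grid) {
  om <- 2 * pi * freqs
  L <- 1 / ((1 - 1i * om / g$alpha) * (1 - 1i * om / g$beta))
  dkx <- 2 * pi / grid$Lx
  dky <- 2 * pi / grid$Ly
  total <- numeric(length(freqs))
  for (m in 0:grid$m_max) for (n in 0:grid$m_max) {
    k2 <- (dkx * m)^2 + (dky * n)^2
    mult <- (if (m > 0) 2 else 1) * (if (n > 0) 2 else 1)
    wt <- exp(-k2 / grid$k0^2) * dkx * dky * mult
    if (wt <= 1e-14 * dkx * dky) next
    total <- total + wt / Mod((1 - 1i * om / g$gamma_e)^2 + k2 * g$r_e^2)^2
  }
  g$amplitude^2 * Mod(L)^4 * total
}

# Frequency-domain total power under the unitary transform convention.
total_power_freq_oracle <- function(x) {
  n <- length(x)
  xhat <- stats::fft(x) / sqrt(n)
  sum(Mod(xhat)^2) / n
}

# Band shape error between two spectra (unit mean band power), as used in
# the fit reports.
shape_error <- function(ps, ref, f_lo = 8, f_hi = 30) {
  keep <- ref$frequency_hz >= f_lo & ref$frequency_hz <= f_hi
  f <- ref$frequency_hz[keep]
  pa <- stats::approx(ps$frequency_hz, ps$power, xout = f)$y
  pb <- ref$power[keep]
  pa <- pa / mean(pa); pb <- pb / mean(pb)
  mean(abs(pa - pb) / pb)
}

band_sum <- function(ps, f_lo = 8, f_hi = 30) {
  sum(ps$power[ps$frequency_hz >= f_lo & ps$frequency_hz <= f_hi])
}

peak_freq <- function(ps, f_lo, f_hi) {
  keep <- ps$frequency_hz >= f_lo & ps$frequency_hz <= f_hi
  ps$frequency_hz[keep][which.max(ps$power[keep])]
}

# Uniform draw from the fit prior box that passes the stability screen.
random_stable_gains <- function(cfg = fit_config()) {
  repeat {
    x <- cfg$lower + stats::runif(8) * (cfg$upper - cfg$lower)
    if (x[["beta"]] < x[["alpha"]]) x[c("alpha", "beta")] <- x[c("beta", "alpha")]
    g <- try(ctm_gains(g_ee = x[["g_ee"]], g_ei = x[["g_ei"]],
                       g_ese = x[["g_ese"]], g_esre = x[["g_esre"]],
                       g_srs = x[["g_srs"]], amplitude = 1,
                       alpha = x[["alpha"]], beta = x[["beta"]],
                       t0 = x[["t0"]], gamma_e = cfg$gamma_e, r_e = cfg$r_e),
             silent = TRUE)
    if (!inherits(g, "try-error") && stability_check(g, cfg)) return(g)
  }
}

# Small, fast synthetic subject for protocol-level tests.
small_cohort_spec <- function(noise = 1, n_epochs = 18, n_channels = 8,
                              identical_classes = FALSE, seed = 4242) {
  cp <- default_class_params()
  if (identical_classes) cp <- list(cp$idle, cp$idle)
  cohort_spec(n_subjects = 1, n_epochs_per_condition = n_epochs,
              n_channels = n_channels, class_params = cp,
              sensor_noise_sd = noise, noise_spread = c(1, 1), seed = seed)
}
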