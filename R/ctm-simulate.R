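#' Simulation configuration
#'
#' Controls for generating artificial cortical source signals from a fitted
#' model. Two methods are available: `"time_domain"` integrates the linearized
#' delay-differential system driven by white noise (semi-implicit Euler with
#' circular delay buffers); `"spectral_synthesis"` draws independent complex
#' Gaussian Fourier coefficients with expected power given by the analytic
#' spectrum and inverse-transforms. Both are deterministic given `seed`.
#'
#' The integration step is adjusted downward so that the half-loop delay
#' `t0/2` is an integer number of steps.
#'
#' @param dt integration step in seconds (time-domain method).
#' @param duration total simulated duration in seconds, including burn-in.
#' @param fs_out output sampling rate in Hz.
#' @param burn_in seconds discarded from the start of time-domain runs.
#' @param seed integer seed.
#' @param method `"time_domain"` or `"spectral_synthesis"`.
#' @param grid_n spatial grid nodes per side; only the spatially uniform
#'   mode (`grid_n = 1`) is implemented.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 1e-4, duration = 10, fs_out = 250, burn_in = 2,
                       seed = 1, method = c("time_domain",
                                            "spectral_synthesis"),
                       grid_n = 1) {
  method <- match.arg(method)
  stopifnot(dt > 0, duration > burn_in, fs_out > 0, fs_out <= 1 / dt,
            burn_in >= 0)
  if (grid_n != 1)
    stop("only the spatially uniform mode (grid_n = 1) is implemented",
         call. = FALSE)
  structure(list(dt = dt, duration = duration, fs_out = fs_out,
                 burn_in = burn_in, seed = as.integer(seed), method = method,
                 grid_n = 1L),
            class = "sim_config")
}

#' Dendritic impulse response
#'
#' Time-domain kernel of the synaptic/dendritic low-pass filter:
#' `L(t) = (alpha beta / (beta - alpha)) (exp(-alpha t) - exp(-beta t))` for
#' `t >= 0` and zero before, with the limit branch `alpha^2 t exp(-alpha t)`
#' when the two rates coincide. Integrates to one (unit DC gain).
#'
#' @param t time in seconds (vectorised).
#' @param alpha,beta decay and rise rates in 1/s.
#' @return Kernel values in 1/s.
#' @export
impulse_response <- function(t, alpha, beta) {
  stopifnot(alpha > 0, beta > 0)
  out <- numeric(length(t))
  pos <- t >= 0
  if (abs(beta - alpha) / alpha < 1e-8) {
    out[pos] <- alpha^2 * t[pos] * exp(-alpha * t[pos])
  } else {
    out[pos] <- alpha * beta / (beta - alpha) *
      (exp(-alpha * t[pos]) - exp(-beta * t[pos]))
  }
  out
}

#' Simulate a cortical source signal from fitted gains
#'
#' Generates the excitatory-field perturbation of the linear corticothalamic
#' model driven by white sensory noise through the thalamic relay nucleus.
#' The white-noise increments are scaled by `1/sqrt(dt)` so the driving
#' spectral density is step-size invariant, and the drive coefficient is
#' chosen so the field transfer matches the analytic spectrum's amplitude
#' parameter. The long-run periodogram therefore matches the analytic
#' spectrum shape (with the spatial sum restricted to the uniform mode).
#'
#' @param g a stable [ctm_gains()] object.
#' @param cfg a [sim_config()].
#' @return An object of class `source_signal`: list with `samples`, `fs`, and
#'   provenance (`gains`, `seed`, `method`, `config`).
#' @export
#' @examples
#' s <- simulate_source(ctm_gains_default(), sim_config(duration = 4, seed = 1))
#' length(s$samples)  # (duration - burn_in) * fs_out
simulate_source <- function(g, cfg = sim_config()) {
  validate_ctm_gains(g)
  n_out <- round((cfg$duration - cfg$burn_in) * cfg$fs_out)
  if (cfg$method == "spectral_synthesis") {
    samples <- withr::with_seed(cfg$seed,
      synth_from_spectrum(g, n_out, cfg$fs_out))
  } else {
    if (cfg$dt > 1 / (2 * max(g$alpha, g$beta, g$gamma_e)))
      stop("ConfigError: dt too coarse for the model's fastest rate",
           call. = FALSE)
    # honour the delay exactly: shrink dt so t0/2 is an integer multiple
    delay_steps <- max(1L, as.integer(ceiling(g$t0 / 2 / cfg$dt - 1e-9)))
    dt <- (g$t0 / 2) / delay_steps
    n_steps <- round(cfg$duration / dt)
    fac <- canonical_factorization(g)
    g_es <- max(fac[["g_es"]], 1e-6)      # keep the drive path alive at zero loop gain
    g_se <- if (g$g_ese > 0) g$g_ese / g_es else 0
    drive <- g$amplitude / g_es
    noise <- withr::with_seed(cfg$seed, stats::rnorm(n_steps) / sqrt(dt))
    x <- ctm_simulate_cpp(g$g_ee, g$g_ei, g_es, g_se, fac[["g_sr"]],
                          fac[["g_re"]], fac[["g_rs"]], g$alpha, g$beta,
                          g$gamma_e, drive, delay_steps, dt, noise)
    x <- x[-seq_len(round(cfg$burn_in / dt))]
    samples <- decimate_to(x, 1 / dt, cfg$fs_out, n_out)
  }
  structure(list(samples = samples, fs = cfg$fs_out, gains = g,
                 seed = cfg$seed, method = cfg$method, config = cfg),
            class = "source_signal")
}

# frequency-domain surrogate with E[periodogram] = analytic spectrum shape
synth_from_spectrum <- function(g, n, fs) {
  grid0 <- spectrum_grid(m_max = 0)   # uniform spatial mode, as in time domain
  nh <- floor(n / 2)
  f <- (1:nh) * fs / n
  pw <- analytic_spectrum(g, f, grid0)$power
  df <- fs / n
  coef <- complex(real = stats::rnorm(nh), imaginary = stats::rnorm(nh)) *
    sqrt(pw * n^2 * df / 4)
  X <- complex(length.out = n)
  X[2:(nh + 1)] <- coef
  if (n %% 2 == 0) X[nh + 1] <- complex(real = sqrt(2) * Re(coef[nh]))
  X[n + 2 - (2:(nh + 1))] <- Conj(X[2:(nh + 1)])
  Re(stats::fft(X, inverse = TRUE)) / n
}

# anti-alias filter then resample onto the output grid
decimate_to <- function(x, fs_in, fs_out, n_out) {
  if (fs_out < fs_in) {
    bf <- signal::butter(4, 0.45 * fs_out / (fs_in / 2))
    x <- signal::filtfilt(bf, x)
  }
  t_in <- (seq_along(x) - 1) / fs_in
  t_out <- (seq_len(n_out) - 1) / fs_out
  stats::approx(t_in, x, xout = t_out, rule = 2)$y
}

#' Calibrate a simulated signal to a target band power
#'
#' Multiplies the signal by a single positive scalar so that its 8-30 Hz (or
#' chosen band) power equals the integral of the target spectrum over the
#' band. Calibration runs on the full continuous signal before epoching;
#' individual epochs then scatter around the target with finite-length
#' variance. Total power features are scale-dependent, so this step is
#' mandatory before feature extraction on artificial data.
#'
#' @param s a [simulate_source()] result.
#' @param target a [power_spectrum()] covering the band.
#' @param band numeric length-2, band edges in Hz.
#' @return A `source_signal` with rescaled samples and a `calibration` scalar.
#' @export
calibrate_amplitude <- function(s, target, band = c(8, 30)) {
  stopifnot(inherits(s, "source_signal"))
  if (band[1] < min(target$frequency_hz) || band[2] > max(target$frequency_hz))
    stop("band not covered by the target spectrum", call. = FALSE)
  ps <- epoch_average_spectrum(list(s$samples), s$fs)
  bp <- band_power(ps, band[1], band[2])
  if (bp <= 0) stop("DegenerateSignal: zero band power", call. = FALSE)
  target_bp <- band_power(target, band[1], band[2])
  scl <- sqrt(target_bp / bp)
  s$samples <- s$samples * scl
  s$calibration <- scl
  s
}

#' Cut a continuous source signal into epochs
#'
#' Non-overlapping, contiguous segments of `epoch_len` seconds; the trailing
#' remainder is dropped.
#'
#' @param s a `source_signal`.
#' @param epoch_len epoch length in seconds (2.5 s matches a typical
#'   motor-imagery window).
#' @return A list of numeric vectors, each of `round(epoch_len * fs)` samples.
#' @export
segment_epochs <- function(s, epoch_len = 2.5) {
  n_ep <- round(epoch_len * s$fs)
  n <- floor(length(s$samples) / n_ep)
  if (n < 1) stop("TooShort: signal shorter than one epoch", call. = FALSE)
  lapply(seq_len(n), function(i)
    s$samples[((i - 1) * n_ep + 1):(i * n_ep)])
}
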