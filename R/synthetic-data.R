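#' Synthetic cohort specification
#'
#' Describes a fully synthetic two-condition motor-imagery cohort: per
#' condition, corticothalamic source signals are simulated, cut into epochs,
#' mixed into EEG channels through fixed spatial patterns, and corrupted
#' with white sensor noise. The class contrast is planted through the model
#' parameters themselves (the "active" gains have a shorter loop delay and a
#' larger amplitude than the "idle" gains), so the generating process lies
#' inside the model family the augmentation fit assumes.
#'
#' Geometry defaults mirror a standard motor-imagery benchmark: 72 epochs
#' per condition, 2.5 s epochs, 22 channels at 250 Hz. Each subject gets
#' small random parameter offsets and a subject-specific sensor-noise level
#' drawn across `noise_spread`, producing the heterogeneous baseline
#' accuracies a real cohort shows.
#'
#' @param n_subjects cohort size.
#' @param n_epochs_per_condition epochs per condition per subject.
#' @param fs sampling rate in Hz.
#' @param n_channels EEG channel count.
#' @param epoch_len epoch length in seconds.
#' @param class_params list of two [ctm_gains()]: active and idle source
#'   states.
#' @param n_sources number of latent sources (>= 2; sources 1 and 2 are the
#'   mirrored discriminative pair, the rest are shared background).
#' @param mixing_patterns optional `n_sources x n_channels` matrix; default
#'   smooth Gaussian topographies.
#' @param sensor_noise_sd sensor noise standard deviation, in units of the
#'   idle source's band-root-power.
#' @param noise_spread per-subject multiplier range on `sensor_noise_sd`.
#' @param subject_t0_sd,subject_amp_sd s.d. of per-subject loop-delay offset
#'   (s) and log-amplitude offset.
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 12, n_epochs_per_condition = 72,
                        fs = 250, n_channels = 22, epoch_len = 2.5,
                        class_params = default_class_params(),
                        n_sources = 3, mixing_patterns = NULL,
                        sensor_noise_sd = 2, noise_spread = c(0.5, 2.75),
                        subject_t0_sd = 0.002, subject_amp_sd = 0.08,
                        seed = 20260101) {
  stopifnot(length(class_params) == 2, n_sources >= 2, n_subjects >= 1,
            n_epochs_per_condition >= 1, fs > 0, epoch_len > 0,
            sensor_noise_sd >= 0)
  if (is.null(mixing_patterns))
    mixing_patterns <- default_mixing(n_sources, n_channels)
  stopifnot(nrow(mixing_patterns) == n_sources,
            ncol(mixing_patterns) == n_channels)
  if (qr(mixing_patterns)$rank < n_sources)
    stop("mixing patterns must have full row rank", call. = FALSE)
  structure(list(n_subjects = n_subjects,
                 n_epochs_per_condition = n_epochs_per_condition, fs = fs,
                 n_channels = n_channels, epoch_len = epoch_len,
                 class_params = class_params, n_sources = n_sources,
                 mixing_patterns = mixing_patterns,
                 sensor_noise_sd = sensor_noise_sd,
                 noise_spread = noise_spread,
                 subject_t0_sd = subject_t0_sd,
                 subject_amp_sd = subject_amp_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_class_params <- function() {
  base <- ctm_gains_default()
  active <- base; active$t0 <- base$t0 - 0.005; active$amplitude <- 1.4
  idle <- base; idle$t0 <- base$t0 + 0.005; idle$amplitude <- 1.0
  list(active = active, idle = idle)
}

# smooth Gaussian channel topographies; discriminative pair lateralized
default_mixing <- function(n_sources, n_channels) {
  centers <- seq(0.25, 0.75, length.out = min(n_sources, 2)) * n_channels
  if (n_sources > 2)
    centers <- c(centers, seq(0.1, 0.9,
                              length.out = n_sources - 2) * n_channels)
  t(vapply(seq_len(n_sources), function(s) {
    w <- exp(-((seq_len(n_channels) - centers[s])^2) / (2 * (n_channels / 6)^2))
    w / sqrt(sum(w^2))
  }, numeric(n_channels)))
}

#' Generate one synthetic subject
#'
#' Per condition, simulates each latent source from its gain set (with the
#' subject's parameter offsets), normalizes the source scale so the idle
#' state has unit 8-30 Hz band power, cuts epochs, mixes sources into
#' channels and adds white sensor noise. In condition 1 source 1 is active
#' and source 2 idle; condition 2 mirrors them. Deterministic per
#' `(spec$seed, subject_index)`.
#'
#' @param spec a [cohort_spec()].
#' @param subject_index subject number in `1..spec$n_subjects`.
#' @return An [epoch_set()] of `2 * n_epochs_per_condition` labeled epochs
#'   (conditions `"L"` and `"R"`).
#' @export
make_subject <- function(spec, subject_index) {
  stopifnot(inherits(spec, "cohort_spec"),
            subject_index >= 1, subject_index <= spec$n_subjects)
  base_seed <- sub_seed(spec$seed, subject_index)
  offs <- withr::with_seed(base_seed, list(
    t0 = stats::rnorm(1, 0, spec$subject_t0_sd),
    amp = exp(stats::rnorm(1, 0, spec$subject_amp_sd))))
  noise_mult <- if (spec$n_subjects == 1) 1 else
    seq(spec$noise_spread[1], spec$noise_spread[2],
        length.out = spec$n_subjects)[subject_index]
  adj <- function(g) {
    g$t0 <- max(0.05, g$t0 + offs$t0)
    g$amplitude <- g$amplitude * offs$amp
    g
  }
  active <- adj(spec$class_params[[1]])
  idle <- adj(spec$class_params[[2]])
  n_ep <- spec$n_epochs_per_condition
  n_samp <- round(spec$epoch_len * spec$fs)
  labels <- rep(c("L", "R"), each = n_ep)
  data <- array(0, c(2 * n_ep, spec$n_channels, n_samp))
  for (cond in 1:2) {
    src_mats <- lapply(seq_len(spec$n_sources), function(s) {
      g <- if (s == 1) (if (cond == 1) active else idle)
      else if (s == 2) (if (cond == 1) idle else active)
      else adj(spec$class_params[[2]])
      cfg <- sim_config(duration = 2 + n_ep * spec$epoch_len + 1 / spec$fs,
                        fs_out = spec$fs, burn_in = 2,
                        method = "spectral_synthesis",
                        seed = sub_seed(base_seed, cond * 100 + s))
      sig <- simulate_source(g, cfg)
      # normalize so the idle state carries unit band power
      ps <- epoch_average_spectrum(list(sig$samples), spec$fs)
      rel <- g$amplitude / idle$amplitude
      sig$samples <- sig$samples * rel * sqrt(1 / band_power(ps, 8, 30))
      do.call(rbind, segment_epochs(sig, spec$epoch_len)[seq_len(n_ep)])
    })
    noise_sd <- spec$sensor_noise_sd * noise_mult
    eps_noise <- withr::with_seed(sub_seed(base_seed, cond * 100 + 99),
      array(stats::rnorm(n_ep * spec$n_channels * n_samp, 0, noise_sd),
            c(n_ep, spec$n_channels, n_samp)))
    for (i in seq_len(n_ep)) {
      mix <- t(spec$mixing_patterns) %*%
        do.call(rbind, lapply(src_mats, function(m) m[i, ]))
      data[(cond - 1) * n_ep + i, , ] <- mix + eps_noise[i, , ]
    }
  }
  epoch_set(data, spec$fs, labels,
            subject_id = sprintf("synth%02d", subject_index))
}

#' Generate a synthetic cohort
#'
#' @param spec a [cohort_spec()].
#' @param n number of subjects (default `spec$n_subjects`).
#' @return List of [epoch_set()] objects, reproducible from `spec` alone.
#' @export
make_cohort <- function(spec, n = spec$n_subjects) {
  spec$n_subjects <- n
  lapply(seq_len(n), function(i) make_subject(spec, i))
}

#' Read and write epoch containers
#'
#' Lossless single-file container for an [epoch_set()] (data, sampling rate,
#' labels, channel names, subject id, format tag). Reading validates the
#' format tag and every required field and fails with a `FormatError` naming
#' whatever is missing.
#'
#' @param e an `epoch_set`.
#' @param path file path.
#' @return `read_epochs()` returns an `epoch_set`; `write_epochs()` its path,
#'   invisibly.
#' @export
write_epochs <- function(e, path) {
  stopifnot(inherits(e, "epoch_set"))
  saveRDS(list(format = "nftda-epochs-v1", data = e$data, fs = e$fs,
               labels = e$labels, subject_id = e$subject_id,
               channel_names = e$channel_names), path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("FormatError: unreadable container: ", conditionMessage(e),
         call. = FALSE))
  if (!identical(obj$format, "nftda-epochs-v1"))
    stop("FormatError: missing or wrong format tag", call. = FALSE)
  for (f in c("data", "fs", "labels", "channel_names"))
    if (is.null(obj[[f]]))
      stop("FormatError: missing field '", f, "'", call. = FALSE)
  epoch_set(obj$data, obj$fs, obj$labels, obj$subject_id %||% "",
            obj$channel_names)
}

#' Read and write spectra as two-column CSV
#'
#' @param ps a [power_spectrum()].
#' @param path file path.
#' @return `read_spectrum()` returns a `power_spectrum`.
#' @export
write_spectrum <- function(ps, path) {
  readr::write_csv(tibble::tibble(frequency_hz = ps$frequency_hz,
                                  power = ps$power), path)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  for (f in c("frequency_hz", "power"))
    if (is.null(x[[f]]))
      stop("FormatError: missing column '", f, "'", call. = FALSE)
  power_spectrum(x$frequency_hz, x$power)
}

#' Read and write gain parameter sets as key = value text
#'
#' Flat text serialization with units spelled out in the key names
#' (rates in 1/s, delay in s, range in m).
#'
#' @param g a [ctm_gains()].
#' @param path file path.
#' @return `read_gains()` returns a `ctm_gains`.
#' @export
write_gains <- function(g, path) {
  validate_ctm_gains(g)
  keys <- c(g_ee = "g_ee", g_ei = "g_ei", g_ese = "g_ese",
            g_esre = "g_esre", g_srs = "g_srs", amplitude = "amplitude",
            alpha = "alpha_per_s", beta = "beta_per_s", t0 = "t0_s",
            gamma_e = "gamma_e_per_s", r_e = "r_e_m")
  lines <- vapply(names(keys), function(k)
    sprintf("%s = %.17g", keys[[k]], g[[k]]), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gains
#' @export
read_gains <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(
    vapply(kv, function(x) as.numeric(trimws(x[2])), numeric(1)),
    vapply(kv, function(x) trimws(x[1]), character(1)))
  need <- c("g_ee", "g_ei", "g_ese", "g_esre", "g_srs", "amplitude",
            "alpha_per_s", "beta_per_s", "t0_s", "gamma_e_per_s", "r_e_m")
  miss <- setdiff(need, names(vals))
  if (length(miss))
    stop("FormatError: missing key '", miss[1], "'", call. = FALSE)
  ctm_gains(g_ee = vals[["g_ee"]], g_ei = vals[["g_ei"]],
            g_ese = vals[["g_ese"]], g_esre = vals[["g_esre"]],
            g_srs = vals[["g_srs"]], amplitude = vals[["amplitude"]],
            alpha = vals[["alpha_per_s"]], beta = vals[["beta_per_s"]],
            t0 = vals[["t0_s"]], gamma_e = vals[["gamma_e_per_s"]],
            r_e = vals[["r_e_m"]])
}
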