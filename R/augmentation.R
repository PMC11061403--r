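#' Parameter jitter specification
#'
#' Controls optional jittering of fitted physiological parameters before
#' artificial-signal generation. Jitter adds independent zero-mean Gaussian
#' perturbations of standard deviation `scale * sigma_typical` to each target
#' parameter; loop gains are deliberately not jitterable, because gain
#' perturbations can push the model across a bifurcation and produce a
#' qualitatively different spectrum. Cortical damping jitter applies to
#' `gamma_e`, the only population with a propagation-scale axonal range.
#'
#' @param targets subset of `c("alpha", "gamma_e", "t0")`.
#' @param sigma_typical named typical spreads: `alpha` 14/s, `gamma_e` 25/s,
#'   `t0` 0.003 s.
#' @param scale multiplier on `sigma_typical` (default 1.5).
#' @param draws_per_factor parameter draws per unit augmentation factor
#'   (default 10).
#' @return An object of class `jitter_spec`.
#' @export
jitter_spec <- function(targets = "t0",
                        sigma_typical = c(alpha = 14, gamma_e = 25,
                                          t0 = 0.003),
                        scale = 1.5, draws_per_factor = 10) {
  allowed <- c("alpha", "gamma_e", "t0")
  if (!all(targets %in% allowed))
    stop("jitter targets must be in: ", paste(allowed, collapse = ", "),
         call. = FALSE)
  stopifnot(scale >= 0, draws_per_factor > 0,
            all(allowed %in% names(sigma_typical)))
  structure(list(targets = targets, sigma_typical = sigma_typical,
                 scale = scale, draws_per_factor = draws_per_factor),
            class = "jitter_spec")
}

#' Draw jittered parameter sets
#'
#' Returns `round(draws_per_factor * factor)` copies of `g` with each target
#' parameter independently perturbed by `N(0, (scale * sigma_typical)^2)`.
#' Draws that fail the stability screen (or violate parameter constraints
#' such as `beta >= alpha > 0`) are redrawn, with a bounded number of
#' retries.
#'
#' @param g a stable [ctm_gains()] object.
#' @param spec a [jitter_spec()].
#' @param factor positive augmentation factor.
#' @param seed integer seed.
#' @param fit_cfg [fit_config()] supplying the stability screen settings.
#' @param max_retries redraw budget per draw.
#' @return List of `ctm_gains`; attribute `n_redraws` counts rejections.
#' @export
jitter_draws <- function(g, spec, factor, seed = 1,
                         fit_cfg = fit_config(), max_retries = 200) {
  stopifnot(factor > 0)
  n <- round(spec$draws_per_factor * factor)
  redraws <- 0L
  draws <- withr::with_seed(seed, lapply(seq_len(n), function(i) {
    for (try in seq_len(max_retries)) {
      gj <- g
      for (tg in spec$targets) {
        gj[[tg]] <- gj[[tg]] +
          stats::rnorm(1, 0, spec$scale * spec$sigma_typical[[tg]])
      }
      ok <- gj$alpha > 0 && gj$beta >= gj$alpha && gj$t0 > 0 &&
        gj$gamma_e > 0 && stability_check(gj, fit_cfg)
      if (ok) return(gj)
      redraws <<- redraws + 1L
    }
    stop("TooManyUnstableDraws: jitter rejected ", max_retries,
         " consecutive draws", call. = FALSE)
  }))
  attr(draws, "n_redraws") <- redraws
  draws
}

#' Model-based augmentation of CSP source epochs
#'
#' The core augmentation procedure. Training epochs are grouped by condition
#' and projected onto the CSP sources; for every (condition, component) pair
#' the epoch-averaged source spectrum is computed, the corticothalamic model
#' is fitted to it by MCMC, artificial source signals are simulated from the
#' fitted (optionally jittered) parameters, calibrated to the fitted
#' spectrum's 8-30 Hz band power, and segmented into epochs of the training
#' epoch length. With jitter, the band-power ratio between the jittered and
#' fitted analytic spectra is applied on top of the calibration so that
#' jitter-induced power changes survive. Parameter draws are cycled
#' round-robin across the required epochs, one continuous simulation per
#' draw. Fully seeded: identical inputs and seed give identical output.
#'
#' Only training-fold epochs may be passed in; the CSP model must have been
#' fitted on the same training epochs (leakage guard is the caller's
#' contract, audited by [inverse_cv()]).
#'
#' @param train a band-passed training [epoch_set()].
#' @param csp a [fit_csp()] model fitted on `train`.
#' @param factor augmentation factor: artificial epochs per condition =
#'   `round(factor * n_train_condition)`.
#' @param spec optional [jitter_spec()]; `NULL` disables jittering (a single
#'   simulation per condition and component).
#' @param fit_cfg a [fit_config()] for the per-source MCMC fits.
#' @param sim_cfg a [sim_config()] template (duration is overridden).
#' @param seed integer seed.
#' @return An object of class `augmented_sources`: nested list
#'   `$epochs[[condition]][[component]]` of epoch matrices (epochs x
#'   samples), plus `$fits`, `$provenance` and `$epoch_len`.
#' @export
nft_augment <- function(train, csp, factor, spec = NULL,
                        fit_cfg = fit_config(n_chains = 2, n_steps = 5000,
                                             burn_in_steps = 1500,
                                             grid = spectrum_grid(m_max = 0)),
                        sim_cfg = sim_config(method = "spectral_synthesis"),
                        seed = 1) {
  stopifnot(inherits(train, "epoch_set"), inherits(csp, "csp_model"),
            factor >= 0)
  sources <- apply_csp(csp, train)
  d <- dim(sources$data)
  epoch_len <- d[3] / train$fs
  conds <- csp$class_order
  out <- list()
  fits <- list()
  prov <- list()
  for (ci in seq_along(conds)) {
    cond <- conds[ci]
    idx <- which(sources$labels == cond)
    n_art <- round(factor * length(idx))
    out[[cond]] <- list()
    for (j in seq_len(d[2])) {
      ep_mat <- sources$data[idx, j, , drop = TRUE]
      if (is.null(dim(ep_mat))) ep_mat <- matrix(ep_mat, nrow = 1)
      target <- epoch_average_spectrum(ep_mat, train$fs)
      fcfg <- fit_cfg
      fcfg$seed <- sub_seed(seed, ci * 1000 + j)
      fit <- fit_ctm_mcmc(target, fcfg)
      fits[[paste(cond, j, sep = ".")]] <- fit
      g_fit <- fit$map_gains
      fitted_ps <- analytic_spectrum(
        g_fit, seq(fcfg$band[1], fcfg$band[2], by = 0.25), fcfg$grid)
      if (n_art == 0) { out[[cond]][[j]] <- matrix(0, 0, d[3]); next }
      draws <- if (is.null(spec)) list(g_fit) else
        jitter_draws(g_fit, spec, factor,
                     seed = sub_seed(seed, ci * 1000 + j + 500),
                     fit_cfg = fcfg)
      assign_draw <- ((seq_len(n_art) - 1) %% length(draws)) + 1
      eps <- vector("list", n_art)
      for (dk in seq_along(draws)) {
        n_d <- sum(assign_draw == dk)
        if (n_d == 0) next
        gj <- draws[[dk]]
        scfg <- sim_cfg
        scfg$fs_out <- train$fs
        scfg$duration <- sim_cfg$burn_in + n_d * epoch_len + 1 / train$fs
        scfg$seed <- sub_seed(seed, ci * 1e6 + j * 1e4 + dk)
        s <- simulate_source(gj, scfg)
        # put artificial sources through the same band filter the real
        # sources saw, so band-limited features compare like for like
        s$samples <- bandpass_vector(s$samples, s$fs, fcfg$band[1],
                                     fcfg$band[2])
        s <- calibrate_amplitude(s, fitted_ps, fcfg$band)
        if (!is.null(spec)) {
          jit_ps <- analytic_spectrum(
            gj, seq(fcfg$band[1], fcfg$band[2], by = 0.25), fcfg$grid)
          ratio <- band_power(jit_ps, fcfg$band[1], fcfg$band[2]) /
            band_power(analytic_spectrum(
              g_fit, seq(fcfg$band[1], fcfg$band[2], by = 0.25), fcfg$grid),
              fcfg$band[1], fcfg$band[2])
          s$samples <- s$samples * sqrt(ratio)
        }
        segs <- segment_epochs(s, epoch_len)
        eps[which(assign_draw == dk)] <- segs[seq_len(n_d)]
        prov[[length(prov) + 1]] <- tibble::tibble(
          condition = cond, component = j, draw = dk, n_epochs = n_d,
          t0 = gj$t0, alpha = gj$alpha, gamma_e = gj$gamma_e,
          seed = scfg$seed)
      }
      out[[cond]][[j]] <- do.call(rbind, eps)
    }
  }
  structure(list(epochs = out, fits = fits,
                 provenance = if (length(prov)) dplyr::bind_rows(prov) else
                   tibble::tibble(),
                 epoch_len = epoch_len, fs = train$fs,
                 factor = factor, seed = seed,
                 train_labels = train$labels),
            class = "augmented_sources")
}

# deterministic sub-seed derivation, kept inside 32-bit integer range
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 2654435761) %% 2147483647)
}

#' Combine real and artificial source epochs into one feature table
#'
#' Artificial feature rows are formed by aligning the i-th generated epoch of
#' every component within a condition (the component simulations are
#' independent, so the alignment is arbitrary but fixed); rows are labeled by
#' condition, tagged `origin = "artificial"`, and appended after the real
#' rows.
#'
#' @param real_sources an [epoch_set()] of real CSP source epochs.
#' @param aug an [nft_augment()] result (or `NULL` for no augmentation).
#' @param feature `"TP"` or `"HFD"`.
#' @param hfd_n_max largest Higuchi scale.
#' @return A feature tibble as from [extract_features()].
#' @export
assemble_training_features <- function(real_sources, aug,
                                       feature = c("TP", "HFD"),
                                       hfd_n_max = 10) {
  feature <- match.arg(feature)
  real <- extract_features(real_sources, feature, hfd_n_max)
  if (is.null(aug)) return(real)
  fun <- if (feature == "TP") total_power else
    function(x) higuchi_fd(x, hfd_n_max)
  rows <- purrr::map_dfr(names(aug$epochs), function(cond) {
    mats <- aug$epochs[[cond]]
    counts <- vapply(mats, nrow, integer(1))
    if (length(unique(counts)) != 1)
      stop("CountMismatch: unequal artificial epoch counts across components",
           call. = FALSE)
    n_art <- counts[1]
    if (n_art == 0) return(tibble::tibble())
    vals <- vapply(seq_along(mats), function(j)
      apply(mats[[j]], 1, fun), numeric(n_art))
    vals <- matrix(vals, nrow = n_art)
    colnames(vals) <- paste0("csp", seq_along(mats), "_", tolower(feature))
    out <- tibble::as_tibble(as.data.frame(vals))
    dplyr::mutate(out, epoch = seq_len(n_art), condition = cond,
                  origin = "artificial", .before = 1)
  })
  dplyr::bind_rows(real, rows)
}

#' Feature-space noise augmentation baseline
#'
#' The naive comparison method: per condition, draw
#' `round(factor * n_rows)` synthetic feature rows from a multivariate
#' normal with the condition's sample mean and `scale` times its sample
#' covariance, and append them to the table. Assumes (often incorrectly)
#' that features are Gaussian.
#'
#' @param f a feature tibble with `condition` and numeric feature columns.
#' @param factor augmentation factor.
#' @param scale covariance inflation (default 1.5).
#' @param seed integer seed.
#' @return The input tibble with synthetic rows appended
#'   (`origin = "artificial"`).
#' @export
noise_augment <- function(f, factor, scale = 1.5, seed = 1) {
  if (!"origin" %in% names(f)) f <- dplyr::mutate(f, origin = "real")
  cols <- feature_cols(f)
  conds <- sort(unique(f$condition))
  new_rows <- withr::with_seed(seed, purrr::map_dfr(conds, function(cond) {
    x <- as.matrix(f[f$condition == cond, cols, drop = FALSE])
    if (nrow(x) < length(cols) + 1)
      stop("need at least n_features + 1 rows per condition", call. = FALSE)
    n_new <- round(factor * nrow(x))
    if (n_new == 0) return(tibble::tibble())
    s <- scale * stats::cov(x)
    draws <- try(MASS::mvrnorm(n_new, colMeans(x), s), silent = TRUE)
    if (inherits(draws, "try-error")) {
      s <- s + 1e-8 * max(sum(diag(s)), 1e-12) * diag(ncol(x))
      draws <- MASS::mvrnorm(n_new, colMeans(x), s)
      if (inherits(draws, "try-error"))
        stop("SingularCovariance", call. = FALSE)
    }
    draws <- matrix(draws, nrow = n_new,
                    dimnames = list(NULL, cols))
    out <- tibble::as_tibble(as.data.frame(draws))
    dplyr::mutate(out, epoch = seq_len(n_new), condition = cond,
                  origin = "artificial", .before = 1)
  }))
  dplyr::bind_rows(f, new_rows)
}
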