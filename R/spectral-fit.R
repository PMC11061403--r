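#' Configuration for spectral model fitting
#'
#' Settings for the random-walk Metropolis fit of the corticothalamic gains
#' to an experimental power spectrum. Eight parameters are sampled (the five
#' gains, `alpha`, `beta`, `t0`) inside a box prior; the overall amplitude is
#' profiled out of the objective in closed form, and `gamma_e`/`r_e` are held
#' fixed. Proposal standard deviations start at `proposal_frac` of the box
#' width and adapt during burn-in towards a 20-40% acceptance rate.
#'
#' Default prior bounds are literature-typical: `G_ee` in (0, 25), `G_ei` in
#' (-25, 0), `G_ese` in (0, 40), `G_esre` in (-40, 0), `G_srs` in (-10, 0),
#' `alpha` in (20, 200)/s, `beta` in (`alpha`, 800)/s, `t0` in (0.06, 0.14) s.
#'
#' @param band fit band in Hz (low, high); the 8-30 Hz sensorimotor band by
#'   default.
#' @param n_chains number of independent chains.
#' @param n_steps sweeps per chain (each sweep updates every parameter once).
#' @param burn_in_steps sweeps treated as burn-in (adaptation window).
#' @param proposal_frac initial proposal s.d. as a fraction of the box width.
#' @param lower,upper named prior bounds for
#'   `g_ee, g_ei, g_ese, g_esre, g_srs, alpha, beta, t0`.
#' @param gamma_e,r_e fixed cortical damping (1/s) and axonal range (m).
#' @param grid [spectrum_grid()] used for model spectra.
#' @param stability_ceiling peak-to-median ratio of the resonance
#'   enhancement factor (spectrum over the open-loop spectrum) above which a
#'   parameter set is rejected as near-bifurcation.
#' @param temperature,temperature_hi Metropolis temperatures on the
#'   objective (squared-log10 units). The chain anneals geometrically from
#'   `temperature_hi` to `temperature` across the burn-in and stays cold
#'   afterwards: hot sweeps explore between basins, cold sweeps refine the
#'   point estimate. Proposal adaptation keeps the acceptance rate in range
#'   throughout.
#' @param seed integer seed.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(band = c(8, 30), n_chains = 3, n_steps = 20000,
                       burn_in_steps = 5000, proposal_frac = 0.05,
                       lower = c(g_ee = 1e-4, g_ei = -25, g_ese = 0,
                                 g_esre = -40, g_srs = -10, alpha = 20,
                                 beta = 20, t0 = 0.06),
                       upper = c(g_ee = 25, g_ei = -1e-4, g_ese = 40,
                                 g_esre = 0, g_srs = 0, alpha = 200,
                                 beta = 800, t0 = 0.14),
                       gamma_e = 116, r_e = 0.086,
                       grid = spectrum_grid(), stability_ceiling = 5,
                       temperature = 1e-4, temperature_hi = 0.03,
                       seed = 1) {
  stopifnot(band[1] < band[2], n_steps > burn_in_steps, n_chains >= 1,
            all(names(lower) == names(upper)), all(lower < upper))
  structure(list(band = band, n_chains = as.integer(n_chains),
                 n_steps = as.integer(n_steps),
                 burn_in_steps = as.integer(burn_in_steps),
                 proposal_frac = proposal_frac, lower = lower, upper = upper,
                 gamma_e = gamma_e, r_e = r_e, grid = grid,
                 stability_ceiling = stability_ceiling,
                 temperature = temperature, temperature_hi = temperature_hi,
                 seed = as.integer(seed)),
            class = "fit_config")
}

#' Epoch-averaged power spectrum
#'
#' Per-epoch periodograms averaged arithmetically across epochs. The
#' normalization is Parseval-consistent: summing the one-sided power over the
#' frequency grid times the bin width recovers the epoch's mean squared
#' amplitude exactly, so band-integrated power and the total-power feature
#' agree by construction.
#'
#' @param source_epochs list of equal-length numeric vectors (or a matrix
#'   with epochs in rows).
#' @param fs sampling rate in Hz.
#' @return A [power_spectrum()] with resolution `fs/N` (units signal^2/Hz).
#' @export
epoch_average_spectrum <- function(source_epochs, fs) {
  if (is.matrix(source_epochs))
    source_epochs <- asplit(source_epochs, 1)
  stopifnot(length(source_epochs) >= 1)
  n <- unique(as.integer(lengths(source_epochs)))
  if (length(n) != 1)
    stop("LengthMismatch: epochs differ in length", call. = FALSE)
  nh <- floor(n / 2)
  df <- fs / n
  acc <- numeric(nh + 1)
  for (x in source_epochs) {
    X <- stats::fft(as.numeric(x))
    p2 <- Mod(X)^2 / (n^2 * df)          # two-sided density
    one <- p2[1:(nh + 1)]
    if (n %% 2 == 0) {
      if (nh > 1) one[2:nh] <- one[2:nh] + p2[n:(n - nh + 2)]
    } else {
      one[2:(nh + 1)] <- one[2:(nh + 1)] + p2[n:(n - nh + 1)]
    }
    acc <- acc + one
  }
  power_spectrum((0:nh) * df, acc / length(source_epochs),
                 units = "signal^2/Hz")
}

#' Welch power spectral density
#'
#' Averaged modified periodogram with Hann-tapered, 50%-overlapping
#' segments; the standard low-leakage estimator used to validate simulated
#' signals against the analytic spectrum (sharp resonances leak badly under
#' a rectangular window). Normalization is density-consistent: integrating
#' over frequency recovers the signal's mean square.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param seg_len segment length in seconds.
#' @param overlap fractional overlap between segments.
#' @return A [power_spectrum()].
#' @export
welch_spectrum <- function(x, fs, seg_len = 2, overlap = 0.5) {
  n <- round(seg_len * fs)
  stopifnot(length(x) >= n, n >= 8)
  step <- max(1, round(n * (1 - overlap)))
  starts <- seq(1, length(x) - n + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  u <- mean(w^2)                      # window power normalization
  nh <- floor(n / 2)
  df <- fs / n
  acc <- numeric(nh + 1)
  for (s0 in starts) {
    X <- stats::fft(x[s0:(s0 + n - 1)] * w)
    p2 <- Mod(X)^2 / (n^2 * df * u)
    one <- p2[1:(nh + 1)]
    if (n %% 2 == 0) {
      if (nh > 1) one[2:nh] <- one[2:nh] + p2[n:(n - nh + 2)]
    } else {
      one[2:(nh + 1)] <- one[2:(nh + 1)] + p2[n:(n - nh + 1)]
    }
    acc <- acc + one
  }
  power_spectrum((0:nh) * df, acc / length(starts), units = "signal^2/Hz")
}

#' Spectral misfit objective
#'
#' Sum over band frequencies of squared log10-power differences between the
#' model's analytic spectrum and a target spectrum, with the multiplicative
#' amplitude profiled out in closed form (the optimal scale is applied before
#' differencing). Zero iff the band shapes match exactly; invariant to
#' rescaling the target. Unstable parameter sets score `Inf`.
#'
#' @param g a [ctm_gains()] object.
#' @param target a [power_spectrum()] covering the band.
#' @param cfg a [fit_config()].
#' @return Nonnegative scalar.
#' @export
spectrum_objective <- function(g, target, cfg = fit_config()) {
  keep <- target$frequency_hz >= cfg$band[1] &
    target$frequency_hz <= cfg$band[2]
  if (!any(keep)) stop("target does not cover the fit band", call. = FALSE)
  f <- target$frequency_hz[keep]
  if (!stability_check(g, cfg)) return(Inf)
  pw <- ctm_spectrum_cpp(par_vec(g), f, cfg$grid$Lx, cfg$grid$Ly,
                         cfg$grid$k0, cfg$grid$m_max)
  if (any(!is.finite(pw)) || any(pw <= 0)) return(Inf)
  x <- log10(target$power[keep]) - log10(pw)
  sum((x - mean(x))^2)
}

#' Stability screen for a gain set
#'
#' A parameter set is accepted when its analytic spectrum is finite and
#' positive on a dense 0.5-45 Hz grid and the peak-to-median ratio of its
#' resonance enhancement factor (the spectrum divided by the open-loop
#' spectrum of the same synaptic and propagation parameters) stays below a
#' ceiling. The enhancement ratio is a divergence proxy: it is near one for
#' weak feedback regardless of how steep the dendritic low-pass is, and
#' grows rapidly as any loop approaches a bifurcation, closely tracking
#' where time-domain integration of the same parameters starts to diverge.
#' Near-critical sets are rejected before they can contaminate fitting or
#' signal generation.
#'
#' @param g a [ctm_gains()] object.
#' @param cfg a [fit_config()] supplying the grid and the ceiling.
#' @return `TRUE` or `FALSE`.
#' @export
stability_check <- function(g, cfg = fit_config()) {
  ctm_stable_cpp(par_vec(g), seq(0.5, 45, by = 0.25),
                 cfg$grid$Lx, cfg$grid$Ly, cfg$grid$k0, cfg$grid$m_max,
                 cfg$stability_ceiling)
}

#' Fit corticothalamic gains to a power spectrum by MCMC
#'
#' Random-walk Metropolis inside the prior box (single-site sweeps plus
#' adaptive joint proposals along the chain's running covariance, with the
#' temperature annealed across burn-in). Chains start at independent uniform
#' draws that pass [stability_check()]; the best-objective sample across
#' chains is the point estimate, with the profiled amplitude restored. A
#' split-chain potential-scale-reduction diagnostic on `t0` and `alpha` flags
#' convergence (advisory only). Deterministic given `cfg$seed`.
#'
#' With `refine = TRUE` the point estimate is polished by a warm-started
#' profile walk over the loop delay: `t0` is stepped across a few
#' milliseconds around the chain optimum while the remaining parameters are
#' re-optimized (BFGS) at each step. The misfit surface has a narrow curved
#' ridge in which `t0` trades against the synaptic rates; the walk follows
#' the ridge floor and resolves the delay decisively where samplers and
#' one-shot local optimizers stall in an adjacent micro-basin.
#'
#' @param target a [power_spectrum()] covering the fit band.
#' @param cfg a [fit_config()].
#' @param refine polish the point estimate by the `t0` profile walk
#'   (recommended when the loop delay itself is of interest; the extra cost
#'   is a second or two).
#' @return An object of class `ctm_fit` with elements `map_gains`, `chains`
#'   (one tibble per chain: parameters + objective per sweep),
#'   `acceptance_rate`, `converged`, `objective`, `shape_error` (band mean
#'   relative error of the fitted vs target shape), and `target`.
#' @export
fit_ctm_mcmc <- function(target, cfg = fit_config(), refine = TRUE) {
  keep <- target$frequency_hz >= cfg$band[1] &
    target$frequency_hz <= cfg$band[2]
  if (sum(keep) < 8)
    stop("target has too few frequencies in the fit band", call. = FALSE)
  f <- target$frequency_hz[keep]
  log10_t <- log10(target$power[keep])
  if (any(!is.finite(log10_t)))
    stop("target power must be positive on the fit band", call. = FALSE)
  stab_f <- seq(0.5, 45, by = 0.25)
  width <- cfg$upper - cfg$lower
  pnames <- names(cfg$lower)

  res <- withr::with_seed(cfg$seed, {
    lapply(seq_len(cfg$n_chains), function(ch) {
      # first chain starts greedily (best of a scatter of stable draws),
      # the rest start at plain stable draws so the chains stay diverse
      init <- draw_stable_init(cfg, log10_t = log10_t, f = f,
                               n_candidates = if (ch == 1) 64 else 8)
      ctm_mcmc_cpp(log10_t, f, init, cfg$lower, cfg$upper,
                   cfg$proposal_frac * width, cfg$n_steps, cfg$burn_in_steps,
                   cfg$gamma_e, cfg$r_e, cfg$grid$Lx, cfg$grid$Ly,
                   cfg$grid$k0, cfg$grid$m_max, stab_f,
                   cfg$stability_ceiling, cfg$temperature,
                   cfg$temperature_hi)
    })
  })

  best_chain <- which.min(vapply(res, function(r) r$best_objective,
                                 numeric(1)))
  best <- res[[best_chain]]$best
  names(best) <- pnames
  best_obj <- res[[best_chain]]$best_objective
  if (refine) {
    ref <- refine_t0_profile(best, log10_t, f, cfg)
    if (ref$objective < best_obj) { best <- ref$par; best_obj <- ref$objective }
  }
  g <- ctm_gains(g_ee = best[["g_ee"]], g_ei = best[["g_ei"]],
                 g_ese = best[["g_ese"]], g_esre = best[["g_esre"]],
                 g_srs = best[["g_srs"]], amplitude = 1,
                 alpha = best[["alpha"]], beta = best[["beta"]],
                 t0 = best[["t0"]], gamma_e = cfg$gamma_e, r_e = cfg$r_e)
  # restore the profiled amplitude
  pw <- ctm_spectrum_cpp(par_vec(g), f, cfg$grid$Lx, cfg$grid$Ly,
                         cfg$grid$k0, cfg$grid$m_max)
  g$amplitude <- 10^(mean(log10_t - log10(pw)) / 2)
  fitted_ps <- analytic_spectrum(g, f, cfg$grid)
  shape_err <- spectrum_shape_error(fitted_ps,
                                    power_spectrum(f, target$power[keep]),
                                    cfg$band[1], cfg$band[2])

  chains <- lapply(res, function(r) {
    m <- r$chain
    colnames(m) <- c(pnames, "objective")
    tibble::as_tibble(as.data.frame(m))
  })
  structure(list(
    map_gains = g,
    chains = chains,
    acceptance_rate = mean(vapply(res, function(r) r$acceptance_rate,
                                  numeric(1))),
    converged = mcmc_converged(chains, cfg),
    objective = best_obj,
    shape_error = shape_err,
    config = cfg,
    target = target), class = "ctm_fit")
}

# warm-started profile walk over t0: at each t0 step the other seven
# parameters are re-optimized from the previous step's optimum, tracking the
# ridge floor; returns the best profiled point that is valid and stable
refine_t0_profile <- function(best, log10_t, f, cfg,
                              span = 0.002, step = 1e-4) {
  pn <- names(cfg$lower)
  obj7 <- function(v, t0v) {
    p <- c(v, t0v)
    if (any(p < cfg$lower) || any(p > cfg$upper) || v[7] < v[6]) return(1e6)
    pw <- ctm_spectrum_cpp(c(p, cfg$gamma_e, cfg$r_e, 1), f, cfg$grid$Lx,
                           cfg$grid$Ly, cfg$grid$k0, cfg$grid$m_max)
    if (any(!is.finite(pw)) || any(pw <= 0)) return(1e6)
    x <- log10_t - log10(pw)
    sum((x - mean(x))^2)
  }
  parscale <- pmax(0.5 * (cfg$upper - cfg$lower)[1:7], 1e-6)
  slice <- function(v, t0v) {
    op <- stats::optim(v, obj7, t0v = t0v, method = "BFGS",
                       control = list(maxit = 400, reltol = 1e-14,
                                      parscale = parscale))
    list(par = c(op$par, t0v), objective = op$value)
  }
  # warm-started walk over a given t0 grid, carrying the re-optimized
  # parameters from slice to slice so the walk follows the ridge floor
  walk <- function(t0s, v0) {
    v <- v0
    out <- vector("list", length(t0s))
    for (i in seq_along(t0s)) {
      out[[i]] <- slice(v, t0s[i])
      v <- out[[i]]$par[1:7]
    }
    out
  }
  # stage 1: coarse profile across the whole delay prior (the sampler can
  # settle many milliseconds off when two resonance combs fit comparably);
  # stage 2: fine walk around the coarse winner
  coarse <- c(walk(seq(best[8], cfg$upper[["t0"]], by = 1e-3), best[1:7]),
              walk(seq(best[8], cfg$lower[["t0"]], by = -1e-3),
                   best[1:7]))
  objs_c <- vapply(coarse, `[[`, numeric(1), "objective")
  ord <- order(objs_c)
  anchors <- list(coarse[[ord[1]]]$par)
  for (i in ord[-1]) {               # a second anchor in a distinct basin
    if (abs(coarse[[i]]$par[8] - anchors[[1]][8]) > 2 * span) {
      anchors <- c(anchors, list(coarse[[i]]$par))
      break
    }
  }
  fine <- list()
  for (anchor in anchors) {
    fine <- c(fine,
              walk(seq(anchor[8], min(anchor[8] + span, cfg$upper[["t0"]]),
                       by = step), anchor[1:7]),
              walk(seq(anchor[8], max(anchor[8] - span, cfg$lower[["t0"]]),
                       by = -step), anchor[1:7]))
  }
  cand <- c(coarse, fine)
  objs <- vapply(cand, `[[`, numeric(1), "objective")
  for (i in order(objs)) {
    p <- cand[[i]]$par
    names(p) <- pn
    g <- try(ctm_gains(g_ee = p[["g_ee"]], g_ei = p[["g_ei"]],
                       g_ese = p[["g_ese"]], g_esre = p[["g_esre"]],
                       g_srs = p[["g_srs"]], amplitude = 1,
                       alpha = p[["alpha"]], beta = p[["beta"]],
                       t0 = p[["t0"]], gamma_e = cfg$gamma_e,
                       r_e = cfg$r_e), silent = TRUE)
    if (!inherits(g, "try-error") && stability_check(g, cfg))
      return(list(par = p, objective = objs[i]))
  }
  list(par = best, objective = Inf)
}

# uniform draws from the prior box until one passes the stability screen;
# among n_candidates such draws the one with the best objective starts the
# chain (a cheap global scatter before the local random walk)
draw_stable_init <- function(cfg, log10_t = NULL, f = NULL,
                             n_candidates = 64, max_tries = 2000) {
  cand <- NULL
  cand_obj <- Inf
  found <- 0L
  for (i in seq_len(max_tries)) {
    x <- cfg$lower + stats::runif(length(cfg$lower)) * (cfg$upper - cfg$lower)
    if (x[["beta"]] < x[["alpha"]])
      x[c("alpha", "beta")] <- x[c("beta", "alpha")]
    g <- try(ctm_gains(g_ee = x[["g_ee"]], g_ei = x[["g_ei"]],
                       g_ese = x[["g_ese"]], g_esre = x[["g_esre"]],
                       g_srs = x[["g_srs"]], amplitude = 1,
                       alpha = x[["alpha"]], beta = x[["beta"]],
                       t0 = x[["t0"]], gamma_e = cfg$gamma_e, r_e = cfg$r_e),
             silent = TRUE)
    if (inherits(g, "try-error") || !stability_check(g, cfg)) next
    found <- found + 1L
    v <- c(x[["g_ee"]], x[["g_ei"]], x[["g_ese"]], x[["g_esre"]],
           x[["g_srs"]], x[["alpha"]], x[["beta"]], x[["t0"]])
    if (is.null(log10_t)) return(v)
    pw <- ctm_spectrum_cpp(c(v, cfg$gamma_e, cfg$r_e, 1), f, cfg$grid$Lx,
                           cfg$grid$Ly, cfg$grid$k0, cfg$grid$m_max)
    xx <- log10_t - log10(pw)
    obj <- sum((xx - mean(xx))^2)
    if (is.finite(obj) && obj < cand_obj) { cand <- v; cand_obj <- obj }
    if (found >= n_candidates) return(cand)
  }
  if (!is.null(cand)) return(cand)
  stop("NoStableInit: no stable initial draw after ", max_tries, " tries",
       call. = FALSE)
}

# split-chain potential scale reduction on t0 and alpha, advisory
mcmc_converged <- function(chains, cfg, threshold = 1.1) {
  halves <- list()
  for (ch in chains) {
    post <- ch[-seq_len(cfg$burn_in_steps), , drop = FALSE]
    n2 <- floor(nrow(post) / 2)
    halves <- c(halves, list(post[1:n2, ], post[(n2 + 1):(2 * n2), ]))
  }
  rhat <- function(param) {
    xs <- lapply(halves, function(h) h[[param]])
    l <- length(xs[[1]])
    wv <- mean(vapply(xs, stats::var, numeric(1)))
    bv <- l * stats::var(vapply(xs, mean, numeric(1)))
    if (wv == 0) return(1)
    sqrt(((l - 1) / l * wv + bv / l) / wv)
  }
  all(vapply(c("t0", "alpha"), rhat, numeric(1)) < threshold)
}

#' @export
print.ctm_fit <- function(x, ...) {
  cat("<ctm_fit>\n")
  cat(sprintf("  objective %.4g  band shape error %.2f%%  acceptance %.0f%%  converged %s\n",
              x$objective, 100 * x$shape_error, 100 * x$acceptance_rate,
              x$converged))
  print(x$map_gains)
  invisible(x)
}

#' Tidy a spectral fit
#'
#' @param x a `ctm_fit` object.
#' @param ... unused.
#' @return Tibble with one row per fitted parameter (point estimate plus
#'   post-burn-in chain quantiles).
#' @method tidy ctm_fit
#' @export
tidy.ctm_fit <- function(x, ...) {
  pnames <- setdiff(colnames(x$chains[[1]]), "objective")
  post <- dplyr::bind_rows(lapply(x$chains, function(ch)
    ch[-seq_len(x$config$burn_in_steps), ]))
  est <- unlist(x$map_gains[pnames])
  purrr::map_dfr(pnames, function(p) tibble::tibble(
    term = p,
    estimate = est[[p]],
    conf.low = stats::quantile(post[[p]], 0.05, names = FALSE),
    conf.high = stats::quantile(post[[p]], 0.95, names = FALSE)))
}

#' Fit summary
#'
#' @param x a `ctm_fit` object.
#' @param ... unused.
#' @return One-row tibble with objective, band shape error, acceptance rate
#'   and the convergence flag.
#' @method glance ctm_fit
#' @export
glance.ctm_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, shape_error = x$shape_error,
                 acceptance_rate = x$acceptance_rate,
                 converged = x$converged,
                 n_steps = x$config$n_steps, n_chains = x$config$n_chains)
}
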