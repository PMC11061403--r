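test_that("epoch-averaged periodogram is Parseval-consistent", {
  fs <- 250; n <- 625
  t <- (0:(n - 1)) / fs
  # bin-centered sinusoid: 10 Hz is an exact multiple of fs/n = 0.4 Hz
  x <- 1.8 * sin(2 * pi * 10 * t)
  ps <- epoch_average_spectrum(list(x), fs)
  df <- fs / n
  band <- sum(ps$power[ps$frequency_hz >= 8 & ps$frequency_hz <= 12]) * df
  expect_equal(band, 1.8^2 / 2, tolerance = 0.01)
  # total integral recovers the mean square exactly
  expect_equal(sum(ps$power) * df, mean(x^2), tolerance = 1e-12)
  # averaging identical epochs changes nothing
  ps3 <- epoch_average_spectrum(list(x, x, x), fs)
  expect_equal(ps3$power, ps$power)
  expect_error(epoch_average_spectrum(list(x, x[-1]), fs), "LengthMismatch")
})

test_that("white-noise average spectrum is flat across the band", {
  set.seed(88)
  eps <- lapply(1:72, function(i) rnorm(625))
  ps <- epoch_average_spectrum(eps, 250)
  keep <- ps$frequency_hz >= 8 & ps$frequency_hz <= 30
  p <- ps$power[keep]
  halves <- split(p, rep(1:2, each = ceiling(length(p) / 2))[seq_along(p)])
  m <- mean(p)
  expect_lt(max(abs(vapply(halves, mean, numeric(1)) - m)) / m, 0.05)
  # density level: white noise with unit variance has PSD 2/fs (one-sided)
  expect_equal(m, 2 / 250, tolerance = 0.05)
})

test_that("Welch estimator recovers total power and tone frequency", {
  fs <- 250
  t <- (0:(60 * fs - 1)) / fs
  x <- sqrt(2) * sin(2 * pi * 11 * t) + rnorm(length(t), sd = 0.3)
  w <- welch_spectrum(x, fs, seg_len = 2)
  df <- diff(w$frequency_hz[1:2])
  expect_equal(sum(w$power) * df, mean(x^2), tolerance = 0.05)
  expect_equal(w$frequency_hz[which.max(w$power)], 11, tolerance = 0.5)
})

test_that("spectral objective is zero on self, scale-free, and t0-sensitive", {
  g <- test_gains()
  cfg <- fit_config()
  target <- analytic_spectrum(g, seq(8, 30, by = 0.4), cfg$grid)
  expect_lt(spectrum_objective(g, target, cfg), 1e-12)
  scaled <- target; scaled$power <- 1000 * target$power
  expect_equal(spectrum_objective(g, scaled, cfg),
               spectrum_objective(g, target, cfg), tolerance = 1e-10)
  g_shift <- g; g_shift$t0 <- g$t0 + 0.003
  expect_gt(spectrum_objective(g_shift, target, cfg), 0.01)
  # local identifiability: misfit grows monotonically with |t0 offset|
  objs <- vapply(c(0, 1, 2, 3) * 1e-3, function(d) {
    gg <- g; gg$t0 <- g$t0 + d
    spectrum_objective(gg, target, cfg)
  }, numeric(1))
  expect_true(all(diff(objs) > 0))
})

test_that("stability screen accepts quiet sets and rejects near-resonance", {
  g0 <- ctm_gains(g_ee = 1e-9, g_ei = -1e-9, g_ese = 0, g_esre = 0,
                  g_srs = 0, amplitude = 1)
  expect_true(stability_check(g0))
  expect_true(stability_check(test_gains()))
  # push the corticothalamic loop towards its resonance until rejected:
  # scanning the intrathalamic gain at a strong excitatory loop crosses the
  # ceiling where the weakly-damped resonance sharpens
  flags <- vapply(seq(-0.5, -6, by = -0.5), function(gsrs) {
    g <- test_gains(); g$g_srs <- gsrs; g$g_ese <- 9.3
    stability_check(g)
  }, logical(1))
  expect_true(any(!flags))
  expect_true(any(flags))
  # attenuating the loops far enough always restores stability: the
  # enhancement factor tends to one as the feedback vanishes
  set.seed(55)
  for (i in 1:50) {
    g64 <- random_stable_gains()
    for (nm in c("g_ee", "g_ei", "g_ese", "g_esre", "g_srs"))
      g64[[nm]] <- g64[[nm]] / 64
    g64$g_ee <- max(g64$g_ee, 1e-4); g64$g_ei <- min(g64$g_ei, -1e-4)
    expect_true(stability_check(g64))
  }
  # along the default operating point's scaling family the screen outcome
  # is monotone: every attenuated version of a stable set stays stable
  for (s in c(1, 0.5, 0.25, 1 / 64)) {
    gs <- test_gains()
    for (nm in c("g_ee", "g_ei", "g_ese", "g_esre", "g_srs"))
      gs[[nm]] <- s * gs[[nm]]
    gs$g_ee <- max(gs$g_ee, 1e-6); gs$g_ei <- min(gs$g_ei, -1e-6)
    expect_true(stability_check(gs))
  }
})

test_that("the sampler is deterministic and improves with more sweeps", {
  g <- test_gains()
  target <- analytic_spectrum(g, seq(8, 30, by = 0.4))
  cfg <- fit_config(n_chains = 1, n_steps = 400, burn_in_steps = 100,
                    seed = 12)
  f1 <- fit_ctm_mcmc(target, cfg, refine = FALSE)
  f2 <- fit_ctm_mcmc(target, cfg, refine = FALSE)
  expect_identical(unlist(f1$map_gains), unlist(f2$map_gains))
  expect_gt(f1$acceptance_rate, 0)
  expect_lt(f1$acceptance_rate, 1)
  # same seed, longer run: the best objective can only improve
  cfg2 <- cfg; cfg2$n_steps <- 1200L
  f3 <- fit_ctm_mcmc(target, cfg2, refine = FALSE)
  expect_lte(f3$objective, f1$objective)
  # chain samples respect the prior box
  ch <- f3$chains[[1]]
  for (nm in names(cfg$lower)) {
    expect_true(all(ch[[nm]] >= cfg$lower[[nm]]))
    expect_true(all(ch[[nm]] <= cfg$upper[[nm]]))
  }
  expect_true(all(ch$beta >= ch$alpha))
})

test_that("accepted chain samples pass the stability screen", {
  g <- test_gains()
  target <- analytic_spectrum(g, seq(8, 30, by = 0.4))
  cfg <- fit_config(n_chains = 1, n_steps = 150, burn_in_steps = 50,
                    seed = 9)
  fit <- fit_ctm_mcmc(target, cfg, refine = FALSE)
  ch <- fit$chains[[1]]
  pick <- seq(1, nrow(ch), by = 10)
  for (i in pick) {
    gi <- ctm_gains(g_ee = ch$g_ee[i], g_ei = ch$g_ei[i],
                    g_ese = ch$g_ese[i], g_esre = ch$g_esre[i],
                    g_srs = ch$g_srs[i], amplitude = 1, alpha = ch$alpha[i],
                    beta = ch$beta[i], t0 = ch$t0[i],
                    gamma_e = cfg$gamma_e, r_e = cfg$r_e)
    expect_true(stability_check(gi, cfg))
  }
})

test_that("tidy and glance summarize a fit", {
  g <- test_gains()
  target <- analytic_spectrum(g, seq(8, 30, by = 0.4))
  fit <- fit_ctm_mcmc(target, fit_config(n_chains = 2, n_steps = 300,
                                         burn_in_steps = 100, seed = 2),
                      refine = FALSE)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$term, names(fit$config$lower))
  expect_true(all(td$conf.low <= td$conf.high))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(is.logical(gl$converged))
})
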