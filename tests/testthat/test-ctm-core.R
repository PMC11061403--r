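test_that("firing-rate sigmoid has the right midpoint, limits and slope", {
  p <- physio_params_default()
  expect_equal(sigmoid_rate(p$theta, p), p$q_max / 2)
  expect_equal(sigmoid_rate(10, p), p$q_max)
  expect_equal(sigmoid_rate(-10, p), 0)
  # closed-form derivative against central differences at several potentials
  for (v in c(-0.01, 0, p$theta, 0.02)) {
    h <- 1e-7
    fd <- (sigmoid_rate(v + h, p) - sigmoid_rate(v - h, p)) / (2 * h)
    expect_equal(nftda:::sigmoid_rate_deriv(v, p), fd, tolerance = 1e-6)
  }
  # strictly increasing
  v <- seq(-0.05, 0.05, length.out = 200)
  expect_true(all(diff(sigmoid_rate(v, p)) > 0))
})

test_that("dendritic frequency response is a unit-DC monotone low-pass", {
  expect_equal(dendritic_transfer(0, 83, 769), 1 + 0i)
  om <- seq(0, 2000, length.out = 300)
  mags <- Mod(dendritic_transfer(om, 83, 769))
  expect_true(all(diff(mags) < 0))
  expect_true(all(mags <= 1))
  # |L|^2 closed form, checked at omega = alpha with huge beta -> 1/2
  expect_equal(Mod(dendritic_transfer(83, 83, 1e9))^2, 0.5, tolerance = 1e-6)
  expect_equal(Mod(dendritic_transfer(120, 83, 769))^2,
               1 / ((1 + 120^2 / 83^2) * (1 + 120^2 / 769^2)))
})

test_that("dendritic response matches the Fourier transform of the kernel", {
  alpha <- 83; beta <- 300
  for (om in c(20, 80, 250)) {
    re <- stats::integrate(function(t) impulse_response(t, alpha, beta) *
                             cos(om * t), 0, Inf, rel.tol = 1e-10)$value
    im <- stats::integrate(function(t) impulse_response(t, alpha, beta) *
                             sin(om * t), 0, Inf, rel.tol = 1e-10)$value
    expect_equal(complex(real = re, imaginary = im),
                 dendritic_transfer(om, alpha, beta), tolerance = 1e-7)
  }
})

test_that("steady state satisfies the fixed-point equations", {
  p <- physio_params_default()
  ss <- steady_state(p)
  expect_lt(ss$residual, 1e-10)
  expect_true(all(ss$rho > 0))
  for (a in names(ss$v))
    expect_equal(ss$rho[[a]], nftda:::sigmoid_rate_deriv(ss$v[[a]], p),
                 tolerance = 1e-8)
})

test_that("decoupled steady state reduces to one sigmoid composition", {
  p <- physio_params_default()
  p$nu[c("ee", "ei", "es", "se", "sr", "re", "rs")] <- 0
  ss <- steady_state(p)
  expect_equal(ss$v[["s"]], p$nu[["sn"]] * p$phi_n0, tolerance = 1e-12)
  expect_equal(ss$v[["e"]], 0, tolerance = 1e-12)
  expect_equal(ss$phi[["s"]], sigmoid_rate(p$nu[["sn"]] * p$phi_n0, p))
})

test_that("linearized gains scale with connection strengths", {
  p <- physio_params_default()
  g <- gains_from_physio(p)
  expect_gt(g$g_ee, 0); expect_lt(g$g_ei, 0)
  expect_gt(g$g_ese, 0); expect_lt(g$g_esre, 0); expect_lt(g$g_srs, 0)
  # no corticothalamic input -> both corticothalamic loops vanish
  p0 <- p; p0$nu[["es"]] <- 0
  g0 <- gains_from_physio(p0)
  expect_equal(g0$g_ese, 0)
  expect_equal(g0$g_esre, 0)
  # linearity in nu at a frozen fixed point
  ss <- steady_state(p)
  p2 <- p; p2$nu[["ee"]] <- 2 * p$nu[["ee"]]
  g2 <- gains_from_physio(p2, ss = ss)
  expect_equal(g2$g_ee, 2 * g$g_ee, tolerance = 1e-12)
})

test_that("physio round-trip reproduces loop gains", {
  p <- physio_params_default()
  g <- gains_from_physio(p)
  p2 <- physio_from_gains(g, template = p)
  g2 <- gains_from_physio(p2)
  for (nm in c("g_ee", "g_ei", "g_ese", "g_esre", "g_srs"))
    expect_equal(g2[[nm]], g[[nm]], tolerance = 1e-6)
  # connection-strength sign pattern respected
  expect_lte(p2$nu[["ei"]], 0); expect_lte(p2$nu[["sr"]], 0)
  expect_true(all(p2$nu[c("ee", "es", "se", "re", "rs", "sn")] >= 0))
  # infeasible: inhibitory corticothalamic loop without an excitatory one
  bad <- g; bad$g_ese <- 0
  expect_error(physio_from_gains(bad, template = p), "InfeasibleGains")
})

test_that("transfer function collapses correctly at the zero-gain point", {
  g0 <- ctm_gains(g_ee = 1e-12, g_ei = -1e-12, g_ese = 0, g_esre = 0,
                  g_srs = 0, amplitude = 1)
  expect_equal(Mod(transfer_function(g0, 0, 0)), 1, tolerance = 1e-9)
  # stronger cortical inhibition monotonically suppresses the field
  mags <- vapply(seq(-1, -20, length.out = 10), function(gei) {
    g <- ctm_gains(g_ee = 1e-6, g_ei = gei, g_ese = 0, g_esre = 0,
                   g_srs = 0, amplitude = 1)
    Mod(transfer_function(g, 0, 0))
  }, numeric(1))
  expect_true(all(diff(mags) < 0))
})

test_that("transfer function agrees with the matrix-solve oracle", {
  set.seed(301)
  for (i in 1:10) {
    g <- random_stable_gains()
    for (pt in list(c(0, 2 * pi * 10), c(12.6, 2 * pi * 22),
                    c(25.1, 2 * pi * 5))) {
      expect_equal(transfer_function(g, pt[1], pt[2]),
                   transfer_matrix_oracle(g, pt[1], pt[2]),
                   tolerance = 1e-9)
    }
  }
})

test_that("analytic spectrum with a single mode is one transfer term", {
  g <- test_gains()
  grid0 <- spectrum_grid(m_max = 0)
  f <- c(5, 10, 20, 30)
  ps <- analytic_spectrum(g, f, grid0)
  expected <- Mod(transfer_function(g, 0, 2 * pi * f))^2 *
    (2 * pi / grid0$Lx) * (2 * pi / grid0$Ly)
  expect_equal(ps$power, expected, tolerance = 1e-12)
})

test_that("zero-gain spectrum equals its closed form", {
  g0 <- ctm_gains(g_ee = 1e-12, g_ei = -1e-12, g_ese = 0, g_esre = 0,
                  g_srs = 0, amplitude = 2)
  grid <- spectrum_grid()
  f <- seq(1, 45, by = 0.5)
  ps <- analytic_spectrum(g0, f, grid)
  expect_equal(ps$power, zero_gain_spectrum_oracle(g0, f, grid),
               tolerance = 1e-10)
})

test_that("mode sum is converged at the default truncation", {
  g <- test_gains()
  f <- seq(8, 30, by = 0.25)
  bp8 <- band_sum(analytic_spectrum(g, f, spectrum_grid(m_max = 8)))
  bp16 <- band_sum(analytic_spectrum(g, f, spectrum_grid(m_max = 16)))
  expect_lt(abs(bp16 - bp8) / bp8, 1e-3)
  # Cauchy in the truncation order
  bps <- vapply(c(2, 4, 8, 16), function(m)
    band_sum(analytic_spectrum(g, f, spectrum_grid(m_max = m))), numeric(1))
  expect_true(all(abs(diff(bps)) / bps[-1] < 0.05))
  expect_lt(abs(bps[4] - bps[3]) / bps[3], abs(bps[2] - bps[1]) / bps[1] + 1e-12)
})

test_that("stable parameter draws always give positive spectra", {
  set.seed(302)
  f <- seq(1, 45, by = 1)
  for (i in 1:100) {
    g <- random_stable_gains()
    ps <- analytic_spectrum(g, f)
    expect_true(all(ps$power > 0))
    expect_true(all(is.finite(ps$power)))
  }
})

test_that("gain and spectrum serialization round-trips", {
  g <- test_gains()
  path <- withr::local_tempfile(fileext = ".txt")
  write_gains(g, path)
  expect_equal(read_gains(path), g)
  ps <- analytic_spectrum(g, seq(2, 40, by = 0.5))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_spectrum(ps, csv)
  ps2 <- read_spectrum(csv)
  expect_equal(ps2$power, ps$power, tolerance = 1e-12)
  writeLines("g_ee = 1", path)
  expect_error(read_gains(path), "FormatError")
})
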