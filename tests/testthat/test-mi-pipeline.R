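make_sine_epochs <- function(freqs_by_epoch, fs = 250, n = 625,
                             labels = NULL) {
  t <- (0:(n - 1)) / fs
  data <- array(0, c(length(freqs_by_epoch), 1, n))
  for (i in seq_along(freqs_by_epoch))
    data[i, 1, ] <- sin(2 * pi * freqs_by_epoch[i] * t)
  if (is.null(labels)) labels <- rep("a", length(freqs_by_epoch))
  epoch_set(data, fs, labels)
}

test_that("band-pass keeps the band and rejects DC and slow drift", {
  e <- make_sine_epochs(c(20, 2))
  eb <- bandpass(e)
  in_band <- eb$data[1, 1, 100:525]           # avoid filter edges
  expect_equal(max(abs(in_band)), 1, tolerance = 0.02)
  out_band <- eb$data[2, 1, 100:525]
  expect_lt(max(abs(out_band)), 10^(-20 / 20))   # >= 20 dB down
  const <- e; const$data[1, 1, ] <- 5
  cb <- bandpass(const)
  expect_lt(max(abs(cb$data[1, 1, ])), 1e-6 * 5)
  expect_error(bandpass(e, f_hi = 200), "Nyquist")
})

test_that("CSP component-count rule matches its formula", {
  expect_identical(n_csp(2), 4L)
  expect_identical(n_csp(3), 6L)
  expect_identical(n_csp(4), 6L)
  expect_error(n_csp(1))
})

test_that("CSP finds a planted variance contrast", {
  set.seed(21)
  n_ep <- 40; n_ch <- 6; n <- 500
  data <- array(rnorm(2 * n_ep * n_ch * n), c(2 * n_ep, n_ch, n))
  # class A carries 3x variance on channel 1 only
  data[1:n_ep, 1, ] <- sqrt(3) * data[1:n_ep, 1, ]
  e <- epoch_set(data, 250, rep(c("A", "B"), each = n_ep))
  m <- fit_csp(e, n_components = 4)
  src <- apply_csp(m, e)
  v <- function(lab, j) mean(apply(src$data[src$labels == lab, j, ], 1,
                                   stats::var))
  ratios <- vapply(1:4, function(j) v("A", j) / v("B", j), numeric(1))
  expect_gt(max(ratios), 2.5)
  expect_equal(dim(m$filters), c(4L, 6L))
  expect_equal(dim(m$patterns), c(6L, 4L))
})

test_that("CSP is equivariant under channel permutation", {
  set.seed(22)
  n_ep <- 20; n_ch <- 5; n <- 400
  data <- array(rnorm(2 * n_ep * n_ch * n), c(2 * n_ep, n_ch, n))
  data[1:n_ep, 2, ] <- 2 * data[1:n_ep, 2, ]
  e <- epoch_set(data, 250, rep(c("A", "B"), each = n_ep))
  perm <- c(3, 1, 5, 2, 4)
  e_perm <- epoch_set(data[, perm, , drop = FALSE], 250, e$labels)
  m <- fit_csp(e, n_components = 2)
  mp <- fit_csp(e_perm, n_components = 2)
  # projected sources are identical up to sign
  s1 <- apply_csp(m, e)$data[1, , ]
  s2 <- apply_csp(mp, e_perm)$data[1, , ]
  for (j in 1:2)
    expect_equal(min(sum((s1[j, ] - s2[j, ])^2),
                     sum((s1[j, ] + s2[j, ])^2)), 0, tolerance = 1e-12)
})

test_that("identical class covariances give chance-level eigenvalues", {
  set.seed(23)
  n_ep <- 60; n_ch <- 4; n <- 500
  data <- array(rnorm(2 * n_ep * n_ch * n), c(2 * n_ep, n_ch, n))
  e <- epoch_set(data, 250, rep(c("A", "B"), each = n_ep))
  m <- fit_csp(e, n_components = 4)
  expect_true(all(abs(m$eigenvalues - 0.5) < 0.05))
})

test_that("CSP filters and patterns are mutual pseudo-inverses", {
  set.seed(24)
  n_ep <- 20; n_ch <- 4; n <- 400
  data <- array(rnorm(2 * n_ep * n_ch * n), c(2 * n_ep, n_ch, n))
  data[1:n_ep, 1, ] <- 2 * data[1:n_ep, 1, ]
  e <- epoch_set(data, 250, rep(c("A", "B"), each = n_ep))
  m <- fit_csp(e, n_components = 4)       # square: full reconstruction
  x <- e$data[3, , ]
  expect_equal(m$patterns %*% (m$filters %*% x), x, tolerance = 1e-8)
  # linearity of the projection
  e2 <- e; e2$data <- 2 * e$data
  expect_equal(apply_csp(m, e2)$data, 2 * apply_csp(m, e)$data)
})

test_that("total power agrees between time and frequency domains", {
  expect_equal(total_power(c(2, 2, 2, 2)), 4)
  expect_equal(total_power(c(1, -1, 1, -1)), 1)
  set.seed(31)
  x <- rnorm(625)
  expect_equal(total_power(x), total_power_freq_oracle(x),
               tolerance = 1e-10)
})

test_that("Higuchi dimension is exact on a ramp and right for noise", {
  expect_equal(higuchi_fd(seq_len(1000)), 1.0, tolerance = 1e-10)
  set.seed(32)
  expect_equal(higuchi_fd(rnorm(10000)), 2.0, tolerance = 0.1)
  # a band-limited tone is much smoother than white noise on the same grid
  t <- (0:624) / 250
  tone <- higuchi_fd(sin(2 * pi * 10 * t))
  expect_gte(tone, 1.0); expect_lte(tone, 1.3)
  set.seed(33)
  expect_lt(tone, higuchi_fd(rnorm(625)))
  # affine invariance
  set.seed(34)
  x <- rnorm(2000)
  expect_equal(higuchi_fd(x), higuchi_fd(5 * x - 3), tolerance = 1e-10)
  expect_warning(h <- higuchi_fd(rep(1, 100)), "Degenerate")
  expect_equal(h, 1.0)
})

test_that("feature extraction has the documented shape and labels", {
  set.seed(41)
  data <- array(rnorm(10 * 4 * 625), c(10, 4, 625))
  data[1, , ] <- 0
  src <- epoch_set(data, 250, rep(c("L", "R"), 5))
  f <- extract_features(src, "TP")
  expect_s3_class(f, "tbl_df")
  expect_equal(nrow(f), 10)
  expect_setequal(setdiff(names(f), c("epoch", "condition", "origin")),
                  paste0("csp", 1:4, "_tp"))
  expect_equal(unlist(f[1, paste0("csp", 1:4, "_tp")]),
               setNames(rep(0, 4), paste0("csp", 1:4, "_tp")))
  expect_identical(f$condition, src$labels)
  fh <- suppressWarnings(extract_features(src, "HFD"))  # zero epoch is degenerate
  expect_true(all(vapply(fh[paste0("csp", 1:4, "_hfd")],
                         function(v) all(v > 0.5 & v < 2.5), logical(1))))
})

test_that("linear discriminant separates, flips and matches the classic fit", {
  set.seed(51)
  n <- 60
  f <- tibble::tibble(
    condition = rep(c("L", "R"), each = n),
    x1 = c(rnorm(n, 0), rnorm(n, 4)),
    x2 = c(rnorm(n, 0), rnorm(n, -3)))
  clf <- train_classifier(f)
  expect_equal(balanced_accuracy(f$condition, predict(clf, f)), 1.0)
  # swapped labels complement the predictions
  f2 <- f; f2$condition <- ifelse(f$condition == "L", "R", "L")
  clf2 <- train_classifier(f2)
  expect_true(all(predict(clf2, f) != predict(clf, f)))
  # agreement with the canonical implementation on well-conditioned data
  ml <- MASS::lda(cbind(f$x1, f$x2), grouping = f$condition)
  expect_equal(as.character(predict(ml, cbind(f$x1, f$x2))$class),
               predict(clf, f))
})

test_that("indistinguishable classes classify at chance", {
  set.seed(52)
  accs <- replicate(100, {
    f <- tibble::tibble(condition = rep(c("L", "R"), each = 30),
                        x1 = rnorm(60), x2 = rnorm(60))
    g <- tibble::tibble(condition = rep(c("L", "R"), each = 30),
                        x1 = rnorm(60), x2 = rnorm(60))
    clf <- train_classifier(f)
    balanced_accuracy(g$condition, predict(clf, g))
  })
  expect_equal(mean(accs), 0.5, tolerance = 0.05)
})

test_that("balanced accuracy averages per-condition recalls", {
  y <- rep(c("L", "R"), each = 36)
  expect_equal(balanced_accuracy(y, y), 1.0)
  expect_equal(balanced_accuracy(y, rep("L", 72)), 0.5)
  pred <- c(rep("L", 30), rep("R", 6), rep("R", 24), rep("L", 12))
  expect_equal(balanced_accuracy(y, pred), 0.75)
  expect_error(balanced_accuracy(y, y[-1]), "LengthMismatch")
})
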