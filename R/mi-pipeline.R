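#' Labeled multichannel epoch container
#'
#' Epochs-by-channels-by-samples array with sampling metadata and per-epoch
#' condition labels; the input/output currency of the classification
#' pipeline. CSP source epochs reuse the same container with sources in the
#' channel dimension.
#'
#' @param data numeric array, epochs x channels x samples; all finite.
#' @param fs sampling rate in Hz.
#' @param labels condition label per epoch (coerced to character).
#' @param subject_id subject identifier string.
#' @param channel_names optional channel names.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, labels, subject_id = "",
                      channel_names = NULL) {
  stopifnot(length(dim(data)) == 3, fs > 0)
  if (length(labels) != dim(data)[1])
    stop("labels must have one entry per epoch", call. = FALSE)
  if (any(!is.finite(data)))
    stop("epoch data must be finite", call. = FALSE)
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(dim(data)[2]))
  structure(list(data = data, fs = fs, labels = as.character(labels),
                 subject_id = subject_id,
                 channel_names = as.character(channel_names)),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  cat("  conditions:", paste(sprintf("%s (%d)", names(table(x$labels)),
                                     table(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

# subset epochs by index, keeping metadata
subset_epochs <- function(e, idx) {
  epoch_set(e$data[idx, , , drop = FALSE], e$fs, e$labels[idx],
            e$subject_id, e$channel_names)
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth band-pass applied per channel
#' per epoch; removes DC and restricts to the mu/beta band by default.
#'
#' @param e an [epoch_set()].
#' @param f_lo,f_hi band edges in Hz; `f_hi` must be below Nyquist.
#' @param order filter order (doubled by the forward-backward pass).
#' @return A filtered `epoch_set` of the same shape.
#' @export
bandpass <- function(e, f_lo = 8, f_hi = 30, order = 4) {
  stopifnot(inherits(e, "epoch_set"))
  if (f_hi >= e$fs / 2)
    stop("NyquistViolation: f_hi must be below fs/2", call. = FALSE)
  bf <- signal::butter(order, c(f_lo, f_hi) / (e$fs / 2), type = "pass")
  d <- e$data
  for (i in seq_len(dim(d)[1]))
    for (j in seq_len(dim(d)[2]))
      d[i, j, ] <- signal::filtfilt(bf, d[i, j, ] - mean(d[i, j, ]))
  e$data <- d
  e
}

# zero-phase band-pass for a single continuous signal
bandpass_vector <- function(x, fs, f_lo = 8, f_hi = 30, order = 4) {
  bf <- signal::butter(order, c(f_lo, f_hi) / (fs / 2), type = "pass")
  signal::filtfilt(bf, x - mean(x))
}

#' Number of CSP components
#'
#' Empirical rule `2 * ceiling(1 + n_conditions / 2)`: enough components to
#' capture the discriminative variance while limiting overfitting and the
#' cost of downstream augmentation.
#'
#' @param n_conditions number of classes (>= 2).
#' @return Integer component count.
#' @export
#' @examples
#' n_csp(2)  # 4
n_csp <- function(n_conditions) {
  stopifnot(n_conditions >= 2)
  as.integer(2 * ceiling(1 + n_conditions / 2))
}

#' Fit common spatial patterns
#'
#' Two-class CSP: per-epoch sample covariances are normalized by their trace
#' and averaged within class; the filters are the generalized eigenvectors of
#' the class-1 covariance against the composite, computed by whitening. The
#' components with the largest and smallest eigenvalues (extremal class
#' variance ratios) are retained, half from each end. Patterns are the
#' pseudo-inverse of the filters.
#'
#' @param e a band-passed [epoch_set()] with exactly two conditions and at
#'   least two epochs per condition.
#' @param n_components number of CSP components; default [n_csp()] of the
#'   condition count.
#' @param reg relative ridge added to the composite covariance if it is
#'   ill-conditioned.
#' @return An object of class `csp_model` with `filters` (components x
#'   channels), `patterns` (channels x components), `eigenvalues` and
#'   `class_order`.
#' @export
fit_csp <- function(e, n_components = NULL, reg = 1e-10) {
  stopifnot(inherits(e, "epoch_set"))
  classes <- sort(unique(e$labels))
  if (length(classes) != 2)
    stop("ClassMissing: exactly two conditions are required", call. = FALSE)
  if (any(table(e$labels) < 2))
    stop("ClassMissing: need at least two epochs per condition",
         call. = FALSE)
  if (is.null(n_components)) n_components <- n_csp(length(classes))
  class_cov <- function(lab) {
    idx <- which(e$labels == lab)
    covs <- lapply(idx, function(i) {
      x <- e$data[i, , , drop = TRUE]
      cc <- tcrossprod(x) / ncol(x)
      cc / sum(diag(cc))
    })
    Reduce(`+`, covs) / length(covs)
  }
  c1 <- class_cov(classes[1])
  c2 <- class_cov(classes[2])
  comp <- c1 + c2
  ev <- eigen(comp, symmetric = TRUE)
  if (min(ev$values) < reg * sum(ev$values)) {
    comp <- comp + reg * sum(diag(comp)) * diag(nrow(comp))
    ev <- eigen(comp, symmetric = TRUE)
    if (min(ev$values) <= 0)
      stop("SingularCovariance: composite covariance not invertible",
           call. = FALSE)
  }
  whiten <- diag(1 / sqrt(ev$values)) %*% t(ev$vectors)
  sw <- whiten %*% c1 %*% t(whiten)
  es <- eigen((sw + t(sw)) / 2, symmetric = TRUE)
  w_all <- t(es$vectors) %*% whiten        # rows ordered by eigenvalue desc
  half <- n_components %/% 2
  pick <- c(seq_len(half), nrow(w_all) - rev(seq_len(n_components - half)) + 1)
  filters <- w_all[pick, , drop = FALSE]
  structure(list(filters = filters,
                 patterns = MASS::ginv(filters),
                 eigenvalues = es$values[pick],
                 n_csp = as.integer(n_components),
                 class_order = classes,
                 channel_names = e$channel_names),
            class = "csp_model")
}

#' Project epochs onto CSP sources
#'
#' @param m a [fit_csp()] model.
#' @param e an [epoch_set()] with matching channel count.
#' @return An `epoch_set` of source epochs (epochs x components x samples).
#' @export
apply_csp <- function(m, e) {
  stopifnot(inherits(m, "csp_model"), inherits(e, "epoch_set"))
  if (ncol(m$filters) != dim(e$data)[2])
    stop("ShapeMismatch: channel count differs from the fitted model",
         call. = FALSE)
  d <- dim(e$data)
  out <- array(0, c(d[1], nrow(m$filters), d[3]))
  for (i in seq_len(d[1]))
    out[i, , ] <- m$filters %*% e$data[i, , , drop = TRUE]
  epoch_set(out, e$fs, e$labels, e$subject_id,
            paste0("csp", seq_len(nrow(m$filters))))
}

#' Total power of a signal
#'
#' Mean squared amplitude, `TP = (1/N) sum X(n)^2`. Under the unitary
#' discrete Fourier transform convention the same value equals the summed
#' squared transform magnitudes divided by the transform length, so the
#' feature can be read off either domain (Parseval).
#'
#' @param x nonempty numeric vector.
#' @return Nonnegative scalar.
#' @export
total_power <- function(x) {
  stopifnot(length(x) > 0)
  mean(x^2)
}

#' Higuchi fractal dimension
#'
#' Curve-length complexity estimate. For each scale `n = 1..n_max` the series
#' is decimated into `n` interleaved sub-series `X(m), X(m+n), X(m+2n), ...`;
#' each sub-series length
#' `L_m(n) = (N-1)/n^2 * (1/p) * sum |X(m+i n) - X(m+(i-1) n)|` (with
#' `p = floor((N-m)/n)`) is averaged over `m`, and an ordinary least-squares
#' line is fitted to `log2 L(n)` against `log2 n`. The negated slope is the
#' dimension estimate: exactly 1 for a straight ramp, about 2 for white
#' noise. Invariant to shifting or rescaling the signal.
#'
#' @param x numeric vector with at least `2 * n_max` samples.
#' @param n_max largest scale (default 10, the common toolbox convention).
#' @return Dimension estimate; a constant signal is degenerate and returns
#'   1.0 with a warning.
#' @export
#' @examples
#' higuchi_fd(seq_len(1000))   # ramp: exactly 1
higuchi_fd <- function(x, n_max = 10) {
  N <- length(x)
  stopifnot(n_max >= 2, N >= 2 * n_max)
  lens <- vapply(seq_len(n_max), function(n) {
    lm_vals <- vapply(seq_len(n), function(m) {
      idx <- seq(m, N, by = n)
      p <- length(idx) - 1
      if (p < 1) return(NA_real_)
      (N - 1) / n^2 * mean(abs(diff(x[idx])))
    }, numeric(1))
    mean(lm_vals, na.rm = TRUE)
  }, numeric(1))
  if (any(lens == 0)) {
    warning("DegenerateInput: constant signal; returning HFD = 1")
    return(1.0)
  }
  -unname(stats::coef(stats::lm(log2(lens) ~ log2(seq_len(n_max))))[2])
}

#' Extract per-component features from source epochs
#'
#' One feature value per CSP component per epoch: total power (`"TP"`) or
#' Higuchi fractal dimension (`"HFD"`). Columns are ordered by component
#' index and labels carried through.
#'
#' @param sources an [epoch_set()] of CSP source epochs.
#' @param feature `"TP"` or `"HFD"`.
#' @param hfd_n_max largest Higuchi scale.
#' @return A tibble with columns `epoch`, `condition`, `origin` ("real"),
#'   and one numeric column per component (e.g. `csp1_tp`).
#' @export
extract_features <- function(sources, feature = c("TP", "HFD"),
                             hfd_n_max = 10) {
  feature <- match.arg(feature)
  stopifnot(inherits(sources, "epoch_set"))
  d <- dim(sources$data)
  fun <- if (feature == "TP") total_power else
    function(x) higuchi_fd(x, hfd_n_max)
  vals <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      vals[i, j] <- fun(sources$data[i, j, ])
  colnames(vals) <- paste0("csp", seq_len(d[2]), "_", tolower(feature))
  out <- tibble::as_tibble(as.data.frame(vals))
  out <- dplyr::mutate(out, epoch = seq_len(d[1]),
                       condition = sources$labels, origin = "real",
                       .before = 1)
  attr(out, "feature") <- feature
  out
}

feature_cols <- function(f) {
  names(f)[vapply(f, is.numeric, logical(1)) & names(f) != "epoch"]
}

#' Train a linear discriminant classifier
#'
#' Two-class linear discriminant with pooled within-class covariance and a
#' small ridge (1e-6 times the trace) for conditioning; the decision rule is
#' linear in the features with empirical class priors. Deterministic.
#'
#' @param f a feature tibble with a `condition` column and numeric feature
#'   columns (as produced by [extract_features()]).
#' @return An object of class `mi_lda`.
#' @export
train_classifier <- function(f) {
  classes <- sort(unique(f$condition))
  if (length(classes) != 2)
    stop("two conditions are required", call. = FALSE)
  cols <- feature_cols(f)
  x <- as.matrix(f[, cols, drop = FALSE])
  y <- f$condition
  if (any(table(y) < 2))
    stop("need at least two samples per condition", call. = FALSE)
  mu <- lapply(classes, function(cl) colMeans(x[y == cl, , drop = FALSE]))
  ns <- vapply(classes, function(cl) sum(y == cl), numeric(1))
  pool <- Reduce(`+`, lapply(seq_along(classes), function(i)
    (ns[i] - 1) * stats::cov(x[y == classes[i], , drop = FALSE]))) /
    (sum(ns) - 2)
  tr <- sum(diag(pool))
  ridge <- if (tr > 0) 1e-6 * tr else 1e-12
  w <- NULL
  for (r in ridge * 10^(0:6)) {
    w <- try(solve(pool + r * diag(ncol(x)), mu[[2]] - mu[[1]]),
             silent = TRUE)
    if (!inherits(w, "try-error")) break
  }
  if (inherits(w, "try-error"))
    stop("SingularPooledCovariance: cannot invert pooled covariance",
         call. = FALSE)
  b <- -sum(w * (mu[[1]] + mu[[2]])) / 2 + log(ns[2] / ns[1])
  structure(list(weights = w, bias = b, classes = classes,
                 feature_names = cols), class = "mi_lda")
}

#' Predict condition labels
#'
#' @param object a [train_classifier()] model.
#' @param f feature tibble with the same feature columns.
#' @param ... unused.
#' @return Character vector of predicted labels.
#' @export
predict.mi_lda <- function(object, f, ...) {
  x <- as.matrix(f[, object$feature_names, drop = FALSE])
  score <- drop(x %*% object$weights) + object$bias
  ifelse(score > 0, object$classes[2], object$classes[1])
}

#' Balanced classification accuracy
#'
#' Mean over conditions of the per-condition true-positive rate (recall), so
#' class imbalance does not inflate the score.
#'
#' @param y_true true labels covering every condition.
#' @param y_pred predicted labels, same length.
#' @return Scalar in `[0, 1]`.
#' @export
#' @examples
#' balanced_accuracy(rep(c("L", "R"), each = 36),
#'                   c(rep("L", 30), rep("R", 6), rep("R", 24), rep("L", 12)))
balanced_accuracy <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("LengthMismatch", call. = FALSE)
  conds <- unique(y_true)
  if (any(table(y_true) == 0)) stop("EmptyCondition", call. = FALSE)
  mean(vapply(conds, function(cl)
    mean(y_pred[y_true == cl] == cl), numeric(1)))
}
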