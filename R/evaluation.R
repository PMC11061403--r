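#' Pipeline configuration
#'
#' Bundles the classification-pipeline choices: feature, band, CSP component
#' count and Higuchi scale.
#'
#' @param feature `"TP"` or `"HFD"`.
#' @param band band-pass edges in Hz.
#' @param hfd_n_max largest Higuchi scale.
#' @param n_components CSP components; `NULL` for the [n_csp()] rule.
#' @return An object of class `mi_config`.
#' @export
mi_config <- function(feature = c("TP", "HFD"), band = c(8, 30),
                      hfd_n_max = 10, n_components = NULL) {
  structure(list(feature = match.arg(feature), band = band,
                 hfd_n_max = hfd_n_max, n_components = n_components),
            class = "mi_config")
}

#' Augmentation strategy descriptors
#'
#' `strategy_nft()` describes model-based augmentation of CSP source epochs
#' (optionally with parameter jittering); `strategy_noise()` the
#' feature-space Gaussian baseline.
#'
#' @param factor augmentation factor.
#' @param jitter_targets optional character subset of
#'   `c("alpha", "gamma_e", "t0")`; `NULL` disables jitter.
#' @param fit_cfg [fit_config()] for the per-source fits.
#' @param sim_cfg [sim_config()] template.
#' @param scale covariance inflation of the noise baseline.
#' @param name label used in reports.
#' @return An object of class `da_strategy`.
#' @export
strategy_nft <- function(factor, jitter_targets = NULL,
                         fit_cfg = fit_config(n_chains = 2, n_steps = 5000,
                                              burn_in_steps = 1500,
                                              grid = spectrum_grid(m_max = 0)),
                         sim_cfg = sim_config(method = "spectral_synthesis"),
                         name = NULL) {
  if (is.null(name))
    name <- paste0("nft_x", factor,
                   if (!is.null(jitter_targets))
                     paste0("_jitter_", paste(jitter_targets, collapse = "+"))
                   else "")
  structure(list(type = "nft", factor = factor,
                 jitter = if (is.null(jitter_targets)) NULL else
                   jitter_spec(targets = jitter_targets),
                 fit_cfg = fit_cfg, sim_cfg = sim_cfg, name = name),
            class = "da_strategy")
}

#' @rdname strategy_nft
#' @export
strategy_noise <- function(factor, scale = 1.5, name = NULL) {
  if (is.null(name)) name <- paste0("noise_x", factor)
  structure(list(type = "noise", factor = factor, scale = scale,
                 name = name), class = "da_strategy")
}

# one cross-validation rotation: fit everything on train, score on val
run_fold <- function(e_band, train_idx, val_idx, cfg, strategy, seed) {
  train <- subset_epochs(e_band, train_idx)
  val <- subset_epochs(e_band, val_idx)
  csp <- fit_csp(train, cfg$n_components)
  src_train <- apply_csp(csp, train)
  src_val <- apply_csp(csp, val)
  feats_val <- extract_features(src_val, cfg$feature, cfg$hfd_n_max)
  aug_used <- NULL
  if (!is.null(strategy) && strategy$type == "nft" && strategy$factor > 0) {
    aug_used <- nft_augment(train, csp, strategy$factor, strategy$jitter,
                            strategy$fit_cfg, strategy$sim_cfg, seed = seed)
    feats_train <- assemble_training_features(src_train, aug_used,
                                              cfg$feature, cfg$hfd_n_max)
  } else {
    feats_train <- extract_features(src_train, cfg$feature, cfg$hfd_n_max)
    if (!is.null(strategy) && strategy$type == "noise" &&
        strategy$factor > 0)
      feats_train <- noise_augment(feats_train, strategy$factor,
                                   strategy$scale, seed = seed)
  }
  clf <- train_classifier(feats_train)
  acc <- balanced_accuracy(val$labels, predict(clf, feats_val))
  list(accuracy = acc, n_train_rows = nrow(feats_train),
       train_idx = train_idx, val_idx = val_idx)
}

# stratified fold assignment: per condition, shuffle then deal round-robin
stratified_folds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Inverse k-fold cross-validation
#'
#' The data-starved evaluation protocol: epochs are partitioned into `k`
#' stratified folds and each fold serves once as the *training* set (CSP fit,
#' optional augmentation and classifier fit happen on that fold alone) while
#' the union of the remaining folds is used for validation. With `k = 3`
#' this trains on 33% and validates on 67%. Returns the mean balanced
#' accuracy over the `k` rotations.
#'
#' Validation epochs are never touched by CSP fitting, spectral fitting,
#' augmentation or the classifier; the returned `audit` attribute records
#' the index partition of every rotation.
#'
#' @param e an [epoch_set()] (raw; band-passing is applied internally).
#' @param cfg an [mi_config()].
#' @param strategy optional [strategy_nft()]/[strategy_noise()].
#' @param k number of folds.
#' @param seed integer seed (partition and augmentation).
#' @return Mean balanced accuracy with attributes `per_fold` and `audit`.
#' @export
inverse_cv <- function(e, cfg = mi_config(), strategy = NULL, k = 3,
                       seed = 1) {
  cv_protocol(e, cfg, strategy, k, seed, inverse = TRUE)
}

#' Regular k-fold cross-validation
#'
#' Standard stratified k-fold: train on `k - 1` folds, validate on the held
#' out fold. Used for the full-set reference accuracy (`k = 7`: 86%
#' training, 14% validation).
#'
#' @inheritParams inverse_cv
#' @return Mean balanced accuracy with attributes `per_fold` and `audit`.
#' @export
full_cv <- function(e, cfg = mi_config(), k = 7, seed = 1) {
  cv_protocol(e, cfg, NULL, k, seed, inverse = FALSE)
}

cv_protocol <- function(e, cfg, strategy, k, seed, inverse) {
  stopifnot(inherits(e, "epoch_set"), k >= 2)
  if (any(table(e$labels) < k))
    stop("TooFewEpochs: fewer epochs than folds in some condition",
         call. = FALSE)
  e_band <- bandpass(e, cfg$band[1], cfg$band[2])
  folds <- stratified_folds(e_band$labels, k, seed)
  res <- lapply(seq_len(k), function(f) {
    in_fold <- which(folds == f)
    out_fold <- which(folds != f)
    if (inverse)
      run_fold(e_band, in_fold, out_fold, cfg, strategy,
               seed = sub_seed(seed, f))
    else
      run_fold(e_band, out_fold, in_fold, cfg, strategy,
               seed = sub_seed(seed, f))
  })
  acc <- vapply(res, `[[`, numeric(1), "accuracy")
  out <- mean(acc)
  attr(out, "per_fold") <- acc
  attr(out, "audit") <- lapply(res, function(r)
    r[c("train_idx", "val_idx", "n_train_rows")])
  out
}

#' Subject eligibility filter
#'
#' Drops subjects for whom augmentation assessment is not meaningful: full
#' set accuracy at or below chance (0.5), small set accuracy at or below
#' chance, or a small-set accuracy that does not drop below the full-set one
#' (no headroom for augmentation to recover). Order is preserved.
#'
#' @param results tibble with columns `subject_id`, `ac_full`, `ac_small`.
#' @return The retained subset of `results`.
#' @export
filter_subjects <- function(results) {
  dplyr::filter(results, .data$ac_full > 0.5, .data$ac_small > 0.5,
                .data$ac_small <= .data$ac_full)
}

#' Paired improvement test
#'
#' Two-sided paired Student's t-test on per-subject accuracy differences.
#' Degenerate all-zero differences give p = 1.
#'
#' @param baseline,treated equal-length accuracy vectors (>= 3 subjects).
#' @return List with `mean_delta` and `p_value`.
#' @export
paired_improvement_test <- function(baseline, treated) {
  if (length(baseline) != length(treated))
    stop("LengthMismatch", call. = FALSE)
  stopifnot(length(baseline) >= 3)
  d <- treated - baseline
  if (all(d == 0)) return(list(mean_delta = 0, p_value = 1))
  if (stats::sd(d) == 0)         # constant nonzero shift: limiting t is infinite
    return(list(mean_delta = mean(d), p_value = 0))
  tt <- stats::t.test(treated, baseline, paired = TRUE)
  list(mean_delta = unname(tt$estimate), p_value = tt$p.value)
}

#' Grid search for a proficiency threshold
#'
#' For each candidate threshold, keeps subjects whose small-set baseline
#' accuracy reaches the threshold and counts the strategies whose paired
#' test against the baseline is significant (p < 0.05) with a positive mean
#' improvement. Returns the threshold maximizing that count (ties go to the
#' lowest threshold). Thresholds retaining fewer than three subjects are
#' skipped.
#'
#' @param results tibble with `ac_small` and one `ac_<strategy>` column per
#'   strategy (as in an `mi_benchmark` object's `subject_results`).
#' @param strategies character vector of strategy column names.
#' @param thresholds numeric candidate thresholds (nonempty).
#' @return The selected threshold; attribute `counts` holds the per-threshold
#'   tally.
#' @export
proficiency_grid_search <- function(results, strategies, thresholds) {
  if (length(thresholds) == 0) stop("no thresholds supplied", call. = FALSE)
  counts <- vapply(thresholds, function(th) {
    sub <- results[results$ac_small >= th, , drop = FALSE]
    if (nrow(sub) < 3) return(NA_integer_)
    sum(vapply(strategies, function(s) {
      tt <- paired_improvement_test(sub$ac_small, sub[[s]])
      tt$p_value < 0.05 && tt$mean_delta > 0
    }, logical(1)))
  }, integer(1))
  if (all(is.na(counts)))
    stop("NoSubjectsAboveThreshold at every candidate", call. = FALSE)
  best <- thresholds[which.max(counts)]   # which.max: first max, lowest thr
  attr(best, "counts") <- stats::setNames(counts, thresholds)
  best
}

#' Benchmark augmentation strategies on a cohort
#'
#' For every subject, computes the full-set reference accuracy (regular
#' 7-fold CV), the small-set baseline (inverse 3-fold CV) and the augmented
#' accuracy per strategy (inverse 3-fold CV with training-fold augmentation);
#' filters subjects with [filter_subjects()]; and reports per-strategy mean
#' augmented accuracy with paired-test improvements against the small and
#' full baselines.
#'
#' @param subjects list of [epoch_set()] objects (>= 3).
#' @param strategies list of [strategy_nft()]/[strategy_noise()] objects.
#' @param cfg an [mi_config()].
#' @param k_small,k_full fold counts for the two protocols.
#' @param seed integer seed.
#' @return An object of class `mi_benchmark` with `report` (one row per
#'   strategy), `subject_results`, `retained` subject ids and the inputs'
#'   descriptors. `tidy()` returns the report, `glance()` the cohort
#'   summary.
#' @export
run_benchmark <- function(subjects, strategies = list(),
                          cfg = mi_config(), k_small = 3, k_full = 7,
                          seed = 1) {
  stopifnot(length(subjects) >= 3)
  snames <- vapply(strategies, `[[`, character(1), "name")
  subject_results <- purrr::imap_dfr(subjects, function(e, i) {
    sid <- if (nzchar(e$subject_id)) e$subject_id else paste0("S", i)
    row <- tibble::tibble(
      subject_id = sid,
      ac_full = as.numeric(full_cv(e, cfg, k_full,
                                   seed = sub_seed(seed, i))),
      ac_small = as.numeric(inverse_cv(e, cfg, NULL, k_small,
                                       seed = sub_seed(seed, i))))
    for (s in seq_along(strategies)) {
      row[[paste0("ac_", snames[s])]] <- as.numeric(
        inverse_cv(e, cfg, strategies[[s]], k_small,
                   seed = sub_seed(seed, i)))
    }
    row
  })
  retained <- filter_subjects(subject_results)
  report <- purrr::map_dfr(seq_along(strategies), function(s) {
    col <- paste0("ac_", snames[s])
    vs_small <- paired_improvement_test(retained$ac_small, retained[[col]])
    vs_full <- paired_improvement_test(retained$ac_full, retained[[col]])
    tibble::tibble(strategy = snames[s],
                   ac_augmented = mean(retained[[col]]),
                   delta_vs_small = vs_small$mean_delta,
                   p_vs_small = vs_small$p_value,
                   delta_vs_full = vs_full$mean_delta,
                   p_vs_full = vs_full$p_value)
  })
  structure(list(report = report, subject_results = subject_results,
                 retained = retained$subject_id,
                 ac_full_mean = mean(retained$ac_full),
                 ac_small_mean = mean(retained$ac_small),
                 feature = cfg$feature, seed = seed),
            class = "mi_benchmark")
}

#' @export
print.mi_benchmark <- function(x, ...) {
  cat(sprintf("<mi_benchmark> %s feature; %d/%d subjects retained\n",
              x$feature, length(x$retained), nrow(x$subject_results)))
  cat(sprintf("  mean full-set Ac %.3f, small-set Ac %.3f\n",
              x$ac_full_mean, x$ac_small_mean))
  print(x$report)
  invisible(x)
}

#' @method tidy mi_benchmark
#' @export
tidy.mi_benchmark <- function(x, ...) x$report

#' @method glance mi_benchmark
#' @export
glance.mi_benchmark <- function(x, ...) {
  tibble::tibble(n_subjects = nrow(x$subject_results),
                 n_retained = length(x$retained),
                 ac_full = x$ac_full_mean, ac_small = x$ac_small_mean,
                 feature = x$feature)
}
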