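#' Area under the ROC curve
#'
#' Mann-Whitney concordance with the tie correction (ties count 1/2),
#' computed from midranks. Invariant under strictly monotone transforms of
#' the scores.
#'
#' @param scores numeric scores (higher = more positive).
#' @param y binary outcome (0/1).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    rlang::abort("both classes must be present.", class = "lnrad_bad_parameter")
  }
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return tibble with `threshold`, `sensitivity`, `specificity` over all
#'   distinct score thresholds.
#' @export
roc_points <- function(scores, y) {
  y <- as.integer(y)
  th <- c(-Inf, sort(unique(scores)), Inf)
  purrr::map_dfr(th, function(t) {
    pred <- scores >= t
    tibble::tibble(threshold = t,
                   sensitivity = sum(pred & y == 1) / sum(y == 1),
                   specificity = sum(!pred & y == 0) / sum(y == 0))
  })
}

#' Bootstrap percentile confidence interval for the AUC
#'
#' `B` class-stratified resamples (positives and negatives resampled
#' separately, so no replicate loses a class), percentile interval,
#' seed-deterministic.
#'
#' @inheritParams roc_auc
#' @param B bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param level confidence level (default 0.95).
#' @return An object of class `lnm_roc`: list with `auc`, `ci`, `level`,
#'   `B`, `seed`, `points` (the ROC curve) and the bootstrap `aucs`.
#' @export
bootstrap_auc_ci <- function(scores, y, B = 1000, seed = 1, level = 0.95) {
  y <- as.integer(y)
  auc <- roc_auc(scores, y)
  ip <- which(y == 1); in_ <- which(y == 0)
  aucs <- with_preserved_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- c(sample(ip, replace = TRUE), sample(in_, replace = TRUE))
      roc_auc(scores[idx], y[idx])
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(aucs, c(alpha, 1 - alpha), type = 7))
  ci[1] <- min(ci[1], auc); ci[2] <- max(ci[2], auc)
  structure(list(auc = auc, ci = ci, level = level, B = B, seed = seed,
                 points = roc_points(scores, y), aucs = aucs),
            class = "lnm_roc")
}

#' @export
print.lnm_roc <- function(x, ...) {
  cat(sprintf("AUC %.3f (%.0f%% CI %.3f-%.3f, %d bootstrap replicates)\n",
              x$auc, 100 * x$level, x$ci[1], x$ci[2], x$B))
  invisible(x)
}

#' Paired comparison of two AUCs
#'
#' Tests the AUC difference of two models scored on the same observations
#' via the paired U-statistic approach: per-observation concordance
#' placements of both score vectors, normal test on the difference using
#' the estimated placement covariance. Identical score vectors give p = 1;
#' the test is symmetric in A and B.
#'
#' @param scores_a,scores_b score vectors of the two models.
#' @param y binary outcome.
#' @return list with `auc_a`, `auc_b`, `delta`, `z`, `p_value`.
#' @export
compare_auc_paired <- function(scores_a, scores_b, y) {
  y <- as.integer(y)
  ip <- which(y == 1); in_ <- which(y == 0)
  if (length(ip) == 0 || length(in_) == 0) {
    rlang::abort("both classes must be present.", class = "lnrad_bad_parameter")
  }
  placements <- function(s) {
    cmp <- outer(s[ip], s[in_], function(a, b) (a > b) + 0.5 * (a == b))
    list(v10 = rowMeans(cmp), v01 = colMeans(cmp), auc = mean(cmp))
  }
  pa <- placements(scores_a)
  pb <- placements(scores_b)
  delta <- pa$auc - pb$auc
  d10 <- pa$v10 - pb$v10
  d01 <- pa$v01 - pb$v01
  v <- stats::var(d10) / length(ip) + stats::var(d01) / length(in_)
  if (!is.finite(v) || v <= 0) {
    return(list(auc_a = pa$auc, auc_b = pb$auc, delta = delta, z = 0,
                p_value = 1))
  }
  z <- delta / sqrt(v)
  list(auc_a = pa$auc, auc_b = pb$auc, delta = delta, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' Confusion-matrix classification metrics
#'
#' All metrics from the integer 2x2 table. MCC with a zero denominator is
#' defined as 0 (flagged).
#'
#' @param pred binary predictions.
#' @param y binary truth.
#' @return An object of class `lnm_confusion` (a one-row tibble): TP, FP,
#'   FN, TN, sensitivity, specificity, PPV, NPV, MCC, balanced accuracy.
#' @export
confusion_metrics <- function(pred, y) {
  pred <- as.integer(pred); y <- as.integer(y)
  confusion_from_counts(tp = sum(pred == 1 & y == 1),
                        fp = sum(pred == 1 & y == 0),
                        fn = sum(pred == 0 & y == 1),
                        tn = sum(pred == 0 & y == 0))
}

#' @rdname confusion_metrics
#' @param tp,fp,fn,tn integer cell counts.
#' @export
confusion_from_counts <- function(tp, fp, fn, tn) {
  rate <- function(a, b) if (a + b > 0) a / (a + b) else NA_real_
  sens <- rate(tp, fn)
  spec <- rate(tn, fp)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den > 0) (tp * tn - fp * fn) / sqrt(den) else 0
  out <- tibble::tibble(
    TP = as.integer(tp), FP = as.integer(fp),
    FN = as.integer(fn), TN = as.integer(tn),
    sensitivity = sens, specificity = spec,
    ppv = rate(tp, fp), npv = rate(tn, fn),
    mcc = mcc,
    balanced_accuracy = (sens + spec) / 2,
    mcc_degenerate = den == 0
  )
  class(out) <- c("lnm_confusion", class(out))
  out
}

#' Reconstruct an integer confusion matrix from printed rates
#'
#' Inverts reported sensitivity/specificity and class counts into the
#' integer 2x2 table: `TP = round(sens * n_pos)`, `TN = round(spec *
#' n_neg)`, complements for FN/FP. Enables internal-consistency checks of
#' published classification tables.
#'
#' @param sensitivity,specificity reported rates in `[0, 1]`.
#' @param n_pos,n_neg class sizes.
#' @return An `lnm_confusion` tibble (as [confusion_metrics()]).
#' @export
reconstruct_confusion <- function(sensitivity, specificity, n_pos, n_neg) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1, n_pos >= 1, n_neg >= 1)
  tp <- round(sensitivity * n_pos)
  tn <- round(specificity * n_neg)
  confusion_from_counts(tp = tp, fp = n_neg - tn, fn = n_pos - tp, tn = tn)
}

#' Calibration curve
#'
#' Equal-width probability bins on `[0, 1]`; empty bins are omitted.
#'
#' @param probabilities predicted probabilities.
#' @param y binary outcome.
#' @param n_bins number of bins (default 10).
#' @return tibble with `bin`, `mean_predicted`, `observed_fraction`, `n`.
#' @export
calibration_curve <- function(probabilities, y, n_bins = 10) {
  stopifnot(all(probabilities >= 0 & probabilities <= 1))
  bin <- pmin(pmax(ceiling(probabilities * n_bins), 1L), n_bins)
  out <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(bin = bin, p = probabilities, y = as.integer(y)),
                    .data$bin),
    mean_predicted = mean(.data$p),
    observed_fraction = mean(.data$y),
    n = dplyr::n(), .groups = "drop")
  class(out) <- c("lnm_calibration", class(out))
  out
}

#' Decision curve analysis (lymph-node level)
#'
#' Net benefit of treating nodes the model calls positive at each threshold
#' probability: `NB(pt) = TP/n - FP/n * pt/(1-pt)` (prediction positive iff
#' probability >= pt), with the treat-all and treat-none reference
#' strategies. One decision per lymph node.
#'
#' @param probabilities predicted probabilities.
#' @param y binary outcome.
#' @param thresholds threshold probability grid in `[0, 1)`.
#' @return An object of class `lnm_decision_curve`: tibble with
#'   `threshold`, `nb_model`, `nb_all`, `nb_none`.
#' @export
decision_curve <- function(probabilities, y,
                           thresholds = seq(0.01, 0.90, by = 0.01)) {
  stopifnot(all(probabilities >= 0 & probabilities <= 1))
  if (any(thresholds < 0 | thresholds >= 1)) {
    rlang::abort("thresholds must lie in [0, 1).", class = "lnrad_bad_parameter")
  }
  y <- as.integer(y)
  n <- length(y)
  pi_hat <- mean(y)
  out <- purrr::map_dfr(thresholds, function(pt) {
    pred <- probabilities >= pt
    tp <- sum(pred & y == 1) / n
    fp <- sum(pred & y == 0) / n
    w <- pt / (1 - pt)
    tibble::tibble(threshold = pt,
                   nb_model = tp - fp * w,
                   nb_all = pi_hat - (1 - pi_hat) * w,
                   nb_none = 0)
  })
  class(out) <- c("lnm_decision_curve", class(out))
  out
}

#' Univariate Wilcoxon screening of features
#'
#' Wilcoxon rank-sum test of each feature between outcome groups, with
#' Bonferroni adjustment over the screened features. Constant features get
#' p = 1 and a degenerate flag.
#'
#' @param features feature table (data frame).
#' @param y binary outcome.
#' @param feature_names columns to screen (default: panel-named columns).
#' @param alpha significance level applied to adjusted p-values.
#' @return tibble with `feature`, `p_value`, `p_adjusted`, `significant`,
#'   `degenerate`.
#' @export
univariate_screen <- function(features, y, feature_names = NULL, alpha = 0.05) {
  if (is.null(feature_names)) {
    feature_names <- names(features)[feature_class(names(features)) != "other"]
  }
  y <- as.integer(y)
  if (length(unique(y)) < 2) {
    rlang::abort("both classes must be present.", class = "lnrad_bad_parameter")
  }
  ps <- vapply(feature_names, function(f) {
    v <- features[[f]]
    if (stats::sd(v) == 0) return(NA_real_)
    stats::wilcox.test(v[y == 1], v[y == 0], exact = NULL)$p.value
  }, numeric(1))
  ps <- unname(ps)
  degenerate <- is.na(ps)
  ps[degenerate] <- 1
  padj <- pmin(1, ps * length(feature_names))
  tibble::tibble(feature = feature_names, p_value = ps, p_adjusted = padj,
                 significant = padj < alpha & !degenerate,
                 degenerate = degenerate)
}

#' Spearman correlation of features with lesion volume
#'
#' Midrank Spearman correlation per feature, flagging the conventionally
#' "volume-confounded" features at `|rho| >= threshold`.
#'
#' @param features feature table.
#' @param volume numeric lesion volume per row.
#' @param feature_names columns to assess (default: panel-named columns).
#' @param threshold flag threshold on `|rho|` (default 0.6).
#' @return tibble with `feature`, `class`, `rho`, `volume_correlated`.
#' @export
spearman_to_volume <- function(features, volume, feature_names = NULL,
                               threshold = 0.6) {
  if (is.null(feature_names)) {
    feature_names <- names(features)[feature_class(names(features)) != "other"]
  }
  if (length(volume) < 3) {
    rlang::abort("need >= 3 nodes.", class = "lnrad_bad_parameter")
  }
  rho <- vapply(feature_names, function(f) {
    v <- features[[f]]
    if (stats::sd(v) == 0 || stats::sd(volume) == 0) return(NA_real_)
    stats::cor(v, volume, method = "spearman")
  }, numeric(1))
  tibble::tibble(feature = feature_names,
                 class = feature_class(feature_names),
                 rho = unname(rho),
                 volume_correlated = !is.na(rho) & abs(rho) >= threshold)
}
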