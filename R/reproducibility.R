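#' Dice similarity coefficient of two masks
#'
#' `2|A n B| / (|A| + |B|)`. Two empty masks are defined to overlap
#' perfectly (Dice 1, with a `"degenerate"` attribute flag).
#'
#' @param a,b [ct_mask()] objects on the same grid.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  check_same_grid(a, b, "masks")
  na <- sum(a$voxels); nb <- sum(b$voxels)
  if (na + nb == 0) {
    return(structure(1, degenerate = TRUE))
  }
  2 * sum(a$voxels & b$voxels) / (na + nb)
}

#' Intraclass correlation coefficient ICC(3,1)
#'
#' Two-way mixed-effects, single-measure, consistency ICC (Shrout-Fleiss
#' 3,1): `(MS_rows - MS_error) / (MS_rows + (k-1) MS_error)` with mean
#' squares from the two-way ANOVA decomposition. Consistency ICC ignores
#' fixed rater offsets and is invariant to common affine rescaling.
#'
#' @param ratings numeric matrix, subjects x raters (no missing cells).
#' @return ICC value in `(-Inf, 1]`; `NA` (flagged degenerate) when the
#'   ANOVA decomposition has no variance at all.
#' @export
icc31 <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) {
    rlang::abort("ICC needs >= 2 subjects and >= 2 raters.",
                 class = "lnrad_bad_parameter")
  }
  if (any(!is.finite(ratings))) {
    rlang::abort("ICC ratings must be complete and finite.",
                 class = "lnrad_bad_parameter")
  }
  grand <- mean(ratings)
  rowm <- rowMeans(ratings)
  colm <- colMeans(ratings)
  ssr <- k * sum((rowm - grand)^2)
  ssc <- n * sum((colm - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr + (k - 1) * mse <= 0) {
    return(structure(NA_real_, degenerate = TRUE))
  }
  (msr - mse) / (msr + (k - 1) * mse)
}

#' ICC-based feature robustness filtering
#'
#' Computes ICC(3,1) per feature between two raters' feature tables and
#' flags features below the threshold for exclusion, the standard guard
#' against segmentation-sensitive features. Constant (zero-variance)
#' features are excluded with a degenerate flag.
#'
#' @param rater1,rater2 feature tables (data frames) with identical feature
#'   columns, rows matched one-to-one by node.
#' @param features feature columns to assess (default: the intersection of
#'   numeric shared columns that belong to the panel naming scheme).
#' @param threshold retention threshold (default 0.8): retained iff
#'   `ICC >= threshold`.
#' @return A robustness report tibble: `feature`, `class`, `icc`,
#'   `retained`, `degenerate`.
#' @export
feature_robustness <- function(rater1, rater2, features = NULL,
                               threshold = 0.8) {
  if (is.null(features)) {
    shared <- intersect(names(rater1), names(rater2))
    features <- shared[feature_class(shared) != "other"]
  }
  if (nrow(rater1) != nrow(rater2)) {
    rlang::abort("rater tables must have matched rows.",
                 class = "lnrad_bad_parameter")
  }
  if (nrow(rater1) < 2) {
    rlang::abort("ICC needs >= 2 paired nodes.", class = "lnrad_bad_parameter")
  }
  res <- purrr::map(features, function(f) {
    m <- cbind(rater1[[f]], rater2[[f]])
    icc_val <- icc31(m)
    tibble::tibble(feature = f,
                   icc = as.numeric(icc_val),
                   degenerate = isTRUE(attr(icc_val, "degenerate")))
  })
  out <- dplyr::bind_rows(res)
  out$class <- feature_class(out$feature)
  out$retained <- !is.na(out$icc) & out$icc >= threshold
  dplyr::select(out, "feature", "class", "icc", "retained", "degenerate")
}

#' Per-class exclusion fractions of a robustness report
#'
#' @param report a tibble from [feature_robustness()].
#' @return tibble with `class`, `n`, `n_excluded`, `excluded_fraction`.
#' @export
exclusion_fractions <- function(report) {
  dplyr::summarise(dplyr::group_by(report, .data$class),
                   n = dplyr::n(),
                   n_excluded = sum(!.data$retained),
                   excluded_fraction = mean(!.data$retained),
                   .groups = "drop")
}
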