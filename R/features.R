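#' The canonical 156-feature panel
#'
#' The fixed, versioned list of feature names the extractor emits: 18
#' first-order + 10 shape + 74 texture (23 GLCM, 16 GLRLM, 16 GLSZM,
#' 14 GLDM, 5 NGTDM) + 54 LBP-derived (18 first-order statistics of each of
#' the level-1, level-2 and kurtosis LBP maps). The panel is a
#' reconstruction of the standard 156-feature CT panel and ships as a JSON
#' manifest alongside extraction settings.
#'
#' @return character vector of 156 unique feature names.
#' @export
feature_panel <- function() {
  c(firstorder_names(), shape_names(), texture_names(), lbp_names())
}

#' Feature class of each panel feature
#'
#' Maps feature names to the four families used in the robustness and
#' modeling stages: `"intensity"` (first-order), `"shape"`, `"texture"`
#' (the five gray-level matrix families) and `"lbp"`.
#'
#' @param features character vector of feature names (default: full panel).
#' @return character vector of classes, same length.
#' @export
feature_class <- function(features = feature_panel()) {
  dplyr::case_when(
    grepl("^firstorder_", features) ~ "intensity",
    grepl("^shape_", features) ~ "shape",
    grepl("^(glcm|glrlm|glszm|gldm|ngtdm)_", features) ~ "texture",
    grepl("^lbp-", features) ~ "lbp",
    TRUE ~ "other"
  )
}

#' Extract the full radiomic panel from one image/mask pair
#'
#' Runs the complete per-node extraction: isotropic resampling, fixed-bin-
#' width discretization, first-order, shape, texture-matrix and 3D-LBP
#' features. Deterministic given its inputs.
#'
#' @param image a [ct_volume()].
#' @param mask a [ct_mask()] on the same grid.
#' @param spacing target isotropic spacing in mm (default 1).
#' @param bin_width discretization bin width in HU (default 5).
#' @param lbp_radius LBP sphere radius in mm (default 1).
#' @param lbp_bin_width bin width for LBP-map entropy/uniformity (default 0.05).
#' @return named numeric vector of 156 features, in [feature_panel()] order.
#' @export
extract_panel <- function(image, mask, spacing = 1, bin_width = 5,
                          lbp_radius = 1, lbp_bin_width = 0.05) {
  rs <- resample_isotropic(image, mask, spacing)
  disc <- discretize_fixed_bin_width(rs$image, rs$mask, bin_width)
  vals <- mask_values(rs$image, rs$mask)
  fo <- first_order_features(vals, bins = disc$values,
                             voxel_volume = voxel_volume(rs$image))
  sh <- shape_features(rs$mask)[shape_names()]
  tx <- texture_features(texture_matrices(disc))
  maps <- lbp3d_maps(rs$image, radius = lbp_radius)
  lb <- lbp_firstorder(maps, rs$mask, w = lbp_bin_width)
  out <- c(fo, sh, tx, lb)
  out[feature_panel()]
}

#' Extract features for every node of a cohort
#'
#' @param cohort a cohort tibble from [generate_cohort()] (or any tibble
#'   with list-columns `image` and a mask column), one row per lymph node.
#' @param mask_col which mask column to use (default `"mask_rater1"`).
#' @inheritParams extract_panel
#' @return A feature table: the cohort metadata columns followed by the 156
#'   feature columns, one row per node.
#' @export
extract_features <- function(cohort, mask_col = "mask_rater1", spacing = 1,
                             bin_width = 5, lbp_radius = 1,
                             lbp_bin_width = 0.05) {
  stopifnot(mask_col %in% names(cohort))
  rows <- purrr::pmap(
    list(cohort$image, cohort[[mask_col]], cohort$node_id),
    function(img, msk, id) {
      if (is.null(msk)) return(NULL)
      tryCatch(
        extract_panel(img, msk, spacing = spacing, bin_width = bin_width,
                      lbp_radius = lbp_radius, lbp_bin_width = lbp_bin_width),
        error = function(e) {
          rlang::abort(paste0("feature extraction failed for node ", id, ": ",
                              conditionMessage(e)),
                       class = "lnrad_extraction_error", parent = e)
        })
    })
  keep <- !purrr::map_lgl(rows, is.null)
  feat <- dplyr::bind_rows(purrr::map(rows[keep], ~ tibble::as_tibble(as.list(.x))))
  meta <- dplyr::select(cohort[keep, ], -dplyr::any_of(
    c("image", "mask_rater1", "mask_rater2")))
  dplyr::bind_cols(meta, feat)
}

#' Extraction settings manifest
#'
#' @param spacing,bin_width,lbp_radius,lbp_bin_width extraction settings.
#' @return a list suitable for JSON serialization, pinning the feature list
#'   and settings of an extraction run.
#' @export
feature_manifest <- function(spacing = 1, bin_width = 5, lbp_radius = 1,
                             lbp_bin_width = 0.05) {
  list(
    panel_version = "1.0",
    n_features = length(feature_panel()),
    settings = list(
      target_spacing_mm = spacing,
      bin_width_hu = bin_width,
      lbp_radius_mm = lbp_radius,
      lbp_bin_width = lbp_bin_width,
      glcm_distance = 1,
      directions = "13 unique 3D directions, feature-level averaging",
      connectivity = "26 (GLSZM zones, GLDM dependence, NGTDM neighborhood)"
    ),
    features = feature_panel(),
    classes = feature_class()
  )
}
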