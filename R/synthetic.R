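#' Configuration for the synthetic CT lymph-node phantom cohort
#'
#' Defines the statistical structure of the generated two-cohort dataset:
#' cohort sizes, per-node metastasis prevalence, scanner batch effects,
#' lesion volumes and intensities, the label-dependent effect, acquisition
#' noise and geometry, and the second-rater perturbation. Defaults emulate
#' a two-cohort lymph-node study: 47 training / 33 testing patients with
#' 1-3 nodes each, ~70%/79% prevalence, small lesions (mean volume ~0.14
#' cm^3), one in-house training scanner and three external testing scanners
#' with additive/multiplicative intensity offsets, and a second independent
#' segmentation for a 20-patient training subset tuned to a median Dice
#' near 0.89. Intensity levels and effect sizes are free parameters of the
#' phantom, not literature-derived: benign nodes average 45 HU; positive
#' nodes are shifted by +6 HU and carry a coarser texture correlation
#' length (3.2 mm vs 1.8 mm) whose amplitude is chosen so the realized
#' within-lesion variance matches the benign nodes'. Most of the label
#' signal therefore lives in spatial structure (seen by the texture-matrix
#' and LBP families) rather than in first-order intensity statistics.
#'
#' @param n_patients_train,n_patients_test cohort sizes (patients).
#' @param nodes_per_patient integer range `c(min, max)`, uniform.
#' @param prevalence probability of LNM per node; length 1 or 2 (train, test).
#' @param scanners data frame with columns `id`, `cohort`, `offset` (HU),
#'   `gain`.
#' @param volume_meanlog,volume_sdlog log-normal lesion volume (cm^3).
#' @param volume_range clamp interval for lesion volume (cm^3).
#' @param volume_lnm_shift additive shift of `volume_meanlog` for positive
#'   nodes (larger metastatic nodes).
#' @param base_intensity mean benign in-lesion intensity (HU).
#' @param base_intensity_sd between-node SD of the base intensity (HU).
#' @param background_offset background intensity relative to base (HU).
#' @param lnm_intensity_shift added to base intensity for positive nodes (HU).
#' @param texture_amplitude multiplicative texture-heterogeneity amplitude
#'   for benign nodes.
#' @param lnm_texture_amplitude same for positive nodes.
#' @param texture_scale correlation length of the band-limited texture
#'   field (mm); length 2 = (benign, positive). Metastatic nodes show
#'   coarser heterogeneity at a matched realized within-lesion variance,
#'   so the label signal lives mostly in spatial structure (LBP/texture
#'   families) rather than in first-order statistics.
#' @param noise_sd voxel-wise Gaussian noise (HU).
#' @param voxel_spacing acquisition spacing, mm triple (may be anisotropic).
#' @param eccentricity_range lesion shape eccentricity, uniform range.
#' @param surface_amplitude lesion surface modulation amplitude.
#' @param rater2_patients number of training patients with a second
#'   segmentation.
#' @param rater2_perturbation second-rater surface displacement (mm).
#' @param suvmax_meanlog log-mean SUVmax surrogate, length 2 (benign,
#'   positive).
#' @param seed integer seed; a fixed seed reproduces the cohort exactly.
#' @return An object of class `phantom_config` (a validated list).
#' @export
phantom_config <- function(n_patients_train = 47,
                           n_patients_test = 33,
                           nodes_per_patient = c(1, 3),
                           prevalence = c(0.70, 0.79),
                           scanners = default_scanners(),
                           volume_meanlog = log(0.115),
                           volume_sdlog = 0.45,
                           volume_range = c(0.05, 1.05),
                           volume_lnm_shift = 0.25,
                           base_intensity = 45,
                           base_intensity_sd = 8,
                           background_offset = -12,
                           lnm_intensity_shift = 6,
                           texture_amplitude = 0.36,
                           lnm_texture_amplitude = 0.41,
                           texture_scale = c(1.8, 3.2),
                           noise_sd = 3,
                           voxel_spacing = c(0.75, 0.75, 1.5),
                           eccentricity_range = c(0, 0.4),
                           surface_amplitude = 0.07,
                           rater2_patients = 20,
                           rater2_perturbation = 0.85,
                           suvmax_meanlog = c(log(2.5), log(9)),
                           seed = 20200416) {
  cfg <- as.list(environment())
  if (n_patients_train < 1 || n_patients_test < 0) {
    rlang::abort("at least one training patient is required.",
                 class = "lnrad_bad_config")
  }
  if (any(prevalence <= 0) || any(prevalence > 1)) {
    rlang::abort("`prevalence` must lie in (0, 1].", class = "lnrad_bad_config")
  }
  if (length(prevalence) == 1) cfg$prevalence <- rep(prevalence, 2)
  if (nrow(scanners) == 0 ||
      !all(c("train", "test")[c(TRUE, n_patients_test > 0)] %in% scanners$cohort)) {
    rlang::abort("`scanners` must cover every generated cohort.",
                 class = "lnrad_bad_config")
  }
  if (any(volume_range <= 0) || diff(volume_range) <= 0) {
    rlang::abort("`volume_range` must be a positive interval.",
                 class = "lnrad_bad_config")
  }
  if (rater2_perturbation < 0) {
    rlang::abort("`rater2_perturbation` must be >= 0.", class = "lnrad_bad_config")
  }
  structure(cfg, class = "phantom_config")
}

#' @rdname phantom_config
#' @export
default_scanners <- function() {
  tibble::tibble(
    id = c("inhouse", "ext1", "ext2", "ext3"),
    cohort = c("train", "test", "test", "test"),
    offset = c(0, 15, -12, 5),
    gain = c(1, 1.05, 0.95, 1.1)
  )
}

#' Generate the synthetic phantom cohort
#'
#' Draws the full two-cohort lymph-node dataset defined by a
#' [phantom_config()]: per patient 1-3 nodes, each a textured ellipsoidal
#' lesion embedded in a background crop, with its scanner's additive offset
#' and multiplicative gain applied to the whole image. Nodes of the
#' designated training subset carry a second, perturbed segmentation.
#' The generator is fully reproducible for a fixed seed.
#'
#' @param config a [phantom_config()].
#' @return A cohort tibble, one row per node: `patient_id`, `node_id`,
#'   `cohort`, `batch`, `label`, `volume_cm3` (generated target volume),
#'   `short_diameter_mm`, `expert_rating`, `suvmax`, and list-columns
#'   `image`, `mask_rater1`, `mask_rater2` (`NULL` where absent).
#' @export
generate_cohort <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  with_preserved_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  pat <- tibble::tibble(
    patient_id = sprintf("P%03d", seq_len(cfg$n_patients_train + cfg$n_patients_test)),
    cohort = rep(c("train", "test"), c(cfg$n_patients_train, cfg$n_patients_test))
  )
  rater2_set <- utils::head(pat$patient_id[pat$cohort == "train"],
                            cfg$rater2_patients)
  rows <- list()
  node_counter <- 0L
  for (p in seq_len(nrow(pat))) {
    coh <- pat$cohort[p]
    sc <- cfg$scanners[cfg$scanners$cohort == coh, , drop = FALSE]
    batch <- sc$id[sample.int(nrow(sc), 1)]
    off <- sc$offset[sc$id == batch]
    gain <- sc$gain[sc$id == batch]
    prev <- cfg$prevalence[if (coh == "train") 1 else 2]
    node_choices <- seq(cfg$nodes_per_patient[1], cfg$nodes_per_patient[2])
    n_nodes <- node_choices[sample.int(length(node_choices), 1)]
    for (k in seq_len(n_nodes)) {
      node_counter <- node_counter + 1L
      label <- stats::rbinom(1, 1, prev)
      vol <- exp(stats::rnorm(1, cfg$volume_meanlog +
                                label * cfg$volume_lnm_shift, cfg$volume_sdlog))
      vol <- min(max(vol, cfg$volume_range[1]), cfg$volume_range[2])
      base <- stats::rnorm(1, cfg$base_intensity + label * cfg$lnm_intensity_shift,
                           cfg$base_intensity_sd)
      amp <- if (label == 1) cfg$lnm_texture_amplitude else cfg$texture_amplitude
      tscale <- cfg$texture_scale[min(label + 1, length(cfg$texture_scale))]
      les <- make_lesion(vol,
                         eccentricity = stats::runif(1, cfg$eccentricity_range[1],
                                                     cfg$eccentricity_range[2]),
                         texture_amplitude = amp,
                         spacing = cfg$voxel_spacing,
                         base_intensity = base,
                         background_offset = cfg$background_offset,
                         noise_sd = cfg$noise_sd,
                         texture_scale = tscale,
                         surface_amplitude = cfg$surface_amplitude)
      img <- les$image
      img$voxels <- img$voxels * gain + off
      mask2 <- if (pat$patient_id[p] %in% rater2_set) {
        perturb_mask(les$mask, cfg$rater2_perturbation)
      } else NULL
      sd_mm <- short_diameter(les$mask)
      latent <- 0.6 * label + 0.25 * (sd_mm - 6.5) / 2 + stats::rnorm(1)
      rating <- findInterval(latent, c(-0.5, 0.3, 1.0, 1.7)) + 1L
      suv <- exp(stats::rnorm(1, cfg$suvmax_meanlog[label + 1], 0.5))
      rows[[node_counter]] <- tibble::tibble(
        patient_id = pat$patient_id[p],
        node_id = sprintf("N%04d", node_counter),
        cohort = coh, batch = batch, label = label,
        volume_cm3 = vol, short_diameter_mm = sd_mm,
        expert_rating = rating, suvmax = suv,
        image = list(img),
        mask_rater1 = list(les$mask),
        mask_rater2 = list(mask2)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Generate a single synthetic lesion
#'
#' An ellipsoid with a smooth random surface modulation, voxelized on the
#' given grid, filled with base intensity plus band-limited multiplicative
#' texture plus Gaussian noise, inside a darker background crop.
#'
#' @param volume_target lesion volume in cm^3.
#' @param eccentricity elongation of the ellipsoid (0 = sphere).
#' @param texture_amplitude amplitude of the multiplicative in-lesion
#'   texture field.
#' @param spacing voxel spacing, mm triple.
#' @param base_intensity mean in-lesion intensity (HU).
#' @param background_offset background minus base intensity (HU).
#' @param noise_sd voxel noise (HU).
#' @param texture_scale texture correlation length (mm).
#' @param surface_amplitude surface modulation amplitude (0 disables).
#' @param psf_sigma Gaussian point-spread sigma in mm applied to the
#'   noiseless structure, emulating the scanner's partial-volume blur at
#'   the lesion boundary (0 disables).
#' @param margin_mm background margin around the lesion (mm).
#' @return list with `image` ([ct_volume()]) and `mask` ([ct_mask()]).
#' @export
make_lesion <- function(volume_target, eccentricity = 0.2,
                        texture_amplitude = 0.05, spacing = c(1, 1, 1),
                        base_intensity = 45, background_offset = -25,
                        noise_sd = 10, texture_scale = 2.5,
                        surface_amplitude = 0.07, psf_sigma = 0.5,
                        margin_mm = 4) {
  if (volume_target <= 0) {
    rlang::abort("`volume_target` must be positive.", class = "lnrad_bad_config")
  }
  vol_mm3 <- volume_target * 1000
  if (vol_mm3 < prod(spacing)) {
    rlang::abort("target volume is smaller than one voxel.",
                 class = "lnrad_bad_config")
  }
  r0 <- (3 * vol_mm3 / (4 * pi))^(1 / 3)
  ax <- c(r0 * (1 + eccentricity), r0, r0 / (1 + eccentricity))
  rot <- random_rotation()
  sh_coef <- stats::rnorm(8) * surface_amplitude / sqrt(8)
  rmax <- max(ax) * (1 + 3 * surface_amplitude)
  half <- rmax + margin_mm
  dims <- pmax(4L, as.integer(ceiling(2 * half / spacing)) + 1L)
  ctr <- (dims - 1) / 2 * spacing
  xs <- lapply(1:3, function(a) (seq_len(dims[a]) - 1) * spacing[a] - ctr[a])
  X <- array(rep(xs[[1]], times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(xs[[2]], each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(xs[[3]], each = dims[1] * dims[2]), dims)
  # lesion frame coordinates
  U1 <- rot[1, 1] * X + rot[1, 2] * Y + rot[1, 3] * Z
  U2 <- rot[2, 1] * X + rot[2, 2] * Y + rot[2, 3] * Z
  U3 <- rot[3, 1] * X + rot[3, 2] * Y + rot[3, 3] * Z
  q <- sqrt((U1 / ax[1])^2 + (U2 / ax[2])^2 + (U3 / ax[3])^2)
  rad <- sqrt(U1^2 + U2^2 + U3^2)
  rad[rad == 0] <- 1e-9
  dirs <- cbind(as.vector(U1 / rad), as.vector(U2 / rad), as.vector(U3 / rad))
  fmod <- 1 + array(sh_basis(dirs) %*% sh_coef, dims)
  inside <- q <= fmod
  if (!any(inside)) {
    rlang::abort("lesion voxelization produced an empty mask.",
                 class = "lnrad_empty_mask")
  }
  tex <- smooth_field(dims, spacing, texture_scale)
  vox <- array(base_intensity + background_offset, dims)
  vox[inside] <- base_intensity * (1 + texture_amplitude * tex[inside])
  # partial-volume / reconstruction blur of the structure; acquisition noise
  # is added afterwards and stays uncorrelated at its nominal SD
  vox <- gaussian_blur(vox, spacing, psf_sigma)
  vox <- vox + stats::rnorm(length(vox), 0, noise_sd)
  list(image = ct_volume(vox, spacing),
       mask = ct_mask(inside, spacing))
}

#' Simulate a second rater's segmentation
#'
#' Displaces the mask surface by a random amount with two components: a
#' spatially smooth zero-mean field (local boundary disagreement) and a
#' per-mask constant (the systematic generous-vs-tight delineation bias
#' raters show against each other). The new mask is the sub-level set of
#' the signed Euclidean distance to the original surface plus `magnitude`
#' times the unit-variance combined displacement. Dice overlap with the
#' original decreases monotonically in expectation as `magnitude` grows;
#' `magnitude = 0` returns the mask unchanged.
#'
#' @param mask a [ct_mask()].
#' @param magnitude surface displacement scale in mm (>= 0).
#' @param field_scale correlation length of the displacement field (mm).
#' @param bias_fraction share of the displacement variance carried by the
#'   constant (systematic) component, in `[0, 1]` (default 0.4).
#' @return a [ct_mask()] on the same grid.
#' @export
perturb_mask <- function(mask, magnitude, field_scale = 4.5, bias_fraction = 0.3) {
  if (magnitude < 0) {
    rlang::abort("`magnitude` must be >= 0.", class = "lnrad_bad_config")
  }
  if (bias_fraction < 0 || bias_fraction > 1) {
    rlang::abort("`bias_fraction` must lie in [0, 1].", class = "lnrad_bad_config")
  }
  if (mask_size(mask) == 0) {
    rlang::abort("mask is empty.", class = "lnrad_empty_mask")
  }
  if (magnitude == 0) return(mask)
  sdist <- signed_distance(mask)
  u <- smooth_field(dim(mask$voxels), mask$spacing, field_scale)
  # the systematic component is truncated: raters differ in generosity but
  # do not grossly re-segment a node
  b <- min(max(stats::rnorm(1), -1.5), 1.5)
  u <- sqrt(1 - bias_fraction) * u + sqrt(bias_fraction) * b
  ct_mask(sdist + magnitude * u <= 0, mask$spacing, mask$origin)
}

# signed distance (mm): negative inside the mask, positive outside
signed_distance <- function(mask) {
  m <- mask$voxels
  edt_mm(m, mask$spacing) - edt_mm(!m, mask$spacing)
}

# Euclidean distance (mm) to the nearest TRUE voxel, separable exact EDT
edt_mm <- function(feature, spacing) {
  d2 <- array(ifelse(feature, 0, Inf), dim(feature))
  for (ax in 1:3) {
    d2 <- apply_along(d2, ax, function(m) {
      apply(m, 2, edt_1d, w = spacing[ax])
    })
  }
  sqrt(d2)
}

# 1D squared distance transform (lower envelope of parabolas); `f` holds
# squared distances in mm^2 from earlier passes, `w` is this axis' spacing
edt_1d <- function(f, w) {
  n <- length(f)
  if (n == 1) return(f)
  w2 <- w * w
  f[!is.finite(f)] <- 1e30
  v <- integer(n); z <- numeric(n + 1)
  k <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
  for (q in 2:n) {
    repeat {
      r <- v[k]
      s <- ((f[q] + q * q * w2) - (f[r] + r * r * w2)) / (2 * w2 * (q - r))
      if (k > 1L && s <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1] <- Inf
  }
  out <- numeric(n)
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1] < q) k <- k + 1L
    out[q] <- (q - v[k])^2 * w2 + f[v[k]]
  }
  out
}

# separable Gaussian convolution with replicate padding (PSF emulation)
gaussian_blur <- function(a, spacing, sigma_mm) {
  if (sigma_mm <= 0) return(a)
  for (ax in 1:3) {
    s_vox <- sigma_mm / spacing[ax]
    r <- max(1L, ceiling(3 * s_vox))
    k <- exp(-0.5 * ((-r:r) / s_vox)^2)
    k <- k / sum(k)
    a <- apply_along(a, ax, function(m) {
      n <- nrow(m)
      idx <- pmin(pmax(seq(1 - r, n + r), 1), n)
      mp <- m[idx, , drop = FALSE]
      out <- matrix(0, n, ncol(m))
      for (j in seq_along(k)) {
        out <- out + k[j] * mp[j:(j + n - 1), , drop = FALSE]
      }
      out
    })
  }
  a
}

# unit-variance Gaussian random field with the given correlation length,
# built by trilinear upsampling of coarse white noise
smooth_field <- function(dims, spacing, scale_mm) {
  cdims <- pmax(2L, as.integer(ceiling((dims - 1) * spacing / scale_mm)) + 1L)
  coarse <- array(stats::rnorm(prod(cdims)), cdims)
  upos <- lapply(1:3, function(a) {
    (seq_len(dims[a]) - 1) * spacing[a] / scale_mm
  })
  f <- interp_separable(coarse, upos, kernel = "linear")
  s <- stats::sd(f)
  if (s > 0) (f - mean(f)) / s else f * 0
}

random_rotation <- function() {
  qr_res <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_res)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# maximum over axial (xy) planes of the in-plane minor-axis extent
short_diameter <- function(mask) {
  m <- mask$voxels
  sp <- mask$spacing
  best <- 0
  for (k in seq_len(dim(m)[3])) {
    sl <- m[, , k]
    if (!any(sl)) next
    idx <- which(sl, arr.ind = TRUE) - 1L
    xy <- sweep(idx, 2, sp[1:2], "*")
    if (nrow(xy) == 1) {
      best <- max(best, min(sp[1:2]))
      next
    }
    cv <- stats::cov(xy)
    e <- eigen(cv, symmetric = TRUE)
    minor <- e$vectors[, 2]
    proj <- xy %*% minor
    best <- max(best, diff(range(proj)) + min(sp[1:2]))
  }
  best
}

# run code with a fixed seed, restoring the caller's RNG state afterwards
with_preserved_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Write a cohort to disk
#'
#' One image and one mask file per node (NRRD by default, NIfTI with
#' `format = "nii.gz"`), a second-rater mask where present, and a
#' `cohort.csv` metadata table.
#'
#' @param cohort a cohort tibble from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param format `"nrrd"` or `"nii.gz"`.
#' @return the metadata file path, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("nrrd", "nii.gz")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$node_id[i]
    write_volume(cohort$image[[i]], file.path(dir, paste0(id, "_image.", format)))
    write_mask(cohort$mask_rater1[[i]], file.path(dir, paste0(id, "_mask.", format)))
    if (!is.null(cohort$mask_rater2[[i]])) {
      write_mask(cohort$mask_rater2[[i]],
                 file.path(dir, paste0(id, "_mask_rater2.", format)))
    }
  }
  meta <- dplyr::select(cohort, -dplyr::any_of(c("image", "mask_rater1",
                                                 "mask_rater2")))
  path <- file.path(dir, "cohort.csv")
  utils::write.csv(meta, path, row.names = FALSE)
  invisible(path)
}
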