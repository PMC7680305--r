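# shared fixtures: small digital phantoms built in code

digital_ball <- function(radius_mm, spacing = c(1, 1, 1), pad = 3) {
  half <- radius_mm + pad * max(spacing)
  dims <- as.integer(ceiling(2 * half / spacing)) + 1L
  ctr <- (dims - 1) / 2 * spacing
  xs <- lapply(1:3, function(a) (seq_len(dims[a]) - 1) * spacing[a] - ctr[a])
  X <- array(rep(xs[[1]], times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(xs[[2]], each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(xs[[3]], each = dims[1] * dims[2]), dims)
  ct_mask(X^2 + Y^2 + Z^2 <= radius_mm^2, spacing)
}

# a small VOI with given bin values (NA outside mask)
toy_discretized <- function(bins3d, w = 5, spacing = c(1, 1, 1)) {
  structure(list(bins = bins3d,
                 values = as.integer(bins3d[!is.na(bins3d)]),
                 n_bins = max(bins3d, na.rm = TRUE),
                 w = w, min_intensity = 0, spacing = spacing),
            class = "ln_discretized")
}

random_voi <- function(dims = c(4, 4, 4), n_bins = 4, p_mask = 0.85, seed = 1) {
  set.seed(seed)
  bins <- array(sample.int(n_bins, prod(dims), replace = TRUE), dims)
  bins[stats::runif(prod(dims)) > p_mask] <- NA_integer_
  if (all(is.na(bins))) bins[1] <- 1L
  toy_discretized(bins)
}

small_image_pair <- function(dims = c(8, 9, 7), spacing = c(1, 1, 1), seed = 5) {
  set.seed(seed)
  img <- ct_volume(array(stats::rnorm(prod(dims), 40, 12), dims), spacing)
  m <- array(FALSE, dims)
  m[3:6, 3:7, 3:5] <- TRUE
  list(image = img, mask = ct_mask(m, spacing))
}

# small, fast phantom for pipeline-level tests; prevalence kept moderate so
# tiny test cohorts retain both classes
mini_phantom <- function(seed = 5, ...) {
  phantom_config(n_patients_train = 14, n_patients_test = 10,
                 prevalence = c(0.6, 0.65),
                 scanners = tibble::tibble(
                   id = c("inhouse", "ext1"),
                   cohort = c("train", "test"),
                   offset = c(0, 15), gain = c(1, 1.05)),
                 rater2_patients = 8, seed = seed, ...)
}
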