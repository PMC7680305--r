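test_that("a fixed seed reproduces the cohort exactly", {
  cfg <- mini_phantom(seed = 3)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(dplyr::select(c1, -image, -mask_rater1, -mask_rater2),
                   dplyr::select(c2, -image, -mask_rater1, -mask_rater2))
  expect_identical(c1$image[[1]]$voxels, c2$image[[1]]$voxels)
  expect_identical(c1$mask_rater1[[5]]$voxels, c2$mask_rater1[[5]]$voxels)
  i2 <- which(!purrr::map_lgl(c1$mask_rater2, is.null))[1]
  expect_identical(c1$mask_rater2[[i2]]$voxels, c2$mask_rater2[[i2]]$voxels)
})

test_that("degenerate and binomial prevalence behave as configured", {
  all_pos <- generate_cohort(phantom_config(
    n_patients_train = 25, n_patients_test = 0, nodes_per_patient = c(2, 2),
    prevalence = 1.0, rater2_patients = 0, seed = 9))
  expect_true(all(all_pos$label == 1))
  expect_gte(nrow(all_pos), 50)

  big <- generate_cohort(phantom_config(
    n_patients_train = 200, n_patients_test = 150, nodes_per_patient = c(1, 3),
    prevalence = 0.7, rater2_patients = 0, seed = 10))
  n <- nrow(big)
  expect_gt(n, 500)
  sd_bin <- sqrt(0.7 * 0.3 / n)
  expect_lt(abs(mean(big$label) - 0.7), 3 * sd_bin)
})

test_that("invalid configurations are rejected", {
  expect_error(phantom_config(n_patients_train = 0), class = "lnrad_bad_config")
  expect_error(phantom_config(prevalence = 0), class = "lnrad_bad_config")
  expect_error(phantom_config(scanners = default_scanners()[0, ]),
               class = "lnrad_bad_config")
  expect_error(phantom_config(rater2_perturbation = -1),
               class = "lnrad_bad_config")
  expect_error(make_lesion(0), class = "lnrad_bad_config")
  expect_error(make_lesion(0.0005, spacing = c(1, 1, 1)),
               class = "lnrad_bad_config")
})

test_that("lesions hit their target volume and noise statistics", {
  set.seed(30)
  les <- make_lesion(0.15, eccentricity = 0.2, texture_amplitude = 0.1,
                     spacing = c(1, 1, 1))
  nvox <- mask_size(les$mask)
  expect_lt(abs(nvox - 150) / 150, 0.15)

  # zero texture (and no PSF blur): interior variance equals the voxel
  # noise variance
  vars <- vapply(1:8, function(s) {
    set.seed(s)
    l0 <- make_lesion(0.3, eccentricity = 0, texture_amplitude = 0,
                      spacing = c(1, 1, 1), noise_sd = 6, psf_sigma = 0)
    stats::var(mask_values(l0$image, l0$mask))
  }, numeric(1))
  expect_lt(abs(mean(vars) - 36) / 36, 0.15)

  # zero eccentricity: near-spherical after extraction
  set.seed(31)
  l0 <- make_lesion(0.3, eccentricity = 0, texture_amplitude = 0,
                    surface_amplitude = 0, spacing = c(1, 1, 1))
  f <- shape_features(l0$mask)
  expect_gte(unname(f["shape_Sphericity"]), 0.9)
})

test_that("batch offsets and gains are imprinted on the images", {
  cfg <- phantom_config(
    n_patients_train = 8, n_patients_test = 8, nodes_per_patient = c(2, 2),
    scanners = tibble::tibble(id = c("a", "b"), cohort = c("train", "test"),
                              offset = c(0, 40), gain = c(1, 1)),
    rater2_patients = 0, noise_sd = 2, seed = 12)
  coh <- generate_cohort(cfg)
  mean_in <- vapply(seq_len(nrow(coh)), function(i) {
    mean(mask_values(coh$image[[i]], coh$mask_rater1[[i]]))
  }, numeric(1))
  gap <- mean(mean_in[coh$batch == "b"]) - mean(mean_in[coh$batch == "a"])
  expect_gt(gap, 25)  # the +40 HU offset dominates the biological spread
})

test_that("rater-2 masks track the configured Dice regime", {
  set.seed(33)
  les <- make_lesion(0.15, eccentricity = 0.2, texture_amplitude = 0.1,
                     spacing = c(0.75, 0.75, 1.5))
  expect_identical(perturb_mask(les$mask, 0)$voxels, les$mask$voxels)

  ds <- vapply(1:100, function(i) {
    dice(les$mask, perturb_mask(les$mask, 0.85))
  }, numeric(1))
  expect_gte(stats::median(ds), 0.85)
  expect_lte(stats::median(ds), 0.93)

  d_big <- stats::median(vapply(1:20, function(i) {
    dice(les$mask, perturb_mask(les$mask, 6))
  }, numeric(1)))
  expect_lt(d_big, 0.5)

  # expectation decreases monotonically with magnitude
  med_at <- function(mag) stats::median(vapply(1:40, function(i) {
    dice(les$mask, perturb_mask(les$mask, mag))
  }, numeric(1)))
  set.seed(34)
  meds <- c(med_at(0.3), med_at(0.9), med_at(2.5))
  expect_true(all(diff(meds) < 0))
  expect_error(perturb_mask(les$mask, -0.1), class = "lnrad_bad_config")
})

test_that("mean in-mask intensity separates the groups at cohort scale", {
  cfg <- phantom_config(n_patients_train = 120, n_patients_test = 40,
                        rater2_patients = 0, seed = 14)
  coh <- generate_cohort(cfg)
  expect_gte(nrow(coh), 250)
  mean_in <- vapply(seq_len(nrow(coh)), function(i) {
    mean(mask_values(coh$image[[i]], coh$mask_rater1[[i]]))
  }, numeric(1))
  p <- stats::wilcox.test(mean_in[coh$label == 1],
                          mean_in[coh$label == 0])$p.value
  expect_lt(p, 0.05)
})

test_that("cohorts round-trip through the on-disk layout", {
  coh <- generate_cohort(phantom_config(
    n_patients_train = 2, n_patients_test = 1, nodes_per_patient = c(1, 1),
    rater2_patients = 1, seed = 15))
  dir <- file.path(tempdir(), "cohort_rt")
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(nrow(back), nrow(coh))
  expect_equal(back$label, coh$label)
  expect_equal(back$image[[1]]$voxels, coh$image[[1]]$voxels,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$mask_rater1[[2]]$voxels, coh$mask_rater1[[2]]$voxels,
               ignore_attr = TRUE)
})
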