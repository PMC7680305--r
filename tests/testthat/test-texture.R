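test_that("the toy 2x2x1 checkerboard GLCM matches the hand count", {
  bins <- array(c(1L, 2L, 2L, 1L), c(2, 2, 1))
  voi <- toy_discretized(bins)
  dirs <- lnrad:::texture_directions()
  ix <- which(vapply(dirs, function(d) all(d == c(1, 0, 0)), logical(1)))
  P <- lnrad:::glcm_one(voi$bins, dirs[[ix]], voi$n_bins)
  # pairs along x: (1,2) and (2,1), symmetrized -> all mass off-diagonal
  expect_equal(P, matrix(c(0, 0.5, 0.5, 0), 2, 2))
})

test_that("texture matrices equal brute-force enumeration on small VOIs", {
  for (seed in c(1, 2, 3)) {
    voi <- random_voi(dims = c(4, 5, 4), n_bins = 4, seed = seed)
    mats <- texture_matrices(voi)
    dirs <- lnrad:::texture_directions()
    for (di in seq_along(dirs)) {
      expect_equal(mats$glcm[[di]],
                   oracle_glcm(voi$bins, dirs[[di]], voi$n_bins),
                   tolerance = 1e-12)
      expect_equal(mats$glrlm[[di]],
                   oracle_glrlm(voi$bins, dirs[[di]], voi$n_bins),
                   tolerance = 1e-12)
    }
    expect_equal(mats$glszm, oracle_glszm(voi$bins, voi$n_bins),
                 tolerance = 1e-12)
    expect_equal(mats$gldm, oracle_gldm(voi$bins, voi$n_bins),
                 tolerance = 1e-12)
    on <- oracle_ngtdm(voi$bins, voi$n_bins)
    expect_equal(mats$ngtdm$p, on$p, tolerance = 1e-12)
    expect_equal(mats$ngtdm$s, on$s, tolerance = 1e-10)
    expect_equal(mats$ngtdm$n_v, on$n_v)
  }
})

test_that("texture features match naive formula recomputation", {
  voi <- random_voi(dims = c(5, 4, 4), n_bins = 5, seed = 7)
  mats <- texture_matrices(voi)
  f <- texture_features(mats)
  dirs <- lnrad:::texture_directions()
  ng <- voi$n_bins

  # GLCM contrast / joint entropy / correlation, averaged over directions
  per_dir <- vapply(seq_along(dirs), function(di) {
    P <- oracle_glcm(voi$bins, dirs[[di]], ng)
    contrast <- 0; jent <- 0; acor <- 0
    mux <- 0; muy <- 0
    for (i in 1:ng) for (j in 1:ng) {
      contrast <- contrast + P[i, j] * (i - j)^2
      if (P[i, j] > 0) jent <- jent - P[i, j] * log2(P[i, j])
      acor <- acor + i * j * P[i, j]
      mux <- mux + i * P[i, j]; muy <- muy + j * P[i, j]
    }
    sx <- sqrt(sum(outer(1:ng, 1:ng, function(i, j) (i - mux)^2) * P))
    sy <- sqrt(sum(outer(1:ng, 1:ng, function(i, j) (j - muy)^2) * P))
    corr <- (acor - mux * muy) / (sx * sy)
    c(contrast, jent, corr)
  }, numeric(3))
  expect_equal(unname(f["glcm_Contrast"]), mean(per_dir[1, ]), tolerance = 1e-10)
  expect_equal(unname(f["glcm_JointEntropy"]), mean(per_dir[2, ]), tolerance = 1e-10)
  expect_equal(unname(f["glcm_Correlation"]), mean(per_dir[3, ]), tolerance = 1e-10)

  # GLRLM long-run emphasis and run percentage per direction
  np <- sum(!is.na(voi$bins))
  lre <- vapply(seq_along(dirs), function(di) {
    runs <- oracle_runs(voi$bins, dirs[[di]])
    sum(runs[, "len"]^2) / nrow(runs)
  }, numeric(1))
  rp <- vapply(seq_along(dirs), function(di) {
    nrow(oracle_runs(voi$bins, dirs[[di]])) / np
  }, numeric(1))
  expect_equal(unname(f["glrlm_LongRunEmphasis"]), mean(lre), tolerance = 1e-10)
  expect_equal(unname(f["glrlm_RunPercentage"]), mean(rp), tolerance = 1e-10)

  # GLSZM small-area emphasis from the zone list
  Pz <- oracle_glszm(voi$bins, ng)
  sae <- 0; nz <- sum(Pz)
  for (i in 1:nrow(Pz)) for (s in 1:ncol(Pz)) sae <- sae + Pz[i, s] / s^2
  expect_equal(unname(f["glszm_SmallAreaEmphasis"]), sae / nz, tolerance = 1e-10)

  # GLDM large-dependence emphasis
  Pd <- oracle_gldm(voi$bins, ng)
  lde <- 0; nd <- sum(Pd)
  for (i in 1:nrow(Pd)) for (j in 1:ncol(Pd)) lde <- lde + Pd[i, j] * j^2
  expect_equal(unname(f["gldm_LargeDependenceEmphasis"]), lde / nd,
               tolerance = 1e-10)

  # all five NGTDM features from the naive s/p vectors
  on <- oracle_ngtdm(voi$bins, ng)
  act <- which(on$p > 0); ngp <- length(act)
  coarse <- 1 / sum(on$p * on$s)
  contrast <- 0
  for (i in act) for (j in act) contrast <- contrast + on$p[i] * on$p[j] * (i - j)^2
  contrast <- contrast / (ngp * (ngp - 1)) * sum(on$s) / on$n_v
  busy_den <- 0
  for (i in act) for (j in act) busy_den <- busy_den + abs(i * on$p[i] - j * on$p[j])
  busy <- sum(on$p * on$s) / busy_den
  compl <- 0
  for (i in act) for (j in act) {
    compl <- compl + abs(i - j) * (on$p[i] * on$s[i] + on$p[j] * on$s[j]) /
      (on$p[i] + on$p[j])
  }
  compl <- compl / on$n_v
  strength <- 0
  for (i in act) for (j in act) strength <- strength + (on$p[i] + on$p[j]) * (i - j)^2
  strength <- strength / sum(on$s)
  expect_equal(unname(f["ngtdm_Coarseness"]), coarse, tolerance = 1e-10)
  expect_equal(unname(f["ngtdm_Contrast"]), contrast, tolerance = 1e-10)
  expect_equal(unname(f["ngtdm_Busyness"]), busy, tolerance = 1e-10)
  expect_equal(unname(f["ngtdm_Complexity"]), compl, tolerance = 1e-10)
  expect_equal(unname(f["ngtdm_Strength"]), strength, tolerance = 1e-10)
})

test_that("normalized matrices sum to one and degenerate VOIs stay defined", {
  voi <- random_voi(dims = c(4, 4, 3), n_bins = 3, seed = 4)
  mats <- texture_matrices(voi)
  for (P in mats$glcm) expect_equal(sum(P), 1, tolerance = 1e-12)

  const <- toy_discretized(array(1L, c(3, 3, 3)))
  f <- texture_features(texture_matrices(const))
  expect_equal(unname(f["glcm_Contrast"]), 0)
  expect_equal(unname(f["glcm_Correlation"]), 1)  # documented degenerate rule
  expect_equal(unname(f["ngtdm_Coarseness"]), 1e6)  # degenerate cap
  expect_true(all(is.finite(f)))
})

test_that("a single straight run is counted with its full length", {
  bins <- array(NA_integer_, c(5, 3, 3))
  bins[1:5, 2, 2] <- 2L
  voi <- toy_discretized(bins)
  mats <- texture_matrices(voi)
  dirs <- lnrad:::texture_directions()
  ix <- which(vapply(dirs, function(d) all(d == c(1, 0, 0)), logical(1)))
  P <- mats$glrlm[[ix]]
  expect_equal(sum(P), 1)           # one run along x
  expect_equal(P[2, 5], 1)          # gray 2, length 5
  f <- lnrad:::glrlm_features_one(P, np = 5)
  expect_equal(unname(f["LongRunEmphasis"]), 25)
})

test_that("direction-averaged texture features are 90-degree rotation invariant", {
  voi <- random_voi(dims = c(5, 5, 4), n_bins = 4, seed = 12)
  f1 <- texture_features(texture_matrices(voi))
  rot <- aperm(voi$bins, c(2, 1, 3))[dim(voi$bins)[2]:1, , , drop = FALSE]
  f2 <- texture_features(texture_matrices(toy_discretized(rot)))
  expect_equal(f1, f2, tolerance = 1e-9)
})
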