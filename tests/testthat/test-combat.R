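# batch B carries an additive shift and a multiplicative widening of the
# fluctuations on every feature, the scanner-effect model ComBat assumes
make_batch_table <- function(n_per_batch = 200, shift = 3, scale = 1,
                             n_features = 8, seed = 30) {
  set.seed(seed)
  n <- 2 * n_per_batch
  batch <- rep(c("A", "B"), each = n_per_batch)
  base_mu <- seq(10, 60, length.out = n_features)
  base_sd <- seq(2, 6, length.out = n_features)
  feats <- lapply(seq_len(n_features), function(j) {
    v <- base_mu[j] + stats::rnorm(n, 0, base_sd[j]) *
      ifelse(batch == "B", scale, 1)
    v + ifelse(batch == "B", shift, 0)
  })
  names(feats) <- c("firstorder_Mean", "glcm_Contrast", "shape_Sphericity",
                    paste0("glrlm_F", seq_len(max(0, n_features - 3))))[
                      seq_len(n_features)]
  out <- tibble::as_tibble(feats)
  out$batch <- batch
  out$label <- rbinom(n, 1, 0.5)
  out
}

test_that("a single batch leaves features essentially unchanged", {
  d <- make_batch_table(shift = 0)
  d$batch <- "A"
  p <- combat_fit(d, d$batch)
  expect_lt(max(abs(p$gamma)), 0.05)
  expect_lt(max(abs(p$delta2 - 1)), 0.15)
  adj <- combat_apply(d, p, d$batch)
  expect_lt(max(abs(adj$firstorder_Mean - d$firstorder_Mean)), 0.2)
})

test_that("simulated additive and multiplicative batch effects are recovered", {
  d <- make_batch_table(shift = 3, scale = 2)
  p <- combat_fit(d, d$batch)
  sd_pool <- sqrt(p$pooled_var["firstorder_Mean"])
  shift_hat <- (p$gamma["B", "firstorder_Mean"] -
                  p$gamma["A", "firstorder_Mean"]) * sd_pool
  expect_lt(abs(shift_hat - 3) / 3, 0.1)
  # variance ratio of the two batches: back on the raw scale, scale^2 = 4
  ratios <- p$delta2["B", ] / p$delta2["A", ]
  expect_lt(abs(mean(ratios) - 4) / 4, 0.2)
})

test_that("applying the fit removes at least 90% of the batch mean gap", {
  # equal feature scales: the EB prior is then centered on the true batch
  # location and shrinkage costs nothing
  d <- make_batch_table(shift = 3, scale = 1)
  d[, 1:8] <- lapply(seq_len(8), function(j) {
    set.seed(300 + j)
    v <- 20 + rnorm(nrow(d), 0, 4)
    v + ifelse(d$batch == "B", 3, 0)
  })
  p <- combat_fit(d, d$batch)
  adj <- combat_apply(d, p, d$batch)
  gap_before <- abs(diff(tapply(d$firstorder_Mean, d$batch, mean)))
  gap_after <- abs(diff(tapply(adj$firstorder_Mean, adj$batch, mean)))
  expect_lt(gap_after, 0.1 * gap_before)
  # metadata (label) passes through bit-identical
  expect_identical(adj$label, d$label)
  # within-batch rank order preserved (monotone affine per batch)
  for (b in c("A", "B")) {
    expect_identical(order(adj$firstorder_Mean[d$batch == b]),
                     order(d$firstorder_Mean[d$batch == b]))
  }
})

test_that("singleton and unseen batches are explicit errors", {
  d <- make_batch_table()
  expect_error(combat_fit(d[c(1:5, 201), ], d$batch[c(1:5, 201)]),
               class = "lnrad_singleton_batch")
  p <- combat_fit(d, d$batch)
  expect_error(combat_apply(d, p, rep("C", nrow(d))),
               class = "lnrad_unseen_batch")
})

test_that("the EB estimates agree with the reference ComBat implementation", {
  skip_if_not_installed("sva")
  d <- make_batch_table(n_per_batch = 60, shift = 2, scale = 1.5, seed = 77)
  feats <- c("firstorder_Mean", "glcm_Contrast", "shape_Sphericity")
  p <- combat_fit(d, d$batch, feature_names = feats)
  adj <- combat_apply(d, p, d$batch)
  ref <- t(sva::ComBat(dat = t(as.matrix(d[, feats])), batch = d$batch,
                       par.prior = TRUE, prior.plots = FALSE))
  expect_equal(as.matrix(adj[, feats]), ref, tolerance = 1e-4,
               ignore_attr = TRUE)
})
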