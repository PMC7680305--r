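sim_logistic <- function(n = 200, p_noise = 10, beta = c(1.2, -1), seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * (length(beta) + p_noise)), n)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  eta <- X[, seq_along(beta), drop = FALSE] %*% beta
  y <- rbinom(n, 1, plogis(eta))
  list(X = X, y = y,
       data = tibble::tibble(as.data.frame(X), label = y,
                             patient_id = sprintf("P%03d", seq_len(n))))
}

test_that("the penalty limits reproduce the null model and the ML fit", {
  s <- sim_logistic(n = 150, p_noise = 0, beta = c(1, -0.8), seed = 2)
  path <- lasso_logistic_path(s$X, s$y)
  # at the top of the path all coefficients vanish and the intercept is the
  # log-odds of the prevalence
  b_top <- as.numeric(coef(path, s = path$lambda[1]))
  expect_equal(b_top[-1], c(0, 0))
  expect_equal(b_top[1], qlogis(mean(s$y)), tolerance = 1e-6)
  # at tiny lambda the solution matches the unpenalized IRLS fit
  b_low <- as.numeric(coef(path, s = 1e-6, exact = TRUE, x = s$X, y = s$y))
  ml <- glm(s$y ~ s$X, family = binomial())
  expect_equal(b_low, unname(coef(ml)), tolerance = 1e-4)
})

test_that("duplicating an informative feature splits its l1 mass", {
  s <- sim_logistic(n = 400, p_noise = 1, beta = c(1.5), seed = 3)
  lam <- 0.02
  single <- as.numeric(coef(lasso_logistic_path(s$X, s$y), s = lam,
                            exact = TRUE, x = s$X, y = s$y))[2]
  Xd <- cbind(s$X, f_dup = s$X[, 1])
  dup <- as.numeric(coef(lasso_logistic_path(Xd, s$y), s = lam,
                         exact = TRUE, x = Xd, y = s$y))[c(2, 4)]
  expect_equal(sum(dup), single, tolerance = 0.02)
})

test_that("cross-validated selection is deterministic and recovers support", {
  s <- sim_logistic(n = 200, p_noise = 50, beta = c(1.5, -1.5, 1.2), seed = 4)
  m1 <- fit_lasso(s$data, paste0("f", 1:53), seed = 9)
  m2 <- fit_lasso(s$data, paste0("f", 1:53), seed = 9)
  expect_equal(m1$lambda, m2$lambda)
  expect_identical(names(m1$beta), names(m2$beta))

  # pure-noise features: lambda lands near the top of the path
  set.seed(5)
  noise <- tibble::tibble(as.data.frame(matrix(rnorm(150 * 20), 150)),
                          label = rbinom(150, 1, 0.5))
  names(noise)[1:20] <- paste0("g", 1:20)
  mn <- fit_lasso(noise, paste0("g", 1:20), group_col = NULL, seed = 1)
  expect_lte(length(mn$beta), 3)

  # support recovery: >= 2 of the 3 informative features in >= 80% of seeds
  hits <- vapply(1:10, function(sd) {
    si <- sim_logistic(n = 200, p_noise = 50, beta = c(1.5, -1.5, 1.2),
                       seed = 100 + sd)
    m <- fit_lasso(si$data, paste0("f", 1:53), seed = sd)
    sum(paste0("f", 1:3) %in% names(m$beta)) >= 2
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("patient-grouped folds never split a patient", {
  y <- rbinom(60, 1, 0.6)
  grp <- rep(sprintf("P%02d", 1:20), each = 3)
  fold <- cv_folds(y, n_folds = 5, group = grp, seed = 3)
  expect_true(all(tapply(fold, grp, function(f) length(unique(f))) == 1))
  expect_identical(fold, cv_folds(y, n_folds = 5, group = grp, seed = 3))
})

test_that("conventional logistic models reproduce the 2x2 odds ratio", {
  # contingency-equivalent binary covariate
  d <- tibble::tibble(
    short_diameter_mm = rep(c(1, 0), c(40, 60)),
    label = c(rep(1, 30), rep(0, 10), rep(1, 20), rep(0, 40)))
  m <- fit_conventional(d, "short_diameter_mm")
  or_hand <- (30 * 40) / (10 * 20)
  expect_equal(m$summary$odds_ratio, or_hand, tolerance = 1e-6)

  # independent covariate, large n -> OR near 1
  set.seed(6)
  d2 <- tibble::tibble(suvmax = rnorm(2000), label = rbinom(2000, 1, 0.5))
  m2 <- fit_conventional(d2, "suvmax")
  expect_lt(abs(m2$summary$odds_ratio - 1), 0.15)

  # perfect separation -> flagged unstable with unbounded CI
  d3 <- tibble::tibble(expert_rating = c(1, 1, 2, 2, 4, 4, 5, 5),
                       label = c(0, 0, 0, 0, 1, 1, 1, 1))
  m3 <- fit_conventional(d3, "expert_rating")
  expect_true(m3$summary$unstable)
  expect_equal(m3$summary$ci_low, 0)
  expect_equal(m3$summary$ci_high, Inf)
})

test_that("maxstat finds the separating cutpoint and matches enumeration", {
  sc <- c(1, 2, 3, 10, 11, 12)
  y <- c(0, 0, 0, 1, 1, 1)
  res <- maxstat_cutpoint(sc, y)
  expect_gt(res$cutpoint, 3)
  expect_lt(res$cutpoint, 10)

  # exhaustive check on a 12-point sample: the returned maximum equals the
  # best standardized two-sample statistic over all admissible splits
  set.seed(7)
  sc2 <- round(rnorm(12), 2)
  y2 <- rbinom(12, 1, 0.5)
  if (length(unique(y2)) < 2) y2[1] <- 1 - y2[1]
  res2 <- maxstat_cutpoint(sc2, y2)
  n <- length(sc2)
  a <- rank(y2); abar <- mean(a); va <- sum((a - abar)^2)
  best <- -Inf; best_cut <- NA
  us <- sort(unique(sc2))
  for (ct in (us[-1] + us[-length(us)]) / 2) {
    m <- sum(sc2 <= ct)
    if (m / n < 0.1 || m / n > 0.9) next
    s <- sum(a[sc2 <= ct])
    stat <- abs(s - m * abar) / sqrt(m * (n - m) * va / (n * (n - 1)))
    if (stat > best) { best <- stat; best_cut <- ct }
  }
  expect_equal(res2$statistic, best, tolerance = 1e-12)
  expect_equal(res2$cutpoint, best_cut)

  expect_error(maxstat_cutpoint(rep(1, 5), c(0, 1, 0, 1, 0)),
               class = "lnrad_bad_parameter")
})

test_that("permuting the labels kills the maxstat significance", {
  set.seed(8)
  sc <- rnorm(60)
  y <- rbinom(60, 1, 0.5)
  obs <- maxstat_cutpoint(sc, y)$statistic
  perm <- vapply(1:200, function(i) {
    maxstat_cutpoint(sc, sample(y))$statistic
  }, numeric(1))
  # the label-free statistic is a typical draw from its permutation null
  p_perm <- mean(perm >= obs)
  expect_gt(p_perm, 0.01)
})

test_that("model scores are invariant to affine feature rescaling", {
  s <- sim_logistic(n = 150, p_noise = 5, beta = c(1.4, -1.1), seed = 10)
  m <- fit_lasso(s$data, paste0("f", 1:7), seed = 2)
  d2 <- s$data
  d2$f1 <- d2$f1 * 10 + 3
  m2 <- fit_lasso(d2, paste0("f", 1:7), seed = 2)
  expect_equal(predict(m, s$data), predict(m2, d2), tolerance = 1e-6)
})
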