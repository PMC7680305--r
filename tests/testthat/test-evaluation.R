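test_that("AUC equals concordant-pair counting with tie handling", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), class = "lnrad_bad_parameter")

  # exact pair-counting oracle with ties
  set.seed(21)
  s <- sample(1:6, 40, replace = TRUE)
  y <- rbinom(40, 1, 0.5)
  conc <- 0
  for (i in which(y == 1)) for (j in which(y == 0)) {
    conc <- conc + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
  }
  expect_equal(roc_auc(s, y), conc / (sum(y == 1) * sum(y == 0)))

  # monotone-transform invariance
  expect_equal(roc_auc(exp(s / 2), y), roc_auc(s, y))

  skip_if_not_installed("pROC")
  expect_equal(roc_auc(s, y),
               as.numeric(suppressMessages(pROC::auc(y, s))), tolerance = 1e-12)
})

test_that("bootstrap AUC intervals are deterministic and cover known truth", {
  set.seed(22)
  s <- c(rnorm(40, 1), rnorm(40))
  y <- rep(c(1, 0), each = 40)
  r1 <- bootstrap_auc_ci(s, y, B = 300, seed = 5)
  r2 <- bootstrap_auc_ci(s, y, B = 300, seed = 5)
  expect_identical(r1$ci, r2$ci)
  expect_true(r1$ci[1] <= r1$auc && r1$auc <= r1$ci[2])

  # perfect separation: degenerate CI at 1
  rp <- bootstrap_auc_ci(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1),
                         B = 100, seed = 1)
  expect_equal(rp$ci, c(1, 1))

  # coverage of a known AUC ~ 0.76 (normal shift model) at reduced reps
  auc_true <- pnorm(1 / sqrt(2))
  cover <- vapply(1:30, function(i) {
    set.seed(400 + i)
    sc <- c(rnorm(250, 1), rnorm(250))
    yy <- rep(c(1, 0), each = 250)
    ci <- bootstrap_auc_ci(sc, yy, B = 200, seed = i)$ci
    ci[1] <= auc_true && auc_true <= ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.8)
})

test_that("paired AUC comparison is symmetric and calibrated at the extremes", {
  set.seed(23)
  y <- rep(c(1, 0), each = 50)
  a <- c(rnorm(50, 3), rnorm(50))       # near-perfect
  b <- rnorm(100)                        # uninformative
  expect_equal(compare_auc_paired(a, a, y)$p_value, 1)
  res_ab <- compare_auc_paired(a, b, y)
  res_ba <- compare_auc_paired(b, a, y)
  expect_lt(res_ab$p_value, 0.01)
  expect_equal(res_ab$p_value, res_ba$p_value)
  expect_equal(res_ab$delta, -res_ba$delta)
})

test_that("confusion metrics reproduce from integer counts", {
  cm <- confusion_metrics(pred = c(1, 1, 1, 0, 0), y = c(1, 1, 1, 0, 0))
  expect_equal(cm$mcc, 1)
  expect_equal(cm$sensitivity, 1)
  expect_equal(cm$balanced_accuracy, 1)
  # zero-denominator MCC -> 0 with flag
  cm0 <- confusion_metrics(pred = rep(1, 5), y = c(1, 1, 1, 0, 1))
  expect_equal(cm0$mcc, 0)
  expect_true(cm0$mcc_degenerate)
  # rates reproduce from the counts
  cm2 <- confusion_from_counts(tp = 30, fp = 5, fn = 10, tn = 25)
  expect_equal(cm2$sensitivity, 30 / 40)
  expect_equal(cm2$ppv, 30 / 35)
  expect_equal(cm2$mcc,
               (30 * 25 - 5 * 10) / sqrt(35 * 40 * 30 * 35), tolerance = 1e-12)
})

test_that("calibration bins behave on degenerate and calibrated inputs", {
  c1 <- calibration_curve(rep(0, 10), rep(0, 10))
  expect_equal(nrow(c1), 1)
  expect_equal(c1$observed_fraction, 0)
  c2 <- calibration_curve(rep(0.5, 40), rbinom(40, 1, 0.7))
  expect_equal(nrow(c2), 1)
  expect_equal(c2$mean_predicted, 0.5)
  set.seed(24)
  p <- runif(2000)
  y <- rbinom(2000, 1, p)
  c3 <- calibration_curve(p, y)
  expect_lt(max(abs(c3$observed_fraction - c3$mean_predicted)), 0.1)
})

test_that("decision curves obey the closed-form identities", {
  set.seed(25)
  y <- rbinom(200, 1, 0.7)
  pi_hat <- mean(y)
  p_perfect <- as.numeric(y)
  dc <- decision_curve(p_perfect, y, thresholds = c(0.1, 0.3, 0.5, 0.8))
  expect_equal(dc$nb_model, rep(pi_hat, 4))             # perfect classifier
  expect_equal(dc$nb_none, rep(0, 4))
  expect_equal(dc$nb_all,
               pi_hat - (1 - pi_hat) * dc$threshold / (1 - dc$threshold))
  # no classifier beats prevalence
  p_rand <- runif(200)
  dcr <- decision_curve(p_rand, y)
  expect_true(all(dcr$nb_model <= pi_hat + 1e-12))
  # when the threshold admits every node the model equals treat-all
  dc0 <- decision_curve(rep(1, 200), y, thresholds = 0.4)
  expect_equal(dc0$nb_model, dc0$nb_all)
  expect_error(decision_curve(p_rand, y, thresholds = 1),
               class = "lnrad_bad_parameter")
})

test_that("the reconstructed short-diameter table gives the stated net benefit", {
  cm <- reconstruct_confusion(0.35, 1.00, 49, 13)
  n <- 62
  nb <- cm$TP / n - cm$FP / n * 0.5 / (1 - 0.5)
  expect_equal(nb, 17 / 62, tolerance = 1e-12)
})

test_that("univariate screening holds its size and matches exact enumeration", {
  # exact small-sample p by full permutation enumeration
  p_pkg <- univariate_screen(tibble::tibble(firstorder_Mean = c(1, 2, 3, 4, 5, 6)),
                             y = c(0, 0, 0, 1, 1, 1))$p_value
  p_exact <- oracle_wilcoxon_exact(c(4, 5, 6), c(1, 2, 3))
  expect_equal(p_pkg, p_exact, tolerance = 1e-12)

  # Bonferroni is capped at 1
  expect_equal(min(1, 0.01 * 156), 1)
  set.seed(26)
  tab <- tibble::as_tibble(as.data.frame(matrix(rnorm(200 * 30), 200)))
  names(tab) <- paste0("glcm_F", 1:30)
  scr <- univariate_screen(tab, rbinom(200, 1, 0.5))
  expect_true(all(scr$p_adjusted <= 1))

  # type-I error of the raw test near 5% on null features
  set.seed(27)
  y <- rep(c(0, 1), each = 100)
  raw_p <- vapply(1:300, function(i) {
    v <- rnorm(200)
    stats::wilcox.test(v[y == 1], v[y == 0])$p.value
  }, numeric(1))
  expect_lt(abs(mean(raw_p < 0.05) - 0.05), 0.03)

  # constant feature flagged with p = 1
  scr2 <- univariate_screen(tibble::tibble(shape_Flatness = rep(2, 20)),
                            y = rep(c(0, 1), 10))
  expect_equal(scr2$p_value, 1)
  expect_true(scr2$degenerate)
})

test_that("Spearman screening flags volume-coupled features", {
  set.seed(28)
  vol <- exp(rnorm(50))
  tab <- tibble::tibble(shape_MeshVolume = vol,
                        glcm_Contrast = -vol,
                        `lbp-k_Mean` = rnorm(50))
  sp <- spearman_to_volume(tab, vol)
  expect_equal(sp$rho[sp$feature == "shape_MeshVolume"], 1)
  expect_equal(sp$rho[sp$feature == "glcm_Contrast"], -1)
  expect_true(sp$volume_correlated[1])
  expect_false(sp$volume_correlated[3])

  # midrank ties against a hand computation
  x <- c(1, 2, 2, 3)
  v <- c(10, 20, 30, 40)
  rho_hand <- stats::cor(c(1, 2.5, 2.5, 4), rank(v))
  sp2 <- spearman_to_volume(tibble::tibble(firstorder_Mean = x), v)
  expect_equal(sp2$rho, rho_hand, tolerance = 1e-12)
})
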