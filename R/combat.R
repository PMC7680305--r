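#' Fit parametric empirical-Bayes batch harmonization (ComBat)
#'
#' Estimates, per feature, a grand mean and pooled variance, and per batch
#' an additive location and multiplicative scale, shrunken across features
#' by the parametric empirical-Bayes scheme: batch locations get a normal
#' prior, batch scales an inverse-gamma prior, with hyperparameters
#' estimated by moments and the posterior solved by the standard fixed-point
#' iteration. Fitting is label-blind (no biological covariates in the
#' design); the outcome column is never touched.
#'
#' @param features a data frame (feature table); feature columns are all
#'   numeric columns named by `feature_names`, metadata is ignored.
#' @param batch character/factor vector of batch (scanner) labels, one per
#'   row.
#' @param feature_names which columns to harmonize (default: panel-named
#'   numeric columns).
#' @param eb use empirical-Bayes shrinkage (default `TRUE`; `FALSE` gives
#'   per-batch location/scale without shrinkage).
#' @param tol,max_iter convergence control of the EB fixed-point iteration.
#' @return An object of class `combat_params`.
#' @export
combat_fit <- function(features, batch, feature_names = NULL, eb = TRUE,
                       tol = 1e-6, max_iter = 100) {
  if (is.null(feature_names)) {
    feature_names <- names(features)[feature_class(names(features)) != "other"]
  }
  X <- as.matrix(features[, feature_names, drop = FALSE])
  if (any(!is.finite(X))) {
    rlang::abort("feature table contains missing or non-finite values.",
                 class = "lnrad_bad_parameter")
  }
  batch <- as.character(batch)
  if (length(batch) != nrow(X)) {
    rlang::abort("`batch` must have one label per row.",
                 class = "lnrad_bad_parameter")
  }
  tb <- table(batch)
  if (any(tb < 2)) {
    rlang::abort(paste0("singleton batch: ",
                        paste(names(tb)[tb < 2], collapse = ", ")),
                 class = "lnrad_singleton_batch")
  }
  levels_b <- names(tb)
  n <- nrow(X)
  # drop constant features from harmonization (passed through unchanged)
  sds <- apply(X, 2, stats::sd)
  active <- sds > 0
  Xa <- X[, active, drop = FALSE]
  bm <- do.call(rbind, lapply(levels_b, function(b) {
    colMeans(Xa[batch == b, , drop = FALSE])
  }))
  rownames(bm) <- levels_b
  wts <- as.numeric(tb[levels_b]) / n
  grand <- colSums(bm * wts)
  resid <- Xa - bm[batch, , drop = FALSE]
  pooled_var <- colSums(resid^2) / n
  pooled_var[pooled_var <= 0] <- 1e-12
  Z <- sweep(sweep(Xa, 2, grand), 2, sqrt(pooled_var), "/")
  gamma_hat <- do.call(rbind, lapply(levels_b, function(b) {
    colMeans(Z[batch == b, , drop = FALSE])
  }))
  delta_hat <- do.call(rbind, lapply(levels_b, function(b) {
    apply(Z[batch == b, , drop = FALSE], 2, stats::var)
  }))
  rownames(gamma_hat) <- rownames(delta_hat) <- levels_b
  delta_hat[delta_hat <= 0] <- 1e-12
  if (eb && ncol(Xa) >= 2) {
    gamma_star <- gamma_hat
    delta_star <- delta_hat
    for (b in levels_b) {
      nb <- as.numeric(tb[b])
      g <- gamma_hat[b, ]; d <- delta_hat[b, ]
      g_bar <- mean(g); t2 <- stats::var(g)
      dm <- mean(d); dv <- stats::var(d)
      a_prior <- (2 * dv + dm^2) / dv
      b_prior <- (dm * dv + dm^3) / dv
      Zb <- Z[batch == b, , drop = FALSE]
      g_new <- g; d_new <- d
      for (it in seq_len(max_iter)) {
        g_old <- g_new; d_old <- d_new
        g_new <- (nb * t2 * g + d_new * g_bar) / (nb * t2 + d_new)
        ss <- colSums((Zb - matrix(g_new, nb, length(g_new), byrow = TRUE))^2)
        d_new <- (b_prior + 0.5 * ss) / (nb / 2 + a_prior - 1)
        ch <- max(abs(g_new - g_old) / (abs(g_old) + 1e-12),
                  abs(d_new - d_old) / (abs(d_old) + 1e-12))
        if (ch < tol) break
      }
      gamma_star[b, ] <- g_new
      delta_star[b, ] <- d_new
    }
  } else {
    gamma_star <- gamma_hat
    delta_star <- delta_hat
  }
  structure(list(features = feature_names, active = active,
                 batches = levels_b, grand_mean = grand,
                 pooled_var = pooled_var, gamma = gamma_star,
                 delta2 = delta_star, eb = eb),
            class = "combat_params")
}

#' Apply fitted ComBat parameters to a feature table
#'
#' Adjusted value: `((z - gamma) / delta) * pooled_sd + grand_mean` with
#' `z` the feature standardized by the fit's grand mean and pooled SD.
#' Metadata columns (including the outcome label) pass through untouched.
#' Batches unseen at fit time are an explicit error.
#'
#' @param features a data frame containing the fitted feature columns.
#' @param params a `combat_params` object from [combat_fit()].
#' @param batch batch label per row.
#' @return the feature table with harmonized feature columns.
#' @export
combat_apply <- function(features, params, batch) {
  stopifnot(inherits(params, "combat_params"))
  batch <- as.character(batch)
  unseen <- setdiff(unique(batch), params$batches)
  if (length(unseen) > 0) {
    rlang::abort(paste0("batch not seen at fit time: ",
                        paste(unseen, collapse = ", ")),
                 class = "lnrad_unseen_batch")
  }
  act <- params$features[params$active]
  X <- as.matrix(features[, act, drop = FALSE])
  Z <- sweep(sweep(X, 2, params$grand_mean), 2, sqrt(params$pooled_var), "/")
  g <- params$gamma[batch, , drop = FALSE]
  d <- sqrt(params$delta2[batch, , drop = FALSE])
  Zadj <- (Z - g) / d
  Xadj <- sweep(sweep(Zadj, 2, sqrt(params$pooled_var), "*"), 2,
                params$grand_mean, "+")
  out <- features
  out[, act] <- as.data.frame(Xadj)
  out
}

#' @export
print.combat_params <- function(x, ...) {
  cat(sprintf("<combat_params> %d features (%d harmonized), %d batches: %s\n",
              length(x$features), sum(x$active), length(x$batches),
              paste(x$batches, collapse = ", ")))
  invisible(x)
}
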