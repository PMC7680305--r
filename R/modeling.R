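#' LASSO-penalized logistic coefficient path
#'
#' Thin wrapper around glmnet's cyclic coordinate descent: the l1-penalized
#' binomial likelihood over a geometric lambda grid starting at the
#' all-zero solution. Features are standardized internally; coefficients
#' are reported on the original scale.
#'
#' @param x numeric matrix (or data frame) of features.
#' @param y binary outcome (0/1).
#' @param lambda optional lambda grid (decreasing); default glmnet's.
#' @param ... passed to [glmnet::glmnet()].
#' @return the glmnet fit object (class `glmnet`).
#' @export
lasso_logistic_path <- function(x, y, lambda = NULL, ...) {
  x <- as.matrix(x)
  glmnet::glmnet(x, y, family = "binomial", alpha = 1, lambda = lambda,
                 standardize = TRUE, ...)
}

#' Stratified, optionally patient-grouped, CV fold assignment
#'
#' Builds fold ids for 10-fold CV. With `group` given (patient ids), whole
#' patients are assigned to folds, ordered by their positive-node count so
#' both classes spread evenly; multiple nodes of one patient never straddle
#' a fold boundary. Without groups, folds are stratified by class.
#'
#' @param y binary outcome.
#' @param n_folds number of folds (default 10).
#' @param group optional grouping vector (e.g. patient id).
#' @param seed integer seed for the fold shuffle.
#' @return integer vector of fold ids in `1..n_folds`.
#' @export
cv_folds <- function(y, n_folds = 10, group = NULL, seed = 1) {
  with_preserved_seed(seed, {
    if (is.null(group)) {
      fold <- integer(length(y))
      for (cls in unique(y)) {
        idx <- sample(which(y == cls))
        fold[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
      fold
    } else {
      gs <- split(seq_along(y), group)
      pos <- vapply(gs, function(i) sum(y[i]), numeric(1))
      ord <- order(pos + stats::runif(length(pos)) * 0.5)
      fold_of_group <- integer(length(gs))
      fold_of_group[ord] <- rep_len(sample(seq_len(n_folds)), length(gs))
      fold <- integer(length(y))
      for (j in seq_along(gs)) fold[gs[[j]]] <- fold_of_group[j]
      fold
    }
  })
}

#' Fit a cross-validated LASSO logistic model
#'
#' Selects lambda by 10-fold cross-validated binomial deviance (the
#' `lambda.min` rule by default; `"1se"` optional) and refits on the full
#' training data. Fold assignment is seed-deterministic and, when `group`
#' is supplied, patient-grouped.
#'
#' @param data training feature table (data frame).
#' @param features character vector of feature column names.
#' @param y_col outcome column name (default `"label"`).
#' @param group_col optional grouping column for folds (default
#'   `"patient_id"` when present).
#' @param n_folds,seed CV control.
#' @param rule `"min"` or `"1se"`.
#' @param name model name.
#' @return An object of class `lnm_model`: intercept, sparse coefficients,
#'   selected lambda, CV curve, and (once set) the decision cutpoint.
#' @export
fit_lasso <- function(data, features, y_col = "label", group_col = NULL,
                      n_folds = 10, seed = 1, rule = c("min", "1se"),
                      name = "radiomics") {
  rule <- match.arg(rule)
  if (is.null(group_col) && "patient_id" %in% names(data)) {
    group_col <- "patient_id"
  }
  missing_f <- setdiff(features, names(data))
  if (length(missing_f) > 0) {
    rlang::abort(paste0("features not in data: ",
                        paste(utils::head(missing_f, 3), collapse = ", ")),
                 class = "lnrad_bad_parameter")
  }
  X <- as.matrix(data[, features, drop = FALSE])
  y <- data[[y_col]]
  keep <- apply(X, 2, function(v) stats::sd(v) > 0)
  if (!all(keep)) {
    rlang::warn(paste0(sum(!keep), " constant feature(s) dropped before fitting."))
  }
  X <- X[, keep, drop = FALSE]
  if (ncol(X) == 0) {
    rlang::abort("no usable features left.", class = "lnrad_bad_parameter")
  }
  if (ncol(X) == 1) {
    # a one-feature "panel" needs no selection: unpenalized ML fit
    df <- data.frame(y = y, x = X[, 1])
    fit <- withCallingHandlers(
      stats::glm(y ~ x, data = df, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities|did not converge",
                  conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    cf <- stats::coef(fit)
    return(structure(list(name = name, type = "lasso",
                          features = colnames(X),
                          intercept = unname(cf[1]),
                          beta = stats::setNames(unname(cf[2]), colnames(X)),
                          lambda = 0, rule = rule,
                          cv_lambda = numeric(0), cv_deviance = numeric(0),
                          cutpoint = NULL, seed = seed, n_folds = n_folds),
                     class = "lnm_model"))
  }
  fold <- cv_folds(y, n_folds = n_folds,
                   group = if (!is.null(group_col)) data[[group_col]],
                   seed = seed)
  # every fold must retain both classes; re-stratify grouped folds if not
  for (attempt in 1:20) {
    ok <- all(vapply(seq_len(n_folds), function(f) {
      length(unique(y[fold != f])) == 2 && sum(fold == f) > 0
    }, logical(1)))
    if (ok) break
    fold <- cv_folds(y, n_folds = n_folds,
                     group = if (!is.null(group_col)) data[[group_col]],
                     seed = seed + attempt * 1000L)
  }
  if (!ok) {
    rlang::abort("could not build folds with both classes present.",
                 class = "lnrad_bad_folds")
  }
  cv <- withCallingHandlers(
    glmnet::cv.glmnet(X, y, family = "binomial", alpha = 1,
                      type.measure = "deviance", foldid = fold,
                      standardize = TRUE, lambda.min.ratio = 1e-3),
    warning = function(w) {
      # glmnet truncates the path on (near-)separable fits; the solutions
      # for the retained lambdas are valid
      if (grepl("from glmnet|fewer than 8|grouped=FALSE", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  lambda <- if (rule == "min") cv$lambda.min else cv$lambda.1se
  cf <- as.numeric(stats::coef(cv$glmnet.fit, s = lambda))
  names(cf) <- c("(Intercept)", colnames(X))
  beta <- cf[-1]
  structure(list(name = name, type = "lasso",
                 features = colnames(X),
                 intercept = cf[1],
                 beta = beta[beta != 0],
                 lambda = lambda, rule = rule,
                 cv_lambda = cv$lambda, cv_deviance = cv$cvm,
                 cutpoint = NULL, seed = seed, n_folds = n_folds),
            class = "lnm_model")
}

#' Fit a conventional-parameter logistic model
#'
#' Plain maximum-likelihood logistic regression for one or several given
#' covariates (short diameter, volume, expert rating, SUVmax, or a
#' radiomic linear predictor), with odds ratios, Wald CIs and p-values.
#' Complete or quasi-complete separation is detected and flagged; the CI
#' of an unstable covariate is reported as (0, Inf).
#'
#' @param data data frame.
#' @param covariates character vector of covariate column names.
#' @param y_col outcome column (default `"label"`).
#' @param name model name.
#' @return An `lnm_model` of type `"logistic"` with a `summary` tibble
#'   (term, estimate, odds ratio, CI, p, unstable flag).
#' @export
fit_conventional <- function(data, covariates, y_col = "label",
                             name = covariates[1]) {
  fml <- stats::as.formula(paste(y_col, "~",
                                 paste(sprintf("`%s`", covariates),
                                       collapse = " + ")))
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = data, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  sm <- summary(fit)$coefficients
  est <- sm[-1, 1]
  se <- sm[-1, 2]
  unstable <- sep_warn | (abs(est) > 10 & se > 10)
  lo <- exp(est - 1.96 * se)
  hi <- exp(est + 1.96 * se)
  lo[unstable] <- 0
  hi[unstable] <- Inf
  tab <- tibble::tibble(term = rownames(sm)[-1],
                        estimate = est,
                        odds_ratio = exp(est),
                        ci_low = lo, ci_high = hi,
                        p_value = sm[-1, 4],
                        unstable = unstable)
  cf <- stats::coef(fit)
  structure(list(name = name, type = "logistic",
                 features = covariates,
                 intercept = cf[1], beta = cf[-1],
                 lambda = NA_real_, summary = tab, fit = fit,
                 cutpoint = NULL),
            class = "lnm_model")
}

#' Linear-predictor scores from a fitted model
#'
#' @param object an `lnm_model`.
#' @param newdata data frame containing the model's feature columns.
#' @param type `"link"` (linear predictor), `"prob"`, or `"class"`
#'   (requires a cutpoint; thresholds the linear predictor).
#' @param ... unused.
#' @export
predict.lnm_model <- function(object, newdata, type = c("link", "prob", "class"),
                              ...) {
  type <- match.arg(type)
  if (object$type == "logistic") {
    feats <- names(object$beta)
    feats <- gsub("^`|`$", "", feats)
    X <- as.matrix(newdata[, object$features, drop = FALSE])
    eta <- drop(object$intercept + X %*% object$beta)
  } else {
    active <- names(object$beta)
    eta <- rep(object$intercept, nrow(newdata))
    if (length(active) > 0) {
      X <- as.matrix(newdata[, active, drop = FALSE])
      eta <- drop(object$intercept + X %*% object$beta)
    }
  }
  switch(type,
         link = eta,
         prob = stats::plogis(eta),
         class = {
           if (is.null(object$cutpoint)) {
             rlang::abort("model has no cutpoint set.",
                          class = "lnrad_bad_parameter")
           }
           as.integer(eta >= object$cutpoint)
         })
}

#' @export
print.lnm_model <- function(x, ...) {
  cat(sprintf("<lnm_model '%s'> type %s, %d feature(s), %d nonzero\n",
              x$name, x$type, length(x$features), length(x$beta)))
  if (!is.na(x$lambda)) cat(sprintf("  lambda = %.5g (%s rule)\n", x$lambda, x$rule))
  if (!is.null(x$cutpoint)) cat(sprintf("  cutpoint = %.4g\n", x$cutpoint))
  invisible(x)
}

#' Maximally selected rank-statistic cutpoint
#'
#' Scans candidate cutpoints (midpoints between consecutive distinct
#' scores whose split proportion lies in the inner `minprop`-`maxprop`
#' range) and returns the split maximizing the absolute standardized
#' two-sample linear rank statistic of the outcome.
#'
#' @param scores numeric scores.
#' @param y binary outcome.
#' @param minprop,maxprop admissible split proportion range (default
#'   0.1-0.9).
#' @return list with `cutpoint`, `statistic` (the maximum standardized
#'   statistic) and the per-candidate table.
#' @export
maxstat_cutpoint <- function(scores, y, minprop = 0.1, maxprop = 0.9) {
  if (length(unique(scores)) < 2) {
    rlang::abort("all scores tied; no cutpoint exists.",
                 class = "lnrad_bad_parameter")
  }
  if (length(unique(y)) < 2) {
    rlang::abort("both classes must be present.", class = "lnrad_bad_parameter")
  }
  n <- length(scores)
  a <- rank(y)  # rank scores of the outcome (binary -> affine in y)
  abar <- mean(a)
  va <- sum((a - abar)^2)
  us <- sort(unique(scores))
  cand <- (us[-1] + us[-length(us)]) / 2
  stats_tab <- purrr::map_dfr(cand, function(ct) {
    low <- scores <= ct
    m <- sum(low)
    prop <- m / n
    if (prop < minprop || prop > maxprop) {
      return(tibble::tibble(cutpoint = ct, statistic = NA_real_))
    }
    s <- sum(a[low])
    es <- m * abar
    vs <- m * (n - m) * va / (n * (n - 1))
    tibble::tibble(cutpoint = ct,
                   statistic = if (vs > 0) abs(s - es) / sqrt(vs) else 0)
  })
  ok <- which(!is.na(stats_tab$statistic))
  if (length(ok) == 0) {
    rlang::abort("no admissible cutpoint in the inner proportion range.",
                 class = "lnrad_bad_parameter")
  }
  best <- ok[which.max(stats_tab$statistic[ok])]
  list(cutpoint = stats_tab$cutpoint[best],
       statistic = stats_tab$statistic[best],
       candidates = stats_tab)
}

#' Set the decision cutpoint of a model from training scores
#'
#' @param model an `lnm_model`.
#' @param data training data.
#' @param y_col outcome column.
#' @return the model with `cutpoint` set (on the linear-predictor scale).
#' @export
set_cutpoint <- function(model, data, y_col = "label") {
  sc <- predict(model, data, type = "link")
  if (length(unique(sc)) < 2) {
    # null model (no selected features): every node gets the same score, so
    # the decision rule degenerates to the majority call at that score
    model$cutpoint <- sc[1]
    model$cutpoint_degenerate <- TRUE
    return(model)
  }
  model$cutpoint <- maxstat_cutpoint(sc, data[[y_col]])$cutpoint
  model
}
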