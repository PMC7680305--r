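#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted lymph-node model
#'
#' One row per (nonzero) model term: LASSO models report the sparse
#' coefficients on the original feature scale; logistic models report odds
#' ratios with Wald CIs and p-values.
#'
#' @param x an `lnm_model`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.lnm_model <- function(x, ...) {
  if (x$type == "logistic") {
    return(x$summary)
  }
  tibble::tibble(term = c("(Intercept)", names(x$beta)),
                 estimate = unname(c(x$intercept, x$beta)),
                 class = c(NA_character_, feature_class(names(x$beta))))
}

#' One-row model summary
#'
#' @param x an `lnm_model`.
#' @param ... unused.
#' @return a one-row tibble: name, type, number of input and selected
#'   features, lambda and cutpoint (where applicable).
#' @export
glance.lnm_model <- function(x, ...) {
  tibble::tibble(name = x$name, type = x$type,
                 n_features = length(x$features),
                 n_selected = length(x$beta),
                 lambda = x$lambda,
                 cutpoint = x$cutpoint %||% NA_real_)
}

#' @rdname tidy.lnm_model
#' @export
tidy.lnm_roc <- function(x, ...) x$points

#' @rdname glance.lnm_model
#' @export
glance.lnm_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, ci_low = x$ci[1], ci_high = x$ci[2],
                 level = x$level, B = x$B)
}
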