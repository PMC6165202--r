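# broom-style accessors for the fitted objects.

#' Tidy a cross-validation result
#'
#' One row per evaluated fold.
#'
#' @param x An `eeg_cv`.
#' @param ... Ignored.
#' @return Tibble with `rep`, `fold`, `n_test`, `accuracy`.
#' @export
tidy.eeg_cv <- function(x, ...) x$folds

#' One-row summary of a cross-validation result
#'
#' @param x An `eeg_cv`.
#' @param ... Ignored.
#' @return Tibble with `mean_acc`, `sd_acc`, `k`, `reps`, `n_trials`.
#' @export
glance.eeg_cv <- function(x, ...) {
  tibble::tibble(mean_acc = x$mean, sd_acc = x$sd, k = x$k, reps = x$reps,
                 n_trials = x$n_trials)
}

#' Tidy a CSP model
#'
#' One row per spatial filter component.
#'
#' @param x A `csp_model`.
#' @param ... Ignored.
#' @return Tibble with `component`, `eigenvalue`, `selected`.
#' @export
tidy.csp_model <- function(x, ...) {
  tibble::tibble(component = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues,
                 selected = seq_along(x$eigenvalues) %in% x$selected)
}

#' Tidy a shrinkage-LDA model
#'
#' One row per feature weight.
#'
#' @param x An `slda_model`.
#' @param ... Ignored.
#' @return Tibble with `feature`, `weight`.
#' @export
tidy.slda_model <- function(x, ...) {
  nm <- names(x$w)
  if (is.null(nm)) nm <- paste0("f", seq_along(x$w))
  tibble::tibble(feature = nm, weight = unname(x$w))
}

#' One-row summary of a shrinkage-LDA model
#'
#' @param x An `slda_model`.
#' @param ... Ignored.
#' @return Tibble with `gamma`, `nu`, `bias`, `n_features`.
#' @export
glance.slda_model <- function(x, ...) {
  tibble::tibble(gamma = x$gamma, nu = x$nu, bias = x$b,
                 n_features = length(x$w))
}
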