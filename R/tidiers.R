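#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a model fit
#'
#' @param x An [fit_model()] result.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`, and
#'   `conf.low`/`conf.high` when a bootstrap CI has been attached
#'   ([attach_ci()]).
#' @export
tidy.adapt_fit <- function(x, ...) {
  out <- tibble::tibble(term = names(x$estimate),
                        estimate = unname(x$estimate))
  if (!is.null(x$ci)) out <- dplyr::left_join(out, x$ci, by = "term")
  out
}

#' Glance at a model fit
#'
#' @inheritParams tidy.adapt_fit
#' @return A one-row tibble: `model_kind`, `r.squared`, `sigma2`, `bic`,
#'   `n_trials`, `n_params`, `n_starts`, `converged`.
#' @export
glance.adapt_fit <- function(x, ...) {
  tibble::tibble(model_kind = x$model_kind, r.squared = x$r_squared,
                 sigma2 = x$residual_variance, bic = x$bic,
                 n_trials = x$n_trials, n_params = x$n_params,
                 n_starts = x$n_starts, converged = x$converged)
}

#' Attach bootstrap confidence intervals to a fit
#'
#' @param fit An [fit_model()] result.
#' @param ci A [bootstrap_ci()] result.
#' @return The fit with `ci` set (shown by [tidy.adapt_fit()]).
#' @export
attach_ci <- function(fit, ci) {
  fit$ci <- ci
  fit
}

#' @export
print.adapt_fit <- function(x, ...) {
  cat(sprintf("<adapt_fit %s> R^2 = %.4f, BIC = %.2f, %d trials\n",
              x$model_kind, x$r_squared, x$bic, x$n_trials))
  print(tidy(x))
  invisible(x)
}
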