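#' Single-rate model parameters
#'
#' The single-rate state-space model (SRM) keeps one internal state `x`, the
#' learner's estimate of the object's mass (dimensionless, expressed relative
#' to the standard 1% body-mass object). On each trial the state decays by the
#' retention constant and is incremented by a fraction of the trial error:
#' `x(n+1) = alpha * x(n) + beta * e(n)`, with `e(n) = f(n) - x(n)`.
#'
#' @param alpha Retention constant, in `[0, 1]`: fraction of the state carried
#'   to the next trial absent error.
#' @param beta Learning-rate constant, in `[0, 1]`: fraction of the trial error
#'   added to the state.
#' @return An object of class `srm_params`.
#' @examples
#' srm_params(alpha = 0.9513, beta = 0.2150)
#' @export
srm_params <- function(alpha, beta) {
  check_unit_interval(c(alpha = alpha, beta = beta))
  structure(list(alpha = alpha, beta = beta), class = c("srm_params", "adapt_params"))
}

#' Dual-rate model parameters
#'
#' The dual-rate model (DRM) keeps two states that adapt in parallel with
#' separate retention and learning rates and sum to the net output. By the
#' usual convention state 1 is the slow process (smaller learning rate) and
#' state 2 the fast process; `drm_params()` enforces `beta2 >= beta1` by
#' relabeling.
#'
#' @param alpha1,beta1 Retention and learning rate of the slow state.
#' @param alpha2,beta2 Retention and learning rate of the fast state.
#' @return An object of class `drm_params`.
#' @examples
#' drm_params(0.9808, 0.0139, 0.9453, 0.2053)
#' @export
drm_params <- function(alpha1, beta1, alpha2, beta2) {
  check_unit_interval(c(alpha1 = alpha1, beta1 = beta1,
                        alpha2 = alpha2, beta2 = beta2))
  if (beta1 > beta2) {   # relabel so that state 2 is the fast learner
    tmp <- c(alpha1, beta1); alpha1 <- alpha2; beta1 <- beta2
    alpha2 <- tmp[1]; beta2 <- tmp[2]
  }
  structure(list(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2, beta2 = beta2),
            class = c("drm_params", "adapt_params"))
}

#' Multiple-context single-rate model parameters
#'
#' The multiple-context SRM (MCSRM) keeps a 16-element state vector `z`, one
#' state per visual-orientation context at 22.5 degree spacing. A
#' context-selection vector `c` (the generalization function, see
#' [tuning_vector()]) weights how much each context contributes to the net
#' output `x = c . z` and how much credit each context receives for the trial
#' error. Two tunings are supported:
#'
#' * `MCSRM4`: Gaussian tuning with width `sigma_deg` and offset `d`
#'   (value of the tuning at 180 degrees away); 4 free parameters in total.
#' * `MCSRM10`: the 8 tuning weights at absolute lags 22.5..180 degrees are
#'   free parameters (lag-0 weight fixed at 1); 10 free parameters in total.
#'
#' @param alpha,beta Retention and learning-rate constants, in `[0, 1]`.
#' @param sigma_deg Gaussian tuning width in degrees (> 0). Supply together
#'   with `offset` for MCSRM4.
#' @param offset Tuning value at +/-180 degrees, in `[0, 1]` (MCSRM4).
#' @param weights Numeric vector of 8 tuning weights for absolute lags
#'   22.5, 45, ..., 180 degrees, each in `[0, 1]` (MCSRM10). Supply instead of
#'   `sigma_deg`/`offset`.
#' @return An object of class `mcsrm_params` with a `tuning` element of class
#'   `"gaussian"` or `"free"`.
#' @examples
#' mcsrm_params(0.9811, 0.0451, sigma_deg = 26.3, offset = 0.09)
#' @export
mcsrm_params <- function(alpha, beta, sigma_deg = NULL, offset = NULL,
                         weights = NULL) {
  check_unit_interval(c(alpha = alpha, beta = beta))
  if (!is.null(weights)) {
    if (!is.null(sigma_deg) || !is.null(offset)) {
      abort("supply either sigma_deg/offset (MCSRM4) or weights (MCSRM10), not both")
    }
    if (length(weights) != 8L) abort("weights must have length 8 (lags 22.5..180 deg)")
    check_unit_interval(setNames(weights, paste0("w", 1:8)))
    tuning <- structure(list(weights = as.numeric(weights)), class = "free")
  } else {
    if (is.null(sigma_deg) || is.null(offset)) {
      abort("MCSRM4 requires both sigma_deg and offset")
    }
    if (sigma_deg <= 0) abort("sigma_deg must be > 0")
    check_unit_interval(c(offset = offset))
    tuning <- structure(list(sigma_deg = sigma_deg, offset = offset),
                        class = "gaussian")
  }
  structure(list(alpha = alpha, beta = beta, tuning = tuning),
            class = c("mcsrm_params", "adapt_params"))
}

#' Compliance profile of the arm
#'
#' Handle displacement per unit of mass-estimate error depends on the
#' direction of the perturbing force, i.e. on the visual orientation of the
#' object, and differs between adaptation (object pushes subject, `k_plus`,
#' used when `f > x`) and de-adaptation (subject pushes object, `k_minus`,
#' used when `f < x`). The profile is calibrated at the five experimental
#' orientations 0, -45, -90, -135 and 180 degrees; values at intermediate
#' on-grid orientations are obtained by circular linear interpolation.
#'
#' @param k_plus,k_minus Positive compliance factors (cm per unit
#'   mass-estimate error) at `orientations`; length 1 (recycled) or
#'   `length(orientations)`.
#' @param gain Dimensionless gain factor `g` multiplying the error output.
#' @param orientations Calibrated orientations in degrees.
#' @return An object of class `compliance_profile`.
#' @examples
#' unit_compliance()
#' compliance_profile(k_plus = c(1, 1.2, 1.4, 1.2, 1), k_minus = 1)
#' @export
compliance_profile <- function(k_plus = 1, k_minus = 1, gain = 1,
                               orientations = c(0, -45, -90, -135, 180)) {
  n <- length(orientations)
  k_plus <- rep_len(as.numeric(k_plus), n)
  k_minus <- rep_len(as.numeric(k_minus), n)
  if (any(k_plus <= 0) || any(k_minus <= 0)) abort("compliance factors must be > 0")
  if (gain <= 0) abort("gain must be > 0")
  structure(list(orientations = wrap_angle(orientations),
                 k_plus = k_plus, k_minus = k_minus, gain = gain),
            class = "compliance_profile")
}

#' @rdname compliance_profile
#' @export
unit_compliance <- function(gain = 1) compliance_profile(gain = gain)

check_unit_interval <- function(x) {
  bad <- !is.finite(x) | x < 0 | x > 1
  if (any(bad)) {
    abort(sprintf("parameter(s) outside [0, 1]: %s",
                  paste(names(x)[bad], collapse = ", ")))
  }
  invisible(x)
}

#' @export
print.adapt_params <- function(x, ...) {
  kind <- model_kind_of(x)
  cat("<", kind, " parameters>\n", sep = "")
  flat <- unlist(x[names(x) != "tuning"])
  for (nm in names(flat)) cat("  ", nm, " = ", format(flat[[nm]]), "\n", sep = "")
  if (!is.null(x$tuning)) {
    if (inherits(x$tuning, "gaussian")) {
      cat("  tuning: Gaussian, sigma = ", x$tuning$sigma_deg,
          " deg, offset d = ", x$tuning$offset, "\n", sep = "")
    } else {
      cat("  tuning: free weights ",
          paste(format(x$tuning$weights, digits = 3), collapse = " "), "\n", sep = "")
    }
  }
  invisible(x)
}

model_kind_of <- function(params) {
  if (inherits(params, "srm_params")) return("srm")
  if (inherits(params, "drm_params")) return("drm")
  if (inherits(params, "mcsrm_params")) {
    return(if (inherits(params$tuning, "gaussian")) "mcsrm4" else "mcsrm10")
  }
  abort("unknown parameter object")
}
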