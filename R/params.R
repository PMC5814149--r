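#' Model parameters for the autocatalytic nucleation model
#'
#' Bundles the five quantities that determine a steady-state monopole in the
#' nucleator-gradient model: the mean microtubule length \eqn{\ell}, the decay
#' length \eqn{\ell_u} of the unbound active-nucleator gradient, the
#' dimensionless branching amplitude \eqn{\alpha} (the branching gain
#' \eqn{\beta(x) = (\alpha/\ell_u) e^{-x/\ell_u}} integrated over all
#' distances), the density amplitude \eqn{\rho(0)} at the center, and the
#' microtubule turnover rate \eqn{\Theta} (reciprocal of the mean lifetime).
#'
#' A uniform activation field (no gradient) is encoded by `ell_u = Inf`
#' together with a finite uniform branching gain `beta0` per micrometer, the
#' limit of \eqn{\alpha/\ell_u} as \eqn{\ell_u \to \infty}.
#'
#' @param ell Mean microtubule length, micrometers. Must be positive.
#' @param ell_u Decay length of the unbound-nucleator gradient, micrometers.
#'   May be `Inf` for uniform activation (then `beta0` is required).
#' @param alpha Dimensionless branching amplitude, >= 0. Ignored when
#'   `ell_u` is infinite.
#' @param rho0 Density amplitude at the center, arbitrary fluorescence units.
#' @param theta Microtubule turnover rate, 1/s, or `NA` when unknown (e.g.
#'   for parameters obtained from a density fit alone).
#' @param beta0 Uniform branching gain per micrometer; only used (and then
#'   required) when `ell_u` is infinite.
#'
#' @return An object of class `"model_params"`.
#' @seealso [density_profile()], [reproductive_number()], [fit_density()]
#' @examples
#' p <- model_params(ell = 8, ell_u = 24.9, alpha = 2.38, rho0 = 4058,
#'                   theta = 0.05)
#' p
#' @export
model_params <- function(ell, ell_u, alpha, rho0 = 1, theta = NA_real_,
                         beta0 = NULL) {
  if (!is.numeric(ell) || length(ell) != 1L || is.na(ell) || ell <= 0)
    stop("'ell' must be a single positive number (micrometers)")
  if (!is.numeric(ell_u) || length(ell_u) != 1L || is.na(ell_u) || ell_u <= 0)
    stop("'ell_u' must be a single positive number or Inf")
  if (!is.numeric(rho0) || length(rho0) != 1L || is.na(rho0) || rho0 <= 0)
    stop("'rho0' must be a single positive number")
  if (!is.na(theta) && (!is.numeric(theta) || theta <= 0))
    stop("'theta' must be positive (1/s) or NA")
  uniform <- is.infinite(ell_u)
  if (uniform) {
    if (is.null(beta0) || !is.numeric(beta0) || length(beta0) != 1L ||
        is.na(beta0) || beta0 < 0)
      stop("uniform activation (ell_u = Inf) requires a finite 'beta0' >= 0")
    alpha <- Inf
  } else {
    if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0)
      stop("'alpha' must be a single non-negative number")
    beta0 <- alpha / ell_u
  }
  structure(
    list(ell = as.numeric(ell), ell_u = as.numeric(ell_u),
         alpha = as.numeric(alpha), rho0 = as.numeric(rho0),
         theta = as.numeric(theta), beta0 = as.numeric(beta0),
         uniform = uniform),
    class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Autocatalytic nucleation model parameters\n")
  cat(sprintf("  ell   (mean MT length)        : %.4g um\n", x$ell))
  if (x$uniform) {
    cat("  ell_u (nucleator gradient)    : Inf (uniform activation)\n")
    cat(sprintf("  beta0 (uniform gain)          : %.4g 1/um\n", x$beta0))
  } else {
    cat(sprintf("  ell_u (nucleator gradient)    : %.4g um\n", x$ell_u))
    cat(sprintf("  alpha (branching amplitude)   : %.4g\n", x$alpha))
  }
  cat(sprintf("  rho0  (central density)       : %.4g a.u.\n", x$rho0))
  if (!is.na(x$theta))
    cat(sprintf("  theta (turnover rate)         : %.4g 1/s  (mean lifetime %.4g s)\n",
                x$theta, 1 / x$theta))
  invisible(x)
}

#' Central reproductive number convention
#'
#' The branching amplitude `alpha` used throughout this package is the total
#' integrated branching gain \eqn{\int_0^\infty \beta(x)\,dx}. An alternative
#' convention found in branching-process language is the central reproductive
#' number \eqn{R(0) = \alpha \ell / \ell_u}, the mean number of daughters a
#' microtubule at the center produces. This helper exposes that derived,
#' read-only quantity.
#'
#' @param params A [model_params()] object.
#' @return The central reproductive number \eqn{R(0)} (for uniform activation,
#'   \eqn{\beta_0 \ell}).
#' @export
central_reproductive_number <- function(params) {
  stopifnot(inherits(params, "model_params"))
  if (params$uniform) params$beta0 * params$ell
  else params$alpha * params$ell / params$ell_u
}
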