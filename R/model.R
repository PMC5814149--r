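#' Steady-state microtubule density profile
#'
#' Closed-form steady-state density of the autocatalytic nucleation model.
#' Microtubules of mean length \eqn{\ell} turn over while new ones are
#' nucleated on existing polymer with a position-dependent branching gain
#' \eqn{\beta(x) = (\alpha/\ell_u)\, e^{-x/\ell_u}} set by the gradient of
#' unbound active nucleators. The density obeys
#' \deqn{d\rho/dx = \beta(x)\rho - \rho/\ell,}
#' whose solution is
#' \deqn{\rho(x) = \rho_0 \exp[\alpha(1 - e^{-x/\ell_u}) - x/\ell].}
#' Under uniform activation (`ell_u = Inf`) the gain is a constant
#' \eqn{\beta_0} and \eqn{\rho(x) = \rho_0 e^{(\beta_0 - 1/\ell)x}}, which
#' grows without bound when \eqn{\beta_0 \ell > 1}.
#'
#' @param params A [model_params()] object.
#' @param grid Non-negative, increasing distances from the center, um.
#' @return A [radial_profile()] of kind `"density"`.
#' @examples
#' p <- model_params(ell = 24, ell_u = 24.9, alpha = 2.38, rho0 = 4058)
#' rho <- density_profile(p, seq(0, 80, by = 0.5))
#' rho$x[which.max(rho$values)]  # peak near ell_u * log(alpha*ell/ell_u)
#' @export
density_profile <- function(params, grid) {
  stopifnot(inherits(params, "model_params"))
  if (anyNA(grid)) stop("'grid' must not contain NA")
  if (any(grid < 0)) stop("'grid' must be non-negative")
  if (length(grid) > 1L && any(diff(grid) <= 0))
    stop("'grid' must be strictly increasing")
  radial_profile(grid, params$rho0 * exp(log_density_shape(params, grid)),
                 kind = "density")
}

# log(rho(x)/rho0); shared by density, nucleation, and the fit objective
log_density_shape <- function(params, x) {
  if (params$uniform) (params$beta0 - 1 / params$ell) * x
  else params$alpha * (1 - exp(-x / params$ell_u)) - x / params$ell
}

#' Nucleation profile of the steady-state model
#'
#' The per-area nucleation rate implied by the model,
#' \eqn{\nu(x) = A\, \beta(x)\, \rho(x)} with
#' \eqn{\beta(x) = (\alpha/\ell_u) e^{-x/\ell_u}}: new microtubules appear
#' on existing polymer at a rate proportional to the local density of both
#' polymer and unbound active nucleators. On any grid the density satisfies
#' \eqn{d\rho/dx = \nu/A - \rho/\ell}.
#'
#' @inheritParams density_profile
#' @param amplitude Positive global amplitude \eqn{A} (arbitrary units).
#' @return A [radial_profile()] of kind `"nucleation"`.
#' @export
nucleation_profile <- function(params, grid, amplitude = 1) {
  stopifnot(inherits(params, "model_params"))
  if (!is.numeric(amplitude) || length(amplitude) != 1L || amplitude <= 0)
    stop("'amplitude' must be a single positive number")
  rho <- density_profile(params, grid)
  beta <- if (params$uniform) rep(params$beta0, length(grid))
          else (params$alpha / params$ell_u) * exp(-grid / params$ell_u)
  radial_profile(grid, amplitude * beta * rho$values, kind = "nucleation")
}

#' Parameter-free rescaling of density profiles between conditions
#'
#' In the model, two conditions that share the nucleator gradient but differ
#' in mean microtubule length satisfy
#' \deqn{\rho_{to}(x) = \rho_{from}(x)\, e^{(1/\ell_{from} - 1/\ell_{to})x},}
#' so the profile measured in one condition predicts the other with no free
#' parameters. This applies the pointwise multiplicative factor.
#'
#' @param profile A [radial_profile()].
#' @param ell_from Mean microtubule length of the measured condition, um.
#' @param ell_to Mean microtubule length of the target condition, um.
#' @return A [radial_profile()] of the same kind.
#' @export
rescale_profile <- function(profile, ell_from, ell_to) {
  stopifnot(inherits(profile, "radial_profile"))
  if (!is.numeric(ell_from) || ell_from <= 0 || !is.numeric(ell_to) ||
      ell_to <= 0)
    stop("lengths must be positive")
  fac <- exp((1 / ell_from - 1 / ell_to) * profile$x)
  out <- radial_profile(profile$x, profile$values * fac,
                        kind = profile_kind(profile))
  if (!is.null(profile$sd)) out$sd <- profile$sd * fac
  out
}

#' Local reproductive number and growth-regime classification
#'
#' \eqn{R(x) = \beta(x)\ell = (\alpha\ell/\ell_u) e^{-x/\ell_u}} is the mean
#' number of new microtubules that a microtubule at distance x generates
#' before turning over. A structure is bounded when microtubules at its
#' periphery produce fewer than one daughter each; with a finite nucleator
#' gradient \eqn{R(x)} always drops below 1 eventually, whereas under uniform
#' activation growth is unbounded iff \eqn{\beta_0 \ell > 1}. Whenever
#' \eqn{R(0) > 1}, the radius where \eqn{R(x) = 1} coincides with the argmax
#' of the density profile.
#'
#' @param params A [model_params()] object.
#' @param x Distances from the center, um.
#' @return Numeric vector of \eqn{R(x)}.
#' @seealso [growth_regime()], [central_reproductive_number()]
#' @export
reproductive_number <- function(params, x) {
  stopifnot(inherits(params, "model_params"))
  if (any(x < 0)) stop("'x' must be non-negative")
  if (params$uniform) rep(params$beta0 * params$ell, length(x))
  else (params$alpha * params$ell / params$ell_u) * exp(-x / params$ell_u)
}

#' @rdname reproductive_number
#' @return `growth_regime()`: a list with `bounded` (logical), `R0`, and
#'   `critical_radius` (um; the solution of R(x)=1 when `R0 > 1`, otherwise
#'   `NA`; also the argmax of the density profile).
#' @export
growth_regime <- function(params) {
  stopifnot(inherits(params, "model_params"))
  R0 <- central_reproductive_number(params)
  if (params$uniform) {
    list(bounded = R0 <= 1, R0 = R0, critical_radius = NA_real_)
  } else {
    xc <- if (R0 > 1) params$ell_u * log(R0) else NA_real_
    list(bounded = TRUE, R0 = R0, critical_radius = xc)
  }
}

#' Predict the density profile of a counterpart condition
#'
#' Keeps the nucleator-gradient parameters (\eqn{\ell_u, \alpha, \rho_0})
#' fixed at their fitted values and swaps in the independently measured mean
#' microtubule length of the other condition. Algebraically identical to
#' [rescale_profile()] applied to the fitted curve.
#'
#' @param fit A [model_params()] object (e.g. from [fit_density()]).
#' @param ell_other Mean microtubule length of the counterpart condition, um.
#' @param grid Distances on which to evaluate, um.
#' @return A [radial_profile()] of kind `"density"`.
#' @export
predict_counterpart <- function(fit, ell_other, grid) {
  stopifnot(inherits(fit, "model_params"))
  if (fit$uniform) stop("counterpart prediction requires a finite ell_u")
  p2 <- model_params(ell = ell_other, ell_u = fit$ell_u, alpha = fit$alpha,
                     rho0 = fit$rho0, theta = NA_real_)
  density_profile(p2, grid)
}
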