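#' Radial profile container
#'
#' A 1D function of distance from the structure center: a microtubule density,
#' a nucleation profile, or a raw intensity profile. Values carry arbitrary
#' fluorescence units; distances are micrometers.
#'
#' @param x Strictly increasing grid of distances from the center, um;
#'   `x[1] == 0` is permitted.
#' @param values Non-negative values, same length as `x`.
#' @param kind One of `"density"`, `"nucleation"`, `"intensity"`.
#' @param sd Optional per-point spread (same length as `x`).
#' @param n Optional per-point observation count.
#'
#' @return An object of class `"radial_profile"`: a data.frame with columns
#'   `x`, `values` and optionally `sd`, `n`, plus a `kind` attribute.
#' @export
radial_profile <- function(x, values, kind = c("density", "nucleation",
                                               "intensity"),
                           sd = NULL, n = NULL) {
  kind <- match.arg(kind)
  if (anyNA(x) || anyNA(values))
    stop("radial profiles must not contain missing values")
  if (length(x) != length(values))
    stop("'x' and 'values' must have the same length")
  if (length(x) > 1L && any(diff(x) <= 0))
    stop("'x' must be strictly increasing")
  if (any(x < 0)) stop("'x' must be non-negative")
  df <- data.frame(x = as.numeric(x), values = as.numeric(values))
  if (!is.null(sd)) {
    stopifnot(length(sd) == length(x))
    df$sd <- as.numeric(sd)
  }
  if (!is.null(n)) {
    stopifnot(length(n) == length(x))
    df$n <- as.numeric(n)
  }
  structure(df, kind = kind, class = c("radial_profile", "data.frame"))
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("Radial %s profile: %d points on [%.3g, %.3g] um\n",
              attr(x, "kind"), nrow(x), min(x$x), max(x$x)))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

profile_kind <- function(p) attr(p, "kind")
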