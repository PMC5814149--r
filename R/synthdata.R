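#' Explicit filament set
#'
#' Microtubules as radial segments: a minus-end distance from the center, a
#' length, and a birth time. Polarity is fixed outward (plus end at
#' `minus_pos + length`).
#'
#' @param minus_pos Minus-end distances from the center, um.
#' @param length Filament lengths, um (>= 0).
#' @param birth_time Birth times, s.
#' @return An object of class `"filament_set"` (data.frame with columns
#'   `minus_pos`, `length`, `birth_time`).
#' @export
filament_set <- function(minus_pos, length = numeric(0), birth_time = 0) {
  if (any(length < 0)) stop("lengths must be non-negative")
  if (any(minus_pos < 0)) stop("minus ends must be at non-negative radii")
  n <- base::length(minus_pos)
  structure(data.frame(minus_pos = as.numeric(minus_pos),
                       length = rep_len(as.numeric(length), n),
                       birth_time = rep_len(as.numeric(birth_time), n)),
            class = c("filament_set", "data.frame"))
}

#' Imaging parameters for synthetic rendering
#'
#' @param pixel_size Pixel size, um (default 0.22, a typical 60x/1.2 NA
#'   EMCCD scale).
#' @param psf_sigma Gaussian PSF sigma, um (default 0.25).
#' @param intensity_per_um Fluorescence per um of polymer, a.u.
#' @param background Constant background, a.u.
#' @param noise `"none"` or `"poisson"`.
#' @param noise_scale Photons per a.u. for Poisson noise.
#' @param frame_interval Frame interval, s.
#' @param img_size Image side length, pixels.
#' @return An object of class `"optics"`.
#' @export
optics <- function(pixel_size = 0.22, psf_sigma = 0.25,
                   intensity_per_um = 100, background = 10,
                   noise = c("none", "poisson"), noise_scale = 1,
                   frame_interval = 0.5, img_size = 512L) {
  noise <- match.arg(noise)
  stopifnot(pixel_size > 0, psf_sigma > 0, intensity_per_um > 0,
            background >= 0, noise_scale > 0, frame_interval > 0,
            img_size >= 16)
  structure(list(pixel_size = pixel_size, psf_sigma = psf_sigma,
                 intensity_per_um = intensity_per_um,
                 background = background, noise = noise,
                 noise_scale = noise_scale, frame_interval = frame_interval,
                 img_size = as.integer(img_size)),
            class = "optics")
}

#' Sample a synthetic monopole with model-distributed nucleation sites
#'
#' Minus-end positions are drawn from the normalized model nucleation
#' profile \eqn{\nu(x)} by inverse-CDF on a fine grid; lengths are i.i.d.
#' exponential with mean \eqn{\ell}. This is the ground truth that the
#' ablation pipeline is expected to recover.
#'
#' @param params A [model_params()] object; must describe a bounded
#'   (normalizable) structure.
#' @param n_filaments Number of filaments (>= 0).
#' @param seed Integer RNG seed.
#' @param x_max Outer extent of the sampling domain, um (default: far
#'   enough that \eqn{\nu} has decayed to 1e-8 of its maximum).
#' @param dx Grid step for the inverse CDF, um.
#' @return A [filament_set()].
#' @export
sample_monopole <- function(params, n_filaments, seed, x_max = NULL,
                            dx = 0.01) {
  stopifnot(inherits(params, "model_params"), n_filaments >= 0)
  if (params$uniform && params$beta0 * params$ell >= 1)
    stop("nucleation profile is not normalizable (supercritical uniform mode)")
  if (is.null(x_max)) {
    x_max <- 4 * (params$ell + if (params$uniform) params$ell
                  else params$ell_u)
    nu_tail <- function(xm) {
      g <- seq(0, xm, by = max(dx, xm / 5e4))
      v <- nucleation_profile(params, g)$values
      v[length(v)] / max(v)
    }
    while (nu_tail(x_max) > 1e-8) x_max <- x_max * 1.5
  }
  if (n_filaments == 0) return(filament_set(numeric(0)))
  set.seed(seed)
  g <- seq(0, x_max, by = dx)
  nu <- nucleation_profile(params, g)$values
  cdf <- cumsum(nu)
  if (cdf[length(cdf)] <= 0) stop("nucleation profile is identically zero")
  cdf <- cdf / cdf[length(cdf)]
  keep <- c(TRUE, diff(cdf) > 0)
  minus <- stats::approx(cdf[keep], g[keep], xout = stats::runif(n_filaments),
                         rule = 2)$y
  len <- stats::rexp(n_filaments, rate = 1 / params$ell)
  filament_set(minus, len)
}

# separable Gaussian convolution with zero padding (sum-preserving away
# from image borders)
gaussian_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(seq(-r, r), sd = sigma_px)
  k <- k / sum(k)
  conv1 <- function(m) {
    # convolve each column with k, same-size output, zero padding
    nr <- nrow(m)
    pad <- matrix(0, r, ncol(m))
    mp <- rbind(pad, m, pad)
    out <- matrix(0, nr, ncol(m))
    for (j in seq_along(k))
      out <- out + k[j] * mp[seq_len(nr) + (j - 1L), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(img))))
}

#' Render filaments into a fluorescence image frame
#'
#' Embeds the 1D radial filament set in 2D by assigning each filament a
#' fixed angle, rasterizes the straight segments at sub-pixel spacing with
#' `intensity_per_um`, convolves with a Gaussian PSF, adds background, and
#' optionally applies Poisson noise. The integrated background-subtracted,
#' noise-free intensity equals total filament length times
#' `intensity_per_um` (up to PSF truncation at the image border).
#'
#' @param filaments A [filament_set()].
#' @param optics An [optics()] object.
#' @param angles Angles in radians, one per filament; drawn uniformly from
#'   `seed` when omitted.
#' @param seed Integer RNG seed (used for angles and noise).
#' @param center Center in pixel coordinates `c(row, col)`; default image
#'   center.
#' @return A numeric matrix (one frame), with attributes `pixel_size` and
#'   `center`.
#' @export
render_frame <- function(filaments, optics, angles = NULL, seed = 1L,
                         center = NULL) {
  stopifnot(inherits(filaments, "filament_set"), inherits(optics, "optics"))
  np <- optics$img_size
  if (is.null(center)) center <- c((np + 1) / 2, (np + 1) / 2)
  set.seed(seed)
  n <- nrow(filaments)
  if (is.null(angles)) angles <- stats::runif(n, 0, 2 * pi)
  img <- matrix(0, np, np)
  keep <- filaments$length > 0
  if (any(keep)) {
    r0 <- filaments$minus_pos[keep]
    len <- filaments$length[keep]
    th <- angles[keep]
    h <- optics$pixel_size / 4
    npts <- pmax(1L, ceiling(len / h))
    wt <- optics$intensity_per_um * len / npts
    idx <- rep.int(seq_along(len), npts)
    # offsets along each filament: midpoint rule within npts sub-segments
    off <- (sequence(npts) - 0.5) / npts[idx]
    rr <- r0[idx] + off * len[idx]
    row <- center[1] + (rr * sin(th[idx])) / optics$pixel_size
    col <- center[2] + (rr * cos(th[idx])) / optics$pixel_size
    ri <- round(row); ci <- round(col)
    inside <- ri >= 1 & ri <= np & ci >= 1 & ci <= np
    if (!all(inside))
      warning("some filament points fall outside the field and were clipped")
    lin <- ri[inside] + (ci[inside] - 1) * np
    acc <- rowsum(wt[idx][inside], group = lin)
    img[as.integer(rownames(acc))] <- acc[, 1]
    img <- gaussian_blur(img, optics$psf_sigma / optics$pixel_size)
  }
  img <- img + optics$background
  if (optics$noise == "poisson")
    img <- stats::rpois(length(img), img * optics$noise_scale) /
      optics$noise_scale
  img <- matrix(img, np, np)
  attr(img, "pixel_size") <- optics$pixel_size
  attr(img, "center") <- center
  img
}

#' Multi-frame image stack
#'
#' @param frames List of numeric matrices of constant shape, a.u.
#' @param pixel_size Pixel size, um.
#' @param frame_interval Frame interval, s.
#' @param center Structure center, `c(row, col)`, subpixel.
#' @param cut_time_index Index of the first post-cut frame (NA if no cut).
#' @return An object of class `"image_stack"`.
#' @export
image_stack <- function(frames, pixel_size, frame_interval, center,
                        cut_time_index = NA_integer_) {
  stopifnot(is.list(frames), length(frames) >= 1, pixel_size > 0,
            frame_interval > 0)
  d <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1))))
    stop("all frames must have the same shape")
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval, center = center,
                 cut_time_index = as.integer(cut_time_index)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("Image stack: %d frames of %dx%d px (%.3g um/px, %.3g s/frame)\n",
              length(x$frames), d[1], d[2], x$pixel_size, x$frame_interval))
  if (!is.na(x$cut_time_index))
    cat(sprintf("  cut at frame %d\n", x$cut_time_index))
  invisible(x)
}

#' Synthetic laser-cut movie with known ground truth
#'
#' Samples a monopole from the model, performs a circular cut, and renders
#' the post-cut depolymerization as a movie: severed proximal fragments
#' shrink inward at the depolymerization velocity while distal fragments and
#' uncut filaments persist. Returns the movie together with the ground-truth
#' filament set for oracle comparisons.
#'
#' @param params A [model_params()] object.
#' @param n_filaments Number of filaments.
#' @param r Cut radius, um.
#' @param v_d Depolymerization velocity, um/s.
#' @param optics An [optics()] object.
#' @param seed Integer RNG seed.
#' @param n_frames Number of post-cut frames (default: enough for the wave
#'   to cross the cut radius).
#' @param pre_frames Number of static pre-cut frames.
#' @return A list with `stack` ([image_stack()]), `filaments`
#'   ([filament_set()]), `cut` ([cut_spec()]), `angles`, and `seed`.
#' @export
make_cut_fixture <- function(params, n_filaments, r, v_d, optics, seed,
                             n_frames = NULL, pre_frames = 2L) {
  fil <- sample_monopole(params, n_filaments, seed = seed)
  angles <- stats::runif(nrow(fil), 0, 2 * pi)  # RNG continues from sampler
  cut <- cut_spec(radius = r, delta_t = 4 * optics$frame_interval)
  stack <- simulate_cut(fil, cut, v_d, optics, angles = angles, seed = seed,
                        n_frames = n_frames, pre_frames = pre_frames)
  list(stack = stack, filaments = fil, cut = cut, angles = angles,
       seed = seed)
}

#' Synthetic speckle lifetime table with movie-length censoring
#'
#' Draws per-speckle distances to the shrinking end from the exponential
#' length distribution (mean \eqn{\ell}; by memorylessness the distance from
#' a length-biased uniform point to the end of an exponential filament is
#' again exponential), simulates first-passage lifetimes with drift `v_d`
#' and diffusion `D`, assigns uniform appearance times within the movie, and
#' flags as censored every track that would outlive the movie.
#'
#' @param params A [model_params()] object (supplies \eqn{\ell}).
#' @param v_d Shrinking-end drift speed, um/s.
#' @param D Shrinking-end diffusion coefficient, um^2/s.
#' @param n Number of speckles.
#' @param movie_length Movie duration, s (may be `Inf`).
#' @param seed Integer RNG seed.
#' @return A data.frame with columns `track_id`, `t_start_s`, `t_end_s`,
#'   `censored`, plus attribute `seed`.
#' @export
make_speckle_table <- function(params, v_d, D, n, movie_length, seed) {
  stopifnot(inherits(params, "model_params"), n >= 1)
  set.seed(seed)
  L0 <- stats::rexp(n, rate = 1 / params$ell)
  t_start <- if (is.finite(movie_length)) stats::runif(n, 0, movie_length)
             else rep(0, n)
  ls <- simulate_speckle_lifetimes(L0, v = v_d, D = D, n = n,
                                   seed = seed + 1L)
  t_end <- t_start + ls$duration
  censored <- ls$censored | (is.finite(movie_length) & t_end > movie_length)
  out <- data.frame(track_id = seq_len(n), t_start_s = t_start,
                    t_end_s = t_end, censored = censored)
  attr(out, "seed") <- seed
  out
}
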