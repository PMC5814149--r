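#' Laser cut specification
#'
#' @param radius Cut radius, um (circle geometry).
#' @param delta_t Differential-intensity interval, s (the raw-frame
#'   subtraction lag; typically 2-3 s).
#' @param geometry `"circle"` (radial cut around the monopole center) or
#'   `"line"` (straight cut perpendicular to a bipolar spindle's long axis).
#' @param offset For line cuts: position of the cut along the long axis, um.
#' @param cut_length For line cuts: length of the cut, um (used for the
#'   per-length normalization in place of the circle's `2*pi*r`).
#' @return An object of class `"cut_spec"`.
#' @export
cut_spec <- function(radius = NULL, delta_t = 2, geometry = c("circle",
                                                              "line"),
                     offset = NULL, cut_length = NULL) {
  geometry <- match.arg(geometry)
  if (geometry == "circle") {
    if (is.null(radius) || radius <= 0) stop("circle cuts need radius > 0")
  } else {
    if (is.null(offset)) stop("line cuts need an 'offset' along the axis")
    if (is.null(cut_length) || cut_length <= 0)
      stop("line cuts need 'cut_length' > 0")
  }
  if (delta_t <= 0) stop("'delta_t' must be positive")
  structure(list(geometry = geometry, radius = radius, delta_t = delta_t,
                 offset = offset, cut_length = cut_length),
            class = "cut_spec")
}

#' Per-time radial profile stack
#'
#' Angularly integrated intensity as a function of radius, one row per
#' frame. Values are linear densities (a.u. per um of radius): the sum of
#' pixel intensities in an annulus divided by the bin width, so the annulus
#' circumference weighting is retained as in the raw angular integral.
#'
#' @param times Frame times, s (relative to the cut when there is one).
#' @param x Radial bin centers, um.
#' @param values Matrix `length(times) x length(x)`.
#' @param cut_time_index Index of the first post-cut row (NA if none).
#' @param differential Logical; TRUE for differential (frame-minus-lagged)
#'   profiles.
#' @return An object of class `"profile_stack"`.
#' @export
profile_stack <- function(times, x, values, cut_time_index = NA_integer_,
                          differential = FALSE) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(times), ncol(values) == length(x))
  structure(list(times = as.numeric(times), x = as.numeric(x),
                 values = values, cut_time_index = as.integer(cut_time_index),
                 differential = isTRUE(differential)),
            class = "profile_stack")
}

# total covered filament length below position q, as a fast closed form:
# G(q) = sum_f (clip(q; start_f, end_f) - start_f)
coverage_integral_fun <- function(starts, ends) {
  ss <- sort(starts); se <- sort(ends)
  cs <- c(0, cumsum(ss)); ce <- c(0, cumsum(se))
  function(q) {
    ks <- findInterval(q, ss); ke <- findInterval(q, se)
    (ks * q - cs[ks + 1L]) - (ke * q - ce[ke + 1L])
  }
}

# per-um coverage profile of a set of segments on given bin edges
segments_profile <- function(starts, ends, edges) {
  keep <- ends > starts
  if (!any(keep)) return(numeric(length(edges) - 1L))
  G <- coverage_integral_fun(starts[keep], ends[keep])
  diff(G(edges)) / diff(edges)
}

#' Simulate a circular laser cut as an image-stack movie
#'
#' Filaments spanning the cut radius are severed: the proximal fragment
#' (minus end to the cut) acquires a new plus end that depolymerizes inward
#' at `v_d` until it reaches the minus end, while the distal fragment and
#' all non-spanning filaments persist unchanged. Frames are rendered with
#' [render_frame()]; the total rendered intensity loss over the movie equals
#' the summed severed proximal lengths times the intensity scale
#' (conservation, exact for noise-free optics away from the image border).
#'
#' @param filaments A [filament_set()] in radial coordinates.
#' @param cut A [cut_spec()] with circle geometry.
#' @param v_d Depolymerization velocity, um/s (> 0).
#' @param optics An [optics()] object.
#' @param angles Per-filament angles, radians; drawn from `seed` if omitted.
#' @param seed Integer RNG seed (angles and per-frame noise).
#' @param n_frames Post-cut frames (default: wave crosses the full radius).
#' @param pre_frames Static pre-cut frames.
#' @return An [image_stack()]; if no filament spans the cut, a valid movie
#'   with a zero wave, carrying attribute `no_spanning = TRUE`.
#' @export
simulate_cut <- function(filaments, cut, v_d, optics, angles = NULL,
                         seed = 1L, n_frames = NULL, pre_frames = 2L) {
  stopifnot(inherits(filaments, "filament_set"), inherits(cut, "cut_spec"),
            inherits(optics, "optics"))
  if (cut$geometry != "circle")
    stop("only circle cuts have a forward movie simulator")
  if (v_d <= 0) stop("'v_d' must be positive")
  r <- cut$radius
  set.seed(seed)
  if (is.null(angles)) angles <- stats::runif(nrow(filaments), 0, 2 * pi)
  if (is.null(n_frames))
    n_frames <- ceiling(r / v_d / optics$frame_interval) + 4L

  plus <- filaments$minus_pos + filaments$length
  sev <- filaments$minus_pos < r & plus > r
  no_spanning <- !any(sev)

  frames <- vector("list", pre_frames + n_frames)
  for (k in seq_len(pre_frames + n_frames)) {
    t_post <- (k - pre_frames - 1L) * optics$frame_interval
    if (t_post <= 0) {
      fs <- filaments; an <- angles
    } else {
      # proximal fragments: [minus, max(minus, r - v_d t)]
      prox_end <- pmax(filaments$minus_pos[sev], r - v_d * t_post)
      fs <- filament_set(
        c(filaments$minus_pos[!sev], filaments$minus_pos[sev], rep(r, sum(sev))),
        c(filaments$length[!sev], prox_end - filaments$minus_pos[sev],
          plus[sev] - r))
      an <- c(angles[!sev], angles[sev], angles[sev])
    }
    frames[[k]] <- render_frame(fs, optics, angles = an,
                                seed = seed + 7919L * k)
  }
  st <- image_stack(frames, optics$pixel_size, optics$frame_interval,
                    center = attr(frames[[1]], "center"),
                    cut_time_index = pre_frames + 1L)
  attr(st, "no_spanning") <- no_spanning
  st
}

#' Simulate a circular cut as an idealized radial profile stack
#'
#' Same post-cut filament dynamics as [simulate_cut()], but each frame is
#' the exact angular integral (per-um linear intensity density) of the 1D
#' filament coverage, with optional additive Gaussian noise and no PSF.
#' This is the "profile stack" input mode of the analysis pipeline.
#'
#' @inheritParams simulate_cut
#' @param bin_width Radial bin width, um.
#' @param intensity_per_um Intensity per um of polymer, a.u.
#' @param noise_sd Additive Gaussian noise per bin, a.u.
#' @param x_max Outer radius of the profile grid, um.
#' @param frame_interval Frame interval, s.
#' @return A [profile_stack()] (raw, not differential).
#' @export
simulate_cut_profiles <- function(filaments, cut, v_d, bin_width = 0.5,
                                  intensity_per_um = 1, noise_sd = 0,
                                  x_max = NULL, frame_interval = 0.5,
                                  n_frames = NULL, pre_frames = 2L,
                                  seed = 1L) {
  stopifnot(inherits(filaments, "filament_set"), inherits(cut, "cut_spec"))
  if (cut$geometry != "circle") stop("profile-stack simulation is radial")
  if (v_d <= 0) stop("'v_d' must be positive")
  r <- cut$radius
  plus <- filaments$minus_pos + filaments$length
  if (is.null(x_max)) x_max <- max(plus, r) + 2
  if (is.null(n_frames)) n_frames <- ceiling(r / v_d / frame_interval) + 4L
  edges <- seq(0, x_max, by = bin_width)
  x <- edges[-1] - bin_width / 2
  sev <- filaments$minus_pos < r & plus > r
  set.seed(seed)
  vals <- matrix(0, pre_frames + n_frames, length(x))
  for (k in seq_len(pre_frames + n_frames)) {
    t_post <- (k - pre_frames - 1L) * frame_interval
    if (t_post <= 0) {
      starts <- filaments$minus_pos; ends <- plus
    } else {
      prox_end <- pmax(filaments$minus_pos[sev], r - v_d * t_post)
      starts <- c(filaments$minus_pos[!sev], filaments$minus_pos[sev],
                  rep(r, sum(sev)))
      ends <- c(plus[!sev], prox_end, plus[sev])
    }
    v <- intensity_per_um * segments_profile(starts, ends, edges)
    if (noise_sd > 0) v <- v + stats::rnorm(length(v), sd = noise_sd)
    vals[k, ] <- v
  }
  times <- (seq_len(pre_frames + n_frames) - pre_frames - 1L) * frame_interval
  profile_stack(times, x, vals, cut_time_index = pre_frames + 1L)
}

#' Differential intensities
#'
#' Subtracts frames with a time lag `delta_t`: \eqn{I(t) = F(t) -
#' F(t+\delta t)}, so positive values mark intensity lost (polymer
#' depolymerized) during the interval. Signed values are retained; negative
#' values are noise and are only clipped in exported visualizations, never
#' in analysis. Differentials are formed from the cut frame onward when a
#' cut index is present.
#'
#' @param x An [image_stack()] or [profile_stack()].
#' @param delta_t Lag, s; must be a positive multiple of the frame interval.
#' @return For a profile stack: a differential [profile_stack()]. For an
#'   image stack: a list of class `"diff_stack"` with `frames`, `times`
#'   (s after the cut), `pixel_size`, `center`.
#' @export
differential_intensity <- function(x, delta_t) {
  UseMethod("differential_intensity")
}

#' @export
differential_intensity.image_stack <- function(x, delta_t) {
  k <- delta_t / x$frame_interval
  if (abs(k - round(k)) > 1e-9 || k < 1)
    stop("'delta_t' must be a positive multiple of the frame interval")
  k <- as.integer(round(k))
  i0 <- if (is.na(x$cut_time_index)) 1L else x$cut_time_index
  nf <- length(x$frames)
  if (i0 + k > nf) stop("'delta_t' is longer than the movie")
  idx <- i0:(nf - k)
  frames <- lapply(idx, function(i) x$frames[[i]] - x$frames[[i + k]])
  times <- (idx - i0) * x$frame_interval
  structure(list(frames = frames, times = times, pixel_size = x$pixel_size,
                 center = x$center, delta_t = delta_t),
            class = "diff_stack")
}

#' @export
differential_intensity.profile_stack <- function(x, delta_t) {
  dtf <- diff(x$times[1:2])
  k <- delta_t / dtf
  if (abs(k - round(k)) > 1e-9 || k < 1)
    stop("'delta_t' must be a positive multiple of the frame interval")
  k <- as.integer(round(k))
  i0 <- if (is.na(x$cut_time_index)) 1L else x$cut_time_index
  nf <- length(x$times)
  if (i0 + k > nf) stop("'delta_t' is longer than the movie")
  idx <- i0:(nf - k)
  profile_stack(x$times[idx] - x$times[i0],
                x$x, x$values[idx, , drop = FALSE] -
                  x$values[idx + k, , drop = FALSE],
                cut_time_index = 1L, differential = TRUE)
}

#' Intensity-weighted centroid of the pre-cut frame
#'
#' @param stack An [image_stack()].
#' @return `c(row, col)` in (sub)pixel coordinates.
#' @export
find_center <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  i <- if (is.na(stack$cut_time_index)) 1L else max(1L,
                                                    stack$cut_time_index - 1L)
  f <- stack$frames[[i]]
  f <- pmax(f - stats::median(f), 0)
  tot <- sum(f)
  rows <- row(f); cols <- col(f)
  c(sum(rows * f) / tot, sum(cols * f) / tot)
}

#' Angular integration of differential frames
#'
#' For circular cuts, sums the (signed) differential intensities in annular
#' radial bins around the center and divides by the bin width, giving the
#' per-um angular integral as a function of radius. For line cuts, sums
#' along the direction of the cut (image rows), giving the per-um integral
#' along the spindle's long axis (columns).
#'
#' @param diffs A `"diff_stack"` from [differential_intensity()].
#' @param center `c(row, col)`; default the stack's stored center.
#' @param bin_width Radial bin width, um.
#' @param direction `"radial"` (circle cuts) or `"line"` (line cuts).
#' @return A differential [profile_stack()] (for `"line"`, `x` is the axial
#'   coordinate relative to the center column).
#' @export
angular_integrate <- function(diffs, center = NULL, bin_width = 0.5,
                              direction = c("radial", "line")) {
  direction <- match.arg(direction)
  stopifnot(inherits(diffs, "diff_stack"))
  d <- dim(diffs$frames[[1]])
  if (is.null(center)) center <- diffs$center
  if (direction == "radial") {
    if (center[1] < 1 || center[1] > d[1] || center[2] < 1 ||
        center[2] > d[2])
      stop("center must lie inside the frame")
    rows <- rep(seq_len(d[1]), times = d[2])
    cols <- rep(seq_len(d[2]), each = d[1])
    rad <- sqrt((rows - center[1])^2 + (cols - center[2])^2) *
      diffs$pixel_size
    nb <- ceiling(max(rad) / bin_width)
    bin <- pmin(floor(rad / bin_width) + 1L, nb)
    vals <- t(vapply(diffs$frames, function(f) {
      s <- rowsum(as.vector(f), group = bin, reorder = TRUE)
      out <- numeric(nb)
      out[as.integer(rownames(s))] <- s[, 1]
      out / bin_width
    }, numeric(nb)))
    x <- (seq_len(nb) - 0.5) * bin_width
  } else {
    x <- (seq_len(d[2]) - center[2]) * diffs$pixel_size
    vals <- t(vapply(diffs$frames, function(f) colSums(f) / diffs$pixel_size,
                     numeric(d[2])))
  }
  profile_stack(diffs$times, x, vals, cut_time_index = 1L,
                differential = TRUE)
}

#' Track the depolymerization wave with per-frame Gaussian fits
#'
#' The wave appears in the differential profiles as a peak traveling toward
#' the center and broadening. Each frame's peak is located at the running
#' maximum (constrained not to move outward) and fitted with a Gaussian
#' `A * exp(-(x-c)^2 / (2 s^2))` by bounded Levenberg-Marquardt least
#' squares. The wave area is integrated directly over `|x - c| <= 4 s`
#' around the fitted center (the differential baseline is zero, so this is
#' unbiased even where the wave shape deviates from a Gaussian); the
#' analytic Gaussian area `A * s * sqrt(2*pi)` is kept in `area_gauss`.
#' Frames
#' whose fit fails or whose peak is indistinguishable from the noise floor
#' are flagged, not fatal; frames with several comparable peaks in the fit
#' window get a `"multi_peak"` quality flag.
#'
#' @param profiles A differential [profile_stack()].
#' @param cut_radius Cut radius, um (bounds the initial peak search); may be
#'   NA.
#' @param direction `"decreasing"` (wave travels toward x = 0, the monopole
#'   case) or `"increasing"`.
#' @param window Half-width of the local fit window, um.
#' @param x_range Optional `c(min, max)` restricting the searched
#'   coordinate range (used for the two waves of a bipolar line cut).
#' @return A `"wave_track"`: data.frame with columns `t_s`, `center_um`,
#'   `sigma_um`, `area`, `accepted`, `flag`; attributes `cut_radius`,
#'   `no_wave`.
#' @export
fit_wave <- function(profiles, cut_radius = NA, direction = c("decreasing",
                                                              "increasing"),
                     window = 6, x_range = NULL) {
  direction <- match.arg(direction)
  stopifnot(inherits(profiles, "profile_stack"))
  if (!profiles$differential)
    warning("fit_wave expects differential profiles")
  x <- profiles$x
  if (is.null(x_range)) x_range <- range(x)
  nfr <- nrow(profiles$values)
  if (nfr < 3L) stop("need at least 3 usable differential frames")
  bw <- stats::median(diff(x))
  noise_floor <- stats::mad(profiles$values[profiles$values <= 0], center = 0)
  if (!is.finite(noise_floor)) noise_floor <- 0

  prev_center <- if (!is.na(cut_radius)) cut_radius + 2 * bw else
    if (direction == "decreasing") x_range[2] else x_range[1] - 2 * bw
  out <- data.frame(t_s = profiles$times, center_um = NA_real_,
                    sigma_um = NA_real_, area = NA_real_,
                    area_gauss = NA_real_, accepted = FALSE,
                    flag = "", stringsAsFactors = FALSE)
  for (i in seq_len(nfr)) {
    v <- profiles$values[i, ]
    sel <- x >= x_range[1] & x <= x_range[2]
    sel <- sel & (if (direction == "decreasing") x <= prev_center + 2 * bw
                  else x >= prev_center - 2 * bw)
    if (!any(sel)) { out$flag[i] <- "empty_window"; next }
    xm <- x[sel][which.max(v[sel])]
    win <- sel & abs(x - xm) <= window
    xa <- x[win]; va <- v[win]
    peak <- max(va)
    if (peak <= 5 * noise_floor || peak <= 0) {
      out$flag[i] <- "no_peak"; next
    }
    fit <- tryCatch(minpack.lm::nlsLM(
      va ~ A * exp(-(xa - c0)^2 / (2 * s0^2)),
      start = list(A = peak, c0 = xm, s0 = 2 * bw),
      lower = c(A = 0, c0 = min(xa), s0 = bw / 2),
      upper = c(A = Inf, c0 = max(xa), s0 = diff(range(xa)) + bw),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) { out$flag[i] <- "fit_failed"; next }
    cf <- stats::coef(fit)
    out$center_um[i] <- cf[["c0"]]
    out$sigma_um[i] <- cf[["s0"]]
    out$area_gauss[i] <- cf[["A"]] * cf[["s0"]] * sqrt(2 * pi)
    integ <- abs(xa - cf[["c0"]]) <= 4 * cf[["s0"]]
    out$area[i] <- sum(va[integ]) * bw
    ok <- cf[["A"]] > 0 &&
      (is.na(cut_radius) || cf[["c0"]] <= cut_radius + 4 * bw)
    # detect merged/secondary peaks: local maxima above half the main peak
    inner <- which(win)[c(-1, -length(which(win)))]
    if (length(inner) > 2) {
      vi <- v[inner]
      locmax <- which(diff(sign(diff(vi))) == -2) + 1L
      big <- vi[locmax] > 0.5 * peak
      if (sum(big) > 1) {
        pos <- x[inner][locmax[big]]
        if (diff(range(pos)) > 3 * bw) {
          out$flag[i] <- "multi_peak"
          ok <- FALSE
        }
      }
    }
    out$accepted[i] <- ok
    if (ok) prev_center <- cf[["c0"]]
  }
  structure(out, cut_radius = cut_radius,
            no_wave = !any(out$accepted), bin_width = bw,
            class = c("wave_track", "data.frame"))
}

#' Two depolymerization waves of a bipolar line cut
#'
#' A line cut across a bipolar spindle creates two waves traveling toward
#' the two poles (microtubules near the cut have mixed polarity). Splits the
#' axial differential profiles at the cut position and tracks each side.
#'
#' @param profiles A differential axial [profile_stack()] (from
#'   [angular_integrate()] with `direction = "line"`).
#' @param cut_pos Cut position on the axial coordinate, um.
#' @return A list with elements `left` and `right`, each a `"wave_track"`.
#' @export
fit_two_waves <- function(profiles, cut_pos) {
  list(left = fit_wave(profiles, cut_radius = NA, direction = "decreasing",
                       x_range = c(min(profiles$x), cut_pos)),
       right = fit_wave(profiles, cut_radius = NA, direction = "increasing",
                        x_range = c(cut_pos, max(profiles$x))))
}

#' Depolymerization velocity from a wave track
#'
#' Linear fit of the Gaussian centers against time over accepted frames;
#' the wave front travels at constant velocity, so the absolute slope is
#' the depolymerization velocity. Two classes of frames are excluded when
#' enough remain: frames whose center is within 2.5 sigma of the origin
#' (the wave piles up against the center and its apparent motion stalls)
#' and frames whose area has fallen below 40% of the maximum (late in the
#' decay the surviving-microtubule density tilts the wave shape and drags
#' the apparent center outward).
#'
#' @param track A `"wave_track"` from [fit_wave()].
#' @param min_frames Minimum accepted frames (default 2; the slope of two
#'   perfect frames is exact).
#' @return A list of class `"depol_velocity"`: `v_um_s`, `v_um_min`, `se`
#'   (um/s), `intercept_um`, `n_used`, `flags` (may contain
#'   `"non_monotone"` or `"stationary"`).
#' @export
depolymerization_velocity <- function(track, min_frames = 2L) {
  stopifnot(inherits(track, "wave_track"))
  ok <- track$accepted & !is.na(track$center_um)
  away <- ok & track$center_um > 2.5 * track$sigma_um
  if (sum(away) >= min_frames) ok <- away
  massy <- ok & track$area >= 0.4 * max(track$area[ok])
  if (sum(massy) >= max(min_frames, 5L)) ok <- massy
  if (sum(ok) < min_frames)
    stop("too few accepted frames to estimate a velocity")
  t <- track$t_s[ok]; c0 <- track$center_um[ok]
  fit <- stats::lm(c0 ~ t)
  slope <- unname(stats::coef(fit)[2])
  se <- if (sum(ok) > 2) summary(fit)$coefficients[2, 2] else 0
  flags <- character(0)
  bw <- attr(track, "bin_width")
  steps <- diff(c0)
  if (mean(steps > bw) > 0.25) flags <- c(flags, "non_monotone")
  if (abs(slope) <= 2 * se) flags <- c(flags, "stationary")
  structure(list(v_um_s = abs(slope), v_um_min = abs(slope) * 60, se = se,
                 intercept_um = unname(stats::coef(fit)[1]),
                 n_used = sum(ok), flags = flags),
            class = "depol_velocity")
}

#' @export
print.depol_velocity <- function(x, ...) {
  cat(sprintf("Depolymerization velocity: %.3g um/min (%.4g um/s, se %.2g, n = %d)%s\n",
              x$v_um_min, x$v_um_s, x$se, x$n_used,
              if (length(x$flags)) paste0("  [", paste(x$flags,
                                                       collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Minus-end density from the decay of the wave area
#'
#' As the wave passes a minus end, that microtubule stops contributing, so
#' the area under the wave decays with distance from the cut in proportion
#' to the surviving fraction of severed microtubules. The distance traveled
#' is taken from the fitted front velocity, `d = r - c(t)` with `c(t)` the
#' fitted linear center (suppressing per-frame jitter). An exponential
#' `A0 * exp(-d/lambda)` is fitted to the areas with weights proportional to
#' the area (Poisson-like), and the decays are normalized by the amplitude
#' at the cut. The normalized slope at the cut times the pre-cut
#' fluorescence at the cut radius gives the minus ends per unit length
#' there; dividing by `2*pi*r` (circle) or the cut length (line) gives the
#' per-area nucleation value. The full decay curve is retained as the
#' (nonparametric) estimate of the minus-end distribution below the cut; for
#' that curve the amplitude at the cut is fixed by conservation rather than
#' extrapolation: the wave mass per differential interval equals the
#' spanning fluorescence times the swept window length (`v_d * delta_t`,
#' clipped where the window runs into the origin or the cut), so the
#' survival samples are `area / (fluorescence_at_cut * window)` at the
#' effective window midpoint.
#'
#' @param track A `"wave_track"`.
#' @param cut A [cut_spec()].
#' @param fluorescence_at_cut Averaged pre-cut angular intensity integral at
#'   the cut position, a.u. per um.
#' @param v_d Depolymerization velocity, um/s; estimated from the track when
#'   omitted.
#' @param delta_t Differential interval, s; defaults to the cut spec's.
#' @param slope_window Width of the window below the cut, um, over which
#'   the minus-end density at the cut is read off the decay curve.
#' @return A list of class `"nucleation_estimate"`: `r`, `v_d`, `lambda`
#'   (decay length, um), `A0` (fitted amplitude at the cut), `A0_phys`
#'   (conservation amplitude), `samples` (d_um, area, area_norm = area/A0,
#'   surv = area/A0_phys), `slope_at_cut` (1/um, <= 0),
#'   `nc_per_length_at_cut`, `per_area_value`, `fluorescence_at_cut`,
#'   `flags`.
#' @export
area_decay_analysis <- function(track, cut, fluorescence_at_cut,
                                v_d = NULL, delta_t = NULL,
                                slope_window = 2) {
  stopifnot(inherits(track, "wave_track"), inherits(cut, "cut_spec"))
  if (isTRUE(attr(track, "no_wave"))) stop("no wave was detected")
  r <- if (cut$geometry == "circle") cut$radius else
    attr(track, "cut_radius")
  ok <- track$accepted & !is.na(track$area)
  if (sum(ok) < 3L) stop("too few accepted frames for the area decay")
  tt <- track$t_s[ok]; area <- track$area[ok]; cen <- track$center_um[ok]

  if (is.null(v_d)) v_d <- depolymerization_velocity(track)$v_um_s
  # distance from the time axis, not per-frame centers: the differential
  # window [r - v(t+dt), r - v t] has midpoint r - v(t + dt/2) exactly
  if (is.null(delta_t)) delta_t <- cut$delta_t
  chat <- r - v_d * (tt + delta_t / 2)
  d <- pmax(0, r - chat)

  if (max(area) <= 0) stop("wave areas are all zero (no wave)")
  flags <- character(0)
  if (isTRUE(stats::cor(d, area) > 0.3)) flags <- c(flags, "increasing_area")

  fit <- minpack.lm::nlsLM(area ~ A0 * exp(-d / lambda),
                           start = list(A0 = max(area),
                                        lambda = max(r / 2, 1)),
                           weights = pmax(area, max(area) * 1e-3),
                           lower = c(A0 = 0, lambda = 1e-3),
                           upper = c(A0 = Inf, lambda = 1e6),
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  A0 <- cf[["A0"]]; lambda <- cf[["lambda"]]
  if (A0 <= 0) stop("fitted wave amplitude at the cut is zero")
  if (is.null(delta_t)) delta_t <- cut$delta_t
  A0_phys <- fluorescence_at_cut * v_d * delta_t
  # effective swept window per frame, clipped at the origin and the cut
  f_hi <- pmin(r, chat + v_d * delta_t / 2)
  f_lo <- pmax(0, chat - v_d * delta_t / 2)
  w_eff <- pmax(f_hi - f_lo, 1e-9)
  surv <- area / (fluorescence_at_cut * w_eff)
  d_surv <- r - (f_hi + f_lo) / 2
  usable <- w_eff > 0.2 * v_d * delta_t
  norm_len <- if (cut$geometry == "circle") 2 * pi * r else cut$cut_length
  est <- structure(list(r = r, v_d = v_d, lambda = lambda, A0 = A0,
                 A0_phys = A0_phys,
                 samples = data.frame(d_um = d, area = area,
                                      area_norm = area / A0,
                                      surv = surv, d_surv = d_surv,
                                      surv_window = w_eff,
                                      surv_usable = usable),
                 slope_at_cut = -1 / lambda,
                 nc_per_length_at_cut = NA_real_,
                 per_area_value = NA_real_,
                 nc_exp_fit = fluorescence_at_cut / lambda / norm_len,
                 fluorescence_at_cut = fluorescence_at_cut,
                 geometry = cut$geometry, flags = flags),
            class = "nucleation_estimate")
  # minus-end density at the cut from the decay curve itself, over a local
  # window just below the cut; the global exponential (lambda, kept above
  # as a diagnostic) misstates the local slope whenever the minus-end
  # density varies along the structure
  nc_len <- minus_end_bins(est, c(max(0, r - slope_window), r))$value
  est$nc_per_length_at_cut <- nc_len
  est$per_area_value <- nc_len / norm_len
  est
}

#' @export
print.nucleation_estimate <- function(x, ...) {
  cat(sprintf("Nucleation estimate from a cut at r = %.3g um\n", x$r))
  cat(sprintf("  area decay length lambda = %.3g um; slope at cut = %.3g 1/um\n",
              x$lambda, x$slope_at_cut))
  cat(sprintf("  minus ends per um at cut = %.4g; per-area value = %.4g\n",
              x$nc_per_length_at_cut, x$per_area_value))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Nonparametric minus-end counts per radial bin from one cut
#'
#' Differences the normalized area-decay curve across bin edges: the drop of
#' the surviving wave fraction across a bin, times the fluorescence at the
#' cut, counts the minus ends (in fluorescence units) of cut-spanning
#' microtubules in that bin. Each survival sample is the average of the
#' true survival over its differential window (width `v_d * delta_t`), so
#' the curve is evaluated at each edge by a local quadratic fit with the
#' exact top-hat deconvolution `S(q) = Sbar(q) - (w^2/24) Sbar''(q)`; the
#' local fit simultaneously averages out the sub-bin aliasing of the
#' per-frame areas against the radial binning grid, and the correction
#' removes the curvature bias where the wave runs out at the center.
#'
#' @param estimate A `"nucleation_estimate"`.
#' @param edges Radial bin edges, um (must lie within `[0, r]`).
#' @return Data.frame with `y_lo`, `y_hi`, `value` (minus ends per um, in
#'   the fluorescence units of `fluorescence_at_cut`); bins outside the
#'   observed decay range get `NA`.
#' @export
minus_end_bins <- function(estimate, edges) {
  stopifnot(inherits(estimate, "nucleation_estimate"))
  r <- estimate$r
  s <- estimate$samples[estimate$samples$surv_usable, ]
  s <- s[order(s$d_surv), ]
  dgrid <- c(0, s$d_surv)
  agrid <- pmin(cummin(c(1, s$surv)), 1)  # enforce monotone survival
  wgrid <- c(0, s$surv_window)            # anchors are exact (no window)
  if (max(dgrid) < r) {  # no severed minus ends below y = 0
    dgrid <- c(dgrid, r)
    agrid <- c(agrid, 0)
    wgrid <- c(wgrid, 0)
  }
  keep <- c(TRUE, diff(dgrid) > 0)
  dgrid <- dgrid[keep]; agrid <- agrid[keep]; wgrid <- wgrid[keep]
  interp <- stats::approxfun(dgrid, agrid, rule = 2)
  Sfun <- function(q) vapply(q, function(qi) {
    near <- abs(dgrid - qi) <= 1
    if (sum(near) >= 5) {
      z <- dgrid[near] - qi
      fit <- stats::lm.fit(cbind(1, z, z^2), agrid[near])
      w2 <- mean(wgrid[near]^2)
      val <- fit$coefficients[1] - (w2 / 24) * 2 * fit$coefficients[3]
    } else if (sum(near) >= 3) {
      z <- dgrid[near] - qi
      val <- stats::lm.fit(cbind(1, z), agrid[near])$coefficients[1]
    } else val <- interp(qi)
    min(max(val, 0), 1)
  }, numeric(1))
  y_lo <- edges[-length(edges)]; y_hi <- edges[-1]
  d_hi <- r - y_lo; d_lo <- r - y_hi
  val <- estimate$fluorescence_at_cut *
    (Sfun(d_lo) - Sfun(d_hi)) / (y_hi - y_lo)
  out_of_range <- d_hi > max(dgrid)
  val[out_of_range] <- NA_real_
  data.frame(y_lo = y_lo, y_hi = y_hi, value = val)
}

#' Assemble a per-area nucleation profile from many cuts
#'
#' Each cut contributes one value at its radius: the minus-end density per
#' unit length at the cut, divided by `2*pi*r` for the two-dimensional
#' per-area convention used on real images (`value = "per_area"`), or left
#' per unit radial length, the native scale of the 1D effective model and
#' of the 1D synthetic generators (`value = "per_length"`). Values are
#' binned by cut radius and summarized as mean and SD.
#'
#' @param estimates A list of `"nucleation_estimate"` objects (>= 2 cuts).
#' @param bin_width Radius bin width, um; default groups cuts within 2 um.
#' @param value Which normalization to assemble (see above).
#' @return A [radial_profile()] of kind `"nucleation"` with `sd` and `n`.
#' @export
assemble_nucleation_profile <- function(estimates, bin_width = 2,
                                        value = c("per_area",
                                                  "per_length")) {
  value <- match.arg(value)
  stopifnot(length(estimates) >= 2)
  r <- vapply(estimates, function(e) e$r, numeric(1))
  v <- vapply(estimates, function(e)
    if (value == "per_area") e$per_area_value else e$nc_per_length_at_cut,
    numeric(1))
  if (length(unique(r)) == 1L)
    warning("all cuts at a single radius; profile has one point")
  bin <- floor(r / bin_width)
  agg_x <- tapply(r, bin, mean)
  agg_m <- tapply(v, bin, mean)
  agg_s <- tapply(v, bin, stats::sd)
  agg_n <- tapply(v, bin, length)
  o <- order(agg_x)
  radial_profile(as.numeric(agg_x[o]), as.numeric(agg_m[o]),
                 kind = "nucleation",
                 sd = as.numeric(agg_s[o]), n = as.numeric(agg_n[o]))
}

#' Microtubule length distribution from cuts at multiple radii
#'
#' The minus-end density \eqn{n_c(y, r)} at a fixed position y, seen through
#' cuts at increasing radii r, decays with r in proportion to the fraction
#' of microtubules at y long enough to span r. For exponential lengths this
#' decay is exponential with the mean length \eqn{\ell}; fitting
#' \eqn{\log n_c(y, r)} against r at several fixed y therefore recovers
#' \eqn{\ell}, and systematic curvature in those regressions flags a
#' non-exponential length distribution.
#'
#' @param estimates List of `"nucleation_estimate"` objects from >= 4
#'   distinct cut radii.
#' @param y_values Fixed positions y, um, at which to evaluate
#'   \eqn{n_c(y, r)}; default a grid over `(0.2, 0.8) * min(r)`.
#' @param min_radii Minimum number of distinct radii.
#' @return A list of class `"length_fit"`: `ell` (um), `ell_se`, `per_y`
#'   (data.frame y, ell_y, r_squared), `flag_nonexponential`,
#'   `distribution` (data.frame length_um, density for the fitted
#'   exponential), `span_radii`.
#' @export
length_distribution <- function(estimates, y_values = NULL, min_radii = 4L) {
  r <- vapply(estimates, function(e) e$r, numeric(1))
  if (length(unique(r)) < min_radii)
    stop("need cuts at >= ", min_radii, " distinct radii")
  if (is.null(y_values))
    y_values <- seq(0.2, 0.8, length.out = 5) * min(r)
  per_y <- do.call(rbind, lapply(y_values, function(y) {
    use <- r > y
    if (sum(use) < 3) return(NULL)
    # n_c(y, r_i): nonparametric minus-end density at y from each cut's
    # retained decay curve, over a 2-um window centered on y
    v <- vapply(estimates[use], function(e)
      minus_end_bins(e, c(max(0, y - 1), min(e$r, y + 1)))$value,
      numeric(1))
    ri <- r[use]
    use2 <- !is.na(v)
    v <- v[use2]; ri <- ri[use2]
    if (length(v) < 3) return(NULL)
    keep <- v > 0
    if (sum(keep) < 3) return(NULL)
    fit <- stats::lm(log(v[keep]) ~ ri[keep])
    sl <- unname(stats::coef(fit)[2])
    # curvature check: quadratic term against the linear model
    curv_p <- if (sum(keep) >= 4) {
      fit2 <- stats::lm(log(v[keep]) ~ ri[keep] + I(ri[keep]^2))
      stats::anova(fit, fit2)[2, "Pr(>F)"]
    } else NA_real_
    data.frame(y = y, ell_y = if (sl < 0) -1 / sl else NA_real_,
               r_squared = summary(fit)$r.squared, curv_p = curv_p)
  }))
  if (is.null(per_y) || all(is.na(per_y$ell_y)))
    stop("length distribution could not be estimated (no decaying n_c)")
  ells <- per_y$ell_y[!is.na(per_y$ell_y)]
  ell <- stats::median(ells)
  # flag on poor log-linearity; a curvature F-test is overpowered on
  # near-noise-free synthetic decays, so the p-values stay diagnostic only
  flag <- stats::median(per_y$r_squared, na.rm = TRUE) < 0.97
  Lgrid <- seq(0, 5 * ell, length.out = 101)
  structure(list(ell = ell,
                 ell_se = stats::sd(ells) / sqrt(max(1, length(ells))),
                 per_y = per_y, flag_nonexponential = flag,
                 distribution = data.frame(length_um = Lgrid,
                                           density = exp(-Lgrid / ell) / ell),
                 span_radii = diff(range(r))),
            class = "length_fit")
}

#' @export
print.length_fit <- function(x, ...) {
  cat(sprintf("Length distribution fit: ell = %.3g um (se %.2g) over a %.3g um span of cut radii\n",
              x$ell, x$ell_se, x$span_radii))
  if (x$flag_nonexponential)
    cat("  WARNING: residuals flag a non-exponential length distribution\n")
  invisible(x)
}

#' One-call ablation analysis of a cut movie or profile stack
#'
#' Runs the full pipeline: differential intensities, angular integration
#' (movies only), wave tracking, velocity, and area-decay analysis.
#'
#' @param x An [image_stack()] or a raw [profile_stack()].
#' @param cut A [cut_spec()].
#' @param fluorescence_at_cut Pre-cut angular intensity integral at the cut
#'   radius, a.u./um; measured from the pre-cut frames when omitted.
#' @param delta_t Differential lag, s; defaults to the cut spec's.
#' @param bin_width Radial bin width for angular integration, um.
#' @return A list: `track` (wave track), `velocity` (`"depol_velocity"`),
#'   `estimate` (`"nucleation_estimate"`).
#' @export
analyze_cut <- function(x, cut, fluorescence_at_cut = NULL, delta_t = NULL,
                        bin_width = 0.5) {
  if (is.null(delta_t)) delta_t <- cut$delta_t
  if (inherits(x, "image_stack")) {
    if (is.null(fluorescence_at_cut))
      fluorescence_at_cut <- fluorescence_at(x, cut$radius, bin_width)
    dif <- differential_intensity(x, delta_t)
    prof <- angular_integrate(dif, bin_width = bin_width)
  } else if (inherits(x, "profile_stack")) {
    if (is.null(fluorescence_at_cut))
      fluorescence_at_cut <- fluorescence_at(x, cut$radius)
    prof <- differential_intensity(x, delta_t)
  } else stop("'x' must be an image_stack or profile_stack")
  track <- fit_wave(prof, cut_radius = cut$radius)
  vel <- depolymerization_velocity(track)
  est <- area_decay_analysis(track, cut, fluorescence_at_cut)
  list(track = track, velocity = vel, estimate = est)
}

#' Pre-cut fluorescence at a given radius
#'
#' Averaged angular intensity integral (a.u. per um of radius) of the
#' pre-cut frames, evaluated at radius `r` by interpolation. Background is
#' removed as the median pixel value (movies) before integration.
#'
#' @param x An [image_stack()] or raw [profile_stack()] containing pre-cut
#'   frames.
#' @param r Radius, um.
#' @param bin_width Radial bin width, um (movies).
#' @return Fluorescence at `r`, a.u./um.
#' @export
fluorescence_at <- function(x, r, bin_width = 0.5) {
  if (inherits(x, "image_stack")) {
    i <- if (is.na(x$cut_time_index)) 1L else seq_len(x$cut_time_index - 1L)
    if (length(i) == 0L) i <- 1L
    fr <- Reduce(`+`, x$frames[i]) / length(i)
    fr <- fr - stats::median(fr)
    ds <- structure(list(frames = list(fr), times = 0,
                         pixel_size = x$pixel_size, center = x$center),
                    class = "diff_stack")
    p <- angular_integrate(ds, bin_width = bin_width)
    stats::approx(p$x, p$values[1, ], xout = r, rule = 2)$y
  } else if (inherits(x, "profile_stack")) {
    i <- if (is.na(x$cut_time_index)) 1L else seq_len(x$cut_time_index - 1L)
    if (length(i) == 0L) i <- 1L
    v <- colMeans(x$values[i, , drop = FALSE])
    stats::approx(x$x, v, xout = r, rule = 2)$y
  } else stop("'x' must be an image_stack or profile_stack")
}
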