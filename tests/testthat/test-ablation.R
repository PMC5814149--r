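test_that("differential intensities: zeros for static movies, linear, conservative", {
  frames <- replicate(6, matrix(3, 16, 16), simplify = FALSE)
  st <- image_stack(frames, 0.5, 0.5, center = c(8.5, 8.5),
                    cut_time_index = 1L)
  d <- differential_intensity(st, 1)
  expect_true(all(vapply(d$frames, function(f) all(f == 0), logical(1))))
  expect_error(differential_intensity(st, 10), "longer than the movie")
  expect_error(differential_intensity(st, 0.7), "multiple")

  # linearity: differential of a summed movie is the sum of differentials
  set.seed(1)
  fa <- replicate(6, matrix(runif(256), 16, 16), simplify = FALSE)
  fb <- replicate(6, matrix(runif(256), 16, 16), simplify = FALSE)
  sa <- image_stack(fa, 0.5, 0.5, c(8.5, 8.5), 1L)
  sb <- image_stack(fb, 0.5, 0.5, c(8.5, 8.5), 1L)
  sab <- image_stack(Map(`+`, fa, fb), 0.5, 0.5, c(8.5, 8.5), 1L)
  da <- differential_intensity(sa, 1)
  db <- differential_intensity(sb, 1)
  dab <- differential_intensity(sab, 1)
  expect_equal(Map(`+`, da$frames, db$frames), dab$frames)

  # conservation on a noise-free cut movie: per-frame differential sums
  # equal the mass depolymerized in each interval times the scale
  p <- params_control()
  op <- optics(img_size = 256L, pixel_size = 0.5, background = 0,
               frame_interval = 0.5)
  fil <- filament_set(c(2, 5, 8), c(20, 10, 30))
  cut <- cut_spec(radius = 12, delta_t = 2)
  stc <- simulate_cut(fil, cut, v_d = 0.56, optics = op, seed = 2,
                      n_frames = 10L)
  dc <- differential_intensity(stc, 2)
  # all three filaments span r=12; each loses v_d*delta_t per interval
  expect_equal(sum(dc$frames[[2]]), 3 * 0.56 * 2 * op$intensity_per_um,
               tolerance = 0.01)
})

test_that("angular integration: delta ring, rotation invariance, line mode", {
  np <- 101
  px <- 0.5
  ctr <- c(51, 51)
  rows <- matrix(seq_len(np), np, np)
  cols <- t(rows)
  rad <- sqrt((rows - 51)^2 + (cols - 51)^2) * px
  ring <- ifelse(abs(rad - 10) < 0.25, 1, 0)
  ring <- ring / sum(ring)  # unit total mass
  ds <- structure(list(frames = list(ring), times = 0, pixel_size = px,
                       center = ctr), class = "diff_stack")
  prof <- angular_integrate(ds, bin_width = 1)
  expect_equal(sum(prof$values[1, ]) * 1, 1, tolerance = 1e-12)
  expect_equal(prof$x[which.max(prof$values[1, ])], 9.5, tolerance = 1)

  # rotationally symmetric input: profile invariant under frame rotation
  blob <- exp(-(rad - 8)^2 / 2)
  ds1 <- structure(list(frames = list(blob), times = 0, pixel_size = px,
                        center = ctr), class = "diff_stack")
  rot <- t(blob)[, np:1]  # 90 degree rotation
  ds2 <- structure(list(frames = list(rot), times = 0, pixel_size = px,
                        center = ctr), class = "diff_stack")
  p1 <- angular_integrate(ds1, bin_width = 1)$values[1, ]
  p2 <- angular_integrate(ds2, bin_width = 1)$values[1, ]
  expect_lt(max(abs(p1 - p2)) / max(p1), 0.02)

  expect_error(angular_integrate(ds, center = c(-3, 4)), "inside")

  # line mode integrates along the cut direction
  pl <- angular_integrate(ds1, direction = "line")
  expect_equal(length(pl$x), np)
  expect_equal(sum(pl$values[1, ]) * px, sum(blob), tolerance = 1e-9)
})

test_that("wave fitting recovers exact Gaussians and flags pathologies", {
  x <- seq(0, 30, by = 0.25)
  gauss <- function(A, c0, s0) A * exp(-(x - c0)^2 / (2 * s0^2))
  vals <- rbind(gauss(3.5, 15, 2), gauss(3.5, 14, 2), gauss(3.5, 13, 2))
  ps <- profile_stack(c(0, 1, 2), x, vals, cut_time_index = 1L,
                      differential = TRUE)
  tr <- fit_wave(ps, cut_radius = 16)
  expect_true(all(tr$accepted))
  expect_equal(tr$center_um, c(15, 14, 13), tolerance = 1e-6)
  expect_equal(tr$sigma_um, rep(2, 3), tolerance = 1e-6)
  expect_equal(tr$area_gauss, rep(3.5 * 2 * sqrt(2 * pi), 3),
               tolerance = 1e-6)

  # two comparable merged peaks raise a quality flag
  merged <- rbind(gauss(3, 15, 1.5) + gauss(2.8, 10.5, 1.5))
  psm <- profile_stack(c(0, 1, 2), x, rbind(merged, merged, merged),
                       cut_time_index = 1L, differential = TRUE)
  trm <- fit_wave(psm, cut_radius = 16)
  expect_true(any(trm$flag == "multi_peak"))

  # no detectable peak anywhere: a "no wave" result, not an error
  flat <- matrix(0, 4, length(x))
  psf <- profile_stack(0:3, x, flat, cut_time_index = 1L,
                       differential = TRUE)
  trf <- fit_wave(psf, cut_radius = 16)
  expect_true(attr(trf, "no_wave"))
})

test_that("depolymerization velocity: exact two-frame slope, flags", {
  # two perfect frames give the exact slope
  tr2 <- structure(data.frame(t_s = c(0, 2), center_um = c(15, 13.88),
                              sigma_um = c(1, 1), area = c(3, 3),
                              area_gauss = c(3, 3),
                              accepted = TRUE, flag = ""),
                   cut_radius = 16, no_wave = FALSE, bin_width = 0.25,
                   class = c("wave_track", "data.frame"))
  v <- depolymerization_velocity(tr2)
  expect_equal(v$v_um_s, 0.56, tolerance = 1e-9)
  expect_equal(v$v_um_min, 33.6, tolerance = 1e-9)

  x <- seq(0, 30, by = 0.25)
  gauss <- function(c0) 3 * exp(-(x - c0)^2 / 8)

  # stationary peak: velocity ~ 0 with a flag
  pss <- profile_stack(0:3, x, t(replicate(4, gauss(15))),
                       cut_time_index = 1L, differential = TRUE)
  vs <- suppressWarnings(
    depolymerization_velocity(fit_wave(pss, cut_radius = 16)))
  expect_lt(vs$v_um_s, 1e-6)
  expect_true("stationary" %in% vs$flags)
})

test_that("area decay analysis matches the brute-force minus-end oracle", {
  p <- params_control()
  fil <- sample_monopole(p, 10000, seed = 42)
  r <- 15
  res <- analyze_profile_cut(fil, r, seed = 7)
  expect_lt(abs(res$velocity$v_um_s / 0.56 - 1), 0.03)

  edges <- seq(0, 14, by = 2)
  truth <- severed_minus_counts(fil, r, edges)
  est <- minus_end_bins(res$estimate, edges)
  big <- truth * 2 >= 100
  expect_true(all(abs(est$value[big] / truth[big] - 1) < 0.05))

  # amplitude linearity: doubling the filament count doubles n_c
  fil2 <- sample_monopole(p, 20000, seed = 42)
  res2 <- analyze_profile_cut(fil2, r, seed = 7)
  expect_equal(res2$estimate$nc_per_length_at_cut /
                 res$estimate$nc_per_length_at_cut, 2, tolerance = 0.1)
})

test_that("flat decay when all minus ends sit at the center", {
  set.seed(2)
  fil <- filament_set(rep(0.01, 400), 20 + runif(400) * 10)
  res <- analyze_profile_cut(fil, r = 12, seed = 3)
  # no minus ends in (0, r): normalized slope at the cut ~ 0
  expect_lt(abs(res$estimate$slope_at_cut), 0.01)
  expect_lt(res$estimate$nc_per_length_at_cut /
              res$estimate$fluorescence_at_cut, 0.01)
})

test_that("assembled nucleation profiles: SD of duplicates, single-radius warning", {
  p <- params_control()
  fil <- sample_monopole(p, 5000, seed = 8)
  e1 <- analyze_profile_cut(fil, 10, seed = 8)$estimate
  e2 <- analyze_profile_cut(fil, 10, seed = 8)$estimate
  expect_warning(prof <- assemble_nucleation_profile(list(e1, e2)),
                 "single radius")
  expect_equal(nrow(prof), 1L)
  expect_equal(prof$sd, 0)

  e3 <- analyze_profile_cut(fil, 14, seed = 8)$estimate
  prof2 <- assemble_nucleation_profile(list(e1, e2, e3))
  expect_equal(nrow(prof2), 2L)
  # per-area and per-length differ by exactly 2*pi*r
  pa <- assemble_nucleation_profile(list(e1, e3), value = "per_area")
  pl <- assemble_nucleation_profile(list(e1, e3), value = "per_length")
  expect_equal(pl$values / pa$values, 2 * pi * c(10, 14), tolerance = 1e-9)
})

test_that("length distribution flags non-exponential truths and thin designs", {
  p <- params_control()
  filD <- sample_monopole(p, 6000, seed = 5)
  filD$length <- rep(10, nrow(filD))
  estD <- lapply(seq(6, 27, by = 3), function(r)
    analyze_profile_cut(filD, r, seed = 5)$estimate)
  lfD <- length_distribution(estD)
  expect_true(lfD$flag_nonexponential)

  expect_error(length_distribution(estD[1:3]), "distinct radii")
})

test_that("bipolar line cuts: two waves tracked on either side", {
  x <- seq(-30, 30, by = 0.25)
  gauss <- function(c0) 4 * exp(-(x - c0)^2 / 2)
  mk <- function(t) gauss(-2 - 0.5 * t) + gauss(2 + 0.5 * t)
  ps <- profile_stack(0:5, x, t(sapply(0:5, mk)), cut_time_index = 1L,
                      differential = TRUE)
  waves <- fit_two_waves(ps, cut_pos = 0)
  vl <- depolymerization_velocity(waves$left)
  vr <- depolymerization_velocity(waves$right)
  expect_equal(vl$v_um_s, 0.5, tolerance = 0.02)
  expect_equal(vr$v_um_s, 0.5, tolerance = 0.02)
})
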