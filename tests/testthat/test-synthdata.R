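test_that("monopole sampler matches the model nucleation profile", {
  p <- params_control()
  expect_equal(nrow(sample_monopole(p, 0, seed = 1)), 0L)

  fil <- sample_monopole(p, 1e5, seed = 42)
  # empirical minus-end distribution vs normalized nu: sup-norm of the CDF
  # discrepancy below 2%, and per-bin densities within sampling error
  gfine <- seq(0, 200, 0.01)
  nufine <- nucleation_profile(p, gfine)$values
  nufine <- nufine / (sum(nufine) * 0.01)
  cdf <- cumsum(nufine) * 0.01
  Fmod <- approxfun(gfine, cdf / max(cdf), rule = 2)
  ks <- suppressWarnings(ks.test(fil$minus_pos, Fmod))
  expect_lt(unname(ks$statistic), 0.02)

  edges <- seq(0, 80, 2)
  cnt <- hist(pmin(fil$minus_pos, 80 - 1e-9), breaks = edges,
              plot = FALSE)$counts
  pb <- vapply(seq_len(40), function(i)
    sum(nufine[gfine >= edges[i] & gfine < edges[i + 1]]) * 0.01,
    numeric(1))
  z <- (cnt - 1e5 * pb) / sqrt(1e5 * pb)
  expect_lt(max(abs(z)), 5)
  expect_lt(abs(mean(fil$length) / 8 - 1), 0.02)

  # deterministic per seed
  expect_identical(fil, sample_monopole(p, 1e5, seed = 42))
  expect_false(identical(fil$minus_pos[1],
                         sample_monopole(p, 10, seed = 43)$minus_pos[1]))
})

test_that("non-normalizable nucleation profiles are rejected", {
  pu <- model_params(ell = 8, ell_u = Inf, rho0 = 1, beta0 = 0.25)
  expect_error(sample_monopole(pu, 100, seed = 1), "normalizable")
})

test_that("rendering is linear, conservative, and background-correct", {
  op <- optics(img_size = 256L, background = 4)
  empty <- render_frame(filament_set(numeric(0)), op, seed = 1)
  expect_true(all(empty == 4))

  f1 <- filament_set(c(10, 20), c(5, 8))
  a <- render_frame(f1, op, angles = c(0.3, 1.2), seed = 1)
  # total background-subtracted intensity = total length * scale
  expect_equal(sum(a - 4), 13 * op$intensity_per_um, tolerance = 1e-6)

  f2 <- filament_set(15, 10)
  b <- render_frame(f2, op, angles = 2.5, seed = 1)
  ab <- render_frame(filament_set(c(10, 20, 15), c(5, 8, 10)), op,
                     angles = c(0.3, 1.2, 2.5), seed = 1)
  expect_equal(a + b - 4, ab, ignore_attr = TRUE, tolerance = 1e-12)

  # doubling total length doubles the integrated signal (inside the field)
  base <- render_frame(filament_set(c(8, 14), c(3, 4)), op,
                       angles = c(0.3, 1.2), seed = 1)
  dbl <- render_frame(filament_set(c(8, 14), c(6, 8)), op,
                      angles = c(0.3, 1.2), seed = 1)
  expect_equal(sum(dbl - 4), 2 * sum(base - 4), tolerance = 1e-6)

  expect_warning(render_frame(filament_set(5, 200), op, angles = 0,
                              seed = 1), "clipped")
})

test_that("cut fixtures are reproducible and flag non-spanning cuts", {
  p <- params_control()
  op <- optics(img_size = 128L, pixel_size = 0.5)
  fx1 <- suppressWarnings(make_cut_fixture(p, 200, r = 10, v_d = 0.56,
                                           optics = op, seed = 9,
                                           n_frames = 5L))
  fx2 <- suppressWarnings(make_cut_fixture(p, 200, r = 10, v_d = 0.56,
                                           optics = op, seed = 9,
                                           n_frames = 5L))
  expect_identical(fx1$stack$frames, fx2$stack$frames)
  expect_identical(fx1$filaments, fx2$filaments)

  far <- max(fx1$filaments$minus_pos + fx1$filaments$length) + 5
  fx3 <- suppressWarnings(make_cut_fixture(p, 200, r = far, v_d = 0.56,
                                           optics = op, seed = 9,
                                           n_frames = 4L))
  expect_true(attr(fx3$stack, "no_spanning"))
})
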