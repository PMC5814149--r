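test_that("density profile boundary value, no-branching limit, and argmax", {
  p <- params_mcak()
  g <- seq(0, 80, by = 0.01)
  rho <- density_profile(p, g)
  expect_equal(rho$values[1], p$rho0)
  expect_true(all(rho$values > 0))

  # no branching: pure exponential decay with the mean length
  p0 <- model_params(ell = 8, ell_u = 24.9, alpha = 0, rho0 = 3)
  r0 <- density_profile(p0, g)
  expect_equal(r0$values, 3 * exp(-g / 8), tolerance = 1e-12)

  # peak location: closed form ell_u*log(alpha*ell/ell_u) vs brute-force
  # grid search at 0.01 um
  x_peak <- g[which.max(rho$values)]
  expect_equal(x_peak, 24.9 * log(2.38 * 24 / 24.9), tolerance = 1e-3)
})

test_that("uniform activation mode: constant gain, unbounded when b0*ell > 1", {
  pu <- model_params(ell = 8, ell_u = Inf, alpha = NA, rho0 = 1,
                     beta0 = 0.25)  # beta0*ell = 2 > 1
  g <- seq(0, 50, by = 1)
  rho <- density_profile(pu, g)
  expect_equal(rho$values, exp((0.25 - 1 / 8) * g), tolerance = 1e-12)
  expect_true(all(diff(rho$values) > 0))  # exponential growth in x
  expect_false(growth_regime(pu)$bounded)
  pu2 <- model_params(ell = 8, ell_u = Inf, rho0 = 1, beta0 = 0.1)
  expect_true(growth_regime(pu2)$bounded)
})

test_that("nucleation profile: zero without branching, monotone for the short-length regime, ODE consistency", {
  g <- seq(0, 60, by = 0.01)
  p0 <- model_params(ell = 8, ell_u = 24.9, alpha = 0, rho0 = 5)
  expect_true(all(nucleation_profile(p0, g)$values == 0))

  pC <- params_control()
  nu <- nucleation_profile(pC, g)
  expect_true(all(diff(nu$values) < 0))

  # central difference of rho equals nu/A - rho/ell to ~1e-6 relative
  A <- 2.5
  nuA <- nucleation_profile(pC, g, amplitude = A)
  rho <- density_profile(pC, g)
  n <- length(g)
  drho <- (rho$values[3:n] - rho$values[1:(n - 2)]) / (2 * 0.01)
  rhs <- (nuA$values / A - rho$values / 8)[2:(n - 1)]
  expect_lt(max(abs(drho - rhs) / pmax(abs(rhs), 1e-12)), 1e-6)
})

test_that("rescaling between conditions is exact and invertible", {
  pM <- params_mcak()
  g <- seq(0, 80, length.out = 400)
  prof <- density_profile(pM, g)
  expect_equal(rescale_profile(prof, 24, 24)$values, prof$values)

  # the printed multiplicative factor at x = 12 for 24 -> 8 um
  r12 <- rescale_profile(radial_profile(12, 1, "density"), 24, 8)
  expect_equal(r12$values, exp(-1), tolerance = 1e-12)

  back <- rescale_profile(rescale_profile(prof, 24, 8), 8, 24)
  expect_equal(back$values, prof$values, tolerance = 1e-12)

  # rescaling identity: the rescaled long-length profile IS the
  # short-length profile of the same gradient parameters
  pC <- model_params(ell = 8, ell_u = 24.9, alpha = 2.38, rho0 = 4058)
  direct <- density_profile(pC, g)
  resc <- rescale_profile(prof, 24, 8)
  expect_equal(resc$values, direct$values, tolerance = 1e-12)
})

test_that("reproductive number: central values, criticality radius, verdicts", {
  pM <- params_mcak()
  pC <- params_control()
  expect_equal(reproductive_number(pM, 0), 2.38 * 24 / 24.9,
               tolerance = 1e-12)
  expect_equal(reproductive_number(pC, 0), 2.38 * 8 / 24.9,
               tolerance = 1e-12)
  expect_lt(reproductive_number(pC, 0), 1)

  # R(x) = 1 radius coincides with the density argmax when R(0) > 1
  gr <- growth_regime(pM)
  expect_true(gr$bounded)
  g <- seq(0, 80, by = 0.01)
  x_peak <- g[which.max(density_profile(pM, g)$values)]
  expect_equal(gr$critical_radius, x_peak, tolerance = 1e-2)
  expect_equal(reproductive_number(pM, gr$critical_radius), 1,
               tolerance = 1e-10)

  p0 <- model_params(ell = 8, ell_u = 24.9, alpha = 0, rho0 = 1)
  expect_equal(reproductive_number(p0, c(0, 10, 30)), c(0, 0, 0))
  expect_true(all(diff(reproductive_number(pM, seq(0, 50, 5))) < 0))
})

test_that("counterpart prediction equals the rescaled fitted curve", {
  pM <- params_mcak()
  g <- seq(0, 80, length.out = 300)
  pred <- predict_counterpart(pM, 8, g)
  resc <- rescale_profile(density_profile(pM, g), 24, 8)
  expect_equal(pred$values, resc$values, tolerance = 1e-12)
  expect_equal(predict_counterpart(pM, pM$ell, g)$values,
               density_profile(pM, g)$values)
  expect_true(all(diff(pred$values) < 0))  # short-length regime is monotone
})

test_that("parameter and grid validation raise errors", {
  expect_error(model_params(ell = -1, ell_u = 10, alpha = 1))
  expect_error(model_params(ell = 8, ell_u = 10, alpha = -0.5))
  expect_error(model_params(ell = 8, ell_u = Inf, alpha = 1))  # no beta0
  p <- params_control()
  expect_error(density_profile(p, c(0, NA, 2)))
  expect_error(density_profile(p, c(0, 2, 1)))
  expect_error(density_profile(p, c(-1, 0, 1)))
  expect_error(rescale_profile(density_profile(p, 0:10), -3, 8))
  expect_error(nucleation_profile(p, 0:10, amplitude = 0))
})

test_that("density fit recovers parameters and flags degenerate input", {
  truth <- model_params(ell = 24, ell_u = 24.9, alpha = 2.38, rho0 = 4058)
  g <- seq(0, 80, length.out = 100)
  prof <- density_profile(truth, g)
  f <- fit_density(prof, ell_fixed = 24)
  expect_true(f$converged)
  expect_false(f$degenerate)
  expect_equal(f$params$ell_u, 24.9, tolerance = 1e-4)
  expect_equal(f$params$alpha, 2.38, tolerance = 1e-4)
  expect_equal(f$params$rho0, 4058, tolerance = 1e-4)

  # noisy recovery at 5% multiplicative noise (quick version; the full
  # 50-seed study runs in the acceptance suite)
  errs <- sapply(1:5, function(s) {
    set.seed(s)
    noisy <- radial_profile(g, prof$values * (1 + 0.05 * rnorm(100)),
                            kind = "density")
    fn <- fit_density(noisy, ell_fixed = 24)
    abs(c(fn$params$ell_u / 24.9, fn$params$alpha / 2.38) - 1)
  })
  expect_lt(median(errs[1, ]), 0.1)
  expect_lt(median(errs[2, ]), 0.1)

  flat <- radial_profile(g, rep(7, 100), kind = "density")
  expect_true(fit_density(flat, ell_fixed = 24)$degenerate)
  expect_error(fit_density(density_profile(truth, seq(0, 10, 2)), 24))
})
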