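test_that("truncated first-passage density integrates to one and matches its CDF", {
  for (tau in c(40, 240)) {
    Z <- integrate(function(t) dlifetime(t, tau, t_min = 2), 2, Inf,
                   rel.tol = 1e-10)$value
    expect_equal(Z, 1, tolerance = 1e-6)
    # CDF against numeric integration of the density at a few quantiles
    for (q in c(5, 20, 100)) {
      Fq <- integrate(function(t) dlifetime(t, tau, t_min = 2), 2, q,
                      rel.tol = 1e-10)$value
      expect_equal(plifetime(q, tau, t_min = 2), Fq, tolerance = 1e-6)
    }
  }
})

test_that("maximum-likelihood fit recovers tau and reports tau/4 and theta", {
  taus <- sapply(1:20, function(s) {
    set.seed(s)
    fit_lifetime(rlifetime(5000, 79.2, t_min = 2), t_min = 2)$tau
  })
  expect_lt(abs(median(taus) / 79.2 - 1), 0.1)

  set.seed(7)
  f <- fit_lifetime(rlifetime(5000, 80, t_min = 2), t_min = 2)
  expect_equal(f$mean_lifetime, f$tau / 4)
  expect_equal(f$theta, 4 / f$tau)
  expect_false(f$gof_flag)
  expect_true(is.data.frame(f$tau_sensitivity))
})

test_that("goodness-of-fit diagnostic flags exponential data", {
  set.seed(11)
  x <- rexp(8000, 1 / 30)
  x <- x[x >= 2]
  f <- fit_lifetime(x, t_min = 2)
  expect_true(f$gof_flag)
})

test_that("histogram fit mode agrees roughly with the MLE", {
  set.seed(3)
  x <- rlifetime(5000, 80, t_min = 2)
  fm <- fit_lifetime(x, t_min = 2)
  fh <- fit_lifetime(x, t_min = 2, method = "histogram")
  expect_lt(abs(fh$tau / fm$tau - 1), 0.25)
})

test_that("first-passage simulator: pure drift is exact, mean is L0/v", {
  s <- simulate_speckle_lifetimes(L0 = 8, v = 0.5, D = 0, n = 50, seed = 1)
  expect_true(all(s$duration == 16))
  expect_true(all(!s$censored))

  s2 <- simulate_speckle_lifetimes(L0 = 8, v = 0.5, D = 2, n = 10000,
                                   seed = 2)
  se <- sd(s2$duration) / sqrt(nrow(s2))
  expect_lt(abs(mean(s2$duration) - 16), 3 * se)
})

test_that("driftless first passage has the -3/2 power-law tail", {
  s <- simulate_speckle_lifetimes(L0 = 1, v = 0, D = 0.5, n = 30000,
                                  seed = 3, dt = 0.01, t_max = 60)
  t <- s$duration[!s$censored]
  edges <- exp(seq(log(5), log(50), length.out = 13))
  h <- hist(t[t >= 5 & t <= 50], breaks = edges, plot = FALSE)
  dens <- h$counts / diff(edges)
  fit <- lm(log(dens) ~ log(h$mids), weights = h$counts)
  expect_lt(abs(unname(coef(fit)[2]) + 1.5), 0.1)
})

test_that("lifetime / turnover conversions", {
  expect_equal(mean_lifetime_to_turnover(20), 0.05)
  expect_equal(mean_lifetime_to_turnover(60.4), 1 / 60.4)
  expect_equal(mean_lifetime_to_turnover(mean_lifetime_to_turnover(17)), 17)
  expect_error(mean_lifetime_to_turnover(0))
})

test_that("speckle tables censor by movie length, monotonically", {
  p <- params_control()
  tab_inf <- make_speckle_table(p, v_d = 0.56, D = 0.5, n = 400,
                                movie_length = Inf, seed = 5)
  expect_equal(nrow(tab_inf), 400)
  expect_true(all(!tab_inf$censored))

  fracs <- sapply(c(600, 120, 30), function(L)
    mean(make_speckle_table(p, v_d = 0.56, D = 0.5, n = 400,
                            movie_length = L, seed = 5)$censored))
  expect_true(all(diff(fracs) > 0))
})

test_that("fit uses only uncensored events and enforces preconditions", {
  set.seed(4)
  x <- rlifetime(300, 80, t_min = 2)
  samp <- lifetime_sample(c(x, rep(500, 3000)),
                          censored = c(rep(FALSE, 300), rep(TRUE, 3000)))
  f <- fit_lifetime(samp, t_min = 2)
  expect_equal(f$n_used, 300)
  expect_error(fit_lifetime(x[1:50], t_min = 2))
  expect_error(fit_lifetime(x, t_min = -1))
})
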