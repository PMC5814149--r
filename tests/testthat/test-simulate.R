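test_that("empty system stays empty and seeds are reproducible", {
  cfg <- sim_config(seed = 1, k_act = 0, k_seed = 0, t_end = 5)
  res <- sim_run(cfg)
  expect_equal(length(res$state$fil_len), 0L)
  expect_equal(length(res$state$nu_pos), 0L)

  cfg2 <- sim_config(seed = 3, t_end = 30)
  r1 <- sim_run(cfg2)
  r2 <- sim_run(cfg2)
  expect_identical(r1$state, r2$state)
  expect_identical(r1$density$values, r2$density$values)
  r3 <- sim_run(sim_config(seed = 4, t_end = 30))
  expect_false(identical(r1$state$fil_minus, r3$state$fil_minus))
})

test_that("config validation enforces rates and dt stability", {
  expect_error(sim_config(k_on = -1), "non-negative")
  expect_error(sim_config(chrom_radius = 200), "smaller")
  expect_error(sim_config(dt = 0.2, k_off = 2), "unstable")
  expect_error(sim_config(obstacle = c(1, 5)), "outside the chromatin")
  expect_error(sim_config(obstacle = c(20, 10)))
})

test_that("bound-nucleator nucleation is Poisson at rate k_nuc", {
  # one immortal filament, one bound nucleator, no other processes:
  # nucleation events over n steps are Binomial(n, k_nuc*dt) ~ Poisson
  cfg <- sim_config(seed = 2, k_act = 0, k_seed = 0, k_inact = 0,
                    k_off = 0, k_nuc = 0.25, v_p = 0, theta = 0,
                    dt = 0.04, t_end = 40)
  st <- sim_init(cfg, filament_set(5, 10))
  set.seed(2)
  n_steps <- 10000
  for (i in seq_len(n_steps)) {
    # re-pin the nucleator to the host (nucleation releases it)
    st$nb_pos <- 8
    st$nb_fid <- 1L
    st$nu_pos <- numeric(0)
    st <- sim_step(st, cfg)
  }
  births <- st$next_id - 2L  # minus the host filament
  lambda <- n_steps * 0.25 * 0.04
  expect_lt(abs(births - lambda), 3 * sqrt(lambda))
})

test_that("without branching the chromatin-seeded density decays with ell = v_p/theta", {
  # k_nuc = 0: only chromatin seeding; steady profile ~ exp(-x/ell)
  cfg <- sim_config(seed = 10, k_nuc = 0, k_act = 0, k_seed = 6,
                    chrom_radius = 1, t_end = 400, domain_length = 60)
  dens <- 0
  for (s in 1:3) {
    cfg$seed <- 10 + s
    r <- sim_run(cfg)
    dens <- dens + r$density$values
  }
  x <- r$density$x
  sel <- x > 2 & x < 35 & dens > 0
  fit <- lm(log(dens[sel]) ~ x[sel])
  ell_hat <- -1 / unname(coef(fit)[2])
  expect_lt(abs(ell_hat / (0.35 / 0.05) - 1), 0.1)
})

test_that("steady-state lengths are exponential (removal mode)", {
  lens <- c()
  for (s in 1:4)
    lens <- c(lens, sim_run(sim_config(seed = 20 + s, t_end = 250,
                                       k_seed = 6))$state$fil_len)
  lens <- lens[lens > 0]
  ks <- suppressWarnings(ks.test(lens, "pexp", rate = 1 / mean(lens)))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(lens) / 7 - 1), 0.2)
})

test_that("simulator state invariants hold after a run", {
  res <- sim_run(sim_config(seed = 6, t_end = 150))
  st <- res$state
  expect_true(all(st$fil_len >= 0))
  expect_true(all(st$fil_minus >= 0 &
                    st$fil_minus <= res$config$domain_length))
  # every bound nucleator's host filament exists
  expect_false(anyNA(match(st$nb_fid, st$fil_id)))
  expect_true(all(st$nu_pos >= 0 &
                    st$nu_pos <= res$config$domain_length))
})

test_that("filaments never extend into an obstacle", {
  cfg <- sim_config(seed = 7, domain_length = 60, obstacle = c(8, 16),
                    t_end = 150)
  st <- sim_run(cfg)$state
  plus <- st$fil_minus + st$fil_len
  expect_true(all(plus[st$fil_minus < 8] <= 8 + 1e-9))
  expect_false(any(st$fil_minus >= 8 & st$fil_minus < 16))
})

test_that("zero-width obstacles do not block growth", {
  cfg <- sim_config(seed = 8, domain_length = 60, obstacle = c(10, 10),
                    t_end = 100)
  expect_null(cfg$obstacle)
})

test_that("catastrophe turnover mode shrinks and removes filaments", {
  cfg <- sim_config(seed = 9, turnover_mode = "catastrophe", k_cat = 0.1,
                    v_d = 0.56, t_end = 100, k_nuc = 0)
  res <- sim_run(cfg)
  expect_true(all(res$state$fil_len >= 0))
  expect_gt(length(res$state$fil_len), 0)
  expect_gt(res$state$next_id, length(res$state$fil_len) + 1)  # removals happened
})

test_that("ran wave: front advances under uniform supercriticality, not with v_p = 0", {
  pre <- sim_config(seed = 3, domain_length = 60, t_end = 150)
  pre_res <- sim_run(pre)
  wave <- sim_config(seed = 3, domain_length = 60, t_end = 60,
                     uniform_activation = TRUE, k_act = 150, k_seed = 0)
  rw <- ran_wave(pre, wave, pre_result = pre_res)
  expect_false(rw$no_front)
  expect_gt(rw$speed_um_s, 0.1)
  expect_true(all(diff(rw$front$front_um) >= -1))

  wave0 <- sim_config(seed = 3, domain_length = 60, t_end = 40,
                      uniform_activation = TRUE, k_act = 150, k_seed = 0,
                      v_p = 0)
  rw0 <- ran_wave(pre, wave0, pre_result = pre_res)
  expect_true(rw0$no_front)
  expect_lt(rw0$speed_um_s, 0.02)
})

test_that("front speed is set by filament growth, not nucleator diffusion", {
  pre <- sim_config(seed = 5, domain_length = 60, t_end = 150)
  pre_res <- sim_run(pre)
  speeds <- sapply(c(5, 20), function(D) {
    wave <- sim_config(seed = 5, domain_length = 60, t_end = 60,
                       uniform_activation = TRUE, k_act = 150,
                       k_seed = 0, D = D)
    ran_wave(pre, wave, pre_result = pre_res)$speed_um_s
  })
  # a 4-fold change in D leaves the speed unchanged within estimation error
  expect_lt(abs(speeds[2] - speeds[1]),
            0.25 * mean(speeds) + 0.05)
})
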