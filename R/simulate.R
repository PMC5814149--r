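#' Configuration of the stochastic nucleator-filament simulator
#'
#' An agent-based, fixed-step (tau-leaping) 1D radial simulation of the
#' autocatalytic nucleation system: inactive nucleators are activated in a
#' chromatin zone around the center, diffuse, inactivate at a constant
#' rate, bind and unbind microtubules, and - once bound - nucleate new
#' microtubules that grow outward at the polymerization speed and turn
#' over. Positions are distances from the center; the 2D embedding happens
#' only at rendering time.
#'
#' Default kinetic rates are not experimental measurements (the binding,
#' unbinding and nucleation rates of the nucleator machinery are unknown);
#' they were chosen by mean-field analysis to produce a subcritical
#' structure with a branching amplitude near 2.4 and a nucleator gradient
#' length near 25 um, the regime of the measured monopoles.
#'
#' @param domain_length Domain size, um.
#' @param chrom_radius Chromatin activation zone `[0, chrom_radius]`, um.
#' @param k_act Activation events per second (in the zone; everywhere under
#'   `uniform_activation`).
#' @param D Nucleator diffusion coefficient, um^2/s.
#' @param k_inact Nucleator inactivation rate, 1/s (gradient length
#'   `sqrt(D/k_inact)`).
#' @param k_on Binding rate per um of filament overlapping the nucleator's
#'   capture neighborhood, 1/(um s).
#' @param capture_radius Capture half-width, um.
#' @param k_off Unbinding rate, 1/s.
#' @param k_nuc Nucleation rate per bound nucleator, 1/s (per unbound
#'   active nucleator under `independent_nucleation`).
#' @param k_seed Spontaneous (chromatin-driven) nucleation events per
#'   second, uniform in the activation zone; seeds the autocatalytic wave.
#' @param v_p Plus-end polymerization speed, um/s.
#' @param turnover_mode `"removal"` (whole filaments disappear at rate
#'   `theta`; clean mapping to the steady-state model) or `"catastrophe"`
#'   (filaments switch at rate `k_cat` and then shrink at `v_d`).
#' @param theta Whole-filament turnover rate, 1/s (removal mode).
#' @param k_cat Catastrophe rate, 1/s (catastrophe mode).
#' @param v_d Depolymerization speed, um/s (catastrophe mode).
#' @param dt Time step, s; `dt` times the largest per-particle total rate
#'   must stay below 0.1.
#' @param t_end Simulated time, s.
#' @param seed Integer RNG seed.
#' @param uniform_activation Activate nucleators uniformly over the whole
#'   domain (the constitutively-active-Ran condition).
#' @param independent_nucleation Nucleation by unbound active nucleators at
#'   their position, without a microtubule host (the alternative,
#'   microtubule-independent hypothesis); the bound pathway is disabled.
#' @param obstacle Optional interval `c(a, b)`, um: filaments cannot extend
#'   into it, nucleation cannot occur inside it, nucleator diffusion is
#'   unaffected. Must lie strictly outside the chromatin zone.
#' @param bin_width Spatial bin width for recorded profiles, um.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(domain_length = 100, chrom_radius = 3, k_act = 20,
                       D = 10, k_inact = 0.016, k_on = 0.0013,
                       capture_radius = 0.25, k_off = 2, k_nuc = 0.4,
                       k_seed = 4, v_p = 0.35,
                       turnover_mode = c("removal", "catastrophe"),
                       theta = 0.05, k_cat = 0.05, v_d = 0.56, dt = 0.04,
                       t_end = 300, seed = 1L, uniform_activation = FALSE,
                       independent_nucleation = FALSE, obstacle = NULL,
                       bin_width = 1) {
  turnover_mode <- match.arg(turnover_mode)
  rates <- c(k_act, D, k_inact, k_on, k_off, k_nuc, k_seed, v_p, theta,
             k_cat, v_d)
  if (any(rates < 0)) stop("all rates must be non-negative")
  if (chrom_radius >= domain_length)
    stop("chromatin zone must be smaller than the domain")
  fixed_rate <- max(k_inact + k_off + k_nuc, k_inact,
                    if (turnover_mode == "removal") theta else k_cat)
  if (dt * fixed_rate >= 0.1)
    stop(sprintf("dt unstable: dt * max rate = %.3g >= 0.1", dt * fixed_rate))
  if (!is.null(obstacle)) {
    if (length(obstacle) != 2 || obstacle[1] > obstacle[2])
      stop("'obstacle' must be c(a, b) with a <= b")
    if (obstacle[1] <= chrom_radius)
      stop("obstacle must lie strictly outside the chromatin zone")
    if (diff(obstacle) <= 0) obstacle <- NULL  # zero width: no obstacle
  }
  structure(list(domain_length = domain_length, chrom_radius = chrom_radius,
                 k_act = k_act, D = D, k_inact = k_inact, k_on = k_on,
                 capture_radius = capture_radius, k_off = k_off,
                 k_nuc = k_nuc, k_seed = k_seed, v_p = v_p,
                 turnover_mode = turnover_mode, theta = theta, k_cat = k_cat,
                 v_d = v_d, dt = dt, t_end = t_end, seed = as.integer(seed),
                 uniform_activation = isTRUE(uniform_activation),
                 independent_nucleation = isTRUE(independent_nucleation),
                 obstacle = obstacle, bin_width = bin_width),
            class = "sim_config")
}

#' Initialize an empty simulator state
#'
#' @param config A [sim_config()].
#' @param filaments Optional initial [filament_set()].
#' @param nucleators Optional positions of pre-existing active unbound
#'   nucleators, um; `"steady"` draws the steady-state pool size
#'   `k_act/k_inact` uniformly over the activation region (useful for
#'   uniform-activation runs, where building the pool from scratch takes
#'   `1/k_inact` seconds).
#' @return A `"sim_state"` list (filament vectors, nucleator pools, time).
#' @export
sim_init <- function(config, filaments = NULL, nucleators = NULL) {
  st <- list(fil_minus = numeric(0), fil_len = numeric(0),
             fil_birth = numeric(0), fil_id = integer(0),
             fil_shrink = logical(0), next_id = 1L,
             nu_pos = numeric(0),      # active unbound
             nb_pos = numeric(0), nb_fid = integer(0),  # active bound
             t = 0)
  if (!is.null(filaments) && nrow(filaments) > 0) {
    n <- nrow(filaments)
    st$fil_minus <- filaments$minus_pos
    st$fil_len <- filaments$length
    st$fil_birth <- filaments$birth_time
    st$fil_id <- seq_len(n)
    st$fil_shrink <- rep(FALSE, n)
    st$next_id <- n + 1L
  }
  if (identical(nucleators, "steady")) {
    n0 <- round(config$k_act / max(config$k_inact, 1e-12))
    hi <- if (config$uniform_activation) config$domain_length
          else config$chrom_radius
    nucleators <- stats::runif(n0, 0, hi)
  }
  if (!is.null(nucleators)) st$nu_pos <- as.numeric(nucleators)
  class(st) <- "sim_state"
  st
}

#' Advance the simulator by one time step
#'
#' One fixed-step stochastic update, in order: activation (Poisson, in the
#' chromatin zone or everywhere), diffusion of unbound nucleators (Gaussian
#' steps, reflecting at both boundaries), inactivation, unbinding, binding
#' to filament length within the capture neighborhood (exact overlapping
#' length from sorted cumulative coverage; the host is drawn with
#' probability proportional to its overlap), nucleation (a new zero-length
#' filament at the nucleator's position), chromatin-driven seeding, plus-end
#' growth with obstacle and domain clamping, and turnover. Refuses to step
#' when the binding probability of any nucleator exceeds 0.1 (tau-leaping
#' instability).
#'
#' @param state A `"sim_state"`.
#' @param config A [sim_config()].
#' @return The updated `"sim_state"`.
#' @export
sim_step <- function(state, config) {
  dt <- config$dt
  L <- config$domain_length
  obs <- config$obstacle

  # activation
  n_act <- stats::rpois(1L, config$k_act * dt)
  if (n_act > 0) {
    new_pos <- if (config$uniform_activation) stats::runif(n_act, 0, L)
               else stats::runif(n_act, 0, config$chrom_radius)
    state$nu_pos <- c(state$nu_pos, new_pos)
  }

  # diffusion with reflection
  nu <- length(state$nu_pos)
  if (nu > 0) {
    p <- state$nu_pos + stats::rnorm(nu, sd = sqrt(2 * config$D * dt))
    p <- abs(p)
    p <- L - abs(L - p)
    state$nu_pos <- p
  }

  # inactivation (both pools)
  if (config$k_inact > 0) {
    if (length(state$nu_pos))
      state$nu_pos <- state$nu_pos[stats::runif(length(state$nu_pos)) >=
                                     config$k_inact * dt]
    if (length(state$nb_pos)) {
      keep <- stats::runif(length(state$nb_pos)) >= config$k_inact * dt
      state$nb_pos <- state$nb_pos[keep]
      state$nb_fid <- state$nb_fid[keep]
    }
  }

  if (!config$independent_nucleation) {
    # unbinding
    if (length(state$nb_pos) && config$k_off > 0) {
      ub <- stats::runif(length(state$nb_pos)) < config$k_off * dt
      if (any(ub)) {
        state$nu_pos <- c(state$nu_pos, state$nb_pos[ub])
        state$nb_pos <- state$nb_pos[!ub]
        state$nb_fid <- state$nb_fid[!ub]
      }
    }
    # binding
    if (length(state$nu_pos) && length(state$fil_minus) &&
        config$k_on > 0) {
      w <- config$capture_radius
      G <- coverage_integral_fun(state$fil_minus,
                                 state$fil_minus + state$fil_len)
      ov <- pmax(0, G(state$nu_pos + w) - G(state$nu_pos - w))
      p_bind <- config$k_on * ov * dt
      if (max(p_bind) >= 0.1)
        stop(sprintf(
          "dt unstable: binding probability per step reached %.3g (>= 0.1); reduce dt",
          max(p_bind)))
      bind <- stats::runif(length(p_bind)) < p_bind
      if (any(bind)) {
        bpos <- state$nu_pos[bind]
        plus <- state$fil_minus + state$fil_len
        hosts <- vapply(bpos, function(q) {
          cand <- which(state$fil_minus < q + w & plus > q - w)
          wt <- pmin(plus[cand], q + w) - pmax(state$fil_minus[cand], q - w)
          if (length(cand) == 1L) cand else
            sample(cand, 1L, prob = pmax(wt, 1e-12))
        }, integer(1))
        state$nb_pos <- c(state$nb_pos, bpos)
        state$nb_fid <- c(state$nb_fid, state$fil_id[hosts])
        state$nu_pos <- state$nu_pos[!bind]
      }
    }
    # microtubule-stimulated nucleation by bound nucleators; nucleation
    # ends the binding episode (the nucleator is released in place), so a
    # single binding event yields at most one daughter
    if (length(state$nb_pos) && config$k_nuc > 0) {
      nuc <- stats::runif(length(state$nb_pos)) < config$k_nuc * dt
      if (any(nuc)) {
        state <- add_filaments(state, state$nb_pos[nuc])
        state$nu_pos <- c(state$nu_pos, state$nb_pos[nuc])
        state$nb_pos <- state$nb_pos[!nuc]
        state$nb_fid <- state$nb_fid[!nuc]
      }
    }
  } else {
    # independent nucleation: unbound active nucleators nucleate in place
    if (length(state$nu_pos) && config$k_nuc > 0) {
      nuc <- stats::runif(length(state$nu_pos)) < config$k_nuc * dt
      pos <- state$nu_pos[nuc]
      if (!is.null(obs)) pos <- pos[pos < obs[1] | pos > obs[2]]
      if (length(pos)) state <- add_filaments(state, pos)
    }
  }

  # chromatin-driven seeding
  n_seed <- stats::rpois(1L, config$k_seed * dt)
  if (n_seed > 0)
    state <- add_filaments(state,
                           stats::runif(n_seed, 0, config$chrom_radius))

  # growth with obstacle and domain clamping
  if (length(state$fil_len)) {
    grow <- !state$fil_shrink
    state$fil_len[grow] <- state$fil_len[grow] + config$v_p * dt
    if (!is.null(obs)) {
      blocked <- state$fil_minus < obs[1] &
        state$fil_minus + state$fil_len > obs[1]
      state$fil_len[blocked] <- obs[1] - state$fil_minus[blocked]
    }
    over <- state$fil_minus + state$fil_len > L
    state$fil_len[over] <- L - state$fil_minus[over]
  }

  # turnover
  nf <- length(state$fil_len)
  if (nf) {
    if (config$turnover_mode == "removal") {
      gone <- stats::runif(nf) < config$theta * dt
      if (any(gone)) state <- drop_filaments(state, gone)
    } else {
      cat_now <- !state$fil_shrink &
        stats::runif(nf) < config$k_cat * dt
      state$fil_shrink[cat_now] <- TRUE
      shr <- state$fil_shrink
      state$fil_len[shr] <- state$fil_len[shr] - config$v_d * dt
      gone <- state$fil_len <= 0
      if (any(gone)) state <- drop_filaments(state, gone)
    }
  }
  # release bound nucleators that the shrinking plus end has passed
  if (length(state$nb_pos)) {
    idx <- match(state$nb_fid, state$fil_id)
    off_end <- state$nb_pos > state$fil_minus[idx] + state$fil_len[idx]
    off_end[is.na(off_end)] <- TRUE
    if (any(off_end)) {
      state$nu_pos <- c(state$nu_pos, state$nb_pos[off_end])
      state$nb_pos <- state$nb_pos[!off_end]
      state$nb_fid <- state$nb_fid[!off_end]
    }
  }
  state$t <- state$t + dt
  state
}

add_filaments <- function(state, minus_pos) {
  n <- length(minus_pos)
  state$fil_minus <- c(state$fil_minus, minus_pos)
  state$fil_len <- c(state$fil_len, numeric(n))
  state$fil_birth <- c(state$fil_birth, rep(state$t, n))
  state$fil_id <- c(state$fil_id, seq.int(state$next_id,
                                          length.out = n))
  state$fil_shrink <- c(state$fil_shrink, rep(FALSE, n))
  state$next_id <- state$next_id + n
  state
}

drop_filaments <- function(state, gone) {
  # bound nucleators on removed hosts return to the unbound pool in place
  if (length(state$nb_pos)) {
    lost <- state$nb_fid %in% state$fil_id[gone]
    if (any(lost)) {
      state$nu_pos <- c(state$nu_pos, state$nb_pos[lost])
      state$nb_pos <- state$nb_pos[!lost]
      state$nb_fid <- state$nb_fid[!lost]
    }
  }
  state$fil_minus <- state$fil_minus[!gone]
  state$fil_len <- state$fil_len[!gone]
  state$fil_birth <- state$fil_birth[!gone]
  state$fil_id <- state$fil_id[!gone]
  state$fil_shrink <- state$fil_shrink[!gone]
  state
}

#' Run the simulator to its end time
#'
#' Advances [sim_step()] to `t_end`, recording the total polymer mass on a
#' fixed schedule and time-averaged spatial profiles (binned filament
#' coverage and unbound-nucleator density) after a burn-in. Deterministic
#' given the config seed.
#'
#' @param config A [sim_config()].
#' @param init_filaments Optional initial [filament_set()].
#' @param init_nucleators Optional initial unbound-nucleator positions, or
#'   `"steady"` (see [sim_init()]).
#' @param init_state Optional `"sim_state"` to continue from (overrides
#'   `init_filaments`; the RNG is reseeded from `config$seed`).
#' @param record_interval Mass-recording interval, s.
#' @param burnin Time before profile averaging starts, s (default
#'   `t_end/2`).
#' @param snapshot_interval If not `NULL`, also store instantaneous density
#'   profiles every `snapshot_interval` seconds.
#' @return A list of class `"sim_result"`: `state`, `filaments`
#'   ([filament_set()]), `density` and `nucleators` ([radial_profile()]s,
#'   per-um time averages), `mass` (data.frame `t_s`,
#'   `total_length_um`), `snapshots` (optional list of `t`/`profile`),
#'   `config`.
#' @export
sim_run <- function(config, init_filaments = NULL, init_nucleators = NULL,
                    init_state = NULL, record_interval = 1, burnin = NULL,
                    snapshot_interval = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(burnin)) burnin <- config$t_end / 2
  set.seed(config$seed)
  state <- if (!is.null(init_state)) init_state
           else sim_init(config, init_filaments, init_nucleators)
  t0 <- state$t
  n_steps <- ceiling(config$t_end / config$dt)
  rec_every <- max(1L, round(record_interval / config$dt))
  snap_every <- if (is.null(snapshot_interval)) NA_integer_ else
    max(1L, round(snapshot_interval / config$dt))

  edges <- seq(0, config$domain_length, by = config$bin_width)
  xmid <- edges[-1] - config$bin_width / 2
  dens_acc <- numeric(length(xmid))
  nuc_acc <- numeric(length(xmid))
  n_avg <- 0L
  mass_t <- numeric(0); mass_v <- numeric(0)
  snapshots <- list()

  for (k in seq_len(n_steps)) {
    state <- sim_step(state, config)
    if (k %% rec_every == 0L) {
      mass_t <- c(mass_t, state$t)
      mass_v <- c(mass_v, sum(state$fil_len))
      if (state$t - t0 >= burnin) {
        dens_acc <- dens_acc + segments_profile(
          state$fil_minus, state$fil_minus + state$fil_len, edges)
        nuc_acc <- nuc_acc +
          graphics::hist(state$nu_pos, breaks = edges,
                         plot = FALSE)$counts / config$bin_width
        n_avg <- n_avg + 1L
      }
    }
    if (!is.na(snap_every) && k %% snap_every == 0L) {
      snapshots[[length(snapshots) + 1L]] <- list(
        t = state$t,
        profile = radial_profile(xmid, segments_profile(
          state$fil_minus, state$fil_minus + state$fil_len, edges),
          kind = "density"))
    }
  }
  if (n_avg == 0L) n_avg <- 1L
  structure(list(
    state = state,
    filaments = filament_set(state$fil_minus, state$fil_len,
                             state$fil_birth),
    density = radial_profile(xmid, dens_acc / n_avg, kind = "density"),
    nucleators = radial_profile(xmid, nuc_acc / n_avg, kind = "intensity"),
    mass = data.frame(t_s = mass_t, total_length_um = mass_v),
    snapshots = if (length(snapshots)) snapshots else NULL,
    config = config), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("Simulation result at t = %.4g s: %d filaments, %d unbound + %d bound nucleators\n",
              x$state$t, length(x$state$fil_len), length(x$state$nu_pos),
              length(x$state$nb_pos)))
  cat(sprintf("  total polymer %.4g um\n", sum(x$state$fil_len)))
  invisible(x)
}

#' Total polymer mass over time
#'
#' Runs the simulator and returns the time series of total filament length,
#' the in-silico analogue of the integrated fluorescence mass of a growing
#' structure. Under supercritical uniform activation the early phase is
#' exponential (linear log-mass).
#'
#' @param config A [sim_config()].
#' @param sampling_interval Sampling interval, s.
#' @param init_filaments Optional initial [filament_set()].
#' @param init_nucleators Optional initial nucleator positions or
#'   `"steady"`.
#' @return Data.frame with `t_s`, `total_length_um`.
#' @export
growth_curve <- function(config, sampling_interval = 1,
                         init_filaments = NULL, init_nucleators = NULL) {
  sim_run(config, init_filaments = init_filaments,
          init_nucleators = init_nucleators,
          record_interval = sampling_interval, burnin = config$t_end)$mass
}

#' Normalized density shadow behind an obstacle
#'
#' Runs the configured simulation with its obstacle and an obstacle-free
#' twin with the same seed, then returns the ratio of time-averaged
#' densities over a window behind the obstacle, with distance rescaled by
#' the obstacle radius `(b - a)/2`. Under microtubule-stimulated nucleation
#' filaments cannot cross the obstacle and diffusing nucleators alone do
#' not nucleate, so the shadow is dark; under independent nucleation the
#' diffusing nucleators repopulate it.
#'
#' @param config A [sim_config()] with an obstacle.
#' @param window Window length behind the obstacle, um (default 4 obstacle
#'   radii).
#' @return Data.frame with `dist_um`, `dist_rescaled`, `density`,
#'   `density_free`, `ratio`; attribute `mean_ratio` is the ratio of mean
#'   densities over the window, `ratio_near` the same over the first
#'   obstacle radius (the contact zone, where even independent nucleation
#'   needs about one filament length of regrowth), and `ratio_far` over
#'   the remainder of the window.
#' @export
shadow_profile <- function(config, window = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$obstacle)) stop("config has no obstacle")
  a <- config$obstacle[1]; b <- config$obstacle[2]
  radius <- (b - a) / 2
  if (is.null(window)) window <- 4 * max(radius, config$bin_width)
  cfg_free <- config
  cfg_free$obstacle <- NULL
  res_obs <- sim_run(config)
  res_free <- sim_run(cfg_free)
  sel <- res_obs$density$x >= b & res_obs$density$x <= b + window
  d <- res_obs$density$x[sel] - b
  dens <- res_obs$density$values[sel]
  dens_free <- res_free$density$values[sel]
  out <- data.frame(dist_um = d,
                    dist_rescaled = d / max(radius, 1e-9),
                    density = dens, density_free = dens_free,
                    ratio = dens / pmax(dens_free, 1e-12))
  attr(out, "mean_ratio") <- mean(dens) / max(mean(dens_free), 1e-12)
  near <- d <= radius
  attr(out, "ratio_near") <- mean(dens[near]) /
    max(mean(dens_free[near]), 1e-12)
  attr(out, "ratio_far") <- mean(dens[!near]) /
    max(mean(dens_free[!near]), 1e-12)
  out
}

#' Nucleation wave under uniform activation of a pre-grown structure
#'
#' Grows a structure under the gradient configuration, then switches to
#' uniform activation (the constitutively-active-Ran condition) and tracks
#' the outward motion of the density front: the outermost position where
#' the binned density exceeds a threshold fraction of the central density
#' at switch-on. The front speed comes from a linear fit of front position
#' against time. When the uniform phase is subcritical no front develops;
#' this is reported as a `no_front` result, not an error. Because
#' propagation is carried by filament growth, not nucleator diffusion, the
#' speed is insensitive to the diffusion coefficient.
#'
#' @param pre_config Gradient-phase [sim_config()] (structure growth).
#' @param wave_config Uniform-activation [sim_config()] for the wave phase
#'   (its `t_end` is the wave duration).
#' @param threshold_frac Front threshold as a fraction of the central
#'   density at switch-on.
#' @param snapshot_interval Snapshot interval for front tracking, s.
#' @param pre_result Optional `"sim_result"` from a previous gradient run,
#'   reused as the pre-grown structure (skips re-running `pre_config`).
#' @return A list of class `"ran_wave"`: `front` (data.frame `t_s`,
#'   `front_um`), `speed_um_s`, `speed_se`, `no_front`.
#' @export
ran_wave <- function(pre_config, wave_config, threshold_frac = 0.2,
                     snapshot_interval = 5, pre_result = NULL) {
  stopifnot(inherits(pre_config, "sim_config"),
            inherits(wave_config, "sim_config"))
  if (!wave_config$uniform_activation)
    stop("'wave_config' must have uniform_activation = TRUE")
  pre <- if (is.null(pre_result)) sim_run(pre_config) else pre_result
  st <- pre$state
  st$t <- 0
  # the wave condition activates nucleators everywhere; start it with the
  # pool it will sustain rather than waiting ~1/k_inact for it to build
  set.seed(wave_config$seed + 1L)
  n0 <- round(wave_config$k_act / max(wave_config$k_inact, 1e-12))
  st$nu_pos <- c(st$nu_pos,
                 stats::runif(n0, 0, wave_config$domain_length))
  res <- sim_run(wave_config, init_state = st,
                 snapshot_interval = snapshot_interval,
                 burnin = wave_config$t_end)
  base <- pre$density$values
  thr <- threshold_frac * max(base)
  front <- vapply(res$snapshots, function(s) {
    above <- which(s$profile$values >= thr)
    if (length(above)) max(s$profile$x[above]) else 0
  }, numeric(1))
  times <- vapply(res$snapshots, function(s) s$t, numeric(1))
  fit <- stats::lm(front ~ times)
  speed <- unname(stats::coef(fit)[2])
  se <- summary(fit)$coefficients[2, 2]
  no_front <- speed <= 2 * se | speed < 1e-3
  structure(list(front = data.frame(t_s = times, front_um = front),
                 speed_um_s = max(speed, 0), speed_se = se,
                 no_front = isTRUE(no_front)),
            class = "ran_wave")
}
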