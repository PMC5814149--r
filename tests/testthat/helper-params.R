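# Parameter sets used throughout the suite: the fitted monopole regimes
# (mean length 8 vs 24 um with a shared nucleator gradient) and small
# helpers for synthetic cut analyses.

params_control <- function(rho0 = 4058)
  model_params(ell = 8, ell_u = 24.9, alpha = 2.38, rho0 = rho0,
               theta = 0.05)

params_mcak <- function(rho0 = 4058)
  model_params(ell = 24, ell_u = 24.9, alpha = 2.38, rho0 = rho0,
               theta = 0.016)

# run the profile-stack ablation pipeline for one cut of a filament set
analyze_profile_cut <- function(filaments, r, v_d = 0.56, seed = 1L,
                                delta_t = 2, bin_width = 0.5) {
  cut <- cut_spec(radius = r, delta_t = delta_t)
  ps <- simulate_cut_profiles(filaments, cut, v_d = v_d,
                              bin_width = bin_width,
                              frame_interval = 0.5, seed = seed)
  analyze_cut(ps, cut)
}

# brute-force oracle: minus ends of cut-spanning filaments per radial bin
severed_minus_counts <- function(filaments, r, edges) {
  plus <- filaments$minus_pos + filaments$length
  sev <- filaments$minus_pos < r & plus > r
  graphics::hist(filaments$minus_pos[sev & filaments$minus_pos < max(edges)],
                 breaks = edges, plot = FALSE)$counts / diff(edges)
}
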