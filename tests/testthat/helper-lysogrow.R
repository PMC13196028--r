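# shared fixtures built in code

# truth used by recovery tests: the package's reference parametrization
truth_params <- function() default_model_params()

truth_vector <- function(p = truth_params()) {
  c(mu_g_max = p$mu_g_max, K_S_g = p$K_S_g, delta = p$delta, k = p$k,
    mu_l_max = p$mu_l_max, K_S_l = p$K_S_l, epsilon = p$epsilon)
}

# reduced-cost fit configuration used where many fits are run; the reduced
# k grid still brackets the reference chain length comfortably
fast_cfg <- function(...) {
  fit_config(sim_dt = 0.1, k_max = 15, ftol = 1e-10, delta_tol = 1e-6, ...)
}

fit_suite <- function(params = truth_params(), od_cv = 0, seed = 1,
                      mixes = c("100WT", "100TS", "73WT-27TS",
                                "19WT-81TS")) {
  suite <- generate_growth_curve_suite(params, batch_noise_model(od_cv),
                                       seed = seed)
  suite[mixes]
}

# a clean exponential track sampled every 5 min
exp_track <- function(rate = 0.6, L0 = 1.5, minutes = seq(0, 60, 5),
                      id = "t1", condition = "WT-sn", replicate = "rep1",
                      x = 5) {
  tibble::tibble(track_id = id, condition = condition,
                 replicate = replicate, time_min = minutes,
                 length_um = L0 * exp(rate * minutes / 60), x_um = x)
}

rel_err_pct <- function(est, truth) 100 * abs(est - truth) / abs(truth)
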