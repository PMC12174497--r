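# Shared fixtures: all synthetic, built in code.

# subject with no stochastic variation, fully practised (plans the full
# external torque), so static equilibrium at lift onset is analytic
ideal_params <- function(...) {
  args <- list(baseline_mcom_gain = 1, interference_slope_nmm = 0,
               trial_noise_sd_nmm = 0, subject_offset_sd_nmm = 0,
               reaction_time_sd_ms = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(subject_sim_params, args)
}

# a single zero-noise, unquantized equilibrium lift plus its detected events
equilibrium_trial <- function(obj = object_spec(),
                              sensors = sensor_spec_ideal(),
                              params = ideal_params(),
                              start_side = "left") {
  sched <- build_schedule(schedule_spec("matched", n_sets = 1L,
                                        run_lengths = 1L,
                                        start_side = start_side))
  plan <- sched[2L, ]  # the pre-switch (practised) trial
  plan$start_side <- start_side
  simulate_trial(plan, obj, sensors, params, start_side = start_side)
}

one_force_sample_ms <- function(sensors = sensor_spec()) {
  1000 / sensors$force_rate_hz + 1e-9
}

# matched + unmatched cohort -> pooled subject cell means, planned metrics
pooled_cells <- function(master_seed, params = subject_sim_params(),
                         n_matched = 8L, n_unmatched = 8L,
                         outcomes = c("mcom", "lf_torque_component",
                                      "grip_torque_component")) {
  cm <- simulate_cohort(n_matched, schedule_spec("matched"),
                        params = params, time_series = FALSE,
                        master_seed = master_seed)
  cu <- simulate_cohort(n_unmatched, schedule_spec("unmatched"),
                        params = params, time_series = FALSE,
                        master_seed = (master_seed + 500003L) %% 2147483647L)
  ca <- aggregate_post_switch(truth_metrics(cm$truth), outcomes)
  ca$design <- "matched"
  cb <- aggregate_post_switch(truth_metrics(cu$truth), outcomes)
  cb$design <- "unmatched"
  dplyr::bind_rows(ca, cb)
}

# within-effect (repetition) p value of one simulated two-cohort experiment
repetition_p <- function(master_seed, slope = 0, n = 8L, rep_level = 5) {
  cells <- pooled_cells(master_seed,
                        subject_sim_params(interference_slope_nmm = slope),
                        n_matched = n, n_unmatched = n, outcomes = "mcom")
  tab <- repetition_anova(cells, "mcom", rep_level)
  tab$p[tab$effect == "run_length"]
}

# textbook sums-of-squares for a balanced two-group x two-level mixed design,
# computed from definitional sums over cell means (independent of aov)
bruteforce_mixed_ss <- function(d) {
  # d: data.frame with y, b (between), w (within), s (subject, unique ids)
  grand <- mean(d$y)
  n_w <- length(unique(d$w))
  subj_means <- tapply(d$y, d$s, mean)
  subj_b <- tapply(as.character(d$b), d$s, function(x) x[1])
  ss_subj_total <- n_w * sum((subj_means - grand)^2)
  b_means <- tapply(d$y, d$b, mean)
  n_b <- table(subj_b)  # subjects per group
  ss_b <- sum(n_w * n_b[names(b_means)] * (b_means - grand)^2)
  ss_err_b <- ss_subj_total - ss_b
  w_means <- tapply(d$y, d$w, mean)
  n_subj <- length(unique(d$s))
  ss_w <- n_subj * sum((w_means - grand)^2)
  cell_means <- tapply(d$y, list(d$b, d$w), mean)
  ss_cells <- 0
  for (bb in rownames(cell_means)) {
    for (ww in colnames(cell_means)) {
      ss_cells <- ss_cells + n_b[[bb]] * (cell_means[bb, ww] - grand)^2
    }
  }
  ss_bw <- ss_cells - ss_b - ss_w
  ss_total <- sum((d$y - grand)^2)
  ss_err_w <- ss_total - ss_subj_total - ss_w - ss_bw
  list(ss_b = unname(ss_b), ss_err_b = unname(ss_err_b), ss_w = ss_w,
       ss_bw = unname(ss_bw), ss_err_w = unname(ss_err_w))
}
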