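# Shared fixtures: deterministic participants with hand-set parameters, so
# closed-form expectations hold exactly.

# Participant with every stochastic nuisance switched off unless asked for.
fixed_participant <- function(pid = "T01", group = "pET", maxf = 40,
                              tremor_freq = 6, amp0 = 0.02, beta = 0.5,
                              weights = c(vo = 1, va = 1.2, ao = 1),
                              drift = 0, noise = 0, trial_sdlog = 0,
                              pupil_base = 4.5, arousal = NULL,
                              pupil_noise = 0, blink_rate = 0,
                              blink_dur = 0.2) {
  if (is.null(arousal))
    arousal <- c(vo.low = 0, vo.high = 0, va.low = 0, va.high = 0,
                 ao.low = 0, ao.high = 0)
  structure(list(
    pid = pid, group = group, maxf = maxf, tremor_freq_hz = tremor_freq,
    tremor_amp0 = amp0, gain_beta = beta, feedback_weight = weights,
    trial_amp_sdlog = trial_sdlog, drift_amp = drift, drift_cutoff_hz = 1.5,
    noise_sd = noise, pupil_base_mm = pupil_base, pupil_arousal_mm = arousal,
    pupil_noise_sd = pupil_noise, pupil_noise_cutoff_hz = 0.5,
    arousal_tau_s = 2, blink_rate_hz = blink_rate, blink_dur_s = blink_dur,
    pupil_trial_sd = 0.06,
    age = 60, tetras = 40, bdi = 5), class = "virtual_participant")
}

# Small synthetic feature table with exactly known cell values.
toy_features <- function(n_per_group = 3, delta = 1, noise = 0, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(trial_in_cell = 1:2,
                      gain_level = c("low", "high"),
                      feedback_type = c("vo", "va", "ao"),
                      pid = sprintf("S%02d", seq_len(2 * n_per_group)),
                      stringsAsFactors = FALSE)
  grid$group <- ifelse(as.integer(sub("S", "", grid$pid)) <= n_per_group,
                       "pET", "HC")
  grid$trial <- ave(seq_len(nrow(grid)), grid$pid, FUN = seq_along)
  grid$tremor_power <- 1 +
    delta * (grid$gain_level == "high") * (grid$group == "pET") +
    rnorm(nrow(grid), 0, noise)
  grid$pupil_mean <- grid$tremor_power / 10
  grid$rmse <- 0.05 + rnorm(nrow(grid), 0, noise)
  grid$mean_force <- 1
  grid$voluntary_power <- 0.002
  grid
}
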