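# Small corpora and helper oracles shared across test files.

tiny_sim_config <- function(...) {
  args <- list(...)
  defaults <- list(n_subjects = 2L, records_per_subject = 2L, duration_s = 8)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# analytic two-bump beat used as a fiducial oracle
oracle_beat <- function(fs = 250) {
  p <- beat_template_params(systolic_time_s = 0.15, systolic_amp = 1.0,
                            dicrotic_time_s = 0.40, dicrotic_amp = 0.4,
                            notch_time_s = 0.275, beat_period_s = 0.8)
  generate_beat_template(p, fs)
}

expect_samples_close <- function(t_est, t_true, fs, tol_samples) {
  expect_lte(abs(t_est - t_true) * fs, tol_samples + 1e-9)
}
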