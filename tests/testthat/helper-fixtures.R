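# simulate without the truncation message noise
quiet_sim <- function(config, seed = config$seed) {
  suppressMessages(simulate_cohort(config, seed = seed))
}

# a small hand-built cohort: 2 strains x 2 arms x 2 mice, complete 9-day series
tiny_cohort <- function() {
  sched <- protocol_schedule()
  grid <- expand.grid(rep = 1:2, treatment_group = c("cocaine", "saline"),
                      strain = c("CC001", "CC002"),
                      stringsAsFactors = FALSE)
  grid$mouse_id <- sprintf("m%02d", seq_len(nrow(grid)))
  rows <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    data.frame(
      mouse_id = grid$mouse_id[i], strain = grid$strain[i],
      sex = c("F", "M")[1 + i %% 2], site = "JAX",
      treatment_group = grid$treatment_group[i],
      day = sched$test_days,
      distance = 1000 + 10 * i + seq_along(sched$test_days),
      body_weight = 20 + i
    )
  }))
  as_cohort_table(rows)
}

# a no-noise config with known effect algebra
algebra_config <- function() {
  sim_config(
    n_strains = 3, mice_per_strain_per_arm = 2,
    var_strain = 0, var_strain_slope = 0, var_mouse = 0, var_resid = 0,
    grand_mean = 1000, day_effects = rep(0, 9),
    cocaine_acute_effect = 300, ramp = c(0, 50, 40, 30, 20),
    expression_effect = 70, conditioned_effect = 25,
    sex_effect = 0, site_effect = 0, seed = 11
  )
}
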