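# shared fixture builders; everything is generated in code at test time

# the 4-subject textbook example: (1, cause 1), (2, cause 2),
# (3, censored), (4, cause 1)
four_subject_fixture <- function() {
  data.frame(time = c(1, 2, 3, 4), event = c(1L, 2L, 0L, 1L))
}

# a default-mechanism dataset with MAR missingness, deterministic given seed
mar_fixture <- function(n = 500, fraction = 0.5, seed = 11) {
  set.seed(seed)
  apply_mdm(generate_dataset(sim_config(n_subjects = n)),
            mdm_spec("MAR", fraction))
}

# hand-built step function wrapped as an aj_cif object, for median logic
step_cif <- function(times, values, ses = rep(0.02, length(times))) {
  structure(list(time = times, est = values, se = ses,
                 surv = 1 - values, n_risk = integer(length(times)),
                 n_event = integer(length(times)),
                 n_event_all = integer(length(times)),
                 n = 100L, cause = 1L),
            class = "aj_cif")
}

# replicate-level runs of one cell, returned as a 4 x n matrix
cell_runs <- function(method, mechanism, fraction, n_reps, m = 5L,
                      base_seed = 1L, config = sim_config(),
                      mnar_direction = "smallest") {
  vapply(seq_len(n_reps), function(r)
    run_replicate(config, method, mechanism, fraction, m = m, rep = r,
                  base_seed = base_seed, mnar_direction = mnar_direction),
    numeric(4))
}
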