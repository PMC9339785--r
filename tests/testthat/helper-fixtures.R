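# shared fixtures for the test suite; everything is generated in code

# fixture with a short horizon for fast full-model evaluations
short_params <- function(horizon_years = 5) {
  param_set(gen_fixture(), "settings.horizon_years", horizon_years)
}

# a parameter set where both arms are exactly exchangeable
symmetric_params <- function(horizon_years = 5) {
  p <- short_params(horizon_years)
  p <- param_set(p, "survival.hr_psa_recurrence", 1)
  p <- param_set(p, "prices.degarelix_first_cycle",
                 p$prices$leuprorelin_per_cycle + p$prices$flare_cover_daily * 28)
  p <- param_set(p, "prices.degarelix_maintenance", p$prices$leuprorelin_per_cycle)
  p <- param_set(p, "ae.incidence.degarelix", p$ae$incidence$leuprorelin)
  p
}

# single-arm log-logistic sample with administrative censoring
loglogistic_sample <- function(n, lambda = 0.005, gamma = 1.5, t_max = 364,
                               seed = 1) {
  gen_survival(n, "loglogistic", lambda = lambda, gamma = gamma,
               t_max = t_max, seed = seed)$reference
}

# vectorized individual-level microsimulation; independent of run_cohort's
# matrix-product path (same transition matrices, sampled per patient)
microsimulate <- function(params, arm, n_patients, seed) {
  set.seed(seed)
  n_cycles <- floor(params$settings$horizon_years * 365.25 /
                    params$settings$cycle_length_days)
  states <- model_states()
  state <- rep(1L, n_patients)  # first_line
  occ <- matrix(0L, n_cycles + 1L, length(states),
                dimnames = list(NULL, states))
  occ[1L, ] <- tabulate(state, nbins = length(states))
  for (k in seq_len(n_cycles)) {
    m <- build_transition_matrix(params, arm, cycle = k - 1L)
    new_state <- state
    for (s in unique(state)) {
      idx <- which(state == s)
      cum <- cumsum(m[s, ])
      new_state[idx] <- findInterval(stats::runif(length(idx)), cum,
                                     left.open = TRUE) + 1L
    }
    state <- new_state
    occ[k + 1L, ] <- tabulate(state, nbins = length(states))
  }
  occ / n_patients
}
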