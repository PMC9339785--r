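#' Health states of the treatment pathway
#'
#' The modelled pathway: first-line castration therapy, then on PSA
#' recurrence anti-androgen addition, anti-androgen withdrawal, a split
#' between abiraterone (the chemotherapy-skip branch) and docetaxel,
#' abiraterone after docetaxel, continued treatment after abiraterone
#' failure, supportive care, palliative care, and absorbing death.
#'
#' @return Character vector of the nine state names in canonical order.
#' @export
model_states <- function() cea_states

#' Treatment arms of the comparison
#' @return Character vector `c("degarelix", "leuprorelin")`.
#' @export
model_arms <- function() cea_arms

n_model_cycles <- function(params) {
  floor(params$settings$horizon_years * 365.25 / params$settings$cycle_length_days)
}

attained_age <- function(params, cycle) {
  params$settings$start_age + cycle * params$settings$cycle_length_days / 365.25
}

# survival function for an arm from the parameter set
arm_survival_fn <- function(params, arm) {
  sv <- params$survival
  ref_fit <- survival_model(sv$family, shape = sv$gamma, scale = sv$lambda)
  if (arm == sv$reference_arm) {
    function(t) survival_at(ref_fit, t)
  } else if (identical(sv$mode, "independent")) {
    fit <- survival_model(sv$family, shape = sv$treated_gamma, scale = sv$treated_lambda)
    function(t) survival_at(fit, t)
  } else {
    apply_hazard_ratio(ref_fit, sv$hr_psa_recurrence)
  }
}

mortality_model <- function(params) {
  m <- params$mortality
  if (identical(m$model, "table")) {
    life_table(m$table_ages, m$table_qx)
  } else {
    logistic_mortality(m$L, m$k, m$a0)
  }
}

# pre-mortality event probabilities out of each transient state at one cycle
pre_mortality_moves <- function(params, p_prog) {
  tr <- params$transitions
  skip <- tr$chemo_skip_fraction
  list(
    first_line = c(aa_addition = p_prog),
    aa_addition = c(aa_withdrawal = 1 - tr$response_aa_addition),
    aa_withdrawal = c(
      abiraterone = (1 - tr$response_aa_withdrawal) * skip,
      docetaxel = (1 - tr$response_aa_withdrawal) * (1 - skip)
    ),
    docetaxel = c(abiraterone = 1 - tr$response_docetaxel),
    abiraterone = c(post_abiraterone = 1 - tr$response_abiraterone),
    post_abiraterone = c(supportive_care = 1 - tr$response_post_abiraterone),
    supportive_care = c(palliative_care = 1 - tr$response_supportive_care),
    palliative_care = numeric(0)
  )
}

#' Build the one-cycle transition matrix
#'
#' Assembles the stochastic matrix over the nine states at a given cycle and
#' attained age. Disease moves (progression from the survival curve, per-cycle
#' non-response exits from second-line states, the configured
#' chemotherapy-skip split) are composed with background mortality by
#' competing-risk bookkeeping: a per-cycle death probability `p_d` (from the
#' mortality model scaled by the state's hazard ratio) takes the death column
#' and all non-death destinations are scaled by `1 - p_d`; the residual stays
#' in the source state. Death is absorbing.
#'
#' @param params A `cea_parameters` object.
#' @param arm `"degarelix"` or `"leuprorelin"`.
#' @param cycle Non-negative cycle index.
#' @param age Attained age in years; default derived from the settings.
#' @return A 9 x 9 row-stochastic matrix with dimnames = states.
#' @export
build_transition_matrix <- function(params, arm, cycle,
                                    age = attained_age(params, cycle)) {
  arm <- match.arg(arm, cea_arms)
  if (cycle < 0) stop("cycle must be >= 0", call. = FALSE)
  surv <- arm_survival_fn(params, arm)
  p_prog <- per_cycle_progression_prob(surv, cycle, params$settings$cycle_length_days)
  mort <- mortality_model(params)
  hr_states <- params$mortality$state_hr
  p_death <- vapply(cea_states[-9L], function(s) {
    cycle_death_prob(mort, age, hr = hr_states[[s]],
                     cycle_length = params$settings$cycle_length_days)
  }, numeric(1))
  transition_matrix_from_parts(pre_mortality_moves(params, p_prog), p_death)
}

transition_matrix_from_parts <- function(moves, p_death) {
  m <- matrix(0, 9, 9, dimnames = list(cea_states, cea_states))
  for (s in cea_states[-9L]) {
    mv <- moves[[s]]
    if (any(mv < 0 | mv > 1)) {
      stop("transition probability out of [0,1] for state `", s, "`", call. = FALSE)
    }
    if (sum(mv) > 1 + 1e-12) {
      stop("outgoing probabilities exceed 1 for state `", s, "`", call. = FALSE)
    }
    pd <- p_death[[s]]
    if (length(mv)) m[s, names(mv)] <- mv * (1 - pd)
    m[s, "death"] <- pd
    m[s, s] <- m[s, s] + 1 - sum(m[s, ])
  }
  m["death", "death"] <- 1
  if (any(abs(rowSums(m) - 1) > 1e-9)) {
    stop("transition-matrix rows do not sum to 1", call. = FALSE)
  }
  m
}

#' Propagate a cohort through the model
#'
#' Runs the full-horizon cohort trace for one treatment arm: the cohort
#' starts entirely in `first_line` and is propagated through
#' `floor(horizon_years * 365.25 / cycle_length)` cycles of time-varying
#' transition matrices (progression probabilities from the arm's survival
#' curve; mortality from the ageing cohort).
#'
#' @param params A `cea_parameters` object.
#' @param arm `"degarelix"` or `"leuprorelin"`.
#' @return A `cohort_trace`: list with `occupancy` ((n_cycles + 1) x 9 matrix,
#'   row k = state distribution at the start of cycle k), `arm`, `ages`,
#'   `cycle_length_days`.
#' @export
run_cohort <- function(params, arm) {
  arm <- match.arg(arm, cea_arms)
  validate_parameters(params)
  n <- n_model_cycles(params)
  cl <- params$settings$cycle_length_days
  surv <- arm_survival_fn(params, arm)

  # precompute time-varying pieces
  knots <- (0:(n + 1)) * cl
  s_vals <- surv(knots)
  s0 <- s_vals[1:(n + 1)]
  s1 <- s_vals[2:(n + 2)]
  p_prog <- ifelse(s0 <= 0, 1, pmin(pmax(1 - s1 / s0, 0), 1))
  ages <- attained_age(params, 0:n)
  mort <- mortality_model(params)
  hr_states <- params$mortality$state_hr
  p_death <- vapply(cea_states[-9L], function(s) {
    cycle_death_prob(mort, ages, hr = hr_states[[s]], cycle_length = cl)
  }, numeric(n + 1))

  occ <- matrix(0, n + 1, 9, dimnames = list(NULL, cea_states))
  state <- c(1, rep(0, 8))
  occ[1, ] <- state
  for (k in seq_len(n)) {
    m <- transition_matrix_from_parts(
      pre_mortality_moves(params, p_prog[k]),
      p_death[k, ]
    )
    state <- as.numeric(state %*% m)
    occ[k + 1, ] <- state
  }
  structure(
    list(occupancy = occ, arm = arm, ages = ages, cycle_length_days = cl),
    class = "cohort_trace"
  )
}

#' @export
print.cohort_trace <- function(x, ...) {
  n <- nrow(x$occupancy) - 1L
  cat(sprintf("Cohort trace: arm %s, %d cycles (%.1f years)\n", x$arm, n,
              n * x$cycle_length_days / 365.25))
  cat(sprintf("  final death occupancy: %.4f\n", x$occupancy[n + 1L, "death"]))
  invisible(x)
}

#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  data.frame(cycle = 0:(nrow(x$occupancy) - 1L), age = x$ages,
             x$occupancy, check.names = FALSE)
}

#' Write a cohort trace as a delimited table
#' @param trace A `cohort_trace`.
#' @param path Output file path.
#' @param header_lines Optional comment lines (prefixed `#`) to prepend.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, header_lines = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(format(as.data.frame(trace), digits = 15, trim = TRUE,
                            scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
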