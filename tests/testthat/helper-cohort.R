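# Shared fixtures: small survival cohorts built in code.

# Direct survival records from the Gompertz sampler (bypasses the
# diagnosis-record layer) for likelihood-level tests.
make_records <- function(n, h0, gamma, eta = 0, seed = 1,
                         enroll = c(40, 70), followup = 8) {
  set.seed(seed)
  age <- draw_event_age(n, h0, gamma, eta)
  t1 <- stats::runif(n, enroll[1], enroll[2])
  t2 <- t1 + followup
  delta <- as.integer(age <= t2)
  data.frame(
    participant_id = sprintf("P%05d", seq_len(n)),
    t1 = t1, t2 = t2,
    td = ifelse(delta == 1L, age, NA_real_),
    delta = delta, stringsAsFactors = FALSE
  )
}

# The five-participant windowed-incidence example used across incidence
# tests: delta, td, t2 chosen so the t = 60, dt = 5 window has a 3-person
# risk set with one diagnosis.
five_participants <- function() {
  data.frame(
    participant_id = paste0("P", 1:5),
    t1 = c(50, 50, 50, 50, 50),
    t2 = c(70, 70, 70, 64, 70),
    td = c(62, NA, 58, NA, 66),
    delta = c(1L, 0L, 1L, 0L, 1L),
    stringsAsFactors = FALSE
  )
}

# Residual weights with prescribed rho and delta (unit-test scaffolding
# for the closed-form statistic; bypasses the model fit).
manual_weights <- function(rho, delta) {
  structure(list(rho = rho, n_d = sum(delta),
                 resid = delta - sum(delta) * rho),
            class = "residual_weights")
}
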