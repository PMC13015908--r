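# Shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# small synthetic arm (6 participants, full session) reused across files
small_arm <- function() {
  if (is.null(fixture_env$small_arm)) {
    fixture_env$small_arm <- simulate_experiment(
      group_params("control"), n = 6, schedule_config(), seed = 421)
  }
  fixture_env$small_arm
}

default_schedule <- function() {
  if (is.null(fixture_env$sched)) {
    fixture_env$sched <- generate_schedule(schedule_config(seed = 42))
  }
  fixture_env$sched
}

# independent brute-force RW recursion (oracle; kept deliberately naive)
oracle_ev_path <- function(us, lr, ev0) {
  ev <- numeric(length(us))
  current <- ev0
  for (t in seq_along(us)) {
    ev[t] <- current
    pe <- us[t] - current
    current <- current + lr * pe
  }
  ev
}

# independent per-trial Gaussian density sum (oracle for observation_loglik)
oracle_loglik <- function(amp, ev, reinf, obs, kappa = 10) {
  total <- 0
  for (t in seq_along(amp)) {
    m <- if (reinf[t]) obs$a_crur + obs$b_crur * ev[t]
         else obs$a_cr + obs$b_cr * ev[t]
    total <- total + log(1 / (obs$sigma * sqrt(2 * pi))) -
      (amp[t] - m)^2 / (2 * obs$sigma^2)
    if (m < 0) total <- total - kappa * m^2
  }
  total
}
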