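#' Rescorla-Wagner update of the expected shock value
#'
#' One trial-wise update of the expected value (EV; modeled probability of
#' shock) for a cue: `ev' = ev + lr * (us - ev)`, where `us - ev` is the
#' prediction error. With `lr` and `ev` in `[0, 1]` and `us` binary the
#' updated EV is guaranteed to stay in `[0, 1]`.
#'
#' @param ev current expected value in `[0, 1]` (vectorized).
#' @param us observed outcome, 0 (unreinforced) or 1 (reinforced).
#' @param lr learning rate in `[0, 1]`.
#' @return updated expected value.
#' @examples
#' rw_update(0.5, 1, 0.2)  # 0.6
#' @export
rw_update <- function(ev, us, lr) {
  if (any(lr < 0 | lr > 1)) stop("learning rate must lie in [0, 1]")
  if (any(ev < 0 | ev > 1)) stop("expected value must lie in [0, 1]")
  if (!all(us %in% c(0, 1))) stop("us must be binary (0/1)")
  ev + lr * (us - ev)
}

#' Simulate an expected-value trajectory under the Rescorla-Wagner rule
#'
#' Iterates [rw_update()] over a reinforcement series for a single cue
#' stream. The returned vector has one element per trial and holds the EV
#' *at the time the cue is shown* (i.e. before that trial's update), so
#' `ev[1] == ev0`.
#'
#' @param us integer vector of outcomes (0/1), one per trial.
#' @param lr learning rate in `[0, 1]`. May be a vector of per-trial
#'   effective learning rates (e.g. from [emotional_lr()]).
#' @param ev0 initial expected value in `[0, 1]`.
#' @return numeric vector of pre-update EVs, same length as `us`.
#' @examples
#' simulate_ev_path(c(1, 1, 0), lr = 0.5, ev0 = 0)  # 0, 0.5, 0.75
#' @export
simulate_ev_path <- function(us, lr, ev0 = 0) {
  n <- length(us)
  if (length(lr) == 1L) lr <- rep(lr, n)
  if (length(lr) != n) stop("lr must have length 1 or length(us)")
  if (any(lr < 0 | lr > 1)) stop("learning rate must lie in [0, 1]")
  if (ev0 < 0 || ev0 > 1) stop("ev0 must lie in [0, 1]")
  ev <- numeric(n)
  cur <- ev0
  for (t in seq_len(n)) {
    ev[t] <- cur
    cur <- cur + lr[t] * (us[t] - cur)
  }
  ev
}

#' Effective learning rate under the emotional learning state model
#'
#' A single learning rate shared across acquisition and extinction is
#' multiplicatively modulated by the current phase and a participant-specific
#' state bias: `lr_shared * (1 + phase * state_bias)` with
#' `phase = +1` during acquisition and `-1` during extinction. Learning is
#' therefore centered on `lr_shared` and adjusted symmetrically across
#' phases; with `|state_bias| < 1` and `lr_shared <= 0.5` the effective rate
#' cannot leave `[0, 1]`. If permissive parameters push the rate outside
#' `[0, 1]` it is clipped with a warning.
#'
#' @param lr_shared shared learning rate in `[0, 1]`.
#' @param phase `+1` (acquisition) or `-1` (extinction); vectorized.
#' @param state_bias emotional-state bias in `(-1, 1)`.
#' @return effective learning rate(s) in `[0, 1]`.
#' @examples
#' emotional_lr(0.3, +1, 0.5)  # 0.45
#' emotional_lr(0.3, -1, 0.5)  # 0.15
#' @export
emotional_lr <- function(lr_shared, phase, state_bias) {
  if (!all(phase %in% c(-1, 1))) stop("phase must be +1 or -1")
  out <- lr_shared * (1 + phase * state_bias)
  if (any(out < 0 | out > 1)) {
    warning("effective learning rate outside [0, 1]; clipped")
    out <- pmin(pmax(out, 0), 1)
  }
  out
}

#' Seed extinction starting values from the end of acquisition
#'
#' Extinction learning is seeded by the individualized outcome of prior
#' conditioning: the initial EV of every cue at the start of extinction
#' equals that cue's EV after the last acquisition trial. Accepts either a
#' data frame of terminal acquisition EVs or an acquisition fit (see
#' [fit_acquisition()]), in which case posterior-mean terminal EVs are used.
#'
#' @param acq a data frame with columns `participant`, `cue`, `ev_final`, or
#'   an object of class `rl_fit` from [fit_acquisition()].
#' @param participants optional character vector; if supplied, every listed
#'   participant must be present in `acq` (an error names any that are not).
#' @return data frame with columns `participant`, `cue`, `ev0`.
#' @export
seed_extinction_evs <- function(acq, participants = NULL) {
  if (inherits(acq, "rl_fit")) acq <- terminal_evs(acq)
  need <- c("participant", "cue", "ev_final")
  if (!all(need %in% names(acq))) {
    stop("acq must contain columns: ", paste(need, collapse = ", "))
  }
  if (!is.null(participants)) {
    missing <- setdiff(participants, acq$participant)
    if (length(missing)) {
      stop("no acquisition EVs for participant(s): ",
           paste(missing, collapse = ", "))
    }
    acq <- acq[acq$participant %in% participants, , drop = FALSE]
  }
  data.frame(participant = acq$participant, cue = acq$cue,
             ev0 = acq$ev_final, stringsAsFactors = FALSE)
}

#' Log likelihood of observed SCR amplitudes under the observation model
#'
#' Observed (square-root transformed) SCRs are modeled as a linear function
#' of the current EV, with separate intercept/slope for unreinforced trials
#' (conditioned response, CR) and reinforced trials (combined conditioned
#' and unconditioned response, CR + UR), plus Gaussian residual noise.
#' Model-predicted SCRs are constrained to non-negative values via a soft
#' constraint: a penalty `-kappa * min(0, mean)^2` is added to the log
#' density wherever a branch mean is negative.
#'
#' @param amplitudes observed amplitudes (sqrt-uS), one per trial.
#' @param ev expected values, aligned with `amplitudes`.
#' @param reinforced logical/0-1 vector marking reinforced trials.
#' @param obs list with elements `a_cr`, `b_cr`, `a_crur`, `b_crur`, `sigma`.
#' @param kappa soft-constraint weight (default 10).
#' @return total log density (scalar).
#' @export
observation_loglik <- function(amplitudes, ev, reinforced, obs, kappa = 10) {
  n <- length(amplitudes)
  if (length(ev) != n || length(reinforced) != n) {
    stop("amplitudes, ev and reinforced must be aligned")
  }
  if (obs$sigma <= 0) stop("sigma must be positive")
  reinforced <- as.logical(reinforced)
  m <- ifelse(reinforced, obs$a_crur + obs$b_crur * ev, obs$a_cr + obs$b_cr * ev)
  ll <- sum(stats::dnorm(amplitudes, mean = m, sd = obs$sigma, log = TRUE))
  ll - kappa * sum(pmin(m, 0)^2)
}
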