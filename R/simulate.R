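#' Group-level generative parameters for a synthetic cohort
#'
#' Group means and SDs are specified on the unconstrained sampling scale
#' (learning rates logit, state bias atanh, residual SD log, observation
#' coefficients identity), mirroring the hierarchical model. By default the
#' per-phase learning rates are coupled through the emotional learning
#' state: `lr_acq = lr_shared * (1 + state_bias)` and
#' `lr_ext = lr_shared * (1 - state_bias)`, so a positive bias produces the
#' canonical fast-learning / slow-forgetting profile. The `"control"` arm
#' carries a positive bias; the `"amygdala"` arm has the bias removed,
#' emulating stimulation that slows acquisition and speeds extinction.
#'
#' @param arm `"control"` (positive emotional-state bias; also used for the
#'   hippocampus-TUS arm) or `"amygdala"` (bias at zero).
#' @param couple_rates derive `lr_acq`/`lr_ext` from the shared rate and
#'   bias (default) instead of drawing them independently.
#' @param ev0 initial expected shock value at the start of acquisition.
#' @param ... override any parameter as `c(mean, sd)` on the unconstrained
#'   scale, e.g. `lr_shared = c(qlogis(0.2), 0.3)`.
#' @return list of class `group_params`.
#' @export
group_params <- function(arm = c("control", "amygdala"),
                         couple_rates = TRUE, ev0 = 0, ...) {
  arm <- match.arg(arm)
  bias_mean <- if (arm == "control") atanh(0.4) else 0
  p <- list(
    lr_shared  = c(stats::qlogis(0.18), 0.4),
    state_bias = c(bias_mean, 0.25),
    lr_acq     = c(stats::qlogis(0.25), 0.4),
    lr_ext     = c(stats::qlogis(0.11), 0.4),
    a_cr       = c(0.35, 0.08),
    b_cr       = c(0.50, 0.12),
    a_crur     = c(0.70, 0.15),
    b_crur     = c(0.50, 0.12),
    log_sigma  = c(log(0.15), 0.20)
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown group parameter(s): ",
                        paste(bad, collapse = ", "))
  for (nm in names(dots)) p[[nm]] <- dots[[nm]]
  for (nm in names(p)) {
    if (length(p[[nm]]) != 2) stop(nm, " must be c(mean, sd)")
    if (p[[nm]][2] < 0) stop(nm, ": SD must be non-negative")
  }
  out <- list(params = p, arm = arm, couple_rates = couple_rates, ev0 = ev0)
  class(out) <- "group_params"
  out
}

#' Draw participant-level parameters from group-level distributions
#'
#' Participant values are drawn from normal distributions on the
#' unconstrained scale and mapped through the link functions (inverse-logit
#' for learning rates, tanh for the state bias, exp for the residual SD),
#' mirroring the hierarchical generative assumption of the models. With all
#' SDs equal to zero every participant equals the group means.
#'
#' @param g a [group_params()] object.
#' @param n number of participants (`>= 1`).
#' @param seed optional integer seed.
#' @return data frame with one row per participant: `participant`,
#'   `lr_acq`, `lr_ext`, `lr_shared`, `state_bias`, `a_cr`, `b_cr`,
#'   `a_crur`, `b_crur`, `sigma`, `ev0`.
#' @export
draw_participant_params <- function(g, n, seed = NULL) {
  stopifnot(inherits(g, "group_params"))
  if (n < 1) stop("n must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  draw <- function(nm) rnorm(n, g$params[[nm]][1], g$params[[nm]][2])
  lr_shared <- stats::plogis(draw("lr_shared"))
  state_bias <- tanh(draw("state_bias"))
  if (g$couple_rates) {
    lr_acq <- pmin(1, lr_shared * (1 + state_bias))
    lr_ext <- pmax(0, lr_shared * (1 - state_bias))
  } else {
    lr_acq <- stats::plogis(draw("lr_acq"))
    lr_ext <- stats::plogis(draw("lr_ext"))
  }
  data.frame(
    participant = sprintf("P%03d", seq_len(n)),
    lr_acq = lr_acq, lr_ext = lr_ext, lr_shared = lr_shared,
    state_bias = state_bias,
    a_cr = draw("a_cr"), b_cr = draw("b_cr"),
    a_crur = draw("a_crur"), b_crur = draw("b_crur"),
    sigma = exp(draw("log_sigma")), ev0 = g$ev0,
    stringsAsFactors = FALSE)
}

#' Simulate trial-level SCR amplitudes for one participant
#'
#' Runs the Rescorla-Wagner recursion per cue stream across the whole
#' session (acquisition uses `lr_acq`; retention, extinction, recovery and
#' re-extinction use `lr_ext`; extinction EVs are thereby seeded from the
#' final acquisition EV of each cue) and draws observed square-root SCR
#' amplitudes from the observation model: Normal around
#' `a_cr + b_cr * EV` on unreinforced trials and `a_crur + b_crur * EV` on
#' reinforced trials, truncated at zero. Unsignaled reinstatement shocks
#' carry no cue and receive no amplitude.
#'
#' @param p one row of [draw_participant_params()] output (or an equivalent
#'   one-row data frame / named list).
#' @param s a schedule from [generate_schedule()].
#' @param seed optional integer seed.
#' @return the schedule with added columns `lr_trial`, `ev` (latent), `scr`
#'   (sqrt-uS) and `amplitude` (uS).
#' @export
simulate_trial_amplitudes <- function(p, s, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- as.list(as.data.frame(p)[1, ])
  out <- as.data.frame(s)
  n <- nrow(out)
  out$lr_trial <- NA_real_
  out$ev <- NA_real_
  out$scr <- NA_real_
  cue_rows <- which(!is.na(out$cs))
  noise <- rnorm(n)
  for (pr in c("active", "sham")) {
    for (cs in c("CS+", "CS-")) {
      idx <- cue_rows[out$pair[cue_rows] == pr & out$cs[cue_rows] == cs]
      if (!length(idx)) next
      ev <- p$ev0
      for (i in idx) {
        out$ev[i] <- ev
        m <- if (out$us[i] == 1) p$a_crur + p$b_crur * ev
             else p$a_cr + p$b_cr * ev
        out$scr[i] <- max(0, m + p$sigma * noise[i])
        # retention / recovery probes read out the association (one
        # unreinforced presentation per cue) without a learning update,
        # so extinction EVs are seeded exactly by the last acquisition EV
        if (out$phase[i] %in% c("retention", "reinstatement")) next
        lr <- if (out$phase[i] == "acquisition") p$lr_acq else p$lr_ext
        out$lr_trial[i] <- lr
        ev <- ev + lr * (out$us[i] - ev)
      }
    }
  }
  out$amplitude <- out$scr^2
  out
}

#' Simulate one experiment arm
#'
#' Draws `n` participants from the group-level distributions and simulates a
#' full session for each, with the cue-identity counterbalance code cycled
#' over participants (Latin square) and an independent schedule
#' randomization per participant.
#'
#' @param g a [group_params()] object.
#' @param n participants in the arm.
#' @param config a [schedule_config()]; its seed is combined with
#'   `seed` and the participant index.
#' @param seed integer master seed for the arm.
#' @param label experiment label stored in the trial table.
#' @return list of class `sim_dataset` with elements `trials` (long trial
#'   table including latent `ev` and ground-truth columns) and `params`
#'   (the ground-truth participant parameters).
#' @export
simulate_experiment <- function(g, n, config = schedule_config(),
                                seed = 1L, label = g$arm) {
  params <- draw_participant_params(g, n, seed = seed)
  trials <- vector("list", n)
  for (i in seq_len(n)) {
    cfg_i <- config
    cfg_i$counterbalance_code <- ((i - 1L) %% 4L) + 1L
    cfg_i$seed <- as.integer((seed * 1000L + i) %% .Machine$integer.max)
    s <- generate_schedule(cfg_i)
    d <- simulate_trial_amplitudes(params[i, ], s,
                                   seed = cfg_i$seed + 500000L)
    d$participant <- params$participant[i]
    d$experiment <- label
    trials[[i]] <- d
  }
  trials <- do.call(rbind, trials)
  trials <- trials[, c("participant", "experiment",
                       setdiff(names(trials),
                               c("participant", "experiment")))]
  out <- list(trials = trials, params = params, label = label, n = n)
  class(out) <- "sim_dataset"
  out
}

#' Simulate a two-experiment cohort
#'
#' Emulates the two-experiment design (active target vs. control target,
#' independent samples) by simulating one arm per group-parameter set.
#'
#' @param g_active group parameters for the active-target arm (e.g.
#'   amygdala stimulation).
#' @param g_control group parameters for the control-target arm.
#' @param n_per_group participants per arm.
#' @param config a [schedule_config()].
#' @param seed integer master seed.
#' @return list with elements `active` and `control`, each a `sim_dataset`.
#' @export
simulate_cohort <- function(g_active = group_params("amygdala"),
                            g_control = group_params("control"),
                            n_per_group = 25, config = schedule_config(),
                            seed = 1L) {
  list(active = simulate_experiment(g_active, n_per_group, config,
                                    seed = seed, label = "active"),
       control = simulate_experiment(g_control, n_per_group, config,
                                     seed = seed + 77003L,
                                     label = "control"))
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("Synthetic SCR dataset ('%s'): %d participants, %d trials\n",
              x$label, x$n, nrow(x$trials)))
  invisible(x)
}

#' Configuration for synthetic electrodermal traces
#'
#' The canonical phasic response is a difference of exponentials
#' (`exp(-t/decay) - exp(-t/rise)`), normalized to unit peak, so a planted
#' response has an exact trough-to-peak amplitude. Any smooth unimodal
#' kernel would do, as the trough-to-peak scorer is shape agnostic.
#'
#' @param sampling_rate samples per second (default 500 Hz).
#' @param rise rise time constant in seconds.
#' @param decay decay time constant in seconds (must exceed `rise`).
#' @param baseline tonic skin conductance level in uS.
#' @param noise_sd Gaussian measurement noise SD in uS.
#' @return list of class `trace_config`.
#' @export
trace_config <- function(sampling_rate = 500, rise = 0.75, decay = 2.0,
                         baseline = 2.0, noise_sd = 0) {
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (rise >= decay) stop("rise time constant must be smaller than decay")
  out <- list(sampling_rate = sampling_rate, rise = rise, decay = decay,
              baseline = baseline, noise_sd = noise_sd)
  class(out) <- "trace_config"
  out
}

scr_kernel <- function(t, rise, decay) {
  tpk <- log(decay / rise) * rise * decay / (decay - rise)
  peak <- exp(-tpk / decay) - exp(-tpk / rise)
  ifelse(t < 0, 0, (exp(-t / decay) - exp(-t / rise)) / peak)
}

#' Synthesize a continuous electrodermal trace with planted responses
#'
#' Builds `baseline + sum of scaled canonical responses + noise` and records
#' the CS-onset markers. Responses must be well separated: an error is
#' raised if two onsets are closer than the effective response duration,
#' since the trough-to-peak scorer assumes the first response in the search
#' window is isolated.
#'
#' @param events data frame with columns `onset` (CS onset time, s),
#'   `amplitude` (planted trough-to-peak amplitude, uS) and optionally
#'   `latency` (response onset after CS onset, s; default 1.5).
#' @param tc a [trace_config()].
#' @param duration total trace duration in seconds (default: 12 s past the
#'   last onset).
#' @param seed optional integer seed for the noise.
#' @return list of class `eda_trace` with elements `conductance` (uS),
#'   `sampling_rate` and `markers` (CS onset times, s).
#' @export
synthesize_trace <- function(events, tc = trace_config(), duration = NULL,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(events) == 0) {
    if (is.null(duration)) stop("duration required when no events are given")
    n <- ceiling(duration * tc$sampling_rate)
    x <- rep(tc$baseline, n)
    if (tc$noise_sd > 0) x <- x + rnorm(n, 0, tc$noise_sd)
    out <- list(conductance = x, sampling_rate = tc$sampling_rate,
                markers = numeric(0))
    class(out) <- "eda_trace"
    return(out)
  }
  if (is.null(events$latency)) events$latency <- 1.5
  if (any(events$amplitude < 0)) stop("planted amplitudes must be >= 0")
  onsets <- events$onset + events$latency
  min_sep <- if (length(onsets) > 1) min(diff(sort(onsets))) else Inf
  # isolation: previous response must have decayed to ~2% of its peak
  eff_dur <- tc$decay * log(40)
  if (min_sep < eff_dur) {
    stop(sprintf("overlapping responses: onsets %.2f s apart, need >= %.2f s",
                 min_sep, eff_dur))
  }
  if (is.null(duration)) duration <- max(events$onset) + 12
  n <- ceiling(duration * tc$sampling_rate)
  x <- rep(tc$baseline, n)
  support_t <- tc$decay * log(1e8)
  support <- ceiling(support_t * tc$sampling_rate)
  # shift the truncated tail to zero so the support edge is continuous
  shift <- scr_kernel(support_t, tc$rise, tc$decay)
  for (k in seq_len(nrow(events))) {
    i0 <- floor(onsets[k] * tc$sampling_rate) + 1L
    idx <- i0:min(n, i0 + support)
    tt <- (idx - 1) / tc$sampling_rate - onsets[k]
    kv <- scr_kernel(tt, tc$rise, tc$decay)
    x[idx] <- x[idx] + events$amplitude[k] * pmax(kv - shift, 0)
  }
  if (tc$noise_sd > 0) x <- x + rnorm(n, 0, tc$noise_sd)
  out <- list(conductance = x, sampling_rate = tc$sampling_rate,
              markers = events$onset)
  class(out) <- "eda_trace"
  out
}

#' Synthesize a full-session trace for one participant's trial table
#'
#' Lays simulated cue trials out in time using the schedule's intertrial
#' intervals and plants each trial's amplitude at a fixed response latency,
#' producing a continuous trace plus one CS-onset marker per cue trial
#' (reinstatement shock events are skipped: they carry no cue).
#'
#' @param trials one participant's simulated trial table (must contain an
#'   `amplitude` column in uS and the schedule columns).
#' @param tc a [trace_config()].
#' @param latency response onset latency after CS onset in seconds.
#' @param seed optional integer seed for the noise.
#' @return an `eda_trace`.
#' @export
synthesize_session_trace <- function(trials, tc = trace_config(),
                                     latency = 1.5, seed = NULL) {
  cue <- trials[!is.na(trials$cs), , drop = FALSE]
  onsets <- 5 + cumsum(cue$iti) - cue$iti[1]
  events <- data.frame(onset = onsets, amplitude = cue$amplitude,
                       latency = latency)
  synthesize_trace(events, tc, duration = max(onsets) + 12, seed = seed)
}

#' @export
print.eda_trace <- function(x, ...) {
  cat(sprintf("EDA trace: %.1f s at %g Hz, %d markers\n",
              length(x$conductance) / x$sampling_rate, x$sampling_rate,
              length(x$markers)))
  invisible(x)
}
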