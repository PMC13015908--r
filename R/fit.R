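#' Sampler configuration for the hierarchical models
#'
#' The `"full"` profile follows the study settings: four independent chains
#' with 200 warm-up and 1800 post-warm-up iterations per chain. The
#' `"test"` profile (2 chains, 200 warm-up, 400 post-warm-up) is a
#' scaled-down variant for simulation studies and test suites, gated by the
#' same split-Rhat < 1.1 convergence rule.
#'
#' @param profile `"full"` or `"test"`, or leave as is and override fields.
#' @param chains,warmup,iter override the profile's chain count, warm-up
#'   iterations, and post-warm-up iterations per chain.
#' @param target_accept dual-averaging acceptance target.
#' @param t_sim leapfrog trajectory length in integration time.
#' @param max_leapfrog cap on leapfrog steps per trajectory.
#' @return list of class `sampler_config`.
#' @export
sampler_config <- function(profile = c("full", "test"), chains = NULL,
                           warmup = NULL, iter = NULL, target_accept = 0.95,
                           t_sim = 6.0, max_leapfrog = 192L) {
  profile <- match.arg(profile)
  def <- if (profile == "full") list(chains = 4L, warmup = 200L, iter = 1800L)
         else list(chains = 2L, warmup = 200L, iter = 400L)
  out <- list(profile = profile,
              chains = as.integer(chains %||% def$chains),
              warmup = as.integer(warmup %||% def$warmup),
              iter = as.integer(iter %||% def$iter),
              target_accept = target_accept, t_sim = t_sim,
              max_leapfrog = as.integer(max_leapfrog))
  class(out) <- "sampler_config"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ind_param_names <- function(model) {
  switch(model,
         acquisition = c("lr", "a_cr", "b_cr", "a_crur", "b_crur", "sigma"),
         extinction = c("lr", "a_cr", "b_cr", "sigma"),
         emotional_state = c("lr_shared", "state_bias", "a_cr", "b_cr",
                             "a_crur", "b_crur", "sigma"))
}

model_code <- function(model) {
  match(model, c("acquisition", "extinction", "emotional_state"))
}

# Arrange a long trial table into per-cue streams for the C++ likelihood.
# Streams are ordered by (participant, pair, cs); trials keep table order.
prep_streams <- function(trials, response, ev_seeds = NULL,
                         phase_sign = FALSE) {
  if (!response %in% names(trials)) {
    stop("response column '", response, "' not found in trial table")
  }
  cue <- trials[!is.na(trials$cs), , drop = FALSE]
  if (anyNA(cue[[response]])) stop("response column contains missing values")
  participants <- sort(unique(cue$participant))
  cue$cue_stream <- paste(cue$pair, cue$cs, sep = ".")
  us <- integer(0); amp <- numeric(0); phs <- integer(0)
  str_start <- integer(0); str_len <- integer(0)
  str_part <- integer(0); str_ev0 <- numeric(0)
  stream_key <- character(0)
  for (ip in seq_along(participants)) {
    di <- cue[cue$participant == participants[ip], , drop = FALSE]
    for (cs in sort(unique(di$cue_stream))) {
      ds <- di[di$cue_stream == cs, , drop = FALSE]
      ev0 <- 0
      if (!is.null(ev_seeds)) {
        hit <- ev_seeds$participant == participants[ip] & ev_seeds$cue == cs
        if (!any(hit)) {
          stop("no extinction seed for participant ", participants[ip],
               ", cue ", cs)
        }
        ev0 <- ev_seeds$ev0[hit][1]
      }
      str_start <- c(str_start, length(us))
      str_len <- c(str_len, nrow(ds))
      str_part <- c(str_part, ip - 1L)
      str_ev0 <- c(str_ev0, ev0)
      stream_key <- c(stream_key, paste(participants[ip], cs))
      us <- c(us, as.integer(ds$us))
      amp <- c(amp, ds[[response]])
      phs <- c(phs, if (phase_sign)
        ifelse(ds$phase == "acquisition", 1L, -1L) else rep(1L, nrow(ds)))
    }
  }
  list(n_participants = length(participants), us = us, amp = amp,
       phase = phs, stream_start = str_start, stream_len = str_len,
       stream_participant = str_part, stream_ev0 = str_ev0,
       participants = participants, stream_key = stream_key)
}

fit_rw_model <- function(trials, model, sampler, kappa, response,
                         ev_seeds = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dat <- prep_streams(trials, response, ev_seeds = ev_seeds,
                      phase_sign = (model == "emotional_state"))
  if (model == "extinction" && any(dat$us == 1L)) {
    stop("extinction model requires an unreinforced trial table (US = 0)")
  }
  code <- model_code(model)
  raw <- .rw_hmc(dat, code, sampler$chains, sampler$warmup, sampler$iter,
                 kappa, sampler$target_accept, sampler$t_sim,
                 sampler$max_leapfrog)
  ind <- ind_param_names(model)
  J <- length(ind); N <- dat$n_participants
  par_names <- c(paste0("mu_", ind), paste0("log_sd_", ind),
                 as.vector(outer(dat$participants, ind,
                                 function(p, j) paste0("z_", j, "[", p, "]"))))
  for (c in seq_along(raw$chains)) colnames(raw$chains[[c]]) <- par_names

  rhat <- vapply(seq_along(par_names), function(k) {
    split_rhat(sapply(raw$chains, function(m) m[, k]))
  }, numeric(1))
  names(rhat) <- par_names

  all_draws <- do.call(rbind, raw$chains)
  # constrained per-participant posterior means
  link <- function(j, x) {
    if (ind[j] %in% c("lr", "lr_shared")) stats::plogis(x)
    else if (ind[j] == "state_bias") tanh(x)
    else if (ind[j] == "sigma") exp(x)
    else x
  }
  ind_est <- matrix(NA_real_, N, J, dimnames = list(dat$participants, ind))
  for (j in seq_len(J)) {
    mu <- all_draws[, j]; sdg <- exp(all_draws[, J + j])
    for (i in seq_len(N)) {
      z <- all_draws[, 2 * J + (j - 1) * N + i]
      ind_est[i, j] <- mean(link(j, mu + sdg * z))
    }
  }
  individual <- data.frame(participant = dat$participants, ind_est,
                           check.names = FALSE, row.names = NULL)

  qs <- t(apply(all_draws, 2, quantile, probs = c(0.025, 0.975)))
  summary <- data.frame(parameter = par_names,
                        mean = colMeans(all_draws),
                        sd = apply(all_draws, 2, sd),
                        q2.5 = qs[, 1], q97.5 = qs[, 2],
                        rhat = rhat, row.names = NULL)

  out <- list(model = model, draws = raw$chains, par_names = par_names,
              ind_params = ind, rhat = rhat, summary = summary,
              individual = individual, data = dat, sampler = sampler,
              kappa = kappa, seed = seed,
              divergences = raw$divergences,
              accept_rate = raw$accept_rate, step_size = raw$step_size)
  class(out) <- "rl_fit"
  if (max(rhat, na.rm = TRUE) >= 1.1) {
    warning(sprintf("max split-Rhat %.3f >= 1.1: chains have not converged",
                    max(rhat, na.rm = TRUE)))
  }
  if (sd(trials[[response]][!is.na(trials[[response]])]) < 1e-12) {
    warning("response variance is (near) zero; fit is degenerate")
  }
  out
}

#' Fit the hierarchical Rescorla-Wagner acquisition model
#'
#' Fits trial-level SCRs from the acquisition phase with a canonical
#' Rescorla-Wagner learner per cue and the two-branch linear observation
#' model, under the hierarchical prior (group means normal(0,1), group SDs
#' half-Cauchy(0,1), non-centered individual deviates), using Hamiltonian
#' Monte Carlo. Convergence is assessed with split-Rhat per parameter; a
#' warning is raised if any parameter exceeds 1.1.
#'
#' @param trials long trial table (simulated or scored); only
#'   `phase == "acquisition"` rows are used.
#' @param sampler a [sampler_config()].
#' @param kappa soft non-negativity penalty weight.
#' @param response name of the amplitude column on the modeled (sqrt-uS)
#'   scale.
#' @param seed integer seed.
#' @return object of class `rl_fit`: posterior draws per chain, split-Rhat
#'   per parameter, a posterior summary table, and per-participant
#'   posterior-mean parameter estimates (`$individual`).
#' @export
fit_acquisition <- function(trials, sampler = sampler_config("full"),
                            kappa = 10, response = "scr", seed = NULL) {
  fit_rw_model(trials[trials$phase == "acquisition", , drop = FALSE],
               "acquisition", sampler, kappa, response, seed = seed)
}

#' Fit the hierarchical Rescorla-Wagner extinction model
#'
#' As [fit_acquisition()], but for the extinction phase, during which no US
#' is delivered: the prediction error is simply the negative of the current
#' EV, and each cue's initial EV is imported from the last acquisition
#' trial via `ev_seeds` (see [seed_extinction_evs()]).
#'
#' @inheritParams fit_acquisition
#' @param ev_seeds data frame with columns `participant`, `cue`
#'   (`"pair.CS"` format, e.g. `"active.CS+"`) and `ev0`.
#' @return an `rl_fit`.
#' @export
fit_extinction <- function(trials, ev_seeds,
                           sampler = sampler_config("full"), kappa = 10,
                           response = "scr", seed = NULL) {
  fit_rw_model(trials[trials$phase == "extinction", , drop = FALSE],
               "extinction", sampler, kappa, response,
               ev_seeds = ev_seeds, seed = seed)
}

#' Fit the unified emotional learning state model
#'
#' Fits acquisition and extinction jointly: each trial carries a phase
#' indicator (+1 acquisition, -1 extinction) and the effective learning
#' rate is `lr_shared * (1 + phase * state_bias)`, so learning is centered
#' on the shared rate and modulated symmetrically across phases by the
#' participant-specific emotional-state bias. EV carries over from the end
#' of acquisition into extinction within each cue stream.
#'
#' @inheritParams fit_acquisition
#' @return an `rl_fit`.
#' @export
fit_emotional_state <- function(trials, sampler = sampler_config("full"),
                                kappa = 10, response = "scr", seed = NULL) {
  keep <- trials$phase %in% c("acquisition", "extinction")
  fit_rw_model(trials[keep, , drop = FALSE], "emotional_state", sampler,
               kappa, response, seed = seed)
}

#' @export
print.rl_fit <- function(x, ...) {
  cat(sprintf("Hierarchical RW fit ('%s'): %d participants, %d chains x %d draws\n",
              x$model, x$data$n_participants, length(x$draws),
              nrow(x$draws[[1]])))
  cat(sprintf("  max split-Rhat %.3f | divergences %s | mean accept %.2f\n",
              max(x$rhat, na.rm = TRUE),
              paste(x$divergences, collapse = "/"),
              mean(x$accept_rate)))
  grp <- x$summary[grepl("^mu_", x$summary$parameter), , drop = FALSE]
  print(grp, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Posterior-mean terminal acquisition EVs per participant and cue
#'
#' Reruns the Rescorla-Wagner recursion for every posterior draw of each
#' participant's learning rate and averages the final EV, giving the
#' posterior-mean EV after the last trial of each cue stream (equal to the
#' mean of per-draw terminal EVs). Used to seed the extinction model.
#'
#' @param fit an `rl_fit` from [fit_acquisition()].
#' @return data frame with columns `participant`, `cue`, `ev_final`.
#' @export
terminal_evs <- function(fit) {
  stopifnot(inherits(fit, "rl_fit"))
  d <- fit$data
  J <- length(fit$ind_params)
  all_draws <- do.call(rbind, fit$draws)
  out <- vector("list", length(d$stream_start))
  for (s in seq_along(d$stream_start)) {
    i <- d$stream_participant[s] + 1L
    mu <- all_draws[, 1]; sdg <- exp(all_draws[, J + 1])
    lr <- stats::plogis(mu + sdg * all_draws[, 2 * J + (1 - 1) * d$n_participants + i])
    ev <- rep(d$stream_ev0[s], nrow(all_draws))
    idx <- d$stream_start[s] + seq_len(d$stream_len[s])
    for (t in idx) ev <- ev + lr * (d$us[t] - ev)
    key <- strsplit(d$stream_key[s], " ")[[1]]
    out[[s]] <- data.frame(participant = key[1], cue = key[2],
                           ev_final = mean(ev), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Split-chain potential scale reduction factor (split-Rhat)
#'
#' Each chain is split in half and the classic potential scale reduction
#' factor is computed over the resulting half-chains: with within-chain
#' variance W and between-chain variance B, `Rhat = sqrt(((n-1)/n * W +
#' B/n) / W)`. Convergence is conventionally accepted below 1.1.
#'
#' @param draws matrix with one column per chain (iterations in rows), or a
#'   list of equal-length numeric vectors.
#' @return the split-Rhat value; `NA` (with a warning) if the chains are
#'   degenerate (zero variance).
#' @export
split_rhat <- function(draws) {
  if (is.list(draws)) draws <- do.call(cbind, draws)
  draws <- as.matrix(draws)
  if (ncol(draws) < 2L) stop("split_rhat requires at least 2 chains")
  if (nrow(draws) < 4L) stop("split_rhat requires at least 4 draws per chain")
  n <- floor(nrow(draws) / 2)
  halves <- do.call(cbind, lapply(seq_len(ncol(draws)), function(c) {
    cbind(draws[seq_len(n), c], draws[n + seq_len(n), c])
  }))
  w <- mean(apply(halves, 2, var))
  if (!is.finite(w) || w <= 0) {
    warning("zero-variance chains: split-Rhat undefined")
    return(NA_real_)
  }
  b <- n * var(colMeans(halves))
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Two-sample contrast of individual parameter estimates between groups
#'
#' Compares per-participant posterior point estimates between two
#' experiment arms with a two-sample t test. The pooled-variance test is
#' the default (matching degrees of freedom n1 + n2 - 2); Welch's
#' correction is available.
#'
#' @param values numeric vector of individual estimates.
#' @param groups vector with exactly two levels, aligned with `values`.
#' @param var_equal pooled variance (default) or Welch.
#' @return list with `t`, `df`, `p` (two-sided), `mean_diff`
#'   (first level minus second), `direction` and the group labels.
#' @export
compare_groups <- function(values, groups, var_equal = TRUE) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("groups must have exactly two levels")
  x <- values[groups == levels(groups)[1]]
  y <- values[groups == levels(groups)[2]]
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 observations")
  }
  if (sd(c(x - mean(x), y - mean(y))) == 0) {
    res <- list(statistic = 0, parameter = length(x) + length(y) - 2,
                p.value = 1)
  } else {
    res <- t.test(x, y, var.equal = var_equal)
  }
  t <- unname(res$statistic)
  list(t = t, df = unname(res$parameter), p = res$p.value,
       mean_diff = mean(x) - mean(y),
       direction = if (t > 0) ">" else if (t < 0) "<" else "=",
       levels = levels(groups))
}

#' Prior-predictive draws of an individual-level parameter
#'
#' Samples the hierarchical prior with no data (group mean standard normal,
#' group SD half-Cauchy(0,1), standard-normal individual deviate) and maps
#' through the requested link, e.g. to check that individual learning
#' rates cover (0, 1).
#'
#' @param n number of draws.
#' @param link `"logit"` (rates), `"tanh"` (state bias), `"exp"` (sigma) or
#'   `"identity"`.
#' @param seed optional seed.
#' @return numeric vector of prior-predictive individual parameter values.
#' @export
prior_predictive <- function(n, link = c("logit", "tanh", "exp", "identity"),
                             seed = NULL) {
  link <- match.arg(link)
  if (!is.null(seed)) set.seed(seed)
  mu <- rnorm(n)
  sdg <- abs(stats::rcauchy(n))
  theta <- mu + sdg * rnorm(n)
  switch(link, logit = stats::plogis(theta), tanh = tanh(theta),
         exp = exp(theta), identity = theta)
}
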