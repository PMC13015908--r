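test_that("participant draws respect links and degenerate SDs", {
  g0 <- group_params("control",
                     lr_shared = c(qlogis(0.2), 0), state_bias = c(atanh(0.3), 0),
                     a_cr = c(0.3, 0), b_cr = c(0.5, 0), a_crur = c(0.7, 0),
                     b_crur = c(0.5, 0), log_sigma = c(log(0.1), 0))
  p <- draw_participant_params(g0, 5, seed = 1)
  expect_equal(p$lr_shared, rep(0.2, 5))
  expect_equal(p$state_bias, rep(0.3, 5))
  expect_equal(p$sigma, rep(0.1, 5))
  expect_equal(p$lr_acq, rep(0.2 * 1.3, 5))        # coupled rates
  expect_equal(p$lr_ext, rep(0.2 * 0.7, 5))

  expect_error(draw_participant_params(group_params(), 0), "at least 1")
  expect_error(group_params(a_cr = c(0.3, -0.1)), "SD must be non-negative")
})

test_that("sample means track group means at Monte-Carlo scale", {
  g <- group_params("control")
  p <- draw_participant_params(g, 400, seed = 2)
  se <- g$params$a_cr[2] / sqrt(400)
  expect_lt(abs(mean(p$a_cr) - g$params$a_cr[1]), 3 * se)
  se_b <- g$params$b_crur[2] / sqrt(400)
  expect_lt(abs(mean(p$b_crur) - g$params$b_crur[1]), 3 * se_b)
  expect_true(all(p$lr_acq >= 0 & p$lr_acq <= 1))
  expect_true(all(abs(p$state_bias) < 1))
  expect_true(all(p$sigma > 0))
})

test_that("noise-free amplitudes equal the branch means", {
  s <- generate_schedule(schedule_config(seed = 3))
  p <- data.frame(participant = "P001", lr_acq = 0.5, lr_ext = 0.2,
                  lr_shared = 0.35, state_bias = 0.3,
                  a_cr = 0.1, b_cr = 0.4, a_crur = 0.5, b_crur = 0.6,
                  sigma = 0, ev0 = 0)
  d <- simulate_trial_amplitudes(p, s, seed = 4)
  cue <- d[!is.na(d$cs), ]
  un <- cue[cue$us == 0, ]
  expect_equal(un$scr, 0.1 + 0.4 * un$ev)
  re <- cue[cue$us == 1, ]
  expect_equal(re$scr, 0.5 + 0.6 * re$ev)
  # a nominal unreinforced trial at EV = 0.5 has amplitude 0.1 + 0.4*0.5
  expect_equal(unique(round(un$scr[abs(un$ev - 0.5) < 1e-12], 10)),
               0.3, tolerance = 1e-9)
})

test_that("latent EV paths equal the brute-force recursion per cue stream", {
  arm <- small_arm()
  d <- arm$trials[arm$trials$participant == "P002", ]
  p <- arm$params[arm$params$participant == "P002", ]
  for (pr in c("active", "sham")) {
    acq <- d[d$phase == "acquisition" & d$pair == pr & d$cs == "CS+", ]
    acq <- acq[order(acq$trial), ]
    expect_equal(acq$ev, oracle_ev_path(acq$us, p$lr_acq, p$ev0),
                 tolerance = 1e-12)
    ext <- d[d$phase == "extinction" & d$pair == pr & d$cs == "CS+", ]
    ext <- ext[order(ext$trial), ]
    # extinction seeded from the terminal acquisition EV
    ev0_ext <- rw_update(acq$ev[nrow(acq)], acq$us[nrow(acq)], p$lr_acq)
    expect_equal(ext$ev, oracle_ev_path(ext$us, p$lr_ext, ev0_ext),
                 tolerance = 1e-12)
  }
  # lr = 0 keeps EV at ev0 everywhere
  p0 <- p; p0$lr_acq <- 0; p0$lr_ext <- 0; p0$ev0 <- 0.4
  s <- generate_schedule(schedule_config(seed = 5))
  d0 <- simulate_trial_amplitudes(p0, s, seed = 6)
  expect_equal(unique(d0$ev[!is.na(d0$ev)]), 0.4)
})

test_that("simulation is reproducible bit-for-bit given seeds", {
  a <- simulate_experiment(group_params("control"), 3, schedule_config(),
                           seed = 9)
  b <- simulate_experiment(group_params("control"), 3, schedule_config(),
                           seed = 9)
  expect_identical(a$trials, b$trials)
  expect_identical(a$params, b$params)
})

test_that("cohorts have the full session per participant", {
  ch <- simulate_cohort(n_per_group = 2, seed = 13)
  for (arm in ch) {
    expect_equal(arm$n, 2)
    per <- table(arm$trials$participant)
    expect_true(all(per == 208 + 3))         # 208 cue trials + 3 shocks
    cue <- arm$trials[!is.na(arm$trials$cs), ]
    expect_true(all(table(cue$participant) == 208))
    expect_true(all(cue$amplitude >= 0))
    expect_true(all(cue$ev >= 0 & cue$ev <= 1))
  }
})

test_that("reinforced trials are stronger when their branch mean dominates", {
  arm <- small_arm()
  acq <- arm$trials[arm$trials$phase == "acquisition" &
                    !is.na(arm$trials$cs) & arm$trials$cs == "CS+", ]
  expect_gt(mean(acq$scr[acq$us == 1]), mean(acq$scr[acq$us == 0]))
})

test_that("synthetic traces are flat at baseline without events or noise", {
  tc <- trace_config(sampling_rate = 100)
  tr <- synthesize_trace(data.frame(onset = numeric(0),
                                    amplitude = numeric(0)), tc,
                         duration = 5)
  expect_equal(unique(tr$conductance), tc$baseline)
  expect_length(tr$conductance, 500)
})

test_that("planted responses are recovered end to end by the scorer", {
  tc <- trace_config(sampling_rate = 500)
  tr <- synthesize_trace(data.frame(onset = 5, amplitude = 0.25), tc)
  sc <- score_trial(tr, 5)
  expect_equal(sc$raw_amplitude, 0.25, tolerance = 0.01)
  expect_equal(sc$scr, 0.5, tolerance = 0.005)
  expect_equal(sc$onset_latency, 1.5, tolerance = 0.01)
})

test_that("overlapping planted responses are rejected", {
  expect_error(synthesize_trace(data.frame(onset = c(5, 7),
                                           amplitude = c(0.2, 0.2)),
                                trace_config()),
               "overlapping")
})
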