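test_that("the C++ log posterior matches an R reference on differences", {
  arm <- small_arm()
  tr <- arm$trials[arm$trials$phase == "acquisition" &
                   arm$trials$participant %in% c("P001", "P002"), ]
  dat <- scrlearn:::prep_streams(tr, "scr")
  J <- 6; N <- dat$n_participants
  dim <- 2 * J + N * J

  # independent R implementation of the same posterior (up to a constant)
  r_lp <- function(q) {
    mu <- q[1:J]; lsd <- q[J + 1:J]; sdg <- exp(lsd)
    lp <- sum(dnorm(mu, log = TRUE)) +
      sum(log(2 / pi) - log1p(sdg^2) + lsd)
    for (i in seq_len(N)) {
      z <- q[2 * J + (seq_len(J) - 1) * N + i]
      lp <- lp + sum(dnorm(z, log = TRUE))
      th <- mu + sdg * z
      pars <- list(lr = plogis(th[1]), a_cr = th[2], b_cr = th[3],
                   a_crur = th[4], b_crur = th[5], sigma = exp(th[6]))
      pid <- dat$participants[i]
      di <- tr[tr$participant == pid, ]
      for (cs in unique(paste(di$pair, di$cs, sep = "."))) {
        ds <- di[paste(di$pair, di$cs, sep = ".") == cs, ]
        ds <- ds[order(ds$trial), ]
        ev <- simulate_ev_path(ds$us, pars$lr, 0)
        lp <- lp + observation_loglik(ds$scr, ev, ds$us, pars, kappa = 10)
      }
    }
    lp
  }
  set.seed(3)
  q1 <- rnorm(dim, 0, 0.3); q2 <- rnorm(dim, 0, 0.3)
  cpp1 <- scrlearn:::.rw_log_post(q1, dat, 1L, 10)$lp
  cpp2 <- scrlearn:::.rw_log_post(q2, dat, 1L, 10)$lp
  expect_equal(cpp1 - cpp2, r_lp(q1) - r_lp(q2), tolerance = 1e-8)
})

test_that("analytic gradients match central finite differences", {
  arm <- small_arm()
  tr <- arm$trials[arm$trials$participant %in% c("P001", "P003"), ]
  for (spec in list(list(phase = "acquisition", model = 1L, J = 6),
                    list(phase = "extinction", model = 2L, J = 4))) {
    sub <- tr[tr$phase == spec$phase, ]
    dat <- scrlearn:::prep_streams(sub, "scr")
    dim <- 2 * spec$J + dat$n_participants * spec$J
    set.seed(spec$model)
    q <- rnorm(dim, 0, 0.4)
    g <- scrlearn:::.rw_log_post(q, dat, spec$model, 10)$grad
    h <- 1e-6
    fd <- vapply(seq_len(dim), function(k) {
      qp <- q; qm <- q; qp[k] <- q[k] + h; qm[k] <- q[k] - h
      (scrlearn:::.rw_log_post(qp, dat, spec$model, 10)$lp -
         scrlearn:::.rw_log_post(qm, dat, spec$model, 10)$lp) / (2 * h)
    }, numeric(1))
    expect_equal(g, fd, tolerance = 1e-4)
  }
  # emotional-state model over both phases
  sub <- tr[tr$phase %in% c("acquisition", "extinction"), ]
  dat <- scrlearn:::prep_streams(sub, "scr", phase_sign = TRUE)
  dim <- 2 * 7 + dat$n_participants * 7
  set.seed(9); q <- rnorm(dim, 0, 0.3)
  g <- scrlearn:::.rw_log_post(q, dat, 3L, 10)$grad
  fd <- vapply(seq_len(dim), function(k) {
    qp <- q; qm <- q; qp[k] <- q[k] + 1e-6; qm[k] <- q[k] - 1e-6
    (scrlearn:::.rw_log_post(qp, dat, 3L, 10)$lp -
       scrlearn:::.rw_log_post(qm, dat, 3L, 10)$lp) / 2e-6
  }, numeric(1))
  expect_equal(g, fd, tolerance = 1e-4)
})

test_that("split-Rhat behaves like the standard diagnostic", {
  set.seed(41)
  draws <- matrix(rnorm(4000), 1000, 4)     # 4 well-mixed chains
  expect_true(split_rhat(draws) > 0.99 && split_rhat(draws) < 1.05)
  apart <- cbind(rnorm(500), rnorm(500, 5)) # separated chains
  expect_gt(split_rhat(apart), 1.1)
  expect_error(split_rhat(matrix(rnorm(100), 100, 1)), "at least 2 chains")
  expect_warning(out <- split_rhat(matrix(1, 100, 2)), "zero-variance")
  expect_true(is.na(out))
})

test_that("group contrasts reproduce the pooled-variance formula", {
  res <- compare_groups(c(1, 2, 3, 4, 5, 6),
                        rep(c("a", "b"), each = 3))
  expect_equal(res$t, -3.674235, tolerance = 1e-6)
  expect_equal(res$df, 4)
  same <- compare_groups(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(same$t, 0)
  expect_error(compare_groups(1:3, c("a", "a", "b")), "at least 2")
  # hand-computed pooled t on random inputs
  set.seed(7)
  x <- rnorm(10); y <- rnorm(12, 0.5)
  sp <- sqrt(((9 * var(x)) + (11 * var(y))) / 20)
  t_hand <- (mean(x) - mean(y)) / (sp * sqrt(1 / 10 + 1 / 12))
  res <- compare_groups(c(x, y), rep(c("x", "y"), c(10, 12)))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
})

test_that("prior-predictive learning rates cover the unit interval", {
  lr <- prior_predictive(5000, "logit", seed = 8)
  expect_true(all(lr >= 0 & lr <= 1))  # inverse-logit saturates in doubles
  expect_lt(min(lr), 0.01)
  expect_gt(max(lr), 0.99)
  bias <- prior_predictive(5000, "tanh", seed = 9)
  expect_true(all(abs(bias) <= 1))   # tanh saturates at double precision
})

test_that("a small hierarchical acquisition fit recovers and converges", {
  arm <- small_arm()
  f <- suppressWarnings(
    fit_acquisition(arm$trials, sampler_config("test"), seed = 51))
  expect_s3_class(f, "rl_fit")
  expect_equal(nrow(f$individual), 6)
  expect_equal(length(f$draws), 2)
  expect_equal(nrow(f$draws[[1]]), 400)
  expect_true(all(is.finite(f$rhat)))
  # with only 6 participants estimates should still be in the ballpark
  expect_lt(abs(mean(f$individual$lr) - mean(arm$params$lr_acq)), 0.15)
  expect_true(all(f$individual$sigma > 0))
})

test_that("extinction fits require seeds and unreinforced data", {
  arm <- small_arm()
  acq <- suppressWarnings(
    fit_acquisition(arm$trials, sampler_config("test", iter = 100),
                    seed = 52))
  seeds <- seed_extinction_evs(acq)
  expect_setequal(unique(seeds$participant), arm$params$participant)
  expect_true(all(seeds$ev0 >= 0 & seeds$ev0 <= 1))
  # dropping one participant from the seeds is an error naming them
  expect_error(
    suppressWarnings(fit_extinction(
      arm$trials, seeds[seeds$participant != "P004", ],
      sampler_config("test", iter = 100), seed = 53)),
    "P004")
  # reinforced trials cannot enter the extinction model
  bad <- arm$trials
  bad$us[bad$phase == "extinction"][1] <- 1L
  expect_error(suppressWarnings(
    fit_extinction(bad, seeds, sampler_config("test", iter = 100))),
    "unreinforced")
})

test_that("degenerate constant data are flagged, not silently fit", {
  arm <- small_arm()
  tr <- arm$trials[arm$trials$phase == "acquisition", ]
  tr$scr <- 0.5
  w <- capture_warnings(fit_acquisition(tr, sampler_config("test", iter = 100),
                                        seed = 54))
  expect_true(any(grepl("degenerate", w)))
})
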