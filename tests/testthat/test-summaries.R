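test_that("adjacent-pair averaging halves the series and keeps its mean", {
  expect_equal(adjacent_pair_average(c(1, 3, 2, 4)), c(2, 3))
  expect_equal(adjacent_pair_average(rep(7, 10)), rep(7, 5))
  expect_error(adjacent_pair_average(1:5), "even")
  set.seed(1)
  x <- rnorm(30)
  expect_equal(mean(adjacent_pair_average(x)), mean(x))
})

test_that("differential series is elementwise and antisymmetric", {
  expect_equal(differential_series(c(2, 3), c(1, 1)), c(1, 2))
  expect_equal(differential_series(c(1, 2, 3), c(1, 2, 3)), c(0, 0, 0))
  expect_error(differential_series(1:3, 1:4), "equal length")
  set.seed(2)
  a <- rnorm(8); b <- rnorm(8)
  expect_equal(differential_series(a, b), -differential_series(b, a))
})

test_that("bin means partition and average the series", {
  bs <- bin_spec("acquisition", 12)
  expect_equal(bs$labels, c("early", "mid", "late"))
  expect_equal(bin_means(1:12, bs),
               c(early = 2.5, mid = 6.5, late = 10.5))
  one <- bin_spec("extinction", 10, labels = "all")
  expect_equal(unname(bin_means(1:10, one)), mean(1:10))
  # overlapping / incomplete ranges are rejected
  bad <- bs; bad$ranges$early <- 1:5
  expect_error(bin_means(1:12, bad), "partition")
  expect_error(bin_means(1:13, bs), "partition")
  expect_equal(bin_spec("extinction", 10)$labels, c("early", "late"))
})

test_that("paired contrasts match the textbook formula", {
  r <- paired_contrast(c(2, 3, 4), c(1, 1, 1))
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(r$df, 2)
  same <- paired_contrast(1:5, 1:5)
  expect_equal(same$t, 0)
  expect_equal(same$cohens_d, 0)
  expect_error(paired_contrast(1, 2), "at least 2")
  set.seed(3)
  for (rep in 1:20) {
    x <- rnorm(12); y <- rnorm(12)
    d <- x - y
    r <- paired_contrast(x, y)
    expect_equal(r$t, mean(d) / (sd(d) / sqrt(12)), tolerance = 1e-12)
    expect_equal(r$cohens_d, mean(d) / sd(d), tolerance = 1e-12)
    expect_equal(r$p, 2 * pt(-abs(r$t), 11), tolerance = 1e-12)
  }
})

test_that("similarity indices reproduce hand-computed correlations", {
  # build a tiny acquisition table with a known reinforcement pattern
  mk <- function(us, amp) {
    data.frame(participant = "P1", phase = "acquisition", pair = "active",
               cs = "CS+", trial = seq_along(us) - 1, us = us, scr = amp,
               cue_identity = "sn033", stringsAsFactors = FALSE)
  }
  # triplets at (1,2,3), (4,5,6), (7,8,9): t0 reinforced, t+1/t+2 not
  us <- c(1, 0, 0, 1, 0, 0, 1, 0, 0)
  amp <- c(1, 2, 9, 2, 4, 7, 3, 5, 8)
  si <- similarity_index(mk(us, amp))
  expect_false(si$missing)
  expect_equal(si$n_triplets, 3)
  expect_equal(si$ur_cr, cor(c(1, 2, 3), c(2, 4, 5)), tolerance = 1e-12)
  expect_equal(si$ur_cr, 0.9819805, tolerance = 1e-6)
  expect_equal(si$cr_cr, cor(c(2, 4, 5), c(9, 7, 8)), tolerance = 1e-12)
  # proportional responses give r = 1
  si2 <- similarity_index(mk(us, c(1, 2, 9, 2, 4, 7, 3, 6, 8)))
  expect_equal(si2$ur_cr, 1, tolerance = 1e-12)
  # fewer than three triplets flags the participant as missing
  si3 <- similarity_index(mk(c(1, 0, 0, 1, 0, 0), c(1, 2, 3, 4, 5, 6)))
  expect_true(si3$missing)
  expect_true(is.na(si3$ur_cr))
})

test_that("similarity is invariant to affine rescaling of amplitudes", {
  arm <- small_arm()
  s1 <- similarity_index(arm$trials)
  tr2 <- arm$trials
  tr2$scr <- 3 * tr2$scr + 0.7
  s2 <- similarity_index(tr2)
  expect_equal(s1$ur_cr, s2$ur_cr, tolerance = 1e-10)
  expect_equal(s1$cr_cr, s2$cr_cr, tolerance = 1e-10)
})

test_that("ratings contrasts cover paired, chi-square and Fisher branches", {
  mk_ratings <- function(shift) {
    g <- expand.grid(participant = sprintf("P%02d", 1:8),
                     tus = c("active", "sham"),
                     cue = c("threat", "safety"),
                     stringsAsFactors = FALSE)
    g$experiment <- "amygdala"
    set.seed(4)
    g$threat_prob <- 50 + rnorm(nrow(g), 0, 5) +
      ifelse(g$cue == "threat" & g$tus == "active", shift, 0)
    g
  }
  # identical active/sham differential ratings give t = 0
  r0 <- mk_ratings(0)
  r0$threat_prob <- ifelse(r0$cue == "threat", 70, 30)
  out0 <- ratings_tests(r0)
  expect_equal(out0$statistic[1], 0)

  beliefs <- data.frame(participant = sprintf("P%02d", 1:20),
                        experiment = rep(c("amygdala", "hippocampus"),
                                         each = 10),
                        believed_real = rep(c(TRUE, FALSE), 10))
  out <- ratings_tests(mk_ratings(8), beliefs)
  chi <- out[out$method == "chi-square", ]
  expect_equal(chi$statistic, 0)            # perfectly balanced table
  # degenerate table forces the Fisher fallback with the exact p-value
  beliefs2 <- data.frame(participant = sprintf("P%02d", 1:10),
                         experiment = rep(c("amygdala", "hippocampus"),
                                          each = 5),
                         believed_real = rep(c(TRUE, FALSE), each = 5))
  out2 <- ratings_tests(mk_ratings(8), beliefs2)
  fis <- out2[out2$method == "Fisher exact", ]
  expect_equal(fis$p, 2 / choose(10, 5), tolerance = 1e-10)
})

test_that("differential trial series pair-averages safety during acquisition", {
  arm <- small_arm()
  X <- differential_trial_series(arm$trials, "acquisition", "active")
  expect_equal(dim(X), c(6, 15))            # 15 unreinforced CS+ trials
  Xe <- differential_trial_series(arm$trials, "extinction", "active")
  expect_equal(dim(Xe), c(6, 10))           # no averaging needed
  # hand-check participant P001
  d <- arm$trials[arm$trials$participant == "P001" &
                  arm$trials$phase == "acquisition" &
                  arm$trials$pair == "active" & !is.na(arm$trials$cs), ]
  d <- d[order(d$trial), ]
  th <- d$scr[d$cs == "CS+" & d$us == 0]
  sa <- adjacent_pair_average(d$scr[d$cs == "CS-"])
  expect_equal(unname(X["P001", ]), th - sa, tolerance = 1e-12)
})
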