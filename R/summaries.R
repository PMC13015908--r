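#' Average a series over adjacent trial pairs
#'
#' Halves a series by averaging trials (1,2), (3,4), ...; used to match the
#' number of safety-cue trials to the number of unreinforced threat trials
#' (the mean of the series is preserved exactly).
#'
#' @param x numeric series of even length.
#' @return series of length `length(x)/2`.
#' @examples
#' adjacent_pair_average(c(1, 3, 2, 4))  # 2 3
#' @export
adjacent_pair_average <- function(x) {
  n <- length(x)
  if (n %% 2 != 0) stop("series length must be even for pair averaging")
  (x[seq(1, n, by = 2)] + x[seq(2, n, by = 2)]) / 2
}

#' Differential (threat minus safety) response series
#'
#' @param threat,safety equal-length numeric series (apply
#'   [adjacent_pair_average()] to the safety series first when threat
#'   trials are the unreinforced subset).
#' @return elementwise `threat - safety`.
#' @export
differential_series <- function(threat, safety) {
  if (length(threat) != length(safety)) {
    stop("threat and safety series must have equal length ",
         "(pair-average the safety series first if needed)")
  }
  threat - safety
}

#' Time-bin specification for a conditioning phase
#'
#' Bins partition the phase's trial sequence into contiguous ranges:
#' early/mid/late thirds for acquisition, early/late halves for extinction
#' and re-extinction (boundaries configurable via `labels`).
#'
#' @param phase phase name (selects the default bin labels).
#' @param n number of trials in the series to be binned.
#' @param labels optional custom bin labels (equal contiguous splits).
#' @return list of class `bin_spec` with `labels` and `ranges` (list of
#'   index vectors).
#' @export
bin_spec <- function(phase = c("acquisition", "extinction",
                               "re_extinction"), n, labels = NULL) {
  phase <- match.arg(phase)
  if (is.null(labels)) {
    labels <- if (phase == "acquisition") c("early", "mid", "late")
              else c("early", "late")
  }
  k <- length(labels)
  sizes <- rep(n %/% k, k)
  if (n %% k) sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  ranges <- lapply(seq_len(k), function(i) starts[i]:ends[i])
  out <- list(phase = phase, labels = labels,
              ranges = stats::setNames(ranges, labels))
  class(out) <- "bin_spec"
  out
}

#' Per-bin means of a trial series
#'
#' @param x numeric series.
#' @param spec a [bin_spec()] whose ranges partition `seq_along(x)`;
#'   overlapping or incomplete ranges are an error.
#' @return named numeric vector of bin means.
#' @export
bin_means <- function(x, spec) {
  idx <- unlist(spec$ranges, use.names = FALSE)
  if (length(idx) != length(x) || anyDuplicated(idx) ||
      !setequal(idx, seq_along(x))) {
    stop("bin ranges must partition the series (no gaps or overlaps)")
  }
  vapply(spec$ranges, function(r) mean(x[r]), numeric(1))
}

#' Paired-sample t test with Cohen's d
#'
#' Two-tailed paired t test on `x - y`: `t = mean(d) / (sd(d) / sqrt(n))`
#' with `df = n - 1`, and standardized effect size
#' `d = mean(d) / sd(d)`.
#'
#' @param x,y paired numeric vectors of equal length `n >= 2`.
#' @return list with `t`, `df`, `p` (two-sided), `cohens_d`, `mean_diff`.
#' @export
paired_contrast <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  d <- x - y
  n <- length(d)
  if (n < 2) stop("need at least 2 pairs")
  s <- sd(d)
  if (s == 0) {
    if (mean(d) != 0) stop("zero variance with nonzero mean difference")
    return(list(t = 0, df = n - 1, p = 1, cohens_d = 0, mean_diff = 0))
  }
  t <- mean(d) / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1),
       cohens_d = mean(d) / s, mean_diff = mean(d))
}

#' SCR similarity index (lagged response correlations)
#'
#' Quantifies post-reinforcement cue-value updating as response
#' autocorrelation across consecutive presentations of the same threat
#' cue: for each reinforced CS+ presentation t0 whose next two
#' presentations of that cue are unreinforced, the pairs
#' (t0, t+1) enter the UR-CR correlation and (t+1, t+2) the CR-CR
#' correlation. Correlations are Pearson r per participant (triplets
#' pooled over that participant's CS+ streams); participants with fewer
#' than three usable triplets are flagged missing.
#'
#' @param trials long trial table (acquisition rows are used).
#' @param response amplitude column name.
#' @return data frame of class `similarity_result`: `participant`,
#'   `ur_cr`, `cr_cr`, `n_triplets`, `missing`.
#' @export
similarity_index <- function(trials, response = "scr") {
  acq <- trials[trials$phase == "acquisition" & !is.na(trials$cs), ,
                drop = FALSE]
  res <- lapply(split(acq, acq$participant), function(d) {
    x0 <- numeric(0); x1 <- numeric(0); x2 <- numeric(0)
    for (p in unique(d$pair)) {
      s <- d[d$pair == p & d$cs == "CS+", , drop = FALSE]
      s <- s[order(s$trial), , drop = FALSE]
      amp <- s[[response]]; us <- s$us
      for (t in seq_len(nrow(s) - 2)) {
        if (us[t] == 1 && us[t + 1] == 0 && us[t + 2] == 0) {
          x0 <- c(x0, amp[t]); x1 <- c(x1, amp[t + 1]); x2 <- c(x2, amp[t + 2])
        }
      }
    }
    k <- length(x0)
    if (k < 3) {
      data.frame(participant = d$participant[1], ur_cr = NA_real_,
                 cr_cr = NA_real_, n_triplets = k, missing = TRUE)
    } else {
      data.frame(participant = d$participant[1],
                 ur_cr = cor(x0, x1), cr_cr = cor(x1, x2),
                 n_triplets = k, missing = FALSE)
    }
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("similarity_result", "data.frame")
  out
}

#' Contrasts on subjective ratings and stimulation beliefs
#'
#' Per experiment and measure, a two-tailed paired t test compares the
#' threat > safety differential rating between active and sham stimulation
#' (see [paired_contrast()]). Categorical debriefing variables (reported
#' sensations, belief that stimulation was real) are compared between
#' experiments with a chi-square test of independence, falling back to
#' Fisher's exact test whenever any expected cell count is below 5.
#'
#' @param ratings data frame with columns `participant`, `experiment`,
#'   `tus` (`"active"`/`"sham"`), `cue` (`"threat"`/`"safety"`) and one or
#'   more numeric measure columns (e.g. `valence`, `arousal`,
#'   `threat_prob`).
#' @param beliefs optional data frame with columns `participant`,
#'   `experiment` and categorical columns (logical or two-level).
#' @return data frame with one row per test: `measure`, `contrast`,
#'   `method`, `statistic`, `df`, `p`, `effect`.
#' @export
ratings_tests <- function(ratings, beliefs = NULL) {
  id_cols <- c("participant", "experiment", "tus", "cue")
  if (!all(id_cols %in% names(ratings))) {
    stop("ratings must contain columns: ", paste(id_cols, collapse = ", "))
  }
  measures <- setdiff(names(ratings), id_cols)
  rows <- list()
  for (exp in unique(ratings$experiment)) {
    re <- ratings[ratings$experiment == exp, ]
    for (m in measures) {
      # differential per stimulation condition, aligned by participant
      diffs <- lapply(c("active", "sham"), function(cond) {
        d <- re[re$tus == cond, ]
        th <- d[d$cue == "threat", ]; sa <- d[d$cue == "safety", ]
        th <- th[order(th$participant), ]; sa <- sa[order(sa$participant), ]
        stats::setNames(th[[m]] - sa[[m]], th$participant)
      })
      pc <- paired_contrast(diffs[[1]], diffs[[2]][names(diffs[[1]])])
      rows[[length(rows) + 1L]] <- data.frame(
        measure = m, contrast = paste0(exp, ": active vs sham differential"),
        method = "paired t", statistic = pc$t, df = pc$df, p = pc$p,
        effect = pc$cohens_d)
    }
  }
  if (!is.null(beliefs)) {
    cats <- setdiff(names(beliefs), c("participant", "experiment"))
    for (cc in cats) {
      tab <- table(beliefs$experiment, beliefs[[cc]])
      if (any(dim(tab) < 2)) next
      expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expd < 5)) {
        ft <- fisher.test(tab)
        rows[[length(rows) + 1L]] <- data.frame(
          measure = cc, contrast = "between experiments",
          method = "Fisher exact", statistic = NA_real_, df = NA_real_,
          p = ft$p.value, effect = unname(ft$estimate %||% NA_real_))
      } else {
        ct <- chisq.test(tab, correct = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          measure = cc, contrast = "between experiments",
          method = "chi-square", statistic = unname(ct$statistic),
          df = unname(ct$parameter), p = ct$p.value, effect = NA_real_)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Participant-by-trial differential response matrix
#'
#' Builds the threat > safety series per participant for one phase and
#' stimulation pair, ready for permutation testing. During acquisition the
#' threat series keeps unreinforced CS+ trials only, and the safety series
#' is averaged over adjacent trial pairs beforehand so both series have
#' equal length.
#'
#' @param trials long trial table.
#' @param phase phase to extract.
#' @param pair `"active"`, `"sham"`, or `NULL` for both pairs stacked in
#'   presentation order.
#' @param response amplitude column name.
#' @return matrix (participants x trials) of differential responses, with
#'   participant row names.
#' @export
differential_trial_series <- function(trials, phase = "acquisition",
                                      pair = "active", response = "scr") {
  d <- trials[trials$phase == phase & !is.na(trials$cs), , drop = FALSE]
  if (!is.null(pair)) d <- d[d$pair == pair, , drop = FALSE]
  rows <- lapply(split(d, d$participant), function(di) {
    di <- di[order(di$trial), ]
    th <- di[[response]][di$cs == "CS+" & di$us == 0]
    sa <- di[[response]][di$cs == "CS-"]
    if (length(sa) == 2 * length(th)) sa <- adjacent_pair_average(sa)
    differential_series(th, sa)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(rows)
  out
}
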