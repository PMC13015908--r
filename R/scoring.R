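#' Parameters for trough-to-peak SCR scoring
#'
#' Defaults follow standard electrodermal scoring recommendations: only the
#' first response whose initial deflection (trough) falls between 1.0 and
#' 4.0 s after CS onset is considered; the ascent from trough to peak may
#' not exceed 5.0 s; responses below 0.01 uS count as nonresponses.
#'
#' @param window two seconds, response-onset search window after CS onset.
#' @param max_ascent maximum trough-to-peak rise time in seconds.
#' @param min_amplitude nonresponse threshold in uS.
#' @return list of class `scoring_params`.
#' @export
scoring_params <- function(window = c(1.0, 4.0), max_ascent = 5.0,
                           min_amplitude = 0.01) {
  if (window[1] >= window[2]) stop("window must be an increasing pair")
  if (max_ascent <= 0) stop("max_ascent must be positive")
  if (min_amplitude < 0) stop("min_amplitude must be non-negative")
  out <- list(window = window, max_ascent = max_ascent,
              min_amplitude = min_amplitude)
  class(out) <- "scoring_params"
  out
}

#' Detect candidate skin conductance deflections after a cue onset
#'
#' Finds trough-to-peak deflections whose trough (initial deflection, i.e.
#' the local minimum preceding an increasing run) lies within the scoring
#' window after `onset`, and whose ascent to the following local maximum
#' does not exceed `max_ascent` seconds. The peak itself may fall after the
#' window. Detection is offset-free (adding a constant to the trace changes
#' nothing) and scale-equivariant.
#'
#' @param trace an `eda_trace` (see [synthesize_trace()]), or any list with
#'   `conductance` and `sampling_rate`.
#' @param onset CS onset time in seconds.
#' @param p a [scoring_params()].
#' @return data frame of candidates ordered by trough time: `trough_time`,
#'   `peak_time`, `amplitude` (uS).
#' @export
detect_scr <- function(trace, onset, p = scoring_params()) {
  x <- trace$conductance
  fs <- trace$sampling_rate
  n <- length(x)
  i1 <- floor((onset + p$window[1]) * fs) + 1L
  i2 <- ceiling((onset + p$window[2]) * fs) + 1L
  if (onset < 0 || i1 < 1L || i2 > n) {
    stop(sprintf("onset %.2f s: scoring window extends outside the trace",
                 onset))
  }
  d <- diff(x)
  res <- list()
  for (i in i1:min(i2, n - 1L)) {
    rising <- d[i] > 0
    was_falling <- if (i == 1L) TRUE else d[i - 1L] <= 0
    if (!(rising && was_falling)) next
    j <- i
    while (j < n && x[j + 1L] > x[j]) j <- j + 1L
    ascent <- (j - i) / fs
    if (ascent > p$max_ascent) next
    if (x[j] - x[i] <= 1e-12) next     # numerical dust, not a deflection
    res[[length(res) + 1L]] <- data.frame(
      trough_time = (i - 1L) / fs, peak_time = (j - 1L) / fs,
      amplitude = x[j] - x[i])
  }
  if (!length(res)) {
    return(data.frame(trough_time = numeric(0), peak_time = numeric(0),
                      amplitude = numeric(0)))
  }
  do.call(rbind, res)
}

#' Score a single trial's SCR
#'
#' Takes the first candidate deflection in the scoring window. An amplitude
#' below the nonresponse threshold (or the absence of any candidate) is a
#' nonresponse: the raw amplitude is recorded as 0 and retained. The
#' transformed score is the square root of the raw amplitude.
#'
#' @inheritParams detect_scr
#' @return one-row data frame: `raw_amplitude` (uS), `scr` (sqrt-uS),
#'   `onset_latency` (s, `NA` for nonresponses), `responder` (0/1).
#' @export
score_trial <- function(trace, onset, p = scoring_params()) {
  cand <- detect_scr(trace, onset, p)
  if (nrow(cand) == 0L || cand$amplitude[1] < p$min_amplitude) {
    return(data.frame(raw_amplitude = 0, scr = 0,
                      onset_latency = NA_real_, responder = 0L))
  }
  amp <- cand$amplitude[1]
  data.frame(raw_amplitude = amp, scr = sqrt(amp),
             onset_latency = cand$trough_time[1] - onset, responder = 1L)
}

#' Score every cue trial of a session trace
#'
#' Scores one SCR per marker and joins the results to the trial table. The
#' trace must carry exactly one marker per cue trial (reinstatement shock
#' events carry no cue and are skipped); a mismatch is an error naming the
#' first trial without a marker.
#'
#' @param trace an `eda_trace` with `markers`.
#' @param trials the participant's trial table (schedule or simulated
#'   table); rows with `cs == NA` are ignored.
#' @param p a [scoring_params()].
#' @return the cue-trial table with appended scoring columns
#'   `raw_amplitude`, `scr`, `onset_latency`, `responder`.
#' @export
score_dataset <- function(trace, trials, p = scoring_params()) {
  cue <- trials[!is.na(trials$cs), , drop = FALSE]
  nm <- length(trace$markers)
  if (nm != nrow(cue)) {
    miss <- if (nm < nrow(cue)) cue[nm + 1L, ] else NULL
    stop(sprintf("marker/trial count mismatch: %d markers for %d cue trials%s",
                 nm, nrow(cue),
                 if (!is.null(miss)) sprintf(" (first unmatched: %s trial %d)",
                                             miss$phase, miss$trial) else ""))
  }
  scores <- do.call(rbind, lapply(trace$markers, function(on) {
    score_trial(trace, on, p)
  }))
  # replace any simulated amplitude columns with the scored ones
  cue$raw_amplitude <- scores$raw_amplitude
  cue$scr_scored <- scores$scr
  cue$onset_latency <- scores$onset_latency
  cue$responder <- scores$responder
  cue
}
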