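#' Configuration for a Pavlovian threat-conditioning trial schedule
#'
#' Defaults reproduce the printed design: threat acquisition (120 trials),
#' threat retention (4 trials), extinction training (40 trials), three
#' unsignaled reinstatement shocks followed by a 4-trial recovery block, and
#' re-extinction (40 trials); four trials per block; 50% CS+ reinforcement;
#' intertrial intervals jittered between 8 and 10 s and interblock intervals
#' between 19 and 21 s.
#'
#' @param n_acquisition number of acquisition cue trials.
#' @param n_retention number of retention cue trials (one per cue identity
#'   per group of four).
#' @param n_extinction number of extinction cue trials.
#' @param n_reinstatement_shocks number of unsignaled reinstatement shocks.
#' @param n_reinstatement number of recovery cue trials after reinstatement.
#' @param n_reextinction number of re-extinction cue trials.
#' @param block_size trials per block (must be even: half CS+, half CS-).
#' @param reinforcement_rate proportion of CS+ acquisition presentations that
#'   are reinforced.
#' @param iti_range intertrial-interval jitter range in seconds.
#' @param interblock_range interblock-interval jitter range in seconds.
#' @param counterbalance_code integer 1-4 selecting the Latin-square
#'   assignment of the four cue identities to the active/sham CS+/CS- roles.
#' @param seed integer seed making schedule generation deterministic.
#' @return list of class `schedule_config`.
#' @export
schedule_config <- function(n_acquisition = 120, n_retention = 4,
                            n_extinction = 40, n_reinstatement_shocks = 3,
                            n_reinstatement = 4, n_reextinction = 40,
                            block_size = 4, reinforcement_rate = 0.5,
                            iti_range = c(8, 10),
                            interblock_range = c(19, 21),
                            counterbalance_code = 1L, seed = 1L) {
  cfg <- list(n_acquisition = n_acquisition, n_retention = n_retention,
              n_extinction = n_extinction,
              n_reinstatement_shocks = n_reinstatement_shocks,
              n_reinstatement = n_reinstatement,
              n_reextinction = n_reextinction, block_size = block_size,
              reinforcement_rate = reinforcement_rate, iti_range = iti_range,
              interblock_range = interblock_range,
              counterbalance_code = as.integer(counterbalance_code),
              seed = as.integer(seed))
  class(cfg) <- "schedule_config"
  check_schedule_config(cfg)
  cfg
}

check_schedule_config <- function(cfg) {
  bs <- cfg$block_size
  if (bs < 2 || bs %% 2 != 0) {
    stop("block_size must be even (half CS+, half CS- per block)")
  }
  for (ph in c("n_acquisition", "n_extinction", "n_reextinction")) {
    n <- cfg[[ph]]
    if (n %% bs != 0) {
      stop(sprintf("%s (%d) is not divisible by block_size (%d)", ph, n, bs))
    }
    if ((n / bs) %% 2 != 0) {
      stop(sprintf("%s (%d) yields an odd number of blocks (%d); ",
                   ph, n, n / bs),
           "active and sham pairs cannot receive equal block counts")
    }
  }
  if (cfg$n_retention %% 4 != 0 || cfg$n_reinstatement %% 4 != 0) {
    stop("n_retention and n_reinstatement must be multiples of 4 ",
         "(one presentation per cue identity)")
  }
  csp_per_pair <- cfg$n_acquisition / 2 / 2
  n_reinf <- cfg$reinforcement_rate * csp_per_pair
  if (abs(n_reinf - round(n_reinf)) > 1e-9) {
    stop(sprintf(paste0("reinforcement_rate (%g) times CS+ presentations ",
                        "per pair (%d) is not an integer"),
                 cfg$reinforcement_rate, csp_per_pair))
  }
  if (cfg$reinforcement_rate < 0 || cfg$reinforcement_rate > 1) {
    stop("reinforcement_rate must lie in [0, 1]")
  }
  invisible(cfg)
}

# Four snake cue identities; the counterbalance code rotates their
# assignment to the (active CS+, active CS-, sham CS+, sham CS-) roles.
cue_identities <- function(code) {
  ids <- c("sn033", "sn094", "sn123", "sn131")
  roles <- c("active.CS+", "active.CS-", "sham.CS+", "sham.CS-")
  k <- ((as.integer(code) - 1L) %% 4L)
  stats::setNames(ids[((seq_len(4) - 1L + k) %% 4L) + 1L], roles)
}

# Balanced active/sham block sequence with no run longer than 2, sampled by
# randomized backtracking (uniform enough for scheduling; always terminates).
pair_block_sequence <- function(n_blocks, max_run = 2L) {
  rec <- function(seq_so_far, remaining) {
    if (sum(remaining) == 0L) return(seq_so_far)
    opts <- sample(names(remaining))
    for (p in opts) {
      if (remaining[[p]] == 0L) next
      k <- length(seq_so_far)
      if (k >= max_run &&
          all(seq_so_far[(k - max_run + 1L):k] == p)) next
      res <- rec(c(seq_so_far, p), remaining - (names(remaining) == p))
      if (!is.null(res)) return(res)
    }
    NULL
  }
  remaining <- c(active = n_blocks / 2, sham = n_blocks / 2)
  storage.mode(remaining) <- "integer"
  rec(character(0), remaining)
}

# Reinforcement pattern for one CS+ stream: exactly n_reinf of n trials,
# with no more than max_run consecutive reinforced presentations.
reinforcement_pattern <- function(n, n_reinf, max_run = 3L) {
  if (n_reinf == 0 || n_reinf == n) return(rep(as.integer(n_reinf > 0), n))
  repeat {
    us <- sample(c(rep(1L, n_reinf), rep(0L, n - n_reinf)))
    r <- rle(us)
    if (max(r$lengths[r$values == 1L]) <= max_run) return(us)
  }
}

# One block of cue trials: a single pair, half CS+ and half CS-, shuffled.
make_block <- function(pair, block_size) {
  cs <- sample(rep(c("CS+", "CS-"), block_size / 2))
  data.frame(pair = pair, cs = cs, stringsAsFactors = FALSE)
}

# Retention / recovery groups: one presentation per cue identity, organized
# as two adjacent same-pair mini-blocks in randomized order.
make_probe_trials <- function(n) {
  out <- list()
  for (g in seq_len(n / 4)) {
    pairs <- sample(c("active", "sham"))
    rows <- do.call(rbind, lapply(pairs, function(p) {
      data.frame(pair = p, cs = sample(c("CS+", "CS-")),
                 stringsAsFactors = FALSE)
    }))
    rows$probe_block <- g * 2L - 1L + rep(c(0L, 1L), each = 2L)
    out[[g]] <- rows
  }
  do.call(rbind, out)
}

#' Generate a pseudorandomized conditioning trial schedule
#'
#' Produces the full five-phase trial sequence (acquisition, retention,
#' extinction, reinstatement with recovery block, re-extinction) subject to
#' the design constraints: four-trial blocks holding one cue pair (half CS+,
#' half CS-), never more than two consecutive blocks of the same pair, each
#' CS+ reinforced on exactly the configured proportion of its acquisition
#' presentations (with no more than three consecutive reinforced
#' presentations), the CS- never reinforced, and no reinforcement outside
#' acquisition apart from the unsignaled reinstatement shocks (which carry
#' no cue). Deterministic given `config$seed`.
#'
#' @param config a [schedule_config()].
#' @return data frame of class `scr_schedule` with columns `phase`, `block`,
#'   `trial` (0-based within phase), `pair`, `cs`, `cue_identity`, `us`,
#'   `iti`; the configuration is attached as attribute `config`.
#' @export
generate_schedule <- function(config = schedule_config()) {
  check_schedule_config(config)
  set.seed(config$seed)
  ids <- cue_identities(config$counterbalance_code)
  bs <- config$block_size
  block_counter <- 0L

  blocked_phase <- function(phase, n_trials) {
    n_blocks <- n_trials / bs
    pairs <- pair_block_sequence(n_blocks)
    rows <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
      blk <- make_block(pairs[b], bs)
      blk$block <- block_counter + b
      blk
    }))
    block_counter <<- block_counter + n_blocks
    rows$phase <- phase
    rows
  }

  acq <- blocked_phase("acquisition", config$n_acquisition)
  acq$us <- 0L
  n_reinf <- as.integer(round(config$reinforcement_rate *
                              config$n_acquisition / 4))
  for (p in c("active", "sham")) {
    idx <- which(acq$pair == p & acq$cs == "CS+")
    acq$us[idx] <- reinforcement_pattern(length(idx), n_reinf)
  }

  ret <- make_probe_trials(config$n_retention)
  ret$block <- block_counter + ret$probe_block
  block_counter <- block_counter + max(ret$probe_block)
  ret$probe_block <- NULL
  ret$phase <- "retention"
  ret$us <- 0L

  ext <- blocked_phase("extinction", config$n_extinction)
  ext$us <- 0L

  shocks <- NULL
  if (config$n_reinstatement_shocks > 0) {
    shocks <- data.frame(pair = NA_character_, cs = NA_character_,
                         block = NA_integer_, phase = "reinstatement",
                         us = 1L, stringsAsFactors = FALSE)
    shocks <- shocks[rep(1, config$n_reinstatement_shocks), , drop = FALSE]
  }
  rec <- make_probe_trials(config$n_reinstatement)
  rec$block <- block_counter + rec$probe_block
  block_counter <- block_counter + max(rec$probe_block)
  rec$probe_block <- NULL
  rec$phase <- "reinstatement"
  rec$us <- 0L
  reinst <- rbind(shocks[, names(rec)], rec)

  reext <- blocked_phase("re_extinction", config$n_reextinction)
  reext$us <- 0L

  sched <- rbind(acq[, names(rec)], ret, ext[, names(rec)], reinst,
                 reext[, names(rec)])
  sched$cue_identity <- ifelse(is.na(sched$cs), NA_character_,
                               unname(ids[paste(sched$pair, sched$cs,
                                                sep = ".")]))
  # 0-based trial index within phase
  sched$trial <- stats::ave(seq_len(nrow(sched)), sched$phase,
                            FUN = seq_along) - 1L
  # intervals: interblock jitter before a new block, intertrial otherwise
  new_block <- c(TRUE, diff(ifelse(is.na(sched$block), -1L,
                                   sched$block)) != 0L)
  n <- nrow(sched)
  sched$iti <- runif(n, config$iti_range[1], config$iti_range[2])
  sched$iti[new_block] <- runif(sum(new_block), config$interblock_range[1],
                                config$interblock_range[2])
  sched <- sched[, c("phase", "block", "trial", "pair", "cs", "cue_identity",
                     "us", "iti")]
  rownames(sched) <- NULL
  attr(sched, "config") <- config
  class(sched) <- c("scr_schedule", "data.frame")
  sched
}

#' Validate a trial schedule against the design constraints
#'
#' Checks every design constraint and reports pass/fail per constraint;
#' validation never raises an error on a failed constraint.
#'
#' @param s a schedule data frame (as from [generate_schedule()]).
#' @param config the [schedule_config()] to validate against; defaults to
#'   the configuration attached to `s`.
#' @return data frame of class `schedule_validation` with columns
#'   `constraint`, `pass`, `detail`.
#' @export
validate_schedule <- function(s, config = attr(s, "config")) {
  if (is.null(config)) config <- schedule_config()
  checks <- list()
  add <- function(name, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      constraint = name, pass = pass, detail = detail,
      stringsAsFactors = FALSE)
  }
  cue <- s[!is.na(s$cs), , drop = FALSE]
  shock <- s[is.na(s$cs), , drop = FALSE]

  counts <- c(acquisition = config$n_acquisition,
              retention = config$n_retention,
              extinction = config$n_extinction,
              reinstatement = config$n_reinstatement,
              re_extinction = config$n_reextinction)
  got <- table(factor(cue$phase, levels = names(counts)))
  add("phase_trial_counts", all(as.integer(got) == unname(counts)),
      paste(names(counts), as.integer(got), sep = "=", collapse = ", "))
  add("reinstatement_shock_count",
      nrow(shock) == config$n_reinstatement_shocks &&
        all(shock$us == 1L) && all(shock$phase == "reinstatement"),
      sprintf("%d unsignaled shocks", nrow(shock)))

  # block composition: one pair per block, half CS+/CS-
  bl <- split(cue[cue$phase %in% c("acquisition", "extinction",
                                   "re_extinction"), ], ~ phase + block,
              drop = TRUE)
  comp_ok <- all(vapply(bl, function(b) {
    nrow(b) == config$block_size && length(unique(b$pair)) == 1L &&
      sum(b$cs == "CS+") == config$block_size / 2
  }, logical(1)))
  add("block_composition", comp_ok,
      sprintf("%d-trial blocks, one pair, balanced CS", config$block_size))

  # run-length constraint per blocked phase
  run_ok <- TRUE; max_run <- 0L
  for (ph in c("acquisition", "extinction", "re_extinction")) {
    d <- cue[cue$phase == ph, ]
    pair_by_block <- vapply(split(d$pair, d$block), function(x) x[1],
                            character(1))
    pair_by_block <- pair_by_block[order(as.integer(names(pair_by_block)))]
    r <- rle(pair_by_block)
    max_run <- max(max_run, max(r$lengths))
    if (max(r$lengths) > 2L) run_ok <- FALSE
  }
  add("max_two_consecutive_same_pair_blocks", run_ok,
      sprintf("longest same-pair block run: %d", max_run))

  # reinforcement: exact proportion per CS+ in acquisition, never on CS-
  acq <- cue[cue$phase == "acquisition", ]
  reinf_ok <- TRUE; det <- character(0)
  for (p in unique(acq$pair)) {
    csp <- acq[acq$pair == p & acq$cs == "CS+", ]
    prop <- mean(csp$us)
    det <- c(det, sprintf("%s CS+ %d/%d", p, sum(csp$us), nrow(csp)))
    if (abs(prop - config$reinforcement_rate) > 1e-12) reinf_ok <- FALSE
  }
  add("csplus_reinforcement_rate", reinf_ok, paste(det, collapse = "; "))
  add("csminus_never_reinforced", all(cue$us[cue$cs == "CS-"] == 0L),
      "CS- unreinforced in all phases")
  add("no_us_outside_acquisition",
      all(cue$us[cue$phase != "acquisition"] == 0L),
      "all post-acquisition cue trials unreinforced")

  # cue identity counterbalancing
  ids <- cue_identities(config$counterbalance_code)
  map <- unique(cue[, c("pair", "cs", "cue_identity")])
  role <- paste(map$pair, map$cs, sep = ".")
  add("cue_identity_counterbalance",
      nrow(map) == 4L && all(ids[role] == map$cue_identity),
      sprintf("code %d", config$counterbalance_code))

  # interval ranges
  new_block <- c(TRUE, diff(ifelse(is.na(s$block), -1L, s$block)) != 0L)
  iti_ok <- all(s$iti[!new_block] >= config$iti_range[1] &
                s$iti[!new_block] <= config$iti_range[2]) &&
    all(s$iti[new_block] >= config$interblock_range[1] &
        s$iti[new_block] <= config$interblock_range[2])
  add("interval_jitter_ranges", iti_ok,
      sprintf("ITI [%g, %g] s, interblock [%g, %g] s",
              config$iti_range[1], config$iti_range[2],
              config$interblock_range[1], config$interblock_range[2]))

  out <- do.call(rbind, checks)
  class(out) <- c("schedule_validation", "data.frame")
  out
}

#' @export
print.schedule_validation <- function(x, ...) {
  status <- ifelse(x$pass, "PASS", "FAIL")
  cat(sprintf("%-40s %-4s %s\n", x$constraint, status, x$detail), sep = "")
  invisible(x)
}
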