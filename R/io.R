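trial_table_columns <- c("participant", "experiment", "phase", "block",
                         "trial", "pair", "cs", "cue_identity", "us", "iti")
known_phases <- c("acquisition", "retention", "extinction", "reinstatement",
                  "re_extinction")

#' Write a trial table to CSV
#'
#' @param trials trial table (schedule or simulated/scored dataset).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  df <- as.data.frame(trials)
  if (!"participant" %in% names(df)) df$participant <- "P001"
  if (!"experiment" %in% names(df)) df$experiment <- "unlabeled"
  extra <- setdiff(names(df), trial_table_columns)
  df <- df[, c(trial_table_columns, extra)]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Load and validate a trial table CSV
#'
#' Reads the documented dialect (columns participant, experiment, phase,
#' block, trial, pair, cs, cue_identity, us, iti, plus optional amplitude
#' columns) and validates the schema: every required column present, known
#' phase labels, binary `us`, non-negative amplitudes, and no duplicate
#' (participant, phase, trial) keys. Schema violations raise informative
#' errors.
#'
#' @param path CSV file in the dialect written by [write_trial_table()].
#' @return validated trial table data frame.
#' @export
load_trial_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(trial_table_columns, names(df))
  if (length(missing)) {
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "))
  }
  bad_phase <- setdiff(unique(df$phase), known_phases)
  if (length(bad_phase)) {
    stop("unknown phase label(s): ", paste(bad_phase, collapse = ", "))
  }
  if (!all(df$us %in% c(0L, 1L))) stop("us must be binary (0/1)")
  for (ac in intersect(c("amplitude", "scr", "raw_amplitude"), names(df))) {
    if (any(df[[ac]] < 0, na.rm = TRUE)) {
      stop("column '", ac, "' contains negative amplitudes")
    }
  }
  key <- paste(df$participant, df$phase, df$trial, is.na(df$cs))
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicate (participant, phase, trial) keys, first: ", key[dup][1])
  }
  df
}

#' Configuration for an end-to-end pipeline run
#'
#' Bundles the stage configurations, output directory, master seed and
#' stage toggles. A YAML file may supply any field (values given directly
#' override the file). The master seed deterministically derives per-stage
#' seeds.
#'
#' @param out_dir output directory for all artifacts.
#' @param n_per_group participants per experiment arm.
#' @param schedule a [schedule_config()].
#' @param g_active,g_control [group_params()] for the two arms.
#' @param sampler a [sampler_config()].
#' @param tfce a [tfce_params()].
#' @param seed master seed.
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "fit", "permtest", "summarize")`.
#' @param file optional YAML file with fields `n_per_group`, `seed`,
#'   `stages`, `out_dir`, `sampler_profile`.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("scrlearn_run_"),
                       n_per_group = 25,
                       schedule = schedule_config(),
                       g_active = group_params("amygdala"),
                       g_control = group_params("control"),
                       sampler = sampler_config("full"),
                       tfce = tfce_params(n_permutations = 1000),
                       seed = 1L,
                       stages = c("simulate", "fit", "permtest",
                                  "summarize"),
                       file = NULL) {
  if (!is.null(file)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read config files")
    }
    y <- yaml::read_yaml(file)
    if (!is.null(y$n_per_group) && missing(n_per_group)) n_per_group <- y$n_per_group
    if (!is.null(y$seed) && missing(seed)) seed <- y$seed
    if (!is.null(y$stages) && missing(stages)) stages <- y$stages
    if (!is.null(y$out_dir) && missing(out_dir)) out_dir <- y$out_dir
    if (!is.null(y$sampler_profile) && missing(sampler)) {
      sampler <- sampler_config(y$sampler_profile)
    }
  }
  bad <- setdiff(stages, c("simulate", "fit", "permtest", "summarize"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  out <- list(out_dir = out_dir, n_per_group = n_per_group,
              schedule = schedule, g_active = g_active,
              g_control = g_control, sampler = sampler, tfce = tfce,
              seed = as.integer(seed), stages = stages)
  class(out) <- "run_config"
  out
}

stage_seed <- function(master, stage) {
  offsets <- c(simulate = 11L, fit = 23L, permtest = 37L, summarize = 53L)
  (master * 1009L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the pipeline end to end
#'
#' Executes the enabled stages in order (simulate, fit, permtest,
#' summarize) on a synthetic cohort, writing stage outputs and a JSON run
#' manifest (resolved configuration, per-stage seeds, wall-clock times and
#' file digests) to `config$out_dir`. Any stage failure aborts with an
#' error naming the stage; requesting a downstream stage without its
#' upstream products is an error naming the gap.
#'
#' @param config a [run_config()].
#' @return the manifest (list), invisibly; all outputs on disk.
#' @export
run_all <- function(config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(packageVersion("scrlearn")),
                   master_seed = config$seed, stages = list())
  cohort <- NULL
  timing <- function(stage, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$stages[[stage]] <<- list(
      seed = unname(stage_seed(config$seed, stage)),
      seconds = round(proc.time()[["elapsed"]] - t0, 2))
    res
  }

  if ("simulate" %in% config$stages) {
    cohort <- timing("simulate", function() {
      ch <- simulate_cohort(config$g_active, config$g_control,
                            config$n_per_group, config$schedule,
                            seed = stage_seed(config$seed, "simulate"))
      for (arm in names(ch)) {
        write_trial_table(ch[[arm]]$trials,
                          file.path(config$out_dir,
                                    paste0("trials_", arm, ".csv")))
        jsonlite::write_json(
          ch[[arm]]$params,
          file.path(config$out_dir, paste0("truth_", arm, ".json")),
          digits = NA)
      }
      ch
    })
  } else {
    paths <- file.path(config$out_dir,
                       c("trials_active.csv", "trials_control.csv"))
    if (any(c("fit", "permtest", "summarize") %in% config$stages)) {
      if (!all(file.exists(paths))) {
        stop("stages requested without the simulate stage, but no trial ",
             "tables found at: ", paste(paths[!file.exists(paths)],
                                        collapse = ", "))
      }
      cohort <- list(
        active = list(trials = load_trial_table(paths[1])),
        control = list(trials = load_trial_table(paths[2])))
    }
  }

  fits <- NULL
  if ("fit" %in% config$stages) {
    fits <- timing("fit", function() {
      sd0 <- stage_seed(config$seed, "fit")
      out <- list()
      for (arm in names(cohort)) {
        tr <- cohort[[arm]]$trials
        acq <- fit_acquisition(tr, config$sampler, seed = sd0)
        ext <- fit_extinction(tr, seed_extinction_evs(acq),
                              config$sampler, seed = sd0 + 1L)
        emo <- fit_emotional_state(tr, config$sampler, seed = sd0 + 2L)
        for (nm in c("acq", "ext", "emo")) {
          f <- get(nm)
          write.csv(f$summary,
                    file.path(config$out_dir,
                              sprintf("posterior_%s_%s.csv", nm, arm)),
                    row.names = FALSE)
          write.csv(f$individual,
                    file.path(config$out_dir,
                              sprintf("individual_%s_%s.csv", nm, arm)),
                    row.names = FALSE)
        }
        out[[arm]] <- list(acquisition = acq, extinction = ext,
                           emotional_state = emo)
      }
      out
    })
  }

  if ("permtest" %in% config$stages) {
    timing("permtest", function() {
      tf <- config$tfce
      tf$seed <- stage_seed(config$seed, "permtest")
      for (arm in names(cohort)) {
        X <- differential_trial_series(cohort[[arm]]$trials, "acquisition",
                                       pair = "active") -
          differential_trial_series(cohort[[arm]]$trials, "acquisition",
                                    pair = "sham")
        res <- tfce_permutation_test(X, "within", tf)
        write.csv(as.data.frame(res),
                  file.path(config$out_dir,
                            sprintf("permtest_acquisition_%s.csv", arm)),
                  row.names = FALSE)
      }
      NULL
    })
  }

  if ("summarize" %in% config$stages) {
    timing("summarize", function() {
      rows <- list()
      for (arm in names(cohort)) {
        tr <- cohort[[arm]]$trials
        X <- differential_trial_series(tr, "acquisition", pair = "active")
        bs <- bin_spec("acquisition", ncol(X))
        bm <- t(apply(X, 1, bin_means, spec = bs))
        Xs <- differential_trial_series(tr, "acquisition", pair = "sham")
        bm_s <- t(apply(Xs, 1, bin_means, spec = bs))
        for (b in colnames(bm)) {
          pc <- paired_contrast(bm[, b], bm_s[, b])
          rows[[length(rows) + 1L]] <- data.frame(
            measure = paste0("acquisition_", b, "_differential"),
            contrast = paste0(arm, ": active vs sham"), statistic = pc$t,
            df = pc$df, p = pc$p, effect = pc$cohens_d)
        }
        sim <- similarity_index(tr)
        write.csv(sim, file.path(config$out_dir,
                                 sprintf("similarity_%s.csv", arm)),
                  row.names = FALSE)
      }
      write.csv(do.call(rbind, rows),
                file.path(config$out_dir, "contrasts.csv"),
                row.names = FALSE)
      NULL
    })
  }

  files <- list.files(config$out_dir, full.names = TRUE)
  manifest$files <- lapply(stats::setNames(files, basename(files)),
                           function(f) unname(tools::md5sum(f)))
  manifest$config <- list(n_per_group = config$n_per_group,
                          stages = config$stages,
                          sampler_profile = config$sampler$profile)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
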