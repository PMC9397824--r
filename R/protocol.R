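session_log_columns <- c("participant", "session", "phase", "condition",
                         "block", "trial_idx", "f_st", "f_co", "diff_ratio",
                         "side", "combination", "odd_index", "response_index",
                         "correct", "seed")

#' Read or write a session log CSV
#'
#' One row per trial with columns participant, session, phase, condition,
#' block (training block number, NA elsewhere), trial_idx, f_st, f_co,
#' diff_ratio, side, combination, odd_index, response_index, correct, seed.
#'
#' @param log session-log data.frame.
#' @param path file path.
#' @return `read_session_log()` returns the validated data.frame;
#'   `write_session_log()` returns `path` invisibly.
#' @export
write_session_log <- function(log, path) {
  stopifnot(is.data.frame(log),
            all(session_log_columns %in% names(log)))
  utils::write.csv(log[, session_log_columns], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_session_log
#' @export
read_session_log <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, fill = FALSE, stringsAsFactors = FALSE),
    error = function(e)
      stop("malformed session log '", path, "': ", conditionMessage(e),
           call. = FALSE),
    warning = function(w)
      stop("malformed session log '", path, "': ", conditionMessage(w),
           call. = FALSE))
  missing <- setdiff(session_log_columns, names(df))
  if (length(missing))
    stop("session log lacks columns: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(df), session_log_columns)
  if (length(extra)) {
    warning("ignoring unknown session-log columns: ",
            paste(extra, collapse = ", "))
    df <- df[, session_log_columns]
  }
  bad <- which(df$correct != as.integer(df$response_index == df$odd_index))
  if (length(bad))
    stop("inconsistent correctness flag at data line ", bad[1])
  df
}

#' Protocol configuration for a simulated study
#'
#' Describes one full three-session study: the stimulus set, block sizes,
#' the simulated observers and the haptic/kinematic options.
#'
#' Each participant's baseline observer slope is drawn uniformly from
#' `beta_range` (the between-subject spread); the retention phases use the
#' slope multiplied by `training_gain` (the training effect). With
#' `training_gain = 1` day-1 and day-2 baselines are generated by identical
#' observers.
#'
#' @param n_participants even number of simulated participants (the two
#'   protocol randomizations each split the sample in half).
#' @param stimulus_set baseline `stimulus_set`.
#' @param repetitions presentations per comparison stimulus per block.
#' @param n_training_blocks training blocks per training session.
#' @param observer_alpha logistic intercept shared by all observers.
#' @param beta_range length-2 range of the between-subject slope draw.
#' @param training_gain multiplier on the slope after training (applied in
#'   RT).
#' @param floor_mode observer response mode (see [observer_model()]).
#' @param haptics a `haptic_params`.
#' @param trace_policy `"none"`, `"first"` (trace the first trial of every
#'   assessment phase) or `"all"` (trace every assessment trial; slow).
#' @param sweeps cycloidal sweeps per texture in traced trials.
#' @return List of class `protocol_config`.
#' @export
protocol_config <- function(n_participants = 10,
                            stimulus_set = default_stimulus_set(),
                            repetitions = 5, n_training_blocks = 3,
                            observer_alpha = -log(2),
                            beta_range = c(5, 20), training_gain = 1.6,
                            floor_mode = "plain_logistic",
                            haptics = haptic_params(),
                            trace_policy = c("first", "none", "all"),
                            sweeps = 1) {
  trace_policy <- match.arg(trace_policy)
  if (n_participants < 2 || n_participants %% 2 != 0)
    stop("`n_participants` must be an even number >= 2")
  if (repetitions < 1 || n_training_blocks < 1)
    stop("`repetitions` and `n_training_blocks` must be >= 1")
  if (length(beta_range) != 2 || any(beta_range < 0) || diff(beta_range) < 0)
    stop("`beta_range` must be an increasing non-negative length-2 range")
  if (training_gain <= 0) stop("`training_gain` must be > 0")
  stopifnot(inherits(stimulus_set, "stimulus_set"),
            inherits(haptics, "haptic_params"))
  structure(list(n_participants = n_participants,
                 stimulus_set = stimulus_set, repetitions = repetitions,
                 n_training_blocks = n_training_blocks,
                 observer_alpha = observer_alpha, beta_range = beta_range,
                 training_gain = training_gain, floor_mode = floor_mode,
                 haptics = haptics, trace_policy = trace_policy,
                 sweeps = sweeps),
            class = "protocol_config")
}

as_log_rows <- function(sim, participant, session, phase, condition,
                        block = NA_integer_, seed = NA_integer_) {
  data.frame(participant = participant, session = session, phase = phase,
             condition = condition, block = block,
             trial_idx = sim$trial_idx, f_st = sim$f_st, f_co = sim$f_co,
             diff_ratio = sim$diff_ratio, side = sim$side,
             combination = sim$combination, odd_index = sim$odd_index,
             response_index = sim$response_index, correct = sim$correct,
             seed = seed, stringsAsFactors = FALSE)
}

familiarization_record <- function(participant, seed) {
  # single acquaintance trial: twin 228 m^-1 gratings with a 100 m^-1 odd one
  trial <- list(triplet = c(228, 228, 100), odd_index = 3L,
                combination = "St/St/Co", f_st = 228, f_co = 100,
                side = "more_coarse",
                diff_ratio = difference_ratio(100, 228))
  data.frame(participant = participant, session = 1L,
             phase = "familiarization", condition = "active",
             block = NA_integer_, trial_idx = 1L, f_st = trial$f_st,
             f_co = trial$f_co, diff_ratio = trial$diff_ratio,
             side = trial$side, combination = trial$combination,
             odd_index = trial$odd_index,
             response_index = trial$odd_index, correct = 1L, seed = seed,
             stringsAsFactors = FALSE)
}

#' Run the full three-session protocol as a seeded simulation
#'
#' Per participant: session 1 holds the familiarization trial and two
#' initial baselines (iBL), one per exploration condition in randomized
#' order (half the sample starts active, half passive); sessions 2 and 3
#' each hold baseline (BL), training blocks with the PSE-adapted comparison
#' set, and retention (RT), with the session-2 condition randomized over
#' half the sample and crossed over in session 3. All randomness derives
#' from `seed`; re-running with the same seed reproduces the logs exactly.
#'
#' @param config a `protocol_config`.
#' @param out_dir output directory; created if absent. Logs are written to
#'   `logs/<participant>.csv`, traces (per `trace_policy`) to `traces/`,
#'   and the configuration echo with assignments to `study.yaml`.
#' @param seed integer master seed.
#' @return Invisibly, the combined session-log data.frame of the study.
#' @export
run_protocol_simulation <- function(config, out_dir, seed = 1L) {
  stopifnot(inherits(config, "protocol_config"))
  dir.create(file.path(out_dir, "logs"), recursive = TRUE,
             showWarnings = FALSE)
  if (config$trace_policy != "none")
    dir.create(file.path(out_dir, "traces"), showWarnings = FALSE)
  n <- config$n_participants
  half <- n / 2

  # the two protocol randomizations, each a half/half split
  ibl_active_first <- with_seed(derive_seed(seed, 1),
                                sample(rep(c(TRUE, FALSE), half)))
  day2_active <- with_seed(derive_seed(seed, 2),
                           sample(rep(c(TRUE, FALSE), half)))
  betas <- with_seed(derive_seed(seed, 3),
                     stats::runif(n, config$beta_range[1],
                                  config$beta_range[2]))

  all_logs <- vector("list", n)
  for (p in seq_len(n)) {
    pid <- sprintf("P%02d", p)
    obs <- observer_model(config$observer_alpha, betas[p],
                          config$floor_mode)
    obs_rt <- observer_model(config$observer_alpha,
                             betas[p] * config$training_gain,
                             config$floor_mode)
    rows <- list(familiarization_record(pid, derive_seed(seed, p, 0)))

    run_phase <- function(set, phase, session, condition, observer,
                          phase_code, block = NA_integer_,
                          block_df = NULL) {
      sseed <- derive_seed(seed, p, phase_code)
      if (is.null(block_df))
        block_df <- constant_stimuli_block(set, config$repetitions, phase,
                                           seed = sseed)
      sim <- simulate_block(block_df, observer,
                            seed = derive_seed(seed, p, phase_code, 1))
      as_log_rows(sim, pid, session, phase, condition, block, sseed)
    }

    # session 1: two iBLs in counterbalanced order
    conds <- if (ibl_active_first[p]) c("active", "passive")
    else c("passive", "active")
    rows <- c(rows, list(
      run_phase(config$stimulus_set, "iBL", 1L, conds[1], obs, 11),
      run_phase(config$stimulus_set, "iBL", 1L, conds[2], obs, 12)))

    # sessions 2 and 3: BL, adapted training, RT; condition crossover
    s2_cond <- if (day2_active[p]) "active" else "passive"
    for (session in 2:3) {
      condition <- if (session == 2L) s2_cond
      else setdiff(c("active", "passive"), s2_cond)
      code <- session * 10
      bl <- run_phase(config$stimulus_set, "BL", session, condition, obs,
                      code + 1)
      fit_mc <- fit_psychometric(bl[bl$side == "more_coarse", ],
                                 "more_coarse")
      fit_lc <- fit_psychometric(bl[bl$side == "less_coarse", ],
                                 "less_coarse")
      train_set <- adapt_training_set(fit_mc$pse, fit_lc$pse,
                                      config$stimulus_set,
                                      fit_mc$converged, fit_lc$converged)
      tb <- training_blocks(train_set, config$repetitions,
                            seed = derive_seed(seed, p, code + 2))
      tr_rows <- lapply(seq_len(config$n_training_blocks), function(b) {
        blk <- tb[[((b - 1) %% 3) + 1]]
        run_phase(train_set, "training", session, condition, obs,
                  code + 2 + b, block = b, block_df = blk)
      })
      rt <- run_phase(config$stimulus_set, "RT", session, condition,
                      obs_rt, code + 9)
      rows <- c(rows, list(bl), tr_rows, list(rt))
    }

    log <- do.call(rbind, rows)
    write_session_log(log, file.path(out_dir, "logs",
                                     paste0(pid, ".csv")))
    all_logs[[p]] <- log

    if (config$trace_policy != "none") {
      assess <- log[log$phase %in% c("iBL", "BL", "RT"), ]
      keys <- unique(assess[, c("session", "phase", "condition")])
      for (r in seq_len(nrow(keys))) {
        ph <- assess[assess$session == keys$session[r] &
                       assess$phase == keys$phase[r] &
                       assess$condition == keys$condition[r], ]
        take <- if (config$trace_policy == "first") 1L else nrow(ph)
        for (ti in seq_len(take)) {
          tr <- simulate_exploration(
            list(triplet = c(ph$f_st[ti], ph$f_st[ti], ph$f_co[ti])),
            mode = ph$condition[ti], params = config$haptics,
            sweeps = config$sweeps)
          write_trace(tr, file.path(out_dir, "traces",
                                    sprintf("%s_s%d_%s_%s_t%03d.csv", pid,
                                            keys$session[r], keys$phase[r],
                                            keys$condition[r], ti)))
        }
      }
    }
  }

  study <- do.call(rbind, all_logs)
  yaml::write_yaml(
    list(seed = as.integer(seed), n_participants = n,
         repetitions = config$repetitions,
         n_training_blocks = config$n_training_blocks,
         observer_alpha = config$observer_alpha,
         beta_range = config$beta_range,
         training_gain = config$training_gain,
         floor_mode = config$floor_mode,
         trace_policy = config$trace_policy,
         stimulus_set = list(standard_frequency = config$stimulus_set$standard,
                             more_coarse = config$stimulus_set$more_coarse,
                             less_coarse = config$stimulus_set$less_coarse),
         ibl_active_first = ibl_active_first, day2_active = day2_active,
         beta_true = betas),
    file.path(out_dir, "study.yaml"))
  invisible(study)
}

#' Analyze a simulated (or recorded) study directory
#'
#' Computes per participant x session x phase x condition the
#' probability-correct phase score and the PSE outcome; study-level
#' test-retest reliability compares each participant's day-1 iBL with the
#' day-2 BL of the same condition, grouping participants by their day-2
#' condition, via [icc_2k()] and [bland_altman()]. Kinematic outcomes are
#' computed from any traces present.
#'
#' @param dir study directory written by [run_protocol_simulation()].
#' @param speed_threshold scanning-speed gate for kinematics (m/s).
#' @return List of class `study_analysis`: `scores` (per-phase table),
#'   `reliability` (per condition and metric: `icc`, `bland_altman`, and
#'   the paired values), `kinematics` (per-trace table or NULL), `meta`.
#' @export
analyze_study <- function(dir, speed_threshold = 0.01) {
  meta <- yaml::read_yaml(file.path(dir, "study.yaml"))
  files <- sort(list.files(file.path(dir, "logs"), pattern = "\\.csv$",
                           full.names = TRUE))
  if (!length(files)) stop("no session logs under ", dir)
  log <- do.call(rbind, lapply(files, read_session_log))

  assess <- log[log$phase %in% c("iBL", "BL", "RT"), ]
  keys <- unique(assess[, c("participant", "session", "phase", "condition")])
  scores <- do.call(rbind, lapply(seq_len(nrow(keys)), function(r) {
    rec <- assess[assess$participant == keys$participant[r] &
                    assess$session == keys$session[r] &
                    assess$phase == keys$phase[r] &
                    assess$condition == keys$condition[r], ]
    ps <- phase_score(rec)
    po <- pse_outcome(rec)
    data.frame(keys[r, , drop = FALSE], score = ps$score, pse = po$pse,
               pse_more_coarse = po$pse_more_coarse,
               pse_less_coarse = po$pse_less_coarse,
               row.names = NULL, stringsAsFactors = FALSE)
  }))

  # expected phases per participant; report anything missing
  expected <- c("1.iBL.active", "1.iBL.passive", "2.BL", "2.RT", "3.BL",
                "3.RT")
  have <- with(scores, paste(session, phase,
                             ifelse(session == 1, condition, ""), sep = "."))
  missing_phases <- character(0)
  for (pid in unique(scores$participant)) {
    h <- have[scores$participant == pid]
    h <- sub("\\.$", "", h)
    miss <- setdiff(expected, h)
    if (length(miss))
      missing_phases <- c(missing_phases, paste0(pid, ": ",
                                                 paste(miss, collapse = ", ")))
  }
  if (length(missing_phases))
    warning("incomplete phases; partial output for: ",
            paste(missing_phases, collapse = "; "))

  reliability <- list()
  for (cond in c("active", "passive")) {
    day2 <- scores[scores$session == 2 & scores$phase == "BL" &
                     scores$condition == cond, ]
    ibl <- scores[scores$session == 1 & scores$phase == "iBL" &
                    scores$condition == cond &
                    scores$participant %in% day2$participant, ]
    m <- merge(ibl[, c("participant", "score", "pse")],
               day2[, c("participant", "score", "pse")],
               by = "participant", suffixes = c("_ibl", "_bl"))
    rel <- list()
    if (nrow(m) >= 3) {
      sm <- as.matrix(m[, c("score_ibl", "score_bl")])
      rel$score <- list(icc = icc_2k(sm),
                        bland_altman = bland_altman(m$score_ibl, m$score_bl),
                        pairs = m[, c("participant", "score_ibl", "score_bl")])
      pm <- m[stats::complete.cases(m[, c("pse_ibl", "pse_bl")]), ]
      if (nrow(pm) >= 3)
        rel$pse <- list(icc = icc_2k(as.matrix(pm[, c("pse_ibl", "pse_bl")])),
                        bland_altman = bland_altman(pm$pse_ibl, pm$pse_bl),
                        pairs = pm[, c("participant", "pse_ibl", "pse_bl")])
    }
    reliability[[cond]] <- rel
  }

  kin <- NULL
  trace_dir <- file.path(dir, "traces")
  if (dir.exists(trace_dir)) {
    tfiles <- sort(list.files(trace_dir, pattern = "\\.csv$",
                              full.names = TRUE))
    if (length(tfiles)) {
      kin <- do.call(rbind, lapply(tfiles, function(f) {
        k <- trial_kinematics(read_trace(f), speed_threshold)
        data.frame(trace = basename(f),
                   scanning_duration = k$scanning_duration,
                   path_length = k$path_length,
                   mean_scanning_speed = k$mean_scanning_speed,
                   stringsAsFactors = FALSE)
      }))
    }
  }

  structure(list(scores = scores, reliability = reliability,
                 kinematics = kin, meta = meta),
            class = "study_analysis")
}

#' @export
print.study_analysis <- function(x, ...) {
  cat("Study analysis:", length(unique(x$scores$participant)),
      "participants,", nrow(x$scores), "phase scores\n")
  for (cond in names(x$reliability)) {
    r <- x$reliability[[cond]]
    if (!is.null(r$score)) {
      cat(sprintf("  %s condition, probability-correct: ", cond))
      print(r$score$icc)
    }
  }
  invisible(x)
}
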