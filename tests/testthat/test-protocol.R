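test_that("session logs round-trip and are validated on read", {
  blk <- constant_stimuli_block(default_stimulus_set(), 2, seed = 61)
  sim <- simulate_block(blk, observer_model(), seed = 62)
  log <- data.frame(participant = "P01", session = 1L, phase = "iBL",
                    condition = "active", block = NA_integer_,
                    trial_idx = sim$trial_idx, f_st = sim$f_st,
                    f_co = sim$f_co, diff_ratio = sim$diff_ratio,
                    side = sim$side, combination = sim$combination,
                    odd_index = sim$odd_index,
                    response_index = sim$response_index,
                    correct = sim$correct, seed = 61L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_session_log(log, path)
  log2 <- read_session_log(path)
  expect_equal(log2$f_co, log$f_co)
  expect_equal(log2$correct, log$correct)

  extra <- cbind(log, mystery = 1)
  utils::write.csv(extra, path, row.names = FALSE)
  expect_warning(read_session_log(path), "unknown")

  lines <- readLines(path)
  writeLines(c(lines[1:5], substr(lines[6], 1, 10)), path)
  expect_error(read_session_log(path), "malformed|lacks")

  bad <- log
  bad$correct[1] <- 1L - bad$correct[1]
  write_session_log(bad, path)
  expect_error(read_session_log(path), "inconsistent.*line 1")
})

test_that("protocol configs are validated before any output", {
  expect_error(protocol_config(n_participants = 3), "even")
  expect_error(protocol_config(repetitions = 0), ">= 1")
  expect_error(protocol_config(beta_range = c(5, 2)), "increasing")
  expect_error(protocol_config(training_gain = 0), "> 0")
})

test_that("a two-participant study has the full protocol structure", {
  dir <- withr::local_tempdir()
  cfg <- protocol_config(n_participants = 2, trace_policy = "none")
  log <- run_protocol_simulation(cfg, dir, seed = 71)

  main <- log[log$phase != "familiarization", ]
  expect_equal(nrow(main), 960)       # 2 x (80 iBL + 2 x (40 + 120 + 40))
  expect_equal(sum(log$phase == "familiarization"), 2)

  for (pid in unique(log$participant)) {
    pl <- log[log$participant == pid, ]
    # session 1: one iBL per condition, 40 trials each
    ibl <- pl[pl$phase == "iBL", ]
    expect_equal(as.integer(table(ibl$condition)[c("active", "passive")]),
                 c(40L, 40L))
    # sessions 2-3: 40 BL + 120 training + 40 RT, crossover of conditions
    conds <- character(2)
    for (ss in 2:3) {
      s <- pl[pl$session == ss, ]
      expect_equal(as.integer(table(s$phase)[c("BL", "RT", "training")]),
                   c(40L, 40L, 120L))
      conds[ss - 1] <- unique(s$condition)
    }
    expect_setequal(conds, c("active", "passive"))
    # training blocks repeat the first block's stimulus order
    tr <- pl[pl$session == 2 & pl$phase == "training", ]
    expect_equal(tr$f_co[tr$block == 2], tr$f_co[tr$block == 1])
    expect_equal(tr$f_co[tr$block == 3], tr$f_co[tr$block == 1])
  }

  # determinism: identical seed reproduces the logs byte for byte
  dir2 <- withr::local_tempdir()
  run_protocol_simulation(cfg, dir2, seed = 71)
  f1 <- file.path(dir, "logs", "P01.csv")
  f2 <- file.path(dir2, "logs", "P01.csv")
  expect_identical(readLines(f1), readLines(f2))
  log3 <- run_protocol_simulation(cfg, withr::local_tempdir(), seed = 72)
  expect_false(identical(log$correct, log3$correct))
})

test_that("counterbalancing splits the sample in half", {
  dir <- withr::local_tempdir()
  cfg <- protocol_config(n_participants = 6, trace_policy = "none")
  log <- run_protocol_simulation(cfg, dir, seed = 73)
  meta <- yaml::read_yaml(file.path(dir, "study.yaml"))
  expect_equal(sum(unlist(meta$ibl_active_first)), 3)
  expect_equal(sum(unlist(meta$day2_active)), 3)
  first_ibl <- do.call(rbind, lapply(split(log[log$phase == "iBL", ],
                                           log$participant[log$phase == "iBL"]),
                                     function(d) d[1, ]))
  expect_equal(sum(first_ibl$condition == "active"), 3)
})

test_that("chance-level cohorts analyze to the guessing score", {
  dir <- withr::local_tempdir()
  cfg <- protocol_config(n_participants = 2, beta_range = c(0, 0),
                         trace_policy = "none")
  run_protocol_simulation(cfg, dir, seed = 74)
  an <- analyze_study(dir)
  # 12 assessment phases x 40 trials at p = 1/3
  se <- sqrt((1 / 3) * (2 / 3) / 480)
  expect_lt(abs(mean(an$scores$score) - 1 / 3), 4 * se)
})

test_that("training gain raises retention above baseline on average", {
  dir <- withr::local_tempdir()
  cfg <- protocol_config(n_participants = 4, beta_range = c(6, 10),
                         training_gain = 3, trace_policy = "none")
  run_protocol_simulation(cfg, dir, seed = 75)
  an <- analyze_study(dir)
  bl <- an$scores$score[an$scores$phase == "BL"]
  rt <- an$scores$score[an$scores$phase == "RT"]
  expect_gt(mean(rt), mean(bl))
})

test_that("analysis computes kinematics from stored traces", {
  dir <- withr::local_tempdir()
  cfg <- protocol_config(n_participants = 2, trace_policy = "first",
                         sweeps = 1)
  run_protocol_simulation(cfg, dir, seed = 76)
  an <- analyze_study(dir)
  expect_false(is.null(an$kinematics))
  expect_equal(nrow(an$kinematics), 2 * 6)  # 6 assessment phases each
  expect_true(all(an$kinematics$path_length > 0))
  expect_true(all(an$kinematics$mean_scanning_speed > 0.05))
})
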