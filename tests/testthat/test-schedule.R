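test_that("default schedule has the full factorial trial counts", {
  sched <- build_trial_schedule(stimulus_set_config(), seed = 1)
  expect_equal(nrow(sched), 183L)
  expect_equal(sum(sched$is_target), 15L)
  per_seq <- table(paste(sched$stimulus_type, sched$first_direction,
                         sched$second_direction)[!sched$is_target])
  expect_equal(unname(per_seq), rep(42L, 4L), ignore_attr = TRUE)
  expect_false(any(duplicated(sched$trial_id)))
  # non-target rows have differing directions; targets have none
  nt <- sched[!sched$is_target, ]
  expect_true(all(nt$first_direction != nt$second_direction))
  expect_true(all(sched$first_direction[sched$is_target] == "none"))
})

test_that("per-sequence count is n_models x n_repetitions for any config", {
  for (reps in c(1L, 2L)) {
    cfg <- stimulus_set_config(n_models_female = 2L, n_models_male = 1L,
                               n_repetitions = reps, n_target_trials = 3L)
    sched <- build_trial_schedule(cfg, seed = reps)
    per_seq <- table(paste(sched$stimulus_type, sched$first_direction)[!sched$is_target])
    expect_equal(unname(c(per_seq)), rep(3L * reps, 4L), ignore_attr = TRUE)
  }
})

test_that("degenerate configurations produce the forced schedules", {
  empty <- build_trial_schedule(
    stimulus_set_config(n_repetitions = 0L, n_target_trials = 0L), seed = 1)
  expect_equal(nrow(empty), 0L)
  four <- build_trial_schedule(tiny_design_cfg(), seed = 2)
  expect_equal(nrow(four), 4L)
  expect_equal(sort(paste(four$stimulus_type, four$first_direction)),
               sort(c("eyes averted", "eyes straight",
                      "mosaic averted", "mosaic straight")))
  expect_error(stimulus_set_config(n_repetitions = -1), "non-negative")
})

test_that("seeds control the shuffle reproducibly", {
  a <- build_trial_schedule(stimulus_set_config(), seed = 7)
  b <- build_trial_schedule(stimulus_set_config(), seed = 7)
  c <- build_trial_schedule(stimulus_set_config(), seed = 8)
  expect_identical(a, b)
  key <- function(s) sort(paste(s$stimulus_type, s$first_direction, s$model_id))
  expect_identical(key(a), key(c))              # same multiset of trials
  expect_false(identical(paste(a$stimulus_type, a$model_id),
                         paste(c$stimulus_type, c$model_id)))
  # onsets increase and respect timing + ITI bounds
  gaps <- diff(a$onset_ms)
  expect_true(all(gaps >= 500 + 1500 + 2000 & gaps <= 500 + 1500 + 5000))
})

test_that("events tables round-trip through TSV losslessly", {
  sched <- build_trial_schedule(stimulus_set_config(), seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events(sched, path)
  back <- read_events(path)
  expect_equal(as.data.frame(back), as.data.frame(sched))
  # target rows serialize directions as "none"
  raw <- read.delim(path)
  expect_true(all(raw$first_direction[raw$is_target] == "none"))
  # empty table: header-only file reads back empty
  empty <- build_trial_schedule(
    stimulus_set_config(n_repetitions = 0L, n_target_trials = 0L), seed = 1)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_events(empty, p2)
  expect_equal(nrow(read_events(p2)), 0L)
  # malformed file is reported
  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("onset\tfoo", "1\t2"), p3)
  expect_error(read_events(p3), "lacks columns")
})
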