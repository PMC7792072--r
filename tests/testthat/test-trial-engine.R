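test_that("a single-stage two-arm trial has everyone in the concurrent set", {
  d <- mini_design()
  run <- run_trial(d, seed = 1)
  expect_setequal(run$concurrent$EXP_vs_CTL, run$patients$id)
  expect_equal(length(run$shared_control_ids), 0)
})

test_that("every patient sits in exactly one arm and one stage, within the active set", {
  d <- flair_design()
  run <- run_trial(d, seed = 2)
  pat <- run$patients
  expect_false(anyNA(pat$arm))
  expect_false(anyNA(pat$stage))
  for (s in unique(pat$stage)) {
    active <- d$stages$active_arms[[s]]
    expect_true(all(pat$arm[pat$stage == s] %in% active))
    # even allocation: per-stage arm totals close to equal
    tab <- table(pat$arm[pat$stage == s])
    expect_lt(max(tab) - min(tab), 12)
  }
})

test_that("stage triggers fire at their recruitment counts and IR leaves stage 3", {
  d <- flair_design()
  run <- run_trial(d, seed = 3)
  pat <- run$patients
  # IR recruitment stops exactly at its 377-patient target
  expect_equal(sum(pat$arm == "IR"), 377)
  expect_false(any(pat$arm == "IR" & pat$stage == 3))
  # stage 2 opened when IR hit 316
  expect_equal(sum(pat$arm == "IR" & pat$stage == 1), 316)
  # recruitment stopped once 274 FCR patients were concurrent with I+V
  expect_equal(sum(pat$arm == "FCR" & pat$stage >= 2), 274)
})

test_that("concurrent sets contain exactly the contemporaneous comparator patients", {
  d <- flair_design()
  run <- run_trial(d, seed = 4)
  pat <- run$patients
  ir <- run$concurrent$IR_vs_FCR_pfs
  iv <- run$concurrent$IV_vs_FCR_pfs
  # stage-1 patients can only appear in the IR comparison
  s1 <- pat$id[pat$stage == 1]
  expect_true(all(setdiff(s1, ir) %in% integer(0)) ||
              all(!s1 %in% iv))
  expect_false(any(s1 %in% iv))
  # stage-3 patients never appear in the IR comparison
  s3 <- pat$id[pat$stage == 3]
  expect_false(any(s3 %in% ir))
  # members are always on one of the two comparison arms
  expect_true(all(pat$arm[pat$id %in% iv] %in% c("I+V", "FCR")))
  # shared controls are exactly the stage-2 control patients in both sets
  expect_setequal(run$shared_control_ids, intersect(ir, iv))
  expect_true(all(pat$arm[pat$id %in% run$shared_control_ids] == "FCR"))
  expect_true(all(pat$stage[pat$id %in% run$shared_control_ids] == 2))
})

test_that("the shared stage-2 control count averages near its design value of 61", {
  d <- flair_design()
  shared <- vapply(1:30, function(s)
    length(run_trial(d, seed = 1000 + s)$shared_control_ids), numeric(1))
  expect_gt(mean(shared), 61 - 8)
  expect_lt(mean(shared), 61 + 8)
})

test_that("replaying a seed reproduces the identical trial", {
  d <- flair_design()
  r1 <- run_trial(d, seed = 99)
  r2 <- run_trial(d, seed = 99)
  expect_identical(r1$patients, r2$patients)
  expect_identical(r1$concurrent, r2$concurrent)
})

test_that("a stop rule that cannot fire raises an error naming the stage", {
  d <- mini_design()
  d$stop_rule <- trigger("arm_recruitment", arm = "CTL", n = 10000)
  expect_error(run_trial(d, seed = 5, n_max = 500), "stage 1")
})

test_that("admin censoring caps observed time at the horizon", {
  d <- mini_design()
  run <- run_trial(d, seed = 6)
  pat <- run$patients
  expect_true(all(pat$observed_time <= run$horizon - pat$entry_time + 1e-12))
  expect_true(all(pat$observed_time >= 0))
  expect_true(all(pat$event_flag == (pat$pfs_time <=
    pmin(pat$dropout_time, run$horizon - pat$entry_time))))
})

test_that("event-count cutoffs deliver exactly the requested number of events", {
  d <- flair_design()
  run <- run_trial(d, seed = 7)
  ds <- analysis_dataset(run, "IV_vs_FCR_pfs", cutoff_events = 116)
  expect_equal(sum(ds$event), 116)
  ds2 <- analysis_dataset(run, "IV_vs_FCR_pfs", cutoff_events = 232)
  expect_equal(sum(ds2$event), 232)
  # default cutoff comes from the hypothesis's planned events
  ds3 <- analysis_dataset(run, "IV_vs_FCR_pfs")
  expect_equal(sum(ds3$event), 232)
  # non-concurrent IR patients never appear in the I+V comparison
  ir_ids <- run$patients$id[run$patients$arm == "IR"]
  expect_false(any(ds2$id %in% ir_ids))
})

test_that("degenerate cutoffs warn and produce empty tables", {
  d <- mini_design()
  run <- run_trial(d, seed = 8)
  expect_warning(ds <- analysis_dataset(run, "EXP_vs_CTL", cutoff_events = 0),
                 "empty")
  expect_equal(nrow(ds), 0)
  expect_warning(analysis_dataset(run, "EXP_vs_CTL", cutoff_years = 0),
                 "empty")
  expect_error(analysis_dataset(run, "nope"), "unknown hypothesis")
  expect_error(analysis_dataset(run, "EXP_vs_CTL", cutoff_events = 1,
                                cutoff_years = 1), "only one")
})

test_that("requesting more events than will ever occur warns and uses them all", {
  d <- mini_design(stop_n = 30, target_events = 40)
  run <- run_trial(d, seed = 9)
  expect_warning(ds <- analysis_dataset(run, "EXP_vs_CTL", cutoff_events = 1e5),
                 "ever occur")
  expect_gt(sum(ds$event), 0)
})
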