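test_that("config validation enforces parameter ranges", {
  expect_error(rgife_config(initial_block_ratio = 0), "block_ratio")
  expect_error(rgife_config(initial_block_ratio = 1.2), "block_ratio")
  expect_error(rgife_config(ratio_divisor = 1), "ratio_divisor")
  expect_error(rgife_config(max_consecutive_fails = 0), "consecutive")
  expect_error(rgife_config(soft_fail_tolerance = -1), "tolerance")
  expect_error(rgife_config(n_runs = 0), "n_runs")
  cfg <- rgife_config()
  expect_equal(cfg$k, 10)
  expect_equal(cfg$N, 10)
  expect_equal(cfg$initial_block_ratio, 0.25)
  expect_equal(cfg$ratio_divisor, 4)
  expect_equal(cfg$max_consecutive_fails, 5)
  expect_equal(cfg$soft_fail_tolerance, 1)
  expect_equal(cfg$n_runs, 3)
})

test_that("select_block walks the rank from the bottom upward", {
  r <- ranked_importance(setNames(8:1, paste0("f", 1:8)))  # f1 best..f8 worst
  expect_setequal(select_block(r, 0, 2), c("f7", "f8"))
  expect_setequal(select_block(r, 2, 2), c("f5", "f6"))
  expect_setequal(select_block(r, 6, 2), c("f1", "f2"))
  expect_error(select_block(r, 7, 2), "exceeds")
  expect_error(select_block(r, -1, 2), "starting_index")
  expect_error(select_block(r, 0, 0), "block_size")
})

test_that("soft-fail search applies the one-sample tolerance and tie rule", {
  m <- 50
  rec <- function(i, status, perf, ref, removed = paste0("f", i)) {
    list(index = i, status = status, removed_features = removed,
         performance = perf, reference_performance = ref,
         block_ratio = 0.25, block_size = 1, starting_index = 0,
         surviving_count = 10, cv_seed = i, importances = NULL)
  }
  ref <- 0.9
  # drop of exactly 1/m qualifies; drop of 2/m does not
  traj <- list(rec(1, "fail", ref - 1 / m, ref),
               rec(2, "fail", ref - 2 / m, ref))
  hit <- find_soft_fail(traj, anchor = 0, tolerance = 1, m = m)
  expect_equal(hit$index, 1)
  expect_null(find_soft_fail(list(traj[[2]]), 0, tolerance = 1, m = m))

  # among qualifiers: highest performance wins, ties to the most recent
  traj2 <- list(rec(1, "fail", ref - 1 / m, ref),
                rec(2, "fail", ref - 0.5 / m, ref),
                rec(3, "fail", ref - 0.5 / m, ref),
                rec(4, "fail", ref - 2 / m, ref))
  hit2 <- find_soft_fail(traj2, 0, 1, m)
  expect_equal(hit2$index, 3)

  # records at or before the anchor are outside the window
  expect_null(find_soft_fail(traj2[1:2], anchor = 2, tolerance = 1, m = m))
  # successes never qualify
  traj3 <- list(rec(1, "success_bottom", ref, ref))
  expect_null(find_soft_fail(traj3, 0, 1, m))
  expect_null(find_soft_fail(list(), 0, 1, m))
})

test_that("a single-feature dataset returns immediately", {
  set.seed(5)
  d <- rgife_dataset(data.frame(only = c(rnorm(10), rnorm(10) + 3)),
                     rep(0:1, each = 10))
  run <- run_rgife(d, rgife_config(k = 3, N = 1, learner = small_forest(20)))
  expect_equal(run$final_signature, "only")
  expect_length(run$trajectory, 0)
})

test_that("the informative feature is recovered across seeds", {
  cfg <- rgife_config(k = 5, N = 1, learner = small_forest(), seed = 1)
  hits <- 0
  for (s in 1:10) {
    d <- make_single_feature_dataset(m = 50, p = 20, seed = 300 + s)
    run <- run_rgife(d, cfg, seed = s)
    if ("key" %in% run$final_signature &&
        run$final_performance == 1.0) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("trajectories are internally consistent and runs deterministic", {
  d <- make_fuzz_dataset(7)
  cfg <- rgife_config(k = 3, N = 1, learner = small_forest(30), seed = 2)
  run1 <- run_rgife(d, cfg)
  run2 <- run_rgife(d, cfg)
  expect_identical(run1$final_signature, run2$final_signature)
  expect_identical(trajectory_table(run1), trajectory_table(run2))

  m <- n_samples(d)
  for (rec in run1$trajectory) {
    if (rec$status %in% c("success_bottom", "success_offset")) {
      expect_gte(rec$performance, rec$reference_performance)
      if (rec$status == "success_bottom") {
        expect_equal(rec$starting_index, 0)
      } else {
        expect_gt(rec$starting_index, 0)
      }
    } else if (rec$status == "fail") {
      expect_lt(rec$performance, rec$reference_performance)
    } else if (rec$status == "soft_fail_accept") {
      drop <- rec$reference_performance - rec$performance
      expect_gt(drop, 0)
      expect_lte(drop, cfg$soft_fail_tolerance / m + 1e-9)
    }
  }
})

test_that("recorded performances replay exactly from their seeds", {
  d <- make_fuzz_dataset(11)
  cfg <- rgife_config(k = 3, N = 1, learner = small_forest(30), seed = 6)
  run <- run_rgife(d, cfg)
  n_rec <- length(run$trajectory)
  expect_gt(n_rec, 0)
  at <- unique(c(1, ceiling(n_rec / 2), n_rec))
  res <- replay_records(run, d, cfg, at)
  for (pair in res) {
    expect_equal(pair[["replayed"]], pair[["recorded"]])
  }
})

test_that("policies combine runs as min / max / union", {
  mk <- function(sig) structure(list(final_signature = sig),
                                class = "rgife_run")
  runs <- list(mk(c("a", "b", "c")),
               mk(letters[1:7]),
               mk(c("x", "y", "z", "w", "v")))
  expect_equal(apply_policy(runs, "min"), c("a", "b", "c"))
  expect_equal(apply_policy(runs, "max"), letters[1:7])
  runs2 <- list(mk(c("A", "B")), mk(c("B", "C")), mk(c("C", "D")))
  expect_setequal(apply_policy(runs2, "union"), c("A", "B", "C", "D"))
  one <- list(mk(c("q", "r")))
  for (p in c("min", "max", "union")) {
    expect_setequal(apply_policy(one, p), c("q", "r"))
  }
  expect_error(apply_policy(list(), "min"), "at least one")
})

test_that("rgife_select runs n_runs seeded runs and applies the policy", {
  d <- make_single_feature_dataset(m = 40, p = 12, seed = 17)
  cfg <- rgife_config(k = 3, N = 1, n_runs = 2, learner = small_forest(30),
                      seed = 9)
  res <- rgife_select(d, cfg, policy = "union")
  expect_length(res$runs, 2)
  expect_setequal(res$signature,
                  Reduce(union, lapply(res$runs, `[[`, "final_signature")))
  res2 <- rgife_select(d, cfg, policy = "union")
  expect_identical(res$signature, res2$signature)
})

test_that("trajectory_table flattens records for plotting", {
  d <- make_fuzz_dataset(4)
  cfg <- rgife_config(k = 3, N = 1, learner = small_forest(30), seed = 3)
  run <- run_rgife(d, cfg)
  tab <- trajectory_table(run)
  expect_true(all(c("run", "index", "status", "block_size", "starting_index",
                    "performance", "reference", "removed") %in% names(tab)))
  expect_equal(nrow(tab), length(run$trajectory))
  expect_true(all(tab$status %in% c("success_bottom", "success_offset",
                                    "fail", "soft_fail_accept")))
})
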