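# Monte Carlo harness and performance measures.

toy_raw <- function() {
  est <- c(0.08, 0.10, 0.12, 0.14)
  data.frame(sim = 1:4, method = "toy", status = "ok", estimate = est,
             se = 0.02, ci_low = est - 1.96 * 0.02,
             ci_high = est + 1.96 * 0.02, stringsAsFactors = FALSE)
}

test_that("performance reproduces a hand-computed toy table", {
  perf <- performance(toy_raw(), psi = 0.10)
  expect_equal(perf$bias, 0.01)
  expect_equal(perf$empirical_se, sqrt(sum((c(0.08, 0.10, 0.12, 0.14) - 0.11)^2) / 3))
  expect_equal(perf$empirical_se, 0.02582, tolerance = 1e-4)
  expect_equal(perf$coverage, 0.75)  # 0.14's interval misses 0.10
  expect_equal(perf$bias_eliminated_coverage, 1)  # all contain the mean 0.11
  expect_equal(perf$avg_model_se, 0.02)      # all SEs equal
  expect_equal(perf$avg_model_se_mean, 0.02)
  expect_equal(perf$mse, mean((c(0.08, 0.10, 0.12, 0.14) - 0.10)^2))
  expect_equal(perf$relative_se_error_pct,
               100 * (0.02 / perf$empirical_se - 1))
  expect_equal(perf$mcse_coverage, sqrt(0.75 * 0.25 / 4))
  expect_equal(perf$n_used, 4)
})

test_that("matched model and empirical SEs give zero relative error", {
  raw <- toy_raw()
  raw$se <- sd(raw$estimate)
  perf <- performance(raw, psi = 0.10)
  expect_equal(perf$relative_se_error_pct, 0)
})

test_that("degenerate constant estimates flag relative error as undefined", {
  raw <- toy_raw()
  raw$estimate <- 0.1
  raw$ci_low <- 0.1 - 0.0392; raw$ci_high <- 0.1 + 0.0392
  perf <- performance(raw, psi = 0.10)
  expect_true(is.na(perf$relative_se_error_pct))
  expect_equal(perf$bias, 0)
  expect_equal(perf$coverage, 1)
  expect_equal(perf$mse, 0)
})

test_that("performance is invariant to row order and excludes flagged rows", {
  raw <- toy_raw()
  flagged <- raw[1, ]
  flagged$sim <- 5; flagged$status <- "failed"; flagged$estimate <- NA
  raw2 <- rbind(raw[c(3, 1, 4, 2), ], flagged)
  perf <- performance(raw2, psi = 0.10)
  base <- performance(toy_raw(), psi = 0.10)
  expect_equal(perf$bias, base$bias)
  expect_equal(perf$coverage, base$coverage)
  expect_equal(perf$n_flagged, 1)
  expect_error(performance(raw[1, ], psi = 0.1), "at least 2")
})

test_that("zip data ranks intervals by |z| and marks coverage", {
  zd <- zip_data(toy_raw(), psi = 0.10)
  expect_equal(nrow(zd), 4)
  expect_true(!is.unsorted(abs(zd$z)))
  expect_equal(zd$rank_pct, (1:4) / 4)
  expect_equal(sum(zd$covers), 3)
})

test_that("scenario configs validate and round-trip through YAML", {
  expect_error(scenario_config(n_sims = 0), "n_sims")
  expect_error(scenario_config(p = 2), ">= 3")
  expect_error(scenario_config(estimators = "aipw"), "unknown estimator")
  expect_error(scenario_config(generalization = 3), "1 or 2")

  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n: 200", "p: [3, 5]", "generalization: 1", "r: 2",
               "n_sims: 2", "seed: 7",
               "learners: [logit_main_effects]", "estimators: [dcf]"),
             path)
  cfg <- read_scenario(path)
  expect_s3_class(cfg, "scenario_config")
  expect_equal(cfg$p, c(3L, 5L))
  writeLines("bogus_key: 1", path)
  expect_error(read_scenario(path), "unknown scenario key")
})

test_that("run_scenario is reproducible, complete and resumable", {
  cfg <- scenario_config(n = 240, p = 3, r = 2, n_sims = 2, seed = 17,
                         learners = FAST, estimators = c("dcf", "tmle"))
  raw <- run_scenario(cfg)
  expect_equal(nrow(raw), 4)  # 2 datasets x (dcf p=3, tmle)
  expect_setequal(unique(raw$method), c("dcf_g1_p3", "tmle"))
  expect_true(all(raw$status == "ok"))
  expect_identical(run_scenario(cfg)$estimate, raw$estimate)

  # resuming from a partial output file reproduces the full run
  out <- withr::local_tempfile(fileext = ".csv")
  cfg1 <- scenario_config(n = 240, p = 3, r = 2, n_sims = 1, seed = 17,
                          learners = FAST, estimators = c("dcf", "tmle"))
  run_scenario(cfg1, output = out)
  resumed <- run_scenario(cfg, output = out)
  expect_equal(resumed$estimate, raw$estimate, tolerance = 1e-12)
  expect_equal(nrow(utils::read.csv(out)), 4)
})

test_that("nested seeding: smaller r replays a prefix of the larger run's repetitions", {
  cfg_small <- scenario_config(n = 200, p = 3, r = 2, n_sims = 1, seed = 23,
                               learners = FAST, estimators = "dcf")
  d <- generate_dataset(200, dcftmle:::child_seed(23, 1, 1))
  est_seed <- dcftmle:::child_seed(23, 1, 2)
  f2 <- dcf_tmle(d, p = 3, r = 2, learners = FAST, seed = est_seed)
  f5 <- dcf_tmle(d, p = 3, r = 5, learners = FAST, seed = est_seed)
  expect_identical(f2$reps$ate_r, f5$reps$ate_r[1:2])
  raw <- run_scenario(cfg_small)
  expect_equal(raw$estimate, f2$ate, tolerance = 1e-12)
})
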