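# Split planning, role assignment, the repetition loop and aggregation.

test_that("splits are near-equal non-overlapping random partitions", {
  expect_equal(sort(tabulate(make_splits(10, 3, seed = 1)), decreasing = TRUE),
               c(4, 3, 3))
  expect_equal(unname(tabulate(make_splits(3000, 5, seed = 2))), rep(600, 5))
  sizes <- sort(tabulate(make_splits(2418, 15, seed = 3)), decreasing = TRUE)
  expect_equal(sizes, c(rep(162, 3), rep(161, 12)))

  expect_identical(make_splits(100, 4, seed = 9), make_splits(100, 4, seed = 9))
  expect_error(make_splits(5, 6, seed = 1), "p > n")
  expect_error(make_splits(100, 2, seed = 1), "p >= 3")
})

test_that("role triples are pairwise disjoint, with every split in every role once", {
  for (p in 3:10) {
    roles <- roles_gen1(p)
    for (tri in roles) {
      expect_length(tri$P, 1); expect_length(tri$Q, 1)
      expect_equal(length(unique(c(tri$est, tri$P, tri$Q))), 3)
    }
    expect_setequal(vapply(roles, `[[`, integer(1), "est"), seq_len(p))
    expect_setequal(vapply(roles, `[[`, integer(1), "P"), seq_len(p))
    expect_setequal(vapply(roles, `[[`, integer(1), "Q"), seq_len(p))
  }
  for (p in c(3, 5, 7, 9)) {
    roles <- roles_gen2(p)
    for (tri in roles) {
      expect_length(tri$P, (p - 1) / 2)
      expect_length(tri$Q, (p - 1) / 2)
      expect_length(intersect(tri$P, tri$Q), 0)
      expect_false(tri$est %in% c(tri$P, tri$Q))
      expect_setequal(c(tri$est, tri$P, tri$Q), seq_len(p))  # full data use
    }
  }
})

test_that("role orientation follows the documented three-split rotation", {
  r3 <- roles_gen1(3)
  # estimation in split 3 uses the propensity model from split 1 and the
  # outcome model from split 2
  expect_equal(r3[[3]], list(est = 3L, P = 1L, Q = 2L))
  expect_equal(r3[[1]], list(est = 1L, P = 2L, Q = 3L))
  # with p = 10, each triple leaves 7 splits unused
  for (tri in roles_gen1(10))
    expect_length(setdiff(1:10, c(tri$est, tri$P, tri$Q)), 7)
})

test_that("generalization 2 alternates the remaining splits as documented", {
  r5 <- roles_gen2(5)
  expect_equal(r5[[1]]$P, c(2L, 4L))
  expect_equal(r5[[1]]$Q, c(3L, 5L))
  for (tri in roles_gen2(9)) {
    expect_length(tri$P, 4)
    expect_length(tri$Q, 4)
  }
  # at p = 3 the two generalizations define identical role triples
  expect_equal(roles_gen2(3), roles_gen1(3))
  expect_error(roles_gen2(4), "odd")
})

test_that("a repetition averages its split estimates and records failures", {
  d <- generate_simple_dataset(300, seed = 12, effect = 0.1)
  rep1 <- run_repetition(d, p = 3, covariates = "W", learners = FAST,
                         seed = 5)
  expect_equal(rep1$status, "success")
  expect_equal(rep1$ate_r, mean(rep1$splits$ate_p), tolerance = 1e-15)
  # variance of the mean of split estimates: split IC variances referred
  # to the full sample size, then averaged
  expect_equal(rep1$var_r,
               sum(rep1$splits$var_p * rep1$splits$n_p) / (300 * 3),
               tolerance = 1e-15)
  expect_equal(sum(rep1$splits$n_p), 300)

  # generalization 2 training pools use all records outside the split
  rep2 <- run_repetition(d, p = 5, generalization = 2, covariates = "W",
                         learners = FAST, seed = 5)
  expect_equal(rep2$status, "success")

  # an almost-constant outcome starves some training pool of events
  d_bad <- d
  d_bad$Y <- c(1L, rep(0L, 299))
  rep_bad <- run_repetition(d_bad, p = 3, covariates = "W", learners = FAST,
                            seed = 5)
  expect_equal(rep_bad$status, "failed")
  expect_true(is.na(rep_bad$ate_r))
  expect_match(rep_bad$reason, "constant")
})

test_that("generalizations coincide exactly at p = 3 under a shared seed", {
  d <- generate_simple_dataset(400, seed = 21, effect = 0.1)
  r1 <- run_repetition(d, p = 3, generalization = 1, covariates = "W",
                       learners = FAST, seed = 99)
  r2 <- run_repetition(d, p = 3, generalization = 2, covariates = "W",
                       learners = FAST, seed = 99)
  expect_identical(r1$ate_r, r2$ate_r)
  expect_identical(r1$var_r, r2$var_r)
})

test_that("aggregation follows the median-of-within-plus-between formula", {
  reps <- data.frame(ate_r = c(0.10, 0.12, 0.20),
                     var_r = c(0.01, 0.01, 0.01),
                     status = "success")
  agg <- aggregate_repetitions(reps)
  expect_equal(agg$ate, 0.12)
  expect_equal(agg$var, 0.0104)
  expect_equal(agg$se, sqrt(0.0104))
  expect_equal(agg$ci95, 0.12 + c(-1.96, 1.96) * sqrt(0.0104))

  # a single success collapses both medians
  one <- aggregate_repetitions(data.frame(ate_r = 0.1, var_r = 0.004,
                                          status = "success"))
  expect_equal(one$ate, 0.1)
  expect_equal(one$var, 0.004)

  # failed repetitions change nothing but the counts
  with_fail <- rbind(reps, data.frame(ate_r = NA, var_r = NA,
                                      status = "failed"))
  agg_f <- aggregate_repetitions(with_fail)
  expect_equal(agg_f$ate, agg$ate)
  expect_equal(agg_f$var, agg$var)
  expect_equal(agg_f$n_failed, 1)

  # permutation invariance and the even-count median convention
  perm <- reps[c(3, 1, 2), ]
  expect_equal(aggregate_repetitions(perm)$var, agg$var)
  four <- data.frame(ate_r = c(0.1, 0.2, 0.3, 0.4), var_r = 0,
                     status = "success")
  expect_equal(aggregate_repetitions(four)$ate, 0.25)

  expect_error(aggregate_repetitions(data.frame(ate_r = NA, var_r = NA,
                                                status = "failed")),
               class = "dcftmle_all_failed")
})

test_that("dcf_tmle repetition seeds are prefix-consistent in r", {
  d <- generate_simple_dataset(200, seed = 31, effect = 0.1)
  short <- dcf_tmle(d, covariates = "W", p = 3, r = 2, learners = FAST,
                    seed = 50)
  long <- dcf_tmle(d, covariates = "W", p = 3, r = 4, learners = FAST,
                   seed = 50)
  expect_identical(short$reps$ate_r, long$reps$ate_r[1:2])
  expect_identical(short$reps$seed, long$reps$seed[1:2])
  expect_equal(short$n_success + short$n_failed, 2)
})

test_that("an entirely degenerate outcome fails every repetition", {
  d <- generate_simple_dataset(150, seed = 41, effect = 0.1)
  d$Y <- 0L
  expect_error(dcf_tmle(d, covariates = "W", p = 3, r = 2, learners = FAST,
                        seed = 1),
               class = "dcftmle_all_failed")
  # retry mode draws fresh child seeds for failed repetitions
  expect_error(dcf_tmle(d, covariates = "W", p = 3, r = 1, learners = FAST,
                        seed = 1, retry_failed = TRUE, max_retries = 2),
               class = "dcftmle_all_failed")
})

test_that("even p under generalization 2 needs the explicit pooling flag", {
  d <- generate_simple_dataset(240, seed = 51, effect = 0.1)
  expect_error(dcf_tmle(d, covariates = "W", p = 4, r = 1,
                        generalization = 2, learners = FAST, seed = 1),
               "odd")
  fit <- dcf_tmle(d, covariates = "W", p = 4, r = 2, generalization = 2,
                  learners = FAST, seed = 1, allow_even_p = TRUE)
  expect_equal(fit$n_success + fit$n_failed, 2)
  expect_true(is.finite(fit$ate))
})

test_that("result object methods are coherent", {
  d <- generate_simple_dataset(300, seed = 61, effect = 0.1)
  fit <- dcf_tmle(d, covariates = "W", p = 3, r = 3, learners = FAST,
                  seed = 8)
  expect_s3_class(fit, "dcf_tmle")
  expect_equal(unname(coef(fit)), fit$ate)
  ci <- confint(fit)
  expect_equal(unname(ci[1, ]), fit$ci95, tolerance = 1e-3)
  expect_output(print(fit), "Double cross-fitted TMLE")
  expect_output(print(summary(fit)), "quartiles")
})
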