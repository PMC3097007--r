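# Monte-Carlo harness: robustness bands, summary metrics, scenario
# enumeration, determinism and stub-based definitions.

test_that("robustness bands are nested around 5% and 95%", {
  expect_equal(classify_robustness(5.2, 5), "10%-robust")
  expect_equal(classify_robustness(5.8, 5), "20%-robust")
  expect_equal(classify_robustness(6.3, 5), "nonrobust")
  expect_equal(classify_robustness(c(4.5, 4.0, 3.99), 5),
               c("10%-robust", "20%-robust", "nonrobust"))
  expect_equal(classify_robustness(94.2, 95), "20%-robust")
  expect_equal(classify_robustness(c(94.5, 95.5, 96.0, 96.01), 95),
               c("10%-robust", "10%-robust", "20%-robust", "nonrobust"))
  expect_error(classify_robustness(5, 0), "between 0 and 100")
  expect_error(classify_robustness(5, 100), "between 0 and 100")
})

test_that("stub tests pin down the rejection-rate definition", {
  u <- make_distribution("uniform", 2)
  always <- run_test_scenario(u, u, 5, 5, function(x, y) 0,
                              replications = 200, seed = 1)
  expect_equal(always$rejection_pct, 100)
  expect_equal(always$mc_se_pct, 0)
  expect_true(always$is_null)

  never <- run_test_scenario(u, u, 5, 5, function(x, y) 1,
                             replications = 200, seed = 1)
  expect_equal(never$rejection_pct, 0)

  # p ~ uniform(0, 1): level equals alpha within 3 MC standard errors
  unif <- run_test_scenario(u, u, 5, 5, function(x, y) runif(1),
                            replications = 10000, seed = 2)
  expect_lt(abs(unif$rejection_pct - 5), 3 * 100 * sqrt(0.05 * 0.95 / 1e4))
  # binomial MC standard error on the proportion scale
  p <- unif$rejection_pct / 100
  expect_equal(unif$mc_se_pct, 100 * sqrt(p * (1 - p) / 1e4))
})

test_that("stub intervals pin down coverage and overshoot definitions", {
  u <- make_distribution("uniform", 2)
  full <- run_ci_scenario(u, u, 5, 5, function(x, y) c(-2, 2),
                          replications = 100, seed = 3)
  expect_equal(full$coverage_pct, 100)
  expect_equal(full$overshoot_pct, 0)
  expect_equal(full$mean_length, 4)

  beyond <- run_ci_scenario(u, u, 5, 5, function(x, y) c(-3, 3),
                            replications = 50, seed = 3)
  expect_equal(beyond$overshoot_pct, 100)

  # zero-width interval at the estimate covers only when the sample
  # difference hits the true difference exactly
  skew1 <- make_distribution("skewed", 3, mean = 0.6)
  pt <- run_ci_scenario(skew1, skew1, 4, 4,
                        function(x, y) rep(mean(x) - mean(y), 2),
                        replications = 2000, seed = 4)
  expect_lt(pt$coverage_pct, 50)
  expect_gt(pt$coverage_pct, 0)
})

test_that("null labelling, pair counts and summary metrics match the
           study design", {
  for (K in c(2, 3)) {
    dists <- reference_distributions(K)
    mu <- sapply(dists, function(d) dist_moments(d)[["mean"]])
    # unordered pairs with self-pairs: 21, of which 9 null
    pairs <- which(outer(mu, mu, function(a, b) abs(a - b) <= 1e-9),
                   arr.ind = TRUE)
    expect_equal(sum(pairs[, 1] <= pairs[, 2]), 9)
    expect_equal(choose(6, 2) + 6, 21)
    # ordered pairs: 36, of which 12 null
    expect_equal(nrow(pairs), 12)
  }

  fake <- tibble::tibble(
    method = rep(c("t", "welch"), each = 2),
    rejection_pct = c(4.5, 5.5, 5.0, 5.0),
    is_null = TRUE
  )
  md <- mean_deviation_summary(fake)
  expect_equal(md$mean_deviation[md$method == "t"], 0.5)
  expect_equal(md$mean_deviation[md$method == "welch"], 0)
  expect_error(mean_deviation_summary(fake[0, ]), "no scenario rows")
  expect_error(
    mean_deviation_summary(dplyr::mutate(fake, is_null = FALSE)),
    "null"
  )

  pw <- tibble::tibble(
    method = rep(c("t", "welch"), each = 2),
    rejection_pct = c(6, 4, 5, 3),
    is_null = FALSE
  )
  rp <- relative_power_summary(pw)
  expect_equal(rp$relative_power_pct[rp$method == "t"], 100)
  expect_equal(rp$relative_power_pct[rp$method == "welch"], 80)
  expect_error(relative_power_summary(dplyr::mutate(pw, is_null = TRUE)),
               "unequal-means")
})

test_that("study runners enumerate 21 unordered / 36 ordered scenarios
           and are deterministic under a fixed seed", {
  res_eq <- run_test_study(3, sample_sizes = list(c(4, 4)),
                           tests = "welch", replications = 20, seed = 9)
  expect_equal(nrow(res_eq), 21)
  expect_equal(sum(res_eq$is_null), 9)

  res_ne <- run_test_study(3, sample_sizes = list(c(5, 4)),
                           tests = "welch", replications = 20, seed = 9)
  expect_equal(nrow(res_ne), 36)
  expect_equal(sum(res_ne$is_null), 12)

  rerun <- run_test_study(3, sample_sizes = list(c(4, 4)),
                          tests = "welch", replications = 20, seed = 9)
  expect_identical(res_eq, rerun)

  # scenario substreams are order-independent: a single scenario run
  # standalone matches its row inside the study
  d <- reference_distributions(3)
  solo <- run_test_scenario(
    d[["uniform"]], d[["step"]], 4, 4, "welch", 20,
    seed = countcompare:::.derive_seed(9, "test", 3, "uniform", "step",
                                       4, 4, "welch"))
  inrow <- dplyr::filter(res_eq, dist1 == "uniform", dist2 == "step")
  expect_equal(solo$rejection_pct, inrow$rejection_pct)
})

test_that("CI study rows carry coverage, length, overshoot and class", {
  res <- run_ci_study(2, sample_sizes = list(c(6, 6)),
                      methods = c("welch", "pb"), replications = 30,
                      n_resamples = 50, seed = 5)
  expect_equal(nrow(res), 21 * 2)
  expect_true(all(res$mean_length >= 0))
  expect_true(all(res$coverage_pct >= 0 & res$coverage_pct <= 100))
  expect_true(all(res$robustness %in%
                    c("10%-robust", "20%-robust", "nonrobust")))
})

test_that("run_study validates configs and writes deterministic outputs", {
  cfg <- list(
    seed = 11,
    tests = list(scales = 2, sample_sizes = list(c(4, 4)),
                 tests = "welch", replications = 10),
    cis = list(scales = 2, sample_sizes = list(c(4, 4)),
               methods = "welch", replications = 10)
  )
  out1 <- run_study(cfg)
  out2 <- run_study(cfg)
  expect_identical(out1$tests, out2$tests)
  expect_identical(out1$cis, out2$cis)
  expect_equal(nrow(out1$tests), 21)
  expect_s3_class(out1$tests_summary, "tbl_df")

  bad <- list(tests = list(scales = 2))
  expect_error(run_study(bad), "missing field")
  bad2 <- list(tests = list(scales = 2, sample_sizes = list(c(4))))
  expect_error(run_study(bad2), "two sizes")

  dir <- withr::local_tempdir()
  cfg$output_dir <- dir
  run_study(cfg)
  expect_true(file.exists(file.path(dir, "tests_results.csv")))
  expect_true(file.exists(file.path(dir, "ci_results.csv")))

  # YAML round trip
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(seed = 11,
                        tests = list(scales = 2,
                                     sample_sizes = list(c(4, 4)),
                                     tests = "welch",
                                     replications = 10)), yml)
  out3 <- run_study(yml)
  expect_identical(out3$tests, out1$tests)
})

test_that("plot builders return ggplot objects", {
  res <- run_test_study(2, sample_sizes = list(c(4, 4)), tests = "welch",
                        replications = 10, seed = 1)
  expect_s3_class(plot_rejection_rates(res), "ggplot")
  ci <- run_ci_study(2, sample_sizes = list(c(4, 4)), methods = "welch",
                     replications = 10, seed = 1)
  expect_s3_class(plot_coverage(ci), "ggplot")
  d <- make_distribution("normal", 4)
  expect_s3_class(ggplot2::autoplot(d), "ggplot")
})
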