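# Monte-Carlo evaluation harness: true significance level, power,
# coverage, interval length and overshoot across scenario grids, with
# nested robustness bands around the nominal level.

# deterministic per-scenario substream: hash a scenario key onto a
# 32-bit seed so scenario results do not depend on enumeration order
.derive_seed <- function(root_seed, ...) {
  key <- paste(c(...), collapse = "|")
  h <- as.double(root_seed %% 2147483647)
  for (cc in utf8ToInt(key)) h <- (h * 31 + cc) %% 2147483647
  as.integer(h)
}

# vectorised two-sided p-values over replication columns
.p_t_vec <- function(X, Y) {
  m <- nrow(X); n <- nrow(Y)
  mx <- colMeans(X); my <- colMeans(Y)
  vx <- (colSums(X^2) - m * mx^2) / (m - 1)
  vy <- (colSums(Y^2) - n * my^2) / (n - 1)
  vx[vx < 0] <- 0; vy[vy < 0] <- 0
  d <- mx - my
  se <- sqrt(((m - 1) * vx + (n - 1) * vy) / (m + n - 2) * (1 / m + 1 / n))
  ifelse(se > 0, 2 * pt(-abs(d / se), m + n - 2), ifelse(d == 0, 1, 0))
}

.p_welch_vec <- function(X, Y) {
  m <- nrow(X); n <- nrow(Y)
  mx <- colMeans(X); my <- colMeans(Y)
  vx <- (colSums(X^2) - m * mx^2) / (m - 1)
  vy <- (colSums(Y^2) - n * my^2) / (n - 1)
  vx[vx < 0] <- 0; vy[vy < 0] <- 0
  d <- mx - my
  se2 <- vx / m + vy / n
  df <- se2^2 / ((vx / m)^2 / (m - 1) + (vy / n)^2 / (n - 1))
  ifelse(se2 > 0, 2 * pt(-abs(d / sqrt(se2)), df), ifelse(d == 0, 1, 0))
}

.check_scenario_dists <- function(dist1, dist2) {
  stopifnot(inherits(dist1, "discrete_dist"),
            inherits(dist2, "discrete_dist"))
  if (dist1$K != dist2$K) {
    stop("both distributions must live on the same scale", call. = FALSE)
  }
  invisible(NULL)
}

#' Estimate the rejection rate of a test under a simulation scenario
#'
#' Draws \code{replications} pairs of independent samples of sizes
#' \code{m} and \code{n} from two discrete distributions, applies a
#' two-sample test, and reports the percentage of two-sided p-values
#' below the nominal level together with its binomial Monte-Carlo
#' standard error. When the two distribution means are equal (within
#' 1e-9) the scenario is a null scenario and the rate estimates the true
#' significance level, which is classified into robustness bands; for
#' unequal means the rate estimates power and the class is \code{"n/a"}.
#'
#' @param dist1,dist2 [make_distribution()] objects on a common scale.
#' @param m,n Group sample sizes.
#' @param test Test label (\code{"t"}, \code{"welch"}, \code{"wmw"},
#'   \code{"bm"}, \code{"bm-perm"}) or a function \code{f(x, y)}
#'   returning a p-value (useful for stubs and custom tests; reported as
#'   method \code{"custom"}).
#' @param replications Number of Monte-Carlo replications.
#' @param seed Integer seed for this scenario's substream.
#' @param nominal_level Nominal significance level (default 0.05).
#' @param n_permutations Permutations per replication when
#'   \code{test = "bm-perm"}.
#' @return A one-row tibble: \code{scale}, \code{dist1}, \code{dist2},
#'   \code{m}, \code{n}, \code{method}, \code{rejection_pct},
#'   \code{mc_se_pct}, \code{is_null}, \code{robustness}.
#' @examples
#' u <- make_distribution("uniform", K = 3)
#' run_test_scenario(u, u, 25, 25, "welch", replications = 500, seed = 7)
#' @export
run_test_scenario <- function(dist1, dist2, m, n, test = "welch",
                              replications = 10000, seed = 1,
                              nominal_level = 0.05,
                              n_permutations = 10000) {
  .check_scenario_dists(dist1, dist2)
  stopifnot(replications >= 1, m >= 2, n >= 2)
  mu1 <- dist_moments(dist1)[["mean"]]
  mu2 <- dist_moments(dist2)[["mean"]]
  is_null <- abs(mu1 - mu2) <= 1e-9
  K <- dist1$K
  set.seed(seed)
  rej <- 0
  left <- replications
  chunk <- max(1L, floor(2e6 / (m + n)))
  while (left > 0) {
    R <- min(chunk, left)
    left <- left - R
    X <- matrix(sample.int(K + 1L, m * R, replace = TRUE,
                           prob = dist1$probs) - 1L, nrow = m)
    Y <- matrix(sample.int(K + 1L, n * R, replace = TRUE,
                           prob = dist2$probs) - 1L, nrow = n)
    pv <- if (is.function(test)) {
      vapply(seq_len(R), function(j) test(X[, j], Y[, j]), numeric(1))
    } else {
      switch(test,
        "t" = .p_t_vec(X, Y),
        "welch" = .p_welch_vec(X, Y),
        "wmw" = vapply(seq_len(R),
                       function(j) .wmw_core(X[, j], Y[, j])$p, numeric(1)),
        "bm" = vapply(seq_len(R),
                      function(j) .bm_core(X[, j], Y[, j])$p, numeric(1)),
        "bm-perm" = vapply(seq_len(R), function(j) {
          bm_permutation_test(X[, j], Y[, j], n_permutations)$p_value
        }, numeric(1)),
        stop("unknown test '", test, "'", call. = FALSE)
      )
    }
    rej <- rej + sum(pv < nominal_level)
  }
  rate <- 100 * rej / replications
  tibble::tibble(
    scale = K, dist1 = dist1$name, dist2 = dist2$name, m = m, n = n,
    method = if (is.function(test)) "custom" else test,
    rejection_pct = rate,
    mc_se_pct = 100 * sqrt(rate / 100 * (1 - rate / 100) / replications),
    is_null = is_null,
    robustness = if (is_null) {
      classify_robustness(rate, nominal_level * 100)
    } else "n/a"
  )
}

# lower/upper limits for the requested interval methods on one dataset,
# sharing the resample draws between pb and bt
.interval_limits <- function(x, y, methods, n_resamples, level) {
  out <- vector("list", length(methods))
  names(out) <- methods
  co <- NULL
  need_boot <- any(methods %in% c("pb", "bt"))
  if (any(methods %in% c("welch", "bt"))) co <- .welch_core(x, y)
  d <- mean(x) - mean(y)
  a <- 1 - level
  if (need_boot) bs <- .boot_draws(x, y, n_resamples)
  for (mth in methods) {
    out[[mth]] <- switch(mth,
      "welch" = if (co$se == 0) c(co$d, co$d) else {
        half <- qt(1 - a / 2, co$df) * co$se
        c(co$d - half, co$d + half)
      },
      "pb" = .os_quantile(sort(bs$dstar), c(a / 2, 1 - a / 2)),
      "bt" = if (co$se == 0) c(co$d, co$d) else {
        q <- .os_quantile(sort(.studentize(bs$dstar, bs$sestar, co$d)),
                          c(a / 2, 1 - a / 2))
        c(co$d - q[2] * co$se, co$d - q[1] * co$se)
      },
      stop("unknown interval method '", mth, "'", call. = FALSE)
    )
  }
  list(limits = out, estimate = d)
}

#' Estimate coverage, length and overshoot of interval methods
#'
#' Draws \code{replications} sample pairs from two discrete
#' distributions and, for each requested interval method, reports the
#' percentage of intervals containing the true difference between the
#' distribution means (analytic, not sample-based), the mean interval
#' length, and the percentage of intervals whose limits overshoot the
#' maximum possible difference of \eqn{\pm K}. Coverage is classified
#' into robustness bands around the nominal confidence level.
#'
#' @inheritParams run_test_scenario
#' @param methods Character vector from \code{"welch"}, \code{"pb"},
#'   \code{"bt"} (evaluated on shared samples and, for the two bootstrap
#'   methods, shared resamples), or a function \code{f(x, y)} returning
#'   \code{c(lower, upper)} (reported as \code{"custom"}).
#' @param n_resamples Bootstrap resamples per interval.
#' @param level Nominal confidence level (default 0.95).
#' @return A tibble with one row per method: \code{scale},
#'   \code{dist1}, \code{dist2}, \code{m}, \code{n}, \code{method},
#'   \code{coverage_pct}, \code{mc_se_pct}, \code{mean_length},
#'   \code{overshoot_pct}, \code{robustness}.
#' @examples
#' u <- make_distribution("uniform", K = 2)
#' run_ci_scenario(u, u, 10, 10, "welch", replications = 200, seed = 3)
#' @export
run_ci_scenario <- function(dist1, dist2, m, n, methods = "welch",
                            replications = 2000, seed = 1,
                            n_resamples = 2000, level = 0.95) {
  .check_scenario_dists(dist1, dist2)
  stopifnot(replications >= 1, m >= 2, n >= 2)
  K <- dist1$K
  true_diff <- dist_moments(dist1)[["mean"]] - dist_moments(dist2)[["mean"]]
  custom <- is.function(methods)
  mlabels <- if (custom) "custom" else methods
  set.seed(seed)

  if (!custom && identical(methods, "welch")) {
    # closed-form method: vectorise across replications
    cover <- 0; len <- 0; over <- 0
    left <- replications
    chunk <- max(1L, floor(2e6 / (m + n)))
    while (left > 0) {
      R <- min(chunk, left)
      left <- left - R
      X <- matrix(sample.int(K + 1L, m * R, TRUE, dist1$probs) - 1L, m)
      Y <- matrix(sample.int(K + 1L, n * R, TRUE, dist2$probs) - 1L, n)
      mx <- colMeans(X); my <- colMeans(Y)
      vx <- (colSums(X^2) - m * mx^2) / (m - 1)
      vy <- (colSums(Y^2) - n * my^2) / (n - 1)
      vx[vx < 0] <- 0; vy[vy < 0] <- 0
      d <- mx - my
      se2 <- vx / m + vy / n
      df <- se2^2 / ((vx / m)^2 / (m - 1) + (vy / n)^2 / (n - 1))
      half <- ifelse(se2 > 0, qt(1 - (1 - level) / 2, df) * sqrt(se2), 0)
      lo <- d - half; hi <- d + half
      cover <- cover + sum(lo <= true_diff & true_diff <= hi)
      len <- len + sum(hi - lo)
      over <- over + sum(lo < -K | hi > K)
    }
    counts <- list(welch = c(cover, len, over))
  } else {
    counts <- lapply(mlabels, function(...) c(0, 0, 0))
    names(counts) <- mlabels
    for (r in seq_len(replications)) {
      x <- sample_dist(dist1, m)
      y <- sample_dist(dist2, n)
      lims <- if (custom) {
        stats::setNames(list(methods(x, y)), "custom")
      } else {
        .interval_limits(x, y, methods, n_resamples, level)$limits
      }
      for (mth in mlabels) {
        lo <- lims[[mth]][1]; hi <- lims[[mth]][2]
        counts[[mth]] <- counts[[mth]] +
          c(lo <= true_diff && true_diff <= hi, hi - lo,
            lo < -K || hi > K)
      }
    }
  }

  purrr::map_dfr(mlabels, function(mth) {
    cc <- counts[[mth]]
    cov <- 100 * cc[1] / replications
    tibble::tibble(
      scale = K, dist1 = dist1$name, dist2 = dist2$name, m = m, n = n,
      method = mth, coverage_pct = cov,
      mc_se_pct = 100 * sqrt(cov / 100 * (1 - cov / 100) / replications),
      mean_length = cc[2] / replications,
      overshoot_pct = 100 * cc[3] / replications,
      robustness = classify_robustness(cov, level * 100)
    )
  })
}

#' Classify an observed rate into nested robustness bands
#'
#' A method is 10%-robust when its observed rate deviates from the
#' nominal rate by at most 10% of the nominal error probability, and
#' 20%-robust within twice that band; otherwise it is nonrobust. For a
#' 5% nominal significance level the bands are 4.5--5.5 and 4.0--6.0;
#' for a 95% nominal confidence level they are 94.5--95.5 and
#' 94.0--96.0.
#'
#' @param observed Observed rate(s) in percent.
#' @param nominal Nominal rate in percent, strictly between 0 and 100
#'   (5 for tests, 95 for confidence intervals).
#' @return Character vector: \code{"10%-robust"}, \code{"20%-robust"}
#'   or \code{"nonrobust"}.
#' @examples
#' classify_robustness(c(5.2, 5.8, 6.3), 5)
#' @export
classify_robustness <- function(observed, nominal) {
  if (any(!is.finite(nominal)) || any(nominal <= 0) ||
      any(nominal >= 100)) {
    stop("nominal must be a percentage strictly between 0 and 100",
         call. = FALSE)
  }
  tol <- 0.10 * pmin(nominal, 100 - nominal)
  dev <- abs(observed - nominal)
  ifelse(dev <= tol + 1e-12, "10%-robust",
         ifelse(dev <= 2 * tol + 1e-12, "20%-robust", "nonrobust"))
}

#' Mean deviation of true significance levels from the nominal level
#'
#' Averages \code{|rate - nominal|} in percentage points over all
#' null (equal-means) scenarios, per test method. This is the headline
#' robustness summary of the evaluation framework: smaller is better.
#'
#' @param results Tibble of [run_test_scenario()] rows, all with
#'   \code{is_null = TRUE} (typically one (scale, m, n) block).
#' @param nominal Nominal significance level in percent (default 5).
#' @return Tibble with columns \code{method} and
#'   \code{mean_deviation}.
#' @export
mean_deviation_summary <- function(results, nominal = 5) {
  if (!nrow(results)) stop("no scenario rows supplied", call. = FALSE)
  if (!all(results$is_null)) {
    stop("mean deviation is defined over null (equal-means) scenarios only",
         call. = FALSE)
  }
  results |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      mean_deviation = mean(abs(.data$rejection_pct - nominal)),
      .groups = "drop"
    )
}

#' Relative power of tests over unequal-means scenarios
#'
#' Sums the percent rejection rates over all power (unequal-means)
#' scenarios per test and expresses each sum as a percentage of the
#' largest sum, so the most powerful test scores exactly 100.
#'
#' @param results Tibble of [run_test_scenario()] rows, all with
#'   \code{is_null = FALSE}.
#' @return Tibble with columns \code{method}, \code{power_sum} and
#'   \code{relative_power_pct}.
#' @export
relative_power_summary <- function(results) {
  if (!nrow(results)) stop("no scenario rows supplied", call. = FALSE)
  if (any(results$is_null)) {
    stop("relative power is defined over unequal-means scenarios only",
         call. = FALSE)
  }
  out <- results |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(power_sum = sum(.data$rejection_pct),
                     .groups = "drop")
  if (max(out$power_sum) <= 0) {
    stop("all tests have zero power sum; relative power undefined",
         call. = FALSE)
  }
  dplyr::mutate(out,
                relative_power_pct = 100 * .data$power_sum /
                  max(.data$power_sum))
}

# distribution pair grid: unordered combinations (with self-pairs) when
# m = n, ordered pairs otherwise
.dist_pairs <- function(dists, ordered) {
  k <- length(dists)
  if (ordered) {
    idx <- expand.grid(i = seq_len(k), j = seq_len(k))
  } else {
    idx <- expand.grid(i = seq_len(k), j = seq_len(k))
    idx <- idx[idx$i <= idx$j, ]
  }
  idx
}

#' Run the full hypothesis-test simulation study for one scale
#'
#' Evaluates each test on every distribution pair of the scale's
#' reference set for every sample-size combination. When m = n the
#' order of the two distributions is irrelevant and the 21 unordered
#' pairs are used (9 with equal means); when m != n all 36 ordered
#' pairs are used (12 with equal means). Each scenario runs on its own
#' seed substream derived from \code{seed} and the scenario identity,
#' so results do not depend on enumeration order.
#'
#' @param K Scale maximum (2..5).
#' @param sample_sizes List of \code{c(m, n)} pairs. Defaults to the
#'   full nine-combination grid (10,10) ... (100,10).
#' @param tests Character vector of test labels.
#' @param replications Replications per scenario.
#' @param seed Root seed.
#' @param nominal_level Nominal significance level.
#' @param dists Optional named list of \code{discrete_dist} objects to
#'   use instead of [reference_distributions()] (e.g. from
#'   [read_distributions()]).
#' @return Tibble of [run_test_scenario()] rows.
#' @seealso [summarize_test_study()] for the mean-deviation and
#'   relative-power summaries.
#' @export
run_test_study <- function(K,
                           sample_sizes = list(
                             c(10, 10), c(25, 25), c(50, 50), c(100, 100),
                             c(25, 10), c(50, 10), c(100, 50),
                             c(100, 25), c(100, 10)),
                           tests = c("t", "welch", "wmw", "bm"),
                           replications = 10000, seed = 1,
                           nominal_level = 0.05, dists = NULL) {
  if (is.null(dists)) dists <- reference_distributions(K)
  purrr::map_dfr(sample_sizes, function(mn) {
    m <- mn[1]; n <- mn[2]
    idx <- .dist_pairs(dists, ordered = m != n)
    purrr::map_dfr(seq_len(nrow(idx)), function(r) {
      d1 <- dists[[idx$i[r]]]; d2 <- dists[[idx$j[r]]]
      purrr::map_dfr(tests, function(tst) {
        run_test_scenario(
          d1, d2, m, n, tst, replications,
          seed = .derive_seed(seed, "test", K, d1$name, d2$name, m, n, tst),
          nominal_level = nominal_level
        )
      })
    })
  })
}

#' Summarise a test study into mean deviation and relative power
#'
#' Applies [mean_deviation_summary()] to the null scenarios and
#' [relative_power_summary()] to the power scenarios within each
#' (scale, m, n) block.
#'
#' @param results Output of [run_test_study()].
#' @param nominal Nominal significance level in percent.
#' @return Tibble with columns \code{scale}, \code{m}, \code{n},
#'   \code{method}, \code{mean_deviation}, \code{relative_power_pct}.
#' @export
summarize_test_study <- function(results, nominal = 5) {
  md <- results |>
    dplyr::filter(.data$is_null) |>
    dplyr::group_by(.data$scale, .data$m, .data$n) |>
    dplyr::group_modify(~ mean_deviation_summary(.x, nominal)) |>
    dplyr::ungroup()
  rp <- results |>
    dplyr::filter(!.data$is_null) |>
    dplyr::group_by(.data$scale, .data$m, .data$n) |>
    dplyr::group_modify(~ relative_power_summary(.x)) |>
    dplyr::ungroup() |>
    dplyr::select(-"power_sum")
  dplyr::full_join(md, rp, by = c("scale", "m", "n", "method"))
}

#' Run the confidence-interval simulation study for one scale
#'
#' Evaluates the interval methods over every distribution pair of the
#' scale's reference set and the given sample-size combinations,
#' reporting coverage, mean length and overshoot per scenario.
#'
#' @inheritParams run_test_study
#' @param methods Interval method labels (\code{"welch"}, \code{"pb"},
#'   \code{"bt"}).
#' @param n_resamples Bootstrap resamples per interval.
#' @param level Nominal confidence level.
#' @return Tibble of [run_ci_scenario()] rows.
#' @export
run_ci_study <- function(K,
                         sample_sizes = list(c(10, 10), c(50, 50),
                                             c(25, 10), c(100, 25)),
                         methods = c("welch", "pb", "bt"),
                         replications = 2000, n_resamples = 2000,
                         seed = 1, level = 0.95, dists = NULL) {
  if (is.null(dists)) dists <- reference_distributions(K)
  purrr::map_dfr(sample_sizes, function(mn) {
    m <- mn[1]; n <- mn[2]
    idx <- .dist_pairs(dists, ordered = m != n)
    purrr::map_dfr(seq_len(nrow(idx)), function(r) {
      d1 <- dists[[idx$i[r]]]; d2 <- dists[[idx$j[r]]]
      run_ci_scenario(
        d1, d2, m, n, methods, replications,
        seed = .derive_seed(seed, "ci", K, d1$name, d2$name, m, n),
        n_resamples = n_resamples, level = level
      )
    })
  })
}

#' Run a configured simulation study
#'
#' Batch entry point over [run_test_study()] and [run_ci_study()].
#' The configuration is a YAML file or an equivalent nested list with
#' optional blocks \code{tests} and \code{cis}, each with fields
#' \code{scales}, \code{sample_sizes} (list of two-element vectors),
#' \code{tests}/\code{methods}, \code{replications} and, for CIs,
#' \code{n_resamples}; plus top-level \code{seed} and optional
#' \code{output_dir} for CSV export.
#'
#' @param config Path to a YAML file or a list.
#' @return Invisibly, a list with elements \code{tests},
#'   \code{tests_summary} and \code{cis} (tibbles; absent blocks are
#'   NULL). With \code{output_dir} set, the same tables are written as
#'   \code{tests_results.csv}, \code{tests_summary.csv} and
#'   \code{ci_results.csv}.
#' @export
run_study <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path",
                             call. = FALSE)
  seed <- config$seed %||% 1
  out <- list(tests = NULL, tests_summary = NULL, cis = NULL)

  if (!is.null(config$tests)) {
    tc <- config$tests
    .check_config_block(tc, "tests", c("scales", "sample_sizes"))
    out$tests <- purrr::map_dfr(tc$scales, function(K) {
      run_test_study(
        K, sample_sizes = lapply(tc$sample_sizes, as.numeric),
        tests = tc$tests %||% c("t", "welch", "wmw", "bm"),
        replications = tc$replications %||% 10000, seed = seed,
        nominal_level = tc$nominal_level %||% 0.05
      )
    })
    out$tests_summary <- summarize_test_study(
      out$tests, nominal = 100 * (config$tests$nominal_level %||% 0.05))
  }

  if (!is.null(config$cis)) {
    cc <- config$cis
    .check_config_block(cc, "cis", c("scales", "sample_sizes"))
    out$cis <- purrr::map_dfr(cc$scales, function(K) {
      run_ci_study(
        K, sample_sizes = lapply(cc$sample_sizes, as.numeric),
        methods = cc$methods %||% c("welch", "pb", "bt"),
        replications = cc$replications %||% 2000,
        n_resamples = cc$n_resamples %||% 2000, seed = seed,
        level = cc$level %||% 0.95
      )
    })
  }

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(out$tests)) {
      write.csv(out$tests,
                file.path(config$output_dir, "tests_results.csv"),
                row.names = FALSE)
      write.csv(out$tests_summary,
                file.path(config$output_dir, "tests_summary.csv"),
                row.names = FALSE)
    }
    if (!is.null(out$cis)) {
      write.csv(out$cis, file.path(config$output_dir, "ci_results.csv"),
                row.names = FALSE)
    }
  }
  invisible(out)
}

.check_config_block <- function(block, name, required) {
  missing <- setdiff(required, names(block))
  if (length(missing)) {
    stop("config block '", name, "' is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (mn in block$sample_sizes) {
    if (length(mn) != 2 || any(as.numeric(mn) < 2)) {
      stop("config block '", name, "': each sample_sizes entry must be ",
           "two sizes >= 2 (got: ", paste(mn, collapse = ","), ")",
           call. = FALSE)
    }
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot estimated true significance levels with robustness bands
#'
#' Dot plot of the rejection rates of the null scenarios in a test
#' study, by method, with the 10%-robust band shaded and the 20%-robust
#' limits drawn, mirroring the green/yellow/red convention of
#' simulation reports.
#'
#' @param results Tibble of [run_test_scenario()] rows.
#' @param nominal Nominal significance level in percent.
#' @return A ggplot object.
#' @export
plot_rejection_rates <- function(results, nominal = 5) {
  df <- dplyr::filter(results, .data$is_null)
  tol <- 0.10 * min(nominal, 100 - nominal)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method,
                                   y = .data$rejection_pct)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = nominal - tol, ymax = nominal + tol,
                      alpha = 0.15, fill = "darkgreen") +
    ggplot2::geom_hline(yintercept = nominal + c(-2, 2) * tol,
                        linetype = "dashed", colour = "orange") +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6) +
    ggplot2::facet_grid(scale ~ m + n, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "estimated true significance level (%)") +
    ggplot2::theme_minimal()
}

#' Plot coverage probabilities with robustness bands
#'
#' Companion to [plot_rejection_rates()] for confidence-interval
#' studies: coverage per scenario and method around the nominal level.
#'
#' @param results Tibble of [run_ci_scenario()] rows.
#' @param nominal Nominal confidence level in percent.
#' @return A ggplot object.
#' @export
plot_coverage <- function(results, nominal = 95) {
  tol <- 0.10 * min(nominal, 100 - nominal)
  ggplot2::ggplot(results, ggplot2::aes(x = .data$method,
                                        y = .data$coverage_pct)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = nominal - tol, ymax = nominal + tol,
                      alpha = 0.15, fill = "darkgreen") +
    ggplot2::geom_hline(yintercept = nominal + c(-2, 2) * tol,
                        linetype = "dashed", colour = "orange") +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6) +
    ggplot2::facet_grid(scale ~ m + n, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "estimated coverage probability (%)") +
    ggplot2::theme_minimal()
}
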