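# Core two-sample machinery. All five tests share the conventions:
#   group 1 = first argument (first-listed arm), effect = mean1 - mean2,
#   two-sided p-values, and the degenerate-data rule: when the standard
#   error is exactly zero the p-value is 1 if the group summaries are
#   equal and 0 (with a degenerate flag) otherwise, so Monte-Carlo loops
#   on small discrete samples never abort.

.new_dn_test <- function(method, statistic, df, p_value, mean_difference,
                         relative_effect = NA_real_, m, n,
                         degenerate = FALSE, n_permutations = NA_integer_) {
  structure(
    list(method = method, statistic = statistic, df = df,
         p_value = p_value, mean_difference = mean_difference,
         relative_effect = relative_effect, m = m, n = n,
         degenerate = degenerate, n_permutations = n_permutations),
    class = "dn_test"
  )
}

.check_two_samples <- function(x, y, min_m = 2L, min_n = min_m) {
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported",
                                 call. = FALSE)
  if (length(x) < min_m || length(y) < min_n) {
    stop("need at least ", min_m, " observations in group 1 and ",
         min_n, " in group 2", call. = FALSE)
  }
  invisible(NULL)
}

# pooled-variance two-sample t
.t_core <- function(x, y) {
  m <- length(x); n <- length(y)
  d <- mean(x) - mean(y)
  sp2 <- ((m - 1) * var(x) + (n - 1) * var(y)) / (m + n - 2)
  se <- sqrt(sp2 * (1 / m + 1 / n))
  df <- m + n - 2
  if (se == 0) {
    return(list(stat = 0, df = df, p = if (d == 0) 1 else 0,
                d = d, se = 0, degenerate = TRUE))
  }
  stat <- d / se
  list(stat = stat, df = df, p = 2 * pt(-abs(stat), df), d = d, se = se,
       degenerate = FALSE)
}

# Welch statistic with Satterthwaite df
.welch_core <- function(x, y) {
  m <- length(x); n <- length(y)
  d <- mean(x) - mean(y)
  v1 <- var(x); v2 <- var(y)
  se2 <- v1 / m + v2 / n
  if (se2 == 0) {
    return(list(stat = 0, df = NA_real_, p = if (d == 0) 1 else 0,
                d = d, se = 0, degenerate = TRUE))
  }
  df <- se2^2 / ((v1 / m)^2 / (m - 1) + (v2 / n)^2 / (n - 1))
  stat <- d / sqrt(se2)
  list(stat = stat, df = df, p = 2 * pt(-abs(stat), df), d = d,
       se = sqrt(se2), degenerate = FALSE)
}

# tie-adjusted WMW: mid-ranks, normal approximation, no continuity
# correction
.wmw_core <- function(x, y) {
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  r1 <- r[seq_len(m)]
  rbar1 <- mean(r1); rbar2 <- mean(r[-seq_len(m)])
  phat <- (rbar2 - rbar1) / N + 0.5
  W <- sum(r1)
  tt <- tabulate(match(c(x, y), unique(c(x, y))))
  v <- m * n / 12 * ((N + 1) - sum(tt^3 - tt) / (N * (N - 1)))
  if (v <= 0) {
    # every observation tied across both groups
    return(list(stat = 0, p = 1, phat = 0.5, degenerate = TRUE))
  }
  z <- (W - m * (N + 1) / 2) / sqrt(v)
  list(stat = z, p = 2 * pnorm(-abs(z)), phat = phat, degenerate = FALSE)
}

# Brunner-Munzel: combined and within-group mid-ranks, Satterthwaite-type
# df. Returns the t-like statistic W oriented so that swapping the groups
# flips its sign.
.bm_core <- function(x, y) {
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  r1 <- r[seq_len(m)]; r2 <- r[-seq_len(m)]
  rbar1 <- mean(r1); rbar2 <- mean(r2)
  ri1 <- rank(x); ri2 <- rank(y)
  S1 <- sum((r1 - ri1 - rbar1 + (m + 1) / 2)^2) / (m - 1)
  S2 <- sum((r2 - ri2 - rbar2 + (n + 1) / 2)^2) / (n - 1)
  phat <- (rbar2 - rbar1) / N + 0.5
  sig <- m * S1 + n * S2
  if (sig <= 0) {
    # complete within-group ties: no rank variability
    if (rbar1 == rbar2) {
      return(list(stat = 0, df = NA_real_, p = 1, phat = phat,
                  degenerate = TRUE))
    }
    return(list(stat = sign(rbar2 - rbar1) * Inf, df = NA_real_, p = 0,
                phat = phat, degenerate = TRUE))
  }
  W <- m * n * (rbar2 - rbar1) / (N * sqrt(sig))
  df <- sig^2 / ((m * S1)^2 / (m - 1) + (n * S2)^2 / (n - 1))
  list(stat = W, df = df, p = 2 * pt(-abs(W), df), phat = phat,
       degenerate = FALSE)
}

#' Two-sample hypothesis tests for bounded count outcomes
#'
#' Five tests of equality between two independent groups of discrete
#' numerical values (counts on a bounded scale \{0, ..., K\}):
#' \describe{
#'   \item{\code{t_test_pooled()}}{ordinary two-sample T test with pooled
#'     variance, df = m + n - 2.}
#'   \item{\code{welch_u_test()}}{Welch U test (T test for unequal
#'     variances) with Welch-Satterthwaite degrees of freedom.}
#'   \item{\code{wmw_test()}}{Wilcoxon-Mann-Whitney rank-sum test on
#'     mid-ranks with tie-corrected variance, normal approximation and no
#'     continuity correction.}
#'   \item{\code{brunner_munzel_test()}}{Brunner-Munzel generalised WMW
#'     test: a t-type statistic on rank means with empirical rank
#'     variances and a Satterthwaite-type df, valid under tied data and
#'     unequal distributions.}
#'   \item{\code{bm_permutation_test()}}{permutation version of the
#'     Brunner-Munzel statistic: the p-value is the proportion of random
#'     relabellings (observed configuration included) whose absolute
#'     statistic is at least the observed one.}
#' }
#'
#' All tests are two-sided. The statistic is oriented so that exchanging
#' the two groups flips its sign (and the reported
#' \code{mean_difference = mean(x) - mean(y)}), while the p-value is
#' unchanged. The rank-based tests additionally report the estimated
#' relative effect Pr(X < Y) + 0.5 Pr(X = Y): 0.5 means stochastically
#' equal groups, values above 0.5 mean group 2 tends to be larger.
#'
#' When both group variances (or all rank variances) are zero the result
#' is degenerate: p = 1 if the groups are identical in location, else
#' p = 0 with \code{degenerate = TRUE}.
#'
#' @param x,y Integer-valued vectors of per-subject counts for group 1
#'   (first-listed arm) and group 2.
#' @param n_permutations Number of random permutations for
#'   \code{bm_permutation_test()} (default 10000).
#' @return An object of class \code{dn_test} with elements
#'   \code{method}, \code{statistic}, \code{df}, \code{p_value},
#'   \code{mean_difference}, \code{relative_effect} (rank-based tests
#'   only), group sizes \code{m}, \code{n}, and \code{degenerate}.
#'   Use [tidy()] for a one-row tibble.
#' @examples
#' standard <- expand_counts(c(19, 10, 7, 3, 6))   # n = 45
#' intensive <- expand_counts(c(39, 8, 8, 0, 0))   # n = 55
#' welch_u_test(standard, intensive)
#' tidy(wmw_test(standard, intensive))
#' @name two_sample_tests
NULL

#' @rdname two_sample_tests
#' @export
t_test_pooled <- function(x, y) {
  .check_two_samples(x, y)
  co <- .t_core(x, y)
  .new_dn_test("t", co$stat, co$df, co$p, co$d,
               m = length(x), n = length(y), degenerate = co$degenerate)
}

#' @rdname two_sample_tests
#' @export
welch_u_test <- function(x, y) {
  .check_two_samples(x, y)
  co <- .welch_core(x, y)
  .new_dn_test("welch", co$stat, co$df, co$p, co$d,
               m = length(x), n = length(y), degenerate = co$degenerate)
}

#' @rdname two_sample_tests
#' @export
wmw_test <- function(x, y) {
  .check_two_samples(x, y, min_m = 1L)
  co <- .wmw_core(x, y)
  .new_dn_test("wmw", co$stat, NA_real_, co$p, mean(x) - mean(y),
               relative_effect = co$phat,
               m = length(x), n = length(y), degenerate = co$degenerate)
}

#' @rdname two_sample_tests
#' @export
brunner_munzel_test <- function(x, y) {
  .check_two_samples(x, y)
  co <- .bm_core(x, y)
  .new_dn_test("bm", co$stat, co$df, co$p, mean(x) - mean(y),
               relative_effect = co$phat,
               m = length(x), n = length(y), degenerate = co$degenerate)
}

# BM statistic only, with the degenerate convention used inside the
# permutation loop: 0 when rank means agree, +/-Inf when they differ with
# zero rank variance (so such resamples always count as extreme).
.bm_W <- function(x, y) {
  co <- .bm_core(x, y)
  co$stat
}

#' @rdname two_sample_tests
#' @export
bm_permutation_test <- function(x, y, n_permutations = 10000) {
  .check_two_samples(x, y)
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  obs <- .bm_core(x, y)
  pooled <- c(x, y)
  m <- length(x); N <- length(pooled)
  thresh <- abs(obs$stat) - 1e-12
  count <- 1L  # the observed configuration
  for (b in seq_len(n_permutations)) {
    idx <- sample.int(N, m)
    if (abs(.bm_W(pooled[idx], pooled[-idx])) >= thresh) count <- count + 1L
  }
  .new_dn_test("bm-perm", obs$stat, NA_real_,
               count / (n_permutations + 1L), mean(x) - mean(y),
               relative_effect = obs$phat,
               m = m, n = N - m, degenerate = obs$degenerate,
               n_permutations = as.integer(n_permutations))
}

#' Compare two groups in a data frame
#'
#' Data-frame-first interface to the two-sample tests: give a data frame,
#' the column of per-subject counts and the grouping column, and the test
#' to run. Group 1 is the first factor level (or first-appearing value)
#' of the grouping column.
#'
#' @param data A data frame with one row per subject.
#' @param value Column of counts (tidy-eval).
#' @param group Column identifying the two groups (tidy-eval).
#' @param test One of \code{"welch"} (default), \code{"t"},
#'   \code{"wmw"}, \code{"bm"}, \code{"bm-perm"}.
#' @param n_permutations Permutations for \code{test = "bm-perm"}.
#' @return A \code{dn_test} object; see [two_sample_tests].
#' @examples
#' df <- data.frame(
#'   visits = c(expand_counts(c(19, 10, 7, 3, 6)),
#'              expand_counts(c(39, 8, 8, 0, 0))),
#'   arm = rep(c("standard", "intensive"), c(45, 55))
#' )
#' compare_groups(df, visits, arm, test = "welch")
#' @export
compare_groups <- function(data, value, group,
                           test = c("welch", "t", "wmw", "bm", "bm-perm"),
                           n_permutations = 10000) {
  test <- match.arg(test)
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- rlang::eval_tidy(rlang::enquo(group), data)
  sp <- .split_two_groups(v, g)
  switch(test,
    "t" = t_test_pooled(sp$x, sp$y),
    "welch" = welch_u_test(sp$x, sp$y),
    "wmw" = wmw_test(sp$x, sp$y),
    "bm" = brunner_munzel_test(sp$x, sp$y),
    "bm-perm" = bm_permutation_test(sp$x, sp$y, n_permutations)
  )
}

.split_two_groups <- function(v, g) {
  lev <- if (is.factor(g)) levels(droplevels(g)) else unique(g)
  if (length(lev) != 2) {
    stop("the grouping column must have exactly two groups, got ",
         length(lev), call. = FALSE)
  }
  list(x = v[g == lev[1]], y = v[g == lev[2]],
       groups = as.character(lev))
}

#' @export
print.dn_test <- function(x, ...) {
  lbl <- c(t = "Two-sample T test (pooled variance)",
           welch = "Welch U test",
           wmw = "Wilcoxon-Mann-Whitney test (tie-adjusted)",
           bm = "Brunner-Munzel test",
           "bm-perm" = "Brunner-Munzel permutation test")[[x$method]]
  cat("\n\t", lbl, "\n\n")
  cat("  groups: m =", x$m, ", n =", x$n, "\n")
  cat("  mean difference (group1 - group2):",
      signif(x$mean_difference, 4), "\n")
  if (!is.na(x$relative_effect)) {
    cat("  relative effect Pr(X<Y) + 0.5 Pr(X=Y):",
        signif(x$relative_effect, 4), "\n")
  }
  cat("  statistic:", signif(x$statistic, 4),
      if (!is.na(x$df)) paste0(" df: ", signif(x$df, 4)), "\n")
  cat("  two-sided p-value:", format.pval(x$p_value, digits = 3), "\n")
  if (x$degenerate) cat("  note: degenerate data (zero variance)\n")
  invisible(x)
}

#' Tidy a two-sample test result
#'
#' @param x A \code{dn_test} object.
#' @param ... Ignored.
#' @return A one-row tibble with columns \code{method},
#'   \code{statistic}, \code{df}, \code{p_value},
#'   \code{mean_difference}, \code{relative_effect}, \code{m}, \code{n},
#'   \code{degenerate}.
#' @method tidy dn_test
#' @export
tidy.dn_test <- function(x, ...) {
  tibble::tibble(
    method = x$method, statistic = x$statistic, df = x$df,
    p_value = x$p_value, mean_difference = x$mean_difference,
    relative_effect = x$relative_effect, m = x$m, n = x$n,
    degenerate = x$degenerate
  )
}

#' @rdname tidy.dn_test
#' @method glance dn_test
#' @export
glance.dn_test <- function(x, ...) tidy(x, ...)
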