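# 95% confidence intervals for the difference between two group means.
# Bootstrap limits use the order-statistic quantile with index
# ceiling(q * B) and no interpolation, so exhaustive enumeration oracles
# can mirror the convention exactly.

.new_dn_interval <- function(method, estimate, lower, upper, level, K,
                             n_resamples = NA_integer_,
                             degenerate = FALSE) {
  overshoot <- if (is.null(K)) NA else (lower < -K || upper > K)
  structure(
    list(method = method, estimate = estimate, lower = lower,
         upper = upper, level = level, K = if (is.null(K)) NA_integer_
         else as.integer(K),
         overshoot = overshoot, n_resamples = n_resamples,
         degenerate = degenerate),
    class = "dn_interval"
  )
}

# order-statistic quantile: value with index ceiling(q * B) in the sorted
# vector (clamped to 1..B); no interpolation
.os_quantile <- function(sorted_values, q) {
  B <- length(sorted_values)
  idx <- pmin(pmax(ceiling(q * B), 1L), B)
  sorted_values[idx]
}

#' Confidence intervals for the difference between group means
#'
#' Three 95% (by default) confidence interval methods for
#' \code{mean(x) - mean(y)} on a bounded count scale:
#' \describe{
#'   \item{\code{welch_interval()}}{the Welch U interval:
#'     \eqn{d \pm t_{\nu, 1-\alpha/2} \sqrt{s_1^2/m + s_2^2/n}} with
#'     Welch-Satterthwaite degrees of freedom \eqn{\nu}.}
#'   \item{\code{percentile_bootstrap_interval()}}{resample each group
#'     independently with replacement; the limits are the empirical
#'     \eqn{\alpha/2} and \eqn{1-\alpha/2} quantiles of the resampled
#'     mean differences.}
#'   \item{\code{bootstrap_t_interval()}}{studentised bootstrap: per
#'     resample \eqn{t^* = (d^* - d)/SE^*} with the Welch standard error
#'     of the resample; the interval is
#'     \eqn{[d - q^*_{1-\alpha/2} SE,\; d - q^*_{\alpha/2} SE]} with the
#'     observed Welch SE.}
#' }
#'
#' Bootstrap quantiles use the order statistic with index
#' \code{ceiling(q * B)} without interpolation. A resample with zero
#' Welch standard error contributes \eqn{t^* = 0} when its mean
#' difference equals the observed one and otherwise a sign-preserving
#' largest-representable value, so the resample distribution stays
#' complete and the computation deterministic. Degenerate observed data
#' (both variances zero) yield a zero-width interval at the estimate,
#' flagged via \code{degenerate}.
#'
#' When the scale maximum \code{K} is supplied, the result records
#' whether a limit overshoots the largest possible mean difference
#' \eqn{\pm K} (e.g. beyond \eqn{\pm 2} on the \{0,1,2\} scale).
#'
#' @param x,y Integer-valued vectors of per-subject counts for group 1
#'   and group 2 (at least 2 each).
#' @param level Confidence level, default 0.95.
#' @param K Scale maximum used for the overshoot flag; \code{NULL}
#'   (default) leaves the flag \code{NA}.
#' @param n_resamples Number of bootstrap resamples (default 2000).
#' @return An object of class \code{dn_interval} with elements
#'   \code{method}, \code{estimate}, \code{lower}, \code{upper},
#'   \code{level}, \code{K}, \code{overshoot}, \code{n_resamples},
#'   \code{degenerate}. Use [tidy()] for a one-row tibble.
#' @examples
#' standard <- expand_counts(c(19, 10, 7, 3, 6))
#' intensive <- expand_counts(c(39, 8, 8, 0, 0))
#' welch_interval(standard, intensive, K = 4)
#' @name difference_intervals
NULL

#' @rdname difference_intervals
#' @export
welch_interval <- function(x, y, level = 0.95, K = NULL) {
  .check_two_samples(x, y)
  co <- .welch_core(x, y)
  if (co$degenerate) {
    return(.new_dn_interval("welch", co$d, co$d, co$d, level, K,
                            degenerate = TRUE))
  }
  half <- qt(1 - (1 - level) / 2, co$df) * co$se
  .new_dn_interval("welch", co$d, co$d - half, co$d + half, level, K)
}

# one pass of within-group resampling; returns resampled mean differences
# and Welch standard errors
.boot_draws <- function(x, y, B) {
  m <- length(x); n <- length(y)
  xs <- matrix(sample(x, m * B, replace = TRUE), nrow = m)
  ys <- matrix(sample(y, n * B, replace = TRUE), nrow = n)
  mx <- colMeans(xs); my <- colMeans(ys)
  vx <- (colSums(xs^2) - m * mx^2) / (m - 1)
  vy <- (colSums(ys^2) - n * my^2) / (n - 1)
  # guard tiny negative values from floating-point cancellation
  vx[vx < 0] <- 0
  vy[vy < 0] <- 0
  list(dstar = mx - my, sestar = sqrt(vx / m + vy / n))
}

#' @rdname difference_intervals
#' @export
percentile_bootstrap_interval <- function(x, y, n_resamples = 2000,
                                          level = 0.95, K = NULL) {
  .check_two_samples(x, y)
  if (n_resamples < 2) stop("n_resamples must be >= 2", call. = FALSE)
  d <- mean(x) - mean(y)
  a <- 1 - level
  bs <- .boot_draws(x, y, n_resamples)
  lims <- .os_quantile(sort(bs$dstar), c(a / 2, 1 - a / 2))
  .new_dn_interval("pb", d, lims[1], lims[2], level, K,
                   n_resamples = as.integer(n_resamples),
                   degenerate = lims[1] == lims[2])
}

#' @rdname difference_intervals
#' @export
bootstrap_t_interval <- function(x, y, n_resamples = 2000, level = 0.95,
                                 K = NULL) {
  .check_two_samples(x, y)
  if (n_resamples < 2) stop("n_resamples must be >= 2", call. = FALSE)
  co <- .welch_core(x, y)
  if (co$se == 0) {
    return(.new_dn_interval("bt", co$d, co$d, co$d, level, K,
                            n_resamples = as.integer(n_resamples),
                            degenerate = TRUE))
  }
  a <- 1 - level
  bs <- .boot_draws(x, y, n_resamples)
  tstar <- .studentize(bs$dstar, bs$sestar, co$d)
  q <- .os_quantile(sort(tstar), c(a / 2, 1 - a / 2))
  .new_dn_interval("bt", co$d, co$d - q[2] * co$se, co$d - q[1] * co$se,
                   level, K, n_resamples = as.integer(n_resamples))
}

# t* = (d* - d)/SE*; zero-SE resamples get 0 when d* = d and otherwise a
# sign-preserving largest-representable value
.studentize <- function(dstar, sestar, d) {
  tstar <- ifelse(sestar > 0, (dstar - d) / sestar,
                  sign(dstar - d) * .Machine$double.xmax)
  tstar[sestar == 0 & dstar == d] <- 0
  tstar
}

#' Estimate the difference between group means from a data frame
#'
#' Data-frame-first interface to the interval methods; the estimate is
#' \code{mean(group1) - mean(group2)} with group 1 the first factor
#' level (or first-appearing value) of the grouping column.
#'
#' @inheritParams compare_groups
#' @param method One of \code{"welch"} (default), \code{"pb"}
#'   (percentile bootstrap), \code{"bt"} (bootstrap-t).
#' @param level Confidence level, default 0.95.
#' @param n_resamples Bootstrap resamples for \code{"pb"}/\code{"bt"}.
#' @param K Scale maximum for the overshoot flag (optional).
#' @return A \code{dn_interval} object; see [difference_intervals].
#' @export
estimate_difference <- function(data, value, group,
                                method = c("welch", "pb", "bt"),
                                level = 0.95, n_resamples = 2000,
                                K = NULL) {
  method <- match.arg(method)
  v <- rlang::eval_tidy(rlang::enquo(value), data)
  g <- rlang::eval_tidy(rlang::enquo(group), data)
  sp <- .split_two_groups(v, g)
  switch(method,
    "welch" = welch_interval(sp$x, sp$y, level, K),
    "pb" = percentile_bootstrap_interval(sp$x, sp$y, n_resamples, level, K),
    "bt" = bootstrap_t_interval(sp$x, sp$y, n_resamples, level, K)
  )
}

#' @export
print.dn_interval <- function(x, ...) {
  lbl <- c(welch = "Welch U interval",
           pb = "Percentile bootstrap interval",
           bt = "Bootstrap-t interval")[[x$method]]
  cat("\n\t", lbl, " (", x$level * 100, "% confidence)\n\n", sep = "")
  cat("  difference between means:", signif(x$estimate, 4), "\n")
  cat("  interval:", signif(x$lower, 4), "to", signif(x$upper, 4), "\n")
  if (!is.na(x$overshoot) && x$overshoot) {
    cat("  WARNING: limits overshoot the maximum possible difference +/-",
        x$K, "\n")
  }
  if (x$degenerate) cat("  note: zero-width interval (degenerate data)\n")
  invisible(x)
}

#' Tidy an interval result
#'
#' @param x A \code{dn_interval} object.
#' @param ... Ignored.
#' @return A one-row tibble with columns \code{method},
#'   \code{estimate}, \code{lower}, \code{upper}, \code{level},
#'   \code{overshoot}, \code{n_resamples}, \code{degenerate}.
#' @method tidy dn_interval
#' @export
tidy.dn_interval <- function(x, ...) {
  tibble::tibble(
    method = x$method, estimate = x$estimate, lower = x$lower,
    upper = x$upper, level = x$level, overshoot = x$overshoot,
    n_resamples = x$n_resamples, degenerate = x$degenerate
  )
}
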