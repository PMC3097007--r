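#' Discrete distribution families on a bounded count scale
#'
#' Constructs a probability mass function on the outcome scale
#' \{0, 1, ..., K\} belonging to one of six named shape families:
#' \describe{
#'   \item{uniform}{all g = K+1 values equally likely; mean K/2.}
#'   \item{normal}{symmetric unimodal, binomial(K, 1/2) weights; mean K/2.}
#'   \item{u-shaped}{symmetric with mass increasing towards both endpoints,
#'     weights proportional to 1 + |i - K/2|; mean K/2.}
#'   \item{linear-trend}{strictly linearly decreasing probabilities
#'     p_i = a - b*i, with (a, b) solved in closed form from
#'     normalisation and the target mean.}
#'   \item{step}{two-level piecewise-constant probabilities: a high level
#'     for values below \code{step_location} and a low level from
#'     \code{step_location} upwards, both solved in closed form.}
#'   \item{skewed}{right-skewed decreasing probabilities, a truncated
#'     geometric p_i proportional to r^i with the ratio r solved
#'     numerically to hit the target mean (tolerance 1e-10).}
#' }
#'
#' The symmetric families (uniform, normal, u-shaped) always have mean
#' K/2; supplying a different target mean is an error. On the \{0,1,2\}
#' scale no skewed family is defined; two step placements
#' (\code{step_location} 2 and 1) are used instead.
#'
#' @param family One of \code{"uniform"}, \code{"normal"},
#'   \code{"u-shaped"}, \code{"linear-trend"}, \code{"step"},
#'   \code{"skewed"}.
#' @param K Maximum outcome value; the scale is \{0, ..., K\}, K >= 1.
#' @param mean Target expected value. Required for the linear-trend, step
#'   and skewed families; must equal K/2 (the forced value) if supplied
#'   for a symmetric family.
#' @param step_location Step family only: the first value at which the
#'   low probability level applies (1 <= step_location <= K). Defaults to
#'   \code{ceiling((K + 1) / 2)}.
#' @param name Optional label used in simulation output tables; defaults
#'   to the family name.
#' @return An object of class \code{discrete_dist}: a list with elements
#'   \code{family}, \code{name}, \code{K}, \code{probs} (length K+1,
#'   summing to 1) and \code{step_location}.
#' @examples
#' make_distribution("linear-trend", K = 3, mean = 1.0)  # (0.4, 0.3, 0.2, 0.1)
#' make_distribution("step", K = 3, mean = 0.9)          # (0.4, 0.4, 0.1, 0.1)
#' @export
make_distribution <- function(family, K, mean = NULL, step_location = NULL,
                              name = family) {
  family <- match.arg(family, c("uniform", "normal", "u-shaped",
                                "linear-trend", "step", "skewed"))
  K <- .check_K(K)
  g <- K + 1L
  i <- 0:K

  symmetric <- family %in% c("uniform", "normal", "u-shaped")
  if (symmetric) {
    if (!is.null(mean) && abs(mean - K / 2) > 1e-9) {
      stop("family '", family, "' is symmetric on {0..", K,
           "}: its mean is forced to K/2 = ", K / 2, call. = FALSE)
    }
    mean <- K / 2
  } else if (is.null(mean)) {
    stop("a target mean is required for the '", family, "' family",
         call. = FALSE)
  }
  if (mean <= 0 || mean >= K) {
    stop("target mean must lie strictly inside (0, ", K, ")", call. = FALSE)
  }

  probs <- switch(family,
    "uniform" = rep(1 / g, g),
    "normal" = dbinom(i, K, 0.5),
    "u-shaped" = {
      w <- 1 + abs(i - K / 2)
      w / sum(w)
    },
    "linear-trend" = .linear_trend_probs(K, mean),
    "step" = {
      if (is.null(step_location)) step_location <- ceiling(g / 2)
      .step_probs(K, mean, step_location)
    },
    "skewed" = .skewed_probs(K, mean)
  )

  structure(
    list(family = family, name = name, K = K, probs = probs,
         step_location = if (family == "step") as.integer(step_location)),
    class = "discrete_dist"
  )
}

.check_K <- function(K) {
  if (length(K) != 1 || !is.finite(K) || K < 1 || K != round(K)) {
    stop("K must be a single integer >= 1", call. = FALSE)
  }
  as.integer(K)
}

# p_i = a - b*i with sum(p) = 1 and sum(i p_i) = mu; errors if any cell < 0
.linear_trend_probs <- function(K, mu) {
  i <- 0:K
  g <- K + 1
  s1 <- sum(i)
  s2 <- sum(i^2)
  # g*a - s1*b = 1 ; s1*a - s2*b = mu
  det <- -g * s2 + s1^2
  a <- (-s2 + s1 * mu) / det
  b <- (-s1 + g * mu) / det
  p <- a - b * i
  bad <- which(p < -1e-12)
  if (length(bad)) {
    stop("linear-trend pmf infeasible for K = ", K, ", mean = ", mu,
         ": probability of value ", bad[1] - 1, " is negative (",
         signif(p[bad[1]], 4), ")", call. = FALSE)
  }
  if (b <= 0) {
    stop("linear-trend requires a decreasing pmf; mean = ", mu,
         " on {0..", K, "} gives a non-decreasing solution", call. = FALSE)
  }
  pmax(p, 0) / sum(pmax(p, 0))
}

# two-level pmf: p_hi for i < s, p_lo for i >= s
.step_probs <- function(K, mu, s) {
  if (length(s) != 1 || s != round(s) || s < 1 || s > K) {
    stop("step_location must be an integer in 1..", K, call. = FALSE)
  }
  i <- 0:K
  g <- K + 1
  n_hi <- s
  n_lo <- g - s
  sum_hi <- sum(i[i < s])
  sum_lo <- sum(i[i >= s])
  # n_hi*p_hi + n_lo*p_lo = 1 ; sum_hi*p_hi + sum_lo*p_lo = mu
  det <- n_hi * sum_lo - n_lo * sum_hi
  p_hi <- (sum_lo - n_lo * mu) / det
  p_lo <- (n_hi * mu - sum_hi) / det
  if (p_hi < -1e-12 || p_lo < -1e-12) {
    cell <- if (p_hi < p_lo) "high" else "low"
    stop("step pmf infeasible for K = ", K, ", mean = ", mu,
         ", step_location = ", s, ": the ", cell,
         " level is negative", call. = FALSE)
  }
  p <- ifelse(i < s, p_hi, p_lo)
  pmax(p, 0) / sum(pmax(p, 0))
}

# truncated geometric p_i \propto r^i; solve r in (0, 1) for the mean
.skewed_probs <- function(K, mu) {
  if (K < 3) {
    stop("no skewed family is defined on {0..", K,
         "}; use two step placements instead", call. = FALSE)
  }
  if (mu >= K / 2) {
    stop("skewed (right-skewed geometric) requires mean < K/2", call. = FALSE)
  }
  i <- 0:K
  mean_of <- function(r) {
    w <- r^i
    sum(i * w) / sum(w)
  }
  r <- uniroot(function(r) mean_of(r) - mu, c(1e-12, 1 - 1e-12),
               tol = 1e-13)$root
  p <- r^i / sum(r^i)
  if (abs(sum(i * p) - mu) > 1e-10) {
    stop("skewed ratio solve did not reach the target mean", call. = FALSE)
  }
  p
}

#' Reference distribution set for a simulation scale
#'
#' Returns the six study distributions on the scale \{0, ..., K\} for
#' K in 2..5, with the standard expected values: the three symmetric
#' families at K/2; linear-trend at 0.63, 1.0, 1.25, 1.625; step at
#' 0.8, 0.9, 1.1, 1.6; and skewed at 0.6, 0.75, 0.88 for K >= 3. On the
#' \{0,1,2\} scale the skewed slot is taken by a second step placement
#' (\code{step2}, step_location 1, mean 0.6), alongside the first step
#' (step_location 2, mean 0.8).
#'
#' @param K Scale maximum, one of 2, 3, 4, 5.
#' @return A named list of six [make_distribution()] objects.
#' @examples
#' sapply(reference_distributions(3), function(d) dist_moments(d)[["mean"]])
#' @export
reference_distributions <- function(K) {
  K <- .check_K(K)
  if (!K %in% 2:5) {
    stop("reference distributions are defined for K in 2..5", call. = FALSE)
  }
  kc <- as.character(K)
  lt_mean <- c("2" = 0.63, "3" = 1.0, "4" = 1.25, "5" = 1.625)[[kc]]
  step_mean <- c("2" = 0.8, "3" = 0.9, "4" = 1.1, "5" = 1.6)[[kc]]
  out <- list(
    "uniform" = make_distribution("uniform", K),
    "normal" = make_distribution("normal", K),
    "u-shaped" = make_distribution("u-shaped", K),
    "linear-trend" = make_distribution("linear-trend", K, mean = lt_mean),
    "step" = make_distribution("step", K, mean = step_mean,
                               step_location = ceiling((K + 1) / 2))
  )
  if (K == 2) {
    out[["step2"]] <- make_distribution("step", K, mean = 0.6,
                                        step_location = 1, name = "step2")
  } else {
    sk_mean <- c("3" = 0.6, "4" = 0.75, "5" = 0.88)[[kc]]
    out[["skewed"]] <- make_distribution("skewed", K, mean = sk_mean)
  }
  for (nm in names(out)) out[[nm]]$name <- nm
  out
}

#' Mean and variance of a discrete distribution
#'
#' @param dist A [make_distribution()] object.
#' @return Named numeric vector with elements \code{mean} and
#'   \code{variance}.
#' @export
dist_moments <- function(dist) {
  stopifnot(inherits(dist, "discrete_dist"))
  i <- 0:dist$K
  m <- sum(i * dist$probs)
  v <- sum((i - m)^2 * dist$probs)
  c(mean = m, variance = v)
}

#' Draw a random sample from a discrete distribution
#'
#' Sampling uses R's global random number generator; set a seed with
#' [set.seed()] for reproducibility.
#'
#' @param dist A [make_distribution()] object.
#' @param n Number of draws, n >= 1.
#' @return Integer vector of length n with values in \{0, ..., K\}.
#' @export
sample_dist <- function(dist, n) {
  stopifnot(inherits(dist, "discrete_dist"))
  if (length(n) != 1 || !is.finite(n) || n < 1 || n != round(n)) {
    stop("n must be a single integer >= 1", call. = FALSE)
  }
  sample.int(dist$K + 1L, n, replace = TRUE, prob = dist$probs) - 1L
}

#' Read distribution overrides from a delimited file
#'
#' Each non-comment row gives one pmf as
#' \code{family, K, p_0, ..., p_K} (comma, tab or semicolon separated),
#' so externally specified probability vectors can replace the built-in
#' family constructions. Probabilities must be non-negative and sum to 1
#' within 1e-6 (they are renormalised to machine precision).
#'
#' @param path Path to the override file.
#' @return Named list of \code{discrete_dist} objects (named by family
#'   label; duplicate labels get a numeric suffix).
#' @export
read_distributions <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no distribution rows in ", path, call. = FALSE)
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "[,;\t]+")[[1]]
    parts <- trimws(parts)
    parts <- parts[nzchar(parts)]
    if (length(parts) < 4) {
      stop("malformed distribution row: '", ln, "'", call. = FALSE)
    }
    fam <- parts[1]
    K <- suppressWarnings(as.integer(parts[2]))
    p <- suppressWarnings(as.numeric(parts[-(1:2)]))
    if (is.na(K) || anyNA(p) || length(p) != K + 1) {
      stop("row '", ln, "': expected K and K+1 probabilities", call. = FALSE)
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6) {
      stop("row '", ln, "': probabilities must be >= 0 and sum to 1",
           call. = FALSE)
    }
    d <- structure(
      list(family = fam, name = fam, K = K, probs = p / sum(p),
           step_location = NULL),
      class = "discrete_dist"
    )
    nm <- fam
    k <- 1
    while (nm %in% names(out)) {
      k <- k + 1
      nm <- paste0(fam, k)
    }
    d$name <- nm
    out[[nm]] <- d
  }
  out
}

#' @export
print.discrete_dist <- function(x, ...) {
  mv <- dist_moments(x)
  cat("<discrete_dist> family:", x$family,
      if (!is.null(x$step_location)) paste0("(step at ", x$step_location, ")"),
      "on {0..", x$K, "}\n")
  cat("  probs:", paste(signif(x$probs, 4), collapse = " "), "\n")
  cat("  mean:", signif(mv[["mean"]], 6),
      " variance:", signif(mv[["variance"]], 6), "\n")
  invisible(x)
}

#' Plot a discrete distribution
#'
#' Bar chart of the probability mass function.
#'
#' @param object A \code{discrete_dist} object.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot discrete_dist
#' @export
autoplot.discrete_dist <- function(object, ...) {
  mv <- dist_moments(object)
  df <- tibble::tibble(value = 0:object$K, probability = object$probs)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$value),
                                   y = .data$probability)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "outcome value", y = "probability",
      title = paste0(object$name, " on {0..", object$K, "}"),
      subtitle = paste0("mean ", signif(mv[["mean"]], 4))
    ) +
    ggplot2::theme_minimal()
}
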