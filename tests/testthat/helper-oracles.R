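# Independent oracles used to cross-check the package's statistics.
# They re-derive every quantity from first principles (explicit mid-rank
# construction, exhaustive enumeration) and never call package internals.

# mid-ranks computed by averaging sorted positions of tied blocks
oracle_midranks <- function(v) {
  o <- order(v)
  s <- v[o]
  r <- numeric(length(v))
  i <- 1
  while (i <= length(v)) {
    j <- i
    while (j < length(v) && s[j + 1] == s[i]) j <- j + 1
    r[o[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}

# Brunner-Munzel statistic, df and p transliterated step by step from the
# defining rank formulas
oracle_bm <- function(x, y) {
  m <- length(x)
  n <- length(y)
  N <- m + n
  R <- oracle_midranks(c(x, y))
  R1 <- R[1:m]
  R2 <- R[(m + 1):N]
  Rbar1 <- sum(R1) / m
  Rbar2 <- sum(R2) / n
  Rw1 <- oracle_midranks(x)
  Rw2 <- oracle_midranks(y)
  S1sq <- sum((R1 - Rw1 - Rbar1 + (m + 1) / 2)^2) / (m - 1)
  S2sq <- sum((R2 - Rw2 - Rbar2 + (n + 1) / 2)^2) / (n - 1)
  W <- m * n * (Rbar2 - Rbar1) / (N * sqrt(m * S1sq + n * S2sq))
  nu <- (m * S1sq + n * S2sq)^2 /
    ((m * S1sq)^2 / (m - 1) + (n * S2sq)^2 / (n - 1))
  list(W = W, df = nu, p = 2 * stats::pt(-abs(W), nu),
       phat = (Rbar2 - Rbar1) / N + 0.5)
}

# exact permutation distribution of the group-1 rank sum over all
# C(N, m) assignments
exact_wmw_ranksums <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x)
  N <- length(pooled)
  r <- oracle_midranks(pooled)
  combs <- utils::combn(N, m)
  apply(combs, 2, function(idx) sum(r[idx]))
}

# exact two-sided WMW p: proportion of assignments at least as extreme
# (in |rank sum - null mean|) as observed
exact_wmw_p <- function(x, y) {
  m <- length(x)
  N <- length(x) + length(y)
  W <- exact_wmw_ranksums(x, y)
  obs <- abs(sum(oracle_midranks(c(x, y))[1:m]) - m * (N + 1) / 2)
  mean(abs(W - m * (N + 1) / 2) >= obs - 1e-9)
}

# |BM statistic| with the degenerate convention (0 when rank means tie,
# Inf otherwise), for permutation enumeration
oracle_abs_bm <- function(x, y) {
  m <- length(x)
  n <- length(y)
  N <- m + n
  R <- oracle_midranks(c(x, y))
  Rbar1 <- mean(R[1:m])
  Rbar2 <- mean(R[(m + 1):N])
  S1sq <- sum((R[1:m] - oracle_midranks(x) - Rbar1 + (m + 1) / 2)^2) /
    (m - 1)
  S2sq <- sum((R[(m + 1):N] - oracle_midranks(y) - Rbar2 +
                 (n + 1) / 2)^2) / (n - 1)
  den <- m * S1sq + n * S2sq
  if (den <= 0) {
    return(if (Rbar1 == Rbar2) 0 else Inf)
  }
  abs(m * n * (Rbar2 - Rbar1) / (N * sqrt(den)))
}

# exact BM permutation p over all C(N, m) label assignments
exact_bm_perm_p <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x)
  N <- length(pooled)
  obs <- oracle_abs_bm(x, y)
  combs <- utils::combn(N, m)
  stats <- apply(combs, 2, function(idx) {
    oracle_abs_bm(pooled[idx], pooled[-idx])
  })
  mean(stats >= obs - 1e-12)
}

# all resample mean/variance pairs for a sample of size 3 (27 index
# triples with replacement)
.enum_resamples3 <- function(v) {
  stopifnot(length(v) == 3)
  g <- expand.grid(1:3, 1:3, 1:3)
  t(apply(g, 1, function(i) {
    s <- v[unlist(i)]
    c(mean = mean(s), var = stats::var(s))
  }))
}

# exhaustive bootstrap distribution for m = n = 3: the 729 equally
# likely resample pairs, each with its mean difference and Welch SE
enum_boot_pairs <- function(x, y) {
  a <- .enum_resamples3(x)
  b <- .enum_resamples3(y)
  idx <- expand.grid(i = 1:27, j = 1:27)
  dstar <- a[idx$i, "mean"] - b[idx$j, "mean"]
  sestar <- sqrt(a[idx$i, "var"] / 3 + b[idx$j, "var"] / 3)
  list(dstar = dstar, sestar = sestar)
}

# order-statistic quantile (index ceiling(q * B), no interpolation) of
# an exhaustively enumerated, equally likely set of values
enum_quantile <- function(values, q) {
  s <- sort(values)
  B <- length(s)
  s[pmin(pmax(ceiling(q * B), 1), B)]
}

# plausible band for a Monte-Carlo estimate of the q-quantile at B
# resamples: the exact quantiles at q +/- 3 binomial standard errors
enum_quantile_band <- function(values, q, B) {
  se <- 3 * sqrt(q * (1 - q) / B)
  enum_quantile(values, c(max(q - se, 0), min(q + se, 1)))
}
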