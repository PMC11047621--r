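# Nonparametric machinery for the paired TNC/VNC comparison: normality
# gate, exact rank tests, pairing effectiveness. The rank tests carry
# their exact tie-aware null distributions (count convolution) so that
# small-sample p-values agree with full enumeration.

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the null z-scores of sample skewness (D'Agostino's
#' transformation) and kurtosis (Anscombe-Glynn) into
#' `K2 = z_skew^2 + z_kurt^2`, referred to a chi-square with 2 df. Used as
#' the gate that routes metrics to nonparametric tests.
#'
#' @param values numeric sample, n >= 8.
#' @return an object of class `htest` with the K2 statistic and p-value.
#' @export
dagostino_pearson <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 8) stop("insufficient sample: D'Agostino-Pearson needs n >= 8")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 == 0) stop("zero variance: normality test undefined")
  g1 <- mean((values - m)^3) / m2^1.5
  b2 <- mean((values - m)^4) / m2^2

  # skewness z (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis z (Anscombe-Glynn 1983)
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  aa <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  term <- (1 - 2 / aa) / (1 + xx * sqrt(2 / (aa - 4)))
  z2 <- ((1 - 2 / (9 * aa)) - sign(term) * abs(term)^(1 / 3)) /
    sqrt(2 / (9 * aa))

  k2 <- z1^2 + z2^2
  structure(list(statistic = c(K2 = k2),
                 parameter = c(df = 2),
                 p.value = pchisq(k2, df = 2, lower.tail = FALSE),
                 method = "D'Agostino-Pearson omnibus normality test",
                 data.name = deparse(substitute(values))),
            class = "htest")
}

# exact null counts of a sum of optionally-included items (doubled
# midranks, so all integers): counts[s + 1] = number of subsets summing s
sum_distribution <- function(items) {
  f <- 1
  for (r in items) {
    g <- numeric(length(f) + r)
    g[seq_along(f)] <- f
    g[seq_along(f) + r] <- g[seq_along(f) + r] + f
    f <- g
  }
  f
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on the per-pair differences `y - x`
#' (VNC minus TNC by convention, so a VNC-lowering effect gives a negative
#' median of differences). Zero differences are discarded before ranking
#' (classic Wilcoxon, `zero_method = "wilcox"`) or handled by Pratt's
#' method. The null distribution is exact (tie-aware, by count
#' convolution over the signed midranks) for up to `exact_limit` nonzero
#' pairs, and a tie-corrected normal approximation with continuity
#' correction beyond that. The exact two-sided p-value is
#' `min(1, 2 * min(P(W <= w), P(W >= w)))` and matches full enumeration of
#' all sign assignments.
#'
#' @param x,y equal-length paired samples (x = TNC, y = VNC).
#' @param exact_limit largest number of nonzero pairs for the exact null.
#' @param zero_method `"wilcox"` (discard zero differences, default) or
#'   `"pratt"` (rank them, then drop their ranks).
#' @return list of class `paired_wilcoxon`: `statistic` (W+, sum of
#'   positive ranks), `p_value`, `n` (pairs used), `n_zero`,
#'   `median_of_differences` (over all pairs), `method`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_limit = 25L,
                                 zero_method = c("wilcox", "pratt")) {
  zero_method <- match.arg(zero_method)
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  d <- y - x
  med <- median(d)
  if (zero_method == "wilcox") {
    dz <- d[d != 0]
    r <- rank(abs(dz))
  } else {
    dz <- d[d != 0]
    rall <- rank(abs(d))
    r <- rall[d != 0]
  }
  n <- length(dz)
  if (n == 0L)
    stop("degenerate pairs: all differences are zero")
  w <- sum(r[dz > 0])

  ties <- table(r)
  if (n <= exact_limit) {
    r2 <- as.integer(round(2 * r))
    counts <- sum_distribution(r2)
    total <- 2^n
    w2 <- as.integer(round(2 * w))
    cl <- sum(counts[seq_len(w2 + 1L)])
    cg <- sum(counts[(w2 + 1L):length(counts)])
    p <- min(1, 2 * min(cl, cg) / total)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation"
  }
  structure(list(statistic = w, p_value = p, n = n,
                 n_zero = sum(d == 0), median_of_differences = med,
                 method = method, test_name = "Wilcoxon signed-rank"),
            class = "paired_wilcoxon")
}

#' @export
print.paired_wilcoxon <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank (%s): W+ = %g, n = %d, p = %.4g\n",
              x$method, x$statistic, x$n, x$p_value))
  cat(sprintf("  median of differences = %g\n", x$median_of_differences))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test for two independent groups, reported as
#' `U = min(U_a, U_b)` with ties handled by midranks. The null is exact
#' (by subset-sum counting over the ranks) for tie-free samples with
#' `m + n <= exact_limit`, and a tie-corrected normal approximation with
#' continuity correction otherwise. `U_a` equals the number of pairs
#' `(i, j)` with `a_i > b_j` counting ties as one half.
#'
#' @param a,b numeric samples.
#' @param exact_limit largest combined size for the exact null.
#' @return list of class `mann_whitney`: `statistic` (min U), `U_a`, `U_b`,
#'   `p_value`, `method`.
#' @export
mann_whitney_u <- function(a, b, exact_limit = 20L) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  m <- length(a); n <- length(b)
  if (m == 0L || n == 0L) stop("empty group: Mann-Whitney U undefined")
  r <- rank(c(a, b))
  ra <- sum(r[seq_len(m)])
  ua <- ra - m * (m + 1) / 2
  ub <- m * n - ua
  u <- min(ua, ub)
  has_ties <- anyDuplicated(c(a, b)) > 0L
  N <- m + n
  if (!has_ties && N <= exact_limit) {
    # distribution of rank-sum of group a over all size-m subsets of 1..N
    f <- matrix(0, nrow = m + 1L, ncol = N * (N + 1) / 2 + 1L)
    f[1L, 1L] <- 1
    for (i in seq_len(N)) {
      for (k in rev(seq_len(min(i, m)))) {
        idx <- (i + 1L):ncol(f)
        f[k + 1L, idx] <- f[k + 1L, idx] + f[k, idx - i]
      }
    }
    counts <- f[m + 1L, ]
    total <- choose(N, m)
    ra_int <- as.integer(round(ra))
    cl <- sum(counts[seq_len(ra_int + 1L)])   # P(Ra <= ra), sums 0..ra
    cg <- sum(counts[(ra_int + 1L):ncol(f)])
    p <- min(1, 2 * min(cl, cg) / total)
    method <- "exact"
  } else {
    ties <- table(r)
    mu <- m * n / 2
    sig2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sig2 <= 0) {
      # every value tied: the test carries no information
      p <- 1
      method <- "degenerate (all values tied)"
    } else {
      z <- (ua - mu - sign(ua - mu) * 0.5) / sqrt(sig2)
      p <- min(1, 2 * pnorm(-abs(z)))
      method <- if (has_ties) "normal approximation (tie-corrected)"
                else "normal approximation"
    }
  }
  structure(list(statistic = u, U_a = ua, U_b = ub, p_value = p,
                 n_a = m, n_b = n, method = method,
                 test_name = "Mann-Whitney U"),
            class = "mann_whitney")
}

#' @export
print.mann_whitney <- function(x, ...) {
  cat(sprintf("Mann-Whitney U (%s): U = %g (U_a = %g, U_b = %g), p = %.4g\n",
              x$method, x$statistic, x$U_a, x$U_b, x$p_value))
  invisible(x)
}

#' Effectiveness of pairing
#'
#' The Pearson correlation between the paired measurements, the `r`
#' commonly reported next to paired tests as a measure of how informative
#' the pairing is.
#'
#' @param x,y paired samples, n >= 3, both with nonzero variance.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pairing_effectiveness <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("pairing effectiveness needs n >= 3")
  if (sd(x) == 0 || sd(y) == 0)
    stop("undefined correlation: zero variance in one member")
  cor(x, y)
}
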