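test_that("signed-rank test matches exact enumeration on random instances", {
  set.seed(11)
  for (i in 1:120) {
    n <- sample(3:10, 1)
    x <- round(rnorm(n, 0, 5), 1)
    y <- round(x + rnorm(n, 0.5, 3), 1)
    if (all(y == x)) next
    got <- wilcoxon_signed_rank(x, y)
    ref <- enum_wilcoxon(x, y)
    expect_identical(got$statistic, ref$statistic)
    expect_identical(got$p_value, ref$p)
  }
})

test_that("signed-rank edge cases: shift, degeneracy, zero handling", {
  x <- rnorm(10)
  got <- wilcoxon_signed_rank(x, x + 1)
  expect_identical(got$p_value, 2 / 2^10)  # smallest attainable, n = 10
  expect_identical(got$statistic, 55)
  expect_error(wilcoxon_signed_rank(x, x), "degenerate")

  # zero differences are discarded before ranking
  x2 <- c(1, 2, 3, 4, 5)
  y2 <- c(1, 2, 3, 6, 7)
  got2 <- wilcoxon_signed_rank(x2, y2)
  expect_identical(got2$n, 2L)
  expect_identical(got2$n_zero, 3L)
  expect_identical(got2$median_of_differences, 0)

  # large n switches to the tie-corrected normal approximation
  set.seed(2)
  x3 <- rnorm(60); y3 <- x3 + rnorm(60, 0.8)
  got3 <- wilcoxon_signed_rank(x3, y3)
  expect_identical(got3$method, "normal approximation")
  ref3 <- stats::wilcox.test(y3, x3, paired = TRUE, exact = FALSE,
                             correct = TRUE)
  expect_equal(got3$p_value, ref3$p.value, tolerance = 1e-10)
})

test_that("Mann-Whitney U matches enumeration and handles ties by midranks", {
  set.seed(13)
  for (i in 1:120) {
    m <- sample(2:8, 1); n <- sample(2:8, 1)
    a <- rnorm(m); b <- rnorm(n, 0.5)   # continuous: tie-free
    got <- mann_whitney_u(a, b)
    ref <- enum_mann_whitney(a, b)
    expect_identical(got$U_a, ref$U_a)
    expect_identical(got$statistic, ref$U)
    expect_identical(got$p_value, ref$p)
  }

  # U conventions
  expect_identical(mann_whitney_u(c(1, 2), c(3, 4))$statistic, 0)
  a <- c(1, 2, 2, 5)
  expect_identical(mann_whitney_u(a, a)$U_a, length(a)^2 / 2)
  # tie-aware U equals the half-counted pairwise wins
  set.seed(5)
  for (i in 1:30) {
    a <- sample(1:4, 6, replace = TRUE)
    b <- sample(1:4, 5, replace = TRUE)
    got <- mann_whitney_u(a, b)
    expect_identical(got$U_a, sum(outer(a, b, ">")) +
                       0.5 * sum(outer(a, b, "==")))
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "empty group")
})

test_that("normality gate flags skew, rejects tiny n, matches scipy", {
  set.seed(21)
  heavy <- rexp(500)^2
  expect_lt(dagostino_pearson(heavy)$p.value, 0.05)
  expect_error(dagostino_pearson(rnorm(5)), "n >= 8")

  x <- round(rnorm(200, 10, 2), 6)
  got <- dagostino_pearson(x)
  py <- paste(
    "import sys, json",
    "from scipy import stats",
    "x = [float(v) for v in sys.stdin.read().split()]",
    "k2, p = stats.normaltest(x)",
    "print(json.dumps({'k2': float(k2), 'p': float(p)}))",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(py)),
                 input = paste(format(x, digits = 17), collapse = " "),
                 stdout = TRUE)
  ref <- jsonlite::fromJSON(paste(out, collapse = ""))
  expect_equal(unname(got$statistic), ref$k2, tolerance = 1e-8)
  expect_equal(got$p.value, ref$p, tolerance = 1e-8)
})

test_that("pairing effectiveness is the Pearson r of the pairs", {
  x <- rnorm(20)
  expect_equal(pairing_effectiveness(x, 2 * x + 3), 1)
  expect_equal(pairing_effectiveness(x, -x), -1)
  expect_error(pairing_effectiveness(x, rep(1, 20)), "zero variance")
  expect_error(pairing_effectiveness(1:2, 2:3), "n >= 3")
  set.seed(31)
  z <- rnorm(1e4); e <- rnorm(1e4)
  xs <- z; ys <- 0.8 * z + sqrt(1 - 0.8^2) * e
  expect_equal(pairing_effectiveness(xs, ys), 0.8, tolerance = 0.02)
})
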