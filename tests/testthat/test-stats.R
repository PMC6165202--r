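# Independent enumeration oracles used below are built in the test file
# itself: sign-flip enumeration for the signed-rank test, and rank-matrix
# enumeration (via stats::friedman.test as an independent statistic
# implementation) for the Friedman permutation null.

test_that("Friedman test handles ties, perfect orderings and matches stats::friedman.test", {
  tied <- matrix(5, 4, 3)
  res <- friedman_test(tied)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # perfectly consistent ordering, k = 4, n = 10 -> Q = 30
  consistent <- matrix(rep(c(1, 2, 3, 4), each = 10), 10, 4)
  consistent <- consistent + matrix(runif(40, 0, 0.01), 10, 4) * 0  # exact
  resc <- friedman_test(consistent)
  expect_equal(resc$statistic, 30, tolerance = 1e-12)
  expect_equal(resc$df, 3)

  withr::with_seed(13, {
    for (i in 1:5) {
      m <- matrix(rnorm(15 * 4), 15, 4)
      mine <- friedman_test(m)
      ref <- stats::friedman.test(m)
      expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    }
  })
  expect_error(friedman_test(matrix(1, 1, 3)), ">= 2")
})

test_that("exact Friedman p matches full permutation enumeration on a 3x3 table", {
  scores <- matrix(c(1, 5, 2,
                     4, 6, 3,
                     2, 9, 1), 3, 3, byrow = TRUE)
  mine <- friedman_test(scores, exact = TRUE)

  # oracle: every row's rank order is equally likely under the null;
  # enumerate all 6^3 rank tables, statistic via stats::friedman.test
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  stat_of <- function(m) unname(suppressWarnings(stats::friedman.test(m)$statistic))
  q_obs <- stat_of(scores)
  count <- 0
  for (a in perms) for (b in perms) for (cc in perms) {
    q <- stat_of(rbind(a, b, cc))
    if (q >= q_obs - 1e-12) count <- count + 1
  }
  expect_equal(mine$p_value, count / 216, tolerance = 1e-12)
  expect_error(friedman_test(rbind(c(1, 1, 2), c(3, 4, 5)), exact = TRUE),
               "ties")
})

test_that("Friedman type-I error under the null is near the nominal level", {
  n_tab <- 10000
  withr::with_seed(14, {
    rej <- 0
    for (i in seq_len(n_tab)) {
      q <- earbci:::friedman_statistic(matrix(rnorm(15 * 4), 15, 4))
      if (pchisq(q, 3, lower.tail = FALSE) < 0.05) rej <- rej + 1
    }
    expect_lt(abs(rej / n_tab - 0.05), 0.01)
  })
})

test_that("Wilcoxon signed-rank statistic and exact p behave as specified", {
  # all six differences positive: W = 0, exact two-sided p = 2/2^6
  res <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6, 7), c(1, 2, 3, 4, 5, 6))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 2 / 64, tolerance = 1e-12)

  # single informative pair: p = 1 two-sided
  x <- c(1, 2, 3); y <- c(1, 2, 5)
  r1 <- wilcoxon_signed_rank(x, y)
  expect_equal(r1$n, 1)
  expect_equal(r1$p_value, 1)

  # antisymmetry
  withr::with_seed(15, {
    a <- rnorm(9); b <- rnorm(9)
    expect_equal(wilcoxon_signed_rank(a, b)$p_value,
                 wilcoxon_signed_rank(b, a)$p_value, tolerance = 1e-12)
  })
  expect_error(wilcoxon_signed_rank(c(1, 2), c(1, 2)), "zero")
  expect_error(wilcoxon_signed_rank(1:3, 1:2), "equal length")
})

test_that("exact Wilcoxon p matches 2^n sign-flip enumeration", {
  # oracle: enumerate every sign assignment of the ranked |d|, build the
  # exact W+ distribution, and form the symmetric two-sided p
  enum_p <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    w_plus <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- signs %*% r
    p_le <- mean(w_all <= w_plus)
    p_ge <- mean(w_all >= w_plus)
    min(1, 2 * min(p_le, p_ge))
  }
  withr::with_seed(16, {
    for (n in c(6, 8, 10)) {
      x <- rnorm(n); y <- rnorm(n)
      mine <- wilcoxon_signed_rank(x, y)
      expect_equal(mine$p_value, enum_p(x - y), tolerance = 1e-10)
      # for untied data the enumeration agrees with the classical exact test
      ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
    }
  })
})

test_that("Bonferroni correction divides the level by the comparison count", {
  expect_equal(bonferroni(0.05, 4), 0.0125)
  expect_equal(bonferroni(0.05, 1), 0.05)
  expect_equal(bonferroni(0.05, 6), 0.05 / 6)
  expect_error(bonferroni(0.05, 0), "m")
})

test_that("pairwise post-hocs cover all condition pairs with corrected level", {
  withr::with_seed(17, {
    m <- matrix(rnorm(10 * 4), 10, 4,
                dimnames = list(NULL, c("frontal", "central", "occipital", "ear")))
    ph <- pairwise_wilcoxon(m)
    expect_equal(nrow(ph), 6)
    expect_equal(unique(ph$corrected_alpha), 0.05 / 6)
    expect_true(all(ph$p_value >= 0 & ph$p_value <= 1))
  })
})

test_that("Friedman statistic is invariant under monotone per-subject transforms", {
  withr::with_seed(18, {
    m <- matrix(rnorm(8 * 4), 8, 4)
    q1 <- friedman_test(m)$statistic
    m2 <- t(apply(m, 1, function(r) exp(3 * r) + 2))   # strictly increasing
    expect_equal(friedman_test(m2)$statistic, q1, tolerance = 1e-12)
  })
})
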