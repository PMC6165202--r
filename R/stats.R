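# Group-level statistics across regions of interest: Friedman test on the
# subjects x conditions score table, Wilcoxon signed-rank post-hocs, and
# Bonferroni correction of the significance level.

#' Friedman rank test for repeated measures
#'
#' Within-subject ranks (ties averaged) with the tie-corrected chi-square
#' statistic; the p-value comes from the chi-square approximation with
#' `k - 1` degrees of freedom, or from exhaustive enumeration of the
#' within-subject rank permutations when `exact = TRUE` (feasible for small
#' tables, and only defined without ties). A fully tied table returns
#' statistic 0 and p = 1.
#'
#' @param scores Numeric matrix or data frame, subjects x conditions
#'   (>= 2 of each).
#' @param exact Enumerate the exact permutation null distribution
#'   (requires `factorial(k)^n <= 1e6` and no within-subject ties).
#' @return A tibble: `test`, `statistic`, `df`, `p_value`, `n`, `k`.
#' @export
friedman_test <- function(scores, exact = FALSE) {
  scores <- as.matrix(scores)
  n <- nrow(scores); k <- ncol(scores)
  if (n < 2 || k < 2) abort("need >= 2 subjects and >= 2 conditions")
  q <- friedman_statistic(scores)
  if (exact) {
    if (factorial(k)^n > 1e6) abort("table too large for exact enumeration")
    if (any(apply(scores, 1, function(r) anyDuplicated(r) > 0))) {
      abort("exact mode requires no within-subject ties")
    }
    p <- friedman_exact_p(scores)
  } else {
    p <- if (is.na(q)) 1 else stats::pchisq(q, df = k - 1, lower.tail = FALSE)
  }
  tibble::tibble(test = paste0("friedman", if (exact) "_exact" else ""),
                 statistic = if (is.na(q)) 0 else q,
                 df = k - 1, p_value = p, n = n, k = k)
}

# Tie-corrected Friedman chi-square statistic:
# Q = 12 sum_j (R_j - n(k+1)/2)^2 / [n k (k+1) - sum(t^3 - t) / (k - 1)]
# with R_j the rank sums and t the tie-group sizes per subject. NA when the
# tie correction exhausts the denominator (all scores tied within subjects).
friedman_statistic <- function(scores) {
  n <- nrow(scores); k <- ncol(scores)
  r <- t(apply(scores, 1, rank))
  ties <- apply(r, 1, function(row) {
    t_sizes <- table(row)
    sum(t_sizes^3 - t_sizes)
  })
  denom <- n * k * (k + 1) - sum(ties) / (k - 1)
  if (denom <= .Machine$double.eps) return(NA_real_)
  12 * sum((colSums(r) - n * (k + 1) / 2)^2) / denom
}

# Exact permutation p-value: each subject's rank vector is, under the null,
# uniform over the k! orderings; enumerate all combinations.
friedman_exact_p <- function(scores) {
  n <- nrow(scores); k <- ncol(scores)
  q_obs <- friedman_statistic(scores)
  if (is.na(q_obs)) return(1)
  perms <- all_permutations(k)
  np <- nrow(perms)
  idx <- rep(1L, n)
  total <- np^n
  count <- 0L
  base_ranks <- matrix(0, n, k)
  repeat {
    for (i in seq_len(n)) base_ranks[i, ] <- perms[idx[i], ]
    q <- friedman_statistic(base_ranks)
    if (!is.na(q) && q >= q_obs - 1e-12) count <- count + 1L
    # odometer increment
    j <- 1L
    while (j <= n) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= np) break
      idx[j] <- 1L
      j <- j + 1L
    }
    if (j > n) break
  }
  count / total
}

all_permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(pos) {
    cbind(sub[, seq_len(pos - 1), drop = FALSE], k,
          sub[, seq(pos, k - 1)[seq_len(k - pos)], drop = FALSE])
  }))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided signed-rank test on the paired differences, zero differences
#' dropped. The statistic is `min(W+, W-)`. For `n <= exact_n` the p-value
#' is exact, by enumeration of all `2^n` sign assignments of the ranked
#' absolute differences (which handles tied ranks exactly); for larger n
#' the normal approximation with continuity correction is used (ties
#' handled by [stats::wilcox.test()]'s variance correction).
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param exact_n Largest n for which the exact distribution is used.
#' @return A tibble: `test`, `statistic` (min signed-rank sum), `p_value`,
#'   `n` (non-zero differences).
#' @export
wilcoxon_signed_rank <- function(x, y, exact_n = 15) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) abort("all differences are zero")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  if (n <= exact_n) {
    # exact sign-flip enumeration: W+ distribution over all 2^n patterns
    w_all <- 0
    for (ri in r) w_all <- c(w_all, w_all + ri)   # subset-sum expansion
    p <- min(1, 2 * min(mean(w_all <= w_plus + 1e-12),
                        mean(w_all >= w_plus - 1e-12)))
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(d, exact = FALSE, correct = TRUE)$p.value
    )
  }
  tibble::tibble(test = "wilcoxon_signed_rank",
                 statistic = min(w_plus, w_minus),
                 p_value = p, n = n)
}

#' Bonferroni-corrected significance level
#'
#' @param alpha Family-wise level (default 0.05).
#' @param m Number of comparisons (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni <- function(alpha = 0.05, m) {
  if (m < 1) abort("m must be >= 1")
  alpha / m
}

#' Pairwise Wilcoxon post-hocs over conditions
#'
#' All pairwise two-sided signed-rank tests between the columns of a
#' subjects x conditions table, with the Bonferroni-corrected level
#' attached.
#'
#' @param scores Numeric matrix or data frame, subjects x conditions with
#'   column names.
#' @param alpha Family-wise significance level.
#' @return A tibble: `comparison`, `statistic`, `p_value`, `n`,
#'   `corrected_alpha`, `significant`.
#' @export
pairwise_wilcoxon <- function(scores, alpha = 0.05) {
  scores <- as.matrix(scores)
  cond <- colnames(scores)
  pairs <- utils::combn(cond, 2, simplify = FALSE)
  alpha_c <- bonferroni(alpha, length(pairs))
  purrr::map_dfr(pairs, function(pr) {
    res <- wilcoxon_signed_rank(scores[, pr[1]], scores[, pr[2]])
    tibble::tibble(comparison = paste(pr, collapse = " vs "),
                   statistic = res$statistic, p_value = res$p_value,
                   n = res$n, corrected_alpha = alpha_c,
                   significant = res$p_value < alpha_c)
  })
}
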