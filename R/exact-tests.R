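#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditional on both margins, the two-sided p-value is the sum of
#' hypergeometric probabilities of all tables whose probability does not
#' exceed that of the observed table (the minimum-likelihood definition,
#' with a 1e-12 relative slack for floating-point ties).
#'
#' @param table A 2x2 matrix of non-negative integer counts
#'   (responders/non-responders by group), or a length-4 vector
#'   \code{c(a, b, c, d)} filled row-wise.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact(matrix(c(2, 0, 0, 2), 2, byrow = TRUE))  # 1/3
#' @export
fisher_exact <- function(table) {
  x <- if (is.matrix(table)) as.vector(t(table)) else as.vector(table)
  .assert(length(x) == 4L, "table must be 2x2 (4 counts)")
  .assert(all(is.finite(x)) && all(x >= 0) && all(x == round(x)),
          "counts must be non-negative integers")
  .assert(sum(x) > 0, "all-zero table: no data to test")
  a <- x[1]; b <- x[2]; cc <- x[3]; d <- x[4]
  m <- a + b      # row 1 margin
  n2 <- cc + d    # row 2 margin
  k <- a + cc     # column 1 margin
  # a zero margin admits a single table conditional on the margins
  if (m == 0 || n2 == 0 || k == 0 || b + d == 0) return(1)
  support <- max(0, k - n2):min(k, m)
  probs <- dhyper(support, m, n2, k)
  p_obs <- dhyper(a, m, n2, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' The exact beta-quantile interval for a binomial proportion. The lower
#' bound is 0 when there are no successes and the upper bound is 1 when all
#' trials succeed.
#'
#' @param successes Number of successes (0..n).
#' @param n Number of trials (>= 1).
#' @param level Confidence level in (0, 1); default 0.95.
#' @return Numeric vector \code{c(lo, hi)}.
#' @examples
#' clopper_pearson(0, 1)  # c(0, 0.975)
#' @export
clopper_pearson <- function(successes, n, level = 0.95) {
  .assert(length(successes) == 1L && length(n) == 1L &&
            is.finite(successes) && is.finite(n), "scalar inputs required")
  .assert(n >= 1 && n == round(n), "n must be a positive integer")
  .assert(successes >= 0 && successes <= n && successes == round(successes),
          "successes must be an integer in [0, n]")
  .assert(is.numeric(level) && length(level) == 1L && level > 0 && level < 1,
          "level must be in (0, 1)")
  alpha <- 1 - level
  lo <- if (successes == 0) 0 else qbeta(alpha / 2, successes, n - successes + 1)
  hi <- if (successes == n) 1 else qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(lo = lo, hi = hi)
}

# all permutations of 1..n as an (n! x n) index matrix; used only for the
# exact small-sample Spearman p-value, so n stays below 10
.all_perms <- function(n) {
  rec <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1L, 1L))
    do.call(rbind, lapply(seq_along(v),
                          function(i) cbind(v[i], rec(v[-i]))))
  }
  rec(seq_len(n))
}

#' Spearman rank correlation with a documented p-value policy
#'
#' Rank correlation with midrank ties. The two-sided p-value uses the
#' t-approximation \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on \eqn{n-2} df for
#' \code{n >= 10}, and full enumeration of all \code{n!} permutations for
#' \code{n < 10} (two-sided: fraction of permutations with \code{|rho|} at
#' least the observed value).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with \code{rho}, \code{p}, \code{n} and \code{estimable}
#'   (\code{FALSE}, with \code{rho = NA}, when either vector is constant).
#' @export
spearman_cor <- function(x, y) {
  .assert(is.numeric(x) && is.numeric(y), "x and y must be numeric")
  .assert(length(x) == length(y), "x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  .assert(n >= 3L, "need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, estimable = FALSE))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n < 10L) {
    perms <- .all_perms(n)
    ry_mat <- matrix(ry[perms], nrow = nrow(perms))
    # cor(rx, ry[perm]) is affine in the cross-sum since rank moments are
    # permutation-invariant
    rhos <- as.vector(ry_mat %*% (rx - mean(rx))) / ((n - 1) * sd(rx) * sd(ry))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n, estimable = TRUE)
}

#' Compare two groups: Wilcoxon rank-sum or Pearson chi-squared
#'
#' Continuous values are compared by the two-sided Wilcoxon rank-sum test
#' (midranks, normal approximation with tie correction and continuity
#' correction); categorical values by the Pearson chi-squared test without
#' continuity correction.
#'
#' @param values Numeric vector (continuous) or factor/character
#'   (categorical).
#' @param group Two-level grouping vector of the same length.
#' @return List with \code{p}, \code{method} and \code{statistic}.
#' @export
group_compare <- function(values, group) {
  .assert(length(values) == length(group), "values and group lengths differ")
  g <- factor(group)
  .assert(nlevels(g) == 2L, "group must have exactly two levels")
  .assert(all(table(g) >= 1L), "each group needs at least one observation")
  if (is.numeric(values)) {
    wt <- suppressWarnings(
      wilcox.test(values[g == levels(g)[1]], values[g == levels(g)[2]],
                  exact = FALSE, correct = TRUE))
    list(p = wt$p.value, method = "wilcoxon", statistic = unname(wt$statistic))
  } else {
    tab <- table(factor(values), g)
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    list(p = ct$p.value, method = "chisq", statistic = unname(ct$statistic))
  }
}
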