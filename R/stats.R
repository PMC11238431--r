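# Self-contained statistical kernel: exact small-sample Wilcoxon tests,
# one-way ANOVA, pooled t, and Benjamini-Hochberg adjustment. Exact p-values
# come from complete enumeration of the permutation null; above the
# enumeration thresholds a normal approximation with tie (and, for the
# signed-rank, zero) corrections and continuity correction is used, and the
# `method` field records which route produced the p-value.

#' Construct a test result
#'
#' Container returned by every kernel test: the statistic, its p-value, how
#' the p-value was obtained, and the number of observations that actually
#' entered the test.
#'
#' @param statistic test statistic
#' @param p_value p-value in \[0, 1\]
#' @param method one of `"exact"`, `"normal_approx"`, `"f_distribution"`
#' @param n_effective number of observations used
#' @return object of class `triplimeth_test`
#' @keywords internal
test_result <- function(statistic, p_value, method, n_effective) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12, n_effective >= 0)
  structure(
    list(statistic = unname(statistic), p_value = min(unname(p_value), 1),
         method = match.arg(method, c("exact", "normal_approx", "f_distribution")),
         n_effective = as.integer(n_effective)),
    class = "triplimeth_test")
}

#' @export
print.triplimeth_test <- function(x, ...) {
  cat(sprintf("statistic = %.6g, p = %.4g (%s, n = %d)\n",
              x$statistic, x$p_value, x$method, x$n_effective))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control: on sorted p-values,
#' `q_(i) = min_(j >= i) p_(j) * n / j`, capped at 1, mapped back to the
#' input order. Guarantees `q >= p` elementwise and monotone q on sorted p.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\]
#' @return adjusted q-values in the input order
#' @examples
#' benjamini_hochberg(c(0.005, 0.1))  # 0.01, 0.10
#' @export
benjamini_hochberg <- function(pvalues) {
  stop_if_not_prob(pvalues, "pvalues")
  n <- length(pvalues)
  o <- order(pvalues)
  q_sorted <- rev(cummin(rev(pvalues[o] * n / seq_len(n))))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# largest permutation count for which complete rank-sum enumeration is run
.MAX_ENUM <- 2e6

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Unpaired two-sample location test on ranks. The p-value is exact --
#' computed by complete enumeration of all `choose(m+n, min(m, n))` group
#' labelings of the pooled sample -- when the smaller group has at most
#' `exact_max` observations, no tied value spans both groups, and the
#' enumeration is tractable; otherwise the normal approximation with mid-rank
#' tie correction and continuity correction is used.
#'
#' @param x,y numeric samples
#' @param alternative `"two_sided"`, `"less"` or `"greater"` (of `x` vs `y`)
#' @param exact_max enumeration threshold on the smaller sample size
#' @return [test_result()] with the Mann-Whitney `U` of `x`
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = c("two_sided", "less", "greater"),
                              exact_max = 8L) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  m <- length(x); n <- length(y); N <- m + n
  r <- rank(c(x, y))
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2

  ties_span <- length(intersect(unique(x), unique(y))) > 0L
  s <- min(m, n)
  if (s <= exact_max && !ties_span && choose(N, s) <= .MAX_ENUM) {
    cmb <- combn(N, s)
    sums <- colSums(matrix(r[cmb], nrow = s))
    if (s == m) {
      u_perm <- sums - m * (m + 1) / 2
    } else {
      u_perm <- (sum(r) - sums) - m * (m + 1) / 2
    }
    eps <- 1e-9
    p_less <- mean(u_perm <= U + eps)
    p_greater <- mean(u_perm >= U - eps)
    p <- switch(alternative,
      less = p_less, greater = p_greater,
      two_sided = min(1, 2 * min(p_less, p_greater)))
    return(test_result(U, p, "exact", N))
  }

  mu <- m * n / 2
  tie_tab <- table(r)
  sigma2 <- m * n / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  if (sigma2 <= 0) return(test_result(U, 1, "normal_approx", N))
  sigma <- sqrt(sigma2)
  z_num <- U - mu
  p <- switch(alternative,
    greater = pnorm((z_num - 0.5) / sigma, lower.tail = FALSE),
    less = pnorm((z_num + 0.5) / sigma),
    two_sided = {
      zz <- (z_num - sign(z_num) * 0.5) / sigma
      min(1, 2 * pnorm(-abs(zz)))
    })
  test_result(U, p, "normal_approx", N)
}

#' Wilcoxon signed-rank test
#'
#' Paired location test. Zero differences are discarded before ranking
#' (Wilcoxon's convention) and `n_effective` reports the remainder; if all
#' differences are zero the test returns `p = 1` with a warning. The p-value
#' is exact by enumeration of all `2^n` sign patterns when `n <= exact_max`,
#' else a normal approximation with tie and continuity corrections.
#'
#' @param x,y paired numeric samples of equal length
#' @param alternative `"two_sided"`, `"less"` or `"greater"` (of `x` vs `y`)
#' @param exact_max enumeration threshold on the number of nonzero pairs
#' @return [test_result()] with `W` = sum of ranks of positive differences
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 alternative = c("two_sided", "less", "greater"),
                                 exact_max = 12L) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) x else {
    if (length(x) != length(y)) stop("paired samples must have equal length")
    x - y
  }
  if (length(d) == 0L) stop("no pairs supplied")
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero; no evidence either way")
    return(test_result(0, 1, "exact", 0L))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])

  if (n <= exact_max) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_perm <- as.vector(signs %*% r)
    eps <- 1e-9
    p_less <- mean(w_perm <= W + eps)
    p_greater <- mean(w_perm >= W - eps)
    p <- switch(alternative,
      less = p_less, greater = p_greater,
      two_sided = min(1, 2 * min(p_less, p_greater)))
    return(test_result(W, p, "exact", n))
  }

  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  if (sigma2 <= 0) return(test_result(W, 1, "normal_approx", n))
  sigma <- sqrt(sigma2)
  z_num <- W - mu
  p <- switch(alternative,
    greater = pnorm((z_num - 0.5) / sigma, lower.tail = FALSE),
    less = pnorm((z_num + 0.5) / sigma),
    two_sided = {
      zz <- (z_num - sign(z_num) * 0.5) / sigma
      min(1, 2 * pnorm(-abs(zz)))
    })
  test_result(W, p, "normal_approx", n)
}

#' One-way analysis of variance
#'
#' `F = MS_between / MS_within` with p from the F distribution on
#' `(k - 1, N - k)` degrees of freedom. When both the between- and
#' within-group variances are zero (all observations identical) the test is
#' uninformative and returns `F = 0, p = 1`.
#'
#' @param groups list of two or more numeric vectors, each of length >= 2
#' @return [test_result()] with method `"f_distribution"`
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least two groups")
  sizes <- lengths(groups)
  if (any(sizes < 2L)) stop("every group needs at least 2 observations")
  k <- length(groups)
  N <- sum(sizes)
  all_x <- unlist(groups, use.names = FALSE)
  grand <- mean(all_x)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(sizes * (means - grand)^2)
  ssw <- sum(vapply(seq_len(k), function(i) sum((groups[[i]] - means[i])^2),
                    numeric(1)))
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  if (msw == 0) {
    if (msb == 0) return(test_result(0, 1, "f_distribution", N))
    return(test_result(Inf, 0, "f_distribution", N))
  }
  f <- msb / msw
  test_result(f, pf(f, k - 1, N - k, lower.tail = FALSE), "f_distribution", N)
}

#' Two-sample pooled-variance t-test
#'
#' Student's two-sample t with pooled variance and a two-sided p-value.
#' `t^2` equals the [one_way_anova()] F statistic on the same two groups.
#'
#' @param x,y numeric samples of length >= 2
#' @return [test_result()]
#' @export
two_sample_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop("both samples need at least 2 observations")
  m <- length(x); n <- length(y)
  sp2 <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) / (m + n - 2)
  if (sp2 == 0) {
    if (mean(x) == mean(y)) return(test_result(0, 1, "f_distribution", m + n))
    return(test_result(sign(mean(x) - mean(y)) * Inf, 0, "f_distribution", m + n))
  }
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / m + 1 / n))
  p <- 2 * pt(-abs(tstat), df = m + n - 2)
  # two-sided pooled t is the square root of the two-group F test, so the
  # p-value is an F-distribution tail probability on (1, m+n-2) df
  test_result(tstat, p, "f_distribution", m + n)
}
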