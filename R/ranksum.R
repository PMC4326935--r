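#' Two-sample Wilcoxon rank-sum test with midrank ties
#'
#' Core two-group test of the pipeline. The statistic is the rank sum `W`
#' of the first group over the pooled midranks. The two-sided p-value is
#' `P(|W - E[W]| >= |w - E[W]|)` under the permutation null (all equally
#' likely assignments of the pooled values to the two group labels).
#'
#' For small samples the permutation distribution is computed exactly by
#' dynamic programming over doubled midranks (exact also under ties); for
#' larger samples the normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param x,y Numeric vectors (at least 2 finite values each).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact permutation
#'   distribution; `NULL` (default) uses it when the combined sample size
#'   is at most `exact_max_n`.
#' @param exact_max_n Combined-size cutoff for the default exact rule
#'   (default 12, i.e. at most `choose(12, 6) = 924` arrangements).
#' @return A list with `statistic` (rank sum of `x`), `p_value`,
#'   `direction` (`"a_greater"`, `"b_greater"`, or `"tie"`, by the sign of
#'   `W - E[W]`), and `exact`.
#' @examples
#' ranksum_test(c(1, 2, 3), c(4, 5, 6))$p_value  # 2/choose(6,3) = 0.1
#' @export
ranksum_test <- function(x, y, exact = NULL, exact_max_n = 12L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("ranksum_test requires finite values; apply a censor policy first")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 < 2L || n2 < 2L)
    stop("untestable: each group needs at least 2 usable values (got ",
         n1, " and ", n2, ")")
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  ew <- n1 * (n + 1) / 2
  if (is.null(exact)) exact <- n <= exact_max_n
  if (exact) {
    p <- ranksum_exact_p(r, n1, w)
  } else {
    tie <- table(r)
    tie_term <- sum(tie^3 - tie)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      d <- max(abs(w - ew) - 0.5, 0)  # continuity correction
      p <- min(1, 2 * stats::pnorm(-d / sqrt(sigma2)))
    }
  }
  dir <- if (w > ew) "a_greater" else if (w < ew) "b_greater" else "tie"
  list(statistic = w, p_value = p, direction = dir, exact = exact)
}

# Exact permutation p-value by DP counting of size-n1 subsets per
# doubled-midrank sum (doubling makes midranks integral).
ranksum_exact_p <- function(r, n1, w) {
  r2 <- as.integer(round(2 * r))
  n <- length(r2)
  total <- sum(r2)  # = n (n + 1)
  dp <- matrix(0, nrow = n1 + 1L, ncol = total + 1L)
  dp[1L, 1L] <- 1
  for (v in r2) {
    dp[2:(n1 + 1L), (v + 1L):(total + 1L)] <-
      dp[2:(n1 + 1L), (v + 1L):(total + 1L)] + dp[1:n1, 1:(total + 1L - v)]
  }
  counts <- dp[n1 + 1L, ]
  s <- 0:total
  e2 <- n1 * (n + 1L)            # doubled E[W]
  w2 <- as.integer(round(2 * w)) # doubled observed W (exact integer)
  sum(counts[abs(s - e2) >= abs(w2 - e2)]) / choose(n, n1)
}

#' Compare two groups of delta-Ct values under a censoring policy
#'
#' Applies the chosen policy to censored (`NA`) values, then runs
#' [ranksum_test()]. Policy `"impute"` (default) substitutes the
#' per-sample detection-limit delta-Ct supplied via `limit_a`/`limit_b`;
#' `"drop"` removes censored values (losing sample size and risking an
#' untestable group).
#'
#' @param a,b Numeric delta-Ct vectors with `NA` marking censored values.
#' @param censor `"impute"` or `"drop"`.
#' @param limit_a,limit_b Detection-limit delta-Ct values for the censored
#'   entries of `a`/`b` (scalar or per-sample vector); required by
#'   `"impute"` when censored values are present.
#' @param exact Passed to [ranksum_test()].
#' @return As [ranksum_test()], plus `n_used` (usable sizes per group).
#' @export
wilcoxon_two_group <- function(a, b, censor = c("impute", "drop"),
                               limit_a = NULL, limit_b = NULL, exact = NULL) {
  censor <- match.arg(censor)
  a <- as.numeric(a); b <- as.numeric(b)
  if (censor == "impute") {
    if (anyNA(a)) {
      if (is.null(limit_a)) stop("censored values in `a` but no `limit_a` supplied")
      lim <- rep_len(limit_a, length(a)); a[is.na(a)] <- lim[is.na(a)]
    }
    if (anyNA(b)) {
      if (is.null(limit_b)) stop("censored values in `b` but no `limit_b` supplied")
      lim <- rep_len(limit_b, length(b)); b[is.na(b)] <- lim[is.na(b)]
    }
  } else {
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) == 0L || length(b) == 0L)
      stop("untestable: all values censored in one group under policy 'drop'")
  }
  out <- ranksum_test(a, b, exact = exact)
  out$n_used <- c(length(a), length(b))
  out
}
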