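# Independent brute-force oracles used to check the package's statistics.

# Two-sided rank-sum p-value by exhaustive enumeration of all
# choose(n, n1) label assignments: P(|W - E[W]| >= |w_obs - E[W]|).
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  ew <- n1 * (n + 1) / 2
  sets <- utils::combn(n, n1)
  w_all <- apply(sets, 2, function(i) sum(r[i]))
  mean(abs(w_all - ew) >= abs(w_obs - ew) - 1e-9)
}

# Literal BH step-up: find the largest rank k with p_(k) <= q k / m and
# reject everything at or below p_(k).
oracle_bh <- function(p, q, m = length(p)) {
  o <- order(p)
  ps <- p[o]
  thresh <- q * seq_along(ps) / m
  k <- suppressWarnings(max(which(ps <= thresh)))
  if (!is.finite(k)) return(rep(FALSE, length(p)))
  p <= ps[k]
}

# Hypergeometric point mass from factorials only (no phyper/dhyper).
oracle_hyper_point <- function(k, a_margin, b_margin, n) {
  choose(a_margin, k) * choose(n - a_margin, b_margin - k) /
    choose(n, b_margin)
}

# Right-tail Fisher p for a 2x2 table by direct summation.
oracle_fisher_right <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  sum(vapply(ks[ks >= a], oracle_hyper_point, numeric(1),
             a_margin = r1, b_margin = c1, n = n))
}

# Two-sided Fisher p: sum of all tables whose point probability does not
# exceed the observed one (within a relative tolerance for float ties).
oracle_fisher_two <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  pk <- vapply(ks, oracle_hyper_point, numeric(1),
               a_margin = r1, b_margin = c1, n = n)
  p_obs <- pk[ks == a]
  sum(pk[pk <= p_obs * (1 + 1e-7)])
}

# One-way ANOVA F from explicit between/within sums of squares.
oracle_anova_f <- function(values, group) {
  group <- factor(group)
  grand <- mean(values)
  ssb <- sum(tapply(values, group, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(values, group, function(v) sum((v - mean(v))^2)))
  dfb <- nlevels(group) - 1
  dfw <- length(values) - nlevels(group)
  (ssb / dfb) / (ssw / dfw)
}

# Small deterministic Ct fixture: 4 samples x 3 assays + control.
tiny_ct <- function(ct_max = 40) {
  m <- matrix(c(30, 31, 29, 32,
                25, NA, 26, 27,
                35, 36, NA, 34,
                20, 21, 22, 23),
              nrow = 4,
              dimnames = list(paste0("S", 1:4),
                              c("miR-a", "miR-b", "miR-c", "RNU48")))
  ct_matrix(m, ct_max = ct_max)
}
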