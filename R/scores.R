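#' Network score of an enrichment p-value
#'
#' The network score used to rank regulatory-interaction networks:
#' `-log10(p)` of the right-tailed Fisher exact p-value of the network's
#' enrichment. A p-value of 1e-24 scores 24; a p-value of 1 scores 0.
#' Strictly decreasing in `p`; out-of-range input is an error (no
#' clamping).
#'
#' @param p Probability value(s) in (0, 1].
#' @return Score(s) `-log10(p)`.
#' @examples
#' network_score(1e-24)  # 24
#' @export
network_score <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0 | p > 1))
    stop("`p` must lie in (0, 1]")
  -log10(p)
}

check_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("expected a 2x2 table")
  if (any(!is.finite(tab)) || any(tab < 0) || any(tab != round(tab)))
    stop("cell counts must be non-negative integers")
  if (sum(tab) == 0) stop("at least one positive margin required")
  storage.mode(tab) <- "integer"
  tab
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact hypergeometric test; the two-sided p-value sums all tables with
#' the observed margins whose point probability does not exceed that of
#' the observed table, `"greater"`/`"less"` give the right/left tail. A
#' degenerate table (a zero row or column margin) carries no information
#' and returns p = 1 with a flag.
#'
#' @param tab 2x2 matrix of counts; rows = exposure (e.g. miRNA
#'   detected), columns = outcome.
#' @param alternative `"two.sided"` (default), `"greater"`, or `"less"`.
#' @return A list with `p_value`, `odds_ratio` (conditional MLE; `NA` for
#'   degenerate tables), `alternative`, `degenerate`.
#' @export
fisher_exact <- function(tab, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  tab <- check_2x2(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(p_value = 1, odds_ratio = NA_real_,
                alternative = alternative, degenerate = TRUE))
  ft <- stats::fisher.test(tab, alternative = alternative)
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate),
       alternative = alternative, degenerate = FALSE)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' One-degree-of-freedom chi-squared test of association, without
#' continuity correction by default (with `correct = TRUE` the Yates
#' correction is applied). Errors on a zero expected count, where
#' [fisher_exact()] should be used instead.
#'
#' @param tab 2x2 matrix of counts.
#' @param correct Apply the Yates continuity correction (default FALSE).
#' @return A list with `statistic`, `p_value`, `df`, `expected`.
#' @export
chi_square_2x2 <- function(tab, correct = FALSE) {
  tab <- check_2x2(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0))
    stop("zero expected cell count; use fisher_exact() instead")
  res <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       df = unname(res$parameter), expected = expected)
}

#' Association between detection state and a clinical outcome
#'
#' Cross-tabulates a miRNA's per-sample detection state against a binary
#' clinical outcome (e.g. periventricular leukomalacia among preterm
#' infants) and reports the Pearson chi-squared test (no continuity
#' correction by default) alongside Fisher's exact test, plus the network
#' score of the Fisher p-value. The two tests are reported side by side
#' because they can disagree at small counts.
#'
#' @param detected Logical vector: miRNA detected per sample.
#' @param outcome Logical vector: outcome present per sample.
#' @param correct Continuity correction for the chi-squared test
#'   (default FALSE).
#' @return A list with `table` (2x2: detected x outcome), `chisq`,
#'   `fisher`, `fisher_right`, `network_score`.
#' @export
detection_association <- function(detected, outcome, correct = FALSE) {
  ok <- !is.na(detected) & !is.na(outcome)
  detected <- as.logical(detected[ok]); outcome <- as.logical(outcome[ok])
  tab <- table(detected = factor(detected, c(TRUE, FALSE)),
               outcome = factor(outcome, c(TRUE, FALSE)))
  tab <- matrix(as.integer(tab), 2L, 2L, dimnames = dimnames(tab))
  chisq <- tryCatch(chi_square_2x2(tab, correct = correct),
                    error = function(e) NULL)
  fisher <- fisher_exact(tab, "two.sided")
  fisher_right <- fisher_exact(tab, "greater")
  list(table = tab, chisq = chisq, fisher = fisher,
       fisher_right = fisher_right,
       network_score = network_score(fisher$p_value))
}
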