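#' Split adult samples at the middle-age cutoff
#'
#' Adults at or below the cutoff (35 years by default, where biological
#' function and physical performance peak) are `young`; older adults are
#' `middle`. Non-adult rows are excluded with a message giving the count.
#'
#' @param meta Sample metadata (`sample_id`, `group`, `age`).
#' @param cutoff Age cutoff in years (boundary inclusive on the young
#'   side).
#' @return The adult rows of `meta` with an added `age_class` column.
#' @export
split_adults <- function(meta, cutoff = 35) {
  adults <- meta[meta$group == "adult", , drop = FALSE]
  dropped <- nrow(meta) - nrow(adults)
  if (dropped > 0L)
    message(dropped, " non-adult sample(s) excluded from the adult split")
  if (nrow(adults) == 0L) stop("no adult samples")
  if (any(!is.finite(adults$age)))
    stop("adult sample(s) with missing age: ",
         paste(adults$sample_id[!is.finite(adults$age)], collapse = ", "))
  adults$age_class <- ifelse(adults$age <= cutoff, "young", "middle")
  adults
}

#' Benjamini-Hochberg step-up selection
#'
#' Standard BH step-up at FDR level `q` over a declared universe of
#' `universe_size` tests (which may exceed the number of p-values
#' supplied, e.g. when only the testable subset of a panel is passed).
#' Also returns the realized crude-p cutoff `q * k / universe_size`, with
#' `k` the number of discoveries -- the largest crude p-value that still
#' passes.
#'
#' @param p P-values in (0, 1].
#' @param q FDR level (default 0.20).
#' @param universe_size Number of tests in the correction universe
#'   (default `length(p)`).
#' @return A list with `pass` (logical flags), `n_pass`, `cutoff`,
#'   `adjusted` (BH-adjusted p-values), `q`, and `universe_size`.
#' @export
bh_select <- function(p, q = 0.20, universe_size = length(p)) {
  if (length(p) == 0L) stop("empty p-value vector")
  if (any(!is.finite(p)) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
    stop("`q` must lie in (0, 1)")
  if (universe_size < length(p))
    stop("`universe_size` must be at least length(p)")
  adjusted <- stats::p.adjust(p, method = "BH", n = universe_size)
  pass <- adjusted <= q
  k <- sum(pass)
  list(pass = pass, n_pass = k,
       cutoff = if (k > 0L) q * k / universe_size else 0,
       adjusted = adjusted, q = q, universe_size = universe_size)
}

#' Correlation and gender-adjusted partial correlation with age
#'
#' Pearson (or Spearman) correlation between an expression variable
#' (conventionally `-dCt`, the log2 expression scale) and age, with a
#' two-sided test, plus the partial correlation adjusted for gender
#' (computed by residualizing both variables on the gender indicator; the
#' partial test uses `n - 3` degrees of freedom). The per-test Bonferroni
#' level is `alpha_family / k_tests`.
#'
#' @param expression Numeric expression values (`-dCt` scale).
#' @param age Ages in years.
#' @param gender Optional factor/character covariate with both levels
#'   present.
#' @param k_tests Number of correlations in the family (default 1).
#' @param alpha_family Family-wise level (default 0.05).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A list with `r`, `p_value`, `partial_r`, `partial_p`, `n`,
#'   `alpha_per_test`, and `significant` (crude p below the per-test
#'   level).
#' @export
age_correlation <- function(expression, age, gender = NULL, k_tests = 1L,
                            alpha_family = 0.05,
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(expression) & is.finite(age)
  if (!is.null(gender)) ok <- ok & !is.na(gender)
  expression <- expression[ok]; age <- age[ok]
  n <- length(expression)
  if (n < 3L) stop("need at least 3 paired observations")
  if (stats::sd(expression) == 0 || stats::sd(age) == 0)
    stop("undefined correlation: zero variance")
  if (method == "spearman") {
    expression <- rank(expression); age <- rank(age)
  }
  ct <- stats::cor.test(expression, age, method = "pearson")
  out <- list(r = unname(ct$estimate), p_value = ct$p.value,
              partial_r = NA_real_, partial_p = NA_real_, n = n,
              alpha_per_test = alpha_family / k_tests)
  if (!is.null(gender)) {
    g <- factor(gender[ok])
    if (nlevels(g) < 2L) stop("gender adjustment needs both genders present")
    rx <- stats::resid(stats::lm(expression ~ g))
    ra <- stats::resid(stats::lm(age ~ g))
    if (stats::sd(rx) == 0 || stats::sd(ra) == 0)
      stop("undefined partial correlation: zero residual variance")
    pr <- stats::cor(rx, ra)
    tt <- pr * sqrt((n - 3) / (1 - pr^2))
    out$partial_r <- pr
    out$partial_p <- 2 * stats::pt(-abs(tt), df = n - 3)
  }
  out$significant <- out$p_value < out$alpha_per_test
  out
}

#' One-way ANOVA with Bonferroni-adjusted pairwise comparisons
#'
#' Three-group validation comparison: overall F test followed by the
#' three pairwise two-sample t comparisons (pooled SD) with Bonferroni
#' adjustment (alpha split across the three contrasts).
#'
#' @param values Numeric response.
#' @param group Grouping with exactly 3 levels, each with at least 2
#'   samples.
#' @param alpha Family level for the pairwise contrasts (default 0.05).
#' @return A list with `f_statistic`, `p_value`, `pairwise` (matrix of
#'   Bonferroni-adjusted pairwise p-values), and `alpha_per_contrast`.
#' @export
three_group_compare <- function(values, group, alpha = 0.05) {
  group <- factor(group)
  if (nlevels(group) != 3L) stop("exactly three groups required")
  sizes <- table(group)
  if (any(sizes < 2L))
    stop("group(s) with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  ok <- is.finite(values)
  fit <- stats::lm(values[ok] ~ group[ok])
  an <- stats::anova(fit)
  pw <- stats::pairwise.t.test(values[ok], group[ok],
                               p.adjust.method = "bonferroni")
  list(f_statistic = an$`F value`[1L], p_value = an$`Pr(>F)`[1L],
       pairwise = pw$p.value, alpha_per_contrast = alpha / 3)
}

#' Post-adulthood aging-diminution analysis
#'
#' Among the miRNAs detectable in adults, compares young (age <= cutoff)
#' against middle-aged adults with the two-sided rank-sum test, controls
#' the FDR with BH step-up at level `q` (universe = the adult-detectable
#' set by default), and, for the BH discoveries, computes the Pearson
#' correlation and gender-adjusted partial correlation between `-dCt`
#' expression and age with per-test level `0.05 / k` (`k` = number of
#' discoveries).
#'
#' The fold change is [signed_fold_change()] with the middle-aged group
#' first, so a negative value means expression decreasing with age.
#'
#' @param delta A `delta_ct_matrix`.
#' @param meta Sample metadata (needs adult samples with finite ages and a
#'   `gender` column for the partial correlation).
#' @param cutoff Middle-age cutoff in years (default 35).
#' @param q BH FDR level (default 0.20).
#' @param min_frac Adult detectability threshold (default 0.30).
#' @param censor Censoring policy, as in [assign_expression_classes()].
#' @param universe `"adult_detectable"` (default) or `"panel"`: the BH
#'   correction universe.
#' @param alpha_corr Family level for the correlation follow-up
#'   (default 0.05).
#' @return A data.frame (class `aging_result`) over the adult-detectable
#'   miRNAs: `fold_change`, `p_value`, `bh_pass`, `r`, `p_r`,
#'   `partial_r`, `partial_p`. Attributes: `bh_cutoff`, `universe_size`,
#'   `n_pass`, `alpha_corr_per_test`, `n_young`, `n_middle`.
#' @export
aging_analysis <- function(delta, meta, cutoff = 35, q = 0.20,
                           min_frac = 0.30, censor = c("impute", "drop"),
                           universe = c("adult_detectable", "panel"),
                           alpha_corr = 0.05) {
  stopifnot(inherits(delta, "delta_ct_matrix"))
  censor <- match.arg(censor)
  universe <- match.arg(universe)
  adults <- split_adults(meta, cutoff)
  adult_ids <- intersect(adults$sample_id, rownames(delta$delta))
  adults <- adults[match(adult_ids, adults$sample_id), , drop = FALSE]
  ids_y <- adults$sample_id[adults$age_class == "young"]
  ids_m <- adults$sample_id[adults$age_class == "middle"]
  if (length(ids_y) < 2L || length(ids_m) < 2L)
    stop("need at least 2 young and 2 middle-aged adults")
  det_frac <- colMeans(is.finite(delta$delta[adult_ids, , drop = FALSE]))
  cand <- names(det_frac)[det_frac >= min_frac]
  if (length(cand) == 0L) stop("no miRNAs detectable in adults")
  universe_size <- if (universe == "adult_detectable") length(cand)
                   else ncol(delta$delta)
  vals <- if (censor == "impute") impute_censored(delta) else delta$delta
  lim <- delta$ct_max - delta$control_ct

  p <- fc <- rep(NA_real_, length(cand))
  for (j in seq_along(cand)) {
    m <- cand[j]
    y <- vals[ids_y, m]; o <- vals[ids_m, m]
    res <- tryCatch(
      wilcoxon_two_group(y, o, censor = censor,
                         limit_a = lim[ids_y], limit_b = lim[ids_m]),
      error = function(e) NULL)
    if (is.null(res)) next
    p[j] <- res$p_value
    # middle-aged group first: negative = decreasing expression with age
    fc[j] <- signed_fold_change(mean(o[!is.na(o)]), mean(y[!is.na(y)]))
  }
  testable <- !is.na(p)
  bh <- bh_select(p[testable], q = q, universe_size = universe_size)
  pass <- logical(length(cand)); pass[testable] <- bh$pass
  k <- bh$n_pass

  r <- pr <- p_r <- pp <- rep(NA_real_, length(cand))
  if (k > 0L) {
    expr_all <- -vals[adult_ids, , drop = FALSE]
    for (j in which(pass)) {
      co <- tryCatch(
        age_correlation(expr_all[, cand[j]], adults$age,
                        gender = adults$gender, k_tests = k,
                        alpha_family = alpha_corr),
        error = function(e) NULL)
      if (is.null(co)) next
      r[j] <- co$r; p_r[j] <- co$p_value
      pr[j] <- co$partial_r; pp[j] <- co$partial_p
    }
  }
  out <- data.frame(mirna_id = cand, fold_change = fc, p_value = p,
                    bh_pass = pass, r = r, p_r = p_r,
                    partial_r = pr, partial_p = pp,
                    stringsAsFactors = FALSE)
  attr(out, "bh_cutoff") <- bh$cutoff
  attr(out, "universe_size") <- universe_size
  attr(out, "n_pass") <- k
  attr(out, "alpha_corr_per_test") <- if (k > 0L) alpha_corr / k else NA_real_
  attr(out, "n_young") <- length(ids_y)
  attr(out, "n_middle") <- length(ids_m)
  class(out) <- c("aging_result", "data.frame")
  out
}

#' Call the lifespan transition pattern of one miRNA
#'
#' Evaluates a trajectory over the four ordered strata preterm infants,
#' children, young adults, middle-aged adults. `adult_onset` is called
#' when the miRNA is nondetectable in the two pre-adult strata but
#' detectable in both adult strata. Otherwise three successive contrasts
#' (rank-sum, each at `alpha / 3`) give a sign triple on the expression
#' scale, matched against:
#' \itemize{
#'   \item `(flat, -, -)`: `stable_then_down_then_diminish`
#'   \item `(flat, +, -)`: `stable_then_up_then_diminish`
#'   \item `(-, +, -)`: `down_then_up_then_diminish`
#' }
#' Anything else is `unclassified`.
#'
#' @param strata List of exactly four numeric vectors of expression
#'   values (`-dCt` scale) in lifespan order, `NA` marking censored
#'   samples.
#' @param alpha Family level split across the three contrasts
#'   (default 0.05).
#' @param min_frac Detectability threshold per stratum (default 0.30).
#' @param exact Passed to [ranksum_test()].
#' @return A list with `pattern`, `signs` (three-element vector in
#'   {-1, 0, 1}), `p_values`, and `detectable` (per-stratum flags).
#' @export
call_transition_pattern <- function(strata, alpha = 0.05, min_frac = 0.30,
                                    exact = NULL) {
  if (!is.list(strata) || length(strata) != 4L)
    stop("`strata` must be a list of four vectors ",
         "(preterm, child, young adult, middle-aged adult)")
  detectable <- vapply(strata, function(v) mean(is.finite(v)) >= min_frac,
                       logical(1L))
  if (!detectable[1L] && !detectable[2L] && detectable[3L] && detectable[4L])
    return(list(pattern = "adult_onset", signs = rep(NA_real_, 3L),
                p_values = rep(NA_real_, 3L), detectable = detectable))
  signs <- rep(NA_real_, 3L); pv <- rep(NA_real_, 3L)
  if (all(detectable)) {
    for (i in 1:3) {
      a <- strata[[i]][is.finite(strata[[i]])]
      b <- strata[[i + 1L]][is.finite(strata[[i + 1L]])]
      res <- tryCatch(ranksum_test(a, b, exact = exact),
                      error = function(e) NULL)
      if (is.null(res)) break
      pv[i] <- res$p_value
      signs[i] <- if (res$p_value < alpha / 3) sign(mean(b) - mean(a)) else 0
    }
  }
  pattern <-
    if (anyNA(signs)) "unclassified"
    else if (identical(signs, c(0, -1, -1))) "stable_then_down_then_diminish"
    else if (identical(signs, c(0, 1, -1)))  "stable_then_up_then_diminish"
    else if (identical(signs, c(-1, 1, -1))) "down_then_up_then_diminish"
    else "unclassified"
  list(pattern = pattern, signs = signs, p_values = pv,
       detectable = detectable)
}

#' Transition-pattern calls across a panel
#'
#' Applies [call_transition_pattern()] to each requested miRNA, building
#' the four strata (preterm, child, young adult, middle-aged adult) from
#' the metadata.
#'
#' @param delta A `delta_ct_matrix`.
#' @param meta Sample metadata with `preterm`, `child`, and `adult`
#'   groups.
#' @param mirnas miRNA ids to call (default: all).
#' @param cutoff Adult age cutoff (default 35).
#' @inheritParams call_transition_pattern
#' @return A data.frame with `mirna_id`, `pattern`, and the three contrast
#'   signs and p-values.
#' @export
transition_patterns <- function(delta, meta, mirnas = NULL, cutoff = 35,
                                alpha = 0.05, min_frac = 0.30, exact = NULL) {
  stopifnot(inherits(delta, "delta_ct_matrix"))
  if (is.null(mirnas)) mirnas <- colnames(delta$delta)
  ids <- function(keep) intersect(meta$sample_id[keep], rownames(delta$delta))
  strata_ids <- list(
    ids(meta$group == "preterm"),
    ids(meta$group == "child"),
    ids(meta$group == "adult" & meta$age <= cutoff),
    ids(meta$group == "adult" & meta$age > cutoff))
  if (any(lengths(strata_ids) == 0L))
    stop("all four lifespan strata (preterm, child, young adult, ",
         "middle-aged adult) must have samples")
  expr <- -delta$delta
  res <- lapply(mirnas, function(m) {
    call_transition_pattern(lapply(strata_ids, function(s) expr[s, m]),
                            alpha = alpha, min_frac = min_frac, exact = exact)
  })
  data.frame(mirna_id = mirnas,
             pattern = vapply(res, `[[`, character(1L), "pattern"),
             sign_preterm_child = vapply(res, function(x) x$signs[1L], numeric(1L)),
             sign_child_young = vapply(res, function(x) x$signs[2L], numeric(1L)),
             sign_young_middle = vapply(res, function(x) x$signs[3L], numeric(1L)),
             p_preterm_child = vapply(res, function(x) x$p_values[1L], numeric(1L)),
             p_child_young = vapply(res, function(x) x$p_values[2L], numeric(1L)),
             p_young_middle = vapply(res, function(x) x$p_values[3L], numeric(1L)),
             stringsAsFactors = FALSE)
}
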