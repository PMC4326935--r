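#' Per-group detection profile of a panel
#'
#' A miRNA counts as *detected* in a sample when its Ct (or delta-Ct)
#' amplified, i.e. is not censored. It is *detectable* in a group when the
#' detected fraction reaches `min_frac` (boundary inclusive; the
#' conventional screening rule is detection in at least 30% of the samples
#' of either comparison group). The panel-level detectable set is the set
#' of miRNAs detectable in at least one of the two groups.
#'
#' @param x A [ct_matrix()] or `delta_ct_matrix`.
#' @param meta Sample metadata with columns `sample_id` and `group`.
#' @param groups Character vector of the two group labels to compare
#'   (default `c("preterm", "adult")`).
#' @param min_frac Detectability threshold on the detected fraction
#'   (default 0.30).
#' @return A data.frame (class `detection_profile`) with one row per
#'   miRNA: per-group sample counts, detected counts, detected fractions,
#'   `detectable_a`/`detectable_b` flags, and `detectable_any`.
#' @export
detection_profile <- function(x, meta, groups = c("preterm", "adult"),
                              min_frac = 0.30) {
  vals <- panel_values(x)
  if (!is.numeric(min_frac) || length(min_frac) != 1L ||
      min_frac < 0 || min_frac > 1)
    stop("`min_frac` must lie in [0, 1]")
  if (length(groups) != 2L) stop("`groups` must name exactly two groups")
  ids <- lapply(groups, function(g) {
    s <- meta$sample_id[meta$group == g]
    s <- intersect(s, rownames(vals))
    if (length(s) == 0L) stop("no samples in group '", g, "'")
    s
  })
  det <- is.finite(vals)
  prof <- data.frame(mirna_id = colnames(vals), stringsAsFactors = FALSE)
  for (i in 1:2) {
    sub <- det[ids[[i]], , drop = FALSE]
    suffix <- c("a", "b")[i]
    prof[[paste0("n_", suffix)]] <- nrow(sub)
    prof[[paste0("detected_", suffix)]] <- colSums(sub)
    prof[[paste0("frac_", suffix)]] <- colMeans(sub)
    prof[[paste0("detectable_", suffix)]] <- colMeans(sub) >= min_frac
  }
  prof$detectable_any <- prof$detectable_a | prof$detectable_b
  attr(prof, "groups") <- groups
  attr(prof, "min_frac") <- min_frac
  class(prof) <- c("detection_profile", "data.frame")
  prof
}

panel_values <- function(x) {
  if (inherits(x, "ct_matrix")) x$ct
  else if (inherits(x, "delta_ct_matrix")) x$delta
  else stop("expected a ct_matrix or delta_ct_matrix")
}

#' Signed fold change between two group-mean delta-Ct values
#'
#' The expression ratio `r = 2^-dCt_A / 2^-dCt_B` computed from the
#' arithmetic group-mean delta-Ct (i.e. the ratio of geometric-mean
#' expressions). Reported as `r` when `r >= 1` and as `-1/r` otherwise, so
#' the magnitude is always at least 1 and the sign says which group is
#' higher: positive means A is the higher-expressed group.
#'
#' @param delta_ct_a,delta_ct_b Finite group-mean delta-Ct values
#'   (cycles); vectorized.
#' @return Signed fold change(s).
#' @examples
#' signed_fold_change(5, 5)          # +1: no change
#' signed_fold_change(5 + log2(1.6), 5)  # -1.6: A lower-expressed
#' @export
signed_fold_change <- function(delta_ct_a, delta_ct_b) {
  if (any(!is.finite(delta_ct_a)) || any(!is.finite(delta_ct_b)))
    stop("signed_fold_change requires finite group-mean delta-Ct values")
  r <- 2^(delta_ct_b - delta_ct_a)
  ifelse(r >= 1, r, -1 / r)
}

#' Classify every panel miRNA into the five expression classes
#'
#' Decision tree over the two comparison groups (A = `groups[1]`,
#' B = `groups[2]`, by default preterm infants vs adults):
#' \enumerate{
#'   \item detectable in neither group: `nonexpressed`;
#'   \item detectable in exactly one group: `<A>_only` / `<B>_only`
#'     (age-limited expression);
#'   \item detectable in both: two-sided rank-sum test on delta-Ct with
#'     per-test Bonferroni threshold `alpha_family / n_detectable`
#'     (`n_detectable` = size of the panel-detectable set). Non-significant
#'     miRNAs are `age_constant`; significant ones are `up_in_<B>` or
#'     `down_in_<B>` by the sign of the fold change.
#' }
#' A miRNA whose test cannot be run (possible under censor policy
#' `"drop"`) is kept with class `untestable` rather than silently dropped.
#'
#' The reported `fold_change` is [signed_fold_change()] with group B
#' first, so positive = higher expression in B (up-regulated in adults
#' under the defaults).
#'
#' @param delta A `delta_ct_matrix` (see [delta_ct()]).
#' @param meta Sample metadata (`sample_id`, `group`).
#' @param groups The two group labels compared (order matters for label
#'   naming and fold-change sign).
#' @param min_frac Detectability threshold (default 0.30).
#' @param alpha_family Family-wise error level for the Bonferroni split
#'   (default 0.05).
#' @param censor Censoring policy for the rank test: `"impute"` (default;
#'   censored delta-Ct set to the per-sample detection limit
#'   `ct_max - Ct(control)`) or `"drop"`.
#' @param exact Passed to [ranksum_test()].
#' @return A data.frame (class `class_assignment`), one row per panel
#'   miRNA: `class`, `p_value` (only for both-group-detectable miRNAs),
#'   `alpha_per_test`, `fold_change`, group-mean delta-Ct, and detection
#'   fractions. Attributes carry `groups`, `n_detectable`,
#'   `alpha_per_test`, and `min_frac`.
#' @export
assign_expression_classes <- function(delta, meta,
                                      groups = c("preterm", "adult"),
                                      min_frac = 0.30, alpha_family = 0.05,
                                      censor = c("impute", "drop"),
                                      exact = NULL) {
  stopifnot(inherits(delta, "delta_ct_matrix"))
  censor <- match.arg(censor)
  prof <- detection_profile(delta, meta, groups, min_frac)
  n_detectable <- sum(prof$detectable_any)
  alpha_per <- if (n_detectable > 0L) alpha_family / n_detectable else NA_real_
  labs <- c(a_only = paste0(groups[1], "_only"),
            b_only = paste0(groups[2], "_only"),
            down   = paste0("down_in_", groups[2]),
            up     = paste0("up_in_", groups[2]))
  ids_a <- intersect(meta$sample_id[meta$group == groups[1]], rownames(delta$delta))
  ids_b <- intersect(meta$sample_id[meta$group == groups[2]], rownames(delta$delta))
  vals <- if (censor == "impute") impute_censored(delta) else delta$delta
  lim <- delta$ct_max - delta$control_ct

  n <- nrow(prof)
  cls <- character(n); p <- rep(NA_real_, n); fc <- rep(NA_real_, n)
  mean_a <- rep(NA_real_, n); mean_b <- rep(NA_real_, n)
  for (j in seq_len(n)) {
    m <- prof$mirna_id[j]
    da <- prof$detectable_a[j]; db <- prof$detectable_b[j]
    if (!da && !db) { cls[j] <- "nonexpressed"; next }
    if (da && !db) { cls[j] <- labs[["a_only"]]; next }
    if (!da && db) { cls[j] <- labs[["b_only"]]; next }
    a <- vals[ids_a, m]; b <- vals[ids_b, m]
    res <- tryCatch(
      wilcoxon_two_group(a, b, censor = censor,
                         limit_a = lim[ids_a], limit_b = lim[ids_b],
                         exact = exact),
      error = function(e) NULL)
    if (is.null(res)) { cls[j] <- "untestable"; next }
    au <- a[!is.na(a)]; bu <- b[!is.na(b)]
    mean_a[j] <- mean(au); mean_b[j] <- mean(bu)
    p[j] <- res$p_value
    fc[j] <- signed_fold_change(mean_b[j], mean_a[j])  # positive = up in B
    cls[j] <- if (p[j] < alpha_per) {
      if (fc[j] > 0) labs[["up"]] else if (fc[j] < 0) labs[["down"]] else "age_constant"
    } else "age_constant"
  }
  out <- data.frame(mirna_id = prof$mirna_id, class = cls, p_value = p,
                    alpha_per_test = alpha_per, fold_change = fc,
                    mean_dct_a = mean_a, mean_dct_b = mean_b,
                    frac_a = prof$frac_a, frac_b = prof$frac_b,
                    stringsAsFactors = FALSE)
  attr(out, "groups") <- groups
  attr(out, "n_detectable") <- n_detectable
  attr(out, "alpha_per_test") <- alpha_per
  attr(out, "alpha_family") <- alpha_family
  attr(out, "min_frac") <- min_frac
  class(out) <- c("class_assignment", "data.frame")
  out
}

#' Summarize a classification into counts and percentages
#'
#' Counts per class, percentage of the whole panel, and percentage of the
#' *differential* super-category (the one-group-only plus up- plus
#' down-regulated classes), mirroring the usual pie/bar decomposition of
#' such screens.
#'
#' @param x A `class_assignment` data.frame, or a named integer vector of
#'   per-class counts.
#' @return A list (class `classification_summary`) with `table`
#'   (class, n, pct_panel, pct_differential), `panel_size`, and
#'   `n_differential`.
#' @export
classification_summary <- function(x) {
  if (inherits(x, "class_assignment")) {
    counts <- table(x$class)
    counts <- stats::setNames(as.integer(counts), names(counts))
  } else if (is.numeric(x) && !is.null(names(x))) {
    counts <- stats::setNames(as.integer(x), names(x))
  } else {
    stop("expected a class_assignment or a named count vector")
  }
  total <- sum(counts)
  if (total == 0L) stop("empty assignment set")
  nondiff <- c("nonexpressed", "age_constant", "untestable")
  is_diff <- !(names(counts) %in% nondiff)
  n_diff <- sum(counts[is_diff])
  tab <- data.frame(class = names(counts), n = unname(counts),
                    pct_panel = 100 * unname(counts) / total,
                    pct_differential = ifelse(is_diff & n_diff > 0,
                                              100 * unname(counts) / n_diff,
                                              NA_real_),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, panel_size = total, n_differential = n_diff),
            class = "classification_summary")
}

#' @export
print.classification_summary <- function(x, ...) {
  cat(sprintf("panel: %d miRNAs, %d differentially expressed\n",
              x$panel_size, x$n_differential))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a classification table to TSV
#'
#' @param x A `class_assignment`.
#' @param path Output path.
#' @export
write_class_table <- function(x, path) {
  stopifnot(inherits(x, "class_assignment"))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
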