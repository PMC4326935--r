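test_that("rank-sum p-values match exhaustive permutation enumeration", {
  # frozen small example: fully separated 3 vs 3
  expect_equal(ranksum_test(c(1, 2, 3), c(4, 5, 6))$p_value, 2 / choose(6, 3))
  # identical multisets are maximally null
  expect_equal(ranksum_test(c(1, 2, 3), c(3, 1, 2))$p_value, 1)
  # random instances with ties, exact path vs combn oracle
  set.seed(42)
  for (n1 in c(3, 4, 5, 6, 8)) {
    for (rep in 1:4) {
      x <- sample(1:6, n1, replace = TRUE)
      y <- sample(1:6, n1, replace = TRUE) + rbinom(n1, 1, 0.5) * 0.5
      got <- ranksum_test(x, y, exact = TRUE)$p_value
      expect_equal(got, oracle_ranksum_p(x, y), tolerance = 1e-12)
    }
  }
})

test_that("exact rank-sum agrees with wilcox.test on tie-free data", {
  set.seed(7)
  for (rep in 1:10) {
    x <- rnorm(5); y <- rnorm(6)
    expect_equal(ranksum_test(x, y, exact = TRUE)$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("normal approximation tracks the exact p for moderate samples", {
  set.seed(11)
  x <- rnorm(10); y <- rnorm(10, 1)
  ex <- ranksum_test(x, y, exact = TRUE)$p_value
  ap <- ranksum_test(x, y, exact = FALSE)$p_value
  expect_lt(abs(ex - ap) / ex, 0.25)
})

test_that("censor policies impute at the limit or drop", {
  a <- c(1, 2, NA, 3)
  b <- c(5, 6, 7, NA)
  res <- wilcoxon_two_group(a, b, censor = "impute",
                            limit_a = 10, limit_b = 12)
  expect_equal(res$n_used, c(4L, 4L))
  res2 <- wilcoxon_two_group(a, b, censor = "drop")
  expect_equal(res2$n_used, c(3L, 3L))
  expect_error(wilcoxon_two_group(a, b, censor = "impute"), "limit_a")
  expect_error(wilcoxon_two_group(c(NA, NA, NA), b, censor = "drop"),
               "untestable")
})

test_that("detection fractions honor the inclusive 30% boundary", {
  ct <- matrix(NA_real_, 10, 2,
               dimnames = list(sprintf("P%02d", 1:10), c("miR-x", "miR-y")))
  ct[1:3, "miR-x"] <- 30       # exactly 30% detected
  ct[1:2, "miR-y"] <- 30       # 20%
  x <- ct_matrix(ct)
  meta <- data.frame(sample_id = rownames(ct),
                     group = rep(c("preterm", "adult"), each = 5),
                     age = c(rep(0, 5), 21:25), gender = "F",
                     stringsAsFactors = FALSE)
  prof <- detection_profile(x, meta, c("preterm", "adult"), min_frac = 0.30)
  # miR-x: 3/5 preterm = 0.6 detectable; fractions are per group
  expect_equal(prof$frac_a[prof$mirna_id == "miR-x"], 3 / 5)
  full <- detection_profile(x, meta, c("preterm", "adult"), min_frac = 0.6)
  expect_true(full$detectable_a[full$mirna_id == "miR-x"])  # boundary in
  expect_false(full$detectable_a[full$mirna_id == "miR-y"])
  expect_error(detection_profile(x, meta, c("preterm", "child")), "child")
  expect_error(detection_profile(x, meta, c("preterm", "adult"), min_frac = 2),
               "min_frac")
})

test_that("lowering min_frac never shrinks the detectable set", {
  set.seed(3)
  sim <- generate_dataset(simulation_config(panel_size = 80, seed = 3))
  prev <- NULL
  for (f in c(0.8, 0.5, 0.3, 0.1)) {
    prof <- detection_profile(sim$ct, sim$meta, min_frac = f)
    cur <- prof$mirna_id[prof$detectable_any]
    if (!is.null(prev)) expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("signed fold change follows the +/-1 sign convention", {
  expect_equal(signed_fold_change(5, 5), 1)
  expect_equal(signed_fold_change(5 + log2(1.6), 5), -1.6)
  expect_equal(signed_fold_change(5, 5 + log2(1.6)), 1.6)
  # antisymmetry when |FC| > 1
  set.seed(1)
  a <- runif(20, 0, 10); b <- runif(20, 0, 10)
  fab <- signed_fold_change(a, b); fba <- signed_fold_change(b, a)
  nz <- abs(fab) > 1
  expect_equal(fab[nz], -fba[nz])
  expect_true(all(abs(fab) >= 1))
  expect_error(signed_fold_change(NA, 1), "finite")
})

test_that("the class decision tree matches hand-built detection patterns", {
  # 10 preterm + 10 adult samples, 5 planted assays + control
  n <- 20
  ids <- c(sprintf("P%02d", 1:10), sprintf("A%02d", 1:10))
  meta <- data.frame(sample_id = ids,
                     group = rep(c("preterm", "adult"), each = 10),
                     age = c(rep(0, 10), seq(21, 61, length.out = 10)),
                     gender = rep(c("F", "M"), 10), stringsAsFactors = FALSE)
  ct <- matrix(NA_real_, n, 6,
               dimnames = list(ids, c("never", "constant", "pt.only",
                                      "ad.only", "up.ad", "RNU48")))
  ct[, "RNU48"] <- 20
  ct[, "constant"] <- 25 + rep(c(0.1, -0.1), 10)
  ct[1:7, "pt.only"] <- 28            # 70% of preterm, 0% adult
  ct[11:20, "ad.only"] <- 27
  ct[, "up.ad"] <- c(rep(30, 10), rep(27, 10))  # 8x higher in adults
  x <- ct_matrix(ct)
  cls <- assign_expression_classes(delta_ct(x), meta)
  got <- setNames(cls$class, cls$mirna_id)
  expect_equal(got[["never"]], "nonexpressed")
  expect_equal(got[["constant"]], "age_constant")
  expect_equal(got[["pt.only"]], "preterm_only")
  expect_equal(got[["ad.only"]], "adult_only")
  expect_equal(got[["up.ad"]], "up_in_adult")
  # partition: every assayed miRNA gets exactly one label
  expect_equal(sort(cls$mirna_id), sort(setdiff(colnames(ct), "RNU48")))
  # p-value present iff detectable in both groups
  expect_equal(!is.na(cls$p_value), got %in% c("age_constant", "up_in_adult",
                                               "down_in_adult"))
  # per-test threshold is alpha over the detectable count (4 here)
  expect_identical(attr(cls, "alpha_per_test"), 0.05 / 4)
  # |fold change| >= 1 wherever defined
  expect_true(all(abs(cls$fold_change) >= 1, na.rm = TRUE))
})

test_that("classification summaries report differential-set percentages", {
  counts <- c(nonexpressed = 137, age_constant = 104, preterm_only = 1,
              adult_only = 22, down_in_adult = 20, up_in_adult = 81)
  s <- classification_summary(counts)
  expect_equal(s$panel_size, 365)
  expect_equal(s$n_differential, 124)
  tab <- s$table
  expect_equal(tab$pct_differential[tab$class == "up_in_adult"], 100 * 81 / 124)
  expect_true(is.na(tab$pct_differential[tab$class == "age_constant"]))
  expect_equal(sum(tab$pct_panel), 100)
  expect_equal(sum(tab$pct_differential, na.rm = TRUE), 100)
  # single-class input
  s1 <- classification_summary(c(up_in_adult = 5))
  expect_equal(s1$table$pct_panel, 100)
  expect_equal(s1$table$pct_differential, 100)
})
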