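make_adult_meta <- function(ages, gender = NULL) {
  n <- length(ages)
  data.frame(sample_id = sprintf("AD%03d", seq_len(n)), group = "adult",
             age = ages,
             gender = if (is.null(gender)) rep(c("F", "M"), length.out = n)
                      else gender,
             stringsAsFactors = FALSE)
}

test_that("the adult split is boundary-inclusive on the young side", {
  meta <- make_adult_meta(c(21, 35, 35.5, 61))
  sp <- split_adults(meta, cutoff = 35)
  expect_equal(sp$age_class, c("young", "young", "middle", "middle"))
  meta2 <- rbind(meta, data.frame(sample_id = "PT001", group = "preterm",
                                  age = 0, gender = "F"))
  expect_message(sp2 <- split_adults(meta2), "1 non-adult")
  expect_equal(nrow(sp2), 4L)
})

test_that("BH flags equal brute-force step-up for short p-vectors", {
  set.seed(5)
  for (len in c(1, 2, 3, 5, 8, 10)) {
    for (rep in 1:10) {
      p <- round(runif(len), 2)
      p[p == 0] <- 0.01
      q <- sample(c(0.05, 0.1, 0.2), 1)
      got <- bh_select(p, q = q)
      expect_identical(got$pass, oracle_bh(p, q),
                       info = paste("len", len, "q", q))
    }
  }
  expect_equal(bh_select(rep(1, 6), q = 0.2)$n_pass, 0L)
})

test_that("the realized BH cutoff is q*k/m over the declared universe", {
  # six clear discoveries in a 205-test universe at the 20% level
  p <- c(0.0004, 0.003, 0.003, 0.003, 0.004, 0.005, rep(0.5, 10))
  bh <- bh_select(p, q = 0.20, universe_size = 205)
  expect_equal(bh$n_pass, 6L)
  expect_equal(bh$cutoff, 0.2 * 6 / 205)  # ~0.006
  expect_error(bh_select(c(0.5, 0), q = 0.2), "\\(0, 1\\]")
  expect_error(bh_select(0.5, q = 1.2), "q")
})

test_that("age correlation recovers exact trends and orthogonal covariates", {
  ages <- seq(21, 61, by = 2)
  expr <- 10 - 0.1 * ages
  co <- age_correlation(expr, ages)
  expect_equal(co$r, -1)
  # gender orthogonal to both variables: partial equals simple correlation
  ages2 <- rep(seq(22, 60, by = 2), each = 2)       # each age once per gender
  gender <- rep(c("F", "M"), length.out = length(ages2))
  set.seed(9)
  expr2 <- 5 - 0.05 * ages2 + rnorm(length(ages2), 0, 0.3)
  # symmetrize noise across genders so the design stays exactly orthogonal
  expr2 <- ave(expr2, ages2)
  co2 <- age_correlation(expr2, ages2, gender = gender)
  expect_equal(co2$partial_r, co2$r, tolerance = 1e-10)
  expect_equal(age_correlation(expr, ages, k_tests = 6)$alpha_per_test,
               0.05 / 6)
  expect_error(age_correlation(rep(1, 10), 1:10), "zero variance")
  expect_error(age_correlation(1:2, 1:2), "at least 3")
})

test_that("three-group comparison matches hand-computed sums of squares", {
  vals <- c(1, 2, 3, 2, 3, 4, 6, 7, 8)
  grp <- rep(c("preterm", "child", "adult"), each = 3)
  res <- three_group_compare(vals, grp)
  expect_equal(res$f_statistic, oracle_anova_f(vals, grp), tolerance = 1e-12)
  # identical groups: no between-group signal
  flat <- three_group_compare(rep(c(1, 2, 3), 3), grp)
  expect_lt(flat$f_statistic, 1e-20)
  # one group shifted far out: overall and only its contrasts significant
  set.seed(21)
  v <- c(rnorm(20), rnorm(20), rnorm(20, 5))
  g <- rep(c("a", "b", "c"), each = 20)
  res2 <- three_group_compare(v, g)
  expect_lt(res2$p_value, 1e-6)
  pw <- res2$pairwise
  expect_gt(pw["b", "a"], 0.05)
  expect_lt(min(pw["c", "a"], pw["c", "b"]), 1e-6)
  expect_error(three_group_compare(1:5, c("a", "a", "b", "b", "c")),
               "fewer than 2")
})

test_that("aging analysis flags planted diminution and reports its universe", {
  cfg <- simulation_config(aging_frac = 0.18, aging_slope = 0.08, seed = 13)
  sim <- generate_dataset(cfg)
  ag <- aging_analysis(delta_ct(sim$ct), sim$meta)
  expect_s3_class(ag, "aging_result")
  planted <- names(sim$truth$aging)[sim$truth$aging]
  hits <- ag$mirna_id[ag$bh_pass]
  # discoveries are overwhelmingly planted miRNAs
  expect_gt(length(hits), 0)
  expect_gt(mean(hits %in% planted), 0.7)
  # planted discoveries decline with age (negative fold change) and the
  # BH cutoff obeys the step-up arithmetic
  expect_true(all(ag$fold_change[ag$bh_pass & ag$mirna_id %in% planted] < 0))
  expect_equal(attr(ag, "bh_cutoff"),
               0.2 * attr(ag, "n_pass") / attr(ag, "universe_size"))
  # correlations computed exactly for the discoveries, at alpha 0.05/k
  expect_equal(!is.na(ag$r), ag$bh_pass)
  expect_equal(attr(ag, "alpha_corr_per_test"), 0.05 / attr(ag, "n_pass"))
  expect_true(all(abs(ag$r) <= 1, na.rm = TRUE))
})

test_that("planted negative aging slopes yield negative correlations", {
  # 60 adults, sigma 1, slope -0.05 expression-units/year
  set.seed(31)
  ages <- c(runif(32, 21, 35), runif(28, 35.5, 61))
  neg <- replicate(60, {
    expr <- -0.05 * ages + rnorm(60, 0, 1)
    age_correlation(expr, ages)$r < 0
  })
  expect_gte(mean(neg), 0.95)
})

test_that("transition patterns are called from noiseless templates", {
  det <- function(v) v                      # detected stratum
  none <- rep(NA_real_, 10)                 # fully censored stratum
  lo <- rep(1, 10); mid <- rep(2, 10); hi <- rep(3, 10)
  expect_equal(call_transition_pattern(list(none, none, det(mid), det(mid)))$pattern,
               "adult_onset")
  expect_equal(call_transition_pattern(list(hi, hi, mid, lo))$pattern,
               "stable_then_down_then_diminish")
  expect_equal(call_transition_pattern(list(lo, lo, hi, mid))$pattern,
               "stable_then_up_then_diminish")
  expect_equal(call_transition_pattern(list(mid, lo, hi, mid - 1))$pattern,
               "down_then_up_then_diminish")
  # flat everywhere fits no template
  expect_equal(call_transition_pattern(list(mid, mid, mid, mid))$pattern,
               "unclassified")
  expect_error(call_transition_pattern(list(lo, mid, hi)), "four")
})
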