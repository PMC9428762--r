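test_that("routing is a pure function of the diagnostics (all 8 combinations)", {
  combos <- expand.grid(n1 = c(TRUE, FALSE), n2 = c(TRUE, FALSE),
                        hom = c(TRUE, FALSE))
  expected2 <- function(n1, n2, hom) {
    if (!n1 || !n2) "wilcoxon" else if (hom) "student_t" else "welch_t"
  }
  expected3 <- function(n1, n2, hom) {
    if (!n1 || !n2) "kruskal_wallis" else if (hom) "anova" else "brown_forsythe"
  }
  for (i in seq_len(nrow(combos))) {
    n1 <- combos$n1[i]; n2 <- combos$n2[i]; hom <- combos$hom[i]
    expect_identical(route_test(c(n1, n2), hom), expected2(n1, n2, hom))
    expect_identical(route_test(c(n1, n2), hom, k = 3), expected3(n1, n2, hom))
  }
  expect_identical(route_test(TRUE, TRUE, paired = TRUE), "paired_t")
  expect_identical(route_test(FALSE, TRUE, paired = TRUE), "paired_wilcoxon")
})

test_that("distribution diagnostics flag skew and variance ratios", {
  skewed <- rep(c(1, 1, 1, 1, 2, 2, 3, 50, 60, 100), 2) +
    withr::with_seed(4, rnorm(20, 0, 0.01))
  d <- assess_distribution(list(skewed = skewed,
                                normal = withr::with_seed(5, rnorm(20))))
  expect_false(d$normal[["skewed"]])
  expect_true(d$normal[["normal"]])
  # calibration: each diagnostic flag has false-positive rate near alpha,
  # so single flags read correctly in >= 90/100 draws (the joint event
  # "both normal AND homoscedastic" is expected near (1-alpha)^3 ~ 86%)
  flags <- withr::with_seed(6, replicate(100, {
    d <- assess_distribution(list(a = rnorm(20), b = rnorm(20)))
    c(d$normal, hom = d$homoscedastic)
  }))
  expect_gte(sum(flags["a", ]), 90)
  expect_gte(sum(flags["b", ]), 90)
  expect_gte(sum(flags["hom", ]), 90)
  # sd ratio 5 flagged heteroscedastic
  het <- withr::with_seed(7, replicate(100, {
    !assess_distribution(list(a = rnorm(20, 0, 1),
                              b = rnorm(20, 0, 5)))$homoscedastic
  }))
  expect_gte(sum(het), 90)
  expect_error(assess_distribution(list(a = c(1, 2))),
               class = "heelpad_insufficient_data_error")
})

test_that("two-group comparison routes and rejects as expected", {
  res <- withr::with_seed(8, compare_two_groups(rnorm(20, 0), rnorm(20, 5)))
  expect_identical(res$test_name, "student_t")
  expect_lt(res$p_value, 0.001)
  # identical paired samples: statistic 0, p = 1 by convention
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  same <- compare_two_groups(x, x, paired = TRUE)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(compare_two_groups(1:4, 1:5, paired = TRUE),
               class = "heelpad_pairing_error")
  # clearly non-normal sample routes to the rank-sum test
  skewed <- c(rep(1, 12), 50, 60, 100, 120, 150, 200, 250, 300)
  res2 <- withr::with_seed(9, compare_two_groups(skewed, rnorm(20, 5)))
  expect_identical(res2$test_name, "wilcoxon")
})

test_that("null rejection rate of the routed two-group pipeline is near alpha", {
  rej <- withr::with_seed(10, replicate(400, {
    compare_two_groups(rnorm(20), rnorm(20))$p_value < 0.05
  }))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.08)
})

test_that("summary t equals the raw-sample pooled t and reproduces t = 1.80", {
  res <- t_from_summary(10, 64.4, 3.4, 10, 67.8, 4.9)
  expect_equal(round(res$statistic, 2), 1.80)
  expect_equal(res$df, 18)
  expect_gt(res$p.value, 0.05)
  expect_equal(t_from_summary(8, 5, 1, 8, 5, 1)$statistic, 0)
  expect_equal(t_from_summary(8, 5, 1, 8, 5, 1)$p.value, 1)
  # construct raw samples with exactly the requested summaries
  mk <- function(n, m, s) {
    z <- scale(seq_len(n))[, 1]
    m + s * z / sd(z)
  }
  a <- mk(12, 10, 2); b <- mk(9, 8.5, 3)
  raw <- t.test(a, b, var.equal = TRUE)
  res2 <- t_from_summary(12, 10, 2, 9, 8.5, 3)
  expect_equal(res2$statistic, abs(unname(raw$statistic)), tolerance = 1e-10)
  expect_equal(res2$p.value, raw$p.value, tolerance = 1e-10)
  expect_error(t_from_summary(1, 0, 1, 5, 0, 1),
               class = "heelpad_parameter_error")
})

test_that("three-group omnibus routes, and post hoc isolates the shifted group", {
  res <- withr::with_seed(11, compare_three_groups(rnorm(10), rnorm(10),
                                                   rnorm(10, 5)))
  expect_lt(res$p_value, 0.001)
  expect_s3_class(res$posthoc, "tbl_df")
  sig_pairs <- res$posthoc[res$posthoc$significant, ]
  expect_setequal(
    paste(sig_pairs$group1, sig_pairs$group2),
    c("g1 g3", "g2 g3"))
  # identical null groups rarely reject, and then no post hoc runs
  nulls <- withr::with_seed(12, replicate(100, {
    compare_three_groups(rnorm(10), rnorm(10), rnorm(10))$p_value > 0.05
  }))
  expect_gte(sum(nulls), 90)
  expect_error(compare_three_groups(1:5, 1:5, c(1, 2)),
               class = "heelpad_arity_error")
})

test_that("heteroscedastic normal groups take the Brown-Forsythe route", {
  # ideal Gaussian quantiles: pass Shapiro-Wilk by construction, while the
  # scale difference forces the heteroscedastic route deterministically
  z <- qnorm(ppoints(15))
  res <- compare_three_groups(z, 6 * z, 8 + 6 * z)
  expect_identical(res$test_name, "brown_forsythe")
  expect_identical(res$posthoc_method, "Tamhane T2")
  sig <- res$posthoc[res$posthoc$significant, ]
  expect_true(all(sig$group2 == "g3"))
})

test_that("three-group comparison separates healthy from diabetic subgroups", {
  # per-leg primary thickness drawn from the reference group distributions
  # (healthy n = 20 legs, two disease-duration subgroups n = 10 each):
  # the omnibus should reject in most seeds; when it does, the post hoc
  # should implicate the healthy contrast and rarely split the subgroups
  out <- withr::with_seed(24, t(replicate(100, {
    h <- rnorm(20, 14.85, 2.81)
    a <- rnorm(10, 12.69, 2.16)
    b <- rnorm(10, 12.54, 2.62)
    res <- compare_three_groups(h, a, b)
    if (res$p_value >= 0.05) return(c(FALSE, NA, NA))
    tab <- res$posthoc
    key <- function(x, y) (tab$group1 == x & tab$group2 == y) |
      (tab$group1 == y & tab$group2 == x)
    c(TRUE,
      tab$significant[key("g1", "g2")] || tab$significant[key("g1", "g3")],
      tab$significant[key("g2", "g3")])
  })))
  expect_gte(sum(out[, 1]), 55)                  # omnibus power ~2/3
  expect_gte(mean(out[, 2], na.rm = TRUE), 0.8)  # healthy drives the signal
  expect_lte(mean(out[, 3], na.rm = TRUE), 0.15) # subgroups rarely split
})

test_that("non-normal groups take Kruskal-Wallis with Dunn post hoc", {
  skew <- function(n, shift = 0) shift + rexp(n)^2
  res <- withr::with_seed(15, compare_three_groups(skew(15), skew(15),
                                                   skew(15, 30)))
  expect_identical(res$test_name, "kruskal_wallis")
  expect_identical(res$posthoc_method, "Dunn")
})

test_that("correlation matrix handles identities, sign and constants", {
  df <- tibble::tibble(x = c(1, 2, 3, 4, 5.5, 7),
                       y = -c(1, 2, 3, 4, 5.5, 7),
                       z = c(2, 1, 4, 3, 7, 5),
                       const = 1)
  cm <- correlation_matrix(df, c("x", "y", "z", "const"))
  expect_equal(cm$r["x", "x"], 1)
  expect_equal(cm$r["x", "y"], -1)
  expect_true(cm$long$undefined[cm$long$var2 == "const" &
                                  cm$long$var1 == "x"])
  expect_true(all(is.na(cm$r["const", c("x", "y", "z")])))
  # sampling check: estimated R near the generating correlation
  hit <- withr::with_seed(16, replicate(100, {
    x <- rnorm(20)
    y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(20)
    est <- correlation_matrix(tibble::tibble(x = x, y = y))$long$estimate
    abs(est - 0.6) < 0.25
  }))
  expect_gte(sum(hit), 90)
})

test_that("significance stars follow the reported tiers", {
  cm <- correlation_matrix(tibble::tibble(x = 1:10 + 0,
                                          y = c(1:9, 9.5) + 0))$long
  expect_identical(cm$stars, "***")
})

test_that("property summaries route between mean±SD and median (range)", {
  norm <- withr::with_seed(17, rnorm(30, 10, 2))
  s1 <- summarize_property(norm)
  expect_identical(s1$form, "mean_sd")
  expect_match(s1$label, "^[0-9.]+±[0-9.]+$")
  course <- c(2, 3, 5, 7, 9.5, 10, 14, 16, 20, 25)^2 / 10  # right-skewed
  s2 <- summarize_property(course)
  expect_identical(s2$form, "median_range")
  expect_match(s2$label, "range:")
  s3 <- summarize_property(rep(4.2, 5))
  expect_identical(s3$form, "median_range")
  expect_identical(s3$label, "4.20 (range: 4.20~4.20)")
})

test_that("wilcoxon routing is invariant to strictly monotone transforms", {
  withr::with_seed(18, {
    a <- rexp(18)^2
    b <- rexp(18)^2 + 0.5
  })
  r1 <- compare_two_groups(a, b)
  r2 <- compare_two_groups(log(a), log(b))
  expect_identical(r1$test_name, "wilcoxon")
  expect_identical(r2$test_name, "wilcoxon")
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("cohort comparison table runs end to end on a synthetic cohort", {
  spec <- cohort_spec(reference_cohort_spec(statuses = "time_zero"),
                      n_subjects = 5)
  props <- cohort_properties(generate_cohort(spec, seed = 19))
  tab <- compare_cohort(props)
  expect_equal(nrow(tab), 6)  # six properties, one status
  expect_true(all(tab$test %in% c("student_t", "welch_t", "wilcoxon")))
  expect_true(all(tab$p.value >= 0 & tab$p.value <= 1))
  expect_true(all(c("healthy", "diabetes") %in% names(tab)))
})
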