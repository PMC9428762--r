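#' Distribution diagnostics for grouped samples
#'
#' Runs the Shapiro-Wilk normality test on each group (p >= 0.05 taken as
#' consistent with normality) and Bartlett's test of equal variances across
#' groups (p >= 0.05 taken as homoscedastic). These diagnostics drive the
#' routing of all downstream comparisons. A group with zero variance cannot
#' be tested by Shapiro-Wilk and is flagged non-normal.
#'
#' @param samples A list of numeric vectors, one per group (each n >= 3).
#' @param alpha Diagnostic significance level, default 0.05.
#' @param var_test `"bartlett"` (classical test with its small-sample
#'   correction factor) or `"levene"` (Levene/Brown-Forsythe on absolute
#'   deviations, via the car package).
#' @return A list: `normal` (logical per group), `normality_p` (numeric per
#'   group), `homoscedastic` (logical), `homoscedasticity_p`.
#' @examples
#' assess_distribution(list(a = rnorm(20), b = rnorm(20)))
#' @export
assess_distribution <- function(samples, alpha = 0.05,
                                var_test = c("bartlett", "levene")) {
  var_test <- match.arg(var_test)
  if (!is.list(samples)) samples <- list(samples)
  ns <- lengths(samples)
  if (any(ns < 3))
    abort("Each group needs at least 3 observations for diagnostics.",
          class = "heelpad_insufficient_data_error")
  sw <- vapply(samples, function(x) {
    if (sd(x) == 0) return(0)  # degenerate: cannot be normal
    shapiro.test(x)$p.value
  }, numeric(1))
  normal <- sw >= alpha
  if (length(samples) >= 2) {
    hp <- if (var_test == "bartlett") {
      bartlett.test(samples)$p.value
    } else {
      if (!requireNamespace("car", quietly = TRUE))
        abort("The 'car' package is required for `var_test = \"levene\"`.")
      g <- factor(rep(seq_along(samples), ns))
      car::leveneTest(unlist(samples), g)[1, "Pr(>F)"]
    }
  } else {
    hp <- NA_real_
  }
  list(normal = normal, normality_p = sw,
       homoscedastic = !is.na(hp) && hp >= alpha, homoscedasticity_p = hp)
}

#' Test routing from distribution diagnostics
#'
#' Pure decision rules mapping diagnostics to the test applied:
#' \itemize{
#'   \item two groups, unpaired: both normal and homoscedastic -> Student
#'     t; both normal, heteroscedastic -> Welch t; any group non-normal ->
#'     Wilcoxon rank sum.
#'   \item two groups, paired: differences normal -> paired t; otherwise
#'     paired Wilcoxon (signed rank).
#'   \item three groups: all normal and homoscedastic -> one-way ANOVA
#'     (post hoc SNK-q); all normal, heteroscedastic -> Brown-Forsythe
#'     ANOVA (post hoc Tamhane T2); any non-normal -> Kruskal-Wallis
#'     (post hoc Dunn).
#' }
#'
#' @param normal Logical vector of per-group normality flags (for the
#'   paired rule, a single flag for the differences).
#' @param homoscedastic Logical homoscedasticity flag.
#' @param paired Paired two-group comparison?
#' @param k Number of groups (2 or 3).
#' @return The test name as a string.
#' @export
route_test <- function(normal, homoscedastic, paired = FALSE, k = 2) {
  if (k == 2 && paired) {
    return(if (all(normal)) "paired_t" else "paired_wilcoxon")
  }
  if (k == 2) {
    if (!all(normal)) return("wilcoxon")
    return(if (homoscedastic) "student_t" else "welch_t")
  }
  if (!all(normal)) return("kruskal_wallis")
  if (homoscedastic) "anova" else "brown_forsythe"
}

new_heelpad_test <- function(...) {
  structure(list(...), class = "heelpad_test")
}

#' @export
print.heelpad_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$test_name, x$statistic,
              x$p_value))
  if (!is.null(x$posthoc)) {
    cat("post hoc (", x$posthoc_method, "):\n", sep = "")
    print(x$posthoc)
  }
  invisible(x)
}

#' @rdname compare_two_groups
#' @param x A `heelpad_test` object.
#' @param ... Unused.
#' @export
tidy.heelpad_test <- function(x, ...) {
  tibble::tibble(test = x$test_name, statistic = x$statistic,
                 p.value = x$p_value,
                 significant = x$p_value < x$alpha)
}

# exact Wilcoxon p for small untied samples, normal approximation with
# continuity correction otherwise
wilcox_routed <- function(x, y, paired, exact_max_n = 25) {
  vals <- if (paired) x - y else c(x, y)
  use_exact <- max(length(x), length(y)) <= exact_max_n &&
    !any(duplicated(if (paired) abs(vals[vals != 0]) else vals))
  suppressWarnings(
    wilcox.test(x, y, paired = paired, exact = use_exact, correct = TRUE))
}

#' Compare two groups with normality-routed tests
#'
#' Routes a two-sample comparison through distribution diagnostics (see
#' [assess_distribution()] and [route_test()]): Student t when both groups
#' are normal and homoscedastic, Welch t when normal but heteroscedastic,
#' Wilcoxon rank sum when any group is non-normal; for paired data, paired
#' t when the differences are normal, paired Wilcoxon otherwise. All tests
#' are two-sided at `alpha` = 0.05.
#'
#' Identical paired samples (all differences zero) are reported with
#' statistic 0 and p = 1 by convention.
#'
#' @param a,b Numeric samples. For `paired = TRUE` they must be equal
#'   length and matched in order.
#' @param paired Paired comparison?
#' @param alpha Significance level (two-sided), default 0.05.
#' @param var_test Variance test for the unpaired route; see
#'   [assess_distribution()].
#' @param exact_max_n Largest per-group n for which the Wilcoxon p-value is
#'   exact (untied samples only); larger samples use the normal
#'   approximation with continuity correction.
#' @return A `heelpad_test` with `test_name`, `statistic`, `p_value`,
#'   `normality_p`, `homoscedasticity_p`, `n`, `alpha`. Supports [tidy()].
#' @examples
#' compare_two_groups(rnorm(20), rnorm(20, 2))
#' @export
compare_two_groups <- function(a, b, paired = FALSE, alpha = 0.05,
                               var_test = "bartlett", exact_max_n = 25) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (paired && length(a) != length(b))
    abort("Paired samples must have equal length.",
          class = "heelpad_pairing_error")
  if (paired) {
    d <- a - b
    if (sd(d) == 0) {
      if (all(d == 0)) {
        return(new_heelpad_test(test_name = "paired_t", statistic = 0,
                                p_value = 1, normality_p = NA_real_,
                                homoscedasticity_p = NA_real_,
                                n = c(length(a), length(b)), alpha = alpha))
      }
      # constant nonzero shift: differences carry no dispersion to test
      normal_d <- TRUE
      swp <- NA_real_
    } else {
      swp <- shapiro.test(d)$p.value
      normal_d <- swp >= alpha
    }
    name <- route_test(normal_d, TRUE, paired = TRUE)
    ht <- if (name == "paired_t") t.test(a, b, paired = TRUE)
          else wilcox_routed(a, b, paired = TRUE, exact_max_n)
    return(new_heelpad_test(test_name = name,
                            statistic = unname(ht$statistic),
                            p_value = ht$p.value, normality_p = swp,
                            homoscedasticity_p = NA_real_,
                            n = c(length(a), length(b)), alpha = alpha))
  }
  diag <- assess_distribution(list(a = a, b = b), alpha = alpha,
                              var_test = var_test)
  name <- route_test(diag$normal, diag$homoscedastic)
  ht <- switch(name,
               student_t = t.test(a, b, var.equal = TRUE),
               welch_t = t.test(a, b, var.equal = FALSE),
               wilcoxon = wilcox_routed(a, b, paired = FALSE, exact_max_n))
  new_heelpad_test(test_name = name, statistic = unname(ht$statistic),
                   p_value = ht$p.value, normality_p = diag$normality_p,
                   homoscedasticity_p = diag$homoscedasticity_p,
                   n = c(length(a), length(b)), alpha = alpha)
}

#' Two-sample pooled t statistic from summary statistics
#'
#' The classical pooled-variance two-sample t computed from group sizes,
#' means and SDs only (as needed to reproduce comparisons reported from
#' summary tables), with a two-sided p-value on n1 + n2 - 2 degrees of
#' freedom.
#'
#' @param n1,mean1,sd1,n2,mean2,sd2 Group summaries; `n1`, `n2` >= 2 and
#'   SDs > 0.
#' @return A tibble with `statistic` (absolute t), `df`, `p.value`.
#' @examples
#' t_from_summary(10, 64.4, 3.4, 10, 67.8, 4.9)  # t = 1.80
#' @export
t_from_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  if (n1 < 2 || n2 < 2 || sd1 <= 0 || sd2 <= 0)
    abort("Need n >= 2 per group and positive SDs.",
          class = "heelpad_parameter_error")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tibble::tibble(statistic = abs(t), df = df,
                 p.value = 2 * pt(abs(t), df, lower.tail = FALSE))
}

# Brown-Forsythe ANOVA (the unequal-variance one-way F* with Satterthwaite
# denominator df); no installed package provides it
brown_forsythe_anova <- function(samples) {
  ns <- lengths(samples)
  N <- sum(ns)
  means <- vapply(samples, mean, numeric(1))
  vars <- vapply(samples, var, numeric(1))
  grand <- sum(ns * means) / N
  num <- sum(ns * (means - grand)^2)
  wts <- (1 - ns / N) * vars
  Fstar <- num / sum(wts)
  ci <- wts / sum(wts)
  df2 <- 1 / sum(ci^2 / (ns - 1))
  df1 <- length(samples) - 1
  list(statistic = Fstar, df1 = df1, df2 = df2,
       p.value = pf(Fstar, df1, df2, lower.tail = FALSE))
}

# Student-Newman-Keuls stepwise q test after a one-way ANOVA
posthoc_snk <- function(samples) {
  k <- length(samples)
  ns <- lengths(samples)
  means <- vapply(samples, mean, numeric(1))
  dfe <- sum(ns) - k
  mse <- sum((ns - 1) * vapply(samples, var, numeric(1))) / dfe
  ord <- order(means)
  pos <- match(seq_len(k), ord)  # rank of each group's mean
  pairs <- utils::combn(k, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    r <- abs(pos[i1] - pos[i2]) + 1  # number of means spanned
    q <- abs(means[i1] - means[i2]) /
      sqrt(mse / 2 * (1 / ns[i1] + 1 / ns[i2]))
    tibble::tibble(group1 = names(samples)[i1], group2 = names(samples)[i2],
                   span = r, statistic = q,
                   p.value = ptukey(q, r, dfe, lower.tail = FALSE))
  })
  # stepwise closure: a pair is declared significant only if every pair
  # spanning it is significant
  res <- res[order(-res$span), ]
  sig <- res$p.value < 0.05
  for (j in seq_len(nrow(res))) {
    if (!sig[j]) {
      # pairs nested inside pair j on the ordered-means scale
      o1 <- range(pos[match(c(res$group1[j], res$group2[j]), names(samples))])
      inner <- res$span < res$span[j] &
        vapply(seq_len(nrow(res)), function(m) {
          o2 <- range(pos[match(c(res$group1[m], res$group2[m]), names(samples))])
          o2[1] >= o1[1] && o2[2] <= o1[2]
        }, logical(1))
      sig[inner] <- FALSE
    }
  }
  res$significant <- sig
  res[order(res$group1, res$group2), c("group1", "group2", "statistic",
                                       "p.value", "significant")]
}

# Tamhane T2: pairwise Welch t tests with Sidak adjustment
posthoc_tamhane_t2 <- function(samples) {
  pairs <- utils::combn(length(samples), 2)
  m <- ncol(pairs)
  purrr::map_dfr(seq_len(m), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    ht <- t.test(samples[[i1]], samples[[i2]], var.equal = FALSE)
    p_adj <- 1 - (1 - ht$p.value)^m
    tibble::tibble(group1 = names(samples)[i1], group2 = names(samples)[i2],
                   statistic = unname(ht$statistic), p.value = p_adj,
                   significant = p_adj < 0.05)
  })
}

# Dunn's rank-sum z test with tie correction and Bonferroni adjustment
posthoc_dunn <- function(samples) {
  ns <- lengths(samples)
  N <- sum(ns)
  g <- rep(seq_along(samples), ns)
  rk <- rank(unlist(samples))
  rbar <- tapply(rk, g, mean)
  ties <- table(rk)
  tiecor <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(length(samples), 2)
  m <- ncol(pairs)
  purrr::map_dfr(seq_len(m), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tiecor) * (1 / ns[i1] + 1 / ns[i2]))
    z <- (rbar[[i1]] - rbar[[i2]]) / se
    p_adj <- min(1, m * 2 * pnorm(abs(z), lower.tail = FALSE))
    tibble::tibble(group1 = names(samples)[i1], group2 = names(samples)[i2],
                   statistic = z, p.value = p_adj, significant = p_adj < 0.05)
  })
}

#' Compare three groups with a routed omnibus test and matched post hoc
#'
#' Routes the omnibus comparison through distribution diagnostics: one-way
#' ANOVA when all groups are normal and homoscedastic, Brown-Forsythe
#' ANOVA (unequal-variance F*) when normal but heteroscedastic,
#' Kruskal-Wallis otherwise. When the omnibus test is significant at
#' `alpha`, the matched pairwise post hoc is run over all three pairs:
#' SNK-q (studentized range with stepwise closure) after ANOVA, Tamhane T2
#' (pairwise Welch with Sidak adjustment) after Brown-Forsythe, and Dunn's
#' rank z test (Bonferroni) after Kruskal-Wallis.
#'
#' @param g1,g2,g3 Numeric samples (each n >= 3). Names are taken from the
#'   arguments when available.
#' @param alpha Significance level, default 0.05.
#' @param var_test See [assess_distribution()].
#' @return A `heelpad_test` with the omnibus result, diagnostics and, when
#'   significant, a `posthoc` tibble.
#' @examples
#' compare_three_groups(rnorm(10), rnorm(10), rnorm(10, 3))
#' @export
compare_three_groups <- function(g1, g2, g3, alpha = 0.05,
                                 var_test = "bartlett") {
  samples <- list(g1 = g1, g2 = g2, g3 = g3)
  if (any(lengths(samples) < 3))
    abort("Each of the three groups needs at least 3 observations.",
          class = "heelpad_arity_error")
  diag <- assess_distribution(samples, alpha = alpha, var_test = var_test)
  name <- route_test(diag$normal, diag$homoscedastic, k = 3)
  values <- unlist(samples)
  fac <- factor(rep(names(samples), lengths(samples)))
  if (name == "anova") {
    fit <- aov(values ~ fac)
    tab <- anova(fit)
    stat <- tab$`F value`[1]; p <- tab$`Pr(>F)`[1]
  } else if (name == "brown_forsythe") {
    bf <- brown_forsythe_anova(samples)
    stat <- bf$statistic; p <- bf$p.value
  } else {
    kw <- kruskal.test(values, fac)
    stat <- unname(kw$statistic); p <- kw$p.value
  }
  posthoc <- NULL
  ph_method <- NULL
  if (p < alpha) {
    ph_method <- switch(name, anova = "SNK-q",
                        brown_forsythe = "Tamhane T2",
                        kruskal_wallis = "Dunn")
    posthoc <- switch(name,
                      anova = posthoc_snk(samples),
                      brown_forsythe = posthoc_tamhane_t2(samples),
                      kruskal_wallis = posthoc_dunn(samples))
  }
  new_heelpad_test(test_name = name, statistic = stat, p_value = p,
                   normality_p = diag$normality_p,
                   homoscedasticity_p = diag$homoscedasticity_p,
                   n = lengths(samples), alpha = alpha,
                   posthoc = posthoc, posthoc_method = ph_method)
}

p_stars <- function(p) {
  dplyr::case_when(p < 0.001 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*",
                   p < 0.10 ~ ".", TRUE ~ "")
}

#' Pairwise Pearson correlation matrix with significance annotation
#'
#' Pairwise Pearson correlations over the chosen columns, with two-sided
#' p-values and the significance tiers `.` p<0.10, `*` p<0.05, `**` p<0.01,
#' `***` p<0.001. Pairs are computed on complete observations; a constant
#' column yields `NA` with an `undefined` flag rather than an error.
#'
#' @param data A data frame.
#' @param columns Character vector of numeric column names; default all
#'   numeric columns.
#' @return A list with `long` (tibble: var1, var2, n, estimate, p.value,
#'   stars, undefined), `r` and `p` (square matrices).
#' @examples
#' correlation_matrix(mtcars, c("mpg", "wt", "hp"))$long
#' @export
correlation_matrix <- function(data, columns = NULL) {
  columns <- columns %||% names(data)[vapply(data, is.numeric, logical(1))]
  k <- length(columns)
  rmat <- matrix(NA_real_, k, k, dimnames = list(columns, columns))
  pmat <- rmat
  diag(rmat) <- 1
  diag(pmat) <- 0
  rows <- list()
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    x <- data[[columns[i]]]; y <- data[[columns[j]]]
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    undefined <- length(x) < 3 || sd(x) == 0 || sd(y) == 0
    if (undefined) {
      est <- NA_real_; p <- NA_real_
    } else {
      ct <- cor.test(x, y, method = "pearson")
      est <- unname(ct$estimate); p <- ct$p.value
    }
    rmat[i, j] <- rmat[j, i] <- est
    pmat[i, j] <- pmat[j, i] <- p
    rows[[length(rows) + 1L]] <- tibble::tibble(
      var1 = columns[i], var2 = columns[j], n = length(x),
      estimate = est, p.value = p,
      stars = if (is.na(p)) "" else p_stars(p), undefined = undefined)
  }
  list(long = dplyr::bind_rows(rows), r = rmat, p = pmat)
}

#' Normality-routed descriptive summary
#'
#' Summarizes a sample the way cohort tables report material properties:
#' `mean±SD` when the Shapiro-Wilk test does not reject normality, and
#' `median (range: min~max)` otherwise. A constant sample is reported as a
#' degenerate median with equal range ends.
#'
#' @param x Numeric sample (n >= 3).
#' @param alpha Normality significance level, default 0.05.
#' @param digits Digits after the decimal point in the formatted string.
#' @return A list: `label` (formatted string), `form` (`"mean_sd"` or
#'   `"median_range"`), `mean`, `sd`, `median`, `min`, `max`,
#'   `normality_p`.
#' @examples
#' summarize_property(c(2, 3, 5, 7, 9.5, 10, 14, 16, 20, 25))
#' @export
summarize_property <- function(x, alpha = 0.05, digits = 2) {
  if (length(x) < 3)
    abort("Need at least 3 observations.",
          class = "heelpad_insufficient_data_error")
  constant <- sd(x) == 0
  swp <- if (constant) 0 else shapiro.test(x)$p.value
  normal <- !constant && swp >= alpha
  fmt <- function(v) formatC(v, format = "f", digits = digits)
  label <- if (normal) {
    paste0(fmt(mean(x)), "±", fmt(sd(x)))
  } else {
    paste0(fmt(median(x)), " (range: ", fmt(min(x)), "~", fmt(max(x)), ")")
  }
  list(label = label, form = if (normal) "mean_sd" else "median_range",
       mean = mean(x), sd = sd(x), median = median(x),
       min = min(x), max = max(x), normality_p = swp)
}

#' Compare material properties across cohort groups
#'
#' Applies the routed comparison framework to a cohort property table (one
#' row per leg and status, as produced by [cohort_properties()]): for each
#' property and loading status, two groups are compared with
#' [compare_two_groups()] and three with [compare_three_groups()]. Legs
#' are treated as independent observations, matching the analysis
#' convention of cohort studies that report n = legs.
#'
#' @param props A data frame with columns `group`, `status` and the
#'   property columns.
#' @param properties Property column names; default the six material
#'   properties present in the table.
#' @param alpha Significance level.
#' @return A tibble with one row per property x status: test name,
#'   statistic, p-value, stars, and per-group formatted summaries.
#' @export
compare_cohort <- function(props, properties = NULL, alpha = 0.05) {
  default_props <- c("primary_thickness_mm", "peak_strain_pct",
                     "peak_stress_kpa", "youngs_modulus_kpa",
                     "viscous_modulus_kpa_s", "edr_pct")
  properties <- properties %||% intersect(default_props, names(props))
  groups <- sort(unique(props$group))
  statuses <- unique(props$status)
  purrr::map_dfr(statuses, function(st) {
    purrr::map_dfr(properties, function(pr) {
      vals <- purrr::map(groups, function(g) {
        props[[pr]][props$group == g & props$status == st]
      })
      names(vals) <- groups
      res <- if (length(groups) == 2) {
        compare_two_groups(vals[[1]], vals[[2]], alpha = alpha)
      } else {
        compare_three_groups(vals[[1]], vals[[2]], vals[[3]], alpha = alpha)
      }
      summaries <- vapply(vals, function(v) summarize_property(v)$label,
                          character(1))
      out <- tibble::tibble(status = st, property = pr,
                            test = res$test_name, statistic = res$statistic,
                            p.value = res$p_value,
                            stars = p_stars(res$p_value))
      for (g in groups) out[[g]] <- summaries[[g]]
      out
    })
  })
}
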