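balanced_2x2 <- tibble::tibble(
  y = c(1, 2, 3, 4, 5, 6, 7, 8),
  a = rep(c("a1", "a2"), each = 4),
  b = rep(rep(c("b1", "b2"), each = 2), 2)
)

test_that("balanced 2x2 ANOVA matches the direct sums-of-squares oracle", {
  av <- tidy(two_way_anova(balanced_2x2, "y", "a", "b"))
  oracle <- anova_ss_oracle(balanced_2x2$y, balanced_2x2$a, balanced_2x2$b)
  expect_equal(av$statistic, c(oracle$F_a, oracle$F_b, oracle$F_ab),
               tolerance = 1e-8)
  expect_equal(av$statistic, c(64, 16, 0), tolerance = 1e-8)
  expect_equal(av$df, c(1L, 1L, 1L))
  expect_equal(av$df_resid, rep(4L, 3))
  # sums of squares decompose the total
  expect_equal(sum(av$sum_sq) + oracle$ss[["within"]], oracle$ss[["total"]],
               tolerance = 1e-8)
})

test_that("ANOVA agrees with the oracle on random balanced designs", {
  withr::with_seed(91L, {
    for (r in 1:8) {
      na <- sample(2:3, 1); nb <- sample(2:3, 1); n <- sample(2:5, 1)
      d <- expand.grid(a = paste0("a", 1:na), b = paste0("b", 1:nb),
                       rep = 1:n)
      d$y <- rnorm(nrow(d), mean = as.integer(d$a) + 0.5 * as.integer(d$b))
      av <- tidy(two_way_anova(d, "y", "a", "b"))
      oracle <- anova_ss_oracle(d$y, d$a, d$b)
      expect_equal(av$statistic, c(oracle$F_a, oracle$F_b, oracle$F_ab),
                   tolerance = 1e-8)
    }
  })
})

test_that("degenerate and malformed designs are handled", {
  d <- balanced_2x2
  d$y <- 5
  av <- tidy(two_way_anova(d, "y", "a", "b"))
  expect_equal(av$statistic, c(0, 0, 0))
  miss <- balanced_2x2[balanced_2x2$a != "a2" | balanced_2x2$b != "b2", ]
  expect_error(two_way_anova(miss, "y", "a", "b"), "empty design cell")
  expect_error(two_way_anova(balanced_2x2, "nope", "a", "b"), "not found")
})

test_that("unbalanced 10/10/5/5-style designs fit with Type II SS", {
  withr::with_seed(92L, {
    d <- tibble::tibble(
      g = rep(c("wt", "ko", "wt", "ko"), times = c(10, 10, 5, 5)),
      w = rep(c("basal", "basal", "fourap", "fourap"),
              times = c(10, 10, 5, 5)),
      y = rnorm(30)
    )
  })
  av <- two_way_anova(d, "y", "g", "w")
  expect_equal(unique(tidy(av)$df_resid), 26L)  # the Fig.-4-style df
  expect_true(all(tidy(av)$statistic >= 0))
  g <- glance(av)
  expect_equal(g$nobs, 30L)
  expect_true(g$shapiro_p > 0 && g$shapiro_p <= 1)
})

test_that("Bonferroni post hoc uses the pooled error and caps p at 1", {
  d <- balanced_2x2
  av <- two_way_anova(d, "y", "a", "b")
  one <- bonferroni_posthoc(av, list(c("a1:b1", "a2:b1")))
  expect_equal(one$adj.p.value, one$p.value)  # single comparison
  all_cmp <- bonferroni_posthoc(av)
  expect_equal(nrow(all_cmp), 6)
  expect_true(all(all_cmp$adj.p.value >= all_cmp$p.value))
  expect_true(all(all_cmp$adj.p.value <= 1))
  expect_error(bonferroni_posthoc(av, list(c("a1:b1", "zz:b9"))),
               "unknown cell")
  # identical groups -> adjusted p of 1
  same <- tibble::tibble(y = rep(c(1, 2), 8),
                         a = rep(c("a1", "a2"), each = 8),
                         b = rep(c("b1", "b2"), 8))
  same$y <- rep(1.5, 16)
  same$y[c(1, 9)] <- c(1.4, 1.4); same$y[c(2, 10)] <- c(1.6, 1.6)
  av2 <- two_way_anova(same, "y", "a", "b")
  ph <- bonferroni_posthoc(av2, list(c("a1:b1", "a2:b1"),
                                     c("a1:b2", "a2:b2")))
  expect_true(all(ph$adj.p.value == 1))
})

test_that("post hoc t statistics agree with emmeans pairwise contrasts", {
  skip_if_not_installed("emmeans")
  d <- tibble::tibble(
    g = rep(c("wt", "ko", "wt", "ko"), times = c(10, 10, 5, 5)),
    w = rep(c("basal", "basal", "fourap", "fourap"), times = c(10, 10, 5, 5)),
    y = withr::with_seed(93L, rnorm(30, rep(c(1, 1, 3, 1),
                                            times = c(10, 10, 5, 5))))
  )
  av <- two_way_anova(d, "y", "g", "w")
  ours <- bonferroni_posthoc(av)
  fit <- stats::lm(y ~ g * w, data = d)
  em <- as.data.frame(emmeans::contrast(
    emmeans::emmeans(fit, ~ g * w), method = "pairwise", adjust = "none"
  ))
  c1 <- gsub(":", " ", ours$cell_1)
  c2 <- gsub(":", " ", ours$cell_2)
  m <- purrr::map2_int(c1, c2, function(u, v) {
    hit <- which(em$contrast %in% c(paste(u, "-", v), paste(v, "-", u),
                                    paste0("(", u, ") - (", v, ")"),
                                    paste0("(", v, ") - (", u, ")")))
    if (length(hit) == 1) hit else NA_integer_
  })
  expect_false(anyNA(m))
  expect_equal(abs(ours$statistic), abs(em$t.ratio[m]), tolerance = 1e-8)
})

test_that("incidence percentages come out at printed precision", {
  expect_equal(proportion_from_counts(8, 18), 44.4)
  expect_equal(proportion_from_counts(8, 21), 38.1)
  expect_equal(proportion_from_counts(0, 7), 0)
  expect_error(proportion_from_counts(3, 0), "positive")
  expect_error(proportion_from_counts(5, 4), "0, total")
})

test_that("2x2 chi-square follows the Pearson formula", {
  expect_equal(pearson_chi2_2x2(matrix(5, 2, 2))$statistic, 0)
  # incidence counts 8/18 vs 8/21: recomputed Pearson statistic
  tab <- matrix(c(8, 8, 10, 13), 2)
  res <- pearson_chi2_2x2(tab)
  # independent direct computation
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - e)^2 / e), tolerance = 1e-12)
  expect_equal(res$statistic, 0.1615, tolerance = 1e-3)
  expect_equal(res$df, 1L)
  # doubling counts doubles the uncorrected statistic
  expect_equal(pearson_chi2_2x2(2 * tab)$statistic, 2 * res$statistic,
               tolerance = 1e-12)
  expect_error(pearson_chi2_2x2(matrix(c(0, 0, 3, 4), 2)), "marginal")
  yates <- pearson_chi2_2x2(tab, yates = TRUE)
  expect_lt(yates$statistic, res$statistic)
})
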