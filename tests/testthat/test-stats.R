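test_that("one-way ANOVA recovers the hand-computed F and handles degeneracy", {
  x <- c(1, 2, 3, 2, 3, 4, 3, 4, 5)
  g <- rep(c("A", "B", "C"), each = 3)
  out <- one_way_anova(x, g)
  expect_equal(out$statistic, 3.0)
  expect_equal(out$df, c(2, 6))

  deg <- one_way_anova(rep(5, 9), g)
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p))
  expect_error(one_way_anova(c(1, 2, 3), c("A", "A", "B")), "insufficient-data")
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(31)
  for (i in 1:10) {
    x <- rnorm(24)
    g <- rep(c("A", "B"), times = c(10, 14))
    f <- one_way_anova(x, g)$statistic
    t2 <- unname(t.test(x ~ g, var.equal = TRUE)$statistic^2)
    expect_equal(f, t2)
  }
})

test_that("Tukey HSD separates shifted groups and matches a permutation oracle", {
  x0 <- rep(c(1, 2, 3), 3)
  g0 <- rep(c("A", "B", "C"), each = 3)
  tk0 <- tukey_hsd(x0, g0)
  expect_true(all(tk0$p > 0.99))

  set.seed(41)
  x1 <- c(rnorm(5), rnorm(5), rnorm(5) + 100)
  g1 <- rep(c("A", "B", "C"), each = 5)
  tk1 <- tukey_hsd(x1, g1)
  expect_true(all(tk1$p[grepl("C", tk1$pair)] < 1e-6))
  expect_gt(tk1$p[tk1$pair == "B-A"], 0.5)

  set.seed(43)
  x2 <- c(rnorm(5), rnorm(5, 1), rnorm(5, 2))
  g2 <- factor(rep(c("A", "B", "C"), each = 5))
  tk2 <- tukey_hsd(x2, g2)
  oracle <- perm_mean_maxstat_pvals(x2, g2, B = 20000)
  # match oracle pairs (A:B, A:C, B:C) to TukeyHSD labels (B-A, C-A, C-B)
  expect_equal(unname(tk2$p[match(c("B-A", "C-A", "C-B"), tk2$pair)]),
               unname(oracle), tolerance = 0.05)
})

test_that("Kruskal-Wallis reproduces the hand-ranked H and degeneracies", {
  out <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("A", "B", "C"), each = 2))
  expect_equal(out$statistic, 192 / 42, tolerance = 1e-6) # = 4.571
  expect_equal(out$df, 2)

  same <- kruskal_wallis(rep(7, 6), rep(c("A", "B", "C"), each = 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(17)
  x <- rnorm(30)
  g <- rep(c("A", "B", "C"), each = 10)
  h0 <- kruskal_wallis(x, g)$statistic
  expect_equal(kruskal_wallis(exp(x), g)$statistic, h0)
  expect_equal(kruskal_wallis(x^3, g)$statistic, h0)
  expect_equal(kruskal_wallis(rank(x), g)$statistic, h0)
})

test_that("two-group KW matches the normal-approximation rank-sum test", {
  set.seed(19)
  x <- c(rnorm(8), rnorm(12, 0.5))
  g <- rep(c("A", "B"), times = c(8, 12))
  h <- kruskal_wallis(x, g)
  w <- wilcox.test(x ~ g, correct = FALSE, exact = FALSE)
  expect_equal(h$p, w$p.value, tolerance = 1e-10)
})

test_that("Nemenyi post hoc: null, separation, and oracle agreement with ties", {
  x0 <- rep(c(1, 2, 3), 3)
  g0 <- rep(c("A", "B", "C"), each = 3)
  nm0 <- nemenyi_posthoc(x0, g0)
  expect_true(all(!nm0$significant))

  set.seed(51)
  x1 <- c(rnorm(10), rnorm(10), rnorm(10) + 1000)
  g1 <- rep(c("A", "B", "C"), each = 10)
  nm1 <- nemenyi_posthoc(x1, g1)
  expect_true(all(nm1$significant[grepl("C", nm1$pair)]))
  expect_false(nm1$significant[nm1$pair == "A-B"])
  expect_equal(unique(nm1$method), "tukey") # continuous data: no ties

  set.seed(53)
  x2 <- c(sample(1:4, 8, TRUE), sample(2:6, 8, TRUE), sample(4:8, 8, TRUE))
  g2 <- factor(rep(c("A", "B", "C"), each = 8))
  nm2 <- nemenyi_posthoc(x2, g2)
  expect_equal(unique(nm2$method), "chisq_ties")
  oracle <- perm_rank_maxstat_pvals(x2, g2, B = 20000)
  expect_equal(unname(nm2$p), unname(oracle), tolerance = 0.07)
})

test_that("per-minute comparisons respect attrition and emit figure letters", {
  set.seed(61)
  n <- c(TE = 12, SE = 12, SY = 12)
  rows <- list()
  for (gr in names(n)) {
    for (i in seq_len(n[[gr]])) {
      last <- if (gr == "TE" && i <= 11) 8 else 10 # TE drops out earlier
      shift <- if (gr == "TE") 2 else 0            # strong TE elevation
      rows[[length(rows) + 1]] <- tibble::tibble(
        id = paste0(gr, i), group = gr, minute = 1:last,
        value = rnorm(last, shift, 0.5))
    }
  }
  d <- dplyr::bind_rows(rows)
  tc <- timecourse_compare(d, alpha = 0.05, min_n = 2)
  expect_true(all(tc$tested[tc$minute <= 8]))
  # minutes 9-10 have a single remaining TE subject: untested
  expect_false(any(tc$tested[tc$minute > 8]))
  expect_true(all(is.na(tc$H[!tc$tested])))
  mid <- tc[tc$minute %in% 2:8, ]
  expect_true(all(grepl("a", mid$letters)) && all(grepl("b", mid$letters)))
  expect_error(timecourse_compare(dplyr::mutate(d, group = "XX")),
               "unknown group")
})
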