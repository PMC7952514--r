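test_that("summary-statistics ANOVA reproduces hand-computable cases", {
  # equal means across groups -> F = 0
  out <- oneway_anova_summary(c(5, 5, 5), c(1, 2, 1.5), c(10, 12, 8))
  expect_equal(out$F, 0)
  expect_equal(out$p, 1)
  # agreement with aov on raw data, via computed summaries
  set.seed(7)
  x <- rnorm(30); g <- factor(rep(letters[1:3], each = 10))
  out2 <- oneway_anova_summary(tapply(x, g, mean), tapply(x, g, sd),
                               tapply(x, g, length))
  ref <- anova(lm(x ~ g))
  expect_equal(out2$F, ref$`F value`[1], tolerance = 1e-9)
  expect_equal(out2$p, ref$`Pr(>F)`[1], tolerance = 1e-9)
  expect_error(oneway_anova_summary(c(1, 2), c(1, 1), c(1, 5)),
               class = "invalid_config")
})

test_that("chi-square matches the direct formula and handles degenerate tables", {
  tab <- matrix(c(5, 13, 10, 15, 13, 25), ncol = 2)
  out <- chi_square_counts(tab)
  # brute-force sum (O-E)^2/E loop
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- 0
  for (i in 1:3) for (j in 1:2) stat <- stat + (tab[i, j] - E[i, j])^2 / E[i, j]
  expect_equal(out$statistic, stat, tolerance = 1e-12)
  expect_equal(out$df, 2)
  flat <- matrix(10, 2, 2)
  out2 <- chi_square_counts(flat)
  expect_equal(out2$statistic, 0)
  expect_equal(out2$p, 1)
  expect_error(chi_square_counts(matrix(c(0, 0, 1, 2), 2)),
               class = "invalid_data")
})

test_that("Bonferroni adjustment is min(1, m p)", {
  expect_equal(bonferroni_adjust(c(0.01, 0.02, 0.5)), c(0.03, 0.06, 1.0))
  expect_equal(bonferroni_adjust(0.2), 0.2)
  expect_equal(bonferroni_adjust(0.4, m = 3), 1.0)
  expect_equal(bonferroni_adjust(c(0.01, 0.5)),
               stats::p.adjust(c(0.01, 0.5), "bonferroni"))
  expect_error(bonferroni_adjust(c(0.5, 1.2)), class = "invalid_data")
})

test_that("mixed ANOVA matches the brute-force sums-of-squares oracle", {
  tab <- make_param_table(n_per_group = 6, seed = 2,
                          shift = list(group = "BD", class = "B",
                                       delta = 0.01))
  res <- mixed_anova(tab, "duration_s")
  oracle <- oracle_mixed_anova(tab, "duration_s")
  expect_equal(res$F[res$effect == "group"], unname(oracle["F_group"]),
               tolerance = 1e-8)
  expect_equal(res$F[res$effect == "class"], unname(oracle["F_class"]),
               tolerance = 1e-8)
  expect_equal(res$F[res$effect == "group:class"], unname(oracle["F_int"]),
               tolerance = 1e-8)
  # and against base R's split-plot aov as a second, independent route
  a <- summary(stats::aov(duration_s ~ group * class +
                            Error(factor(subject)),
                          data = tab))
  f_aov_group <- a[["Error: factor(subject)"]][[1]]["group", "F value"]
  f_aov_class <- a[["Error: Within"]][[1]]["class", "F value"]
  expect_equal(res$F[res$effect == "group"], f_aov_group, tolerance = 1e-8)
  expect_equal(res$F[res$effect == "class"], f_aov_class, tolerance = 1e-8)
})

test_that("mixed ANOVA on constant data gives F = 0 and flags missing cells", {
  tab <- make_param_table(n_per_group = 4, seed = 3)
  tab$duration_s <- 0.07
  res <- mixed_anova(tab, "duration_s")
  expect_true(all(res$F < 1e-20))
  bad <- tab[-1, ]
  expect_error(mixed_anova(bad, "duration_s"), class = "missing_cells")
})

test_that("Greenhouse-Geisser epsilon lies in its admissible range", {
  tab <- make_param_table(n_per_group = 8, seed = 4)
  res <- mixed_anova(tab, "duration_s")
  eps <- res$gg_epsilon[res$effect == "class"]
  expect_gte(eps, 1 / 3)
  expect_lte(eps, 1)
  expect_gte(res$p_gg[res$effect == "class"], res$p[res$effect == "class"])
})

test_that("permuted group labels give calibrated group-effect p-values", {
  tab <- make_param_table(n_per_group = 6, seed = 5)
  subjects <- unique(tab$subject)
  base_groups <- tab$group[match(subjects, tab$subject)]
  set.seed(99)
  pvals <- replicate(200, {
    pg <- sample(base_groups)
    tab$group <- pg[match(tab$subject, subjects)]
    mixed_anova(tab, "duration_s")$p[1]
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("simple effects agree with the summary ANOVA route and detect shifts", {
  tab <- make_param_table(n_per_group = 20, seed = 6,
                          shift = list(group = "BD", class = "B",
                                       delta = 5 * 0.008))
  se <- simple_effects(tab, "duration_s")
  # internal consistency: per-class F equals summary-statistics ANOVA on
  # the same cells
  for (cl in c("A", "B", "C", "D")) {
    sel <- tab$class == cl
    m <- tapply(tab$duration_s[sel], tab$group[sel], mean)
    s <- tapply(tab$duration_s[sel], tab$group[sel], sd)
    n <- tapply(tab$duration_s[sel], tab$group[sel], length)
    ref <- oneway_anova_summary(m, s, n)
    expect_equal(se$anova$F[se$anova$class == cl], ref$F, tolerance = 1e-9)
  }
  pw <- se$pairwise
  hitB <- pw[pw$class == "B" & (pw$group1 == "BD" | pw$group2 == "BD"), ]
  expect_true(all(hitB$p_adj < 0.05))
  others <- pw[pw$class != "B", ]
  expect_true(mean(others$p_adj < 0.05) <= 0.2)
})

test_that("identical groups give adjusted p-values of 1 in simple effects", {
  tab <- make_param_table(n_per_group = 5, seed = 7)
  tab$duration_s <- rep(tab$duration_s[tab$group == "SCH"], 3)
  se <- simple_effects(tab, "duration_s")
  expect_true(all(se$pairwise$p_adj == 1))
})

test_that("transition tests exclude undefined subjects and flag planted effects", {
  set.seed(8)
  sw <- default_switching(4)
  mk_group <- function(g, n, pAB) {
    tm <- sw$transition_matrix
    tm[1, ] <- c(0, pAB, (1 - pAB) / 2, (1 - pAB) / 2)
    do.call(rbind, lapply(seq_len(n), function(i) {
      labs <- simulate_state_sequence(tm, sw$mean_durations, 250, 60,
                                      seed = 1000 * match(g, c("G1", "G2", "G3")) + i)
      seg <- manual_segmentation(labs, epoch_ids = rep(1:30, each = 500))
      tmx <- transition_probabilities(seg)
      transition_table(setNames(list(tmx), paste0(g, i)), g)
    }))
  }
  trans_tab <- rbind(mk_group("G1", 15, 2 / 3), mk_group("G2", 15, 1 / 3),
                     mk_group("G3", 15, 1 / 3))
  res <- transition_tests(trans_tab)
  ab <- res$pairwise[res$pairwise$from == "A" & res$pairwise$to == "B", ]
  expect_true(any(ab$p_adj[ab$group1 == "G1" | ab$group2 == "G1"] < 0.05))
  expect_error(transition_tests(trans_tab[trans_tab$group == "G1", ]),
               class = "invalid_config")
})
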