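test_that("log2 fold change matches its worked values", {
  expect_equal(log2_fold_change(4, 1), -2)
  expect_equal(log2_fold_change(5, 5), 0)
  expect_equal(log2_fold_change(1, 9), log2(9))
  expect_equal(log2_fold_change(0, 0, pseudocount = 1), 0)
  expect_error(log2_fold_change(0, 0), class = "undefined_value")
  expect_error(log2_fold_change(-1, 2), class = "config_error")
})

test_that("two-group ANOVA reproduces hand-computed F and degenerate limits", {
  same <- two_group_anova(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$f, 0)
  expect_equal(same$p_value, 1)

  # SSB = 6, SSW = 4, df = (1, 4): F = 6 exactly
  res <- two_group_anova(c(1, 2, 3), c(3, 4, 5))
  expect_equal(res$f, 6)
  expect_equal(res$p_value, pf(6, 1, 4, lower.tail = FALSE))
  expect_equal(res$p_value, 0.0705, tolerance = 1e-3)

  flat <- two_group_anova(c(2, 2), c(5, 5))
  expect_equal(flat$p_value, 0)
  expect_error(two_group_anova(1, c(1, 2)), class = "config_error")
})

test_that("F equals t-squared and matches aov across random draws", {
  set.seed(42)
  for (i in 1:200) {
    a <- rnorm(sample(2:5, 1)); b <- rnorm(sample(2:5, 1))
    res <- two_group_anova(a, b)
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(res$f, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
  }
  # independent route: stats::aov on one random case
  a <- rnorm(4); b <- rnorm(3)
  fit <- summary(aov(y ~ g, data.frame(y = c(a, b),
                                       g = rep(c("a", "b"), c(4, 3)))))
  expect_equal(two_group_anova(a, b)$f, fit[[1]]$`F value`[1],
               tolerance = 1e-10)
})

test_that("BH adjustment matches the worked step-up example and edge cases", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.037), 0.037)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.1, NA)), class = "config_error")
})

test_that("the DEG boundary is inclusive: log2fc exactly 1 with small FDR is 'up'", {
  rpkm <- tibble::tibble(
    gene_symbol = c("g1", "filler1", "filler2"),
    X_young_rep1 = c(0.99, 5, 5), X_young_rep2 = c(0.99, 5.2, 4.9),
    X_aged_rep1 = c(1.99, 5.1, 5), X_aged_rep2 = c(1.99, 4.9, 5.1))
  deg <- classify_deg(rpkm, "X", pseudocount = 0.01)
  g1 <- deg[deg$gene_symbol == "g1", ]
  expect_equal(g1$log2fc, 1)               # (1.99+0.01)/(0.99+0.01) = 2
  expect_equal(as.character(g1$status), "up")
})

test_that("classification bookkeeping: triple adds up, order-invariant, monotone in thresholds", {
  study <- simulate_expression_study(
    study_design(n_genes = 600, frac_up = 0.05, frac_down = 0.05,
                 nb_dispersion = 0.02, seed = 21))
  deg <- classify_deg(study$rpkm, "IHC")
  g <- glance(deg)
  expect_equal(g$n_deg, g$n_up + g$n_down)

  shuffled <- study$rpkm[sample(nrow(study$rpkm)), ]
  deg2 <- classify_deg(shuffled, "IHC")
  merged <- merge(as.data.frame(deg), as.data.frame(deg2),
                  by = "gene_symbol")
  expect_equal(merged$fdr.x, merged$fdr.y)
  expect_equal(as.character(merged$status.x),
               as.character(merged$status.y))

  for (th in list(deg_thresholds(log2fc_min = 1.5),
                  deg_thresholds(fdr_max = 0.01),
                  deg_thresholds(background_rpkm = 1))) {
    tightened <- classify_deg(study$rpkm, "IHC", thresholds = th)
    loose_deg <- deg$gene_symbol[deg$status %in% c("up", "down")]
    tight_deg <- tightened$gene_symbol[tightened$status %in%
                                         c("up", "down")]
    expect_true(all(tight_deg %in% loose_deg))
  }
})

test_that("null studies stay under the FDR target and planted effects are recovered", {
  null_study <- simulate_expression_study(
    study_design(n_genes = 2000, frac_up = 0, frac_down = 0, seed = 31))
  deg <- classify_deg(null_study$rpkm, "IHC")
  frac_pos <- mean(deg$status %in% c("up", "down"))
  mc_se <- sqrt(0.10 * 0.90 / 2000)
  expect_lte(frac_pos, 0.10 + 3 * mc_se)

  planted <- simulate_expression_study(
    study_design(n_genes = 2000, frac_up = 0.025, frac_down = 0.025,
                 effect_log2fc = 2, nb_dispersion = 0.01, seed = 32))
  degp <- classify_deg(planted$rpkm, "OHC")
  tab <- merge(as.data.frame(degp), planted$truth, by = "gene_symbol")
  hits <- sum((tab$planted == "up" & tab$status == "up") |
                (tab$planted == "down" & tab$status == "down"))
  expect_gte(hits, 90)
})
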