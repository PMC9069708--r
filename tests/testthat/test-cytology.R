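base_counts <- function() {
  tibble::tibble(location_um = rep(c(800, 2400, 4000), each = 2),
                 cell_type = rep(c("IHC", "OHC"), 3),
                 count = rep(c(50, 200), 3))
}

test_that("survival percentages follow the definition and scale invariance", {
  aged <- tibble::tibble(location_um = 800, cell_type = "OHC",
                         count = 60)
  base <- tibble::tibble(location_um = 800, cell_type = "OHC",
                         count = 100)
  expect_equal(survival_percentage(aged, base)$percent, 60)
  expect_equal(survival_percentage(dplyr::mutate(aged, count = 0),
                                   base)$percent, 0)
  # doubling all counts leaves percentages unchanged
  expect_equal(
    survival_percentage(dplyr::mutate(aged, count = count * 2),
                        dplyr::mutate(base, count = count * 2))$percent,
    60)
  # zero baseline is NA, unmatched location is an error
  expect_true(is.na(survival_percentage(
    aged, dplyr::mutate(base, count = 0))$percent))
  expect_error(
    survival_percentage(dplyr::mutate(aged, location_um = 999), base),
    class = "config_error")
})

test_that("binomial cochleograms hit their expected survival", {
  base <- tibble::tibble(location_um = 800, cell_type = "OHC",
                         count = 200)
  # degenerate probabilities
  all_live <- simulate_cochleogram(base, 1, seed = 1)
  expect_equal(all_live$count[all_live$age == "aged"], 200)
  all_dead <- simulate_cochleogram(base, 0, seed = 1)
  expect_equal(all_dead$count[all_dead$age == "aged"], 0)

  draws <- vapply(1:500, function(s) {
    cg <- simulate_cochleogram(base, 0.6, seed = s)
    cg$count[cg$age == "aged"]
  }, numeric(1))
  se <- sqrt(200 * 0.6 * 0.4) / sqrt(500)
  expect_lt(abs(mean(draws) - 120), 3 * se)

  pcts <- vapply(1:300, function(s) {
    cg <- simulate_cochleogram(base_counts(), 0.8, seed = s)
    mean(survival_percentage(
      dplyr::filter(cg, age == "aged"),
      dplyr::filter(cg, age == "young"))$percent)
  }, numeric(1))
  expect_lt(abs(mean(pcts) - 80), 3 * stats::sd(pcts) / sqrt(300))

  expect_error(simulate_cochleogram(dplyr::mutate(base, count = -1),
                                    0.5),
               class = "config_error")
})

test_that("group comparison reproduces the pooled t worked example and identities", {
  same <- group_compare(c(2, 3, 4), c(2, 3, 4))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  res <- group_compare(c(1, 2, 3), c(3, 4, 5))
  expect_equal(res$t, -2.449, tolerance = 1e-3)
  expect_equal(res$p_value, 0.0705, tolerance = 1e-3)
  expect_equal(res$df, 4)

  set.seed(8)
  for (i in 1:100) {
    a <- rnorm(sample(2:6, 1)); b <- rnorm(sample(2:6, 1))
    gc <- group_compare(a, b)
    expect_equal(gc$t^2, two_group_anova(a, b)$f, tolerance = 1e-10)
    # antisymmetry under group exchange
    expect_equal(gc$t, -group_compare(b, a)$t, tolerance = 1e-12)
  }
  expect_error(group_compare(1, c(2, 3)), class = "config_error")
})

test_that("Holm-Sidak matches the worked pair, the literal definition, and inflates", {
  expect_equal(holm_sidak(c(0.01, 0.04)), c(0.0199, 0.04))
  expect_equal(holm_sidak(0.3), 0.3)
  set.seed(5)
  for (i in 1:20) {
    p <- runif(4)
    for (perm in list(1:4, 4:1, c(2, 4, 1, 3))) {
      expect_equal(holm_sidak(p[perm]), holm_sidak_literal(p[perm]))
    }
    expect_true(all(holm_sidak(p) >= p))
  }
  expect_error(holm_sidak(c(0.1, NA)), class = "config_error")
})

test_that("integrated density fold changes follow their definition", {
  aged <- tibble::tibble(target = "Slc26a5", cell_type = "OHC",
                         mean_gray = c(100, 100), area = c(50, 50))
  base <- tibble::tibble(target = "Slc26a5", cell_type = "OHC",
                         mean_gray = c(50, 50), area = c(50, 50))
  res <- integrated_density_foldchange(aged, base)
  expect_equal(res$mean_id_aged, 5000)      # 100 x 50
  expect_equal(res$log2fc, 1)
  expect_equal(integrated_density_foldchange(base, base)$log2fc, 0)
  expect_error(integrated_density_foldchange(
    aged, dplyr::mutate(base, mean_gray = 0)),
    class = "undefined_value")
})

test_that("fluorescence generator plants recoverable fold changes", {
  q <- simulate_fluorescence(c("Slc26a5", "Cbx3"), c(-1.5, 0.8),
                             n_cells = 400, seed = 9)
  fc <- integrated_density_foldchange(
    dplyr::filter(q, age == "aged"), dplyr::filter(q, age == "young"))
  expect_equal(fc$log2fc[fc$target == "Slc26a5"], -1.5, tolerance = 0.15)
  expect_equal(fc$log2fc[fc$target == "Cbx3"], 0.8, tolerance = 0.15)
})
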