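test_that("pf is 0 under full retention and 100 under full propagation", {
  full <- new_segregation_counts(61, 33, 6, a = 100, b = 100, c = 100)
  expect_equal(compute_pf(full, "consistent")$pf, 0)
  none <- new_segregation_counts(61, 33, 6, a = 0, b = 0, c = 0)
  expect_equal(compute_pf(none, "consistent")$pf, 100)
  expect_equal(compute_pf(none, "as_printed")$pf, 100)
  res <- compute_pf(none)
  expect_equal(res$per_plasmid_retention, 1 - res$pf / 100)
  expect_identical(res$n_effective, 61L + 2L * 33L + 4L * 6L)
})

test_that("consistent variant inverts the binomial retention law exactly", {
  # percentages at their expectations for p = 0.1: pf must be exactly 10
  cnt <- new_segregation_counts(61, 33, 6, a = 90, b = 81, c = 65.61)
  expect_equal(compute_pf(cnt, "consistent")$pf, 10, tolerance = 1e-12)
})

test_that("as_printed evaluates the literal formula, which diverges whenever
           multi-plasmid cells are scored", {
  cnt <- new_segregation_counts(61, 33, 6, a = 90, b = 81, c = 65.61)
  literal <- 100 - (61 * 90 + 2 * 33 * sqrt(81) + 4 * 6 * 65.61^(1 / 4)) /
    (61 + 2 * 33 + 4 * 6)
  expect_equal(compute_pf(cnt, "as_printed")$pf, literal)
  expect_gt(abs(compute_pf(cnt, "as_printed")$pf -
                  compute_pf(cnt, "consistent")$pf), 10)
  # with only single-plasmid cells the two readings coincide
  only1 <- new_segregation_counts(100, 0, 0, a = 92, b = NA, c = NA)
  expect_equal(compute_pf(only1, "as_printed")$pf,
               compute_pf(only1, "consistent")$pf)
  # the roots of a full-retention percentage are 10 and ~3.16, not 100:
  # the literal formula reports spurious propagation for m > 1 cells
  at_full <- new_segregation_counts(10, 10, 10, a = 100, b = 100, c = 100)
  expect_gt(compute_pf(at_full, "as_printed")$pf, 50)
  expect_equal(compute_pf(at_full, "consistent")$pf, 0)
})

test_that("pf rejects inconsistent tallies", {
  bad <- new_segregation_counts(10, 10, 0, a = 90, b = 80, c = NA)
  expect_silent(compute_pf(bad))  # empty category may be undefined
  bad2 <- bad; bad2$z <- 5L
  expect_error(compute_pf(bad2), "undefined")
  expect_error(new_segregation_counts(10, 10, 10, a = 90, b = -5, c = 50),
               "\\[0, 100\\]")
})

test_that("pf estimator is consistent for 100p and monotone in p", {
  means <- vapply(c(0.05, 0.1), function(p) {
    pr <- new_preset("p", list(p_prop = p, count_mix = c(0.61, 0.33, 0.06)))
    mean(vapply(1:50, function(i)
      compute_pf(gen_segregation_counts(pr, 5000,
                                        seed = derive_seed(17, paste0(p, i))))$pf,
      numeric(1)))
  }, numeric(1))
  expect_lt(abs(means[1] - 5), 0.5)
  expect_lt(abs(means[2] - 10), 0.5)
  expect_lt(means[1], means[2])
})

test_that("pedigree retention equals (1-p)^k within Monte-Carlo error", {
  p0 <- new_preset("ped0", list(k_circles = 5, p_prop = 0))
  expect_equal(pedigree_retention_frequency(gen_pedigree_table(p0, 500, seed = 1)),
               100)
  cases <- list(c(k = 24, p = 0.039), c(k = 24, p = 0.11), c(k = 1, p = 0.5))
  for (cs in cases) {
    pr <- new_preset("ped", list(k_circles = cs[["k"]], p_prop = cs[["p"]]))
    tab <- gen_pedigree_table(pr, 10000, seed = 21)
    expect_equal(pedigree_retention_frequency(tab),
                 100 * (1 - cs[["p"]])^cs[["k"]],
                 tolerance = 2 / (100 * (1 - cs[["p"]])^cs[["k"]]))
  }
})

test_that("half-sector rate is the exact fraction and follows the product law", {
  tab <- data.frame(colony_id = 1:1000,
                    sector_class = factor(rep(c("half", "none"), c(5, 995)),
                                          levels = c("half", "other", "none")))
  expect_identical(half_sector_rate(tab), 5 / 1000)
  pr <- preset("sectors", "wt")  # p_excise 0.01, p_first_loss 0.5
  r1 <- half_sector_rate(gen_sector_colonies(pr, 1e5, seed = 31))
  expect_lt(abs(r1 - 0.005), 0.0005)
  pr2 <- modify_preset(pr, p_excise = 0.02)
  r2 <- half_sector_rate(gen_sector_colonies(pr2, 1e5, seed = 32))
  expect_lt(abs(r2 / r1 - 2), 0.25)
  p0 <- modify_preset(pr, p_excise = 0)
  expect_identical(half_sector_rate(gen_sector_colonies(p0, 1000, seed = 1)), 0)
})

test_that("ChIP fold enrichment is the control-normalized IP/Input ratio", {
  expect_equal(as.numeric(chip_fold_enrichment(5, 2, 5, 2)), 1)
  expect_equal(as.numeric(chip_fold_enrichment(10, 2, 1, 2)), 10)
  expect_equal(as.numeric(chip_fold_enrichment(3, 6, 1, 1)), 0.5)
  expect_error(chip_fold_enrichment(0, 1, 1, 1), "positive")
  multi <- chip_fold_enrichment(ip = c(ARS = 8, NCS1 = 4), input = c(2, 2),
                                ip_ctrl = c(1, 1), input_ctrl = c(2, 2))
  expect_equal(as.numeric(multi), c(8, 4))
})

test_that("group comparisons detect large effects and respect the null", {
  set.seed(41)
  v <- c(rnorm(50, 0), rnorm(50, 5))
  g <- rep(c("a", "b"), each = 50)
  tt <- compare_groups(v, g, design = "t_test")
  expect_lt(tt$p_value, 0.001)
  dn <- compare_groups(v, g, design = "anova_dunnett", reference = "a")
  expect_lt(dn$comparisons$p_adjusted[1], 0.001)
  # all-constant groups are flagged, no p-value fabricated
  dg <- compare_groups(rep(1, 30), rep(c("a", "b", "c"), 10))
  expect_true(dg$degenerate)
  expect_true(is.na(dg$p_value))
})

test_that("Dunnett adjustment controls the familywise error on null groups", {
  set.seed(43)
  hits <- vapply(1:40, function(i) {
    v <- rnorm(45)
    g <- rep(c("ctrl", "g1", "g2"), each = 15)
    cmp <- compare_groups(v, g, design = "anova_dunnett", reference = "ctrl")
    any(cmp$comparisons$p_adjusted < 0.05)
  }, logical(1))
  expect_lte(mean(hits), 0.15)  # FWER ~5%, generous Monte-Carlo margin
})
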