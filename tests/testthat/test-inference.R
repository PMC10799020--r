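test_that("complex fraction reproduces worked examples and is scale invariant", {
  expect_equal(complex_fraction(64, 39), 100 * 25 / 64, tolerance = 1e-12)
  expect_equal(round(complex_fraction(64, 39)), 39)
  expect_equal(round(complex_fraction(56, 18)), 68)
  for (x in c(10, 47, 93)) expect_equal(complex_fraction(x, x), 0)
  # fractions and percentages give the same answer
  for (c_scale in c(0.01, 1, 3)) {
    expect_equal(complex_fraction(c_scale * 64, c_scale * 39),
                 complex_fraction(64, 39))
  }
  expect_error(complex_fraction(39, 64), "no mobility reduction")
  expect_error(complex_fraction(0, 0), "Rf_free")
})

test_that("two-group comparison is a t test with mean +/- SEM reporting", {
  set.seed(1)
  a <- draw_cell_Rf(30, 0.64)
  b <- draw_cell_Rf(30, 0.39)
  fits <- dplyr::bind_rows(fits_tbl("free", a), fits_tbl("CL", b))
  cmp <- compare_groups(fits, "Rf")
  expect_equal(cmp$pairwise$p_adj, t.test(a, b)$p.value, tolerance = 1e-12)
  expect_equal(sort(cmp$means$mean), sort(c(mean(a), mean(b))))
  expect_equal(cmp$means$sem[cmp$means$group_label == "free"],
               sd(a) / sqrt(30))
  expect_true(is.na(cmp$omnibus_p))
})

test_that("multi-group comparison runs ANOVA with Bonferroni post-hoc contrasts", {
  set.seed(2)
  fits <- dplyr::bind_rows(
    fits_tbl("g1", draw_cell_Rf(20, 0.6)),
    fits_tbl("g2", draw_cell_Rf(20, 0.6)),
    fits_tbl("g3", draw_cell_Rf(20, 0.35))
  )
  cmp <- compare_groups(fits, "Rf")
  expect_equal(nrow(cmp$pairwise), 3)
  expect_lt(cmp$omnibus_p, 1e-4)
  p12 <- cmp$pairwise$p_adj[cmp$pairwise$group1 == "g1" &
                              cmp$pairwise$group2 == "g2"]
  expect_gt(p12, 0.05)
  expect_lt(max(cmp$pairwise$p_adj[cmp$pairwise$group2 == "g3" |
                                     cmp$pairwise$group1 == "g3"]), 0.01)
  # identical values in all groups: adjusted p-values of 1
  same <- dplyr::bind_rows(fits_tbl("g1", rep(0.5, 5)),
                           fits_tbl("g2", rep(0.5, 5)),
                           fits_tbl("g3", rep(0.5, 5)))
  expect_true(all(compare_groups(same, "Rf")$pairwise$p_adj == 1))
  expect_error(compare_groups(fits_tbl("only", draw_cell_Rf(5, 0.5)), "Rf"),
               "at least 2 groups")
  expect_error(
    compare_groups(dplyr::bind_rows(fits_tbl("a", 0.5), fits_tbl("b", draw_cell_Rf(5, 0.5))), "Rf"),
    "n >= 2")
})

test_that("D comparisons use only QC-passing cells, mirroring smaller per-panel n", {
  set.seed(3)
  fits <- dplyr::bind_rows(
    fits_tbl("free", draw_cell_Rf(12, 0.6), D = rnorm(12, 0.03, 0.003),
             d_reliable = rep(c(TRUE, FALSE), c(9, 3))),
    fits_tbl("CL", draw_cell_Rf(12, 0.6), D = rnorm(12, 0.03, 0.003))
  )
  cmp_Rf <- compare_groups(fits, "Rf")
  cmp_D <- compare_groups(fits, "D")
  n_Rf <- cmp_Rf$means$n[cmp_Rf$means$group_label == "free"]
  n_D <- cmp_D$means$n[cmp_D$means$group_label == "free"]
  expect_equal(n_Rf, 12)
  expect_equal(n_D, 9)
})

test_that("the decision table maps contrast significance onto interaction classes", {
  set.seed(4)
  n <- 25
  D_base <- function() rnorm(n, 0.03, 0.004)
  free <- fits_tbl("free", draw_cell_Rf(n, 0.64), D = D_base())

  stable_arm <- fits_tbl("CL", draw_cell_Rf(n, 0.39), D = D_base())
  call_s <- classify_interaction(free, stable_arm)
  expect_identical(call_s$classification, "stable")
  expect_equal(call_s$complex_fraction, 39, tolerance = 6)

  transient_arm <- fits_tbl("CL", draw_cell_Rf(n, 0.64),
                            D = rnorm(n, 0.018, 0.0025))
  expect_identical(classify_interaction(free, transient_arm)$classification,
                   "transient")

  mixed_arm <- fits_tbl("CL", draw_cell_Rf(n, 0.39),
                        D = rnorm(n, 0.018, 0.0025))
  expect_identical(classify_interaction(free, mixed_arm)$classification,
                   "mixed")

  null_arm <- fits_tbl("CL", draw_cell_Rf(n, 0.64), D = D_base())
  call_n <- classify_interaction(free, null_arm)
  expect_identical(call_n$classification, "none")
  expect_true(is.na(call_n$complex_fraction))

  # arms measured under different ligand conditions must be rejected
  lig <- dplyr::mutate(stable_arm, ligand = "VEGF-A")
  base <- dplyr::mutate(free, ligand = "none")
  expect_error(classify_interaction(base, lig), "ligand")
})

test_that("bootstrap interval on the complex fraction brackets the point estimate", {
  set.seed(5)
  free <- fits_tbl("free", draw_cell_Rf(30, 0.64))
  cl <- fits_tbl("CL", draw_cell_Rf(30, 0.39))
  call <- classify_interaction(free, cl, n_boot = 400)
  expect_false(is.null(call$boot_ci))
  expect_lt(call$boot_ci[1], call$complex_fraction)
  expect_gt(call$boot_ci[2], call$complex_fraction)
})

test_that("ligand contrasts detect published effect sizes and pass nulls", {
  set.seed(6)
  for (means in list(c(0.39, 0.26), c(0.42, 0.27))) {
    base <- fits_tbl("base", draw_cell_Rf(30, means[1]))
    lig <- dplyr::mutate(fits_tbl("lig", draw_cell_Rf(30, means[2])),
                         ligand = "VEGF-A")
    le <- ligand_effect(base, lig)
    expect_true(le$significant)
    expect_identical(le$direction, "decrease")
  }
  null_lig <- dplyr::mutate(fits_tbl("lig", draw_cell_Rf(30, 0.39)),
                            ligand = "BMP9")
  le0 <- ligand_effect(fits_tbl("base", draw_cell_Rf(30, 0.39)), null_lig)
  expect_false(le0$significant)
})

test_that("significance stars follow the conventional tiers", {
  expect_identical(significance_stars(c(0.2, 0.03, 0.005, 5e-4, 5e-5)),
                   c("ns", "*", "**", "***", "****"))
})
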