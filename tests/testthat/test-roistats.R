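fake_maps <- function(f, d, valid) {
  structure(list(f_int = f, d_int = d, valid = valid,
                 n_fitted = sum(!is.nan(f)), n_failed = 0L,
                 n_invalid_b0 = 0L, reference = NULL),
            class = "sda_maps")
}

test_that("ROI extraction averages valid voxels and warns on empty regions", {
  dm <- c(2, 2, 2)
  f <- array(50, dm); d <- array(2.5, dm); v <- array(1, dm)
  labels <- array(c(1L, 1L, 0L, 0L, 2L, 2L, 0L, 0L), dm)
  f[labels == 2] <- c(10, 30)
  d[labels == 2][1] <- NaN; v[labels == 2][1] <- 0
  roi <- extract_roi(fake_maps(f, d, v), labels)
  expect_equal(roi$f_int, c(50, 20))
  expect_equal(roi$n_voxels, c(2L, 2L))
  expect_equal(roi$n_d, c(2L, 1L))
  expect_equal(roi$d_int, c(2.5, 2.5))

  # a label with no fitted voxel warns and is omitted
  f2 <- f; f2[labels == 1] <- NaN
  expect_warning(roi2 <- extract_roi(fake_maps(f2, d, v), labels),
                 "no fitted voxel")
  expect_equal(roi2$region, "region_2")
  expect_error(extract_roi(fake_maps(f, d, v), array(0L, c(3, 2, 2))),
               "grid")
})

test_that("zero-F_int exclusion flags both markers and is idempotent", {
  tab <- data.frame(subject = sprintf("s%d", 1:10), group = "g",
                    f_int = c(0, runif(9, 5, 60)), d_int = runif(10, 0.5, 2))
  ex <- apply_exclusion(tab)
  expect_equal(sum(ex$included), 9)
  expect_equal(attr(ex, "n_excluded"), 1)
  expect_false(ex$included[1])
  expect_identical(apply_exclusion(ex)$included, ex$included)
  # no zeros: pass-through
  ex2 <- apply_exclusion(tab[-1, ])
  expect_true(all(ex2$included))
  # all zeros: downstream comparison refuses explicitly
  allz <- data.frame(group = rep(c("a", "b"), each = 5), f_int = 0,
                     d_int = 1)
  expect_error(group_compare(allz, "f_int"), "analyzable")
})

test_that("the omnibus test matches the hand-computed Kruskal-Wallis statistic", {
  tab <- data.frame(group = rep(c("a", "b"), each = 3),
                    f_int = c(1, 2, 3, 4, 5, 6))
  gc <- group_compare(tab, "f_int")
  # ranks (1,2,3) vs (4,5,6): H = 12/(6*7) * 3 * ((2-3.5)^2 + (5-3.5)^2)
  expect_equal(gc$kruskal$statistic, 27 / 7, tolerance = 1e-12)
  expect_equal(gc$kruskal$df, 1)

  same <- data.frame(group = rep(c("a", "b"), each = 3),
                     f_int = rep(c(1, 2, 3), 2))
  expect_gt(group_compare(same, "f_int")$kruskal$p.value, 0.99)
})

test_that("Dunn's z and p match hand computation and square to the omnibus H", {
  v <- c(1, 2, 3, 4, 5, 6)
  g <- rep(c("a", "b"), each = 3)
  dn <- dunn_test(v, g)
  # tie-free: z = (5 - 2) / sqrt((6*7/12) * (2/3)) = 3 / sqrt(7/3)
  expect_equal(abs(dn$z), 3 / sqrt(7 / 3), tolerance = 1e-12)
  expect_equal(dn$p, 2 * pnorm(-3 / sqrt(7 / 3)), tolerance = 1e-12)
  expect_equal(dn$p_adj, dn$p)  # single comparison: no adjustment
  # with two groups the squared Dunn z equals the Kruskal-Wallis H
  expect_equal(dn$z^2, unname(kruskal.test(v, factor(g))$statistic),
               tolerance = 1e-12)
  # tie correction: duplicated values shrink the standard error consistently
  vt <- c(1, 2, 2, 3, 4, 4)
  dt_ <- dunn_test(vt, g)
  expect_equal(dt_$z^2, unname(kruskal.test(vt, factor(g))$statistic),
               tolerance = 1e-12)
  # the Bonferroni family is all pairwise comparisons
  g3 <- rep(c("a", "b", "c"), each = 3)
  dn3 <- dunn_test(c(v, 7, 8, 9), g3)
  expect_equal(nrow(dn3), 3)
  expect_equal(dn3$p_adj, pmin(dn3$p * 3, 1))
})

test_that("group comparison is invariant to strictly monotone transforms", {
  set.seed(17)
  tab <- data.frame(group = rep(c("a", "b", "c"), each = 8),
                    f_int = c(runif(8, 5, 20), runif(8, 10, 40),
                              runif(8, 25, 70)))
  g1 <- group_compare(tab, "f_int")
  tab2 <- tab; tab2$f_int <- exp(tab$f_int / 20)
  g2 <- group_compare(tab2, "f_int")
  expect_equal(g1$kruskal$statistic, g2$kruskal$statistic)
  expect_equal(g1$pairwise$z, g2$pairwise$z)
})

test_that("group comparison enforces minimum analyzable group sizes", {
  tab <- data.frame(group = c("a", "a", "b"), f_int = c(10, 12, 14))
  expect_error(group_compare(tab, "f_int"), ">= 2")
})

test_that("Spearman correlation handles hand cases, ties and subsetting", {
  tab <- data.frame(age = c(30, 40, 50), group = "hc", f_int = c(1, 2, 3))
  expect_equal(age_correlation(tab, "f_int")$rho, 1)
  tab2 <- data.frame(age = c(1, 2, 3), group = "hc", f_int = c(3, 1, 2))
  expect_equal(age_correlation(tab2, "f_int")$rho, -0.5)
  expect_error(age_correlation(tab2[1:2, ], "f_int"), ">= 3")
  # inclusion scheme: restricting to a group subset drops the others
  tab3 <- rbind(tab, data.frame(age = c(60, 70, 80), group = "pvh",
                                f_int = c(90, 95, 99)))
  r_all <- age_correlation(tab3, "f_int")
  r_hc <- age_correlation(tab3, "f_int", groups = "hc")
  expect_equal(r_hc$n, 3)
  expect_equal(r_all$n, 6)
  expect_equal(r_hc$rho, 1)
})

test_that("phantom maps flow through ROI extraction to the group tests", {
  dict <- build_component_linear_dictionary()
  tis <- phantom_tissues(snap_to_atoms(dict, c(0.7e-3, 2.5e-3, 50e-3)))
  ph <- make_default_phantom(noise_sd = 0, seed = 5, shape = c(8, 8, 4),
                             b_values = b_scheme_previous(), tissues = tis)
  roi <- extract_roi(fit_volume(ph$dwi, dict), ph$labels,
                     region_names = ph$regions$name)
  expect_equal(roi$f_int, 100 * c(ph$ground_truth$HC_WM$f_int,
                                  ph$ground_truth$iNPH_PVH$f_int),
               tolerance = 1e-3)
})
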