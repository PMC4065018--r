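test_that("mixed ANOVA matches the sums-of-squares oracle", {
  set.seed(14)
  # hand-scale 6-subject, 2-network table
  M <- matrix(c(3, 5, 4, 8, 9, 7,
                6, 6, 5, 10, 12, 11), 6, 2)
  grp <- rep(c("a", "b"), each = 3)
  got <- mixed_anova(M, grp)
  want <- mixed_anova_oracle(M, grp)
  expect_equal(got$F_group, want$F_group, tolerance = 1e-8)
  expect_equal(got$F_network, want$F_network, tolerance = 1e-8)
  expect_equal(got$F_interaction, want$F_interaction, tolerance = 1e-8)

  # larger balanced table
  M2 <- matrix(rnorm(32), 8, 4)
  grp2 <- rep(c("a", "b"), each = 4)
  got2 <- mixed_anova(M2, grp2)
  want2 <- mixed_anova_oracle(M2, grp2)
  expect_equal(got2$F_group, want2$F_group, tolerance = 1e-8)
  expect_equal(got2$F_network, want2$F_network, tolerance = 1e-8)
  expect_equal(got2$F_interaction, want2$F_interaction, tolerance = 1e-8)
  expect_equal(got2$df_group, c(1, 6))
  expect_equal(got2$df_network, c(3, 18))

  # location invariance
  got3 <- mixed_anova(M2 + 100, grp2)
  expect_equal(got3$F_group, got2$F_group, tolerance = 1e-10)
  expect_equal(got3$F_network, got2$F_network, tolerance = 1e-10)
  expect_equal(got3$F_interaction, got2$F_interaction, tolerance = 1e-10)

  M2[2, 3] <- NA
  expect_error(mixed_anova(M2, grp2), class = "amynet_domain_error")
})

test_that("group F is calibrated under label permutation", {
  set.seed(15)
  rej <- vapply(1:200, function(i) {
    M <- matrix(rnorm(24), 8, 3)
    mixed_anova(M, sample(rep(c("a", "b"), each = 4)))$p_group < 0.05
  }, logical(1))
  # binomial 95% band around 0.05 for 200 draws
  expect_gte(sum(rej), qbinom(0.025, 200, 0.05))
  expect_lte(sum(rej), qbinom(0.975, 200, 0.05))
})

test_that("t-tests match the pooled-variance formula oracle", {
  x <- c(2.1, 3.4, 2.8); y <- c(1.0, 1.9, 1.4)
  tt <- two_sample_t(x, y)
  expect_equal(tt$statistic, pooled_t_oracle(x, y), tolerance = 1e-12)
  expect_equal(tt$df, 4)
  expect_equal(tt$p_raw, 2 * pt(-abs(tt$statistic), 4), tolerance = 1e-12)

  same <- c(1, 2, 3, 4)
  t0 <- two_sample_t(same, same)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_raw, 1)

  expect_error(paired_t(same, same), class = "amynet_degeneracy_error")
  expect_error(two_sample_t(rep(1, 4), rep(1, 4)),
               class = "amynet_degeneracy_error")

  os <- one_sample_t(x, 2)
  expect_equal(os$statistic, (mean(x) - 2) / (sd(x) / sqrt(3)),
               tolerance = 1e-12)

  p <- paired_t(x, y)
  d <- x - y
  expect_equal(p$statistic, mean(d) / (sd(d) / sqrt(3)), tolerance = 1e-12)

  # family-size correction flows through
  tfam <- two_sample_t(x, y, family_size = 7)
  expect_equal(tfam$p_corrected, min(1, tfam$p_raw * 7))
})

test_that("Bonferroni multiplies, clips and preserves order", {
  expect_equal(bonferroni(0.01, 7), 0.07)
  expect_equal(bonferroni(0.5, 7), 1)
  p <- c(0.001, 0.01, 0.04, 0.2)
  expect_identical(order(bonferroni(p, 10)), order(p))
  expect_error(bonferroni(c(0.1, 0.2), 1), class = "amynet_domain_error")
})

test_that("group t-map is antisymmetric under group swap", {
  set.seed(16)
  maps <- lapply(1:10, function(i)
    volume_map(array(rnorm(12^3), c(12, 12, 12))))
  grp <- rep(c("patient", "control"), each = 5)
  t1 <- voxelwise_group_tmap(maps, grp, height_p = 0.01, min_extent = 5)
  # reverse which maps belong to which group: the contrast negates exactly
  t2 <- voxelwise_group_tmap(maps[c(6:10, 1:5)], grp, height_p = 0.01,
                             min_extent = 5)
  expect_equal(t1$t_map$values, -t2$t_map$values, tolerance = 1e-10)
})

test_that("a planted group difference emerges as the largest cluster", {
  set.seed(17)
  dims <- c(16, 16, 16)
  blob <- array(0, dims)
  blob[6:11, 6:11, 6:11] <- 3   # 3 pooled-SD offset in patients
  maps <- c(lapply(1:8, function(i) volume_map(array(rnorm(prod(dims)),
                                                     dims) + blob)),
            lapply(1:8, function(i) volume_map(array(rnorm(prod(dims)),
                                                     dims))))
  grp <- rep(c("patient", "control"), each = 8)
  cm <- voxelwise_group_tmap(maps, grp, height_p = 0.001, min_extent = 10,
                             n_permutations = 199, seed = 2)
  expect_gt(nrow(cm$clusters), 0)
  top <- cm$clusters[which.max(cm$clusters$extent), ]
  expect_equal(top$sign, 1)
  expect_lt(top$p_corrected, 0.05)
  # the peak voxel lies inside the planted blob
  peak <- which(cm$label_map$values == top$cluster, arr.ind = TRUE)
  expect_true(all(peak[, 1] >= 5 & peak[, 1] <= 12))
})

test_that("cluster labelling follows 26-connectivity", {
  m <- array(FALSE, c(6, 6, 6))
  m[1, 1, 1] <- TRUE; m[2, 2, 2] <- TRUE  # diagonal touch: one cluster
  m[5, 5, 5] <- TRUE                       # far away: its own cluster
  lab <- amynet:::label_components_26(m)
  expect_equal(lab[1, 1, 1], lab[2, 2, 2])
  expect_false(lab[5, 5, 5] == lab[1, 1, 1])
  expect_equal(max(lab), 2L)
})

test_that("subject-level PiB vs r_GLOBAL correlation behaves", {
  x <- c(1, 2, 3, 4, 5)
  ct <- pib_vs_rglobal_correlation(x, 2 * x + 1)
  expect_equal(ct$r, 1, tolerance = 1e-12)
  set.seed(18)
  nul <- pib_vs_rglobal_correlation(rnorm(40), rnorm(40))
  expect_lt(abs(nul$r), 0.4)
  expect_error(pib_vs_rglobal_correlation(x, rep(1, 5)),
               class = "amynet_degeneracy_error")
})

test_that("patient subsampling control is reproducible and recovers effects", {
  set.seed(19)
  metric <- c(rnorm(12, 2), rnorm(6, 0))   # strong effect
  grp <- rep(c("patient", "control"), c(12, 6))
  s1 <- subsample_control(metric, grp, n_draws = 50, seed = 4)
  s2 <- subsample_control(metric, grp, n_draws = 50, seed = 4)
  expect_identical(s1$draws, s2$draws)
  expect_gte(s1$frac_significant, 0.9)

  # identical patients: every draw gives the same statistic
  metric2 <- c(rep(1.5, 12), rnorm(6))
  s3 <- subsample_control(metric2, grp, n_draws = 20, seed = 5)
  expect_equal(length(unique(round(s3$draws$t, 12))), 1L)

  expect_message(
    subsample_control(rnorm(12), rep(c("patient", "control"), each = 6),
                      n_draws = 10, seed = 1),
    "matched")
})
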