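test_that("network voxel selection uses a strict z threshold", {
  z <- array(0, c(4, 4, 4))
  z[1, 1, 1] <- 0.5; z[2, 1, 1] <- 1.0; z[3, 1, 1] <- 1.5
  pib <- array(seq_len(64) / 10, c(4, 4, 4))
  s <- toy_subject(z, pib)
  nvs <- select_network_voxels(s, "net", z_threshold = 1, min_size = 1L)
  expect_equal(length(nvs$ifc_values), 1L)   # exactly 1.0 is excluded
  expect_equal(nvs$ifc_values, 1.5)
  expect_equal(nvs$pib_values, pib[3, 1, 1])

  # count agrees with an exhaustive scan on a noise-free template
  des <- small_design(1, grid = c(20, 20, 20))
  tpl <- make_network_templates(des)[[1]]
  s2 <- toy_subject(tpl$values, pib = array(1, c(20, 20, 20)))
  nvs2 <- select_network_voxels(s2, "net", min_size = 10L)
  expect_equal(length(nvs2$ifc_values), sum(tpl$values > 1))

  expect_error(select_network_voxels(
    toy_subject(array(0, c(4, 4, 4)), pib), "net"),
    class = "amynet_degenerate_network_error")
})

test_that("connectivity log transform behaves like a natural log", {
  expect_equal(log_transform_ifc(exp(1)), 1)
  expect_lt(max(abs(log_transform_ifc(rep(1 + 1e-9, 3)))), 1e-8)
  set.seed(4)
  v <- 1 + runif(50)
  expect_identical(order(log_transform_ifc(v)), order(v))
  expect_error(log_transform_ifc(c(1, -2)), class = "amynet_domain_error")
})

test_that("median summaries follow the even-length convention", {
  nvs <- list(pib_values = c(1, 2, 3), ifc_values = exp(c(1, 1, 1)))
  expect_equal(median_network_pib(nvs), 2)
  nvs$pib_values <- c(1, 2, 3, 10)
  expect_equal(median_network_pib(nvs), 2.5)
  set.seed(5)
  p <- rnorm(21)
  expect_equal(median_network_pib(list(pib_values = p)),
               median_network_pib(list(pib_values = sample(p))))

  expect_equal(network_connectivity_score(nvs), 1)  # values all e -> log = 1
  v <- 1 + rexp(40)
  s1 <- network_connectivity_score(list(ifc_values = v))
  s2 <- network_connectivity_score(list(ifc_values = 2 * v))
  expect_equal(s2 - s1, log(2), tolerance = 1e-12)
  expect_equal(s1, median(log(v)))
})

test_that("r_global matches the direct-formula oracle and its invariances", {
  nvs <- list(subject_id = "s", network_name = "n",
              ifc_values = c(1.1, 1.5, 2.0, 2.4),
              pib_values = c(1.0, 1.2, 1.3, 1.6))
  rg <- r_global(nvs)
  expect_equal(rg$r_global,
               pearson_oracle(log(nvs$ifc_values), nvs$pib_values),
               tolerance = 1e-12)
  expect_equal(rg$fisher_z, atanh(rg$r_global), tolerance = 1e-12)
  expect_equal(rg$n_voxels, 4L)

  # perfect linear relation: clipped before atanh, stays finite
  nvs2 <- nvs; nvs2$pib_values <- 0.5 + 2 * log(nvs$ifc_values)
  rg2 <- r_global(nvs2)
  expect_equal(rg2$r_global, 1, tolerance = 1e-9)
  expect_true(is.finite(rg2$fisher_z))

  # invariant to positive affine PiB rescaling and power transforms of ifc
  nvs3 <- nvs; nvs3$pib_values <- 3 + 10 * nvs$pib_values
  expect_equal(r_global(nvs3)$r_global, rg$r_global, tolerance = 1e-12)
  nvs4 <- nvs; nvs4$ifc_values <- nvs$ifc_values^2.7
  expect_equal(r_global(nvs4)$r_global, rg$r_global, tolerance = 1e-12)

  # independent vectors at scale: near-zero correlation
  set.seed(6)
  big <- list(subject_id = "s", network_name = "n",
              ifc_values = 1 + rexp(10000), pib_values = rnorm(10000))
  expect_lt(abs(r_global(big)$r_global), 0.05)

  nvs5 <- nvs; nvs5$pib_values <- rep(1, 4)
  expect_error(r_global(nvs5), class = "amynet_degeneracy_error")
})

test_that("PiB positivity flips exactly at the SUVR cut-off", {
  expect_equal(classify_pib_status(c(1.1499, 1.15, 2.0)),
               c("negative", "positive", "positive"))
  expect_equal(classify_pib_status(1.3, cutoff = 1.4), "negative")
  expect_error(classify_pib_status(-1), class = "amynet_domain_error")
})

test_that("residualization is an exact OLS projection", {
  set.seed(7)
  n <- 24
  cov <- data.frame(gm = runif(n, 0.6, 0.9), age = rnorm(n, 70, 6),
                    gender = sample(c("F", "M"), n, TRUE))
  grp <- rep(c("patient", "control"), each = n / 2)

  # constant covariates degrade to demeaning
  cov_const <- data.frame(gm = rep(0.8, n), age = rep(70, n),
                          gender = rep("F", n))
  y <- rnorm(n)
  r0 <- residualize(y, cov_const)
  expect_equal(r0$residuals, y - mean(y), tolerance = 1e-12)

  # a metric exactly linear in age leaves zero residuals
  y_lin <- 2 + 0.3 * cov$age
  expect_lt(max(abs(residualize(y_lin, cov)$residuals)), 1e-10)

  # residuals orthogonal to every covariate; idempotent
  r1 <- residualize(y, cov)
  g_num <- as.numeric(cov$gender == "F")
  expect_lt(abs(sum(r1$residuals * cov$age)), 1e-8)
  expect_lt(abs(sum(r1$residuals * cov$gm)), 1e-8)
  expect_lt(abs(sum(r1$residuals * g_num)), 1e-8)
  expect_equal(residualize(r1$residuals, cov)$residuals, r1$residuals,
               tolerance = 1e-10)

  # per-group scope: residuals orthogonal within each group
  r2 <- residualize(y, cov, scope = "per_group", group = grp)
  for (g in unique(grp)) {
    i <- grp == g
    expect_lt(abs(sum(r2$residuals[i] * cov$age[i])), 1e-8)
    expect_lt(abs(mean(r2$residuals[i])), 1e-10)
  }

  # collinear covariates are a rank error
  cov_bad <- cov; cov_bad$gm <- 2 * cov_bad$age + 1
  expect_error(residualize(y, cov_bad), class = "amynet_rank_error")
})
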