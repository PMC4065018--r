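test_that("network templates have the designed geometry", {
  des <- cohort_design()
  tpl <- make_network_templates(des)
  expect_named(tpl, des$networks)
  for (nm in des$networks) {
    vals <- tpl[[nm]]$values
    expect_equal(max(vals),
                 max(des$blob_spec[[nm]]$amplitude), tolerance = 1e-6)
    expect_gte(sum(vals > 1), 2000)  # non-trivial z>1 voxel sets
    expect_true(all(vals >= 0))
  }
  # value at a blob centre equals its amplitude
  b <- des$blob_spec$aDMN[1, ]
  ijk <- round(c(b$cx, b$cy, b$cz) / des$voxel_size_mm) + 1
  expect_equal(tpl$aDMN$values[ijk[1], ijk[2], ijk[3]], b$amplitude,
               tolerance = 1e-3)
})

test_that("degenerate templates raise a generation error", {
  des <- small_design(1)
  des$blob_spec$netA$amplitude <- 0
  expect_error(make_network_templates(des), class = "amynet_generation_error")
})

test_that("spatially disjoint templates are nearly uncorrelated", {
  des <- small_design(1, networks = c("netA", "netB"), coupled = c(TRUE, TRUE),
                      grid = c(30, 26, 26))
  tpl <- make_network_templates(des)
  r <- cor(as.vector(tpl$netA$values), as.vector(tpl$netB$values))
  expect_lt(abs(r), 0.2)
})

test_that("cohort generation is bitwise reproducible from the seed", {
  des <- small_design(7, n_patients = 2, n_controls = 2)
  c1 <- generate_cohort(des)
  c2 <- generate_cohort(des)
  expect_identical(c1[[1]]$pib_map$values, c2[[1]]$pib_map$values)
  expect_identical(c1[[3]]$connectivity_maps$netA$values,
                   c2[[3]]$connectivity_maps$netA$values)
  expect_identical(vapply(c1, `[[`, numeric(1), "age"),
                   vapply(c2, `[[`, numeric(1), "age"))
  c3 <- generate_cohort(small_design(8, n_patients = 2, n_controls = 2))
  expect_false(identical(c1[[1]]$pib_map$values, c3[[1]]$pib_map$values))
})

test_that("neocortical SUVR always separates the groups at 1.15", {
  for (seed in 1:4) {
    coh <- generate_cohort(small_design(seed, n_patients = 8, n_controls = 8,
                                        grid = c(20, 20, 20)))
    suvr <- vapply(coh, `[[`, numeric(1), "neocortical_suvr")
    grp <- vapply(coh, `[[`, character(1), "group")
    expect_true(all(suvr[grp == "patient"] >= 1.15))
    expect_true(all(suvr[grp == "control"] < 1.15))
  }
})

test_that("negative couplings are rejected", {
  expect_error(cohort_design(b_global = c(patient = -1, control = 0)),
               class = "amynet_domain_error")
  expect_error(cohort_design(c_local = c(patient = 0, control = -0.1)),
               class = "amynet_domain_error")
})

test_that("cohort round-trips through the on-disk manifest", {
  coh <- generate_cohort(small_design(3, n_patients = 1, n_controls = 1,
                                      grid = c(16, 16, 16)))
  dir <- file.path(tempfile(), "cohort")
  mf <- write_cohort(coh, dir)
  tab <- read.csv(mf)
  expect_equal(nrow(tab), 2)
  expect_true(all(file.exists(file.path(dir, c(tab$pib_path, tab$gm_path,
                                               tab$net1_path)))))
  coh2 <- read_cohort(mf)
  expect_identical(coh2[[1]]$pib_map$values, coh[[1]]$pib_map$values)
  expect_identical(names(coh2[[2]]$connectivity_maps),
                   names(coh[[2]]$connectivity_maps))
  expect_equal(coh2[[2]]$age, coh[[2]]$age)

  # corrupt the manifest: missing file must be a validation error
  file.remove(file.path(dir, tab$gm_path[1]))
  expect_error(read_cohort(mf), class = "amynet_validation_error")

  # duplicate ids rejected at write time
  coh_dup <- c(coh, coh[1])
  expect_error(write_cohort(coh_dup, tempfile()),
               class = "amynet_validation_error")
})

test_that("null cohorts carry no spurious coupling and injected signs recover", {
  offs <- sphere_offsets(6, c(2, 2, 2))
  run_cohort <- function(des) {
    coh <- generate_cohort(des)
    grp <- vapply(coh, `[[`, character(1), "group")
    vals <- t(vapply(coh, function(s) {
      nvs <- select_network_voxels(s, "netA")
      c(rg = r_global(nvs)$r_global,
        rl = median_rlocal(symmetric_rlocal(nvs, offs)))
    }, numeric(2)))
    list(rg = vals[, 1], rl = vals[, 2], grp = grp)
  }
  # couplings off: both statistics centred near zero (cohort of 20,
  # averaged over subjects and networks)
  null_des <- cohort_design(n_patients = 10, n_controls = 10,
                            b_global = c(patient = 0, control = 0),
                            c_local = c(patient = 0, control = 0), seed = 21)
  null_coh <- generate_cohort(null_des)
  vals <- do.call(rbind, lapply(null_coh, function(s) {
    t(vapply(null_des$networks, function(nm) {
      nvs <- select_network_voxels(s, nm)
      c(rg = r_global(nvs)$r_global,
        rl = median_rlocal(symmetric_rlocal(nvs, offs)))
    }, numeric(2)))
  }))
  expect_lt(abs(mean(vals[, "rg"])), 0.05)
  expect_lt(abs(mean(vals[, "rl"])), 0.05)

  # global coupling only: patient r_GLOBAL positive and above controls
  gl <- run_cohort(small_design(22, b = 0.3))
  expect_gt(mean(gl$rg[gl$grp == "patient"]), 0)
  expect_gt(mean(gl$rg[gl$grp == "patient"]),
            mean(gl$rg[gl$grp == "control"]))

  # local coupling only: patient median r_LOCAL negative and below controls
  lo <- run_cohort(small_design(23, cl = 0.6))
  expect_lt(mean(lo$rl[lo$grp == "patient"]), 0)
  expect_lt(mean(lo$rl[lo$grp == "patient"]),
            mean(lo$rl[lo$grp == "control"]))
})
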