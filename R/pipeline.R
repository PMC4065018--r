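#' Pipeline run configuration
#'
#' Bundles every tunable of the full analysis. A run consumes either a
#' simulation `design` or a cohort `manifest` written by [write_cohort()].
#'
#' @param design A [cohort_design] (used when `manifest` is `NULL`).
#' @param manifest Optional path to a cohort manifest CSV.
#' @param z_threshold Network-voxel connectivity threshold (strict `>`).
#' @param log_transform Log-transform connectivity before correlations.
#' @param radius_mm Searchlight radius in mm (> 0).
#' @param min_neighbors Minimum searchlight neighbourhood size (>= 3).
#' @param min_network_size Minimum admissible network voxel count.
#' @param covariate_scope `"pooled"` or `"per_group"` residualization.
#' @param match_networks Run template matching of group-mean connectivity
#'   maps against the design templates as a labelling check (simulated runs
#'   only).
#' @param subsample_draws Draws for the patient-subsampling control
#'   (0 disables it).
#' @param tmap_networks Networks for which a voxel-wise group t-map of
#'   connectivity is computed (empty disables; expensive stage).
#' @param tmap_permutations Permutations for cluster-extent correction.
#' @param alpha Significance level used in report flags.
#' @param seed Seed for all pipeline-level randomness (subsampling,
#'   permutations).
#' @param outdir Optional output directory for tables, maps and the JSON
#'   report.
#' @return A classed list (`pipeline_config`).
#' @export
pipeline_config <- function(design = cohort_design(),
                            manifest = NULL,
                            z_threshold = 1,
                            log_transform = TRUE,
                            radius_mm = 6,
                            min_neighbors = 25L,
                            min_network_size = 200L,
                            covariate_scope = c("pooled", "per_group"),
                            match_networks = TRUE,
                            subsample_draws = 0L,
                            tmap_networks = character(),
                            tmap_permutations = 200L,
                            alpha = 0.05,
                            seed = 1L,
                            outdir = NULL) {
  covariate_scope <- match.arg(covariate_scope)
  if (!is.finite(radius_mm) || radius_mm <= 0)
    amy_stop("`radius_mm` must be positive", "amynet_validation_error")
  if (min_neighbors < 3)
    amy_stop("`min_neighbors` must be >= 3", "amynet_validation_error")
  if (z_threshold <= 0)
    amy_stop("`z_threshold` must be positive", "amynet_validation_error")
  if (is.null(manifest) && !inherits(design, "cohort_design"))
    amy_stop("provide a cohort_design or a manifest path",
             "amynet_validation_error")
  structure(list(design = design, manifest = manifest,
                 z_threshold = z_threshold, log_transform = log_transform,
                 radius_mm = radius_mm,
                 min_neighbors = as.integer(min_neighbors),
                 min_network_size = as.integer(min_network_size),
                 covariate_scope = covariate_scope,
                 match_networks = match_networks,
                 subsample_draws = as.integer(subsample_draws),
                 tmap_networks = tmap_networks,
                 tmap_permutations = as.integer(tmap_permutations),
                 alpha = alpha, seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' Per-subject, per-network metric table
#'
#' Runs voxel selection, median PiB, grey-matter median, the connectivity
#' score, r_GLOBAL and the bidirectional searchlight median r_LOCAL for every
#' subject and network.
#'
#' @param subjects List of [subject_record].
#' @param config A [pipeline_config].
#' @return Data frame with one row per subject x network: `subject_id`,
#'   `group`, `network`, `age`, `gender`, `neocortical_suvr`, `pib_status`,
#'   `n_voxels`, `median_pib`, `gm_median`, `net_score`, `r_global`,
#'   `fisher_z`, `median_rlocal`, `n_sl_voxels`, `n_skipped_small`,
#'   `n_skipped_variance`.
#' @export
analyze_cohort <- function(subjects, config = pipeline_config()) {
  offs <- sphere_offsets(config$radius_mm, subjects[[1]]$pib_map$voxel_size_mm)
  net_names <- names(subjects[[1]]$connectivity_maps)
  rows <- list()
  for (s in subjects) {
    for (nm in net_names) {
      nvs <- select_network_voxels(s, nm, config$z_threshold,
                                   config$min_network_size)
      rg <- r_global(nvs, config$log_transform)
      sl <- symmetric_rlocal(nvs, offs, config$min_neighbors,
                             config$log_transform)
      sel <- nvs$voxel_indices
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s$subject_id, group = s$group, network = nm,
        age = s$age, gender = s$gender,
        neocortical_suvr = s$neocortical_suvr,
        pib_status = classify_pib_status(s$neocortical_suvr),
        n_voxels = rg$n_voxels,
        median_pib = median_network_pib(nvs),
        gm_median = stats::median(s$gm_map$values[sel]),
        net_score = network_connectivity_score(nvs),
        r_global = rg$r_global, fisher_z = rg$fisher_z,
        median_rlocal = median_rlocal(sl),
        n_sl_voxels = sum(sl$valid_mask$values),
        n_skipped_small = sl$n_skipped_small,
        n_skipped_variance = sl$n_skipped_variance,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# residualize one metric column network-by-network; returns vector aligned
# with the metric table
residualize_metric <- function(metrics, column, scope) {
  res <- numeric(nrow(metrics))
  for (nm in unique(metrics$network)) {
    i <- which(metrics$network == nm)
    res[i] <- residualize(
      metrics[[column]][i],
      data.frame(gm = metrics$gm_median[i], age = metrics$age[i],
                 gender = metrics$gender[i]),
      scope = scope, group = metrics$group[i])$residuals
  }
  res
}

# subject x network matrix of one (residualized) metric column
metric_matrix <- function(metrics, column) {
  nets <- unique(metrics$network)
  subs <- unique(metrics$subject_id)
  M <- matrix(NA_real_, length(subs), length(nets),
              dimnames = list(subs, nets))
  M[cbind(match(metrics$subject_id, subs), match(metrics$network, nets))] <-
    metrics[[column]]
  M
}

#' Cohort-level statistics on a metric table
#'
#' Residualizes median PiB, Fisher-z r_GLOBAL and median r_LOCAL against
#' grey-matter median, age and gender (per network), then runs for each
#' metric: the mixed group x network ANOVA, per-network two-sample t-tests
#' (Bonferroni family = number of networks), per-network one-sample t-tests
#' of median r_LOCAL against 0 within each group, the across-subject
#' correlation of median PiB with r_GLOBAL (per group, pooled over networks
#' and per network), and optionally the patient-subsampling control.
#'
#' @param metrics Output of [analyze_cohort()].
#' @param config A [pipeline_config].
#' @return List of result tables and test objects (see report structure of
#'   [run_pipeline()]).
#' @export
cohort_statistics <- function(metrics, config = pipeline_config()) {
  scope <- config$covariate_scope
  nets <- unique(metrics$network)
  fam <- length(nets)
  metrics$median_pib_resid <- residualize_metric(metrics, "median_pib", scope)
  metrics$fisher_z_resid <- residualize_metric(metrics, "fisher_z", scope)
  metrics$median_rlocal_resid <-
    residualize_metric(metrics, "median_rlocal", scope)

  subs <- unique(metrics$subject_id)
  grp <- metrics$group[match(subs, metrics$subject_id)]

  anovas <- lapply(c(median_pib = "median_pib_resid",
                     r_global = "fisher_z_resid",
                     median_rlocal = "median_rlocal_resid"),
                   function(col) mixed_anova(metric_matrix(metrics, col), grp))

  posthoc <- do.call(rbind, lapply(
    c("median_pib_resid", "fisher_z_resid", "median_rlocal_resid"),
    function(col) do.call(rbind, lapply(nets, function(nm) {
      i <- metrics$network == nm
      tt <- two_sample_t(metrics[[col]][i & metrics$group == "patient"],
                         metrics[[col]][i & metrics$group == "control"],
                         family_size = fam)
      data.frame(metric = sub("_resid$", "", col), network = nm,
                 t = tt$statistic, df = tt$df, p_raw = tt$p_raw,
                 p_corrected = tt$p_corrected, stringsAsFactors = FALSE)
    }))))

  one_sample <- do.call(rbind, lapply(c("patient", "control"), function(g)
    do.call(rbind, lapply(nets, function(nm) {
      i <- metrics$network == nm & metrics$group == g
      tt <- one_sample_t(metrics$median_rlocal[i], 0, family_size = fam)
      data.frame(group = g, network = nm, t = tt$statistic, df = tt$df,
                 p_raw = tt$p_raw, p_corrected = tt$p_corrected,
                 stringsAsFactors = FALSE)
    }))))

  pib_rg <- lapply(c(patient = "patient", control = "control"), function(g) {
    i <- metrics$group == g
    pooled <- pib_vs_rglobal_correlation(metrics$median_pib[i],
                                         metrics$r_global[i])
    per_net <- do.call(rbind, lapply(nets, function(nm) {
      j <- i & metrics$network == nm
      ct <- pib_vs_rglobal_correlation(metrics$median_pib[j],
                                       metrics$r_global[j])
      data.frame(network = nm, r = ct$r, p_raw = ct$p_raw, n = ct$n,
                 stringsAsFactors = FALSE)
    }))
    list(pooled = pooled, per_network = per_net)
  })

  subsamp <- NULL
  if (config$subsample_draws > 0 &&
      sum(grp == "patient") > sum(grp == "control")) {
    subsamp <- lapply(stats::setNames(nets, nets), function(nm) {
      i <- metrics$network == nm
      sub_grp <- metrics$group[i]
      lapply(c(r_global = "fisher_z_resid",
               median_rlocal = "median_rlocal_resid"), function(col) {
        sc <- subsample_control(metrics[[col]][i], sub_grp,
                                n_draws = config$subsample_draws,
                                seed = config$seed, alpha = config$alpha)
        list(frac_significant = sc$frac_significant, n_draws = sc$n_draws)
      })
    })
  }

  list(metrics = metrics, anovas = anovas, posthoc = posthoc,
       one_sample_rlocal = one_sample, pib_vs_rglobal = pib_rg,
       subsampling = subsamp)
}

#' Run the full analysis pipeline
#'
#' Executes the complete study workflow: obtain the cohort (simulate from the
#' design or load a manifest), optionally confirm network labelling by
#' template matching of group-mean connectivity maps, compute the
#' subject x network metric table, residualize, and run the cohort-level
#' statistics. With `outdir` set, writes `metrics.csv`, `report.json` and a
#' file inventory with content hashes. Identical config and seed give an
#' identical report.
#'
#' @param config A [pipeline_config].
#' @return The run report (list), invisibly when `outdir` is set.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  subjects <- if (!is.null(config$manifest)) read_cohort(config$manifest)
  else generate_cohort(config$design)

  match_tab <- NULL
  if (config$match_networks && is.null(config$manifest)) {
    templates <- make_network_templates(config$design)
    comp <- lapply(names(subjects[[1]]$connectivity_maps), function(nm) {
      acc <- Reduce(`+`, lapply(subjects, function(s)
        s$connectivity_maps[[nm]]$values)) / length(subjects)
      volume_map(acc, config$design$voxel_size_mm)
    })
    masks <- lapply(templates, function(t)
      volume_map(array(as.numeric(t$values > 1), dim(t$values)),
                 t$voxel_size_mm))
    match_tab <- match_components(comp, masks)
  }

  metrics <- analyze_cohort(subjects, config)
  stats_out <- cohort_statistics(metrics, config)

  tmaps <- NULL
  if (length(config$tmap_networks) > 0) {
    grp_of <- vapply(subjects, `[[`, character(1), "group")
    tmaps <- lapply(stats::setNames(config$tmap_networks,
                                    config$tmap_networks), function(nm) {
      maps <- lapply(subjects, `[[`, "connectivity_maps")
      maps <- lapply(maps, `[[`, nm)
      cm <- voxelwise_group_tmap(maps, grp_of, height_p = 1e-3,
                                 min_extent = 20L,
                                 n_permutations = config$tmap_permutations,
                                 seed = config$seed)
      cm$clusters
    })
  }

  sig <- function(p) !is.na(p) & p < config$alpha
  report <- list(
    config = list(z_threshold = config$z_threshold,
                  log_transform = config$log_transform,
                  radius_mm = config$radius_mm,
                  min_neighbors = config$min_neighbors,
                  min_network_size = config$min_network_size,
                  covariate_scope = config$covariate_scope,
                  subsample_draws = config$subsample_draws,
                  alpha = config$alpha, seed = config$seed,
                  simulated = is.null(config$manifest),
                  design_seed = if (is.null(config$manifest))
                    config$design$seed else NA),
    cohort = list(
      n_patients = sum(vapply(subjects, `[[`, character(1), "group") ==
                         "patient"),
      n_controls = sum(vapply(subjects, `[[`, character(1), "group") ==
                         "control"),
      networks = unique(metrics$network),
      pib_positive_patients = sum(metrics$pib_status == "positive" &
                                    metrics$group == "patient") /
        length(unique(metrics$network)),
      skipped_searchlight_voxels = sum(metrics$n_skipped_small),
      zero_variance_neighborhoods = sum(metrics$n_skipped_variance)),
    network_matching = match_tab,
    anova = lapply(stats_out$anovas, function(a)
      list(F_group = a$F_group, df_group = a$df_group, p_group = a$p_group,
           F_network = a$F_network, df_network = a$df_network,
           p_network = a$p_network, F_interaction = a$F_interaction,
           df_interaction = a$df_interaction,
           p_interaction = a$p_interaction)),
    posthoc = stats_out$posthoc,
    one_sample_rlocal = stats_out$one_sample_rlocal,
    pib_vs_rglobal = lapply(stats_out$pib_vs_rglobal, function(g)
      list(pooled = g$pooled, per_network = g$per_network)),
    subsampling = stats_out$subsampling,
    tmap_clusters = tmaps,
    significant_group_effects = list(
      median_pib = sig(stats_out$anovas$median_pib$p_group),
      r_global = sig(stats_out$anovas$r_global$p_group),
      median_rlocal = sig(stats_out$anovas$median_rlocal$p_group)))

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    metrics_path <- file.path(config$outdir, "metrics.csv")
    utils::write.csv(stats_out$metrics, metrics_path, row.names = FALSE)
    files <- "metrics.csv"
    report$files <- data.frame(
      path = files,
      md5 = unname(tools::md5sum(file.path(config$outdir, files))),
      stringsAsFactors = FALSE)
    jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         na = "null")
    return(invisible(report))
  }
  report
}
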