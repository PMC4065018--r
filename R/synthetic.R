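#' Cohort design for the synthetic generator
#'
#' Describes a synthetic multimodal cohort: grid geometry, per-network
#' Gaussian-blob templates standing in for group ICA component maps, group
#' sizes, and the two injected couplings between amyloid load and intrinsic
#' connectivity. The two couplings live at separate spatial scales so each is
#' independently recoverable downstream:
#'
#' * `b_global` scales a wide-smoothed (`w_fwhm_mm`) aggregate of the coupled
#'   network templates added to the PiB map, producing a positive
#'   whole-network correlation between PiB uptake and connectivity (the
#'   r_GLOBAL effect).
#' * `c_local` scales the subject's own local connectivity fluctuation
#'   (connectivity map minus its `local_fwhm_mm` smoothed version), weighted
#'   by template amplitude so it concentrates in network cores, and enters
#'   the PiB map with a negative sign (the r_LOCAL effect).
#'
#' Both couplings apply only to networks flagged in `coupled`; the last
#' network defaults to uncoupled and plays the role of a primary sensory
#' control network. Noise standard deviations are the marginal SD of the
#' smoothed noise fields (white noise is smoothed at `noise_fwhm_mm` and then
#' rescaled), so they are comparable across smoothness settings.
#'
#' Defaults mirror the study conditions the pipeline targets: 23 patients vs
#' 12 controls, seven networks (six coupled heteromodal analogues plus one
#' uncoupled control), 2-mm isotropic voxels, network sizes of a few thousand
#' supra-threshold voxels, patients with elevated PiB baseline and positive
#' neocortical SUVR status (>= 1.15), controls below the cut-off.
#'
#' @param n_patients,n_controls Group sizes.
#' @param grid_dims Integer triple, lattice dimensions.
#' @param voxel_size_mm Numeric triple, voxel edge lengths in mm.
#' @param networks Character vector of network names.
#' @param blob_spec Named list (one entry per network) of data frames with
#'   columns `cx, cy, cz` (blob centre, mm), `sd_mm`, `amplitude`.
#' @param coupled Logical vector per network: does this network participate
#'   in the injected PiB-connectivity couplings?
#' @param b_global Named numeric `c(patient=, control=)`: network-scale
#'   coupling strength (>= 0).
#' @param c_local Named numeric: local negative coupling strength (>= 0).
#' @param pib_baseline Named numeric: group baseline SUVR level of the PiB map.
#' @param suvr_mean Named numeric: mean neocortical SUVR elevation above /
#'   below the 1.15 cut-off used when drawing the scalar summary SUVR.
#' @param noise_sd_ifc,noise_sd_pib Marginal SD of the smoothed noise added
#'   to connectivity and PiB maps.
#' @param noise_fwhm_mm Smoothness (FWHM, mm) of all noise fields.
#' @param w_fwhm_mm FWHM of the wide kernel defining the global coupling
#'   field (>= 16 mm so it is flat at searchlight scale).
#' @param local_fwhm_mm Scale separating "local fluctuation" from network
#'   structure; matches the 6-mm searchlight radius.
#' @param age_mean,age_sd Named numerics, group age distributions (years).
#' @param p_female Named numerics, probability of gender `F`.
#' @param seed Integer seed making the cohort fully reproducible.
#' @return A classed list (`cohort_design`).
#' @seealso [generate_cohort()], [make_network_templates()]
#' @export
cohort_design <- function(n_patients = 23,
                          n_controls = 12,
                          grid_dims = c(40L, 48L, 38L),
                          voxel_size_mm = c(2, 2, 2),
                          networks = c("aDMN", "pDMN", "lATN", "rATN",
                                       "dATN", "SN", "pAN"),
                          blob_spec = default_blob_spec(networks),
                          coupled = c(rep(TRUE, length(networks) - 1L), FALSE),
                          b_global = c(patient = 0.3, control = 0),
                          c_local = c(patient = 0.6, control = 0),
                          pib_baseline = c(patient = 1.6, control = 1.2),
                          suvr_mean = c(patient = 0.35, control = 0.08),
                          noise_sd_ifc = 0.35,
                          noise_sd_pib = 0.12,
                          noise_fwhm_mm = 8,
                          w_fwhm_mm = 20,
                          local_fwhm_mm = 6,
                          age_mean = c(patient = 69.3, control = 63.8),
                          age_sd = c(patient = 7.4, control = 5.15),
                          p_female = c(patient = 9 / 23, control = 0.6),
                          seed = 1L) {
  groups <- c("patient", "control")
  need_groups <- function(x, nm) {
    if (!all(groups %in% names(x)))
      amy_stop(sprintf("`%s` needs named entries 'patient' and 'control'", nm),
               "amynet_domain_error")
    x[groups]
  }
  b_global <- need_groups(b_global, "b_global")
  c_local <- need_groups(c_local, "c_local")
  if (any(b_global < 0) || any(c_local < 0))
    amy_stop("coupling strengths `b_global`/`c_local` must be >= 0",
             "amynet_domain_error")
  if (n_patients < 1 || n_controls < 1)
    amy_stop("group sizes must be positive", "amynet_domain_error")
  if (length(blob_spec) != length(networks))
    amy_stop("`blob_spec` must have one entry per network",
             "amynet_domain_error")
  if (noise_sd_ifc <= 0 || noise_sd_pib <= 0)
    amy_stop("noise SDs must be positive", "amynet_domain_error")
  for (bs in blob_spec)
    if (any(bs$sd_mm <= 0) || any(bs$amplitude < 0))
      amy_stop("blob SDs must be positive and amplitudes non-negative",
               "amynet_domain_error")
  structure(list(n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 grid_dims = as.integer(rep_len(grid_dims, 3L)),
                 voxel_size_mm = rep_len(as.numeric(voxel_size_mm), 3L),
                 networks = networks,
                 blob_spec = stats::setNames(blob_spec, networks),
                 coupled = stats::setNames(rep_len(coupled, length(networks)),
                                           networks),
                 b_global = b_global, c_local = c_local,
                 pib_baseline = need_groups(pib_baseline, "pib_baseline"),
                 suvr_mean = need_groups(suvr_mean, "suvr_mean"),
                 noise_sd_ifc = noise_sd_ifc, noise_sd_pib = noise_sd_pib,
                 noise_fwhm_mm = noise_fwhm_mm, w_fwhm_mm = w_fwhm_mm,
                 local_fwhm_mm = local_fwhm_mm,
                 age_mean = need_groups(age_mean, "age_mean"),
                 age_sd = need_groups(age_sd, "age_sd"),
                 p_female = need_groups(p_female, "p_female"),
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' Default blob layout for the synthetic networks
#'
#' Two Gaussian blobs per network, spread over a 80 x 96 x 76 mm lattice.
#' The last network (the control-network analogue) sits inferior and lateral,
#' spatially apart from the heteromodal analogues.
#'
#' @param networks Character vector of network names.
#' @return Named list of blob data frames (`cx, cy, cz, sd_mm, amplitude`).
#' @export
default_blob_spec <- function(networks) {
  blob <- function(cx, cy, cz, sd = 10, amp = 3.5)
    data.frame(cx = cx, cy = cy, cz = cz, sd_mm = sd, amplitude = amp)
  layouts <- list(
    rbind(blob(40, 70, 40), blob(40, 80, 52)),   # anterior midline
    rbind(blob(40, 24, 44), blob(40, 14, 54)),   # posterior midline
    rbind(blob(14, 40, 44), blob(18, 60, 50)),   # left lateral
    rbind(blob(64, 40, 44), blob(60, 60, 50)),   # right lateral
    rbind(blob(28, 32, 64), blob(52, 32, 64)),   # dorsal posterior
    rbind(blob(40, 56, 22), blob(30, 68, 28)),   # fronto-limbic
    rbind(blob(12, 42, 14), blob(66, 42, 14))    # inferior lateral (control)
  )
  n <- length(networks)
  if (n > length(layouts))
    amy_stop("default blob layout supports at most 7 networks",
             "amynet_domain_error")
  stats::setNames(layouts[seq_len(n)], networks)
}

#' Build the noise-free network template maps
#'
#' Each template is the pointwise maximum over that network's Gaussian blobs
#' (`amplitude * exp(-d^2 / (2 sd^2))`, distances in world mm), so values lie
#' in `[0, max amplitude]`. Templates are the ground-truth connectivity
#' patterns to which per-subject noise is added.
#'
#' @param design A [cohort_design].
#' @return Named list of [volume_map] templates, one per network, with the
#'   `coupled` flags attached as an attribute.
#' @export
make_network_templates <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  d <- design$grid_dims
  vs <- design$voxel_size_mm
  cx <- (seq_len(d[1]) - 1) * vs[1]
  cy <- (seq_len(d[2]) - 1) * vs[2]
  cz <- (seq_len(d[3]) - 1) * vs[3]
  templates <- lapply(design$networks, function(nm) {
    bs <- design$blob_spec[[nm]]
    acc <- array(0, d)
    for (b in seq_len(nrow(bs))) {
      dx2 <- outer(outer((cx - bs$cx[b])^2, (cy - bs$cy[b])^2, "+"),
                   (cz - bs$cz[b])^2, "+")
      acc <- pmax(acc, bs$amplitude[b] * exp(-dx2 / (2 * bs$sd_mm[b]^2)))
    }
    n_supra <- sum(acc > 1)
    if (n_supra < 500)
      amy_stop(sprintf(
        "network '%s': only %d voxels exceed z=1 (need >= 500 for searchlight)",
        nm, n_supra), "amynet_generation_error")
    volume_map(acc, vs)
  })
  names(templates) <- design$networks
  attr(templates, "coupled") <- design$coupled
  templates
}

# smoothed unit-variance, zero-mean Gaussian random field
noise_field <- function(dims, voxel_size_mm, sd, fwhm_mm) {
  x <- array(stats::rnorm(prod(dims)), dims)
  if (fwhm_mm > 0)
    x <- smooth_array3d(x, fwhm_to_sigma(fwhm_mm) / voxel_size_mm)
  x <- x - mean(x)
  x * (sd / stats::sd(x))
}

#' Generate a complete synthetic cohort
#'
#' Draws, reproducibly from `design$seed`, one [subject_record] per
#' participant. For subject *k* and network *j* the connectivity z-map is
#' `template_j + noise`; the PiB map is
#' `baseline(group) + b_global(group) * W - c_local(group) * L_k + noise`
#' where `W` is the wide-smoothed aggregate (pointwise maximum, then
#' normalized to unit peak deviation) of the coupled templates (driving the
#' positive whole-network coupling) and `L_k` is the template-weighted sum of
#' the subject's local connectivity fluctuations `z_kj - S(z_kj)` over coupled
#' networks (driving the negative neighbourhood-scale coupling, concentrated
#' in network cores). Grey-matter density declines linearly with age plus a
#' subject-level offset and smooth spatial noise; neocortical SUVR is drawn above 1.15 for every patient and
#' below 1.15 for every control.
#'
#' @param design A [cohort_design].
#' @param templates Optional pre-built [make_network_templates()] output.
#' @return List of [subject_record] objects (patients first).
#' @export
generate_cohort <- function(design, templates = make_network_templates(design)) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  d <- design$grid_dims
  vs <- design$voxel_size_mm
  coupled_names <- design$networks[design$coupled]
  if (length(coupled_names) > 0) {
    tmpl_field <- Reduce(pmax, lapply(templates[coupled_names],
                                      function(t) t$values))
    W <- smooth_array3d(tmpl_field, fwhm_to_sigma(design$w_fwhm_mm) / vs)
    uncoupled <- design$networks[!design$coupled]
    if (length(uncoupled) > 0) {
      # keep the control network genuinely uncoupled: fade the global field
      # to zero inside uncoupled network territory
      u <- Reduce(pmax, lapply(templates[uncoupled], function(t) t$values))
      # the fade hits zero far below the z>1 selection threshold, so every
      # selected control-network voxel sees a flat (zero) coupling field
      W <- W * pmax(0, 1 - u / 0.2)
    }
    W <- (W - mean(W)) / max(abs(W - mean(W)))
  } else {
    W <- array(0, d)
  }
  sig_local <- fwhm_to_sigma(design$local_fwhm_mm) / vs
  amp_max <- vapply(templates, function(t) max(t$values), numeric(1))

  n_total <- design$n_patients + design$n_controls
  groups <- rep(c("patient", "control"),
                c(design$n_patients, design$n_controls))
  ids <- sprintf("sub%02d", seq_len(n_total))

  lapply(seq_len(n_total), function(k) {
    g <- groups[k]
    zmaps <- vector("list", length(design$networks))
    names(zmaps) <- design$networks
    L <- array(0, d)
    for (j in seq_along(design$networks)) {
      nm <- design$networks[j]
      e <- noise_field(d, vs, design$noise_sd_ifc, design$noise_fwhm_mm)
      z <- templates[[nm]]$values + e
      zmaps[[nm]] <- volume_map(z, vs)
      if (design$coupled[j]) {
        # local fluctuation of the subject-specific component only: using
        # z - S(z) directly would fold in the deterministic template
        # curvature and leak a negative coupling into the global scale
        fluct <- e - smooth_array3d(e, sig_local)
        L <- L + (templates[[nm]]$values / amp_max[j]) * fluct
      }
    }
    pib <- design$pib_baseline[[g]] +
      design$b_global[[g]] * W -
      design$c_local[[g]] * L +
      noise_field(d, vs, design$noise_sd_pib, design$noise_fwhm_mm)
    age <- min(max(stats::rnorm(1, design$age_mean[[g]], design$age_sd[[g]]),
                   50), 90)
    gm <- 0.8 - 0.004 * (age - 65) + stats::rnorm(1, 0, 0.04) +
      noise_field(d, vs, 0.03, design$noise_fwhm_mm)
    gm <- pmin(pmax(gm, 0), 1)
    suvr <- if (g == "patient")
      1.15 + abs(stats::rnorm(1, design$suvr_mean[[g]], 0.15))
    else
      1.15 - 0.01 - abs(stats::rnorm(1, design$suvr_mean[[g]], 0.04))
    subject_record(subject_id = ids[k], group = g,
                   connectivity_maps = zmaps,
                   pib_map = volume_map(pib, vs),
                   gm_map = volume_map(gm, vs),
                   age = age,
                   gender = if (stats::runif(1) < design$p_female[[g]]) "F" else "M",
                   neocortical_suvr = suvr)
  })
}

#' One participant's maps and covariates
#'
#' @param subject_id Unique identifier string.
#' @param group `"patient"` or `"control"`.
#' @param connectivity_maps Named list of [volume_map] z-score maps, one per
#'   network.
#' @param pib_map [volume_map] of PiB standardized uptake ratio.
#' @param gm_map [volume_map] of grey-matter density in `[0, 1]`.
#' @param age Years.
#' @param gender `"F"` or `"M"`.
#' @param neocortical_suvr Positive scalar summary SUVR.
#' @return A classed list (`subject_record`).
#' @export
subject_record <- function(subject_id, group, connectivity_maps, pib_map,
                           gm_map, age, gender, neocortical_suvr) {
  if (!group %in% c("patient", "control"))
    amy_stop("group must be 'patient' or 'control'", "amynet_domain_error")
  if (neocortical_suvr <= 0)
    amy_stop("neocortical_suvr must be positive", "amynet_domain_error")
  ref_dim <- dim(pib_map$values)
  for (m in c(connectivity_maps, list(gm_map)))
    if (!identical(dim(m$values), ref_dim))
      amy_stop("all maps of a subject must share one grid", "amynet_dim_error")
  structure(list(subject_id = subject_id, group = group,
                 connectivity_maps = connectivity_maps,
                 pib_map = pib_map, gm_map = gm_map,
                 age = age, gender = gender,
                 neocortical_suvr = neocortical_suvr),
            class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record> %s (%s), age %.1f, %s, SUVR %.3f, %d networks\n",
              x$subject_id, x$group, x$age, x$gender, x$neocortical_suvr,
              length(x$connectivity_maps)))
  invisible(x)
}

#' Write a cohort to disk
#'
#' One NIfTI file per map plus a CSV manifest with columns
#' `subject_id, group, age, gender, neocortical_suvr, pib_path, gm_path,
#' net1_path, ...`. Network names are embedded in the connectivity file names
#' (`<id>_net<j>-<name>.nii.gz`) so [read_cohort()] recovers them.
#'
#' @param subjects List of [subject_record].
#' @param directory Output directory (created if absent).
#' @return Path of the manifest file, invisibly.
#' @export
write_cohort <- function(subjects, directory) {
  ids <- vapply(subjects, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids))
    amy_stop(sprintf("duplicate subject_id: %s",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")),
             "amynet_validation_error")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  net_names <- names(subjects[[1]]$connectivity_maps)
  rows <- lapply(subjects, function(s) {
    pib_path <- sprintf("%s_pib.nii.gz", s$subject_id)
    gm_path <- sprintf("%s_gm.nii.gz", s$subject_id)
    write_volume(s$pib_map, file.path(directory, pib_path))
    write_volume(s$gm_map, file.path(directory, gm_path))
    net_paths <- vapply(seq_along(net_names), function(j) {
      p <- sprintf("%s_net%d-%s.nii.gz", s$subject_id, j, net_names[j])
      write_volume(s$connectivity_maps[[j]], file.path(directory, p))
      p
    }, character(1))
    c(subject_id = s$subject_id, group = s$group,
      age = as.character(s$age), gender = s$gender,
      neocortical_suvr = as.character(s$neocortical_suvr),
      pib_path = pib_path, gm_path = gm_path,
      stats::setNames(net_paths, sprintf("net%d_path", seq_along(net_paths))))
  })
  manifest <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  manifest_path <- file.path(directory, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  invisible(manifest_path)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param manifest_path Path to a cohort `manifest.csv`.
#' @return List of [subject_record].
#' @export
read_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path))
    amy_stop(sprintf("manifest not found: %s", manifest_path),
             "amynet_validation_error")
  mf <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  base <- dirname(manifest_path)
  net_cols <- grep("^net[0-9]+_path$", names(mf), value = TRUE)
  net_cols <- net_cols[order(as.integer(gsub("\\D", "", net_cols)))]
  all_paths <- unlist(mf[c("pib_path", "gm_path", net_cols)])
  missing <- all_paths[!file.exists(file.path(base, all_paths))]
  if (length(missing))
    amy_stop(sprintf("manifest references missing files: %s",
                     paste(utils::head(missing, 5), collapse = ", ")),
             "amynet_validation_error")
  lapply(seq_len(nrow(mf)), function(i) {
    nets <- lapply(mf[i, net_cols], function(p)
      read_volume(file.path(base, p)))
    names(nets) <- vapply(unlist(mf[i, net_cols]), function(p) {
      m <- regmatches(p, regexec("net[0-9]+-([^_.]+)", p))[[1]]
      if (length(m) == 2) m[2] else p
    }, character(1), USE.NAMES = FALSE)
    subject_record(subject_id = mf$subject_id[i], group = mf$group[i],
                   connectivity_maps = nets,
                   pib_map = read_volume(file.path(base, mf$pib_path[i])),
                   gm_map = read_volume(file.path(base, mf$gm_path[i])),
                   age = as.numeric(mf$age[i]), gender = mf$gender[i],
                   neocortical_suvr = as.numeric(mf$neocortical_suvr[i]))
  })
}
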