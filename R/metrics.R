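#' Extract a subject's network voxel set
#'
#' Identifies every voxel whose connectivity z-score strictly exceeds
#' `z_threshold` (default 1) in the subject's back-projected map for one
#' network, and pairs each with the subject's PiB uptake at the same voxel.
#' This voxel set is the common substrate of all downstream per-subject
#' metrics.
#'
#' @param subject A [subject_record].
#' @param network_name Name of a network in `subject$connectivity_maps`.
#' @param z_threshold Connectivity threshold (strict `>`).
#' @param min_size Minimum admissible voxel count; below it the network is
#'   degenerate for searchlight purposes and an error is raised.
#' @return An object of class `network_voxel_set`: `subject_id`,
#'   `network_name`, `voxel_indices` (n x 3 integer matrix, 1-based),
#'   `ifc_values`, `pib_values`, `dim`, `voxel_size_mm`.
#' @export
select_network_voxels <- function(subject, network_name, z_threshold = 1,
                                  min_size = 200L) {
  stopifnot(inherits(subject, "subject_record"))
  zmap <- subject$connectivity_maps[[network_name]]
  if (is.null(zmap))
    amy_stop(sprintf("subject %s has no network '%s'",
                     subject$subject_id, network_name),
             "amynet_domain_error")
  z <- zmap$values
  sel <- which(is.finite(z) & z > z_threshold)
  if (length(sel) < min_size)
    amy_stop(sprintf(
      "subject %s, network %s: %d voxels above z=%g (< %d) - degenerate network",
      subject$subject_id, network_name, length(sel), z_threshold, min_size),
      "amynet_degenerate_network_error")
  idx <- arrayInd(sel, dim(z))
  structure(list(subject_id = subject$subject_id,
                 network_name = network_name,
                 voxel_indices = idx,
                 ifc_values = z[sel],
                 pib_values = subject$pib_map$values[sel],
                 dim = dim(z),
                 voxel_size_mm = zmap$voxel_size_mm),
            class = "network_voxel_set")
}

#' Natural-log transform of connectivity values
#'
#' Connectivity z-scores entering the correlations are log-transformed to
#' reduce the right skew induced by thresholding at z > 1 (all retained
#' values exceed 1, so the log is well defined and positive).
#'
#' @param values Numeric vector, all strictly positive.
#' @return `log(values)`.
#' @export
log_transform_ifc <- function(values) {
  if (any(!is.finite(values)) || any(values <= 0))
    amy_stop("connectivity values must be finite and > 0 for the log transform",
             "amynet_domain_error")
  log(values)
}

#' Median PiB uptake over a network voxel set
#'
#' @param nvs A `network_voxel_set`.
#' @return Sample median (mean of the middle two for even counts).
#' @export
median_network_pib <- function(nvs) {
  if (length(nvs$pib_values) == 0)
    amy_stop("empty voxel set", "amynet_domain_error")
  stats::median(nvs$pib_values)
}

#' Median log-transformed connectivity score of a network
#'
#' The conservative scalar summary of a subject's network connectivity:
#' median of the natural-log-transformed z-scores over all network voxels.
#'
#' @param nvs A `network_voxel_set`.
#' @return Numeric scalar.
#' @export
network_connectivity_score <- function(nvs) {
  stats::median(log_transform_ifc(nvs$ifc_values))
}

#' Whole-network spatial correlation r_GLOBAL
#'
#' Pearson correlation, across all voxels of one subject's network, between
#' (log-transformed) connectivity and PiB uptake, plus its Fisher transform
#' `atanh(r)`. Perfect correlations are clipped to `1 - 1e-7` in magnitude so
#' the Fisher value stays finite.
#'
#' @param nvs A `network_voxel_set`.
#' @param log_transform Use log connectivity (default) or raw z-scores.
#' @return Object of class `global_correlation`: `subject_id`,
#'   `network_name`, `r_global`, `fisher_z`, `n_voxels`.
#' @export
r_global <- function(nvs, log_transform = TRUE) {
  x <- if (log_transform) log_transform_ifc(nvs$ifc_values) else nvs$ifc_values
  y <- nvs$pib_values
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    amy_stop(sprintf(
      "subject %s, network %s: zero variance, correlation undefined",
      nvs$subject_id, nvs$network_name), "amynet_degeneracy_error")
  r <- stats::cor(x, y)
  structure(list(subject_id = nvs$subject_id,
                 network_name = nvs$network_name,
                 r_global = r,
                 fisher_z = fisher_z(r),
                 n_voxels = length(x)),
            class = "global_correlation")
}

#' Fisher transform with clipping
#'
#' `atanh(r)` after clipping `r` to `+/-(1 - 1e-7)`, keeping degenerate
#' perfect correlations finite.
#'
#' @param r Correlation value(s) in `[-1, 1]`.
#' @return Fisher-z value(s).
#' @export
fisher_z <- function(r) atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))

#' Classify PiB status from neocortical SUVR
#'
#' @param neocortical_suvr Positive scalar (or vector) of neocortical
#'   standardized uptake value ratios.
#' @param cutoff Positivity cut-off; uptake at or above it is positive.
#' @return `"positive"` or `"negative"` per input value.
#' @examples
#' classify_pib_status(c(1.1499, 1.15, 2))
#' @export
classify_pib_status <- function(neocortical_suvr, cutoff = 1.15) {
  if (any(!is.finite(neocortical_suvr)) || any(neocortical_suvr <= 0))
    amy_stop("SUVR must be finite and positive", "amynet_domain_error")
  ifelse(neocortical_suvr >= cutoff, "positive", "negative")
}

#' Residualize a per-subject metric against nuisance covariates
#'
#' Ordinary least squares of a metric (median PiB, Fisher-z r_GLOBAL or
#' median r_LOCAL of one network, one value per subject) on median
#' grey-matter density, age and gender (coded F = 1, M = 0), with intercept.
#' The residuals are exactly orthogonal to each fitted covariate. With
#' `scope = "pooled"` one model is fitted across both groups, preserving
#' group mean differences for the downstream ANOVA; `scope = "per_group"`
#' fits each group separately (which also removes group means).
#'
#' Covariates that are constant within a fitted scope are dropped (the fit
#' degrades gracefully to fewer regressors); genuinely collinear covariate
#' pairs raise a rank error.
#'
#' @param metric Numeric vector, one value per subject.
#' @param covariates Data frame with columns `gm`, `age`, `gender` (factor or
#'   `"F"`/`"M"` character).
#' @param scope `"pooled"` or `"per_group"`.
#' @param group Required for `scope = "per_group"`: per-subject labels.
#' @return List with `residuals` (same length as `metric`) and `models`
#'   (per-scope coefficient vectors).
#' @export
residualize <- function(metric, covariates, scope = c("pooled", "per_group"),
                        group = NULL) {
  scope <- match.arg(scope)
  stopifnot(length(metric) == nrow(covariates))
  g_num <- as.numeric(covariates$gender == "F")
  X_all <- cbind(gm = covariates$gm, age = covariates$age, gender = g_num)
  fit_one <- function(idx) {
    if (length(idx) < 5)
      amy_stop("need >= 5 subjects per fitted covariate model",
               "amynet_domain_error")
    X <- X_all[idx, , drop = FALSE]
    keep <- apply(X, 2, function(col) stats::sd(col) > 0)
    X <- X[, keep, drop = FALSE]
    D <- cbind(intercept = 1, X)
    if (qr(D)$rank < ncol(D))
      amy_stop("collinear covariates: design matrix is rank deficient",
               "amynet_rank_error")
    fit <- stats::lm.fit(D, metric[idx])
    list(residuals = fit$residuals, coefficients = fit$coefficients)
  }
  if (scope == "pooled") {
    f <- fit_one(seq_along(metric))
    list(residuals = f$residuals, models = list(pooled = f$coefficients))
  } else {
    if (is.null(group))
      amy_stop("`group` is required for per_group scope", "amynet_domain_error")
    res <- numeric(length(metric))
    models <- list()
    for (g in unique(group)) {
      idx <- which(group == g)
      f <- fit_one(idx)
      res[idx] <- f$residuals
      models[[g]] <- f$coefficients
    }
    list(residuals = res, models = models)
  }
}
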