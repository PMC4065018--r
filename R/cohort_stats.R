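#' Mixed between/within-subject ANOVA (group x network)
#'
#' Classical split-plot decomposition for a complete subject x network table:
#' the group effect is tested against the subjects-within-groups mean square,
#' network and the group x network interaction against the
#' subject-by-network-within-groups mean square. No sphericity correction is
#' applied. Fitted through [stats::aov()] with an `Error(subject)` stratum.
#'
#' @param values Numeric matrix, one row per subject, one column per network
#'   (complete; no missing cells).
#' @param group Per-subject labels (two or more levels, >= 2 subjects each).
#' @return Object of class `mixed_anova_result` with fields `F_group`,
#'   `F_network`, `F_interaction`, their `df_*` pairs and `p_*` values, plus
#'   `cell_means` (group x network).
#' @export
mixed_anova <- function(values, group) {
  values <- as.matrix(values)
  if (any(!is.finite(values)))
    amy_stop("incomplete table: remove subjects with missing networks upstream",
             "amynet_domain_error")
  if (nrow(values) != length(group))
    amy_stop("`group` must have one label per row of `values`",
             "amynet_domain_error")
  if (any(table(group) < 2))
    amy_stop("need >= 2 subjects per group", "amynet_domain_error")
  n_sub <- nrow(values); n_net <- ncol(values)
  if (is.null(colnames(values))) colnames(values) <- paste0("net", seq_len(n_net))
  long <- data.frame(
    y = as.vector(values),
    subject = factor(rep(seq_len(n_sub), times = n_net)),
    group = factor(rep(group, times = n_net)),
    network = factor(rep(colnames(values), each = n_sub),
                     levels = colnames(values)))
  fit <- stats::aov(y ~ group * network + Error(subject), data = long)
  s <- summary(fit)
  between <- s[["Error: subject"]][[1]]
  within <- s[["Error: Within"]][[1]]
  row_of <- function(tab, nm) {
    i <- which(trimws(rownames(tab)) == nm)
    if (!length(i)) amy_stop(paste("missing ANOVA term", nm),
                             "amynet_internal_error")
    tab[i, ]
  }
  g <- row_of(between, "group"); eb <- row_of(between, "Residuals")
  nw <- row_of(within, "network"); ia <- row_of(within, "group:network")
  ew <- row_of(within, "Residuals")
  cm <- tapply(long$y, list(long$group, long$network), mean)
  structure(list(
    F_group = g[["F value"]], df_group = c(g[["Df"]], eb[["Df"]]),
    p_group = g[["Pr(>F)"]],
    F_network = nw[["F value"]], df_network = c(nw[["Df"]], ew[["Df"]]),
    p_network = nw[["Pr(>F)"]],
    F_interaction = ia[["F value"]],
    df_interaction = c(ia[["Df"]], ew[["Df"]]),
    p_interaction = ia[["Pr(>F)"]],
    cell_means = cm), class = "mixed_anova_result")
}

#' @export
print.mixed_anova_result <- function(x, ...) {
  cat(sprintf("Mixed ANOVA: group F(%d,%d) = %.3f, p = %.3g\n",
              x$df_group[1], x$df_group[2], x$F_group, x$p_group))
  cat(sprintf("             network F(%d,%d) = %.3f, p = %.3g\n",
              x$df_network[1], x$df_network[2], x$F_network, x$p_network))
  cat(sprintf("             interaction F(%d,%d) = %.3f, p = %.3g\n",
              x$df_interaction[1], x$df_interaction[2], x$F_interaction,
              x$p_interaction))
  invisible(x)
}

test_result <- function(statistic, df, p_raw, family_size, kind) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_raw = p_raw,
                 p_corrected = min(1, p_raw * family_size),
                 family_size = family_size, kind = kind),
            class = "amynet_test_result")
}

#' Post hoc t-tests with explicit Bonferroni family
#'
#' `two_sample_t` is the Student (pooled-variance) test by default, the
#' convention for the post hoc group comparisons; set `var_equal = FALSE` for
#' Welch. `paired_t` and `one_sample_t` follow the same result contract.
#'
#' @param x,y Numeric samples (>= 3 values each; equal length for paired).
#' @param mu0 Null mean for the one-sample test.
#' @param family_size Bonferroni family size applied to `p_corrected`.
#' @param var_equal Pooled-variance (Student) vs Welch.
#' @return A list of class `amynet_test_result`: `statistic`, `df`, `p_raw`,
#'   `p_corrected = min(1, p_raw * family_size)`, `family_size`, `kind`.
#' @export
two_sample_t <- function(x, y, family_size = 1, var_equal = TRUE) {
  if (length(x) < 3 || length(y) < 3)
    amy_stop("need >= 3 observations per sample", "amynet_domain_error")
  if (stats::sd(c(x, y)) == 0)
    amy_stop("zero variance: t-test undefined", "amynet_degeneracy_error")
  tt <- stats::t.test(x, y, var.equal = var_equal)
  test_result(tt$statistic, tt$parameter, tt$p.value, family_size,
              "two_sample")
}

#' @rdname two_sample_t
#' @export
paired_t <- function(x, y, family_size = 1) {
  if (length(x) != length(y))
    amy_stop("paired samples must have equal length", "amynet_domain_error")
  d <- x - y
  if (length(d) < 3 || stats::sd(d) == 0)
    amy_stop("zero-variance differences: paired t-test undefined",
             "amynet_degeneracy_error")
  tt <- stats::t.test(x, y, paired = TRUE)
  test_result(tt$statistic, tt$parameter, tt$p.value, family_size, "paired")
}

#' @rdname two_sample_t
#' @export
one_sample_t <- function(x, mu0 = 0, family_size = 1) {
  if (length(x) < 3 || stats::sd(x) == 0)
    amy_stop("zero variance: one-sample t-test undefined",
             "amynet_degeneracy_error")
  tt <- stats::t.test(x, mu = mu0)
  test_result(tt$statistic, tt$parameter, tt$p.value, family_size,
              "one_sample")
}

#' Bonferroni correction with explicit family size
#'
#' @param p_values Numeric vector of raw p-values.
#' @param family_size Number of tests in the family (>= `length(p_values)`).
#' @return `pmin(1, p_values * family_size)`.
#' @export
bonferroni <- function(p_values, family_size) {
  if (family_size < length(p_values))
    amy_stop("family_size must be >= number of p-values",
             "amynet_domain_error")
  pmin(1, p_values * family_size)
}

# pooled-variance two-sample t per row of a voxels x subjects matrix
rowwise_t <- function(V, is_g1) {
  n1 <- sum(is_g1); n2 <- sum(!is_g1)
  m1 <- rowMeans(V[, is_g1, drop = FALSE])
  m2 <- rowMeans(V[, !is_g1, drop = FALSE])
  ss1 <- rowSums((V[, is_g1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((V[, !is_g1, drop = FALSE] - m2)^2)
  sp2 <- (ss1 + ss2) / (n1 + n2 - 2)
  (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# 26-connected components of a logical 3-D array; returns integer label array
label_components_26 <- function(mask) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(offs == 0) < 3, , drop = FALSE]
  lab <- array(0L, d)
  todo <- which(mask)
  nxt <- 0L
  for (start in todo) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    lab[start] <- nxt
    frontier <- matrix(arrayInd(start, d), ncol = 3)
    while (nrow(frontier) > 0) {
      nb <- frontier[rep(seq_len(nrow(frontier)), each = nrow(offs)), ,
                     drop = FALSE] +
        offs[rep(seq_len(nrow(offs)), times = nrow(frontier)), , drop = FALSE]
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
      keep <- mask[lin] & lab[lin] == 0L
      lin <- unique(lin[keep])
      if (!length(lin)) break
      lab[lin] <- nxt
      frontier <- matrix(arrayInd(lin, d), ncol = 3)
    }
  }
  lab
}

max_cluster_extent <- function(tvec, map_template, idx_lin, thr) {
  m <- array(FALSE, dim(map_template))
  best <- 0L
  for (sgn in c(1, -1)) {
    m[] <- FALSE
    m[idx_lin] <- sgn * tvec >= thr
    if (!any(m)) next
    lab <- label_components_26(m)
    best <- max(best, max(tabulate(lab[lab > 0L])))
  }
  best
}

#' Voxel-wise two-sample group t-map with cluster-extent thresholding
#'
#' Computes a pooled-variance two-sample t statistic at every in-mask voxel,
#' thresholds at the two-sided height threshold `height_p`, extracts
#' 26-connected clusters of each sign, discards clusters smaller than
#' `min_extent` voxels, and (optionally) assigns each surviving cluster a
#' family-wise corrected p-value from a permutation null of maximum cluster
#' extents (group labels permuted, both signs pooled).
#'
#' @param maps List of [volume_map], one per subject, on one grid.
#' @param group Per-subject labels (first level = first group in the
#'   contrast `group1 - group2`).
#' @param height_p Two-sided voxel-level height threshold (default 1e-4).
#' @param min_extent Minimum cluster extent k in voxels (default 100).
#' @param n_permutations Number of label permutations for corrected cluster
#'   p-values; 0 disables correction. Fewer than 100 triggers a warning.
#' @param mask Optional [volume_map]; only voxels with finite, nonzero mask
#'   values are tested.
#' @param seed Seed for the permutation draw.
#' @return Object of class `cluster_map`: `t_map` ([volume_map], `NaN`
#'   outside the mask), `threshold_t`, `df`, `clusters` (data frame with
#'   `cluster`, `sign`, `extent`, `peak_t`, `p_corrected`), `label_map`.
#' @export
voxelwise_group_tmap <- function(maps, group, height_p = 1e-4,
                                 min_extent = 100L, n_permutations = 0L,
                                 mask = NULL, seed = 1L) {
  d <- dim(maps[[1]]$values)
  V <- vapply(maps, function(m) as.vector(m$values), numeric(prod(d)))
  ok <- rowSums(!is.finite(V)) == 0
  if (!is.null(mask))
    ok <- ok & is.finite(as.vector(mask$values)) & as.vector(mask$values) != 0
  idx_lin <- which(ok)
  V <- V[idx_lin, , drop = FALSE]
  glev <- unique(group)
  if (length(glev) != 2)
    amy_stop("exactly two groups required", "amynet_domain_error")
  is_g1 <- group == glev[1]
  df <- length(group) - 2
  tvec <- rowwise_t(V, is_g1)
  thr <- stats::qt(1 - height_p / 2, df)
  tarr <- array(NaN, d)
  tarr[idx_lin] <- tvec

  lab_all <- array(0L, d)
  clusters <- list()
  cl_id <- 0L
  for (sgn in c(1, -1)) {
    m <- array(FALSE, d)
    m[idx_lin] <- sgn * tvec >= thr
    if (!any(m)) next
    lab <- label_components_26(m)
    sizes <- tabulate(lab[lab > 0L])
    for (l in which(sizes >= min_extent)) {
      cl_id <- cl_id + 1L
      vox <- which(lab == l)
      lab_all[vox] <- cl_id
      clusters[[cl_id]] <- data.frame(
        cluster = cl_id, sign = sgn, extent = sizes[l],
        peak_t = sgn * max(sgn * tarr[vox]), p_corrected = NA_real_)
    }
  }
  clusters <- if (length(clusters)) do.call(rbind, clusters) else
    data.frame(cluster = integer(), sign = numeric(), extent = integer(),
               peak_t = numeric(), p_corrected = numeric())

  if (n_permutations > 0 && nrow(clusters) > 0) {
    if (n_permutations < 100)
      warning("fewer than 100 permutations: corrected p-values are coarse")
    set.seed(seed)
    null_max <- vapply(seq_len(n_permutations), function(p) {
      perm <- sample(is_g1)
      max_cluster_extent(rowwise_t(V, perm), tarr, idx_lin, thr)
    }, numeric(1))
    clusters$p_corrected <- vapply(clusters$extent, function(k)
      (1 + sum(null_max >= k)) / (n_permutations + 1), numeric(1))
  }
  structure(list(t_map = volume_map(tarr, maps[[1]]$voxel_size_mm,
                                    maps[[1]]$origin),
                 threshold_t = thr, df = df, clusters = clusters,
                 label_map = volume_map(array(as.numeric(lab_all), d),
                                        maps[[1]]$voxel_size_mm)),
            class = "cluster_map")
}

#' Across-subject correlation of median PiB with r_GLOBAL
#'
#' The subject-level counterpart of the within-subject analyses: does a
#' subject's (network's) overall amyloid burden predict the strength of its
#' PiB-connectivity spatial coupling?
#'
#' @param median_pib,r_global_values Aligned numeric vectors, one value per
#'   subject (optionally pooled over networks).
#' @return List with `r`, `statistic` (t), `df`, `p_raw`, `n`.
#' @export
pib_vs_rglobal_correlation <- function(median_pib, r_global_values) {
  if (length(median_pib) != length(r_global_values) || length(median_pib) < 5)
    amy_stop("need >= 5 aligned subject values", "amynet_domain_error")
  if (stats::sd(median_pib) == 0 || stats::sd(r_global_values) == 0)
    amy_stop("zero variance: correlation undefined", "amynet_degeneracy_error")
  ct <- stats::cor.test(median_pib, r_global_values)
  list(r = unname(ct$estimate), statistic = unname(ct$statistic),
       df = unname(ct$parameter), p_raw = ct$p.value, n = length(median_pib))
}

#' Subsampling control for unequal group sizes
#'
#' Repeatedly draws, without replacement, a patient subgroup matched in size
#' to the control group, re-runs the two-sample comparison on the subset, and
#' reports the fraction of draws significant at `alpha`. Guards against group
#' effects driven purely by the larger patient sample.
#'
#' @param metric Numeric vector, one value per subject.
#' @param group Per-subject labels (`"patient"` / `"control"`).
#' @param n_draws Number of random subgroups.
#' @param seed Seed for reproducible draws.
#' @param alpha Significance threshold applied per draw.
#' @param var_equal Pooled-variance t (default) per draw.
#' @return List with `draws` (data frame `t`, `p` per draw),
#'   `frac_significant`, `n_draws`, `matched` (`TRUE` when groups were
#'   already matched and no subsampling was needed).
#' @export
subsample_control <- function(metric, group, n_draws = 1000L, seed = 1L,
                              alpha = 0.05, var_equal = TRUE) {
  pat <- which(group == "patient"); ctl <- which(group == "control")
  if (length(pat) < length(ctl))
    amy_stop("patient group must not be smaller than control group",
             "amynet_domain_error")
  if (length(pat) == length(ctl)) {
    message("groups already matched in size: subsampling is a no-op")
    tt <- two_sample_t(metric[pat], metric[ctl], var_equal = var_equal)
    return(list(draws = data.frame(t = tt$statistic, p = tt$p_raw),
                frac_significant = as.numeric(tt$p_raw < alpha),
                n_draws = 1L, matched = TRUE))
  }
  set.seed(seed)
  draws <- t(vapply(seq_len(n_draws), function(i) {
    sub <- sample(pat, length(ctl))
    tt <- stats::t.test(metric[sub], metric[ctl], var.equal = var_equal)
    c(t = unname(tt$statistic), p = tt$p.value)
  }, numeric(2)))
  draws <- as.data.frame(draws)
  list(draws = draws,
       frac_significant = mean(draws$p < alpha),
       n_draws = as.integer(n_draws), matched = FALSE)
}
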