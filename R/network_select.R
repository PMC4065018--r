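#' Select networks of interest by spatial template matching
#'
#' For every binary template mask, fits one multiple regression of the
#' flattened mask on all candidate component maps jointly (over voxels finite
#' in every map) and assigns the component with the largest positive
#' coefficient. By default assignment is greedy one-to-one: templates are
#' visited in order of their winning coefficient (largest first) and a
#' component already taken is skipped; ties break toward the lower component
#' index. This mirrors automated component selection after group ICA, where a
#' handful of canonical network masks must each be matched to a distinct
#' component.
#'
#' @param components List of candidate [volume_map] (e.g. ICA component maps).
#' @param templates Named list of binary [volume_map] masks.
#' @param allow_reuse If `TRUE`, a component may win several templates.
#' @return Data frame with one row per template: `template_name`,
#'   `component_index`, `beta` (its multiple-regression coefficient) and
#'   `rank` (1 = strongest match overall).
#' @export
match_components <- function(components, templates, allow_reuse = FALSE) {
  if (length(components) < 1 || length(templates) < 1)
    amy_stop("need at least one component and one template",
             "amynet_domain_error")
  ref_dim <- dim(components[[1]]$values)
  for (m in c(components, templates))
    if (!identical(dim(m$values), ref_dim))
      amy_stop("components and templates must share one grid",
               "amynet_dim_error")
  X <- vapply(components, function(m) as.vector(m$values),
              numeric(prod(ref_dim)))
  ok <- rowSums(!is.finite(X)) == 0
  for (t in templates) ok <- ok & is.finite(as.vector(t$values))
  X <- X[ok, , drop = FALSE]
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    cc <- stats::cor(X)
    dup <- which(abs(cc) > 1 - 1e-12 & upper.tri(cc), arr.ind = TRUE)
    amy_stop(sprintf(
      "rank-deficient component set%s",
      if (nrow(dup)) sprintf(" (duplicates: %s)",
                             paste(sprintf("%d~%d", dup[, 1], dup[, 2]),
                                   collapse = ", ")) else ""),
      "amynet_degeneracy_error")
  }
  beta_mat <- vapply(templates, function(t) {
    y <- as.vector(t$values)[ok]
    qr.coef(qrX, y)[-1]
  }, numeric(length(components)))  # components x templates
  beta_mat <- matrix(beta_mat, nrow = length(components))

  n_t <- length(templates)
  win_idx <- integer(n_t)
  win_beta <- numeric(n_t)
  # numerically equal coefficients count as tied; the lower index wins
  pick <- function(b, idx) {
    m <- max(b)
    idx[b >= m - 1e-9 * max(1, abs(m))][1]
  }
  if (allow_reuse) {
    for (t in seq_len(n_t)) {
      win_idx[t] <- pick(beta_mat[, t], seq_len(nrow(beta_mat)))
      win_beta[t] <- beta_mat[win_idx[t], t]
    }
  } else {
    taken <- rep(FALSE, length(components))
    assigned <- rep(FALSE, n_t)
    # greedy by descending best-available coefficient
    while (!all(assigned)) {
      open <- which(!assigned)
      avail <- which(!taken)
      best_c <- vapply(open, function(t)
        pick(beta_mat[avail, t], avail), integer(1))
      best_b <- beta_mat[cbind(best_c, open)]
      sel <- which.max(best_b)
      win_idx[open[sel]] <- best_c[sel]
      win_beta[open[sel]] <- best_b[sel]
      taken[best_c[sel]] <- TRUE
      assigned[open[sel]] <- TRUE
    }
  }
  out <- data.frame(template_name = names(templates),
                    component_index = win_idx,
                    beta = win_beta,
                    stringsAsFactors = FALSE)
  out$rank <- rank(-out$beta, ties.method = "first")
  out
}
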