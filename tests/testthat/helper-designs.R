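# Shared fixtures and independent oracles, all built in code at test time.

# one-network design on a small grid; couplings off unless given
small_design <- function(seed, b = 0, cl = 0, n_patients = 10,
                         n_controls = 10, networks = "netA",
                         coupled = TRUE, grid = c(26, 26, 26)) {
  blobs <- stats::setNames(rep(list(
    data.frame(cx = 26, cy = 26, cz = 26, sd_mm = 10, amplitude = 3.5)),
    length(networks)), networks)
  if (length(networks) > 1)  # spread multi-network blobs apart
    for (j in seq_along(networks))
      blobs[[j]]$cx <- 14 + 24 * ((j - 1) %% 2)
  cohort_design(n_patients = n_patients, n_controls = n_controls,
                grid_dims = grid, networks = networks, coupled = coupled,
                blob_spec = blobs,
                b_global = c(patient = b, control = 0),
                c_local = c(patient = cl, control = 0),
                seed = seed)
}

# subject with hand-chosen connectivity and PiB arrays on one grid
toy_subject <- function(zvals, pibvals, id = "toy", group = "patient",
                        vox = c(2, 2, 2)) {
  gm <- volume_map(array(0.8, dim(zvals)), vox)
  subject_record(subject_id = id, group = group,
                 connectivity_maps = list(net = volume_map(zvals, vox)),
                 pib_map = volume_map(pibvals, vox), gm_map = gm,
                 age = 70, gender = "F", neocortical_suvr = 1.5)
}

# ---- independent oracles -------------------------------------------------

# textbook Pearson r from raw sums
pearson_oracle <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# brute-force lattice points in a closed world-space ball
ball_count_oracle <- function(radius, vox) {
  h <- 10L
  g <- expand.grid(i = -h:h, j = -h:h, k = -h:h)
  sum((g$i * vox[1])^2 + (g$j * vox[2])^2 + (g$k * vox[3])^2 <=
        radius^2 + 1e-9)
}

# searchlight value at one centre by explicit neighbour enumeration
rlocal_oracle_voxel <- function(x, y, idx, centre_row, radius, vox,
                                min_neighbors = 25) {
  dd <- sweep(idx, 2, idx[centre_row, ])
  dist2 <- (dd[, 1] * vox[1])^2 + (dd[, 2] * vox[2])^2 + (dd[, 3] * vox[3])^2
  nb <- which(dist2 <= radius^2 + 1e-9)
  if (length(nb) < min_neighbors) return(NA_real_)
  atanh(min(max(cor(x[nb], y[nb]), -(1 - 1e-7)), 1 - 1e-7))
}

# classical split-plot sums of squares for a balanced group x network table
mixed_anova_oracle <- function(M, group) {
  N <- nrow(M); J <- ncol(M)
  grand <- mean(M)
  subj_means <- rowMeans(M)
  net_means <- colMeans(M)
  glev <- unique(group)
  G <- length(glev)
  n_g <- as.vector(table(factor(group, glev)))
  g_means <- tapply(subj_means, factor(group, glev), mean)
  ss_between_sub <- J * sum((subj_means - grand)^2)
  ss_group <- J * sum(n_g * (g_means - grand)^2)
  ss_subj_within <- ss_between_sub - ss_group
  ss_network <- N * sum((net_means - grand)^2)
  cell <- matrix(NA_real_, G, J)
  for (g in seq_len(G)) cell[g, ] <- colMeans(M[group == glev[g], , drop = FALSE])
  ss_cells <- 0
  for (g in seq_len(G)) ss_cells <- ss_cells + n_g[g] * sum((cell[g, ] - grand)^2)
  ss_int <- ss_cells - ss_group - ss_network
  ss_total <- sum((M - grand)^2)
  ss_err_within <- ss_total - ss_between_sub - ss_network - ss_int
  df_g <- G - 1; df_sw <- N - G
  df_n <- J - 1; df_i <- (G - 1) * (J - 1); df_ew <- (N - G) * (J - 1)
  list(F_group = (ss_group / df_g) / (ss_subj_within / df_sw),
       F_network = (ss_network / df_n) / (ss_err_within / df_ew),
       F_interaction = (ss_int / df_i) / (ss_err_within / df_ew))
}

# pooled-variance two-sample t from first principles
pooled_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}
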