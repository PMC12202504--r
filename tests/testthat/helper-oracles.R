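# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each quantity so they stay
# independent of the implementation they check.

# all-pairs nearest-mask-voxel distance in mm
brute_force_distance <- function(mask_values, spacing) {
  d <- dim(mask_values)
  coords <- which(mask_values, arr.ind = TRUE)
  out <- array(NA_real_, dim = d)
  all_idx <- which(array(TRUE, d), arr.ind = TRUE)
  for (i in seq_len(nrow(all_idx))) {
    dd <- sweep(coords, 2, all_idx[i, ]) %*% diag(spacing)
    out[i] <- sqrt(min(rowSums(dd^2)))
  }
  out
}

# pairwise concordance AUC with ties counted 1/2 (greater-is-positive)
concordance_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# a small straight-tube phantom used by several files
small_phantom <- function(shape = c(36, 36, 16), noise_sd = 0, seed = 1,
                          close = -70, distant = -80) {
  make_phantom(phantom_spec(shape = shape, lumen_radius_mm = 3,
                            wall_thickness_mm = 1.5,
                            hu_fat_close = close, hu_fat_distant = distant,
                            noise_sd = noise_sd, seed = seed))
}

# two-group cohort with only the attenuation markers separating the groups,
# plus nuisance covariates correlated with the markers but with no
# conditional effect on the outcome
markers_only_cohort <- function(seed) {
  set.seed(seed)
  n1 <- 56; n2 <- 76
  hu_delta <- c(rnorm(n1, 8.75, 3.29), rnorm(n2, 5.16, 2.84))
  hu_ratio <- c(rnorm(n1, 0.73, 0.13), rnorm(n2, 0.85, 0.11))
  data.frame(
    outcome = factor(rep(c("residual", "closed"), c(n1, n2)),
                     levels = c("residual", "closed")),
    hu_delta = hu_delta, hu_ratio = hu_ratio,
    nz1 = 0.5 * scale(hu_delta)[, 1] + rnorm(n1 + n2),
    nz2 = -0.5 * scale(hu_ratio)[, 1] + rnorm(n1 + n2),
    nz3 = rnorm(n1 + n2))
}
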