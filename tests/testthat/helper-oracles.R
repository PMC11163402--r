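# Shared fixtures and independent oracles, kept deliberately naive so
# they stay independent of the implementation paths they check.

# small synthetic designs used across tests
tiny_config <- function(..., n_rois = 8, seed = 42) {
  simulation_config(n_controls_f = 2, n_controls_m = 2, n_patients_f = 2,
                    n_patients_m = 2, n_responders = 2, n_rois = n_rois,
                    seed = seed, ...)
}

controls_only_config <- function(..., n_rois = 8, seed = 42) {
  simulation_config(n_controls_f = 2, n_controls_m = 2, n_patients_f = 0,
                    n_patients_m = 0, n_responders = 0, n_rois = n_rois,
                    seed = seed, ...)
}

# explicit double loop over unordered unit pairs
loop_effect_average <- function(z, mask) {
  n <- ncol(z)
  total <- 0
  count <- 0
  for (u in seq_len(n - 1)) {
    for (v in (u + 1):n) {
      if (mask[u, v]) {
        total <- total + z[u, v]
        count <- count + 1
      }
    }
  }
  total / count
}

# brute-force BH step-up: largest k with p_(k) <= k q / m
brute_force_bh <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  k <- max(c(0, which(p[ord] <= seq_len(m) * q / m)))
  rej <- rep(FALSE, m)
  if (k > 0) rej[ord[seq_len(k)]] <- TRUE
  rej
}

# exhaustive sign-flip distribution of the paired t statistic
exhaustive_perm_p <- function(d) {
  n <- length(d)
  t_of <- function(x) mean(x) / (sd(x) / sqrt(n))
  t_obs <- t_of(d)
  flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  t_all <- apply(flips, 1, function(s) t_of(s * d))
  mean(abs(t_all) >= abs(t_obs) - 1e-12)
}

# naive per-timepoint parcel means
loop_parcel_means <- function(voxel_data, labels) {
  ids <- sort(unique(labels))
  out <- matrix(NA_real_, nrow(voxel_data), length(ids))
  for (k in seq_along(ids)) {
    cols <- which(labels == ids[k])
    for (t in seq_len(nrow(voxel_data))) {
      out[t, k] <- mean(voxel_data[t, cols])
    }
  }
  colnames(out) <- as.character(ids)
  out
}
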