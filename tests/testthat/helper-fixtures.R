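# Fixtures and independent oracles used across the suite.

# exact Cox partial log-likelihood for one covariate with distinct event
# times (no ties); independent of the survival package
exact_coxpl <- function(beta, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  ll <- 0
  for (i in seq_along(time)) {
    if (!event[i]) next
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# brute-force maximum of the exact partial likelihood on a bounded grid;
# returns NA when the maximiser sits at the boundary (separation)
brute_force_cox <- function(time, event, x, bound = 8) {
  opt <- optimize(function(b) exact_coxpl(b, time, event, x),
                  interval = c(-bound - 2, bound + 2), maximum = TRUE,
                  tol = 1e-10)
  if (abs(opt$maximum) > bound) return(NA_real_)
  opt$maximum
}

# Spearman rank correlation from first principles (Pearson on mid-ranks)
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

ball_fixture <- function(radius_mm = 20, spacing = 1, seed = 1) {
  generate_shape(shape_spec("ball", radius_mm = radius_mm,
                            spacing = spacing, seed = seed))
}

# two balls separated by a gap of >= 2 background voxels along x
bifocal_fixture <- function(radius_vox = 4, gap_vox = 3) {
  r <- radius_vox
  n1 <- 2 * r + 5
  nx <- 2 * n1 + gap_vox
  vox <- array(0L, dim = c(nx, n1, n1))
  ctr <- c((n1 - 1) / 2, (n1 - 1) / 2, (n1 - 1) / 2)
  ax <- seq_len(n1) - 1
  d2 <- outer(outer((ax - ctr[1])^2, (ax - ctr[2])^2, `+`),
              (ax - ctr[3])^2, `+`)
  ball <- array(as.integer(d2 <= r^2), dim = c(n1, n1, n1))
  vox[seq_len(n1), , ] <- ball
  vox[n1 + gap_vox + seq_len(n1), , ] <- ball
  segmentation_mask(vox, spacing = c(1, 1, 1), role = "tumor_pre")
}

measure_ball_si <- function(radius_mm, spacing) {
  m <- ball_fixture(radius_mm, spacing)
  tsa <- compute_tsa(extract_mesh(m))
  sphericity_index(tsa, compute_volume(m))
}

# minimal cohort for episode/Cox plumbing tests
toy_cohort <- function(n, seed = 1, log_hr = c(mgmt = log(2)),
                       shape = 1, scale = 400,
                       accrual = 1e7, kps_decay_day = NULL) {
  spec <- cohort_spec(n = n, log_hr = log_hr, baseline_shape = shape,
                      baseline_scale_days = scale,
                      accrual_window_days = accrual,
                      kps_decay_day = kps_decay_day, seed = seed)
  simulate_cohort(spec)
}

# patch bytes of an uncompressed .nii file in place
patch_nii <- function(path, offset, bytes) {
  r <- readBin(path, "raw", file.size(path))
  r[offset + seq_along(bytes)] <- bytes
  writeBin(r, path)
  path
}

float_bytes <- function(x) writeBin(as.numeric(x), raw(), size = 4,
                                    endian = "little")
int16_bytes <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                    endian = "little")
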