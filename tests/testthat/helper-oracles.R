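# Independent brute-force oracles used to cross-check the package's
# implementations, plus small fixture builders. These deliberately use the
# most literal formulation available (double loops, dense sampling).

# exhaustive nearest-point search, plain R double loop, first-minimum tie-break
oracle_nearest <- function(query, ref) {
  idx <- integer(nrow(query))
  dst <- numeric(nrow(query))
  for (i in seq_len(nrow(query))) {
    d2 <- rep(Inf, nrow(ref))
    for (j in seq_len(nrow(ref)))
      d2[j] <- sum((query[i, ] - ref[j, ])^2)
    idx[i] <- which.min(d2)        # first minimum = smallest index
    dst[i] <- sqrt(d2[idx[i]])
  }
  list(index = idx, distance = dst)
}

# two-sample KS statistic as a sup over the pooled sample points
oracle_ks <- function(x, y) {
  pool <- sort(unique(c(x, y)))
  Fx <- vapply(pool, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(pool, function(t) mean(y <= t), numeric(1))
  max(abs(Fx - Fy))
}

# ROI membership by dense sampling of the centerline at 0.1 mm arc steps
oracle_roi_members <- function(points, cl, s_lo, s_hi, r) {
  svals <- seq(s_lo, s_hi, by = 0.1)
  interp <- function(s) {
    i <- findInterval(s, cl$arclengths, rightmost.closed = TRUE)
    i <- min(max(i, 1), nrow(cl$points) - 1)
    s0 <- cl$arclengths[i]; s1 <- cl$arclengths[i + 1]
    f <- if (s1 > s0) (s - s0) / (s1 - s0) else 0
    cl$points[i, ] + f * (cl$points[i + 1, ] - cl$points[i, ])
  }
  curve <- t(vapply(svals, interp, numeric(3)))
  which(vapply(seq_len(nrow(points)), function(i)
    min(sqrt(colSums((t(curve) - points[i, ])^2))) <= r, logical(1)))
}

# analytic copy of a volume with its content translated by +t_mm:
# vol2(x) = vol(x - t_mm), so the true fixed->moving displacement is +t_mm
translate_volume <- function(vol, t_mm, phase = 10) {
  d <- dim(vol$voxels)
  sp <- diag(vol$affine)[1:3]
  idx <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1), 0:(d[3] - 1)))
  src <- sweep(idx, 2, t_mm / sp, "-")
  vals <- eatmotion:::cpp_sample_scalar(as.numeric(vol$voxels), as.integer(d), src)
  ct_volume(array(vals, d), vol$affine, phase)
}

# smooth deterministic test image (gaussian blob + sinusoidal texture)
blob_volume <- function(d = c(32, 32, 32), spacing = 2, phase = 50) {
  orig <- -spacing * (d - 1) / 2
  aff <- rbind(cbind(diag(spacing, 3), orig), c(0, 0, 0, 1))
  idx <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1), 0:(d[3] - 1)))
  w <- sweep(idx * spacing, 2, orig, "+")
  r2 <- rowSums(w^2)
  v <- 300 * exp(-r2 / (2 * (0.3 * d[1] * spacing)^2)) +
    30 * sin(w[, 1] / 4) * sin(w[, 2] / 5) * sin(w[, 3] / 6)
  ct_volume(array(v, d), aff, phase)
}

# 9-phase series of identical blob volumes (static heart)
static_series <- function(d = c(16, 16, 16), spacing = 2) {
  vols <- lapply(seq(10, 90, 10), function(p) {
    v <- blob_volume(d, spacing, phase = p)
    v
  })
  phase_series(vols, ref_phase = 50)
}

# a small coarse phantom for fast integration tests (explicitly non-default
# size; the study-scale phantom is exercised in the acceptance tests)
small_phantom <- function(kappa = 0, seed = 3) {
  generate_phantom(phantom_spec(dim = c(40, 40, 40), spacing = 2.8,
                                semi_axes = c(24, 21, 31),
                                coupling = kappa, rng_seed = seed))
}
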