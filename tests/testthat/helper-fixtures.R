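# Shared fixtures and independent oracles, all built in code at test time.

# Random orthonormal 3x3 matrix with det +1.
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

random_geometry <- function(dim = sample(3:6, 3, replace = TRUE)) {
  affine_geometry(spacing = runif(3, 0.5, 6),
                  origin = runif(3, -50, 50),
                  orientation = random_rotation(),
                  dim = dim)
}

# A coarse phantom for pipeline smoke tests (fast to build).
small_phantom_spec <- function(...) {
  phantom_spec(spect_dim = c(32, 32, 44), spect_spacing = c(9.6, 9.6, 9.6),
               ct_dim = c(64, 64, 88), ct_spacing = c(4.8, 4.8, 4.8), ...)
}

# Brute-force nearest-neighbour resampling oracle: explicit per-voxel loop.
resample_oracle <- function(mask, target) {
  dm <- target$dim
  sdm <- mask$geometry$dim
  out <- array(FALSE, dm)
  for (k in seq_len(dm[3])) for (j in seq_len(dm[2])) for (i in seq_len(dm[1])) {
    w <- index_to_world(target, c(i - 1, j - 1, k - 1))
    s <- round(world_to_index(mask$geometry, w))
    if (all(s >= 0) && all(s < sdm)) {
      out[i, j, k] <- mask$mask[s[1] + 1, s[2] + 1, s[3] + 1]
    }
  }
  out
}

# Brute-force metric-ellipsoid dilation: voxel v is in the dilation iff some
# true source voxel u satisfies sum(((v-u)*spacing/semi)^2) <= 1.
dilate_oracle <- function(mask, semi_mm, spacing_mm) {
  if (all(semi_mm <= 0)) return(mask)
  dm <- dim(mask)
  src <- which(mask, arr.ind = TRUE)
  out <- array(FALSE, dm)
  semi <- ifelse(semi_mm > 0, semi_mm, NA)
  for (k in seq_len(dm[3])) for (j in seq_len(dm[2])) for (i in seq_len(dm[1])) {
    d <- t(t(src) - c(i, j, k)) %*% diag(spacing_mm)
    q <- rep(0, nrow(d)); ok <- rep(TRUE, nrow(d))
    for (ax in 1:3) {
      if (is.na(semi[ax])) ok <- ok & d[, ax] == 0 else q <- q + (d[, ax] / semi[ax])^2
    }
    out[i, j, k] <- any(ok & q <= 1 + 1e-9)
  }
  out
}

# Brute-force VOI augmentation oracle implementing the precedence
# original lung > original liver > augmented lung (right wins ties) >
# augmented liver, voxel by voxel.
augment_oracle <- function(liver, lung_left, lung_right, params) {
  sp <- liver$geometry$spacing
  semi <- function(r) c(r, r, r + params$extra_cranio_caudal_mm)
  d_ll <- dilate_oracle(lung_left$mask, semi(params$lung_radius_mm), sp)
  d_lr <- dilate_oracle(lung_right$mask, semi(params$lung_radius_mm), sp)
  d_lv <- dilate_oracle(liver$mask, semi(params$liver_radius_mm), sp)
  orig_lung <- lung_left$mask | lung_right$mask
  orig_any <- orig_lung | liver$mask
  aug_lr <- d_lr & !orig_any
  aug_ll <- d_ll & !orig_any & !aug_lr
  aug_lv <- d_lv & !orig_any & !aug_lr & !aug_ll
  list(liver = liver$mask | aug_lv,
       lung_left = lung_left$mask | aug_ll,
       lung_right = lung_right$mask | aug_lr)
}

# Random pair/triple of adjacent disjoint masks on a small grid.
random_adjacent_masks <- function(dim = c(8, 8, 8), spacing = runif(3, 1, 5)) {
  g <- affine_geometry(spacing, c(0, 0, 0), diag(3), dim)
  blob <- function(excl) {
    repeat {
      c0 <- sapply(dim, function(n) sample(seq_len(n), 1))
      r <- sample(1:2, 1)
      m <- array(FALSE, dim)
      idx <- expand.grid(i = seq_len(dim[1]), j = seq_len(dim[2]),
                         k = seq_len(dim[3]))
      inside <- (idx$i - c0[1])^2 + (idx$j - c0[2])^2 + (idx$k - c0[3])^2 <= r^2
      m[as.matrix(idx)[inside, ]] <- TRUE
      m <- m & !excl
      if (any(m)) return(m)
    }
  }
  lv <- blob(array(FALSE, dim))
  ll <- blob(lv)
  lr <- blob(lv | ll)
  list(liver = organ_mask("LIVER", lv, g),
       lung_left = organ_mask("LUNG_LEFT", ll, g),
       lung_right = organ_mask("LUNG_RIGHT", lr, g),
       geometry = g)
}
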