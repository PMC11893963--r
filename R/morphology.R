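# 3D binary morphology in millimetre metric. Kernels are built as integer
# voxel offsets whose physical displacement lies inside an (ellipsoidal) ball,
# so anisotropic grids behave isotropically.

# Integer voxel offsets (n x 3) with ||d * spacing|| inside the axis-aligned
# ellipsoid with semi-axes `semi_mm` (zero semi-axis => offset 0 on that axis).
ball_offsets <- function(semi_mm, spacing_mm) {
  semi_mm <- rep_len(as.numeric(semi_mm), 3L)
  stopifnot(all(semi_mm >= 0), all(spacing_mm > 0))
  r_vox <- ifelse(semi_mm > 0, floor(semi_mm / spacing_mm + 1e-9), 0)
  ax <- lapply(1:3, function(i) seq.int(-r_vox[i], r_vox[i]))
  g <- expand.grid(d1 = ax[[1]], d2 = ax[[2]], d3 = ax[[3]])
  d <- as.matrix(g)
  q <- rep(0, nrow(d))
  ok <- rep(TRUE, nrow(d))
  for (i in 1:3) {
    phys <- d[, i] * spacing_mm[i]
    if (semi_mm[i] > 0) {
      q <- q + (phys / semi_mm[i])^2
    } else {
      ok <- ok & d[, i] == 0L
    }
  }
  d[ok & q <= 1 + 1e-9, , drop = FALSE]
}

# Dilate a logical 3D array by the metric ball with semi-axes `semi_mm`.
dilate_mm <- function(mask, semi_mm, spacing_mm) {
  if (all(semi_mm <= 0)) return(mask)
  offs <- ball_offsets(semi_mm, spacing_mm)
  out <- array(FALSE, dim(mask))
  for (r in seq_len(nrow(offs))) {
    out <- out | shift_array(mask, offs[r, ])
  }
  out
}

# 6-connected component labelling of a logical 3D array via vectorised BFS on
# linear indices. Returns an integer array (0 = background).
label_components <- function(mask) {
  dm <- dim(mask)
  nx <- dm[1]; ny <- dm[2]; nz <- dm[3]
  nxy <- nx * ny
  n <- length(mask)
  lab <- integer(n)
  mv <- as.logical(mask)
  todo <- which(mv)
  next_lab <- 0L
  in_queue <- logical(n)
  for (seed in todo) {
    if (lab[seed] != 0L) next
    next_lab <- next_lab + 1L
    frontier <- seed
    lab[seed] <- next_lab
    while (length(frontier)) {
      i0 <- (frontier - 1L) %% nx
      j0 <- ((frontier - 1L) %/% nx) %% ny
      k0 <- (frontier - 1L) %/% nxy
      cand <- c(frontier[i0 > 0L] - 1L,
                frontier[i0 < nx - 1L] + 1L,
                frontier[j0 > 0L] - nx,
                frontier[j0 < ny - 1L] + nx,
                frontier[k0 > 0L] - nxy,
                frontier[k0 < nz - 1L] + nxy)
      cand <- unique(cand)
      cand <- cand[mv[cand] & lab[cand] == 0L]
      lab[cand] <- next_lab
      frontier <- cand
    }
  }
  array(lab, dm)
}

# Fill interior cavities: background is flood-filled (6-connectivity) from the
# volume faces; anything not reached and not mask is a hole.
fill_holes <- function(mask) {
  dm <- dim(mask)
  bg <- !mask
  # seed with all face voxels that are background
  face <- array(FALSE, dm)
  face[c(1, dm[1]), , ] <- TRUE
  face[, c(1, dm[2]), ] <- TRUE
  face[, , c(1, dm[3])] <- TRUE
  seeds <- which(bg & face)
  if (!length(seeds)) return(array(TRUE, dm))
  nx <- dm[1]; ny <- dm[2]; nz <- dm[3]; nxy <- nx * ny
  reached <- logical(length(mask))
  bgv <- as.logical(bg)
  reached[seeds] <- TRUE
  frontier <- seeds
  while (length(frontier)) {
    i0 <- (frontier - 1L) %% nx
    j0 <- ((frontier - 1L) %/% nx) %% ny
    k0 <- (frontier - 1L) %/% nxy
    cand <- c(frontier[i0 > 0L] - 1L,
              frontier[i0 < nx - 1L] + 1L,
              frontier[j0 > 0L] - nx,
              frontier[j0 < ny - 1L] + nx,
              frontier[k0 > 0L] - nxy,
              frontier[k0 < nz - 1L] + nxy)
    cand <- unique(cand)
    cand <- cand[bgv[cand] & !reached[cand]]
    reached[cand] <- TRUE
    frontier <- cand
  }
  mask | array(!reached & bgv, dm)
}
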