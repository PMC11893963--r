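#' @keywords internal
"_PACKAGE"

#' Log a message to standard error
#'
#' All pipeline logging goes to stderr so that stdout stays clean for
#' machine-readable output (reports, JSON).
#'
#' @param level one of "INFO", "WARN", "ERROR".
#' @param ... message parts, pasted with no separator.
#' @keywords internal
lsf_log <- function(level = "INFO", ...) {
  message(sprintf("[%s] %s", level, paste0(...)))
  invisible(NULL)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Shift an array by an integer offset per axis, filling vacated cells with
# zero/FALSE. Works for 2D and 3D arrays.
shift_array <- function(a, d) {
  dm <- dim(a)
  stopifnot(length(d) == length(dm))
  out <- array(vector(typeof(a), 1L), dm)
  src <- vector("list", length(dm))
  dst <- vector("list", length(dm))
  for (ax in seq_along(dm)) {
    n <- dm[ax]
    k <- as.integer(round(d[ax]))
    if (abs(k) >= n) return(out)
    if (k >= 0L) {
      dst[[ax]] <- seq.int(1L + k, n)
      src[[ax]] <- seq.int(1L, n - k)
    } else {
      dst[[ax]] <- seq.int(1L, n + k)
      src[[ax]] <- seq.int(1L - k, n)
    }
  }
  if (length(dm) == 3L) {
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  } else {
    out[dst[[1]], dst[[2]]] <- a[src[[1]], src[[2]]]
  }
  out
}

# Separable Gaussian blur of a 2D/3D array; sigma given in mm per axis
# (scalar recycled). Zero-padded edges, kernel truncated at 4 sigma and
# renormalized, so interior counts are conserved.
gaussian_blur <- function(a, sigma_mm, spacing_mm) {
  dm <- dim(a)
  nd <- length(dm)
  sigma_mm <- rep_len(sigma_mm, nd)
  spacing_mm <- rep_len(spacing_mm, nd)
  out <- a
  for (ax in seq_len(nd)) {
    s_vox <- sigma_mm[ax] / spacing_mm[ax]
    if (s_vox <= 0) next
    r <- max(1L, ceiling(4 * s_vox))
    off <- seq.int(-r, r)
    w <- exp(-0.5 * (off / s_vox)^2)
    w <- w / sum(w)
    acc <- array(0, dm)
    e <- rep(0L, nd)
    for (t in seq_along(off)) {
      e[ax] <- off[t]
      acc <- acc + w[t] * shift_array(out, e)
    }
    out <- acc
  }
  out
}

# Shift a 3D array along one axis by a fractional number of voxels using
# linear interpolation (zero fill outside).
shift_fractional <- function(a, axis, s_vox) {
  m <- floor(s_vox)
  t <- s_vox - m
  e1 <- rep(0L, length(dim(a))); e1[axis] <- m
  if (t < 1e-12) return(shift_array(a, e1))
  e2 <- e1; e2[axis] <- m + 1
  (1 - t) * shift_array(a, e1) + t * shift_array(a, e2)
}
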