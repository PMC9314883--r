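# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so the generators stay pure functions of their seed without
#' clobbering the session RNG.
#' @noRd
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Shift a 3D array by integer voxel offsets, zero-filling
#' @noRd
shift3d <- function(a, di, dj, dk, fill = 0) {
  d <- dim(a)
  out <- array(fill, d)
  src <- function(n, s) {
    i <- seq_len(n)
    i[i - s >= 1 & i - s <= n]
  }
  ii <- src(d[1], di); jj <- src(d[2], dj); kk <- src(d[3], dk)
  if (!length(ii) || !length(jj) || !length(kk)) return(out)
  out[ii, jj, kk] <- a[ii - di, jj - dj, kk - dk]
  out
}

#' Separable Gaussian smoothing of a 3D array (matrix-operator form)
#'
#' `sigma_vox` is per-axis in voxels; boundary handled by kernel
#' renormalization (no flux leak at edges).
#' @noRd
gauss_smooth3d <- function(a, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3)
  d <- dim(a)
  smooth_op <- function(n, s) {
    if (s <= 0) return(diag(n))
    x <- seq_len(n)
    K <- outer(x, x, function(i, j) exp(-(i - j)^2 / (2 * s^2)))
    K / rowSums(K)
  }
  # axis 1
  if (sigma_vox[1] > 0) {
    a <- array(smooth_op(d[1], sigma_vox[1]) %*% matrix(a, d[1]), d)
  }
  # axis 2: permute to front
  if (sigma_vox[2] > 0) {
    a <- aperm(a, c(2, 1, 3))
    a <- array(smooth_op(d[2], sigma_vox[2]) %*% matrix(a, d[2]),
               c(d[2], d[1], d[3]))
    a <- aperm(a, c(2, 1, 3))
  }
  if (sigma_vox[3] > 0) {
    a <- aperm(a, c(3, 1, 2))
    a <- array(smooth_op(d[3], sigma_vox[3]) %*% matrix(a, d[3]),
               c(d[3], d[1], d[2]))
    a <- aperm(a, c(2, 3, 1))
  }
  a
}

#' Voxel-center coordinate grids (mm), 1-based centers
#' @noRd
coord_grids <- function(dims, voxel_size = c(1, 1, 1)) {
  list(
    x = array(rep(seq_len(dims[1]), times = dims[2] * dims[3]), dims) * voxel_size[1],
    y = array(rep(rep(seq_len(dims[2]), each = dims[1]), times = dims[3]), dims) * voxel_size[2],
    z = array(rep(seq_len(dims[3]), each = dims[1] * dims[2]), dims) * voxel_size[3]
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_geom <- function(what) {
  stop(sprintf("geometry mismatch: %s", what), call. = FALSE)
}
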