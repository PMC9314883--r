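# Shared fixtures, built in code at test time.

# Small nested-ellipsoid label volume for dosimetry tests (coarser and
# simpler than make_phantom, any size >= ~16).
tiny_head <- function(n = 24, voxel_mm = 2) {
  d <- c(n, n, n)
  g <- persardose:::coord_grids(d, c(1, 1, 1))
  cx <- n / 2 + 0.5
  u <- sqrt(((g$x - cx) / (0.42 * n))^2 + ((g$y - cx) / (0.45 * n))^2 +
            ((g$z - cx) / (0.45 * n))^2)
  lab <- array(0L, d)
  lab[u <= 1.00] <- tissue_code("muscle")
  lab[u <= 0.85] <- tissue_code("fat")
  lab[u <= 0.72] <- tissue_code("bone")
  lab[u <= 0.60] <- tissue_code("csf")
  lab[u <= 0.52] <- tissue_code("gray_matter")
  lab[u <= 0.35] <- tissue_code("white_matter")
  label_volume(lab, rep(voxel_mm, 3))
}

# Brute-force sorted-accumulation oracle for the 10 g averaging.
avg10g_oracle <- function(values, labels, voxel_volume, target_mass = 0.010,
                          at = NULL) {
  mass <- voxel_masses(labels, voxel_volume = voxel_volume)
  d <- dim(labels$grid)
  idx <- which(mass > 0)
  coords <- arrayInd(idx, d)
  mvec <- mass[idx]; vvec <- values[idx]
  at <- at %||% seq_along(idx)
  one <- function(r) {
    dx <- coords[, 1] - coords[r, 1]
    dy <- coords[, 2] - coords[r, 2]
    dz <- coords[, 3] - coords[r, 3]
    d2 <- dx * dx + dy * dy + dz * dz
    o <- order(d2, coords[, 1], coords[, 2], coords[, 3])
    cm <- cumsum(mvec[o])
    k <- which(cm >= target_mass)[1]
    wts <- mvec[o[seq_len(k)]]
    wts[k] <- target_mass - (cm[k] - mvec[o[k]])
    sum(wts * vvec[o[seq_len(k)]]) / target_mass
  }
  list(values = vapply(at, one, numeric(1)), idx = idx[at])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
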