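# Synthetic per-channel complex electric fields.
#
# Band-limited Gaussian random complex 3-vector fields, modulated by a
# per-channel amplitude envelope and spatial phase ramp emulating loop
# elements placed azimuthally around the head. The fields are not
# Maxwell-consistent (a stated non-goal): the downstream dosimetry math is
# field-source-agnostic.

#' Construct a field set
#'
#' @param E Complex array of dim `(nx, ny, nz, 3, C)`: 3-vector electric
#'   field (V/m) per voxel per channel.
#' @param voxel_volume Voxel volume in m^3.
#' @param normalization Declared total input power (W), default 1.
#' @param voxel_size mm per axis (kept for geometry checks).
#' @return Object of class `field_set`.
#' @export
field_set <- function(E, voxel_volume, normalization = 1,
                      voxel_size = c(1, 1, 1)) {
  d <- dim(E)
  stopifnot(length(d) == 5, d[4] == 3, d[5] >= 1)
  if (!all(is.finite(Re(E))) || !all(is.finite(Im(E)))) {
    stop("field values must be finite")
  }
  if (normalization <= 0) stop("normalization (input power) must be positive")
  structure(list(E = E, channels = d[5], voxel_volume = voxel_volume,
                 normalization = normalization,
                 voxel_size = rep_len(voxel_size, 3)),
            class = "field_set")
}

#' @export
print.field_set <- function(x, ...) {
  d <- dim(x$E)
  cat("field_set ", paste(d[1:3], collapse = "x"), " voxels, ",
      x$channels, " channel(s), voxel volume ", signif(x$voxel_volume, 4),
      " m^3, normalized to ", x$normalization, " W\n", sep = "")
  invisible(x)
}

#' Generate synthetic multi-channel E-fields over a phantom
#'
#' Each channel is a smooth complex random 3-vector field multiplied by an
#' exponential amplitude envelope decaying away from the channel's rim
#' position (channels spaced azimuthally, loop-array style) and a radial
#' phase ramp. Fields are exactly zero outside the body support and
#' deterministic per seed.
#'
#' @param labels A [label_volume()] defining the body support.
#' @param channels Number of transmit channels C >= 1.
#' @param seed Integer seed.
#' @param smoothness_mm 1/e autocorrelation length of the underlying random
#'   field (mm).
#' @param amplitude Typical field magnitude scale (V/m).
#' @param normalization Declared input power (W).
#' @return A [field_set()].
#' @export
make_efields <- function(labels, channels, seed = 1, smoothness_mm = 30,
                         amplitude = 30, normalization = 1) {
  stopifnot(inherits(labels, "label_volume"), channels >= 1)
  d <- dim(labels$grid)
  vs <- labels$voxel_size
  mask <- body_mask(labels)
  g <- coord_grids(d, vs)
  cx <- mean(g$x[mask]); cy <- mean(g$y[mask]); cz <- mean(g$z[mask])
  R <- 0.75 * max(d[1] * vs[1], d[2] * vs[2])     # rim radius, outside body
  k_ramp <- 2 * pi / 120                          # rad/mm phase ramp
  E <- array(complex(real = 0, imaginary = 0), c(d, 3, channels))
  for (ch in seq_len(channels)) {
    th <- 2 * pi * (ch - 1) / channels
    px <- cx + R * cos(th); py <- cy + R * sin(th)
    dist <- sqrt((g$x - px)^2 + (g$y - py)^2 + 0.25 * (g$z - cz)^2)
    env <- exp(-dist / (0.6 * R))
    ramp <- exp(complex(imaginary = -k_ramp * dist))
    mod <- amplitude * env * ramp
    for (comp in 1:3) {
      s <- synth_smooth_noise(d, vs, smoothness_mm,
                              seed = seed + 7919L * ch + 104729L * comp,
                              complex_valued = TRUE)
      Ec <- s * mod
      Ec[!mask] <- 0 + 0i
      E[, , , comp, ch] <- Ec
    }
  }
  field_set(E, voxel_volume = prod(vs) * 1e-9, normalization = normalization,
            voxel_size = vs)
}
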