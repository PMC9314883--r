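# Synthetic head phantom generation.
#
# The phantom is a minimal head-and-neck anatomy: nested ellipsoidal shells
# (muscle -> fat -> bone -> CSF -> gray matter -> white matter core), two
# eye spheres, 1-3 paranasal-sinus-like air cavities embedded in local bone
# blocks, and a neck cylinder (muscle with a bone core and a fat sheath)
# that keeps the body a single 6-connected component. Every tissue
# adjacency the SAR averaging has to handle is present; anatomical realism
# is a non-goal.

#' Specification of a synthetic head phantom
#'
#' @param shape Integer length-3, voxels per axis (sagittal, coronal,
#'   transverse). Default `c(64, 64, 64)`.
#' @param seed Integer seed; the phantom is a pure function of the spec.
#' @param voxel_size mm per axis (default 1 mm isotropic, the anatomical
#'   resolution; dosimetry grids are typically generated at 2 mm).
#' @param cavity_count Number of air cavities (paranasal-sinus analogues),
#'   1--3.
#' @param noise_sd Relative intensity noise used by [simulate_t1w()] when
#'   driven from this spec.
#' @param neck_dropoff_strength Strength of the inferior signal drop-off
#'   (0 = none, 1 = severe) used by [make_bias_field()].
#' @param jitter Relative geometric jitter of the shells across seeds.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), seed = 1,
                         voxel_size = c(1, 1, 1),
                         cavity_count = 2, noise_sd = 0.05,
                         neck_dropoff_strength = 1,
                         jitter = 0.05) {
  shape <- as.integer(rep_len(shape, 3))
  if (any(shape <= 0)) stop("shape must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!cavity_count %in% 1:3) stop("cavity_count must be 1, 2 or 3")
  structure(list(shape = shape, seed = as.integer(seed),
                 voxel_size = rep_len(voxel_size, 3),
                 cavity_count = as.integer(cavity_count),
                 noise_sd = noise_sd,
                 neck_dropoff_strength = neck_dropoff_strength,
                 jitter = jitter),
            class = "phantom_spec")
}

#' Write / read a phantom spec as YAML
#' @param spec A `phantom_spec`.
#' @param path File path.
#' @export
write_phantom_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(phantom_spec, y)
}

#' Generate a synthetic head phantom
#'
#' Deterministic for a fixed spec (seed included). All nine tissue codes are
#' present; internal air occurs only inside bone, with a bone wall of at
#' least 2 voxels (2 mm at the default 1 mm resolution) around each cavity.
#' A 1 mm skin layer is enforced afterwards via [enforce_skin_layer()].
#'
#' @param spec A [phantom_spec()].
#' @return A [label_volume()].
#' @export
#' @examples
#' ph <- make_phantom(phantom_spec(shape = c(48, 48, 48), seed = 7))
#' table(tissue_name(ph$grid[ph$grid != 0]))
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  if (min(d) < 32) {
    stop("shape too small to contain the nested tissue shells (need >= 32 voxels per axis)")
  }
  with_local_seed(spec$seed, {
    jit <- function(x) x * (1 + stats::runif(1, -spec$jitter, spec$jitter))
    g <- coord_grids(d, c(1, 1, 1))  # voxel units; scale-free geometry
    cx <- jit(d[1] / 2); cy <- jit(d[2] / 2); cz <- jit(d[3] * 0.60)
    ax <- jit(d[1] * 0.40); ay <- jit(d[2] * 0.42); az <- jit(d[3] * 0.36)

    u <- sqrt(((g$x - cx) / ax)^2 + ((g$y - cy) / ay)^2 + ((g$z - cz) / az)^2)

    lab <- array(0L, d)

    # neck: elliptical cylinder from the bottom face up into the head
    nx <- d[1] * 0.22; ny <- d[2] * 0.26
    ncx <- cx; ncy <- cy + d[2] * 0.05
    un <- sqrt(((g$x - ncx) / nx)^2 + ((g$y - ncy) / ny)^2)
    neck <- un <= 1 & g$z <= cz
    lab[neck] <- tissue_code("muscle")
    lab[neck & un > 0.82] <- tissue_code("fat")
    # spine-like bone core, posterior offset
    us <- sqrt(((g$x - ncx) / (nx * 0.30))^2 +
               ((g$y - (ncy + d[2] * 0.10)) / (ny * 0.30))^2)
    lab[us <= 1 & g$z <= cz] <- tissue_code("bone")

    # head shells overwrite the neck where they overlap
    shell <- function(lo, hi) u > lo & u <= hi
    lab[shell(0.94, 1.00)] <- tissue_code("muscle")
    lab[shell(0.86, 0.94)] <- tissue_code("fat")
    lab[shell(0.78, 0.86)] <- tissue_code("bone")
    lab[shell(0.71, 0.78)] <- tissue_code("csf")
    lab[shell(0.55, 0.71)] <- tissue_code("gray_matter")
    lab[u <= 0.55]         <- tissue_code("white_matter")

    # two eyes, anterior, seated in the bone/fat shells (orbit-like)
    er <- max(3, round(min(d) * 0.055))
    for (sx in c(-1, 1)) {
      ec <- c(cx + sx * 0.30 * ax, cy - 0.80 * ay, cz - 0.10 * az)
      ue <- sqrt((g$x - ec[1])^2 + (g$y - ec[2])^2 + (g$z - ec[3])^2)
      lab[ue <= er & u <= 1] <- tissue_code("eye")
    }

    # air cavities inside local bone blocks (2-voxel wall guaranteed by
    # construction: bone sphere of radius r + wall around each air sphere)
    wall <- 2L
    r <- max(2, round(min(d) * 0.055))  # ~1% air fraction, adult sinus-like
    base_dir <- c(0, -0.75, -0.45)
    for (k in seq_len(spec$cavity_count)) {
      ang <- (k - (spec$cavity_count + 1) / 2) * 0.7
      dir <- c(sin(ang) * 0.8, base_dir[2] * cos(ang * 0.4), base_dir[3])
      dir <- dir / sqrt(sum(dir^2))
      cc <- c(cx, cy, cz) + 0.62 * c(ax, ay, az) * dir +
        stats::runif(3, -0.5, 0.5)
      uc <- sqrt((g$x - cc[1])^2 + (g$y - cc[2])^2 + (g$z - cc[3])^2)
      lab[uc <= r + wall] <- tissue_code("bone")
      lab[uc <= r] <- tissue_code("internal_air")
    }

    lv <- label_volume(lab, spec$voxel_size)
    lv <- enforce_skin_layer(lv, thickness_mm = max(spec$voxel_size))
    missing <- setdiff(tissue_labels()$code, unique(as.vector(lv$grid)))
    if (length(missing)) {
      stop("phantom geometry failed to realize tissue(s): ",
           paste(tissue_name(missing), collapse = ", "))
    }
    lv
  })
}

#' Enforce a skin layer on a phantom
#'
#' Relabels every fat voxel within `thickness_mm` (Euclidean) of the
#' background as muscle, emulating a skin layer at the body surface. All
#' other voxels are unchanged; the operation is idempotent.
#'
#' @param labels A [label_volume()].
#' @param thickness_mm Skin thickness in mm (default 1); must be at least
#'   one voxel.
#' @return The modified [label_volume()].
#' @export
enforce_skin_layer <- function(labels, thickness_mm = 1) {
  stopifnot(inherits(labels, "label_volume"))
  vs <- labels$voxel_size
  if (thickness_mm < min(vs)) stop("thickness must be >= voxel size")
  bg <- labels$grid == 0L
  # dilate background by a Euclidean ball of radius thickness_mm
  rv <- floor(thickness_mm / vs + 1e-9)
  near_bg <- array(FALSE, dim(labels$grid))
  for (di in -rv[1]:rv[1]) for (dj in -rv[2]:rv[2]) for (dk in -rv[3]:rv[3]) {
    if (sqrt((di * vs[1])^2 + (dj * vs[2])^2 + (dk * vs[3])^2) <= thickness_mm + 1e-9) {
      near_bg <- near_bg | shift3d(bg, di, dj, dk, fill = TRUE)
    }
  }
  out <- labels$grid
  out[near_bg & out == tissue_code("fat")] <- tissue_code("muscle")
  label_volume(out, vs, labels$orientation)
}
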