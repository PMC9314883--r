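# Field-set and Q-matrix volume persistence.
#
# Complex data are stored as paired real/imaginary NIfTI-1 float volumes
# (5D for field sets, 4D for packed Q-matrices) with a YAML sidecar
# carrying channel count, voxel volume and power normalization. Round
# trips are exact at float64 -> the on-disk float32 precision; use
# `double = TRUE` for lossless storage.

#' Write a field set to disk
#'
#' Creates `<prefix>_re.nii.gz`, `<prefix>_im.nii.gz` (dims
#' `(nx, ny, nz, 3, C)`) and `<prefix>.yaml`.
#'
#' @param fs A [field_set()].
#' @param prefix Path prefix.
#' @param double Store float64 (exact round trip) instead of float32.
#' @return `prefix`, invisibly.
#' @export
write_fieldset <- function(fs, prefix, double = TRUE) {
  stopifnot(inherits(fs, "field_set"))
  dt <- if (double) "double" else "float"
  RNifti::writeNifti(RNifti::asNifti(Re(fs$E), datatype = dt),
                     paste0(prefix, "_re.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(Im(fs$E), datatype = dt),
                     paste0(prefix, "_im.nii.gz"))
  yaml::write_yaml(list(channels = fs$channels,
                        voxel_volume = fs$voxel_volume,
                        normalization = fs$normalization,
                        voxel_size = fs$voxel_size),
                   paste0(prefix, ".yaml"))
  invisible(prefix)
}

#' Read a field set written by [write_fieldset()]
#' @param prefix Path prefix used at write time.
#' @return A [field_set()].
#' @export
read_fieldset <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, ".yaml"))
  re <- RNifti::readNifti(paste0(prefix, "_re.nii.gz"))
  im <- RNifti::readNifti(paste0(prefix, "_im.nii.gz"))
  d <- dim(re)
  if (length(d) != 5 || d[4] != 3 || d[5] != meta$channels) {
    stop("field-set file '", prefix, "' has unexpected dimensions")
  }
  E <- array(complex(real = as.vector(re), imaginary = as.vector(im)), d)
  field_set(E, voxel_volume = meta$voxel_volume,
            normalization = meta$normalization,
            voxel_size = as.numeric(meta$voxel_size))
}

#' Write / read a Q-matrix volume
#'
#' Stored as `(nx, ny, nz, C(C+1)/2)` packed-upper-triangle real/imaginary
#' NIfTI pairs plus a YAML sidecar.
#'
#' @param q A `qmatrix_volume` from [build_q10g()].
#' @param prefix Path prefix.
#' @param double Store float64 (exact) instead of float32.
#' @return `prefix`, invisibly.
#' @export
write_qmatrix <- function(q, prefix, double = TRUE) {
  stopifnot(inherits(q, "qmatrix_volume"))
  np <- ncol(q$Q)
  dt <- if (double) "double" else "float"
  RNifti::writeNifti(RNifti::asNifti(array(Re(q$Q), c(q$dims, np)),
                                     datatype = dt),
                     paste0(prefix, "_re.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(array(Im(q$Q), c(q$dims, np)),
                                     datatype = dt),
                     paste0(prefix, "_im.nii.gz"))
  yaml::write_yaml(list(channels = q$channels, dims = q$dims,
                        normalization = q$normalization,
                        target_mass = q$target_mass,
                        tissue = which(q$tissue)),
                   paste0(prefix, ".yaml"))
  invisible(prefix)
}

#' @rdname write_qmatrix
#' @export
read_qmatrix <- function(prefix) {
  meta <- yaml::read_yaml(paste0(prefix, ".yaml"))
  re <- RNifti::readNifti(paste0(prefix, "_re.nii.gz"))
  im <- RNifti::readNifti(paste0(prefix, "_im.nii.gz"))
  dims <- as.integer(meta$dims)
  nvox <- prod(dims)
  np <- meta$channels * (meta$channels + 1) / 2
  Q <- matrix(complex(real = as.vector(re), imaginary = as.vector(im)),
              nvox, np)
  tissue <- logical(nvox); tissue[meta$tissue] <- TRUE
  structure(list(Q = Q, channels = meta$channels, dims = dims,
                 tissue = tissue, normalization = meta$normalization,
                 target_mass = meta$target_mass),
            class = "qmatrix_volume")
}
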