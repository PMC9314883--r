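# Volume containers and NIfTI I/O.
#
# Volumes are stored sagittal-first: axis 1 indexes sagittal slices (L-R),
# axis 2 coronal slices (A-P), axis 3 transverse slices (I-S, inferior
# first).  Slicing along axis k therefore yields the orientation named in
# the `orientation` attribute.

ORIENTATIONS <- c("sagittal", "coronal", "transverse")

#' Construct a label volume
#'
#' A 3D integer grid of tissue codes (see [tissue_labels()]) with voxel
#' geometry.
#'
#' @param grid 3D integer array of tissue codes.
#' @param voxel_size Numeric length-3, mm per axis.
#' @param orientation Axis-name triple; default sagittal/coronal/transverse.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(grid, voxel_size = c(1, 1, 1),
                         orientation = ORIENTATIONS) {
  stopifnot(length(dim(grid)) == 3, length(voxel_size) == 3, all(voxel_size > 0))
  g <- array(as.integer(grid), dim(grid))
  bad <- setdiff(unique(as.vector(g)), tissue_labels()$code)
  if (length(bad)) stop("invalid tissue codes in label grid: ", paste(bad, collapse = ", "))
  structure(list(grid = g, voxel_size = as.numeric(voxel_size),
                 orientation = orientation),
            class = "label_volume")
}

#' Construct an image volume
#'
#' A 3D real-valued intensity grid sharing geometry with a label volume.
#'
#' @param grid 3D numeric array; must be finite.
#' @inheritParams label_volume
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(grid, voxel_size = c(1, 1, 1),
                         orientation = ORIENTATIONS) {
  stopifnot(length(dim(grid)) == 3, length(voxel_size) == 3, all(voxel_size > 0))
  if (!all(is.finite(grid))) stop("image grid contains non-finite values")
  structure(list(grid = array(as.numeric(grid), dim(grid)),
                 voxel_size = as.numeric(voxel_size),
                 orientation = orientation),
            class = "image_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cnt <- table(factor(x$grid, levels = tissue_labels()$code,
                      labels = tissue_labels()$name))
  cat("label_volume ", paste(dim(x$grid), collapse = "x"),
      " @ ", paste(x$voxel_size, collapse = "x"), " mm\n", sep = "")
  print(cnt)
  invisible(x)
}

#' @export
print.image_volume <- function(x, ...) {
  cat("image_volume ", paste(dim(x$grid), collapse = "x"),
      " @ ", paste(x$voxel_size, collapse = "x"), " mm, range [",
      signif(min(x$grid), 4), ", ", signif(max(x$grid), 4), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.label_volume <- function(x) dim(x$grid)
#' @export
dim.image_volume <- function(x) dim(x$grid)

same_geometry <- function(a, b) {
  identical(dim(a$grid), dim(b$grid)) &&
    isTRUE(all.equal(a$voxel_size, b$voxel_size, tolerance = 1e-9))
}

check_same_geometry <- function(a, b, what = "volumes") {
  if (!same_geometry(a, b)) stop_geom(what)
  invisible(TRUE)
}

#' Body (non-background) mask of a label volume
#' @param labels A `label_volume`.
#' @return Logical 3D array, TRUE on non-background voxels.
#' @export
body_mask <- function(labels) labels$grid != 0L

#' Write a volume to NIfTI-1
#'
#' Labels are written as int16, images as float32; voxel size goes into the
#' pixdim. A YAML sidecar (`<path>.yaml`) records the orientation convention
#' and class so a read round-trips the typed object.
#'
#' @param vol A `label_volume` or `image_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  is_lab <- inherits(vol, "label_volume")
  if (!is_lab && !inherits(vol, "image_volume")) stop("not a volume object")
  img <- RNifti::asNifti(vol$grid,
                         datatype = if (is_lab) "int16" else "float",
                         pixdim = vol$voxel_size)
  RNifti::writeNifti(img, path)
  yaml::write_yaml(list(class = class(vol)[1],
                        orientation = vol$orientation,
                        voxel_size = vol$voxel_size),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' @param path NIfTI path.
#' @param expect One of `"label"`, `"image"`, or `NULL` (take the sidecar's
#'   word). A mismatch is an error naming the file.
#' @return The typed volume object.
#' @export
read_volume <- function(path, expect = NULL) {
  img <- RNifti::readNifti(path)
  side <- paste0(path, ".yaml")
  meta <- if (file.exists(side)) yaml::read_yaml(side) else NULL
  vs <- RNifti::pixdim(img)[1:3]
  if (!is.null(meta) && !isTRUE(all.equal(as.numeric(meta$voxel_size), as.numeric(vs),
                                          tolerance = 1e-5))) {
    stop("voxel size in NIfTI header of '", path, "' disagrees with its sidecar")
  }
  cls <- meta$class %||% if (identical(expect, "label")) "label_volume" else "image_volume"
  if (!is.null(expect)) {
    want <- paste0(expect, "_volume")
    if (!identical(cls, want)) {
      stop("file '", path, "' holds a ", cls, ", expected a ", want)
    }
  }
  ori <- meta$orientation %||% ORIENTATIONS
  g <- array(as.vector(img), dim(img)[1:3])
  if (cls == "label_volume") label_volume(round(g), vs, ori)
  else image_volume(g, vs, ori)
}
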