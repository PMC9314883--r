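# 2.5D fusion of the three orientation networks and Dice evaluation.

#' Fuse the three orientation outputs into a label volume
#'
#' Sums the three probability-map stacks and assigns each voxel the label
#' of the maximum summed channel (ties broken by the lowest channel
#' index). Voxels where every summed channel is exactly zero -- which
#' would leave a void in the model -- receive the modal label of their
#' 26-neighborhood instead; background is excluded from that vote whenever
#' any tissue neighbor exists.
#'
#' @param out_t,out_c,out_s Arrays `(nx, ny, nz, classes)` from
#'   [predict_maps()] for the transverse, coronal and sagittal networks
#'   (any consistent order; they are summed).
#' @param voxel_size Geometry carried into the result.
#' @return A [label_volume()].
#' @export
fuse_2p5d <- function(out_t, out_c, out_s, voxel_size = c(1, 1, 1)) {
  if (!identical(dim(out_t), dim(out_c)) || !identical(dim(out_t), dim(out_s))) {
    stop_geom("orientation outputs")
  }
  s <- out_t + out_c + out_s
  d <- dim(s)
  ncls <- d[4]
  m <- matrix(s, prod(d[1:3]), ncls)
  lab <- max.col(m, ties.method = "first") - 1L   # channel c = code c-1
  void <- rowSums(m) == 0
  lab[void] <- 0L
  lab <- array(lab, d[1:3])
  if (any(void)) {
    vidx <- which(array(void, d[1:3]), arr.ind = TRUE)
    for (r in seq_len(nrow(vidx))) {
      v <- vidx[r, ]
      ii <- max(1, v[1] - 1):min(d[1], v[1] + 1)
      jj <- max(1, v[2] - 1):min(d[2], v[2] + 1)
      kk <- max(1, v[3] - 1):min(d[3], v[3] + 1)
      nb <- as.vector(lab[ii, jj, kk])
      # remove the center voxel itself
      ci <- which(ii == v[1]); cj <- which(jj == v[2]); ck <- which(kk == v[3])
      center_lin <- ci + length(ii) * (cj - 1) + length(ii) * length(jj) * (ck - 1)
      nb <- nb[-center_lin]
      tissue_nb <- nb[nb != 0L]
      pool <- if (length(tissue_nb)) tissue_nb else nb
      tab <- tabulate(pool + 1L, nbins = ncls)
      lab[v[1], v[2], v[3]] <- which.max(tab) - 1L
    }
  }
  label_volume(lab, voxel_size)
}

#' Segment a volume with three trained orientation networks
#'
#' @param nets Named list of trained networks as from
#'   [train_forknet_2p5d()].
#' @param image An [image_volume()].
#' @return A [label_volume()].
#' @export
segment_volume <- function(nets, image) {
  stopifnot(all(ORIENTATIONS %in% names(nets)))
  maps <- lapply(ORIENTATIONS, function(o) predict_maps(nets[[o]], image))
  fuse_2p5d(maps[[1]], maps[[2]], maps[[3]], voxel_size = image$voxel_size)
}

#' Per-class Dice table for a predicted segmentation
#'
#' @param pred,truth [label_volume()]s on the same grid.
#' @param classes Tissue codes to evaluate (default the eight tissue
#'   classes, background excluded).
#' @return List: `table` (data.frame code/name/dice), `mean`, `sd`.
#' @export
evaluate_segmentation <- function(pred, truth,
                                  classes = tissue_labels()$code[-1]) {
  check_same_geometry(pred, truth, "pred vs truth")
  dv <- vapply(classes, function(code) {
    dice(pred$grid == code, truth$grid == code)
  }, numeric(1))
  tab <- data.frame(code = classes, name = tissue_name(classes), dice = dv)
  list(table = tab, mean = mean(dv), sd = stats::sd(dv))
}
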