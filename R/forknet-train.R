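# Slice bookkeeping, Dice metrics/loss, training loop and volume
# segmentation for the 2.5D approach: three independent 2D networks, one
# per orthogonal slice orientation, trained on randomized slices of the
# raw (biased) T1w-like data.

orientation_axis <- function(orientation) {
  ax <- match(orientation, ORIENTATIONS)
  if (is.na(ax)) stop("orientation must be one of: ",
                      paste(ORIENTATIONS, collapse = ", "))
  ax
}

#' Slice plan for a set of volumes
#'
#' Bookkeeping of the 2D training slices extracted from a list of volumes
#' for one orientation: one row per slice, `n_volumes * axis_length` in
#' total (e.g., nine 192x256x256 volumes yield 2304 transverse or coronal
#' slices of 192x256 and 1728 sagittal slices of 256x256).
#'
#' @param shapes List (or matrix rows) of integer length-3 volume shapes.
#' @param orientation `"transverse"`, `"coronal"` or `"sagittal"`.
#' @return data.frame with columns `volume`, `slice`, plus attributes
#'   `slice_shape` (2D) and `orientation`.
#' @export
slice_plan <- function(shapes, orientation) {
  if (is.matrix(shapes)) shapes <- asplit(shapes, 1)
  ax <- orientation_axis(orientation)
  sh1 <- shapes[[1]]
  for (s in shapes) {
    if (!identical(as.integer(s), as.integer(sh1))) {
      stop("volume shapes differ across the dataset")
    }
  }
  plan <- do.call(rbind, lapply(seq_along(shapes), function(v) {
    data.frame(volume = v, slice = seq_len(sh1[ax]))
  }))
  attr(plan, "slice_shape") <- as.integer(sh1[-ax])
  attr(plan, "orientation") <- orientation
  plan
}

extract_slice <- function(grid, axis, i) {
  if (axis == 1) grid[i, , ] else if (axis == 2) grid[, i, ] else grid[, , i]
}

#' Assemble a randomized slice batch from image/label volume pairs
#'
#' Pairs every 2D slice of every volume (along the given orientation) with
#' its one-hot label masks, in an order randomized by `seed`. Slices are
#' extracted lazily via the returned accessor to keep memory bounded.
#'
#' @param volumes List of `list(image = image_volume, labels = label_volume)`.
#' @param orientation Slice orientation.
#' @param seed Shuffle seed.
#' @return Object of class `slice_batch`: `plan` (shuffled), `n`,
#'   `slice_shape`, and `get(i)` returning `list(x = 2D matrix, y = one-hot
#'   array (H, W, 9))`.
#' @export
slice_volumes <- function(volumes, orientation, seed = 1) {
  shapes <- lapply(volumes, function(v) dim(v$image$grid))
  for (v in volumes) check_same_geometry(v$image, v$labels, "image vs labels")
  plan <- slice_plan(shapes, orientation)
  ord <- with_local_seed(seed, sample.int(nrow(plan)))
  plan <- plan[ord, , drop = FALSE]
  ax <- orientation_axis(orientation)
  ncls <- nrow(tissue_labels())
  get <- function(i) {
    v <- plan$volume[i]; s <- plan$slice[i]
    x <- extract_slice(volumes[[v]]$image$grid, ax, s)
    lab <- extract_slice(volumes[[v]]$labels$grid, ax, s)
    y <- array(0, c(dim(lab), ncls))
    for (c in seq_len(ncls)) y[, , c] <- (lab == (c - 1L)) * 1
    list(x = x, y = y)
  }
  structure(list(plan = plan, n = nrow(plan),
                 slice_shape = attr(plan, "slice_shape"),
                 orientation = orientation, get = get),
            class = "slice_batch")
}

#' Dice coefficient of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b Logical/0-1 arrays of the same shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks must have the same shape")
  sa <- sum(a != 0); sb <- sum(b != 0)
  if (sa + sb == 0) return(1)
  2 * sum(a != 0 & b != 0) / (sa + sb)
}

#' Soft Dice loss over the decoder outputs
#'
#' `1 - mean_c (2 * sum(p_c t_c) + s) / (sum(p_c) + sum(t_c) + s)` with
#' smoothing constant `s` (default 1) in numerator and denominator,
#' averaged (unweighted) over the nine decoder channels. Differentiable in
#' the predictions.
#'
#' @param pred Array `(H, W, classes, N)` of probabilities.
#' @param target Array of matching one-hot masks.
#' @param smooth Smoothing constant.
#' @param with_grad If TRUE also return `grad`, the derivative w.r.t.
#'   `pred`.
#' @return Scalar loss, or `list(loss, grad)` when `with_grad`.
#' @export
dice_loss <- function(pred, target, smooth = 1, with_grad = FALSE) {
  if (!identical(dim(pred), dim(target))) stop("shape mismatch")
  ncls <- dim(pred)[3]
  loss <- 0
  grad <- if (with_grad) array(0, dim(pred))
  for (c in seq_len(ncls)) {
    p <- pred[, , c, , drop = FALSE]; t <- target[, , c, , drop = FALSE]
    I <- sum(p * t); D <- sum(p) + sum(t) + smooth
    loss <- loss + (1 - (2 * I + smooth) / D)
    if (with_grad) {
      grad[, , c, ] <- -(2 * t * D - (2 * I + smooth)) / D^2 / ncls
    }
  }
  loss <- loss / ncls
  if (with_grad) list(loss = loss, grad = grad) else loss
}

#' Training configuration
#'
#' @param batch_size Slices per iteration (default 10).
#' @param epochs Training epochs (default 40).
#' @param train_fraction Fraction of slices used for training, the rest
#'   for validation (default 0.9).
#' @param learning_rate,beta1,beta2,adam_eps ADAM hyperparameters
#'   (framework defaults). `learning_rate` may be a vector, recycled to
#'   one value per epoch, to implement a step schedule.
#' @param seed Master seed for initialization, split and shuffling.
#' @return Object of class `train_config`.
#' @export
train_config <- function(batch_size = 10, epochs = 40, train_fraction = 0.9,
                         learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         adam_eps = 1e-8, seed = 1) {
  stopifnot(train_fraction > 0, train_fraction < 1, batch_size >= 1,
            epochs >= 1)
  structure(list(batch_size = batch_size, epochs = epochs,
                 train_fraction = train_fraction,
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps, seed = as.integer(seed)),
            class = "train_config")
}

#' Per-volume intensity normalization scale
#'
#' Training and inference divide each volume by its 99th-percentile
#' intensity so the raw (biased) data land on a comparable scale.
#' @param image An [image_volume()] or array.
#' @return Scalar divisor.
#' @export
intensity_scale <- function(image) {
  g <- if (inherits(image, "image_volume")) image$grid else image
  s <- stats::quantile(g, 0.99, names = FALSE)
  if (s <= 0) 1 else s
}

#' Train one orientation network
#'
#' Randomized slices of the given volumes, 90/10 train/validation split,
#' soft-Dice loss over the nine decoder outputs, ADAM updates in batches.
#' Deterministic for a fixed config seed.
#'
#' @param volumes List of `list(image=, labels=)` pairs (training subjects
#'   only; the held-out test subject must not be in this list).
#' @param orientation Slice orientation for this network.
#' @param spec A [network_spec()].
#' @param config A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return List: `net` (trained `fork_network`), `history` (data.frame of
#'   per-epoch train/validation loss), `scales` (per-volume intensity
#'   divisors), `orientation`.
#' @export
train_forknet <- function(volumes, orientation, spec = network_spec(),
                          config = train_config(), verbose = FALSE) {
  if (!length(volumes)) stop("empty training set")
  batch <- slice_volumes(volumes, orientation, seed = config$seed)
  scales <- vapply(volumes, function(v) intensity_scale(v$image), numeric(1))
  n <- batch$n
  n_train <- max(1, floor(config$train_fraction * n))
  idx_train <- seq_len(n_train)           # plan is already seed-shuffled
  idx_val <- setdiff(seq_len(n), idx_train)
  net <- build_network(spec, seed = config$seed)
  state <- adam_init(net)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  make_tensor <- function(ids) {
    sh <- batch$slice_shape
    X <- array(0, c(sh[1], sh[2], 1, length(ids)))
    Y <- array(0, c(sh[1], sh[2], nrow(tissue_labels()), length(ids)))
    for (k in seq_along(ids)) {
      sl <- batch$get(ids[k])
      X[, , 1, k] <- sl$x / scales[batch$plan$volume[ids[k]]]
      Y[, , , k] <- sl$y
    }
    list(X = X, Y = Y)
  }
  lr_by_epoch <- rep_len(config$learning_rate, config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- with_local_seed(config$seed + 1000L * ep,
                           idx_train[sample.int(n_train)])
    ep_loss <- 0; nb <- 0
    for (b0 in seq(1, n_train, by = config$batch_size)) {
      ids <- ord[b0:min(b0 + config$batch_size - 1, n_train)]
      tb <- make_tensor(ids)
      fw <- network_forward(net, tb$X, training = TRUE)
      net <- absorb_bn_stats(net, fw)
      dl <- dice_loss(fw$probs, tb$Y, with_grad = TRUE)
      grads <- network_backward(net, fw, dl$grad)
      st <- adam_step(net, grads, state, lr = lr_by_epoch[ep],
                      b1 = config$beta1, b2 = config$beta2,
                      eps = config$adam_eps)
      net <- st$net; state <- st$state
      ep_loss <- ep_loss + dl$loss; nb <- nb + 1
    }
    val_loss <- NA_real_
    if (length(idx_val)) {
      vl <- 0; nv <- 0
      for (b0 in seq(1, length(idx_val), by = config$batch_size)) {
        ids <- idx_val[b0:min(b0 + config$batch_size - 1, length(idx_val))]
        tb <- make_tensor(ids)
        fw <- network_forward(net, tb$X, training = FALSE)
        vl <- vl + dice_loss(fw$probs, tb$Y); nv <- nv + 1
      }
      val_loss <- vl / nv
    }
    history <- rbind(history, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                         val_loss = val_loss))
    if (verbose) {
      message(sprintf("[%s] epoch %d/%d train %.4f val %.4f", orientation,
                      ep, config$epochs, ep_loss / nb, val_loss))
    }
  }
  list(net = net, history = history, scales = scales,
       orientation = orientation)
}

#' Train the three orientation networks of the 2.5D approach
#'
#' @inheritParams train_forknet
#' @return Named list of [train_forknet()] results, one per orientation.
#' @export
train_forknet_2p5d <- function(volumes, spec = network_spec(),
                               config = train_config(), verbose = FALSE) {
  res <- lapply(seq_along(ORIENTATIONS), function(i) {
    cfg <- config
    cfg$seed <- config$seed + 17L * (i - 1L)  # independent init per net
    train_forknet(volumes, ORIENTATIONS[i], spec, cfg, verbose)
  })
  names(res) <- ORIENTATIONS
  res
}

#' Per-class probability maps for one volume from one orientation network
#'
#' Runs the network (inference mode) slice by slice along its orientation
#' and reassembles 3D probability maps, one per decoder.
#'
#' @param trained A result of [train_forknet()].
#' @param image An [image_volume()].
#' @param batch_size Slices per forward pass.
#' @return Array `(nx, ny, nz, classes)` with values in `[0, 1]`.
#' @export
predict_maps <- function(trained, image, batch_size = 16) {
  ax <- orientation_axis(trained$orientation)
  g <- image$grid / intensity_scale(image)
  d <- dim(g)
  ncls <- trained$net$spec$decoders
  out <- array(0, c(d, ncls))
  ns <- d[ax]
  for (b0 in seq(1, ns, by = batch_size)) {
    ids <- b0:min(b0 + batch_size - 1, ns)
    sh <- d[-ax]
    X <- array(0, c(sh[1], sh[2], 1, length(ids)))
    for (k in seq_along(ids)) X[, , 1, k] <- extract_slice(g, ax, ids[k])
    fw <- network_forward(trained$net, X, training = FALSE)
    for (k in seq_along(ids)) {
      i <- ids[k]
      if (ax == 1) out[i, , , ] <- fw$probs[, , , k]
      else if (ax == 2) out[, i, , ] <- fw$probs[, , , k]
      else out[, , i, ] <- fw$probs[, , , k]
    }
  }
  out
}
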