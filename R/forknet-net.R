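# Multi-decoder ("fork") 2D segmentation network: one shared convolutional
# encoder and nine parallel decoders, one per output class. Implemented
# directly on BLAS matrix products: activations flow through the network
# as (H*W*N) x C matrices (row order h-fastest, then w, then slice), with
# precomputed, cached gather indices for the 3x3 convolutions and 2x2
# transposed convolutions. This keeps the whole pass allocation-light.
#
# Topology (defaults): encoder = conv block + 6 x (maxpool + conv block),
# feature widths 8, 16, ..., 512 doubling after every pooling; each decoder
# = 6 x (2x2 transposed-conv block, with 3x3 refine blocks at the three
# intermediate scales) + 1x1 sigmoid output conv. Each transposed-conv
# output additionally receives an additive skip from the matching encoder
# scale through a bias-free 1x1 projection (lateral connections; they keep
# small structures localizable without changing the 23-layer path depth).
# That is 23 layers along an input-to-output path, 6 of them pooling, and
# ~5 million trainable parameters in total (see count_parameters()).

#' Network architecture specification
#'
#' @param base_features Feature maps encoded by the first layer (default 8);
#'   widths double after each pooling step.
#' @param pooling_steps Number of 2x2 max-pooling steps (default 6).
#' @param decoders Number of parallel decoders: tissue classes plus
#'   background (default 9).
#' @param input_shape Advisory 2D input size; the network is fully
#'   convolutional and accepts any size divisible by `2^pooling_steps`.
#' @param bn_momentum Batch-normalization momentum (default 0.9).
#' @param bn_eps Batch-normalization stability epsilon (default 0.001).
#' @return Object of class `network_spec`. The element `total_layers`
#'   counts layers along one input-to-output path (convolutions, poolings,
#'   transposed convolutions and the output convolution; the lateral skip
#'   projections do not add path depth).
#' @export
network_spec <- function(base_features = 8, pooling_steps = 6, decoders = 9,
                         input_shape = c(256, 256), bn_momentum = 0.9,
                         bn_eps = 0.001) {
  stopifnot(base_features >= 1, pooling_steps >= 1, decoders >= 1)
  p <- pooling_steps
  enc_widths <- base_features * 2^(0:p)
  # decoder channel schedule: first upsampling quarters the bottleneck
  # width (keeps the nine parallel decoders affordable), then halves,
  # floored at base_features
  dec_widths <- numeric(p)
  dec_widths[1] <- max(base_features, enc_widths[p + 1] / 4)
  if (p >= 2) for (k in 2:p) dec_widths[k] <- max(base_features, dec_widths[k - 1] / 2)
  refine_at <- if (p >= 4) 2:min(4, p - 2) else if (p == 3) 2L else integer(0)
  total_layers <- (1 + 2 * p) + (p + length(refine_at) + 1)
  structure(list(base_features = base_features, pooling_steps = p,
                 decoders = decoders, input_shape = input_shape,
                 enc_widths = enc_widths, dec_widths = dec_widths,
                 refine_at = refine_at, total_layers = total_layers,
                 bn_momentum = bn_momentum, bn_eps = bn_eps),
            class = "network_spec")
}

he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

new_conv <- function(cin, cout, k = 3, bn = TRUE, act = "relu") {
  list(type = if (k == 3) "conv" else "conv1x1",
       W = he_init(c(k, k, cin, cout), k * k * cin),
       b = numeric(cout),
       bn = if (bn) list(gamma = rep(1, cout), beta = numeric(cout),
                         rmean = numeric(cout), rvar = rep(1, cout)),
       act = act)
}

new_deconv <- function(cin, cout, bn = TRUE, act = "relu",
                       skip_width = NULL, skip_scale = NULL) {
  l <- list(type = "deconv",
            W = he_init(c(2, 2, cin, cout), 4 * cin),
            b = numeric(cout),
            bn = if (bn) list(gamma = rep(1, cout), beta = numeric(cout),
                              rmean = numeric(cout), rvar = rep(1, cout)),
            act = act)
  if (!is.null(skip_width)) {
    l$Ws <- he_init(c(skip_width, cout), skip_width)
    l$skip_scale <- skip_scale
  }
  l
}

#' Build a trainable fork network
#'
#' Instantiates all weights (He initialization, seeded). The model is fully
#' convolutional: any input size divisible by `2^pooling_steps` is accepted
#' at run time, and the parameter count is independent of input size.
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed for the weight initialization.
#' @return Object of class `fork_network`.
#' @export
build_network <- function(spec = network_spec(), seed = 1) {
  stopifnot(inherits(spec, "network_spec"))
  p <- spec$pooling_steps
  with_local_seed(seed, {
    enc <- list(new_conv(1, spec$enc_widths[1]))
    for (d in seq_len(p)) {
      enc <- c(enc, list(list(type = "pool")),
               list(new_conv(spec$enc_widths[d], spec$enc_widths[d + 1])))
    }
    decs <- lapply(seq_len(spec$decoders), function(j) {
      lay <- list()
      cin <- spec$enc_widths[p + 1]
      for (k in seq_len(p)) {
        cout <- spec$dec_widths[k]
        lay <- c(lay, list(new_deconv(cin, cout,
                                      skip_width = spec$enc_widths[p - k + 1],
                                      skip_scale = p - k)))
        if (k %in% spec$refine_at) lay <- c(lay, list(new_conv(cout, cout)))
        cin <- cout
      }
      out <- new_conv(cin, 1, k = 1, bn = FALSE, act = "sigmoid")
      out$b[] <- -2   # start outputs near 0.12: rare classes skip the
                      # initial push-down phase and avoid saturating low
      c(lay, list(out))
    })
    structure(list(spec = spec, encoder = enc, decoders = decs),
              class = "fork_network")
  })
}

#' Count trainable parameters of a fork network
#'
#' Sums all convolution/deconvolution weights and biases, the skip
#' projections, and the trainable batch-normalization scales and shifts
#' (running statistics are not trainable).
#'
#' @param net A `fork_network`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(net) {
  stopifnot(inherits(net, "fork_network"))
  n_layer <- function(l) {
    if (l$type == "pool") return(0)
    n <- length(l$W) + length(l$b)
    if (!is.null(l$bn)) n <- n + length(l$bn$gamma) + length(l$bn$beta)
    if (!is.null(l$Ws)) n <- n + length(l$Ws)
    n
  }
  sum(vapply(net$encoder, n_layer, numeric(1))) +
    sum(vapply(unlist(net$decoders, recursive = FALSE), n_layer, numeric(1)))
}

#' @export
print.fork_network <- function(x, ...) {
  s <- x$spec
  cat("fork_network: encoder widths ", paste(s$enc_widths, collapse = "-"),
      ", ", s$decoders, " decoders (widths ",
      paste(s$dec_widths, collapse = "-"), "), ",
      s$total_layers, " layers/path (", s$pooling_steps, " pooling), ",
      format(count_parameters(x), big.mark = ","), " parameters\n", sep = "")
  invisible(x)
}

## ---- cached gather indices -------------------------------------------
## Activations are (H*W*N) x C matrices; these indices implement the
## spatial reads/writes of 3x3 conv (with zero padding via a sentinel row)
## and 2x2 stride-2 transposed conv.

.idx_cache <- new.env(parent = emptyenv())

conv_gather_idx <- function(H, W, N) {
  key <- paste0("c", H, "_", W, "_", N)
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  m <- H * W * N
  hh <- rep.int(seq_len(H), W * N)
  ww <- rep.int(rep(seq_len(W), each = H), N)
  nn <- rep(seq_len(N), each = H * W)
  idx <- vector("list", 9)
  o <- 0
  for (dx in -1:1) for (dy in -1:1) {
    o <- o + 1
    hs <- hh + dy; ws <- ww + dx
    ok <- hs >= 1L & hs <= H & ws >= 1L & ws <= W
    v <- rep.int(m + 1L, m)  # sentinel zero row
    v[ok] <- hs[ok] + H * (ws[ok] - 1L) + H * W * (nn[ok] - 1L)
    idx[[o]] <- list(src = v, ok = which(ok), okv = v[ok])
  }
  all_src <- unlist(lapply(idx, `[[`, "src"), use.names = FALSE)
  res <- list(per = idx, all = all_src, m = m)
  .idx_cache[[key]] <- res
  res
}

deconv_scatter_idx <- function(H, W, N) {
  key <- paste0("d", H, "_", W, "_", N)
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  hh <- rep.int(seq_len(H), W * N)
  ww <- rep.int(rep(seq_len(W), each = H), N)
  nn <- rep(seq_len(N), each = H * W)
  res <- vector("list", 4)
  q <- 0
  for (s in 1:2) for (r in 1:2) {
    q <- q + 1
    res[[q]] <- (2L * (hh - 1L) + r) + 2L * H * (2L * (ww - 1L) + s - 1L) +
      4L * H * W * (nn - 1L)
  }
  res <- list(pos = res)
  .idx_cache[[key]] <- res
  res
}

## ---- layer kernels on the matrix representation -----------------------
## A "tensor" is list(M = (H*W*N) x C matrix, H, W, N).

conv3x3_fwd <- function(tm, W, b) {
  C <- ncol(tm$M); Cout <- dim(W)[4]
  gi <- conv_gather_idx(tm$H, tm$W, tm$N)
  M2 <- rbind(tm$M, 0)
  cols <- M2[gi$all, , drop = FALSE]        # (9m) x C
  dim(cols) <- c(gi$m, 9L * C)              # columns: offset fast, channel slow
  Y <- cols %*% matrix(W, 9L * C, Cout)
  Y <- Y + rep(b, each = gi$m)
  list(Y = list(M = Y, H = tm$H, W = tm$W, N = tm$N), cols = cols, C = C)
}

conv3x3_bwd <- function(dY, cache, W, H, Wd, N) {
  C <- cache$C; Cout <- dim(W)[4]
  gi <- conv_gather_idx(H, Wd, N)
  dWmat <- crossprod(cache$cols, dY$M)      # (9C) x Cout
  dW <- array(dWmat, dim(W))
  db <- colSums(dY$M)
  dcols <- tcrossprod(dY$M, matrix(W, 9L * C, Cout))  # m x 9C
  dM <- matrix(0, gi$m, C)
  for (o in 1:9) {
    pi <- gi$per[[o]]
    blk <- dcols[pi$ok, seq.int(o, 9L * C, by = 9L), drop = FALSE]
    dM[pi$okv, ] <- dM[pi$okv, , drop = FALSE] + blk
  }
  list(dX = list(M = dM, H = H, W = Wd, N = N), dW = dW, db = db)
}

conv1x1_fwd <- function(tm, W, b) {
  Cout <- dim(W)[4]
  Y <- tm$M %*% matrix(W, ncol(tm$M), Cout)
  Y <- Y + rep(b, each = nrow(Y))
  list(Y = list(M = Y, H = tm$H, W = tm$W, N = tm$N), Xm = tm$M)
}

conv1x1_bwd <- function(dY, cache, W, H, Wd, N) {
  Cout <- dim(W)[4]; C <- ncol(cache$Xm)
  dW <- array(crossprod(cache$Xm, dY$M), dim(W))
  db <- colSums(dY$M)
  dM <- tcrossprod(dY$M, matrix(W, C, Cout))
  list(dX = list(M = dM, H = H, W = Wd, N = N), dW = dW, db = db)
}

deconv2x2_fwd <- function(tm, W, b) {
  C <- ncol(tm$M); Cout <- dim(W)[4]
  di <- deconv_scatter_idx(tm$H, tm$W, tm$N)
  m_out <- 4L * tm$H * tm$W * tm$N
  Y <- matrix(0, m_out, Cout)
  q <- 0
  for (s in 1:2) for (r in 1:2) {
    q <- q + 1
    Yrs <- tm$M %*% matrix(W[r, s, , ], C, Cout)
    Y[di$pos[[q]], ] <- Yrs
  }
  Y <- Y + rep(b, each = m_out)
  list(Y = list(M = Y, H = 2L * tm$H, W = 2L * tm$W, N = tm$N), Xm = tm$M)
}

deconv2x2_bwd <- function(dY, cache, W, H, Wd, N) {
  # H, Wd are the *input* dims of the layer
  C <- ncol(cache$Xm); Cout <- dim(W)[4]
  di <- deconv_scatter_idx(H, Wd, N)
  dM <- matrix(0, nrow(cache$Xm), C)
  dW <- array(0, dim(W)); db <- numeric(Cout)
  q <- 0
  for (s in 1:2) for (r in 1:2) {
    q <- q + 1
    dYrs <- dY$M[di$pos[[q]], , drop = FALSE]
    dM <- dM + tcrossprod(dYrs, matrix(W[r, s, , ], C, Cout))
    dW[r, s, , ] <- crossprod(cache$Xm, dYrs)
    db <- db + colSums(dYrs)
  }
  list(dX = list(M = dM, H = H, W = Wd, N = N), dW = dW, db = db)
}

maxpool_fwd <- function(tm) {
  H <- tm$H; Wd <- tm$W; N <- tm$N; C <- ncol(tm$M)
  if (H %% 2 || Wd %% 2) stop("input dims must be divisible by 2^pooling_steps")
  A <- tm$M
  dim(A) <- c(2L, H %/% 2L, 2L, Wd %/% 2L, N * C)
  s1 <- A[1, , 1, , , drop = TRUE]; s2 <- A[2, , 1, , , drop = TRUE]
  s3 <- A[1, , 2, , , drop = TRUE]; s4 <- A[2, , 2, , , drop = TRUE]
  mdim <- c((H %/% 2L) * (Wd %/% 2L) * N, C)
  dim(s1) <- mdim; dim(s2) <- mdim; dim(s3) <- mdim; dim(s4) <- mdim
  m <- pmax(s1, s2, s3, s4)
  m1 <- s1 == m; m2 <- s2 == m & !m1; m3 <- s3 == m & !m1 & !m2
  m4 <- !m1 & !m2 & !m3
  list(Y = list(M = m, H = H %/% 2L, W = Wd %/% 2L, N = N),
       masks = list(m1, m2, m3, m4), in_dims = c(H, Wd, N))
}

maxpool_bwd <- function(dY, cache) {
  H <- cache$in_dims[1]; Wd <- cache$in_dims[2]; N <- cache$in_dims[3]
  C <- ncol(dY$M)
  dA <- array(0, c(2L, H %/% 2L, 2L, Wd %/% 2L, N * C))
  hw <- c(H %/% 2L, Wd %/% 2L, N * C)
  g <- function(mask) { x <- dY$M * mask; dim(x) <- hw; x }
  dA[1, , 1, , ] <- g(cache$masks[[1]])
  dA[2, , 1, , ] <- g(cache$masks[[2]])
  dA[1, , 2, , ] <- g(cache$masks[[3]])
  dA[2, , 2, , ] <- g(cache$masks[[4]])
  dim(dA) <- c(H * Wd * N, C)
  list(M = dA, H = H, W = Wd, N = N)
}

bn_fwd <- function(tm, bn, momentum, eps, training) {
  m <- nrow(tm$M)
  if (training) {
    mu <- colMeans(tm$M)
    v <- colMeans(tm$M * tm$M) - mu^2
    v[v < 0] <- 0
    bn$rmean <- momentum * bn$rmean + (1 - momentum) * mu
    bn$rvar <- momentum * bn$rvar + (1 - momentum) * v
  } else {
    mu <- bn$rmean; v <- bn$rvar
  }
  istd <- 1 / sqrt(v + eps)
  r <- .bn_fwd_cpp(tm$M, bn$gamma, bn$beta, mu, istd)
  list(Y = list(M = r$Y, H = tm$H, W = tm$W, N = tm$N), bn = bn,
       cache = list(xhat = r$xhat, istd = istd, training = training))
}

bn_bwd <- function(dY, bn, cache) {
  r <- .bn_bwd_cpp(dY$M, cache$xhat, bn$gamma, cache$istd,
                   isTRUE(cache$training))
  list(dX = list(M = r$dM, H = dY$H, W = dY$W, N = dY$N),
       dgamma = r$dgamma, dbeta = r$dbeta)
}

layer_fwd <- function(l, tm, training, spec, skip_feats = NULL) {
  if (l$type == "pool") {
    r <- maxpool_fwd(tm)
    return(list(Y = r$Y, pool = r, ltype = "pool"))
  }
  raw <- switch(l$type,
    conv = conv3x3_fwd(tm, l$W, l$b),
    conv1x1 = conv1x1_fwd(tm, l$W, l$b),
    deconv = deconv2x2_fwd(tm, l$W, l$b))
  out <- raw$Y
  skip_cache <- NULL
  if (!is.null(l$Ws)) {
    S <- skip_feats[[l$skip_scale + 1L]]
    out$M <- out$M + S$M %*% l$Ws
    skip_cache <- S$M
  }
  bnres <- NULL
  if (!is.null(l$bn)) {
    bnres <- bn_fwd(out, l$bn, spec$bn_momentum, spec$bn_eps, training)
    out <- bnres$Y
  }
  act_cache <- NULL
  if (identical(l$act, "relu")) {
    act_cache <- out$M > 0
    out$M <- out$M * act_cache
  } else if (identical(l$act, "sigmoid")) {
    out$M <- 1 / (1 + exp(-out$M))
    act_cache <- out$M
  }
  list(Y = out, raw = raw, bnres = bnres, act_cache = act_cache,
       skip_cache = skip_cache, in_dims = c(tm$H, tm$W, tm$N),
       ltype = l$type)
}

layer_bwd <- function(l, dY, fw) {
  if (l$type == "pool") {
    return(list(dX = maxpool_bwd(dY, fw$pool), grads = NULL))
  }
  if (identical(l$act, "relu")) {
    dY$M <- dY$M * fw$act_cache
  } else if (identical(l$act, "sigmoid")) {
    dY$M <- dY$M * fw$act_cache * (1 - fw$act_cache)
  }
  dgamma <- NULL; dbeta <- NULL
  if (!is.null(l$bn)) {
    bb <- bn_bwd(dY, fw$bnres$bn, fw$bnres$cache)
    dY <- bb$dX; dgamma <- bb$dgamma; dbeta <- bb$dbeta
  }
  dWs <- NULL; dskip <- NULL
  if (!is.null(l$Ws)) {
    dWs <- crossprod(fw$skip_cache, dY$M)
    dskip <- tcrossprod(dY$M, l$Ws)
  }
  H <- fw$in_dims[1]; Wd <- fw$in_dims[2]; N <- fw$in_dims[3]
  bw <- switch(l$type,
    conv = conv3x3_bwd(dY, fw$raw, l$W, H, Wd, N),
    conv1x1 = conv1x1_bwd(dY, fw$raw, l$W, H, Wd, N),
    deconv = deconv2x2_bwd(dY, fw$raw, l$W, H, Wd, N))
  list(dX = bw$dX, dskip = dskip, skip_scale = l$skip_scale,
       grads = list(dW = bw$dW, db = bw$db, dgamma = dgamma, dbeta = dbeta,
                    dWs = dWs))
}

#' Forward pass of a fork network
#'
#' @param net A `fork_network`.
#' @param X Input array `(H, W, 1, N)`; `H` and `W` must be divisible by
#'   `2^pooling_steps`.
#' @param training Logical: batch statistics (TRUE) or running statistics
#'   (FALSE) in the batch-normalization layers.
#' @return List with `probs` (array `(H, W, decoders, N)`, each channel a
#'   sigmoid output in `[0, 1]`) and the per-layer caches needed by the
#'   backward pass.
#' @export
network_forward <- function(net, X, training = FALSE) {
  spec <- net$spec
  d <- dim(X)
  stopifnot(length(d) == 4, d[3] == 1)
  if (any(d[1:2] %% 2^spec$pooling_steps != 0)) {
    stop("input dims must be divisible by 2^pooling_steps = ",
         2^spec$pooling_steps)
  }
  # (H, W, 1, N) -> (H*W*N) x 1 matrix, rows h-fastest then w then n
  Xm <- matrix(aperm(X, c(1, 2, 4, 3)), d[1] * d[2] * d[4], 1)
  cur <- list(M = Xm, H = d[1], W = d[2], N = d[4])
  enc_fw <- vector("list", length(net$encoder))
  enc_scale_out <- vector("list", spec$pooling_steps + 1)
  for (i in seq_along(net$encoder)) {
    enc_fw[[i]] <- layer_fwd(net$encoder[[i]], cur, training, spec)
    cur <- enc_fw[[i]]$Y
    if (i %% 2 == 1) enc_scale_out[[(i + 1) %/% 2]] <- cur
  }
  bottleneck <- cur
  dec_fw <- vector("list", spec$decoders)
  probs <- array(0, c(d[1], d[2], spec$decoders, d[4]))
  pm <- matrix(0, d[1] * d[2] * d[4], spec$decoders)
  for (j in seq_len(spec$decoders)) {
    lf <- vector("list", length(net$decoders[[j]]))
    cur <- bottleneck
    for (i in seq_along(net$decoders[[j]])) {
      lf[[i]] <- layer_fwd(net$decoders[[j]][[i]], cur, training, spec,
                           skip_feats = enc_scale_out)
      cur <- lf[[i]]$Y
    }
    dec_fw[[j]] <- lf
    pm[, j] <- cur$M
  }
  probs[] <- aperm(array(pm, c(d[1], d[2], d[4], spec$decoders)),
                   c(1, 2, 4, 3))
  list(probs = probs, enc_fw = enc_fw, dec_fw = dec_fw,
       dims = c(d[1], d[2], d[4]))
}

# Backward pass: dprobs (H, W, decoders, N) -> gradients mirroring the
# network structure.
network_backward <- function(net, fw, dprobs) {
  spec <- net$spec
  d <- fw$dims
  dpm <- matrix(aperm(dprobs, c(1, 2, 4, 3)), d[1] * d[2] * d[3],
                spec$decoders)
  enc_grads <- vector("list", length(net$encoder))
  dec_grads <- vector("list", spec$decoders)
  d_skip <- vector("list", spec$pooling_steps + 1)
  d_bottleneck <- NULL
  for (j in seq_len(spec$decoders)) {
    lay <- net$decoders[[j]]; lf <- fw$dec_fw[[j]]
    nlay <- length(lay)
    dY <- list(M = dpm[, j, drop = FALSE],
               H = d[1], W = d[2], N = d[3])
    gj <- vector("list", nlay)
    for (i in rev(seq_len(nlay))) {
      bw <- layer_bwd(lay[[i]], dY, lf[[i]])
      gj[[i]] <- bw$grads
      dY <- bw$dX
      if (!is.null(bw$dskip)) {
        s <- bw$skip_scale + 1L
        d_skip[[s]] <- if (is.null(d_skip[[s]])) bw$dskip
                       else d_skip[[s]] + bw$dskip
      }
    }
    dec_grads[[j]] <- gj
    d_bottleneck <- if (is.null(d_bottleneck)) dY$M else d_bottleneck + dY$M
  }
  dY <- list(M = d_bottleneck,
             H = d[1] %/% 2^spec$pooling_steps,
             W = d[2] %/% 2^spec$pooling_steps, N = d[3])
  for (i in rev(seq_along(net$encoder))) {
    if (i %% 2 == 1) {  # conv at scale s = (i-1)/2: add decoders' skip grads
      s <- (i + 1) %/% 2
      if (!is.null(d_skip[[s]])) dY$M <- dY$M + d_skip[[s]]
    }
    bw <- layer_bwd(net$encoder[[i]], dY, fw$enc_fw[[i]])
    enc_grads[i] <- list(bw$grads)   # keep NULL slots for pool layers
    dY <- bw$dX
  }
  list(enc = enc_grads, dec = dec_grads)
}

# Pull updated BN running stats out of a forward cache into the network.
absorb_bn_stats <- function(net, fw) {
  for (i in seq_along(net$encoder)) {
    if (!is.null(net$encoder[[i]]$bn)) {
      net$encoder[[i]]$bn <- fw$enc_fw[[i]]$bnres$bn
    }
  }
  for (j in seq_along(net$decoders)) {
    for (i in seq_along(net$decoders[[j]])) {
      if (!is.null(net$decoders[[j]][[i]]$bn)) {
        net$decoders[[j]][[i]]$bn <- fw$dec_fw[[j]][[i]]$bnres$bn
      }
    }
  }
  net
}

## ---- ADAM -------------------------------------------------------------

adam_init <- function(net) {
  zero_like <- function(l) {
    if (l$type == "pool") return(NULL)
    g <- list(mW = array(0, dim(l$W)), vW = array(0, dim(l$W)),
              mb = numeric(length(l$b)), vb = numeric(length(l$b)))
    if (!is.null(l$bn)) {
      g$mg <- numeric(length(l$bn$gamma)); g$vg <- g$mg
      g$mB <- g$mg; g$vB <- g$mg
    }
    if (!is.null(l$Ws)) {
      g$mWs <- array(0, dim(l$Ws)); g$vWs <- g$mWs
    }
    g
  }
  list(t = 0,
       enc = lapply(net$encoder, zero_like),
       dec = lapply(net$decoders, function(dj) lapply(dj, zero_like)))
}

adam_update_layer <- function(l, g, s, lr, b1, b2, eps, t) {
  if (is.null(g)) return(list(l = l, s = s))
  corr <- sqrt(1 - b2^t) / (1 - b1^t)
  upd <- function(m, v, grad, par) {
    m <- b1 * m + (1 - b1) * grad
    v <- b2 * v + (1 - b2) * grad^2
    par <- par - lr * corr * m / (sqrt(v) + eps)
    list(m = m, v = v, par = par)
  }
  u <- upd(s$mW, s$vW, g$dW, l$W); s$mW <- u$m; s$vW <- u$v; l$W <- u$par
  u <- upd(s$mb, s$vb, g$db, l$b); s$mb <- u$m; s$vb <- u$v; l$b <- u$par
  if (!is.null(l$bn)) {
    u <- upd(s$mg, s$vg, g$dgamma, l$bn$gamma)
    s$mg <- u$m; s$vg <- u$v; l$bn$gamma <- u$par
    u <- upd(s$mB, s$vB, g$dbeta, l$bn$beta)
    s$mB <- u$m; s$vB <- u$v; l$bn$beta <- u$par
  }
  if (!is.null(l$Ws)) {
    u <- upd(s$mWs, s$vWs, g$dWs, l$Ws)
    s$mWs <- u$m; s$vWs <- u$v; l$Ws <- u$par
  }
  list(l = l, s = s)
}

adam_step <- function(net, grads, state, lr = 1e-3, b1 = 0.9, b2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (i in seq_along(net$encoder)) {
    r <- adam_update_layer(net$encoder[[i]], grads$enc[[i]],
                           state$enc[[i]], lr, b1, b2, eps, state$t)
    net$encoder[[i]] <- r$l; state$enc[i] <- list(r$s)
  }
  for (j in seq_along(net$decoders)) {
    for (i in seq_along(net$decoders[[j]])) {
      r <- adam_update_layer(net$decoders[[j]][[i]], grads$dec[[j]][[i]],
                             state$dec[[j]][[i]], lr, b1, b2, eps, state$t)
      net$decoders[[j]][[i]] <- r$l; state$dec[[j]][[i]] <- r$s
    }
  }
  list(net = net, state = state)
}
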