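# Fork-network topology, Dice metrics, training mechanics and 2.5D fusion.

# Layer-by-layer closed-form parameter count, kept independent of the
# implementation: this is the documented reconciliation of the topology
# (23 layers, 6 pooling, first layer 8 features doubling after each
# pooling, one encoder + nine decoders) with the stated ~5 million
# trainable parameters.
expected_parameter_count <- function(spec) {
  p <- spec$pooling_steps
  ew <- spec$enc_widths                      # F * 2^(0..p)
  enc <- 0
  prev <- 1
  for (s in 0:p) {
    enc <- enc + ew[s + 1] * (prev * 9 + 1) + 2 * ew[s + 1]   # conv + BN
    prev <- ew[s + 1]
  }
  dec <- 0
  cw <- spec$dec_widths
  cin <- ew[p + 1]
  for (k in seq_len(p)) {
    dec <- dec + cw[k] * (cin * 4 + 1) + 2 * cw[k]            # deconv + BN
    dec <- dec + ew[p - k + 1] * cw[k]                        # 1x1 skip proj
    if (k %in% spec$refine_at) {
      dec <- dec + cw[k] * (cw[k] * 9 + 1) + 2 * cw[k]        # refine conv
    }
    cin <- cw[k]
  }
  dec <- dec + (cin + 1)                                      # 1x1 output
  enc + spec$decoders * dec
}

test_that("network spec invariants: doubling widths, 23-layer path, 9 decoders", {
  s <- network_spec()
  expect_equal(s$enc_widths, 8 * 2^(0:6))
  expect_equal(s$total_layers, 23)
  expect_equal(s$decoders, 9)
  expect_equal(length(s$refine_at), 3)
})

test_that("parameter count matches the layer-wise closed form exactly", {
  for (spec in list(network_spec(),
                    network_spec(base_features = 4),
                    network_spec(base_features = 4, pooling_steps = 3),
                    network_spec(base_features = 2, pooling_steps = 2,
                                 decoders = 3))) {
    net <- build_network(spec, seed = 1)
    expect_identical(count_parameters(net), expected_parameter_count(spec))
  }
})

test_that("halving base_features quarters the conv-dominated parameter count", {
  n8 <- count_parameters(build_network(network_spec(), seed = 1))
  n4 <- count_parameters(build_network(network_spec(base_features = 4),
                                       seed = 1))
  expect_lt(abs(n4 / n8 - 0.25), 0.025)
})

test_that("the network is fully convolutional with size-independent parameters", {
  spec <- network_spec(base_features = 2, pooling_steps = 3, decoders = 4)
  net <- build_network(spec, seed = 1)
  f1 <- network_forward(net, array(0.1, c(32, 64, 1, 1)))
  f2 <- network_forward(net, array(0.1, c(64, 64, 1, 1)))
  expect_equal(dim(f1$probs), c(32, 64, 4, 1))
  expect_equal(dim(f2$probs), c(64, 64, 4, 1))
  expect_error(network_forward(net, array(0.1, c(30, 64, 1, 1))),
               "divisible")
})

test_that("slice bookkeeping reproduces the training-set slice counts", {
  shapes <- rep(list(c(192L, 256L, 256L)), 9)   # leave-one-out of 10
  expect_equal(nrow(slice_plan(shapes, "transverse")), 2304)
  expect_equal(nrow(slice_plan(shapes, "coronal")), 2304)
  expect_equal(nrow(slice_plan(shapes, "sagittal")), 1728)
  expect_equal(attr(slice_plan(shapes, "transverse"), "slice_shape"),
               c(192L, 256L))
  expect_equal(attr(slice_plan(shapes, "sagittal"), "slice_shape"),
               c(256L, 256L))
  expect_equal(nrow(slice_plan(shapes[1], "transverse")), 256)
  expect_error(slice_plan(list(c(192, 256, 256), c(192, 256, 128)),
                          "coronal"), "differ")
})

test_that("dice coefficient follows its definition including the empty case", {
  a <- array(0, c(4, 4)); a[1:2, 1:2] <- 1
  expect_equal(dice(a, a), 1)
  b <- array(0, c(4, 4)); b[3:4, 3:4] <- 1
  expect_equal(dice(a, b), 0)
  # |a| = |b| = 4, overlap 2 -> 0.5
  c1 <- array(0, c(4, 4)); c1[1, 1:4] <- 1
  c2 <- array(0, c(4, 4)); c2[1, 3:4] <- 1; c2[2, 1:2] <- 1
  expect_equal(dice(c1, c2), 0.5)
  expect_equal(dice(array(0, c(3, 3)), array(0, c(3, 3))), 1)
})

test_that("soft Dice loss hits its closed forms and matches the gradient", {
  d <- c(8, 8, 3, 2)
  t <- array(0, d); t[, , 1, ][array(runif(128) > 0.5, c(8, 8, 2))] <- 1
  t[, , 2, ] <- 1 - t[, , 1, ]
  # perfect prediction -> loss below the smoothing tolerance
  expect_lt(dice_loss(t, t), 0.01)
  # complemented prediction -> loss near 1
  expect_gt(dice_loss(1 - t, t), 0.95)
  # uniform 0.5 prediction: per-class closed form
  p <- array(0.5, d)
  n_pix <- prod(d[c(1, 2, 4)])
  per_class <- vapply(1:3, function(c) {
    tc <- sum(t[, , c, ])
    1 - (2 * 0.5 * tc + 1) / (0.5 * n_pix + tc + 1)
  }, numeric(1))
  expect_equal(dice_loss(p, t), mean(per_class), tolerance = 1e-12)
  # analytic gradient agrees with central differences
  set.seed(1)
  p <- array(runif(prod(d), 0.2, 0.8), d)
  g <- dice_loss(p, t, with_grad = TRUE)$grad
  for (probe in 1:4) {
    i <- sample(prod(d), 1)
    eps <- 1e-6
    p1 <- p; p1[i] <- p1[i] + eps
    p2 <- p; p2[i] <- p2[i] - eps
    num <- (dice_loss(p1, t) - dice_loss(p2, t)) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-5)
  }
})

test_that("backpropagation matches numeric gradients through every layer type", {
  spec <- network_spec(base_features = 2, pooling_steps = 2, decoders = 3)
  net <- build_network(spec, seed = 2)
  set.seed(3)
  X <- array(rnorm(8 * 8 * 2), c(8, 8, 1, 2))
  T <- array(0, c(8, 8, 3, 2))
  T[, , 1, ][X[, , 1, ] > 0] <- 1
  T[, , 2, ] <- 1 - T[, , 1, ]
  fw <- network_forward(net, X, training = TRUE)
  dl <- dice_loss(fw$probs, T, with_grad = TRUE)
  gr <- persardose:::network_backward(net, fw, dl$grad)
  eps <- 1e-6
  probe <- function(get, set, gval) {
    w0 <- get(net)
    i <- sample(length(w0), 1)
    f1 <- dice_loss(network_forward(set(net, replace(w0, i, w0[i] + eps)),
                                    X, training = TRUE)$probs, T)
    f2 <- dice_loss(network_forward(set(net, replace(w0, i, w0[i] - eps)),
                                    X, training = TRUE)$probs, T)
    expect_equal(gval[i], (f1 - f2) / (2 * eps), tolerance = 1e-4)
  }
  set.seed(4)
  probe(function(n) n$encoder[[1]]$W,
        function(n, w) { n$encoder[[1]]$W[] <- w; n }, gr$enc[[1]]$dW)
  probe(function(n) n$encoder[[5]]$W,
        function(n, w) { n$encoder[[5]]$W[] <- w; n }, gr$enc[[5]]$dW)
  probe(function(n) n$decoders[[2]][[1]]$W,
        function(n, w) { n$decoders[[2]][[1]]$W[] <- w; n },
        gr$dec[[2]][[1]]$dW)
  probe(function(n) n$decoders[[2]][[1]]$Ws,
        function(n, w) { n$decoders[[2]][[1]]$Ws[] <- w; n },
        gr$dec[[2]][[1]]$dWs)
  probe(function(n) n$encoder[[3]]$bn$gamma,
        function(n, w) { n$encoder[[3]]$bn$gamma <- w; n },
        gr$enc[[3]]$dgamma)
})

test_that("one epoch of training reduces the loss, deterministically per seed", {
  sub1 <- make_subject(31, shape = c(32, 32, 32), noise_sd = 0.02)
  vols <- list(list(image = sub1$image, labels = sub1$labels))
  spec <- network_spec(base_features = 2, pooling_steps = 2)
  cfg <- train_config(epochs = 2, seed = 5, learning_rate = 1e-2)
  r1 <- train_forknet(vols, "transverse", spec, cfg)
  expect_lt(r1$history$train_loss[2], r1$history$train_loss[1])
  # bit-identical re-run under the same seed-controlled shuffle
  r2 <- train_forknet(vols, "transverse", spec, cfg)
  expect_identical(r1$net$encoder[[1]]$W, r2$net$encoder[[1]]$W)
  expect_identical(r1$net$decoders[[3]][[1]]$W, r2$net$decoders[[3]][[1]]$W)
  expect_identical(r1$history, r2$history)
  # different seeds give different initial weights
  n1 <- build_network(spec, seed = 1)
  n2 <- build_network(spec, seed = 2)
  expect_false(identical(n1$encoder[[1]]$W, n2$encoder[[1]]$W))
  expect_error(train_forknet(list(), "transverse", spec, cfg), "empty")
})

test_that("2.5D fusion takes the summed argmax and fills voids by majority vote", {
  d <- c(5, 5, 5)
  z <- array(0, c(d, 9))
  # one orientation hard one-hot, others zero -> that orientation's argmax
  m <- z
  m[, , , 4] <- 1   # channel 4 = code 3 (muscle)
  out <- fuse_2p5d(m, z, z)
  expect_true(all(out$grid == 3L))
  # strictly largest channel wins regardless of the others' ordering
  m2 <- array(runif(prod(d) * 9, 0, 0.4), c(d, 9))
  m2[2, 3, 4, 4] <- 5
  out2 <- fuse_2p5d(m2, z, z)
  expect_identical(out2$grid[2, 3, 4], 3L)
  # all-zero voxel surrounded by muscle -> muscle via 26-neighborhood vote
  m3 <- z
  m3[, , , 4] <- 1
  m3[3, 3, 3, ] <- 0
  out3 <- fuse_2p5d(m3, z, z)
  expect_identical(out3$grid[3, 3, 3], 3L)
  # background is excluded from the vote when tissue neighbors exist
  m4 <- z
  m4[, , , 1] <- 1                 # background everywhere
  m4[2:4, 2:4, 2:4, 1] <- 0
  m4[2:4, 2:4, 2:4, 6] <- 1        # white-matter cube
  m4[3, 3, 3, ] <- 0               # void at the center
  out4 <- fuse_2p5d(m4, z, z)
  expect_identical(out4$grid[3, 3, 3], 5L)
  # no unassigned voxels, ever
  expect_true(all(out4$grid %in% tissue_labels()$code))
  # ties break to the lowest channel index
  m5 <- z
  m5[, , , 3] <- 1
  m5[, , , 5] <- 1
  out5 <- fuse_2p5d(m5, z, z)
  expect_true(all(out5$grid == 2L))
})

test_that("segmentation evaluation aggregates per-class Dice as defined", {
  ph <- make_phantom(phantom_spec(shape = c(40, 40, 40), seed = 6))
  ev <- evaluate_segmentation(ph, ph)
  expect_true(all(ev$table$dice == 1))
  expect_equal(ev$mean, 1)
  expect_equal(ev$sd, 0)
  # one class fully mislabeled: its Dice 0, the aggregate is the mean
  g <- ph$grid
  g[g == tissue_code("eye")] <- tissue_code("muscle")
  pred <- label_volume(g, ph$voxel_size)
  ev2 <- evaluate_segmentation(pred, ph)
  expect_equal(ev2$table$dice[ev2$table$name == "eye"], 0)
  expect_equal(ev2$mean, mean(ev2$table$dice))
  unchanged <- setdiff(ev2$table$name, c("eye", "muscle"))
  expect_true(all(ev2$table$dice[ev2$table$name %in% unchanged] == 1))
})
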