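# Synthetic phantom, MR-signal and E-field generators.

test_that("phantom generation is deterministic and realizes all nine classes", {
  sp <- phantom_spec(shape = c(48, 48, 48), seed = 1)
  ph1 <- make_phantom(sp)
  ph2 <- make_phantom(sp)
  expect_identical(ph1$grid, ph2$grid)
  counts <- table(factor(ph1$grid, levels = tissue_labels()$code))
  expect_true(all(counts > 0))
  # label closure: only the nine declared codes
  expect_true(all(ph1$grid %in% tissue_labels()$code))
})

test_that("air cavities sit inside bone with a >= 2-voxel wall", {
  for (s in c(1, 4, 9)) {
    ph <- make_phantom(phantom_spec(shape = c(48, 48, 48), seed = s,
                                    cavity_count = 1 + (s %% 3)))
    air <- ph$grid == tissue_code("internal_air")
    expect_gt(sum(air), 0)
    dil <- air
    for (di in -2:2) for (dj in -2:2) for (dk in -2:2) {
      if (di^2 + dj^2 + dk^2 <= 4) {
        dil <- dil | persardose:::shift3d(air, di, dj, dk)
      }
    }
    expect_true(all(ph$grid[dil & !air] == tissue_code("bone")))
  }
})

test_that("too-small phantom shapes are rejected", {
  expect_error(make_phantom(phantom_spec(shape = c(16, 16, 16))),
               "too small")
})

test_that("the body support is a single 6-connected component", {
  ph <- make_phantom(phantom_spec(shape = c(48, 48, 48), seed = 2))
  bm <- body_mask(ph)
  d <- dim(bm)
  # BFS flood fill from one body voxel over 6-neighborhoods
  visited <- array(FALSE, d)
  start <- which(bm)[1]
  queue <- start
  visited[start] <- TRUE
  strides <- c(1L, -1L, d[1], -d[1], d[1] * d[2], -d[1] * d[2])
  coords <- arrayInd(seq_len(prod(d)), d)
  while (length(queue)) {
    v <- queue[length(queue)]; queue <- queue[-length(queue)]
    vi <- coords[v, ]
    for (s in 1:6) {
      w <- v + strides[s]
      ax <- c(1, 1, 2, 2, 3, 3)[s]
      if (vi[ax] + c(1, -1, 1, -1, 1, -1)[s] < 1 ||
          vi[ax] + c(1, -1, 1, -1, 1, -1)[s] > d[ax]) next
      if (bm[w] && !visited[w]) {
        visited[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  expect_identical(sum(visited), sum(bm))
})

test_that("skin enforcement relabels only surface fat, idempotently", {
  ph <- make_phantom(phantom_spec(shape = c(48, 48, 48), seed = 3))
  # construct a volume with fat at the surface
  g <- ph$grid
  bg_adjacent <- persardose:::shift3d(g == 0L, 1, 0, 0, fill = TRUE) & g != 0L
  g[bg_adjacent] <- tissue_code("fat")
  lv <- label_volume(g, ph$voxel_size)
  out <- enforce_skin_layer(lv, 1)
  expect_true(all(out$grid[bg_adjacent] == tissue_code("muscle")))
  # non-fat voxels unchanged
  non_fat <- lv$grid != tissue_code("fat")
  expect_identical(out$grid[non_fat], lv$grid[non_fat])
  # idempotent
  expect_identical(enforce_skin_layer(out, 1)$grid, out$grid)
  # no surface fat -> no-op
  g2 <- lv$grid
  g2[g2 == tissue_code("fat")] <- tissue_code("muscle")
  lv2 <- label_volume(g2, ph$voxel_size)
  expect_identical(enforce_skin_layer(lv2, 1)$grid, lv2$grid)
  # deep interior fat beyond the layer is untouched
  ph2 <- make_phantom(phantom_spec(shape = c(48, 48, 48), seed = 5))
  deep_fat <- ph2$grid == tissue_code("fat")
  for (di in -5:5) for (dj in -5:5) for (dk in -5:5) {
    if (di^2 + dj^2 + dk^2 <= 25) {
      deep_fat <- deep_fat & !persardose:::shift3d(ph2$grid == 0L, di, dj, dk,
                                                   fill = TRUE)
    }
  }
  out2 <- enforce_skin_layer(ph2, 1)
  expect_true(all(out2$grid[deep_fat] == tissue_code("fat")))
})

test_that("simulate_t1w is piecewise-constant without bias/noise and linear in bias", {
  ph <- make_phantom(phantom_spec(shape = c(48, 48, 48), seed = 1))
  ones <- image_volume(array(1, dim(ph$grid)), ph$voxel_size)
  img <- simulate_t1w(ph, ones, noise_sd = 0)
  means <- default_t1w_means()
  for (code in 0:8) {
    vals <- img$grid[ph$grid == code]
    expect_equal(unname(vals), rep(unname(means[code + 1]), length(vals)))
  }
  # same seed -> identical
  b <- make_bias_field(make_b1_maps(ph, seed = 2), ph)
  i1 <- simulate_t1w(ph, b, noise_sd = 0.05, seed = 7)
  i2 <- simulate_t1w(ph, b, noise_sd = 0.05, seed = 7)
  expect_identical(i1$grid, i2$grid)
  # doubling the bias doubles the noiseless intensity
  b2 <- image_volume(2 * b$grid, ph$voxel_size)
  expect_equal(simulate_t1w(ph, b2, 0)$grid, 2 * simulate_t1w(ph, b, 0)$grid)
})

test_that("DREAM simulation round-trips through dream_maps", {
  ph <- make_phantom(phantom_spec(shape = c(40, 40, 40), seed = 4))
  b1 <- make_b1_maps(ph, seed = 6)
  dr <- simulate_dream(b1$b1plus, b1$m0b1minus)
  m <- dream_maps(dr$ste, dr$fid, steam_angle = 50)
  expect_lt(max(abs(m$b1plus$grid[m$mask] - b1$b1plus$grid[m$mask])), 1e-10)
  # nominal B1+ -> recovered flip equals the nominal STEAM angle
  ones <- image_volume(array(1, dim(ph$grid)), ph$voxel_size)
  m0 <- image_volume(array(2, dim(ph$grid)), ph$voxel_size)
  dr1 <- simulate_dream(ones, m0, steam_angle = 50)
  a <- atan(sqrt(2 * dr1$ste$grid / dr1$fid$grid)) * 180 / pi
  expect_equal(max(abs(a - 50)), 0, tolerance = 1e-10)
  # M0 cancellation: scaling M0B1- scales both images, ratio invariant
  m0b <- image_volume(2 * b1$m0b1minus$grid, ph$voxel_size)
  dr2 <- simulate_dream(b1$b1plus, m0b)
  expect_equal(dr2$ste$grid, 2 * dr$ste$grid)
  expect_equal(dr2$fid$grid, 2 * dr$fid$grid)
  expect_error(simulate_dream(image_volume(array(0, dim(ph$grid))),
                              b1$m0b1minus), "positive")
})

test_that("E-field generator is deterministic and supported on the body", {
  ph <- make_phantom(phantom_spec(shape = c(40, 40, 40), seed = 4))
  f1 <- make_efields(ph, channels = 3, seed = 5)
  f2 <- make_efields(ph, channels = 3, seed = 5)
  expect_identical(f1$E, f2$E)
  outside <- !body_mask(ph)
  for (ch in 1:3) for (comp in 1:3) {
    expect_true(all(Mod(f1$E[, , , comp, ch][outside]) == 0))
  }
})

test_that("smooth-noise autocorrelation length tracks the requested smoothness", {
  sm <- 16
  s <- synth_smooth_noise(c(96, 96, 96), smoothness_mm = sm, seed = 5)
  s <- s - mean(s)
  ac <- function(lag) {
    n <- dim(s)[1]
    mean(s[1:(n - lag), , ] * s[(1 + lag):n, , ]) / mean(s^2)
  }
  lags <- 1:40
  a <- vapply(lags, ac, numeric(1))
  first_below <- which(a < exp(-1))[1]
  l1e <- lags[first_below - 1] +
    (a[first_below - 1] - exp(-1)) / (a[first_below - 1] - a[first_below])
  expect_lt(abs(l1e - sm) / sm, 0.25)
})
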