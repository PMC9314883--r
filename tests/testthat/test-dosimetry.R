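# SAR, 10 g averaging, Q-matrices, shims and margin statistics.

test_that("pointwise SAR follows sigma |E|^2 / (2 rho) with zero-sigma exclusion", {
  lab <- tiny_head(20, voxel_mm = 2)
  d <- dim(lab$grid)
  # single-channel unit field along x
  E <- array(complex(real = 0), c(d, 3, 1))
  E[, , , 1, 1] <- 2 + 0i
  fs <- field_set(E, voxel_volume = 8e-9)
  props <- default_tissue_properties()
  props$sigma[props$name == "muscle"] <- 1
  props$rho[props$name == "muscle"] <- 1000
  ps <- pointwise_sar(fs, lab, props, shim = complex(real = 1))
  muscle <- lab$grid == tissue_code("muscle")
  # sigma = 1 S/m, |E| = 2 V/m, rho = 1000 kg/m^3 -> 0.002 W/kg
  expect_equal(unname(ps$grid[muscle][1]), 0.002, tolerance = 1e-12)
  expect_true(all(ps$grid[lab$grid == 0] == 0))
  # destructive combination: E2 = i E1, w = (1, i)/sqrt(2) cancels exactly
  E2 <- array(complex(real = 0), c(d, 3, 2))
  set.seed(1)
  base <- array(complex(real = rnorm(prod(d) * 3),
                        imaginary = rnorm(prod(d) * 3)), c(d, 3))
  E2[, , , , 1] <- base
  E2[, , , , 2] <- 1i * base
  fs2 <- field_set(E2, voxel_volume = 8e-9)
  ps2 <- pointwise_sar(fs2, lab, props,
                       shim = c(1, 1i) / sqrt(2))
  expect_lt(max(ps2$grid), 1e-25)
  expect_error(pointwise_sar(fs2, lab, props, shim = complex(real = 1)),
               "channel-count")
})

test_that("10 g averaging: uniform invariance, mass dilution, exact region mass", {
  lab <- tiny_head(24, voxel_mm = 2)
  vv <- 8e-9
  mass <- voxel_masses(lab, voxel_volume = vv)
  # uniform SAR s -> 10 g average = s everywhere (and the all-ones field
  # doubles as a per-voxel proof that region masses equal 10 g exactly)
  s <- 3.7
  u <- average_10g(array(s, dim(lab$grid)), lab, voxel_volume = vv)
  tis <- mass > 0
  expect_lt(max(abs(u$grid[tis] / s - 1)), 1e-12)
  expect_true(all(u$grid[!tis] == 0))
  # single hot voxel in a zero-SAR body: 10 g average = s * m / 0.010
  hot <- which(tis)[123]
  v <- array(0, dim(lab$grid)); v[hot] <- 5
  h <- average_10g(v, lab, voxel_volume = vv)
  expect_equal(h$grid[hot], 5 * mass[hot] / 0.010, tolerance = 1e-12)
  # total mass below 10 g is an explicit error
  small <- label_volume(array(c(0L, 3L)[1 + (seq_len(6^3) %% 2)], c(6, 6, 6)),
                        c(2, 2, 2))
  expect_error(average_10g(array(1, c(6, 6, 6)), small, voxel_volume = vv),
               "below the averaging mass")
})

test_that("region-growing averager matches the brute-force oracle", {
  lab <- tiny_head(18, voxel_mm = 2)
  vv <- 8e-9
  set.seed(7)
  val <- array(runif(prod(dim(lab$grid))), dim(lab$grid))
  got <- average_10g(val, lab, voxel_volume = vv)
  ora <- avg10g_oracle(val, lab, vv, at = seq(1, sum(voxel_masses(
    lab, voxel_volume = vv) > 0), by = 7))
  rel <- abs(got$grid[ora$idx] - ora$values) / abs(ora$values)
  expect_lt(max(rel), 1e-12)
})

test_that("Q-matrices: rank-1 collapse, Hermitian PSD, shim evaluation identities", {
  lab <- tiny_head(16, voxel_mm = 2)
  vv <- 8e-9
  fs1 <- make_efields(lab, channels = 1, seed = 3)
  q1 <- build_q10g(fs1, lab, voxel_volume = vv)
  # C = 1: Q10g equals the scalar 10 g-averaged SAR at unit drive
  s10 <- average_10g(pointwise_sar(fs1, lab, shim = complex(real = 1)),
                     lab, voxel_volume = vv)
  tis <- which(q1$tissue)
  expect_lt(max(abs(Re(q1$Q[tis, 1]) - s10$grid[tis]) /
                pmax(s10$grid[tis], 1e-300)), 1e-10)
  # C = 3: Hermitian by construction, PSD up to round-off
  fs3 <- make_efields(lab, channels = 3, seed = 4)
  q3 <- build_q10g(fs3, lab, voxel_volume = vv)
  for (v in tis[c(1, 25, 50)]) {
    M <- q_matrix_at(q3, v)
    expect_lt(max(abs(M - Conj(t(M)))), 1e-14)
    ev <- eigen(M, only.values = TRUE)$values
    expect_gte(min(Re(ev)), -1e-10 * max(abs(ev)))
  }
  # identity-Q sanity: w^H I w = ||w||^2 = 1
  qi <- q3
  qi$Q[] <- 0
  diag_cols <- cumsum(seq_len(3))
  qi$Q[tis[1], diag_cols] <- 1
  es <- eval_shim(qi, quadrature_shim(3))
  expect_equal(es$peak, 1, tolerance = 1e-12)
  expect_equal(es$sar$grid[tis[1]], 1, tolerance = 1e-12)
  # global phase invariance and peak max-dominance
  shims <- random_shims(3, n = 8, seed = 5)
  p0 <- vapply(shims, function(w) eval_shim(q3, w)$peak, numeric(1))
  p1 <- vapply(shims, function(w) eval_shim(q3, w * exp(1i * 0.83))$peak,
               numeric(1))
  expect_equal(p0, p1, tolerance = 1e-12)
  expect_gte(max(p0), max(p0[3]))
  expect_warning(eval_shim(q3, c(2, 0, 0)), "renormaliz")
})

test_that("Q-matrix path equals the direct field pipeline for random shims", {
  lab <- tiny_head(16, voxel_mm = 2)
  vv <- 8e-9
  fs <- make_efields(lab, channels = 4, seed = 6)
  q <- build_q10g(fs, lab, voxel_volume = vv)
  tis <- array(q$tissue, q$dims)
  for (w in random_shims(4, n = 3, seed = 9)) {
    via_q <- eval_shim(q, w)$sar$grid
    direct <- average_10g(pointwise_sar(fs, lab, shim = w), lab,
                          voxel_volume = vv)$grid
    expect_lt(max(abs(via_q[tis] - direct[tis]) /
                  pmax(direct[tis], 1e-300)), 1e-10)
  }
})

test_that("random shims are power-normalized and deterministic", {
  s1 <- random_shims(8, n = 1000, seed = 11)
  s2 <- random_shims(8, n = 1000, seed = 11)
  expect_length(s1, 1000)
  expect_identical(s1, s2)
  norms <- vapply(s1, function(w) sum(Mod(w)^2), numeric(1))
  expect_lt(max(abs(norms - 1)), 1e-12)
  expect_false(identical(s1[[1]], random_shims(8, 1, seed = 12)[[1]]))
  wq <- quadrature_shim(16)
  expect_equal(sum(Mod(wq)^2), 1, tolerance = 1e-12)
  expect_equal(Arg(wq[2]) - Arg(wq[1]), 2 * pi / 16, tolerance = 1e-12)
})

test_that("head-averaged SAR is the energy-bookkeeping mass-weighted mean", {
  lab <- tiny_head(16, voxel_mm = 2)
  vv <- 8e-9
  fs <- make_efields(lab, channels = 2, seed = 8)
  w <- random_shims(2, 1, seed = 2)[[1]]
  ps <- pointwise_sar(fs, lab, shim = w)
  mass <- voxel_masses(lab, voxel_volume = vv)
  # uniform SAR s -> s
  expect_equal(head_average_sar(array(4.2, dim(lab$grid)), lab,
                                voxel_volume = vv), 4.2, tolerance = 1e-12)
  # equals total absorbed power / total tissue mass
  expect_equal(head_average_sar(ps, lab, voxel_volume = vv),
               sum(ps$grid * mass) / sum(mass), tolerance = 1e-12)
})

test_that("underestimation error and shim-study statistics follow their definitions", {
  expect_equal(underestimation_error(1, 1), 0)
  expect_equal(underestimation_error(1, 0.9), 10)
  # antisymmetry only in the numerator; denominator stays the ground truth
  expect_equal(underestimation_error(1, 1.2), -20)
  expect_error(underestimation_error(0, 1), "positive")

  lab <- tiny_head(16, voxel_mm = 2)
  fs <- make_efields(lab, channels = 3, seed = 12)
  q <- build_q10g(fs, lab, voxel_volume = 8e-9)
  shims <- random_shims(3, n = 40, seed = 13)
  # identical models: all errors zero, margin zero
  st0 <- shim_study(q, q, shims)
  expect_true(all(st0$error == 0))
  expect_equal(st0$safety_margin, 0, tolerance = 1e-9)
  # scaled model: q_gen = 0.9 q_gt -> every error +10%
  q9 <- q; q9$Q <- 0.9 * q9$Q
  st9 <- shim_study(q, q9, shims)
  expect_equal(max(abs(st9$error - 10)), 0, tolerance = 1e-9)
  expect_equal(st9$q95_error, 10, tolerance = 1e-9)
  # reported quantile equals the direct quantile oracle of the error list
  qh <- q
  qh$Q <- q$Q * 0.95
  # perturb to make errors vary across shims
  qh$Q[, 2] <- q$Q[, 2] * 0.7
  st <- shim_study(q, qh, shims)
  expect_equal(st$q95_error,
               unname(quantile(st$error, 0.95)), tolerance = 1e-12)
  expect_equal(st$mean_error, mean(st$error), tolerance = 1e-12)
  expect_error(shim_study(q, qh, list()), "empty")
})

test_that("generic one-size-fits-all margins: closed forms and monotonicity", {
  # all models identical -> all overestimations zero
  pk <- matrix(5, 3, 10)
  expect_true(all(generic_margin(pk)$over == 0))
  # two models with peaks p and 2p: +100% and -50% exactly
  p2 <- rbind(rep(1, 7), rep(2, 7))
  gm <- generic_margin(p2)
  expect_true(all(gm$over[1, ] == 100))
  expect_true(all(gm$over[2, ] == -50))
  # adding a uniformly dominant model weakly increases all others
  set.seed(3)
  base <- matrix(runif(30, 1, 2), 3, 10)
  g1 <- generic_margin(base)
  g2 <- generic_margin(rbind(base, 10))
  expect_true(all(g2$over[1:3, ] >= g1$over - 1e-12))
  expect_error(generic_margin(matrix(1, 1, 5)), "at least 2")
})
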