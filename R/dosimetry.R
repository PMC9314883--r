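# Local SAR dosimetry: pointwise SAR, mass-based 10 g region-growing
# averaging, Q-matrices, random-shim exposure statistics and safety
# margins.
#
# Conventions: E-fields are peak-amplitude phasors, so pointwise
# SAR = sigma |E|^2 / (2 rho) (W/kg) for the combined field E = sum_c w_c
# E_c. Background contributes neither mass nor power; internal air has
# zero conductivity and is excluded from averaging masses as well. All
# parallel-transmit results are normalized to a total input power of 1 W
# (||w||^2 = 1).

props_lookup <- function(props, what) {
  v <- numeric(9)
  v[props$code + 1L] <- props[[what]]
  v
}

#' Per-voxel tissue masses (kg)
#'
#' @param labels A [label_volume()].
#' @param props Tissue property table (see [default_tissue_properties()]).
#' @param voxel_volume Voxel volume in m^3.
#' @return 3D array of masses; zero for background and internal air (which
#'   contribute no mass to averaging regions).
#' @export
voxel_masses <- function(labels, props = default_tissue_properties(),
                         voxel_volume) {
  rho <- props_lookup(props, "rho")
  rho[tissue_code(c("background", "internal_air")) + 1L] <- 0
  array(rho[labels$grid + 1L] * voxel_volume, dim(labels$grid))
}

combine_fields <- function(fields, shim) {
  d <- dim(fields$E)
  if (length(shim) != fields$channels) stop("channel-count mismatch")
  E <- array(complex(real = 0, imaginary = 0), d[1:4])
  for (ch in seq_len(fields$channels)) {
    E <- E + shim[ch] * fields$E[, , , , ch]
  }
  E
}

#' Pointwise SAR for a given RF shim
#'
#' Combines the per-channel fields with the shim weights and evaluates
#' `sigma |E|^2 / (2 rho)` per voxel; exactly zero wherever the
#' conductivity is zero (background, internal air).
#'
#' @param fields A [field_set()].
#' @param labels A [label_volume()] on the same grid.
#' @param props Tissue property table.
#' @param shim Complex vector of per-channel weights (see [random_shims()]).
#' @return List of class `sar_volume`: `grid` (W/kg), `mass_kind =
#'   "pointwise"`, `normalization` (W).
#' @export
pointwise_sar <- function(fields, labels, props = default_tissue_properties(),
                          shim) {
  if (!identical(dim(fields$E)[1:3], dim(labels$grid))) {
    stop_geom("fields vs labels")
  }
  E <- combine_fields(fields, shim)
  E2 <- Re(E[, , , 1])^2 + Im(E[, , , 1])^2 +
        Re(E[, , , 2])^2 + Im(E[, , , 2])^2 +
        Re(E[, , , 3])^2 + Im(E[, , , 3])^2
  sigma <- props_lookup(props, "sigma")
  rho <- props_lookup(props, "rho")
  coef <- ifelse(sigma > 0 & rho > 0, sigma / (2 * rho), 0)
  structure(list(grid = coef[labels$grid + 1L] * E2,
                 mass_kind = "pointwise",
                 normalization = fields$normalization),
            class = "sar_volume")
}

# Offsets sorted by (distance, then lexicographic (di, dj, dk)): adding the
# center voxel preserves lexicographic order of absolute indices, so this
# tie-break equals the brute-force oracle's.
sorted_offsets <- function(r_vox) {
  r <- ceiling(r_vox)
  di <- seq(-r, r)
  g <- expand.grid(di = di, dj = di, dk = di)
  d2 <- g$di^2 + g$dj^2 + g$dk^2
  keep <- d2 <= r_vox^2
  g <- g[keep, ]; d2 <- d2[keep]
  o <- order(d2, g$di, g$dj, g$dk)
  as.matrix(g[o, ])
}

avg10g_engine <- function(labels, props, voxel_volume, values,
                          target_mass = 0.010) {
  d <- dim(labels$grid)
  mass <- voxel_masses(labels, props, voxel_volume)
  tissue <- mass > 0
  total_mass <- sum(mass)
  if (total_mass < target_mass) {
    stop(sprintf("total body mass (%.4f kg) is below the averaging mass (%.3f kg)",
                 total_mass, target_mass))
  }
  values <- as.matrix(values)
  # initial radius: interior sphere at mean tissue density, with margin for
  # boundary voxels whose region grows into a half-space
  rho_mean <- total_mass / (sum(tissue) * voxel_volume)
  r_m <- (3 * target_mass / (4 * pi * rho_mean))^(1 / 3)
  vox_m <- voxel_volume^(1 / 3)
  r_vox <- 1.8 * r_m / vox_m + 2
  todo <- tissue
  avg <- matrix(0, prod(d), ncol(values))
  for (attempt in 1:8) {
    off <- sorted_offsets(r_vox)
    res <- .avg10g_cpp(as.integer(d), as.vector(tissue), as.vector(mass),
                       values, target_mass, off, as.vector(todo))
    done <- array(res$complete, d)
    avg[as.vector(done), ] <- res$avg[as.vector(done), , drop = FALSE]
    todo <- todo & !done
    if (!any(todo)) break
    r_vox <- r_vox * 1.5
    max_r <- sqrt(sum((d - 1)^2)) + 1
    if (r_vox > max_r) r_vox <- max_r
  }
  if (any(todo)) {
    # unreachable given the total-mass check, but guard anyway
    warning(sum(todo), " voxel(s) could not accumulate the averaging mass; ",
            "assigned the whole-body average")
    wb <- colSums(values * as.vector(mass)) / total_mass
    avg[as.vector(todo), ] <- matrix(wb, sum(todo), ncol(values), byrow = TRUE)
  }
  avg
}

#' Mass-based 10 g region-growing average of a SAR volume
#'
#' For each tissue voxel, tissue voxels are accumulated in order of
#' increasing Euclidean center distance (ties by lexicographic index)
#' until the region mass reaches `target_mass`, the final voxel
#' contributing fractionally so the mass is matched exactly; the averaged
#' value is the mass-weighted mean over the region. This keeps the
#' averaging correct around the outer borders of the model, where cubical
#' averaging volumes would be truncated.
#'
#' @param sar A `sar_volume` from [pointwise_sar()] (or a plain 3D array of
#'   pointwise SAR).
#' @param labels A [label_volume()].
#' @param props Tissue property table.
#' @param voxel_volume Voxel volume in m^3.
#' @param target_mass Averaging mass in kg (default 0.010 = 10 g).
#' @return A `sar_volume` with `mass_kind = "10g"`.
#' @export
average_10g <- function(sar, labels, props = default_tissue_properties(),
                        voxel_volume, target_mass = 0.010) {
  g <- if (inherits(sar, "sar_volume")) sar$grid else sar
  if (!identical(dim(g), dim(labels$grid))) stop_geom("sar vs labels")
  if (target_mass <= 0) stop("target_mass must be positive")
  avg <- avg10g_engine(labels, props, voxel_volume, as.vector(g), target_mass)
  structure(list(grid = array(avg[, 1], dim(g)),
                 mass_kind = "10g",
                 normalization = if (inherits(sar, "sar_volume"))
                   sar$normalization else 1),
            class = "sar_volume")
}

#' 10 g-averaged Q-matrix volume
#'
#' Builds the raw per-voxel Q-matrix `Q_ab = sigma/(2 rho) * E_a . conj(E_b)`
#' (summed over the three field components) for every channel pair, then
#' applies the identical mass-based 10 g averaging ([average_10g()])
#' entry-wise, so that `w^H Q10g(v) w` equals the 10 g-averaged SAR of the
#' combined field for any shim `w`. Hermitian symmetry holds by
#' construction; matrices are PSD up to round-off.
#'
#' @param fields A [field_set()].
#' @param labels A [label_volume()].
#' @param props Tissue property table.
#' @param voxel_volume Voxel volume m^3; defaults to the field set's.
#' @param target_mass Averaging mass (kg).
#' @return Object of class `qmatrix_volume`: `Q` (complex matrix, one row
#'   per voxel in column-major grid order, columns = packed upper triangle
#'   including the diagonal, channel-pair order (a,b) a<=b column-major),
#'   `channels`, `dims`, `tissue` (logical vector), `normalization`.
#' @export
build_q10g <- function(fields, labels, props = default_tissue_properties(),
                       voxel_volume = NULL, target_mass = 0.010) {
  if (!identical(dim(fields$E)[1:3], dim(labels$grid))) {
    stop_geom("fields vs labels")
  }
  voxel_volume <- voxel_volume %||% fields$voxel_volume
  C <- fields$channels
  d <- dim(labels$grid)
  nvox <- prod(d)
  sigma <- props_lookup(props, "sigma")
  rho <- props_lookup(props, "rho")
  coef <- ifelse(sigma > 0 & rho > 0, sigma / (2 * rho), 0)
  coefv <- coef[labels$grid + 1L]
  np <- C * (C + 1) / 2
  Qre <- matrix(0, nvox, np); Qim <- matrix(0, nvox, np)
  col <- 0
  for (b in seq_len(C)) for (a in seq_len(b)) {
    col <- col + 1
    acc <- complex(length.out = nvox)
    for (comp in 1:3) {
      Ea <- as.vector(fields$E[, , , comp, a])
      Eb <- as.vector(fields$E[, , , comp, b])
      acc <- acc + Ea * Conj(Eb)
    }
    q <- coefv * acc
    Qre[, col] <- Re(q); Qim[, col] <- Im(q)
  }
  avg <- avg10g_engine(labels, props, voxel_volume, cbind(Qre, Qim),
                       target_mass)
  Q <- matrix(complex(real = avg[, seq_len(np)],
                      imaginary = avg[, np + seq_len(np)]), nvox, np)
  # diagonal entries are real by construction; drop round-off imaginaries
  diag_cols <- cumsum(seq_len(C))
  Q[, diag_cols] <- complex(real = Re(Q[, diag_cols]), imaginary = 0)
  mass <- voxel_masses(labels, props, voxel_volume)
  structure(list(Q = Q, channels = C, dims = d,
                 tissue = as.vector(mass > 0),
                 normalization = fields$normalization,
                 target_mass = target_mass),
            class = "qmatrix_volume")
}

#' Expand one packed Q-matrix row into a full Hermitian matrix
#' @param q A `qmatrix_volume`.
#' @param voxel Linear voxel index (column-major).
#' @return A `channels x channels` complex Hermitian matrix.
#' @export
q_matrix_at <- function(q, voxel) {
  C <- q$channels
  M <- matrix(complex(real = 0), C, C)
  col <- 0
  # packed entry (a <= b) holds P_ab = (sigma/2rho) E_a . conj(E_b);
  # the conventional Q with SAR = w^H Q w has Q_ab = P_ba = conj(P_ab)
  for (b in seq_len(C)) for (a in seq_len(b)) {
    col <- col + 1
    M[a, b] <- Conj(q$Q[voxel, col])
    M[b, a] <- q$Q[voxel, col]
  }
  M
}

#' Evaluate the 10 g SAR of an RF shim from a Q-matrix volume
#'
#' `SAR10g(v) = w^H Q(v) w`, evaluated for all voxels with one matrix
#' product over the packed upper triangle.
#'
#' @param q A `qmatrix_volume`.
#' @param shim Complex weight vector; re-normalized to `||w||^2 = 1` (1 W)
#'   with a warning if needed.
#' @return List: `sar` (a `sar_volume`, `mass_kind = "10g"`), `peak`
#'   (W/kg) and `location` (voxel `(i, j, k)` of the peak).
#' @export
eval_shim <- function(q, shim) {
  stopifnot(inherits(q, "qmatrix_volume"))
  if (length(shim) != q$channels) stop("channel-count mismatch")
  p <- sum(Mod(shim)^2)
  if (abs(p - 1) > 1e-9) {
    warning("shim not normalized to 1 W total input power; renormalizing")
    shim <- shim / sqrt(p)
  }
  coefs <- shim_pair_coefs(shim, q$channels)
  sar <- Re(q$Q %*% coefs)
  sar[sar < 0] <- 0     # round-off guard; Q is PSD
  g <- array(sar, q$dims)
  peak_idx <- which.max(g)
  structure_list <- structure(list(grid = g, mass_kind = "10g",
                                   normalization = q$normalization),
                              class = "sar_volume")
  list(sar = structure_list, peak = g[peak_idx],
       location = as.integer(arrayInd(peak_idx, q$dims)))
}

# Coefficient vector c such that SAR = Re(Qpacked %*% c). With packed
# P_ab = (sigma/2rho) E_a . conj(E_b) (a <= b) and combined field
# E = sum_c w_c E_c, |E|^2 expands to sum_ab w_a conj(w_b) P_ab, so the
# coefficient is |w_a|^2 on the diagonal and 2 w_a conj(w_b) (real part
# taken at the end) on the off-diagonal.
shim_pair_coefs <- function(shim, C) {
  coefs <- complex(length.out = C * (C + 1) / 2)
  col <- 0
  for (b in seq_len(C)) for (a in seq_len(b)) {
    col <- col + 1
    coefs[col] <- if (a == b) Mod(shim[a])^2 else 2 * shim[a] * Conj(shim[b])
  }
  coefs
}

#' Generate random RF shims
#'
#' Per-channel phases uniform on `[0, 2pi)` and amplitudes uniform on
#' `[0, 1]`, then normalized to 1 W total input power (`||w||^2 = 1`).
#' Deterministic per seed.
#'
#' @param channels Number of channels.
#' @param n Number of shims (default 1000).
#' @param seed Integer seed.
#' @return List of complex weight vectors.
#' @export
random_shims <- function(channels, n = 1000, seed = 1) {
  stopifnot(n >= 1, channels >= 1)
  with_local_seed(seed, {
    lapply(seq_len(n), function(i) {
      amp <- stats::runif(channels)
      ph <- stats::runif(channels, 0, 2 * pi)
      w <- complex(modulus = amp, argument = ph)
      nrm <- sqrt(sum(Mod(w)^2))
      if (nrm == 0) w <- rep(complex(real = 1), channels) / sqrt(channels)
      else w <- w / nrm
      w
    })
  })
}

#' Quadrature drive shim
#'
#' Equal amplitudes with successive phase increments of `360/channels`
#' degrees (22.5 degrees for a 16-port birdcage), normalized to 1 W: the
#' single-channel reference configuration represented on a synthetic
#' multi-port field set.
#'
#' @param channels Number of ports (default 16).
#' @return Complex weight vector with `||w||^2 = 1`.
#' @export
quadrature_shim <- function(channels = 16) {
  ph <- 2 * pi * (seq_len(channels) - 1) / channels
  complex(modulus = 1 / sqrt(channels), argument = ph)
}

#' Head-averaged SAR
#'
#' Mass-weighted mean pointwise SAR over all tissue voxels (equivalently
#' total absorbed power divided by total tissue mass). Internal air and
#' background carry no mass.
#'
#' @param sar A pointwise `sar_volume` (or array).
#' @param labels A [label_volume()].
#' @param props Tissue property table.
#' @param voxel_volume Voxel volume m^3.
#' @return Scalar W/kg.
#' @export
head_average_sar <- function(sar, labels, props = default_tissue_properties(),
                             voxel_volume) {
  g <- if (inherits(sar, "sar_volume")) sar$grid else sar
  mass <- voxel_masses(labels, props, voxel_volume)
  total <- sum(mass)
  if (total <= 0) stop("no tissue mass")
  sum(g * mass) / total
}

#' Peak-SAR underestimation error
#'
#' `100 * (peak_gt - peak_gen) / peak_gt` (percent): positive when the
#' generated (predicted-segmentation) model underestimates the ground
#' truth, the unsafe direction that drives the safety margin.
#'
#' @param peak_gt Ground-truth peak SAR10g (> 0).
#' @param peak_gen Generated-model peak SAR10g.
#' @return Percent error (vectorized).
#' @export
underestimation_error <- function(peak_gt, peak_gen) {
  if (any(peak_gt <= 0)) stop("ground-truth peak must be positive")
  100 * (peak_gt - peak_gen) / peak_gt
}

#' Random-shim study comparing ground-truth and generated models
#'
#' Evaluates every shim in both Q-matrix volumes, forms the per-shim peak
#' SAR10g underestimation errors, and summarizes the distribution: mean,
#' 95th-percentile error (linear-interpolation quantile), and the safety
#' margin, defined as the multiplicative factor on the generated-model
#' peaks that makes the stated fraction of shims conservative:
#' `margin = 100 * (quantile(peak_gt/peak_gen, conf) - 1)`.
#'
#' @param q_gt,q_gen `qmatrix_volume`s with equal channel counts.
#' @param shims List of shim vectors (see [random_shims()]).
#' @param confidence Conservative fraction for the margin (default 0.95).
#' @return Object of class `shim_study`: per-shim peaks and errors plus
#'   the summary statistics.
#' @export
shim_study <- function(q_gt, q_gen, shims, confidence = 0.95) {
  if (q_gt$channels != q_gen$channels) stop("channel-count mismatch")
  if (!length(shims)) stop("empty shim list")
  pk <- function(q, w) {
    coefs <- shim_pair_coefs(w, q$channels)
    max(Re(q$Q %*% coefs))
  }
  peaks_gt <- vapply(shims, function(w) pk(q_gt, w), numeric(1))
  peaks_gen <- vapply(shims, function(w) pk(q_gen, w), numeric(1))
  err <- underestimation_error(peaks_gt, peaks_gen)
  q95 <- stats::quantile(err, confidence, names = FALSE)   # type 7: linear
  margin <- 100 * (stats::quantile(peaks_gt / peaks_gen, confidence,
                                   names = FALSE) - 1)
  structure(list(peaks_gt = peaks_gt, peaks_gen = peaks_gen, error = err,
                 mean_error = mean(err), q95_error = q95,
                 safety_margin = margin, confidence = confidence,
                 n_shims = length(shims)),
            class = "shim_study")
}

#' @export
print.shim_study <- function(x, ...) {
  cat("shim_study over", x$n_shims, "shims: mean error",
      sprintf("%.2f%%,", x$mean_error),
      sprintf("%.0f%%-ile error %.2f%%,", 100 * x$confidence, x$q95_error),
      sprintf("safety margin %.2f%%\n", x$safety_margin))
  invisible(x)
}

#' Generic ("one-size-fits-all") overestimation distribution
#'
#' For each model `m` and shim `s`, the overestimation incurred by using
#' the worst case over the other models:
#' `100 * (max_{m' != m} peak[m', s] - peak[m, s]) / peak[m, s]`.
#'
#' @param peaks Matrix of peak SAR10g values, models in rows, shims in
#'   columns (>= 2 models).
#' @return List: `over` (same shape matrix of percent overestimations),
#'   `mean`, `frac_negative` (fraction of cases where the generic
#'   approach underestimates), `q95`.
#' @export
generic_margin <- function(peaks) {
  peaks <- as.matrix(peaks)
  if (nrow(peaks) < 2) stop("need at least 2 models")
  M <- nrow(peaks)
  over <- matrix(0, M, ncol(peaks))
  for (m in seq_len(M)) {
    others <- peaks[-m, , drop = FALSE]
    mx <- apply(others, 2, max)
    over[m, ] <- 100 * (mx - peaks[m, ]) / peaks[m, ]
  }
  list(over = over, mean = mean(over),
       frac_negative = mean(over < 0),
       q95 = stats::quantile(over, 0.95, names = FALSE))
}
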