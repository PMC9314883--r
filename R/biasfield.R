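# DREAM-based intensity bias estimation and correction.
#
# Pipeline: stimulated-echo/FID image pair -> B1+ and M0B1- maps
# (dream_maps) -> smooth solid-harmonic fits on the body mask
# (fit_spherical_basis; the fit retains only smooth structure, which
# removes the piecewise-constant tissue M0 component and the noise) ->
# sequence-specific bias field (bias_field_gre / bias_field_fse) ->
# division with a floor (correct_image).

#' Derive B1+ and M0B1- maps from a DREAM image pair
#'
#' The actual flip angle is `alpha = arctan(sqrt(2 * STE / FID))` per the
#' DREAM signal expressions; `b1plus = alpha / steam_angle` and the
#' receive-weighted proton density follows from the FID amplitude given
#' `alpha` and the imaging flip angle.
#'
#' @param ste,fid [image_volume()]s of the stimulated-echo and FID images.
#' @param steam_angle Nominal STEAM flip angle (degrees, default 50).
#' @param imaging_angle Nominal imaging flip angle (degrees, default 10).
#' @param mask Optional logical foreground mask; defaults to `fid > 0`.
#'   Voxels with non-positive FID inside the mask are excluded (with a
#'   message) rather than propagated.
#' @return List of class `b1_maps`: `b1plus`, `m0b1minus` ([image_volume()])
#'   and `mask` (logical array).
#' @export
dream_maps <- function(ste, fid, steam_angle = 50, imaging_angle = 10,
                       mask = NULL) {
  stopifnot(inherits(ste, "image_volume"), inherits(fid, "image_volume"))
  check_same_geometry(ste, fid, "ste vs fid")
  d <- dim(ste$grid)
  if (is.null(mask)) mask <- fid$grid > 0
  bad <- mask & fid$grid <= 0
  if (any(bad)) {
    message("dream_maps: excluding ", sum(bad), " voxel(s) with non-positive FID")
    mask <- mask & !bad
  }
  alpha <- array(0, d)
  ratio <- pmax(ste$grid, 0) / fid$grid
  alpha[mask] <- atan(sqrt(2 * ratio[mask]))
  b1p <- alpha / (steam_angle * pi / 180)
  m0 <- array(0, d)
  b <- b1p * imaging_angle * pi / 180
  den <- sin(b) * cos(alpha)^2
  ok <- mask & den > 0
  m0[ok] <- fid$grid[ok] / den[ok]
  vs <- ste$voxel_size
  structure(list(b1plus = image_volume(b1p, vs, ste$orientation),
                 m0b1minus = image_volume(m0, vs, ste$orientation),
                 mask = mask),
            class = "b1_maps")
}

# Real solid-harmonic basis r^l P_l^m(cos theta) {cos,sin}(m phi), evaluated
# on given mm coordinates (already centered); radius scaled by `rscale` for
# conditioning. Returns an N x (order+1)^2 matrix.
solid_harmonic_basis <- function(x, y, z, order, rscale) {
  n <- length(x)
  r <- sqrt(x^2 + y^2 + z^2) / rscale
  ct <- ifelse(r > 0, (z / rscale) / r, 1)
  ct <- pmin(pmax(ct, -1), 1)
  phi <- atan2(y, x)
  B <- matrix(0, n, (order + 1)^2)
  col <- 1
  for (l in 0:order) {
    P <- if (l == 0) matrix(1, 1, n) else pracma::legendre(l, ct)  # (l+1) x n
    rl <- r^l
    for (m in 0:l) {
      base <- rl * P[m + 1, ]
      if (m == 0) {
        B[, col] <- base; col <- col + 1
      } else {
        B[, col] <- base * cos(m * phi); col <- col + 1
        B[, col] <- base * sin(m * phi); col <- col + 1
      }
    }
  }
  B
}

#' Fit a map onto a spherical (solid-harmonic) function basis
#'
#' Weighted least-squares fit of real solid harmonics up to `order`,
#' evaluated on the voxel lattice centered on the mask centroid. The fit
#' keeps only smooth spatial structure, which is how the piecewise-constant
#' tissue M0 component and voxel noise are removed from DREAM-derived maps.
#'
#' @param map An [image_volume()].
#' @param mask Logical array (non-empty) of voxels entering the fit.
#' @param order Maximum harmonic order L >= 0; `(L+1)^2` coefficients.
#' @param weights Optional per-voxel weights (same shape as the map).
#' @return Object of class `harmonic_fit`: `order`, `coefficients`,
#'   `fitted_map` (an [image_volume()] evaluated on the full grid),
#'   `center`, `rscale`.
#' @export
fit_spherical_basis <- function(map, mask, order = 6, weights = NULL) {
  stopifnot(inherits(map, "image_volume"), order >= 0)
  d <- dim(map$grid)
  if (!any(mask)) stop("mask is empty")
  vs <- map$voxel_size
  g <- coord_grids(d, vs)
  ctr <- c(mean(g$x[mask]), mean(g$y[mask]), mean(g$z[mask]))
  xs <- g$x[mask] - ctr[1]; ys <- g$y[mask] - ctr[2]; zs <- g$z[mask] - ctr[3]
  rscale <- max(sqrt(xs^2 + ys^2 + zs^2), 1e-6)
  B <- solid_harmonic_basis(xs, ys, zs, order, rscale)
  yv <- map$grid[mask]
  w <- if (is.null(weights)) rep(1, length(yv)) else weights[mask]
  sw <- sqrt(w)
  qr_fit <- qr(B * sw)
  if (qr_fit$rank < ncol(B)) {
    stop("rank-deficient harmonic design (degenerate mask); reduce order")
  }
  coef <- qr.coef(qr_fit, yv * sw)
  # evaluate on the full grid in blocks to bound memory
  fitted <- array(0, d)
  idx_all <- seq_len(prod(d))
  blk <- 2e6L
  for (start in seq(1, length(idx_all), by = blk)) {
    ii <- idx_all[start:min(start + blk - 1L, length(idx_all))]
    Bi <- solid_harmonic_basis(g$x[ii] - ctr[1], g$y[ii] - ctr[2],
                               g$z[ii] - ctr[3], order, rscale)
    fitted[ii] <- as.vector(Bi %*% coef)
  }
  structure(list(order = order, coefficients = as.numeric(coef),
                 fitted_map = image_volume(fitted, vs, map$orientation),
                 center = ctr, rscale = rscale),
            class = "harmonic_fit")
}

bias_field_core <- function(b1plus_fit, b1minus_fit, tau_gamma, mask, power,
                            kind) {
  s <- sin(tau_gamma * b1plus_fit$grid)
  f <- s^power * b1minus_fit$grid
  mu <- mean(f[mask])
  if (!is.finite(mu) || mu == 0) stop("degenerate bias field on mask")
  f <- f / mu
  structure(list(field = f, kind = kind, tau_gamma = tau_gamma, mask = mask),
            class = "bias_field")
}

#' Bias field for gradient-recalled (GRE) acquisitions
#'
#' `field = sin(tau_gamma * b1plus) * b1minus_hat`, normalized to mean 1 on
#' the mask. `b1minus_hat` is the harmonically fitted receive profile (the
#' smooth part of M0B1-). In the small-flip limit the field is proportional
#' to `B1+ * B1-`.
#'
#' @param b1plus_fit,b1minus_fit [image_volume()]s of the fitted maps (see
#'   [fit_spherical_basis()]).
#' @param tau_gamma Effective nominal flip angle in radians at unit B1+
#'   (gamma*tau); default 10 degrees, the imaging flip angle.
#' @param mask Logical array on which the mean-1 normalization holds.
#' @return Object of class `bias_field` with elements `field` (3D array,
#'   strictly positive on the mask), `kind`, `tau_gamma`, `mask`.
#' @export
bias_field_gre <- function(b1plus_fit, b1minus_fit,
                           tau_gamma = 10 * pi / 180, mask) {
  bias_field_core(b1plus_fit, b1minus_fit, tau_gamma, mask, power = 1,
                  kind = "GRE")
}

#' Bias field for fast spin-echo (FSE) acquisitions
#'
#' As [bias_field_gre()] but with the spin-echo signal model
#' `field = sin(tau_gamma * b1plus)^3 * b1minus_hat`, mean-1 normalized.
#'
#' @inheritParams bias_field_gre
#' @export
bias_field_fse <- function(b1plus_fit, b1minus_fit,
                           tau_gamma = 70 * pi / 180, mask) {
  bias_field_core(b1plus_fit, b1minus_fit, tau_gamma, mask, power = 3,
                  kind = "FSE")
}

#' Correct an image for a multiplicative bias field
#'
#' Divides by `max(bias, floor)` inside the mask and zeroes the outside.
#' The floor prevents noise blow-up where the bias estimate collapses
#' (e.g., the low-SNR neck).
#'
#' @param image An [image_volume()].
#' @param bias A `bias_field` (from [bias_field_gre()]/[bias_field_fse()])
#'   or an [image_volume()]/array used directly.
#' @param floor Division floor; default `0.05 * mean(bias on mask)`.
#' @param mask Optional logical array; defaults to the bias field's mask.
#' @return The corrected [image_volume()].
#' @export
correct_image <- function(image, bias, floor = NULL, mask = NULL) {
  stopifnot(inherits(image, "image_volume"))
  if (inherits(bias, "bias_field")) {
    f <- bias$field
    mask <- mask %||% bias$mask
  } else if (inherits(bias, "image_volume")) {
    f <- bias$grid
  } else {
    f <- bias
  }
  if (!identical(dim(f), dim(image$grid))) stop_geom("image vs bias field")
  mask <- mask %||% array(TRUE, dim(f))
  floor <- floor %||% (0.05 * mean(f[mask]))
  if (floor <= 0) stop("floor must be positive")
  out <- array(0, dim(image$grid))
  out[mask] <- image$grid[mask] / pmax(f[mask], floor)
  image_volume(out, image$voxel_size, image$orientation)
}

#' Estimate a bias field from a DREAM acquisition
#'
#' Convenience driver for the full estimation chain:
#' [dream_maps()] on the STE/FID pair, solid-harmonic fits of the B1+ and
#' M0B1- maps on the mask, then [bias_field_gre()] or [bias_field_fse()].
#'
#' @inheritParams dream_maps
#' @param kind `"gre"` or `"fse"`.
#' @param order Harmonic order of the fits (default 6).
#' @param tau_gamma Effective nominal flip angle (radians); defaults to the
#'   imaging angle for GRE and 70 degrees (refocusing) for FSE.
#' @param mask Logical foreground mask (required: the fit needs a body
#'   support).
#' @return A `bias_field`.
#' @export
estimate_bias <- function(ste, fid, mask, kind = c("gre", "fse"),
                          steam_angle = 50, imaging_angle = 10, order = 6,
                          tau_gamma = NULL) {
  kind <- match.arg(kind)
  maps <- dream_maps(ste, fid, steam_angle, imaging_angle, mask = mask)
  b1p_fit <- fit_spherical_basis(maps$b1plus, maps$mask, order)
  b1m_fit <- fit_spherical_basis(maps$m0b1minus, maps$mask, order)
  if (kind == "gre") {
    tg <- tau_gamma %||% (imaging_angle * pi / 180)
    bias_field_gre(b1p_fit$fitted_map, b1m_fit$fitted_map, tg, maps$mask)
  } else {
    tg <- tau_gamma %||% (70 * pi / 180)
    bias_field_fse(b1p_fit$fitted_map, b1m_fit$fitted_map, tg, maps$mask)
  }
}
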