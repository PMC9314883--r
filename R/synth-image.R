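# Synthetic MR signal generation: smooth random fields, B1 maps, biased
# T1w-like images, and DREAM stimulated-echo/FID pairs.

#' Seeded band-limited Gaussian random field
#'
#' White Gaussian noise smoothed with a Gaussian kernel and renormalized to
#' unit variance. `smoothness_mm` is the 1/e autocorrelation length of the
#' result (the kernel sigma is `smoothness_mm / 2`).
#'
#' @param shape Integer length-3 grid shape.
#' @param voxel_size mm per axis.
#' @param smoothness_mm Target 1/e autocorrelation length (mm).
#' @param seed Integer seed.
#' @param complex_valued If TRUE, returns a complex field with independent
#'   real and imaginary parts (each unit variance / 2).
#' @return A 3D array (numeric or complex).
#' @export
synth_smooth_noise <- function(shape, voxel_size = c(1, 1, 1), smoothness_mm = 20,
                               seed = 1, complex_valued = FALSE) {
  shape <- as.integer(rep_len(shape, 3))
  sig_vox <- (smoothness_mm / 2) / rep_len(voxel_size, 3)
  with_local_seed(seed, {
    one <- function() {
      w <- array(stats::rnorm(prod(shape)), shape)
      s <- gauss_smooth3d(w, sig_vox)
      s / stats::sd(s)
    }
    if (complex_valued) {
      re <- one(); im <- one()
      complex(real = re / sqrt(2), imaginary = im / sqrt(2))
    } else one()
  })
}

neck_profile <- function(shape, strength, voxel_size = c(1, 1, 1)) {
  # multiplicative logistic attenuation along the inferior (3rd) axis
  z <- seq_len(shape[3])
  z0 <- 0.28 * shape[3]; w <- 0.06 * shape[3]
  p <- 1 / (1 + exp(-(z - z0) / w))
  prof <- (1 - strength) + strength * p
  array(rep(prof, each = shape[1] * shape[2]), shape)
}

#' Synthetic transmit/receive B1 maps over a phantom
#'
#' Generates a smooth relative transmit field `b1plus` (actual/nominal flip,
#' dimensionless, strictly positive) and a receive-weighted proton-density
#' map `m0b1minus` (tissue-wise M0 times a smooth receive profile). Both
#' are attenuated towards the neck by a logistic profile, reproducing the
#' severe inferior signal drop-off seen at 7T.
#'
#' @param labels A [label_volume()].
#' @param seed Integer seed.
#' @param variation Relative amplitude of the smooth spatial variation.
#' @param smoothness_mm Spatial scale of the variation.
#' @param neck_dropoff_strength 0 (none) to 1 (severe).
#' @return List with `b1plus` and `m0b1minus` [image_volume()]s.
#' @export
make_b1_maps <- function(labels, seed = 1, variation = 0.4, smoothness_mm = 36,
                         neck_dropoff_strength = NULL) {
  stopifnot(inherits(labels, "label_volume"))
  d <- dim(labels$grid)
  nd <- neck_dropoff_strength %||% 0.85
  s1 <- synth_smooth_noise(d, labels$voxel_size, smoothness_mm, seed)
  s2 <- synth_smooth_noise(d, labels$voxel_size, smoothness_mm, seed + 1000L)
  prof <- neck_profile(d, nd, labels$voxel_size)
  # clamp: keep the actual STEAM flip below 90 deg (DREAM validity range)
  b1p <- pmin(pmax((1 + variation * s1) * (0.15 + 0.85 * prof), 0.02), 1.6)
  # proton-density-like M0 per tissue (fluid high, bone/air low)
  m0_means <- c(background = 0.01, internal_air = 0.02, bone = 0.15,
                muscle = 0.75, fat = 0.95, white_matter = 0.75,
                gray_matter = 0.85, csf = 1.0, eye = 0.95)
  m0 <- array(m0_means[tissue_name(labels$grid)], d)
  b1m <- pmax(1 + variation * s2, 0.05) * (0.15 + 0.85 * prof)
  list(b1plus = image_volume(b1p, labels$voxel_size, labels$orientation),
       m0b1minus = image_volume(m0 * b1m, labels$voxel_size, labels$orientation))
}

#' Reference GRE-model bias field from known B1 maps
#'
#' The multiplicative intensity bias of a spoiled gradient-echo acquisition:
#' `sin(tau_gamma * b1plus) * b1minus`, normalized to mean 1 over the body.
#' Used to imprint a known bias on simulated images; the estimation side
#' lives in [estimate_bias()].
#'
#' @param b1 List as from [make_b1_maps()] (`b1minus` taken as
#'   `m0b1minus` divided by its tissue M0 component is not needed here:
#'   the receive profile enters multiplied by M0 in the image model, so the
#'   smooth part is what matters).
#' @param labels A [label_volume()] giving the body mask.
#' @param receive_profile Optional smooth receive field (3D array); default
#'   derives it from `b1$m0b1minus` by dividing out the tissue M0 means.
#' @param tau_gamma Effective nominal flip angle (radians) standing for
#'   gamma*tau at unit B1+; default 10 degrees (the imaging flip angle).
#' @return An [image_volume()] bias field, mean 1 over the body.
#' @export
make_bias_field <- function(b1, labels, receive_profile = NULL,
                            tau_gamma = 10 * pi / 180) {
  d <- dim(labels$grid)
  if (is.null(receive_profile)) {
    m0_means <- c(background = 0.01, internal_air = 0.02, bone = 0.15,
                  muscle = 0.75, fat = 0.95, white_matter = 0.75,
                  gray_matter = 0.85, csf = 1.0, eye = 0.95)
    m0 <- array(m0_means[tissue_name(labels$grid)], d)
    receive_profile <- b1$m0b1minus$grid / m0
  }
  f <- sin(tau_gamma * b1$b1plus$grid) * receive_profile
  mask <- body_mask(labels)
  f <- f / mean(f[mask])
  f <- pmax(f, 1e-6)
  image_volume(f, labels$voxel_size, labels$orientation)
}

#' Simulate a biased T1w-like image from a label volume
#'
#' Per-tissue mean intensity times a multiplicative bias field, plus seeded
#' noise; optionally an additional logistic attenuation of inferior slices.
#'
#' @param labels A [label_volume()].
#' @param bias An [image_volume()] with strictly positive values, same
#'   geometry (use [make_bias_field()], or a constant field of 1s).
#' @param noise_sd Relative noise standard deviation: noise is
#'   signal-proportional (a voxel's noiseless intensity times
#'   `noise_sd`), so "5% noise" means 5% of the local signal in every
#'   tissue. Low absolute SNR in the neck then arises through the bias
#'   drop-off rather than through the noise model.
#' @param seed Integer seed.
#' @param tissue_means Named vector of per-tissue means, see
#'   [default_t1w_means()].
#' @param noise_model `"gaussian"` (default) or `"rician"`.
#' @param neck_dropoff_strength Extra inferior attenuation applied on top
#'   of the bias field; default 0 (drop-off normally enters via the bias).
#' @return An [image_volume()].
#' @export
simulate_t1w <- function(labels, bias, noise_sd = 0, seed = 1,
                         tissue_means = default_t1w_means(),
                         noise_model = c("gaussian", "rician"),
                         neck_dropoff_strength = 0) {
  stopifnot(inherits(labels, "label_volume"), inherits(bias, "image_volume"))
  check_same_geometry(labels, bias, "labels vs bias field")
  if (any(bias$grid <= 0)) stop("bias field must be strictly positive")
  noise_model <- match.arg(noise_model)
  d <- dim(labels$grid)
  img <- array(tissue_means[tissue_name(labels$grid)], d) * bias$grid
  if (neck_dropoff_strength > 0) {
    img <- img * neck_profile(d, neck_dropoff_strength, labels$voxel_size)
  }
  if (noise_sd > 0) {
    img <- with_local_seed(seed, {
      n1 <- array(stats::rnorm(prod(d), sd = noise_sd), d)
      if (noise_model == "gaussian") {
        img * (1 + n1)
      } else {
        n2 <- array(stats::rnorm(prod(d), sd = noise_sd), d)
        img * sqrt((1 + n1)^2 + n2^2)
      }
    })
  }
  image_volume(img, labels$voxel_size, labels$orientation)
}

#' Simulate a DREAM acquisition (stimulated echo + FID)
#'
#' Forward model of the DREAM B1+ mapping sequence: with actual STEAM flip
#' `a = b1plus * steam_angle` and imaging flip `b = b1plus * imaging_angle`,
#' the stimulated-echo and FID signals are
#' `STE = M0B1- * sin(b) * sin(a)^2 / 2` and
#' `FID = M0B1- * sin(b) * cos(a)^2`, so that
#' `STE/FID = tan(a)^2 / 2` and [dream_maps()] recovers `a` exactly in the
#' noiseless case (round-trip contract).
#'
#' @param b1plus [image_volume()] of the relative transmit field
#'   (actual/nominal), strictly positive.
#' @param m0b1minus [image_volume()] of the receive-weighted proton density.
#' @param steam_angle Nominal STEAM flip angle (degrees, default 50).
#' @param imaging_angle Nominal imaging flip angle (degrees, default 10).
#' @param noise_sd Optional Gaussian noise added to both images.
#' @param seed Seed for the noise.
#' @return List with `ste` and `fid` [image_volume()]s.
#' @export
simulate_dream <- function(b1plus, m0b1minus, steam_angle = 50,
                           imaging_angle = 10, noise_sd = 0, seed = 1) {
  stopifnot(inherits(b1plus, "image_volume"), inherits(m0b1minus, "image_volume"))
  check_same_geometry(b1plus, m0b1minus, "b1plus vs m0b1minus")
  if (any(b1plus$grid <= 0)) stop("b1plus must be strictly positive")
  a <- b1plus$grid * steam_angle * pi / 180
  b <- b1plus$grid * imaging_angle * pi / 180
  ste <- m0b1minus$grid * sin(b) * sin(a)^2 / 2
  fid <- m0b1minus$grid * sin(b) * cos(a)^2
  if (noise_sd > 0) {
    d <- dim(ste)
    noise <- with_local_seed(seed, list(
      array(stats::rnorm(prod(d), sd = noise_sd), d),
      array(stats::rnorm(prod(d), sd = noise_sd), d)))
    ste <- ste + noise[[1]]; fid <- fid + noise[[2]]
  }
  vs <- b1plus$voxel_size
  list(ste = image_volume(ste, vs, b1plus$orientation),
       fid = image_volume(fid, vs, b1plus$orientation))
}
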