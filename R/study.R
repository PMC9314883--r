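# End-to-end study driver: reproduces the study design at synthetic scale.
# N phantoms -> leave-one-out 2.5D training -> segmentation of each
# held-out subject -> birdcage-mode and PTx random-shim dosimetry on
# ground-truth vs network-generated labels -> JSON + Markdown report.

#' Modal-label downsampling of a label volume
#'
#' Reduces resolution by an integer factor, assigning each target voxel
#' the modal label of its source block (ties to the lowest code). Used to
#' move 1 mm anatomical labels onto the coarser uniform dosimetry grid.
#'
#' @param labels A [label_volume()].
#' @param factor Integer downsampling factor per axis (default 2).
#' @return A [label_volume()] with `factor`-fold larger voxels.
#' @export
downsample_labels <- function(labels, factor = 2) {
  d <- dim(labels$grid)
  if (any(d %% factor != 0)) stop("dims must be divisible by the factor")
  dn <- d %/% factor
  ncls <- nrow(tissue_labels())
  counts <- matrix(0L, prod(dn), ncls)
  for (di in 0:(factor - 1)) for (dj in 0:(factor - 1)) for (dk in 0:(factor - 1)) {
    blk <- labels$grid[seq(1 + di, d[1], factor),
                       seq(1 + dj, d[2], factor),
                       seq(1 + dk, d[3], factor)]
    for (c in seq_len(ncls)) {
      counts[, c] <- counts[, c] + (as.vector(blk) == (c - 1L))
    }
  }
  lab <- max.col(counts, ties.method = "first") - 1L
  label_volume(array(lab, dn), labels$voxel_size * factor,
               labels$orientation)
}

#' Study configuration
#'
#' Collects the sub-configurations of a full synthetic study. All stages
#' derive their seeds from `seed`, so a fixed configuration regenerates
#' every artifact bit-identically.
#'
#' @param n_subjects Number of synthetic subjects (default 10, the study
#'   design; use 3 for a quick scaled-down run).
#' @param shape Phantom shape in voxels (1 mm grid).
#' @param seed Master seed.
#' @param network A [network_spec()].
#' @param train A [train_config()].
#' @param noise_sd T1w noise level.
#' @param ptx_channels,n_shims PTx loop-array channel count and number of
#'   random shims.
#' @param birdcage_channels Ports of the quadrature-mode reference coil.
#' @param dosimetry_factor Label downsampling factor onto the dosimetry
#'   grid (default 2: 1 mm -> 2 mm).
#' @param out_dir Optional output directory for the JSON/Markdown report.
#' @return Object of class `study_config`.
#' @export
study_config <- function(n_subjects = 10, shape = c(64, 64, 64), seed = 1,
                         network = network_spec(base_features = 4,
                                                pooling_steps = 3),
                         train = train_config(epochs = 10,
                                              learning_rate = c(rep(1e-2, 7),
                                                                rep(3e-3, 3))),
                         noise_sd = 0.05, ptx_channels = 8, n_shims = 1000,
                         birdcage_channels = 16, dosimetry_factor = 2,
                         out_dir = NULL) {
  stopifnot(n_subjects >= 2)
  structure(list(n_subjects = n_subjects, shape = shape,
                 seed = as.integer(seed),
                 network = network, train = train, noise_sd = noise_sd,
                 ptx_channels = ptx_channels, n_shims = n_shims,
                 birdcage_channels = birdcage_channels,
                 dosimetry_factor = dosimetry_factor, out_dir = out_dir),
            class = "study_config")
}

#' Generate one synthetic subject (phantom, B1 maps, bias, biased T1w)
#'
#' @param seed Subject seed.
#' @param shape Phantom shape.
#' @param noise_sd T1w noise level.
#' @return List: `labels`, `image`, `b1`, `bias`.
#' @export
make_subject <- function(seed, shape = c(64, 64, 64), noise_sd = 0.05) {
  ph <- make_phantom(phantom_spec(shape = shape, seed = seed))
  b1 <- make_b1_maps(ph, seed = seed + 100L)
  bias <- make_bias_field(b1, ph)
  t1 <- simulate_t1w(ph, bias, noise_sd = noise_sd, seed = seed + 200L)
  list(labels = ph, image = t1, b1 = b1, bias = bias)
}

#' Run the full synthetic study
#'
#' Generates `n_subjects` phantoms, runs leave-one-out 2.5D training and
#' segmentation for every fold, then evaluates each subject's RF exposure
#' in a quadrature birdcage mode (fixed shim) and a PTx loop array
#' (random shims) on both ground-truth and network-generated labels.
#'
#' @param config A [study_config()].
#' @param verbose Print stage progress.
#' @return Study report list (also written as JSON + Markdown when
#'   `config$out_dir` is set): per-fold Dice tables, per-subject
#'   birdcage peak/head SAR errors, per-subject PTx shim-study summaries,
#'   and the generic one-size-fits-all overestimation distribution.
#' @export
run_study <- function(config = study_config(), verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", what, conditionMessage(e)), call. = FALSE)
    })
  }
  N <- config$n_subjects
  subj_seeds <- config$seed + 1000L * seq_len(N)
  say("generating %d subjects", N)
  subjects <- stage("synth", lapply(subj_seeds, make_subject,
                                    shape = config$shape,
                                    noise_sd = config$noise_sd))
  folds <- list()
  preds <- vector("list", N)
  for (f in seq_len(N)) {
    say("fold %d/%d: leave-one-out training", f, N)
    train_ids <- setdiff(seq_len(N), f)
    cfg <- config$train
    cfg$seed <- config$seed + 41L * f
    vols <- lapply(subjects[train_ids], function(s)
      list(image = s$image, labels = s$labels))
    nets <- stage("train", train_forknet_2p5d(vols, config$network, cfg))
    pred <- stage("segment", segment_volume(nets, subjects[[f]]$image))
    preds[[f]] <- pred
    ev <- evaluate_segmentation(pred, subjects[[f]]$labels)
    folds[[f]] <- list(test_subject = f, train_subjects = train_ids,
                       seed = cfg$seed, dice = ev$table,
                       mean_dice = ev$mean, sd_dice = ev$sd)
  }
  # dosimetry on the coarser uniform grid
  fac <- config$dosimetry_factor
  birdcage <- list(); ptx <- list()
  peaks_gt_all <- NULL
  for (f in seq_len(N)) {
    say("dosimetry %d/%d", f, N)
    gt <- stage("dosimetry", downsample_labels(subjects[[f]]$labels, fac))
    gen <- stage("dosimetry", downsample_labels(preds[[f]], fac))
    vv <- prod(gt$voxel_size) * 1e-9
    # quadrature birdcage mode (fixed shim on a multi-port field set)
    fs_b <- stage("dosimetry", make_efields(gt, config$birdcage_channels,
                                            seed = config$seed + 7L * f))
    wq <- quadrature_shim(config$birdcage_channels)
    sar_gt <- pointwise_sar(fs_b, gt, shim = wq)
    sar_gen <- pointwise_sar(fs_b, gen, shim = wq)
    p_gt <- max(average_10g(sar_gt, gt, voxel_volume = vv)$grid)
    p_gen <- max(average_10g(sar_gen, gen, voxel_volume = vv)$grid)
    birdcage[[f]] <- list(
      peak_gt = p_gt, peak_gen = p_gen,
      peak_error_pct = underestimation_error(p_gt, p_gen),
      head_sar_gt = head_average_sar(sar_gt, gt, voxel_volume = vv),
      head_sar_gen = head_average_sar(sar_gen, gen, voxel_volume = vv))
    birdcage[[f]]$head_sar_error_pct <-
      100 * (birdcage[[f]]$head_sar_gt - birdcage[[f]]$head_sar_gen) /
      birdcage[[f]]$head_sar_gt
    # PTx loop array: Q-matrices + random shims
    fs_p <- stage("dosimetry", make_efields(gt, config$ptx_channels,
                                            seed = config$seed + 13L * f))
    q_gt <- stage("dosimetry", build_q10g(fs_p, gt, voxel_volume = vv))
    q_gen <- stage("dosimetry", build_q10g(fs_p, gen, voxel_volume = vv))
    shims <- random_shims(config$ptx_channels, n = config$n_shims,
                          seed = config$seed + 17L)
    st <- shim_study(q_gt, q_gen, shims)
    ptx[[f]] <- list(mean_error = st$mean_error, q95_error = st$q95_error,
                     safety_margin = st$safety_margin,
                     shim_seed = config$seed + 17L)
    peaks_gt_all <- rbind(peaks_gt_all, st$peaks_gt)
  }
  gm <- generic_margin(peaks_gt_all)
  report <- list(
    config = list(n_subjects = N, shape = config$shape, seed = config$seed,
                  noise_sd = config$noise_sd,
                  ptx_channels = config$ptx_channels,
                  n_shims = config$n_shims,
                  birdcage_channels = config$birdcage_channels,
                  dosimetry_factor = fac,
                  epochs = config$train$epochs,
                  base_features = config$network$base_features,
                  pooling_steps = config$network$pooling_steps),
    folds = folds,
    dice_mean = mean(vapply(folds, `[[`, numeric(1), "mean_dice")),
    birdcage = birdcage,
    max_abs_peak_error_pct =
      max(abs(vapply(birdcage, `[[`, numeric(1), "peak_error_pct"))),
    max_abs_head_sar_error_pct =
      max(abs(vapply(birdcage, `[[`, numeric(1), "head_sar_error_pct"))),
    ptx = ptx,
    generic = list(mean_overestimation = gm$mean,
                   frac_underestimating = gm$frac_negative,
                   q95 = gm$q95))
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_study_markdown(report, file.path(config$out_dir, "report.md"))
  }
  report
}

write_study_markdown <- function(report, path) {
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# Synthetic personalized-SAR study report")
  w("")
  w("Subjects: %d | seed: %d | shims: %d | PTx channels: %d",
    report$config$n_subjects, report$config$seed, report$config$n_shims,
    report$config$ptx_channels)
  w("")
  w("## Leave-one-out segmentation (Dice)")
  w("")
  w("| fold | mean | sd |")
  w("|------|------|----|")
  for (f in report$folds) {
    w("| %d | %.3f | %.3f |", f$test_subject, f$mean_dice, f$sd_dice)
  }
  w("")
  w("Overall mean Dice: %.3f", report$dice_mean)
  w("")
  w("## Quadrature birdcage exposure")
  w("")
  w("| subject | peak GT | peak gen | peak err %% | head-SAR err %% |")
  w("|---------|---------|----------|------------|-----------------|")
  for (i in seq_along(report$birdcage)) {
    b <- report$birdcage[[i]]
    w("| %d | %.4g | %.4g | %.2f | %.2f |", i, b$peak_gt, b$peak_gen,
      b$peak_error_pct, b$head_sar_error_pct)
  }
  w("")
  w("## PTx random-shim study")
  w("")
  w("| subject | mean err %% | 95th pct err %% | margin %% |")
  w("|---------|------------|----------------|-----------|")
  for (i in seq_along(report$ptx)) {
    p <- report$ptx[[i]]
    w("| %d | %.2f | %.2f | %.2f |", i, p$mean_error, p$q95_error,
      p$safety_margin)
  }
  w("")
  w("Generic one-size-fits-all: mean overestimation %.1f%%, %.1f%% of cases underestimate.",
    report$generic$mean_overestimation,
    100 * report$generic$frac_underestimating)
  invisible(path)
}
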