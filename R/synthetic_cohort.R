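#' Configuration for the synthetic paired two-scan cohort
#'
#' The generator emulates the design of a two-scan prostate segmentation
#' reproducibility study: a cohort of subjects, each with two scans of the
#' same organ, segmented by a manual reference and several simulated
#' automatic methods of graded error severity. The organ is a superellipsoid
#' whole gland (WP) with a posterior-crescent peripheral zone (PZ); scan 2
#' is compressed along the anterior-posterior axis (emulating an endorectal
#' probe and prone positioning) with compensatory in-plane scaling so the
#' gland volume is preserved. Each method's mask is the scan's ground truth
#' perturbed by a smooth random radial boundary displacement field, plus
#' (for the automatic methods) occasional spurious disconnected components
#' and occasional gross failures (global over/under-segmentation by several
#' mm). Quality scores decrease with the injected error, mimicking an
#' automated quality-control system.
#'
#' @param n_subjects Number of subjects (default 62).
#' @param spacing Voxel size mm (slice, row, column); default `c(3, .5, .5)`
#'   (3 mm slices, 0.5 mm in-plane).
#' @param wp_volume_mean,wp_volume_sd Mean and SD (mm^3) of the log-normal
#'   whole-gland volume distribution across subjects.
#' @param axis_ratio_range Range of the anterior-posterior and
#'   superior-inferior semi-axis ratios relative to the left-right semi-axis.
#' @param pz_thickness_fraction Posterior shell thickness as a fraction of
#'   the local gland radius.
#' @param scan2_compression Mean anterior-posterior scale factor of scan 2
#'   in (0.5, 1]; 1 disables the deformation. A small per-subject jitter
#'   (+/- 0.03) is added around this mean.
#' @param scan2_slice_dropout_prob Probability that a scan-2 mask loses one
#'   end slice, emulating a smaller segmented slice extent on scan 2.
#' @param method_noise Named numeric: boundary-perturbation amplitude in mm
#'   per method; must include `"manual"` and at least one other method.
#' @param spurious_component_prob Probability (per automatic-method mask) of
#'   an added small disconnected blob (at most 2% of the WP volume).
#' @param gross_failure_prob Probability (per automatic-method mask) of a
#'   gross failure: global erosion or dilation by at least 3 mm.
#' @param quality_score_noise SD (score units) of the noise on the quality
#'   scores.
#' @param seed Master seed; per-subject seeds are derived from it so each
#'   subject is independently reproducible.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_subjects = 62,
                             spacing = c(3.0, 0.5, 0.5),
                             wp_volume_mean = 55000,
                             wp_volume_sd = 19000,
                             axis_ratio_range = c(0.75, 0.95),
                             pz_thickness_fraction = 0.35,
                             scan2_compression = 0.9,
                             scan2_slice_dropout_prob = 0.3,
                             method_noise = c(manual = 0.5, vnet = 1.8,
                                              nnunet2d = 1.0, nnunet3d = 0.8),
                             spurious_component_prob = 0.15,
                             gross_failure_prob = 0.08,
                             quality_score_noise = 2,
                             seed = 1) {
  probs <- c(scan2_slice_dropout_prob, spurious_component_prob,
             gross_failure_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (scan2_compression <= 0.5 || scan2_compression > 1)
    stop("scan2_compression must be in (0.5, 1]")
  if (!"manual" %in% names(method_noise) || length(method_noise) < 2)
    stop("method_noise must name 'manual' plus at least one other method")
  if (any(method_noise < 0)) stop("method_noise amplitudes must be >= 0")
  structure(list(
    n_subjects = as.integer(n_subjects), spacing = as.numeric(spacing),
    wp_volume_mean = wp_volume_mean, wp_volume_sd = wp_volume_sd,
    axis_ratio_range = axis_ratio_range,
    pz_thickness_fraction = pz_thickness_fraction,
    scan2_compression = scan2_compression,
    scan2_slice_dropout_prob = scan2_slice_dropout_prob,
    method_noise = method_noise,
    spurious_component_prob = spurious_component_prob,
    gross_failure_prob = gross_failure_prob,
    quality_score_noise = quality_score_noise,
    seed = as.integer(seed)), class = "synthetic_config")
}

# superellipsoid |x/a|^n + |y/b|^n + |z/c|^n <= 1 volume factor:
# V = k(n) * a*b*c with k(n) = 8 gamma(1+1/n)^3 / gamma(1+3/n)
SUPERELL_EXPONENT <- 2.5
superell_volume_factor <- function(n = SUPERELL_EXPONENT)
  8 * gamma(1 + 1 / n)^3 / gamma(1 + 3 / n)

# directional boundary radius of the superellipsoid for unit directions
# (matrix u with columns slice,row,col), semi-axes in the same order
superell_radius <- function(u, semi, n = SUPERELL_EXPONENT) {
  (abs(u[, 1] / semi[1])^n + abs(u[, 2] / semi[2])^n +
     abs(u[, 3] / semi[3])^n)^(-1 / n)
}

# smooth random field on the unit sphere: weighted von Mises-Fisher-like
# bumps at random centers, normalized to unit SD over a fixed direction
# sample, then scaled by `amplitude` (mm)
random_sphere_field <- function(amplitude, n_bumps = 12, ell = 0.3) {
  centers <- matrix(rnorm(3 * n_bumps), ncol = 3)
  centers <- centers / sqrt(rowSums(centers^2))
  weights <- rnorm(n_bumps)
  # reference directions for normalization (deterministic Fibonacci sphere)
  i <- seq_len(256) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  zs <- 1 - 2 * i / 256
  rs <- sqrt(pmax(0, 1 - zs^2))
  ref <- cbind(zs, rs * cos(phi), rs * sin(phi))
  eval_field <- function(u, sc) {
    acc <- 0
    for (j in seq_len(n_bumps))
      acc <- acc + weights[j] * exp((u %*% centers[j, ] - 1) / ell)
    drop(acc) * sc
  }
  s0 <- sqrt(mean(eval_field(ref, 1)^2))  # RMS, so a global offset counts
  sc <- if (s0 > 0) amplitude / s0 else 0
  function(u) eval_field(u, sc)
}

#' Generate one synthetic subject
#'
#' Draws the subject's organ geometry, rasterizes the two-scan ground truth
#' on a common grid at the configured spacing, and derives one label volume
#' per (scan, method) by perturbing the ground-truth boundary. See
#' [synthetic_config()] for the generative model. Fully deterministic given
#' the configuration (the subject seed is derived from the master seed and
#' the subject index).
#'
#' @param config A [synthetic_config()].
#' @param subject_index Integer subject index (1-based).
#' @return A `synthetic_subject` list: `subject_id`, `true_params` (per-scan
#'   semi-axes, centre, drawn target volume), `label_volumes` (named list
#'   `scanX.method`), `quality_scores` (data frame with subject_id, scan_id,
#'   method_id, quality_score), and per-mask injected-error metadata.
#' @export
generate_subject <- function(config, subject_index) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed((config$seed + 7919L * as.integer(subject_index)) %% 2147483647L)

  sp <- config$spacing
  subject_id <- sprintf("sub%03d", subject_index)
  # organ geometry (scan 1)
  cv2 <- (config$wp_volume_sd / config$wp_volume_mean)^2
  sdlog <- sqrt(log(1 + cv2))
  v_target <- rlnorm(1, log(config$wp_volume_mean) - sdlog^2 / 2, sdlog)
  r_ap <- runif(1, config$axis_ratio_range[1], config$axis_ratio_range[2])
  r_si <- runif(1, config$axis_ratio_range[1], config$axis_ratio_range[2])
  kf <- superell_volume_factor()
  a_lr <- (v_target / (kf * r_ap * r_si))^(1 / 3)
  semi1 <- c(si = a_lr * r_si, ap = a_lr * r_ap, lr = a_lr)  # slice,row,col
  # scan 2: anterior-posterior compression, volume-preserving
  gam <- config$scan2_compression
  if (gam < 1) gam <- min(1, max(0.51, gam + runif(1, -0.03, 0.03)))
  semi2 <- c(semi1[1] / sqrt(gam), semi1[2] * gam, semi1[3] / sqrt(gam))

  # common grid covering both scans plus margin
  margin <- 10
  ext <- 2 * pmax(semi1, semi2) + 2 * margin
  dims <- as.integer(ceiling(ext / sp))
  center <- (dims + 1) / 2 * sp  # mm, grid centre at a voxel-ish position

  # voxel-center coordinates relative to centre (vectorized per axis)
  cs <- (seq_len(dims[1]) * sp[1]) - center[1]
  cr <- (seq_len(dims[2]) * sp[2]) - center[2]
  cc <- (seq_len(dims[3]) * sp[3]) - center[3]
  S <- array(cs, dims)
  R <- array(rep(cr, each = dims[1]), dims)
  C <- array(rep(cc, each = dims[1] * dims[2]), dims)
  rad <- sqrt(S^2 + R^2 + C^2)
  rad[rad == 0] <- 1e-9
  U <- cbind(as.vector(S / rad), as.vector(R / rad), as.vector(C / rad))
  radv <- as.vector(rad)

  methods <- names(config$method_noise)
  label_volumes <- list()
  qs <- list()
  meta <- list()
  for (scan in c("scan1", "scan2")) {
    semi <- if (scan == "scan1") semi1 else semi2
    r_bound <- superell_radius(U, semi)
    # posterior weighting (+row = posterior): an abrupt rim with a minimum
    # shell thickness, so the rasterized crescent stays connected instead
    # of tapering into sub-voxel fragments
    w_post <- ifelse(U[, 2] > 0, 0.35 + 0.65 * U[, 2]^0.75, 0)
    for (m in methods) {
      amp <- config$method_noise[[m]]
      disp <- if (amp > 0) random_sphere_field(amp)(U) else 0
      err_mm <- amp
      gross <- FALSE; spur <- FALSE
      if (m != "manual") {
        if (runif(1) < config$gross_failure_prob) {
          gross <- TRUE
          disp <- disp + sample(c(-1, 1), 1) * (3 + runif(1, 0, 2))
        }
        spur <- runif(1) < config$spurious_component_prob
      }
      r_out <- pmax(r_bound + disp, 0)
      inside <- radv <= r_out
      r_in <- r_out * (1 - config$pz_thickness_fraction * w_post)
      pz <- inside & (radv > r_in)
      vox <- integer(length(inside))
      vox[pz] <- 1L
      vox[inside & !pz] <- 2L
      vox <- array(vox, dims)
      if (spur) {
        # small disconnected blob, <= 2% of the WP volume
        blob_r <- (0.02 * v_target * 3 / (4 * pi))^(1 / 3) * runif(1, 0.6, 1)
        dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
        dist0 <- superell_radius(matrix(dir, 1), semi) + blob_r + runif(1, 4, 8)
        bc <- center + dir * dist0
        bc <- pmin(pmax(bc, blob_r + sp), dims * sp - blob_r - sp)
        blob <- (S + center[1] - bc[1])^2 + (R + center[2] - bc[2])^2 +
          (C + center[3] - bc[3])^2 <= blob_r^2
        blob <- blob & vox == 0L
        vox[blob] <- sample(c(1L, 2L), 1)
        err_mm <- err_mm + 1
      }
      if (scan == "scan2" && runif(1) < config$scan2_slice_dropout_prob) {
        occ <- which(apply(vox > 0L, 1, any))
        if (length(occ) > 2) {
          drop_slice <- if (runif(1) < 0.5) occ[1] else occ[length(occ)]
          vox[drop_slice, , ] <- 0L
        }
      }
      if (gross) err_mm <- err_mm + 15
      score <- min(100, max(0, 100 - 4 * err_mm +
                              rnorm(1, 0, config$quality_score_noise)))
      label_volumes[[paste(scan, m, sep = ".")]] <-
        label_volume(vox, sp, subject_id = subject_id, scan_id = scan,
                     method_id = m)
      qs[[length(qs) + 1L]] <- data.frame(
        subject_id = subject_id, scan_id = scan, method_id = m,
        quality_score = score, stringsAsFactors = FALSE)
      meta[[paste(scan, m, sep = ".")]] <-
        list(gross_failure = gross, spurious = spur, err_mm = err_mm)
    }
  }
  structure(list(
    subject_id = subject_id,
    true_params = list(scan1 = list(semi_axes = semi1, center = center,
                                    target_volume = v_target),
                       scan2 = list(semi_axes = semi2, center = center,
                                    target_volume = v_target,
                                    compression = gam)),
    label_volumes = label_volumes,
    quality_scores = do.call(rbind, qs),
    meta = meta), class = "synthetic_subject")
}

#' Generate a full synthetic paired cohort on disk
#'
#' Writes one NIfTI file per (subject, scan, method) and a manifest CSV with
#' columns `subject_id`, `scan_id`, `method_id`, `path`, `quality_score`.
#' Per-subject seeds are derived from the master seed, so any subject can be
#' regenerated independently and the manifest is identical across runs.
#'
#' @param config A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `manifest` (data frame), `manifest_path`,
#'   `config` and `dir`.
#' @export
generate_cohort <- function(config, dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    subj <- generate_subject(config, i)
    sq <- subj$quality_scores
    paths <- character(nrow(sq))
    for (j in seq_len(nrow(sq))) {
      key <- paste(sq$scan_id[j], sq$method_id[j], sep = ".")
      f <- file.path(dir, sprintf("%s_%s_%s.nii.gz", subj$subject_id,
                                  sq$scan_id[j], sq$method_id[j]))
      write_label_volume(subj$label_volumes[[key]], f)
      paths[j] <- f
    }
    sq$path <- paths
    rows[[i]] <- sq[, c("subject_id", "scan_id", "method_id", "path",
                        "quality_score")]
  }
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(dir, "manifest.csv")
  write.csv(manifest, manifest_path, row.names = FALSE)
  invisible(list(manifest = manifest, manifest_path = manifest_path,
                 config = config, dir = dir))
}
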