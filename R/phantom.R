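#' @title Synthetic tumor phantom generator
#'
#' @description Seeded generator of paired axial/sagittal tumor phantoms with
#'   class-dependent appearance and age. Each patient carries one latent
#'   tumor (shared shape parameters) rendered in both planes; benign tumors
#'   are smooth regular ellipses with homogeneous interiors, malignant tumors
#'   show irregular boundaries (rendered in the axial projection) and
#'   heterogeneous high-variance internal texture (rendered in the sagittal
#'   projection), with an interior intensity shift in both planes. How much
#'   of the discriminative signal lands in each plane is controlled by
#'   `cross_plane_signal_split`, so multi-plane fusion can be made necessary
#'   for ceiling accuracy.
#'
#' @name phantom
NULL

#' Phantom generator configuration
#'
#' @param n_patients Number of patients to generate.
#' @param malignant_fraction Fraction of malignant patients; the malignant
#'   count is allocated deterministically as `round(n_patients * fraction)`,
#'   not sampled.
#' @param image_size Side of the square slices, pixels.
#' @param n_axial_range,n_sagittal_range Integer intervals `c(lo, hi)` for
#'   the per-patient number of axial (n) and sagittal (m) slices.
#' @param benign_age_distribution,malignant_age_distribution `c(mean, sd)` in
#'   years of the truncated-at-zero normal age distribution per class.
#'   Defaults give a pooled distribution near 41 +/- 20 years with age alone
#'   only weakly informative (age-only AUC about 0.6).
#' @param texture_contrast Nonnegative scale of the class-discriminative
#'   appearance signal. 0 makes benign and malignant pixel distributions
#'   identical up to noise; 1 is a moderately hard problem; around 3 the
#'   classes are separable even by mean crop intensity.
#' @param cross_plane_signal_split Fraction of the discriminative signal
#'   placed in the axial rendering (the remainder goes to the sagittal
#'   rendering). At 0.5 each plane alone carries only part of the signal:
#'   boundary irregularity appears only axially, texture heterogeneity only
#'   sagittally, each at half strength.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param seed Integer seed; generation is a pure function of the config.
#'
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(n_patients = 40,
                           malignant_fraction = 0.5,
                           image_size = 64,
                           n_axial_range = c(2L, 4L),
                           n_sagittal_range = c(2L, 4L),
                           benign_age_distribution = c(36, 20),
                           malignant_age_distribution = c(46, 20),
                           texture_contrast = 1,
                           cross_plane_signal_split = 0.5,
                           noise_sd = 0.04,
                           seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              malignant_fraction = malignant_fraction,
              image_size = as.integer(image_size),
              n_axial_range = as.integer(n_axial_range),
              n_sagittal_range = as.integer(n_sagittal_range),
              benign_age_distribution = benign_age_distribution,
              malignant_age_distribution = malignant_age_distribution,
              texture_contrast = texture_contrast,
              cross_plane_signal_split = cross_plane_signal_split,
              noise_sd = noise_sd,
              seed = as.integer(seed))
  stopifnot(cfg$n_patients >= 1L,
            cfg$malignant_fraction >= 0, cfg$malignant_fraction <= 1,
            length(cfg$n_axial_range) == 2L, length(cfg$n_sagittal_range) == 2L,
            cfg$n_axial_range[1] >= 1L, cfg$n_axial_range[2] >= cfg$n_axial_range[1],
            cfg$n_sagittal_range[1] >= 1L,
            cfg$n_sagittal_range[2] >= cfg$n_sagittal_range[1],
            cfg$texture_contrast >= 0,
            cfg$cross_plane_signal_split >= 0, cfg$cross_plane_signal_split <= 1,
            cfg$noise_sd >= 0)
  if (cfg$image_size < 24L)
    stop("image_size too small to contain the minimum tumor (need >= 24)",
         call. = FALSE)
  structure(cfg, class = "phantom_config")
}

#' Generate a synthetic phantom dataset
#'
#' Deterministic given `config$seed`: the same config always yields an
#' identical in-memory manifest. Malignant patients are the first
#' `round(n_patients * malignant_fraction)` patient indices (deterministic
#' allocation); ages are drawn from the class's truncated normal; each
#' patient receives n axial and m sagittal renderings of one latent tumor.
#'
#' @param config A [phantom_config()].
#' @param split Manifest split tag, `"train"` or `"test"`.
#' @return A [dataset_manifest()] with pixels attached (quantized to the
#'   8-bit grid so [write_manifest()] round-trips are lossless).
#' @export
generate_dataset <- function(config, split = c("train", "test")) {
  stopifnot(inherits(config, "phantom_config"))
  split <- match.arg(split)
  with_seed(config$seed, {
    n <- config$n_patients
    n_mal <- round(n * config$malignant_fraction)
    labels <- c(rep("malignant", n_mal), rep("benign", n - n_mal))
    loc_probs <- c(cervical = 0.50, thoracic = 0.30, lumbar = 0.16, sacral = 0.04)
    patients <- lapply(seq_len(n), function(i) {
      lab <- labels[i]
      agep <- if (lab == "malignant") config$malignant_age_distribution
              else config$benign_age_distribution
      age <- rtruncnorm0(1, agep[1], agep[2])
      loc <- sample(names(loc_probs), 1, prob = loc_probs)
      pid <- sprintf("P%03d", i)
      n_ax <- sample(seq(config$n_axial_range[1], config$n_axial_range[2]), 1)
      n_sg <- sample(seq(config$n_sagittal_range[1], config$n_sagittal_range[2]), 1)
      latent <- draw_latent_tumor(config, lab)
      ax <- lapply(seq_len(n_ax), function(k)
        render_phantom_slice(config, latent, "axial", pid,
                             sprintf("%s_ax%02d", pid, k)))
      sg <- lapply(seq_len(n_sg), function(k)
        render_phantom_slice(config, latent, "sagittal", pid,
                             sprintf("%s_sg%02d", pid, k)))
      patient_record(pid, age, lab, axial_images = ax, sagittal_images = sg,
                     location = loc)
    })
    dataset_manifest(patients, split = split,
                     provenance = list(generator = "bgnet_phantom",
                                       seed = config$seed,
                                       texture_contrast = config$texture_contrast,
                                       cross_plane_signal_split =
                                         config$cross_plane_signal_split))
  })
}

# Latent tumor shared by all slices of one patient: base radius (fraction of
# the image side), per-plane elongation, boundary-irregularity harmonics and
# a texture phase, all drawn once per patient.
draw_latent_tumor <- function(config, label) {
  s <- config$cross_plane_signal_split
  c0 <- config$texture_contrast
  malignant <- label == "malignant"
  list(
    malignant = malignant,
    radius_frac = stats::runif(1, 0.16, 0.26),
    elong_ax = stats::runif(1, 0.7, 1.0),   # axial in-plane aspect
    elong_sg = stats::runif(1, 1.1, 1.6),   # sagittal tumors look elongated
    # patient- and plane-level baseline intensity variability (both
    # classes), emulating scanner/patient variation; keeps a plain mean
    # intensity from carrying the whole signal at moderate contrast
    base_ax = 0.58 + stats::rnorm(1, 0, 0.03),
    base_sg = 0.58 + stats::rnorm(1, 0, 0.03),
    # boundary irregularity: random 3rd-6th harmonics, axial share of signal
    irregular_amp = if (malignant) min(0.5, 0.8 * c0 * s) else 0,
    irregular_coef = stats::runif(4, -1, 1),
    irregular_phase = stats::runif(4, 0, 2 * pi),
    # texture heterogeneity: sagittal share of signal
    texture_sd = if (malignant) 0.22 * min(1.2, c0 * (1 - s)) else 0,
    # low spatial frequencies so the heterogeneity survives the 2x vertical
    # downsampling of the bipartite splice
    texture_freq = stats::runif(2, 0.06, 0.15),
    texture_phase = stats::runif(2, 0, 2 * pi),
    # interior intensity shift present in both planes, scaled by each
    # plane's signal share (at high contrast this alone separates the
    # classes even through crop-mean intensities)
    shift_ax = if (malignant) 0.10 * c0 * s else 0,
    shift_sg = if (malignant) 0.10 * c0 * (1 - s) else 0)
}

render_phantom_slice <- function(config, latent, plane, patient_id, image_id) {
  sz <- config$image_size
  # per-slice variation: position through the tumor scales the apparent
  # radius; small center jitter
  zfac <- sqrt(1 - stats::runif(1, 0, 0.6)^2)
  cx <- sz / 2 + stats::runif(1, -0.06, 0.06) * sz
  cy <- sz / 2 + stats::runif(1, -0.06, 0.06) * sz
  r0 <- latent$radius_frac * sz * zfac
  if (plane == "axial") { rx <- r0 * latent$elong_ax; ry <- r0 }
  else { rx <- r0; ry <- r0 * latent$elong_sg }
  ry <- min(ry, 0.45 * sz)

  xs <- matrix(rep(seq_len(sz), each = sz), sz, sz)   # col index = x
  ys <- matrix(rep(seq_len(sz), times = sz), sz, sz)  # row index = y
  dx <- (xs - cx) / rx
  dy <- (ys - cy) / ry
  theta <- atan2(dy, dx)
  rad <- sqrt(dx^2 + dy^2)

  # boundary irregularity (axial only carries it; amplitude 0 for benign)
  boundary <- 1
  if (plane == "axial" && latent$irregular_amp > 0) {
    pert <- 0
    for (k in 1:4)
      pert <- pert + latent$irregular_coef[k] *
        cos((k + 2) * theta + latent$irregular_phase[k])
    boundary <- 1 + latent$irregular_amp * pert / 2
  }
  inside <- rad <= boundary

  # background: soft tissue with a gentle intensity gradient
  bg <- 0.32 + 0.06 * (ys / sz) + 0.03 * sin(2 * pi * xs / sz)
  base <- (if (plane == "axial") latent$base_ax else latent$base_sg) +
    (if (plane == "axial") latent$shift_ax else latent$shift_sg)

  tumor <- matrix(base, sz, sz)
  if (plane == "sagittal" && latent$texture_sd > 0) {
    # heterogeneous interior: low-frequency speckle field
    f <- latent$texture_freq; ph <- latent$texture_phase
    field <- sin(2 * pi * f[1] * xs + ph[1]) * cos(2 * pi * f[2] * ys + ph[2])
    tumor <- tumor + latent$texture_sd * field +
      matrix(stats::rnorm(sz * sz, 0, latent$texture_sd / 3), sz, sz)
  }
  px <- ifelse(inside, tumor, bg)
  px <- px + matrix(stats::rnorm(sz * sz, 0, config$noise_sd), sz, sz)
  px <- pmin(pmax(px, 0), 1)
  px <- round(px * 255) / 255  # 8-bit grid: PNG round-trip is lossless

  # tight bounding box of the rendered tumor, 0-based half-open
  rows <- which(apply(inside, 1, any))
  cols <- which(apply(inside, 2, any))
  if (length(rows) == 0L) {  # degenerate: tumor rendered off-grid
    rows <- cols <- c(floor(sz / 2), floor(sz / 2) + 1)
  }
  box <- c(min(cols) - 1L, min(rows) - 1L, max(cols), max(rows))
  annotated_image(image_id, patient_id, plane, px, box)
}
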