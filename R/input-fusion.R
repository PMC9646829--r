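#' @title Input layer fusion
#'
#' @description Turns one matching edge (or one single-plane image) into the
#'   standardized model input: the tumor box is expanded by a margin and
#'   cropped (clipped at the image border), optionally flipped, the axial
#'   crop is spliced above the sagittal crop, the result is resized to
#'   `output_side x output_side`, replicated to three identical channels and
#'   standardized to mean 0 / sd 1 over the whole fused image.
#'
#' @name input-fusion
NULL

#' Augmentation / preprocessing configuration
#'
#' @param margin_min,margin_max Training-time margin range in pixels: each
#'   training draw expands the tumor box by a uniform integer margin in
#'   `[margin_min, margin_max]` on every side, so the model also sees tissue
#'   around the tumor.
#' @param test_margin Fixed margin at test time (midpoint of the training
#'   range by default), making inference deterministic.
#' @param flip_vertical_prob,flip_horizontal_prob Probabilities of the
#'   up-down and left-right flips during training (0 at test time).
#' @param output_side Side of the square model input; must be even so the
#'   splice can give each plane exactly half the height.
#' @param per_crop_standardize If `TRUE`, standardize each crop before
#'   splicing instead of the fused image as a whole.
#' @param joint_flip If `TRUE`, the two crops of an edge share one flip draw
#'   instead of being flipped independently.
#'
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(margin_min = 40L, margin_max = 60L,
                           test_margin = 50L,
                           flip_vertical_prob = 0.5,
                           flip_horizontal_prob = 0.5,
                           output_side = 224L,
                           per_crop_standardize = FALSE,
                           joint_flip = FALSE) {
  stopifnot(margin_min >= 0L, margin_max >= margin_min, test_margin >= 0L,
            flip_vertical_prob >= 0, flip_vertical_prob <= 1,
            flip_horizontal_prob >= 0, flip_horizontal_prob <= 1,
            output_side >= 2L)
  structure(list(margin_min = as.integer(margin_min),
                 margin_max = as.integer(margin_max),
                 test_margin = as.integer(test_margin),
                 flip_vertical_prob = flip_vertical_prob,
                 flip_horizontal_prob = flip_horizontal_prob,
                 output_side = as.integer(output_side),
                 per_crop_standardize = per_crop_standardize,
                 joint_flip = joint_flip),
            class = "augment_config")
}

#' Crop the tumor box with a margin
#'
#' Expands the image's 0-based half-open tumor box by `margin` pixels on
#' every side, clips the expanded box to the image bounds, and returns the
#' cropped pixel matrix.
#'
#' @param image An [annotated_image()].
#' @param margin Nonnegative integer margin in pixels.
#' @return Numeric pixel matrix (never empty).
#' @export
crop_with_margin <- function(image, margin) {
  stopifnot(inherits(image, "annotated_image"), margin >= 0)
  margin <- as.integer(margin)
  b <- image$tumor_box
  h <- nrow(image$pixels); w <- ncol(image$pixels)
  x0 <- max(0L, b[1] - margin); y0 <- max(0L, b[2] - margin)
  x1 <- min(w, b[3] + margin);  y1 <- min(h, b[4] + margin)
  image$pixels[(y0 + 1L):y1, (x0 + 1L):x1, drop = FALSE]
}

#' Randomly flip a pixel grid
#'
#' Applies an up-down flip with probability `config$flip_vertical_prob` and,
#' independently, a left-right flip with probability
#' `config$flip_horizontal_prob`, consuming R's current RNG stream.
#'
#' @param pixels Numeric matrix.
#' @param config An [augment_config()].
#' @return The (possibly flipped) matrix.
#' @export
random_flip <- function(pixels, config) {
  if (config$flip_vertical_prob > 0 &&
      stats::runif(1) < config$flip_vertical_prob)
    pixels <- pixels[nrow(pixels):1L, , drop = FALSE]
  if (config$flip_horizontal_prob > 0 &&
      stats::runif(1) < config$flip_horizontal_prob)
    pixels <- pixels[, ncol(pixels):1L, drop = FALSE]
  pixels
}

#' Standardize a pixel grid to mean 0, sd 1
#'
#' Subtracts the mean of all entries and divides by their standard
#' deviation. A constant input (sd 0) maps to all zeros rather than erroring,
#' since synthetic fixtures can produce flat crops.
#'
#' @param pixels Numeric matrix or array.
#' @return Standardized object of the same shape.
#' @export
standardize <- function(pixels) {
  mu <- mean(pixels)
  sigma <- stats::sd(as.vector(pixels))
  if (!is.finite(sigma) || sigma == 0) return(pixels * 0)
  (pixels - mu) / sigma
}

# Bilinear resize of a grayscale matrix to target_rows x target_cols.
# EBImage's first dimension maps to our row axis.
resize_bilinear <- function(pixels, target_rows, target_cols) {
  r <- EBImage::resize(pixels, w = target_rows, h = target_cols)
  matrix(as.numeric(r), nrow = target_rows, ncol = target_cols)
}

# Replicate a grayscale matrix into an H x W x 3 array.
gray_to_3ch <- function(pixels) {
  array(rep(as.numeric(pixels), 3L), dim = c(nrow(pixels), ncol(pixels), 3L))
}

new_fused_input <- function(pixels, provenance, standardized = TRUE) {
  structure(list(pixels = pixels, provenance = provenance,
                 standardized = standardized),
            class = "fused_input")
}

#' Splice an axial and a sagittal crop into one model input
#'
#' Each crop is resized (bilinear) to `output_side/2 x output_side`, the
#' axial crop is stacked above the sagittal crop, the grayscale result is
#' replicated to three identical channels and standardized over the whole
#' fused image.
#'
#' @param axial_crop,sagittal_crop Numeric pixel matrices.
#' @param output_side Even side length of the square output (default 224).
#' @param per_crop_standardize Standardize each crop before splicing instead
#'   of the fused image afterwards.
#' @param provenance Optional reference attached to the result.
#' @return A `fused_input` with `pixels` of dim
#'   `output_side x output_side x 3`.
#' @export
splice_edge <- function(axial_crop, sagittal_crop, output_side = 224L,
                        per_crop_standardize = FALSE, provenance = NULL) {
  stopifnot(length(axial_crop) > 0L, length(sagittal_crop) > 0L)
  output_side <- as.integer(output_side)
  if (output_side %% 2L != 0L)
    stop("output_side must be even: the axial and sagittal halves must tile it exactly",
         call. = FALSE)
  half <- output_side %/% 2L
  a <- resize_bilinear(axial_crop, half, output_side)
  s <- resize_bilinear(sagittal_crop, half, output_side)
  if (per_crop_standardize) { a <- standardize(a); s <- standardize(s) }
  stacked <- rbind(a, s)  # axial above, sagittal below
  px <- gray_to_3ch(stacked)
  if (!per_crop_standardize) px <- standardize(px)
  new_fused_input(px, provenance)
}

#' Prepare one edge as a standardized model input
#'
#' Applies the full training or test chain to a matching edge: margin
#' expansion (uniform in `[margin_min, margin_max]` when `train`, fixed
#' `test_margin` otherwise), random flips (training only, each crop flipped
#' independently unless `joint_flip`), then [splice_edge()].
#'
#' @param axial_image,sagittal_image [annotated_image()] objects of the two
#'   planes.
#' @param config An [augment_config()].
#' @param train Logical; training mode consumes the RNG stream, test mode is
#'   a pure function of its inputs.
#' @return A `fused_input`.
#' @export
prepare_edge <- function(axial_image, sagittal_image, config, train = FALSE) {
  margin_a <- edge_margin(config, train)
  margin_s <- if (train) edge_margin(config, train) else margin_a
  a <- crop_with_margin(axial_image, margin_a)
  s <- crop_with_margin(sagittal_image, margin_s)
  if (train) {
    if (config$joint_flip) {
      flip_v <- stats::runif(1) < config$flip_vertical_prob
      flip_h <- stats::runif(1) < config$flip_horizontal_prob
      if (flip_v) { a <- a[nrow(a):1L, , drop = FALSE]; s <- s[nrow(s):1L, , drop = FALSE] }
      if (flip_h) { a <- a[, ncol(a):1L, drop = FALSE]; s <- s[, ncol(s):1L, drop = FALSE] }
    } else {
      a <- random_flip(a, config)
      s <- random_flip(s, config)
    }
  }
  splice_edge(a, s, config$output_side,
              per_crop_standardize = config$per_crop_standardize,
              provenance = list(axial = axial_image$image_id,
                                sagittal = sagittal_image$image_id))
}

edge_margin <- function(config, train) {
  if (!train) return(config$test_margin)
  if (config$margin_max == config$margin_min) return(config$margin_min)
  sample(seq(config$margin_min, config$margin_max), 1L)
}

#' Prepare a single-plane image as a standardized model input
#'
#' Same crop / flip / standardize chain as [prepare_edge()] but the single
#' crop is resized to `output_side x output_side` with no splice.
#'
#' @param image An [annotated_image()].
#' @param config An [augment_config()].
#' @param train Logical; see [prepare_edge()].
#' @return A `fused_input` with `pixels` of dim
#'   `output_side x output_side x 3`.
#' @export
prepare_single <- function(image, config, train = FALSE) {
  crop <- crop_with_margin(image, edge_margin(config, train))
  if (train) crop <- random_flip(crop, config)
  side <- config$output_side
  px <- gray_to_3ch(resize_bilinear(crop, side, side))
  new_fused_input(standardize(px), provenance = list(image = image$image_id))
}

#' @export
print.fused_input <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<fused_input> %dx%dx%d%s\n", d[1], d[2], d[3],
              if (isTRUE(x$standardized)) ", standardized" else ""))
  invisible(x)
}
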