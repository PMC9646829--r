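#' @title ResNetST: the feature-layer fusion model
#'
#' @description A five-part hybrid backbone: (1) a convolutional stem
#'   (7x7 stride-2 conv, batch norm, ReLU, 3x3 stride-2 max-pool) reducing
#'   resolution 4x; (2) a residual bottleneck stage at 1/4 resolution;
#'   (3) a residual bottleneck stage at 1/8 resolution; (4) an attention
#'   fusion stage -- a linear projection of the 1/8-resolution feature map
#'   into token embeddings followed by shifted-window self-attention blocks
#'   with patch merging between stages; (5) global average pooling and a
#'   fully connected 2-way head. All forward and backward passes are
#'   implemented explicitly in R, so training is CPU-only and bitwise
#'   reproducible under a fixed seed.
#'
#' @name resnetst
NULL

#' Model configuration
#'
#' Defaults follow the stage-1/stage-2 layout of the 50-layer residual
#' network (bottleneck counts 3 and 4, output channels 256 and 512) and the
#' tiny shifted-window transformer for the attention stages (embedding 192
#' at 1/8 scale, depths `c(2, 6, 2)`, heads `c(6, 12, 24)`, window 7).
#' `tiny_preset = TRUE` switches every width down to a CPU-scale variant
#' (input 64, stem 16, stage channels 32/64 with one block each, embedding
#' 32, depths `c(1, 1)`, heads `c(1, 2)`, window 4) used throughout the
#' test suite.
#'
#' @param input_side Side of the square input image.
#' @param stem_channels Stem output channels.
#' @param stage1_blocks,stage2_blocks Bottleneck counts of the two residual
#'   stages.
#' @param stage1_channels,stage2_channels Output channels of the two stages
#'   (bottleneck mid-width is a quarter of these).
#' @param attention_embed_dim Token embedding dimension entering the
#'   attention stage.
#' @param attention_depths Integer vector: blocks per attention stage (patch
#'   merging between consecutive stages doubles the embedding).
#' @param attention_heads Heads per attention stage (same length as depths).
#' @param window_size Attention window side; must divide the token grid of
#'   every attention stage.
#' @param num_classes Number of output classes (2).
#' @param tiny_preset Use the CPU-scale variant described above.
#'
#' @return An object of class `model_config`.
#' @export
model_config <- function(input_side = 224L,
                         stem_channels = 64L,
                         stage1_blocks = 3L, stage2_blocks = 4L,
                         stage1_channels = 256L, stage2_channels = 512L,
                         attention_embed_dim = 192L,
                         attention_depths = c(2L, 6L, 2L),
                         attention_heads = c(6L, 12L, 24L),
                         window_size = 7L,
                         num_classes = 2L,
                         tiny_preset = FALSE) {
  if (tiny_preset) {
    input_side <- 64L; stem_channels <- 16L
    stage1_blocks <- 1L; stage2_blocks <- 1L
    stage1_channels <- 32L; stage2_channels <- 64L
    attention_embed_dim <- 32L
    attention_depths <- c(1L, 1L); attention_heads <- c(1L, 2L)
    window_size <- 4L
  }
  cfg <- structure(
    list(input_side = as.integer(input_side),
         stem_channels = as.integer(stem_channels),
         stage1_blocks = as.integer(stage1_blocks),
         stage2_blocks = as.integer(stage2_blocks),
         stage1_channels = as.integer(stage1_channels),
         stage2_channels = as.integer(stage2_channels),
         attention_embed_dim = as.integer(attention_embed_dim),
         attention_depths = as.integer(attention_depths),
         attention_heads = as.integer(attention_heads),
         window_size = as.integer(window_size),
         num_classes = as.integer(num_classes),
         tiny_preset = tiny_preset),
    class = "model_config")
  validate_model_config(cfg)
  cfg
}

validate_model_config <- function(cfg) {
  if (cfg$num_classes != 2L)
    stop("num_classes must be 2 (benign vs malignant)", call. = FALSE)
  if (length(cfg$attention_depths) != length(cfg$attention_heads))
    stop("attention_depths and attention_heads must have the same length",
         call. = FALSE)
  if (cfg$input_side %% 8L != 0L)
    stop("input_side must be divisible by 8", call. = FALSE)
  side <- cfg$input_side %/% 8L
  for (si in seq_along(cfg$attention_depths)) {
    if (side %% cfg$window_size != 0L)
      stop(sprintf("attention stage %d: window size %d does not divide the %dx%d token grid",
                   si, cfg$window_size, side, side), call. = FALSE)
    if (si < length(cfg$attention_depths)) {
      if (side %% 2L != 0L)
        stop(sprintf("attention stage %d: grid side %d is odd, patch merging impossible",
                     si, side), call. = FALSE)
      side <- side %/% 2L
    }
  }
  invisible(cfg)
}

#' Build a ResNetST model with seeded initialization
#'
#' @param config A [model_config()].
#' @param seed Integer seed for parameter initialization; the same seed
#'   yields identical initial parameters.
#' @return An object of class `resnetst_model`.
#' @export
build_model <- function(config = model_config(), seed = 42L) {
  stopifnot(inherits(config, "model_config"))
  validate_model_config(config)
  with_seed(seed, {
    layers <- list()
    add <- function(l) layers[[length(layers) + 1L]] <<- l
    # part 1: stem
    add(nn_conv(3L, config$stem_channels, 7L, stride = 2L, pad = 3L))
    add(nn_bn(config$stem_channels)); add(nn_relu())
    add(nn_maxpool(3L, 2L, 1L))
    # part 2: residual stage at 1/4 resolution
    cin <- config$stem_channels
    for (i in seq_len(config$stage1_blocks)) {
      add(nn_bottleneck(cin, config$stage1_channels,
                        config$stage1_channels %/% 4L, stride = 1L))
      cin <- config$stage1_channels
    }
    # part 3: residual stage at 1/8 resolution
    for (i in seq_len(config$stage2_blocks)) {
      add(nn_bottleneck(cin, config$stage2_channels,
                        config$stage2_channels %/% 4L,
                        stride = if (i == 1L) 2L else 1L))
      cin <- config$stage2_channels
    }
    # part 4: token projection + shifted-window attention stages
    D <- config$attention_embed_dim
    add(nn_linear(cin, D, init = "xavier"))
    add(nn_ln(D))
    for (si in seq_along(config$attention_depths)) {
      for (d in seq_len(config$attention_depths[si])) {
        shift <- if (d %% 2L == 0L) config$window_size %/% 2L else 0L
        add(nn_swin_block(D, config$attention_heads[si], config$window_size,
                          shift = shift))
      }
      if (si < length(config$attention_depths)) {
        add(nn_patch_merge(D))
        D <- 2L * D
      }
    }
    # part 5: norm, global average pooling and the 2-way head
    add(nn_ln(D))
    add(nn_head(D, config$num_classes))
    structure(list(config = config, layers = layers, init_seed = seed),
              class = "resnetst_model")
  })
}

#' @export
print.resnetst_model <- function(x, ...) {
  np <- n_parameters(x)
  cat(sprintf("<resnetst_model> input %dx%dx3, %d layers, %s parameters%s\n",
              x$config$input_side, x$config$input_side, length(x$layers),
              format(np, big.mark = ","),
              if (x$config$tiny_preset) " (tiny preset)" else ""))
  invisible(x)
}

count_layer_params <- function(layer) {
  n <- sum(vapply(layer$params, length, integer(1)))
  if (!is.null(layer$sub))
    n <- n + sum(vapply(layer$sub, count_layer_params, numeric(1)))
  n
}

n_parameters <- function(model) {
  sum(vapply(model$layers, count_layer_params, numeric(1)))
}

#' Training configuration
#'
#' @param learning_rate SGD learning rate. The published setting for the
#'   full-size, ImageNet-initialized backbone is 0.0002; randomly
#'   initialized tiny-preset models train with a larger rate (the experiment
#'   driver uses 0.02 for those).
#' @param epochs Number of passes over the training set.
#' @param batch_size Mini-batch size.
#' @param momentum Classical SGD momentum.
#' @param seed Seed controlling edge sampling, augmentation draws and batch
#'   shuffling for the whole training run.
#' @param draws_per_patient Bipartite mode: how many edges to draw per
#'   patient per epoch; default (`NULL`) is `max(n, m)`, keeping epoch size
#'   commensurate with the image counts without enumerating all n x m pairs.
#' @param pretrained_stem_path Optional path to a checkpoint whose stem and
#'   residual-stage parameters are copied into the new model before
#'   training (external weights; none ship with the package).
#'
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 2e-4, epochs = 20L, batch_size = 32L,
                         momentum = 0.9, seed = 42L,
                         draws_per_patient = NULL,
                         pretrained_stem_path = NULL) {
  stopifnot(learning_rate > 0, epochs >= 1L, batch_size >= 1L,
            momentum >= 0, momentum < 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), momentum = momentum,
                 seed = as.integer(seed),
                 draws_per_patient = draws_per_patient,
                 pretrained_stem_path = pretrained_stem_path),
            class = "train_config")
}

#' Predict benign/malignant probabilities for one model input
#'
#' Deterministic in evaluation mode (batch-norm running statistics, no
#' augmentation randomness).
#'
#' @param model A trained (or freshly built) [build_model()] network.
#' @param input A `fused_input` whose side matches the model config.
#' @return An `edge_prediction`: list with `p_benign`, `p_malignant`
#'   (softmax over the 2 logits, summing to 1) and the input's provenance.
#' @export
predict_edge <- function(model, input) {
  stopifnot(inherits(model, "resnetst_model"), inherits(input, "fused_input"))
  d <- dim(input$pixels)
  if (d[1] != model$config$input_side || d[2] != model$config$input_side)
    stop(sprintf("input is %dx%d but the model expects %dx%d",
                 d[1], d[2], model$config$input_side, model$config$input_side),
         call. = FALSE)
  p <- predict_proba(model, list(input))
  structure(list(p_benign = 1 - p, p_malignant = p,
                 source = input$provenance),
            class = "edge_prediction")
}

#' Malignant probabilities for a list of model inputs
#'
#' @param model A `resnetst_model`.
#' @param inputs List of `fused_input` objects.
#' @param batch_size Forward-pass chunk size.
#' @return Numeric vector of malignant probabilities, one per input.
#' @export
predict_proba <- function(model, inputs, batch_size = 32L) {
  out <- numeric(length(inputs))
  i <- 1L
  while (i <= length(inputs)) {
    j <- min(i + batch_size - 1L, length(inputs))
    x <- inputs_to_tensor(inputs[i:j])
    fw <- model_forward(model, x, training = FALSE)
    out[i:j] <- softmax_rows(fw$logits)[, 2L]
    i <- j + 1L
  }
  out
}

# Assemble the per-epoch list of training units for a mode. Each unit is a
# closure-free descriptor: list(patient index, kind = "edge"/"single",
# image refs resolved at batch time so augmentation stays per-draw).
training_units <- function(manifest, mode, draws_per_patient = NULL) {
  pats <- manifest$patients
  if (mode == "bg") {
    missing <- vapply(pats, function(p)
      length(p$axial_images) == 0L || length(p$sagittal_images) == 0L,
      logical(1))
    if (any(missing))
      stop(sprintf("bipartite mode requires both planes; missing for: %s",
                   paste(vapply(pats[missing], `[[`, character(1),
                                "patient_id"), collapse = ", ")),
           call. = FALSE)
    units <- list()
    for (pi in seq_along(pats)) {
      p <- pats[[pi]]
      k <- draws_per_patient %||%
        max(length(p$axial_images), length(p$sagittal_images))
      for (d in seq_len(k))
        units[[length(units) + 1L]] <- list(patient = pi, kind = "edge")
    }
    return(units)
  }
  units <- list()
  for (pi in seq_along(pats)) {
    p <- pats[[pi]]
    imgs <- switch(mode,
                   axi = p$axial_images,
                   sag = p$sagittal_images,
                   axi_sag = c(p$axial_images, p$sagittal_images))
    for (ii in seq_along(imgs))
      units[[length(units) + 1L]] <- list(patient = pi, kind = "single",
                                          mode = mode, index = ii)
  }
  units
}

unit_input <- function(unit, manifest, augment, train) {
  p <- manifest$patients[[unit$patient]]
  if (unit$kind == "edge") {
    e <- sample_edge(p)
    prepare_edge(p$axial_images[[e$axial_index]],
                 p$sagittal_images[[e$sagittal_index]], augment, train = train)
  } else {
    imgs <- switch(unit$mode,
                   axi = p$axial_images,
                   sag = p$sagittal_images,
                   axi_sag = c(p$axial_images, p$sagittal_images))
    prepare_single(imgs[[unit$index]], augment, train = train)
  }
}

#' Train a ResNetST model
#'
#' Minimizes cross-entropy with SGD over edge draws (`mode = "bg"`: one
#' uniform bipartite edge per visit, spliced at the input layer) or single
#' images (`axi` / `sag` / `axi_sag`). The whole run -- edge sampling,
#' augmentation, shuffling, updates -- is seeded by `train_cfg$seed`.
#'
#' @param model A [build_model()] network.
#' @param manifest Training [dataset_manifest()] (non-empty; in `bg` mode
#'   every patient must have both planes).
#' @param mode One of `"axi"`, `"sag"`, `"axi_sag"`, `"bg"`.
#' @param augment An [augment_config()] whose `output_side` matches the
#'   model.
#' @param train_cfg A [train_config()].
#' @param verbose Print one line per epoch.
#' @return List with the trained `model`, `loss_trace` (per-epoch mean
#'   cross-entropy) and `acc_trace` (per-epoch training accuracy over the
#'   augmented draws).
#' @export
train_model <- function(model, manifest, mode = c("bg", "axi", "sag", "axi_sag"),
                        augment = augment_config(), train_cfg = train_config(),
                        verbose = FALSE) {
  stopifnot(inherits(model, "resnetst_model"),
            inherits(manifest, "dataset_manifest"))
  mode <- match.arg(mode)
  if (length(manifest$patients) == 0L)
    stop("cannot train on an empty manifest", call. = FALSE)
  if (!is.null(train_cfg$pretrained_stem_path))
    model <- load_pretrained_stem(model, train_cfg$pretrained_stem_path)
  units <- training_units(manifest, mode, train_cfg$draws_per_patient)
  labels <- vapply(units, function(u)
    match(manifest$patients[[u$patient]]$label, LABELS), integer(1))
  vel <- lapply(model$layers, init_velocity)
  loss_trace <- acc_trace <- numeric(train_cfg$epochs)
  with_seed(train_cfg$seed, {
    for (ep in seq_len(train_cfg$epochs)) {
      ord <- sample.int(length(units))
      losses <- c(); hits <- 0L; total <- 0L
      i <- 1L
      while (i <= length(ord)) {
        j <- min(i + train_cfg$batch_size - 1L, length(ord))
        sel <- ord[i:j]
        inputs <- lapply(units[sel], unit_input, manifest = manifest,
                         augment = augment, train = TRUE)
        y <- labels[sel]
        x <- inputs_to_tensor(inputs)
        fw <- model_forward(model, x, training = TRUE)
        model <- fw$model
        ce <- cross_entropy(fw$logits, y)
        losses <- c(losses, ce$loss * length(sel))
        hits <- hits + sum(max.col(ce$probs) == y)
        total <- total + length(sel)
        grads <- model_backward(model, fw$caches, ce$dlogits)
        st <- sgd_step(model, grads, vel, train_cfg$learning_rate,
                       train_cfg$momentum)
        model <- st$model; vel <- st$vel
        i <- j + 1L
      }
      loss_trace[ep] <- sum(losses) / total
      acc_trace[ep] <- hits / total
      if (verbose)
        message(sprintf("epoch %02d: loss %.4f, train acc %.3f",
                        ep, loss_trace[ep], acc_trace[ep]))
    }
  })
  list(model = model, loss_trace = loss_trace, acc_trace = acc_trace)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive holding the model config, all
#' parameters and buffers, and the initialization seed.
#'
#' @param model A `resnetst_model`.
#' @param path Destination file.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored `resnetst_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "resnetst_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "resnetst_model"))
    stop("not a resnetst checkpoint: ", path, call. = FALSE)
  model
}

# Copy stem + residual-stage parameters (and batch-norm buffers) from a
# checkpoint into a freshly built model; the attention stages and head keep
# their fresh initialization. This is the hook for externally trained
# weights.
load_pretrained_stem <- function(model, path) {
  src <- load_checkpoint(path)
  n_backbone <- 4L + model$config$stage1_blocks + model$config$stage2_blocks
  for (i in seq_len(n_backbone)) {
    a <- model$layers[[i]]; b <- src$layers[[i]]
    if (!identical(a$type, b$type))
      stop("pretrained checkpoint does not match the model architecture",
           call. = FALSE)
    model$layers[[i]] <- b
  }
  model
}
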