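# Gradient and architectural checks of the layer implementations; these use
# package internals directly.

micro_config <- function() {
  model_config(input_side = 32L, stem_channels = 4L,
               stage1_blocks = 1L, stage2_blocks = 1L,
               stage1_channels = 8L, stage2_channels = 8L,
               attention_embed_dim = 8L, attention_depths = c(2L, 1L),
               attention_heads = c(2L, 4L), window_size = 2L)
}

test_that("analytic gradients match finite differences on a micro model", {
  ns <- asNamespace("bgnet")
  set.seed(1)
  model <- build_model(micro_config(), seed = 3)
  N <- 2L
  X <- ns$nn_tensor(matrix(rnorm(N * 32 * 32 * 3), N * 32 * 32, 3), 32L, 32L, N)
  y <- c(1L, 2L)
  loss_of <- function(m)
    ns$cross_entropy(ns$model_forward(m, X, training = TRUE)$logits, y)$loss

  fw <- ns$model_forward(model, X, training = TRUE)
  ce <- ns$cross_entropy(fw$logits, y)
  grads <- ns$model_backward(fw$model, fw$caches, ce$dlogits)

  # one representative parameter per layer family, several coordinates each
  get_set <- function(li, sub, nm) {
    list(
      get = function(m) {
        l <- m$layers[[li]]; for (s in sub) l <- l$sub[[s]]
        l$params[[nm]]
      },
      set = function(m, v) {
        if (length(sub) == 0) m$layers[[li]]$params[[nm]] <- v
        else if (length(sub) == 1) m$layers[[li]]$sub[[sub[1]]]$params[[nm]] <- v
        else m$layers[[li]]$sub[[sub[1]]]$sub[[sub[2]]]$params[[nm]] <- v
        m
      },
      grad = function(g) {
        gg <- g[[li]]; for (s in sub) gg <- gg$sub[[s]]
        if (length(sub) == 0 && is.null(gg$params)) gg[[nm]]
        else if (!is.null(gg$params)) gg$params[[nm]] else gg[[nm]]
      })
  }
  types <- vapply(model$layers, `[[`, character(1), "type")
  cases <- list(
    get_set(which(types == "conv")[1], c(), "W"),           # stem conv
    get_set(which(types == "bn")[1], c(), "gamma"),         # stem norm
    get_set(which(types == "bottleneck")[1], "c2", "W"),    # 3x3 in block
    get_set(which(types == "bottleneck")[2], "cd", "W"),    # strided shortcut
    get_set(which(types == "swin")[1], "qkv", "W"),         # attention qkv
    get_set(which(types == "swin")[2], "proj", "W"),        # shifted block
    get_set(which(types == "swin")[1], "fc1", "W"),         # MLP
    get_set(which(types == "patch_merge")[1], "red", "W"),  # merge reduction
    get_set(which(types == "ln")[2], c(), "gamma"),         # final norm
    get_set(which(types == "head")[1], c(), "W"))           # classifier
  eps <- 1e-5
  for (cs in cases) {
    p <- cs$get(model); g <- cs$grad(grads)
    for (k in sample(length(p), min(3, length(p)))) {
      p1 <- p; p1[k] <- p1[k] + eps
      p2 <- p; p2[k] <- p2[k] - eps
      num <- (loss_of(cs$set(model, p1)) - loss_of(cs$set(model, p2))) / (2 * eps)
      expect_equal(g[k], num, tolerance = 1e-3)
    }
  }
})

test_that("spatial contract: residual stages sit at 1/4 and 1/8 resolution", {
  ns <- asNamespace("bgnet")
  run_until <- function(model, x, stop_type) {
    for (l in model$layers) {
      if (l$type == stop_type) return(x)
      x <- ns$layer_forward(l, x, training = FALSE)$x
    }
    x
  }
  # tiny preset, input 64: attention stage receives an 8x8 grid
  tiny <- build_model(model_config(tiny_preset = TRUE), seed = 1)
  x <- ns$nn_tensor(matrix(rnorm(64 * 64 * 3), 64 * 64, 3), 64L, 64L, 1L)
  at <- run_until(tiny, x, "linear")
  expect_equal(c(at$H, at$W), c(8L, 8L))

  # default config, input 224: stage-2 feature map has side 28 = 224/8
  big <- build_model(model_config(), seed = 1)
  types <- vapply(big$layers, `[[`, character(1), "type")
  x2 <- ns$nn_tensor(matrix(0, 224 * 224 * 3, 3), 224L, 224L, 1L)
  # stem + maxpool -> 1/4
  for (l in big$layers[1:4]) x2 <- ns$layer_forward(l, x2, FALSE)$x
  expect_equal(c(x2$H, x2$W), c(56L, 56L))
  # after stage 1 (no downsampling) and stage 2 (stride 2) -> 1/8
  for (l in big$layers[which(types == "bottleneck")]) {
    x2 <- ns$layer_forward(l, x2, FALSE)$x
  }
  expect_equal(c(x2$H, x2$W), c(28L, 28L))

  # window/grid mismatch is a configuration error
  expect_error(model_config(input_side = 224L, window_size = 5L),
               "window size")
})

test_that("seeded initialization and eval-mode prediction are deterministic", {
  m1 <- build_model(model_config(tiny_preset = TRUE), seed = 9)
  m2 <- build_model(model_config(tiny_preset = TRUE), seed = 9)
  expect_identical(m1, m2)
  m3 <- build_model(model_config(tiny_preset = TRUE), seed = 10)
  expect_false(identical(m1$layers[[1]]$params$W, m3$layers[[1]]$params$W))

  img <- test_image(h = 70, w = 70, box = c(10L, 10L, 40L, 40L))
  inp <- prepare_single(img, tiny_augment(), train = FALSE)
  p1 <- predict_edge(m1, inp)
  p2 <- predict_edge(m1, inp)
  expect_identical(p1$p_malignant, p2$p_malignant)
  expect_equal(p1$p_benign + p1$p_malignant, 1, tolerance = 1e-6)
})

test_that("softmax head is balanced at initialization", {
  model <- build_model(model_config(tiny_preset = TRUE), seed = 4)
  set.seed(21)
  inputs <- lapply(1:100, function(i) {
    px <- array(rnorm(64 * 64 * 3), c(64, 64, 3))
    bgnet:::new_fused_input(px, provenance = NULL)
  })
  p <- predict_proba(model, inputs)
  expect_true(all(p >= 0 & p <= 1))
  expect_lt(abs(mean(p) - 0.5), 0.15)
})

test_that("unshifted window attention is local to its window", {
  ns <- asNamespace("bgnet")
  set.seed(6)
  D <- 8L; H <- W <- 4L; s <- 2L
  blk <- ns$nn_swin_block(D, heads = 2L, window = s, shift = 0L)
  a <- matrix(rnorm(H * W * D), H * W, D)
  x_full <- ns$nn_tensor(a, H, W, 1L)
  # zero out all tokens outside the top-left window
  wp <- ns$win_perm(H, W, s, 1L)
  w1 <- wp$perm[1:(s * s)]
  a0 <- matrix(0, H * W, D); a0[w1, ] <- a[w1, ]
  y_full <- ns$swin_fwd(blk, x_full, FALSE)$x$a
  y_zero <- ns$swin_fwd(blk, ns$nn_tensor(a0, H, W, 1L), FALSE)$x$a
  expect_equal(y_full[w1, ], y_zero[w1, ], tolerance = 1e-10)
})

test_that("checkpoints round-trip the model", {
  m <- build_model(model_config(tiny_preset = TRUE), seed = 2)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(m, m2)
})
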