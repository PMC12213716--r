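#' Specification for a learned super-resolution model
#'
#' Desk-scale configurations of the three learned methods: ESPCN (conv stack
#' plus sub-pixel shuffle trained on MSE), SRGAN (residual-block generator
#' plus a convolutional discriminator with leaky-ReLU, trained adversarially
#' with pixel and perceptual terms), and TCGAN (a transformer generator in
#' series with a CNN U-Net generator, judged by a patch-level discriminator).
#' `scale = 1` is the same-grid restoration mode.
#'
#' @param arch `"espcn"`, `"srgan"` or `"tcgan"`.
#' @param scale Integer upsampling factor (>= 1).
#' @param base_channels Width of the first conv layer.
#' @param n_residual_blocks Residual blocks in the SRGAN generator.
#' @param transformer List with `patch_size`, `depth`, `heads` (TCGAN only).
#' @param loss_weights List with `adversarial`, `pixel`, `perceptual` weights
#'   for the GAN objectives (ESPCN uses pure MSE).
#' @param lr Adam learning rate.
#' @param seed Integer seed: weight init and data shuffling derive from it.
#' @return An object of class `sr_model_spec`.
#' @export
sr_model_spec <- function(arch = c("espcn", "srgan", "tcgan"), scale = 2L,
                          base_channels = 16L, n_residual_blocks = 2L,
                          transformer = list(patch_size = 8L, depth = 2L, heads = 2L),
                          loss_weights = list(adversarial = 1e-3, pixel = 1,
                                              perceptual = 6e-3),
                          lr = 2e-3, seed = 1L) {
  arch <- match.arg(arch)
  scale <- as.integer(scale)
  if (scale < 1) stopf("scale must be >= 1")
  structure(list(arch = arch, scale = scale,
                 base_channels = as.integer(base_channels),
                 n_residual_blocks = as.integer(n_residual_blocks),
                 transformer = transformer, loss_weights = loss_weights,
                 lr = lr, seed = as.integer(seed)),
            class = "sr_model_spec")
}

# deterministic fixed-weight conv feature extractor, shared by the perceptual
# metric and the GAN perceptual loss. Never trained.
build_perceptual_backbone <- function(seed = 424242L, channels = c(8L, 16L, 16L)) {
  s <- function(tag) derive_seed(seed, "backbone", tag)
  net <- nn_seq(nn_conv(1L, channels[1], 3L, s("c1")), nn_act("relu"), nn_pool2(),
                nn_conv(channels[1], channels[2], 3L, s("c2")), nn_act("relu"), nn_pool2(),
                nn_conv(channels[2], channels[3], 3L, s("c3")), nn_act("relu"))
  structure(list(net = net, act_positions = c(2L, 5L, 8L), seed = seed),
            class = "perceptual_backbone")
}

# forward pass recording the activations after each ReLU stage
backbone_features <- function(backbone, img) {
  x <- if (is.matrix(img)) array(img, c(dim(img), 1L)) else img
  feats <- list()
  kids <- backbone$net$cfg$children
  caches <- vector("list", length(kids))
  h <- x
  for (i in seq_along(kids)) {
    fw <- nn_forward(kids[[i]], h)
    h <- fw$y
    caches[[i]] <- fw$cache
    if (i %in% backbone$act_positions) feats[[length(feats) + 1L]] <- h
  }
  list(features = feats, caches = caches)
}

# gradient of sum_l w_l * mean((f_l(x) - f_l(y))^2) wrt x (backbone frozen)
backbone_feature_loss_grad <- function(backbone, fx, fy, caches) {
  kids <- backbone$net$cfg$children
  n_stage <- length(backbone$act_positions)
  loss <- 0
  dylist <- vector("list", length(kids))
  for (l in seq_len(n_stage)) {
    diff <- fx$features[[l]] - fy[[l]]
    loss <- loss + mean(diff^2)
    dylist[[backbone$act_positions[l]]] <- 2 * diff / length(diff)
  }
  g <- NULL
  for (i in rev(seq_along(kids))) {
    if (!is.null(dylist[[i]])) g <- if (is.null(g)) dylist[[i]] else g + dylist[[i]]
    if (!is.null(g)) g <- nn_backward(kids[[i]], caches[[i]], g, acc = FALSE)
  }
  list(loss = loss, grad = g)
}

build_generator <- function(spec) {
  s <- function(...) derive_seed(spec$seed, "gen", ...)
  F <- spec$base_channels; r <- spec$scale
  switch(spec$arch,
    espcn = nn_seq(
      nn_conv(1L, F, 5L, s("c1")), nn_act("tanh"),
      nn_conv(F, F, 3L, s("c2")), nn_act("tanh"),
      nn_conv(F, r^2, 3L, s("c3"), init_scale = 0.1), nn_pshuffle(r)),
    srgan = {
      blocks <- lapply(seq_len(spec$n_residual_blocks), function(i)
        nn_res(nn_conv(F, F, 3L, s("rb", i, 1)), nn_act("lrelu"),
               nn_conv(F, F, 3L, s("rb", i, 2), init_scale = 0.3)))
      nn_seq(
        nn_conv(1L, F, 3L, s("c1")), nn_act("lrelu"),
        nn_res(c(blocks, list(nn_conv(F, F, 3L, s("post"), init_scale = 0.3)))),
        nn_conv(F, F * r^2, 3L, s("up")), nn_pshuffle(r), nn_act("lrelu"),
        nn_conv(F, 1L, 3L, s("out"), init_scale = 0.1))
    },
    tcgan = {
      p <- spec$transformer$patch_size
      D <- max(16L, p)  # embedding width
      tb <- lapply(seq_len(spec$transformer$depth), function(i)
        nn_tblock(D, spec$transformer$heads, s("tb", i)))
      transformer <- nn_seq(c(
        list(nn_patchify(p), nn_linear(p^2, D, s("emb")), nn_posenc()),
        tb,
        list(nn_linear(D, p^2, s("dec")), nn_unpatchify(p))))
      list(transformer = transformer, cnn = build_unet(spec))
    },
    stopf("unknown arch '%s'", spec$arch))
}

# small U-Net: one pooling level with a skip connection, pixel-shuffle head
build_unet <- function(spec) {
  s <- function(...) derive_seed(spec$seed, "unet", ...)
  F <- spec$base_channels; r <- spec$scale
  list(enc1 = nn_seq(nn_conv(1L, F, 3L, s("e1")), nn_act("lrelu")),
       enc2 = nn_seq(nn_pool2(), nn_conv(F, 2L * F, 3L, s("e2")), nn_act("lrelu")),
       dec = nn_seq(nn_conv(3L * F, F, 3L, s("d1")), nn_act("lrelu")),
       head = nn_seq(nn_conv(F, r^2, 3L, s("h"), init_scale = 0.1), nn_pshuffle(r)))
}

unet_forward <- function(u, x) {
  f1 <- nn_forward(u$enc1, x)
  f2 <- nn_forward(u$enc2, f1$y)
  up <- nn_forward(nn_up2(), f2$y)
  cat_in <- abind3(f1$y, up$y)
  fd <- nn_forward(u$dec, cat_in)
  fh <- nn_forward(u$head, fd$y)
  list(y = fh$y, cache = list(f1 = f1$cache, f2 = f2$cache, up = up$cache,
                              fd = fd$cache, fh = fh$cache,
                              c1 = dim(f1$y)[3]))
}

unet_backward <- function(u, cache, dy, acc = TRUE) {
  g <- nn_backward(u$head, cache$fh, dy, acc)
  g <- nn_backward(u$dec, cache$fd, g, acc)
  c1 <- cache$c1
  g1 <- g[, , seq_len(c1), drop = FALSE]
  g2 <- g[, , -seq_len(c1), drop = FALSE]
  g2 <- nn_backward(nn_up2(), cache$up, g2, acc)
  g2 <- nn_backward(u$enc2, cache$f2, g2, acc)
  g1 <- nn_backward(u$enc1, cache$f1, g1 + g2, acc)
  g1
}

abind3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}

build_discriminator <- function(spec) {
  s <- function(...) derive_seed(spec$seed, "disc", ...)
  F <- spec$base_channels
  if (spec$arch == "tcgan") {
    # patch-level discriminator: emits a grid of patch scores
    nn_seq(nn_conv(1L, F, 3L, s("c1")), nn_act("lrelu"), nn_pool2(),
           nn_conv(F, 2L * F, 3L, s("c2")), nn_act("lrelu"), nn_pool2(),
           nn_conv(2L * F, 1L, 3L, s("c3")))
  } else {
    nn_seq(nn_conv(1L, F, 3L, s("c1")), nn_act("lrelu"), nn_pool2(),
           nn_conv(F, 2L * F, 3L, s("c2")), nn_act("lrelu"), nn_pool2(),
           nn_gap_linear(2L * F, s("fc")))
  }
}

#' Build a super-resolution model from its spec
#'
#' Constructs the generator (and, for the GAN architectures, the
#' discriminator) with seeded deterministic initialization. TCGAN's generator
#' is the series composition transformer-then-CNN-U-Net; its discriminator is
#' patch-level (scores a grid of overlapping receptive fields rather than a
#' single scalar).
#'
#' @param spec An [sr_model_spec()].
#' @return An object of class `sr_model` with elements `spec`, `generator`,
#'   `discriminator` (GANs only), `trained` flag and `history`.
#' @export
build_model <- function(spec) {
  if (!inherits(spec, "sr_model_spec")) stopf("spec must be an sr_model_spec")
  gen <- build_generator(spec)
  disc <- if (spec$arch %in% c("srgan", "tcgan")) build_discriminator(spec)
  structure(list(spec = spec, generator = gen, discriminator = disc,
                 trained = FALSE, history = NULL,
                 backbone = if (spec$arch %in% c("srgan", "tcgan"))
                   build_perceptual_backbone()),
            class = "sr_model")
}

#' @export
print.sr_model <- function(x, ...) {
  cat(sprintf("sr_model: arch=%s scale=%d base_channels=%d trained=%s\n",
              x$spec$arch, x$spec$scale, x$spec$base_channels, x$trained))
  invisible(x)
}

# generator forward/backward that hides the espcn/srgan vs tcgan difference
generator_forward <- function(model, x, ablate_transformer = FALSE) {
  if (model$spec$arch == "tcgan") {
    if (ablate_transformer) {
      ft <- NULL
      mid <- x
    } else {
      ftf <- nn_forward(model$generator$transformer, x)
      mid <- x + ftf$y          # transformer stage refines on a global skip
      ft <- ftf$cache
    }
    fu <- unet_forward(model$generator$cnn, mid)
    list(y = fu$y, cache = list(ft = ft, fu = fu$cache))
  } else {
    nn_forward(model$generator, x)
  }
}

generator_backward <- function(model, cache, dy, acc = TRUE) {
  if (model$spec$arch == "tcgan") {
    g <- unet_backward(model$generator$cnn, cache$fu, dy, acc)
    if (!is.null(cache$ft))
      g <- g + nn_backward(model$generator$transformer, cache$ft, g, acc)
    g
  } else {
    nn_backward(model$generator, cache, dy, acc)
  }
}

gen_modules <- function(model) {
  if (model$spec$arch == "tcgan")
    c(list(model$generator$transformer), unname(model$generator$cnn))
  else list(model$generator)
}

zero_all <- function(mods) for (m in mods) nn_zero_grads(m)
step_all <- function(mods, lr, t) for (m in mods) nn_adam_step(m, lr = lr, t = t)

as_chw <- function(img) if (is.matrix(img)) array(img, c(dim(img), 1L)) else img

# binary cross-entropy with logits; target in {0, 1}; returns loss and dlogit
bce_logits <- function(z, target) {
  p <- 1 / (1 + exp(-z))
  loss <- mean(ifelse(target == 1, log(pmax(p, 1e-12)), log(pmax(1 - p, 1e-12))))
  list(loss = -loss, dz = (p - target) / length(z))
}

#' Train a super-resolution model
#'
#' ESPCN minimizes mean squared error. SRGAN and TCGAN minimize a weighted sum
#' of adversarial (binary cross-entropy against the discriminator), L1 pixel,
#' and perceptual feature losses, alternating generator and discriminator
#' updates. Per-sample Adam updates; data order is reshuffled each epoch from
#' the spec seed, so training is bit-reproducible.
#'
#' @param model An [build_model()] result.
#' @param pairs List of `list(low = matrix, high = matrix)` aligned pairs with
#'   `dim(high) == scale * dim(low)`.
#' @param epochs Number of passes over the data (>= 1).
#' @return The model with updated weights, `trained = TRUE`, and a `history`
#'   data frame of per-epoch mean losses (class `train_state`).
#' @export
train_sr <- function(model, pairs, epochs = 20L) {
  if (!inherits(model, "sr_model")) stopf("model must be an sr_model")
  if (length(pairs) == 0) stopf("no training pairs supplied")
  if (epochs < 1) stopf("epochs must be >= 1")
  r <- model$spec$scale
  for (p in pairs) {
    if (!all(dim(p$high) == r * dim(p$low)))
      stopf("pair dimensions must satisfy dim(high) = scale * dim(low)")
  }
  spec <- model$spec
  gm <- gen_modules(model)
  is_gan <- spec$arch %in% c("srgan", "tcgan")
  hist <- data.frame(epoch = integer(0), generator_loss = numeric(0),
                     discriminator_loss = numeric(0))
  t_g <- 0L; t_d <- 0L
  for (ep in seq_len(epochs)) {
    ord <- with_seed(derive_seed(spec$seed, "shuffle", ep),
                     sample(length(pairs)))
    gl <- 0; dl <- 0
    for (i in ord) {
      x <- as_chw(pairs[[i]]$low)
      y <- as_chw(pairs[[i]]$high)
      if (!is_gan) {
        fw <- generator_forward(model, x)
        diff <- fw$y - y
        loss <- mean(diff^2)
        zero_all(gm)
        generator_backward(model, fw$cache, 2 * diff / length(diff))
        t_g <- t_g + 1L
        step_all(gm, spec$lr, t_g)
        gl <- gl + loss
      } else {
        lw <- spec$loss_weights
        # --- discriminator step ---
        fw <- generator_forward(model, x)
        fake <- fw$y
        fr <- nn_forward(model$discriminator, y)
        ff <- nn_forward(model$discriminator, fake)
        br <- bce_logits(fr$y, 1)
        bf <- bce_logits(ff$y, 0)
        nn_zero_grads(model$discriminator)
        nn_backward(model$discriminator, fr$cache, br$dz)
        nn_backward(model$discriminator, ff$cache, bf$dz)
        t_d <- t_d + 1L
        nn_adam_step(model$discriminator, lr = spec$lr / 2, t = t_d)
        dl <- dl + br$loss + bf$loss
        # --- generator step (fresh forward through updated D) ---
        fw <- generator_forward(model, x)
        fake <- fw$y
        ff <- nn_forward(model$discriminator, fake)
        badv <- bce_logits(ff$y, 1)
        dz_fake <- nn_backward(model$discriminator, ff$cache, badv$dz, acc = FALSE)
        pix_diff <- fake - y
        pix_loss <- mean(abs(pix_diff))
        d_pix <- sign(pix_diff) / length(pix_diff)
        fb_x <- backbone_features(model$backbone, fake)
        fb_y <- backbone_features(model$backbone, y)
        perc <- backbone_feature_loss_grad(model$backbone, fb_x, fb_y$features,
                                           fb_x$caches)
        g_total <- lw$adversarial * dz_fake + lw$pixel * d_pix +
          lw$perceptual * perc$grad
        zero_all(gm)
        generator_backward(model, fw$cache, g_total)
        t_g <- t_g + 1L
        step_all(gm, spec$lr, t_g)
        gl <- gl + lw$adversarial * badv$loss + lw$pixel * pix_loss +
          lw$perceptual * perc$loss
      }
    }
    hist <- rbind(hist, data.frame(epoch = ep, generator_loss = gl / length(pairs),
                                   discriminator_loss = if (is_gan) dl / length(pairs) else NA_real_))
    if (!all(is.finite(unlist(hist[nrow(hist), 2:3])[!is.na(unlist(hist[nrow(hist), 2:3]))])))
      stopf("training diverged (non-finite loss) at epoch %d", ep)
  }
  model$trained <- TRUE
  model$history <- hist
  class(model$history) <- c("train_state", "data.frame")
  model
}

#' Apply a super-resolution model to a low-field stack
#'
#' Per-slice inference; outputs are clipped to `[0, max_range]` and the result
#' is tagged as synthetic high-field.
#'
#' @param model A trained `sr_model` (untrained models error unless
#'   `strict = FALSE`).
#' @param low A low-field `slice_stack`.
#' @param max_range Upper clip bound (default 1, the phantom convention).
#' @param strict Error on untrained models (default `TRUE`).
#' @param ablate_transformer TCGAN only: bypass the transformer stage
#'   (diagnostic for the series composition).
#' @return A `slice_stack` with dimensions `scale` times the input, tagged
#'   `field_strength = "high"` with attribute `synthetic = TRUE`.
#' @export
apply_sr <- function(model, low, max_range = 1, strict = TRUE,
                     ablate_transformer = FALSE) {
  if (!inherits(model, "sr_model")) stopf("model must be an sr_model")
  if (strict && !model$trained) stopf("model has not been trained (strict mode)")
  out <- lapply(low$slices, function(s) {
    y <- generator_forward(model, as_chw(s), ablate_transformer)$y
    pmin(pmax(matrix(y[, , 1], dim(y)[1], dim(y)[2]), 0), max_range)
  })
  res <- slice_stack(out, low$subject_id, low$pixel_spacing_mm / model$spec$scale,
                     "high", low$vendor, low$repeat_index)
  attr(res, "synthetic") <- TRUE
  res
}
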