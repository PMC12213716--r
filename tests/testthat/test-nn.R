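# The engine's layers are validated against central finite differences; the
# check covers every layer kind used by the three architectures.

num_grad_check <- function(net, x, n_sample = 40, eps = 1e-5) {
  loss_fn <- function() {
    fw <- fieldbridge:::nn_forward(net, x)
    sum(0.5 * fw$y^2)
  }
  fw <- fieldbridge:::nn_forward(net, x)
  fieldbridge:::nn_zero_grads(net)
  dx <- fieldbridge:::nn_backward(net, fw$cache, fw$y)
  v <- fieldbridge:::nn_param_vector(net)
  set.seed(99)
  pick <- sort(sample(length(v), min(n_sample, length(v))))
  num <- numeric(length(pick))
  for (j in seq_along(pick)) {
    i <- pick[j]
    vp <- v; vp[i] <- v[i] + eps
    fieldbridge:::nn_set_param_vector(net, vp); lp <- loss_fn()
    vm <- v; vm[i] <- v[i] - eps
    fieldbridge:::nn_set_param_vector(net, vm); lm <- loss_fn()
    num[j] <- (lp - lm) / (2 * eps)
  }
  fieldbridge:::nn_set_param_vector(net, v)
  ana <- unlist(lapply(fieldbridge:::nn_leaves(net),
                       function(m) lapply(m$grads, as.numeric)), use.names = FALSE)
  list(err = max(abs(ana[pick] - num)),
       rel = max(abs(ana[pick] - num) / (abs(num) + 1e-6)),
       dx = dx, x = x, loss_fn = loss_fn)
}

test_that("convolutional path gradients match finite differences", {
  net <- fieldbridge:::nn_seq(
    fieldbridge:::nn_conv(1, 4, 3, seed = 11),
    fieldbridge:::nn_act("lrelu"),
    fieldbridge:::nn_conv(4, 4, 3, seed = 12),
    fieldbridge:::nn_pshuffle(2),
    fieldbridge:::nn_conv(1, 2, 3, seed = 13),
    fieldbridge:::nn_act("tanh"),
    fieldbridge:::nn_pool2(),
    fieldbridge:::nn_gap_linear(2, seed = 14))
  set.seed(1)
  res <- num_grad_check(net, array(rnorm(64), c(8, 8, 1)))
  expect_lt(res$rel, 1e-5)
})

test_that("transformer path gradients match finite differences", {
  net <- fieldbridge:::nn_seq(
    fieldbridge:::nn_patchify(4),
    fieldbridge:::nn_linear(16, 8, seed = 21),
    fieldbridge:::nn_posenc(),
    fieldbridge:::nn_tblock(8, 2, seed = 22),
    fieldbridge:::nn_linear(8, 16, seed = 23),
    fieldbridge:::nn_unpatchify(4))
  set.seed(2)
  res <- num_grad_check(net, array(rnorm(64), c(8, 8, 1)))
  expect_lt(res$rel, 1e-5)
})

test_that("residual and U-Net containers backpropagate correctly", {
  spec <- sr_model_spec("tcgan", scale = 2, base_channels = 4,
                        transformer = list(patch_size = 4, depth = 1, heads = 2),
                        seed = 5)
  model <- build_model(spec)
  set.seed(3)
  x <- array(abs(rnorm(64, 0.4, 0.2)), c(8, 8, 1))
  gm <- fieldbridge:::gen_modules(model)
  fw <- fieldbridge:::generator_forward(model, x)
  fieldbridge:::zero_all(gm)
  fieldbridge:::generator_backward(model, fw$cache, fw$y)
  vs <- lapply(gm, fieldbridge:::nn_param_vector)
  v <- unlist(vs)
  setv <- function(vv) {
    pos <- 1
    for (i in seq_along(gm)) {
      n <- length(vs[[i]])
      fieldbridge:::nn_set_param_vector(gm[[i]], vv[pos:(pos + n - 1)])
      pos <- pos + n
    }
  }
  loss_fn <- function() sum(0.5 * fieldbridge:::generator_forward(model, x)$y^2)
  set.seed(98); pick <- sort(sample(length(v), 30)); eps <- 1e-5
  num <- numeric(length(pick))
  for (j in seq_along(pick)) {
    i <- pick[j]
    vp <- v; vp[i] <- v[i] + eps; setv(vp); lp <- loss_fn()
    vm <- v; vm[i] <- v[i] - eps; setv(vm); lm <- loss_fn()
    num[j] <- (lp - lm) / (2 * eps)
  }
  setv(v)
  ana <- unlist(lapply(gm, function(m)
    lapply(fieldbridge:::nn_leaves(m), function(l) lapply(l$grads, as.numeric))),
    use.names = FALSE)
  expect_lt(max(abs(ana[pick] - num) / (abs(num) + 1e-6)), 1e-5)
})

test_that("pixel shuffle follows the sub-pixel layout and is bijective", {
  x <- array(c(1, 2, 3, 4), c(1, 1, 4))
  expect_equal(pixel_shuffle(x, 2)[, , 1], matrix(c(1, 3, 2, 4), 2, 2))
  y <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  expect_equal(pixel_unshuffle(pixel_shuffle(y, 2), 2), y)
  expect_equal(pixel_shuffle(y, 1), y)
  expect_error(pixel_shuffle(array(0, c(2, 2, 3)), 2), "divisible")
})
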