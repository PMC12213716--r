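test_that("model builders honour shape contracts and seeded determinism", {
  m <- build_model(sr_model_spec("espcn", scale = 2, base_channels = 8, seed = 3))
  y <- fieldbridge:::generator_forward(m, array(runif(32 * 32), c(32, 32, 1)))$y
  expect_equal(dim(y), c(64, 64, 1))

  m1 <- build_model(sr_model_spec("srgan", seed = 4))
  m2 <- build_model(sr_model_spec("srgan", seed = 4))
  expect_identical(fieldbridge:::nn_param_vector(m1$generator),
                   fieldbridge:::nn_param_vector(m2$generator))
  m3 <- build_model(sr_model_spec("srgan", seed = 5))
  expect_false(identical(fieldbridge:::nn_param_vector(m1$generator),
                         fieldbridge:::nn_param_vector(m3$generator)))
  expect_error(sr_model_spec("vdsr"), "arg")
})

test_that("the TCGAN discriminator scores patches, not a scalar", {
  m <- build_model(sr_model_spec("tcgan", scale = 1, base_channels = 8, seed = 9))
  d <- fieldbridge:::nn_forward(m$discriminator, array(runif(64 * 64), c(64, 64, 1)))
  expect_equal(dim(d$y), c(16, 16, 1))   # a grid of patch scores
  ms <- build_model(sr_model_spec("srgan", base_channels = 8, seed = 9))
  ds <- fieldbridge:::nn_forward(ms$discriminator, array(runif(32 * 32), c(32, 32, 1)))
  expect_length(ds$y, 1)                 # SRGAN: one scalar logit
})

test_that("ESPCN training reduces the MSE loss and is reproducible", {
  dat <- make_sr_dataset(7, 4)
  spec <- sr_model_spec("espcn", scale = 2, base_channels = 8, seed = 7)
  m <- train_sr(build_model(spec), dat$pairs, epochs = 8)
  expect_true(m$trained)
  expect_lt(tail(m$history$generator_loss, 1), m$history$generator_loss[1])
  m2 <- train_sr(build_model(spec), dat$pairs, epochs = 8)
  expect_equal(tail(m2$history$generator_loss, 1),
               tail(m$history$generator_loss, 1), tolerance = 1e-6)
  expect_error(train_sr(build_model(spec), list()), "pairs")
  bad <- list(list(low = matrix(0, 8, 8), high = matrix(0, 15, 15)))
  expect_error(train_sr(build_model(spec), bad), "dimensions")
})

test_that("scale-1 restoration fits the identity mapping on clean pairs", {
  imgs <- lapply(1:6, function(i)
    make_high_field_subject(sprintf("I%d", i), 1, 32, "A", i)$slices[[1]])
  pairs <- lapply(imgs, function(im) list(low = im, high = im))
  spec <- sr_model_spec("espcn", scale = 1, base_channels = 8, lr = 5e-3, seed = 2)
  m <- train_sr(build_model(spec), pairs, epochs = 60)
  out <- fieldbridge:::generator_forward(m, fieldbridge:::as_chw(imgs[[1]]))$y
  expect_lt(mean((out[, , 1] - imgs[[1]])^2), 1e-3)
})

test_that("GAN training keeps finite losses and trains both networks", {
  dat <- make_sr_dataset(11, 2)
  for (arch in c("srgan", "tcgan")) {
    spec <- sr_model_spec(arch, scale = 2, base_channels = 8,
                          n_residual_blocks = 2,
                          transformer = list(patch_size = 8, depth = 1, heads = 2),
                          seed = 9)
    m0 <- build_model(spec)
    w0 <- fieldbridge:::nn_param_vector(
      if (arch == "tcgan") m0$generator$transformer else m0$generator)
    m <- train_sr(m0, dat$pairs[1:4], epochs = 3)
    expect_true(all(is.finite(m$history$generator_loss)))
    expect_true(all(is.finite(m$history$discriminator_loss)))
    w1 <- fieldbridge:::nn_param_vector(
      if (arch == "tcgan") m$generator$transformer else m$generator)
    expect_false(identical(w0, w1))  # generator actually updated
  }
})

test_that("TCGAN transformer stage is live: ablation changes the output", {
  spec <- sr_model_spec("tcgan", scale = 2, base_channels = 4,
                        transformer = list(patch_size = 4, depth = 1, heads = 2),
                        seed = 5)
  m <- build_model(spec)
  x <- fieldbridge:::as_chw(make_high_field_subject("a", 1, 32, "A", 1)$slices[[1]])
  full <- fieldbridge:::generator_forward(m, x)$y
  ablated <- fieldbridge:::generator_forward(m, x, ablate_transformer = TRUE)$y
  expect_gt(max(abs(full - ablated)), 0)
})

test_that("inference is deterministic, clipped, and shape-correct", {
  dat <- make_sr_dataset(13, 2)
  spec <- sr_model_spec("espcn", scale = 2, base_channels = 8, seed = 3)
  m <- train_sr(build_model(spec), dat$pairs[1:4], epochs = 2)
  lds <- slice_stack(lapply(dat$stacks[[1]]$low$slices, downsample_block,
                            factor = 2), "t", c(2, 2), "low", "A")
  o1 <- apply_sr(m, lds)
  o2 <- apply_sr(m, lds)
  expect_identical(o1$slices, o2$slices)
  expect_equal(dim(o1$slices[[1]]), 2L * dim(lds$slices[[1]]))
  expect_true(all(unlist(o1$slices) >= 0 & unlist(o1$slices) <= 1))
  expect_equal(o1$field_strength, "high")
  expect_true(attr(o1, "synthetic"))
  expect_error(apply_sr(build_model(spec), lds), "trained")
})
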