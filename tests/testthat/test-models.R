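test_that("denoiser initialisation is seed-deterministic", {
  spec <- denoiser_spec_2d(base_width = 8, depth = 1,
                           attention_levels = integer(0),
                           time_embedding_dim = 16)
  m1 <- build_denoiser(spec, seed = 5)
  m2 <- build_denoiser(spec, seed = 5)
  expect_identical(m1$params, m2$params)
  m3 <- build_denoiser(spec, seed = 6)
  expect_false(identical(m1$params, m3$params))
})

test_that("receptive depth drives the divisibility contract", {
  expect_equal(count_receptive_depth(denoiser_spec_3d()), 3)
  expect_equal(count_receptive_depth(denoiser_spec_3d(depth = 4)), 4)
  expect_equal(count_receptive_depth(denoiser_spec_2d(depth = 0)), 0)
  spec4 <- denoiser_spec_3d(base_width = 4, depth = 4,
                            time_embedding_dim = 8)
  m4 <- build_denoiser(spec4, seed = 1)
  x <- array(0, c(32, 32, 16))
  r <- array(0.5, c(32, 32, 16, 3))
  expect_silent(m4$fn(x, x, 10, ramps = r))        # divisible by 16
  x8 <- array(0, c(40, 32, 16))
  expect_error(build_denoiser(spec4, 1)$fn(x8, x8, 10,
                                           ramps = array(0, c(40, 32, 16, 3))),
               "divisible by 16")
  # depth-0 degenerate spec accepts any size
  spec0 <- denoiser_spec_2d(base_width = 4, depth = 0,
                            attention_levels = integer(0),
                            time_embedding_dim = 8)
  m0 <- build_denoiser(spec0, seed = 1)
  expect_silent(m0$fn(matrix(0, 7, 13), matrix(0, 7, 13), 3))
})

test_that("3D denoiser is shape-preserving and size-agnostic in parameters", {
  spec <- denoiser_spec_3d(base_width = 4, depth = 3, time_embedding_dim = 8)
  m <- build_denoiser(spec, seed = 2)
  x1 <- array(rnorm(40 * 48 * 32), c(40, 48, 32))
  r1 <- array(runif(40 * 48 * 32 * 3), c(40, 48, 32, 3))
  y1 <- m$fn(x1, x1, 7, ramps = r1)
  expect_identical(dim(y1), dim(x1))
  x2 <- array(0, c(41, 48, 32))
  expect_error(m$fn(x2, x2, 7, ramps = array(0, c(41, 48, 32, 3))),
               "axis 1")
  # parameter count does not depend on the input size
  n1 <- n_parameters(m)
  invisible(m$fn(array(0, c(16, 16, 8)), array(0, c(16, 16, 8)), 3,
                 ramps = array(0, c(16, 16, 8, 3))))
  expect_identical(n_parameters(m), n1)
})

test_that("gradients match finite differences on both architectures", {
  set.seed(1)
  spec2 <- denoiser_spec_2d(base_width = 4, depth = 2, attention_levels = 3,
                            time_embedding_dim = 8)
  w2 <- grad_check_worst(spec2, array(rnorm(128), c(8, 8, 2)),
                         array(rnorm(128), c(8, 8, 2)), c(5, 700),
                         paths = list(list("stem", "W"),
                                      list("enc", 1L, "conv1", "W"),
                                      list("enc", 3L, "gn2", "gamma"),
                                      list("attn", 3L, "Wq"),
                                      list("dec", 1L, "conv2", "W"),
                                      list("temb", "mlp1", "W")))
  expect_lt(w2, 1e-5)
  spec3 <- denoiser_spec_3d(base_width = 4, depth = 1, time_embedding_dim = 8)
  w3 <- grad_check_worst(spec3, array(rnorm(128), c(8, 4, 4)),
                         array(rnorm(128), c(8, 4, 4)), 50,
                         ramps = array(runif(384), c(8, 4, 4, 3)),
                         paths = list(list("stem", "W"),
                                      list("enc", 2L, "conv1", "W"),
                                      list("dec", 1L, "reduce", "W"),
                                      list("temb", "mlp2", "W")))
  expect_lt(w3, 1e-5)
})

test_that("3D network is translation-equivariant away from borders", {
  spec <- denoiser_spec_3d(base_width = 4, depth = 3, time_embedding_dim = 8)
  m <- build_denoiser(spec, seed = 3)
  m$params$out$W <- array(rnorm(length(m$params$out$W), 0, 0.2),
                          dim(m$params$out$W))
  d <- c(48, 24, 16)
  x <- array(0, d); x[20, 12, 8] <- 1        # delta impulse
  xs <- array(0, d); xs[28, 12, 8] <- 1      # shifted by 8 along axis 1
  ramps <- array(0.5, c(d, 3))               # constant: no positional cue
  cond <- array(0, d)
  y <- m$fn(x, cond, 5, ramps = ramps)
  ys <- m$fn(xs, cond, 5, ramps = ramps)
  # compare interior windows around the impulse responses
  win <- function(a, c0) a[(c0 - 6):(c0 + 6), 6:18, 4:12]
  expect_equal(win(ys, 28), win(y, 20), tolerance = 1e-8)
})

test_that("training on the phantom oracle reduces the loss (smoke)", {
  cs <- normalized_phantom(seed = 41)
  recs <- make_2d_dataset(list(cs), crop_size = 16, mode = "train", seed = 1)
  spec <- denoiser_spec_2d(base_width = 8, depth = 1,
                           attention_levels = integer(0),
                           time_embedding_dim = 16)
  fit <- train_translator(recs, spec, make_schedule(), mode = "image",
                          steps = 150, lr = 1e-3, batch_size = 4, seed = 2,
                          cond_dropout_p = 0)
  expect_lt(mean(utils::tail(fit$losses, 30)),
            mean(utils::head(fit$losses, 30)))
  expect_s3_class(fit, "ddim_translator")
  expect_output(print(fit), "ddim_translator")
  expect_output(print(summary(fit)), "training loss")
  # predict returns an in-range image of the right shape
  out <- predict(fit, recs[[1]]$mr,
                 sampler_config(mode = "image", n_steps = 5, seed = 1))
  expect_identical(dim(out), dim(recs[[1]]$mr))
  expect_true(all(out >= -1 & out <= 1))
  # simulate draws differ across seeds under eta = 1
  sims <- simulate(fit, nsim = 2, seed = 7, newdata = recs[[1]]$mr)
  expect_false(identical(sims[[1]], sims[[2]]))
  # mode mismatch between checkpoint and sampler is a contract error
  expect_error(predict(fit, recs[[1]]$mr, sampler_config(mode = "noise")),
               "mode")
})
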