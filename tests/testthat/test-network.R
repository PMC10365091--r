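tiny_cfg <- function(...) {
  encoder_config("tiny", input_size = 64, grid_size = 4, n_classes = 3,
                 stage_channels = c(4, 6, 8, 8), head_channels = 8,
                 decoder_channels = c(6, 6), ...)
}

test_that("encoder output shapes and determinism follow the configuration", {
  set.seed(20)
  model <- build_model(tiny_cfg())
  x <- array(0, c(64, 64, 1, 2))
  out <- model_forward(model, x)
  expect_equal(dim(out$grid_logits), c(4, 4, 3, 2))
  expect_equal(dim(out$decoder_logits), c(32, 32, 3, 2))
  expect_true(all(is.finite(out$grid_logits)))
  expect_true(all(out$spatial_activation > 0 & out$spatial_activation < 1))

  # seed-controlled initialization reproduces outputs exactly
  set.seed(20)
  model2 <- build_model(tiny_cfg())
  out2 <- model_forward(model2, x)
  expect_identical(out$grid_logits, out2$grid_logits)

  expect_error(model_forward(model, array(0, c(32, 32, 1, 1))),
               "letterbox")
})

test_that("multi-resolution taps change the head input by the branch channels", {
  m_on <- build_model(tiny_cfg(multi_resolution = TRUE))
  m_off <- build_model(tiny_cfg(multi_resolution = FALSE))
  ch_on <- dim(m_on$head[[1]]$w)[3]
  ch_off <- dim(m_off$head[[1]]$w)[3]
  expect_equal(ch_on - ch_off, 4 + 6 + 8)  # non-final stage channels
  # both run
  x <- array(rnorm(64 * 64), c(64, 64, 1, 1))
  expect_equal(dim(model_forward(m_off, x)$grid_logits), c(4, 4, 3, 1))
})

test_that("the default test backbone stays under 500k parameters", {
  model <- build_model(encoder_config("tiny"))  # 512-px, 32-grid, 10 classes
  expect_lt(n_params(model), 5e5)
})

test_that("the decoder upscales 8x to per-label maps and trains the encoder", {
  set.seed(21)
  cfg <- encoder_config("tiny", input_size = 64, grid_size = 4,
                        n_classes = 10, stage_channels = c(4, 6, 8, 8),
                        head_channels = 8, decoder_channels = c(6, 6))
  model <- build_model(cfg)
  x <- array(rnorm(64 * 64 * 2), c(64, 64, 1, 2))
  fwd <- model_forward(model, x, train = TRUE)
  expect_equal(dim(fwd$decoder_logits), c(32, 32, 10, 2))

  # gradient from the decoder loss alone reaches encoder parameters
  t <- array((runif(32 * 32 * 10 * 2) > 0.5) * 1, c(32, 32, 10, 2))
  st <- matrix("annotated_positive", 10, 2)
  mt <- mtl_loss(fwd$decoder_logits, t, st, want_grad = TRUE)
  grads <- model_backward(fwd$model, fwd, fwd$grid_logits * 0, mt$dlogits)
  flat <- model_grads(fwd$model, grads)
  expect_gt(max(abs(flat[["stage1.1.w"]])), 0)
  expect_gt(max(abs(flat[["head.1.w"]])), 0)
  # and the classifier head receives none from the decoder path
  expect_equal(max(abs(flat[["classifier.1.w"]])), 0)
})

test_that("encode and decode match the fused forward pass", {
  set.seed(24)
  model <- build_model(tiny_cfg())
  x <- array(rnorm(64 * 64 * 2), c(64, 64, 1, 2))
  enc <- encode(model, x)
  fwd <- model_forward(model, x)
  expect_identical(enc$grid_logits, fwd$grid_logits)
  expect_identical(decode(model, enc$features), fwd$decoder_logits)
  expect_error(decode(model, array(0, c(2, 2, 3, 1))), "configuration")
})

test_that("checkpoints reload bit-identically", {
  set.seed(22)
  model <- build_model(tiny_cfg())
  # give running stats some structure
  x <- array(rnorm(64 * 64 * 2), c(64, 64, 1, 2))
  model <- model_forward(model, x, train = TRUE)$model
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(model, f)
  back <- load_model(f)
  y1 <- model_forward(model, x)$grid_logits
  y2 <- model_forward(back, x)$grid_logits
  expect_identical(y1, y2)
  saveRDS(list(a = 1), f)
  expect_error(load_model(f), "checkpoint")
})

test_that("the residual-bottleneck backbone builds and runs", {
  set.seed(23)
  cfg <- encoder_config("resnet50_shaped", input_size = 128, grid_size = 32,
                        n_classes = 3,
                        stage_channels = c(16, 24, 32, 40),
                        head_channels = 16, decoder_channels = c(8, 8))
  model <- build_model(cfg)
  x <- array(rnorm(128 * 128), c(128, 128, 1, 1))
  out <- model_forward(model, x, with_decoder = FALSE)
  expect_equal(dim(out$grid_logits), c(32, 32, 3, 1))
  expect_true(all(is.finite(out$grid_logits)))
})

test_that("the AMSGrad step reduces a simple quadratic objective", {
  opt <- amsgrad(lr = 0.1, weight_decay = 0)
  params <- list(w = c(3, -2))
  for (i in 1:200) {
    g <- list(w = 2 * params$w)
    st <- amsgrad_step(opt, params, g)
    params <- st$params
    opt <- st$opt
  }
  expect_lt(sum(params$w^2), 1e-3)
})

test_that("configuration invariants are enforced", {
  expect_error(encoder_config("tiny", input_size = 500, grid_size = 32),
               "divide")
  expect_error(encoder_config("tiny", input_size = 96, grid_size = 32),
               "power of 2")
})
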