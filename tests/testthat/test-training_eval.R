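test_that("augmentation applies one geometric transform to image and maps", {
  set.seed(30)
  img <- matrix(runif(64 * 64), 64)
  msk <- matrix(0, 64, 64)
  msk[20:30, 25:35] <- 1

  # zero-range draw is the identity
  a <- augment_pair(img, list(m = msk),
                    aug = list(rotate = 0, translate = 0, scale = 0))
  expect_equal(a$image, img, tolerance = 1e-12)
  expect_equal(a$maps$m, msk)

  # a pure translation moves the annotation centroid by the same offset
  fwd <- diag(3)
  fwd[1, 3] <- 5; fwd[2, 3] <- -3
  wm <- gazemil:::warp_affine(msk, fwd)
  centroid <- function(m) {
    c(x = sum(col(m) * m) / sum(m), y = sum(row(m) * m) / sum(m))
  }
  expect_equal(centroid(wm), centroid(msk) + c(x = 5, y = -3),
               tolerance = 0.05)

  # rotations preserve annotation area within interpolation tolerance
  for (i in 1:5) {
    a <- augment_pair(img, list(m = msk),
                      aug = list(rotate = 45, translate = 0, scale = 0))
    expect_equal(sum(a$maps$m), sum(msk), tolerance = 0.1)
    expect_true(all(a$maps$m %in% c(0, 1)))
  }
})

test_that("AUC evaluation handles perfect, random and degenerate labels", {
  y <- matrix(c(rep(1, 100), rep(0, 100)), ncol = 1)
  s <- matrix(c(runif(100, 0.6, 1), runif(100, 0, 0.4)), ncol = 1)
  expect_equal(evaluate_auc(s, y), 1.0)

  set.seed(31)
  s2 <- matrix(runif(200), ncol = 1)
  expect_lt(abs(evaluate_auc(s2, y) - 0.5), 0.1)

  y1 <- matrix(rep(1, 50), ncol = 1)
  expect_true(is.na(evaluate_auc(matrix(runif(50), ncol = 1), y1)))
})

test_that("IoU evaluation binarizes, upsamples and averages per positive pair", {
  mask <- matrix(0, 8, 8)
  mask[1:2, 1:2] <- 1
  mask[5, 5] <- 1
  hm <- array(0, c(8, 8, 1))
  hm[1:2, 1:2, 1] <- 0.9
  hm[8, 8, 1] <- 0.9
  cases <- list(list(id = "a", labels = c(X = TRUE), masks = list(X = mask)))
  # intersection 4, union 4 + 1 + 1
  r <- evaluate_iou(list(hm), cases, 0.5, labels = "X")
  expect_equal(r$mean, 4 / 6)

  r1 <- evaluate_iou(list(array(mask, c(8, 8, 1))), cases, 0.5, "X")
  expect_equal(r1$mean, 1.0)
  r0 <- evaluate_iou(list(array(0, c(8, 8, 1))), cases, 0.5, "X")
  expect_equal(r0$mean, 0.0)

  # a low-resolution heatmap is upscaled with nearest neighbour
  small <- array(0, c(2, 2, 1))
  small[1, 1, 1] <- 1
  r2 <- evaluate_iou(list(small), cases, 0.5, "X")
  # upscaled quadrant (rows 1:4, cols 1:4) vs mask of 5 px: int 4, union 17
  expect_equal(r2$mean, 4 / 17)
})

test_that("threshold selection maximizes mean validation IoU with low-tie rule", {
  mask <- matrix(0, 10, 10)
  mask[3:6, 3:6] <- 1
  hm <- array(0.3, c(10, 10, 1))
  hm[3:6, 3:6, 1] <- 0.7
  cases <- list(list(id = "a", labels = c(X = TRUE), masks = list(X = mask)))
  th <- select_threshold(list(list(hm)), cases, seq(0.05, 0.95, 0.05), "X")
  # every threshold in [0.30, 0.65] is perfect; the lowest is returned
  expect_equal(unname(th["X"]), 0.30)

  th1 <- select_threshold(list(list(hm)), cases, 0.5, "X")
  expect_equal(unname(th1["X"]), 0.5)
  expect_error(select_threshold(list(list(hm)), cases, numeric(0), "X"),
               "threshold")
})

test_that("heatmap source selection prefers the better IoU, ties to spatial", {
  expect_equal(select_heatmap_source(c(decoder = 0.4, spatial = 0.2)),
               "decoder")
  expect_equal(select_heatmap_source(c(decoder = 0.2, spatial = 0.4)),
               "spatial")
  expect_equal(select_heatmap_source(c(decoder = 0.3, spatial = 0.3)),
               "spatial")
})

test_that("training runs end-to-end and the loss decreases", {
  set.seed(32)
  params <- sim_params(image_size = 64, prevalence = 0.3)
  ds <- simulate_dataset(params, n_train = 10, n_val = 4, n_test = 2,
                         seed = 33)
  config <- train_config(epochs = 2, input_size = 64, grid_size = 4,
                         seeds = 1, batch_size = 5)
  drops <- 0
  for (s in 1:3) {
    rec <- prepare_training_data(ds$train, "et", config)
    fit <- train_model(rec, ds$val, config, seed = s)
    expect_s3_class(fit, "gazemil_fit")
    expect_equal(nrow(fit$log), 2)
    if (fit$log$train_loss[2] < fit$log$train_loss[1]) drops <- drops + 1
  }
  expect_gte(drops, 2)
  expect_error(train_model(list(), ds$val, config), "empty training set")
})

test_that("ellipse supervision flows through the identical annotation path", {
  set.seed(34)
  params <- sim_params(image_size = 64, prevalence = 0.4)
  cs <- simulate_case(params, "e1")
  config <- train_config(input_size = 64, grid_size = 4)
  rec <- prepare_training_data(list(cs), "ellipse", config)[[1]]
  expect_setequal(names(rec$maps), names(cs$masks))
  for (lab in names(rec$maps)) {
    expect_identical(rec$maps[[lab]], cs$masks[[lab]])
  }
  st <- gazemil:::record_status(rec, config$labels)
  expect_true(all(st[rec$labels & config$labels %in% names(rec$maps)] ==
                    "annotated_positive"))

  # unannotated preparation strips localization entirely
  rec_u <- prepare_training_data(list(cs), "unannotated", config)[[1]]
  expect_null(rec_u$maps)
  st_u <- gazemil:::record_status(rec_u, config$labels)
  expect_true(all(st_u %in% c("unannotated_positive",
                              "unannotated_negative")))
})

test_that("a lambda_T of zero disables the decoder during training", {
  set.seed(35)
  params <- sim_params(image_size = 64, prevalence = 0.4)
  ds <- simulate_dataset(params, n_train = 6, n_val = 2, n_test = 2,
                         seed = 36)
  config <- train_config(epochs = 1, input_size = 64, grid_size = 4,
                         seeds = 1, batch_size = 6, lambda_T = 0)
  rec <- prepare_training_data(ds$train, "et", config)
  fit <- train_model(rec, list(), config, seed = 1)
  # decoder parameters never moved from their initialization
  set.seed(1)  # train_model used with_seed(1) for init
  init <- with_seed(1, build_model(gazemil:::config_encoder(config)))
  expect_identical(model_params(fit$model)[["decoder.2.w"]],
                   model_params(init)[["decoder.2.w"]])
})

test_that("the ablation harness toggles components and reports IoU rows", {
  set.seed(37)
  params <- sim_params(image_size = 64, prevalence = 0.4)
  ds <- simulate_dataset(params, n_train = 8, n_val = 3, n_test = 3,
                         seed = 38)
  config <- train_config(epochs = 1, input_size = 64, grid_size = 4,
                         seeds = 1, batch_size = 8)
  combos <- data.frame(lsh = c(TRUE, FALSE), brn = c(TRUE, FALSE),
                       mra = c(TRUE, FALSE), mtl = c(TRUE, FALSE))
  tab <- ablation_suite(ds, config, combos, seeds = 1)
  expect_equal(nrow(tab), 2)
  expect_true(all(is.finite(tab$test_iou)))
  expect_true(all(tab$test_iou >= 0 & tab$test_iou <= 1))
})
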