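test_that("letterboxing scales the long side and pads the short side", {
  m <- matrix(runif(768 * 1024), nrow = 768, ncol = 1024)  # 1024 wide
  lb <- letterbox(m, 512)
  expect_equal(dim(lb$image), c(512, 512))
  expect_equal(lb$transform$scale, 0.5)
  expect_equal(lb$transform$pad_y, 64)
  expect_equal(lb$transform$pad_x, 0)
  # padding bands are black
  expect_equal(max(abs(lb$image[1:64, ])), 0)
  expect_equal(max(abs(lb$image[449:512, ])), 0)

  sq <- matrix(runif(256^2), 256)
  lb2 <- letterbox(sq, 512)
  expect_equal(lb2$transform$pad_x + lb2$transform$pad_y, 0)

  expect_error(letterbox(matrix(numeric(0), 0, 0)), "dimensions")
})

test_that("point coordinates map through the letterbox transform", {
  m <- matrix(0, nrow = 768, ncol = 1024)
  tf <- letterbox(m, 512)$transform
  p <- letterbox_points(data.frame(x = 1023, y = 0), tf)
  expect_equal(round(p$x), 511)
  expect_equal(round(p$y), tf$pad_y)
})

test_that("grid annotation is a thresholded block maximum", {
  u <- matrix(0.2, 512, 512)
  ga <- to_grid(u, threshold = 0.15, grid = c(32, 32))
  expect_equal(length(ga$positive_cells), 1024)

  expect_length(to_grid(matrix(0, 512, 512))$positive_cells, 0)

  z <- matrix(0, 512, 512)
  z[200, 300] <- 0.16
  ga1 <- to_grid(z)
  expect_length(ga1$positive_cells, 1)
  # pixel (200, 300) sits in cell (ceiling(200/16), ceiling(300/16))
  expect_equal(ga1$positive_cells,
               which(row(matrix(0, 32, 32)) == ceiling(200 / 16) &
                       col(matrix(0, 32, 32)) == ceiling(300 / 16)))

  expect_error(to_grid(matrix(0, 100, 100), grid = c(32, 32)), "divide")
})

test_that("decoder targets use the same block-max path", {
  u <- matrix(0.2, 512, 512)
  expect_true(all(to_decoder_target(u) == 1))

  cb <- matrix(0, 8, 8)
  cb[, seq(1, 8, 2)] <- 0.5   # alternating 2-wide? no: alternating columns
  tg <- to_decoder_target(cb, threshold = 0.15, size = c(4, 4))
  # each 2x2 block contains one above-threshold column
  expect_true(all(tg == 1))
  tg2 <- to_decoder_target(cb, threshold = 0.6, size = c(4, 4))
  expect_true(all(tg2 == 0))

  # max-pooled masks never lose a contained positive pixel's cell
  msk <- matrix(0, 64, 64)
  msk[20:30, 40:50] <- 1
  dt <- to_decoder_target(msk, size = c(32, 32))
  expect_true(all(dt[cbind(ceiling((20:30) / 2), ceiling((40:50) / 2))] == 1))
})

test_that("thresholding commutes with max-pooling", {
  set.seed(5)
  for (i in 1:20) {
    m <- matrix(runif(64 * 64), 64)
    th <- runif(1, 0.1, 0.9)
    a <- to_grid(m, th, c(8, 8))$cells
    pooled <- gazemil:::block_max(m, 8, 8)
    b <- (pooled > th) * 1
    expect_identical(a, b)
  }
})

test_that("raising the threshold never adds positive cells", {
  set.seed(6)
  m <- matrix(runif(64 * 64), 64)
  prev <- to_grid(m, 0.1, c(8, 8))$positive_cells
  for (th in c(0.3, 0.5, 0.7, 0.9)) {
    cur <- to_grid(m, th, c(8, 8))$positive_cells
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("grid annotations serialize losslessly through RLE JSON", {
  set.seed(7)
  ann <- list(
    Edema = to_grid(matrix(runif(64^2), 64), 0.8, c(8, 8), "Edema"),
    Opacity = to_grid(matrix(runif(64^2), 64), 0.9, c(8, 8), "Opacity"))
  f <- withr::local_tempfile(fileext = ".json")
  write_grid_annotations(ann, f)
  back <- read_grid_annotations(f)
  expect_equal(back$Edema$cells, ann$Edema$cells)
  expect_equal(back$Opacity$positive_cells, ann$Opacity$positive_cells)
})
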