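# direct-product reference implementations (no log-space), used as oracles
oracle_ck <- function(gamma_k, spec) {
  J <- length(gamma_k)
  1 - prod(normalize_factor(1 - plogis(gamma_k), J, spec))
}
oracle_ann <- function(gamma_k, t, spec) {
  J <- length(gamma_k)
  s <- plogis(gamma_k)
  -log(prod(normalize_factor(s[t], J, spec)) *
         prod(normalize_factor(1 - s[!t], J, spec)))
}

test_that("the balanced factor floor matches its closed form", {
  expect_equal(factor_floor(256, norm_spec()), 0.98, tolerance = 1e-5)
  expect_equal(normalize_factor(1, 7, norm_spec()), 1)
  expect_equal(normalize_factor(0, 1, norm_spec()), 0.0056738)
  expect_equal(factor_floor(10, norm_spec("fixed_098")), 0.98)
  expect_equal(normalize_factor(0.3, 99, norm_spec("none")), 0.3)
  expect_error(factor_floor(0, norm_spec()), "nt")
  expect_error(norm_spec(base = 1.2), "base")
})

test_that("the product of floor-valued factors equals the base for any grid", {
  for (J in c(1, 4, 64, 256, 1024)) {
    lo <- factor_floor(J, norm_spec())
    expect_equal(lo^J, 0.0056738, tolerance = 1e-9)
  }
})

test_that("the soft-OR image probability matches its direct product", {
  expect_equal(image_probability(rep(-50, 9), norm_spec("none")), 0)
  expect_equal(image_probability(0, norm_spec("none")), 0.5)
  set.seed(8)
  for (spec in list(norm_spec("balanced"), norm_spec("fixed_098"),
                    norm_spec("none"))) {
    g <- matrix(rnorm(9 * 3, sd = 2), 9, 3)
    expect_equal(image_probability(g, spec),
                 apply(g, 2, oracle_ck, spec = spec), tolerance = 1e-10)
  }
})

test_that("annotated and unannotated losses match closed forms", {
  none <- norm_spec("none")
  # perfect prediction drives the annotated loss to zero
  g <- c(50, -50, -50, -50)
  expect_equal(loss_annotated(g, 1, none), 0, tolerance = 1e-12)
  # sigma = 0.5 on a 2x2 grid with |B| = 1: loss = 4 log 2
  expect_equal(loss_annotated(rep(0, 4), 2, none), 4 * log(2))
  # balanced floors bound the loss by -log(base)
  set.seed(9)
  for (i in 1:10) {
    g <- rnorm(16, sd = 50)
    l <- loss_annotated(g, sample(16, 4), norm_spec())
    expect_lte(l, -log(0.0056738) + 1e-9)
  }
  expect_equal(loss_unannotated_positive(c(50, -50), none), 0,
               tolerance = 1e-12)
  expect_equal(loss_unannotated_negative(rep(-50, 4), none), 0,
               tolerance = 1e-12)
})

test_that("batch MIL loss reproduces a hand-worked two-image example", {
  spec <- norm_spec("none")
  w <- loss_weights(lambda_A = 3, lambda_T = 0)
  # image 1: annotated, class 1 with B = {1}, class 2 negative annotated
  # image 2: unannotated, class 1 positive, class 2 negative
  g1 <- matrix(c(2, -1, 0.5, -0.5), 2, 2)
  g2 <- matrix(c(1, 1, -2, -1), 2, 2)
  batch <- list(
    list(gamma = g1, status = c("annotated_positive", "annotated_negative"),
         B = list(1L, integer(0))),
    list(gamma = g2, status = c("unannotated_positive",
                                "unannotated_negative"), B = list(NULL, NULL)))
  hand <- (3 * oracle_ann(g1[, 1], c(TRUE, FALSE), spec) +
             3 * oracle_ann(g1[, 2], c(FALSE, FALSE), spec) +
             -log(oracle_ck(g2[, 1], spec)) +
             oracle_ann(g2[, 2], c(FALSE, FALSE), spec)) / 4
  expect_equal(mil_loss(batch, w, spec), hand, tolerance = 1e-12)

  # lambda_A = 0 removes the annotated contribution entirely
  w0 <- loss_weights(lambda_A = 0, lambda_T = 0)
  hand0 <- (-log(oracle_ck(g2[, 1], spec)) +
              oracle_ann(g2[, 2], c(FALSE, FALSE), spec)) / 4
  expect_equal(mil_loss(batch, w0, spec), hand0, tolerance = 1e-12)

  # an all-confident-negative unannotated-negative image costs nothing
  batch1 <- list(list(gamma = matrix(-50, 4, 1),
                      status = "unannotated_negative", B = list(NULL)))
  expect_equal(mil_loss(batch1, w, spec), 0, tolerance = 1e-12)
})

test_that("MIL gradients match finite differences", {
  set.seed(10)
  J <- 9; K <- 2; N <- 3
  gamma <- array(rnorm(J * K * N), c(J, K, N))
  status <- matrix(sample(annotation_statuses(), K * N, TRUE), K, N)
  targets <- array(runif(J * K * N) > 0.6, c(J, K, N))
  for (spec in list(norm_spec("balanced"), norm_spec("none"))) {
    r <- mil_loss_grad(gamma, status, targets, loss_weights(3, 0), spec)
    for (i in sample(length(gamma), 8)) {
      eps <- 1e-6
      gp <- gamma; gp[i] <- gp[i] + eps
      gm <- gamma; gm[i] <- gm[i] - eps
      num <- (mil_loss_grad(gp, status, targets, loss_weights(3, 0), spec,
                            want_grad = FALSE)$loss -
                mil_loss_grad(gm, status, targets, loss_weights(3, 0), spec,
                              want_grad = FALSE)$loss) / (2 * eps)
      expect_equal(r$dgamma[i], num, tolerance = 1e-4)
    }
  }
})

test_that("the soft-OR probability is strictly increasing in every logit", {
  set.seed(11)
  g <- rnorm(9)
  base <- image_probability(g, norm_spec())
  for (i in seq_along(g)) {
    g2 <- g
    g2[i] <- g2[i] + 1e-3
    expect_gt(image_probability(g2, norm_spec()), base)
  }
})

test_that("the multi-task loss is a masked per-pixel cross-entropy", {
  K <- 2
  t <- array(0, c(4, 4, K, 1))
  t[, , 1, 1] <- matrix(rep(c(1, 0), each = 8), 4)
  z <- array(0, c(4, 4, K, 1))
  z[, , 1, 1] <- ifelse(t[, , 1, 1] == 1, 50, -50)
  status <- matrix(c("annotated_positive", "annotated_negative"), K, 1)
  expect_equal(mtl_loss(z, t, status)$loss, 0, tolerance = 1e-12)

  # sigma = 0.5 everywhere: log 2 per annotated-positive channel
  z0 <- array(0, c(4, 4, K, 1))
  expect_equal(mtl_loss(z0, t, status)$loss, log(2) / K)

  # no annotated-positive channels: zero loss and zero gradient
  st2 <- matrix("unannotated_positive", K, 1)
  r <- mtl_loss(z0, t, st2, want_grad = TRUE)
  expect_equal(r$loss, 0)
  expect_equal(max(abs(r$dlogits)), 0)

  expect_error(mtl_loss(z0, t[, 1:2, , , drop = FALSE], status), "shape")

  # gradient check
  set.seed(12)
  z <- array(rnorm(4 * 4 * K), c(4, 4, K, 1))
  tt <- array((runif(4 * 4 * K) > 0.5) * 1, c(4, 4, K, 1))
  st <- matrix(c("annotated_positive", "annotated_positive"), K, 1)
  r <- mtl_loss(z, tt, st, want_grad = TRUE)
  for (i in sample(length(z), 5)) {
    eps <- 1e-6
    zp <- z; zp[i] <- zp[i] + eps
    zm <- z; zm[i] <- zm[i] - eps
    num <- (mtl_loss(zp, tt, st)$loss - mtl_loss(zm, tt, st)$loss) / (2 * eps)
    expect_equal(r$dlogits[i], num, tolerance = 1e-5)
  }
})

test_that("the total loss combines terms with the multi-task weight", {
  expect_equal(total_loss(1.5, 0.01, loss_weights(3, 0)), 1.5)
  expect_equal(total_loss(1, 0.01, loss_weights(3, 300)), 4)
  set.seed(13)
  a <- runif(1); b <- runif(1)
  expect_equal(total_loss(a, b, loss_weights(3, 17)), a + 17 * b)
})
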