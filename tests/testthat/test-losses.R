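mk <- function(v) array(v, c(2, 2, 2))

test_that("tversky loss: perfect, inverted, and hand-evaluated cases", {
  s <- mk(c(1, 1, 1, 1, 0, 0, 0, 0))
  expect_lt(tversky_loss(s, s), 1e-6)
  expect_gt(tversky_loss(s, 1 - s), 1 - 1e-5)

  # half-ones target, uniform 0.5 prediction, alpha = (0.3, 0.7):
  # I = 4*0.5 = 2; FN = 2; FP = 2; TI = 2 / (2 + .3*2 + .7*2) = 0.5
  expect_equal(tversky_loss(s, mk(0.5), 0.3, 0.7), 0.5, tolerance = 1e-6)
  expect_error(tversky_loss(s, array(0.5, c(2, 2, 1))), "shape")
})

test_that("focal loss: perfect prediction, BCE reduction, one-voxel case", {
  s <- mk(c(1, 0, 1, 0, 1, 0, 1, 0))
  expect_lt(focal_loss(s, s), 1e-5)

  # gamma = 0, beta = 0.5 -> half the mean binary cross-entropy
  set.seed(4)
  p <- mk(runif(8, 0.05, 0.95))
  bce <- -mean(s * log(p) + (1 - s) * log(1 - p))
  expect_equal(focal_loss(s, p, beta = 0.5, gamma = 0), bce / 2,
               tolerance = 1e-9)

  # single voxel, s = 1, p = 0.5, beta = 0.8, gamma = 2
  s1 <- array(1, c(1, 1, 1)); p1 <- array(0.5, c(1, 1, 1))
  expect_equal(focal_loss(s1, p1, 0.8, 2), -0.8 * 0.25 * log(0.5),
               tolerance = 1e-9)
})

test_that("mse vector loss is the elementwise mean of squared differences", {
  v <- array(0, c(2, 2, 2, 3))
  expect_identical(mse_vector_loss(v, v), 0)
  expect_identical(mse_vector_loss(v, v + 1), 1)
  set.seed(9)
  a <- array(rnorm(24), c(2, 2, 2, 3))
  b <- array(rnorm(24), c(2, 2, 2, 3))
  expect_equal(mse_vector_loss(a, b), sum((a - b)^2) / 24)
  expect_error(mse_vector_loss(a, array(0, c(2, 2, 1, 3))), "shape")
})

test_that("combined loss is the stated weighted sum and zero when perfect", {
  s <- mk(c(1, 1, 0, 0, 1, 0, 1, 0))
  v <- array(rnorm(24), c(2, 2, 2, 3))
  expect_lt(combined_loss(s, s, v, v), 1e-4)

  set.seed(2)
  p <- mk(runif(8, 0.1, 0.9))
  vhat <- v + array(rnorm(24, sd = 0.5), c(2, 2, 2, 3))
  w <- loss_weights()   # (1, 10, 10), alpha (0.3, 0.7), beta 0.8, gamma 2
  expect_equal(combined_loss(s, p, v, vhat, w),
               1 * tversky_loss(s, p, 0.3, 0.7) +
                 10 * focal_loss(s, p, 0.8, 2) +
                 10 * mse_vector_loss(v, vhat),
               tolerance = 1e-12)

  # lambda_mse = 0 -> independent of the vector prediction
  w0 <- loss_weights(lambda_mse = 0)
  expect_identical(combined_loss(s, p, v, vhat, w0),
                   combined_loss(s, p, v, v * 2, w0))

  # linearity in the weights at fixed predictions
  w2 <- loss_weights(lambda_tversky = 2, lambda_focal = 20, lambda_mse = 20)
  expect_equal(combined_loss(s, p, v, vhat, w2),
               2 * combined_loss(s, p, v, vhat), tolerance = 1e-12)
})

test_that("analytic loss gradients match numerical differentiation", {
  set.seed(13)
  s <- mk(rbinom(8, 1, 0.5))
  p <- mk(runif(8, 0.2, 0.8))
  v <- array(rnorm(24), c(2, 2, 2, 3))
  vhat <- array(rnorm(24), c(2, 2, 2, 3))
  w <- loss_weights()
  g <- nucsplit3d:::combined_loss_grad(s, p, v, vhat, w)
  h <- 1e-6
  for (i in c(1, 5, 8)) {
    pp <- p; pp[i] <- p[i] + h
    pm <- p; pm[i] <- p[i] - h
    num <- (combined_loss(s, pp, v, vhat, w) -
              combined_loss(s, pm, v, vhat, w)) / (2 * h)
    expect_equal(g$dprob[i], num, tolerance = 1e-4)
  }
  for (i in c(2, 17)) {
    vp <- vhat; vp[i] <- vhat[i] + h
    vm <- vhat; vm[i] <- vhat[i] - h
    num <- (combined_loss(s, p, v, vp, w) -
              combined_loss(s, p, v, vm, w)) / (2 * h)
    expect_equal(g$dvec[i], num, tolerance = 1e-4)
  }
})
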