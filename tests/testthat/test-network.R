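test_that("model outputs match the input shape and probability range", {
  m <- nn_unet3d(levels = 3, base_width = 4, seed = 1)
  set.seed(2)
  vol <- array(runif(16^3), c(16, 16, 16))
  out <- predict(m, vol)
  expect_identical(dim(out$prob), c(16L, 16L, 16L))
  expect_identical(dim(out$vec), c(16L, 16L, 16L, 3L))
  expect_true(all(out$prob >= 0 & out$prob <= 1))
  # shape violation: not divisible by 2^(levels-1)
  expect_error(predict(m, array(0, c(15, 16, 16))), "divisible")
})

test_that("parameter count grows with width and forward is deterministic", {
  expect_gt(n_params(nn_unet3d(3, 8, seed = 1)),
            n_params(nn_unet3d(3, 4, seed = 1)))
  m <- nn_unet3d(2, 4, seed = 3)
  set.seed(4)
  vol <- array(runif(8^3), c(8, 8, 8))
  a <- predict(m, vol)
  b <- predict(m, vol)
  expect_identical(a, b)   # eval mode: frozen batch-norm statistics
})

test_that("zero learning rate freezes the loss history", {
  fx <- make_fixture("separated", c(16L, 16L, 16L), seed = 6)
  m <- nn_unet3d(2, 4, seed = 6)
  train_unet3d(m, list(list(intensity = fx$intensity, labels = fx$labels)),
               epochs = 4, lr = 0, seed = 6)
  expect_equal(diff(range(m$history)), 0, tolerance = 1e-12)
})

test_that("training is reproducible under a fixed seed", {
  fx <- make_fixture("separated", c(16L, 16L, 16L), seed = 7)
  h <- lapply(1:2, function(i) {
    m <- nn_unet3d(2, 4, seed = 11)
    train_unet3d(m, list(list(intensity = fx$intensity, labels = fx$labels)),
                 epochs = 3, lr = 1e-3, seed = 11)
    m$history
  })
  expect_identical(h[[1]], h[[2]])
})

test_that("backpropagated gradients match numerical differentiation", {
  # tiny model, no attention/residual for speed; check a few parameters
  m <- nn_unet3d(2, 4, use_attention = TRUE, use_residual = TRUE, seed = 21)
  set.seed(22)
  vol <- array(runif(8^3), c(8, 8, 8))
  lab <- array(0L, c(8, 8, 8)); lab[3:6, 3:6, 3:6] <- 1L
  s <- matrix(as.numeric(lab > 0), 512, 1)
  v <- matrix(generate_vector_field(lab), ncol = 3)
  w <- loss_weights()
  lossfun <- function() {
    out <- nucsplit3d:::model_forward(m, vol, train = TRUE)
    combined_loss(s, out$prob, v, out$vec, w)
  }
  out <- nucsplit3d:::model_forward(m, vol, train = TRUE)
  g <- nucsplit3d:::combined_loss_grad(s, out$prob, v, out$vec, w)
  nucsplit3d:::model_backward(m, g$dprob, g$dvec)
  slots <- nucsplit3d:::param_slots(m)
  set.seed(23)
  for (si in sample(length(slots), 6)) {
    sl <- slots[[si]]
    par <- nucsplit3d:::slot_get(sl, sl$par)
    gr <- nucsplit3d:::slot_get(sl, sl$grad)
    i <- sample(length(par), 1)
    h <- 1e-5
    orig <- par[i]
    par[i] <- orig + h; nucsplit3d:::slot_set(sl, par)
    up <- lossfun()
    par[i] <- orig - h; nucsplit3d:::slot_set(sl, par)
    dn <- lossfun()
    par[i] <- orig; nucsplit3d:::slot_set(sl, par)
    expect_equal(gr[i], (up - dn) / (2 * h), tolerance = 5e-3)
  }
})
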