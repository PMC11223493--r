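test_that("architecture and parameter count follow the stated design", {
  net <- build_classifier(3)
  d <- net$dims
  expect_equal(d$K, 25L)        # two conv layers with 10 filters of width 25
  expect_equal(d$F, 10L)
  expect_equal(d$L1, 251L - 24L)
  expect_equal(d$L2, 251L - 48L)
  expect_equal(d$pool, 10L)
  expect_equal(d$n_flat, (203L %/% 10L) * 10L)
  expect_output(print(net), "conv\\(10 filters, width 25")
  expect_error(build_classifier(3, input_width = 50), "too small")
  expect_error(build_classifier(1), ">= 2")
})

test_that("untrained network outputs probabilities on the simplex", {
  set.seed(200)
  net <- build_classifier(3)
  params <- coapore:::cnn_init_params(net$dims)
  state <- coapore:::cnn_init_state(net$dims)
  x <- matrix(rnorm(5 * 251), 5, 251)
  pr <- coapore:::cnn_probs(params, state, x, net$dims)
  expect_equal(dim(pr), c(5L, 3L))
  expect_true(all(pr >= 0))
  expect_equal(rowSums(pr), rep(1, 5), tolerance = 1e-6)
})

test_that("backward pass matches numerical gradients", {
  # small geometry (width 60 -> conv 36 -> conv 12 -> pool 1) keeps the
  # finite-difference loop cheap; dropout disabled so the loss is smooth
  set.seed(201)
  d <- coapore:::cnn_dims(60L, n_classes = 2L)
  params <- coapore:::cnn_init_params(d)
  state <- coapore:::cnn_init_state(d)
  n <- 6L
  X <- matrix(rnorm(n * 60), n, 60)
  y <- matrix(0, n, 2); y[cbind(1:n, rep(1:2, 3))] <- 1

  loss_fn <- function(p) {
    set.seed(42)  # freeze (disabled) dropout draws for bit-identical paths
    fwd <- coapore:::cnn_forward(p, state, X, d, training = TRUE,
                                 dropout = 0)
    -sum(y * log(pmax(fwd$probs, 1e-12))) / n
  }
  set.seed(42)
  fwd <- coapore:::cnn_forward(params, state, X, d, training = TRUE,
                               dropout = 0)
  grads <- coapore:::cnn_backward(params, fwd, y, d, dropout = 0)

  eps <- 1e-5
  for (nm in c("W1", "b1", "g1", "be1", "W2", "b2", "g2", "be2",
               "Wd", "bd")) {
    p <- params[[nm]]
    idx <- sample(length(p), min(4, length(p)))
    for (j in idx) {
      pp <- params; pp[[nm]][j] <- pp[[nm]][j] + eps
      pm <- params; pm[[nm]][j] <- pm[[nm]][j] - eps
      num_grad <- (loss_fn(pp) - loss_fn(pm)) / (2 * eps)
      expect_equal(grads[[nm]][j], num_grad, tolerance = 1e-4,
                   label = paste("grad", nm, j))
    }
  }
})

test_that("batchnorm normalizes per channel in training mode", {
  set.seed(202)
  A <- matrix(rnorm(500, 3, 2), 100, 5)
  bn <- coapore:::bn_fwd_train(A, g = rep(2, 5), be = rep(1, 5))
  expect_equal(colMeans(bn$Y), rep(1, 5), tolerance = 1e-10)
  expect_equal(apply(bn$Y, 2, sd), rep(2, 5), tolerance = 1e-2)
})

test_that("maxpool forward/backward route values and gradients correctly", {
  n <- 3L; L <- 20L; F_ <- 2L
  set.seed(203)
  A <- matrix(rnorm(n * L * F_), n * L, F_)
  pl <- coapore:::pool_fwd(A, n, L, F_, 10L)
  expect_equal(dim(pl$M), c(n * 2L, F_))
  # oracle: direct max over each window of the (n, L, F) array
  arr <- array(A, c(n, L, F_))
  for (i in 1:n) for (w in 1:2) for (f in 1:F_) {
    expect_equal(pl$M[i + (w - 1) * n, f],
                 max(arr[i, (w - 1) * 10 + 1:10, f]))
  }
  dM <- matrix(1, n * 2L, F_)
  dA <- coapore:::pool_bwd(dM, pl, n, L, F_)
  expect_equal(sum(dA != 0), n * 2L * F_)   # one winner per pooled cell
  expect_equal(sum(dA), sum(dM))
})
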