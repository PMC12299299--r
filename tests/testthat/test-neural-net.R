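test_that("topology arithmetic and parameter counts", {
  topo <- mlp_topology(3, 10, 1)
  expect_equal(topo$n_params, 3 * 10 + 10 + 10 * 1 + 1)  # 51
  expect_error(mlp_topology(3, 0, 1), "sizes")
  two <- mlp_topology(3, c(5, 4), 1)
  expect_equal(two$n_params, 3 * 5 + 5 + 5 * 4 + 4 + 4 + 1)
})

test_that("initialization is seeded with zero thresholds", {
  topo <- mlp_topology()
  a <- init_network(topo, seed = 3)
  b <- init_network(topo, seed = 3)
  expect_identical(a, b)
  expect_true(all(abs(flatten_params(a)) <= 0.5))
  expect_true(all(a$layers[[1]]$b == 0) && all(a$layers[[2]]$b == 0))
})

test_that("flatten and unflatten are a lossless bijection", {
  topo <- mlp_topology(4, c(6, 3), 2)
  set.seed(12)
  for (i in 1:20) {
    v <- rnorm(topo$n_params)
    expect_identical(flatten_params(unflatten_params(v, topo)), v)
  }
  p <- init_network(topo, seed = 1)
  expect_equal(unflatten_params(flatten_params(p), topo)$layers, p$layers)
  expect_error(unflatten_params(1:5, topo), "length")
})

test_that("forward pass limits and a hand-computed 2-2-1 case", {
  topo <- mlp_topology(2, 2, 1)
  zero <- unflatten_params(rep(0, topo$n_params), topo)
  expect_equal(mlp_forward(zero, c(3, -7)), 0.5 * 0 + 0)  # sigmoid(0)=0.5, W2=0
  # saturated single hidden unit: output = w_out * 1 + bias
  t1 <- mlp_topology(1, 1, 1)
  p <- unflatten_params(c(50, 0, 0.7, 0.2), t1)  # W1=50, b1=0, W2=0.7, b2=0.2
  expect_equal(mlp_forward(p, 10), 0.7 * 1 + 0.2, tolerance = 1e-9)
  expect_equal(mlp_forward(p, -10), 0.7 * 0 + 0.2, tolerance = 1e-9)
  # full hand computation on a fixed 2-2-1 network
  p2 <- unflatten_params(c(0.3, -0.2, 0.5, 0.1, 0.05, -0.05, 1.2, -0.8, 0.25),
                         topo)
  x <- c(0.4, 0.6)
  sig <- function(z) 1 / (1 + exp(-z))
  h1 <- sig(0.3 * 0.4 - 0.2 * 0.6 + 0.05)
  h2 <- sig(0.5 * 0.4 + 0.1 * 0.6 - 0.05)
  expect_equal(mlp_forward(p2, x), 1.2 * h1 - 0.8 * h2 + 0.25,
               tolerance = 1e-12)
  expect_error(mlp_forward(p2, c(1, 2, 3)), "input size")
})

test_that("mse_loss equals the independently computed mean squared residual", {
  topo <- mlp_topology(3, 5, 1)
  p <- init_network(topo, seed = 4)
  set.seed(4)
  x <- matrix(runif(30), ncol = 3); y <- runif(10)
  expect_equal(mse_loss(p, x, y), mean((mlp_forward(p, x) - y)^2))
  perfect <- mlp_forward(p, x)
  expect_equal(mse_loss(p, x, perfect), 0)
  zero <- unflatten_params(rep(0, topo$n_params), topo)
  expect_equal(mse_loss(zero, x, rep(1, 10)), 1)
  expect_error(mse_loss(p, x[0, , drop = FALSE], numeric(0)), "empty")
})

test_that("backprop gradients match central finite differences", {
  topo <- mlp_topology(2, 3, 1)
  eps <- 1e-6
  worst <- 0
  for (k in 1:20) {
    set.seed(100 + k)
    v <- rnorm(topo$n_params, sd = 0.8)
    x <- matrix(runif(10), ncol = 2); y <- runif(5)
    g <- uriquant:::.mlp_gradient(unflatten_params(v, topo), x, y)
    gflat <- unlist(lapply(g, function(l) c(as.vector(l$W), l$b)))
    gnum <- vapply(seq_along(v), function(i) {
      vp <- v; vp[i] <- vp[i] + eps
      vm <- v; vm[i] <- vm[i] - eps
      (mse_loss(unflatten_params(vp, topo), x, y) -
         mse_loss(unflatten_params(vm, topo), x, y)) / (2 * eps)
    }, numeric(1))
    worst <- max(worst, max(abs(gflat - gnum) / pmax(abs(gnum), 1e-6)))
  }
  expect_lt(worst, 1e-5)
})

test_that("gradient descent trains a small regression to low error", {
  # y = 2x on [0,1] through a 1-4-1 network
  set.seed(7)
  x <- matrix(runif(80), ncol = 1)
  y <- 2 * x[, 1]
  p0 <- init_network(mlp_topology(1, 4, 1), seed = 7)
  p <- train_gd(p0, x, y, lr = 0.1, epochs = 2000)
  hist <- attr(p, "loss_history")
  expect_lt(hist[length(hist)], 1e-3)
  # lr 0 leaves parameters untouched
  same <- train_gd(p0, x, y, lr = 0, epochs = 5)
  expect_identical(same$layers, p0$layers)
  # small steps never increase the loss here
  expect_true(all(diff(hist) <= 1e-10))
})

test_that("min-max scaling round-trips and handles saturated columns", {
  set.seed(9)
  x <- cbind(runif(40, 50, 250), runif(40, 0, 30), rep(255, 40))
  sc <- scaler_fit(x)
  z <- scaler_apply(sc, x)
  expect_true(all(z[, 1:2] >= 0 & z[, 1:2] <= 1))
  expect_true(all(z[, 3] == 0))  # constant column maps to 0
  expect_lt(max(abs(scaler_invert(sc, z) - x)), 1e-12)
  sy <- scaler_fit(runif(20, 0, 500))
  yv <- runif(20, 0, 500)
  expect_lt(max(abs(scaler_invert(sy, scaler_apply(sy, yv)) - yv)), 1e-12)
})
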