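# Feedforward engine: forward pass, gradients, early stopping.

test_that("forward pass matches a hand-computed sigmoid chain", {
  z <- constantNet(D = 4, H = 3, value = 0)
  expect_identical(nnForward(z, rep(1, 4)), 0.5)      # sigmoid(0)

  # toy 2-input, 1-hidden net with hand-set weights
  net <- list(W1 = matrix(c(0.3, -0.2), 2, 1), b1 = 0.1,
              W2 = 0.7, b2 = -0.4)
  x <- c(0.5, -1)
  sig <- function(u) 1 / (1 + exp(-u))
  byHand <- sig(0.7 * sig(0.3 * 0.5 + (-0.2) * (-1) + 0.1) - 0.4)
  expect_equal(nnForward(net, x), byHand, tolerance = 1e-12)

  expect_identical(nnForward(net, x), nnForward(net, x))
  expect_error(nnForward(net, c(1, 2, 3)), "dimension")
})

test_that("scores stay strictly inside (0, 1)", {
  set.seed(1)
  net <- newNetwork(6, 4, seed = 2)
  X <- matrix(rnorm(50 * 6, sd = 5), 50)
  s <- nnForward(net, X)
  expect_true(all(s > 0 & s < 1))
})

test_that("analytic gradients agree with central finite differences", {
  lossOf <- function(net, X, y) mean((nnForward(net, X) - y)^2) / 2
  for (case in 1:3) {
    set.seed(100 + case)
    D <- sample(3:6, 1); H <- sample(2:4, 1); n <- 7
    net <- newNetwork(D, H, seed = case)
    X <- matrix(rnorm(n * D), n)
    y <- runif(n)
    g <- nnGradients(net, X, y)
    eps <- 1e-5
    numGrad <- function(get, set) {
      p0 <- get(net)
      vapply(seq_along(p0), function(i) {
        up <- net; dn <- net
        pu <- p0; pu[i] <- pu[i] + eps; up <- set(up, pu)
        pd <- p0; pd[i] <- pd[i] - eps; dn <- set(dn, pd)
        (lossOf(up, X, y) - lossOf(dn, X, y)) / (2 * eps)
      }, numeric(1))
    }
    gW1 <- numGrad(function(n) as.vector(n$W1),
                   function(n, p) { n$W1 <- matrix(p, D, H); n })
    expect_lt(max(abs(gW1 - as.vector(g$W1))), 1e-6)
    gb1 <- numGrad(function(n) n$b1, function(n, p) { n$b1 <- p; n })
    expect_lt(max(abs(gb1 - g$b1)), 1e-6)
    gW2 <- numGrad(function(n) n$W2, function(n, p) { n$W2 <- p; n })
    expect_lt(max(abs(gW2 - g$W2)), 1e-6)
    gb2 <- numGrad(function(n) n$b2, function(n, p) { n$b2 <- p; n })
    expect_lt(abs(gb2 - g$b2), 1e-6)
  }
})

test_that("a gradient step reduces batch error; zero rate is a no-op", {
  set.seed(5)
  net <- newNetwork(5, 3, seed = 5)
  X <- matrix(rnorm(20 * 5), 20)
  y <- runif(20)
  err <- function(n) mean((nnForward(n, X) - y)^2)
  stepped <- backpropStep(net, X, y, learnRate = 0.1)
  expect_lt(err(stepped), err(net))

  same <- backpropStep(net, X, y, learnRate = 0)
  expect_identical(same$W1, net$W1)
  expect_identical(same$b2, net$b2)

  expect_error(backpropStep(net, X, y + 2), "0, 1")
})

test_that("repeated online steps drive a single example to its target", {
  net <- newNetwork(4, 3, seed = 9)
  x <- matrix(c(0.2, -0.5, 1, 0.3), 1)
  for (i in 1:1000) net <- backpropStep(net, x, 0.8, learnRate = 0.5)
  expect_lt(abs(nnForward(net, x) - 0.8), 0.01)
})

test_that("early stopping returns the best-epoch weights", {
  set.seed(11)
  D <- 6
  X <- matrix(rnorm(80 * D), 80)
  truth <- as.numeric(X[, 1] > 0)
  y <- panMHC:::.clamp01(truth * 0.8 + 0.1 + rnorm(80, 0, 0.15))
  fit <- trainEarlyStopping(X[1:50, ], y[1:50], X[51:80, ], y[51:80],
                            hidden = 4, seed = 3, maxEpochs = 80,
                            learnRate = 0.3)
  expect_lte(fit$stopErr[fit$bestEpoch], fit$stopErr[length(fit$stopErr)])
  expect_equal(min(fit$stopErr), fit$stopErr[fit$bestEpoch])

  # degenerate check: stopping on the training data itself, separable data
  ysep <- as.numeric(X[, 1] > 0)
  fit2 <- trainEarlyStopping(X, ysep, X, ysep, hidden = 6, seed = 4,
                             maxEpochs = 300, learnRate = 0.5)
  expect_lt(min(fit2$stopErr), 0.02)

  expect_error(trainEarlyStopping(X, y, X[0, , drop = FALSE], numeric(0)),
               "stop set")
})

test_that("maxEpochs = 0 returns the seeded initial network untouched", {
  X <- matrix(rnorm(10 * 4), 10)
  y <- runif(10)
  fit <- trainEarlyStopping(X, y, X, y, hidden = 3, seed = 21, maxEpochs = 0)
  init <- newNetwork(4, 3, seed = 21)
  expect_identical(fit$net$W1, init$W1)
  expect_identical(fit$net$b2, init$b2)
  expect_identical(fit$bestEpoch, 0L)
})

test_that("training is reproducible from the seed", {
  set.seed(2)
  X <- matrix(rnorm(40 * 5), 40)
  y <- runif(40)
  f1 <- trainEarlyStopping(X[1:30, ], y[1:30], X[31:40, ], y[31:40],
                           hidden = 4, seed = 8, maxEpochs = 25)
  f2 <- trainEarlyStopping(X[1:30, ], y[1:30], X[31:40, ], y[31:40],
                           hidden = 4, seed = 8, maxEpochs = 25)
  expect_identical(f1$net, f2$net)
  expect_identical(f1$stopErr, f2$stopErr)
})
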