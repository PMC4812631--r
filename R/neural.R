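# R-level surface of the feedforward engine (compiled core in src/).

#' Create a feedforward network with seeded random weights
#'
#' One hidden layer and a single output unit, logistic activations
#' throughout. Weights are drawn uniformly from \[-0.05, 0.05\] by a
#' deterministic generator seeded with \code{seed}.
#'
#' @param D input dimension.
#' @param H hidden-layer size.
#' @param seed initialisation seed.
#' @return a network: list with \code{W1} (D x H), \code{b1}, \code{W2},
#'   \code{b2}, \code{D}, \code{H}, \code{seed}.
#' @export
newNetwork <- function(D, H, seed = 1) {
  n <- cppInitNet(as.integer(D), as.integer(H), as.integer(seed))
  n$W2 <- as.numeric(n$W2); n$b1 <- as.numeric(n$b1)
  c(n, list(D = as.integer(D), H = as.integer(H), seed = as.integer(seed)))
}

.asInputMatrix <- function(net, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != nrow(net$W1))
    stop(sprintf("input dimension %d does not match network dimension %d",
                 ncol(X), nrow(net$W1)), call. = FALSE)
  X
}

#' Forward pass
#'
#' @param net a network from [newNetwork()] (or an ensemble member).
#' @param X input vector or matrix (rows are examples).
#' @return numeric vector of scores strictly inside (0, 1).
#' @export
nnForward <- function(net, X) {
  X <- .asInputMatrix(net, X)
  as.numeric(cppForward(net$W1, net$b1, net$W2, net$b2, X))
}

#' Gradient of the batch loss
#'
#' Loss is the mean over the batch of \code{(o - y)^2 / 2}.
#'
#' @param net a network.
#' @param X input matrix.
#' @param y targets in \[0, 1\].
#' @return list of gradients with the same shapes as the parameters.
#' @export
nnGradients <- function(net, X, y) {
  X <- .asInputMatrix(net, X)
  stopifnot(length(y) == nrow(X))
  g <- cppGradBatch(net$W1, net$b1, net$W2, net$b2, X, y)
  g$W2 <- as.numeric(g$W2); g$b1 <- as.numeric(g$b1)
  g
}

#' One batch gradient-descent step
#'
#' @inheritParams nnGradients
#' @param learnRate step size; 0 leaves the network unchanged.
#' @return the updated network.
#' @export
backpropStep <- function(net, X, y, learnRate = 0.05) {
  if (any(y < 0 | y > 1)) stop("targets must lie in [0, 1]", call. = FALSE)
  g <- nnGradients(net, X, y)
  net$W1 <- net$W1 - learnRate * g$W1
  net$b1 <- net$b1 - learnRate * g$b1
  net$W2 <- net$W2 - learnRate * g$W2
  net$b2 <- net$b2 - learnRate * g$b2
  net
}

#' Train a network with early stopping on a held-out stop set
#'
#' Online (per-example) back-propagation in a freshly shuffled order each
#' epoch; after each epoch the squared error on the stop set is measured
#' and the weights of the best epoch are returned. With
#' \code{maxEpochs = 0} the untouched seeded initial network is returned
#' (identical to \code{newNetwork(ncol(trainX), hidden, seed)}).
#'
#' @param trainX,trainY training inputs (matrix) and targets.
#' @param stopX,stopY stop-set inputs and targets (must be non-empty).
#' @param hidden hidden-layer size.
#' @param seed seed for weight initialisation and shuffling.
#' @param maxEpochs epoch budget.
#' @param learnRate online learning rate.
#' @param patience epochs without stop-set improvement before training
#'   ends early (default: never).
#' @return list with the trained network (\code{net}), \code{bestEpoch},
#'   and per-epoch \code{trainErr}/\code{stopErr} logs.
#' @export
trainEarlyStopping <- function(trainX, trainY, stopX, stopY, hidden = 5,
                               seed = 1, maxEpochs = 300, learnRate = 0.05,
                               patience = maxEpochs + 1L) {
  if (is.null(dim(trainX))) trainX <- matrix(trainX, ncol = length(trainX))
  if (is.null(dim(stopX))) stopX <- matrix(stopX, ncol = ncol(trainX))
  if (nrow(stopX) == 0) stop("empty stop set", call. = FALSE)
  stopifnot(nrow(trainX) == length(trainY), nrow(stopX) == length(stopY))
  if (any(c(trainY, stopY) < 0 | c(trainY, stopY) > 1))
    stop("targets must lie in [0, 1]", call. = FALSE)
  X <- rbind(trainX, stopX)
  n <- nrow(trainX); m <- nrow(stopX)
  fit <- cppTrainNNAlign(X, candStart = 0:(n + m - 1),
                         candCount = rep(1L, n + m),
                         target = c(trainY, stopY),
                         trainIdx = seq_len(n) - 1L,
                         stopIdx = n + seq_len(m) - 1L,
                         H = as.integer(hidden), lr = learnRate,
                         maxEpochs = as.integer(maxEpochs),
                         patience = as.integer(min(patience, .Machine$integer.max)),
                         seed = as.integer(seed))
  net <- list(W1 = fit$W1, b1 = as.numeric(fit$b1),
              W2 = as.numeric(fit$W2), b2 = fit$b2,
              D = ncol(trainX), H = as.integer(hidden),
              seed = as.integer(seed))
  list(net = net, bestEpoch = fit$bestEpoch,
       trainErr = as.numeric(fit$trainErr),
       stopErr = as.numeric(fit$stopErr))
}
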