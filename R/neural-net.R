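# A from-scratch feed-forward BP regression network: sigmoid hidden layers,
# linear output, full-batch gradient descent on the mean squared error via
# backpropagation, and a flat parameter-vector interface so metaheuristic
# optimizers can treat the weights and thresholds as a single real vector.

#' Network topology
#'
#' @param input number of input features (default 3: the R, G, B channels).
#' @param hidden integer vector of hidden layer sizes (default 10, one
#'   layer). All hidden units use the logistic sigmoid.
#' @param output number of outputs (default 1: the concentration).
#' @return an object of class `mlp_topology` with the total parameter count
#'   in `$n_params`.
#' @export
mlp_topology <- function(input = 3, hidden = 10, output = 1) {
  sizes <- as.integer(c(input, hidden, output))
  if (any(sizes < 1L)) stop("all layer sizes must be >= 1", call. = FALSE)
  n_params <- sum(sizes[-length(sizes)] * sizes[-1]) + sum(sizes[-1])
  structure(list(input = sizes[1], hidden = sizes[-c(1, length(sizes))],
                 output = sizes[length(sizes)], sizes = sizes,
                 n_params = n_params),
            class = "mlp_topology")
}

#' Initialize network parameters
#'
#' Weights are drawn uniformly from \[-0.5, 0.5\] (seeded); thresholds
#' (biases) start at zero.
#'
#' @param topology an [mlp_topology()].
#' @param seed integer RNG seed.
#' @return an object of class `mlp_params`: per-layer weight matrices `W`
#'   (n_in x n_out) and threshold vectors `b`, plus the topology.
#' @export
init_network <- function(topology, seed = 1) {
  stopifnot(inherits(topology, "mlp_topology"))
  s <- topology$sizes
  layers <- with_seed(seed, lapply(seq_len(length(s) - 1L), function(i) {
    list(W = matrix(stats::runif(s[i] * s[i + 1], -0.5, 0.5), s[i], s[i + 1]),
         b = rep(0, s[i + 1]))
  }))
  structure(list(layers = layers, topology = topology), class = "mlp_params")
}

#' Flatten parameters to a vector / rebuild them from one
#'
#' The flattening (layer by layer: weight matrix column-major, then the
#' thresholds) is a lossless bijection, so optimizers can operate on a single
#' real vector of length `topology$n_params`.
#'
#' @param params an `mlp_params`.
#' @param vec a numeric vector of length `topology$n_params`.
#' @param topology an [mlp_topology()].
#' @return `flatten_params` returns a numeric vector; `unflatten_params`
#'   an `mlp_params`.
#' @export
flatten_params <- function(params) {
  stopifnot(inherits(params, "mlp_params"))
  unlist(lapply(params$layers, function(l) c(as.vector(l$W), l$b)),
         use.names = FALSE)
}

#' @rdname flatten_params
#' @export
unflatten_params <- function(vec, topology) {
  stopifnot(inherits(topology, "mlp_topology"))
  vec <- as.numeric(vec)
  if (length(vec) != topology$n_params)
    stop("parameter vector has length ", length(vec), ", expected ",
         topology$n_params, call. = FALSE)
  s <- topology$sizes
  layers <- vector("list", length(s) - 1L)
  pos <- 0L
  for (i in seq_along(layers)) {
    nw <- s[i] * s[i + 1]
    layers[[i]] <- list(W = matrix(vec[pos + seq_len(nw)], s[i], s[i + 1]),
                        b = vec[pos + nw + seq_len(s[i + 1])])
    pos <- pos + nw + s[i + 1]
  }
  structure(list(layers = layers, topology = topology), class = "mlp_params")
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Forward pass
#'
#' Sigmoid hidden layers, identity output.
#'
#' @param params an `mlp_params`.
#' @param x a feature vector (length = input size) or an n x input matrix of
#'   scaled feature rows.
#' @return predictions: a vector of length n (single-output networks) or an
#'   n x output matrix.
#' @export
mlp_forward <- function(params, x) {
  stopifnot(inherits(params, "mlp_params"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) != params$topology$input)
    stop("feature length ", ncol(x), " does not match input size ",
         params$topology$input, call. = FALSE)
  a <- x
  nl <- length(params$layers)
  for (i in seq_len(nl)) {
    z <- a %*% params$layers[[i]]$W +
      matrix(params$layers[[i]]$b, nrow(a), ncol = length(params$layers[[i]]$b),
             byrow = TRUE)
    a <- if (i < nl) .sigmoid(z) else z
  }
  if (ncol(a) == 1L) drop(a) else a
}

#' Mean squared error of a network on a dataset
#'
#' @param params an `mlp_params`.
#' @param x n x input matrix of scaled features.
#' @param y length-n vector of scaled targets.
#' @return mean of squared residuals (non-negative scalar).
#' @export
mse_loss <- function(params, x, y) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (nrow(x) == 0L) stop("empty dataset", call. = FALSE)
  if (nrow(x) != length(y))
    stop("x and y sizes disagree", call. = FALSE)
  mean((mlp_forward(params, x) - y)^2)
}

# Full-batch MSE gradient by backpropagation; returns list of layer grads.
.mlp_gradient <- function(params, x, y) {
  n <- nrow(x)
  nl <- length(params$layers)
  acts <- vector("list", nl + 1L)
  acts[[1]] <- x
  for (i in seq_len(nl)) {
    z <- acts[[i]] %*% params$layers[[i]]$W +
      matrix(params$layers[[i]]$b, n, length(params$layers[[i]]$b), byrow = TRUE)
    acts[[i + 1]] <- if (i < nl) .sigmoid(z) else z
  }
  grads <- vector("list", nl)
  delta <- 2 * (acts[[nl + 1]] - matrix(y, n)) / n    # dL/dz at the output
  for (i in nl:1) {
    grads[[i]] <- list(W = t(acts[[i]]) %*% delta, b = colSums(delta))
    if (i > 1) {
      a <- acts[[i]]
      delta <- (delta %*% t(params$layers[[i]]$W)) * a * (1 - a)
    }
  }
  grads
}

#' Train by full-batch gradient descent
#'
#' Plain backpropagation on the mean squared error: every epoch computes the
#' exact full-batch gradient and takes one step of size `lr`. The loss after
#' every epoch is recorded.
#'
#' @param params initial `mlp_params` (e.g. from [init_network()] or an
#'   optimizer's best vector via [unflatten_params()]).
#' @param x,y scaled training features (n x input matrix) and targets.
#' @param lr learning rate (default 0.1).
#' @param epochs number of full-batch epochs (default 4000).
#' @return the trained `mlp_params`, with the per-epoch loss history in
#'   attribute `loss_history` (length `epochs + 1`, starting loss first).
#' @export
train_gd <- function(params, x, y, lr = 0.1, epochs = 4000) {
  stopifnot(inherits(params, "mlp_params"))
  if (is.null(dim(x))) x <- matrix(x, ncol = params$topology$input)
  if (lr < 0) stop("lr must be >= 0", call. = FALSE)
  history <- numeric(epochs + 1L)
  history[1] <- mse_loss(params, x, y)
  for (e in seq_len(epochs)) {
    g <- .mlp_gradient(params, x, y)
    for (i in seq_along(params$layers)) {
      params$layers[[i]]$W <- params$layers[[i]]$W - lr * g[[i]]$W
      params$layers[[i]]$b <- params$layers[[i]]$b - lr * g[[i]]$b
    }
    history[e + 1L] <- mse_loss(params, x, y)
    if (!is.finite(history[e + 1L]))
      stop("training diverged at epoch ", e, " (non-finite loss; lr = ", lr,
           ")", call. = FALSE)
  }
  attr(params, "loss_history") <- history
  params
}

#' Min-max scaler
#'
#' Fits per-column minimum and maximum (on the training split only) and maps
#' values linearly onto \[0, 1\]. `scaler_invert` is the exact inverse.
#' A constant column — e.g. a color channel saturated at 255 over the whole
#' calibration range — carries no information: it is recorded as degenerate
#' and scaled to 0 for any input, so the network ignores that feature;
#' inverting a degenerate column returns the fitted constant.
#'
#' @param x a numeric matrix (or vector, treated as one column).
#' @param scaler a fitted `minmax_scaler`.
#' @return `scaler_fit` returns a `minmax_scaler`; `scaler_apply` and
#'   `scaler_invert` return data of the input shape.
#' @export
scaler_fit <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L)
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  structure(list(min = lo, max = hi,
                 span = ifelse(hi > lo, hi - lo, 1),
                 degenerate = hi <= lo),
            class = "minmax_scaler")
}

#' @rdname scaler_fit
#' @export
scaler_apply <- function(scaler, x) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = length(scaler$min))
  span <- scaler$span %||% (scaler$max - scaler$min)
  out <- sweep(sweep(x, 2, scaler$min, "-"), 2, span, "/")
  deg <- scaler$degenerate %||% (scaler$max <= scaler$min)
  if (any(deg)) out[, deg] <- 0
  if (vec) drop(out) else out
}

#' @rdname scaler_fit
#' @export
scaler_invert <- function(scaler, x) {
  stopifnot(inherits(scaler, "minmax_scaler"))
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = length(scaler$min))
  span <- scaler$span %||% (scaler$max - scaler$min)
  out <- sweep(sweep(x, 2, span, "*"), 2, scaler$min, "+")
  deg <- scaler$degenerate %||% (scaler$max <= scaler$min)
  if (any(deg)) out[, deg] <- rep(scaler$min[deg], each = nrow(out))
  if (vec) drop(out) else out
}
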