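#' Specify a feed-forward sigmoid network
#'
#' Fully-connected architecture with sigmoid units in every hidden and
#' output layer, trained by stochastic backpropagation with momentum.
#' The defaults follow the hyperparameters found effective for the
#' structural-feature predictors: learning rate 0.001 and momentum 0.85.
#'
#' @param layer_sizes Integer vector (input, hidden..., output), at least
#'   two layers, all sizes positive.
#' @param seed Seed for weight initialization (and default training order).
#' @param learning_rate Positive step size.
#' @param momentum Momentum coefficient in `[0, 1)`.
#' @return Object of class `network_spec`.
#' @export
network_spec <- function(layer_sizes, seed = 1L,
                         learning_rate = 0.001, momentum = 0.85) {
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L || any(layer_sizes < 1L)) {
    stop("layer_sizes must list at least an input and an output layer, all positive")
  }
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (momentum < 0 || momentum >= 1) stop("momentum must lie in [0, 1)")
  structure(
    list(layer_sizes = layer_sizes, seed = as.integer(seed),
         learning_rate = learning_rate, momentum = momentum),
    class = "network_spec"
  )
}

#' Initialize a network from its spec
#'
#' Weights and biases are drawn uniformly from `[-0.5, 0.5]` by a generator
#' seeded from the spec, so initialization is fully reproducible.
#'
#' @param spec A [network_spec()].
#' @return Object of class `ppa_network` with per-layer weight matrices
#'   (`n_in x n_out`) and bias vectors.
#' @export
init_network <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  ls <- spec$layer_sizes
  nl <- length(ls) - 1L
  with_seed(spec$seed, {
    W <- vector("list", nl)
    b <- vector("list", nl)
    for (l in seq_len(nl)) {
      W[[l]] <- matrix(stats::runif(ls[l] * ls[l + 1], -0.5, 0.5),
                       ls[l], ls[l + 1])
      b[[l]] <- stats::runif(ls[l + 1], -0.5, 0.5)
    }
    structure(list(spec = spec, W = W, b = b, loss = numeric(0)),
              class = "ppa_network")
  })
}

#' Forward propagation
#'
#' @param net A `ppa_network`.
#' @param x Input vector of length `layer_sizes[1]`, or an
#'   `n x layer_sizes[1]` matrix of row-vector inputs.
#' @return Output vector (or `n x out` matrix); every entry lies in (0, 1).
#' @export
nn_forward <- function(net, x) {
  stopifnot(inherits(net, "ppa_network"))
  vec <- is.null(dim(x))
  A <- if (vec) matrix(x, 1) else as.matrix(x)
  if (ncol(A) != net$spec$layer_sizes[1]) {
    stop("input width ", ncol(A), " does not match input layer size ",
         net$spec$layer_sizes[1])
  }
  for (l in seq_along(net$W)) {
    A <- 1 / (1 + exp(-(A %*% net$W[[l]] + rep(net$b[[l]], each = nrow(A)))))
  }
  if (vec) drop(A) else A
}

# Forward pass for a single example keeping all layer activations.
nn_forward_full <- function(net, x) {
  acts <- vector("list", length(net$W) + 1L)
  acts[[1]] <- x
  a <- x
  for (l in seq_along(net$W)) {
    a <- drop(1 / (1 + exp(-(a %*% net$W[[l]] + net$b[[l]]))))
    acts[[l + 1]] <- a
  }
  acts
}

#' Analytic backpropagation gradient for one example
#'
#' Gradient of the squared error `sum((out - y)^2) / 2` with respect to all
#' weights and biases, computed by backpropagation through the sigmoid
#' layers. Exposed so the analytic gradient can be checked against finite
#' differences.
#'
#' @param net A `ppa_network`.
#' @param x Input vector.
#' @param y Target vector in `[0, 1]`.
#' @return List with per-layer `dW` matrices and `db` vectors.
#' @export
nn_gradient <- function(net, x, y) {
  acts <- nn_forward_full(net, x)
  nl <- length(net$W)
  dW <- vector("list", nl)
  db <- vector("list", nl)
  out <- acts[[nl + 1]]
  delta <- (out - y) * out * (1 - out)
  for (l in nl:1) {
    dW[[l]] <- outer(drop(acts[[l]]), delta)
    db[[l]] <- delta
    if (l > 1L) {
      a <- acts[[l]]
      delta <- drop(net$W[[l]] %*% delta) * a * (1 - a)
    }
  }
  list(dW = dW, db = db)
}

#' Train by stochastic backpropagation with momentum
#'
#' Examples are presented one at a time; after each, every weight receives
#' the update `v <- momentum * v - learning_rate * grad; w <- w + v`, the
#' classic momentum rule. Presentation order is reshuffled each epoch by a
#' generator seeded from `seed`, so training is fully deterministic. The
#' mean squared error over the whole dataset is recorded after each epoch
#' in the returned network's `loss` field.
#'
#' @param net A `ppa_network`.
#' @param X `n x d` input matrix.
#' @param Y `n x out` target matrix (or vector for a single output), values
#'   in `[0, 1]`.
#' @param epochs Number of passes over the data; 0 returns `net` unchanged.
#' @param seed Seed controlling the presentation order.
#' @param shuffle Reshuffle the presentation order each epoch.
#' @return The trained `ppa_network`.
#' @export
nn_train <- function(net, X, Y, epochs, seed = net$spec$seed, shuffle = TRUE) {
  stopifnot(inherits(net, "ppa_network"))
  X <- as.matrix(X)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1L)
  Y <- as.matrix(Y)
  n <- nrow(X)
  ls <- net$spec$layer_sizes
  if (ncol(X) != ls[1]) stop("X width does not match input layer")
  if (ncol(Y) != ls[length(ls)]) stop("Y width does not match output layer")
  if (nrow(Y) != n) stop("X and Y must have the same number of rows")
  if (any(Y < 0 | Y > 1)) stop("targets must lie in [0, 1]")
  epochs <- as.integer(epochs)
  if (epochs == 0L) return(net)

  lr <- net$spec$learning_rate
  mom <- net$spec$momentum
  nl <- length(net$W)
  vW <- lapply(net$W, function(w) w * 0)
  vb <- lapply(net$b, function(b) b * 0)
  losses <- numeric(epochs)

  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- if (shuffle) sample.int(n) else seq_len(n)
      for (k in ord) {
        x <- X[k, ]
        acts <- nn_forward_full(net, x)
        out <- acts[[nl + 1]]
        delta <- (out - Y[k, ]) * out * (1 - out)
        for (l in nl:1) {
          a <- drop(acts[[l]])
          if (l > 1L) {
            nxt <- drop(net$W[[l]] %*% delta) * a * (1 - a)
          }
          vW[[l]] <- mom * vW[[l]] - lr * outer(a, delta)
          vb[[l]] <- mom * vb[[l]] - lr * delta
          net$W[[l]] <- net$W[[l]] + vW[[l]]
          net$b[[l]] <- net$b[[l]] + vb[[l]]
          if (l > 1L) delta <- nxt
        }
      }
      pred <- nn_forward(net, X)
      losses[ep] <- mean((pred - Y)^2)
      if (!is.finite(losses[ep])) {
        stop(sprintf("training diverged: non-finite loss at epoch %d", ep))
      }
    }
  })
  net$loss <- c(net$loss, losses)
  net
}

#' Serialize / load a network as JSON
#'
#' @param net A `ppa_network`.
#' @param path File path.
#' @return `path` (save) or the restored network (load).
#' @export
save_network <- function(net, path) {
  stopifnot(inherits(net, "ppa_network"))
  obj <- list(
    layer_sizes = net$spec$layer_sizes,
    seed = net$spec$seed,
    learning_rate = net$spec$learning_rate,
    momentum = net$spec$momentum,
    W = stats::setNames(net$W, paste0("layer", seq_along(net$W))),
    b = stats::setNames(net$b, paste0("layer", seq_along(net$b)))
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname save_network
#' @export
load_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- network_spec(obj$layer_sizes, seed = obj$seed,
                       learning_rate = obj$learning_rate,
                       momentum = obj$momentum)
  W <- unname(lapply(obj$W, as.matrix))
  b <- unname(lapply(obj$b, as.numeric))
  structure(list(spec = spec, W = W, b = b, loss = numeric(0)),
            class = "ppa_network")
}
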