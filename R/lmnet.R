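#' Construct a small tanh network for LM training
#'
#' Feedforward network with tanh hidden layers and a linear output
#' layer, the static configuration used for emotion classification:
#' by default three hidden layers of three units. (With all delay
#' factors at zero the recurrent formulation collapses to this
#' feedforward network; no delay paths are modelled.) Weights and
#' biases are initialized uniformly in `[-initRange, +initRange]`
#' from the current RNG stream.
#'
#' @param inputSize number of inputs (the feature dimension).
#' @param hidden integer vector of hidden layer sizes (default `c(3, 3, 3)`).
#' @param outputSize number of outputs (1 for one-vs-all, 9 for the
#'   all-together scheme).
#' @param initRange half-width of the uniform initialization (default 0.5).
#' @return An `LmNet`: list with `sizes`, `W` (list of weight
#'   matrices), `b` (list of bias vectors), `trace` (training log).
#' @examples
#' set.seed(1)
#' net <- lmNet(2)
#' nnPredict(net, c(0, 1))
#' @export
lmNet <- function(inputSize, hidden = c(3L, 3L, 3L), outputSize = 1L,
                  initRange = 0.5) {
  stopifnot(inputSize >= 1L, outputSize >= 1L, all(hidden >= 1L))
  sizes <- c(inputSize, hidden, outputSize)
  nl <- length(sizes) - 1L
  W <- vector("list", nl); b <- vector("list", nl)
  for (l in seq_len(nl)) {
    W[[l]] <- matrix(stats::runif(sizes[l + 1L] * sizes[l],
                                  -initRange, initRange),
                     sizes[l + 1L], sizes[l])
    b[[l]] <- stats::runif(sizes[l + 1L], -initRange, initRange)
  }
  structure(list(sizes = sizes, W = W, b = b, trace = NULL),
            class = "LmNet")
}

#' @export
print.LmNet <- function(x, ...) {
  cat(sprintf("LmNet: %s (tanh hidden, linear output)\n",
              paste(x$sizes, collapse = "-")))
  if (!is.null(x$trace)) {
    cat(sprintf("  trained: %d accepted step(s), final X2 = %.3g\n",
                sum(x$trace$accepted), x$finalX2))
  }
  invisible(x)
}

# forward pass; X rows = samples. Returns output and all activations.
.nnForward <- function(net, X) {
  acts <- vector("list", length(net$W) + 1L)
  acts[[1L]] <- X
  a <- X
  nl <- length(net$W)
  for (l in seq_len(nl)) {
    z <- a %*% t(net$W[[l]]) + rep(net$b[[l]], each = nrow(a))
    a <- if (l < nl) tanh(z) else z  # linear output layer
    acts[[l + 1L]] <- a
  }
  list(out = a, acts = acts)
}

.netToVec <- function(net) {
  unlist(c(lapply(net$W, as.numeric), net$b))
}

.vecToNet <- function(net, v) {
  pos <- 0L
  for (l in seq_along(net$W)) {
    n <- length(net$W[[l]])
    net$W[[l]] <- matrix(v[pos + seq_len(n)], nrow(net$W[[l]]))
    pos <- pos + n
  }
  for (l in seq_along(net$b)) {
    n <- length(net$b[[l]])
    net$b[[l]] <- v[pos + seq_len(n)]
    pos <- pos + n
  }
  net
}

# Exact Jacobian d out / d params by backpropagation, all samples at
# once. Rows ordered column-major over the (samples x outputs) output
# matrix (matching as.vector of the residual matrix); columns ordered
# as .netToVec: all weight matrices (column-major), then all biases.
.nnJacobian <- function(net, X) {
  m <- nrow(X)
  nl <- length(net$W)
  q <- net$sizes[length(net$sizes)]
  fw <- .nnForward(net, X)
  nW <- vapply(net$W, length, integer(1))
  nb <- vapply(net$b, length, integer(1))
  p <- sum(nW) + sum(nb)
  J <- matrix(0, m * q, p)
  offW <- cumsum(c(0L, nW))[seq_len(nl)]
  offB <- sum(nW) + cumsum(c(0L, nb))[seq_len(nl)]
  for (o in seq_len(q)) {
    rows <- (o - 1L) * m + seq_len(m)
    # delta at output layer for output o: d out_o / d z_L = e_o
    delta <- matrix(0, m, q)
    delta[, o] <- 1
    for (l in nl:1) {
      a_in <- fw$acts[[l]]          # m x sizes[l]
      # d out / d W[[l]][j, i] = delta[, j] * a_in[, i]
      nj <- nrow(net$W[[l]]); ni <- ncol(net$W[[l]])
      block <- delta[, rep(seq_len(nj), times = ni), drop = FALSE] *
        a_in[, rep(seq_len(ni), each = nj), drop = FALSE]
      J[rows, offW[l] + seq_len(nW[l])] <- block
      J[rows, offB[l] + seq_len(nb[l])] <- delta
      if (l > 1L) {
        # back through W[[l]] and the tanh of layer l-1
        delta <- (delta %*% net$W[[l]]) * (1 - fw$acts[[l]]^2)
      }
    }
  }
  J
}

#' Train a network by Levenberg--Marquardt
#'
#' Damped Gauss--Newton least-squares training of an [lmNet()]: each
#' step solves
#' \deqn{(J^T W J + \lambda\, diag(J^T W J))\, h = J^T W (y - \hat y)}
#' and is accepted only if it strictly decreases the weighted squared
#' error \eqn{X^2}; accepted steps divide the damping factor by
#' `lambdaFactor`, rejected ones multiply it. Training stops after
#' `maxIter` accepted steps, when \eqn{X^2} reaches `errTarget`, or
#' when no acceptable step is found within `maxRescue` rescues.
#'
#' @param net an `LmNet`.
#' @param X feature matrix, samples x inputs.
#' @param y targets in `[0, 1]`: vector (single output) or samples x
#'   outputs matrix.
#' @param maxIter maximum accepted steps (default 5).
#' @param errTarget error target on X2 (default 1e-10).
#' @param lambda initial damping factor (default 3).
#' @param lambdaFactor damping adaptation factor (default 10).
#' @param weights optional per-residual weights (diagonal of W;
#'   default identity -- no per-sample measurement variances exist
#'   here).
#' @param maxRescue bound on consecutive rejected/singular steps.
#' @return The trained `LmNet`, with a `trace` data.frame (one row per
#'   attempted step: `iter`, `lambda`, `X2`, `accepted`) and `finalX2`.
#' @examples
#' set.seed(7)
#' X <- matrix(seq(0, 1, length.out = 10))
#' net <- lmFit(lmNet(1), X, 0.5 * X[, 1])
#' net$finalX2 < 1e-2
#' @export
lmFit <- function(net, X, y, maxIter = 5L, errTarget = 1e-10, lambda = 3,
                  lambdaFactor = 10, weights = NULL, maxRescue = 30L) {
  stopifnot(inherits(net, "LmNet"))
  X <- as.matrix(X)
  q <- net$sizes[length(net$sizes)]
  Y <- if (is.matrix(y)) y else matrix(y, ncol = 1L)
  if (ncol(X) != net$sizes[1L]) stop("X columns must match the input size")
  if (ncol(Y) != q || nrow(Y) != nrow(X)) {
    stop("y must be ", nrow(X), " x ", q)
  }
  if (min(Y) < 0 || max(Y) > 1) stop("targets must lie in [0, 1]")
  wt <- if (is.null(weights)) rep(1, nrow(X) * q) else rep(weights,
                                                           length.out = nrow(X) * q)
  X2of <- function(nn) {
    r <- as.vector(Y - .nnForward(nn, X)$out)
    sum(wt * r^2)
  }
  trace <- list()
  X2 <- X2of(net)
  accepted <- 0L
  while (accepted < maxIter && X2 > errTarget) {
    r <- as.vector(Y - .nnForward(net, X)$out)
    J <- .nnJacobian(net, X)
    A <- crossprod(J * wt, J)
    g <- crossprod(J, wt * r)
    D <- pmax(diag(A), 1e-12)
    stepped <- FALSE
    for (rescue in seq_len(maxRescue)) {
      M <- A + lambda * diag(D, length(D))
      h <- tryCatch(solve(M, g), error = function(e) NULL)
      if (!is.null(h)) {
        cand <- .vecToNet(net, .netToVec(net) + as.numeric(h))
        X2new <- X2of(cand)
        trace[[length(trace) + 1L]] <-
          data.frame(iter = accepted + 1L, lambda = lambda, X2 = X2new,
                     accepted = is.finite(X2new) && X2new < X2)
        if (is.finite(X2new) && X2new < X2) {
          net <- cand
          X2 <- X2new
          lambda <- lambda / lambdaFactor
          stepped <- TRUE
          break
        }
      }
      lambda <- lambda * lambdaFactor
    }
    if (!stepped) break
    accepted <- accepted + 1L
  }
  net$trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(iter = integer(), lambda = numeric(), X2 = numeric(),
               accepted = logical())
  net$finalX2 <- X2
  net
}

#' Predict with a trained network
#'
#' Forward pass through the tanh network. For a single-output
#' (one-vs-all) network the scalar output is thresholded at 0.9 -- the
#' midpoint of the raw output range `[-0.1, 1.9]` -- to a 0/1
#' target/outlier decision. For a multi-output (all-together) network
#' the predicted label is the argmax output.
#'
#' @param net an `LmNet`.
#' @param x numeric vector (one sample) or samples x inputs matrix.
#' @param labels optional labels for multi-output networks (argmax
#'   decision); defaults to output indices.
#' @param threshold decision threshold for single-output networks.
#' @return For single-output nets, integer 0/1 (vector for a matrix
#'   input); for multi-output nets, the argmax label(s). The raw
#'   outputs are attached as attribute `"raw"`.
#' @export
nnPredict <- function(net, x, labels = NULL, threshold = 0.9) {
  stopifnot(inherits(net, "LmNet"))
  single <- is.vector(x)
  X <- if (single) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(X) != net$sizes[1L]) {
    stop("dimension mismatch: network expects ", net$sizes[1L], " input(s)")
  }
  out <- .nnForward(net, X)$out
  q <- ncol(out)
  if (q == 1L) {
    res <- as.integer(out[, 1L] >= threshold)
  } else {
    if (is.null(labels)) labels <- seq_len(q)
    stopifnot(length(labels) == q)
    res <- labels[apply(out, 1L, which.max)]
  }
  if (single) res <- res[1L]
  attr(res, "raw") <- if (single) out[1L, ] else out
  res
}
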