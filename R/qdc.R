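#' Fit a quadratic discriminant classifier
#'
#' Per-class multivariate-Gaussian model: sample mean, sample
#' covariance and empirical prior for each class. A covariance that is
#' not positive definite is repaired by adding
#' `eps = 1e-6 * trace / d` to the diagonal (escalated tenfold until a
#' Cholesky factorization succeeds). The optional `shrink` argument
#' blends each covariance toward a scaled identity,
#' `(1 - s) S + s (tr S / d) I`; this is needed when a class has fewer
#' samples than feature dimensions (the sample covariance is then
#' rank-deficient and the bare eps repair makes the discriminant
#' reject every in-class point), as in small-trial one-vs-all training.
#'
#' @param X numeric feature matrix, samples x dimensions.
#' @param y class labels (factor or character); every class needs at
#'   least 2 samples.
#' @param shrink shrinkage weight in `[0, 1]` (default 0: plain QDC).
#' @return A `QdcModel`: list with `classes`, `means`, `covs`, `chol`
#'   (upper Cholesky factors), `logdet`, `priors`, `dim`, `shrink`.
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 4), 20))
#' y <- rep(c("a", "b"), each = 20)
#' m <- qdcFit(X, y)
#' qdcPredict(m, c(4, 4))$label
#' @export
qdcFit <- function(X, y, shrink = 0) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("X must be numeric")
  y <- as.character(y)
  stopifnot(nrow(X) == length(y), shrink >= 0, shrink <= 1)
  d <- ncol(X)
  if (d < 1L) stop("feature dimension must be >= 1")
  classes <- unique(y)
  tab <- table(y)
  if (any(tab < 2L)) {
    stop("training error: class '", names(tab)[which(tab < 2L)[1L]],
         "' has fewer than 2 samples")
  }
  means <- list(); covs <- list(); chols <- list()
  logdet <- numeric(0)
  for (cl in classes) {
    Xc <- X[y == cl, , drop = FALSE]
    mu <- colMeans(Xc)
    S <- stats::cov(Xc)
    if (shrink > 0) {
      S <- (1 - shrink) * S + shrink * (sum(diag(S)) / d) * diag(d)
    }
    R <- .safeChol(S)
    means[[cl]] <- mu
    covs[[cl]] <- R$S
    chols[[cl]] <- R$R
    logdet[cl] <- 2 * sum(log(diag(R$R)))
  }
  priors <- as.numeric(tab[classes]) / length(y)
  names(priors) <- classes
  structure(list(classes = classes, means = means, covs = covs,
                 chol = chols, logdet = logdet, priors = priors,
                 dim = d, shrink = shrink),
            class = "QdcModel")
}

# Cholesky with the eps * I repair for rank-deficient covariances
.safeChol <- function(S) {
  d <- ncol(S)
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(R)) return(list(S = S, R = R))
  eps <- 1e-6 * sum(diag(S)) / d
  if (!is.finite(eps) || eps <= 0) eps <- 1e-6
  for (i in 1:8) {
    S2 <- S + eps * diag(d)
    R <- tryCatch(chol(S2), error = function(e) NULL)
    if (!is.null(R)) return(list(S = S2, R = R))
    eps <- eps * 10
  }
  stop("covariance could not be regularized to positive definite")
}

#' @export
print.QdcModel <- function(x, ...) {
  cat(sprintf("QdcModel: %d class(es), %d dimension(s)%s\n",
              length(x$classes), x$dim,
              if (x$shrink > 0) sprintf(", shrink = %g", x$shrink) else ""))
  invisible(x)
}

#' Predict with a quadratic discriminant classifier
#'
#' Evaluates the quadratic discriminant
#' \deqn{\delta_k(x) = -\tfrac12 \log|\Sigma_k|
#'   - \tfrac12 (x - \mu_k)^T \Sigma_k^{-1} (x - \mu_k) + \log\phi_k}
#' for every class and returns the argmax (ties go to the first class
#' in training order).
#'
#' @param model a `QdcModel` from [qdcFit()].
#' @param x numeric vector (one sample) or samples x dimensions matrix.
#' @return For a single sample, list with `label` and `scores`; for a
#'   matrix, list with `label` (vector) and `scores` (samples x
#'   classes matrix).
#' @export
qdcPredict <- function(model, x) {
  stopifnot(inherits(model, "QdcModel"))
  single <- is.vector(x)
  X <- if (single) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(X) != model$dim) {
    stop("dimension mismatch: model expects ", model$dim, " feature(s)")
  }
  scores <- matrix(NA_real_, nrow(X), length(model$classes),
                   dimnames = list(NULL, model$classes))
  for (cl in model$classes) {
    dev <- sweep(X, 2L, model$means[[cl]])
    z <- backsolve(model$chol[[cl]], t(dev), transpose = TRUE)
    maha <- colSums(z^2)
    scores[, cl] <- -0.5 * model$logdet[cl] - 0.5 * maha +
      log(model$priors[cl])
  }
  lab <- model$classes[apply(scores, 1L, which.max)]
  if (single) list(label = lab[1L], scores = scores[1L, ])
  else list(label = lab, scores = scores)
}
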