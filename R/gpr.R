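## ---------------------------------------------------------------------
## Gaussian process regression with the rational quadratic kernel
##
##   k(x, x') = sigma^2 (1 + r^2 / (2 alpha l^2))^(-alpha),
##   r^2 = (x - x')' (x - x'),
##
## a scale mixture of squared-exponential kernels (alpha -> Inf recovers
## the squared exponential). Hyperparameters (sigma, alpha, l, noiseSd)
## are fitted by maximising the log marginal likelihood with analytic
## gradients on the log-parameter scale; when the training set exceeds
## the block size the likelihood is evaluated on a seeded subset of
## block-size rows, while the predictive equations always use the full
## training set exactly. The mean function is the constant training
## target mean (zero after target standardisation).
## ---------------------------------------------------------------------

#' Construct kernel hyperparameters
#'
#' @param sigma signal standard deviation (amplitude), > 0.
#' @param alpha scale-mixture parameter, > 0.
#' @param lengthScale length-scale l, > 0.
#' @param noiseSd observation noise SD, >= 0.
#' @return a [KernelParams-class].
#' @export
kernelParameters <- function(sigma = 1, alpha = 1, lengthScale = 1,
                             noiseSd = 0.1) {
  new("KernelParams", sigma = sigma, alpha = alpha,
      lengthScale = lengthScale, noiseSd = noiseSd)
}

#' Rational quadratic kernel between two feature vectors
#'
#' \eqn{k(x, x') = \sigma^2 (1 + r^2/(2\alpha l^2))^{-\alpha}} with
#' \eqn{r} the Euclidean distance. Symmetric and positive; equals
#' \eqn{\sigma^2} at \eqn{r = 0} and tends to the squared-exponential
#' kernel as \eqn{\alpha \to \infty}.
#'
#' @param x,xPrime equal-length finite numeric vectors.
#' @param params a [KernelParams-class].
#' @return kernel value (scalar).
#' @examples
#' p <- kernelParameters(sigma = 1, alpha = 1, lengthScale = 1)
#' rqKernel(c(0, 0), c(1, 1), p)  # (1 + 2/2)^-1 = 0.5
#' @export
rqKernel <- function(x, xPrime, params) {
  stopifnot(is(params, "KernelParams"))
  if (length(x) != length(xPrime))
    stopNamed("myofuse_length_mismatch", "x and xPrime must match in length")
  if (!all(is.finite(x)) || !all(is.finite(xPrime)))
    stopNamed("myofuse_invalid_argument", "inputs must be finite")
  r2 <- sum((x - xPrime)^2)
  params@sigma^2 *
    (1 + r2 / (2 * params@alpha * params@lengthScale^2))^(-params@alpha)
}

## squared Euclidean distances between rows of A and rows of B
sqDistMatrix <- function(A, B = A) {
  d <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d[d < 0] <- 0
  d
}

.rqKernelFromD2 <- function(D2, sigma, alpha, l) {
  sigma^2 * (1 + D2 / (2 * alpha * l^2))^(-alpha)
}

#' Optimizer settings for GPR hyperparameter fitting
#'
#' Gradient-based (L-BFGS-B) maximisation of the marginal likelihood on
#' the log-parameter scale, with multi-restart and a block-size cap:
#' above `blockSize` training rows the likelihood is evaluated on a
#' seeded subset of `blockSize` rows (prediction always uses all rows).
#'
#' @param gradTol gradient tolerance (maps to L-BFGS-B `pgtol`).
#' @param stepTol objective step tolerance.
#' @param maxit iteration cap per restart.
#' @param blockSize subset size for the likelihood above this row count.
#' @param restarts number of seeded restarts.
#' @param seed RNG seed for subset sampling and restart jitter.
#' @param jitter relative diagonal jitter added for numerical stability.
#' @return named list.
#' @export
gprControl <- function(gradTol = 1e-3, stepTol = 1e-3, maxit = 200,
                       blockSize = 1000, restarts = 3, seed = 1L,
                       jitter = 1e-8) {
  list(gradTol = gradTol, stepTol = stepTol, maxit = maxit,
       blockSize = blockSize, restarts = restarts, seed = as.integer(seed),
       jitter = jitter)
}

## negative log marginal likelihood and its gradient wrt log-params.
## theta = log(sigma, alpha, l, noiseSd); y standardized.
.gprObjective <- function(theta, D2, y) {
  n <- length(y)
  sigma <- exp(theta[1]); alpha <- exp(theta[2])
  l <- exp(theta[3]); noise <- exp(theta[4])
  u <- 1 + D2 / (2 * alpha * l^2)
  Kf <- sigma^2 * u^(-alpha)
  K <- Kf + diag(noise^2 + 1e-10 * sigma^2, n)
  ch <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(ch))
    return(list(value = 1e10, gradient = rep(0, 4)))
  av <- backsolve(ch, forwardsolve(t(ch), y))
  nll <- 0.5 * sum(y * av) + sum(log(diag(ch))) + 0.5 * n * log(2 * pi)
  Kinv <- chol2inv(ch)
  A <- tcrossprod(av) - Kinv
  gr <- c(
    -0.5 * sum(A * (2 * Kf)),
    -0.5 * sum(A * (alpha * Kf * (-log(u) + (u - 1) / u))),
    -0.5 * sum(A * (2 * alpha * Kf * (u - 1) / u)),
    -0.5 * sum(diag(A)) * 2 * noise^2
  )
  list(value = nll, gradient = gr)
}

.gprOptimize <- function(D2, y, control) {
  n <- length(y)
  off <- D2[upper.tri(D2)]
  l0 <- sqrt(stats::median(off[off > 0]))
  if (!is.finite(l0) || l0 <= 0) l0 <- 1
  inits <- withSeed(control$seed, {
    lapply(seq_len(control$restarts), function(r) {
      base <- c(0, 0, log(l0), log(0.1))
      if (r > 1) base <- base + rnorm(4, 0, c(0.3, 0.7, 0.7, 0.7))
      base
    })
  })
  lower <- c(-6, log(1e-3), log(l0) - 6, log(1e-4))
  upper <- c(6, log(1e3), log(l0) + 6, log(10))
  best <- NULL
  for (init in inits) {
    cache <- new.env(parent = emptyenv())
    evalAt <- function(th) {
      key <- paste(format(th, digits = 17), collapse = ",")
      if (!identical(cache$key, key)) {
        cache$res <- .gprObjective(th, D2, y)
        cache$key <- key
      }
      cache$res
    }
    fit <- tryCatch(
      stats::optim(pmin(pmax(init, lower), upper),
                   fn = function(th) evalAt(th)$value,
                   gr = function(th) evalAt(th)$gradient,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = control$maxit,
                                  pgtol = control$gradTol,
                                  factr = control$stepTol / 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best))
    stopNamed("myofuse_fit_failed", "hyperparameter optimisation failed")
  list(params = kernelParameters(sigma = exp(best$par[1]),
                                 alpha = exp(best$par[2]),
                                 lengthScale = exp(best$par[3]),
                                 noiseSd = exp(best$par[4])),
       converged = best$convergence == 0,
       logMarginal = -best$value)
}

## weight vector (K + noise^2 I)^(-1) y on precomputed squared distances
.gprWeights <- function(D2, y, params, jitter) {
  n <- length(y)
  K <- .rqKernelFromD2(D2, params@sigma, params@alpha, params@lengthScale) +
    diag(params@noiseSd^2 + jitter * params@sigma^2, n)
  ch <- chol(K)
  backsolve(ch, forwardsolve(t(ch), y))
}

#' Fit a Gaussian process regression model
#'
#' Standardises features (per column) and target from the training data,
#' then maximises the log marginal likelihood over
#' (sigma, alpha, lengthScale, noiseSd) by seeded multi-restart L-BFGS-B
#' with analytic gradients. When `nrow(X)` exceeds
#' `control$blockSize`, the likelihood is evaluated on a seeded subset
#' of that size; the returned model always performs exact dense
#' prediction with the full training set. Supplying `params` skips the
#' optimisation (useful for fixed-hyperparameter analyses).
#'
#' @param X training feature matrix (rows = observations).
#' @param y training target vector.
#' @param params optional fixed [KernelParams-class].
#' @param control a [gprControl()] list.
#' @return a [GPRModel-class].
#' @export
fitGpr <- function(X, y, params = NULL, control = gprControl()) {
  X <- as.matrix(X)
  if (nrow(X) != length(y))
    stopNamed("myofuse_length_mismatch", "rows of X must match length of y")
  if (nrow(X) < 10L)
    stopNamed("myofuse_invalid_argument", "need at least 10 training rows")
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stopNamed("myofuse_invalid_argument", "X and y must be finite")
  if (stats::var(y) == 0)
    stopNamed("myofuse_degenerate_target",
              "target has zero variance; nothing to regress")

  xc <- colMeans(X)
  xs <- apply(X, 2, stats::sd)
  xs[xs < 1e-12] <- 1
  Z <- sweep(sweep(X, 2, xc), 2, xs, "/")
  yc <- mean(y)
  ys <- stats::sd(y)
  z <- (y - yc) / ys

  n <- nrow(Z)
  if (is.null(params)) {
    sub <- if (n > control$blockSize)
      withSeed(control$seed, sort(sample.int(n, control$blockSize)))
    else seq_len(n)
    opt <- .gprOptimize(sqDistMatrix(Z[sub, , drop = FALSE]), z[sub], control)
    pStd <- opt$params
    ## sigma and noiseSd are fitted on the standardized target; report
    ## them in output units
    params <- kernelParameters(sigma = pStd@sigma * ys, alpha = pStd@alpha,
                               lengthScale = pStd@lengthScale,
                               noiseSd = pStd@noiseSd * ys)
    converged <- opt$converged
    logMarg <- opt$logMarginal
  } else {
    stopifnot(is(params, "KernelParams"))
    pStd <- kernelParameters(sigma = params@sigma / ys, alpha = params@alpha,
                             lengthScale = params@lengthScale,
                             noiseSd = max(params@noiseSd / ys, 0))
    converged <- TRUE
    logMarg <- NA_real_
  }
  av <- .gprWeights(sqDistMatrix(Z), z, pStd, control$jitter)
  new("GPRModel", params = params, Xtrain = Z, alphaVec = av,
      xCenter = xc, xScale = xs, yCenter = yc, yScale = ys,
      converged = converged, logMarginal = logMarg, control = control)
}

#' Posterior mean prediction
#'
#' \eqn{m + k(X_{new}, X_{train}) (K + \sigma_n^2 I)^{-1} (y - m)}
#' de-standardised to output units; far from all training inputs the
#' prediction decays to the training-target mean.
#'
#' @param model a fitted [GPRModel-class].
#' @param Xnew feature matrix with the training column count.
#' @return numeric vector of predicted targets.
#' @export
predictMean <- function(model, Xnew) {
  stopifnot(is(model, "GPRModel"))
  Xnew <- as.matrix(Xnew)
  if (ncol(Xnew) != ncol(model@Xtrain))
    stopNamed("myofuse_length_mismatch",
              "Xnew has %d columns; model expects %d",
              ncol(Xnew), ncol(model@Xtrain))
  Z <- sweep(sweep(Xnew, 2, model@xCenter), 2, model@xScale, "/")
  ## the weight vector lives on the standardized target scale, where the
  ## amplitude is sigma / yScale
  Ks <- .rqKernelFromD2(sqDistMatrix(Z, model@Xtrain),
                        model@params@sigma / model@yScale,
                        model@params@alpha, model@params@lengthScale)
  as.vector(model@yCenter + model@yScale * (Ks %*% model@alphaVec))
}

#' @describeIn predictMean `predict` method alias.
#' @param object a [GPRModel-class].
#' @param newdata feature matrix.
#' @param ... ignored.
#' @export
setMethod("predict", "GPRModel", function(object, newdata, ...) {
  predictMean(object, newdata)
})
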