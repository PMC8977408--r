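# Independent brute-force oracles used across the suite. These are kept
# deliberately naive (explicit loops, dense solves) so they share no code
# path with the implementation they check.

# features of explicitly materialised sliding windows, via the exported
# per-window primitives
bruteWindowFeatures <- function(signals, fs, windowS, stepS, deadband = 0) {
  wlen <- round(windowS * fs)
  step <- round(stepS * fs)
  nWin <- floor((nrow(signals) - wlen) / step) + 1
  out <- NULL
  for (w in seq_len(nWin)) {
    idx <- ((w - 1) * step + 1):((w - 1) * step + wlen)
    row <- c()
    for (ch in seq_len(ncol(signals))) {
      x <- signals[idx, ch]
      ar <- suppressWarnings(arCoefficients(x))
      row <- c(row, mav(x), zeroCrossings(x, deadband),
               slopeSignChanges(x, deadband), waveformLength(x), ar)
    }
    out <- rbind(out, row)
  }
  unname(out)
}

# block means by an explicit double loop over pixel sub-arrays
bruteBlockMeans <- function(frame, blockPxAx, blockPxLat) {
  gAx <- nrow(frame) %/% blockPxAx
  gLat <- ncol(frame) %/% blockPxLat
  out <- matrix(0, gAx, gLat)
  for (i in seq_len(gAx)) {
    for (j in seq_len(gLat)) {
      out[i, j] <- mean(frame[((i - 1) * blockPxAx + 1):(i * blockPxAx),
                              ((j - 1) * blockPxLat + 1):(j * blockPxLat)])
    }
  }
  out
}

# dense GP posterior mean with a plain solve(), no caching or
# factorisation reuse: m + k(X*, X) (K + noise^2 I)^(-1) (y - m) in
# output units, with the constant mean m = mean(y) and features
# standardized as the model standardizes them
bruteGprMean <- function(Xtrain, y, Xnew, params) {
  xc <- colMeans(Xtrain)
  xs <- apply(Xtrain, 2, sd)
  xs[xs < 1e-12] <- 1
  Zt <- sweep(sweep(Xtrain, 2, xc), 2, xs, "/")
  Zn <- sweep(sweep(Xnew, 2, xc), 2, xs, "/")
  n <- nrow(Zt)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    K[i, j] <- rqKernel(Zt[i, ], Zt[j, ], params)
  Ks <- matrix(0, nrow(Zn), n)
  for (i in seq_len(nrow(Zn))) for (j in seq_len(n))
    Ks[i, j] <- rqKernel(Zn[i, ], Zt[j, ], params)
  w <- solve(K + diag(n) * params@noiseSd^2, y - mean(y))
  mean(y) + as.vector(Ks %*% w)
}

# one-way ANOVA F and p from the textbook sums-of-squares formulas
bruteAnova <- function(values, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  n <- length(values)
  gm <- tapply(values, groups, mean)
  cn <- tapply(values, groups, length)
  ssb <- sum(cn * (gm - mean(values))^2)
  ssw <- sum((values - gm[groups])^2)
  Fv <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = Fv, p = pf(Fv, k - 1, n - k, lower.tail = FALSE))
}

# small, fast synthetic dataset for pipeline-level tests
tinyDataset <- function(seed = 11, strides = 2L, noise = noiseConfig()) {
  cfg <- datasetConfig(
    stridesPerTask = setNames(rep(strides, 5),
                              c("level_walk", "incline_walk", "decline_walk",
                                "stair_ascent", "stair_descent")),
    noise = noise)
  generateGaitDataset(cfg, seed = seed)
}
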