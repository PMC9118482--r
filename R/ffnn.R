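## Minimal dense feed-forward network with ReLU hidden units, a sigmoid
## output, class-weighted binary cross-entropy, Adam updates and early
## stopping on validation AUC. Deliberately self-contained: the meta-model
## is the package's core method and its training must be byte-reproducible
## from a single seed, which plain R arithmetic guarantees.

.initNet <- function(d, hidden) {
  widths <- c(d, hidden, 1L)
  W <- list()
  b <- list()
  for (l in seq_len(length(widths) - 1L)) {
    fanIn <- widths[l]
    ## He initialization for ReLU layers; also fine for the sigmoid output
    W[[l]] <- matrix(stats::rnorm(fanIn * widths[l + 1L], sd = sqrt(2 / fanIn)),
                     fanIn, widths[l + 1L])
    b[[l]] <- numeric(widths[l + 1L])
  }
  list(W = W, b = b)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

.ffForward <- function(net, X) {
  L <- length(net$W)
  A <- X
  for (l in seq_len(L - 1L)) {
    A <- pmax(sweep(A %*% net$W[[l]], 2L, net$b[[l]], "+"), 0)
  }
  drop(.sigmoid(sweep(A %*% net$W[[L]], 2L, net$b[[L]], "+")))
}

## One forward+backward pass on a batch; returns gradients.
.ffGrad <- function(net, X, y, wgt) {
  L <- length(net$W)
  Z <- vector("list", L)
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% net$W[[l]], 2L, net$b[[l]], "+")
    A[[l + 1L]] <- if (l < L) pmax(Z[[l]], 0) else .sigmoid(Z[[l]])
  }
  m <- nrow(X)
  gW <- vector("list", L)
  gb <- vector("list", L)
  ## sigmoid + weighted BCE: output-layer delta is (p - y) * weight
  delta <- (A[[L + 1L]] - y) * wgt / m
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) delta <- (delta %*% t(net$W[[l]])) * (Z[[l - 1L]] > 0)
  }
  list(W = gW, b = gb)
}

.ffTrain <- function(X, y, Xval, yval, hidden,
                     epochs = 100L, batch = 256L, lr = 0.005,
                     patience = 10L) {
  n <- nrow(X)
  net <- .initNet(ncol(X), hidden)
  ## class weights inversely proportional to class frequency
  nPos <- sum(y == 1)
  wgt <- ifelse(y == 1, n / (2 * nPos), n / (2 * (n - nPos)))
  ## Adam state
  L <- length(net$W)
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(w) w * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t <- 0L
  bestAuc <- -Inf
  bestNet <- net
  wait <- 0L
  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = batch)
    for (s in starts) {
      idx <- ord[s:min(s + batch - 1L, n)]
      g <- .ffGrad(net, X[idx, , drop = FALSE], y[idx], wgt[idx])
      t <- t + 1L
      corr <- sqrt(1 - b2^t) / (1 - b1^t)
      for (l in seq_len(L)) {
        mW[[l]] <- b1 * mW[[l]] + (1 - b1) * g$W[[l]]
        vW[[l]] <- b2 * vW[[l]] + (1 - b2) * g$W[[l]]^2
        net$W[[l]] <- net$W[[l]] - lr * corr * mW[[l]] / (sqrt(vW[[l]]) + eps)
        mb[[l]] <- b1 * mb[[l]] + (1 - b1) * g$b[[l]]
        vb[[l]] <- b2 * vb[[l]] + (1 - b2) * g$b[[l]]^2
        net$b[[l]] <- net$b[[l]] - lr * corr * mb[[l]] / (sqrt(vb[[l]]) + eps)
      }
    }
    valAuc <- .aucFast(yval, .ffForward(net, Xval))
    if (valAuc > bestAuc + 1e-6) {
      bestAuc <- valAuc
      bestNet <- net
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  list(net = bestNet, valAuc = bestAuc, epochsRun = epoch)
}
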