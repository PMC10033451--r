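# Minimal feed-forward trainer for the classifier backbone: 1-D convolution
# (im2col), batch normalisation, max pooling (size 4, stride 2), halving
# dense layers with dropout, sigmoid outputs, binary cross-entropy loss and
# Adadelta updates. Written in base R matrix operations; gradients are
# checked against finite differences in the unit tests.

.convForward <- function(A, W, b) {
  dims <- dim(A); n <- dims[1]; L <- dims[2]; C <- dims[3]
  k <- nrow(W) / C; F <- ncol(W)
  Lout <- L - k + 1L
  if (Lout < 1L) stop("input too short for convolution kernel")
  Xcol <- matrix(0, n * Lout, k * C)
  for (c in seq_len(C)) for (j in seq_len(k))
    Xcol[, (c - 1L) * k + j] <- as.vector(A[, j:(j + Lout - 1L), c, drop = FALSE])
  Out <- sweep(Xcol %*% W, 2L, b, "+")
  O <- Out; dim(O) <- c(n, Lout, F)
  list(out = O, Xcol = Xcol, dims = c(n = n, L = L, C = C, k = k, F = F, Lout = Lout))
}

.convBackward <- function(cache, W, dO) {
  d <- cache$dims
  dOut <- dO; dim(dOut) <- c(d["n"] * d["Lout"], d["F"])
  dW <- crossprod(cache$Xcol, dOut)
  db <- colSums(dOut)
  dXcol <- dOut %*% t(W)
  dA <- array(0, dim = c(d["n"], d["L"], d["C"]))
  for (c in seq_len(d["C"])) for (j in seq_len(d["k"])) {
    slice <- matrix(dXcol[, (c - 1L) * d["k"] + j], d["n"], d["Lout"])
    dA[, j:(j + d["Lout"] - 1L), c] <- dA[, j:(j + d["Lout"] - 1L), c] + slice
  }
  list(dA = dA, dW = dW, db = db)
}

.bnForward <- function(A, gamma, beta, eps, training, rmean, rvar) {
  dims <- dim(A); C <- dims[3]
  xhat <- A; mu <- numeric(C); v <- numeric(C)
  for (c in seq_len(C)) {
    x <- A[, , c, drop = FALSE]
    if (training) { mu[c] <- mean(x); v[c] <- mean((x - mu[c])^2) }
    else { mu[c] <- rmean[c]; v[c] <- rvar[c] }
    xhat[, , c] <- (x - mu[c]) / sqrt(v[c] + eps)
  }
  out <- xhat
  for (c in seq_len(C)) out[, , c] <- gamma[c] * xhat[, , c] + beta[c]
  list(out = out, xhat = xhat, mu = mu, var = v, A = A)
}

.bnBackward <- function(cache, gamma, eps, dO) {
  dims <- dim(cache$A); C <- dims[3]; M <- dims[1] * dims[2]
  dA <- cache$A; dgamma <- numeric(C); dbeta <- numeric(C)
  for (c in seq_len(C)) {
    dy <- dO[, , c, drop = FALSE]
    xhat <- cache$xhat[, , c, drop = FALSE]
    invstd <- 1 / sqrt(cache$var[c] + eps)
    dgamma[c] <- sum(dy * xhat)
    dbeta[c] <- sum(dy)
    dxhat <- dy * gamma[c]
    xc <- cache$A[, , c, drop = FALSE] - cache$mu[c]
    dvar <- sum(dxhat * xc) * (-0.5) * invstd^3
    dmu <- -invstd * sum(dxhat) + dvar * mean(-2 * xc)
    dA[, , c] <- dxhat * invstd + dvar * 2 * xc / M + dmu / M
  }
  list(dA = dA, dgamma = dgamma, dbeta = dbeta)
}

.poolForward <- function(A, size = 4L, stride = 2L) {
  dims <- dim(A); n <- dims[1]; L <- dims[2]; C <- dims[3]
  P <- (L - size) %/% stride + 1L
  if (P < 1L) stop("input too short for max pooling")
  starts <- seq.int(1L, by = stride, length.out = P)
  M <- matrix(0, n * P * C, size)
  for (t in seq_len(size))
    M[, t] <- as.vector(A[, starts + t - 1L, , drop = FALSE])
  amax <- max.col(M, ties.method = "first")
  out <- M[cbind(seq_len(nrow(M)), amax)]
  dim(out) <- c(n, P, C)
  list(out = out, amax = amax, dims = c(n = n, L = L, C = C, P = P),
       starts = starts)
}

.poolBackward <- function(cache, dO) {
  d <- cache$dims; n <- d["n"]; L <- d["L"]; C <- d["C"]; P <- d["P"]
  dOv <- as.vector(dO)
  r <- seq_along(dOv)
  i <- ((r - 1L) %% n) + 1L
  p <- (((r - 1L) %/% n) %% P) + 1L
  c <- ((r - 1L) %/% (n * P)) + 1L
  pos <- cache$starts[p] + cache$amax - 1L
  idx <- i + (pos - 1L) * n + (c - 1L) * n * L
  dAvec <- numeric(n * L * C)
  agg <- rowsum(dOv, idx)
  dAvec[as.integer(rownames(agg))] <- agg[, 1L]
  array(dAvec, dim = c(n, L, C))
}

# Build the layer stack for an ArchitectureSpec. Dense sizes halve; the
# channel count is shared across conv layers.
.nnBuild <- function(spec, inputLen, outputLen, seed) {
  set.seed(seed)
  layers <- list()
  L <- inputLen; C <- 1L
  for (i in seq_len(spec@convLayers)) {
    k <- spec@kernelSize; F <- spec@filters
    if (L < k) stop("input too short for architecture (conv)")
    W <- matrix(stats::rnorm(k * C * F, sd = sqrt(2 / (k * C))), k * C, F)
    layers <- c(layers, list(list(type = "conv", W = W, b = numeric(F))))
    L <- L - k + 1L
    layers <- c(layers, list(list(type = "bn", gamma = rep(1, F),
                                  beta = numeric(F), rmean = numeric(F),
                                  rvar = rep(1, F), eps = 1e-5,
                                  momentum = 0.9)))
    layers <- c(layers, list(list(type = "relu")))
    P <- (L - spec@poolSize) %/% spec@poolStride + 1L
    if (P < 1L) stop("input too short for architecture (pool)")
    layers <- c(layers, list(list(type = "pool", size = spec@poolSize,
                                  stride = spec@poolStride)))
    L <- P; C <- F
  }
  layers <- c(layers, list(list(type = "flatten")))
  width <- L * C
  for (j in seq_len(spec@denseLayers)) {
    size <- max(1L, spec@firstDenseSize %/% (2L^(j - 1L)))
    W <- matrix(stats::rnorm(width * size, sd = sqrt(2 / width)), width, size)
    layers <- c(layers, list(list(type = "dense", W = W, b = numeric(size)),
                             list(type = "relu")))
    if (spec@dropout > 0)
      layers <- c(layers, list(list(type = "dropout", p = spec@dropout)))
    width <- size
  }
  W <- matrix(stats::rnorm(width * outputLen, sd = sqrt(1 / width)),
              width, outputLen)
  layers <- c(layers, list(list(type = "out", W = W, b = numeric(outputLen))))
  list(layers = layers, spec = spec, inputLen = inputLen, outputLen = outputLen)
}

.nnForward <- function(model, X, training = FALSE) {
  a <- X
  if (model$spec@convLayers > 0L) dim(a) <- c(nrow(X), ncol(X), 1L)
  caches <- vector("list", length(model$layers))
  layers <- model$layers
  for (li in seq_along(layers)) {
    lay <- layers[[li]]
    if (lay$type == "conv") {
      cf <- .convForward(a, lay$W, lay$b)
      a <- cf$out; caches[[li]] <- cf
    } else if (lay$type == "bn") {
      bf <- .bnForward(a, lay$gamma, lay$beta, lay$eps, training,
                       lay$rmean, lay$rvar)
      if (training) {
        layers[[li]]$rmean <- lay$momentum * lay$rmean + (1 - lay$momentum) * bf$mu
        layers[[li]]$rvar <- lay$momentum * lay$rvar + (1 - lay$momentum) * bf$var
      }
      a <- bf$out; caches[[li]] <- bf
    } else if (lay$type == "relu") {
      caches[[li]] <- list(mask = a > 0)
      a <- a * (a > 0)
    } else if (lay$type == "pool") {
      pf <- .poolForward(a, lay$size, lay$stride)
      a <- pf$out; caches[[li]] <- pf
    } else if (lay$type == "flatten") {
      caches[[li]] <- list(dims = dim(a))
      dim(a) <- c(dim(a)[1L], prod(dim(a)[-1L]))
    } else if (lay$type == "dropout") {
      if (training) {
        mask <- matrix(stats::rbinom(length(a), 1L, 1 - lay$p) / (1 - lay$p),
                       nrow(a), ncol(a))
        caches[[li]] <- list(mask = mask)
        a <- a * mask
      } else caches[[li]] <- list(mask = NULL)
    } else if (lay$type %in% c("dense", "out")) {
      caches[[li]] <- list(x = a)
      a <- sweep(a %*% lay$W, 2L, lay$b, "+")
    }
  }
  probs <- 1 / (1 + exp(-a))
  model$layers <- layers  # running BN stats
  list(probs = probs, logits = a, caches = caches, model = model)
}

# Full loss + gradients for one (mini-)batch. Returns mean BCE and one
# gradient entry per learnable layer (same list index).
.nnLossGrad <- function(model, X, Y, training = TRUE) {
  fw <- .nnForward(model, X, training = training)
  p <- fw$probs
  eps <- 1e-12
  loss <- -mean(Y * log(p + eps) + (1 - Y) * log(1 - p + eps))
  grad <- (p - Y) / length(Y)
  grads <- vector("list", length(model$layers))
  d <- grad
  for (li in rev(seq_along(model$layers))) {
    lay <- model$layers[[li]]
    cache <- fw$caches[[li]]
    if (lay$type %in% c("dense", "out")) {
      grads[[li]] <- list(W = crossprod(cache$x, d), b = colSums(d))
      d <- d %*% t(lay$W)
    } else if (lay$type == "dropout") {
      if (!is.null(cache$mask)) d <- d * cache$mask
    } else if (lay$type == "flatten") {
      dim(d) <- cache$dims
    } else if (lay$type == "pool") {
      d <- .poolBackward(cache, d)
    } else if (lay$type == "relu") {
      d <- d * cache$mask
    } else if (lay$type == "bn") {
      bb <- .bnBackward(cache, lay$gamma, lay$eps, d)
      grads[[li]] <- list(gamma = bb$dgamma, beta = bb$dbeta)
      d <- bb$dA
    } else if (lay$type == "conv") {
      cb <- .convBackward(cache, lay$W, d)
      grads[[li]] <- list(W = cb$dW, b = cb$db)
      d <- cb$dA
    }
  }
  list(loss = loss, grads = grads, model = fw$model)
}

.paramNames <- function(lay)
  switch(lay$type, conv = , dense = , out = c("W", "b"),
         bn = c("gamma", "beta"), character(0))

.adadeltaInit <- function(model) {
  lapply(model$layers, function(lay) {
    nms <- .paramNames(lay)
    if (!length(nms)) return(NULL)
    setNames(lapply(nms, function(nm)
      list(Eg2 = lay[[nm]] * 0, Edx2 = lay[[nm]] * 0)), nms)
  })
}

.adadeltaStep <- function(model, grads, state, lr, rho = 0.95, eps = 1e-6) {
  for (li in seq_along(model$layers)) {
    nms <- .paramNames(model$layers[[li]])
    for (nm in nms) {
      g <- grads[[li]][[nm]]
      st <- state[[li]][[nm]]
      st$Eg2 <- rho * st$Eg2 + (1 - rho) * g^2
      dx <- -sqrt((st$Edx2 + eps) / (st$Eg2 + eps)) * g
      st$Edx2 <- rho * st$Edx2 + (1 - rho) * dx^2
      model$layers[[li]][[nm]] <- model$layers[[li]][[nm]] + lr * dx
      state[[li]][[nm]] <- st
    }
  }
  list(model = model, state = state)
}

# Train one network. Early stopping (patience in epochs) on a held-out
# validation slice; the best-validation weights are restored.
.nnTrain <- function(X, Y, spec, epochs = 50L, batchSize = 32L, lr = 0.001,
                     seed = 1L, validationFraction = 0.1, patience = 3L,
                     verbose = FALSE) {
  set.seed(deriveSeed(seed, 17L))
  n <- nrow(X)
  nVal <- max(1L, round(validationFraction * n))
  valIdx <- sample.int(n, nVal)
  trIdx <- setdiff(seq_len(n), valIdx)
  model <- .nnBuild(spec, ncol(X), ncol(Y), seed = deriveSeed(seed, 23L))
  state <- .adadeltaInit(model)
  best <- list(loss = Inf, model = model)
  bad <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample(trIdx)
    batches <- split(ord, ceiling(seq_along(ord) / batchSize))
    for (bt in batches) {
      lg <- .nnLossGrad(model, X[bt, , drop = FALSE], Y[bt, , drop = FALSE],
                        training = TRUE)
      if (!is.finite(lg$loss))
        stop("divergent loss (NaN) while training member; aborting")
      model <- lg$model
      upd <- .adadeltaStep(model, lg$grads, state, lr)
      model <- upd$model; state <- upd$state
    }
    valFw <- .nnForward(model, X[valIdx, , drop = FALSE], training = FALSE)
    p <- valFw$probs
    valLoss <- -mean(Y[valIdx, , drop = FALSE] * log(p + 1e-12) +
                     (1 - Y[valIdx, , drop = FALSE]) * log(1 - p + 1e-12))
    txMessage(sprintf("epoch %d: val loss %.5f", ep, valLoss), verbose = verbose)
    if (valLoss < best$loss - 1e-6) {
      best <- list(loss = valLoss, model = model); bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) break
    }
  }
  structure(list(model = best$model, valLoss = best$loss, epochs = ep,
                 backbone = "cnn"), class = "txatlasMember")
}

.nnPredict <- function(member, X) {
  .nnForward(member$model, X, training = FALSE)$probs
}
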