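# Internal neural-network engine.
#
# Activations flow as C x (l*N) matrices (channels x time-major columns,
# grouped by case) so every layer is one BLAS matmul; convolutions use a
# compiled im2col construction (src/im2col.cpp). Backward passes are
# explicit; gradients are checked against finite differences in the test
# suite.
#
#' @useDynLib SupConTSC, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.rs <- function(x) .rowSums(x, nrow(x), ncol(x))
.rm <- function(x) .rowMeans(x, nrow(x), ncol(x))
.relu <- function(x) { x[x < 0] <- 0; x }

.heInit <- function(nOut, fanIn, shape) {
  array(stats::rnorm(prod(shape), 0, sqrt(2 / fanIn)), shape)
}

# ---- conv1d, stride 1, same padding (im2col/col2im compiled) ----

.conv1dFwd <- function(x, W, b, C, l, N, k) {
  Xcol <- im2col1d(x, C, l, N, k)
  y <- W %*% Xcol + b
  list(y = y, Xcol = Xcol)
}

.conv1dBwd <- function(dy, Xcol, W, C, l, N, k) {
  dW <- tcrossprod(dy, Xcol)
  db <- .rs(dy)
  dXcol <- crossprod(W, dy)            # (C*k) x (l*N)
  dx <- col2im1d(dXcol, C, l, N, k)
  list(dx = dx, dW = dW, db = db)
}

# ---- batch normalisation over (time x batch) per feature map ----

.bnFwd <- function(x, gamma, beta, run, train, momentum = 0.1, eps = 1e-5) {
  if (train) {
    mu <- .rm(x)
    v <- .rm((x - mu)^2)
    run$mean <- (1 - momentum) * run$mean + momentum * mu
    run$var <- (1 - momentum) * run$var + momentum * v
  } else {
    mu <- run$mean
    v <- run$var
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- (x - mu) * invstd
  list(y = xhat * gamma + beta, xhat = xhat, invstd = invstd, run = run)
}

.bnBwd <- function(dy, cache, gamma) {
  xhat <- cache$xhat
  M <- ncol(dy)
  dgamma <- .rs(dy * xhat)
  dbeta <- .rs(dy)
  dxhat <- dy * gamma
  dx <- (cache$invstd / M) *
    (M * dxhat - .rs(dxhat) - xhat * .rs(dxhat * xhat))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- network construction ----

.bnNames <- function(cfg) {
  out <- character()
  inC <- cfg$inChannels
  for (b in seq_along(cfg$blockFilters)) {
    out <- c(out, sprintf("enc.b%d.%s", b, c("ca", "cb", "cc")))
    if (inC != cfg$blockFilters[b]) out <- c(out, sprintf("enc.b%d.cs", b))
    inC <- cfg$blockFilters[b]
  }
  out
}

.initParams <- function(cfg) {
  p <- list()
  inC <- cfg$inChannels
  for (b in seq_along(cfg$blockFilters)) {
    f <- cfg$blockFilters[b]
    ks <- cfg$kernelSizes
    dims <- list(ca = c(inC, ks[1L]), cb = c(f, ks[2L]), cc = c(f, ks[3L]))
    for (nm in names(dims)) {
      C <- dims[[nm]][1L]; k <- dims[[nm]][2L]
      p[[sprintf("enc.b%d.%s.W", b, nm)]] <- .heInit(f, C * k, c(f, C * k))
      p[[sprintf("enc.b%d.%s.b", b, nm)]] <- numeric(f)
      p[[sprintf("enc.b%d.%s.gamma", b, nm)]] <- rep(1, f)
      p[[sprintf("enc.b%d.%s.beta", b, nm)]] <- numeric(f)
    }
    if (inC != f) {
      p[[sprintf("enc.b%d.cs.W", b)]] <- .heInit(f, inC, c(f, inC))
      p[[sprintf("enc.b%d.cs.b", b)]] <- numeric(f)
      p[[sprintf("enc.b%d.cs.gamma", b)]] <- rep(1, f)
      p[[sprintf("enc.b%d.cs.beta", b)]] <- numeric(f)
    }
    inC <- f
  }
  Dh <- cfg$blockFilters[length(cfg$blockFilters)]
  p[["proj.fc1.W"]] <- .heInit(cfg$projHidden, Dh, c(cfg$projHidden, Dh))
  p[["proj.fc1.b"]] <- numeric(cfg$projHidden)
  p[["proj.fc2.W"]] <- array(stats::rnorm(cfg$projDim * cfg$projHidden, 0,
                                          sqrt(1 / cfg$projHidden)),
                             c(cfg$projDim, cfg$projHidden))
  p[["proj.fc2.b"]] <- numeric(cfg$projDim)
  p[["cls.fc1.W"]] <- .heInit(cfg$clsHidden, Dh, c(cfg$clsHidden, Dh))
  p[["cls.fc1.b"]] <- numeric(cfg$clsHidden)
  p[["cls.fc2.W"]] <- array(stats::rnorm(cfg$nClasses * cfg$clsHidden, 0,
                                         sqrt(1 / cfg$clsHidden)),
                            c(cfg$nClasses, cfg$clsHidden))
  p[["cls.fc2.b"]] <- numeric(cfg$nClasses)
  p
}

.initBn <- function(cfg) {
  out <- list()
  inC <- cfg$inChannels
  for (b in seq_along(cfg$blockFilters)) {
    f <- cfg$blockFilters[b]
    for (nm in c("ca", "cb", "cc")) {
      out[[sprintf("enc.b%d.%s", b, nm)]] <- list(mean = numeric(f),
                                                  var = rep(1, f))
    }
    if (inC != f) {
      out[[sprintf("enc.b%d.cs", b)]] <- list(mean = numeric(f),
                                              var = rep(1, f))
    }
    inC <- f
  }
  out
}

# ---- encoder forward/backward ----

.encoderFwd <- function(net, x, l, N, train) {
  # x: C x (l*N) matrix
  cfg <- net$cfg
  caches <- list()
  a <- x
  inC <- cfg$inChannels
  for (b in seq_along(cfg$blockFilters)) {
    f <- cfg$blockFilters[b]
    ks <- cfg$kernelSizes
    bc <- list(inC = inC, input = a)
    nmC <- c(inC, f, f)
    cur <- a
    for (s in 1:3) {
      nm <- c("ca", "cb", "cc")[s]
      key <- sprintf("enc.b%d.%s", b, nm)
      cv <- .conv1dFwd(cur, net$params[[paste0(key, ".W")]],
                       net$params[[paste0(key, ".b")]],
                       nmC[s], l, N, ks[s])
      bn <- .bnFwd(cv$y, net$params[[paste0(key, ".gamma")]],
                   net$params[[paste0(key, ".beta")]],
                   net$bn[[key]], train)
      if (train) net$bn[[key]] <- bn$run
      bc[[nm]] <- list(Xcol = cv$Xcol, xhat = bn$xhat, invstd = bn$invstd,
                       preRelu = bn$y)
      cur <- if (s < 3L) .relu(bn$y) else bn$y
    }
    if (inC != f) {
      key <- sprintf("enc.b%d.cs", b)
      cv <- .conv1dFwd(a, net$params[[paste0(key, ".W")]],
                       net$params[[paste0(key, ".b")]], inC, l, N, 1L)
      bn <- .bnFwd(cv$y, net$params[[paste0(key, ".gamma")]],
                   net$params[[paste0(key, ".beta")]],
                   net$bn[[key]], train)
      if (train) net$bn[[key]] <- bn$run
      bc$cs <- list(Xcol = cv$Xcol, xhat = bn$xhat, invstd = bn$invstd)
      shortcut <- bn$y
    } else {
      shortcut <- a
    }
    s3 <- cur + shortcut
    bc$sum <- s3
    a <- .relu(s3)
    caches[[b]] <- bc
    inC <- f
  }
  A <- a                                   # final feature maps, F3 x (l*N)
  dim3 <- c(cfg$blockFilters[length(cfg$blockFilters)], l, N)
  Aarr <- A
  dim(Aarr) <- dim3
  h <- colMeans(aperm(Aarr, c(2, 1, 3)))   # Dh x N
  if (is.null(dim(h))) h <- matrix(h, dim3[1L], N)
  list(h = h, A = A, caches = caches, l = l, N = N)
}

.encoderBwd <- function(net, fwd, dh) {
  cfg <- net$cfg
  l <- fwd$l; N <- fwd$N
  Dh <- cfg$blockFilters[length(cfg$blockFilters)]
  dA <- dh[, rep(seq_len(N), each = l), drop = FALSE] / l
  grads <- list()
  dout <- dA
  ks <- cfg$kernelSizes
  for (b in rev(seq_along(cfg$blockFilters))) {
    bc <- fwd$caches[[b]]
    f <- cfg$blockFilters[b]
    inC <- bc$inC
    dsum <- dout * (bc$sum > 0)
    # main path: cc -> relu -> cb -> relu -> ca
    d <- dsum
    nmC <- c(inC, f, f)
    for (s in 3:1) {
      nm <- c("ca", "cb", "cc")[s]
      key <- sprintf("enc.b%d.%s", b, nm)
      lc <- bc[[nm]]
      bnb <- .bnBwd(d, lc, net$params[[paste0(key, ".gamma")]])
      grads[[paste0(key, ".gamma")]] <- bnb$dgamma
      grads[[paste0(key, ".beta")]] <- bnb$dbeta
      cvb <- .conv1dBwd(bnb$dx, lc$Xcol, net$params[[paste0(key, ".W")]],
                        nmC[s], l, N, ks[s])
      grads[[paste0(key, ".W")]] <- cvb$dW
      grads[[paste0(key, ".b")]] <- cvb$db
      d <- cvb$dx
      if (s > 1L) {
        prevPre <- bc[[c("ca", "cb", "cc")[s - 1L]]]$preRelu
        d <- d * (prevPre > 0)
      }
    }
    dmain <- d
    if (inC != f) {
      key <- sprintf("enc.b%d.cs", b)
      lc <- bc$cs
      bnb <- .bnBwd(dsum, lc, net$params[[paste0(key, ".gamma")]])
      grads[[paste0(key, ".gamma")]] <- bnb$dgamma
      grads[[paste0(key, ".beta")]] <- bnb$dbeta
      cvb <- .conv1dBwd(bnb$dx, lc$Xcol, net$params[[paste0(key, ".W")]],
                        inC, l, N, 1L)
      grads[[paste0(key, ".W")]] <- cvb$dW
      grads[[paste0(key, ".b")]] <- cvb$db
      dsc <- cvb$dx
    } else {
      dsc <- dsum
    }
    dout <- dmain + dsc
  }
  list(dx = dout, grads = grads)
}

# ---- projection head / classifier ----

.mlpFwd <- function(net, h, prefix) {
  W1 <- net$params[[paste0(prefix, ".fc1.W")]]
  b1 <- net$params[[paste0(prefix, ".fc1.b")]]
  W2 <- net$params[[paste0(prefix, ".fc2.W")]]
  b2 <- net$params[[paste0(prefix, ".fc2.b")]]
  a1 <- W1 %*% h + b1
  r1 <- .relu(a1)
  y <- W2 %*% r1 + b2
  list(y = y, a1 = a1, r1 = r1, h = h)
}

.mlpBwd <- function(net, cache, dy, prefix) {
  W1 <- net$params[[paste0(prefix, ".fc1.W")]]
  W2 <- net$params[[paste0(prefix, ".fc2.W")]]
  grads <- list()
  grads[[paste0(prefix, ".fc2.W")]] <- dy %*% t(cache$r1)
  grads[[paste0(prefix, ".fc2.b")]] <- .rs(dy)
  dr1 <- crossprod(W2, dy)
  da1 <- dr1 * (cache$a1 > 0)
  grads[[paste0(prefix, ".fc1.W")]] <- da1 %*% t(cache$h)
  grads[[paste0(prefix, ".fc1.b")]] <- .rs(da1)
  dh <- crossprod(W1, da1)
  list(dh = dh, grads = grads)
}

.l2normFwd <- function(v) {
  nrm <- sqrt(colSums(v^2))
  nrm[nrm == 0] <- 1
  z <- v / rep(nrm, each = nrow(v))
  list(z = z, nrm = nrm)
}

.l2normBwd <- function(cache, dz) {
  z <- cache$z
  (dz - z * rep(colSums(z * dz), each = nrow(z))) /
    rep(cache$nrm, each = nrow(z))
}

.softmaxCols <- function(logits) {
  mx <- apply(logits, 2, max)
  e <- exp(logits - rep(mx, each = nrow(logits)))
  e / rep(colSums(e), each = nrow(logits))
}

# ---- Adam ----

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adamStep <- function(net, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  net$adam$t <- net$adam$t + 1L
  t <- net$adam$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    net$adam$m[[nm]] <- beta1 * net$adam$m[[nm]] + (1 - beta1) * g
    net$adam$v[[nm]] <- beta2 * net$adam$v[[nm]] + (1 - beta2) * g^2
    mhat <- net$adam$m[[nm]] / (1 - beta1^t)
    vhat <- net$adam$v[[nm]] / (1 - beta2^t)
    net$params[[nm]] <- net$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  invisible(net)
}

.sumGrads <- function(g1, g2) {
  for (nm in names(g2)) {
    g1[[nm]] <- if (is.null(g1[[nm]])) g2[[nm]] else g1[[nm]] + g2[[nm]]
  }
  g1
}

# batch array helper: dataset layout n x m x l -> engine layout m x (l*N)
.toEngine <- function(x) {
  if (length(dim(x)) == 2L) x <- array(x, c(1L, dim(x)))
  N <- dim(x)[1L]; m <- dim(x)[2L]; l <- dim(x)[3L]
  y <- aperm(x, c(2, 3, 1))
  dim(y) <- c(m, l * N)
  list(x = y, m = m, l = l, N = N)
}
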