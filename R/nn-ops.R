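# Numerical core of the temporal classifier: plain-matrix forward and
# backward passes for every layer (linear projection, sinusoidal/learned
# positional encoding, multihead self-attention, layer normalization,
# position-wise feedforward, 1-D temporal convolution, masked mean pooling,
# softmax head) plus the Adam optimizer. Parameters live in a flat named
# list of numeric arrays; gradients mirror that structure. Correctness is
# established by finite-difference gradient checks and closed-form oracles
# in the test suite.

LN_EPS <- 1e-5

softmax_rows <- function(x) {
  m <- apply(x, 1, max)
  e <- exp(x - m)
  e / rowSums(e)
}

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# ---- positional encoding ----------------------------------------------------

# Classic sinusoidal table: PE[p, 2i]   = sin(p / 10000^(2i/d))
#                           PE[p, 2i+1] = cos(p / 10000^(2i/d))
# with zero-based position p and dimension index 2i.
sinusoidal_encoding <- function(n_pos, d) {
  pe <- matrix(0, n_pos, d)
  pos <- 0:(n_pos - 1)
  for (i in 0:(ceiling(d / 2) - 1)) {
    freq <- 1 / 10000^((2 * i) / d)
    if (2 * i + 1 <= d) pe[, 2 * i + 1] <- sin(pos * freq)
    if (2 * i + 2 <= d) pe[, 2 * i + 2] <- cos(pos * freq)
  }
  pe
}

# ---- layer norm -------------------------------------------------------------

layernorm_fwd <- function(x, gamma, beta) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  s <- sqrt(v + LN_EPS)
  xhat <- xc / s
  y <- sweep(xhat, 2, gamma, "*")
  y <- sweep(y, 2, beta, "+")
  list(y = y, xhat = xhat, s = s)
}

layernorm_bwd <- function(dy, cache, gamma) {
  xhat <- cache$xhat; s <- cache$s
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, gamma, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) / s
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- multihead self-attention ----------------------------------------------

mha_fwd <- function(x, p, prefix, n_heads, mask) {
  d <- ncol(x)
  dh <- d %/% n_heads
  Q <- sweep(x %*% p[[paste0(prefix, "Wq")]], 2, p[[paste0(prefix, "bq")]], "+")
  K <- sweep(x %*% p[[paste0(prefix, "Wk")]], 2, p[[paste0(prefix, "bk")]], "+")
  V <- sweep(x %*% p[[paste0(prefix, "Wv")]], 2, p[[paste0(prefix, "bv")]], "+")
  O <- matrix(0, nrow(x), d)
  heads <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    idx <- (h - 1) * dh + seq_len(dh)
    S <- (Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE])) / sqrt(dh)
    if (!all(mask)) S[, !mask] <- -Inf
    A <- softmax_rows(S)
    O[, idx] <- A %*% V[, idx, drop = FALSE]
    heads[[h]] <- list(A = A, idx = idx)
  }
  out <- sweep(O %*% p[[paste0(prefix, "Wo")]], 2, p[[paste0(prefix, "bo")]], "+")
  list(out = out, cache = list(x = x, Q = Q, K = K, V = V, O = O,
                               heads = heads, dh = dh))
}

mha_bwd <- function(dout, cache, p, prefix, grads) {
  x <- cache$x; Q <- cache$Q; K <- cache$K; V <- cache$V; O <- cache$O
  dh <- cache$dh
  grads[[paste0(prefix, "Wo")]] <- t(O) %*% dout
  grads[[paste0(prefix, "bo")]] <- colSums(dout)
  dO <- dout %*% t(p[[paste0(prefix, "Wo")]])
  dQ <- matrix(0, nrow(x), ncol(x))
  dK <- dQ; dV <- dQ
  for (head in cache$heads) {
    idx <- head$idx; A <- head$A
    dOh <- dO[, idx, drop = FALSE]
    dA <- dOh %*% t(V[, idx, drop = FALSE])
    dV[, idx] <- t(A) %*% dOh
    dS <- A * (dA - rowSums(dA * A)) # softmax jacobian, row-wise
    dQ[, idx] <- (dS %*% K[, idx, drop = FALSE]) / sqrt(dh)
    dK[, idx] <- (t(dS) %*% Q[, idx, drop = FALSE]) / sqrt(dh)
  }
  dx <- matrix(0, nrow(x), ncol(x))
  for (nm in c("q", "k", "v")) {
    dmat <- switch(nm, q = dQ, k = dK, v = dV)
    grads[[paste0(prefix, "W", nm)]] <- t(x) %*% dmat
    grads[[paste0(prefix, "b", nm)]] <- colSums(dmat)
    dx <- dx + dmat %*% t(p[[paste0(prefix, "W", nm)]])
  }
  list(dx = dx, grads = grads)
}

# ---- temporal 1-D convolution ----------------------------------------------

# Same-padded conv along the time axis: input T x d, kernel k (odd),
# output T x C. Implemented by unfolding windows into a T x (k*d) matrix.
conv1d_fwd <- function(x, Wc, bc) {
  k <- dim(Wc)[1]; d <- dim(Wc)[2]; cc <- dim(Wc)[3]
  half <- (k - 1L) %/% 2L
  tt <- nrow(x)
  xpad <- rbind(matrix(0, half, d), x, matrix(0, half, d))
  U <- matrix(0, tt, k * d)
  for (j in seq_len(k)) {
    U[, (j - 1) * d + seq_len(d)] <- xpad[j:(j + tt - 1), , drop = FALSE]
  }
  Wm <- matrix(Wc, k * d, cc) # array stride: (j, dim, channel), matches U blocks
  y <- sweep(U %*% Wm, 2, bc, "+")
  list(y = y, cache = list(U = U, Wm = Wm, k = k, d = d, half = half, tt = tt))
}

conv1d_bwd <- function(dy, cache) {
  U <- cache$U; Wm <- cache$Wm
  k <- cache$k; d <- cache$d; half <- cache$half; tt <- cache$tt
  dWm <- t(U) %*% dy
  dbc <- colSums(dy)
  dU <- dy %*% t(Wm)
  dxpad <- matrix(0, tt + 2 * half, d)
  for (j in seq_len(k)) {
    dxpad[j:(j + tt - 1), ] <- dxpad[j:(j + tt - 1), ] +
      dU[, (j - 1) * d + seq_len(d), drop = FALSE]
  }
  list(dx = dxpad[(half + 1):(half + tt), , drop = FALSE],
       dWc = array(dWm, dim = c(k, d, dim(dy)[2])), dbc = dbc)
}

# ---- dropout ----------------------------------------------------------------

dropout_fwd <- function(x, p, train) {
  if (!train || p <= 0) return(list(y = x, mask = NULL))
  keep <- matrix(stats::runif(length(x)) >= p, nrow(x), ncol(x))
  list(y = x * keep / (1 - p), mask = keep / (1 - p))
}

dropout_bwd <- function(dy, mask) {
  if (is.null(mask)) dy else dy * mask
}

# ---- full temporal model forward / backward ---------------------------------

# Forward pass over one feature sequence. `x` is T x input_dim; `mask` is a
# logical vector (TRUE = real frame). Returns logits and, when
# `need_cache`, everything the backward pass needs.
temporal_forward <- function(params, config, x, mask = NULL,
                             train = FALSE, need_cache = FALSE) {
  tt <- nrow(x)
  mask <- mask %||% rep(TRUE, tt)
  assert_that(length(mask) == tt, "mask length must match sequence length")
  assert_that(tt <= config$max_len, "sequence longer than max_len")
  d <- config$model_dim
  cache <- list(x = x, mask = mask)

  h <- sweep(x %*% params$proj_W, 2, params$proj_b, "+")
  pe <- if (config$positional_encoding == "learned") {
    params$pos_P[seq_len(tt), , drop = FALSE]
  } else {
    sinusoidal_encoding(tt, d)
  }
  h <- h + pe
  drop0 <- dropout_fwd(h, config$dropout, train)
  h <- drop0$y
  cache$drop0 <- drop0$mask

  layer_caches <- vector("list", config$n_encoder_layers)
  for (l in seq_len(config$n_encoder_layers)) {
    pre <- paste0("l", l, "_")
    att <- mha_fwd(h, params, pre, config$n_heads, mask)
    dropa <- dropout_fwd(att$out, config$dropout, train)
    ln1 <- layernorm_fwd(h + dropa$y, params[[paste0(pre, "ln1_g")]],
                         params[[paste0(pre, "ln1_b")]])
    h1 <- ln1$y
    z <- sweep(h1 %*% params[[paste0(pre, "W1")]], 2,
               params[[paste0(pre, "b1")]], "+")
    a <- pmax(z, 0)
    f <- sweep(a %*% params[[paste0(pre, "W2")]], 2,
               params[[paste0(pre, "b2")]], "+")
    dropf <- dropout_fwd(f, config$dropout, train)
    ln2 <- layernorm_fwd(h1 + dropf$y, params[[paste0(pre, "ln2_g")]],
                         params[[paste0(pre, "ln2_b")]])
    layer_caches[[l]] <- list(h_in = h, att = att, dropa = dropa$mask,
                              ln1 = ln1, h1 = h1, z = z, a = a,
                              dropf = dropf$mask, ln2 = ln2)
    h <- ln2$y
  }
  cache$layers <- layer_caches
  cache$encoded <- h

  hm <- h * mask # zero padded rows so they cannot leak through the conv
  cv <- conv1d_fwd(hm, params$conv_W, params$conv_b)
  act <- if (config$conv_activation == "relu") pmax(cv$y, 0) else cv$y
  nvalid <- sum(mask)
  assert_that(nvalid > 0, "all-padded sequence")
  g <- colSums(act * mask) / nvalid
  logits <- as.numeric(g %*% params$head_W + params$head_b)
  cache$conv <- cv$cache; cache$cv_y <- cv$y; cache$act <- act
  cache$g <- g; cache$nvalid <- nvalid

  out <- list(logits = logits, probs = softmax_vec(logits),
              embedding = g, encoded = h)
  if (need_cache) out$cache <- cache
  out
}

# Backward pass. `dlogits` is a length-2 numeric. Returns a gradient list
# mirroring `params`, plus the gradient wrt the input features (`dx`) for
# class-activation mapping.
temporal_backward <- function(params, config, cache, dlogits) {
  grads <- list()
  mask <- cache$mask
  g <- cache$g
  grads$head_W <- outer(g, dlogits)
  grads$head_b <- dlogits
  dg <- as.numeric(params$head_W %*% dlogits)

  dact <- (matrix(dg, nrow = length(mask), ncol = length(dg), byrow = TRUE) *
             mask) / cache$nvalid
  dcv <- if (config$conv_activation == "relu") dact * (cache$cv_y > 0) else dact
  cb <- conv1d_bwd(dcv, cache$conv)
  grads$conv_W <- cb$dWc
  grads$conv_b <- cb$dbc
  dh <- cb$dx * mask

  for (l in rev(seq_len(config$n_encoder_layers))) {
    pre <- paste0("l", l, "_")
    lc <- cache$layers[[l]]
    ln2b <- layernorm_bwd(dh, lc$ln2, params[[paste0(pre, "ln2_g")]])
    grads[[paste0(pre, "ln2_g")]] <- ln2b$dgamma
    grads[[paste0(pre, "ln2_b")]] <- ln2b$dbeta
    dsum2 <- ln2b$dx
    df <- dropout_bwd(dsum2, lc$dropf)
    grads[[paste0(pre, "W2")]] <- t(lc$a) %*% df
    grads[[paste0(pre, "b2")]] <- colSums(df)
    da <- df %*% t(params[[paste0(pre, "W2")]])
    dz <- da * (lc$z > 0)
    grads[[paste0(pre, "W1")]] <- t(lc$h1) %*% dz
    grads[[paste0(pre, "b1")]] <- colSums(dz)
    dh1 <- dsum2 + dz %*% t(params[[paste0(pre, "W1")]])
    ln1b <- layernorm_bwd(dh1, lc$ln1, params[[paste0(pre, "ln1_g")]])
    grads[[paste0(pre, "ln1_g")]] <- ln1b$dgamma
    grads[[paste0(pre, "ln1_b")]] <- ln1b$dbeta
    dsum1 <- ln1b$dx
    datt <- dropout_bwd(dsum1, lc$dropa)
    mb <- mha_bwd(datt, lc$att$cache, params, pre, grads)
    grads <- mb$grads
    dh <- dsum1 + mb$dx
  }

  d0 <- dropout_bwd(dh, cache$drop0)
  if (config$positional_encoding == "learned") {
    dP <- matrix(0, nrow(params$pos_P), ncol(params$pos_P))
    dP[seq_len(nrow(d0)), ] <- d0
    grads$pos_P <- dP
  }
  grads$proj_W <- t(cache$x) %*% d0
  grads$proj_b <- colSums(d0)
  dx <- d0 %*% t(params$proj_W)
  list(grads = grads, dx = dx)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

accumulate_grads <- function(total, grads) {
  if (is.null(total)) return(grads)
  for (nm in names(grads)) total[[nm]] <- total[[nm]] + grads[[nm]]
  total
}

scale_grads <- function(grads, s) lapply(grads, function(g) g * s)
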