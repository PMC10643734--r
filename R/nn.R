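# Minimal dense/convolutional neural-network primitives with hand-written
# backward passes, sufficient for the denoiser architectures used here.
# Tensor layout: 2D feature maps are arrays (H, W, N, C); 3D feature maps are
# arrays (X, Y, Z, N, C). N is the batch axis. All convolutions are
# stride-1, kernel-3, zero-padded "same" (im2col + BLAS matmul), so spatial
# shape is preserved and downsampling happens only in pooling layers.
#
# Each primitive `*_fwd` returns list(y, cache); the matching `*_bwd` takes
# (dy, cache) and returns list(dx, and parameter gradients where relevant).

nn_init_conv2d <- function(cin, cout, gain = sqrt(2), zero = FALSE) {
  sd <- if (zero) 0 else gain / sqrt(9 * cin)
  list(W = array(stats::rnorm(9 * cin * cout, 0, sd), c(cin, 3, 3, cout)),
       b = numeric(cout))
}

nn_init_conv3d <- function(cin, cout, gain = sqrt(2), zero = FALSE) {
  sd <- if (zero) 0 else gain / sqrt(27 * cin)
  list(W = array(stats::rnorm(27 * cin * cout, 0, sd), c(cin, 3, 3, 3, cout)),
       b = numeric(cout))
}

nn_init_dense <- function(cin, cout, gain = 1, zero = FALSE) {
  sd <- if (zero) 0 else gain / sqrt(cin)
  list(W = matrix(stats::rnorm(cin * cout, 0, sd), cin, cout),
       b = numeric(cout))
}

# ---- 2D convolution, kernel 3x3, pad 1 ------------------------------------

conv2d_fwd <- function(x, p, need_cache = TRUE) {
  d <- dim(x)
  cout <- dim(p$W)[4]
  Wm <- matrix(p$W, 9 * d[4], cout)
  r <- conv2d3x3_cpp(x, d, Wm, p$b, need_cache)
  list(y = array(r$y, c(d[1], d[2], d[3], cout)),
       cache = if (need_cache) list(col = r$col, dimx = d))
}

# transposed kernel: backward of a 3x3 "same" conv is a 3x3 "same" conv of dy
# with the spatially flipped, channel-swapped kernel
flip_kernel2d <- function(W) aperm(W[, 3:1, 3:1, , drop = FALSE], c(4, 2, 3, 1))

conv2d_bwd <- function(dy, cache, p) {
  d <- cache$dimx
  cout <- dim(p$W)[4]
  dym <- matrix(dy, d[1] * d[2] * d[3], cout)
  dW <- array(crossprod(cache$col, dym), dim(p$W))
  db <- colSums(dym)
  dx <- conv2d_fwd(array(dy, c(d[1], d[2], d[3], cout)),
                   list(W = flip_kernel2d(p$W), b = numeric(d[4])),
                   need_cache = FALSE)$y
  list(dx = dx, dW = dW, db = db)
}

# ---- 3D convolution, kernel 3x3x3, pad 1 ----------------------------------

conv3d_fwd <- function(x, p, need_cache = TRUE) {
  d <- dim(x)  # X Y Z N C
  cout <- dim(p$W)[5]
  Wm <- matrix(p$W, 27 * d[5], cout)
  xp <- array(0, c(d[1] + 2, d[2] + 2, d[3] + 2, d[4], d[5]))
  xp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), , ] <- x

  build_col <- function(zs) {  # zs: output z indices of this slab
    col <- matrix(0, d[1] * d[2] * length(zs) * d[4], 27 * d[5])
    blk <- 0L
    for (kz in 0:2) for (kx in 0:2) for (ky in 0:2) {
      s <- xp[ky + seq_len(d[1]), kx + seq_len(d[2]), kz + zs, , ,
              drop = FALSE]
      col[, blk * d[5] + seq_len(d[5])] <-
        matrix(s, d[1] * d[2] * length(zs) * d[4], d[5])
      blk <- blk + 1L
    }
    col
  }

  if (need_cache) {
    col <- build_col(seq_len(d[3]))
    y <- sweep(col %*% Wm, 2, p$b, `+`)
    return(list(y = array(y, c(d[1], d[2], d[3], d[4], cout)),
                cache = list(col = col, dimx = d)))
  }
  # inference path: bound memory by processing z-slabs
  slab <- max(1L, min(d[3], floor(2e7 / (d[1] * d[2] * d[4] * 27 * d[5]))))
  y <- array(0, c(d[1], d[2], d[3], d[4], cout))
  z0 <- 1L
  while (z0 <= d[3]) {
    zs <- z0:min(d[3], z0 + slab - 1L)
    ys <- sweep(build_col(zs) %*% Wm, 2, p$b, `+`)
    y[, , zs, , ] <- array(ys, c(d[1], d[2], length(zs), d[4], cout))
    z0 <- z0 + slab
  }
  list(y = y, cache = NULL)
}

conv3d_bwd <- function(dy, cache, p) {
  d <- cache$dimx
  cout <- dim(p$W)[5]
  dym <- matrix(dy, prod(d[1:4]), cout)
  Wm <- matrix(p$W, 27 * d[5], cout)
  dW <- array(crossprod(cache$col, dym), dim(p$W))
  db <- colSums(dym)
  dcol <- dym %*% t(Wm)
  dxp <- array(0, c(d[1] + 2, d[2] + 2, d[3] + 2, d[4], d[5]))
  blk <- 0L
  for (kz in 0:2) for (kx in 0:2) for (ky in 0:2) {
    dxp[ky + seq_len(d[1]), kx + seq_len(d[2]), kz + seq_len(d[3]), , ] <-
      dxp[ky + seq_len(d[1]), kx + seq_len(d[2]), kz + seq_len(d[3]), , ,
          drop = FALSE] +
      array(dcol[, blk * d[5] + seq_len(d[5])], c(d[1:4], d[5]))
    blk <- blk + 1L
  }
  list(dx = dxp[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1), , , drop = FALSE],
       dW = dW, db = db)
}

# ---- pointwise (1x1) convolution over the channel (last) axis -------------

pointwise_fwd <- function(x, p) {
  d <- dim(x)
  nd <- length(d)
  xm <- matrix(x, prod(d[-nd]), d[nd])
  y <- sweep(xm %*% p$W, 2, p$b, `+`)
  list(y = array(y, c(d[-nd], ncol(p$W))), cache = list(xm = xm, dimx = d))
}

pointwise_bwd <- function(dy, cache, p) {
  d <- cache$dimx
  nd <- length(d)
  dym <- matrix(dy, prod(d[-nd]), ncol(p$W))
  list(dx = array(dym %*% t(p$W), d),
       dW = crossprod(cache$xm, dym), db = colSums(dym))
}

# ---- activations -----------------------------------------------------------

silu_fwd <- function(x) {
  s <- 1 / (1 + exp(-x))
  list(y = x * s, cache = list(x = x, s = s))
}

silu_bwd <- function(dy, cache) {
  s <- cache$s
  dy * (s * (1 + cache$x * (1 - s)))
}

# ---- group normalisation ---------------------------------------------------
# Normalises over spatial axes and channels-within-group, per sample.
# gamma/beta are per channel. Works for 2D and 3D layouts (batch axis is
# second-to-last, channels last).

groupnorm_fwd <- function(x, gamma, beta, groups, eps = 1e-5) {
  d <- dim(x)
  nd <- length(d)
  C <- d[nd]; N <- d[nd - 1]
  S <- prod(d[1:(nd - 2)])  # spatial size
  G <- min(groups, C)
  while (C %% G != 0) G <- G - 1
  cg <- C / G
  xm <- matrix(x, S * N, C)
  xhat <- matrix(0, S * N, C)
  mu <- matrix(0, N, G); istd <- matrix(0, N, G)
  nrow_idx <- rep(seq_len(N), each = S)
  for (g in seq_len(G)) {
    cols <- ((g - 1) * cg + 1):(g * cg)
    sub <- xm[, cols, drop = FALSE]
    # per-sample mean/var over spatial x channels-in-group
    cm <- .colMeans(sub, S, N * cg)            # (n, c) means
    m <- .rowMeans(matrix(cm, N, cg), N, cg)
    cm2 <- .colMeans(sub * sub, S, N * cg)
    v <- .rowMeans(matrix(cm2, N, cg), N, cg) - m^2
    mu[, g] <- m; istd[, g] <- 1 / sqrt(pmax(v, 0) + eps)
    xhat[, cols] <- (sub - m[nrow_idx]) * istd[nrow_idx, g]
  }
  y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(y = array(y, d),
       cache = list(xhat = xhat, istd = istd, dimx = d, G = G, cg = cg,
                    nrow_idx = nrow_idx))
}

groupnorm_bwd <- function(dy, cache, gamma) {
  d <- cache$dimx
  nd <- length(d)
  C <- d[nd]; N <- d[nd - 1]
  S <- prod(d[1:(nd - 2)])
  dym <- matrix(dy, S * N, C)
  xhat <- cache$xhat
  dgamma <- colSums(dym * xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, gamma, `*`)
  dx <- matrix(0, S * N, C)
  idx <- cache$nrow_idx
  for (g in seq_len(cache$G)) {
    cols <- ((g - 1) * cache$cg + 1):(g * cache$cg)
    dxh <- array(dxhat[, cols, drop = FALSE], c(S, N, cache$cg))
    xh <- array(xhat[, cols, drop = FALSE], c(S, N, cache$cg))
    cg <- cache$cg
    m1 <- .rowMeans(matrix(.colMeans(dxh, S, N * cg), N, cg), N, cg)
    m2 <- .rowMeans(matrix(.colMeans(dxh * xh, S, N * cg), N, cg), N, cg)
    corr <- sweep(sweep(xh, 2, m2, `*`), 2, m1, `+`)
    dx[, cols] <- matrix(sweep(dxh - corr, 2, cache$istd[, g], `*`),
                         S * N, cache$cg)
  }
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

# ---- 2x pooling / nearest upsampling (2D) ----------------------------------

avgpool2_fwd <- function(x) {
  d <- dim(x)
  io <- seq(1, d[1], 2); jo <- seq(1, d[2], 2)
  y <- (x[io, jo, , , drop = FALSE] + x[io + 1, jo, , , drop = FALSE] +
        x[io, jo + 1, , , drop = FALSE] + x[io + 1, jo + 1, , , drop = FALSE]) / 4
  list(y = y, cache = d)
}

avgpool2_bwd <- function(dy, d) {
  dx <- array(0, d)
  io <- seq(1, d[1], 2); jo <- seq(1, d[2], 2)
  q <- dy / 4
  dx[io, jo, , ] <- q; dx[io + 1, jo, , ] <- q
  dx[io, jo + 1, , ] <- q; dx[io + 1, jo + 1, , ] <- q
  dx
}

upnn2_fwd <- function(x) {
  d <- dim(x)
  list(y = x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
             drop = FALSE],
       cache = d)
}

upnn2_bwd <- function(dy, d) {
  io <- seq(1, 2 * d[1], 2); jo <- seq(1, 2 * d[2], 2)
  dy[io, jo, , , drop = FALSE] + dy[io + 1, jo, , , drop = FALSE] +
    dy[io, jo + 1, , , drop = FALSE] + dy[io + 1, jo + 1, , , drop = FALSE]
}

# ---- 2x pooling / nearest upsampling (3D) ----------------------------------

avgpool2_3d_fwd <- function(x) {
  d <- dim(x)
  io <- seq(1, d[1], 2); jo <- seq(1, d[2], 2); ko <- seq(1, d[3], 2)
  y <- array(0, c(d[1] / 2, d[2] / 2, d[3] / 2, d[4], d[5]))
  for (a in 0:1) for (b in 0:1) for (cc in 0:1)
    y <- y + x[io + a, jo + b, ko + cc, , , drop = FALSE]
  list(y = y / 8, cache = d)
}

avgpool2_3d_bwd <- function(dy, d) {
  dx <- array(0, d)
  io <- seq(1, d[1], 2); jo <- seq(1, d[2], 2); ko <- seq(1, d[3], 2)
  q <- dy / 8
  for (a in 0:1) for (b in 0:1) for (cc in 0:1)
    dx[io + a, jo + b, ko + cc, , ] <- q
  dx
}

upnn2_3d_fwd <- function(x) {
  d <- dim(x)
  list(y = x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2),
             rep(seq_len(d[3]), each = 2), , , drop = FALSE],
       cache = d)
}

upnn2_3d_bwd <- function(dy, d) {
  io <- seq(1, 2 * d[1], 2); jo <- seq(1, 2 * d[2], 2); ko <- seq(1, 2 * d[3], 2)
  out <- array(0, d)
  for (a in 0:1) for (b in 0:1) for (cc in 0:1)
    out <- out + dy[io + a, jo + b, ko + cc, , , drop = FALSE]
  out
}

# ---- convolutional self-attention (2D), single head ------------------------
# 1x1 projections q/k/v, scaled dot-product over the H*W token grid, 1x1
# output projection, residual connection.

attention2d_fwd <- function(x, p) {
  d <- dim(x)  # H W N C
  C <- d[4]; L <- d[1] * d[2]
  scale <- 1 / sqrt(C)
  caches <- vector("list", d[3])
  y <- x
  for (n in seq_len(d[3])) {
    Xn <- matrix(x[, , n, , drop = FALSE], L, C)
    Q <- Xn %*% p$Wq; K <- Xn %*% p$Wk; V <- Xn %*% p$Wv
    S <- tcrossprod(Q, K) * scale
    S <- S - apply(S, 1, max)
    A <- exp(S); A <- A / rowSums(A)
    Yn <- A %*% V
    On <- Yn %*% p$Wo
    y[, , n, ] <- array(Xn + On, c(d[1], d[2], C))
    caches[[n]] <- list(Xn = Xn, Q = Q, K = K, V = V, A = A, Yn = Yn)
  }
  list(y = y, cache = list(per_n = caches, dimx = d, scale = scale))
}

attention2d_bwd <- function(dy, cache, p) {
  d <- cache$dimx
  C <- d[4]; L <- d[1] * d[2]
  dWq <- matrix(0, C, C); dWk <- dWq; dWv <- dWq; dWo <- dWq
  dx <- dy  # residual path
  for (n in seq_len(d[3])) {
    cn <- cache$per_n[[n]]
    dOn <- matrix(dy[, , n, , drop = FALSE], L, C)
    dWo <- dWo + crossprod(cn$Yn, dOn)
    dYn <- dOn %*% t(p$Wo)
    dA <- tcrossprod(dYn, cn$V)
    dV <- crossprod(cn$A, dYn)
    dS <- cn$A * (dA - rowSums(dA * cn$A))
    dQ <- (dS %*% cn$K) * cache$scale
    dK <- (crossprod(dS, cn$Q)) * cache$scale
    dWq <- dWq + crossprod(cn$Xn, dQ)
    dWk <- dWk + crossprod(cn$Xn, dK)
    dWv <- dWv + crossprod(cn$Xn, dV)
    dXn <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
    dx[, , n, ] <- dx[, , n, , drop = FALSE] +
      array(dXn, c(d[1], d[2], 1, C))
  }
  list(dx = dx, dWq = dWq, dWk = dWk, dWv = dWv, dWo = dWo)
}

# ---- timestep embedding ----------------------------------------------------
# Sinusoidal features of the (1-based) timestep followed by a 2-layer MLP.

sinusoidal_embedding <- function(t, dim) {
  half <- dim %/% 2
  freqs <- exp(-log(10000) * (seq_len(half) - 1) / max(half - 1, 1))
  ang <- outer(as.numeric(t), freqs)
  cbind(sin(ang), cos(ang))
}

temb_fwd <- function(t, p, dim) {
  e0 <- sinusoidal_embedding(t, dim)           # N x dim
  h1 <- sweep(e0 %*% p$mlp1$W, 2, p$mlp1$b, `+`)
  a1 <- silu_fwd(h1)
  h2 <- sweep(a1$y %*% p$mlp2$W, 2, p$mlp2$b, `+`)
  list(y = h2, cache = list(e0 = e0, a1 = a1))
}

temb_bwd <- function(dy, cache, p) {
  dW2 <- crossprod(cache$a1$y, dy); db2 <- colSums(dy)
  da1 <- dy %*% t(p$mlp2$W)
  dh1 <- silu_bwd(da1, cache$a1$cache)
  dW1 <- crossprod(cache$e0, dh1); db1 <- colSums(dh1)
  list(dmlp1 = list(W = dW1, b = db1), dmlp2 = list(W = dW2, b = db2))
}

# add a per-(sample, channel) bias vector field to a feature map
add_temb_fwd <- function(x, tproj) {
  d <- dim(x)
  nd <- length(d)
  S <- prod(d[1:(nd - 2)])
  xm <- matrix(x, S, d[nd - 1] * d[nd])
  bias <- as.vector(tproj)  # N x C flattened, matches (n, c) blocks
  y <- sweep(xm, 2, bias, `+`)
  list(y = array(y, d), cache = d)
}

add_temb_bwd <- function(dy, d) {
  nd <- length(d)
  S <- prod(d[1:(nd - 2)])
  dtproj <- matrix(colSums(matrix(dy, S, d[nd - 1] * d[nd])),
                   d[nd - 1], d[nd])
  list(dx = dy, dtproj = dtproj)
}

# ---- Adam ------------------------------------------------------------------

zero_like <- function(p) {
  if (is.null(p)) return(NULL)
  if (is.list(p)) lapply(p, zero_like) else p * 0
}

adam_state <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

# keys of a list: names when present, positions otherwise
list_keys <- function(p) {
  nm <- names(p)
  if (is.null(nm) || any(nm == "")) seq_along(p) else nm
}

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  walk <- function(p, g, m, v) {
    if (is.null(p) || is.null(g)) return(list(p = p, m = m, v = v))
    if (is.list(p)) {
      for (k in list_keys(p)) {
        r <- walk(p[[k]], g[[k]], m[[k]], v[[k]])
        if (!is.null(r$p)) {
          p[[k]] <- r$p; m[[k]] <- r$m; v[[k]] <- r$v
        }
      }
      list(p = p, m = m, v = v)
    } else {
      m2 <- beta1 * m + (1 - beta1) * g
      v2 <- beta2 * v + (1 - beta2) * g * g
      mhat <- m2 / (1 - beta1^state$t)
      vhat <- v2 / (1 - beta2^state$t)
      list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m2, v = v2)
    }
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}

# elementwise sum of two nested gradient lists
grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    for (k in list_keys(a)) a[[k]] <- grad_add(a[[k]], b[[k]])
    a
  } else a + b
}
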