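# Denoiser architectures.
#
# 2D: a U-shaped encoder/decoder with timestep embeddings injected at every
# level and convolutional self-attention at the coarsest levels (SA-UNet).
# Skip connections are channel concatenations.
#
# 3D: the memory-lean variant used for volumetric translation: attention
# removed, concatenation skips replaced by additions, and three normalized
# position-ramp channels appended to the input. The network is fully
# convolutional: any input whose spatial sides are divisible by 2^depth is
# accepted, and the parameter count is independent of input size.

#' Specification of the 2D self-attention U-Net denoiser
#'
#' @param in_channels input channels (noisy target + condition).
#' @param base_width channels at the finest level; level widths double up to
#'   a cap of 8x base.
#' @param depth number of 2x downsamplings (resolution levels = depth + 1).
#' @param attention_levels level indices (1 = finest) that include
#'   convolutional self-attention; default the two coarsest.
#' @param time_embedding_dim width of the sinusoidal timestep embedding.
#' @return a `denoiser_spec` (kind "2d").
#' @export
denoiser_spec_2d <- function(in_channels = 2, base_width = 64, depth = 4,
                             attention_levels = c(depth, depth + 1),
                             time_embedding_dim = 64) {
  structure(list(kind = "2d", in_channels = in_channels,
                 base_width = base_width, depth = depth,
                 attention_levels = attention_levels,
                 time_embedding_dim = time_embedding_dim),
            class = "denoiser_spec")
}

#' Specification of the 3D attention-free denoiser
#'
#' @param in_channels input channels (noisy target + condition + 3 ramps).
#' @param base_width channels at the finest level.
#' @param depth number of 2x downsamplings; spatial sides must be divisible
#'   by `2^depth`.
#' @param time_embedding_dim width of the sinusoidal timestep embedding.
#' @return a `denoiser_spec` (kind "3d", additive skips, no attention).
#' @export
denoiser_spec_3d <- function(in_channels = 5, base_width = 32, depth = 3,
                             time_embedding_dim = 64) {
  structure(list(kind = "3d", in_channels = in_channels,
                 base_width = base_width, depth = depth,
                 attention_levels = integer(0),
                 time_embedding_dim = time_embedding_dim),
            class = "denoiser_spec")
}

#' Number of 2x downsamplings of a denoiser spec
#'
#' Determines the fully-convolutional shape contract: input sides must be
#' divisible by `2^count_receptive_depth(spec)` (8 for the default 3D spec).
#'
#' @param spec a `denoiser_spec`.
#' @return integer number of downsampling stages.
#' @export
count_receptive_depth <- function(spec) spec$depth

spec_widths <- function(spec) {
  l <- seq_len(spec$depth + 1)
  pmin(spec$base_width * 2^(l - 1), spec$base_width * 8L)
}

init_block <- function(a, c, tdim, conv_init) {
  list(conv1 = conv_init(a, c),
       tproj = nn_init_dense(tdim, c),
       gn1 = list(gamma = rep(1, c), beta = rep(0, c)),
       conv2 = conv_init(c, c),
       gn2 = list(gamma = rep(1, c), beta = rep(0, c)),
       skip = if (a != c) nn_init_dense(a, c, zero = FALSE) else NULL)
}

#' Build a denoiser with randomly initialised weights
#'
#' @param spec a [denoiser_spec_2d()] or [denoiser_spec_3d()].
#' @param seed RNG seed for the weight initialisation.
#' @return an object of class `denoiser`: list with `spec`, `params`, and
#'   `$fn(noisy, condition, t, ramps)` returning the prediction.
#' @export
build_denoiser <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "denoiser_spec"))
  conv_init <- if (spec$kind == "2d") nn_init_conv2d else nn_init_conv3d
  widths <- spec_widths(spec)
  L <- spec$depth + 1
  params <- with_seed(seed, {
    p <- list(
      temb = list(mlp1 = nn_init_dense(spec$time_embedding_dim,
                                       spec$time_embedding_dim),
                  mlp2 = nn_init_dense(spec$time_embedding_dim,
                                       spec$time_embedding_dim)),
      stem = conv_init(spec$in_channels, widths[1]),
      enc = vector("list", L), attn = vector("list", L),
      dec = vector("list", max(L - 1, 0)),
      out = conv_init(widths[1], 1, zero = TRUE))
    for (l in seq_len(L)) {
      a <- if (l == 1) widths[1] else widths[l - 1]
      p$enc[[l]] <- init_block(a, widths[l], spec$time_embedding_dim, conv_init)
      if (l %in% spec$attention_levels && spec$kind == "2d") {
        C <- widths[l]
        p$attn[[l]] <- list(Wq = nn_init_dense(C, C)$W,
                            Wk = nn_init_dense(C, C)$W,
                            Wv = nn_init_dense(C, C)$W,
                            Wo = nn_init_dense(C, C, zero = TRUE)$W)
      }
    }
    if (L > 1) for (l in seq_len(L - 1)) {
      a <- if (spec$kind == "2d") widths[l + 1] + widths[l] else widths[l]
      p$dec[[l]] <- init_block(a, widths[l], spec$time_embedding_dim, conv_init)
      if (spec$kind == "3d")
        p$dec[[l]]$reduce <- nn_init_dense(widths[l + 1], widths[l])
    }
    p
  })
  model <- structure(list(spec = spec, params = params), class = "denoiser")
  model$fn <- function(noisy, condition, t, ramps = NULL)
    denoiser_predict(model, noisy, condition, t, ramps)
  model
}

#' Total number of trainable parameters
#' @param model a `denoiser` or `ddim_translator`.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) {
  p <- if (inherits(model, "ddim_translator")) model$model$params else model$params
  sum(rapply(p, length, how = "unlist"))
}

# ---- shared forward / backward --------------------------------------------

block_fwd <- function(x, p, temb, conv_fwd, need_cache = TRUE) {
  c1 <- conv_fwd(x, p$conv1, need_cache)
  g1 <- groupnorm_fwd(c1$y, p$gn1$gamma, p$gn1$beta, 8)
  s1 <- silu_fwd(g1$y)
  tp <- sweep(temb %*% p$tproj$W, 2, p$tproj$b, `+`)  # N x C
  at <- add_temb_fwd(s1$y, tp)
  c2 <- conv_fwd(at$y, p$conv2, need_cache)
  g2 <- groupnorm_fwd(c2$y, p$gn2$gamma, p$gn2$beta, 8)
  s2 <- silu_fwd(g2$y)
  if (is.null(p$skip)) {
    y <- s2$y + x
    sk <- NULL
  } else {
    sk <- pointwise_fwd(x, p$skip)
    y <- s2$y + sk$y
  }
  list(y = y, cache = if (need_cache)
    list(c1 = c1$cache, at = at$cache, g1 = g1$cache, s1 = s1$cache,
         c2 = c2$cache, g2 = g2$cache, s2 = s2$cache,
         sk = if (!is.null(sk)) sk$cache) else NULL)
}

block_bwd <- function(dy, cache, p, temb, conv_bwd) {
  ds2 <- silu_bwd(dy, cache$s2)
  dg2 <- groupnorm_bwd(ds2, cache$g2, p$gn2$gamma)
  dc2 <- conv_bwd(dg2$dx, cache$c2, p$conv2)
  dat <- add_temb_bwd(dc2$dx, cache$at)
  ds1 <- silu_bwd(dat$dx, cache$s1)
  dg1 <- groupnorm_bwd(ds1, cache$g1, p$gn1$gamma)
  dc1 <- conv_bwd(dg1$dx, cache$c1, p$conv1)
  dtp <- dat$dtproj  # N x C
  dtemb <- dtp %*% t(p$tproj$W)
  grads <- list(conv1 = list(W = dc1$dW, b = dc1$db),
                tproj = list(W = crossprod(temb, dtp), b = colSums(dtp)),
                gn1 = list(gamma = dg1$dgamma, beta = dg1$dbeta),
                conv2 = list(W = dc2$dW, b = dc2$db),
                gn2 = list(gamma = dg2$dgamma, beta = dg2$dbeta))
  dx <- dc1$dx
  if (!is.null(p$skip)) {
    dsk <- pointwise_bwd(dy, cache$sk, p$skip)
    grads$skip <- list(W = dsk$dW, b = dsk$db)
    dx <- dx + dsk$dx
  } else {
    dx <- dx + dy
  }
  list(dx = dx, grads = grads, dtemb = dtemb)
}

check_divisible <- function(d, depth, nd) {
  div <- 2^depth
  ax <- which(d[seq_len(nd)] %% div != 0)
  if (length(ax) > 0)
    stop(sprintf("input side %d on axis %d is not divisible by %d (depth %d)",
                 d[ax[1]], ax[1], div, depth))
}

# Assemble the input tensor and run the U-Net. Returns prediction (+ caches).
unet_forward <- function(params, spec, x_in, tvec, need_cache = TRUE) {
  is2d <- spec$kind == "2d"
  conv_fwd <- if (is2d) conv2d_fwd else conv3d_fwd
  pool_fwd <- if (is2d) avgpool2_fwd else avgpool2_3d_fwd
  up_fwd <- if (is2d) upnn2_fwd else upnn2_3d_fwd
  nd <- if (is2d) 2L else 3L
  d <- dim(x_in)
  check_divisible(d, spec$depth, nd)
  L <- spec$depth + 1

  te <- temb_fwd(tvec, params$temb, spec$time_embedding_dim)
  stem <- conv_fwd(x_in, params$stem, need_cache)
  cc <- list(te = te$cache, stem = stem$cache, enc = vector("list", L),
             attn = vector("list", L), pool = vector("list", L),
             dec = vector("list", max(L - 1, 0)),
             up = vector("list", max(L - 1, 0)))
  h <- stem$y
  skips <- vector("list", L)
  for (l in seq_len(L)) {
    bl <- block_fwd(h, params$enc[[l]], te$y, conv_fwd, need_cache)
    cc$enc[[l]] <- bl$cache
    h <- bl$y
    if (!is.null(params$attn[[l]])) {
      at <- attention2d_fwd(h, params$attn[[l]])
      cc$attn[[l]] <- at$cache
      h <- at$y
    }
    skips[[l]] <- h
    if (l < L) {
      pl <- pool_fwd(h)
      cc$pool[[l]] <- pl$cache
      h <- pl$y
    }
  }
  if (L > 1) for (l in rev(seq_len(L - 1))) {
    upl <- up_fwd(h)
    cc$up[[l]] <- upl$cache
    h <- upl$y
    if (spec$kind == "2d") {
      nd_all <- length(dim(h))
      h <- abind_channels(h, skips[[l]])
      cc$dec_in_ch <- cc$dec_in_ch %||% list()
      cc$dec_in_ch[[l]] <- c(dim(upl$y)[nd_all], dim(skips[[l]])[nd_all])
    } else {
      rd <- pointwise_fwd(h, params$dec[[l]]$reduce)
      cc$reduce <- cc$reduce %||% list()
      cc$reduce[[l]] <- rd$cache
      h <- rd$y + skips[[l]]
    }
    bl <- block_fwd(h, params$dec[[l]], te$y, conv_fwd, need_cache)
    cc$dec[[l]] <- bl$cache
    h <- bl$y
  }
  out <- conv_fwd(h, params$out, need_cache)
  cc$out <- out$cache
  cc$temb_y <- te$y
  list(y = out$y, cache = if (need_cache) cc else NULL)
}

abind_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  nd <- length(da)
  out <- array(0, c(da[-nd], da[nd] + db[nd]))
  if (nd == 4) {
    out[, , , seq_len(da[4])] <- a
    out[, , , da[4] + seq_len(db[4])] <- b
  } else {
    out[, , , , seq_len(da[5])] <- a
    out[, , , , da[5] + seq_len(db[5])] <- b
  }
  out
}

unet_backward <- function(dout, cache, params, spec) {
  is2d <- spec$kind == "2d"
  conv_bwd <- if (is2d) conv2d_bwd else conv3d_bwd
  pool_bwd <- if (is2d) avgpool2_bwd else avgpool2_3d_bwd
  up_bwd <- if (is2d) upnn2_bwd else upnn2_3d_bwd
  L <- spec$depth + 1
  te_y <- cache$temb_y
  G <- list(enc = vector("list", L), attn = vector("list", L),
            dec = vector("list", max(L - 1, 0)))
  dtemb <- matrix(0, nrow(te_y), ncol(te_y))

  dout_conv <- conv_bwd(dout, cache$out, params$out)
  G$out <- list(W = dout_conv$dW, b = dout_conv$db)
  dh <- dout_conv$dx
  dskips <- vector("list", L)

  if (L > 1) for (l in seq_len(L - 1)) {  # decoder, reverse of forward order
    bl <- block_bwd(dh, cache$dec[[l]], params$dec[[l]], te_y, conv_bwd)
    G$dec[[l]] <- bl$grads
    dtemb <- dtemb + bl$dtemb
    dh <- bl$dx
    if (is2d) {
      chs <- cache$dec_in_ch[[l]]
      nd <- length(dim(dh))
      if (nd == 4) {
        dup <- dh[, , , seq_len(chs[1]), drop = FALSE]
        dskips[[l]] <- dh[, , , chs[1] + seq_len(chs[2]), drop = FALSE]
      }
    } else {
      drd <- pointwise_bwd(dh, cache$reduce[[l]], params$dec[[l]]$reduce)
      G$dec[[l]]$reduce <- list(W = drd$dW, b = drd$db)
      dskips[[l]] <- dh
      dup <- drd$dx
    }
    dh <- up_bwd(dup, cache$up[[l]])
  }

  for (l in rev(seq_len(L))) {
    dsk <- if (l < L) pool_bwd(dh, cache$pool[[l]]) else dh
    if (l < L && !is.null(dskips[[l]])) dsk <- dsk + dskips[[l]]
    if (l == L && !is.null(dskips[[l]])) dsk <- dsk + dskips[[l]]
    if (!is.null(params$attn[[l]])) {
      at <- attention2d_bwd(dsk, cache$attn[[l]], params$attn[[l]])
      G$attn[[l]] <- list(Wq = at$dWq, Wk = at$dWk, Wv = at$dWv, Wo = at$dWo)
      dsk <- at$dx
    }
    bl <- block_bwd(dsk, cache$enc[[l]], params$enc[[l]], te_y, conv_bwd)
    G$enc[[l]] <- bl$grads
    dtemb <- dtemb + bl$dtemb
    dh <- bl$dx
  }
  dstem <- conv_bwd(dh, cache$stem, params$stem)
  G$stem <- list(W = dstem$dW, b = dstem$db)
  G$temb <- temb_bwd(dtemb, cache$te, params$temb)
  names(G$temb) <- c("mlp1", "mlp2")
  G
}

# Normalise user input shapes to (H,W,N,1)/(X,Y,Z,N,1) and run forward.
denoiser_predict <- function(model, noisy, condition, t, ramps = NULL,
                             need_cache = FALSE, return_cache = FALSE) {
  spec <- model$spec
  is2d <- spec$kind == "2d"
  nd <- if (is2d) 2L else 3L
  to5 <- function(x) {
    d <- dim(x) %||% length(x)
    if (length(d) == nd) array(x, c(d, 1, 1))
    else if (length(d) == nd + 1) array(x, c(d, 1))
    else x
  }
  xn <- to5(noisy); xc <- to5(condition)
  if (!identical(dim(xn)[seq_len(nd)], dim(xc)[seq_len(nd)]))
    stop("noisy target and condition spatial shapes differ")
  parts <- list(xn, xc)
  if (!is2d) {
    if (is.null(ramps))
      stop("the 3D denoiser requires position ramp channels")
    N <- dim(xn)[4]
    parts <- c(parts, lapply(seq_len(dim(ramps)[length(dim(ramps))]),
                             function(i) {
                               r <- to5(ramps[, , , i])
                               if (dim(r)[4] != N)
                                 r <- array(rep(r, N), c(dim(r)[1:3], N, 1))
                               r
                             }))
  }
  x_in <- Reduce(abind_channels, parts)
  if (dim(x_in)[nd + 2] != spec$in_channels)
    stop(sprintf("input has %d channels but the spec expects %d",
                 dim(x_in)[nd + 2], spec$in_channels))
  N <- dim(x_in)[nd + 1]
  tvec <- rep_len(as.numeric(t), N)
  fw <- unet_forward(model$params, spec, x_in, tvec, need_cache = need_cache)
  y <- fw$y
  dn <- dim(noisy) %||% length(noisy)
  out <- array(y, dn)
  if (return_cache) list(y = out, cache = fw$cache, x_in_dim = dim(x_in),
                         tvec = tvec) else out
}

#' @export
print.denoiser <- function(x, ...) {
  cat(sprintf("<denoiser %s> base %d, depth %d (%d levels), %s, %s parameters\n",
              x$spec$kind, x$spec$base_width, x$spec$depth, x$spec$depth + 1,
              if (length(x$spec$attention_levels) > 0)
                paste("attention at levels",
                      paste(x$spec$attention_levels, collapse = ","))
              else "no attention",
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}
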