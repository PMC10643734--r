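# Image-quality metrics with spine masking, and Dice evaluation protocols.
# Quality metrics are computed on the normalized [-1, 1] scale (range 2) by
# default, i.e. where the translation operates.

# ---- exact Euclidean distance transform (squared), separable parabola scan

dt1d_sq <- function(f, w = 1) {
  n <- length(f)
  finite <- which(is.finite(f))
  if (length(finite) == 0 || n == 1) return(f)
  d <- numeric(n); v <- integer(n); z <- numeric(n + 1)
  k <- 1L; v[1] <- finite[1]; z[1] <- -Inf; z[2] <- Inf
  for (q in finite[-1]) {
    repeat {
      s <- ((f[q] + (q * w)^2) - (f[v[k]] + (v[k] * w)^2)) /
        (2 * w * (q - v[k]))
      if (s <= z[k] && k > 1L) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q; z[k] <- s; z[k + 1] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1] < q * w) k <- k + 1L
    d[q] <- (w * (q - v[k]))^2 + f[v[k]]
  }
  d
}

# distance (in voxel units by default) from every voxel to the nearest TRUE
# voxel; works on 2D matrices and 3D arrays
distance_transform <- function(feature, spacing = NULL) {
  d <- dim(feature)
  spacing <- spacing %||% rep(1, length(d))
  f <- array(ifelse(feature, 0, Inf), d)
  if (length(d) == 2) {
    for (j in seq_len(d[2])) f[, j] <- dt1d_sq(f[, j], spacing[1])
    for (i in seq_len(d[1])) f[i, ] <- dt1d_sq(f[i, ], spacing[2])
  } else {
    for (j in seq_len(d[2])) for (k in seq_len(d[3]))
      f[, j, k] <- dt1d_sq(f[, j, k], spacing[1])
    for (i in seq_len(d[1])) for (k in seq_len(d[3]))
      f[i, , k] <- dt1d_sq(f[i, , k], spacing[2])
    for (i in seq_len(d[1])) for (j in seq_len(d[2]))
      f[i, j, ] <- dt1d_sq(f[i, j, ], spacing[3])
  }
  sqrt(f)
}

as_arr <- function(x) if (inherits(x, "spine_volume")) x$data else x

#' Mask an image pair to the spine neighbourhood
#'
#' Sets voxels farther than `radius` (pixels/voxels) from the nearest
#' segmented spine voxel to zero in both images, so that quality metrics
#' score the bone neighbourhood rather than uncontrolled soft tissue and
#' background. The distance is the exact Euclidean distance transform by
#' default; `metric = "chessboard"` uses the Chebyshev distance.
#'
#' @param a,b images (arrays or `spine_volume`s) on the same grid as `seg`.
#' @param seg segmentation (`label_mask`, array, or logical); nonzero = spine.
#' @param radius retention radius in pixels (default 10).
#' @param metric `"euclidean"` or `"chessboard"`.
#' @return list with masked `a`, `b`, the logical `keep` map, and the
#'   `mask_policy` record.
#' @export
spine_mask <- function(a, b, seg, radius = 10, metric = c("euclidean",
                                                          "chessboard")) {
  metric <- match.arg(metric)
  av <- as_arr(a); bv <- as_arr(b); sv <- as_arr(seg) != 0
  if (!all(dim(av) == dim(sv)) || !all(dim(bv) == dim(sv)))
    stop("images and segmentation must share a grid")
  if (!any(sv)) stop("empty segmentation: cannot build a spine mask")
  dist <- if (metric == "euclidean") distance_transform(sv) else {
    ch <- sv
    dd <- array(Inf, dim(sv))
    dd[sv] <- 0
    r <- 0
    while (r < radius && !all(ch)) {
      r <- r + 1
      ch <- dilate_box(ch)
      dd[ch & !is.finite(dd)] <- r
    }
    dd
  }
  keep <- dist <= radius
  av[!keep] <- 0; bv[!keep] <- 0
  list(a = av, b = bv, keep = keep,
       mask_policy = list(radius = radius, metric = metric))
}

# 3^d box dilation (chessboard unit ball), separable along axes
dilate_box <- function(x) {
  d <- dim(x)
  sh <- function(arr, ax, by) {
    idx <- lapply(d, seq_len)
    src <- lapply(d, seq_len)
    if (by == 1) { idx[[ax]] <- 2:d[ax]; src[[ax]] <- 1:(d[ax] - 1) }
    else { idx[[ax]] <- 1:(d[ax] - 1); src[[ax]] <- 2:d[ax] }
    res <- array(FALSE, d)
    res <- do.call(`[<-`, c(list(res), idx,
                            list(do.call(`[`, c(list(arr), src,
                                                list(drop = FALSE))))))
    res
  }
  out <- x
  for (ax in seq_along(d)) {
    out <- out | sh(x, ax, 1) | sh(x, ax, -1)
    x <- out
  }
  out
}

# ---- SSIM / VIFp -----------------------------------------------------------

gaussian_kernel <- function(n, sd) {
  u <- seq_len(n) - (n + 1) / 2
  g <- exp(-u^2 / (2 * sd^2))
  g / sum(g)
}

# separable "valid" filtering of a 2D matrix
filt2_valid <- function(m, g) {
  L <- length(g); H <- nrow(m); W <- ncol(m)
  if (H < L || W < L) stop("image smaller than the filter window")
  o1 <- matrix(0, H - L + 1, W)
  for (l in seq_len(L)) o1 <- o1 + g[l] * m[l:(H - L + l), , drop = FALSE]
  o2 <- matrix(0, H - L + 1, W - L + 1)
  for (l in seq_len(L)) o2 <- o2 + g[l] * o1[, l:(W - L + l), drop = FALSE]
  o2
}

ssim_2d <- function(a, b, range, win = 11L, sd = 1.5) {
  K1 <- 0.01; K2 <- 0.03
  C1 <- (K1 * range)^2; C2 <- (K2 * range)^2
  g <- gaussian_kernel(win, sd)
  mu1 <- filt2_valid(a, g); mu2 <- filt2_valid(b, g)
  s11 <- filt2_valid(a * a, g) - mu1^2
  s22 <- filt2_valid(b * b, g) - mu2^2
  s12 <- filt2_valid(a * b, g) - mu1 * mu2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)
  mean(num / den)
}

#' Structural similarity index
#'
#' Gaussian-windowed SSIM (11 x 11 window, sd 1.5, standard constants
#' K1 = 0.01, K2 = 0.03) on the declared dynamic range. 3D inputs are scored
#' slice-wise along the third axis and averaged.
#'
#' @param a,b images of the same shape.
#' @param range dynamic range (2 for [-1, 1] data).
#' @return scalar SSIM.
#' @export
ssim <- function(a, b, range = 2) {
  a <- as_arr(a); b <- as_arr(b)
  if (length(dim(a)) == 3) {
    return(mean(vapply(seq_len(dim(a)[3]),
                       function(k) ssim_2d(a[, , k], b[, , k], range),
                       numeric(1))))
  }
  ssim_2d(a, b, range)
}

vifp_2d <- function(ref, dist, sigma_nsq = 2) {
  num <- 0; den <- 0
  odd_fit <- function(n, lim) {  # largest odd window <= min(n, lim)
    k <- min(n, lim)
    k - (k + 1) %% 2
  }
  for (scale in 1:4) {
    N <- 2^(4 - scale + 1) + 1
    if (scale > 1) {
      # smooth + 2x subsample; on small images shrink the window to fit
      Ns <- odd_fit(N, min(dim(ref)))
      if (Ns < 3) break
      g <- gaussian_kernel(Ns, Ns / 5)
      ref <- filt2_valid(ref, g)
      dist <- filt2_valid(dist, g)
      ref <- ref[seq(1, nrow(ref), 2), seq(1, ncol(ref), 2), drop = FALSE]
      dist <- dist[seq(1, nrow(dist), 2), seq(1, ncol(dist), 2), drop = FALSE]
    }
    N <- odd_fit(N, min(dim(ref)))
    if (N < 3) break
    g <- gaussian_kernel(N, N / 5)
    mu1 <- filt2_valid(ref, g); mu2 <- filt2_valid(dist, g)
    s11 <- pmax(filt2_valid(ref * ref, g) - mu1^2, 0)
    s22 <- pmax(filt2_valid(dist * dist, g) - mu2^2, 0)
    s12 <- filt2_valid(ref * dist, g) - mu1 * mu2
    gg <- s12 / (s11 + 1e-10)
    sv <- s22 - gg * s12
    gg[s11 < 1e-10] <- 0; sv[s11 < 1e-10] <- s22[s11 < 1e-10]
    s11[s11 < 1e-10] <- 0
    gg[s22 < 1e-10] <- 0; sv[s22 < 1e-10] <- 0
    sv[gg < 0] <- s22[gg < 0]; gg[gg < 0] <- 0
    sv[sv <= 1e-10] <- 1e-10
    num <- num + sum(log10(1 + gg^2 * s11 / (sv + sigma_nsq)))
    den <- den + sum(log10(1 + s11 / sigma_nsq))
  }
  num / den
}

#' Pixel-domain visual information fidelity (VIFp)
#'
#' Four Gaussian scales, additive-noise variance 2, the standard
#' pixel-domain formulation. 3D inputs are scored slice-wise and averaged.
#'
#' @param reference,distorted images of the same shape.
#' @return scalar VIFp (1 for identical images).
#' @export
vifp <- function(reference, distorted) {
  a <- as_arr(reference); b <- as_arr(distorted)
  if (length(dim(a)) == 3) {
    return(mean(vapply(seq_len(dim(a)[3]),
                       function(k) vifp_2d(a[, , k], b[, , k]),
                       numeric(1))))
  }
  vifp_2d(a, b)
}

#' Image-quality report between a synthesized and a reference image
#'
#' L1 (mean absolute difference), MSE, PSNR = 10 log10(range^2 / MSE), SSIM
#' and VIFp. When `seg` is given, the 10-pixel spine mask is applied first
#' (voxels far from segmented spine are zeroed in both images). Identical
#' images report `psnr = Inf`.
#'
#' @param synth,reference images of the same shape.
#' @param range dynamic range (default 2, the normalized [-1, 1] scale).
#' @param seg optional segmentation for [spine_mask()].
#' @param mask_radius retention radius in pixels.
#' @return a `quality_report` list: `l1`, `mse`, `psnr`, `ssim`, `vifp`,
#'   `mask_policy`.
#' @export
quality <- function(synth, reference, range = 2, seg = NULL,
                    mask_radius = 10) {
  a <- as_arr(synth); b <- as_arr(reference)
  if (!all(dim(a) == dim(b))) stop("images must share a shape")
  policy <- list(masked = !is.null(seg))
  if (!is.null(seg)) {
    sm <- spine_mask(a, b, seg, radius = mask_radius)
    a <- sm$a; b <- sm$b
    policy <- c(policy, sm$mask_policy)
  }
  mse <- mean((a - b)^2)
  rep_ <- list(l1 = mean(abs(a - b)), mse = mse,
               psnr = if (mse == 0) Inf else 10 * log10(range^2 / mse),
               ssim = ssim(a, b, range), vifp = vifp(b, a),
               mask_policy = policy)
  class(rep_) <- "quality_report"
  rep_
}

#' @export
print.quality_report <- function(x, ...) {
  cat(sprintf("<quality_report%s> L1 %.4f | MSE %.5f | PSNR %.2f dB | SSIM %.4f | VIFp %.4f\n",
              if (isTRUE(x$mask_policy$masked)) " (spine-masked)" else "",
              x$l1, x$mse, x$psnr, x$ssim, x$vifp))
  invisible(x)
}

dsc_bin <- function(a, b) {
  den <- sum(a) + sum(b)
  if (den == 0) return(NA_real_)
  2 * sum(a & b) / den
}

#' Dice similarity between two label masks
#'
#' DSC = 2|A n B| / (|A| + |B|). Protocols: `global` binarizes the union of
#' evaluated labels; `per_vertebra` scores each vertebra (body + process
#' labels) separately; `posterior_only` removes vertebral-body labels before
#' scoring, isolating the posterior structures (spinous process and arch).
#' Excluded vertebrae (e.g. partially visualized ones) are removed from both
#' masks first. Units with no voxels on either side are reported as `NA`
#' (undefined), never 0.
#'
#' @param seg_a,seg_b `label_mask`s (or integer arrays) on the same grid,
#'   package label scheme (body `2*id - 1`, process `2*id`).
#' @param protocol one or more of `"global"`, `"per_vertebra"`,
#'   `"posterior_only"`.
#' @param exclude vertebra ids excluded from evaluation.
#' @return a `dice_report`: `per_volume`, `per_vertebra` (named vector),
#'   `posterior_only` (list with the same pair), `excluded`.
#' @export
dice <- function(seg_a, seg_b, protocol = c("global", "per_vertebra",
                                            "posterior_only"),
                 exclude = integer(0)) {
  protocol <- match.arg(protocol, several.ok = TRUE)
  a <- as_arr(seg_a); b <- as_arr(seg_b)
  if (!all(dim(a) == dim(b))) stop("masks must share a grid")
  if (length(exclude) > 0) {
    drop_labs <- c(2L * exclude - 1L, 2L * exclude)
    a[a %in% drop_labs] <- 0L
    b[b %in% drop_labs] <- 0L
  }
  ids <- sort(unique(c((setdiff(unique(as.vector(a)), 0L) + 1L) %/% 2L,
                       (setdiff(unique(as.vector(b)), 0L) + 1L) %/% 2L)))
  out <- list(excluded = exclude)
  if ("global" %in% protocol) out$per_volume <- dsc_bin(a != 0, b != 0)
  if ("per_vertebra" %in% protocol) {
    pv <- vapply(ids, function(v) {
      labs <- c(2L * v - 1L, 2L * v)
      dsc_bin(a %in% labs, b %in% labs)
    }, numeric(1))
    names(pv) <- ids
    out$per_vertebra <- pv
  }
  if ("posterior_only" %in% protocol) {
    ap <- a; bp <- b
    ap[ap %% 2L == 1L] <- 0L  # drop body labels
    bp[bp %% 2L == 1L] <- 0L
    post <- list(per_volume = dsc_bin(ap != 0, bp != 0))
    pv <- vapply(ids, function(v) dsc_bin(ap == 2L * v, bp == 2L * v),
                 numeric(1))
    names(pv) <- ids
    post$per_vertebra <- pv
    out$posterior_only <- post
  }
  class(out) <- "dice_report"
  out
}

#' @export
print.dice_report <- function(x, ...) {
  if (!is.null(x$per_volume))
    cat(sprintf("<dice_report> per-volume DSC %.4f\n", x$per_volume))
  if (!is.null(x$per_vertebra))
    cat("  per-vertebra:", paste(sprintf("%s=%.3f", names(x$per_vertebra),
                                         x$per_vertebra), collapse = " "), "\n")
  if (!is.null(x$posterior_only))
    cat(sprintf("  posterior-only per-volume DSC %.4f\n",
                x$posterior_only$per_volume))
  if (length(x$excluded) > 0)
    cat("  excluded vertebrae:", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}
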