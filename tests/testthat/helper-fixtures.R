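# Shared fixtures, built in code. Small grids keep the suite fast; the
# phantom geometry itself is unchanged from the package defaults.

tiny_phantom <- function(seed = 1L, misalign = NULL, noise = c(mr = 30, ct = 20)) {
  generate_phantom(phantom_config(seed = seed, noise_sd = noise,
                                  misalignment = misalign))
}

# a normalized phantom case ready for 2D dataset building
normalized_phantom <- function(seed = 1L) {
  cs <- tiny_phantom(seed)
  cs$mr <- normalize_mr(cs$mr)
  cs$ct <- normalize_ct(cs$ct)
  cs
}

random_rotation <- function(max_deg = 30) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  rotation_about(stats::runif(1, -max_deg, max_deg), ax,
                 center = stats::runif(3, -10, 10),
                 translation = stats::runif(3, -20, 20))
}

# landmark set in general (non-degenerate) position
random_landmarks <- function(n = 8, seed = NULL) {
  draw <- function() {
    landmark_set(rep(seq_len(n), each = 2)[seq_len(n)],
                 rep(c("body", "spinous_process"), length.out = n),
                 matrix(stats::runif(3 * n, -50, 50), n, 3))
  }
  if (is.null(seed)) draw() else with_seed_test(seed, draw())
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  expr
}

lm_points_test <- function(lm) as.matrix(lm[, c("x", "y", "z")])

# finite-difference gradient check against the analytic backward pass;
# randomises the zero-initialised layers first so gradients can flow
grad_check_worst <- function(spec, noisy, cond, tvec, ramps = NULL, paths) {
  m <- build_denoiser(spec, seed = 7)
  m$params$out$W <- array(stats::rnorm(length(m$params$out$W), 0, 0.2),
                          dim(m$params$out$W))
  for (l in seq_along(m$params$attn)) {
    if (!is.null(m$params$attn[[l]]))
      m$params$attn[[l]]$Wo <- matrix(
        stats::rnorm(length(m$params$attn[[l]]$Wo), 0, 0.2),
        nrow(m$params$attn[[l]]$Wo))
  }
  target <- array(stats::rnorm(length(noisy)), dim(noisy))
  fw <- spinesynth:::denoiser_predict(m, noisy, cond, tvec, ramps = ramps,
                                      need_cache = TRUE, return_cache = TRUE)
  nd <- length(fw$x_in_dim)
  dout <- array(2 * (fw$y - target) / length(target),
                c(fw$x_in_dim[seq_len(nd - 1)], 1))
  G <- spinesynth:::unet_backward(dout, fw$cache, m$params, spec)
  getv <- function(lst, path) { for (k in path) lst <- lst[[k]]; lst }
  setv <- function(lst, path, i, delta) {
    k <- path[[1]]
    if (length(path) == 1) lst[[k]][i] <- lst[[k]][i] + delta
    else lst[[k]] <- setv(lst[[k]], path[-1], i, delta)
    lst
  }
  loss_at <- function(params) {
    m2 <- m; m2$params <- params
    mean((spinesynth:::denoiser_predict(m2, noisy, cond, tvec,
                                        ramps = ramps) - target)^2)
  }
  worst <- 0
  for (pth in paths) {
    g <- getv(G, pth); p <- getv(m$params, pth)
    i <- sample(length(p), 1)
    num <- (loss_at(setv(m$params, pth, i, 1e-5)) -
            loss_at(setv(m$params, pth, i, -1e-5))) / 2e-5
    worst <- max(worst, abs(num - g[i]) / max(abs(num), abs(g[i]), 1e-8))
  }
  worst
}

rotation_angle_test <- function(R) {
  if (inherits(R, "rigid_transform")) R <- R$rotation
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}

posterior_dsc <- function(mask_ref, mask_mov) {
  dice(mask_ref, mask_mov, protocol = "posterior_only")$posterior_only$per_volume
}
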