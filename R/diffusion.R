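# Conditional DDIM machinery: noise schedules, the forward (noising) process,
# inter-conversion between noise- and image-prediction, the DDIM update with
# stochasticity parameter eta, and few-step conditional sampling with
# optional classifier-free guidance.

#' Build a diffusion noise schedule
#'
#' Linear: beta ramps from 1e-4 to 0.02 over T steps. Cosine: the
#' squared-cosine cumulative schedule with offset 0.008, betas clipped to
#' 0.999. Both satisfy: alphabar strictly decreasing, alphabar_1 >= 0.99,
#' alphabar_T <= 0.01 for the usual T.
#'
#' @param T_steps number of training timesteps (>= 2).
#' @param kind `"linear"` or `"cosine"`.
#' @return a `diffusion_schedule`: list with `T`, `beta`, `alpha`, `alphabar`.
#' @export
make_schedule <- function(T_steps = 1000L, kind = c("linear", "cosine")) {
  kind <- match.arg(kind)
  if (T_steps < 2) stop("T_steps must be >= 2")
  if (kind == "linear") {
    beta <- seq(1e-4, 0.02, length.out = T_steps)
  } else {
    s <- 0.008
    f <- function(u) cos((u / T_steps + s) / (1 + s) * pi / 2)^2
    ab <- f(seq_len(T_steps)) / f(0)
    ab_prev <- c(f(0) / f(0), ab[-T_steps])
    beta <- pmin(1 - ab / ab_prev, 0.999)
  }
  alpha <- 1 - beta
  structure(list(T = as.integer(T_steps), beta = beta, alpha = alpha,
                 alphabar = cumprod(alpha), kind = kind),
            class = "diffusion_schedule")
}

#' Sampler configuration
#'
#' @param mode what the denoiser predicts: `"image"` (the clean target) or
#'   `"noise"` (the injected noise); the other is computed during inference.
#' @param eta DDIM stochasticity in [0, 1]: 0 = deterministic, 1 = fully
#'   random noise injection (ancestral-equivalent).
#' @param n_steps number of inference steps (the paper's t: 20 in 2D, 25 in 3D).
#' @param guidance_w classifier-free guidance weight (>= 0; 0 disables the
#'   unconditional branch entirely).
#' @param clip_x0 clamp the predicted clean image to [-1, 1] at each step.
#' @param seed RNG seed for the start noise and any stochastic injections.
#' @return a `sampler_config`.
#' @export
sampler_config <- function(mode = c("image", "noise"), eta = 1, n_steps = 20L,
                           guidance_w = 0, clip_x0 = TRUE, seed = 1L) {
  mode <- match.arg(mode)
  if (eta < 0 || eta > 1) stop("eta must lie in [0, 1]")
  if (guidance_w < 0) stop("guidance_w must be >= 0")
  structure(list(mode = mode, eta = eta, n_steps = as.integer(n_steps),
                 guidance_w = guidance_w, clip_x0 = clip_x0,
                 seed = as.integer(seed)),
            class = "sampler_config")
}

#' Forward diffusion: noise a clean image to timestep t
#'
#' `x_t = sqrt(alphabar_t) x0 + sqrt(1 - alphabar_t) eps`.
#'
#' @param x0 clean image (any shape), values in [-1, 1].
#' @param t timestep index in 1..T.
#' @param eps unit-Gaussian noise, same shape as `x0`.
#' @param schedule a [make_schedule()].
#' @return the noised image, same shape.
#' @export
q_sample <- function(x0, t, eps, schedule) {
  if (any(t < 1) || any(t > schedule$T)) stop("t out of range 1..T")
  ab <- schedule$alphabar[t]
  sqrt(ab) * x0 + sqrt(1 - ab) * eps
}

#' Convert between noise- and image-prediction
#'
#' Given the model output in the declared mode and the noisy input `x_t`,
#' computes both the implied clean image `x0_hat` and the implied noise
#' `eps_hat`. If `clip_x0`, `x0_hat` is clamped to [-1, 1] and `eps_hat`
#' recomputed from the clamped value. Divisions are guarded with a small
#' epsilon against alphabar numerically reaching 0 or 1.
#'
#' @param pred model output.
#' @param mode `"noise"` or `"image"` — what `pred` is.
#' @param x_t the noisy image at timestep `t`.
#' @param t timestep index in 1..T.
#' @param schedule a [make_schedule()].
#' @param clip_x0 clamp the implied clean image.
#' @return list with `x0_hat` and `eps_hat`.
#' @export
convert_prediction <- function(pred, mode = c("noise", "image"), x_t, t,
                               schedule, clip_x0 = FALSE) {
  mode <- match.arg(mode)
  ab <- schedule$alphabar[t]
  sab <- sqrt(max(ab, 1e-12))
  s1ab <- sqrt(max(1 - ab, 1e-12))
  if (mode == "noise") {
    eps_hat <- pred
    x0_hat <- (x_t - s1ab * pred) / sab
  } else {
    x0_hat <- pred
    eps_hat <- (x_t - sab * pred) / s1ab
  }
  if (clip_x0) {
    x0_hat <- pmin(pmax(x0_hat, -1), 1)
    eps_hat <- (x_t - sab * x0_hat) / s1ab
  }
  list(x0_hat = x0_hat, eps_hat = eps_hat)
}

#' One DDIM update from timestep t to t_prev
#'
#' `sigma = eta sqrt((1-ab_prev)/(1-ab_t)) sqrt(1 - ab_t/ab_prev)`;
#' `x_prev = sqrt(ab_prev) x0_hat + sqrt(1 - ab_prev - sigma^2) eps_hat +
#' sigma noise_draw`. `t_prev = 0` denotes the fully denoised endpoint
#' (alphabar = 1).
#'
#' @param x_t current state (unused by the update itself but kept for the
#'   interface contract; the update is a function of the two predictions).
#' @param x0_hat,eps_hat predictions from [convert_prediction()].
#' @param t,t_prev current and target timestep indices (`t_prev < t`;
#'   `t_prev = 0` allowed).
#' @param eta stochasticity in [0, 1].
#' @param schedule a [make_schedule()].
#' @param noise_draw unit-Gaussian noise; required when `eta > 0` and
#'   `t_prev > 0`.
#' @return the state at `t_prev`.
#' @export
ddim_step <- function(x_t, x0_hat, eps_hat, t, t_prev, eta, schedule,
                      noise_draw = NULL) {
  if (t_prev >= t) stop("t_prev must be < t")
  ab_t <- schedule$alphabar[t]
  ab_prev <- if (t_prev == 0) 1 else schedule$alphabar[t_prev]
  sigma <- eta * sqrt((1 - ab_prev) / (1 - ab_t)) * sqrt(1 - ab_t / ab_prev)
  rad <- 1 - ab_prev - sigma^2
  if (rad < -1e-12)
    stop("negative radicand in DDIM step; eta must be <= 1")
  rad <- max(rad, 0)
  out <- sqrt(ab_prev) * x0_hat + sqrt(rad) * eps_hat
  if (eta > 0 && sigma > 0) {
    if (is.null(noise_draw))
      stop("noise_draw required for eta > 0 with t_prev > 0")
    out <- out + sigma * noise_draw
  }
  out
}

# inference timestep subset: n uniformly spaced values over 1..T, descending,
# always including T and ending at the final (smallest) step
inference_timesteps <- function(T_steps, n_steps) {
  ts <- unique(round(seq(T_steps, 1, length.out = n_steps)))
  ts[ts >= 1]
}

#' Conditional DDIM sampling
#'
#' Starts from unit Gaussian noise and iterates [ddim_step()] over `n_steps`
#' uniformly spaced timesteps of the training schedule. The model callable is
#' invoked as `model(x_t, condition, t)` and must return a prediction in the
#' configured mode. With `guidance_w > 0` the prediction is extrapolated as
#' `(1 + w) pred_cond - w pred_uncond`, the unconditional branch using the
#' null condition (an all -1 image, i.e. air).
#'
#' @param condition the source (MR) image driving the translation.
#' @param model denoiser callable, or a `denoiser` object.
#' @param config a [sampler_config()].
#' @param schedule a [make_schedule()].
#' @param ramps optional position-ramp channels forwarded to 3D denoisers.
#' @return the synthesized image, same shape as `condition`, in [-1, 1] when
#'   `clip_x0` is set.
#' @export
sample_translation <- function(condition, model, config = sampler_config(),
                               schedule = make_schedule(), ramps = NULL) {
  fn <- if (inherits(model, "denoiser")) {
    function(x, c, t) denoiser_predict(model, x, c, t, ramps = ramps)
  } else if (is.function(model)) {
    if (!is.null(ramps)) function(x, c, t) model(x, c, t, ramps = ramps)
    else model
  } else stop("`model` must be a function or a denoiser object")
  if (config$n_steps > schedule$T) stop("n_steps must be <= schedule T")
  shp <- dim(condition) %||% length(condition)
  null_cond <- array(-1, shp)
  with_seed(config$seed, {
    x <- array(stats::rnorm(prod(shp)), shp)
    ts <- inference_timesteps(schedule$T, config$n_steps)
    for (i in seq_along(ts)) {
      t <- ts[i]
      t_prev <- if (i < length(ts)) ts[i + 1] else 0L
      pred <- fn(x, condition, t)
      if (!identical(dim(pred) %||% length(pred), shp))
        stop("model output shape does not match the input shape")
      if (config$guidance_w > 0) {
        pred_u <- fn(x, null_cond, t)
        pred <- (1 + config$guidance_w) * pred - config$guidance_w * pred_u
      }
      cv <- convert_prediction(pred, config$mode, x, t, schedule,
                               clip_x0 = config$clip_x0)
      nz <- if (config$eta > 0 && t_prev > 0)
        array(stats::rnorm(prod(shp)), shp) else NULL
      x <- ddim_step(x, cv$x0_hat, cv$eps_hat, t, t_prev, config$eta,
                     schedule, nz)
    }
    if (config$clip_x0) x <- pmin(pmax(x, -1), 1)
    x
  })
}

#' Diffusion training loss for an arbitrary prediction callable
#'
#' Draws a uniform timestep and Gaussian noise, noises the target CT, and
#' scores the callable's prediction against the mode's target (the noise in
#' noise mode, the clean CT in image mode) with mean squared error, plus an
#' optional weighted (1 - SSIM) term. With probability `cond_dropout_p` the
#' condition is replaced by the null (all -1) image, which is what enables
#' classifier-free guidance at inference.
#'
#' @param pred_fn callable `(x_t, condition, t) -> prediction`.
#' @param mr,ct condition and target images in [-1, 1], same shape.
#' @param schedule a [make_schedule()].
#' @param mode `"noise"` or `"image"`.
#' @param cond_dropout_p probability of replacing the condition by null.
#' @param lambda_ssim weight of the (1 - SSIM) term (2D inputs only).
#' @param seed RNG seed for the draw.
#' @return scalar loss; attributes carry the drawn `t` and whether the
#'   condition was dropped.
#' @export
training_step <- function(pred_fn, mr, ct, schedule, mode = c("image", "noise"),
                          cond_dropout_p = 0, lambda_ssim = 0, seed = NULL) {
  mode <- match.arg(mode)
  if (!identical(dim(mr), dim(ct))) stop("mr and ct shapes differ")
  draw <- function() {
    t <- sample.int(schedule$T, 1)
    eps <- array(stats::rnorm(length(ct)), dim(ct) %||% length(ct))
    dropped <- stats::runif(1) < cond_dropout_p
    list(t = t, eps = eps, dropped = dropped)
  }
  dr <- if (is.null(seed)) draw() else with_seed(seed, draw())
  x_t <- q_sample(ct, dr$t, dr$eps, schedule)
  cond <- if (dr$dropped) array(-1, dim(mr) %||% length(mr)) else mr
  pred <- pred_fn(x_t, cond, dr$t)
  target <- if (mode == "noise") dr$eps else ct
  loss <- mean((pred - target)^2)
  if (lambda_ssim > 0) {
    cv <- convert_prediction(pred, mode, x_t, dr$t, schedule)
    loss <- loss + lambda_ssim * (1 - ssim(cv$x0_hat, ct, range = 2))
  }
  if (!is.finite(loss))
    stop("training divergence: non-finite loss at timestep ", dr$t)
  structure(loss, t = dr$t, cond_dropped = dr$dropped)
}
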