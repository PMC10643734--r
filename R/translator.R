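# Training a conditional DDIM denoiser on paired (MR, CT) samples, and the
# fitted-model object. The trainer follows the classic modelling idiom:
# `train_translator()` returns a classed object with print / summary /
# predict / simulate methods.

stack_batch <- function(lst, field, H, W) {
  N <- length(lst)
  arr <- array(0, c(H, W, N))
  for (n in seq_len(N)) arr[, , n] <- lst[[n]][[field]]
  arr
}

#' Train a conditional diffusion translator
#'
#' Optimises the denoiser with Adam on the standard diffusion objective: draw
#' a timestep and Gaussian noise, noise the CT, and regress the configured
#' target (clean image or noise) with mean squared error, conditioning on the
#' paired MR. Condition dropout (probability `cond_dropout_p`) trains the
#' null-condition branch used by classifier-free guidance.
#'
#' @param pairs list of training samples, each `list(mr = , ct = )` with 2D
#'   matrices in [-1, 1] of a common size (see [make_2d_dataset()]).
#' @param spec a [denoiser_spec_2d()].
#' @param schedule a [make_schedule()].
#' @param mode `"image"` or `"noise"` prediction.
#' @param steps number of optimiser steps.
#' @param lr Adam learning rate (default 2e-5).
#' @param batch_size samples per step.
#' @param cond_dropout_p condition-dropout probability.
#' @param lambda_ssim must be 0: the gradient trainer supports the plain MSE
#'   objective; the (1 - SSIM) term is available in [training_step()] for
#'   loss reporting only.
#' @param seed RNG seed covering initialisation and all draws.
#' @param val_pairs optional held-out pairs; validation loss is recorded
#'   every `val_every` steps under a fixed draw.
#' @param val_every interval (steps) between validation evaluations.
#' @param verbose print progress every 200 steps.
#' @return an object of class `ddim_translator`.
#' @export
train_translator <- function(pairs, spec = denoiser_spec_2d(base_width = 16,
                                                            depth = 2),
                             schedule = make_schedule(), mode = c("image", "noise"),
                             steps = 2000L, lr = 2e-5, batch_size = 8L,
                             cond_dropout_p = 0.1, lambda_ssim = 0,
                             seed = 1L, val_pairs = NULL, val_every = 200L,
                             verbose = FALSE) {
  mode <- match.arg(mode)
  if (lambda_ssim != 0)
    stop("lambda_ssim > 0 is not supported by the gradient trainer")
  stopifnot(length(pairs) > 0)
  H <- nrow(pairs[[1]]$mr); W <- ncol(pairs[[1]]$mr)
  model <- build_denoiser(spec, seed = seed)
  opt <- adam_state(model$params)
  losses <- numeric(steps)
  val_losses <- NULL

  val_loss <- function(params) {
    m2 <- model; m2$params <- params
    tot <- 0
    for (i in seq_along(val_pairs)) {
      fn <- function(x, c, t) denoiser_predict(m2, x, c, t)
      tot <- tot + as.numeric(training_step(
        fn, val_pairs[[i]]$mr, val_pairs[[i]]$ct, schedule, mode,
        cond_dropout_p = 0, seed = 90000L + i))
    }
    tot / length(val_pairs)
  }

  with_seed(seed + 1L, {
    for (step in seq_len(steps)) {
      idx <- sample.int(length(pairs), batch_size, replace = TRUE)
      batch <- pairs[idx]
      x0 <- stack_batch(batch, "ct", H, W)
      cond <- stack_batch(batch, "mr", H, W)
      tvec <- sample.int(schedule$T, batch_size, replace = TRUE)
      eps <- array(stats::rnorm(H * W * batch_size), c(H, W, batch_size))
      drop_n <- stats::runif(batch_size) < cond_dropout_p
      if (any(drop_n)) cond[, , drop_n] <- -1
      ab <- schedule$alphabar[tvec]
      x_t <- sweep(x0, 3, sqrt(ab), `*`) + sweep(eps, 3, sqrt(1 - ab), `*`)
      target <- if (mode == "noise") eps else x0

      fw <- denoiser_predict(model, x_t, cond, tvec, need_cache = TRUE,
                             return_cache = TRUE)
      resid <- fw$y - target
      loss <- mean(resid^2)
      if (!is.finite(loss))
        stop("training divergence: non-finite loss at step ", step)
      losses[step] <- loss
      dout <- array(2 * resid / length(resid), c(H, W, batch_size, 1))
      grads <- unet_backward(dout, fw$cache, model$params, spec)
      upd <- adam_update(model$params, grads, opt, lr)
      model$params <- upd$params
      opt <- upd$state
      if (!is.null(val_pairs) && step %% val_every == 0) {
        vl <- val_loss(model$params)
        val_losses <- rbind(val_losses, c(step = step, loss = vl))
        if (verbose) message(sprintf("step %d train %.4f val %.4f",
                                     step, loss, vl))
      } else if (verbose && step %% 200 == 0) {
        message(sprintf("step %d loss %.4f", step, loss))
      }
    }
  })
  model$fn <- function(noisy, condition, t, ramps = NULL)
    denoiser_predict(model, noisy, condition, t, ramps)

  structure(list(model = model, schedule = schedule, mode = mode,
                 config = list(steps = steps, lr = lr,
                               batch_size = batch_size,
                               cond_dropout_p = cond_dropout_p, seed = seed,
                               input_size = c(H, W)),
                 losses = losses,
                 val_losses = if (!is.null(val_losses))
                   as.data.frame(val_losses)),
            class = "ddim_translator")
}

#' @export
print.ddim_translator <- function(x, ...) {
  cat(sprintf("<ddim_translator> %s mode, %s parameters, %d steps (lr %g)\n",
              x$mode, format(n_parameters(x), big.mark = ","),
              x$config$steps, x$config$lr))
  k <- max(1, length(x$losses) - 99)
  cat(sprintf("  final training loss (last 100 steps): %.4f\n",
              mean(x$losses[k:length(x$losses)])))
  invisible(x)
}

#' @export
summary.ddim_translator <- function(object, ...) {
  sm <- list(mode = object$mode,
             n_parameters = n_parameters(object),
             steps = object$config$steps,
             lr = object$config$lr,
             input_size = object$config$input_size,
             loss_first100 = mean(object$losses[seq_len(min(100,
               length(object$losses)))]),
             loss_last100 = mean(rev(object$losses)[seq_len(min(100,
               length(object$losses)))]),
             val_losses = object$val_losses)
  class(sm) <- "summary.ddim_translator"
  sm
}

#' @export
print.summary.ddim_translator <- function(x, ...) {
  cat(sprintf("Conditional DDIM translator (%s mode)\n", x$mode))
  cat(sprintf("  parameters: %s, trained %d steps at lr %g on %dx%d inputs\n",
              format(x$n_parameters, big.mark = ","), x$steps, x$lr,
              x$input_size[1], x$input_size[2]))
  cat(sprintf("  training loss: %.4f (first 100 steps) -> %.4f (last 100)\n",
              x$loss_first100, x$loss_last100))
  if (!is.null(x$val_losses)) {
    cat("  validation loss:\n")
    print(x$val_losses, row.names = FALSE)
  }
  invisible(x)
}

#' Translate MR input with a fitted translator
#'
#' @param object a `ddim_translator`.
#' @param newdata a 2D matrix (single slice, in [-1, 1]) or a 3D array of
#'   slices stacked along the third axis.
#' @param sampler a [sampler_config()]; its mode must match the training mode.
#' @param ... unused.
#' @return translated image(s), same shape as `newdata`.
#' @export
predict.ddim_translator <- function(object, newdata,
                                    sampler = sampler_config(mode = object$mode),
                                    ...) {
  if (sampler$mode != object$mode)
    stop(sprintf("sampler mode '%s' does not match the checkpoint mode '%s'",
                 sampler$mode, object$mode))
  if (is.matrix(newdata)) {
    return(sample_translation(newdata, object$model, sampler, object$schedule))
  }
  stopifnot(length(dim(newdata)) == 3)
  out <- newdata
  for (k in seq_len(dim(newdata)[3])) {
    cfg_k <- sampler
    cfg_k$seed <- sampler$seed + k
    out[, , k] <- sample_translation(newdata[, , k], object$model, cfg_k,
                                     object$schedule)
  }
  out
}

#' Draw repeated stochastic translations
#'
#' With eta = 1 the sampler injects fresh noise at every step, so repeated
#' runs are draws from the model's conditional distribution.
#'
#' @param object a `ddim_translator`.
#' @param nsim number of draws.
#' @param seed base seed; draw i uses `seed + i`.
#' @param newdata a 2D matrix in [-1, 1].
#' @param ... unused.
#' @return list of `nsim` translated matrices.
#' @export
simulate.ddim_translator <- function(object, nsim = 1, seed = 1L,
                                     newdata, ...) {
  lapply(seq_len(nsim), function(i)
    predict(object, newdata,
            sampler = sampler_config(mode = object$mode, eta = 1,
                                     seed = seed + i)))
}
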