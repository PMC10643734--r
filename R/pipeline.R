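# End-to-end orchestration: tiled/stitched translation of whole volumes, a
# pluggable segmenter interface, and a config-driven experiment runner that
# writes NIfTI intermediates, metric CSVs and a JSON summary.

# ---- segmenter registry ----------------------------------------------------

.segmenters <- new.env(parent = emptyenv())

#' Register a CT segmenter implementation
#'
#' The downstream evaluation treats segmentation as an external, pluggable
#' step. The built-in `"phantom"` segmenter is registered at load time; users
#' can register trained models or wrap external command-line tools.
#'
#' @param name segmenter name.
#' @param fn callable `spine_volume -> label_mask` on the same grid.
#' @export
register_segmenter <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = .segmenters)
  invisible(name)
}

#' Look up a registered segmenter
#' @param name segmenter name.
#' @return the segmenter callable.
#' @export
get_segmenter <- function(name) {
  if (!exists(name, envir = .segmenters))
    stop("no segmenter registered under '", name, "'; see register_segmenter()")
  get(name, envir = .segmenters)
}

#' Wrap an external segmentation command
#'
#' Returns a segmenter callable that writes the CT to a temporary NIfTI,
#' invokes `command <in.nii.gz> <out.nii.gz>`, and reads the result back. A
#' nonzero exit or a grid mismatch raises an error with the captured output.
#'
#' @param command path to the executable.
#' @param args extra arguments placed before the two paths.
#' @return a segmenter function.
#' @export
external_segmenter <- function(command, args = character(0)) {
  force(command); force(args)
  function(ct) {
    fin <- tempfile(fileext = ".nii.gz")
    fout <- tempfile(fileext = ".nii.gz")
    on.exit(unlink(c(fin, fout)))
    write_volume(ct, fin)
    res <- suppressWarnings(system2(command, c(args, fin, fout),
                                    stdout = TRUE, stderr = TRUE))
    status <- attr(res, "status") %||% 0L
    if (status != 0)
      stop("external segmenter failed (exit ", status, "): ",
           paste(res, collapse = "\n"))
    out <- read_volume(fout, mask = TRUE)
    if (!identical(dim(out$data), dim(ct$data)))
      stop("external segmenter returned a different grid: ",
           paste(dim(out$data), collapse = "x"), " vs ",
           paste(dim(ct$data), collapse = "x"))
    out
  }
}

# ---- whole-volume translation ----------------------------------------------

tile_starts <- function(n, win, overlap) {
  if (n <= win) return(1L)
  s <- seq(1L, n - win + 1L, by = win - overlap)
  if (s[length(s)] != n - win + 1L) s <- c(s, n - win + 1L)
  unique(s)
}

#' Translate a full volume with a fitted model
#'
#' `slice2d`: every sagittal slice is tiled into square windows matching the
#' model's training size (32-pixel overlap), each window is translated, and
#' windows are blended with linear feathering so no seams appear. `patch3d`:
#' the volume is padded to sides divisible by 8, translated in one fully
#' convolutional pass, cropped back, and (optionally) resampled onto
#' `target_grid` — the 1-mm-isotropic-to-native step.
#'
#' @param mr normalized MR `spine_volume` (resampled per the chosen mode).
#' @param model a `ddim_translator` (slice2d), a 3D `denoiser` (patch3d), or
#'   a bare denoiser callable `(noisy, condition, t) -> prediction` (slice2d,
#'   requires `win`).
#' @param sampler a [sampler_config()].
#' @param mode `"slice2d"` or `"patch3d"`.
#' @param overlap tile overlap in pixels for slice2d.
#' @param target_grid optional [grid_spec()] to resample the result onto.
#' @param win tile size for slice2d when `model` is a bare callable.
#' @param schedule diffusion schedule for bare callables (default T = 1000
#'   linear).
#' @return translated CT-like `spine_volume` in [-1, 1].
#' @export
translate_volume <- function(mr, model, sampler = NULL,
                             mode = c("slice2d", "patch3d"), overlap = 32L,
                             target_grid = NULL, win = NULL,
                             schedule = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(mr, "spine_volume"))
  d <- dim(mr$data)
  if (mode == "slice2d") {
    if (inherits(model, "ddim_translator")) {
      if (is.null(sampler)) sampler <- sampler_config(mode = model$mode)
      if (sampler$mode != model$mode)
        stop("sampler/checkpoint mode mismatch: ", sampler$mode, " vs ",
             model$mode)
      win <- model$config$input_size[1]
      schedule <- model$schedule
      tile_model <- model$model
    } else if (is.function(model)) {
      if (is.null(win)) stop("`win` is required for a bare callable")
      if (is.null(sampler)) sampler <- sampler_config()
      tile_model <- model
    } else stop("unsupported model type for slice2d")
    schedule <- schedule %||% make_schedule()
    overlap <- min(overlap, win - 1L)
    out <- array(0, d)
    for (k in seq_len(d[3])) {
      sl <- mr$data[, , k]
      si <- tile_starts(d[1], win, overlap)
      sj <- tile_starts(d[2], win, overlap)
      num <- matrix(0, d[1], d[2]); den <- matrix(0, d[1], d[2])
      wfe <- pmin(seq_len(win), win:1, overlap + 1) / (overlap + 1)
      wmap <- outer(wfe, wfe)
      widx <- 0L
      for (i0 in si) for (j0 in sj) {
        widx <- widx + 1L
        tile <- crop_or_pad_2d(sl, i0, j0, win, -1)
        cfg <- sampler
        cfg$seed <- sampler$seed + 1000L * k + widx
        tr <- sample_translation(tile, tile_model, cfg, schedule)
        ii <- i0:min(i0 + win - 1L, d[1]); jj <- j0:min(j0 + win - 1L, d[2])
        num[ii, jj] <- num[ii, jj] +
          (tr * wmap)[seq_along(ii), seq_along(jj)]
        den[ii, jj] <- den[ii, jj] + wmap[seq_along(ii), seq_along(jj)]
      }
      out[, , k] <- num / den
    }
    res <- spine_volume(out, mr$spacing, mr$origin)
  } else {
    den_model <- if (inherits(model, "ddim_translator")) model$model else model
    stopifnot(inherits(den_model, "denoiser"), den_model$spec$kind == "3d")
    if (is.null(sampler)) sampler <- sampler_config(n_steps = 25L)
    div <- 2^den_model$spec$depth
    pad_to <- as.integer(ceiling(d / div) * div)
    arr <- array(-1, pad_to)
    arr[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- mr$data
    ramps <- array(0, c(pad_to, 3))
    ramps[, , , 1] <- array(axis_ramp(pad_to[1]), pad_to)
    ramps[, , , 2] <- array(rep(axis_ramp(pad_to[2]), each = pad_to[1]),
                            pad_to)
    ramps[, , , 3] <- array(rep(axis_ramp(pad_to[3]),
                                each = pad_to[1] * pad_to[2]), pad_to)
    fn <- function(x, c, t)
      denoiser_predict(den_model, x, c, t, ramps = ramps)
    tr <- sample_translation(arr, fn, sampler,
                             if (inherits(model, "ddim_translator"))
                               model$schedule else make_schedule())
    res <- spine_volume(tr[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]),
                           drop = FALSE],
                        mr$spacing, mr$origin)
  }
  if (!is.null(target_grid))
    res <- resample_onto(res, rigid_transform(), target_grid, "linear",
                         background = -1)
  res
}

# ---- experiment runner -----------------------------------------------------

#' Default experiment configuration
#'
#' @param out_dir run directory.
#' @param seed global seed; every stage derives its randomness from it.
#' @param n_cases number of phantom cases.
#' @param phantom named arguments forwarded to [phantom_config()].
#' @param misalign_deg,misalign_translation_mm per-case CT misalignment about
#'   the craniocaudal axis (0 disables).
#' @param registration_points landmark modes to run and compare (subset of
#'   `c(1, 2)`; empty disables the registration stage).
#' @param translate run the oracle MR->CT translation + evaluation stage.
#' @param mask_radius spine-mask radius in pixels for quality metrics.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("spinesynth_run_"), seed = 1L,
                       n_cases = 3L, phantom = list(),
                       misalign_deg = 10, misalign_translation_mm = c(2, 1, 0),
                       registration_points = c(1L, 2L), translate = TRUE,
                       mask_radius = 10L) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_cases = as.integer(n_cases), phantom = phantom,
                 misalign_deg = misalign_deg,
                 misalign_translation_mm = misalign_translation_mm,
                 registration_points = as.integer(registration_points),
                 translate = isTRUE(translate),
                 mask_radius = as.integer(mask_radius)),
            class = "run_config")
}

log_line <- function(con, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  writeLines(msg, con)
}

#' Run a phantom-scale experiment end to end
#'
#' Stages: generate phantom cases (with per-case misalignment), register the
#' CT side back with 1- and/or 2-point landmarks, translate the MR with the
#' analytic phantom oracle, segment the synthetic CT, and evaluate image
#' quality and Dice overlap. All intermediates are written under the run
#' directory (NIfTI volumes, per-case metric CSV, JSON summary, log). Two
#' runs with the same config produce identical metric CSVs.
#'
#' @param config a [run_config()].
#' @return the run directory path, invisibly; the metric tables are also
#'   returned as the `summary` attribute.
#' @export
run_experiment <- function(config = run_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$out_dir, "run.log")
  con <- file(logf, open = "wt")
  on.exit(close(con))
  jsonlite::write_json(unclass(config), file.path(config$out_dir,
                                                  "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  rows <- list()
  manifest <- list()
  for (i in seq_len(config$n_cases)) {
    case_seed <- config$seed * 1000L + i
    log_line(con, "case ", i, ": phantom (seed ", case_seed, ")")
    mis <- if (config$misalign_deg != 0 ||
               any(config$misalign_translation_mm != 0))
      list(angle_deg = config$misalign_deg, axis = "craniocaudal",
           translation_mm = config$misalign_translation_mm)
    cfg <- do.call(phantom_config,
                   c(config$phantom, list(seed = case_seed,
                                          misalignment = mis)))
    case <- generate_phantom(cfg)
    cdir <- file.path(config$out_dir, sprintf("case_%02d", i))
    dir.create(cdir, showWarnings = FALSE)
    write_volume(case$mr, file.path(cdir, "mr.nii.gz"))
    write_volume(case$ct, file.path(cdir, "ct.nii.gz"))
    write_volume(case$mask, file.path(cdir, "mask.nii.gz"))
    if (!is.null(case$truth_transform))
      write_transform(case$truth_transform,
                      file.path(cdir, "truth_transform.json"))
    manifest[[i]] <- list(case = i, dir = basename(cdir), seed = case_seed)
    row <- list(case = i)

    oracle <- phantom_oracle_translator(cfg)
    segmenter <- get_segmenter("phantom")

    if (length(config$registration_points) > 0 &&
        !is.null(case$truth_transform)) {
      for (pts in config$registration_points) {
        st <- if (pts == 1) "body" else c("body", "spinous_process")
        lm_ct <- extract_centroids(phantom_segmenter(case$ct), st)
        lm_mr <- extract_centroids(case$mask, st)
        tf <- suppressWarnings(fit_rigid(lm_ct, lm_mr))
        write_transform(tf, file.path(cdir, sprintf("reg_%dpt.json", pts)))
        mask_reg <- resample_onto(case$ct_mask, tf, grid_of(case$mask))
        dr <- dice(case$mask, mask_reg,
                   protocol = c("global", "posterior_only"))
        resid <- compose_transforms(tf, case$truth_transform)
        row[[sprintf("dsc_reg_%dpt", pts)]] <- dr$per_volume
        row[[sprintf("dsc_posterior_reg_%dpt", pts)]] <-
          dr$posterior_only$per_volume
        row[[sprintf("residual_rot_deg_%dpt", pts)]] <-
          rotation_angle(resid) * 180 / pi
        log_line(con, "case ", i, ": ", pts, "-point registration, ",
                 sprintf("posterior DSC %.3f", dr$posterior_only$per_volume))
      }
    }

    if (config$translate) {
      synth <- oracle(case$mr)
      write_volume(synth, file.path(cdir, "synth_ct.nii.gz"))
      seg_synth <- segmenter(synth)
      write_volume(seg_synth, file.path(cdir, "synth_seg.nii.gz"))
      q <- quality(normalize_ct(synth), normalize_ct(case$meta$ct_clean),
                   seg = case$mask, mask_radius = config$mask_radius)
      dr <- dice(case$mask, seg_synth, protocol = c("global", "per_vertebra"))
      row$psnr <- q$psnr; row$ssim <- q$ssim; row$l1 <- q$l1
      row$dsc_translation <- dr$per_volume
      log_line(con, "case ", i, sprintf(
        ": translation PSNR %.2f dB, DSC %.3f", q$psnr, dr$per_volume))
    }
    rows[[i]] <- as.data.frame(row)
  }
  metrics <- do.call(rbind, rows)
  utils::write.csv(metrics, file.path(config$out_dir, "metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(n_cases = config$n_cases,
         means = as.list(colMeans(metrics[, -1, drop = FALSE])),
         manifest = manifest),
    file.path(config$out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  log_line(con, "done")
  structure(invisible(config$out_dir), summary = metrics)
}
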