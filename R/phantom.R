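#' Thermal sequence container
#'
#' @param frames List of numeric matrices (degrees C), identical shapes,
#'   rows = y, cols = x.
#' @param fps Frames per second.
#' @param subject_id Subject identifier.
#' @return A `thermal_sequence` object.
#' @export
thermal_sequence <- function(frames, fps = 2, subject_id = "subject") {
  stopifnot(is.list(frames))
  if (length(frames) > 0) {
    d <- dim(frames[[1]])
    ok <- vapply(frames, function(f) identical(dim(f), d), logical(1))
    if (!all(ok))
      stop("all frames must share the same shape (first mismatch at frame ",
           which(!ok)[1], ")")
  }
  structure(list(frames = frames, fps = fps, subject_id = subject_id),
            class = "thermal_sequence")
}

#' @export
print.thermal_sequence <- function(x, ...) {
  d <- if (length(x$frames)) dim(x$frames[[1]]) else c(0, 0)
  cat(sprintf("thermal_sequence '%s': %d frames of %dx%d at %g fps\n",
              x$subject_id, length(x$frames), d[2], d[1], x$fps))
  invisible(x)
}

#' Per-ROI x emotion response amplitudes for the two severity groups
#'
#' Amplitude array (degrees C) indexed `[roi, emotion, group]` describing the
#' asymptotic temperature change each emotion type evokes in each facial
#' region for the "moderate" and "marked" severity groups. The default
#' encodes the qualitative structure reported for the two patient groups:
#' group differences in the forehead under all three emotions (largest under
#' LVHA), in the nose under all three, and in the right cheek under HVLA;
#' mouth and left cheek respond equally in both groups.
#'
#' @return Numeric array `5 x 3 x 2` with dimnames.
#' @export
default_amplitudes <- function() {
  rois <- c("forehead", "nose", "mouth", "left_cheek", "right_cheek")
  a <- array(0, dim = c(5, 3, 2),
             dimnames = list(roi = rois, emotion = .EMOTIONS,
                             group = c("moderate", "marked")))
  a["forehead", , "moderate"] <- c(0.15, 0.15, 0.20)
  a["forehead", , "marked"]   <- c(0.30, 0.30, 0.45)
  a["nose", , "moderate"]     <- c(0.10, 0.10, 0.10)
  a["nose", , "marked"]       <- c(0.25, 0.25, 0.25)
  a["right_cheek", "HVLA", ]  <- c(0.10, 0.25)
  a["mouth", , ]              <- 0.10
  a["left_cheek", , ]         <- 0.10
  a
}

#' @rdname default_amplitudes
#' @return `null_amplitudes()`: the all-zero array (no evoked response, no
#'   group difference) for type-I calibration.
#' @export
null_amplitudes <- function() {
  a <- default_amplitudes()
  a[] <- 0
  a
}

#' @rdname default_amplitudes
#' @param roi,emotion Cell carrying the single planted effect.
#' @param base Moderate-group amplitude in that cell, degrees C.
#' @param gap Marked-minus-moderate amplitude difference, degrees C.
#' @return `single_effect_amplitudes()`: all-zero array except the planted
#'   cell, for signal-recovery experiments.
#' @export
single_effect_amplitudes <- function(roi = "forehead", emotion = "LVHA",
                                     base = 0.15, gap = 0.25) {
  a <- null_amplitudes()
  a[roi, emotion, "moderate"] <- base
  a[roi, emotion, "marked"] <- base + gap
  a
}

#' @rdname default_amplitudes
#' @param between_subject_sd Between-subject amplitude sd of the
#'   signal-recovery experiment, degrees C.
#' @param ... Passed on to [phantom_config()].
#' @return `signal_recovery_config()`: a [phantom_config()] for the planted
#'   single-effect experiment — forehead-LVHA group gap `gap` (default
#'   0.25 degrees C) over between-subject amplitude heterogeneity
#'   `between_subject_sd` (default 0.05, i.e. a standardized amplitude
#'   separation of 5), all other cells zero.
#' @export
signal_recovery_config <- function(gap = 0.25, base = 0.15,
                                   between_subject_sd = 0.05, ...) {
  phantom_config(amplitudes = single_effect_amplitudes(base = base,
                                                       gap = gap),
                 between_subject_sd = between_subject_sd, ...)
}

#' Synthetic thermal-face phantom configuration
#'
#' Describes the face-shaped temperature field (background ellipse with
#' rectangular ROI plateaus and two cool circular eye regions), the
#' emotion-locked response model (first-order exponential kinetics), head
#' motion jitter, sensor noise and drift. All temperatures in degrees C,
#' lengths in pixels, times in seconds.
#'
#' @param width,height Frame size in pixels (camera format 320 x 240).
#' @param face_center,face_axes Ellipse center (x, y) and semi-axes, px.
#' @param eye_centers 2 x 2 matrix of (x, y) eye centers, rows = left, right.
#' @param eye_radius Eye-disk radius, px.
#' @param eye_offset Eye-region temperature offset from face base, degrees C
#'   (negative: eyes are the coolest face structures, giving the contrast the
#'   binocular pre-alignment needs).
#' @param ambient Background temperature, degrees C (acquisition protocol
#'   keeps the room within 26-28).
#' @param face_base Base skin temperature, degrees C.
#' @param roi_baseline_offset Named per-ROI baseline offsets from
#'   `face_base`, degrees C. The right cheek is 0.3 warmer than the left by
#'   default: a deliberate lateral asymmetry that makes mirror detection
#'   decidable.
#' @param amplitudes Response-amplitude array, see [default_amplitudes()].
#' @param between_subject_sd Between-subject sd of per-cell amplitudes,
#'   degrees C.
#' @param tau_s Response time constant, seconds.
#' @param jitter_sd Named vector: per-frame head-motion sd for `tx`, `ty`
#'   (px), `theta` (degrees) and `scale` (fraction).
#' @param noise_sd Additive i.i.d. Gaussian sensor noise sd per pixel,
#'   degrees C.
#' @param roi_fluctuation_sd Per-frame, per-ROI physiological temperature
#'   fluctuation sd, degrees C. Skin perfusion varies on the scale of a few
#'   hundredths of a degree from frame to frame; unlike pixel sensor noise
#'   this variability is spatially coherent within a region and is therefore
#'   not averaged away by the ROI mean.
#' @param drift_per_min Linear sensor drift, degrees C per minute.
#' @return A `phantom_config` object.
#' @export
phantom_config <- function(width = 320L, height = 240L,
                           face_center = c(160, 126),
                           face_axes = c(85, 105),
                           eye_centers = matrix(c(132, 96, 188, 96), 2, 2,
                                                byrow = TRUE),
                           eye_radius = 8, eye_offset = -3.5,
                           ambient = 27, face_base = 33.5,
                           roi_baseline_offset = c(forehead = 1.0,
                                                   nose = -0.5, mouth = 0.5,
                                                   left_cheek = 0.3,
                                                   right_cheek = 0.6),
                           amplitudes = default_amplitudes(),
                           between_subject_sd = 0.1,
                           tau_s = 5,
                           jitter_sd = c(tx = 2, ty = 2, theta = 1,
                                         scale = 0.005),
                           noise_sd = 0.05, roi_fluctuation_sd = 0.05,
                           drift_per_min = 0.1) {
  stopifnot(all(is.finite(amplitudes)), noise_sd >= 0, all(jitter_sd >= 0),
            between_subject_sd >= 0, tau_s > 0, roi_fluctuation_sd >= 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 face_center = face_center, face_axes = face_axes,
                 eye_centers = eye_centers, eye_radius = eye_radius,
                 eye_offset = eye_offset, ambient = ambient,
                 face_base = face_base,
                 roi_baseline_offset = roi_baseline_offset,
                 amplitudes = amplitudes,
                 between_subject_sd = between_subject_sd, tau_s = tau_s,
                 jitter_sd = jitter_sd, noise_sd = noise_sd,
                 roi_fluctuation_sd = roi_fluctuation_sd,
                 drift_per_min = drift_per_min),
            class = "phantom_config")
}

#' Static face template of a phantom
#'
#' @param config A [phantom_config()].
#' @return Numeric `height x width` matrix: ambient background, elliptic face
#'   with per-ROI plateau offsets, cool eye disks.
#' @export
face_template <- function(config) {
  w <- config$width; h <- config$height
  x <- matrix(rep(0:(w - 1), each = h), h, w)
  y <- matrix(rep(0:(h - 1), times = w), h, w)
  fc <- config$face_center; fa <- config$face_axes
  face <- ((x - fc[1]) / fa[1])^2 + ((y - fc[2]) / fa[2])^2 <= 1
  tmpl <- matrix(config$ambient, h, w)
  tmpl[face] <- config$face_base
  rois <- default_roi_geometry(config$eye_centers, width = w, height = h)
  for (nm in names(rois)) {
    r <- rois[[nm]]
    tmpl[(r["y0"] + 1):r["y1"], (r["x0"] + 1):r["x1"]] <-
      config$face_base + config$roi_baseline_offset[[nm]]
  }
  for (i in 1:2) {
    ec <- config$eye_centers[i, ]
    eye <- (x - ec[1])^2 + (y - ec[2])^2 <= config$eye_radius^2
    tmpl[eye] <- config$face_base + config$eye_offset
  }
  tmpl
}

#' Unit-amplitude emotion response shapes
#'
#' Closed-form first-order response to each emotion's stimulation segments:
#' during a segment of emotion `e` the response rises exponentially toward
#' the amplitude (here 1), and decays toward 0 elsewhere, with time constant
#' `tau_s`. By linearity a subject's ROI response is
#' `sum_e amplitude[roi, e] * shape[, e]`.
#'
#' @param schedule A `stim_schedule`.
#' @param tau_s Time constant, seconds.
#' @return Matrix `total_frames(schedule) x 3` (columns HVLA, LVLA, LVHA)
#'   evaluated at frame times `k / fps`.
#' @export
emotion_shapes <- function(schedule, tau_s = 5) {
  validate_schedule(schedule)
  n <- total_frames(schedule)
  fps <- schedule$fps
  t_frames <- (seq_len(n) - 1) / fps
  ev <- schedule$events
  shapes <- matrix(0, n, length(.EMOTIONS),
                   dimnames = list(NULL, .EMOTIONS))
  for (e in .EMOTIONS) {
    r0 <- 0
    vals <- numeric(n)
    for (i in seq_len(nrow(ev))) {
      t0 <- ev$start_s[i]; t1 <- t0 + ev$duration_s[i]
      target <- if (ev$emotion[i] == e) 1 else 0
      k <- which(t_frames >= t0 - 1e-9 & t_frames < t1 - 1e-9)
      if (length(k))
        vals[k] <- target + (r0 - target) * exp(-(t_frames[k] - t0) / tau_s)
      r0 <- target + (r0 - target) * exp(-(t1 - t0) / tau_s)
    }
    shapes[, e] <- vals
  }
  shapes
}

# Draw per-subject amplitudes around the group means.
draw_subject_amplitudes <- function(config, group) {
  a <- config$amplitudes[, , group]
  a + matrix(rnorm(length(a), 0, config$between_subject_sd),
             nrow(a), ncol(a), dimnames = dimnames(a))
}

#' Generate one synthetic subject
#'
#' Each frame is the face template plus emotion-locked ROI responses and
#' linear drift, warped by a per-frame random rigid-plus-scale jitter
#' transform, plus i.i.d. Gaussian sensor noise. The exact per-frame
#' transforms and per-cell amplitudes used are returned as ground truth.
#' Deterministic given `seed`.
#'
#' @param config A [phantom_config()].
#' @param schedule A `stim_schedule`.
#' @param group `"moderate"` or `"marked"`.
#' @param seed Integer seed.
#' @param subject_id Subject identifier.
#' @return List with elements `sequence` (a [thermal_sequence()]) and
#'   `truth` (list: `affine` data frame of per-frame jitter parameters,
#'   `amplitudes` 5 x 3 matrix, `group`).
#' @export
generate_subject <- function(config, schedule = build_default_schedule(),
                             group = c("moderate", "marked"), seed = 1,
                             subject_id = NULL) {
  group <- match.arg(group)
  stopifnot(inherits(config, "phantom_config"))
  n <- total_frames(schedule)
  subject_id <- subject_id %||% sprintf("%s_seed%d", group, seed)
  tmpl <- face_template(config)
  shapes <- emotion_shapes(schedule, config$tau_s)
  rois <- default_roi_geometry(config$eye_centers,
                               width = config$width, height = config$height)
  js <- config$jitter_sd
  with_seed(seed, {
    amp <- draw_subject_amplitudes(config, group)
    jit <- data.frame(
      tx = rnorm(n, 0, js[["tx"]]), ty = rnorm(n, 0, js[["ty"]]),
      theta = rnorm(n, 0, js[["theta"]]),
      s = 1 + rnorm(n, 0, js[["scale"]]))
    fluct <- matrix(rnorm(n * length(rois), 0, config$roi_fluctuation_sd),
                    n, length(rois), dimnames = list(NULL, names(rois)))
    frames <- vector("list", n)
    for (k in seq_len(n)) {
      f <- tmpl
      for (nm in rownames(amp)) {
        r <- rois[[nm]]
        resp <- sum(amp[nm, ] * shapes[k, ]) + fluct[k, nm]
        if (resp != 0)
          f[(r["y0"] + 1):r["y1"], (r["x0"] + 1):r["x1"]] <-
            f[(r["y0"] + 1):r["y1"], (r["x0"] + 1):r["x1"]] + resp
      }
      drift <- config$drift_per_min * ((k - 1) / schedule$fps) / 60
      if (drift != 0) f <- f + drift
      p <- affine_params(tx = jit$tx[k], ty = jit$ty[k], theta = jit$theta[k],
                         sx = jit$s[k], sy = jit$s[k])
      f <- apply_affine(f, p, fill = config$ambient)
      if (config$noise_sd > 0)
        f <- f + matrix(rnorm(length(f), 0, config$noise_sd),
                        nrow(f), ncol(f))
      frames[[k]] <- f
    }
    list(sequence = thermal_sequence(frames, fps = schedule$fps,
                                     subject_id = subject_id),
         truth = list(affine = data.frame(frame = seq_len(n) - 1L,
                                          tx = jit$tx, ty = jit$ty,
                                          theta = jit$theta,
                                          sx = jit$s, sy = jit$s, shear = 0),
                      amplitudes = amp, group = group))
  })
}

#' Generate a two-group synthetic cohort of full image sequences
#'
#' Per-subject seeds are derived deterministically from the master seed.
#' Default group sizes follow the study design of 18 moderately and 17
#' markedly ill subjects.
#'
#' @param config A [phantom_config()].
#' @param schedule A `stim_schedule`.
#' @param n_moderate,n_marked Group sizes (>= 1).
#' @param seed Master seed.
#' @return List of [generate_subject()] results, with a `groups` attribute.
#' @export
generate_cohort <- function(config, schedule = build_default_schedule(),
                            n_moderate = 18, n_marked = 17, seed = 1) {
  stopifnot(n_moderate >= 1, n_marked >= 1)
  groups <- c(rep("moderate", n_moderate), rep("marked", n_marked))
  seeds <- derive_seeds(seed, length(groups))
  out <- lapply(seq_along(groups), function(i)
    generate_subject(config, schedule, groups[i], seed = seeds[i],
                     subject_id = sprintf("S%02d_%s", i, groups[i])))
  attr(out, "groups") <- groups
  out
}

#' Simulate a cohort at the ROI-series level
#'
#' Fast statistical twin of [generate_cohort()]: emits each subject's
#' per-ROI mean-temperature series directly from the closed-form response
#' model, skipping image rendering, head jitter and registration. The ROI
#' mean of i.i.d. pixel noise is Gaussian with sd `noise_sd / sqrt(n_pixels)`,
#' so the series are distributed exactly as ROI means extracted from
#' noiseless-jitter-registered image sequences. Intended for calibration
#' studies that need hundreds of cohorts.
#'
#' @inheritParams generate_cohort
#' @return List of subjects, each a list with `series` (named list of 5
#'   numeric vectors), `group`, `subject_id`, `amplitudes`; `groups`
#'   attribute as in [generate_cohort()].
#' @export
simulate_cohort_series <- function(config,
                                   schedule = build_default_schedule(),
                                   n_moderate = 18, n_marked = 17, seed = 1) {
  stopifnot(inherits(config, "phantom_config"), n_moderate >= 1,
            n_marked >= 1)
  groups <- c(rep("moderate", n_moderate), rep("marked", n_marked))
  seeds <- derive_seeds(seed, length(groups))
  n <- total_frames(schedule)
  shapes <- emotion_shapes(schedule, config$tau_s)
  rois <- default_roi_geometry(config$eye_centers,
                               width = config$width, height = config$height)
  npix <- vapply(rois, function(r)
    (r[["x1"]] - r[["x0"]]) * (r[["y1"]] - r[["y0"]]), numeric(1))
  drift <- config$drift_per_min * ((seq_len(n) - 1) / schedule$fps) / 60
  out <- lapply(seq_along(groups), function(i) {
    with_seed(seeds[i], {
      amp <- draw_subject_amplitudes(config, groups[i])
      series <- lapply(names(rois), function(nm) {
        base <- config$face_base + config$roi_baseline_offset[[nm]]
        noise_sd <- config$noise_sd / sqrt(npix[[nm]])
        base + as.vector(shapes %*% amp[nm, ]) + drift +
          rnorm(n, 0, config$roi_fluctuation_sd) + rnorm(n, 0, noise_sd)
      })
      names(series) <- names(rois)
      list(series = series, group = groups[i],
           subject_id = sprintf("S%02d_%s", i, groups[i]),
           amplitudes = amp)
    })
  })
  attr(out, "groups") <- groups
  out
}
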