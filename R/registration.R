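#' Face and eye segmentation helpers
#'
#' The face mask is the set of pixels warmer than the frame median by
#' `offset` degrees C (the background occupies most of the 320 x 240 field,
#' so the frame median sits at ambient temperature).
#'
#' @param frame Temperature matrix.
#' @param offset Threshold above the frame median, degrees C.
#' @return Logical matrix.
#' @export
face_mask <- function(frame, offset = 1) {
  frame > stats::median(frame) + offset
}

#' Locate the binocular centers of a thermal frame
#'
#' The eye regions are the coolest structures inside the face: pixels colder
#' than the face-mask median by `margin` degrees C are thresholded within
#' the eroded face interior (erosion excludes the face boundary, where
#' resampled frames blend skin and background temperatures), speckle
#' components below `min_area` pixels are discarded, and exactly two
#' components must remain. Returns their coldness-weighted centroids with
#' sub-pixel precision, left eye (smaller column) first.
#'
#' @param frame Temperature matrix.
#' @param margin Eye threshold below the face median, degrees C.
#' @param min_area Minimum component area in pixels.
#' @param mask_offset Passed to [face_mask()].
#' @param erode_px Radius of the face-interior erosion, pixels.
#' @return 2 x 2 numeric matrix, rows `left`/`right`, columns `x`/`y`
#'   (0-based pixel coordinates).
#' @export
locate_binocular_centers <- function(frame, margin = 2, min_area = 10,
                                     mask_offset = 1, erode_px = 2) {
  mask <- face_mask(frame, mask_offset)
  if (!any(mask))
    stop("binocular localization failed: no face pixels above background")
  fmed <- stats::median(frame[mask])
  interior <- if (erode_px > 0)
    EBImage::erode(mask * 1,
                   EBImage::makeBrush(2 * erode_px + 1, "box")) > 0
  else mask
  cand <- interior & (frame < fmed - margin)
  if (!any(cand))
    stop("binocular localization failed: no eye candidates after thresholding")
  lab <- EBImage::bwlabel(cand * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  if (length(keep) != 2)
    stop("binocular localization failed: found ", length(keep),
         " candidate region(s) of at least ", min_area,
         " px, expected exactly 2")
  centers <- t(vapply(keep, function(id) {
    idx <- which(lab == id, arr.ind = TRUE)
    w <- fmed - frame[idx]          # coldness depth as centroid weight
    w <- pmax(w, 1e-12)
    c(x = sum(w * (idx[, 2] - 1)) / sum(w),
      y = sum(w * (idx[, 1] - 1)) / sum(w))
  }, numeric(2)))
  centers <- centers[order(centers[, 1]), , drop = FALSE]
  rownames(centers) <- c("left", "right")
  centers
}

#' Build the fixed (reference) image of a sequence
#'
#' Takes the first frame, optionally mirror-corrects it, and translates it so
#' that the binocular midpoint sits at a canonical position. Mirror detection
#' (`flip = "auto"`) compares the mean face temperature of the two lateral
#' halves about the binocular midline: the canonical orientation has the
#' warmer half on the side named by `warm_side`. This is decidable only for
#' faces with a lateral temperature asymmetry (the default phantom has a
#' warmer right cheek).
#'
#' @param sequence A [thermal_sequence()].
#' @param canonical Canonical (x, y) of the binocular midpoint, 0-based;
#'   default `(width/2, 0.4 * height)`.
#' @param flip `"auto"` or `"never"`.
#' @param warm_side Side (`"right"`/`"left"` in image coordinates, i.e.
#'   larger/smaller x) carrying the warmer face half in canonical
#'   orientation.
#' @param ... Passed to [locate_binocular_centers()].
#' @return A `fixed_image`: list with `frame`, `eyes` (post-transform eye
#'   centers), `canonical`, `flipped`.
#' @export
build_fixed_image <- function(sequence, canonical = NULL,
                              flip = c("auto", "never"),
                              warm_side = c("right", "left"), ...) {
  flip <- match.arg(flip)
  warm_side <- match.arg(warm_side)
  stopifnot(inherits(sequence, "thermal_sequence"),
            length(sequence$frames) >= 1)
  frame <- sequence$frames[[1]]
  w <- ncol(frame); h <- nrow(frame)
  canonical <- canonical %||% c(x = w / 2, y = 0.4 * h)
  eyes <- locate_binocular_centers(frame, ...)
  flipped <- FALSE
  if (flip == "auto") {
    msk <- face_mask(frame)
    col0 <- matrix(rep(0:(w - 1), each = h), h, w)
    mid_x <- mean(eyes[, 1])
    left_mean <- mean(frame[msk & col0 < mid_x])
    right_mean <- mean(frame[msk & col0 > mid_x])
    if ((right_mean > left_mean) != (warm_side == "right")) {
      frame <- frame[, w:1]
      flipped <- TRUE
      eyes <- locate_binocular_centers(frame, ...)
    }
  }
  shift <- c(mean(eyes[, 1]), mean(eyes[, 2])) - canonical
  if (max(abs(shift)) > 1e-12) {
    bg <- stats::median(frame[!face_mask(frame)])
    frame <- apply_affine(frame, affine_params(tx = shift[1], ty = shift[2]),
                          fill = bg)
    eyes <- sweep(eyes, 2, shift)
  }
  structure(list(frame = frame, eyes = eyes, canonical = canonical,
                 flipped = flipped),
            class = "fixed_image")
}

#' Two-stage GA registration configuration
#'
#' Stage 1 searches translation and rotation over wide bounds with scales
#' fixed at 1; stage 2 searches all six affine parameters within narrow
#' bounds centered on the stage-1 optimum. Fitness is the negative mean
#' absolute temperature difference (MAD) over the fixed image's face mask.
#'
#' @param population Population size.
#' @param generations Generations per stage.
#' @param stage1_bounds Half-widths for `tx`, `ty` (px) and `theta` (deg).
#' @param stage2_bounds Half-widths for `tx`, `ty`, `theta`, `sx`, `sy`,
#'   `shear` around the stage-1 optimum.
#' @param crossover_rate Probability of uniform crossover per offspring pair.
#' @param mutation_rate Per-gene mutation probability.
#' @param mutation_sd_frac Mutation sd as a fraction of each gene's bound
#'   width.
#' @param elitism Number of elites copied unchanged each generation.
#' @param tournament_k Tournament selection size.
#' @param fitness_sample Maximum number of face-mask pixels the fitness is
#'   evaluated on (evenly spaced over the mask; the reported overlap errors
#'   always use the full mask). Metric subsampling is the standard speed
#'   device of intensity-based registration.
#' @param seed Integer seed; the GA is deterministic given it.
#' @return A `ga_config` object.
#' @export
ga_config <- function(population = 50, generations = 60,
                      stage1_bounds = c(tx = 15, ty = 15, theta = 10),
                      stage2_bounds = c(tx = 3, ty = 3, theta = 2,
                                        sx = 0.05, sy = 0.05, shear = 0.05),
                      crossover_rate = 0.8, mutation_rate = 0.1,
                      mutation_sd_frac = 0.1, elitism = 2, tournament_k = 3,
                      fitness_sample = 8000, seed = 1) {
  stopifnot(population >= 4, generations >= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            elitism >= 0, elitism < population)
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 stage1_bounds = stage1_bounds,
                 stage2_bounds = stage2_bounds,
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 mutation_sd_frac = mutation_sd_frac,
                 elitism = as.integer(elitism),
                 tournament_k = as.integer(tournament_k),
                 fitness_sample = as.integer(fitness_sample),
                 seed = as.integer(seed)),
            class = "ga_config")
}

# Real-coded GA maximizing fitfun over a box. Returns best genes, best
# fitness and the per-generation best-fitness trace (non-decreasing thanks
# to elitism).
ga_run <- function(fitfun, lower, upper, config, init = NULL) {
  np <- config$population; ng <- length(lower)
  width <- upper - lower
  pop <- matrix(runif(np * ng), np, ng)
  pop <- sweep(sweep(pop, 2, width, "*"), 2, lower, "+")
  if (!is.null(init)) pop[1, ] <- pmin(pmax(init, lower), upper)
  fit <- apply(pop, 1, fitfun)
  trace <- numeric(config$generations)
  for (g in seq_len(config$generations)) {
    ord <- order(fit, decreasing = TRUE)
    elite_idx <- ord[seq_len(config$elitism)]
    new_pop <- matrix(0, np, ng)
    if (config$elitism > 0)
      new_pop[seq_len(config$elitism), ] <- pop[elite_idx, , drop = FALSE]
    i <- config$elitism
    while (i < np) {
      pick <- function() {
        cand <- sample.int(np, config$tournament_k, replace = TRUE)
        cand[which.max(fit[cand])]
      }
      p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
      if (runif(1) < config$crossover_rate) {
        swap <- runif(ng) < 0.5
        tmp <- p1[swap]; p1[swap] <- p2[swap]; p2[swap] <- tmp
      }
      for (child in list(p1, p2)) {
        if (i >= np) break
        mut <- runif(ng) < config$mutation_rate
        if (any(mut))
          child[mut] <- child[mut] +
            rnorm(sum(mut), 0, config$mutation_sd_frac * width[mut])
        child <- pmin(pmax(child, lower), upper)
        i <- i + 1
        new_pop[i, ] <- child
      }
    }
    pop <- new_pop
    fit <- apply(pop, 1, fitfun)
    # keep the running best even if offspring regressed past the elites
    if (config$elitism == 0 && g > 1 && max(fit) < trace[g - 1]) {
      worst <- which.min(fit)
      pop[worst, ] <- best_genes; fit[worst] <- best_fit
    }
    if (g == 1 || max(fit) > best_fit) {
      best_fit <- max(fit); best_genes <- pop[which.max(fit), ]
    }
    trace[g] <- best_fit
  }
  list(genes = best_genes, fitness = best_fit, trace = trace)
}

mad_fitfun <- function(moving, fixed, mask_idx, fill) {
  rows <- mask_idx[, 1] - 1L; cols <- mask_idx[, 2] - 1L
  function(genes6) {
    p <- affine_params(tx = genes6[1], ty = genes6[2], theta = genes6[3],
                       sx = genes6[4], sy = genes6[5], shear = genes6[6])
    M <- affine_matrix(p)
    -affine_mad_cpp(moving, fixed, rows, cols,
                    c(M[1, 1], M[1, 2], M[2, 1], M[2, 2], M[1, 3], M[2, 3]),
                    fill)
  }
}

#' Two-stage GA affine registration of one frame
#'
#' Maximizes the negative face-mask MAD between the warped moving frame and
#' the fixed image. Stage 1 explores translation and rotation over the wide
#' stage-1 bounds; stage 2 refines all six affine parameters within narrow
#' bounds centered on the stage-1 optimum. Deterministic given
#' `config$seed`.
#'
#' @param moving Moving frame (matrix).
#' @param fixed Fixed frame (matrix or `fixed_image`).
#' @param config A [ga_config()].
#' @param center Optional 6-vector (tx, ty, theta, sx, sy, shear) on which to
#'   center the stage-2 search, skipping stage 1 (warm start).
#' @return List: `params` ([affine_params()]), `fitness` (negative MAD,
#'   degrees C), `trace` (list of per-generation best fitness per stage).
#' @export
ga_affine_register <- function(moving, fixed, config = ga_config(),
                               center = NULL) {
  if (inherits(fixed, "fixed_image")) fixed <- fixed$frame
  stopifnot(is.matrix(moving), is.matrix(fixed),
            identical(dim(moving), dim(fixed)))
  msk <- face_mask(fixed)
  if (!any(msk) || stats::sd(fixed[msk]) < 1e-8)
    stop("degenerate fixed image: no contrast over the face mask")
  mask_idx <- which(msk, arr.ind = TRUE)
  if (nrow(mask_idx) > config$fitness_sample)
    mask_idx <- mask_idx[round(seq(1, nrow(mask_idx),
                                   length.out = config$fitness_sample)), ,
                         drop = FALSE]
  fill <- stats::median(moving[!face_mask(moving)])
  fitfun <- mad_fitfun(moving, fixed, mask_idx, fill)
  b1 <- config$stage1_bounds; b2 <- config$stage2_bounds
  with_seed(config$seed, {
    if (is.null(center)) {
      s1 <- ga_run(function(g) fitfun(c(g, 1, 1, 0)),
                   lower = -abs(b1[c("tx", "ty", "theta")]),
                   upper = abs(b1[c("tx", "ty", "theta")]),
                   config, init = c(0, 0, 0))
      center <- c(s1$genes, 1, 1, 0)
      trace1 <- s1$trace
    } else {
      trace1 <- numeric(0)
    }
    lower <- center - abs(b2[c("tx", "ty", "theta", "sx", "sy", "shear")])
    upper <- center + abs(b2[c("tx", "ty", "theta", "sx", "sy", "shear")])
    lower[4:5] <- pmax(lower[4:5], 0.1)   # scales must stay positive
    s2 <- ga_run(fitfun, lower, upper, config, init = center)
    list(params = affine_params(tx = s2$genes[1], ty = s2$genes[2],
                                theta = s2$genes[3], sx = s2$genes[4],
                                sy = s2$genes[5], shear = s2$genes[6]),
         fitness = s2$fitness,
         trace = list(stage1 = trace1, stage2 = s2$trace))
  })
}

#' Register every frame of a sequence to its fixed image
#'
#' Builds the fixed image from the first frame (binocular pre-alignment),
#' then GA-registers each frame to it, reporting the face-mask overlap error
#' (MAD, degrees C) before and after registration. Per-frame GA seeds are
#' derived from `config$seed`.
#'
#' @param sequence A [thermal_sequence()].
#' @param config A [ga_config()].
#' @param fixed Optional precomputed `fixed_image`.
#' @param warm_start If `TRUE`, each frame after the first skips stage 1 and
#'   centers its stage-2 search on the previous frame's solution.
#' @return List: `sequence` (registered [thermal_sequence()]), `result`
#'   (data frame: frame, tx..shear, fitness, err_before, err_after),
#'   `fixed` (the `fixed_image`).
#' @export
register_sequence <- function(sequence, config = ga_config(), fixed = NULL,
                              warm_start = FALSE) {
  stopifnot(inherits(sequence, "thermal_sequence"))
  fixed <- fixed %||% build_fixed_image(sequence)
  fframe <- fixed$frame
  msk <- face_mask(fframe)
  mask_idx <- which(msk, arr.ind = TRUE)
  rows <- mask_idx[, 1] - 1L; cols <- mask_idx[, 2] - 1L
  n <- length(sequence$frames)
  seeds <- derive_seeds(config$seed, n)
  reg_frames <- vector("list", n)
  res <- vector("list", n)
  prev <- NULL
  for (k in seq_len(n)) {
    frame <- sequence$frames[[k]]
    fill <- stats::median(frame[!face_mask(frame)])
    err_before <- affine_mad_cpp(frame, fframe, rows, cols,
                                 c(1, 0, 0, 1, 0, 0), fill)
    cfg <- config; cfg$seed <- seeds[k]
    fit <- tryCatch(
      ga_affine_register(frame, fframe, cfg,
                         center = if (warm_start) prev else NULL),
      error = function(e) stop("registration failed at frame ", k - 1, ": ",
                               conditionMessage(e)))
    p <- fit$params
    prev <- c(p$tx, p$ty, p$theta, p$sx, p$sy, p$shear)
    reg_frames[[k]] <- apply_affine(frame, p, fill = fill)
    err_after <- affine_mad_cpp(reg_frames[[k]], fframe, rows, cols,
                                c(1, 0, 0, 1, 0, 0), fill)
    res[[k]] <- data.frame(frame = k - 1L, tx = p$tx, ty = p$ty,
                           theta = p$theta, sx = p$sx, sy = p$sy,
                           shear = p$shear, fitness = fit$fitness,
                           err_before = err_before,
                           err_after = err_after)
  }
  list(sequence = thermal_sequence(reg_frames, fps = sequence$fps,
                                   subject_id = sequence$subject_id),
       result = do.call(rbind, res),
       fixed = fixed)
}
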