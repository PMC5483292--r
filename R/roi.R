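#' Facial regions of interest
#'
#' Five axis-aligned rectangles in fixed-image coordinates: forehead, nose,
#' mouth, left cheek and right cheek. Rectangles are 0-based half-open
#' `c(x0, y0, x1, y1)`: a pixel belongs to the ROI iff its column index lies
#' in `[x0, x1)` and its row index in `[y0, y1)`; no partial pixel weighting.
#'
#' @name roi_set
NULL

.ROI_NAMES <- c("forehead", "nose", "mouth", "left_cheek", "right_cheek")

# Eye-anchored proportional ROI layout. All sizes are multiples of the
# inter-ocular distance d so the layout is translation- and
# scale-equivariant with the eye pair (up to pixel rounding).
default_roi_geometry <- function(eyes, width, height) {
  mx <- mean(eyes[, 1]); my <- mean(eyes[, 2])
  d <- sqrt(sum((eyes[2, ] - eyes[1, ])^2))
  rect <- function(cx, cy, w, h) {
    c(x0 = round(cx - w / 2), y0 = round(cy - h / 2),
      x1 = round(cx + w / 2), y1 = round(cy + h / 2))
  }
  list(
    forehead    = rect(mx,            my - 0.55 * d, 1.6 * d, 0.6 * d),
    nose        = rect(mx,            my + 0.50 * d, 0.5 * d, 0.6 * d),
    mouth       = rect(mx,            my + 1.15 * d, 0.9 * d, 0.4 * d),
    left_cheek  = rect(mx - 0.70 * d, my + 0.50 * d, 0.6 * d, 0.6 * d),
    right_cheek = rect(mx + 0.70 * d, my + 0.50 * d, 0.6 * d, 0.6 * d)
  )
}

#' Default eye-anchored ROI set
#'
#' Places the five facial ROIs relative to the binocular midpoint and
#' inter-ocular distance `d`: forehead (1.6d x 0.6d) above the eyes, nose
#' (0.5d x 0.6d) below the midpoint, mouth (0.9d x 0.4d) below the nose,
#' cheeks (0.6d x 0.6d) lateral to the nose. Deterministic given the eyes.
#'
#' @param frame Frame matrix (or `fixed_image`) supplying the image bounds.
#' @param eyes 2 x 2 matrix of (x, y) eye centers (rows: left, right).
#' @return A `roi_set`: named list of `c(x0, y0, x1, y1)` rectangles.
#' @export
default_roi_set <- function(frame, eyes) {
  if (inherits(frame, "fixed_image")) {
    if (missing(eyes)) eyes <- frame$eyes
    frame <- frame$frame
  }
  stopifnot(is.matrix(frame), is.matrix(eyes), nrow(eyes) == 2)
  rois <- default_roi_geometry(eyes, width = ncol(frame),
                               height = nrow(frame))
  for (nm in names(rois)) {
    r <- rois[[nm]]
    if (r["x0"] < 0 || r["y0"] < 0 || r["x1"] > ncol(frame) ||
        r["y1"] > nrow(frame) || r["x1"] <= r["x0"] || r["y1"] <= r["y0"])
      stop("ROI '", nm, "' falls outside the frame bounds")
  }
  structure(rois, class = "roi_set")
}

#' Read / write ROI sets as JSON
#'
#' Serialized as `{name: [x0, y0, x1, y1]}` so deployments can override the
#' default geometry.
#'
#' @param rois A `roi_set`.
#' @param path JSON file path.
#' @return `read_roi_set` returns a `roi_set`; `write_roi_set` the path,
#'   invisibly.
#' @export
write_roi_set <- function(rois, path) {
  jsonlite::write_json(lapply(unclass(rois), unname), path, digits = NA)
  invisible(path)
}

#' @rdname write_roi_set
#' @export
read_roi_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!setequal(names(obj), .ROI_NAMES))
    stop("ROI file must define exactly: ", paste(.ROI_NAMES, collapse = ", "))
  structure(lapply(obj[.ROI_NAMES], function(v) {
    stats::setNames(as.numeric(v), c("x0", "y0", "x1", "y1"))
  }), class = "roi_set")
}

#' Extract per-ROI mean-temperature series
#'
#' For each ROI, the arithmetic mean temperature of its pixels at every
#' frame of a (registered) sequence.
#'
#' @param sequence A [thermal_sequence()].
#' @param rois A `roi_set`.
#' @return Named list of numeric vectors (one value per frame, degrees C)
#'   with attribute `fps`.
#' @export
extract_roi_series <- function(sequence, rois) {
  stopifnot(inherits(sequence, "thermal_sequence"), inherits(rois, "roi_set"))
  out <- lapply(rois, function(r) {
    ry <- (r[["y0"]] + 1):r[["y1"]]
    rx <- (r[["x0"]] + 1):r[["x1"]]
    vapply(sequence$frames, function(f) mean(f[ry, rx]), numeric(1))
  })
  attr(out, "fps") <- sequence$fps
  out
}

# Baseline frame window (0-based half-open) for the event containing the
# window starting at frame `a`, under the "prev_event" rule: last
# `baseline_frames` frames of the immediately preceding event, or the first
# `baseline_frames` frames of the sequence for the first event.
baseline_window <- function(schedule, a, baseline_frames) {
  ev <- schedule$events
  starts <- floor(ev$start_s * schedule$fps)
  i <- max(which(starts <= a))
  if (i == 1) return(c(0L, baseline_frames))
  prev_end <- starts[i]
  c(prev_end - baseline_frames, prev_end)
}

#' Stimulation-locked temperature-change features of one ROI series
#'
#' Concatenates the frame windows of `emotion` (see [frame_windows()]) in
#' temporal order, expressing each window relative to a baseline so the
#' features are temperature *changes*, not absolutes. With the default
#' schedule and policy each emotion (and REST, for "no stimulus" features)
#' yields 3 windows x 16 frames = 48 features.
#'
#' @param series Numeric per-frame ROI mean temperatures.
#' @param schedule A `stim_schedule`; `length(series)` must equal
#'   [total_frames()].
#' @param emotion One of [emotion_levels()].
#' @param policy A [window_policy()].
#' @param baseline Baseline rule: `"prev_event"` subtracts the mean of the
#'   final `baseline_s` seconds of the event immediately preceding each
#'   window's segment (first event: the sequence's first `baseline_s`
#'   seconds), removing slow drift; `"global"` subtracts the mean of the
#'   sequence's first `baseline_s` seconds from everything; `"none"` keeps
#'   raw temperatures.
#' @param baseline_s Baseline-window length, seconds.
#' @return Numeric feature vector (length 48 under defaults).
#' @export
build_features <- function(series, schedule, emotion,
                           policy = window_policy(),
                           baseline = c("prev_event", "global", "none"),
                           baseline_s = 3) {
  baseline <- match.arg(baseline)
  n <- total_frames(schedule)
  if (length(series) != n)
    stop("series length (", length(series),
         ") does not match schedule frame count (", n, ")")
  bf <- as.integer(round(baseline_s * schedule$fps))
  wins <- frame_windows(schedule, emotion, policy)
  feats <- lapply(wins, function(w) {
    vals <- series[(w[1] + 1):w[2]]
    b <- switch(baseline,
      none = 0,
      global = mean(series[seq_len(bf)]),
      prev_event = {
        bw <- baseline_window(schedule, w[1], bf)
        mean(series[(bw[1] + 1):bw[2]])
      })
    vals - b
  })
  unlist(feats, use.names = FALSE)
}

new_feature_matrix <- function(values, labels, roi, emotion) {
  structure(list(values = values, labels = labels, roi = roi,
                 emotion = emotion),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix %s x %s: %d subjects x %d features (%s)\n",
              x$roi, x$emotion, nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", levels(x$labels),
                            tabulate(x$labels)), collapse = ", ")))
  invisible(x)
}

#' Cohort feature matrices per ROI x emotion block
#'
#' Assembles one subjects x features matrix per (ROI, emotion) cell,
#' including the REST ("no stimulus") block, with group labels aligned to
#' the rows.
#'
#' @param cohort List of subjects as returned by [simulate_cohort_series()],
#'   or any list whose elements have `series` (named list of per-ROI
#'   vectors), `group` and `subject_id`.
#' @param schedule A `stim_schedule`.
#' @param policy A [window_policy()].
#' @param baseline,baseline_s Passed to [build_features()].
#' @param emotions Emotion blocks to build.
#' @return Named list (keys `"roi.emotion"`) of `feature_matrix` objects.
#' @export
cohort_feature_matrix <- function(cohort, schedule = build_default_schedule(),
                                  policy = window_policy(),
                                  baseline = "prev_event", baseline_s = 3,
                                  emotions = emotion_levels()) {
  stopifnot(length(cohort) >= 1)
  labels <- factor(vapply(cohort, function(s) s$group, character(1)),
                   levels = c("moderate", "marked"))
  ids <- vapply(cohort, function(s) s$subject_id, character(1))
  rois <- names(cohort[[1]]$series)
  out <- list()
  for (roi in rois) {
    for (emo in emotions) {
      rows <- lapply(cohort, function(s)
        build_features(s$series[[roi]], schedule, emo, policy,
                       baseline = baseline, baseline_s = baseline_s))
      m <- do.call(rbind, rows)
      rownames(m) <- ids
      out[[paste(roi, emo, sep = ".")]] <-
        new_feature_matrix(m, labels, roi, emo)
    }
  }
  out
}
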