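#' Emotion stimulation schedules
#'
#' A stimulation schedule describes the timed presentation of emotion-evoking
#' image segments (HVLA: high valence / low arousal; LVLA: low valence / low
#' arousal; LVHA: low valence / high arousal) interleaved with rest breaks
#' (`REST`), and maps wall-clock time onto thermal-camera frame indices.
#'
#' @name stim_schedule
NULL

.EMOTIONS <- c("HVLA", "LVLA", "LVHA")

#' Valid emotion labels
#'
#' @return Character vector `c("HVLA", "LVLA", "LVHA", "REST")`. `REST`
#'   denotes rest breaks and never carries stimulation images.
#' @export
emotion_levels <- function() c(.EMOTIONS, "REST")

new_schedule <- function(events, fps, image_duration_s) {
  structure(list(events = events, fps = fps,
                 image_duration_s = image_duration_s),
            class = "stim_schedule")
}

#' Build the default 225 s stimulation schedule
#'
#' Nine 15 s image segments (5 images of 3 s each), one per emotion in a
#' repeating HVLA, LVLA, LVHA cycle, each followed by a 10 s rest break:
#' 9 x 15 + 9 x 10 = 225 s in total, sampled at 2 frames per second.
#'
#' @param fps Camera sampling rate, frames/second.
#' @param image_duration_s Presentation time of a single image, seconds.
#' @param images_per_segment Images shown in one segment.
#' @param break_s Rest-break duration, seconds.
#' @param cycles Number of HVLA/LVLA/LVHA cycles.
#' @param order Emotion order within a cycle.
#' @return A `stim_schedule` object.
#' @export
#' @examples
#' sched <- build_default_schedule()
#' sum(sched$events$duration_s)  # 225
#' total_frames(sched)           # 450
build_default_schedule <- function(fps = 2, image_duration_s = 3,
                                   images_per_segment = 5, break_s = 10,
                                   cycles = 3,
                                   order = c("HVLA", "LVLA", "LVHA")) {
  stopifnot(all(order %in% .EMOTIONS))
  seg_s <- images_per_segment * image_duration_s
  emo <- character(0); dur <- numeric(0); img <- integer(0)
  for (cy in seq_len(cycles)) {
    for (e in order) {
      emo <- c(emo, e, "REST")
      dur <- c(dur, seg_s, break_s)
      img <- c(img, images_per_segment, 0L)
    }
  }
  events <- data.frame(
    emotion = emo,
    start_s = cumsum(c(0, dur[-length(dur)])),
    duration_s = dur,
    image_count = img,
    stringsAsFactors = FALSE
  )
  sched <- new_schedule(events, fps = fps, image_duration_s = image_duration_s)
  validate_schedule(sched)
  sched
}

#' Validate a stimulation schedule
#'
#' Checks contiguity/non-overlap of events, positive durations, the
#' image-count x image-duration = segment-duration identity for image
#' segments, zero image count on rest breaks, and that every non-REST emotion
#' present occurs equally often.
#'
#' @param schedule A `stim_schedule`.
#' @return The schedule, invisibly; errors on violation.
#' @export
validate_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "stim_schedule"))
  ev <- schedule$events
  if (nrow(ev) == 0) return(invisible(schedule))
  if (!all(ev$emotion %in% emotion_levels()))
    stop("unknown emotion label in schedule")
  if (any(ev$duration_s <= 0)) stop("event durations must be positive")
  if (any(ev$start_s < 0)) stop("event start times must be non-negative")
  expected_start <- cumsum(c(0, ev$duration_s[-nrow(ev)]))
  if (max(abs(ev$start_s - expected_start)) > 1e-9)
    stop("schedule events must be contiguous and non-overlapping")
  img <- ev$emotion != "REST"
  if (any(ev$image_count[!img] != 0))
    stop("REST events must have image_count 0")
  if (any(abs(ev$image_count[img] * schedule$image_duration_s -
              ev$duration_s[img]) > 1e-9))
    stop("image segments must satisfy image_count * image_duration_s = duration_s")
  counts <- table(ev$emotion[img])
  if (length(counts) > 1 && length(unique(as.integer(counts))) != 1)
    stop("each stimulated emotion must occur the same number of times")
  invisible(schedule)
}

#' Total number of camera frames covered by a schedule
#'
#' @param schedule A `stim_schedule`.
#' @return Integer frame count, `total duration x fps` (225 s at 2 fps gives
#'   450 frames).
#' @export
total_frames <- function(schedule) {
  stopifnot(inherits(schedule, "stim_schedule"))
  as.integer(round(sum(schedule$events$duration_s) * schedule$fps))
}

#' Per-segment analysis window policy
#'
#' Selects, within each matching schedule event, a fixed sub-window of frames
#' used for feature extraction. The default (offset 0, 16 frames, first 3
#' matching events) takes the first 8 s of each of the 3 segments per emotion
#' at 2 fps, yielding 3 x 16 = 48 features per emotion.
#'
#' @param offset_frames Frames skipped at the start of each event.
#' @param length_frames Window length in frames.
#' @param n_segments Number of matching events used, in temporal order;
#'   `NULL` means all.
#' @return A `window_policy` object.
#' @export
window_policy <- function(offset_frames = 0L, length_frames = 16L,
                          n_segments = 3L) {
  stopifnot(offset_frames >= 0, length_frames >= 1)
  structure(list(offset_frames = as.integer(offset_frames),
                 length_frames = as.integer(length_frames),
                 n_segments = if (is.null(n_segments)) NULL
                              else as.integer(n_segments)),
            class = "window_policy")
}

#' Frame-index windows of one emotion
#'
#' Converts the schedule events matching `emotion` into half-open, 0-based
#' frame-index ranges according to a [window_policy()]. Time is mapped to
#' frames by `floor(start_s * fps)`.
#'
#' @param schedule A `stim_schedule`.
#' @param emotion One of [emotion_levels()] (REST gives the rest-break
#'   windows used for "no stimulus" features).
#' @param policy A [window_policy()].
#' @return List of integer vectors `c(start, end)` (half-open, 0-based), one
#'   per used event; empty list if no event matches.
#' @export
frame_windows <- function(schedule, emotion, policy = window_policy()) {
  validate_schedule(schedule)
  stopifnot(emotion %in% emotion_levels(), inherits(policy, "window_policy"))
  ev <- schedule$events
  idx <- which(ev$emotion == emotion)
  if (!is.null(policy$n_segments)) idx <- utils::head(idx, policy$n_segments)
  fps <- schedule$fps
  out <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    seg_start <- as.integer(floor(ev$start_s[i] * fps))
    seg_len <- as.integer(floor(ev$duration_s[i] * fps))
    if (policy$offset_frames + policy$length_frames > seg_len)
      stop(sprintf("window policy (offset %d + length %d frames) exceeds the %g s event at %g s",
                   policy$offset_frames, policy$length_frames,
                   ev$duration_s[i], ev$start_s[i]))
    a <- seg_start + policy$offset_frames
    out[[j]] <- c(a, a + policy$length_frames)
  }
  out
}

#' Read / write schedules
#'
#' Serialization as YAML or JSON (chosen by file extension) with fields
#' `fps`, `image_duration_s` and `events` (emotion, start_s, duration_s,
#' image_count).
#'
#' @param schedule A `stim_schedule`.
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @return `read_schedule` returns a validated `stim_schedule`;
#'   `write_schedule` returns `path` invisibly.
#' @export
write_schedule <- function(schedule, path) {
  validate_schedule(schedule)
  obj <- list(fps = schedule$fps,
              image_duration_s = schedule$image_duration_s,
              events = schedule$events)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    ev <- lapply(seq_len(nrow(schedule$events)), function(i)
      as.list(schedule$events[i, , drop = FALSE]))
    ev <- lapply(ev, function(e) lapply(e, function(v) v[[1]]))
    yaml::write_yaml(list(fps = schedule$fps,
                          image_duration_s = schedule$image_duration_s,
                          events = ev), path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  } else stop("unsupported schedule format: ", path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    obj <- yaml::read_yaml(path)
    ev <- do.call(rbind, lapply(obj$events, function(e)
      data.frame(emotion = e$emotion, start_s = e$start_s,
                 duration_s = e$duration_s, image_count = e$image_count,
                 stringsAsFactors = FALSE)))
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    ev <- as.data.frame(obj$events, stringsAsFactors = FALSE)
  } else stop("unsupported schedule format: ", path)
  sched <- new_schedule(ev, fps = obj$fps,
                        image_duration_s = obj$image_duration_s)
  validate_schedule(sched)
  sched
}
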