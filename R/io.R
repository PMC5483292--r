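#' Sequence TIFF I/O
#'
#' Thermal sequences are stored as multi-page 32-bit TIFF stacks (one page
#' per frame, raw temperature matrices, never color-mapped renderings) plus
#' a JSON sidecar (`<path>.json`) carrying `fps`, `subject_id` and the
#' linear sample-to-temperature map. Samples are written as 32-bit values of
#' `(T - offset) / scale`; with the default map the quantization step is
#' about 2.3e-8 degrees C, far below sensor noise.
#'
#' @param sequence A [thermal_sequence()].
#' @param path TIFF file path.
#' @param scale,offset Linear map: stored sample = `(T - offset) / scale`.
#' @param compression TIFF compression.
#' @return `write_sequence` returns `path` invisibly; `read_sequence` a
#'   [thermal_sequence()].
#' @export
write_sequence <- function(sequence, path, scale = 100, offset = 0,
                           compression = "none") {
  stopifnot(inherits(sequence, "thermal_sequence"),
            length(sequence$frames) >= 1)
  pages <- lapply(sequence$frames, function(f) (f - offset) / scale)
  rng <- range(unlist(lapply(pages, range)))
  if (rng[1] < 0 || rng[2] > 1)
    stop("temperatures outside the storable range [", offset, ", ",
         offset + scale, "] degC; adjust scale/offset")
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE,
                  compression = compression)
  meta <- list(fps = sequence$fps, subject_id = sequence$subject_id,
               scale = scale, offset = offset,
               n_frames = length(sequence$frames),
               width = ncol(sequence$frames[[1]]),
               height = nrow(sequence$frames[[1]]))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_sequence
#' @export
read_sequence <- function(path) {
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e)
                      stop("failed to read TIFF '", path, "': ",
                           conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  for (i in seq_along(pages)) {
    bps <- attr(pages[[i]], "bits.per.sample")
    if (!is.null(bps) && bps != 32)
      stop("unsupported TIFF sample depth (", bps, " bits) on page ", i,
           "; 32-bit temperature samples are required")
    if (!identical(dim(pages[[i]]), d))
      stop("page ", i, " shape ", paste(dim(pages[[i]]), collapse = "x"),
           " differs from page 1 (", paste(d, collapse = "x"), ")")
  }
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar, simplifyVector = TRUE)
  else
    list(fps = NA_real_, subject_id = basename(path), scale = 1, offset = 0)
  frames <- lapply(pages, function(p) {
    f <- p * meta$scale + meta$offset
    attributes(f) <- list(dim = dim(p))
    f
  })
  thermal_sequence(frames, fps = meta$fps, subject_id = meta$subject_id)
}

#' Order-insensitive configuration hash
#'
#' Hash of the canonicalized (recursively name-sorted) configuration,
#' stable under field reordering; embedded in every result CSV so outputs
#' are traceable to the configuration that produced them.
#'
#' @param config Any R list / object.
#' @return Character hash.
#' @export
config_hash <- function(config) {
  canon <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, canon)
      if (!is.null(names(x)) && any(nzchar(names(x))))
        x <- x[order(names(x))]
    }
    x
  }
  digest::digest(canon(unclass_deep(config)), algo = "sha1")
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}

#' Result CSV with configuration-hash header
#'
#' @param df Data frame.
#' @param path CSV path.
#' @param hash Configuration hash to embed as a `# config_hash:` comment.
#' @return `write_result_csv` returns `path` invisibly; `read_result_csv`
#'   the data frame with a `config_hash` attribute.
#' @export
write_result_csv <- function(df, path, hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(hash)) writeLines(paste0("# config_hash: ", hash), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_result_csv
#' @export
read_result_csv <- function(path) {
  first <- readLines(path, n = 1)
  hash <- if (startsWith(first, "# config_hash: "))
    sub("^# config_hash: ", "", first) else NULL
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  attr(df, "config_hash") <- hash
  df
}

#' Write a simulated cohort to disk
#'
#' One TIFF stack (plus JSON sidecar with ground truth) per subject and a
#' manifest CSV (`subject_id`, `group`, `path`).
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Manifest data frame, invisibly; written to
#'   `file.path(dir, "manifest.csv")`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(subj) {
    sid <- subj$sequence$subject_id
    p <- file.path(dir, paste0(sid, ".tiff"))
    write_sequence(subj$sequence, p)
    truth <- list(group = subj$truth$group,
                  amplitudes = subj$truth$amplitudes,
                  affine = subj$truth$affine)
    jsonlite::write_json(truth, file.path(dir, paste0(sid, "_truth.json")),
                         digits = NA, dataframe = "columns")
    data.frame(subject_id = sid, group = subj$truth$group, path = p,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.csv"), sep = ",",
                     row.names = FALSE, quote = TRUE)
  invisible(manifest)
}
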