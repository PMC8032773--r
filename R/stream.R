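#' Construct a per-frame detection stream
#'
#' A `video_stream` holds the detector output for one endoscopy video: for
#' every frame, zero or more scored bounding boxes. Frames are indexed from 0
#' and form a contiguous sequence; the time of frame `k` is `k / fps` seconds.
#' Boxes use a half-open pixel rectangle convention `[x0, x1) x [y0, y1)`.
#'
#' @param video_id Character scalar identifying the video.
#' @param case_id Character scalar identifying the patient/case.
#' @param modality `"WLI"` (white-light imaging) or `"NBI"` (narrow-band
#'   imaging).
#' @param fps Frames per second (default 30, the native rate of the
#'   endoscope recordings).
#' @param n_frames Total number of frames in the video.
#' @param boxes Data frame of detections with columns `frame` (0-based frame
#'   index), `x0`, `y0`, `x1`, `y1` (pixels) and `score` (detector confidence
#'   in \[0, 1\]). Frames without detections simply have no rows. May be
#'   `NULL` for an all-empty stream.
#'
#' @return An object of class `video_stream`.
#' @seealso [validate_stream()], [read_detection_stream()],
#'   [run_confirmation()]
#' @export
video_stream <- function(video_id, case_id, modality, fps = 30, n_frames,
                         boxes = NULL) {
  if (is.null(boxes) || nrow(boxes) == 0L) {
    boxes <- empty_boxes()
  } else {
    boxes <- as.data.frame(boxes)[, c("frame", "x0", "y0", "x1", "y1", "score")]
    boxes <- boxes[order(boxes$frame), , drop = FALSE]
    rownames(boxes) <- NULL
    boxes$frame <- as.integer(boxes$frame)
  }
  obj <- structure(
    list(video_id = as.character(video_id),
         case_id = as.character(case_id),
         modality = as.character(modality),
         fps = as.numeric(fps),
         n_frames = as.integer(n_frames),
         boxes = boxes),
    class = "video_stream")
  issues <- validate_stream(obj)
  if (length(issues)) {
    stop("invalid video_stream: ", paste(issues, collapse = "; "),
         call. = FALSE)
  }
  obj
}

empty_boxes <- function() {
  data.frame(frame = integer(0), x0 = numeric(0), y0 = numeric(0),
             x1 = numeric(0), y1 = numeric(0), score = numeric(0))
}

#' @export
print.video_stream <- function(x, ...) {
  cat(sprintf("<video_stream> %s (case %s, %s, %g fps)\n",
              x$video_id, x$case_id, x$modality, x$fps))
  cat(sprintf("  %d frames, %d boxes in %d detection frames\n",
              x$n_frames, nrow(x$boxes), length(unique(x$boxes$frame))))
  invisible(x)
}

#' Check a detection stream against its structural invariants
#'
#' Reports, rather than raises: each violated rule yields one message naming
#' the offending frame where applicable. An empty return value means the
#' stream satisfies all invariants (modality is one of WLI/NBI, fps positive,
#' boxes lie on frames inside `[0, n_frames)`, rectangles are non-degenerate,
#' scores lie in \[0, 1\]).
#'
#' @param stream A [video_stream()] (or a structurally similar list, so that
#'   malformed objects can be inspected).
#' @return Character vector of issues; `character(0)` if the stream is valid.
#' @export
validate_stream <- function(stream) {
  issues <- character(0)
  add <- function(msg) issues <<- c(issues, msg)
  if (!is.character(stream$video_id) || length(stream$video_id) != 1L ||
      is.na(stream$video_id) || !nzchar(stream$video_id)) {
    add("video_id must be a non-empty string")
  }
  if (!stream$modality %in% c("WLI", "NBI")) {
    add(sprintf("modality must be WLI or NBI, got '%s'", stream$modality))
  }
  if (!is.numeric(stream$fps) || length(stream$fps) != 1L ||
      is.na(stream$fps) || stream$fps <= 0) {
    add("fps must be a positive number")
  }
  if (!is.numeric(stream$n_frames) || length(stream$n_frames) != 1L ||
      is.na(stream$n_frames) || stream$n_frames < 0) {
    add("n_frames must be a non-negative integer")
  }
  b <- stream$boxes
  if (!is.data.frame(b)) {
    add("boxes must be a data frame")
    return(issues)
  }
  need <- c("frame", "x0", "y0", "x1", "y1", "score")
  if (!all(need %in% names(b))) {
    add(paste("boxes missing columns:",
              paste(setdiff(need, names(b)), collapse = ", ")))
    return(issues)
  }
  bad <- which(b$frame < 0 | b$frame >= stream$n_frames)
  for (i in bad) {
    add(sprintf("frame %d: box outside frame range [0, %d)",
                b$frame[i], stream$n_frames))
  }
  bad <- which(!(b$x0 < b$x1))
  for (i in bad) add(sprintf("frame %d: degenerate box (x1 <= x0)", b$frame[i]))
  bad <- which(!(b$y0 < b$y1))
  for (i in bad) add(sprintf("frame %d: degenerate box (y1 <= y0)", b$frame[i]))
  bad <- which(is.na(b$score) | b$score < 0 | b$score > 1)
  for (i in bad) {
    add(sprintf("frame %d: score %s outside [0, 1]", b$frame[i],
                format(b$score[i])))
  }
  issues
}

#' Read a per-frame detection stream from disk
#'
#' Two on-disk dialects are supported. JSON-lines: one object per frame,
#' `{"video_id", "case_id", "modality", "fps", "frame", "boxes": [...]}`,
#' with `boxes` an array of `{"x0","y0","x1","y1","score"}`. CSV: one row
#' per box plus a sentinel row (empty box fields) for each frame without
#' detections; columns `video_id, case_id, modality, fps, frame, x0, y0, x1,
#' y1, score`.
#'
#' Frames must form a contiguous 0-based sequence. Missing frame indices are
#' an error by default — silent gaps would corrupt the gap-based confirmation
#' logic — unless `fill_gaps = TRUE`, in which case absent frames are treated
#' as empty detections.
#'
#' @param path Path to the stream file.
#' @param format `"jsonl"` or `"csv"`; the default guesses from the file
#'   extension.
#' @param fill_gaps Treat frame indices absent from the file as empty frames
#'   rather than raising an error.
#' @return A validated [video_stream()].
#' @export
read_detection_stream <- function(path, format = c("auto", "jsonl", "csv"),
                                  fill_gaps = FALSE) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  parsed <- switch(format,
                   jsonl = parse_stream_jsonl(path),
                   csv = parse_stream_csv(path))
  frames <- parsed$frames
  if (anyDuplicated(frames)) {
    stop(sprintf("duplicate frame_index %d in %s",
                 frames[duplicated(frames)][1L], path), call. = FALSE)
  }
  o <- order(frames)
  frames <- frames[o]
  n <- max(frames) + 1L
  expected <- seq.int(0L, n - 1L)
  if (!identical(as.integer(frames), expected)) {
    if (!fill_gaps) {
      missing <- setdiff(expected, frames)
      stop(sprintf("stream %s has missing frame indices (first: %d); %s",
                   path, missing[1L],
                   "pass fill_gaps = TRUE to treat them as empty frames"),
           call. = FALSE)
    }
    # with fill_gaps the absent frames become empty detections implicitly:
    # the stream stores boxes sparsely and n_frames = max declared index + 1
  }
  video_stream(video_id = parsed$video_id, case_id = parsed$case_id,
               modality = parsed$modality, fps = parsed$fps,
               n_frames = n, boxes = parsed$boxes)
}

parse_stream_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty stream file: ", path, call. = FALSE)
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyDataFrame = TRUE),
      error = function(e) {
        stop(sprintf("parse error in %s, line %d: %s", path, i,
                     conditionMessage(e)), call. = FALSE)
      })
    for (f in c("video_id", "case_id", "modality", "fps", "frame")) {
      if (is.null(rec[[f]])) {
        stop(sprintf("parse error in %s, line %d: missing field '%s'",
                     path, i, f), call. = FALSE)
      }
    }
    recs[[i]] <- rec
  }
  frames <- vapply(recs, function(r) as.integer(r$frame), integer(1))
  box_list <- lapply(seq_along(recs), function(i) {
    b <- recs[[i]]$boxes
    if (is.null(b) || length(b) == 0L || NROW(b) == 0L) return(NULL)
    b <- as.data.frame(b)
    b$frame <- frames[i]
    b[, c("frame", "x0", "y0", "x1", "y1", "score")]
  })
  boxes <- do.call(rbind, box_list)
  if (is.null(boxes)) boxes <- empty_boxes()
  list(video_id = recs[[1L]]$video_id, case_id = recs[[1L]]$case_id,
       modality = recs[[1L]]$modality, fps = recs[[1L]]$fps,
       frames = frames, boxes = boxes)
}

parse_stream_csv <- function(path) {
  d <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(video_id = "character",
                                   case_id = "character",
                                   modality = "character")),
    error = function(e) {
      stop(sprintf("parse error in %s: %s", path, conditionMessage(e)),
           call. = FALSE)
    })
  need <- c("video_id", "case_id", "modality", "fps", "frame",
            "x0", "y0", "x1", "y1", "score")
  if (!all(need %in% names(d))) {
    stop(sprintf("parse error in %s: missing columns %s", path,
                 paste(setdiff(need, names(d)), collapse = ", ")),
         call. = FALSE)
  }
  is_sentinel <- is.na(d$x0) & is.na(d$score)
  frames <- sort(unique(as.integer(d$frame)))
  boxes <- d[!is_sentinel, c("frame", "x0", "y0", "x1", "y1", "score")]
  boxes$frame <- as.integer(boxes$frame)
  # sentinel rows declare empty frames; duplicates among them are harmless,
  # but a frame listed both as sentinel and with a box is contradictory
  dup_sent <- intersect(d$frame[is_sentinel], boxes$frame)
  if (length(dup_sent)) {
    stop(sprintf("parse error in %s: frame %d has both a sentinel and boxes",
                 path, as.integer(dup_sent[1L])), call. = FALSE)
  }
  # duplicate frame declaration = same frame appearing as >1 sentinel row
  sent_frames <- as.integer(d$frame[is_sentinel])
  if (anyDuplicated(sent_frames)) {
    stop(sprintf("duplicate frame_index %d in %s",
                 sent_frames[duplicated(sent_frames)][1L], path),
         call. = FALSE)
  }
  list(video_id = d$video_id[1L], case_id = d$case_id[1L],
       modality = d$modality[1L], fps = d$fps[1L],
       frames = frames, boxes = boxes)
}

#' Write a detection stream to disk
#'
#' Inverse of [read_detection_stream()]: the written file reads back to a
#' stream identical to the input, with scores serialized at full double
#' precision.
#'
#' @param stream A valid [video_stream()].
#' @inheritParams read_detection_stream
#' @return The path, invisibly.
#' @export
write_detection_stream <- function(stream, path,
                                   format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "jsonl"
  }
  issues <- validate_stream(stream)
  if (length(issues)) {
    stop("refusing to write invalid stream: ", issues[1L], call. = FALSE)
  }
  split_boxes <- split(stream$boxes, factor(stream$boxes$frame,
                                            levels = 0:(stream$n_frames - 1L)))
  if (format == "jsonl") {
    lines <- vapply(seq_len(stream$n_frames), function(i) {
      b <- split_boxes[[i]]
      boxes_json <- if (nrow(b) == 0L) "[]" else {
        entries <- sprintf(
          '{"x0":%s,"y0":%s,"x1":%s,"y1":%s,"score":%s}',
          num_full(b$x0), num_full(b$y0), num_full(b$x1), num_full(b$y1),
          num_full(b$score))
        paste0("[", paste(entries, collapse = ","), "]")
      }
      sprintf('{"video_id":%s,"case_id":%s,"modality":%s,"fps":%s,"frame":%d,"boxes":%s}',
              json_str(stream$video_id), json_str(stream$case_id),
              json_str(stream$modality), num_full(stream$fps), i - 1L,
              boxes_json)
    }, character(1))
    writeLines(lines, path)
  } else {
    rows <- lapply(seq_len(stream$n_frames), function(i) {
      b <- split_boxes[[i]]
      if (nrow(b) == 0L) {
        sprintf("%s,%s,%s,%s,%d,,,,,",
                stream$video_id, stream$case_id, stream$modality,
                num_full(stream$fps), i - 1L)
      } else {
        sprintf("%s,%s,%s,%s,%d,%s,%s,%s,%s,%s",
                stream$video_id, stream$case_id, stream$modality,
                num_full(stream$fps), i - 1L,
                num_full(b$x0), num_full(b$y0), num_full(b$x1),
                num_full(b$y1), num_full(b$score))
      }
    })
    writeLines(c("video_id,case_id,modality,fps,frame,x0,y0,x1,y1,score",
                 unlist(rows)), path)
  }
  invisible(path)
}

# shortest decimal string that round-trips the double exactly
num_full <- function(x) {
  vapply(x, function(v) {
    s <- format(v, digits = 15)
    if (as.numeric(s) != v) s <- sprintf("%.17g", v)
    s
  }, character(1))
}

json_str <- function(x) {
  sprintf('"%s"', gsub('"', '\\\\"', x))
}
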