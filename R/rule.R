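#' Parameters of the discovery-signal confirmation rule
#'
#' The deployed detection system does not alarm on a single positive frame.
#' When a frame crosses the score threshold it reviews the following
#' `review_window_s` seconds of video and emits a discovery signal only if
#' the review contains enough corroborating positive frames
#' (`min_votes`) and the most recent positive frame is no more than
#' `max_gap_s` before the end of the review. At the native 30 fps this is a
#' 0.5 s (15-frame) review requiring more than 3 positive frames with the
#' latest one at most 0.1 s (3 frames) back.
#'
#' Window and gap lengths in frames are `round(seconds * fps)` (half-up),
#' which yields 15 and 3 at 30 fps and generalizes to other frame rates.
#'
#' @param score_threshold Confidence cutoff for a frame to count as a cancer
#'   frame. The detector's deployed cutoff is not published; the default is a
#'   fixed, conventional 0.5.
#' @param review_window_s Length of the post-trigger review, seconds.
#' @param min_votes Minimum number of positive frames inside the review
#'   window ("more than 3 frames" = at least 4). The trigger frame itself is
#'   not counted.
#' @param max_gap_s Maximum allowed interval, in seconds, from the latest
#'   positive frame to the end of the review.
#' @param refractory_clear_frames After a signal, new triggers are suppressed
#'   until this many consecutive negative frames have elapsed, so one lesion
#'   encounter yields one alarm. `NULL` (default) means one review window's
#'   worth of frames.
#' @param gap_mode `"latest"` applies `max_gap_s` as a recency condition on
#'   the single latest positive frame (default); `"all_gaps"` additionally
#'   requires every interval between consecutive positive frames (starting
#'   from the trigger) to be at most `max_gap_s`.
#' @return An object of class `rule_config`.
#' @seealso [run_confirmation()], [min_latency()]
#' @export
rule_config <- function(score_threshold = 0.5, review_window_s = 0.5,
                        min_votes = 4L, max_gap_s = 0.1,
                        refractory_clear_frames = NULL,
                        gap_mode = c("latest", "all_gaps")) {
  gap_mode <- match.arg(gap_mode)
  stopifnot(review_window_s > 0, min_votes >= 1L, max_gap_s >= 0,
            score_threshold >= 0, score_threshold <= 1)
  if (!is.null(refractory_clear_frames)) {
    stopifnot(refractory_clear_frames >= 1L)
    refractory_clear_frames <- as.integer(refractory_clear_frames)
  }
  structure(list(score_threshold = score_threshold,
                 review_window_s = review_window_s,
                 min_votes = as.integer(min_votes),
                 max_gap_s = max_gap_s,
                 refractory_clear_frames = refractory_clear_frames,
                 gap_mode = gap_mode),
            class = "rule_config")
}

#' @export
print.rule_config <- function(x, ...) {
  cat(sprintf(paste0("<rule_config> threshold %.3g, review %g s, ",
                     ">= %d votes, max gap %g s, gap mode '%s'\n"),
              x$score_threshold, x$review_window_s, x$min_votes,
              x$max_gap_s, x$gap_mode))
  invisible(x)
}

# resolve the config's second-valued parameters to frame counts at a given
# frame rate; W < min_votes would make the rule unsatisfiable
rule_frames <- function(config, fps) {
  W <- round_half_up(config$review_window_s * fps)
  G <- round_half_up(config$max_gap_s * fps)
  R <- config$refractory_clear_frames %||% W
  if (W < config$min_votes) {
    stop(sprintf(paste0("review window of %d frames cannot hold the ",
                        "required %d votes"), W, config$min_votes),
         call. = FALSE)
  }
  list(W = as.integer(W), G = as.integer(G), R = as.integer(R))
}

round_half_up <- function(x) floor(x + 0.5)

#' Which frames of a stream count as positive?
#'
#' A frame is positive when at least one of its boxes scores at or above the
#' threshold — the condition under which the on-screen bounding rectangle is
#' drawn.
#'
#' @param stream A [video_stream()].
#' @param score_threshold Confidence cutoff in \[0, 1\].
#' @return Logical vector of length `n_frames`; element `k + 1` refers to
#'   0-based frame `k`.
#' @export
frame_is_positive <- function(stream, score_threshold) {
  pos <- logical(stream$n_frames)
  hit <- stream$boxes$frame[stream$boxes$score >= score_threshold]
  pos[hit + 1L] <- TRUE
  pos
}

#' Run the discovery-signal confirmation engine over a stream
#'
#' Streaming semantics: every positive frame `t0` encountered while the
#' engine is armed becomes a candidate trigger and opens a review of the `W`
#' following frames. At frame `t0 + W` a signal is emitted iff the review
#' window holds at least `min_votes` positive frames and the latest positive
#' frame (trigger included) is at most `G` frames before the window end. The
#' emitted signal's snapshot — the still image the system would insert on the
#' monitor as evidence — is that latest positive frame, with its
#' highest-scoring box. A failed candidate does not consume later ones: the
#' next positive frame strictly after `t0` is evaluated independently. After
#' a signal, triggers are suppressed until `refractory_clear_frames`
#' consecutive negative frames have elapsed. Reviews truncated by the end of
#' the video never emit.
#'
#' @param stream A [video_stream()].
#' @param config A [rule_config()].
#' @return A data frame of discovery signals in frame order with columns
#'   `video_id`, `trigger_frame`, `signal_frame`, `snapshot_frame`,
#'   `latency_s` (trigger-to-signal, seconds), and the snapshot box
#'   `snapshot_x0, snapshot_y0, snapshot_x1, snapshot_y1, snapshot_score`.
#' @seealso [brute_force_signals()] for the enumeration oracle with the same
#'   contract.
#' @examples
#' s <- video_stream("v", "c", "WLI", fps = 30, n_frames = 240,
#'                   boxes = data.frame(frame = 100:200, x0 = 10, y0 = 10,
#'                                      x1 = 50, y1 = 50, score = 0.9))
#' run_confirmation(s, rule_config())  # one signal at frame 115, 0.5 s
#' @export
run_confirmation <- function(stream, config = rule_config()) {
  fr <- rule_frames(config, stream$fps)
  W <- fr$W; G <- fr$G; R <- fr$R
  pos <- frame_is_positive(stream, config$score_threshold)
  n <- stream$n_frames
  all_gaps <- config$gap_mode == "all_gaps"

  state <- "armed"
  neg_run <- 0L
  cand <- integer(0)   # pending candidate triggers (0-based), ascending
  wpos <- integer(0)   # positive frames seen while armed (0-based)
  out <- list()

  for (t in seq_len(n)) {
    f <- t - 1L
    if (state == "refractory") {
      neg_run <- if (pos[t]) 0L else neg_run + 1L
      if (neg_run >= R) state <- "armed"
      next
    }
    if (pos[t]) {
      cand <- c(cand, f)
      wpos <- c(wpos, f)
    }
    if (length(cand) && f == cand[1L] + W) {
      t0 <- cand[1L]
      win <- wpos[wpos > t0 & wpos <= t0 + W]
      votes <- length(win)
      latest <- if (votes) max(win) else t0
      ok <- votes >= config$min_votes && (f - latest) <= G
      if (ok && all_gaps) ok <- all(diff(c(t0, win)) <= G)
      if (ok) {
        out[[length(out) + 1L]] <- make_signal(stream, t0, f, latest)
        state <- "refractory"
        neg_run <- 0L
        cand <- integer(0)
        wpos <- integer(0)
      } else {
        cand <- cand[-1L]
      }
    }
  }
  rbind_signals(out, stream$video_id)
}

#' Brute-force oracle for the confirmation rule
#'
#' Evaluates every positive frame as a candidate trigger by direct
#' enumeration over the positive-frame index set, applying the same
#' emission and refractory contract as [run_confirmation()] but without the
#' incremental frame-by-frame state machine. The two implementations must
#' produce identical signal lists on any input; this function exists so that
#' equivalence can be asserted.
#'
#' @inheritParams run_confirmation
#' @return As [run_confirmation()].
#' @export
brute_force_signals <- function(stream, config = rule_config()) {
  fr <- rule_frames(config, stream$fps)
  W <- fr$W; G <- fr$G; R <- fr$R
  pos <- frame_is_positive(stream, config$score_threshold)
  n <- stream$n_frames
  posf <- which(pos) - 1L
  out <- list()
  arm_from <- 0L
  for (t0 in posf) {
    if (t0 < arm_from) next
    s <- t0 + W
    if (s > n - 1L) break  # truncated review; later candidates even later
    win <- posf[posf > t0 & posf <= s]
    latest <- if (length(win)) max(win) else t0
    ok <- length(win) >= config$min_votes && (s - latest) <= G
    if (ok && config$gap_mode == "all_gaps") {
      ok <- all(diff(c(t0, win)) <= G)
    }
    if (ok) {
      out[[length(out) + 1L]] <- make_signal(stream, t0, s, latest)
      arm_from <- rearm_frame(pos, s, R)
      if (is.na(arm_from)) break
    }
  }
  rbind_signals(out, stream$video_id)
}

# first frame eligible as trigger after a signal at frame s: the frame
# following the first run of R consecutive negative frames strictly after s.
# NA when no such run exists before the end of the video.
rearm_frame <- function(pos, s, R) {
  n <- length(pos)
  if (s + 2L > n) return(NA_integer_)
  neg <- !pos[(s + 2L):n]          # frames s+1 .. n-1
  r <- rle(neg)
  ends <- cumsum(r$lengths)
  k <- which(r$values & r$lengths >= R)
  if (!length(k)) return(NA_integer_)
  run_start <- ends[k[1L]] - r$lengths[k[1L]] + 1L  # position within neg
  (s + 1L + run_start - 1L) + R
}

make_signal <- function(stream, trigger, signal, snapshot) {
  b <- stream$boxes[stream$boxes$frame == snapshot, , drop = FALSE]
  best <- b[which.max(b$score), , drop = FALSE]
  data.frame(trigger_frame = trigger, signal_frame = signal,
             snapshot_frame = snapshot,
             latency_s = (signal - trigger) / stream$fps,
             snapshot_x0 = best$x0, snapshot_y0 = best$y0,
             snapshot_x1 = best$x1, snapshot_y1 = best$y1,
             snapshot_score = best$score)
}

rbind_signals <- function(out, video_id) {
  if (!length(out)) {
    return(data.frame(video_id = character(0), trigger_frame = integer(0),
                      signal_frame = integer(0), snapshot_frame = integer(0),
                      latency_s = numeric(0), snapshot_x0 = numeric(0),
                      snapshot_y0 = numeric(0), snapshot_x1 = numeric(0),
                      snapshot_y1 = numeric(0), snapshot_score = numeric(0)))
  }
  d <- do.call(rbind, out)
  cbind(data.frame(video_id = rep(video_id, nrow(d))), d)
}

#' Minimum achievable trigger-to-signal latency
#'
#' The earliest a signal can follow its trigger is one full review window: a
#' lesion detected in every frame triggers immediately on entry and the
#' signal fires when the review completes. In seconds this is
#' `round(review_window_s * fps) / fps` — 0.5 s under the default rule at
#' 30 fps.
#'
#' @param config A [rule_config()].
#' @param fps Frames per second.
#' @return Latency floor in seconds.
#' @export
min_latency <- function(config = rule_config(), fps = 30) {
  rule_frames(config, fps)$W / fps
}

#' Write discovery signals as JSON-lines
#'
#' One object per signal:
#' `{"video_id","trigger_frame","signal_frame","snapshot_frame","latency_s","snapshot_box"}`.
#'
#' @param signals Data frame from [run_confirmation()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_signals <- function(signals, path) {
  lines <- vapply(seq_len(nrow(signals)), function(i) {
    s <- signals[i, ]
    sprintf(paste0('{"video_id":%s,"trigger_frame":%d,"signal_frame":%d,',
                   '"snapshot_frame":%d,"latency_s":%s,"snapshot_box":',
                   '{"x0":%s,"y0":%s,"x1":%s,"y1":%s,"score":%s}}'),
            json_str(s$video_id), s$trigger_frame, s$signal_frame,
            s$snapshot_frame, num_full(s$latency_s),
            num_full(s$snapshot_x0), num_full(s$snapshot_y0),
            num_full(s$snapshot_x1), num_full(s$snapshot_y1),
            num_full(s$snapshot_score))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read discovery signals from JSON-lines
#'
#' @param path Path written by [write_signals()].
#' @return Data frame in the layout of [run_confirmation()].
#' @export
read_signals <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(rbind_signals(list(), character(0)))
  rows <- lapply(lines, function(ln) {
    r <- jsonlite::fromJSON(ln)
    data.frame(video_id = r$video_id, trigger_frame = r$trigger_frame,
               signal_frame = r$signal_frame,
               snapshot_frame = r$snapshot_frame, latency_s = r$latency_s,
               snapshot_x0 = r$snapshot_box$x0, snapshot_y0 = r$snapshot_box$y0,
               snapshot_x1 = r$snapshot_box$x1, snapshot_y1 = r$snapshot_box$y1,
               snapshot_score = r$snapshot_box$score)
  })
  do.call(rbind, rows)
}
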