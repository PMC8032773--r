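# test fixtures are generated in code; no files on disk

# stream whose positive frames (score 0.9) are exactly `pos`; other frames
# empty unless subthreshold boxes are requested
stream_with_positives <- function(pos, n = 60L, fps = 30, video_id = "v1",
                                  modality = "WLI", score = 0.9) {
  boxes <- if (length(pos)) {
    data.frame(frame = as.integer(pos), x0 = 10, y0 = 20, x1 = 110, y1 = 140,
               score = score)
  }
  video_stream(video_id, "case1", modality, fps = fps, n_frames = n,
               boxes = boxes)
}

# random stream: each frame positive with probability `density`; positive
# frames get 1-2 boxes with scores straddling the 0.5 threshold
random_stream <- function(n = 600L, density = 0.5, fps = 30,
                          video_id = "vr") {
  pos <- which(stats::runif(n) < density) - 1L
  boxes <- NULL
  if (length(pos)) {
    extra <- pos[stats::runif(length(pos)) < 0.3]  # second, subthreshold box
    boxes <- rbind(
      data.frame(frame = pos,
                 x0 = stats::runif(length(pos), 0, 600),
                 y0 = stats::runif(length(pos), 0, 600),
                 x1 = NA, y1 = NA,
                 score = stats::runif(length(pos), 0.5, 1)),
      if (length(extra)) {
        data.frame(frame = extra,
                   x0 = stats::runif(length(extra), 0, 600),
                   y0 = stats::runif(length(extra), 0, 600),
                   x1 = NA, y1 = NA,
                   score = stats::runif(length(extra), 0, 0.49))
      })
    boxes$x1 <- boxes$x0 + stats::runif(nrow(boxes), 1, 200)
    boxes$y1 <- boxes$y0 + stats::runif(nrow(boxes), 1, 200)
  }
  video_stream(video_id, "caser", "WLI", fps = fps, n_frames = n,
               boxes = boxes)
}

# random rule configuration drawn from a plausible range
random_rule <- function() {
  rule_config(score_threshold = 0.5,
              review_window_s = sample(c(0.3, 0.5, 1), 1),
              min_votes = sample(2:6, 1),
              max_gap_s = sample(c(0.1, 0.2), 1),
              refractory_clear_frames = sample(c(NA, 5L, 15L), 1) |>
                (\(x) if (is.na(x)) NULL else x)(),
              gap_mode = sample(c("latest", "all_gaps"), 1))
}

# minimal one-lesion ground truth
gt_one_lesion <- function(video_id = "v1", first = 300L, last = 420L,
                          regions = NULL, fp_frames = NULL) {
  video_ground_truth(
    video_id, TRUE,
    list(lesion_annotation("L1", matrix(c(first, last), ncol = 2),
                           regions = regions, size_mm = 17,
                           wall_position = "left")),
    fp_frames = fp_frames)
}

signal_row <- function(video_id = "v1", snapshot_frame, signal_frame = NULL,
                       trigger_frame = NULL,
                       box = c(10, 20, 110, 140), score = 0.9) {
  if (is.null(signal_frame)) signal_frame <- snapshot_frame + 1L
  if (is.null(trigger_frame)) trigger_frame <- signal_frame - 15L
  data.frame(video_id = video_id, trigger_frame = trigger_frame,
             signal_frame = signal_frame, snapshot_frame = snapshot_frame,
             latency_s = (signal_frame - trigger_frame) / 30,
             snapshot_x0 = box[1], snapshot_y0 = box[2],
             snapshot_x1 = box[3], snapshot_y1 = box[4],
             snapshot_score = score)
}

no_signals <- function(video_id = character(0)) {
  escadet::run_confirmation(stream_with_positives(integer(0), n = 20L))[0, ]
}
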