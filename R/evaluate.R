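#' Round-half-up integer percent
#'
#' The printed convention throughout the diagnostic tables: `100 * num / den`
#' rounded half-up to an integer (so 54.55 prints as 55 and 12.5 as 13).
#'
#' @param numerator,denominator Non-negative counts; `denominator` must be
#'   positive.
#' @return Integer percent (vectorized).
#' @export
round_percent <- function(numerator, denominator) {
  if (any(denominator <= 0)) {
    stop("round_percent: undefined for zero denominator", call. = FALSE)
  }
  as.integer(floor(100 * numerator / denominator + 0.5))
}

#' Classify discovery signals against ground truth
#'
#' A signal is a true positive when its snapshot — the inserted still image —
#' contains any part of a lesion. In `"interval"` mode this is judged
#' temporally: the snapshot frame lies inside a lesion's visibility interval.
#' In `"box_overlap"` mode the snapshot box must additionally intersect the
#' annotated lesion rectangle at that frame ("any part" means any nonzero
#' overlap; no IoU threshold). When box mode is requested but no region is
#' annotated at the snapshot frame, the classification falls back to interval
#' mode for that signal with a warning.
#'
#' False positives are attributed to a cause category when the ground truth
#' tags the snapshot frame as a known false-positive source; untagged false
#' positives get category `"other"`.
#'
#' @param signals Data frame from [run_confirmation()], all rows belonging to
#'   `gt`'s video.
#' @param gt A [video_ground_truth()].
#' @param mode `"interval"` or `"box_overlap"`.
#' @return `signals` with added columns `verdict` (`"TP"`/`"FP"`),
#'   `matched_lesion_id`, `fp_category`.
#' @export
classify_signals <- function(signals, gt, mode = c("interval", "box_overlap")) {
  mode <- match.arg(mode)
  n <- nrow(signals)
  verdict <- character(n)
  matched <- rep(NA_character_, n)
  fp_cat <- rep(NA_character_, n)
  if (n && any(signals$video_id != gt$video_id)) {
    stop("signals do not all belong to ground-truth video ", gt$video_id,
         call. = FALSE)
  }
  for (i in seq_len(n)) {
    f <- signals$snapshot_frame[i]
    hit <- NA_character_
    for (l in gt$lesions) {
      if (!frame_in_lesion(l, f)) next
      if (mode == "box_overlap") {
        reg <- lesion_region_at(l, f)
        if (is.null(reg)) {
          warning(sprintf(paste0("video %s: no region annotated at frame %d; ",
                                 "falling back to interval matching"),
                          gt$video_id, f), call. = FALSE)
          hit <- l$lesion_id
          break
        }
        box <- c(signals$snapshot_x0[i], signals$snapshot_y0[i],
                 signals$snapshot_x1[i], signals$snapshot_y1[i])
        if (rects_overlap(box, reg)) {
          hit <- l$lesion_id
          break
        }
      } else {
        hit <- l$lesion_id
        break
      }
    }
    if (!is.na(hit)) {
      verdict[i] <- "TP"
      matched[i] <- hit
    } else {
      verdict[i] <- "FP"
      fp_cat[i] <- fp_category_at(gt, f)
    }
  }
  signals$verdict <- verdict
  signals$matched_lesion_id <- matched
  signals$fp_category <- fp_cat
  signals
}

lesion_region_at <- function(lesion, f) {
  if (is.null(lesion$regions)) return(NULL)
  r <- lesion$regions[lesion$regions$frame == f, , drop = FALSE]
  if (nrow(r) == 0L) return(NULL)
  c(r$x0[1L], r$y0[1L], r$x1[1L], r$y1[1L])
}

# half-open rectangles [x0,x1) x [y0,y1): nonzero-area intersection test
rects_overlap <- function(a, b) {
  a[1L] < b[3L] && b[1L] < a[3L] && a[2L] < b[4L] && b[2L] < a[4L]
}

fp_category_at <- function(gt, f) {
  if (is.null(gt$fp_frames)) return("other")
  m <- gt$fp_frames$category[gt$fp_frames$frame == f]
  if (length(m)) m[1L] else "other"
}

#' Summarize one video's classified signals into a diagnostic outcome
#'
#' The per-video call used by all four diagnostic metrics: a video is
#' AI-positive when at least one signal of any verdict fired, and correctly
#' detected when at least one true-positive signal fired. A cancer video
#' whose only signals are false positives is therefore AI-positive but not
#' correctly detected — it enters the PPV denominator without entering its
#' numerator. Time to detection is measured from the matched lesion's first
#' visible frame to the signal frame of the earliest true positive.
#'
#' @param signals Classified signals from [classify_signals()].
#' @param gt A [video_ground_truth()].
#' @param fps Frames per second used to express the detection time in
#'   seconds.
#' @return One-row data frame: `video_id`, `cancer_present`, `ai_positive`,
#'   `correctly_detected`, `first_tp_latency_s`.
#' @export
video_outcome <- function(signals, gt, fps = 30) {
  tp <- signals[signals$verdict == "TP", , drop = FALSE]
  lat <- NA_real_
  if (nrow(tp)) {
    first <- tp[which.min(tp$signal_frame), ]
    lesion <- Find(function(l) l$lesion_id == first$matched_lesion_id,
                   gt$lesions)
    lat <- (first$signal_frame - first_visible_frame(lesion)) / fps
  }
  data.frame(video_id = gt$video_id,
             cancer_present = gt$cancer_present,
             ai_positive = nrow(signals) > 0L,
             correctly_detected = nrow(tp) > 0L,
             first_tp_latency_s = lat)
}

#' Per-video diagnostic accuracy for one modality
#'
#' All four metrics are video-counting ratios: sensitivity = correctly
#' detected cancer videos / cancer videos; specificity = alarm-free
#' non-cancer videos / non-cancer videos; PPV = correctly detected cancer
#' videos / videos with any alarm; NPV = alarm-free non-cancer videos /
#' videos with no alarm. Ratios with a zero denominator are reported as
#' undefined (`NA`), never as 0.
#'
#' @param outcomes Data frame of [video_outcome()] rows (one per video).
#' @param modality Label stored on the result (`"WLI"`, `"NBI"`,
#'   `"WLI+NBI"`, ...).
#' @return An object of class `modality_metrics`: per metric, numerator,
#'   denominator and half-up rounded integer percent.
#' @export
modality_metrics <- function(outcomes, modality = "") {
  ratio <- function(num, den) {
    list(numerator = num, denominator = den,
         percent = if (den > 0) round_percent(num, den) else NA_integer_)
  }
  cancer <- outcomes$cancer_present
  pos <- outcomes$ai_positive
  det <- outcomes$correctly_detected
  structure(list(
    modality = modality,
    n_videos = nrow(outcomes),
    sensitivity = ratio(sum(det & cancer), sum(cancer)),
    specificity = ratio(sum(!pos & !cancer), sum(!cancer)),
    ppv = ratio(sum(det & cancer), sum(pos)),
    npv = ratio(sum(!pos & !cancer), sum(!pos))),
    class = "modality_metrics")
}

#' @export
print.modality_metrics <- function(x, ...) {
  fmt <- function(r) {
    if (is.na(r$percent)) return("undef")
    sprintf("%d%% (%d/%d)", r$percent, r$numerator, r$denominator)
  }
  cat(sprintf("<modality_metrics> %s (%d videos)\n", x$modality, x$n_videos))
  cat(sprintf("  sensitivity %s  specificity %s\n", fmt(x$sensitivity),
              fmt(x$specificity)))
  cat(sprintf("  PPV %s  NPV %s\n", fmt(x$ppv), fmt(x$npv)))
  invisible(x)
}

#' Combine paired modality outcomes into per-case outcomes
#'
#' The comprehensive analysis: a case counts as detected when the cancer was
#' detected in either the white-light or the narrow-band video, and as
#' AI-positive when either video raised any alarm. Detection time is the
#' earlier of the two modalities' first true positives.
#'
#' @param cases List of [study_case()] objects (or a data frame with columns
#'   `case_id`, `wli_video_id`, `nbi_video_id`, `cancer_present`).
#' @param outcomes Data frame of per-video [video_outcome()] rows covering
#'   both videos of every case.
#' @return Data frame of case-level outcomes in the [video_outcome()] layout
#'   (with `video_id` = case id and an extra `case_id` column).
#' @export
comprehensive_outcomes <- function(cases, outcomes) {
  if (is.data.frame(cases)) {
    cases <- lapply(seq_len(nrow(cases)), function(i) {
      study_case(cases$case_id[i], cases$wli_video_id[i],
                 cases$nbi_video_id[i], cases$cancer_present[i])
    })
  }
  rows <- lapply(cases, function(cs) {
    w <- outcomes[outcomes$video_id == cs$wli_video_id, , drop = FALSE]
    n <- outcomes[outcomes$video_id == cs$nbi_video_id, , drop = FALSE]
    if (nrow(w) != 1L || nrow(n) != 1L) {
      stop(sprintf("case %s: missing outcome for %s", cs$case_id,
                   if (nrow(w) != 1L) cs$wli_video_id else cs$nbi_video_id),
           call. = FALSE)
    }
    lat <- suppressWarnings(min(c(w$first_tp_latency_s, n$first_tp_latency_s),
                                na.rm = TRUE))
    data.frame(video_id = cs$case_id, case_id = cs$case_id,
               cancer_present = cs$cancer_present,
               ai_positive = w$ai_positive || n$ai_positive,
               correctly_detected = w$correctly_detected || n$correctly_detected,
               first_tp_latency_s = if (is.finite(lat)) lat else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Median and range of time to detection
#'
#' Summarizes the first true-positive detection times over the correctly
#' detected cancer videos (or cases). The median uses the midpoint
#' convention for even counts.
#'
#' @param outcomes Data frame with a `first_tp_latency_s` column.
#' @return List with `n`, `median_s`, `min_s`, `max_s`; all `NA` when
#'   nothing was detected.
#' @export
time_to_detection_summary <- function(outcomes) {
  lat <- outcomes$first_tp_latency_s
  lat <- lat[!is.na(lat)]
  if (!length(lat)) {
    return(list(n = 0L, median_s = NA_real_, min_s = NA_real_,
                max_s = NA_real_))
  }
  list(n = length(lat), median_s = stats::median(lat),
       min_s = min(lat), max_s = max(lat))
}

#' Tabulate causes of false positives or missed lesions
#'
#' Counts events per category and reports half-up rounded percentages of the
#' total (which therefore may not sum to exactly 100). False-positive cause
#' tabulation operates on signal events, not videos — one video can
#' contribute several categorized false alarms.
#'
#' @param categories Character vector, one entry per categorized event
#'   (false-positive signal or missed lesion).
#' @param levels Optional category order; defaults to order of first
#'   appearance.
#' @return An object of class `cause_tabulation`: data frame `category`,
#'   `count`, `percent`, with the total as attribute `total`.
#' @export
tabulate_causes <- function(categories, levels = unique(categories)) {
  counts <- table(factor(categories, levels = levels))
  total <- sum(counts)
  out <- data.frame(category = names(counts),
                    count = as.integer(counts),
                    percent = round_percent(as.integer(counts), total))
  attr(out, "total") <- as.integer(total)
  class(out) <- c("cause_tabulation", "data.frame")
  out
}

#' @export
print.cause_tabulation <- function(x, ...) {
  cat(sprintf("<cause_tabulation> n = %d\n", attr(x, "total")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-24s %d%% (%d)\n", x$category[i], x$percent[i],
                x$count[i]))
  }
  invisible(x)
}

#' Score an endoscopist's button-press responses for one video
#'
#' A cancer video is answered correctly iff at least one button press occurs
#' while a lesion is on the monitor (inside a visibility interval); presses
#' outside every interval are false alarms. The scoring is strict: noticing
#' the lesion only after it has left the monitor counts as incorrect. For a
#' non-cancer video only the false-alarm count is recorded.
#'
#' @param response List or one-row data frame with `reader_id`, `video_id`,
#'   `assisted`, and `press_frames` (integer vector of 0-based frames).
#' @param gt The [video_ground_truth()] of the same video.
#' @return One-row data frame: `reader_id`, `video_id`, `assisted`,
#'   `cancer_present`, `correct` (`NA` for non-cancer videos),
#'   `false_alarms`.
#' @export
score_reader <- function(response, gt) {
  presses <- as.integer(unlist(response$press_frames))
  in_lesion <- if (length(presses) && length(gt$lesions)) {
    vapply(presses, function(f) {
      any(vapply(gt$lesions, frame_in_lesion, logical(1), f))
    }, logical(1))
  } else {
    rep(FALSE, length(presses))
  }
  data.frame(reader_id = as.character(response$reader_id),
             video_id = gt$video_id,
             assisted = isTRUE(response$assisted),
             cancer_present = gt$cancer_present,
             correct = if (gt$cancer_present) any(in_lesion) else NA,
             false_alarms = sum(!in_lesion))
}

#' Write per-video outcomes as CSV
#' @param outcomes Data frame of outcomes.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_outcomes_csv <- function(outcomes, path) {
  utils::write.csv(outcomes, path, row.names = FALSE, na = "")
  invisible(path)
}

metrics_as_list <- function(m) {
  list(modality = m$modality, n_videos = m$n_videos,
       sensitivity = m$sensitivity, specificity = m$specificity,
       ppv = m$ppv, npv = m$npv)
}
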