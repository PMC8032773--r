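#' Configuration of the synthetic detection-stream simulator
#'
#' The simulator stands in for the trained detector network: it emits the
#' per-frame scored boxes such a detector would produce while an endoscope
#' traverses the esophagus, so that the confirmation rule and the evaluation
#' layer can be exercised end to end. The defaults emulate the high-speed
#' screening condition: a 25 cm esophagus traversed at 2 cm/s without
#' stopping, recorded at 30 fps, with one superficial lesion per cancer case
#' whose diameter is drawn log-uniformly between 5 and 60 mm (median
#' ~17 mm). While a lesion is in the field of view each frame independently
#' yields a supra-threshold detection with probability `p_detect_*`;
#' peristalsis episodes transiently multiply that probability down.
#' False-positive detections arrive as per-category Poisson bursts (luminal
#' shadow, mucosal inflammation, post-endoscopic-resection scar, and the
#' esophagogastric junction, the latter only near the distal end of the
#' traversal).
#'
#' Setting `dwell_s` switches to the slow-observation condition in which the
#' endoscopist holds the lesion in view for the given 5-15 s range instead of
#' passing it at traversal speed.
#'
#' @param seed Root seed; per-case seeds are derived from it so any case can
#'   be regenerated independently.
#' @param fps Frames per second.
#' @param traversal_speed_cm_s Endoscope speed, cm/s.
#' @param esophagus_length_cm Length of the traversed esophagus, cm.
#' @param n_cancer_cases,n_control_cases Numbers of cancer and cancer-free
#'   cases (each case yields one WLI and one NBI video).
#' @param lesion_size_range_mm Support of the log-uniform lesion diameter
#'   distribution, mm.
#' @param field_margin_cm Extra visibility on either side of the lesion: the
#'   lesion is in the field of view while the scope tip is within this
#'   distance of it.
#' @param p_detect_wli,p_detect_nbi Per-frame probability of a
#'   supra-threshold detection while the lesion is visible, per modality.
#'   The real detector's frame-level hit rates are unpublished; these are
#'   calibration knobs, not estimates.
#' @param detectability_sd Standard deviation of a per-case latent
#'   detectability factor (logit scale) shared by the two modalities, so that
#'   the same lesion drives correlated success in both videos.
#' @param peristalsis_rate_per_s Poisson rate of peristalsis episodes.
#' @param peristalsis_len_s Duration of one episode, seconds.
#' @param peristalsis_detect_multiplier Factor applied to the detection
#'   probability during an episode (the lesion appears bent or shrunk on the
#'   contracting wall).
#' @param fp_rates_per_min Named per-category false-positive burst rates per
#'   minute (`shadow`, `inflammation`, `post_ER_scar`, `EGJ`).
#' @param fp_burst_len_frames Mean burst length in frames (geometric).
#' @param dwell_s Length-2 range of lesion observation time, seconds, for
#'   the slow-observation condition; `NULL` (default) keeps constant-speed
#'   visibility.
#' @param frame_width,frame_height Frame size in pixels, used for box
#'   geometry.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, fps = 30,
                              traversal_speed_cm_s = 2,
                              esophagus_length_cm = 25,
                              n_cancer_cases = 20L, n_control_cases = 20L,
                              lesion_size_range_mm = c(5, 60),
                              field_margin_cm = 2,
                              p_detect_wli = 0.4, p_detect_nbi = 0.3,
                              detectability_sd = 0.5,
                              peristalsis_rate_per_s = 0.1,
                              peristalsis_len_s = 1,
                              peristalsis_detect_multiplier = 0.3,
                              fp_rates_per_min = c(shadow = 3,
                                                   inflammation = 2.4,
                                                   post_ER_scar = 0.7,
                                                   EGJ = 1.3),
                              fp_burst_len_frames = 8,
                              dwell_s = NULL,
                              frame_width = 1280, frame_height = 1024) {
  stopifnot(fps > 0, traversal_speed_cm_s > 0, esophagus_length_cm > 0,
            n_cancer_cases >= 0, n_control_cases >= 0,
            p_detect_wli >= 0, p_detect_wli <= 1,
            p_detect_nbi >= 0, p_detect_nbi <= 1,
            all(fp_rates_per_min >= 0), fp_burst_len_frames >= 1,
            lesion_size_range_mm[1L] > 0,
            lesion_size_range_mm[2L] >= lesion_size_range_mm[1L])
  if (!is.null(dwell_s)) stopifnot(length(dwell_s) == 2L, all(dwell_s > 0))
  structure(as.list(environment()), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0("<simulation_config> seed %d: %d cancer + %d control ",
                     "cases, %g cm at %g cm/s, %g fps\n"),
              x$seed, x$n_cancer_cases, x$n_control_cases,
              x$esophagus_length_cm, x$traversal_speed_cm_s, x$fps))
  invisible(x)
}

sim_n_frames <- function(config) {
  as.integer(round(config$esophagus_length_cm / config$traversal_speed_cm_s *
                     config$fps))
}

#' Generate one study case: paired WLI/NBI streams plus ground truth
#'
#' The two modality videos share the physical situation — lesion placement,
#' size, visibility window and peristalsis episodes — but draw detection
#' noise and false-positive bursts independently, coupled only through a
#' latent per-case detectability factor.
#'
#' @param config A [simulation_config()].
#' @param case_seed Integer seed for this case (reproducible in isolation).
#' @param cancer Logical: does the case carry a lesion?
#' @param case_id Identifier.
#' @return List with `case` ([study_case()]), `streams` (named list of two
#'   [video_stream()]s) and `ground_truth` (named list of two
#'   [video_ground_truth()]s).
#' @export
generate_case <- function(config, case_seed, cancer = TRUE,
                          case_id = sprintf("case%05d", case_seed %% 100000L)) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(case_seed)
  n <- sim_n_frames(config)
  fps <- config$fps

  lesion <- NULL
  if (cancer) {
    r <- config$lesion_size_range_mm
    size_mm <- exp(stats::runif(1, log(r[1L]), log(r[2L])))
    wall <- sample(c("anterior", "posterior", "left", "right"), 1L,
                   prob = c(8, 4, 8, 2))
    half_cm <- size_mm / 20 + config$field_margin_cm
    vis_s <- if (is.null(config$dwell_s)) {
      2 * half_cm / config$traversal_speed_cm_s
    } else {
      stats::runif(1, config$dwell_s[1L], config$dwell_s[2L])
    }
    vis_frames <- round(vis_s * fps)
    if (vis_frames < 1) {
      stop(paste("lesion visibility shorter than one frame;",
                 "increase field_margin_cm or lower traversal speed"),
           call. = FALSE)
    }
    vis_frames <- min(vis_frames, n)
    first <- sample.int(n - vis_frames + 1L, 1L) - 1L
    lesion <- list(size_mm = size_mm, wall = wall,
                   first = first, last = first + vis_frames - 1L,
                   rect = lesion_rect(size_mm, wall, config))
  }

  # physical nuisance shared by both videos
  z <- stats::rnorm(1, 0, config$detectability_sd)
  peri <- peristalsis_frames(config, n)

  streams <- list()
  gts <- list()
  for (mod in c("WLI", "NBI")) {
    vid <- paste0(case_id, "-", mod)
    p0 <- if (mod == "WLI") config$p_detect_wli else config$p_detect_nbi
    p_eff <- if (p0 <= 0) 0 else if (p0 >= 1) 1 else
      stats::plogis(stats::qlogis(p0) + z)
    boxes <- list()
    if (cancer && p_eff > 0) {
      vis <- lesion$first:lesion$last
      p_frame <- rep(p_eff, length(vis))
      p_frame[vis %in% peri] <- p_frame[vis %in% peri] *
        config$peristalsis_detect_multiplier
      hit <- vis[stats::runif(length(vis)) < p_frame]
      if (length(hit)) {
        boxes[[length(boxes) + 1L]] <- jitter_boxes(lesion$rect, hit, config,
                                                    score_lo = 0.55,
                                                    score_hi = 0.95)
      }
    }
    fp <- fp_bursts(config, n)
    if (nrow(fp)) {
      for (cat in unique(fp$category)) {
        fr <- fp$frame[fp$category == cat]
        boxes[[length(boxes) + 1L]] <- jitter_boxes(fp_rect(cat, config), fr,
                                                    config, score_lo = 0.5,
                                                    score_hi = 0.9)
      }
    }
    boxes <- if (length(boxes)) do.call(rbind, boxes) else NULL
    streams[[mod]] <- video_stream(vid, case_id, mod, fps, n, boxes)
    ann <- if (cancer) {
      reg <- data.frame(frame = lesion$first:lesion$last,
                        x0 = lesion$rect[1L], y0 = lesion$rect[2L],
                        x1 = lesion$rect[3L], y1 = lesion$rect[4L])
      list(lesion_annotation(paste0(case_id, "-L1"),
                             matrix(c(lesion$first, lesion$last), ncol = 2L),
                             regions = reg, size_mm = lesion$size_mm,
                             wall_position = lesion$wall))
    } else {
      list()
    }
    gts[[vid]] <- video_ground_truth(vid, cancer, ann,
                                     if (nrow(fp)) fp else NULL)
  }
  list(case = study_case(case_id, paste0(case_id, "-WLI"),
                         paste0(case_id, "-NBI"), cancer),
       streams = streams, ground_truth = gts)
}

# lesion pixel footprint from diameter and wall position; walls map to frame
# quadrants (anterior top, posterior bottom, left/right sides)
lesion_rect <- function(size_mm, wall, config) {
  px <- min(0.45 * min(config$frame_width, config$frame_height), size_mm * 9)
  cx <- switch(wall, left = 0.3, right = 0.7, 0.5) * config$frame_width
  cy <- switch(wall, anterior = 0.3, posterior = 0.7, 0.5) * config$frame_height
  clip_rect(c(cx - px / 2, cy - px / 2, cx + px / 2, cy + px / 2), config)
}

fp_rect <- function(category, config) {
  w <- config$frame_width; h <- config$frame_height
  base <- switch(category,
                 shadow = c(0.40, 0.40, 0.60, 0.60),      # dark lumen center
                 EGJ = c(0.30, 0.55, 0.70, 0.90),          # distal mucosa
                 post_ER_scar = c(0.15, 0.15, 0.40, 0.40),
                 c(0.55, 0.20, 0.85, 0.50))                # inflammation/other
  c(base[1L] * w, base[2L] * h, base[3L] * w, base[4L] * h)
}

jitter_boxes <- function(rect, frames, config, score_lo, score_hi) {
  k <- length(frames)
  jw <- (rect[3L] - rect[1L]) * 0.1
  jh <- (rect[4L] - rect[2L]) * 0.1
  dx <- stats::runif(k, -jw, jw); dy <- stats::runif(k, -jh, jh)
  out <- data.frame(frame = frames,
                    x0 = rect[1L] + dx, y0 = rect[2L] + dy,
                    x1 = rect[3L] + dx, y1 = rect[4L] + dy,
                    score = stats::runif(k, score_lo, score_hi))
  out[c("x0", "x1")] <- pmax(pmin(out[c("x0", "x1")], config$frame_width), 0)
  out[c("y0", "y1")] <- pmax(pmin(out[c("y0", "y1")], config$frame_height), 0)
  out
}

clip_rect <- function(r, config) {
  c(max(r[1L], 0), max(r[2L], 0),
    min(r[3L], config$frame_width), min(r[4L], config$frame_height))
}

# 0-based frames covered by peristalsis episodes (Poisson arrivals)
peristalsis_frames <- function(config, n) {
  dur_s <- n / config$fps
  k <- stats::rpois(1, config$peristalsis_rate_per_s * dur_s)
  if (k == 0L) return(integer(0))
  len <- max(1L, round(config$peristalsis_len_s * config$fps))
  starts <- sample.int(n, k, replace = TRUE) - 1L
  unique(unlist(lapply(starts, function(s) s:min(s + len - 1L, n - 1L))))
}

# categorized false-positive burst frames; EGJ bursts only in the distal 10%
fp_bursts <- function(config, n) {
  dur_min <- n / config$fps / 60
  rows <- list()
  for (cat in names(config$fp_rates_per_min)) {
    k <- stats::rpois(1, config$fp_rates_per_min[[cat]] * dur_min)
    if (k == 0L) next
    lo <- if (cat == "EGJ") floor(0.9 * n) else 0L
    starts <- lo + sample.int(n - lo, k, replace = TRUE) - 1L
    lens <- stats::rgeom(k, 1 / config$fp_burst_len_frames) + 1L
    fr <- unlist(mapply(function(s, l) s:min(s + l - 1L, n - 1L),
                        starts, lens, SIMPLIFY = FALSE))
    rows[[length(rows) + 1L]] <- data.frame(frame = fr, category = cat)
  }
  if (!length(rows)) {
    return(data.frame(frame = integer(0), category = character(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out$frame), , drop = FALSE]
  out[order(out$frame), , drop = FALSE]
}

#' Generate a full synthetic study
#'
#' Draws per-case seeds from the root seed and generates
#' `n_cancer_cases + n_control_cases` paired cases. The manifest records the
#' per-case seeds so that any case — or the whole study — can be regenerated
#' bit-identically.
#'
#' @param config A [simulation_config()].
#' @return List with `config`, `cases` (data frame), `streams` (named list
#'   of [video_stream()]s), `ground_truth` (named list), and `manifest`
#'   (config echo plus per-case seeds).
#' @export
generate_study <- function(config) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)
  n_cases <- config$n_cancer_cases + config$n_control_cases
  case_seeds <- sample.int(.Machine$integer.max - 1L, n_cases)
  cancer <- rep(c(TRUE, FALSE),
                c(config$n_cancer_cases, config$n_control_cases))
  streams <- list(); gts <- list(); case_rows <- list()
  for (i in seq_len(n_cases)) {
    cid <- sprintf("C%03d", i)
    g <- generate_case(config, case_seeds[i], cancer = cancer[i],
                       case_id = cid)
    streams[[g$case$wli_video_id]] <- g$streams$WLI
    streams[[g$case$nbi_video_id]] <- g$streams$NBI
    gts <- c(gts, g$ground_truth)
    case_rows[[i]] <- data.frame(case_id = cid,
                                 wli_video_id = g$case$wli_video_id,
                                 nbi_video_id = g$case$nbi_video_id,
                                 cancer_present = cancer[i],
                                 case_seed = case_seeds[i])
  }
  cases <- do.call(rbind, case_rows)
  manifest <- list(seed = config$seed,
                   n_cancer_cases = config$n_cancer_cases,
                   n_control_cases = config$n_control_cases,
                   fps = config$fps, n_frames = sim_n_frames(config),
                   case_seeds = stats::setNames(as.list(case_seeds),
                                                cases$case_id))
  list(config = config, cases = cases, streams = streams,
       ground_truth = gts, manifest = manifest)
}

#' Simulate a reader panel with and without real-time assistance
#'
#' Emulates the crossover reader study: each endoscopist views every video
#' twice, once with and once without on-screen assistance (half the panel
#' starts assisted). For each cancer video the reader presses the button
#' inside the lesion's visibility window with probability equal to their
#' sensitivity (a per-reader draw from `base_sensitivity_range`, plus
#' `assist_effect` when assisted, clipped to \[0, 1\]); false alarms arrive
#' as Poisson events over the video.
#'
#' @param study Output of [generate_study()].
#' @param n_readers Number of readers.
#' @param base_sensitivity_range Range of per-reader unassisted per-video
#'   sensitivity.
#' @param assist_effect Additive sensitivity gain under assistance.
#' @param fa_rate_per_min False alarms per minute of video.
#' @param seed Seed for the panel.
#' @return Data frame with one row per reader x video x condition:
#'   `reader_id`, `video_id`, `assisted`, `starts_assisted`, and a
#'   `press_frames` list column of 0-based button-press frames.
#' @export
generate_reader_panel <- function(study, n_readers = 18L,
                                  base_sensitivity_range = c(0.15, 0.6),
                                  assist_effect = 0.1,
                                  fa_rate_per_min = 0.2, seed = 1L) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  vids <- names(study$ground_truth)
  n_frames <- vapply(vids, function(v) study$streams[[v]]$n_frames, integer(1))
  fps <- study$config$fps
  rows <- list()
  for (r in seq_len(n_readers)) {
    base <- stats::runif(1, base_sensitivity_range[1L],
                         base_sensitivity_range[2L])
    starts_assisted <- r <= n_readers / 2
    for (assisted in c(FALSE, TRUE)) {
      sens <- min(1, max(0, base + if (assisted) assist_effect else 0))
      for (j in seq_along(vids)) {
        gt <- study$ground_truth[[vids[j]]]
        presses <- integer(0)
        if (gt$cancer_present && stats::runif(1) < sens) {
          l <- gt$lesions[[1L]]
          iv <- l$visible_intervals[1L, ]
          presses <- sample(iv[1L]:iv[2L], 1L)
        }
        k <- stats::rpois(1, fa_rate_per_min * n_frames[j] / fps / 60)
        if (k > 0L) {
          presses <- sort(c(presses, sample.int(n_frames[j], k) - 1L))
        }
        rows[[length(rows) + 1L]] <-
          data.frame(reader_id = sprintf("R%02d", r), video_id = vids[j],
                     assisted = assisted, starts_assisted = starts_assisted)
        rows[[length(rows)]]$press_frames <- list(presses)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
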