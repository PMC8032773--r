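#' Construct a lesion annotation
#'
#' Records where and when one superficial squamous cell carcinoma lesion is
#' visible in a video: inclusive frame intervals of visibility, an optional
#' per-frame rectangle covering the lesion (used for box-overlap matching of
#' alarms), the lesion diameter and esophageal wall position, and an optional
#' cause category used when tabulating missed lesions.
#'
#' @param lesion_id Identifier, unique within the video.
#' @param visible_intervals Two-column matrix (or list of length-2 vectors) of
#'   inclusive `[first_frame, last_frame]` 0-based frame ranges; must be
#'   sorted and non-overlapping.
#' @param regions Optional data frame with columns `frame, x0, y0, x1, y1`
#'   giving the pixel rectangle covering the lesion at each annotated frame;
#'   every annotated frame must lie inside a visible interval.
#' @param size_mm Lesion diameter in millimetres.
#' @param wall_position One of `"anterior"`, `"posterior"`, `"left"`,
#'   `"right"`.
#' @param cause_category Optional category used for miss attribution.
#' @return An object of class `lesion_annotation`.
#' @export
lesion_annotation <- function(lesion_id, visible_intervals, regions = NULL,
                              size_mm = NA_real_,
                              wall_position = NA_character_,
                              cause_category = NA_character_) {
  iv <- visible_intervals
  if (is.list(iv)) iv <- do.call(rbind, lapply(iv, as.integer))
  iv <- matrix(as.integer(iv), ncol = 2L,
               dimnames = list(NULL, c("first_frame", "last_frame")))
  if (nrow(iv) == 0L) stop("lesion must have >= 1 visible interval",
                           call. = FALSE)
  if (any(iv[, 1L] > iv[, 2L])) {
    stop("visible interval with first_frame > last_frame", call. = FALSE)
  }
  if (nrow(iv) > 1L) {
    if (is.unsorted(iv[, 1L], strictly = TRUE) ||
        any(iv[-1L, 1L] <= iv[-nrow(iv), 2L])) {
      stop("visible intervals must be sorted and non-overlapping",
           call. = FALSE)
    }
  }
  if (!is.null(regions)) {
    regions <- as.data.frame(regions)[, c("frame", "x0", "y0", "x1", "y1")]
    regions$frame <- as.integer(regions$frame)
    inside <- vapply(regions$frame, function(f) {
      any(f >= iv[, 1L] & f <= iv[, 2L])
    }, logical(1))
    if (!all(inside)) {
      stop(sprintf("region at frame %d lies outside every visible interval",
                   regions$frame[which(!inside)[1L]]), call. = FALSE)
    }
  }
  structure(list(lesion_id = as.character(lesion_id),
                 visible_intervals = iv, regions = regions,
                 size_mm = as.numeric(size_mm),
                 wall_position = as.character(wall_position),
                 cause_category = as.character(cause_category)),
            class = "lesion_annotation")
}

#' Construct video-level ground truth
#'
#' @param video_id Video identifier.
#' @param cancer_present Logical; must agree with `lesions` being non-empty.
#' @param lesions List of [lesion_annotation()] objects (empty iff
#'   `cancer_present` is `FALSE`).
#' @param fp_frames Optional data frame `frame, category` tagging frames
#'   whose spurious detections arise from a known false-positive source
#'   (`shadow`, `inflammation`, `post_ER_scar`, `EGJ`); used for cause
#'   attribution of false alarms.
#' @return An object of class `video_ground_truth`.
#' @export
video_ground_truth <- function(video_id, cancer_present, lesions = list(),
                               fp_frames = NULL) {
  if (isTRUE(cancer_present) != (length(lesions) > 0L)) {
    stop(sprintf("video %s: cancer_present must match presence of lesions",
                 video_id), call. = FALSE)
  }
  if (!all(vapply(lesions, inherits, logical(1), "lesion_annotation"))) {
    stop("lesions must be lesion_annotation objects", call. = FALSE)
  }
  if (!is.null(fp_frames)) {
    fp_frames <- as.data.frame(fp_frames)[, c("frame", "category")]
    fp_frames$frame <- as.integer(fp_frames$frame)
    fp_frames$category <- as.character(fp_frames$category)
  }
  structure(list(video_id = as.character(video_id),
                 cancer_present = isTRUE(cancer_present),
                 lesions = lesions, fp_frames = fp_frames),
            class = "video_ground_truth")
}

#' Construct a study case pairing the two modality videos of one patient
#'
#' Each patient is screened twice, once under white-light imaging and once
#' under narrow-band imaging; the comprehensive (union) analysis operates on
#' these pairs.
#'
#' @param case_id Case identifier.
#' @param wli_video_id,nbi_video_id Identifiers of the paired videos.
#' @param cancer_present Logical cancer status of the case.
#' @return An object of class `study_case`.
#' @export
study_case <- function(case_id, wli_video_id, nbi_video_id, cancer_present) {
  structure(list(case_id = as.character(case_id),
                 wli_video_id = as.character(wli_video_id),
                 nbi_video_id = as.character(nbi_video_id),
                 cancer_present = isTRUE(cancer_present)),
            class = "study_case")
}

#' Read a ground-truth document
#'
#' The document (YAML or JSON) has two top-level arrays. `videos`: objects
#' with `video_id`, `cancer_present`, and per-lesion entries carrying
#' `visible_intervals` as inclusive frame pairs plus optional `regions`,
#' `size_mm`, `wall_position`, `cause_category`, and optional `fp_frames`
#' tags. `cases`: objects with `case_id`, `wli_video_id`, `nbi_video_id`,
#' `cancer_present`. All structural invariants are enforced: a non-cancer
#' video listing lesions, or a case referencing an unknown video or
#' contradicting its videos' cancer status, is an error.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `videos` (named list of
#'   [video_ground_truth()]) and `cases` (list of [study_case()]).
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  ground_truth_from_list(doc)
}

ground_truth_from_list <- function(doc) {
  videos <- list()
  for (v in doc$videos %||% list()) {
    lesions <- lapply(v$lesions %||% list(), function(l) {
      regions <- if (!is.null(l$regions)) {
        do.call(rbind, lapply(l$regions, function(r) {
          data.frame(frame = r$frame, x0 = r$x0, y0 = r$y0,
                     x1 = r$x1, y1 = r$y1)
        }))
      }
      lesion_annotation(
        lesion_id = l$lesion_id,
        visible_intervals = lapply(l$visible_intervals, unlist),
        regions = regions,
        size_mm = l$size_mm %||% NA_real_,
        wall_position = l$wall_position %||% NA_character_,
        cause_category = l$cause_category %||% NA_character_)
    })
    fp <- if (!is.null(v$fp_frames)) {
      do.call(rbind, lapply(v$fp_frames, function(r) {
        data.frame(frame = r$frame, category = r$category)
      }))
    }
    gt <- video_ground_truth(v$video_id, isTRUE(v$cancer_present),
                             lesions, fp)
    videos[[gt$video_id]] <- gt
  }
  cases <- lapply(doc$cases %||% list(), function(cs) {
    for (vid in c(cs$wli_video_id, cs$nbi_video_id)) {
      if (!vid %in% names(videos)) {
        stop(sprintf("case %s references unknown video %s",
                     cs$case_id, vid), call. = FALSE)
      }
      if (videos[[vid]]$cancer_present != isTRUE(cs$cancer_present)) {
        stop(sprintf("case %s cancer status contradicts video %s",
                     cs$case_id, vid), call. = FALSE)
      }
    }
    study_case(cs$case_id, cs$wli_video_id, cs$nbi_video_id,
               isTRUE(cs$cancer_present))
  })
  list(videos = videos, cases = cases)
}

#' Write a ground-truth document
#'
#' @param gt List as returned by [read_ground_truth()] (elements `videos`
#'   and `cases`).
#' @param path Output path; `.yaml`/`.yml` writes YAML, anything else JSON.
#' @return The path, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  doc <- list(
    videos = unname(lapply(gt$videos, function(v) {
      out <- list(video_id = v$video_id, cancer_present = v$cancer_present)
      out$lesions <- lapply(v$lesions, function(l) {
        entry <- list(
          lesion_id = l$lesion_id,
          visible_intervals = lapply(seq_len(nrow(l$visible_intervals)),
                                     function(i) as.list(unname(l$visible_intervals[i, ]))))
        if (!is.null(l$regions)) {
          entry$regions <- lapply(seq_len(nrow(l$regions)), function(i) {
            as.list(l$regions[i, ])
          })
        }
        if (!is.na(l$size_mm)) entry$size_mm <- l$size_mm
        if (!is.na(l$wall_position)) entry$wall_position <- l$wall_position
        if (!is.na(l$cause_category)) entry$cause_category <- l$cause_category
        entry
      })
      if (!is.null(v$fp_frames) && nrow(v$fp_frames)) {
        out$fp_frames <- lapply(seq_len(nrow(v$fp_frames)), function(i) {
          as.list(v$fp_frames[i, ])
        })
      }
      out
    })),
    cases = lapply(gt$cases, function(cs) {
      list(case_id = cs$case_id, wli_video_id = cs$wli_video_id,
           nbi_video_id = cs$nbi_video_id,
           cancer_present = cs$cancer_present)
    }))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(doc, path)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# does 0-based frame f fall inside any visible interval of the lesion?
frame_in_lesion <- function(lesion, f) {
  any(f >= lesion$visible_intervals[, 1L] &
        f <= lesion$visible_intervals[, 2L])
}

first_visible_frame <- function(lesion) min(lesion$visible_intervals[, 1L])
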