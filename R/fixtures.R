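#' Per-case outcome fixture for the high-speed screening study
#'
#' A deterministic 40-case study (20 cancer, 20 control, each with paired
#' WLI and NBI videos) whose per-video outcomes encode the published
#' high-speed validation results exactly: WLI detects 15/20 cancers with 6/20
#' alarm-free controls, NBI detects 11/20 cancers with 16/20 alarm-free
#' controls, 9 cancers are detected by both modalities so the either-modality
#' union is 17/20 (85%), and the NBI false-positive control set is nested
#' inside the WLI one. Feeding these outcomes through [modality_metrics()]
#' and [comprehensive_outcomes()] reproduces every cell of the published
#' per-modality table.
#'
#' @return List with `outcomes` (per-video outcome data frame, 80 rows) and
#'   `cases` (40-row case table with `case_id`, `wli_video_id`,
#'   `nbi_video_id`, `cancer_present`).
#' @export
fixture_high_speed <- function() {
  n_cancer <- 20L; n_control <- 20L
  case_id <- sprintf("C%03d", seq_len(n_cancer + n_control))
  cancer <- rep(c(TRUE, FALSE), c(n_cancer, n_control))
  cases <- data.frame(case_id = case_id,
                      wli_video_id = paste0(case_id, "-WLI"),
                      nbi_video_id = paste0(case_id, "-NBI"),
                      cancer_present = cancer)
  # detected cancer cases chosen so |WLI| = 15, |NBI| = 11, overlap 9,
  # union 17 (inclusion-exclusion against the printed union count)
  wli_det <- 1:15
  nbi_det <- 7:17
  # false-alarm controls: 14 under WLI, 4 under NBI, nested
  wli_fp <- 21:34
  nbi_fp <- 21:24
  idx <- seq_len(n_cancer + n_control)
  mk <- function(modality, det, fp) {
    data.frame(video_id = paste0(case_id, "-", modality),
               case_id = case_id, modality = modality,
               cancer_present = cancer,
               ai_positive = idx %in% c(det, fp),
               correctly_detected = idx %in% det,
               first_tp_latency_s = NA_real_)
  }
  outcomes <- rbind(mk("WLI", wli_det, wli_fp), mk("NBI", nbi_det, nbi_fp))
  rownames(outcomes) <- NULL
  list(outcomes = outcomes, cases = cases)
}

#' Cause fixtures for false-positive signals and missed lesions
#'
#' The categorized event lists behind the published cause breakdown: 74
#' false-positive signal events (luminal shadow 30, mucosal inflammation 24,
#' post-endoscopic-resection scar 7, esophagogastric junction 13 — note the
#' unit is signal events, which outnumber the false-positive videos) and 12
#' missed lesions in 11 cases (background-mucosa inflammation 5, anterior
#' wall 4, obscure under white light 2, under 5 mm 1).
#'
#' @return List with `fp` (data frame `event_id`, `category`, 74 rows) and
#'   `fn` (data frame `lesion_id`, `case_id`, `category`, 12 rows; two
#'   lesions share one case).
#' @export
fixture_causes <- function() {
  fp_counts <- c(shadow = 30L, inflammation = 24L, post_ER_scar = 7L,
                 EGJ = 13L)
  fp <- data.frame(event_id = sprintf("FP%02d", seq_len(sum(fp_counts))),
                   category = rep(names(fp_counts), fp_counts))
  fn_counts <- c(inflammation = 5L, anterior_wall = 4L, obscure_WLI = 2L,
                 under_5mm = 1L)
  fn_case <- sprintf("FNC%02d", c(1:11, 11L))  # 12 lesions in 11 cases
  fn <- data.frame(lesion_id = sprintf("FN%02d", 1:12),
                   case_id = fn_case,
                   category = rep(names(fn_counts), fn_counts))
  list(fp = fp, fn = fn)
}
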