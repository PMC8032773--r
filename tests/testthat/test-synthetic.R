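cfg_clean <- function(...) {
  # deterministic detector, no false alarms, no peristalsis
  args <- utils::modifyList(
    list(p_detect_wli = 1, p_detect_nbi = 1, detectability_sd = 0,
         peristalsis_rate_per_s = 0,
         fp_rates_per_min = c(shadow = 0, inflammation = 0,
                              post_ER_scar = 0, EGJ = 0)),
    list(...))
  do.call(simulation_config, args)
}

test_that("a perfectly detected lesion yields exactly one signal, 0.5 s after entry", {
  g <- generate_case(cfg_clean(), case_seed = 101L, cancer = TRUE)
  for (mod in c("WLI", "NBI")) {
    s <- g$streams[[mod]]
    gt <- g$ground_truth[[s$video_id]]
    sig <- run_confirmation(s, rule_config())
    expect_equal(nrow(sig), 1L)
    cls <- classify_signals(sig, gt)
    expect_equal(cls$verdict, "TP")
    out <- video_outcome(cls, gt, fps = s$fps)
    expect_equal(out$first_tp_latency_s, 0.5)  # trigger on first visible frame
    first <- gt$lesions[[1]]$visible_intervals[1, 1]
    expect_equal(sig$trigger_frame, as.integer(first))
  }
})

test_that("a blind detector never produces a true positive", {
  cfg <- cfg_clean(p_detect_wli = 0, p_detect_nbi = 0)
  g <- generate_case(cfg, case_seed = 55L, cancer = TRUE)
  expect_equal(nrow(run_confirmation(g$streams$WLI)), 0L)
  expect_equal(nrow(run_confirmation(g$streams$NBI)), 0L)
})

test_that("the same seed regenerates a bit-identical case and study", {
  cfg <- simulation_config(seed = 7L, n_cancer_cases = 2L,
                           n_control_cases = 2L)
  a <- generate_case(cfg, case_seed = 31L, cancer = TRUE)
  b <- generate_case(cfg, case_seed = 31L, cancer = TRUE)
  expect_identical(a$streams$WLI$boxes, b$streams$WLI$boxes)
  expect_identical(a$streams$NBI$boxes, b$streams$NBI$boxes)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(lapply(s1$streams, `[[`, "boxes"),
                   lapply(s2$streams, `[[`, "boxes"))
  expect_identical(s1$manifest, s2$manifest)
})

test_that("study composition matches the configured case counts", {
  cfg <- simulation_config(seed = 3L, n_cancer_cases = 3L,
                           n_control_cases = 2L)
  st <- generate_study(cfg)
  expect_length(st$streams, 10L)  # two videos per case
  expect_equal(sum(st$cases$cancer_present), 3L)
  expect_equal(nrow(st$cases), 5L)
  # control cases carry no lesions; cancer cases exactly one
  for (i in seq_len(nrow(st$cases))) {
    gt <- st$ground_truth[[st$cases$wli_video_id[i]]]
    expect_equal(length(gt$lesions), as.integer(st$cases$cancer_present[i]))
  }
  # all-cancer study
  st2 <- generate_study(simulation_config(seed = 4L, n_cancer_cases = 2L,
                                          n_control_cases = 0L))
  expect_true(all(st2$cases$cancer_present))
})

test_that("a case regenerates identically from its manifest seed", {
  cfg <- simulation_config(seed = 11L, n_cancer_cases = 1L,
                           n_control_cases = 1L)
  st <- generate_study(cfg)
  seed1 <- st$manifest$case_seeds[["C001"]]
  redo <- generate_case(cfg, seed1, cancer = TRUE, case_id = "C001")
  expect_identical(redo$streams$WLI$boxes, st$streams[["C001-WLI"]]$boxes)
})

test_that("video geometry follows the traversal parameters", {
  cfg <- cfg_clean()
  g <- generate_case(cfg, case_seed = 12L, cancer = TRUE)
  # 25 cm at 2 cm/s -> 12.5 s at 30 fps
  expect_equal(g$streams$WLI$n_frames, 375L)
  l <- g$ground_truth[["case00012-WLI"]]$lesions[[1]]
  iv <- l$visible_intervals[1, ]
  expected_frames <- round((l$size_mm / 10 + 2 * cfg$field_margin_cm) /
                             cfg$traversal_speed_cm_s * cfg$fps)
  expect_equal(as.integer(iv[2] - iv[1] + 1L), as.integer(expected_frames))
  # slow-observation mode dwells 5-15 s on the lesion
  cfg_slow <- cfg_clean(dwell_s = c(5, 15))
  g2 <- generate_case(cfg_slow, case_seed = 12L, cancer = TRUE)
  iv2 <- g2$ground_truth[["case00012-WLI"]]$lesions[[1]]$visible_intervals[1, ]
  dur_s <- (iv2[2] - iv2[1] + 1) / cfg$fps
  expect_gte(dur_s, 5 - 1 / 30)
  expect_lte(dur_s, 15 + 1 / 30)
})

test_that("EGJ false-positive bursts only occur near the distal end", {
  cfg <- simulation_config(seed = 2L, p_detect_wli = 0, p_detect_nbi = 0,
                           fp_rates_per_min = c(shadow = 0, inflammation = 0,
                                                post_ER_scar = 0, EGJ = 20))
  hits <- integer(0)
  n <- sim_frames <- NULL
  for (seed in 1:10) {
    g <- generate_case(cfg, case_seed = seed, cancer = FALSE)
    fp <- g$ground_truth[[g$case$wli_video_id]]$fp_frames
    n <- g$streams$WLI$n_frames
    if (!is.null(fp)) hits <- c(hits, fp$frame)
  }
  expect_gt(length(hits), 0)
  expect_true(all(hits >= floor(0.9 * n)))
})

test_that("false-positive signal count grows with the burst rate", {
  rates <- c(0.2, 1, 5)
  mean_fp <- vapply(rates, function(r) {
    cfg <- simulation_config(seed = 5L, p_detect_wli = 0, p_detect_nbi = 0,
                             fp_rates_per_min = c(shadow = r,
                                                  inflammation = r,
                                                  post_ER_scar = r, EGJ = r))
    n_sig <- vapply(1:15, function(s) {
      g <- generate_case(cfg, case_seed = 1000L + s, cancer = FALSE)
      nrow(run_confirmation(g$streams$WLI))
    }, numeric(1))
    mean(n_sig)
  }, numeric(1))
  expect_equal(cor(rates, mean_fp, method = "spearman"), 1)
})

test_that("pipeline sensitivity is monotone in detection probability", {
  grid <- c(0.1, 0.5, 1)
  sens <- vapply(grid, function(p) {
    cfg <- simulation_config(seed = 6L, p_detect_wli = p, p_detect_nbi = p,
                             detectability_sd = 0,
                             peristalsis_rate_per_s = 0,
                             fp_rates_per_min = c(shadow = 0,
                                                  inflammation = 0,
                                                  post_ER_scar = 0, EGJ = 0))
    hit <- vapply(1:40, function(s) {
      g <- generate_case(cfg, case_seed = 2000L + s, cancer = TRUE)
      gt <- g$ground_truth[[g$case$wli_video_id]]
      cls <- classify_signals(run_confirmation(g$streams$WLI), gt)
      any(cls$verdict == "TP")
    }, logical(1))
    mean(hit)
  }, numeric(1))
  expect_true(all(diff(sens) >= 0))
  expect_equal(sens[3], 1)  # near-certain detection with adequate visibility
})

test_that("reader panel respects its sensitivity parameters and seed", {
  cfg <- simulation_config(seed = 8L, n_cancer_cases = 3L,
                           n_control_cases = 2L)
  st <- generate_study(cfg)
  # perfect readers press inside the lesion window on every cancer video
  panel <- generate_reader_panel(st, n_readers = 4L,
                                 base_sensitivity_range = c(1, 1),
                                 assist_effect = 0, fa_rate_per_min = 0,
                                 seed = 2L)
  for (i in seq_len(nrow(panel))) {
    gt <- st$ground_truth[[panel$video_id[i]]]
    sc <- score_reader(panel[i, ], gt)
    if (gt$cancer_present) expect_true(sc$correct)
  }
  # crossover bookkeeping: half the panel starts assisted
  expect_equal(sum(panel$starts_assisted) / 2, nrow(panel) / 4)
  # determinism
  p2 <- generate_reader_panel(st, n_readers = 4L,
                              base_sensitivity_range = c(1, 1),
                              assist_effect = 0, fa_rate_per_min = 0,
                              seed = 2L)
  expect_identical(panel, p2)
})

test_that("a null assistance effect leaves assisted and unassisted sensitivity equal in expectation", {
  cfg <- simulation_config(seed = 9L, n_cancer_cases = 4L,
                           n_control_cases = 0L)
  st <- generate_study(cfg)
  panel <- generate_reader_panel(st, n_readers = 200L,
                                 base_sensitivity_range = c(0.3, 0.6),
                                 assist_effect = 0, fa_rate_per_min = 0,
                                 seed = 3L)
  correct <- vapply(seq_len(nrow(panel)), function(i) {
    isTRUE(score_reader(panel[i, ],
                        st$ground_truth[[panel$video_id[i]]])$correct)
  }, logical(1))
  p_a <- mean(correct[panel$assisted])
  p_u <- mean(correct[!panel$assisted])
  n_per_arm <- sum(panel$assisted)
  se <- sqrt(0.45 * 0.55 * 2 / n_per_arm)
  expect_lt(abs(p_a - p_u), 3 * se)
})

test_that("generation errors are informative for impossible visibility", {
  cfg <- simulation_config(field_margin_cm = 0.001,
                           lesion_size_range_mm = c(0.01, 0.011),
                           traversal_speed_cm_s = 50, fps = 1)
  expect_error(generate_case(cfg, 1L, cancer = TRUE), "visibility")
})
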