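test_that("snapshot inside a visibility interval is a true positive", {
  gt <- gt_one_lesion("v1", 300L, 420L)
  cls <- classify_signals(signal_row("v1", snapshot_frame = 350L), gt)
  expect_equal(cls$verdict, "TP")
  expect_equal(cls$matched_lesion_id, "L1")
  cls2 <- classify_signals(signal_row("v1", snapshot_frame = 430L), gt)
  expect_equal(cls2$verdict, "FP")
})

test_that("any signal on a non-cancer video is a false positive, with cause tag", {
  gt <- video_ground_truth("v2", FALSE,
                           fp_frames = data.frame(frame = 50L,
                                                  category = "EGJ"))
  cls <- classify_signals(rbind(signal_row("v2", 50L),
                                signal_row("v2", 80L)), gt)
  expect_equal(cls$verdict, c("FP", "FP"))
  expect_equal(cls$fp_category, c("EGJ", "other"))
})

test_that("box-overlap mode demands nonzero overlap with the lesion region", {
  reg <- data.frame(frame = 300:420, x0 = 500, y0 = 500, x1 = 700, y1 = 700)
  gt <- gt_one_lesion("v1", 300L, 420L, regions = reg)
  disjoint <- signal_row("v1", 350L, box = c(0, 0, 100, 100))
  touching <- signal_row("v1", 350L, box = c(600, 600, 800, 800))
  edge <- signal_row("v1", 350L, box = c(400, 400, 500, 500))  # shares edge only
  expect_equal(classify_signals(disjoint, gt, "interval")$verdict, "TP")
  expect_equal(classify_signals(disjoint, gt, "box_overlap")$verdict, "FP")
  expect_equal(classify_signals(touching, gt, "box_overlap")$verdict, "TP")
  # half-open rectangles: a shared boundary is zero overlap
  expect_equal(classify_signals(edge, gt, "box_overlap")$verdict, "FP")
})

test_that("box-overlap mode falls back to interval matching when no region exists", {
  gt <- gt_one_lesion("v1", 300L, 420L)
  expect_warning(
    cls <- classify_signals(signal_row("v1", 350L), gt, "box_overlap"),
    "falling back")
  expect_equal(cls$verdict, "TP")
})

test_that("video outcomes follow the per-video definitions", {
  gt <- gt_one_lesion("v1", 300L, 420L)
  tp <- classify_signals(signal_row("v1", 350L, signal_frame = 351L), gt)
  out <- video_outcome(tp, gt)
  expect_true(out$ai_positive && out$correctly_detected)
  expect_equal(out$first_tp_latency_s, (351 - 300) / 30)

  # cancer video with only false alarms: positive but not correct
  fp_only <- classify_signals(signal_row("v1", 500L), gt)
  out2 <- video_outcome(fp_only, gt)
  expect_true(out2$ai_positive)
  expect_false(out2$correctly_detected)
  expect_true(is.na(out2$first_tp_latency_s))

  # silent non-cancer video: a true negative
  gt0 <- video_ground_truth("v2", FALSE)
  out3 <- video_outcome(classify_signals(no_signals(), gt0), gt0)
  expect_false(out3$ai_positive)
})

test_that("half-up percent rounding matches the printed tables", {
  expect_equal(round_percent(15, 20), 75L)
  expect_equal(round_percent(6, 11), 55L)   # 54.55 rounds up
  expect_equal(round_percent(1, 8), 13L)    # 12.5 rounds half-up
  expect_equal(round_percent(16, 25), 64L)
  expect_equal(round_percent(c(30, 24, 7, 13), 74), c(41L, 32L, 9L, 18L))
  expect_error(round_percent(1, 0), "zero denominator")
})

test_that("per-modality metrics reproduce the published per-case table", {
  fx <- fixture_high_speed()
  w <- modality_metrics(fx$outcomes[fx$outcomes$modality == "WLI", ], "WLI")
  expect_equal(vapply(w[c("sensitivity", "specificity", "ppv", "npv")],
                      `[[`, integer(1), "percent"),
               c(sensitivity = 75L, specificity = 30L, ppv = 52L, npv = 55L))
  expect_equal(w$sensitivity[c("numerator", "denominator")],
               list(numerator = 15L, denominator = 20L))
  expect_equal(w$ppv[c("numerator", "denominator")],
               list(numerator = 15L, denominator = 29L))
  expect_equal(w$npv[c("numerator", "denominator")],
               list(numerator = 6L, denominator = 11L))
  nb <- modality_metrics(fx$outcomes[fx$outcomes$modality == "NBI", ], "NBI")
  expect_equal(vapply(nb[c("sensitivity", "specificity", "ppv", "npv")],
                      `[[`, integer(1), "percent"),
               c(sensitivity = 55L, specificity = 80L, ppv = 73L, npv = 64L))
  expect_equal(nb$ppv$denominator, 15L)
  expect_equal(nb$npv$denominator, 25L)
})

test_that("PPV accounting cross-checks against sensitivity and specificity counts", {
  fx <- fixture_high_speed()
  for (m in c("WLI", "NBI")) {
    o <- fx$outcomes[fx$outcomes$modality == m, ]
    mm <- modality_metrics(o, m)
    expect_equal(mm$ppv$numerator, sum(o$ai_positive & o$correctly_detected))
    expect_equal(mm$ppv$denominator, sum(o$ai_positive))
    # positives = detected cancers + false-alarm controls
    expect_equal(mm$ppv$denominator,
                 mm$sensitivity$numerator +
                   (mm$specificity$denominator - mm$specificity$numerator))
  }
})

test_that("metrics with an empty denominator are undefined, not zero", {
  o <- data.frame(video_id = "a-WLI", cancer_present = TRUE,
                  ai_positive = FALSE, correctly_detected = FALSE,
                  first_tp_latency_s = NA_real_)
  m <- modality_metrics(o, "WLI")
  expect_true(is.na(m$specificity$percent))  # no non-cancer videos
  expect_true(is.na(m$ppv$percent))          # no positives
  expect_equal(m$sensitivity$percent, 0L)
})

test_that("all videos correct gives 100% across the board", {
  o <- data.frame(video_id = c("a-WLI", "b-WLI"),
                  cancer_present = c(TRUE, FALSE),
                  ai_positive = c(TRUE, FALSE),
                  correctly_detected = c(TRUE, FALSE),
                  first_tp_latency_s = c(0.5, NA))
  m <- modality_metrics(o, "WLI")
  expect_equal(vapply(m[c("sensitivity", "specificity", "ppv", "npv")],
                      `[[`, integer(1), "percent"),
               c(sensitivity = 100L, specificity = 100L, ppv = 100L,
                 npv = 100L))
})

test_that("either-modality union reproduces the comprehensive sensitivity", {
  fx <- fixture_high_speed()
  comp <- comprehensive_outcomes(fx$cases, fx$outcomes)
  m <- modality_metrics(comp, "WLI+NBI")
  expect_equal(m$sensitivity$percent, 85L)
  expect_equal(m$sensitivity$numerator, 17L)
  expect_equal(m$sensitivity$denominator, 20L)
  # inclusion-exclusion: union = WLI TP + NBI TP - both
  w <- fx$outcomes[fx$outcomes$modality == "WLI", ]
  n <- fx$outcomes[fx$outcomes$modality == "NBI", ]
  both <- sum(w$correctly_detected & n$correctly_detected)
  expect_equal(both, 9L)
  expect_equal(m$sensitivity$numerator,
               sum(w$correctly_detected) + sum(n$correctly_detected) - both)
  # union dominance
  expect_gte(m$sensitivity$percent, 75L)
})

test_that("a case detected by one modality only counts as detected; missing modality errors", {
  fx <- fixture_high_speed()
  comp <- comprehensive_outcomes(fx$cases, fx$outcomes)
  w <- fx$outcomes[fx$outcomes$modality == "WLI", ]
  n <- fx$outcomes[fx$outcomes$modality == "NBI", ]
  wli_only <- w$correctly_detected & !n$correctly_detected
  expect_true(all(comp$correctly_detected[wli_only]))
  expect_error(comprehensive_outcomes(fx$cases, fx$outcomes[-1, ]),
               "missing outcome")
})

test_that("time-to-detection summary uses median and range conventions", {
  o <- data.frame(first_tp_latency_s = c(0.5, 0.5, 3.63))
  s <- time_to_detection_summary(o)
  expect_equal(s$median_s, 0.5)
  expect_equal(c(s$min_s, s$max_s), c(0.5, 3.63))
  s1 <- time_to_detection_summary(data.frame(first_tp_latency_s = 1.2))
  expect_equal(c(s1$median_s, s1$min_s, s1$max_s), rep(1.2, 3))
  s2 <- time_to_detection_summary(data.frame(first_tp_latency_s = c(0.5, 1)))
  expect_equal(s2$median_s, 0.75)
  s0 <- time_to_detection_summary(data.frame(first_tp_latency_s = NA_real_))
  expect_equal(s0$n, 0L)
  expect_true(is.na(s0$median_s))
})

test_that("cause tabulation reproduces the published breakdowns", {
  cz <- fixture_causes()
  fp <- tabulate_causes(cz$fp$category)
  expect_equal(attr(fp, "total"), 74L)
  expect_equal(fp$count, c(30L, 24L, 7L, 13L))
  expect_equal(fp$percent, c(41L, 32L, 9L, 18L))
  fn <- tabulate_causes(cz$fn$category)
  expect_equal(attr(fn, "total"), 12L)
  expect_equal(fn$percent, c(42L, 33L, 17L, 8L))
  expect_equal(length(unique(cz$fn$case_id)), 11L)  # 12 lesions in 11 cases
  one <- tabulate_causes(rep("shadow", 5))
  expect_equal(one$percent, 100L)
})

test_that("reader scoring follows the strict on-monitor rule", {
  gt <- gt_one_lesion("v1", 300L, 420L)
  ok <- score_reader(list(reader_id = "R1", assisted = FALSE,
                          press_frames = 350L), gt)
  expect_true(ok$correct)
  expect_equal(ok$false_alarms, 0L)
  # press after the lesion left the monitor: incorrect plus one false alarm
  late <- score_reader(list(reader_id = "R1", assisted = FALSE,
                            press_frames = 430L), gt)
  expect_false(late$correct)
  expect_equal(late$false_alarms, 1L)
  # non-cancer video records false alarms only
  gt0 <- video_ground_truth("v2", FALSE)
  none <- score_reader(list(reader_id = "R1", assisted = TRUE,
                            press_frames = integer(0)), gt0)
  expect_true(is.na(none$correct))
  expect_equal(none$false_alarms, 0L)
  # pressing at every frame is always correct on a cancer video
  all_presses <- score_reader(list(reader_id = "R1", assisted = FALSE,
                                   press_frames = 0:499), gt)
  expect_true(all_presses$correct)
})
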