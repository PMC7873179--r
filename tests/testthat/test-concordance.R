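test_that("channels are restricted to the half-open imaged segment", {
  expect_equal(map_channels_to_segment(c(0, 100, 200, 300), c(50, 250)),
               c(2, 3))
  ## four of eight catheter channels fall inside a 400 mm imaged window
  pos <- seq(0, 700, by = 100)
  expect_length(map_channels_to_segment(pos, c(150, 550)), 4)
  ## boundary behaviour: start included, end excluded
  expect_equal(map_channels_to_segment(c(100, 200), c(100, 200)), 1)
  expect_error(map_channels_to_segment(c(0, 100), c(400, 500)),
               "no cross-modality comparison")
})

test_that("MRI activity during an HAPC is labelled by residual trough depth", {
  pos <- seq(0, 258, by = 2)
  tt <- 0:299
  zero <- matrix(0, length(pos), length(tt))
  mk_session <- function(r, hapcs) {
    aligned_session(fake_rmap(r, pos, tt), hapcs,
                    channel_positions_mm = c(30, 130, 230),
                    imaged_segment_mm = c(0, 260), clock_offset_s = 0)
  }
  h <- fake_hapc(c(100, 130))

  ## identically zero residuals: absent
  cls <- classify_mri_activity(mk_session(zero, list(h)), h)
  expect_equal(cls$label, "absent")
  expect_equal(cls$score_mm, 0)

  ## 6 mm trough inside the window near channel 2: high (theta_high = 4)
  r <- zero; r[66, 110:120] <- -6
  expect_equal(classify_mri_activity(mk_session(r, list(h)), h)$label, "high")

  ## 2 mm trough: between thresholds, minimal
  r <- zero; r[66, 110:120] <- -2
  expect_equal(classify_mri_activity(mk_session(r, list(h)), h)$label,
               "minimal")

  ## trough outside the included channels' bands does not count: with the
  ## imaged segment cut at 140 mm only channels 1-2 remain, whose bands
  ## end at 180 mm
  r <- zero; r[which(pos == 240), 110:120] <- -6
  ses_cut <- aligned_session(fake_rmap(r, pos, tt), list(h),
                             channel_positions_mm = c(30, 130, 230),
                             imaged_segment_mm = c(0, 140))
  expect_equal(classify_mri_activity(ses_cut, h)$label, "absent")

  ## window fully outside the MRI recording: not_recorded, distinct
  h_out <- fake_hapc(c(500, 530))
  expect_equal(classify_mri_activity(mk_session(zero, list(h_out)),
                                     h_out)$label, "not_recorded")
})

test_that("phantom wave residuals classify as high at default thresholds", {
  cfg <- quiet_config(duration_s = 300,
                      waves = list(wave_spec(60, -60, 10, 0.8, 30)))
  arm <- run_mri_arm(cfg)
  rec <- simulate_manometry(arm$truth, cfg)
  h <- detect_hapcs(detect_contractions(rec), rec)
  expect_length(h, 1)
  ses <- aligned_session(arm$rmap, h, cfg$sensor_positions_mm,
                         c(0, max(arm$rmap$positions_mm)))
  cls <- classify_mri_activity(ses, h[[1]])
  expect_equal(cls$label, "high")
  ## trough depth agrees with the explicit least-squares oracle
  oracle <- lm_residual_oracle(arm$diams)
  expect_equal(cls$score_mm, max(-oracle, na.rm = TRUE), tolerance = 1e-6)
  expect_gt(cls$score_mm, 4)
})

test_that("MRI-only episodes are detected, ordered and annotated", {
  pos <- seq(0, 258, by = 2)
  tt <- 0:299
  zero <- matrix(0, length(pos), length(tt))
  ses0 <- aligned_session(fake_rmap(zero, pos, tt), list(),
                          c(30, 130, 230), c(0, 260))
  expect_equal(nrow(detect_mri_episodes(ses0)), 0)

  ## one activity burst, no manometric HAPC: flagged non-overlapping
  r <- zero; r[50, 100:120] <- -3
  ses1 <- aligned_session(fake_rmap(r, pos, tt), list(),
                          c(30, 130, 230), c(0, 260))
  ep <- detect_mri_episodes(ses1)
  expect_equal(nrow(ep), 1)
  expect_false(ep$overlaps_hapc)
  expect_equal(ep$label, "minimal")
  expect_equal(ep$start_s, 99)   # column 100 holds t = 99 s
  expect_equal(ep$end_s, 120)    # half-open: last active frame + 1 s

  ## two disjoint bursts: two episodes ordered by start, deep one high
  r <- zero; r[50, 40:60] <- -6; r[80, 200:215] <- -2
  ses2 <- aligned_session(fake_rmap(r, pos, tt),
                          list(fake_hapc(c(35, 65))),
                          c(30, 130, 230), c(0, 260))
  ep <- detect_mri_episodes(ses2)
  expect_equal(nrow(ep), 2)
  expect_true(ep$start_s[1] < ep$start_s[2])
  expect_equal(ep$label, c("high", "minimal"))
  expect_equal(ep$overlaps_hapc, c(TRUE, FALSE))

  ## sub-minimum-duration activity is ignored
  r <- zero; r[50, 100:102] <- -3
  ses3 <- aligned_session(fake_rmap(r, pos, tt), list(),
                          c(30, 130, 230), c(0, 260))
  expect_equal(nrow(detect_mri_episodes(ses3, min_duration_s = 5)), 0)
})

test_that("concordance summary reproduces the reported percentage arithmetic", {
  mk <- function(labels) lapply(labels, function(l)
    list(label = l, score_mm = NA_real_, window_mri_s = c(0, 1)))

  cls <- mk(c(rep("high", 2), rep("minimal", 7), rep("absent", 2)))
  s <- concordance_summary(cls)
  expect_equal(s$n_hapcs, 11)
  expect_equal(s$percentages$high, 18)
  expect_equal(s$percentages$minimal, 64)
  expect_equal(s$percentages$absent, 18)

  s2 <- concordance_summary(mk(c("high", "minimal", "minimal", "absent")))
  expect_equal(unlist(s2$percentages[c("high", "minimal", "absent")]),
               c(high = 25, minimal = 50, absent = 25))

  s0 <- concordance_summary(list())
  expect_equal(s0$n_hapcs, 0)
  expect_true(all(is.na(unlist(s0$percentages))))
  expect_equal(sum(unlist(s0$counts)), 0)

  ## not-recorded stays distinct but merges into the compatible view
  s3 <- concordance_summary(mk(c("high", "absent", "not_recorded")))
  expect_equal(s3$counts$absent, 1)
  expect_equal(s3$counts$not_recorded, 1)
  expect_equal(s3$absent_or_not_recorded, 2)
})

test_that("per-patient HAPC count aggregation", {
  agg <- summarise_hapc_counts(c(0, 0, 3, 4, 4, 0))
  expect_equal(agg$total_hapcs, 11)
  expect_equal(agg$patients_with_hapcs, 3)
  expect_equal(agg$n_patients, 6)
  expect_error(summarise_hapc_counts(c(1, -2)), "non-negative")
})

test_that("labels partition the HAPCs and respect threshold monotonicity", {
  pos <- seq(0, 258, by = 2)
  tt <- 0:299
  set.seed(13)
  r <- matrix(0, length(pos), length(tt))
  for (k in 1:6) {                       # assorted troughs
    r[sample(10:120, 1), seq(sample(1:250, 1), length.out = 20)] <-
      -runif(1, 0.5, 7)
  }
  hapcs <- list(fake_hapc(c(20, 50)), fake_hapc(c(120, 150)),
                fake_hapc(c(230, 260)), fake_hapc(c(400, 430)))
  ses <- aligned_session(fake_rmap(r, pos, tt), hapcs,
                         c(30, 130, 230), c(0, 260))
  labels_at <- function(th, tm) vapply(hapcs, function(h)
    classify_mri_activity(ses, h, theta_high_mm = th,
                          theta_min_mm = tm)$label, character(1))

  base <- labels_at(4, 1)
  expect_length(base, length(hapcs))
  expect_true(all(base %in% c("high", "minimal", "absent", "not_recorded")))
  s <- concordance_summary(lapply(base, function(l)
    list(label = l, score_mm = 0, window_mri_s = c(0, 1))))
  expect_equal(sum(unlist(s$counts)), length(hapcs))

  ## raising theta_high never increases high; raising theta_min never
  ## increases high + minimal
  for (th in c(5, 6.5)) {
    expect_lte(sum(labels_at(th, 1) == "high"), sum(base == "high"))
  }
  for (tm in c(2, 3)) {
    expect_lte(sum(labels_at(4, tm) %in% c("high", "minimal")),
               sum(base %in% c("high", "minimal")))
  }
})

test_that("shifting both clocks by the same constant leaves labels unchanged", {
  pos <- seq(0, 258, by = 2)
  tt <- 0:299
  r <- matrix(0, length(pos), length(tt))
  r[66, 110:125] <- -5
  h <- fake_hapc(c(100, 130))
  ses <- aligned_session(fake_rmap(r, pos, tt), list(h),
                         c(30, 130, 230), c(0, 260), clock_offset_s = 0)
  base <- classify_mri_activity(ses, h)$label
  for (shift in c(-40, 25, 300)) {
    h2 <- h; h2$window_s <- h$window_s + shift
    ses2 <- aligned_session(fake_rmap(r, pos, tt), list(h2),
                            c(30, 130, 230), c(0, 260),
                            clock_offset_s = shift)
    expect_equal(classify_mri_activity(ses2, h2)$label, base)
  }
})
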