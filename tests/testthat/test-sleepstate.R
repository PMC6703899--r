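# Epoch-level features for a target label sequence, noise-free, so scoring
# fixtures can be written as intended hypnograms.
features_for <- function(labels) {
  generate_epoch_features(hypnogram(labels), feature_params(sigma = 0), seed = 1)
}

test_that("epoch scoring rules map canonical feature patterns to states", {
  f <- data.frame(delta_power = c(10, 10, 1, 1),
                  theta_power = c(2, 2, 3, 3),
                  emg_rms = c(5, 0.5, 0.1, 1.5),
                  movement_flag = c(TRUE, FALSE, FALSE, FALSE))
  hyp <- score_epochs(f)
  expect_identical(hyp$labels[1], "AW")     # high EMG + movement
  expect_identical(hyp$labels[2], "NREMS")  # low EMG, delta-dominant
  expect_identical(hyp$labels[4], "QW")     # awake but immobile, moderate EMG
  expect_error(score_epochs(f[, -2]), "theta_power")
})

test_that("bout segmentation tiles the recording with half-open runs", {
  b <- segment_bouts(hypnogram(c("AW", "AW", "QW")))
  expect_equal(nrow(b), 2)
  expect_equal(b$start_epoch, c(0, 2))
  expect_equal(b$end_epoch, c(2, 3))
  expect_equal(b$start_frame, c(0, 80))
  expect_equal(b$end_frame, c(80, 120))

  alt <- rep(c("AW", "QW"), 10)
  expect_equal(nrow(segment_bouts(hypnogram(alt))), 20)

  set.seed(6)
  labs <- sample(c("AW", "QW", "NREMS"), 200, replace = TRUE)
  b2 <- segment_bouts(hypnogram(labs))
  expect_identical(rep(b2$state, times = b2$end_epoch - b2$start_epoch), labs)
  expect_equal(b2$start_epoch[-1], b2$end_epoch[-nrow(b2)])  # no gaps
})

test_that("cataplexy validation applies the four bout criteria", {
  # 10 wake epochs then a 2-epoch atonic theta-dominant run: qualifies
  lab1 <- c(rep("AW", 10), "CATAPLEXY", "CATAPLEXY", rep("QW", 3))
  hyp1 <- score_epochs(features_for(lab1))
  expect_identical(hyp1$labels, lab1)

  # same run lasting only 4 s: rejected (minimum 8 s)
  lab2 <- c(rep("AW", 10), "CATAPLEXY", rep("QW", 4))
  hyp2 <- score_epochs(features_for(lab2))
  expect_false(any(hyp2$labels == "CATAPLEXY"))

  # insufficient prior wake: rejected, relabeled REMS after NREMS
  lab3 <- c(rep("AW", 4), rep("NREMS", 6), "CATAPLEXY", "CATAPLEXY", rep("QW", 3))
  hyp3 <- score_epochs(features_for(lab3))
  expect_identical(hyp3$labels[11:12], c("REMS", "REMS"))

  # genuine REMS from NREMS is preserved
  lab4 <- c(rep("AW", 4), rep("NREMS", 6), rep("REMS", 3), rep("QW", 2))
  expect_identical(score_epochs(features_for(lab4))$labels, lab4)

  # chaining: a second short-prior-wake run within 40 s of a qualifying bout
  lab5 <- c(rep("AW", 10), "CATAPLEXY", "CATAPLEXY", rep("AW", 5),
            "CATAPLEXY", "CATAPLEXY", rep("QW", 2))
  expect_identical(score_epochs(features_for(lab5))$labels, lab5)

  # no chaining across a sleep gap
  lab6 <- c(rep("AW", 10), "CATAPLEXY", "CATAPLEXY", rep("NREMS", 3),
            rep("AW", 2), "CATAPLEXY", "CATAPLEXY", rep("QW", 2))
  hyp6 <- score_epochs(features_for(lab6))
  expect_identical(hyp6$labels[11:12], c("CATAPLEXY", "CATAPLEXY"))
  expect_false(any(hyp6$labels[16:17] == "CATAPLEXY"))
})

test_that("hyperactive-wake labeling detects shifted post-odor bouts", {
  set.seed(41)
  n_cells <- 50
  # 100 baseline AW epochs, 5 QW, one post-odor AW bout of 5 epochs
  bouts <- make_bouts(c("AW", "QW", "AW"), c(100, 5, 5))
  nf <- 110 * 40
  base <- matrix(rnorm(n_cells * nf), n_cells)
  post_frames <- (105 * 40 + 1):nf

  null_z <- as_zscore(base)
  b0 <- label_haw(bouts, null_z, odor_onset_s = 105 * 4)
  # a null bout is usually not flagged (type-I error is checked elsewhere)
  expect_true(b0$label[3] %in% c("AWO", "HAW"))

  shifted <- base
  shifted[, post_frames] <- shifted[, post_frames] + 1.0
  b1 <- label_haw(bouts, as_zscore(shifted), odor_onset_s = 105 * 4)
  expect_identical(b1$label[3], "HAW")
  expect_lt(b1$haw_p[3], 1e-6)
  expect_identical(b1$label[1], "AW")  # baseline bouts untouched

  # no post-odor AW bouts: nothing relabeled, no error
  b2 <- label_haw(make_bouts(c("AW", "QW"), c(100, 10)), null_z,
                  odor_onset_s = 105 * 4)
  expect_false(any(b2$label %in% c("AWO", "HAW")))
  # no pre-odor AW baseline: error
  expect_error(label_haw(bouts, null_z, odor_onset_s = 0), "baseline")
})

test_that("cataplexy subtype follows the nearest preceding AW-family bout", {
  z <- as_zscore(matrix(rnorm(2 * 30 * 40), 2))

  pre_sc <- make_bouts(c("AW", "QW", "CATAPLEXY", "QW"), c(12, 3, 3, 12))
  expect_identical(label_cataplexy_type(pre_sc)$label[3], "SC")

  ec <- make_bouts(c("AW", "HAW", "CATAPLEXY", "QW"), c(12, 3, 3, 12))
  expect_identical(label_cataplexy_type(ec)$label[3], "EC")

  awo <- make_bouts(c("AW", "AWO", "CATAPLEXY", "QW"), c(12, 3, 3, 12))
  expect_identical(label_cataplexy_type(awo)$label[3], "SC")

  # chained bout inherits the type of the chain's first bout
  chain <- make_bouts(c("AW", "HAW", "CATAPLEXY", "AW", "CATAPLEXY"),
                      c(10, 3, 3, 4, 3))
  out <- label_cataplexy_type(chain)
  expect_identical(out$label[c(3, 5)], c("EC", "EC"))

  # post-odor cataplexy whose nearest AW-family bout is pre-odor is flagged
  amb <- make_bouts(c("AW", "QW", "CATAPLEXY", "QW"), c(10, 12, 3, 5))
  out2 <- label_cataplexy_type(amb, odor_onset_s = 44)
  expect_identical(out2$label[3], "SC")
  expect_true(out2$flagged[3])

  orphan <- make_bouts(c("NREMS", "CATAPLEXY"), c(12, 3))
  expect_error(label_cataplexy_type(orphan), "no preceding wake")
})

test_that("bout durations summarize and compare SC vs EC", {
  b <- make_bouts(c("AW", "SC", "AW", "SC", "AW", "EC", "AW", "EC"),
                  c(12, 3, 12, 5, 12, 2, 12, 4))
  res <- bout_durations(b)
  expect_equal(res$summary$n, c(2, 2))
  expect_equal(res$summary$mean_s, c(16, 12))
  set.seed(42)
  b$duration_s[b$label == "SC"] <- rnorm(2, 20, 4)
  b$duration_s[b$label == "EC"] <- rnorm(2, 15, 4)
  res2 <- bout_durations(b)
  ref <- summary(aov(d ~ g, data.frame(d = unlist(res2$durations),
                                       g = rep(c("SC", "EC"), each = 2))))[[1]]
  expect_equal(res2$anova$F, ref[["F value"]][1], tolerance = 1e-9)

  only_sc <- make_bouts(c("AW", "SC"), c(12, 3))
  expect_null(bout_durations(only_sc)$anova)
})
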