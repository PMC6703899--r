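test_that("session_config enforces its invariants", {
  expect_error(session_config(duration_s = 4001), "multiple of epoch_s")
  expect_error(session_config(frame_rate_hz = 0.3, epoch_s = 3), "integer")
  expect_error(session_config(odor_onset_s = 13000, odor_duration_s = 3600),
               "within the recording")
  expect_error(state_model("control", cataplexy_hazard = 0.2), "hazard")
  expect_error(
    generate_hypnogram(session_config("control", odor_onset_s = NULL),
                       state_model("narcoleptic")),
    "cataplexy_hazard")
})

test_that("control sessions never contain cataplexy epochs", {
  for (seed in c(1, 7, 99)) {
    cfg <- session_config("control", duration_s = 7200, odor_onset_s = 3600,
                          seed = seed)
    sim <- generate_hypnogram(cfg)
    expect_false(any(sim$hypnogram$labels == "CATAPLEXY"))
  }
})

test_that("cataplexy bouts require 40 s prior wake or chain onto one", {
  cfg <- session_config("narcoleptic", duration_s = 7200, odor_onset_s = NULL,
                        seed = 5)
  sim <- generate_hypnogram(cfg, state_model(cataplexy_hazard = 0.3))
  b <- sim$bouts
  cat_idx <- which(b$state == "CATAPLEXY")
  expect_gt(length(cat_idx), 0)
  labels <- rep(b$state, times = b$end_epoch - b$start_epoch)
  for (i in cat_idx) {
    s <- b$start_epoch[i]
    expect_gte(b$end_epoch[i] - s, 2)  # >= 8 s
    prior_wake <- s >= 10 && all(labels[(s - 9):s] %in% c("AW", "QW"))
    chained <- FALSE
    earlier <- cat_idx[cat_idx < i]
    if (length(earlier) > 0) {
      pe <- max(b$end_epoch[earlier])
      chained <- (s - pe) < 10 &&
        all(labels[seq(pe + 1, s)] %in% c("AW", "QW"))
    }
    expect_true(prior_wake || chained)
  }
  # EC only inside odor windows: undisturbed session has no EC ground truth
  expect_false(any(b$gt_label == "EC"))
})

test_that("state occupancy matches an independent semi-Markov oracle", {
  # Oracle: minimal epoch-level simulator written here, run as 10
  # independent replicates; the generator's occupancy must fall within 3
  # replicate-SDs of the oracle mean.
  model <- state_model("control", cataplexy_hazard = 0)
  n_ep <- 1e5
  oracle_run <- function(seed) {
    set.seed(seed)
    counts <- c(AW = 0, QW = 0, NREMS = 0, REMS = 0)
    state <- "AW"; done <- 0
    while (done < n_ep) {
      len <- min(max(1, ceiling(rexp(1, 4 / model$mean_bout_duration_s[[state]]))),
                 n_ep - done)
      counts[state] <- counts[state] + len
      done <- done + len
      w <- model$transition_weights[[state]]
      state <- sample(names(w), 1, prob = w)
    }
    counts / n_ep
  }
  oracle <- t(vapply(1:10, oracle_run, numeric(4)))
  cfg <- session_config("control", duration_s = n_ep * 4, odor_onset_s = NULL,
                        seed = 31)
  sim <- generate_hypnogram(cfg, model)
  occ <- table(factor(sim$hypnogram$labels, c("AW", "QW", "NREMS", "REMS"))) / n_ep
  for (s in colnames(oracle)) {
    expect_lt(abs(occ[[s]] - mean(oracle[, s])), 3 * sd(oracle[, s]) + 1e-12)
  }
})

test_that("epoch features separate states as constructed", {
  hyp <- hypnogram(rep("NREMS", 50))
  f <- generate_epoch_features(hyp, feature_params(sigma = 0.2), seed = 3)
  expect_true(all(tapply(f$delta_power - f$theta_power, rep(1, 50), mean) > 0))
  # cataplexy shares the REMS atonia EMG distribution by construction
  fp <- feature_params()
  expect_identical(fp$states$CATAPLEXY$emg, fp$states$REMS$emg)
  expect_false(fp$states$CATAPLEXY$move)
})

test_that("noise-free features round-trip through score_epochs exactly", {
  cfg <- session_config("narcoleptic", duration_s = 14400, odor_onset_s = 10800,
                        seed = 17)
  sim <- generate_hypnogram(cfg)
  f <- generate_epoch_features(sim, feature_params(sigma = 0), seed = 17)
  rec <- score_epochs(f, score_thresholds(), cfg$epoch_s)
  expect_identical(rec$labels, sim$hypnogram$labels)
})

test_that("traces reduce to the baseline when rates and noise are zero", {
  cfg <- session_config("narcoleptic", n_cells = 1, duration_s = 400,
                        odor_onset_s = NULL, seed = 2)
  sim <- generate_hypnogram(cfg)
  tun <- list(cell_tuning("c1", "unscored_flat",
                          setNames(rep(0, 7),
                                   c("AW", "QW", "NREMS", "REMS", "HAW", "SC", "EC"))))
  tr <- generate_traces(sim, tun, cfg, trace_params(noise_sd = 0))
  expect_true(all(tr$traces$values == 100))
  expect_length(tr$event_frames[["c1"]], 0)
})

test_that("the transient kernel rises fast and decays slowly", {
  p <- trace_params(tau_r = 0.2, tau_d = 1.5)
  k <- sleepscope:::transient_kernel(p, 10)
  peak <- which.max(k)
  # analytic argmax log(tau_d/tau_r) * tau_r*tau_d/(tau_d - tau_r) = 0.465 s
  expect_lte((peak - 1) / 10, 5 * p$tau_r)
  expect_gt(peak, 1)
  # decay is slower than rise: falling back to half-maximum takes at least
  # twice as long as the whole onset-to-peak rise
  decay_half <- peak + which(k[(peak + 1):length(k)] < 0.5)[1]
  expect_gt(decay_half - peak, 2 * (peak - 1))
  expect_error(trace_params(tau_r = 2, tau_d = 1), "tau_r")
})

test_that("event counts follow the configured state-conditioned rates", {
  cfg <- session_config("narcoleptic", n_cells = 1, duration_s = 1800,
                        odor_onset_s = NULL, seed = 13)
  sim <- generate_hypnogram(cfg)
  rates <- setNames(rep(0.01, 7), c("AW", "QW", "NREMS", "REMS", "HAW", "SC", "EC"))
  rates["REMS"] <- 0.5
  tun <- list(cell_tuning("c1", "REMS_ON", rates))
  tr <- generate_traces(sim, tun, cfg, trace_params())
  fpe <- 40
  b <- sim$bouts
  rems_frames <- unlist(lapply(which(b$state == "REMS"), function(i) {
    seq(b$start_epoch[i] * fpe, b$end_epoch[i] * fpe - 1)
  }))
  expect_gt(length(rems_frames), 1000)
  n_in_rems <- sum(tr$event_frames[["c1"]] %in% rems_frames)
  lambda <- 0.5 * length(rems_frames) / 10
  expect_lt(abs(n_in_rems - lambda), 3 * sqrt(lambda))
})

test_that("identical config and seed reproduce identical output", {
  cfg <- session_config("narcoleptic", n_cells = 5, duration_s = 1200,
                        odor_onset_s = 800, odor_duration_s = 400, seed = 77)
  s1 <- simulate_session(cfg)
  s2 <- simulate_session(cfg)
  expect_identical(s1$sim_hyp$hypnogram$labels, s2$sim_hyp$hypnogram$labels)
  expect_identical(s1$traces$values, s2$traces$values)
  expect_identical(s1$features, s2$features)
})

test_that("peak-count proxy increases with the configured event rate", {
  counts <- vapply(c(0.05, 0.2, 0.8), function(rate) {
    cfg <- session_config("narcoleptic", n_cells = 1, duration_s = 1800,
                          odor_onset_s = NULL, seed = 55)
    sim <- generate_hypnogram(cfg)
    rates <- setNames(rep(rate, 7),
                      c("AW", "QW", "NREMS", "REMS", "HAW", "SC", "EC"))
    tr <- generate_traces(sim, list(cell_tuning("c1", "unscored_flat", rates)),
                          cfg, trace_params())
    z <- compute_zscore(compute_dff(tr$traces))
    length(detect_peaks(z, threshold_frac = 0.3)[[1]]$peak_frames)
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("session artifacts round-trip through the CSV/JSON writers", {
  cfg <- session_config("control", n_cells = 3, duration_s = 800,
                        odor_onset_s = 400, odor_duration_s = 400, seed = 9)
  sim <- simulate_session(cfg)
  dir <- tempfile("sess")
  on.exit(unlink(dir, recursive = TRUE))
  files <- write_session_csv(sim, dir)
  expect_true(all(file.exists(files)))
  hyp <- read_hypnogram_csv(files[["hypnogram"]])
  expect_identical(hyp$labels, sim$sim_hyp$hypnogram$labels)
  cfg2 <- read_session_config(files[["config"]])
  expect_identical(cfg2$genotype, cfg$genotype)
  expect_equal(cfg2$odor_onset_s, cfg$odor_onset_s)
  tr <- read_traces_csv(files[["traces"]], kind = "raw")
  expect_equal(tr$values, sim$traces$values, tolerance = 1e-12)
})
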