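# Epoch scoring, bout segmentation, cataplexy validation and the
# hyperactive-wake / cataplexy-subtype rules.

#' Hypnogram container
#'
#' Per-epoch behavioral-state labels at fixed epoch resolution. The label
#' vocabulary is closed: AW, QW, NREMS, REMS, CATAPLEXY.
#'
#' @param labels Character vector of per-epoch states.
#' @param epoch_s Epoch length in seconds (default 4).
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(labels, epoch_s = 4) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), state_vocab())
  if (length(bad) > 0) stop("unknown state labels: ", paste(bad, collapse = ", "))
  structure(list(labels = labels, epoch_s = epoch_s,
                 n_epochs = length(labels)),
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tb <- table(factor(x$labels, levels = state_vocab()))
  cat(sprintf("<hypnogram: %d epochs x %gs [%s]>\n", x$n_epochs, x$epoch_s,
              paste(names(tb), tb, sep = ":", collapse = " ")))
  invisible(x)
}

#' Write/read a hypnogram CSV (epoch_index, state)
#' @param hyp A `hypnogram`.
#' @param path File path.
#' @export
write_hypnogram_csv <- function(hyp, path) {
  utils::write.csv(data.frame(epoch_index = seq_len(hyp$n_epochs) - 1L,
                              state = hyp$labels),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram_csv
#' @param epoch_s Epoch length in seconds.
#' @export
read_hypnogram_csv <- function(path, epoch_s = 4) {
  df <- utils::read.csv(path)
  hypnogram(df$state, epoch_s)
}

#' Scoring thresholds
#'
#' Decision thresholds for [score_epochs()], in the units of the epoch
#' features. `emg_wake` separates wake from sleep, `emg_active` marks
#' unambiguous active wake, `emg_atonia` marks nuchal atonia (set near the
#' upper tail of REMS EMG), and `theta_ratio` is the minimum theta/delta
#' ratio for a REMS/cataplexy candidate.
#'
#' @param emg_wake,emg_active,emg_atonia EMG RMS cutoffs.
#' @param theta_ratio Theta-to-delta power ratio cutoff.
#' @return List of thresholds, class `score_thresholds`.
#' @export
score_thresholds <- function(emg_wake = 1.0, emg_active = 2.0,
                             emg_atonia = 0.3, theta_ratio = 2.0) {
  structure(list(emg_wake = emg_wake, emg_active = emg_active,
                 emg_atonia = emg_atonia, theta_ratio = theta_ratio),
            class = "score_thresholds")
}

#' Score epochs into behavioral states
#'
#' Rule-based scoring of 4 s epochs from EEG/EMG summary features:
#' high EMG means wake (split into AW vs QW by the movement flag or very
#' high EMG); low EMG with delta-dominant EEG means NREMS; atonic EMG with
#' a theta-dominant EEG marks a REMS/cataplexy candidate, resolved by
#' [validate_cataplexy()] using the waking context (candidates qualifying
#' as cataplexy keep that label, the rest become REMS or QW). Remaining
#' low-EMG epochs default to QW.
#'
#' @param features Data frame with `delta_power`, `theta_power`, `emg_rms`,
#'   `movement_flag` per epoch.
#' @param thresholds A [score_thresholds()] object.
#' @param epoch_s Epoch length in seconds.
#' @return A [hypnogram()].
#' @export
score_epochs <- function(features, thresholds = score_thresholds(), epoch_s = 4) {
  need <- c("delta_power", "theta_power", "emg_rms", "movement_flag")
  missing_ch <- setdiff(need, names(features))
  if (length(missing_ch) > 0) {
    stop("missing feature channels: ", paste(missing_ch, collapse = ", "))
  }
  th <- thresholds
  n <- nrow(features)
  lab <- character(n)
  wake <- features$emg_rms >= th$emg_wake
  active <- wake & (features$movement_flag | features$emg_rms >= th$emg_active)
  candidate <- !wake & features$emg_rms < th$emg_atonia &
    features$theta_power / features$delta_power >= th$theta_ratio
  nrem <- !wake & !candidate & features$delta_power > features$theta_power
  lab[wake] <- "QW"
  lab[active] <- "AW"
  lab[candidate] <- "CATAPLEXY"   # provisional candidate
  lab[nrem] <- "NREMS"
  lab[lab == ""] <- "QW"
  hyp <- hypnogram(lab, epoch_s)
  bouts <- segment_bouts(hyp)
  validated <- validate_cataplexy(bouts, features, thresholds)
  hypnogram(rep(validated$state, times = validated$end_epoch - validated$start_epoch),
            epoch_s)
}

#' Segment a hypnogram into maximal bouts
#'
#' Maximal runs of identical labels; half-open, 0-based epoch and frame
#' intervals. The bouts tile the recording without overlap.
#'
#' @param hyp A [hypnogram()].
#' @param frame_rate_hz Imaging rate used to derive frame ranges.
#' @return A `bout_table` data frame with columns `state`, `label`,
#'   `start_epoch`, `end_epoch`, `start_frame`, `end_frame`, `start_s`,
#'   `duration_s`, `flagged`. `label` starts equal to `state` and is later
#'   refined to AWO/HAW/SC/EC.
#' @export
segment_bouts <- function(hyp, frame_rate_hz = 10) {
  stopifnot(inherits(hyp, "hypnogram"))
  r <- rle(hyp$labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  fpe <- as.integer(round(frame_rate_hz * hyp$epoch_s))
  out <- data.frame(state = r$values, label = r$values,
                    start_epoch = as.integer(starts), end_epoch = as.integer(ends),
                    start_frame = as.integer(starts * fpe),
                    end_frame = as.integer(ends * fpe),
                    start_s = starts * hyp$epoch_s,
                    duration_s = r$lengths * hyp$epoch_s,
                    flagged = FALSE,
                    stringsAsFactors = FALSE)
  structure(out, epoch_s = hyp$epoch_s, frame_rate_hz = frame_rate_hz,
            n_epochs = hyp$n_epochs,
            class = c("bout_table", "data.frame"))
}

rebuild_bouts <- function(states, template) {
  hyp <- hypnogram(states, attr(template, "epoch_s"))
  segment_bouts(hyp, attr(template, "frame_rate_hz"))
}

bout_epoch_states <- function(bouts) {
  rep(bouts$state, times = bouts$end_epoch - bouts$start_epoch)
}

#' Validate candidate cataplexy bouts
#'
#' A candidate run of atonic, theta-dominant epochs qualifies as cataplexy
#' iff (1) it lasts at least 8 s (2 epochs) with atonic EMG throughout,
#' (2) the movement flag is false throughout, (3) theta exceeds delta
#' throughout, and (4) the 40 s immediately preceding are all wake (AW/QW)
#' -- or the candidate starts within 40 s of the end of a qualifying
#' cataplexy bout with only wake epochs in the gap (sequential chaining).
#' Non-qualifying candidates are relabeled REMS when preceded by NREMS,
#' otherwise QW.
#'
#' @param bouts A `bout_table` containing candidate CATAPLEXY bouts.
#' @param features The per-epoch feature data frame.
#' @param thresholds A [score_thresholds()] object.
#' @return A re-segmented `bout_table` with only qualifying CATAPLEXY runs.
#' @export
validate_cataplexy <- function(bouts, features, thresholds = score_thresholds()) {
  stopifnot(inherits(bouts, "bout_table"))
  epoch_s <- attr(bouts, "epoch_s")
  min_ep <- ceiling(8 / epoch_s)
  wake_ep <- ceiling(40 / epoch_s)
  states <- bout_epoch_states(bouts)
  # Wake context is judged on the labels as scored: a relabeled candidate
  # must never manufacture the prior-wake context for a later candidate.
  orig <- states
  qualified_ends <- integer(0)  # end epochs of qualifying bouts

  idx <- which(bouts$state == "CATAPLEXY")
  for (i in idx) {
    s <- bouts$start_epoch[i]; e <- bouts$end_epoch[i]
    eps <- (s + 1):e
    ok <- (e - s) >= min_ep &&
      all(features$emg_rms[eps] < thresholds$emg_atonia) &&
      all(!features$movement_flag[eps]) &&
      all(features$theta_power[eps] > features$delta_power[eps])
    if (ok) {
      prior_wake <- s >= wake_ep &&
        all(orig[(s - wake_ep + 1):s] %in% wake_states())
      chained <- FALSE
      if (!prior_wake && length(qualified_ends) > 0) {
        pe <- max(qualified_ends)
        chained <- pe <= s && (s - pe) < wake_ep &&
          (pe == s || all(orig[(pe + 1):s] %in% wake_states()))
      }
      ok <- prior_wake || chained
    }
    if (ok) {
      qualified_ends <- c(qualified_ends, e)
    } else {
      prev_state <- if (s > 0) orig[s] else NA_character_
      states[(s + 1):e] <- if (identical(prev_state, "NREMS")) "REMS" else "QW"
    }
  }
  rebuild_bouts(states, bouts)
}

#' Label post-odor active-wake bouts as AWO or hyperactive (HAW)
#'
#' The baseline is the grand mean Z-score over all frames of all pre-odor
#' AW bouts, pooled across cells. For each post-odor AW bout, the per-cell
#' mean Z within the bout is tested against that baseline with a one-sided
#' one-sample t test; a significant elevation (p < `alpha`) marks the bout
#' hyperactive (HAW), otherwise it is ordinary post-odor active wake (AWO).
#'
#' @param bouts A validated `bout_table`.
#' @param zmat A `trace_matrix` of kind "zscore" aligned to the bouts.
#' @param odor_onset_s Odor onset in seconds; `NULL` leaves bouts untouched.
#' @param alpha Significance level (default 0.05).
#' @return The `bout_table` with post-odor AW bouts labeled AWO/HAW and a
#'   `haw_p` column; attribute `baseline_mu` records the pooled baseline.
#' @export
label_haw <- function(bouts, zmat, odor_onset_s, alpha = 0.05) {
  stopifnot(inherits(bouts, "bout_table"), inherits(zmat, "trace_matrix"))
  if (zmat$kind != "zscore") stop("label_haw needs Z-scored traces")
  bouts$haw_p <- NA_real_
  if (is.null(odor_onset_s)) return(bouts)
  aw <- bouts$state == "AW"
  pre <- aw & bouts$start_s < odor_onset_s
  post <- aw & bouts$start_s >= odor_onset_s
  if (!any(pre)) stop("no pre-odor AW bouts: baseline undefined")
  base_frames <- unlist(lapply(which(pre), function(i) {
    (bouts$start_frame[i] + 1):bouts$end_frame[i]
  }))
  mu <- mean(zmat$values[, base_frames])
  for (i in which(post)) {
    frames <- (bouts$start_frame[i] + 1):bouts$end_frame[i]
    per_cell <- rowMeans(zmat$values[, frames, drop = FALSE])
    if (length(per_cell) < 2) {
      bouts$label[i] <- "AWO"
      next
    }
    tt <- one_sample_t(per_cell, mu, "greater")
    bouts$haw_p[i] <- tt$p
    bouts$label[i] <- if (tt$p < alpha && tt$mean > mu) "HAW" else "AWO"
  }
  attr(bouts, "baseline_mu") <- mu
  bouts
}

#' Subtype cataplexy bouts as spontaneous (SC) or emotion-induced (EC)
#'
#' For each cataplexy bout the nearest preceding active-wake-family bout
#' (AW, AWO or HAW), skipping quiet wake, decides the subtype: a preceding
#' HAW makes it emotion-induced (EC); a preceding undisturbed AW -- or an
#' AWO that failed the hyperactivity test -- makes it spontaneous (SC).
#' Bouts chained onto an earlier cataplexy bout (gap < 40 s, all wake)
#' inherit the type of the chain's first bout. Post-odor bouts whose
#' nearest AW-family bout started before odor onset are flagged for review.
#'
#' @param bouts A `bout_table` after [label_haw()].
#' @param odor_onset_s Odor onset in seconds, or `NULL`.
#' @return The `bout_table` with CATAPLEXY bouts labeled SC/EC.
#' @export
label_cataplexy_type <- function(bouts, odor_onset_s = NULL) {
  stopifnot(inherits(bouts, "bout_table"))
  epoch_s <- attr(bouts, "epoch_s")
  wake_ep <- ceiling(40 / epoch_s)
  wake_fam <- c(wake_states(), aw_family())
  last_cat <- NULL  # list(end_epoch, type)
  for (i in which(bouts$state == "CATAPLEXY")) {
    s <- bouts$start_epoch[i]
    chained <- FALSE
    if (!is.null(last_cat)) {
      gap_idx <- which(bouts$start_epoch >= last_cat$end & bouts$end_epoch <= s)
      chained <- (s - last_cat$end) < wake_ep &&
        all(bouts$label[gap_idx] %in% wake_fam)
    }
    if (chained) {
      bouts$label[i] <- last_cat$type
    } else {
      type <- NA_character_
      for (j in rev(seq_len(i - 1))) {
        if (bouts$label[j] %in% aw_family()) {
          type <- switch(bouts$label[j], HAW = "EC", AW = "SC", AWO = "SC")
          if (!is.null(odor_onset_s) && bouts$start_s[i] >= odor_onset_s &&
              bouts$start_s[j] < odor_onset_s) {
            bouts$flagged[i] <- TRUE
          }
          break
        }
      }
      if (is.na(type)) {
        stop("cataplexy bout at epoch ", s, " has no preceding wake bout")
      }
      bouts$label[i] <- type
    }
    last_cat <- list(end = bouts$end_epoch[i], type = bouts$label[i])
  }
  bouts
}

#' Bout durations with group comparison
#'
#' Collects bout durations (seconds) for the requested derived labels and,
#' when both groups have at least two bouts, compares them with a
#' closed-form one-way ANOVA.
#'
#' @param bouts A labeled `bout_table`.
#' @param labels Derived labels to collect (default SC vs EC).
#' @return List with `durations` (named list), `summary` (label, n, mean,
#'   SEM) and `anova` (`NULL` when undefined).
#' @export
bout_durations <- function(bouts, labels = c("SC", "EC")) {
  stopifnot(inherits(bouts, "bout_table"))
  durations <- lapply(labels, function(l) bouts$duration_s[bouts$label == l])
  names(durations) <- labels
  summary <- data.frame(
    label = labels,
    n = vapply(durations, length, integer(1)),
    mean_s = vapply(durations, function(d) if (length(d)) mean(d) else NA_real_, numeric(1)),
    sem_s = vapply(durations, sem, numeric(1)),
    row.names = NULL)
  anova <- NULL
  if (all(summary$n >= 2)) anova <- oneway_anova(durations)
  list(durations = durations, summary = summary, anova = anova)
}

#' Write a labeled bout table to CSV
#'
#' @param bouts A `bout_table`.
#' @param path Output path.
#' @export
write_bouts_csv <- function(bouts, path) {
  cols <- c("state", "label", "start_epoch", "end_epoch", "start_s",
            "duration_s", "flagged")
  utils::write.csv(as.data.frame(bouts)[, cols], path, row.names = FALSE)
  invisible(path)
}
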