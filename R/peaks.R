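# Prominent calcium transient peak detection and peak statistics.

# Local maxima of a numeric vector: strictly greater than both neighbors,
# plateaus contribute their leftmost frame, boundary frames are eligible.
local_maxima <- function(y) {
  n <- length(y)
  if (n == 1) return(1L)
  keep <- logical(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && y[j + 1] == y[i]) j <- j + 1L  # plateau [i, j]
    left_ok <- i == 1L || y[i - 1] < y[i]
    right_ok <- j == n || y[j + 1] < y[i]
    if (left_ok && right_ok) keep[i] <- TRUE
    i <- j + 1L
  }
  which(keep)
}

#' Detect prominent calcium transient peaks
#'
#' Candidate peaks are local maxima of a cell's Z-score trace whose value
#' reaches `threshold_frac` (default 80%) of that cell's maximum Z over the
#' whole recording. A minimum interval between adjacent peaks (default 2 s)
#' is enforced by amplitude-priority greedy selection: candidates are
#' accepted in decreasing amplitude order (ties to the earlier frame) and
#' any candidate closer than the minimum interval to an accepted peak is
#' rejected, preserving the most prominent transients.
#'
#' @param zmat A `trace_matrix` of kind "zscore".
#' @param min_interval_s Minimum spacing between adjacent peaks, seconds.
#' @param threshold_frac Fraction of the per-cell maximum Z (default 0.8).
#' @return A list of `peak_train` objects (one per cell) with 0-based
#'   `peak_frames`, `peak_amplitudes`, `threshold_used` and a `degenerate`
#'   flag for cells whose maximum Z is nonpositive.
#' @export
detect_peaks <- function(zmat, min_interval_s = 2.0, threshold_frac = 0.8) {
  stopifnot(inherits(zmat, "trace_matrix"))
  if (zmat$kind != "zscore") stop("detect_peaks needs Z-scored traces")
  min_frames <- as.integer(round(min_interval_s * zmat$frame_rate_hz))
  out <- lapply(seq_len(nrow(zmat$values)), function(i) {
    y <- zmat$values[i, ]
    mx <- max(y)
    if (mx <= 0) {
      return(structure(list(cell_id = zmat$cell_ids[i],
                            peak_frames = integer(0),
                            peak_amplitudes = numeric(0),
                            threshold_used = NA_real_, degenerate = TRUE),
                       class = "peak_train"))
    }
    thr <- threshold_frac * mx
    cand <- local_maxima(y)
    cand <- cand[y[cand] >= thr]
    ord <- cand[order(-y[cand], cand)]
    accepted <- integer(0)
    for (f in ord) {
      if (length(accepted) == 0 || all(abs(accepted - f) >= min_frames)) {
        accepted <- c(accepted, f)
      }
    }
    accepted <- sort(accepted)
    structure(list(cell_id = zmat$cell_ids[i],
                   peak_frames = accepted - 1L,
                   peak_amplitudes = unname(y[accepted]),
                   threshold_used = thr, degenerate = FALSE),
              class = "peak_train")
  })
  names(out) <- zmat$cell_ids
  out
}

#' @export
print.peak_train <- function(x, ...) {
  cat(sprintf("<peak_train %s: %d peaks, threshold %.3g%s>\n", x$cell_id,
              length(x$peak_frames), x$threshold_used,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Per-cell, per-state peak statistics
#'
#' Assigns each peak to the bout containing its frame and reports, per cell
#' and bout label, the peak frequency (peaks per minute of scored state
#' time) and mean peak amplitude. States with zero scored time are absent
#' from the output rather than reported as zero.
#'
#' @param trains List of `peak_train` objects from [detect_peaks()].
#' @param bouts A labeled `bout_table`.
#' @return Data frame with `cell_id`, `state`, `n_peaks`,
#'   `frequency_per_min`, `mean_amplitude`.
#' @export
peak_stats_by_state <- function(trains, bouts) {
  stopifnot(inherits(bouts, "bout_table"))
  labels <- unique(bouts$label)
  minutes <- vapply(labels, function(l) {
    sum(bouts$duration_s[bouts$label == l]) / 60
  }, numeric(1))
  rows <- list()
  for (tr in trains) {
    if (tr$degenerate) next
    # locate the bout containing each peak frame (0-based, half-open bouts)
    bout_of <- findInterval(tr$peak_frames, bouts$start_frame)
    peak_label <- bouts$label[bout_of]
    for (l in labels) {
      sel <- peak_label == l
      rows[[length(rows) + 1]] <- data.frame(
        cell_id = tr$cell_id, state = l, n_peaks = sum(sel),
        frequency_per_min = sum(sel) / minutes[[l]],
        mean_amplitude = if (any(sel)) mean(tr$peak_amplitudes[sel]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write peak trains to CSV (cell_id, frame, time_s, amplitude)
#' @param trains List of `peak_train` objects.
#' @param path Output path.
#' @param frame_rate_hz Imaging rate for the time column.
#' @export
write_peaks_csv <- function(trains, path, frame_rate_hz = 10) {
  rows <- lapply(trains, function(tr) {
    if (length(tr$peak_frames) == 0) return(NULL)
    data.frame(cell_id = tr$cell_id, frame = tr$peak_frames,
               time_s = tr$peak_frames / frame_rate_hz,
               amplitude = tr$peak_amplitudes, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cell_id = character(0), frame = integer(0),
                      time_s = numeric(0), amplitude = numeric(0))
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
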