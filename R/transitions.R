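# Time-normalized activity profiles across wake-to-cataplexy transitions.

#' Normalized-time transition activity profile
#'
#' For each selected cataplexy bout, each member cell's Z-score trace
#' within the bout is resampled to 101 points (0-100% of bout duration,
#' inclusive) by linear interpolation at fractional frame positions; the
#' profile averages across cells first, then across bouts, so every bout
#' carries equal weight regardless of duration. A native-time pre-onset
#' window (mean Z per frame over `pre_window_s` before bout onset,
#' truncated at the recording start) is returned alongside.
#'
#' @param zmat A `trace_matrix` of kind "zscore".
#' @param bouts A labeled `bout_table`.
#' @param profiles A `cell_profiles` data frame (used to resolve
#'   `group`), or `NULL` when `group` is a vector of cell ids.
#' @param group Group selector: a category name (e.g. "unscored",
#'   "REMS_ON"), one of the flags "HAW_ON"/"EC_ON", or a character vector
#'   of cell ids.
#' @param bout_label Which cataplexy subtype to profile ("EC" or "SC").
#' @param pre_window_s Pre-onset window length, seconds.
#' @return An object of class `transition_profile` with `bout_profile`
#'   (length 101), `sem_profile`, `pre_window`, `n_cells`, `n_bouts`.
#' @export
transition_profile <- function(zmat, bouts, profiles = NULL, group,
                               bout_label = "EC", pre_window_s = 60) {
  stopifnot(inherits(zmat, "trace_matrix"), inherits(bouts, "bout_table"))
  cells <- resolve_group(group, profiles, zmat$cell_ids)
  if (length(cells) == 0) stop("empty cell group")
  rows <- match(cells, zmat$cell_ids)
  sel <- which(bouts$label %in% bout_label)
  sel <- sel[(bouts$end_frame[sel] - bouts$start_frame[sel]) >= 2]
  if (length(sel) == 0) stop("no ", paste(bout_label, collapse = "/"),
                             " bout with at least 2 frames")
  pts <- seq(0, 100)
  pre_n <- as.integer(round(pre_window_s * zmat$frame_rate_hz))

  bout_profiles <- matrix(NA_real_, nrow = length(sel), ncol = 101)
  pre_rows <- matrix(NA_real_, nrow = length(sel), ncol = pre_n)
  for (k in seq_along(sel)) {
    i <- sel[k]
    frames <- (bouts$start_frame[i] + 1):bouts$end_frame[i]
    L <- length(frames)
    xout <- pts / 100 * (L - 1)
    cellwise <- vapply(rows, function(r) {
      stats::approx(x = 0:(L - 1), y = zmat$values[r, frames], xout = xout)$y
    }, numeric(101))
    bout_profiles[k, ] <- rowMeans(cellwise)
    pre_from <- bouts$start_frame[i] - pre_n
    avail <- max(0, pre_from):(bouts$start_frame[i] - 1)
    avail <- avail[avail >= 0]
    if (length(avail) > 0) {
      vals <- colMeans(zmat$values[rows, avail + 1, drop = FALSE])
      pre_rows[k, (pre_n - length(avail) + 1):pre_n] <- vals
    }
  }
  structure(list(
    group_label = if (is.character(group) && length(group) == 1) group else "custom",
    bout_label = paste(bout_label, collapse = "/"),
    normalized_pct = pts,
    bout_profile = colMeans(bout_profiles),
    sem_profile = apply(bout_profiles, 2, sem),
    pre_window = colMeans(pre_rows, na.rm = TRUE),
    pre_window_s = pre_window_s,
    n_cells = length(cells), n_bouts = length(sel)),
    class = "transition_profile")
}

resolve_group <- function(group, profiles, all_ids) {
  if (length(group) == 0) return(character(0))
  if (length(group) > 1 || group %in% all_ids) {
    return(intersect(group, all_ids))
  }
  if (is.null(profiles)) stop("profiles needed to resolve group '", group, "'")
  if (group == "HAW_ON") return(profiles$cell_id[profiles$haw_on])
  if (group == "EC_ON") return(profiles$cell_id[profiles$ec_on])
  profiles$cell_id[profiles$category == group]
}

#' @export
print.transition_profile <- function(x, ...) {
  cat(sprintf("<transition_profile: %s cells over %s bouts (n_cells=%d, n_bouts=%d), mean Z %.3f>\n",
              x$group_label, x$bout_label, x$n_cells, x$n_bouts,
              mean(x$bout_profile)))
  invisible(x)
}

#' @export
plot.transition_profile <- function(x, ...) {
  graphics::plot(x$normalized_pct, x$bout_profile, type = "l", lwd = 2,
                 xlab = "% of bout duration", ylab = "mean Z-score",
                 main = sprintf("%s during %s", x$group_label, x$bout_label), ...)
  if (any(!is.na(x$sem_profile))) {
    graphics::lines(x$normalized_pct, x$bout_profile + x$sem_profile, lty = 3)
    graphics::lines(x$normalized_pct, x$bout_profile - x$sem_profile, lty = 3)
  }
  invisible(x)
}

#' Write a transition profile to CSV
#' @param tp A `transition_profile`.
#' @param path Output path.
#' @export
write_transition_csv <- function(tp, path) {
  utils::write.csv(data.frame(group = tp$group_label,
                              normalized_pct = tp$normalized_pct,
                              mean_z = tp$bout_profile,
                              sem_z = tp$sem_profile),
                   path, row.names = FALSE)
  invisible(path)
}
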