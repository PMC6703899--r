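# ON-cell classification against the quiet-wake baseline, ANOVA
# verification, composition summaries and percent-of-max heat maps.

# States that define the pre-odor (undisturbed) category of a cell.
pre_odor_states <- function() c("AW", "REMS", "NREMS", "SC")

state_frame_index <- function(bouts, label) {
  rows <- which(bouts$label == label)
  if (length(rows) == 0) return(integer(0))
  unlist(lapply(rows, function(i) (bouts$start_frame[i] + 1):bouts$end_frame[i]))
}

#' Classify cells as state-ON against the quiet-wake baseline
#'
#' For every cell and scored state, the state mean is the mean Z-score over
#' all frames of all bouts carrying that label. A cell is "ON" in a state
#' when its state mean is greater than or equal to its own quiet-wake mean
#' plus one Z-score unit (boundary inclusive). The reported pre-odor
#' category is mutually exclusive: cells ON in both REMS and AW are
#' REMS_AW_ON; otherwise the precedence is REMS, AW, SC, NREMS (so a cell
#' ON in both spontaneous cataplexy and NREMS reports as SC_ON, with the
#' overlap retained in `on_states`); cells ON in no pre-odor state are
#' unscored. EC-ON and HAW-ON are additional non-exclusive flags.
#'
#' @param zmat A `trace_matrix` of kind "zscore".
#' @param bouts A labeled `bout_table` (after [label_haw()] and
#'   [label_cataplexy_type()] where applicable).
#' @param on_margin ON threshold above the QW baseline, Z units (default 1).
#' @return A `cell_profiles` data frame: `cell_id`, one `mean_<state>`
#'   column per scored state, `z_qw`, `max_z`, `on_states`
#'   (comma-separated), `category`, `ec_on`, `haw_on`.
#' @export
classify_cells <- function(zmat, bouts, on_margin = 1) {
  stopifnot(inherits(zmat, "trace_matrix"), inherits(bouts, "bout_table"))
  if (zmat$kind != "zscore") stop("classify_cells needs Z-scored traces")
  states <- intersect(c("AW", "QW", "NREMS", "REMS", "SC", "EC", "HAW", "AWO"),
                      unique(bouts$label))
  if (!"QW" %in% states) stop("no QW bouts: baseline undefined")
  frames_by_state <- lapply(states, function(s) state_frame_index(bouts, s))
  names(frames_by_state) <- states
  means <- vapply(states, function(s) {
    rowMeans(zmat$values[, frames_by_state[[s]], drop = FALSE])
  }, numeric(nrow(zmat$values)))
  if (is.null(dim(means))) means <- matrix(means, nrow = 1, dimnames = list(NULL, states))
  z_qw <- means[, "QW"]
  on <- means >= z_qw + on_margin

  pre <- intersect(pre_odor_states(), states)
  category <- character(nrow(means))
  on_states <- character(nrow(means))
  for (i in seq_len(nrow(means))) {
    on_i <- states[on[i, ]]
    on_states[i] <- paste(on_i, collapse = ",")
    pre_on <- intersect(pre, on_i)
    category[i] <- if (all(c("REMS", "AW") %in% pre_on)) {
      "REMS_AW_ON"
    } else if ("REMS" %in% pre_on) {
      "REMS_ON"
    } else if ("AW" %in% pre_on) {
      "AW_ON"
    } else if ("SC" %in% pre_on) {
      "SC_ON"
    } else if ("NREMS" %in% pre_on) {
      "NREMS_ON"
    } else {
      "unscored"
    }
  }
  out <- data.frame(cell_id = zmat$cell_ids, stringsAsFactors = FALSE)
  for (s in states) out[[paste0("mean_", s)]] <- means[, s]
  out$z_qw <- z_qw
  out$max_z <- apply(zmat$values, 1, max)
  out$on_states <- on_states
  out$category <- category
  out$ec_on <- if ("EC" %in% states) on[, "EC"] else FALSE
  out$haw_on <- if ("HAW" %in% states) on[, "HAW"] else FALSE
  structure(out, states = states, on_margin = on_margin,
            class = c("cell_profiles", "data.frame"))
}

#' Confirm ON / non-ON separation by one-way ANOVA
#'
#' For each requested state with at least two ON and two non-ON cells,
#' compares the state-mean Z of the two groups with a closed-form one-way
#' ANOVA; p values are Bonferroni-adjusted for the number of comparisons
#' actually run (capped at 1).
#'
#' @param profiles A `cell_profiles` data frame.
#' @param states States to verify; defaults to all scored states except QW.
#' @return Data frame with `state`, `n_on`, `n_off`, `F`, `df1`, `df2`,
#'   `p`, `p_bonferroni`.
#' @export
verify_on_separation <- function(profiles, states = NULL) {
  stopifnot(inherits(profiles, "cell_profiles"))
  all_states <- setdiff(attr(profiles, "states"), "QW")
  states <- states %||% all_states
  rows <- list()
  for (s in states) {
    col <- paste0("mean_", s)
    if (!col %in% names(profiles)) next
    on <- grepl(paste0("(^|,)", s, "(,|$)"), profiles$on_states)
    if (sum(on) < 2 || sum(!on) < 2) {
      warning("state ", s, ": degenerate group sizes, skipped")
      next
    }
    a <- oneway_anova(list(on = profiles[[col]][on], off = profiles[[col]][!on]))
    rows[[s]] <- data.frame(state = s, n_on = sum(on), n_off = sum(!on),
                            F = a$F, df1 = a$df1, df2 = a$df2, p = a$p)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  rownames(out) <- NULL
  out
}

#' Percentage table from category counts
#'
#' Percentages are 100 x count / total, rounded half-up to two decimals --
#' the convention used throughout the reported summaries.
#'
#' @param counts Named integer vector of category counts.
#' @param total Denominator; defaults to `sum(counts)`.
#' @return Data frame with `category`, `count`, `percent`.
#' @examples
#' fraction_table(c(REMS_ON = 51), total = 207)  # 24.64
#' @export
fraction_table <- function(counts, total = sum(counts)) {
  if (total <= 0) stop("total must be positive")
  data.frame(category = names(counts), count = as.integer(counts),
             percent = round_half_up(100 * as.numeric(counts) / total, 2),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Summarize category composition of a session
#'
#' Counts and percentages of total recorded cells per pre-odor category,
#' plus explicit overlap lines (for example cells ON in both SC and NREMS,
#' which the exclusive category list would otherwise hide).
#'
#' @param profiles A `cell_profiles` data frame.
#' @param group_label Optional label attached to the output.
#' @return List with `fractions` (a [fraction_table()]), `overlaps`,
#'   `n_cells`, `group_label`.
#' @export
summarize_fractions <- function(profiles, group_label = NULL) {
  stopifnot(inherits(profiles, "cell_profiles"))
  if (nrow(profiles) == 0) stop("empty profile list")
  cats <- c("REMS_ON", "AW_ON", "REMS_AW_ON", "NREMS_ON", "SC_ON", "unscored")
  counts <- vapply(cats, function(cc) sum(profiles$category == cc), integer(1))
  on_has <- function(s) grepl(paste0("(^|,)", s, "(,|$)"), profiles$on_states)
  overlaps <- data.frame(
    overlap = c("SC_and_NREMS", "EC_and_HAW"),
    count = c(sum(on_has("SC") & on_has("NREMS")),
              sum(profiles$ec_on & profiles$haw_on)))
  list(fractions = fraction_table(counts, total = nrow(profiles)),
       overlaps = overlaps, n_cells = nrow(profiles),
       group_label = group_label)
}

#' Composition of HAW-ON and EC-ON cells by pre-odor category
#'
#' Cross-tabulates the odor-response flags against the pre-odor categories:
#' one row for HAW-ON cells and one for EC-ON cells, with columns for
#' unscored, AW-ON, REMS-ON/REMS_AW-ON (combined), NREMS-ON/SC-ON
#' (combined) origins plus the EC-ON/HAW-ON cross-membership. Cell values
#' are counts with percentages of the row total.
#'
#' @param profiles A `cell_profiles` data frame with EC/HAW flags.
#' @return An object of class `composition_table` with `counts`, `percent`
#'   matrices and `row_totals`.
#' @export
composition_table <- function(profiles) {
  stopifnot(inherits(profiles, "cell_profiles"))
  col_of <- function(category) {
    switch(category,
      unscored = "unscored",
      AW_ON = "AW_ON",
      REMS_ON = "REMS_or_REMS_AW_ON", REMS_AW_ON = "REMS_or_REMS_AW_ON",
      NREMS_ON = "NREMS_or_SC_ON", SC_ON = "NREMS_or_SC_ON")
  }
  cols <- c("unscored", "AW_ON", "REMS_or_REMS_AW_ON", "NREMS_or_SC_ON", "cross")
  rows <- c("HAW_ON", "EC_ON")
  counts <- matrix(0L, nrow = 2, ncol = length(cols),
                   dimnames = list(rows, cols))
  sel <- list(HAW_ON = profiles$haw_on, EC_ON = profiles$ec_on)
  for (r in rows) {
    sub <- profiles[sel[[r]], , drop = FALSE]
    for (cat in unique(sub$category)) {
      counts[r, col_of(cat)] <- counts[r, col_of(cat)] + sum(sub$category == cat)
    }
    counts[r, "cross"] <- sum(sub$ec_on & sub$haw_on)
  }
  row_totals <- c(HAW_ON = sum(sel$HAW_ON), EC_ON = sum(sel$EC_ON))
  percent <- counts
  for (r in rows) {
    percent[r, ] <- if (row_totals[r] > 0) {
      round_half_up(100 * counts[r, ] / row_totals[r], 2)
    } else {
      0
    }
  }
  structure(list(counts = counts, percent = percent, row_totals = row_totals),
            class = "composition_table")
}

#' @export
print.composition_table <- function(x, ...) {
  cat("Composition of odor-responsive cells (count (% of row total)):\n")
  for (r in rownames(x$counts)) {
    cells <- sprintf("%d (%.2f%%)", x$counts[r, ], x$percent[r, ])
    cat(sprintf("  %s (n=%d): %s\n", r, x$row_totals[r],
                paste(colnames(x$counts), cells, sep = "=", collapse = ", ")))
  }
  invisible(x)
}

#' Percent-of-max activity heat map
#'
#' Expresses each cell's Z-score trace as a percentage of its maximum over
#' the whole recording (clipped below at 0 for display) and orders cells by
#' category then id. Cells with a nonpositive maximum are excluded with a
#' warning.
#'
#' @param zmat A `trace_matrix` of kind "zscore".
#' @param profiles Optional `cell_profiles` used for row ordering.
#' @param bouts Optional `bout_table`; bout boundaries are kept for
#'   annotation by the plot method.
#' @return An object of class `activity_heatmap` with the percent matrix.
#' @export
activity_heatmap <- function(zmat, profiles = NULL, bouts = NULL) {
  stopifnot(inherits(zmat, "trace_matrix"))
  if (zmat$kind != "zscore") stop("activity_heatmap needs Z-scored traces")
  mx <- apply(zmat$values, 1, max)
  keep <- mx > 0
  if (any(!keep)) {
    warning("excluding cells with nonpositive maximum Z: ",
            paste(zmat$cell_ids[!keep], collapse = ", "))
  }
  vals <- zmat$values[keep, , drop = FALSE]
  pct <- pmax(sweep(vals, 1, mx[keep], "/") * 100, 0)
  if (!is.null(profiles)) {
    ord_tab <- profiles[match(rownames(pct), profiles$cell_id), ]
    pct <- pct[order(ord_tab$category, ord_tab$cell_id), , drop = FALSE]
  }
  structure(list(percent = pct,
                 bout_starts = if (!is.null(bouts)) bouts$start_frame else NULL,
                 frame_rate_hz = zmat$frame_rate_hz),
            class = "activity_heatmap")
}

#' @export
plot.activity_heatmap <- function(x, ...) {
  nf <- ncol(x$percent)
  graphics::image(x = seq_len(nf) / x$frame_rate_hz,
                  y = seq_len(nrow(x$percent)),
                  z = t(x$percent),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "time (s)", ylab = "cell", ...)
  if (!is.null(x$bout_starts)) {
    graphics::abline(v = x$bout_starts / x$frame_rate_hz,
                     col = grDevices::adjustcolor("grey30", 0.4))
  }
  invisible(x)
}

#' Write cell profiles to CSV
#' @param profiles A `cell_profiles` data frame.
#' @param path Output path.
#' @export
write_profiles_csv <- function(profiles, path) {
  utils::write.csv(as.data.frame(profiles), path, row.names = FALSE)
  invisible(path)
}
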