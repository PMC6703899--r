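# Bout-conditioned pairwise correlation, Fisher-Z synchrony summaries and
# spatial connectivity maps.

#' Pairwise synchrony within one bout
#'
#' Pearson correlation over the bout's frames for every unordered cell
#' pair, Fisher-Z transformed ([fisher_z()], with near-unit correlations
#' clipped at `1 - 1e-6`). Pairs where either cell has zero variance within
#' the bout are recorded as missing. The per-cell synchrony is the mean
#' Z_R over that cell's positively correlated partners (R > 0) only;
#' `state_mean_zr` averages it over cells with at least one positive
#' partner.
#'
#' @param zmat A `trace_matrix` of kind "zscore".
#' @param bout One-row slice of a `bout_table` (or any list with
#'   `start_frame`, `end_frame`, `label`).
#' @param min_bout_s Minimum bout length in seconds (default 10); shorter
#'   bouts are skipped with a warning and return `NULL`.
#' @return An object of class `synchrony_result` with `R`, `Z_R`,
#'   `per_cell_mean_pos_zr`, `state_mean_zr`, `label`, `n_frames`, or
#'   `NULL` for a too-short bout.
#' @export
boutwise_correlation <- function(zmat, bout, min_bout_s = 10) {
  stopifnot(inherits(zmat, "trace_matrix"))
  if (nrow(zmat$values) < 2) stop("need at least 2 cells")
  frames <- (bout$start_frame + 1):bout$end_frame
  if (length(frames) < min_bout_s * zmat$frame_rate_hz) {
    warning(sprintf("bout at frame %d shorter than %gs: skipped",
                    bout$start_frame, min_bout_s))
    return(NULL)
  }
  x <- t(zmat$values[, frames, drop = FALSE])
  sds <- apply(x, 2, stats::sd)
  R <- suppressWarnings(stats::cor(x))
  R[sds == 0, ] <- NA
  R[, sds == 0] <- NA
  diag(R) <- NA
  Z <- fisher_z(R)
  per_cell <- vapply(seq_len(ncol(R)), function(i) {
    pos <- which(!is.na(R[i, ]) & R[i, ] > 0)
    if (length(pos) == 0) NA_real_ else mean(Z[i, pos])
  }, numeric(1))
  names(per_cell) <- zmat$cell_ids
  structure(list(R = R, Z_R = Z, per_cell_mean_pos_zr = per_cell,
                 state_mean_zr = mean(per_cell, na.rm = TRUE),
                 label = bout$label, start_frame = bout$start_frame,
                 n_frames = length(frames), cell_ids = zmat$cell_ids),
            class = "synchrony_result")
}

#' @export
print.synchrony_result <- function(x, ...) {
  cat(sprintf("<synchrony_result: %s bout @frame %d, %d cells, mean +Z_R = %.4f>\n",
              x$label, x$start_frame, length(x$cell_ids), x$state_mean_zr))
  invisible(x)
}

#' Synchrony for every sufficiently long bout of selected states
#'
#' @param zmat A `trace_matrix` of kind "zscore".
#' @param bouts A labeled `bout_table`.
#' @param labels Bout labels to analyze; default all.
#' @param min_bout_s Minimum bout length in seconds.
#' @return List of `synchrony_result` objects (short bouts omitted).
#' @export
bout_synchrony <- function(zmat, bouts, labels = NULL, min_bout_s = 10) {
  stopifnot(inherits(bouts, "bout_table"))
  labels <- labels %||% unique(bouts$label)
  keep <- bouts$label %in% labels &
    (bouts$end_frame - bouts$start_frame) >= min_bout_s * zmat$frame_rate_hz
  lapply(which(keep), function(i) boutwise_correlation(zmat, bouts[i, ], min_bout_s))
}

#' Per-state synchrony summary with group-by-state comparison
#'
#' Averages `state_mean_zr` unweighted across the bouts of each state and,
#' when results from two or more groups are supplied, compares them with a
#' closed-form two-way (group x state) ANOVA.
#'
#' @param results List of `synchrony_result` objects, or (for a multi-group
#'   comparison) a named list of such lists, one per group.
#' @return List with `table` (group, state, n_bouts, mean_zr, sem_zr) and
#'   `anova` (`NULL` for a single group or degenerate designs).
#' @export
state_summary <- function(results) {
  if (length(results) > 0 && inherits(results[[1]], "synchrony_result")) {
    results <- list(all = results)
  }
  rows <- list()
  for (g in names(results)) {
    for (r in results[[g]]) {
      if (is.null(r)) next
      rows[[length(rows) + 1]] <- data.frame(
        group = g, state = r$label, zr = r$state_mean_zr,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  if (is.null(df)) stop("no valid synchrony results")
  agg <- do.call(rbind, lapply(split(df, list(df$group, df$state), drop = TRUE),
    function(d) data.frame(group = d$group[1], state = d$state[1],
                           n_bouts = nrow(d), mean_zr = mean(d$zr),
                           sem_zr = sem(d$zr), stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  anova <- NULL
  if (length(unique(df$group)) >= 2 && length(unique(df$state)) >= 2) {
    complete <- all(table(df$group, df$state) > 0)
    if (complete) {
      anova <- tryCatch(twoway_anova(df$zr, df$group, df$state),
                        error = function(e) NULL)
    }
  }
  list(table = agg, anova = anova, observations = df)
}

#' Spatial connectivity edges from a synchrony result
#'
#' One edge per unordered cell pair with `R >= r_min` (default 0.6, the
#' strong-positive band rendered from 0.6 blue to 1.0 red on the spatial
#' maps). Cells without centroids are dropped from the map with a warning
#' but remain in the synchrony statistics.
#'
#' @param result A `synchrony_result`.
#' @param centroids Data frame with `cell_id`, `x`, `y`.
#' @param r_min Minimum correlation for an edge.
#' @return An object of class `connectivity_map` with the edge data frame
#'   (`cell_a`, `cell_b`, `R`, `x_a`, `y_a`, `x_b`, `y_b`) and `n_edges`.
#' @export
connectivity_map <- function(result, centroids, r_min = 0.6) {
  stopifnot(inherits(result, "synchrony_result"))
  ids <- result$cell_ids
  have <- ids %in% centroids$cell_id
  if (any(!have)) {
    warning("missing centroids, dropped from map: ",
            paste(ids[!have], collapse = ", "))
  }
  keep_idx <- which(have)
  edges <- list()
  for (ai in seq_along(keep_idx)) {
    for (bi in seq_len(ai - 1L)) {
      i <- keep_idx[ai]; j <- keep_idx[bi]
      r <- result$R[i, j]
      if (!is.na(r) && r >= r_min) {
        a <- min(i, j); b <- max(i, j)
        ca <- centroids[centroids$cell_id == ids[a], ]
        cb <- centroids[centroids$cell_id == ids[b], ]
        edges[[length(edges) + 1]] <- data.frame(
          cell_a = ids[a], cell_b = ids[b], R = r,
          x_a = ca$x, y_a = ca$y, x_b = cb$x, y_b = cb$y,
          stringsAsFactors = FALSE)
      }
    }
  }
  edges <- do.call(rbind, edges)
  if (is.null(edges)) {
    edges <- data.frame(cell_a = character(0), cell_b = character(0),
                        R = numeric(0), x_a = numeric(0), y_a = numeric(0),
                        x_b = numeric(0), y_b = numeric(0))
  }
  structure(list(edges = edges, n_edges = nrow(edges), r_min = r_min,
                 label = result$label,
                 centroids = centroids[centroids$cell_id %in% ids, ]),
            class = "connectivity_map")
}

#' @export
print.connectivity_map <- function(x, ...) {
  cat(sprintf("<connectivity_map: %s bout, %d edges with R >= %g>\n",
              x$label %||% "?", x$n_edges, x$r_min))
  invisible(x)
}

#' @export
plot.connectivity_map <- function(x, ...) {
  graphics::plot(x$centroids$x, x$centroids$y, pch = 16, col = "grey40",
                 xlab = "x (px)", ylab = "y (px)",
                 main = sprintf("%s: %d edges (R >= %g)",
                                x$label %||% "", x$n_edges, x$r_min), ...)
  if (x$n_edges > 0) {
    ramp <- grDevices::colorRamp(c("blue", "red"))
    frac <- pmin(1, pmax(0, (x$edges$R - x$r_min) / (1 - x$r_min)))
    cols <- grDevices::rgb(ramp(frac), maxColorValue = 255)
    graphics::segments(x$edges$x_a, x$edges$y_a, x$edges$x_b, x$edges$y_b,
                       col = cols)
  }
  invisible(x)
}

#' Write connectivity edges to CSV
#' @param map A `connectivity_map`.
#' @param path Output path.
#' @export
write_edges_csv <- function(map, path) {
  utils::write.csv(map$edges, path, row.names = FALSE)
  invisible(path)
}
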