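# Fluorescence trace container and normalization (dF/F, Z-score).

#' Construct a trace matrix
#'
#' Container for cells x frames fluorescence values at a fixed frame rate.
#' `kind` tracks the processing stage: `"raw"` fluorescence (strictly
#' positive), `"dff"` (background-normalized dF/F) or `"zscore"` (per-cell
#' standardized dF/F).
#'
#' @param values Numeric matrix, one row per cell, one column per frame.
#' @param frame_rate_hz Frames per second (default 10).
#' @param kind One of "raw", "dff", "zscore".
#' @param cell_ids Character cell identifiers; defaults to rownames or
#'   `cell_1 ... cell_n`.
#' @return An object of class `trace_matrix`.
#' @export
trace_matrix <- function(values, frame_rate_hz = 10,
                         kind = c("raw", "dff", "zscore"),
                         cell_ids = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (any(!is.finite(values))) stop("trace values must be finite, no missing frames")
  if (is.null(cell_ids)) {
    cell_ids <- rownames(values) %||% paste0("cell_", seq_len(nrow(values)))
  }
  if (length(cell_ids) != nrow(values)) stop("one cell id per row required")
  rownames(values) <- cell_ids
  if (kind == "raw" && any(values <= 0)) {
    bad <- cell_ids[apply(values <= 0, 1, any)]
    stop("raw fluorescence must be strictly positive; offending cells: ",
         paste(bad, collapse = ", "))
  }
  if (kind == "zscore") {
    m <- rowMeans(values)
    s <- sqrt(rowMeans(sweep(values, 1, m)^2))
    if (any(abs(m) > 1e-9) || any(abs(s - 1) > 1e-9)) {
      stop("zscore traces must have per-cell mean 0 and SD 1")
    }
  }
  structure(list(values = values, frame_rate_hz = frame_rate_hz,
                 kind = kind, cell_ids = cell_ids),
            class = "trace_matrix")
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("<trace_matrix: %d cells x %d frames, %g fps, kind=%s>\n",
              nrow(x$values), ncol(x$values), x$frame_rate_hz, x$kind))
  invisible(x)
}

#' @export
dim.trace_matrix <- function(x) dim(x$values)

n_frames <- function(tm) ncol(tm$values)

#' Normalize raw fluorescence to dF/F
#'
#' Per cell, the background fluorescence F0 is the mean of that cell's raw
#' trace over the whole recording, and every frame is expressed as
#' \code{(F_i - F0) / F0}. The per-cell mean of the output is therefore zero
#' by construction.
#'
#' @param raw A `trace_matrix` of kind "raw".
#' @return A `trace_matrix` of kind "dff".
#' @examples
#' tm <- trace_matrix(matrix(c(100, 300), 1), kind = "raw")
#' compute_dff(tm)$values  # F0 = 200 -> -0.5, 0.5
#' @export
compute_dff <- function(raw) {
  stopifnot(inherits(raw, "trace_matrix"))
  if (raw$kind != "raw") stop("compute_dff expects a raw trace_matrix, got kind=", raw$kind)
  if (any(raw$values <= 0)) {
    bad <- raw$cell_ids[apply(raw$values <= 0, 1, any)]
    stop("nonpositive raw values in cells: ", paste(bad, collapse = ", "))
  }
  f0 <- rowMeans(raw$values)
  out <- sweep(raw$values, 1, f0, "-")
  out <- sweep(out, 1, f0, "/")
  trace_matrix(out, raw$frame_rate_hz, "dff", raw$cell_ids)
}

#' Standardize dF/F traces to per-cell Z-scores
#'
#' Per cell, \code{z_i = (x_i - mean) / SD} with the population (divisor N)
#' standard deviation over the full recording. Flat cells (SD = 0) are an
#' error: silently emitting NaN would corrupt downstream classification, so
#' the caller must drop them explicitly.
#'
#' @param dff A `trace_matrix` of kind "dff".
#' @return A `trace_matrix` of kind "zscore".
#' @export
compute_zscore <- function(dff) {
  stopifnot(inherits(dff, "trace_matrix"))
  if (dff$kind != "dff") stop("compute_zscore expects a dff trace_matrix, got kind=", dff$kind)
  m <- rowMeans(dff$values)
  s <- sqrt(rowMeans(sweep(dff$values, 1, m)^2))
  if (any(s == 0)) {
    stop("flat cells (SD = 0), cannot Z-score: ",
         paste(dff$cell_ids[s == 0], collapse = ", "))
  }
  out <- sweep(sweep(dff$values, 1, m, "-"), 1, s, "/")
  trace_matrix(out, dff$frame_rate_hz, "zscore", dff$cell_ids)
}

#' Write traces to CSV
#'
#' First column `frame` (0-based index), one column per cell id.
#'
#' @param tm A `trace_matrix`.
#' @param path Output file path.
#' @export
write_traces_csv <- function(tm, path) {
  stopifnot(inherits(tm, "trace_matrix"))
  df <- data.frame(frame = seq_len(n_frames(tm)) - 1L,
                   t(tm$values), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read traces from CSV
#'
#' @param path CSV path in the dialect written by [write_traces_csv()].
#' @param frame_rate_hz Frames per second.
#' @param kind Trace kind of the stored values.
#' @return A `trace_matrix`.
#' @export
read_traces_csv <- function(path, frame_rate_hz = 10, kind = "raw") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "frame") stop("expected first column 'frame' in ", path)
  vals <- t(as.matrix(df[, -1, drop = FALSE]))
  trace_matrix(vals, frame_rate_hz, kind, cell_ids = rownames(vals))
}
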