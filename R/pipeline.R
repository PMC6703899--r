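# End-to-end orchestration: simulate -> normalize -> score -> classify ->
# peaks -> synchrony -> transitions -> report, with a reproducibility
# manifest.

#' Run a complete session analysis
#'
#' Executes the full pipeline on a synthetic session: simulation, dF/F and
#' Z-score normalization, epoch scoring, bout segmentation and cataplexy
#' validation, hyperactive-wake labeling and SC/EC subtyping, ON-cell
#' classification, peak detection and statistics, bout-wise synchrony with
#' per-state summary, and EC/SC transition profiles. When `out_dir` is
#' given, every intermediate artifact is written as CSV/JSON together with
#' a manifest of file digests; rerunning with the same config and seed
#' reproduces byte-identical outputs.
#'
#' @param config A [session_config()] or path to a flat key=value config
#'   file readable by [read_session_config()].
#' @param out_dir Optional output directory.
#' @param thresholds A [score_thresholds()] object.
#' @param write_traces Whether to include the (large) raw trace CSV in the
#'   outputs.
#' @param fparams [feature_params()] forwarded to the simulator.
#' @param tparams [trace_params()] forwarded to the simulator.
#' @param verbose Print per-stage progress.
#' @return An object of class `ca_session` collecting all stage results
#'   and, when `out_dir` was given, the run manifest.
#' @export
run_session <- function(config, out_dir = NULL,
                        thresholds = score_thresholds(),
                        write_traces = FALSE,
                        fparams = feature_params(),
                        tparams = trace_params(), verbose = FALSE) {
  if (is.character(config)) config <- read_session_config(config)
  stopifnot(inherits(config, "session_config"))
  say <- function(...) if (verbose) message(sprintf(...))

  say("simulate: %s session, %d cells", config$genotype, config$n_cells)
  sim <- simulate_session(config, fparams = fparams, tparams = tparams)

  say("normalize: dF/F and Z-score")
  dff <- compute_dff(sim$traces)
  zmat <- compute_zscore(dff)

  say("score: epochs and bouts")
  hyp <- score_epochs(sim$features, thresholds, config$epoch_s)
  bouts <- segment_bouts(hyp, config$frame_rate_hz)
  bouts <- label_haw(bouts, zmat, config$odor_onset_s)
  bouts <- label_cataplexy_type(bouts, config$odor_onset_s)

  say("classify: ON cells")
  profiles <- classify_cells(zmat, bouts)
  fractions <- summarize_fractions(profiles, group_label = config$genotype)
  composition <- composition_table(profiles)
  separation <- tryCatch(suppressWarnings(verify_on_separation(profiles)),
                         error = function(e) NULL)

  say("peaks: detection and per-state stats")
  trains <- detect_peaks(zmat)
  peak_stats <- peak_stats_by_state(trains, bouts)

  say("synchrony: bout-wise correlations")
  sync <- suppressWarnings(bout_synchrony(zmat, bouts))
  sync <- Filter(Negate(is.null), sync)
  sync_summary <- if (length(sync) > 0) state_summary(sync) else NULL

  say("transitions: cataplexy profiles")
  transitions <- list()
  for (lbl in c("EC", "SC")) {
    if (any(bouts$label == lbl &
            (bouts$end_frame - bouts$start_frame) >= 2)) {
      transitions[[lbl]] <- lapply(
        stats::setNames(nm = c("HAW_ON", "REMS_ON", "unscored")),
        function(g) {
          tryCatch(transition_profile(zmat, bouts, profiles, g, lbl),
                   error = function(e) NULL)
        })
    }
  }

  durations <- bout_durations(bouts)

  session <- structure(list(
    config = config, sim = sim, zmat = zmat, hypnogram = hyp, bouts = bouts,
    profiles = profiles, fractions = fractions, composition = composition,
    separation = separation, trains = trains, peak_stats = peak_stats,
    synchrony = sync, synchrony_summary = sync_summary,
    transitions = transitions, durations = durations, manifest = NULL),
    class = "ca_session")

  if (!is.null(out_dir)) {
    session$manifest <- write_session_outputs(session, out_dir,
                                              write_traces = write_traces)
  }
  session
}

write_session_outputs <- function(session, out_dir, write_traces = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- session$config
  files <- character(0)
  put <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    files[[name]] <<- path
  }
  put("config.txt", function(p) {
    keys <- c("genotype", "n_cells", "duration_s", "frame_rate_hz", "epoch_s",
              "odor_onset_s", "odor_duration_s", "seed")
    writeLines(vapply(keys, function(k) {
      paste0(k, "=", if (is.null(cfg[[k]])) "" else as.character(cfg[[k]]))
    }, character(1)), p)
  })
  if (write_traces) {
    put("traces_raw.csv", function(p) write_traces_csv(session$sim$traces, p))
  }
  put("hypnogram.csv", function(p) write_hypnogram_csv(session$hypnogram, p))
  put("epoch_features.csv", function(p) utils::write.csv(session$sim$features, p, row.names = FALSE))
  put("bouts.csv", function(p) write_bouts_csv(session$bouts, p))
  put("cell_profiles.csv", function(p) write_profiles_csv(session$profiles, p))
  put("fractions.csv", function(p) utils::write.csv(session$fractions$fractions, p, row.names = FALSE))
  put("composition.csv", function(p) {
    m <- session$composition
    df <- data.frame(row = rownames(m$counts), total = m$row_totals,
                     m$counts, check.names = FALSE)
    for (col in colnames(m$percent)) df[[paste0(col, "_pct")]] <- m$percent[, col]
    utils::write.csv(df, p, row.names = FALSE)
  })
  put("peaks.csv", function(p) write_peaks_csv(session$trains, p, cfg$frame_rate_hz))
  if (!is.null(session$peak_stats)) {
    put("peak_state_stats.csv", function(p) utils::write.csv(session$peak_stats, p, row.names = FALSE))
  }
  if (!is.null(session$synchrony_summary)) {
    put("synchrony_states.csv", function(p) {
      utils::write.csv(session$synchrony_summary$table, p, row.names = FALSE)
    })
  }
  put("centroids.csv", function(p) utils::write.csv(session$sim$centroids, p, row.names = FALSE))
  for (lbl in names(session$transitions)) {
    for (g in names(session$transitions[[lbl]])) {
      tp <- session$transitions[[lbl]][[g]]
      if (!is.null(tp)) {
        put(sprintf("transition_%s_%s.csv", lbl, g),
            function(p) write_transition_csv(tp, p))
      }
    }
  }
  put("report.md", function(p) writeLines(build_report(session), p))

  manifest <- list(
    package_version = as.character(utils::packageVersion("sleepscope")),
    seed = cfg$seed,
    config = Filter(Negate(is.null), unclass(cfg)),
    files = lapply(files, function(p) unname(tools::md5sum(p))),
    warnings = character(0))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest$path <- file.path(out_dir, "manifest.json")
  manifest
}

#' Build a Markdown summary report for an analyzed session
#'
#' Includes per-session cell counts, the ON-category fractions, the
#' HAW-ON/EC-ON composition table, per-state synchrony means and SC/EC
#' durations. Sections whose upstream results are missing are marked
#' unavailable. Percentages are recomputed from the raw counts.
#'
#' @param session A `ca_session` from [run_session()].
#' @return Character vector of Markdown lines.
#' @export
build_report <- function(session) {
  stopifnot(inherits(session, "ca_session"))
  lines <- c(sprintf("# Session report (%s, seed %d)",
                     session$config$genotype, session$config$seed), "")
  lines <- c(lines, sprintf("- Cells recorded: %d", nrow(session$profiles)),
             sprintf("- Epochs: %d x %gs", session$hypnogram$n_epochs,
                     session$hypnogram$epoch_s), "")
  fr <- session$fractions$fractions
  lines <- c(lines, "## ON-cell composition", "",
             "| category | count | % of cells |", "|---|---|---|",
             sprintf("| %s | %d | %.2f |", fr$category, fr$count, fr$percent), "")
  comp <- session$composition
  lines <- c(lines, "## HAW-ON / EC-ON origins", "")
  for (r in rownames(comp$counts)) {
    lines <- c(lines, sprintf("- %s (n=%d): %s", r, comp$row_totals[r],
      paste(sprintf("%s %d (%.2f%%)", colnames(comp$counts),
                    comp$counts[r, ], comp$percent[r, ]), collapse = ", ")))
  }
  lines <- c(lines, "", "## Synchrony by state", "")
  if (is.null(session$synchrony_summary)) {
    lines <- c(lines, "_unavailable_")
  } else {
    tb <- session$synchrony_summary$table
    lines <- c(lines, "| state | bouts | mean +Z_R | SEM |", "|---|---|---|---|",
               sprintf("| %s | %d | %.4f | %.4f |", tb$state, tb$n_bouts,
                       tb$mean_zr, ifelse(is.na(tb$sem_zr), 0, tb$sem_zr)))
  }
  lines <- c(lines, "", "## Cataplexy durations", "")
  ds <- session$durations$summary
  if (all(ds$n == 0)) {
    lines <- c(lines, "_no cataplexy bouts_")
  } else {
    lines <- c(lines, sprintf("- %s: n=%d, mean %.1f s (SEM %.1f)",
                              ds$label, ds$n, ds$mean_s,
                              ifelse(is.na(ds$sem_s), 0, ds$sem_s)))
    if (!is.null(session$durations$anova) && !session$durations$anova$degenerate) {
      a <- session$durations$anova
      lines <- c(lines, sprintf("- SC vs EC one-way ANOVA: F(%d,%d) = %.2f, p = %.3f",
                                a$df1, a$df2, a$F, a$p))
    }
  }
  lines
}

#' @export
print.ca_session <- function(x, ...) {
  cat(sprintf("<ca_session: %s, %d cells, %d epochs>\n", x$config$genotype,
              nrow(x$profiles), x$hypnogram$n_epochs))
  tb <- table(x$bouts$label)
  cat("  bouts:", paste(names(tb), tb, sep = ":", collapse = " "), "\n")
  cat(sprintf("  categories: %s\n",
              paste(x$fractions$fractions$category,
                    x$fractions$fractions$count, sep = ":", collapse = " ")))
  invisible(x)
}

#' @export
summary.ca_session <- function(object, ...) {
  cat(paste(build_report(object), collapse = "\n"), "\n")
  invisible(object)
}
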