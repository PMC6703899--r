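# Fixture builders shared across test files. Sessions are memoized so that
# several test files can reuse the same simulated recording.

# Standardize rows (population SD) and wrap as a zscore trace_matrix.
as_zscore <- function(mat, fps = 10, ids = NULL) {
  mat <- as.matrix(mat)
  m <- rowMeans(mat)
  s <- sqrt(rowMeans(sweep(mat, 1, m)^2))
  z <- sweep(sweep(mat, 1, m, "-"), 1, s, "/")
  trace_matrix(z, fps, "zscore", ids)
}

# Build a bout_table directly from run-length (label, n_epochs) pairs,
# mapping derived labels onto their underlying states.
make_bouts <- function(labels, n_epochs, epoch_s = 4, fps = 10) {
  state_of <- c(SC = "CATAPLEXY", EC = "CATAPLEXY", HAW = "AW", AWO = "AW")
  states <- ifelse(labels %in% names(state_of), state_of[labels], labels)
  ends <- cumsum(n_epochs)
  starts <- ends - n_epochs
  fpe <- as.integer(fps * epoch_s)
  structure(
    data.frame(state = unname(states), label = labels,
               start_epoch = as.integer(starts), end_epoch = as.integer(ends),
               start_frame = as.integer(starts * fpe),
               end_frame = as.integer(ends * fpe),
               start_s = starts * epoch_s, duration_s = n_epochs * epoch_s,
               flagged = FALSE, stringsAsFactors = FALSE),
    epoch_s = epoch_s, frame_rate_hz = fps, n_epochs = sum(n_epochs),
    class = c("bout_table", "data.frame"))
}

# Minimal cell_profiles object from categories and flags, for summary tests.
make_profiles <- function(categories, ec_on = FALSE, haw_on = FALSE,
                          on_states = NULL) {
  n <- length(categories)
  out <- data.frame(cell_id = sprintf("c%03d", seq_len(n)),
                    z_qw = 0, max_z = 1,
                    on_states = on_states %||% "",
                    category = categories,
                    ec_on = rep_len(ec_on, n), haw_on = rep_len(haw_on, n),
                    stringsAsFactors = FALSE)
  structure(out, states = c("AW", "QW", "NREMS", "REMS"),
            class = c("cell_profiles", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exact-margin fixture: two equal-length states (QW, REMS), traces built so
# the per-cell mean is 0 and population SD is 1, with a chosen mean
# separation between the states.
margin_zmat <- function(margins) {
  bouts <- make_bouts(c("QW", "REMS"), c(5, 5))
  half <- 200
  vals <- t(vapply(margins, function(m) {
    c_sp <- sqrt(1 - (m / 2)^2)
    c(rep(c(-m / 2 - c_sp, -m / 2 + c_sp), half / 2),
      rep(c(m / 2 - c_sp, m / 2 + c_sp), half / 2))
  }, numeric(2 * half)))
  list(zmat = trace_matrix(vals, 10, "zscore",
                           cell_ids = sprintf("m%.3f", margins)),
       bouts = bouts)
}

# Expected pre-odor category for a ground-truth tuning class.
expected_category <- function(tuning_class) {
  switch(tuning_class,
         unscored_ECrecruit = "unscored",
         unscored_flat = "unscored",
         tuning_class)
}

.fixture_env <- new.env(parent = emptyenv())

memo_session <- function(key, maker) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- maker()
  .fixture_env[[key]]
}

# Narcoleptic reference session: 3 h with odor in the final hour, 60 cells.
fx_narco <- function() {
  memo_session("narco", function() {
    cfg <- session_config("narcoleptic", n_cells = 60, duration_s = 10800,
                          odor_onset_s = 7200, odor_duration_s = 3600,
                          seed = 101)
    run_session(cfg)
  })
}

# As fx_narco but with noise-free EEG/EMG features, so the scored
# hypnogram (and hence bout labels) can be compared to ground truth exactly.
fx_narco_clean <- function() {
  memo_session("narco_clean", function() {
    cfg <- session_config("narcoleptic", n_cells = 60, duration_s = 10800,
                          odor_onset_s = 7200, odor_duration_s = 3600,
                          seed = 101)
    run_session(cfg, fparams = feature_params(sigma = 0))
  })
}

# Control reference session: same protocol shape, 40 cells.
fx_control <- function() {
  memo_session("control", function() {
    cfg <- session_config("control", n_cells = 40, duration_s = 5400,
                          odor_onset_s = 3600, odor_duration_s = 1800,
                          seed = 202)
    run_session(cfg)
  })
}
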