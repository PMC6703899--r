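# Synthetic-session generator: hypnogram, EEG/EMG epoch features, cell
# tunings and calcium traces with known ground truth. The generator emulates
# the statistical structure the analysis assumes -- two genotypes, a
# sleep/wake hypnogram with cataplexy restricted to narcoleptics, an odor
# window that elevates activity and cataplexy hazard, and state-tuned cell
# populations with fast-rise/slow-decay calcium transients.

#' Session configuration
#'
#' Defaults mirror the recording protocol the analysis targets: 10 frames/s
#' imaging, 4 s scoring epochs, a 4 h session with a 1 h odor exposure
#' starting 3 h in.
#'
#' @param genotype "narcoleptic" or "control".
#' @param n_cells Number of cells to simulate.
#' @param duration_s Session length in seconds (integer multiple of `epoch_s`).
#' @param frame_rate_hz Imaging rate, frames per second.
#' @param epoch_s Scoring epoch length in seconds.
#' @param odor_onset_s Odor-exposure onset in seconds, or `NULL` for an
#'   undisturbed session.
#' @param odor_duration_s Odor-exposure duration in seconds.
#' @param seed Master seed; all generator randomness derives from it.
#' @return An object of class `session_config`.
#' @export
session_config <- function(genotype = c("narcoleptic", "control"),
                           n_cells = 60, duration_s = 14400,
                           frame_rate_hz = 10, epoch_s = 4,
                           odor_onset_s = 10800, odor_duration_s = 3600,
                           seed = 1) {
  genotype <- match.arg(genotype)
  if (duration_s %% epoch_s != 0) stop("duration_s must be a multiple of epoch_s")
  fpe <- frame_rate_hz * epoch_s
  if (abs(fpe - round(fpe)) > 1e-9) stop("frame_rate_hz * epoch_s must be an integer")
  if (!is.null(odor_onset_s)) {
    if (odor_onset_s + odor_duration_s > duration_s) {
      stop("odor window must end within the recording")
    }
    if (odor_onset_s %% epoch_s != 0) stop("odor_onset_s must align to epoch boundaries")
  }
  if (n_cells < 1) stop("n_cells must be positive")
  structure(list(genotype = genotype, n_cells = as.integer(n_cells),
                 duration_s = duration_s, frame_rate_hz = frame_rate_hz,
                 epoch_s = epoch_s, odor_onset_s = odor_onset_s,
                 odor_duration_s = odor_duration_s, seed = as.integer(seed)),
            class = "session_config")
}

#' @export
print.session_config <- function(x, ...) {
  cat(sprintf("<session_config: %s, %d cells, %gs @%g fps, odor=%s, seed=%d>\n",
              x$genotype, x$n_cells, x$duration_s, x$frame_rate_hz,
              if (is.null(x$odor_onset_s)) "none" else x$odor_onset_s, x$seed))
  invisible(x)
}

#' Semi-Markov state model for hypnogram generation
#'
#' Bout durations are exponential with the given means, truncated below at
#' one epoch; REMS is reachable only from NREMS, the standard rodent sleep
#' architecture. Cataplexy is inserted after wake runs of at least 40 s with
#' per-bout probability `cataplexy_hazard`, multiplied by
#' `odor_hazard_multiplier` inside the odor window; with probability
#' `chain_prob` a cataplexy bout chains into a further bout across a short
#' (< 40 s) all-wake gap, emulating sequential cataplexy.
#'
#' @param genotype Genotype the model is for; controls the hazard default.
#' @param mean_bout_duration_s Named numeric: mean bout duration per state.
#' @param transition_weights Named list of named outgoing weight vectors.
#' @param cataplexy_hazard Probability per qualifying wake bout (0 for controls).
#' @param odor_hazard_multiplier Hazard multiplier inside the odor window.
#' @param chain_prob Probability of chaining a further cataplexy bout.
#' @return An object of class `state_model`.
#' @export
state_model <- function(genotype = "narcoleptic",
                        mean_bout_duration_s = c(AW = 80, QW = 40, NREMS = 160,
                                                 REMS = 60, CATAPLEXY = 40),
                        transition_weights = list(
                          AW = c(QW = 0.7, NREMS = 0.3),
                          QW = c(AW = 0.5, NREMS = 0.5),
                          NREMS = c(QW = 0.25, AW = 0.25, REMS = 0.5),
                          REMS = c(AW = 0.6, QW = 0.4)),
                        cataplexy_hazard = if (genotype == "narcoleptic") 0.25 else 0,
                        odor_hazard_multiplier = 3,
                        chain_prob = 0.25) {
  if (genotype == "control" && cataplexy_hazard > 0) {
    stop("control genotype must have cataplexy_hazard = 0")
  }
  for (s in names(transition_weights)) {
    w <- transition_weights[[s]]
    if (any(w < 0) || sum(w) <= 0) stop("outgoing weights for ", s, " must be nonnegative with positive sum")
  }
  if (!is.null(transition_weights$AW) && "REMS" %in% names(transition_weights$AW) &&
      transition_weights$AW[["REMS"]] > 0) {
    stop("REMS may only be entered from NREMS")
  }
  structure(list(mean_bout_duration_s = mean_bout_duration_s,
                 transition_weights = transition_weights,
                 cataplexy_hazard = cataplexy_hazard,
                 odor_hazard_multiplier = odor_hazard_multiplier,
                 chain_prob = chain_prob),
            class = "state_model")
}

#' Generate a hypnogram with ground-truth bout flags
#'
#' Simulates a semi-Markov sequence over AW/QW/NREMS/REMS with cataplexy
#' bouts (minimum 2 epochs = 8 s) inserted after wake runs of at least 10
#' epochs (40 s). In narcoleptic sessions with an odor window, active-wake
#' bouts starting inside the window are flagged hyperactive (HAW) in the
#' ground truth -- the analysis must rediscover them from the traces -- and
#' cataplexy entered from such bouts is flagged emotion-induced (EC), all
#' other cataplexy spontaneous (SC).
#'
#' @param config A [session_config()].
#' @param model A [state_model()]; defaults to the genotype-appropriate model.
#' @return An object of class `sim_hypnogram`: `$hypnogram` (a [hypnogram()])
#'   plus `$bouts`, a ground-truth bout table with `gt_label` in
#'   AW/HAW/QW/NREMS/REMS/SC/EC and a `chained` flag.
#' @export
generate_hypnogram <- function(config, model = state_model(config$genotype)) {
  stopifnot(inherits(config, "session_config"), inherits(model, "state_model"))
  if (config$genotype == "control" && model$cataplexy_hazard > 0) {
    stop("control genotype must have cataplexy_hazard = 0")
  }
  set.seed(derive_seed(config$seed, "hypnogram"))
  epoch_s <- config$epoch_s
  n_epochs <- as.integer(config$duration_s / epoch_s)
  wake_req <- ceiling(40 / epoch_s)      # 40 s of prior wake
  cat_min <- ceiling(8 / epoch_s)        # 8 s minimum cataplexy
  has_odor <- !is.null(config$odor_onset_s)
  in_odor <- function(ep) {
    has_odor && ep * epoch_s >= config$odor_onset_s &&
      ep * epoch_s < config$odor_onset_s + config$odor_duration_s
  }

  st <- character(0); gl <- character(0); se <- integer(0); ne <- integer(0)
  ch <- logical(0)
  add_bout <- function(state, gt_label, start, len, chained = FALSE) {
    st[length(st) + 1] <<- state
    gl[length(gl) + 1] <<- gt_label
    se[length(se) + 1] <<- start
    ne[length(ne) + 1] <<- len
    ch[length(ch) + 1] <<- chained
  }
  draw_len <- function(state, minimum = 1L) {
    max(minimum, as.integer(ceiling(
      stats::rexp(1, 1 / model$mean_bout_duration_s[[state]]) / epoch_s)))
  }
  # Ground-truth cataplexy type: nearest earlier AW-family ground-truth bout.
  last_aw_gt <- function() {
    for (i in rev(seq_along(gl))) {
      if (gl[i] %in% c("AW", "HAW")) return(gl[i])
    }
    NA_character_
  }

  cur <- 0L
  wake_run <- 0L
  state <- "AW"
  while (cur < n_epochs) {
    len <- min(draw_len(state), n_epochs - cur)
    gt_label <- state
    if (state == "AW" && config$genotype == "narcoleptic" && in_odor(cur)) {
      gt_label <- "HAW"
    }
    add_bout(state, gt_label, cur, len)
    cur <- cur + len
    wake_run <- if (state %in% wake_states()) wake_run + len else 0L
    if (cur >= n_epochs) break

    inserted <- FALSE
    if (state %in% wake_states() && wake_run >= wake_req) {
      hazard <- model$cataplexy_hazard *
        (if (in_odor(cur)) model$odor_hazard_multiplier else 1)
      if (stats::runif(1) < min(1, hazard)) {
        cat_type <- if (in_odor(cur) && identical(last_aw_gt(), "HAW")) "EC" else "SC"
        chained <- FALSE
        repeat {
          len_c <- min(draw_len("CATAPLEXY", cat_min), n_epochs - cur)
          if (len_c < cat_min) break
          add_bout("CATAPLEXY", cat_type, cur, len_c, chained)
          cur <- cur + len_c
          inserted <- TRUE
          if (cur >= n_epochs || stats::runif(1) >= model$chain_prob) break
          gap <- min(sample.int(wake_req - 1L, 1), n_epochs - cur)
          if (gap < 1 || cur + gap + cat_min > n_epochs) break
          gap_gt <- if (config$genotype == "narcoleptic" && in_odor(cur)) "HAW" else "AW"
          add_bout("AW", gap_gt, cur, gap)
          cur <- cur + gap
          chained <- TRUE
        }
        wake_run <- 0L
        state <- "AW"
        next
      }
    }
    if (!inserted) {
      w <- model$transition_weights[[state]]
      state <- sample(names(w), 1, prob = w)
    }
  }

  bouts <- data.frame(state = st, gt_label = gl, start_epoch = se,
                      end_epoch = se + ne, chained = ch,
                      stringsAsFactors = FALSE)
  labels <- rep(bouts$state, times = ne)
  structure(list(hypnogram = hypnogram(labels, epoch_s),
                 bouts = bouts, config = config),
            class = "sim_hypnogram")
}

#' @export
print.sim_hypnogram <- function(x, ...) {
  tb <- table(x$bouts$gt_label)
  cat(sprintf("<sim_hypnogram: %d epochs, %d bouts [%s]>\n",
              length(x$hypnogram$labels), nrow(x$bouts),
              paste(names(tb), tb, sep = ":", collapse = " ")))
  invisible(x)
}

#' State-conditioned EEG/EMG feature parameters
#'
#' Lognormal location parameters per state for delta power, theta power and
#' EMG RMS (arbitrary units), a shared log-scale spread `sigma`, and the
#' deterministic movement flag (true only in AW). Cataplexy shares the REMS
#' atonia parameters for EMG and the theta-dominant EEG, differing only in
#' its waking context. With `sigma = 0` the features are noise-free and the
#' default scoring thresholds recover the generating labels exactly.
#'
#' @param sigma Log-scale SD applied to all three channels.
#' @return List of per-state parameters, class `feature_params`.
#' @export
feature_params <- function(sigma = 0.2) {
  rems_atonia_emg <- 0.08
  theta_eeg <- c(delta = 0.8, theta = 2.8)
  structure(list(
    sigma = sigma,
    states = list(
      AW = list(delta = 0.8, theta = 1.2, emg = 3.0, move = TRUE),
      QW = list(delta = 1.0, theta = 0.8, emg = 1.4, move = FALSE),
      NREMS = list(delta = 4.0, theta = 1.0, emg = 0.5, move = FALSE),
      REMS = list(delta = theta_eeg[["delta"]], theta = theta_eeg[["theta"]],
                  emg = rems_atonia_emg, move = FALSE),
      CATAPLEXY = list(delta = theta_eeg[["delta"]], theta = theta_eeg[["theta"]],
                       emg = rems_atonia_emg, move = FALSE))),
    class = "feature_params")
}

#' Generate per-epoch EEG/EMG summary features
#'
#' Draws delta power, theta power and EMG RMS from state-conditioned
#' lognormal distributions and sets the movement flag, so that wake epochs
#' have high EMG / low delta, NREMS high delta / low EMG, REMS and cataplexy
#' a high theta-to-delta ratio with atonic EMG.
#'
#' @param hyp A [hypnogram()] or `sim_hypnogram`.
#' @param params A [feature_params()] object.
#' @param seed Seed for the feature noise.
#' @return Data frame with `epoch`, `delta_power`, `theta_power`, `emg_rms`,
#'   `movement_flag`.
#' @export
generate_epoch_features <- function(hyp, params = feature_params(), seed = 1) {
  if (inherits(hyp, "sim_hypnogram")) hyp <- hyp$hypnogram
  stopifnot(inherits(hyp, "hypnogram"))
  set.seed(derive_seed(seed, "features"))
  labels <- hyp$labels
  n <- length(labels)
  draw <- function(channel) {
    mu <- vapply(labels, function(s) params$states[[s]][[channel]], numeric(1))
    if (params$sigma == 0) return(unname(mu))
    unname(mu * exp(stats::rnorm(n, 0, params$sigma)))
  }
  data.frame(
    epoch = seq_len(n) - 1L,
    delta_power = draw("delta"),
    theta_power = draw("theta"),
    emg_rms = draw("emg"),
    movement_flag = vapply(labels, function(s) params$states[[s]]$move, logical(1)),
    row.names = NULL)
}

#' Cell tuning specification
#'
#' @param cell_id Identifier.
#' @param tuning_class One of REMS_ON, AW_ON, REMS_AW_ON, NREMS_ON, SC_ON,
#'   unscored_ECrecruit, unscored_flat.
#' @param event_rate_by_state Named events/s over
#'   AW/QW/NREMS/REMS/HAW/SC/EC (ground-truth states; HAW/SC/EC only matter
#'   for narcoleptic sessions).
#' @param coupling Weight in `[0, 1]` on the shared latent drive during
#'   emotion-induced cataplexy.
#' @param amplitude_mu,amplitude_sigma Log-scale event amplitude parameters.
#' @param centroid_xy Length-2 numeric, pixels.
#' @return An object of class `cell_tuning`.
#' @export
cell_tuning <- function(cell_id, tuning_class, event_rate_by_state,
                        coupling = 0.3, amplitude_mu = log(25),
                        amplitude_sigma = 0.35, centroid_xy = c(0, 0)) {
  if (any(event_rate_by_state < 0)) stop("event rates must be nonnegative")
  if (coupling < 0 || coupling > 1) stop("coupling must lie in [0, 1]")
  structure(list(cell_id = as.character(cell_id), tuning_class = tuning_class,
                 event_rate_by_state = event_rate_by_state, coupling = coupling,
                 amplitude_mu = amplitude_mu, amplitude_sigma = amplitude_sigma,
                 centroid_xy = centroid_xy),
            class = "cell_tuning")
}

#' Default tuning population for a session
#'
#' Splits `n_cells` across tuning classes in proportions modeled on the
#' cell-type composition reported for amygdala GABAergic populations:
#' roughly a quarter REMS-ON, a third AW-ON, small REMS/AW and NREMS-ON
#' groups, and (narcoleptic only) spontaneous-cataplexy-ON cells plus a
#' block of "unscored" cells, many of which are recruited by odor/EC via a
#' high shared-drive coupling.
#'
#' @param config A [session_config()].
#' @return List of [cell_tuning()] objects, one per cell.
#' @export
default_tunings <- function(config) {
  set.seed(derive_seed(config$seed, "tunings"))
  narco <- config$genotype == "narcoleptic"
  fr <- if (narco) {
    c(REMS_ON = 0.24, AW_ON = 0.30, REMS_AW_ON = 0.06, NREMS_ON = 0.04,
      SC_ON = 0.08, unscored_ECrecruit = 0.16, unscored_flat = 0.12)
  } else {
    c(REMS_ON = 0.25, AW_ON = 0.30, REMS_AW_ON = 0.05, NREMS_ON = 0.04,
      SC_ON = 0, unscored_ECrecruit = 0.04, unscored_flat = 0.32)
  }
  counts <- round(fr * config$n_cells)
  while (sum(counts) > config$n_cells) counts[which.max(counts)] <- counts[which.max(counts)] - 1
  while (sum(counts) < config$n_cells) counts["unscored_flat"] <- counts["unscored_flat"] + 1
  classes <- rep(names(counts), times = counts)

  base <- 0.01; on <- 0.5
  rates_for <- function(class) {
    r <- c(AW = base, QW = base, NREMS = base, REMS = base,
           HAW = base, SC = base, EC = base)
    switch(class,
      REMS_ON = { r["REMS"] <- on },
      AW_ON = { r["AW"] <- on; r["HAW"] <- if (narco) 0.55 else on },
      REMS_AW_ON = { r["REMS"] <- on; r["AW"] <- on; r["HAW"] <- on },
      NREMS_ON = { r["NREMS"] <- 0.4 },
      SC_ON = { r["SC"] <- 0.6; r["NREMS"] <- 0.05 },
      unscored_ECrecruit = { r["HAW"] <- 0.55; r["EC"] <- 0.6; r[c("AW", "QW", "NREMS", "REMS")] <- base },
      unscored_flat = { r[] <- 0.03 })
    r
  }
  coupling_for <- function(class) {
    switch(class,
      unscored_ECrecruit = 0.85,
      AW_ON = 0.5,
      REMS_AW_ON = 0.4,
      unscored_flat = 0.1,
      0.25)
  }
  lapply(seq_len(config$n_cells), function(i) {
    cl <- classes[i]
    cell_tuning(cell_id = sprintf("cell_%03d", i), tuning_class = cl,
                event_rate_by_state = rates_for(cl),
                coupling = coupling_for(cl),
                centroid_xy = stats::runif(2, 5, 245))
  })
}

#' Calcium transient kernel and noise parameters
#'
#' Double-exponential kernel \code{k(t) = exp(-t/tau_d) - exp(-t/tau_r)}
#' (rise must be faster than decay), normalized to unit peak so event
#' amplitudes are in raw fluorescence units. Defaults are GCaMP6s-like at
#' 10 fps: 0.2 s rise, 1.5 s decay, so transients span many frames.
#'
#' @param tau_r Rise time constant, seconds.
#' @param tau_d Decay time constant, seconds; must exceed `tau_r`.
#' @param baseline Baseline raw fluorescence (keeps traces positive).
#' @param noise_sd Additive Gaussian noise SD, raw units.
#' @param shared_rate Rate (events/s) of the shared latent drive active
#'   during emotion-induced cataplexy.
#' @return List of parameters, class `trace_params`.
#' @export
trace_params <- function(tau_r = 0.2, tau_d = 1.5, baseline = 100,
                         noise_sd = 2, shared_rate = 0.8) {
  if (tau_r >= tau_d) stop("tau_r must be smaller than tau_d")
  structure(list(tau_r = tau_r, tau_d = tau_d, baseline = baseline,
                 noise_sd = noise_sd, shared_rate = shared_rate),
            class = "trace_params")
}

transient_kernel <- function(params, frame_rate_hz) {
  t <- seq(0, 8 * params$tau_d, by = 1 / frame_rate_hz)
  k <- exp(-t / params$tau_d) - exp(-t / params$tau_r)
  k / max(k)
}

#' Generate raw fluorescence traces with ground-truth events
#'
#' Per cell, events form an inhomogeneous Poisson process whose rate follows
#' the ground-truth state at each frame. During emotion-induced cataplexy,
#' events are a mixture of private events (rate scaled by `1 - coupling`)
#' and a shared latent Poisson train each cell samples with probability
#' `coupling` -- the mechanism producing EC hyper-synchrony. Each event
#' contributes an amplitude-scaled double-exponential transient; Gaussian
#' noise and a positive baseline complete the raw trace.
#'
#' @param sim_hyp A `sim_hypnogram` from [generate_hypnogram()].
#' @param tunings List of [cell_tuning()] objects (nonempty).
#' @param config The [session_config()].
#' @param params A [trace_params()] object.
#' @return List with `traces` (raw [trace_matrix()]), `event_frames`
#'   (per-cell 0-based ground-truth event frames), `centroids` data frame.
#' @export
generate_traces <- function(sim_hyp, tunings, config = sim_hyp$config,
                            params = trace_params()) {
  stopifnot(inherits(sim_hyp, "sim_hypnogram"))
  if (length(tunings) == 0) stop("tunings must be nonempty")
  if (params$tau_r >= params$tau_d) stop("tau_r must be smaller than tau_d")
  fps <- config$frame_rate_hz
  fpe <- as.integer(fps * config$epoch_s)
  bouts <- sim_hyp$bouts
  gt_frame <- rep(bouts$gt_label, times = (bouts$end_epoch - bouts$start_epoch) * fpe)
  nf <- length(gt_frame)
  kernel <- transient_kernel(params, fps)

  # Shared latent drive on EC frames, one train for the whole session.
  set.seed(derive_seed(config$seed, "shared_drive"))
  ec_frames <- which(gt_frame == "EC")
  shared <- ec_frames[stats::runif(length(ec_frames)) < params$shared_rate / fps]

  values <- matrix(0, nrow = length(tunings), ncol = nf)
  event_frames <- vector("list", length(tunings))
  ids <- vapply(tunings, function(tu) tu$cell_id, character(1))
  for (i in seq_along(tunings)) {
    tu <- tunings[[i]]
    set.seed(derive_seed(config$seed, paste0("trace_", tu$cell_id)))
    rate <- unname(tu$event_rate_by_state[gt_frame]) / fps
    rate[gt_frame == "EC"] <- rate[gt_frame == "EC"] * (1 - tu$coupling)
    ev <- which(stats::runif(nf) < rate)
    if (length(shared) > 0 && tu$coupling > 0) {
      take <- shared[stats::runif(length(shared)) < tu$coupling]
      ev <- sort(unique(c(ev, take)))
    }
    impulses <- numeric(nf)
    if (length(ev) > 0) {
      amps <- stats::rlnorm(length(ev), tu$amplitude_mu, tu$amplitude_sigma)
      impulses[ev] <- impulses[ev] + amps
      sig <- stats::convolve(impulses, rev(kernel), type = "open")[seq_len(nf)]
    } else {
      sig <- impulses
    }
    noise <- if (params$noise_sd > 0) stats::rnorm(nf, 0, params$noise_sd) else 0
    tr <- params$baseline + sig + noise
    values[i, ] <- pmax(tr, 0.01 * params$baseline)
    event_frames[[i]] <- ev - 1L  # 0-based
  }
  rownames(values) <- ids
  names(event_frames) <- ids
  centroids <- data.frame(
    cell_id = ids,
    x = vapply(tunings, function(tu) tu$centroid_xy[1], numeric(1)),
    y = vapply(tunings, function(tu) tu$centroid_xy[2], numeric(1)))
  list(traces = trace_matrix(values, fps, "raw", ids),
       event_frames = event_frames, centroids = centroids)
}

#' Simulate a complete session
#'
#' Convenience wrapper chaining [generate_hypnogram()],
#' [generate_epoch_features()] and [generate_traces()] with a shared seed.
#'
#' @param config A [session_config()].
#' @param model Optional [state_model()].
#' @param tunings Optional tuning list; defaults to [default_tunings()].
#' @param fparams Optional [feature_params()].
#' @param tparams Optional [trace_params()].
#' @return An object of class `sim_session` with elements `config`,
#'   `sim_hyp`, `features`, `traces`, `centroids`, `tunings`,
#'   `event_frames`.
#' @export
simulate_session <- function(config, model = state_model(config$genotype),
                             tunings = default_tunings(config),
                             fparams = feature_params(),
                             tparams = trace_params()) {
  sim_hyp <- generate_hypnogram(config, model)
  features <- generate_epoch_features(sim_hyp, fparams, seed = config$seed)
  tr <- generate_traces(sim_hyp, tunings, config, tparams)
  structure(list(config = config, sim_hyp = sim_hyp, features = features,
                 traces = tr$traces, centroids = tr$centroids,
                 tunings = tunings, event_frames = tr$event_frames),
            class = "sim_session")
}

#' @export
print.sim_session <- function(x, ...) {
  cat(sprintf("<sim_session: %s, %d cells, %d frames>\n",
              x$config$genotype, nrow(x$traces$values), ncol(x$traces$values)))
  invisible(x)
}

#' Write the synthetic-session artifacts to a directory
#'
#' Emits the trace CSV, hypnogram CSV, epoch-feature CSV, centroid CSV,
#' ground-truth JSON and a flat key=value config file.
#'
#' @param sim A `sim_session`.
#' @param dir Output directory, created if missing.
#' @return Invisibly, the vector of files written.
#' @export
write_session_csv <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(
    traces = file.path(dir, "traces_raw.csv"),
    hypnogram = file.path(dir, "hypnogram.csv"),
    features = file.path(dir, "epoch_features.csv"),
    centroids = file.path(dir, "centroids.csv"),
    ground_truth = file.path(dir, "ground_truth.json"),
    config = file.path(dir, "config.txt"))
  write_traces_csv(sim$traces, files["traces"])
  write_hypnogram_csv(sim$sim_hyp$hypnogram, files["hypnogram"])
  utils::write.csv(sim$features, files["features"], row.names = FALSE)
  utils::write.csv(sim$centroids, files["centroids"], row.names = FALSE)
  gt <- list(
    bouts = sim$sim_hyp$bouts,
    tuning_class = stats::setNames(
      vapply(sim$tunings, function(tu) tu$tuning_class, character(1)),
      vapply(sim$tunings, function(tu) tu$cell_id, character(1))),
    event_frames = sim$event_frames)
  jsonlite::write_json(gt, files["ground_truth"], auto_unbox = TRUE, digits = NA)
  cfg <- sim$config
  keys <- c("genotype", "n_cells", "duration_s", "frame_rate_hz", "epoch_s",
            "odor_onset_s", "odor_duration_s", "seed")
  lines <- vapply(keys, function(k) {
    v <- cfg[[k]]
    paste0(k, "=", if (is.null(v)) "" else as.character(v))
  }, character(1))
  writeLines(lines, files["config"])
  invisible(files)
}

#' Read a flat key=value session config file
#'
#' @param path Path written by [write_session_csv()].
#' @return A [session_config()].
#' @export
read_session_config <- function(path) {
  kv <- strsplit(readLines(path), "=", fixed = TRUE)
  vals <- stats::setNames(
    vapply(kv, function(x) if (length(x) > 1) x[2] else "", character(1)),
    vapply(kv, `[`, character(1), 1))
  num <- function(k) if (!nzchar(vals[[k]])) NULL else as.numeric(vals[[k]])
  session_config(genotype = vals[["genotype"]], n_cells = num("n_cells"),
                 duration_s = num("duration_s"),
                 frame_rate_hz = num("frame_rate_hz"), epoch_s = num("epoch_s"),
                 odor_onset_s = num("odor_onset_s"),
                 odor_duration_s = num("odor_duration_s") %||% 3600,
                 seed = num("seed"))
}
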