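#' Synthetic cohort configuration
#'
#' All knobs of the anchor-based generative gaze model. A trial owns a set of
#' spatial anchors (attractor locations standing in for informative scene
#' parts); a scanpath is a sequence of anchor visits, each visit emitting one
#' or more fixations (a dwell) with Gaussian within-anchor jitter. Four
#' regimes are emulated through the levers:
#'
#' * `free`: anchors toured once, moderate revisit probability, single-
#'   fixation visits, low order fidelity — ordinary free viewing.
#' * `part_based`: high revisit probability and order fidelity with dwells of
#'   two or more fixations — the part-by-part inspection forced by a
#'   gaze-contingent window.
#' * `holistic`: almost no revisits, large dispersed exploratory jumps — the
#'   peripheral, gist-oriented viewing forced by an artificial scotoma.
#' * `imagery`: replays a subset of the encoding fixations (weighted by the
#'   coupling `encoding_coupling`), with high revisit rate, sequential order
#'   and dwells — imagery-like looking at nothing.
#'
#' Anchors are placed with a minimum pairwise separation so that distinct
#' anchors never fall within one recurrence radius of each other; if the
#' requested number of anchors does not fit the screen at that separation a
#' configuration error is raised.
#'
#' @param n_participants,n_trials Cohort size.
#' @param n_fixations Fixations generated per phase and trial.
#' @param n_anchors Number of anchor locations per trial.
#' @param revisit_prob Probability that, once all anchors have been toured, a
#'   visit returns to a previously visited location rather than exploring a
#'   fresh one.
#' @param order_fidelity Probability that a revisit follows the original
#'   first-visit order (cycling) rather than picking a visited anchor at
#'   random.
#' @param cluster_dwell Mean number of consecutive fixations per anchor visit
#'   (dwell length is `1 + Poisson(cluster_dwell - 1)`).
#' @param jitter_sd Within-anchor spatial noise, px.
#' @param saccade_scale Mean length of exploratory jumps, px.
#' @param encoding_coupling Weight `lambda` in `[0, 1]` with which imagery
#'   fixations reuse encoding locations; the remainder are fresh uniform
#'   locations.
#' @param seed Master seed; every trial derives its own substream from it, so
#'   cohorts are bit-reproducible and extensible without reshuffling.
#' @param geometry A [screen_geometry()].
#' @param anchor_min_sep_px Minimum pairwise anchor distance (default 300 px,
#'   comfortably above twice the 135 px recurrence radius).
#' @param margin_px Keep anchors this far from the screen edge.
#' @param duration_meanlog,duration_sdlog Log-normal fixation-duration
#'   parameters (ms); draws are clamped into [100, 5000] ms.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 20L, n_trials = 15L,
                          n_fixations = 30L, n_anchors = 8L,
                          revisit_prob = 0.3, order_fidelity = 0.2,
                          cluster_dwell = 1, jitter_sd = 15,
                          saccade_scale = 500, encoding_coupling = 0.7,
                          seed = 1L, geometry = screen_geometry(),
                          anchor_min_sep_px = 300, margin_px = 100,
                          duration_meanlog = log(250), duration_sdlog = 0.35) {
  probs <- c(revisit_prob, order_fidelity, encoding_coupling)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  counts <- c(n_participants, n_trials, n_fixations, n_anchors)
  if (any(counts < 1)) stop("counts must be positive")
  if (cluster_dwell < 1) stop("cluster_dwell must be >= 1")
  if (seed >= 2^31 - 1) stop("seed must be a 32-bit integer")
  structure(list(
    n_participants = as.integer(n_participants), n_trials = as.integer(n_trials),
    n_fixations = as.integer(n_fixations), n_anchors = as.integer(n_anchors),
    revisit_prob = revisit_prob, order_fidelity = order_fidelity,
    cluster_dwell = cluster_dwell, jitter_sd = jitter_sd,
    saccade_scale = saccade_scale, encoding_coupling = encoding_coupling,
    seed = as.integer(seed), geometry = geometry,
    anchor_min_sep_px = anchor_min_sep_px, margin_px = margin_px,
    duration_meanlog = duration_meanlog, duration_sdlog = duration_sdlog),
    class = "cohort_config")
}

#' Lever presets for the four gaze regimes
#'
#' @param mode One of `"free"`, `"part_based"`, `"holistic"`, `"imagery"`.
#' @return Named list of lever values overriding a [cohort_config()].
#' @export
mode_preset <- function(mode = c("free", "part_based", "holistic", "imagery")) {
  mode <- match.arg(mode)
  switch(mode,
    free       = list(revisit_prob = 0.30, order_fidelity = 0.20,
                      cluster_dwell = 1.0, jitter_sd = 15),
    part_based = list(revisit_prob = 0.60, order_fidelity = 0.90,
                      cluster_dwell = 2.5, jitter_sd = 10),
    holistic   = list(revisit_prob = 0.05, order_fidelity = 0.00,
                      cluster_dwell = 1.0, jitter_sd = 5),
    imagery    = list(revisit_prob = 0.70, order_fidelity = 0.85,
                      cluster_dwell = 2.0, jitter_sd = 25))
}

apply_preset <- function(config, mode, use_preset = TRUE) {
  if (!use_preset) return(config)
  preset <- mode_preset(mode)
  config[names(preset)] <- preset
  config
}

# deterministic 32-bit substream seed for a trial
derive_seed <- function(seed, p_idx, t_idx, phase_idx = 1L) {
  ((as.numeric(seed) * 1000003 + p_idx * 7919 + t_idx * 104729 +
      phase_idx * 499979) %% 2147483629) + 1
}

clamp_screen <- function(x, y, geometry) {
  list(x = pmin(pmax(x, 0), geometry$width_px - 1e-6),
       y = pmin(pmax(y, 0), geometry$height_px - 1e-6))
}

sample_anchors <- function(config) {
  g <- config$geometry
  m <- config$margin_px
  sep <- config$anchor_min_sep_px
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(pts) < config$n_anchors) {
    cand <- c(stats::runif(1, m, g$width_px - m),
              stats::runif(1, m, g$height_px - m))
    if (!nrow(pts) || all(sqrt((pts[, 1] - cand[1])^2 +
                               (pts[, 2] - cand[2])^2) >= sep)) {
      pts <- rbind(pts, cand)
    }
    tries <- tries + 1L
    if (tries > 2000L * config$n_anchors)
      stop("configuration error: ", config$n_anchors,
           " anchors do not fit the screen at a minimum separation of ",
           sep, " px")
  }
  unname(pts)
}

sample_durations <- function(n, config) {
  d <- stats::rlnorm(n, config$duration_meanlog, config$duration_sdlog)
  pmin(pmax(d, 100), 5000)
}

dwell_length <- function(config) {
  1L + stats::rpois(1, max(0, config$cluster_dwell - 1))
}

emit_fixation <- function(base, config) {
  g <- config$geometry
  clamp_screen(base[1] + stats::rnorm(1, 0, config$jitter_sd),
               base[2] + stats::rnorm(1, 0, config$jitter_sd), g)
}

# anchor-tour generator behind the free / part_based / holistic regimes
tour_positions <- function(config) {
  g <- config$geometry
  anchors <- sample_anchors(config)
  ord <- sample.int(nrow(anchors))
  visited <- integer(0)     # anchor row indices in first-visit order
  rev_ptr <- 0L
  xs <- ys <- numeric(0)
  current <- NULL
  while (length(xs) < config$n_fixations) {
    if (length(visited) < length(ord)) {
      id <- ord[length(visited) + 1L]
      visited <- c(visited, id)
      base <- anchors[id, ]
    } else if (stats::runif(1) < config$revisit_prob) {
      if (stats::runif(1) < config$order_fidelity) {
        rev_ptr <- rev_ptr %% length(visited) + 1L
        base <- anchors[visited[rev_ptr], ]
      } else {
        base <- anchors[visited[sample.int(length(visited), 1)], ]
      }
    } else {
      ang <- stats::runif(1, 0, 2 * pi)
      # gamma-distributed jump length (mean saccade_scale, shape 4): genuinely
      # large dispersed saccades, with negligible mass inside one recurrence
      # radius -- exploration is not a revisit
      len <- config$saccade_scale * stats::rgamma(1, shape = 4, rate = 4)
      fresh <- clamp_screen(current[1] + len * cos(ang),
                            current[2] + len * sin(ang), g)
      anchors <- rbind(anchors, c(fresh$x, fresh$y))
      visited <- c(visited, nrow(anchors))
      base <- c(fresh$x, fresh$y)
    }
    current <- base
    for (k in seq_len(dwell_length(config))) {
      if (length(xs) >= config$n_fixations) break
      p <- emit_fixation(base, config)
      xs <- c(xs, p$x); ys <- c(ys, p$y)
    }
  }
  list(x = xs, y = ys)
}

# imagery generator: replay of (a lambda-weighted subset of) the encoding
# fixation locations, cycling in encoding order with occasional jumps
replay_positions <- function(config, encoding) {
  g <- config$geometry
  ex <- encoding$fixations$x_px; ey <- encoding$fixations$y_px
  n_enc <- length(ex)
  m <- min(config$n_anchors, n_enc)
  targets <- sort(sample.int(n_enc, m))
  r <- 0L
  xs <- ys <- numeric(0)
  while (length(xs) < config$n_fixations) {
    if (stats::runif(1) < config$order_fidelity) r <- r %% m + 1L
    else r <- sample.int(m, 1)
    base <- c(ex[targets[r]], ey[targets[r]])
    for (k in seq_len(dwell_length(config))) {
      if (length(xs) >= config$n_fixations) break
      if (stats::runif(1) < config$encoding_coupling) {
        p <- emit_fixation(base, config)
      } else {
        p <- list(x = stats::runif(1, config$margin_px, g$width_px - config$margin_px),
                  y = stats::runif(1, config$margin_px, g$height_px - config$margin_px))
      }
      xs <- c(xs, p$x); ys <- c(ys, p$y)
    }
  }
  list(x = xs, y = ys)
}

mode_condition <- c(free = "FP", part_based = "GCW", holistic = "AS")

#' Generate one synthetic scanpath
#'
#' Draws a single trial under one of the four gaze regimes. Bit-reproducible
#' for a given `seed`; when `seed` is `NULL` the current RNG stream is used.
#'
#' @param config A [cohort_config()].
#' @param mode Gaze regime; see [mode_preset()]. `"imagery"` requires the
#'   `encoding` scanpath it replays.
#' @param encoding Encoding-phase [scanpath()] (imagery mode only).
#' @param participant,trial Labels for the generated scanpath.
#' @param category Stimulus category label.
#' @param seed Optional integer seed for this trial.
#' @param use_preset Apply [mode_preset()] levers for `mode` (default TRUE);
#'   set to `FALSE` to use the levers in `config` as given.
#' @return A [scanpath()] with exactly `config$n_fixations` on-screen
#'   fixations.
#' @export
generate_trial <- function(config, mode = c("free", "part_based", "holistic",
                                            "imagery"),
                           encoding = NULL, participant = "p01", trial = "t01",
                           category = NA_character_, seed = NULL,
                           use_preset = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(as.integer(seed))
  cfg <- apply_preset(config, mode, use_preset)
  if (mode == "imagery") {
    if (is.null(encoding)) stop("imagery mode needs the encoding scanpath")
    pos <- replay_positions(cfg, encoding)
    phase <- "imagery"
    condition <- if (!is.null(encoding$condition)) encoding$condition else NA_character_
  } else {
    pos <- tour_positions(cfg)
    phase <- "encoding"
    condition <- mode_condition[[mode]]
  }
  dur <- sample_durations(cfg$n_fixations, cfg)
  onset <- cumsum(c(0, dur[-length(dur)] + 30))  # 30 ms saccade gaps
  scanpath(data.frame(onset_ms = onset, duration_ms = dur,
                      x_px = pos$x, y_px = pos$y),
           participant = participant, trial = trial, phase = phase,
           condition = condition, category = category,
           geometry = cfg$geometry)
}

#' Generate a synthetic cohort
#'
#' Produces a full multi-participant, multi-trial cohort: for each trial an
#' encoding scanpath in the regime matching its condition (FP = free,
#' GCW = part_based, AS = holistic) and an imagery scanpath replaying it with
#' coupling `encoding_coupling`. Conditions and stimulus categories rotate
#' across trials. Each (participant, trial, phase) draws its own seed
#' substream from the master seed, so the cohort is bit-reproducible and can
#' be extended without reshuffling earlier trials. A behavioural table with
#' simulated probe accuracy and vividness ratings is included for the
#' reporting stage.
#'
#' @param config A [cohort_config()].
#' @param conditions Conditions cycled over trials (default FP, GCW, AS).
#' @return List with `scanpaths` (encoding and imagery [scanpath()]s), `truth`
#'   (one row per generated scanpath recording the generating parameters and
#'   substream seed), and `behaviour` (per-trial accuracy 0/1 and vividness
#'   1-7).
#' @export
generate_cohort <- function(config, conditions = c("FP", "GCW", "AS")) {
  stopifnot(inherits(config, "cohort_config"))
  condition_mode <- c(FP = "free", GCW = "part_based", AS = "holistic")
  categories <- c("abstract", "indoor", "outdoor")
  scanpaths <- list()
  truth <- list()
  behaviour <- list()
  for (p in seq_len(config$n_participants)) {
    pid <- sprintf("p%02d", p)
    for (t in seq_len(config$n_trials)) {
      tid <- sprintf("t%02d", t)
      condition <- conditions[(t - 1) %% length(conditions) + 1]
      category <- categories[(t - 1) %% length(categories) + 1]
      enc_mode <- condition_mode[[condition]]
      enc_seed <- derive_seed(config$seed, p, t, 1L)
      enc <- generate_trial(config, enc_mode, participant = pid, trial = tid,
                            category = category, seed = enc_seed)
      img_seed <- derive_seed(config$seed, p, t, 2L)
      img <- generate_trial(config, "imagery", encoding = enc,
                            participant = pid, trial = tid,
                            category = category, seed = img_seed)
      scanpaths <- c(scanpaths, list(enc, img))
      for (sp in list(enc, img)) {
        mode <- if (sp$phase == "imagery") "imagery" else enc_mode
        lev <- apply_preset(config, mode)
        truth[[length(truth) + 1L]] <- data.frame(
          participant = pid, trial = tid, phase = sp$phase,
          condition = condition, category = category, mode = mode,
          revisit_prob = lev$revisit_prob, order_fidelity = lev$order_fidelity,
          cluster_dwell = lev$cluster_dwell, jitter_sd = lev$jitter_sd,
          encoding_coupling = config$encoding_coupling,
          seed = if (sp$phase == "imagery") img_seed else enc_seed)
      }
      beh_seed <- derive_seed(config$seed, p, t, 3L)
      set.seed(beh_seed)
      behaviour[[length(behaviour) + 1L]] <- data.frame(
        participant = pid, trial = tid, condition = condition,
        category = category,
        accuracy = stats::rbinom(1, 1, 0.70),
        vividness = sample(1:7, 1, prob = c(2, 5, 12, 25, 25, 20, 11)))
    }
  }
  list(scanpaths = scanpaths, truth = do.call(rbind, truth),
       behaviour = do.call(rbind, behaviour), config = config)
}

#' Render a scanpath as a raw gaze-sample track
#'
#' Piecewise-stationary samples at the fixation positions plus isotropic
#' Gaussian noise, joined by linear saccadic transitions paced at roughly
#' 300 deg/s (comfortably above the 30 deg/s detection threshold). Optional
#' blink gaps mark samples invalid mid-fixation, which splits the fixation at
#' detection. Feeds [detect_fixations()] for round-trip testing.
#'
#' @param sp A [scanpath()].
#' @param rate_hz Sampling rate (default 1000 Hz).
#' @param noise_sd_deg Sample noise, degrees (0 for noise-free tracks).
#' @param blink Optional data.frame with columns `fixation` (index) and
#'   `gap_ms`: a blink of that length is inserted in the middle of the given
#'   fixation.
#' @return A [raw_track()] with attribute `truth`: a data.frame of the
#'   rendered fixations on the track's own timeline (`onset_ms`,
#'   `duration_ms`, `x_px`, `y_px`), for round-trip comparisons against
#'   [detect_fixations()].
#' @export
render_raw_track <- function(sp, rate_hz = 1000, noise_sd_deg = 0.05,
                             blink = NULL) {
  stopifnot(inherits(sp, "scanpath"))
  fx <- sp$fixations
  if (!nrow(fx)) stop("cannot render an empty scanpath")
  g <- sp$geometry
  dt <- 1000 / rate_hz
  noise_px <- if (noise_sd_deg > 0)
    2 * g$distance_mm * tan(noise_sd_deg * pi / 360) / g$pitch_mm else 0
  xs <- ys <- tms <- numeric(0)
  valid <- logical(0)
  truth <- fx[c("x_px", "y_px")]
  truth$onset_ms <- truth$duration_ms <- NA_real_
  t_now <- 0
  for (i in seq_len(nrow(fx))) {
    n_fix <- max(1L, round(fx$duration_ms[i] / dt))
    fx_t <- t_now + (seq_len(n_fix) - 1) * dt
    truth$onset_ms[i] <- t_now
    truth$duration_ms[i] <- n_fix * dt
    fx_valid <- rep(TRUE, n_fix)
    if (!is.null(blink) && i %in% blink$fixation) {
      gap <- blink$gap_ms[match(i, blink$fixation)]
      gap_n <- max(1L, round(gap / dt))
      mid <- n_fix %/% 2L
      idx <- seq(mid, min(n_fix, mid + gap_n - 1L))
      fx_valid[idx] <- FALSE
    }
    xs <- c(xs, fx$x_px[i] + stats::rnorm(n_fix, 0, noise_px))
    ys <- c(ys, fx$y_px[i] + stats::rnorm(n_fix, 0, noise_px))
    tms <- c(tms, fx_t)
    valid <- c(valid, fx_valid)
    t_now <- t_now + n_fix * dt
    if (i < nrow(fx)) {
      amp_px <- sqrt((fx$x_px[i + 1] - fx$x_px[i])^2 +
                     (fx$y_px[i + 1] - fx$y_px[i])^2)
      amp_deg <- px_to_deg(amp_px, g)
      n_sac <- max(2L, ceiling(amp_deg / 0.3 / dt))
      frac <- seq_len(n_sac) / (n_sac + 1)
      xs <- c(xs, fx$x_px[i] + frac * (fx$x_px[i + 1] - fx$x_px[i]))
      ys <- c(ys, fx$y_px[i] + frac * (fx$y_px[i + 1] - fx$y_px[i]))
      tms <- c(tms, t_now + (seq_len(n_sac) - 1) * dt)
      valid <- c(valid, rep(TRUE, n_sac))
      t_now <- t_now + n_sac * dt
    }
  }
  cl <- clamp_screen(xs, ys, g)
  out <- raw_track(tms, cl$x, cl$y, valid)
  attr(out, "truth") <- truth[c("onset_ms", "duration_ms", "x_px", "y_px")]
  out
}
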