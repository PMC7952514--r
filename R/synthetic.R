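#' Simulation configuration
#'
#' Defaults mirror the study conditions the generator emulates: 64 channels,
#' 5,000 Hz native rate, 180 s of eyes-closed rest, four microstate classes,
#' a 50 Hz line-interference component, and white sensor noise at the given
#' signal-to-noise ratio (signal RMS / noise RMS).
#'
#' @param n_channels electrode count.
#' @param fs native sampling rate, Hz.
#' @param duration recording length, seconds.
#' @param k number of microstate classes.
#' @param snr ratio of signal RMS to noise RMS (> 0; `Inf` for noiseless).
#' @param line_freq line-interference frequency in Hz, or NULL for none.
#' @param line_amp line-component amplitude, microvolts.
#' @param signal_rms target RMS of the microstate signal, microvolts.
#' @param carrier_band frequency band of the field-power carrier
#'   oscillation, Hz.
#' @param carrier_floor baseline added to the rectified carrier (in units
#'   of the carrier's standard deviation) so the field never collapses
#'   completely between oscillation peaks.
#' @param seed integer seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_channels = 64, fs = 5000, duration = 180,
                              k = 4, snr = 2, line_freq = 50, line_amp = 5,
                              signal_rms = 12, carrier_band = c(12, 18),
                              carrier_floor = 1, seed = 1) {
  if (fs <= 0) stop_ms("fs must be > 0", class = "invalid_config")
  if (duration <= 0) stop_ms("duration must be > 0", class = "invalid_config")
  if (k < 2) stop_ms("k must be >= 2", class = "invalid_config")
  if (!(snr > 0)) stop_ms("snr must be > 0", class = "invalid_config")
  structure(list(n_channels = n_channels, fs = fs, duration = duration,
                 k = k, snr = snr, line_freq = line_freq,
                 line_amp = line_amp, signal_rms = signal_rms,
                 carrier_band = carrier_band, carrier_floor = carrier_floor,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Default microstate switching regime of the generator
#'
#' Mean dwell times of 65-90 ms across the four classes and a mildly
#' non-uniform zero-diagonal transition matrix, chosen so the pipeline
#' measures durations in the 0.05-0.10 s band and per-class occurrences
#' near 3-4.5 per second, the plausibility range of resting-state
#' microstate studies.
#'
#' @param k number of classes.
#' @return list with `transition_matrix` and `mean_durations` (seconds).
#' @export
default_switching <- function(k = 4) {
  if (k == 4) {
    tm <- matrix(c(0.00, 0.40, 0.35, 0.25,
                   0.40, 0.00, 0.30, 0.30,
                   0.30, 0.30, 0.00, 0.40,
                   0.25, 0.35, 0.40, 0.00),
                 nrow = 4, byrow = TRUE)
    md <- c(0.075, 0.065, 0.090, 0.070)
  } else {
    tm <- matrix(1 / (k - 1), k, k); diag(tm) <- 0
    md <- rep(0.075, k)
  }
  list(transition_matrix = tm, mean_durations = md)
}

validate_transition_matrix <- function(tm, k = nrow(tm)) {
  tm <- as.matrix(tm)
  if (nrow(tm) != ncol(tm) || nrow(tm) != k)
    stop_ms("transition matrix must be k x k", class = "invalid_matrix")
  if (any(abs(diag(tm)) > 0))
    stop_ms("transition matrix must have a zero diagonal",
            class = "invalid_matrix")
  if (any(abs(rowSums(tm) - 1) > 1e-9))
    stop_ms("every transition-matrix row must sum to 1",
            class = "invalid_matrix")
  if (any(tm < 0))
    stop_ms("transition probabilities must be non-negative",
            class = "invalid_matrix")
  tm
}

#' Simulate a semi-Markov microstate label sequence
#'
#' Run lengths are drawn geometrically (memoryless) with mean
#' `mean_durations[class] * fs` samples and a minimum of 1 sample;
#' successive run labels follow the zero-diagonal transition matrix. A
#' gamma run-length law is available but off by default.
#'
#' @param transition_matrix k x k row-stochastic matrix, zero diagonal.
#' @param mean_durations per-class mean dwell times in seconds.
#' @param fs sampling rate, Hz.
#' @param duration sequence length in seconds (n = round(fs * duration)).
#' @param seed integer seed.
#' @param run_dist `"geometric"` (default) or `"gamma"`.
#' @param gamma_shape shape parameter for the gamma option.
#' @return integer vector of 1-based class indices, length round(fs*duration).
#' @export
simulate_state_sequence <- function(transition_matrix, mean_durations,
                                    fs, duration, seed = 1,
                                    run_dist = c("geometric", "gamma"),
                                    gamma_shape = 2) {
  run_dist <- match.arg(run_dist)
  k <- length(mean_durations)
  tm <- validate_transition_matrix(transition_matrix, k)
  if (any(mean_durations <= 0))
    stop_ms("mean_durations must be positive", class = "invalid_config")
  n <- round(fs * duration)
  mean_samples <- pmax(mean_durations * fs, 1)
  with_seed(seed, {
    labels <- integer(n)
    pos <- 0L
    state <- sample.int(k, 1)
    while (pos < n) {
      len <- switch(run_dist,
        geometric = stats::rgeom(1, prob = 1 / mean_samples[state]) + 1L,
        gamma = max(1L, as.integer(round(stats::rgamma(
          1, shape = gamma_shape,
          scale = mean_samples[state] / gamma_shape)))))
      len <- min(len, n - pos)
      labels[(pos + 1L):(pos + len)] <- state
      pos <- pos + len
      state <- sample.int(k, 1, prob = tm[state, ])
    }
    labels
  })
}

#' Band-limited field-power carrier oscillation
#'
#' Zero-mean unit-variance band-limited Gaussian noise, synthesized in the
#' frequency domain. Its rectified modulus (plus the configured floor) is
#' the generator's GFP envelope; its zero crossings define the switching
#' grid of [simulate_labels_on_carrier()].
#'
#' @param n number of samples.
#' @param fs sampling rate, Hz.
#' @param band length-2 frequency band, Hz.
#' @param seed integer seed.
#' @return numeric vector, sd 1.
#' @export
microstate_carrier <- function(n, fs, band = c(12, 18), seed = 1) {
  with_seed(seed, {
    white <- stats::rnorm(n)
    f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
    f <- pmin(f, fs - f)
    keep <- f >= band[1] & f <= band[2]
    if (!any(keep)) keep <- f <= fs / 4  # very low fs fallback
    osc <- Re(stats::fft(stats::fft(white) * keep, inverse = TRUE)) / n
    osc / stats::sd(osc)
  })
}

#' Simulate a label sequence locked to the carrier's oscillation cycles
#'
#' The study-level switching model: microstates switch at troughs of the
#' global field power, so run boundaries sit on the carrier's full-cycle
#' grid (upward zero crossings). Dwell times are geometric in whole
#' cycles with per-class means `mean_durations` (converted using the
#' carrier's realized mean cycle length); run labels follow the
#' transition matrix.
#'
#' @param carrier output of [microstate_carrier()].
#' @param transition_matrix k x k row-stochastic, zero diagonal.
#' @param mean_durations per-class mean dwell, seconds.
#' @param fs sampling rate, Hz.
#' @param seed integer seed.
#' @return integer label vector, same length as `carrier`.
#' @export
simulate_labels_on_carrier <- function(carrier, transition_matrix,
                                       mean_durations, fs, seed = 1) {
  k <- length(mean_durations)
  tm <- validate_transition_matrix(transition_matrix, k)
  n <- length(carrier)
  up <- which(diff(sign(carrier)) > 0)
  cb <- c(0, up, n)
  n_seg <- length(cb) - 1
  if (n_seg < 2)
    stop_ms("carrier too short for cycle-locked switching",
            class = "invalid_config")
  mean_cyc <- n / fs / n_seg
  mu <- pmax(mean_durations / mean_cyc, 1)
  with_seed(seed, {
    labels <- integer(n)
    seg_i <- 1L
    state <- sample.int(k, 1)
    while (seg_i <= n_seg) {
      dwell <- stats::rgeom(1, prob = 1 / mu[state]) + 1L
      last <- min(seg_i + dwell - 1L, n_seg)
      labels[(cb[seg_i] + 1L):cb[last + 1L]] <- state
      seg_i <- last + 1L
      state <- sample.int(k, 1, prob = tm[state, ])
    }
    labels
  })
}

#' Ground truth for a synthetic study subject
#'
#' @param templates a `template_set` (the true maps).
#' @param labels per-sample true class indices.
#' @param transition_matrix the generating k x k matrix.
#' @param mean_durations generating per-class dwell means, seconds.
#' @param seed the seed used.
#' @return a `ground_truth` list.
#' @export
ground_truth <- function(templates, labels, transition_matrix,
                         mean_durations, seed) {
  validate_transition_matrix(transition_matrix, length(mean_durations))
  structure(list(templates = templates, labels = as.integer(labels),
                 transition_matrix = transition_matrix,
                 mean_durations = mean_durations, seed = as.integer(seed)),
            class = "ground_truth")
}

#' Synthesize a multichannel EEG recording from ground truth
#'
#' Each sample is `a_t * s_t * template[, L_t] * scale + noise (+ line)`:
#' `a_t = |carrier| + floor` is the rectified band-limited GFP envelope,
#' `s_t` combines the carrier's sign (polarity alternates at every
#' envelope trough, as in oscillatory EEG) with an independent random
#' polarity flip per run, white sensor noise is scaled to the configured
#' SNR, and an optional quasi-common-mode line sinusoid is added.
#'
#' @param truth a `ground_truth` whose label sequence matches the config.
#' @param config a `simulation_config`.
#' @param carrier optional carrier from [microstate_carrier()]; generated
#'   from `config$seed` when NULL. Supplying the carrier used to build a
#'   cycle-locked label sequence keeps switching aligned with the
#'   envelope's troughs.
#' @return list with `recording` (class `recording`) and `truth`, the
#'   input ground truth augmented with the per-run polarity flips.
#' @export
synthesize_eeg <- function(truth, config, carrier = NULL) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(config, "simulation_config"))
  n <- length(truth$labels)
  n_ch <- nrow(truth$templates$maps)
  if (n != round(config$fs * config$duration))
    stop_ms("label sequence length does not match config fs * duration",
            class = "invalid_config")
  if (is.null(carrier))
    carrier <- microstate_carrier(n, config$fs, config$carrier_band,
                                  seed = config$seed + 1L)
  out <- with_seed(config$seed + 2L, {
    runs <- rle(truth$labels)
    flips <- sample(c(-1, 1), length(runs$lengths), replace = TRUE)
    s_run <- rep(flips, runs$lengths)
    m <- s_run * (carrier + config$carrier_floor * sign(carrier))
    maps <- truth$templates$maps
    sig <- matrix(0, n_ch, n)
    for (i in seq_len(n_ch)) sig[i, ] <- maps[i, truth$labels] * m
    scale <- config$signal_rms / sqrt(mean(sig^2))
    sig <- sig * scale
    if (is.finite(config$snr)) {
      sigma <- config$signal_rms / config$snr
      for (i in seq_len(n_ch)) sig[i, ] <- sig[i, ] + stats::rnorm(n, sd = sigma)
    }
    if (!is.null(config$line_freq) && config$line_amp > 0) {
      tvec <- (seq_len(n) - 1) / config$fs
      line <- config$line_amp * sin(2 * pi * config$line_freq * tvec)
      gains <- 1 + 0.3 * sin(seq_len(n_ch))
      for (i in seq_len(n_ch)) sig[i, ] <- sig[i, ] + gains[i] * line
    }
    list(data = sig, polarity = flips)
  })
  rec <- recording(out$data, fs = config$fs)
  truth$polarity <- out$polarity
  list(recording = rec, truth = truth)
}

#' Project the generator's true labels onto the analysis grid
#'
#' Decimates the native-rate true label sequence to the analysis sampling
#' rate (sample-aligned with [resample_recording()]'s decimation grid),
#' trims to whole epochs, optionally restricts to surviving epochs, and
#' wraps the result as a `segmentation` so the same parameter and
#' transition estimators apply to truth and to backfitted labels.
#'
#' @param truth a `ground_truth`.
#' @param native_fs the generation sampling rate, Hz.
#' @param target_fs the analysis rate, Hz (native_fs must be a multiple).
#' @param epoch_length epoch length in seconds.
#' @param kept_epoch_ids epochs to keep (default: all full epochs).
#' @return a `segmentation` of the true labels.
#' @export
true_segmentation <- function(truth, native_fs, target_fs = 250,
                              epoch_length = 2, kept_epoch_ids = NULL) {
  q <- native_fs / target_fs
  if (abs(q - round(q)) > 1e-9)
    stop_ms("native_fs must be an integer multiple of target_fs",
            class = "invalid_config")
  lab <- truth$labels[seq(1, length(truth$labels), by = round(q))]
  epl <- round(target_fs * epoch_length)
  n_ep <- floor(length(lab) / epl)
  if (n_ep < 1) stop_ms("labels shorter than one epoch",
                        class = "invalid_data")
  lab <- lab[seq_len(n_ep * epl)]
  epoch_ids <- rep(seq_len(n_ep), each = epl)
  if (!is.null(kept_epoch_ids)) {
    keep <- epoch_ids %in% kept_epoch_ids
    lab <- lab[keep]; epoch_ids <- epoch_ids[keep]
  }
  k <- nrow(truth$transition_matrix)
  cls <- if (k == 4) c("A", "B", "C", "D") else paste0("M", seq_len(k))
  structure(list(labels = lab, r_values = rep(1, length(lab)),
                 epoch_ids = epoch_ids, fs = target_fs, k = k,
                 class_labels = cls, n_flat = 0L),
            class = "segmentation")
}

#' Simulate one complete synthetic subject
#'
#' The study-level generator: a band-limited carrier defines the GFP
#' envelope; the microstate label sequence switches on the carrier's
#' full-cycle grid (states change at field-power troughs); the recording
#' is synthesized with per-run polarity flips, sensor noise, and line
#' interference. All randomness derives from `config$seed`.
#'
#' @param config a `simulation_config`.
#' @param templates optional shared true `template_set`.
#' @param switching optional list(transition_matrix, mean_durations);
#'   defaults to [default_switching()].
#' @return list with `recording` and `truth`.
#' @export
simulate_subject <- function(config = simulation_config(),
                             templates = NULL, switching = NULL) {
  if (is.null(switching)) switching <- default_switching(config$k)
  if (is.null(templates))
    templates <- make_templates(config$n_channels, config$k, seed = 1000)
  n <- round(config$fs * config$duration)
  carrier <- microstate_carrier(n, config$fs, config$carrier_band,
                                seed = config$seed + 1L)
  labels <- simulate_labels_on_carrier(
    carrier, switching$transition_matrix, switching$mean_durations,
    config$fs, seed = config$seed)
  truth <- ground_truth(templates, labels, switching$transition_matrix,
                        switching$mean_durations, config$seed)
  synthesize_eeg(truth, config, carrier = carrier)
}
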