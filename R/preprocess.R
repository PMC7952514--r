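# Equiripple FIR design with windowed-design fallback: remez's exchange
# algorithm fails to converge at the multi-thousand-tap orders narrow bands
# at high sampling rates require; a windowed (Hamming/Blackman) design then
# provides the attenuation contract instead.
design_fir <- function(n_order, bands, amps) {
  h <- try(suppressWarnings(signal::remez(n_order, bands, amps)),
           silent = TRUE)
  if (!inherits(h, "try-error") && all(is.finite(h))) return(as.numeric(h))
  # windowed fallback: cutoffs at the transition-band midpoints
  chg <- which(amps[-1] != amps[-length(amps)])
  mid <- (bands[chg] + bands[chg + 1]) / 2
  type <- if (amps[1] == 1 && amps[length(amps)] == 1) "stop"
          else if (amps[1] == 1) "low" else "high"
  as.numeric(signal::fir1(n_order, mid, type = type,
                          window = signal::hamming(n_order + 1)))
}

# Zero-phase application of a symmetric (linear-phase) FIR via FFT
# convolution with edge reflection; delay-compensated, so the net phase is
# exactly zero. Channels are packed pairwise into one complex FFT (the
# kernel is real, so convolution acts on real and imaginary parts
# independently), halving the transform count.
fir_apply_zerophase <- function(data, h) {
  n_tap <- length(h)
  half <- (n_tap - 1) / 2
  n <- ncol(data)
  pad <- min(n - 1, n_tap)
  n_ext <- n + 2 * pad
  nfft <- stats::nextn(n_ext + n_tap, c(2, 3, 5))
  H <- stats::fft(c(h, numeric(nfft - n_tap)))
  out <- data
  n_ch <- nrow(data)
  extend <- function(x) c(2 * x[1] - x[(pad + 1):2], x,
                          2 * x[n] - x[(n - 1):(n - pad)])
  sel <- (pad + half + 1):(pad + half + n)
  i <- 1L
  while (i <= n_ch) {
    if (i < n_ch) {
      z <- complex(real = extend(data[i, ]), imaginary = extend(data[i + 1L, ]))
      y <- stats::fft(stats::fft(c(z, complex(real = numeric(nfft - n_ext)))) * H,
                      inverse = TRUE) / nfft
      out[i, ] <- Re(y)[sel]
      out[i + 1L, ] <- Im(y)[sel]
      i <- i + 2L
    } else {
      X <- stats::fft(c(extend(data[i, ]), numeric(nfft - n_ext)))
      y <- Re(stats::fft(X * H, inverse = TRUE)) / nfft
      out[i, ] <- y[sel]
      i <- i + 1L
    }
  }
  out
}

# single-pass IIR y = filter(b, a, x) at C speed
iir_once <- function(b, a, x) {
  nb <- length(b)
  y <- stats::filter(c(numeric(nb - 1), x), b, method = "convolution",
                     sides = 1)
  y <- y[-seq_len(nb - 1)]
  if (length(a) > 1) y <- stats::filter(y, -a[-1], method = "recursive")
  as.numeric(y)
}

# Zero-phase IIR (Butterworth) filtering with edge reflection, per channel.
# `pad` should cover the filter's transient (a few time constants of its
# lowest corner frequency).
iir_filtfilt <- function(data, flt, pad) {
  n <- ncol(data)
  pad <- max(12L, min(n - 1L, as.integer(pad)))
  out <- data
  b <- as.numeric(flt$b); a <- as.numeric(flt$a)
  for (i in seq_len(nrow(data))) {
    x <- data[i, ]
    ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
    y <- rev(iir_once(b, a, rev(iir_once(b, a, ext))))
    out[i, ] <- y[(pad + 1):(pad + n)]
  }
  out
}

#' Band-stop (notch) filter a recording
#'
#' Zero-phase equiripple (Parks-McClellan) FIR band-stop, defaulting to the
#' 48-52 Hz stop band used against 50 Hz line interference. The design
#' contract is attenuation at the line frequency >= 40 dB with passband
#' ripple below 1 dB outside the transition bands.
#'
#' @param rec a `recording`.
#' @param stop_band length-2 numeric, stop-band edges in Hz.
#' @param trans_width transition bandwidth in Hz on each side.
#' @return the filtered `recording`.
#' @export
notch_filter <- function(rec, stop_band = c(48, 52), trans_width = 4) {
  stopifnot(inherits(rec, "recording"))
  if (rec$fs <= 2 * stop_band[2])
    stop_ms("sampling rate too low for the requested stop band",
            class = "invalid_config")
  nyq <- rec$fs / 2
  f <- c(0, stop_band[1] - trans_width, stop_band[1], stop_band[2],
         stop_band[2] + trans_width, nyq) / nyq
  # odd tap count, symmetric -> exactly linear phase, type I
  n_tap <- 2 * round(3.3 * rec$fs / trans_width / 2) + 1
  h <- design_fir(n_tap - 1, f, c(1, 1, 0, 0, 1, 1))
  rec$data <- fir_apply_zerophase(rec$data, h)
  rec
}

#' Band-pass filter a recording
#'
#' Zero-phase Butterworth band-pass implemented as cascaded high-pass and
#' low-pass sections, each applied forward-backward. The -3 dB points fall
#' within 20% of the requested edges.
#'
#' @param rec a `recording`.
#' @param low lower edge, Hz.
#' @param high upper edge, Hz.
#' @param order filter order per section (doubled by the two-pass).
#' @return the filtered `recording`.
#' @export
bandpass_filter <- function(rec, low, high, order = 4) {
  stopifnot(inherits(rec, "recording"))
  if (!(low > 0 && low < high && high < rec$fs / 2))
    stop_ms("need 0 < low < high < fs/2", class = "invalid_config")
  nyq <- rec$fs / 2
  # low-order high-pass keeps the recursion numerically safe at very low
  # normalized cutoffs (0.1 Hz at 5 kHz)
  hp <- signal::butter(2, low / nyq, type = "high")
  lp <- signal::butter(order, high / nyq, type = "low")
  pad_hp <- round(3 * rec$fs / (2 * pi * low))   # ~3 time constants
  pad_lp <- round(3 * rec$fs / (2 * pi * high)) + 12
  rec$data <- iir_filtfilt(iir_filtfilt(rec$data, hp, pad_hp), lp, pad_lp)
  rec
}

#' Resample a recording
#'
#' Anti-alias filtered resampling: integer decimation after a zero-phase
#' FIR low-pass when `fs / target_fs` is an integer, polyphase resampling
#' otherwise. Output length is `round(n * target_fs / fs)`.
#'
#' @param rec a `recording`.
#' @param target_fs target sampling rate, Hz.
#' @return the resampled `recording`.
#' @export
resample_recording <- function(rec, target_fs = 250) {
  stopifnot(inherits(rec, "recording"))
  if (target_fs > rec$fs)
    stop_ms("target_fs must not exceed fs", class = "invalid_config")
  if (target_fs == rec$fs) return(rec)
  n <- ncol(rec$data)
  n_out <- round(n * target_fs / rec$fs)
  ratio <- rec$fs / target_fs
  if (abs(ratio - round(ratio)) < 1e-9) {
    q <- round(ratio)
    cutoff <- 0.8 * (target_fs / 2)
    trans <- 0.4 * (target_fs / 2)
    n_tap <- 2 * round(3.3 * rec$fs / trans / 2) + 1
    nyq <- rec$fs / 2
    h <- design_fir(n_tap - 1,
                    c(0, cutoff, cutoff + trans, nyq) / nyq,
                    c(1, 1, 0, 0))
    filtered <- fir_apply_zerophase(rec$data, h)
    idx <- seq(1, by = q, length.out = n_out)
    rec$data <- filtered[, idx, drop = FALSE]
  } else {
    p <- target_fs; q <- rec$fs
    g <- function(a, b) if (b == 0) a else g(b, a %% b)
    d <- g(round(p * 1e6), round(q * 1e6))
    p <- round(p * 1e6) / d; q <- round(q * 1e6) / d
    res <- t(apply(rec$data, 1, function(x) signal::resample(x, p, q)))
    rec$data <- res[, seq_len(min(ncol(res), n_out)), drop = FALSE]
  }
  rec$fs <- target_fs
  rec
}

#' Segment a recording into fixed-length epochs
#'
#' Consecutive, non-overlapping epochs; a trailing partial epoch is
#' discarded.
#'
#' @param rec a `recording`.
#' @param epoch_length epoch length in seconds (default 2 s).
#' @return an `epoched` object.
#' @export
epoch_recording <- function(rec, epoch_length = 2) {
  stopifnot(inherits(rec, "recording"))
  n_samp <- round(rec$fs * epoch_length)
  n_ep <- floor(ncol(rec$data) / n_samp)
  if (n_ep < 1)
    stop_ms("recording shorter than one epoch", class = "invalid_data")
  d <- rec$data[, seq_len(n_ep * n_samp), drop = FALSE]
  arr <- aperm(array(d, dim = c(nrow(d), n_samp, n_ep)), c(3, 1, 2))
  epoched_data(arr, fs = rec$fs, epoch_length = epoch_length,
               channel_labels = rec$channel_labels,
               reference = rec$reference)
}

#' Reject high-amplitude epochs
#'
#' Automated surrogate for visual artifact inspection: any epoch whose
#' peak-to-peak amplitude on any channel exceeds the limit is dropped.
#' Surviving original epoch indices are kept in `kept_epoch_ids` and the
#' rejection count is attached as attribute `n_rejected`.
#'
#' @param ep an `epoched` object.
#' @param peak_to_peak_limit amplitude limit in microvolts (default 150).
#' @return the cleaned `epoched` object.
#' @export
reject_bad_epochs <- function(ep, peak_to_peak_limit = 150) {
  stopifnot(inherits(ep, "epoched"))
  ptp <- apply(ep$data, 1, function(e) max(apply(e, 1, function(ch)
    diff(range(ch)))))
  keep <- ptp <= peak_to_peak_limit
  if (!any(keep))
    stop_ms("all epochs rejected at limit ", peak_to_peak_limit, " uV",
            class = "empty_result")
  out <- epoched_data(ep$data[keep, , , drop = FALSE], fs = ep$fs,
                      epoch_length = ep$epoch_length,
                      kept_epoch_ids = ep$kept_epoch_ids[keep],
                      channel_labels = ep$channel_labels,
                      reference = ep$reference)
  attr(out, "n_rejected") <- sum(!keep)
  out
}

#' Re-reference epochs to the average reference
#'
#' Subtracts the instantaneous mean across channels at every sample, so the
#' per-sample channel mean is 0 (within 1e-10). Idempotent: applying it to
#' already average-referenced data warns and returns an identical result.
#'
#' @param ep an `epoched` object.
#' @return the re-referenced `epoched` object.
#' @export
average_reference <- function(ep) {
  stopifnot(inherits(ep, "epoched"))
  if (dim(ep$data)[2] < 2)
    stop_ms("average reference needs >= 2 channels", class = "invalid_data")
  if (identical(ep$reference, "average"))
    warning("data already average-referenced; re-applying is a no-op")
  m <- apply(ep$data, c(1, 3), mean)
  ep$data <- ep$data - aperm(
    array(m, dim = c(dim(ep$data)[1], dim(ep$data)[3], dim(ep$data)[2])),
    c(1, 3, 2))
  ep$reference <- "average"
  ep
}

# band-pass on epoched data (applied per epoch, channels x samples)
bandpass_epochs <- function(ep, low, high, order = 4) {
  stopifnot(inherits(ep, "epoched"))
  for (e in seq_len(dim(ep$data)[1])) {
    rec_e <- recording(ep$data[e, , ], fs = ep$fs,
                       channel_labels = ep$channel_labels)
    ep$data[e, , ] <- bandpass_filter(rec_e, low, high, order = order)$data
  }
  ep
}

#' Run the full preprocessing chain
#'
#' The exact stage order is: notch (48-52 Hz) -> band-pass 0.1-40 Hz ->
#' resample to 250 Hz -> 2 s epochs -> peak-to-peak rejection ->
#' average reference -> band-pass 2-20 Hz (applied per epoch).
#'
#' @param rec a raw `recording`.
#' @param notch_band stop-band edges, Hz.
#' @param broad_band first band-pass edges, Hz.
#' @param target_fs resampling target, Hz.
#' @param epoch_length epoch length, seconds.
#' @param peak_to_peak_limit rejection limit, microvolts.
#' @param narrow_band final band-pass edges, Hz.
#' @return an `epoched` object ready for microstate analysis.
#' @export
preprocess <- function(rec, notch_band = c(48, 52), broad_band = c(0.1, 40),
                       target_fs = 250, epoch_length = 2,
                       peak_to_peak_limit = 150, narrow_band = c(2, 20)) {
  rec <- notch_filter(rec, stop_band = notch_band)
  rec <- bandpass_filter(rec, broad_band[1], broad_band[2])
  rec <- resample_recording(rec, target_fs)
  ep <- epoch_recording(rec, epoch_length)
  ep <- reject_bad_epochs(ep, peak_to_peak_limit)
  n_rej <- attr(ep, "n_rejected")
  ep <- average_reference(ep)
  ep <- bandpass_epochs(ep, narrow_band[1], narrow_band[2])
  attr(ep, "n_rejected") <- n_rej
  ep
}
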