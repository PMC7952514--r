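#' Write a recording to the internal array container
#'
#' Two files: `<path>.json` (metadata: fs, channel labels, reference,
#' dimensions) and `<path>.dat` (channel-major IEEE doubles,
#' little-endian). The round trip is bit-exact.
#'
#' @param rec a `recording`.
#' @param path file path prefix (without extension).
#' @return `path`, invisibly.
#' @export
write_container <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  meta <- list(format = "microstatr-container", version = 1L,
               n_channels = nrow(rec$data), n_samples = ncol(rec$data),
               fs = rec$fs, channel_labels = rec$channel_labels,
               reference = rec$reference)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(path, ".dat"), "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$data), con, size = 8, endian = "little")
  invisible(path)
}

#' Read a recording from the internal array container
#'
#' @param path file path prefix used in [write_container()].
#' @return a `recording`.
#' @export
read_container <- function(path) {
  jf <- paste0(path, ".json"); df <- paste0(path, ".dat")
  if (!file.exists(jf)) stop_ms("missing container metadata file: ", jf,
                                class = "missing_file")
  if (!file.exists(df)) stop_ms("missing container data file: ", df,
                                class = "missing_file")
  meta <- jsonlite::read_json(jf, simplifyVector = TRUE)
  if (!identical(meta$format, "microstatr-container"))
    stop_ms("not a microstatr container: ", jf, class = "parse_error")
  n <- meta$n_channels * meta$n_samples
  con <- file(df, "rb")
  on.exit(close(con))
  x <- readBin(con, what = "double", n = n, size = 8, endian = "little")
  if (length(x) != n) stop_ms("container data truncated: ", df,
                              class = "parse_error")
  recording(matrix(x, nrow = meta$n_channels), fs = as.numeric(meta$fs),
            channel_labels = meta$channel_labels,
            reference = meta$reference)
}

edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1, width)
}

#' Write a recording as EDF
#'
#' Minimal continuous EDF: 16-bit samples with per-channel symmetric
#' physical ranges. Record duration is 1 s; a trailing partial record is
#' dropped. The quantization step is
#' `(phys_max - phys_min) / (dig_max - dig_min)`.
#'
#' @param rec a `recording` (fs must be a positive integer).
#' @param path output `.edf` path.
#' @return `path`, invisibly; attribute `quant_step` holds the per-channel
#'   quantization step in microvolts.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop_ms("EDF export needs an integer sampling rate", class = "invalid_config")
  fs <- round(fs)
  n_ch <- nrow(rec$data)
  n_rec <- floor(ncol(rec$data) / fs)
  if (n_rec < 1) stop_ms("recording shorter than one EDF record",
                         class = "invalid_data")
  pmaxs <- pmax(apply(abs(rec$data), 1, max), 1e-6)
  phys_min <- -pmaxs; phys_max <- pmaxs
  dig_min <- -32768; dig_max <- 32767
  header <- paste0(
    edf_field("0", 8),
    edf_field("X X X X", 80),
    edf_field("Startdate X X X microstatr", 80),
    edf_field("01.01.00", 8), edf_field("00.00.00", 8),
    edf_field(256 * (1 + n_ch), 8),
    edf_field("", 44),
    edf_field(n_rec, 8),
    edf_field(1, 8),
    edf_field(n_ch, 4))
  sig <- paste0(
    paste(vapply(rec$channel_labels, edf_field, "", width = 16),
          collapse = ""),
    paste(rep(edf_field("", 80), n_ch), collapse = ""),
    paste(rep(edf_field("uV", 8), n_ch), collapse = ""),
    paste(vapply(sprintf("%.6g", phys_min), edf_field, "", width = 8),
          collapse = ""),
    paste(vapply(sprintf("%.6g", phys_max), edf_field, "", width = 8),
          collapse = ""),
    paste(rep(edf_field(dig_min, 8), n_ch), collapse = ""),
    paste(rep(edf_field(dig_max, 8), n_ch), collapse = ""),
    paste(rep(edf_field("", 80), n_ch), collapse = ""),
    paste(rep(edf_field(fs, 8), n_ch), collapse = ""),
    paste(rep(edf_field("", 32), n_ch), collapse = ""))
  # re-read the printed physical ranges so scaling matches the header text
  pm_lo <- as.numeric(sprintf("%.6g", phys_min))
  pm_hi <- as.numeric(sprintf("%.6g", phys_max))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(header, sig), con, eos = NULL)
  scale <- (dig_max - dig_min) / (pm_hi - pm_lo)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    block <- rec$data[, idx, drop = FALSE]
    dig <- round((block - pm_lo) * scale + dig_min)
    dig <- pmin(pmax(dig, dig_min), dig_max)
    writeBin(as.integer(t(dig)), con, size = 2, endian = "little")
  }
  out <- path
  attr(out, "quant_step") <- (pm_hi - pm_lo) / (dig_max - dig_min)
  invisible(out)
}

read_edf_header_field <- function(raw, offset, width) {
  trimws(rawToChar(raw[(offset + 1):(offset + width)]))
}

#' Read an EDF recording
#'
#' Supports continuous 16-bit EDF with a uniform sampling rate across
#' channels; samples are rescaled to physical units (microvolts) using the
#' header's physical/digital ranges.
#'
#' @param path `.edf` file path.
#' @return a `recording`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop_ms("no such file: ", path,
                                  class = "missing_file")
  sz <- file.size(path)
  if (sz < 256) stop_ms("truncated EDF header: ", path, class = "parse_error")
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", 256)
  n_header <- suppressWarnings(as.integer(read_edf_header_field(head, 184, 8)))
  n_rec <- suppressWarnings(as.integer(read_edf_header_field(head, 236, 8)))
  dur <- suppressWarnings(as.numeric(read_edf_header_field(head, 244, 8)))
  n_ch <- suppressWarnings(as.integer(read_edf_header_field(head, 252, 4)))
  if (any(is.na(c(n_header, n_rec, dur, n_ch))) || n_ch < 1)
    stop_ms("unparseable EDF header: ", path, class = "parse_error")
  if (sz < n_header) stop_ms("truncated EDF header: ", path,
                             class = "parse_error")
  sig <- readBin(con, "raw", 256 * n_ch)
  fld <- function(off_per, width) vapply(seq_len(n_ch) - 1, function(i)
    read_edf_header_field(sig, off_per + i * width, width), "")
  labels <- fld(0, 16)
  phys_min <- as.numeric(fld(n_ch * (16 + 80 + 8), 8))
  phys_max <- as.numeric(fld(n_ch * (16 + 80 + 8 + 8), 8))
  dig_min <- as.numeric(fld(n_ch * (16 + 80 + 8 + 8 + 8), 8))
  dig_max <- as.numeric(fld(n_ch * (16 + 80 + 8 + 8 + 8 + 8), 8))
  spr <- as.integer(fld(n_ch * (16 + 80 + 8 + 8 + 8 + 8 + 8 + 80), 8))
  if (length(unique(spr)) != 1)
    stop_ms("mixed per-channel sampling rates are not supported",
            class = "parse_error")
  fs <- spr[1] / dur
  need <- n_rec * n_ch * spr[1]
  x <- readBin(con, "integer", n = need, size = 2, signed = TRUE,
               endian = "little")
  if (length(x) != need) stop_ms("truncated EDF data: ", path,
                                 class = "parse_error")
  dat <- matrix(NA_real_, n_ch, n_rec * spr[1])
  arr <- array(x, dim = c(spr[1], n_ch, n_rec))
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (i in seq_len(n_ch)) {
    dat[i, ] <- as.vector(arr[, i, ]) * scale[i] +
      (phys_min[i] - dig_min[i] * scale[i])
  }
  recording(dat, fs = fs, channel_labels = labels)
}

#' Write a recording in BrainVision format
#'
#' Emits the `.vhdr`/`.eeg`/`.vmrk` triad with multiplexed IEEE float32
#' binary data and unit channel resolution. Intended for fixtures and
#' round-trip testing.
#'
#' @param rec a `recording`.
#' @param path_base path without extension.
#' @return `path_base`, invisibly.
#' @export
write_brainvision <- function(rec, path_base) {
  stopifnot(inherits(rec, "recording"))
  base <- basename(path_base)
  vhdr <- paste0(path_base, ".vhdr")
  lines <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "", "[Common Infos]",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(rec$data)),
    sprintf("SamplingInterval=%.10g", 1e6 / rec$fs),
    "", "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "", "[Channel Infos]",
    sprintf("Ch%d=%s,,1,%s", seq_len(nrow(rec$data)),
            rec$channel_labels, "µV"))
  writeLines(lines, vhdr)
  writeLines(c("Brain Vision Data Exchange Marker File, Version 1.0",
               "", "[Common Infos]", paste0("DataFile=", base, ".eeg"),
               "", "[Marker Infos]",
               "Mk1=New Segment,,1,1,0"), paste0(path_base, ".vmrk"))
  con <- file(paste0(path_base, ".eeg"), "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$data), con, size = 4, endian = "little")
  invisible(path_base)
}

parse_vhdr <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !grepl("Brain Vision", lines[1], fixed = TRUE))
    stop_ms("not a BrainVision header: ", path, class = "parse_error")
  section <- ""
  kv <- list(); channels <- list()
  for (ln in lines[-1]) {
    ln <- trimws(ln)
    if (ln == "" || startsWith(ln, ";")) next
    if (grepl("^\\[.*\\]$", ln)) { section <- ln; next }
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) next
    key <- substr(ln, 1, eq - 1); val <- substr(ln, eq + 1, nchar(ln))
    if (section == "[Channel Infos]") channels[[key]] <- val
    else kv[[key]] <- val
  }
  list(kv = kv, channels = channels)
}

#' Read a BrainVision recording
#'
#' Parses the `.vhdr` header and loads the binary `.eeg` payload
#' (IEEE float32 or signed int16; multiplexed or vectorized orientation),
#' applying each channel's resolution so output is in microvolts. Errors
#' name any missing sidecar file.
#'
#' @param path path to the `.vhdr` file.
#' @return a `recording`.
#' @export
read_brainvision <- function(path) {
  if (!file.exists(path)) stop_ms("no such file: ", path,
                                  class = "missing_file")
  hd <- parse_vhdr(path)
  kv <- hd$kv
  need <- c("DataFile", "NumberOfChannels", "SamplingInterval")
  for (k in need) if (is.null(kv[[k]]))
    stop_ms("BrainVision header missing ", k, ": ", path,
            class = "parse_error")
  dir <- dirname(path)
  data_file <- file.path(dir, kv$DataFile)
  if (!file.exists(data_file))
    stop_ms("missing BrainVision data file: ", data_file,
            class = "missing_file")
  if (!is.null(kv$MarkerFile) &&
      !file.exists(file.path(dir, kv$MarkerFile)))
    stop_ms("missing BrainVision marker file: ",
            file.path(dir, kv$MarkerFile), class = "missing_file")
  n_ch <- as.integer(kv$NumberOfChannels)
  fs <- 1e6 / as.numeric(kv$SamplingInterval)
  fmt <- toupper(if (is.null(kv$BinaryFormat)) "IEEE_FLOAT_32"
                 else kv$BinaryFormat)
  orient <- toupper(if (is.null(kv$DataOrientation)) "MULTIPLEXED"
                    else kv$DataOrientation)
  ch_info <- lapply(hd$channels, function(v) strsplit(v, ",")[[1]])
  labels <- vapply(seq_len(n_ch), function(i) {
    ci <- ch_info[[paste0("Ch", i)]]
    if (is.null(ci) || length(ci) < 1 || ci[1] == "") sprintf("Ch%02d", i)
    else ci[1]
  }, "")
  resol <- vapply(seq_len(n_ch), function(i) {
    ci <- ch_info[[paste0("Ch", i)]]
    r <- if (!is.null(ci) && length(ci) >= 3 && nzchar(ci[3]))
      as.numeric(ci[3]) else 1
    if (is.na(r)) 1 else r
  }, 0)
  sz <- file.size(data_file)
  bytes <- if (fmt == "INT_16") 2L else 4L
  n_tot <- floor(sz / bytes)
  n_samp <- floor(n_tot / n_ch)
  con <- file(data_file, "rb")
  on.exit(close(con))
  x <- if (fmt == "INT_16")
    readBin(con, "integer", n = n_ch * n_samp, size = 2, signed = TRUE,
            endian = "little")
  else if (fmt == "IEEE_FLOAT_32")
    readBin(con, "double", n = n_ch * n_samp, size = 4, endian = "little")
  else stop_ms("unsupported BinaryFormat: ", fmt, class = "parse_error")
  dat <- if (orient == "MULTIPLEXED") matrix(x, nrow = n_ch)
         else t(matrix(x, ncol = n_ch))
  dat <- dat * resol
  recording(dat, fs = fs, channel_labels = labels)
}

#' Read a recording in any supported format
#'
#' @param path file path (`.vhdr` for BrainVision, `.edf` for EDF, path
#'   prefix for the internal container).
#' @param format one of `"brainvision"`, `"edf"`, `"internal"`; guessed
#'   from the extension when missing.
#' @return a `recording` in microvolts.
#' @export
read_recording <- function(path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, vhdr = "brainvision", edf = "edf", "internal")
  }
  switch(match.arg(format, c("brainvision", "edf", "internal")),
         brainvision = read_brainvision(path),
         edf = read_edf(path),
         internal = read_container(path))
}

#' Write a ground-truth sidecar for a synthetic recording
#'
#' CSV of (sample, true_label, polarity) plus a JSON metadata file with
#' the true transition matrix, dwell means, and seed.
#'
#' @param truth a `ground_truth` (with `polarity` when synthesized).
#' @param path_base path prefix; writes `<path>_truth.csv` and
#'   `<path>_truth.json`.
#' @return `path_base`, invisibly.
#' @export
write_ground_truth <- function(truth, path_base) {
  runs <- rle(truth$labels)
  pol <- if (!is.null(truth$polarity)) rep(truth$polarity, runs$lengths)
         else rep(NA_integer_, length(truth$labels))
  utils::write.csv(
    data.frame(sample = seq_along(truth$labels), true_label = truth$labels,
               polarity = pol),
    paste0(path_base, "_truth.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(transition_matrix = truth$transition_matrix,
         mean_durations = truth$mean_durations, seed = truth$seed,
         n_runs = length(runs$lengths)),
    paste0(path_base, "_truth.json"), digits = NA)
  invisible(path_base)
}
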