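#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the global `.Random.seed` so that seeded package
#' functions do not disturb the caller's RNG stream.
#'
#' @param seed integer seed, or NULL to leave the RNG alone.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_ms <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "microstatr_error")))
}

#' Construct a Recording object
#'
#' A Recording is the package's continuous multichannel container:
#' a channels x samples numeric matrix in microvolts plus sampling-rate and
#' channel metadata.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one label per channel.
#' @param reference reference tag, `"raw"` or `"average"`.
#' @return an object of class `recording`.
#' @export
recording <- function(data, fs, channel_labels = NULL, reference = "raw") {
  data <- as.matrix(data)
  if (!is.numeric(data) || !all(is.finite(data)))
    stop_ms("recording data must be a finite numeric matrix",
            class = "invalid_data")
  if (nrow(data) < 2)
    stop_ms("a recording needs at least 2 channels", class = "invalid_data")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0)
    stop_ms("fs must be a single positive number", class = "invalid_config")
  if (is.null(channel_labels))
    channel_labels <- sprintf("Ch%02d", seq_len(nrow(data)))
  if (length(channel_labels) != nrow(data))
    stop_ms("channel_labels length must equal the channel count",
            class = "invalid_config")
  reference <- match.arg(reference, c("raw", "average"))
  structure(list(data = data, fs = fs,
                 channel_labels = as.character(channel_labels),
                 reference = reference),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s), ref=%s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              x$reference))
  invisible(x)
}

#' Construct an EpochedData object
#'
#' @param data numeric array, epochs x channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param epoch_length epoch length in seconds.
#' @param kept_epoch_ids original (1-based, strictly increasing) epoch indices.
#' @param channel_labels channel labels.
#' @param reference reference tag.
#' @return an object of class `epoched`.
#' @export
epoched_data <- function(data, fs, epoch_length, kept_epoch_ids = NULL,
                         channel_labels = NULL, reference = "raw") {
  if (length(dim(data)) != 3)
    stop_ms("epoched data must be a 3-d array (epochs x channels x samples)",
            class = "invalid_data")
  n_samp <- round(fs * epoch_length)
  if (dim(data)[3] != n_samp)
    stop_ms("epoch sample count must equal round(fs * epoch_length)",
            class = "invalid_data")
  if (is.null(kept_epoch_ids)) kept_epoch_ids <- seq_len(dim(data)[1])
  if (length(kept_epoch_ids) != dim(data)[1] ||
      (length(kept_epoch_ids) > 1 && any(diff(kept_epoch_ids) <= 0)))
    stop_ms("kept_epoch_ids must be strictly increasing, one per epoch",
            class = "invalid_data")
  if (is.null(channel_labels))
    channel_labels <- sprintf("Ch%02d", seq_len(dim(data)[2]))
  structure(list(data = data, fs = fs, epoch_length = epoch_length,
                 kept_epoch_ids = as.integer(kept_epoch_ids),
                 channel_labels = as.character(channel_labels),
                 reference = reference),
            class = "epoched")
}

#' @export
print.epoched <- function(x, ...) {
  cat(sprintf("<epoched> %d epochs x %d channels x %d samples @ %g Hz, ref=%s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs,
              x$reference))
  invisible(x)
}

#' Flatten epoched data to a channels x samples matrix with epoch ids
#'
#' @param epoched an `epoched` object.
#' @return list with `data` (channels x samples) and `epoch_ids` (per sample).
#' @keywords internal
flatten_epochs <- function(epoched) {
  d <- dim(epoched$data)
  n_ep <- d[1]; n_ch <- d[2]; n_sa <- d[3]
  mat <- matrix(aperm(epoched$data, c(2, 3, 1)), nrow = n_ch)
  list(data = mat,
       epoch_ids = rep(epoched$kept_epoch_ids, each = n_sa))
}
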