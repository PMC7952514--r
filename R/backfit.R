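#' Backfit template maps to every sample
#'
#' Labels each sample with the class whose template has the highest
#' polarity-invariant spatial correlation with the sample's topography.
#' Ties break to the lowest class index; no temporal smoothing is applied
#' by default. Zero-variance (flat) samples inherit the previous sample's
#' label (class 1 at an epoch start) and are counted in attribute
#' `n_flat`.
#'
#' @param ep an `epoched` object (preprocessed).
#' @param templates a `template_set` (normally the global set).
#' @param smooth_window optional odd integer; when > 1, labels are
#'   post-processed by a majority vote over this window within epochs
#'   (off by default).
#' @return a `segmentation` list: per-sample `labels` (1-based class
#'   indices), `r_values`, `epoch_ids`, `fs`, `k`, `class_labels`.
#' @export
backfit <- function(ep, templates, smooth_window = 1) {
  stopifnot(inherits(ep, "epoched"), inherits(templates, "template_set"))
  if (dim(ep$data)[2] != nrow(templates$maps))
    stop_ms("channel counts of data and templates differ",
            class = "invalid_data")
  fl <- flatten_epochs(ep)
  x <- fl$data
  x <- sweep(x, 2, colMeans(x))
  nrm <- sqrt(colSums(x^2))
  flat <- nrm < .Machine$double.eps * nrow(x) * 16
  nrm[flat] <- 1
  xn <- sweep(x, 2, nrm, "/")
  cr <- abs(crossprod(templates$maps, xn))     # k x n
  labels <- max.col(t(cr), ties.method = "first")
  r_values <- cr[cbind(labels, seq_along(labels))]
  if (any(flat)) {
    idx <- which(flat)
    ep_start <- c(TRUE, diff(fl$epoch_ids) != 0)
    for (t in idx) {
      labels[t] <- if (t == 1 || ep_start[t]) 1L else labels[t - 1L]
      r_values[t] <- 0
    }
  }
  if (smooth_window > 1) {
    if (smooth_window %% 2 == 0)
      stop_ms("smooth_window must be odd", class = "invalid_config")
    labels <- smooth_labels(labels, fl$epoch_ids, smooth_window,
                            ncol(templates$maps))
  }
  structure(list(labels = labels, r_values = r_values,
                 epoch_ids = fl$epoch_ids, fs = ep$fs,
                 k = ncol(templates$maps),
                 class_labels = templates$labels,
                 n_flat = sum(flat)),
            class = "segmentation")
}

# majority-vote label smoothing within epochs (off-by-default option)
smooth_labels <- function(labels, epoch_ids, w, k) {
  half <- (w - 1) / 2
  out <- labels
  for (e in unique(epoch_ids)) {
    sel <- which(epoch_ids == e)
    l <- labels[sel]
    n <- length(l)
    for (t in seq_len(n)) {
      lo <- max(1, t - half); hi <- min(n, t + half)
      tab <- tabulate(l[lo:hi], nbins = k)
      out[sel[t]] <- which.max(tab)
    }
  }
  out
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("<segmentation> %d samples @ %g Hz, k=%d, mean r=%.3f\n",
              length(x$labels), x$fs, x$k, mean(x$r_values)))
  invisible(x)
}

# run-length encode a segmentation within epochs: returns data.frame with
# epoch, label, length (samples)
segmentation_runs <- function(seg) {
  out <- vector("list", 64)
  i <- 0L
  for (e in unique(seg$epoch_ids)) {
    r <- rle(seg$labels[seg$epoch_ids == e])
    i <- i + 1L
    out[[i]] <- data.frame(epoch = e, label = r$values, length = r$lengths)
  }
  do.call(rbind, out[seq_len(i)])
}

#' Temporal microstate parameters from a segmentation
#'
#' Runs are maximal constant-label stretches, never bridged across epoch
#' boundaries; epoch-edge-truncated runs are included, so the identity
#' `coverage = occurrence x duration` holds exactly per class.
#' Duration is the mean run length in seconds; occurrence the number of
#' runs per second of labeled data; coverage the fraction of samples.
#'
#' @param seg a `segmentation`.
#' @param subject_id,group optional identifiers carried into the result.
#' @return a `microstate_parameters` list with per-class vectors
#'   `duration`, `occurrence`, `coverage` (classes never present have
#'   duration `NA`, occurrence and coverage 0).
#' @export
compute_parameters <- function(seg, subject_id = NA_character_,
                               group = NA_character_) {
  stopifnot(inherits(seg, "segmentation"))
  n <- length(seg$labels)
  if (n == 0) stop_ms("empty segmentation", class = "invalid_data")
  k <- seg$k
  runs <- segmentation_runs(seg)
  total_s <- n / seg$fs
  duration <- occurrence <- coverage <- numeric(k)
  for (j in seq_len(k)) {
    rl <- runs$length[runs$label == j]
    if (length(rl) == 0) {
      duration[j] <- NA_real_; occurrence[j] <- 0; coverage[j] <- 0
    } else {
      duration[j] <- mean(rl) / seg$fs
      occurrence[j] <- length(rl) / total_s
      coverage[j] <- sum(rl) / n
    }
  }
  names(duration) <- names(occurrence) <- names(coverage) <- seg$class_labels
  structure(list(duration = duration, occurrence = occurrence,
                 coverage = coverage, subject_id = subject_id,
                 group = group, fs = seg$fs, n_samples = n),
            class = "microstate_parameters")
}

#' @export
print.microstate_parameters <- function(x, ...) {
  df <- data.frame(class = names(x$duration),
                   duration_s = round(x$duration, 4),
                   occurrence_per_s = round(x$occurrence, 3),
                   coverage = round(x$coverage, 4))
  cat(sprintf("<microstate_parameters> subject=%s group=%s\n",
              x$subject_id, x$group))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Directed run-level transition probabilities
#'
#' Collapses the label sequence to runs per epoch and counts directed
#' transitions between consecutive runs within epochs only (never across
#' epoch boundaries). `probs[i, j] = counts[i, j] / sum_j counts[i, j]`;
#' rows with no outgoing transitions are `NA` (undefined), not zero.
#' With k = 4 this yields the 12 off-diagonal directed transitions.
#'
#' @param seg a `segmentation`.
#' @return a `transition_matrix` list with `probs`, `counts`,
#'   `undefined_rows`.
#' @export
transition_probabilities <- function(seg) {
  stopifnot(inherits(seg, "segmentation"))
  k <- seg$k
  runs <- segmentation_runs(seg)
  if (nrow(runs) < 2)
    stop_ms("need at least 2 runs for transition analysis",
            class = "too_few_runs")
  counts <- matrix(0L, k, k,
                   dimnames = list(seg$class_labels, seg$class_labels))
  same_epoch <- runs$epoch[-1] == runs$epoch[-nrow(runs)]
  from <- runs$label[-nrow(runs)][same_epoch]
  to <- runs$label[-1][same_epoch]
  if (length(from) == 0) {
    warning("segmentation has a single run per epoch; all transitions undefined")
  } else {
    tab <- table(factor(from, levels = seq_len(k)),
                 factor(to, levels = seq_len(k)))
    counts <- matrix(as.integer(tab), k, k,
                     dimnames = list(seg$class_labels, seg$class_labels))
  }
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs > 0, rs, NA_real_)
  diag(probs)[rs > 0] <- 0
  structure(list(probs = probs, counts = counts,
                 undefined_rows = which(rs == 0)),
            class = "transition_matrix")
}

#' Tidy per-subject parameter table
#'
#' @param params list of `microstate_parameters`.
#' @return data.frame: subject, group, class, duration_s, occurrence_per_s,
#'   coverage.
#' @export
parameter_table <- function(params) {
  do.call(rbind, lapply(params, function(p)
    data.frame(subject = p$subject_id, group = p$group,
               class = names(p$duration),
               duration_s = unname(p$duration),
               occurrence_per_s = unname(p$occurrence),
               coverage = unname(p$coverage))))
}

#' Tidy per-subject transition table
#'
#' @param tms named list of `transition_matrix` objects (names = subjects).
#' @param groups group per subject, same order.
#' @return data.frame: subject, group, from, to, probability, count
#'   (off-diagonal entries only).
#' @export
transition_table <- function(tms, groups) {
  out <- list()
  cls <- rownames(tms[[1]]$probs)
  k <- length(cls)
  for (i in seq_along(tms)) {
    tm <- tms[[i]]
    for (a in seq_len(k)) for (b in seq_len(k)) {
      if (a == b) next
      out[[length(out) + 1]] <- data.frame(
        subject = names(tms)[i], group = groups[i],
        from = cls[a], to = cls[b],
        probability = tm$probs[a, b], count = tm$counts[a, b])
    }
  }
  do.call(rbind, out)
}
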