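#' Channel positions on a unit-disk scalp approximation
#'
#' Deterministic sunflower (Fibonacci) layout of `n` electrodes on the unit
#' disk, oriented with +y anterior and +x right. Used by the template
#' generator and the canonical class prototypes; not a measured montage.
#'
#' @param n_channels number of electrodes.
#' @return n x 2 matrix of (x, y) positions.
#' @export
channel_layout <- function(n_channels) {
  if (n_channels < 2)
    stop_ms("need at least 2 channels", class = "invalid_config")
  i <- seq_len(n_channels)
  golden <- (1 + sqrt(5)) / 2
  r <- sqrt((i - 0.5) / n_channels)
  theta <- 2 * pi * i / golden^2
  cbind(x = r * cos(theta), y = r * sin(theta))
}

# Smooth raw class patterns over a layout: two diagonal dipoles, one
# anterior-posterior (left-right symmetric) pattern, one fronto-central
# focal pattern, then Gaussian-bump extras for k > 4.
raw_class_patterns <- function(pos, k) {
  n <- nrow(pos)
  x <- pos[, 1]; y <- pos[, 2]
  smooth_dipole <- function(ux, uy) {
    # potential of a tangential dipole under the disk centre, smoothed
    proj <- x * ux + y * uy
    proj * exp(-(x^2 + y^2) / 1.5)
  }
  pats <- list(
    A = smooth_dipole(cos(3 * pi / 4), sin(-3 * pi / 4)) * -1, # left-post/right-ant
    B = smooth_dipole(cos(pi / 4), sin(-pi / 4)) * -1,         # right-post/left-ant
    C = (y^2 - 0.5 * x^2) * exp(-(x^2 + y^2) / 2) + 0.8 * y,   # ant-post, symmetric in x
    D = exp(-((x - 0)^2 + (y - 0.35)^2) / 0.18)                # fronto-central focal
  )
  if (k > 4) {
    centers <- channel_layout(max(k - 4, 2)) * 0.7
    for (j in seq_len(k - 4)) {
      pats[[paste0("M", j + 4)]] <-
        exp(-((x - centers[j, 1])^2 + (y - centers[j, 2])^2) / 0.1)
    }
  }
  out <- do.call(cbind, pats[seq_len(k)])
  sweep(out, 2, colMeans(out))
}

# Gram-Schmidt in the zero-mean channel subspace; columns come out
# zero-mean, unit-norm, mutually orthogonal (pairwise r = 0).
orthonormalize_maps <- function(m) {
  n <- nrow(m); k <- ncol(m)
  for (j in seq_len(k)) {
    v <- m[, j] - mean(m[, j])
    if (j > 1) {
      proj <- m[, seq_len(j - 1), drop = FALSE]
      v <- v - proj %*% crossprod(proj, v)
    }
    nv <- sqrt(sum(v^2))
    if (nv < 1e-10)
      stop_ms("template patterns are rank-deficient on this layout; ",
              "k must be below the channel count for decorrelation",
              class = "invalid_config")
    m[, j] <- v / nv
  }
  m
}

#' Canonical microstate class prototypes A-D
#'
#' Deterministic normalized prototype topographies used to assign class
#' labels: A and B are the two diagonal dipolar maps, C the
#' anterior-posterior left-right-symmetric map, D the fronto-central focal
#' map. These are synthetic conventions of the microstate literature, not
#' measured group templates.
#'
#' @param n_channels number of electrodes (>= 5 for four distinct classes).
#' @return a `template_set` with labels A-D.
#' @export
canonical_templates <- function(n_channels) {
  pos <- channel_layout(n_channels)
  maps <- orthonormalize_maps(raw_class_patterns(pos, 4))
  template_set(maps, labels = c("A", "B", "C", "D"), level = "canonical")
}

#' Generate a synthetic template set with known structure
#'
#' Builds `k` smooth dipolar/focal patterns over the unit-disk layout
#' (canonical A-D shapes for the first four classes), adds a small seeded
#' smooth perturbation, and orthonormalizes in the zero-mean subspace so
#' every map is zero-mean, unit L2 norm, and pairwise polarity-invariant
#' spatial correlation is 0 (<= 0.5 contract).
#'
#' @param n_channels number of electrodes.
#' @param k number of classes (>= 2).
#' @param seed integer seed for the perturbation.
#' @return a `template_set` of k maps.
#' @export
make_templates <- function(n_channels, k = 4, seed = 1) {
  if (k < 2) stop_ms("k must be >= 2", class = "invalid_config")
  if (k > n_channels)
    stop_ms("k (", k, ") exceeds the channel count (", n_channels, ")",
            class = "invalid_config")
  pos <- channel_layout(n_channels)
  raw <- raw_class_patterns(pos, k)
  raw <- sweep(raw, 2, sqrt(colSums(raw^2)), "/")
  pert <- with_seed(seed, {
    # smooth random field: random linear + quadratic surface per class
    co <- matrix(stats::rnorm(5 * k, sd = 0.08), nrow = 5)
    basis <- cbind(pos[, 1], pos[, 2], pos[, 1] * pos[, 2],
                   pos[, 1]^2 - 0.5, pos[, 2]^2 - 0.5)
    basis %*% co
  })
  maps <- orthonormalize_maps(raw + pert)
  labels <- if (k == 4) c("A", "B", "C", "D") else paste0("M", seq_len(k))
  template_set(maps, labels = labels, level = "truth")
}

#' Construct a TemplateSet
#'
#' @param maps channels x k matrix of topographic maps; each column is
#'   normalized (zero mean, unit L2 norm) on construction.
#' @param labels class labels, unique, one per map.
#' @param level one of subject/group/global/canonical/truth.
#' @param gev fraction of global variance explained, in `[0, 1]`, or NA.
#' @return an object of class `template_set`.
#' @export
template_set <- function(maps, labels = NULL, level = "subject", gev = NA_real_) {
  maps <- as.matrix(maps)
  k <- ncol(maps)
  if (is.null(labels))
    labels <- if (k == 4) c("A", "B", "C", "D") else paste0("M", seq_len(k))
  if (anyDuplicated(labels) || length(labels) != k)
    stop_ms("labels must be unique, one per map", class = "invalid_config")
  if (!is.na(gev) && (gev < 0 || gev > 1))
    stop_ms("gev must lie in [0, 1]", class = "invalid_config")
  maps <- apply(maps, 2, function(v) {
    v <- v - mean(v)
    nv <- sqrt(sum(v^2))
    if (nv == 0) stop_ms("zero-variance template map", class = "invalid_data")
    v / nv
  })
  colnames(maps) <- labels
  structure(list(maps = maps, labels = as.character(labels),
                 level = level, gev = gev),
            class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> %d maps x %d channels, level=%s%s\n",
              ncol(x$maps), nrow(x$maps), x$level,
              if (is.na(x$gev)) "" else sprintf(", GEV=%.3f", x$gev)))
  cat("  labels:", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}
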