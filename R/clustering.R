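#' Global field power
#'
#' The spatial population standard deviation of the potential across
#' channels at each sample:
#' `GFP_t = sqrt(mean((v_it - mean_i(v_it))^2))`.
#'
#' @param data channels x samples numeric matrix.
#' @return numeric vector of per-sample GFP values.
#' @export
gfp <- function(data) {
  data <- as.matrix(data)
  if (nrow(data) < 2)
    stop_ms("GFP needs at least 2 channels", class = "invalid_data")
  m <- colMeans(data)
  sqrt(colMeans(data^2) - m^2)
}

#' Find GFP peaks
#'
#' Strict local maxima (`g[t-1] < g[t] > g[t+1]`), computed within each
#' epoch independently so epoch-boundary samples are never peaks. Plateau
#' samples are not peaks under the strict inequality.
#'
#' @param gfp_series numeric GFP vector.
#' @param epoch_ids optional per-sample epoch membership; peaks are found
#'   within each epoch separately.
#' @return integer vector of peak sample indices (into `gfp_series`).
#' @export
find_gfp_peaks <- function(gfp_series, epoch_ids = NULL) {
  n <- length(gfp_series)
  if (n < 3) return(integer(0))
  g <- gfp_series
  inner <- 2:(n - 1)
  is_peak <- logical(n)
  is_peak[inner] <- g[inner] > g[inner - 1] & g[inner] > g[inner + 1]
  if (!is.null(epoch_ids)) {
    if (length(epoch_ids) != n)
      stop_ms("epoch_ids length must match the series", class = "invalid_data")
    boundary <- c(TRUE, diff(epoch_ids) != 0)          # first sample of epoch
    boundary <- boundary | c(boundary[-1], TRUE)       # last sample of epoch
    is_peak[boundary] <- FALSE
  }
  which(is_peak)
}

#' Spatial correlation between two topographic maps
#'
#' Pearson correlation across channels after per-map mean removal;
#' with `polarity_invariant = TRUE` the absolute value is returned, so a
#' map and its sign-flipped copy are identical.
#'
#' @param map1,map2 numeric per-channel vectors of equal length.
#' @param polarity_invariant return `|r|` instead of signed r.
#' @return the correlation, scalar.
#' @export
spatial_correlation <- function(map1, map2, polarity_invariant = TRUE) {
  if (length(map1) != length(map2))
    stop_ms("maps must have the same channel count", class = "invalid_data")
  v1 <- map1 - mean(map1); v2 <- map2 - mean(map2)
  s1 <- sqrt(sum(v1^2)); s2 <- sqrt(sum(v2^2))
  if (s1 == 0 || s2 == 0)
    stop_ms("zero-variance map has no defined spatial correlation",
            class = "invalid_data")
  r <- sum(v1 * v2) / (s1 * s2)
  if (polarity_invariant) abs(r) else r
}

#' Clustering configuration
#'
#' @param k number of classes (default 4).
#' @param n_restarts random restarts (default 100).
#' @param max_iter iteration cap per restart (default 100).
#' @param tol relative GEV improvement below which iteration stops.
#' @param seed integer seed.
#' @return a `clustering_config` list.
#' @export
clustering_config <- function(k = 4, n_restarts = 100, max_iter = 100,
                              tol = 1e-6, seed = 1) {
  if (k < 1 || n_restarts < 1 || max_iter < 1)
    stop_ms("k, n_restarts and max_iter must all be >= 1",
            class = "invalid_config")
  if (tol <= 0) stop_ms("tol must be > 0", class = "invalid_config")
  structure(list(k = k, n_restarts = n_restarts, max_iter = max_iter,
                 tol = tol, seed = as.integer(seed)),
            class = "clustering_config")
}

# normalize map columns to zero mean, unit L2 norm; drop zero-variance ones
normalize_maps <- function(maps) {
  maps <- sweep(maps, 2, colMeans(maps))
  nrm <- sqrt(colSums(maps^2))
  list(maps = sweep(maps, 2, pmax(nrm, .Machine$double.eps), "/"),
       norms = nrm)
}

# one modified-k-means pass from given seed template indices
mkmeans_once <- function(nm, w2, k, seed_idx, max_iter, tol) {
  templates <- nm[, seed_idx, drop = FALSE]
  n <- ncol(nm)
  gev_prev <- -Inf
  assign <- integer(n)
  total_w2 <- sum(w2)
  for (iter in seq_len(max_iter)) {
    # assignment: maximize squared spatial correlation (polarity ignored)
    cr <- crossprod(templates, nm)           # k x n, maps & templates unit-norm
    cr2 <- cr^2
    assign <- max.col(t(cr2), ties.method = "first")
    # empty-cluster repair: reseed from the worst-fit map
    best <- cr2[cbind(assign, seq_len(n))]
    for (j in seq_len(k)) {
      if (!any(assign == j)) {
        worst <- which.min(best)
        templates[, j] <- nm[, worst]
        assign[worst] <- j
        best[worst] <- 1
      }
    }
    # update: principal eigenvector of the outer-product sum of the
    # assigned raw (GFP-scaled) maps, i.e. GFP^2-weighted normalized maps --
    # the update that makes the weighted GEV non-decreasing
    for (j in seq_len(k)) {
      idx <- which(assign == j)
      x <- nm[, idx, drop = FALSE]
      wj <- if (sum(w2[idx]) > 0) w2[idx] else rep(1, length(idx))
      cc <- x %*% (wj * t(x))
      ev <- eigen(cc, symmetric = TRUE)
      v <- ev$vectors[, 1]
      v <- v - mean(v)
      nv <- sqrt(sum(v^2))
      if (nv > 0) templates[, j] <- v / nv
    }
    cr <- crossprod(templates, nm)
    cr2 <- cr^2
    assign <- max.col(t(cr2), ties.method = "first")
    gev <- sum(w2 * cr2[cbind(assign, seq_len(n))]) / total_w2
    if (gev < gev_prev - 1e-12)
      stop_ms("internal error: GEV decreased across an iteration",
              class = "gev_decrease")
    if (is.finite(gev_prev) && gev - gev_prev < tol * max(gev_prev, 1e-12))
      break
    gev_prev <- gev
  }
  list(templates = templates, assign = assign, gev = gev)
}

#' Polarity-invariant modified k-means over topographic maps
#'
#' Iterates (i) assignment of each map to the class with the highest
#' squared spatial correlation (polarity ignored) and (ii) template update
#' as the normalized principal eigenvector of the cluster's outer-product
#' sum, until the relative GEV gain drops below `tol` or `max_iter` is hit.
#' `n_restarts` random initializations (k distinct maps as seeds) are run
#' and the restart with the highest GEV kept. GEV is the GFP^2-weighted
#' mean squared correlation with the assigned template:
#' `GEV = sum(gfp_t^2 r_t^2) / sum(gfp_t^2)`.
#'
#' @param peak_maps channels x n matrix of maps (GFP-peak topographies).
#' @param config a `clustering_config`.
#' @param gfp_weights per-map GFP values used as GEV weights; computed from
#'   `peak_maps` when NULL.
#' @return list: `templates` (a `template_set` with `gev` filled),
#'   `assignment` (per-map class index), `gev`.
#' @export
modified_kmeans <- function(peak_maps, config = clustering_config(),
                            gfp_weights = NULL) {
  peak_maps <- as.matrix(peak_maps)
  k <- config$k
  n <- ncol(peak_maps)
  if (n < k)
    stop_ms("need at least k maps to cluster (", n, " < ", k, ")",
            class = "too_few_maps")
  if (is.null(gfp_weights)) gfp_weights <- gfp(peak_maps)
  w2 <- gfp_weights^2
  nrm <- normalize_maps(peak_maps)
  nm <- nrm$maps
  best <- NULL
  with_seed(config$seed, {
    for (r in seq_len(config$n_restarts)) {
      seed_idx <- sample.int(n, k)
      fit <- mkmeans_once(nm, w2, k, seed_idx, config$max_iter, config$tol)
      if (is.null(best) || fit$gev > best$gev) best <- fit
    }
  })
  labels <- if (k == 4) c("A", "B", "C", "D") else paste0("M", seq_len(k))
  best$gev <- min(max(best$gev, 0), 1)   # guard rounding at the boundary
  ts <- template_set(best$templates, labels = labels, level = "subject",
                     gev = best$gev)
  list(templates = ts, assignment = best$assign, gev = best$gev)
}

#' Two-level microstate clustering
#'
#' Level 1: modified k-means per subject on that subject's GFP-peak maps.
#' Level 2: modified k-means over the pooled normalized subject templates
#' (each template one observation, unit weight) within each group, and once
#' over all subjects for the global template set, which is the set used for
#' backfitting. Subjects with fewer peak maps than k are skipped with a
#' warning.
#'
#' @param per_subject_peak_maps named list of channels x n matrices.
#' @param groups character/factor of group membership, one per subject.
#' @param config a `clustering_config`.
#' @param gfp_weights optional named list of per-subject GFP weight vectors.
#' @return list: `subject` (named list of `template_set`), `group` (named
#'   list of `template_set`), `global` (a `template_set`).
#' @export
two_level_clustering <- function(per_subject_peak_maps, groups,
                                 config = clustering_config(),
                                 gfp_weights = NULL) {
  n_sub <- length(per_subject_peak_maps)
  stopifnot(length(groups) == n_sub, n_sub >= 1)
  ids <- names(per_subject_peak_maps)
  if (is.null(ids)) ids <- sprintf("S%02d", seq_len(n_sub))
  subject_sets <- vector("list", n_sub)
  names(subject_sets) <- ids
  for (i in seq_len(n_sub)) {
    maps <- per_subject_peak_maps[[i]]
    if (ncol(maps) < config$k) {
      warning("subject ", ids[i], " has fewer than k peak maps; skipped")
      next
    }
    w <- if (!is.null(gfp_weights)) gfp_weights[[i]] else NULL
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    subject_sets[[i]] <- modified_kmeans(maps, cfg_i, gfp_weights = w)$templates
  }
  kept <- !vapply(subject_sets, is.null, logical(1))
  if (!any(kept))
    stop_ms("no subject had enough peak maps to cluster",
            class = "empty_result")
  pool <- function(sel) do.call(cbind, lapply(subject_sets[sel], `[[`, "maps"))
  # GEV of a template set against the subjects' original peak maps: the
  # level-2 clustering runs on pooled templates, but the explained
  # variance a template set is quoted with refers to the data it must
  # describe, so it is recomputed here over the GFP-peak maps.
  data_gev <- function(ts, sel) {
    if (is.null(gfp_weights)) return(ts$gev)
    num <- 0; den <- 0
    for (i in which(sel)) {
      nm <- normalize_maps(per_subject_peak_maps[[i]])$maps
      r2max <- apply(crossprod(ts$maps, nm)^2, 2, max)
      w2 <- gfp_weights[[i]]^2
      num <- num + sum(w2 * r2max)
      den <- den + sum(w2)
    }
    num / den
  }
  cluster_pool <- function(maps, level, seed_shift, sel) {
    cfg <- config
    cfg$seed <- config$seed + seed_shift
    res <- modified_kmeans(maps, cfg, gfp_weights = rep(1, ncol(maps)))
    res$templates$level <- level
    res$templates$gev <- data_gev(res$templates, sel)
    res$templates
  }
  group_sets <- list()
  for (g in unique(as.character(groups))) {
    sel <- kept & (as.character(groups) == g)
    if (!any(sel)) next
    group_sets[[g]] <- cluster_pool(pool(sel), "group",
                                    match(g, unique(as.character(groups))) * 1000L,
                                    sel)
  }
  global_set <- cluster_pool(pool(kept), "global", 999999L, kept)
  list(subject = subject_sets, group = group_sets, global = global_set)
}

#' Assign canonical class labels A-D to a template set
#'
#' Exhaustive search over all 4! permutations maximizing the summed
#' polarity-invariant spatial correlation against the canonical A-D
#' prototypes; ties broken by the lexicographically smallest permutation.
#' For k != 4 the maps are labeled M1..Mk with a warning.
#'
#' @param ts a `template_set` with 4 maps.
#' @param canonical a `template_set` of 4 canonical prototypes; defaults to
#'   [canonical_templates()] on the matching channel count.
#' @return the `template_set`, maps reordered and labeled A-D; the matching
#'   score (sum of 4 correlations) is attached as attribute `label_score`.
#' @export
label_templates <- function(ts, canonical = NULL) {
  k <- ncol(ts$maps)
  if (k != 4) {
    warning("canonical A-D labeling requires k = 4; using M1..Mk")
    ts$labels <- paste0("M", seq_len(k))
    colnames(ts$maps) <- ts$labels
    return(ts)
  }
  if (is.null(canonical)) canonical <- canonical_templates(nrow(ts$maps))
  r <- abs(crossprod(canonical$maps, ts$maps))  # 4x4, rows=canonical classes
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ,
                 drop = FALSE]
  perms <- perms[do.call(order, as.data.frame(perms)), , drop = FALSE]
  scores <- apply(perms, 1, function(p) sum(r[cbind(1:4, p)]))
  best <- which.max(scores > max(scores) - 1e-12) # first (lexicographic) max
  p <- perms[best, ]
  out <- template_set(ts$maps[, p, drop = FALSE],
                      labels = c("A", "B", "C", "D"),
                      level = ts$level, gev = ts$gev)
  attr(out, "label_score") <- max(scores)
  out
}

#' Extract per-subject GFP-peak maps from epoched data
#'
#' @param ep an `epoched` object (preprocessed).
#' @return list: `maps` (channels x n_peaks), `gfp` (peak GFP values),
#'   `peak_idx` (sample indices in the flattened data), `epoch_ids`.
#' @export
gfp_peak_maps <- function(ep) {
  fl <- flatten_epochs(ep)
  g <- gfp(fl$data)
  pk <- find_gfp_peaks(g, fl$epoch_ids)
  list(maps = fl$data[, pk, drop = FALSE], gfp = g[pk], peak_idx = pk,
       epoch_ids = fl$epoch_ids[pk])
}
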