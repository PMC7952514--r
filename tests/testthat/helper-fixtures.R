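# Small-scale simulation fixtures shared across test files.
# 16 channels at 500 Hz keeps full-pipeline tests in seconds while
# exercising every stage (notch, both band-passes, decimation by 2).

small_config <- function(seed = 1, duration = 30, snr = 2, ...) {
  simulation_config(n_channels = 16, fs = 500, duration = duration,
                    snr = snr, seed = seed, ...)
}

small_subject <- function(seed = 1, duration = 30, snr = 2, ...) {
  simulate_subject(small_config(seed = seed, duration = duration,
                                snr = snr, ...))
}

# segmentation wrapper around an explicit label vector (one epoch unless
# epoch_ids given)
manual_segmentation <- function(labels, fs = 250, epoch_ids = NULL, k = 4) {
  if (is.null(epoch_ids)) epoch_ids <- rep(1L, length(labels))
  cls <- if (k == 4) c("A", "B", "C", "D") else paste0("M", seq_len(k))
  structure(list(labels = as.integer(labels),
                 r_values = rep(1, length(labels)),
                 epoch_ids = as.integer(epoch_ids), fs = fs, k = k,
                 class_labels = cls, n_flat = 0L),
            class = "segmentation")
}

backfit_smooth_for_test <- function(seg, w) {
  microstatr:::smooth_labels(seg$labels, seg$epoch_ids, w, seg$k)
}

# independent Pearson correlation between two maps (oracle for
# spatial_correlation and template matching)
oracle_corr <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

# brute-force modified-k-means oracle for tiny instances: enumerate every
# assignment of n maps to k clusters, fit the optimal (GFP^2-weighted
# principal eigenvector) template per cluster, return the best achievable
# GEV. Independent of the package's iterative implementation.
brute_force_gev <- function(maps, k, gfp_weights) {
  maps <- sweep(maps, 2, colMeans(maps))
  nrm <- sqrt(colSums(maps^2))
  nm <- sweep(maps, 2, pmax(nrm, 1e-300), "/")
  w2 <- gfp_weights^2
  n <- ncol(nm)
  best <- 0
  grid <- rep(list(seq_len(k)), n)
  asn <- do.call(expand.grid, grid)
  for (row in seq_len(nrow(asn))) {
    a <- as.integer(asn[row, ])
    if (length(unique(a)) < k) next
    gev <- 0
    for (j in seq_len(k)) {
      idx <- which(a == j)
      x <- nm[, idx, drop = FALSE]
      cc <- x %*% (w2[idx] * t(x))
      # GFP^2-weighted squared correlations with the optimal template =
      # top eigenvalue of the weighted outer-product sum
      gev <- gev + eigen(cc, symmetric = TRUE, only.values = TRUE)$values[1]
    }
    best <- max(best, gev / sum(w2))
  }
  best
}

# brute-force split-plot ANOVA oracle from explicit sums of squares over
# cell means, written independently of mixed_anova
oracle_mixed_anova <- function(tab, metric) {
  v <- tab[[metric]]
  s <- as.character(tab$subject); g <- as.character(tab$group)
  cl <- as.character(tab$class)
  subjects <- unique(s)
  sg <- g[match(subjects, s)]
  classes <- sort(unique(cl))
  k <- length(classes); N <- length(subjects)
  groups <- unique(sg); G <- length(groups)
  mu <- mean(v)
  ss <- function(x) sum(x^2)
  # subject means/classes means etc. via explicit loops
  sub_mean <- sapply(subjects, function(si) mean(v[s == si]))
  grp_mean <- sapply(groups, function(gi) mean(v[g == gi]))
  cls_mean <- sapply(classes, function(ci) mean(v[cl == ci]))
  cell_mean <- outer(groups, classes,
                     Vectorize(function(gi, ci) mean(v[g == gi & cl == ci])))
  n_g <- sapply(groups, function(gi) sum(sg == gi))
  ss_group <- k * sum(n_g * (grp_mean - mu)^2)
  ss_subj <- k * sum((sub_mean - mu)^2) - ss_group
  ss_class <- N * sum((cls_mean - mu)^2)
  ss_int <- sum(outer(n_g, rep(1, k)) * (cell_mean - mu)^2) -
    ss_group - ss_class
  ss_tot <- sum((v - mu)^2)
  ss_err <- ss_tot - ss_group - ss_subj - ss_class - ss_int
  c(F_group = (ss_group / (G - 1)) / (ss_subj / (N - G)),
    F_class = (ss_class / (k - 1)) / (ss_err / ((N - G) * (k - 1))),
    F_int = (ss_int / ((G - 1) * (k - 1))) /
      (ss_err / ((N - G) * (k - 1))))
}

# build a balanced parameter table for the statistics tests
make_param_table <- function(n_per_group = 6, groups = c("SCH", "BD", "HC"),
                             seed = 1, shift = NULL) {
  set.seed(seed)
  rows <- list()
  for (g in groups) for (i in seq_len(n_per_group)) {
    sid <- paste0(g, i)
    base <- c(A = 0.07, B = 0.065, C = 0.09, D = 0.07)
    val <- base + rnorm(4, sd = 0.008)
    if (!is.null(shift) && g == shift$group)
      val[shift$class] <- val[shift$class] + shift$delta
    rows[[length(rows) + 1]] <- data.frame(
      subject = sid, group = g, class = names(base),
      duration_s = val, occurrence_per_s = 3 + rnorm(4, sd = 0.3),
      coverage = rep(0.25, 4))
  }
  do.call(rbind, rows)
}
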