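#' Mixed-design (split-plot) ANOVA for microstate parameters
#'
#' One within-subject factor (microstate class) and one between-subject
#' factor (group). Sums of squares follow the standard univariate
#' split-plot decomposition: group is tested against subjects-within-groups;
#' class and the class x group interaction against the class x
#' subjects-within-groups residual. Within-subject effects are reported
#' both uncorrected and with Greenhouse-Geisser correction of the degrees
#' of freedom.
#'
#' @param tab data.frame with columns subject, group, class, and the metric
#'   column named by `metric` (as produced by [parameter_table()]).
#' @param metric name of the value column (e.g. `"duration_s"`).
#' @return data.frame of class `anova_result`: effect, F, df_num, df_den,
#'   p, p_gg, gg_epsilon, correction.
#' @export
mixed_anova <- function(tab, metric) {
  v <- tab[[metric]]
  if (is.null(v)) stop_ms("no column '", metric, "' in table",
                          class = "invalid_config")
  subject <- as.character(tab$subject)
  group <- as.character(tab$group)
  cls <- as.character(tab$class)
  classes <- sort(unique(cls))
  subjects <- unique(subject)
  k <- length(classes)
  # completeness check: every subject must have every class exactly once
  for (s in subjects) {
    have <- sort(cls[subject == s])
    if (!identical(have, classes))
      stop_ms("subject ", s, " is missing classes: ",
              paste(setdiff(classes, have), collapse = ","),
              class = "missing_cells")
  }
  if (any(is.na(v))) {
    bad <- tab[is.na(v), ]
    stop_ms("missing value for subject ", bad$subject[1], ", class ",
            bad$class[1], class = "missing_cells")
  }
  # wide matrix: subjects x classes
  wide <- matrix(NA_real_, length(subjects), k,
                 dimnames = list(subjects, classes))
  wide[cbind(match(subject, subjects), match(cls, classes))] <- v
  sub_group <- group[match(subjects, subject)]
  groups <- unique(sub_group)
  g <- length(groups)
  n_i <- as.vector(table(factor(sub_group, levels = groups)))
  N <- length(subjects)
  grand <- mean(wide)
  sub_means <- rowMeans(wide)
  cls_means <- colMeans(wide)
  grp_means <- tapply(sub_means, factor(sub_group, levels = groups), mean)
  cellm <- matrix(NA_real_, g, k)
  for (gi in seq_len(g))
    cellm[gi, ] <- colMeans(wide[sub_group == groups[gi], , drop = FALSE])
  ss_between_subj <- k * sum((sub_means - grand)^2)
  ss_group <- k * sum(n_i * (grp_means - grand)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_total <- sum((wide - grand)^2)
  ss_class <- N * sum((cls_means - grand)^2)
  ss_cells <- sum(rep(n_i, times = k) * (as.vector(cellm) - grand)^2)
  ss_interact <- ss_cells - ss_group - ss_class
  ss_within_subj <- ss_total - ss_between_subj
  ss_err_within <- ss_within_subj - ss_class - ss_interact
  df_group <- g - 1; df_subj <- N - g
  df_class <- k - 1; df_int <- (g - 1) * (k - 1)
  df_err_w <- (N - g) * (k - 1)
  ms <- function(ss, df) ss / df
  f_group <- ms(ss_group, df_group) / ms(ss_subj_within, df_subj)
  f_class <- ms(ss_class, df_class) / ms(ss_err_within, df_err_w)
  f_int <- ms(ss_interact, df_int) / ms(ss_err_within, df_err_w)
  eps <- gg_epsilon(wide, sub_group)
  res <- data.frame(
    effect = c("group", "class", "group:class"),
    F = c(f_group, f_class, f_int),
    df_num = c(df_group, df_class, df_int),
    df_den = c(df_subj, df_err_w, df_err_w),
    p = c(stats::pf(f_group, df_group, df_subj, lower.tail = FALSE),
          stats::pf(f_class, df_class, df_err_w, lower.tail = FALSE),
          stats::pf(f_int, df_int, df_err_w, lower.tail = FALSE)),
    p_gg = c(NA,
             stats::pf(f_class, df_class * eps, df_err_w * eps,
                       lower.tail = FALSE),
             stats::pf(f_int, df_int * eps, df_err_w * eps,
                       lower.tail = FALSE)),
    gg_epsilon = c(NA, eps, eps),
    stringsAsFactors = FALSE)
  res$F[!is.finite(res$F)] <- 0
  res$p[!is.finite(res$F)] <- 1
  class(res) <- c("anova_result", "data.frame")
  res
}

# Greenhouse-Geisser epsilon from the pooled within-group covariance of the
# repeated measures
gg_epsilon <- function(wide, sub_group) {
  k <- ncol(wide)
  groups <- unique(sub_group)
  S <- matrix(0, k, k)
  df <- 0
  for (g in groups) {
    x <- wide[sub_group == g, , drop = FALSE]
    if (nrow(x) < 2) next
    S <- S + stats::cov(x) * (nrow(x) - 1)
    df <- df + nrow(x) - 1
  }
  if (df == 0) return(1)
  S <- S / df
  # epsilon on the double-centered covariance
  C <- diag(k) - 1 / k
  Sc <- C %*% S %*% C
  ev <- sum(diag(Sc))
  eps <- ev^2 / ((k - 1) * sum(Sc^2))
  min(1, max(eps, 1 / (k - 1)))
}

#' Per-class simple-effects tests with Bonferroni post hoc comparisons
#'
#' For each microstate class: a one-way ANOVA of the metric across groups,
#' followed by all pairwise two-sample pooled-variance t tests with
#' Bonferroni adjustment over the pairs.
#'
#' @param tab parameter table as in [mixed_anova()].
#' @param metric value column name.
#' @return list with `anova` (per-class data.frame: class, F, df_num,
#'   df_den, p) and `pairwise` (class, group1, group2, t, df, p, p_adj).
#' @export
simple_effects <- function(tab, metric) {
  v <- tab[[metric]]
  classes <- sort(unique(as.character(tab$class)))
  res_a <- list(); res_p <- list()
  for (cl in classes) {
    sel <- tab$class == cl
    x <- v[sel]; gr <- factor(as.character(tab$group[sel]))
    a <- oneway_anova_raw(x, gr)
    res_a[[cl]] <- data.frame(class = cl, F = a$F, df_num = a$df_num,
                              df_den = a$df_den, p = a$p)
    pairs <- utils::combn(levels(gr), 2)
    pw <- apply(pairs, 2, function(pr) {
      x1 <- x[gr == pr[1]]; x2 <- x[gr == pr[2]]
      tt <- stats::t.test(x1, x2, var.equal = TRUE)
      data.frame(class = cl, group1 = pr[1], group2 = pr[2],
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value)
    })
    pw <- do.call(rbind, pw)
    pw$p_adj <- bonferroni_adjust(pw$p)
    res_p[[cl]] <- pw
  }
  list(anova = do.call(rbind, res_a), pairwise = do.call(rbind, res_p))
}

# one-way ANOVA on raw values (between-group F)
oneway_anova_raw <- function(x, gr) {
  gr <- factor(gr)
  ns <- tapply(x, gr, length)
  ms <- tapply(x, gr, mean)
  sds <- tapply(x, gr, stats::sd)
  oneway_anova_summary(ms, sds, ns)
}

#' One-way ANOVA from printed summary statistics
#'
#' Reconstructs the between/within sums of squares from per-group means,
#' standard deviations and sample sizes:
#' `SSB = sum n_g (m_g - m)^2`, `SSW = sum (n_g - 1) sd_g^2`,
#' with df `(G - 1, N - G)`. This is the test applied to published
#' group-summary tables where raw data are unavailable.
#'
#' @param means,sds,ns per-group summary vectors (equal length >= 2).
#' @return list: F, df_num, df_den, p.
#' @export
oneway_anova_summary <- function(means, sds, ns) {
  if (length(means) < 2)
    stop_ms("need at least 2 groups", class = "invalid_config")
  if (length(sds) != length(means) || length(ns) != length(means))
    stop_ms("means, sds, ns must have equal length", class = "invalid_config")
  if (any(ns < 2)) stop_ms("every group needs n >= 2", class = "invalid_config")
  if (any(sds < 0)) stop_ms("sds must be >= 0", class = "invalid_config")
  N <- sum(ns); G <- length(means)
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  df1 <- G - 1; df2 <- N - G
  f <- (ssb / df1) / (ssw / df2)
  if (!is.finite(f)) f <- 0
  list(F = f, df_num = df1, df_den = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson chi-square without continuity correction,
#' df = (rows - 1)(cols - 1). Used for categorical demographics such as
#' group x gender counts.
#'
#' @param counts matrix of non-negative counts with no zero marginal.
#' @return list: statistic, df, p, expected.
#' @export
chi_square_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop_ms("counts must be >= 0", class = "invalid_data")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop_ms("contingency table has a zero marginal", class = "invalid_data")
  ct <- stats::chisq.test(counts, correct = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = ct$expected)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m p)` with `m = length(p_values)`.
#'
#' @param p_values numeric p values in `[0, 1]`.
#' @param m number of comparisons (defaults to `length(p_values)`).
#' @return adjusted p values.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop_ms("p values must lie in [0, 1]", class = "invalid_data")
  pmin(1, m * p_values)
}

#' Group tests for every directed transition
#'
#' For each directed transition (12 when k = 4): one-way ANOVA of the
#' transition probability across groups, then pairwise pooled-variance t
#' tests with Bonferroni adjustment over the group pairs. Subjects with an
#' undefined (NA) probability are excluded per transition; transitions with
#' fewer than 2 groups having >= 2 defined subjects are skipped with a
#' warning.
#'
#' @param trans_tab data.frame from [transition_table()].
#' @return list: `anova` (from, to, F, df_num, df_den, p, n_excluded) and
#'   `pairwise` (from, to, group1, group2, t, df, p, p_adj).
#' @export
transition_tests <- function(trans_tab) {
  grp_all <- unique(as.character(trans_tab$group))
  if (length(grp_all) < 2)
    stop_ms("transition tests need at least 2 groups", class = "invalid_config")
  keys <- unique(trans_tab[, c("from", "to")])
  res_a <- list(); res_p <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- trans_tab$from == keys$from[i] & trans_tab$to == keys$to[i]
    x <- trans_tab$probability[sel]
    gr <- as.character(trans_tab$group[sel])
    ok <- !is.na(x)
    n_excl <- sum(!ok)
    x <- x[ok]; gr <- gr[ok]
    counts <- table(gr)
    usable <- names(counts)[counts >= 2]
    if (length(usable) < 2) {
      warning(sprintf("transition %s->%s defined in fewer than 2 groups; skipped",
                      keys$from[i], keys$to[i]))
      next
    }
    keep <- gr %in% usable
    x <- x[keep]; gr <- factor(gr[keep], levels = usable)
    a <- oneway_anova_raw(x, gr)
    res_a[[length(res_a) + 1]] <-
      data.frame(from = keys$from[i], to = keys$to[i], F = a$F,
                 df_num = a$df_num, df_den = a$df_den, p = a$p,
                 n_excluded = n_excl)
    pairs <- utils::combn(levels(gr), 2)
    pw <- apply(pairs, 2, function(pr) {
      tt <- stats::t.test(x[gr == pr[1]], x[gr == pr[2]], var.equal = TRUE)
      data.frame(from = keys$from[i], to = keys$to[i],
                 group1 = pr[1], group2 = pr[2],
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value)
    })
    pw <- do.call(rbind, pw)
    pw$p_adj <- bonferroni_adjust(pw$p)
    res_p[[length(res_p) + 1]] <- pw
  }
  list(anova = do.call(rbind, res_a), pairwise = do.call(rbind, res_p))
}
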