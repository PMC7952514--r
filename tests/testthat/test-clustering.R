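test_that("GFP matches hand-computed spatial standard deviations", {
  expect_equal(gfp(matrix(c(1, -1), 2, 1))[1], 1)
  expect_equal(gfp(matrix(c(3, 3, 3), 3, 1))[1], 0)
  expect_equal(gfp(matrix(c(2, -2, 0, 0), 4, 1))[1], sqrt(2))
  expect_error(gfp(matrix(1, 1, 5)), class = "invalid_data")
})

test_that("GFP peak detection uses strict maxima and respects epochs", {
  expect_equal(find_gfp_peaks(c(0, 1, 0, 2, 0)), c(2, 4))
  expect_length(find_gfp_peaks(1:10), 0)
  expect_length(find_gfp_peaks(c(0, 1, 1, 0)), 0)  # plateau rule
  # a maximum on an epoch's first sample is not a peak
  g <- c(0, 2, 3, 4, 1, 0)
  expect_equal(find_gfp_peaks(g), 4)
  expect_length(find_gfp_peaks(g, epoch_ids = c(1, 1, 1, 2, 2, 2)), 0)
})

test_that("spatial correlation handles sign, orthogonality, and errors", {
  a <- c(1, -1, 0.5, -0.5)
  expect_equal(spatial_correlation(a, a, FALSE), 1)
  expect_equal(spatial_correlation(a, -a, FALSE), -1)
  expect_equal(spatial_correlation(a, -a, TRUE), 1)
  expect_equal(spatial_correlation(c(1, -1, 0, 0), c(0, 0, 1, -1), FALSE), 0)
  expect_error(spatial_correlation(a, rep(2, 4)), class = "invalid_data")
  expect_error(spatial_correlation(a, a[1:3]), class = "invalid_data")
})

test_that("modified k-means recovers exact noiseless cluster structure", {
  tpl <- make_templates(8, 2, seed = 3)
  signs <- rep(c(1, -1), 10)
  maps <- cbind(tpl$maps[, rep(1, 10)] * rep(signs[1:10], each = 8),
                tpl$maps[, rep(2, 10)] * rep(signs[11:20], each = 8))
  res <- modified_kmeans(maps, clustering_config(k = 2, n_restarts = 10,
                                                 seed = 1),
                         gfp_weights = rep(1, 20))
  expect_equal(res$gev, 1, tolerance = 1e-9)
  match1 <- max(abs(oracle_corr(res$templates$maps[, 1], tpl$maps[, 1])),
                abs(oracle_corr(res$templates$maps[, 2], tpl$maps[, 1])))
  match2 <- max(abs(oracle_corr(res$templates$maps[, 1], tpl$maps[, 2])),
                abs(oracle_corr(res$templates$maps[, 2], tpl$maps[, 2])))
  expect_equal(match1, 1, tolerance = 1e-9)
  expect_equal(match2, 1, tolerance = 1e-9)
})

test_that("k = 1 template equals the dominant eigenvector of the outer-product sum", {
  set.seed(42)
  maps <- matrix(rnorm(6 * 30), 6, 30)
  g <- gfp(maps)
  res <- modified_kmeans(maps, clustering_config(k = 1, n_restarts = 3,
                                                 seed = 2),
                         gfp_weights = g)
  # independent oracle: full eigendecomposition of the weighted sum of
  # outer products of the centered, normalized maps
  cm <- sweep(maps, 2, colMeans(maps))
  nm <- sweep(cm, 2, sqrt(colSums(cm^2)), "/")
  S <- nm %*% (g^2 * t(nm))
  v <- eigen(S, symmetric = TRUE)$vectors[, 1]
  expect_equal(abs(oracle_corr(res$templates$maps[, 1], v)), 1,
               tolerance = 1e-8)
})

test_that("clustering beats or matches brute-force enumeration on tiny instances", {
  wins <- 0
  n_cases <- 20
  for (case in seq_len(n_cases)) {
    set.seed(100 + case)
    n_ch <- sample(4:6, 1)
    n_maps <- sample(8:12, 1)
    maps <- matrix(rnorm(n_ch * n_maps), n_ch, n_maps)
    g <- gfp(maps)
    res <- modified_kmeans(maps,
                           clustering_config(k = 2, n_restarts = 50,
                                             max_iter = 50, seed = case),
                           gfp_weights = g)
    oracle <- brute_force_gev(maps, 2, g)
    expect_lte(res$gev, oracle + 1e-9)
    if (res$gev >= oracle - 1e-6) wins <- wins + 1
  }
  expect_gte(wins, 18)
})

test_that("clustering is deterministic and invariant to sign flips and permutations", {
  sim <- small_subject(seed = 12, duration = 10)
  ep <- preprocess(sim$recording)
  pk <- gfp_peak_maps(ep)
  cfg <- clustering_config(n_restarts = 10, seed = 3)
  r1 <- modified_kmeans(pk$maps, cfg, gfp_weights = pk$gfp)
  r2 <- modified_kmeans(pk$maps, cfg, gfp_weights = pk$gfp)
  expect_identical(r1$templates$maps, r2$templates$maps)
  # global sign flip of the input data
  r3 <- modified_kmeans(-pk$maps, cfg, gfp_weights = pk$gfp)
  expect_identical(r3$assignment, r1$assignment)
  for (j in 1:4)
    expect_equal(abs(oracle_corr(r3$templates$maps[, j],
                                 r1$templates$maps[, j])), 1,
                 tolerance = 1e-9)
  # channel permutation applied consistently
  perm <- sample(seq_len(nrow(pk$maps)))
  r4 <- modified_kmeans(pk$maps[perm, ], cfg, gfp_weights = pk$gfp)
  expect_identical(r4$assignment, r1$assignment)
  for (j in 1:4)
    expect_equal(abs(oracle_corr(r4$templates$maps[, j],
                                 r1$templates$maps[perm, j])), 1,
                 tolerance = 1e-9)
})

test_that("clustering refuses fewer maps than classes", {
  maps <- matrix(rnorm(8 * 3), 8, 3)
  expect_error(modified_kmeans(maps, clustering_config(k = 4)),
               class = "too_few_maps")
})

test_that("two-level clustering reduces to the subject set for one subject", {
  sim <- small_subject(seed = 13, duration = 10)
  ep <- preprocess(sim$recording)
  pk <- gfp_peak_maps(ep)
  cfg <- clustering_config(n_restarts = 10, seed = 4)
  out <- two_level_clustering(list(S1 = pk$maps), groups = "G1", cfg,
                              gfp_weights = list(pk$gfp))
  for (j in 1:4) {
    best <- max(abs(crossprod(out$global$maps[, j], out$subject$S1$maps)))
    expect_gt(best, 0.99)
  }
})

test_that("two-level clustering recovers shared truth across groups", {
  cfg <- clustering_config(n_restarts = 20, seed = 5)
  tpl <- make_templates(16, 4, seed = 1000)
  peak_maps <- list(); gfps <- list(); groups <- character()
  for (i in 1:6) {
    sim <- small_subject(seed = 20 + i, duration = 15)
    ep <- preprocess(sim$recording)
    pk <- gfp_peak_maps(ep)
    sid <- sprintf("S%d", i)
    peak_maps[[sid]] <- pk$maps
    gfps[[sid]] <- pk$gfp
    groups <- c(groups, c("G1", "G2", "G3")[(i - 1) %/% 2 + 1])
  }
  out <- two_level_clustering(peak_maps, groups, cfg, gfp_weights = gfps)
  # global templates match the shared generating truth
  for (j in 1:4) {
    best <- max(abs(crossprod(tpl$maps[, j], out$global$maps)))
    expect_gte(best, 0.95)
  }
  # group-level sets agree pairwise after class matching
  gs <- out$group
  for (a in 1:2) for (b in (a + 1):3) {
    r <- abs(crossprod(gs[[a]]$maps, gs[[b]]$maps))
    matched <- apply(r, 1, max)
    expect_true(all(matched >= 0.9))
  }
})

test_that("subjects with too few peaks are skipped with a warning", {
  good <- matrix(rnorm(8 * 30), 8, 30)
  bad <- matrix(rnorm(8 * 2), 8, 2)
  expect_warning(
    out <- two_level_clustering(list(A = good, B = bad), c("G", "G"),
                                clustering_config(n_restarts = 5, seed = 1),
                                gfp_weights = list(gfp(good), gfp(bad))),
    "skipped")
  expect_null(out$subject$B)
  expect_false(is.null(out$global))
})

test_that("GEV never decreases across iterations", {
  # the implementation asserts monotonicity internally and aborts on
  # violation; a spread of random instances must run clean
  for (s in 1:5) {
    set.seed(s)
    maps <- matrix(rnorm(8 * 60), 8, 60)
    expect_no_error(modified_kmeans(
      maps, clustering_config(k = 3, n_restarts = 10, seed = s),
      gfp_weights = gfp(maps)))
  }
})
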