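test_that("backfit labels template-pure data perfectly, polarity-invariantly", {
  tpl <- make_templates(8, 4, seed = 2)
  # data equal to template B at every sample
  n <- 500
  dat <- array(0, dim = c(1, 8, n))
  dat[1, , ] <- tpl$maps[, 2] %o% rep(1, n)
  ep <- epoched_data(dat, fs = 250, epoch_length = 2)
  seg <- backfit(ep, tpl)
  expect_true(all(seg$labels == 2))
  expect_equal(unname(seg$r_values), rep(1, n), tolerance = 1e-9)
  # sign-flipped data gives identical labels
  ep2 <- ep; ep2$data <- -ep2$data
  seg2 <- backfit(ep2, tpl)
  expect_identical(seg2$labels, seg$labels)
})

test_that("flat samples inherit the previous label and are counted", {
  tpl <- make_templates(8, 4, seed = 2)
  dat <- array(0, dim = c(1, 8, 6))
  dat[1, , 1:3] <- tpl$maps[, 3] %o% rep(1, 3)
  # samples 4:6 exactly flat
  ep <- epoched_data(dat, fs = 3, epoch_length = 2)
  seg <- backfit(ep, tpl)
  expect_equal(seg$labels, rep(3L, 6))
  expect_equal(seg$n_flat, 3L)
  # flat at sequence start falls back to class 1
  dat2 <- array(0, dim = c(1, 8, 4))
  dat2[1, , 3:4] <- tpl$maps[, 2] %o% rep(1, 2)
  ep2 <- epoched_data(dat2, fs = 2, epoch_length = 2)
  seg2 <- backfit(ep2, tpl)
  expect_equal(seg2$labels[1:2], c(1L, 1L))
})

test_that("channel-count mismatch errors", {
  tpl <- make_templates(8, 4, seed = 2)
  ep <- epoched_data(array(rnorm(1 * 6 * 10), c(1, 6, 10)), fs = 5,
                     epoch_length = 2)
  expect_error(backfit(ep, tpl), class = "invalid_data")
})

test_that("parameters match hand-counted runs and the coverage identity", {
  # 1 s at 250 Hz: A x100, B x50, A x50, C x50
  seg <- manual_segmentation(rep(c(1, 2, 1, 3), c(100, 50, 50, 50)))
  p <- compute_parameters(seg)
  expect_equal(unname(p$duration["A"]), 0.3)
  expect_equal(unname(p$occurrence["A"]), 2)
  expect_equal(unname(p$coverage["A"]), 0.6)
  expect_true(is.na(p$duration["D"]))
  expect_equal(unname(p$occurrence["D"]), 0)
  expect_equal(sum(p$coverage), 1, tolerance = 1e-12)
  present <- !is.na(p$duration)
  expect_equal(unname(p$coverage[present]),
               unname(p$occurrence[present] * p$duration[present]),
               tolerance = 1e-9)
})

test_that("single-class segmentations count one run per epoch", {
  seg <- manual_segmentation(rep(1L, 1000), epoch_ids = rep(1:2, each = 500))
  p <- compute_parameters(seg)
  expect_equal(unname(p$coverage["A"]), 1)
  expect_equal(unname(p$occurrence["A"]), 2 / 4)  # 2 epochs over 4 s
})

test_that("transition probabilities match hand counts and flag undefined rows", {
  # run sequence A, B, A, C
  seg <- manual_segmentation(rep(c(1, 2, 1, 3), c(10, 10, 10, 10)))
  tm <- transition_probabilities(seg)
  expect_equal(tm$probs["A", "B"], 0.5)
  expect_equal(tm$probs["A", "C"], 0.5)
  expect_equal(tm$probs["B", "A"], 1)
  expect_true(all(is.na(tm$probs["C", ])))
  expect_equal(tm$undefined_rows, c(C = 3L, D = 4L))
  rs <- rowSums(tm$probs, na.rm = FALSE)
  expect_equal(unname(rs[c("A", "B")]), c(1, 1), tolerance = 1e-12)
})

test_that("deterministic cycles give unit transition probabilities", {
  labs <- rep(rep(1:4, each = 10), 375)  # A->B->C->D->A... 15000 samples
  seg <- manual_segmentation(labs)
  tm <- transition_probabilities(seg)
  expect_equal(tm$probs[1, 2], 1)
  expect_equal(tm$probs[2, 3], 1)
  expect_equal(tm$probs[3, 4], 1)
  expect_equal(tm$probs[4, 1], 1)
})

test_that("transitions are never counted across epoch boundaries", {
  labs <- c(rep(1, 10), rep(2, 10), rep(3, 10), rep(4, 10))
  seg <- manual_segmentation(labs, epoch_ids = rep(1:2, each = 20))
  tm <- transition_probabilities(seg)
  expect_equal(tm$counts[2, 3], 0L)  # B ends epoch 1, C starts epoch 2
  expect_equal(tm$counts[1, 2], 1L)
  expect_equal(tm$counts[3, 4], 1L)
})

test_that("backfit and parameters are invariant to permutation and polarity", {
  sim <- small_subject(seed = 31, duration = 10)
  ep <- preprocess(sim$recording)
  tpl <- sim$truth$templates
  seg <- backfit(ep, tpl)
  p <- compute_parameters(seg)
  # polarity flip
  ep_f <- ep; ep_f$data <- -ep_f$data
  seg_f <- backfit(ep_f, tpl)
  expect_identical(seg_f$labels, seg$labels)
  # channel permutation of data and templates together
  perm <- sample(16)
  ep_p <- ep; ep_p$data <- ep_p$data[, perm, , drop = FALSE]
  tpl_p <- tpl; tpl_p$maps <- tpl_p$maps[perm, ]
  seg_p <- backfit(ep_p, tpl_p)
  expect_identical(seg_p$labels, seg$labels)
  p_p <- compute_parameters(seg_p)
  expect_equal(p_p$duration, p$duration)
})

test_that("label smoothing removes isolated flips without moving boundaries", {
  labs <- rep(c(1, 2), c(50, 50))
  labs[25] <- 3  # isolated blip
  seg <- manual_segmentation(labs)
  seg_s <- backfit_smooth_for_test(seg, 3)
  expect_equal(seg_s[25], 1L)
  expect_equal(seg_s[50], 1L)
  expect_equal(seg_s[51], 2L)
})
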