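test_that("alignment quality follows the zero-shift NCC definition", {
  set.seed(3)
  a <- matrix(rnorm(64), 8, 8)
  expect_equal(qa(a, a), 1)
  expect_equal(qa(a, -a), -1)
  # B = A reversed: deviations exactly negated
  A <- matrix(c(1, 3, 2, 4), 2, 2)  # [[1,2],[3,4]] row-wise
  B <- matrix(c(4, 2, 3, 1), 2, 2)  # [[4,3],[2,1]]
  expect_equal(qa(A, B), -1)
  # symmetry property over random pairs
  for (i in 1:10) {
    x <- matrix(rnorm(100), 10, 10); y <- matrix(rnorm(100), 10, 10)
    expect_equal(qa(x, y), qa(y, x), tolerance = 1e-12)
    expect_true(abs(qa(x, y)) <= 1 + 1e-9)
  }
  expect_error(qa(matrix(1, 4, 4), matrix(1, 4, 4)), "sigma")
})

test_that("rate of change of QA matches hand arithmetic", {
  qa_tbl <- tibble::tibble(k = 1:3, index = 1:3, qa = c(0.9, 0.6, 0.6))
  rs <- roc_series(qa_tbl)
  expect_equal(rs$roc[1], abs(0.6 - 0.9) / 0.9 * 100, tolerance = 1e-12)
  expect_equal(rs$roc[2], 0)
  # constant series -> all zero
  rs0 <- roc_series(tibble::tibble(k = 1:4, index = 1:4, qa = rep(0.8, 4)))
  expect_true(all(rs0$roc == 0))
  # non-positive denominator flagged unusable, not thrown
  rsu <- roc_series(tibble::tibble(k = 1:3, index = 1:3, qa = c(-0.1, 0.5, 0.5)))
  expect_false(rsu$usable[1])
  expect_true(is.na(rsu$roc[1]))
  # alternative denominator convention
  rsc <- roc_series(qa_tbl, denominator = "current")
  expect_equal(rsc$roc[1], abs(0.6 - 0.9) / 0.6 * 100, tolerance = 1e-12)
})

test_that("planted corrupted frames are flagged exactly at a fixed seed", {
  sim <- simulate_sequence(scenario = 2, n = 20, seed = 3)
  expect_equal(length(sim$truth$corrupted), 5)  # 25% of 20
  flags <- detect_uninformative(sim$seq)
  expect_equal(which(flags), sim$truth$corrupted)
  s1 <- remove_uninformative(sim$seq, flags)
  expect_equal(n_frames(s1), 15)
  expect_false(any(s1$meta$index %in% sim$truth$corrupted))
})

test_that("clean near-identical sequences raise no flags", {
  set.seed(9)
  base <- make_texture("smooth", 96, seed = 2)[1:32, 1:32]
  fr <- lapply(1:8, function(k) base + rnorm(length(base), 0, 1e-4))
  flags <- detect_uninformative(frame_seq(fr))
  expect_false(any(flags))
})

test_that("supervised mode classifies held-out frames", {
  train <- simulate_sequence(scenario = 2, n = 20, seed = 21)
  model <- fit_frame_classifier(train$seq, seq_len(20) %in% train$truth$corrupted)
  test <- simulate_sequence(scenario = 2, n = 20, seed = 22)
  flags <- detect_uninformative(test$seq, mode = "fit", model = model)
  expect_equal(which(flags), test$truth$corrupted)
})

test_that("homogeneous sequences yield a single segment", {
  sim <- simulate_sequence(scenario = 1, n = 10, frame_size = 64, seed = 4,
                           noise_sd = 0.005)
  sp <- split_scenes(sim$seq)
  expect_equal(nrow(sp$segments), 1)
  expect_length(sp$break_points, 0)
  expect_equal(tidy(sp)$start, 1L)
})

test_that("a planted scene change is recovered without spurious breaks", {
  sim <- simulate_sequence(scenario = 3, n = 20, seed = 1,
                           scene_script = 12L)
  s1 <- remove_uninformative(sim$seq, detect_uninformative(sim$seq))
  sp <- split_scenes(s1)
  expect_equal(sp$break_points, 12L)
  expect_equal(nrow(sp$segments), 2)
  # scene ids assigned in order over the retained frames
  expect_true(all(diff(sp$seq$meta$scene_id) >= 0))
  # within-scene pairs stay well correlated; the straddling pair collapses
  qs <- sp$qa
  within <- which(qs$index <= 9)   # both frames in scene 1
  straddle <- which(qs$index %in% 10:11)
  expect_gt(min(qs$qa[within]), 0.5)
  expect_lt(min(qs$qa[straddle]), 0.3)
})

test_that("short segments are merged into neighbours", {
  # force a break right before the last frame: the 1-frame tail is merged
  sim <- simulate_sequence(scenario = 1, n = 8, frame_size = 64, seed = 6,
                           noise_sd = 0.005)
  seq <- sim$seq
  other <- make_texture("smooth", 192, seed = 99)[33:96, 33:96]
  seq$frames[, , 8] <- other
  sp <- split_scenes(seq)
  expect_equal(nrow(sp$segments), 1)  # length-1 tail cannot stand alone
})
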