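test_that("the generator is deterministic in its seed", {
  s1 <- simulate_sequence(scenario = 3, n = 12, frame_size = 64, seed = 5)
  s2 <- simulate_sequence(scenario = 3, n = 12, frame_size = 64, seed = 5)
  expect_identical(s1$seq$frames, s2$seq$frames)
  expect_identical(s1$truth$table, s2$truth$table)
  s3 <- simulate_sequence(scenario = 3, n = 12, frame_size = 64, seed = 6)
  expect_false(identical(s1$seq$frames, s3$seq$frames))
})

test_that("ground truth is complete: every frame has shift, flag and scene", {
  for (sc in 1:4) {
    sim <- simulate_sequence(scenario = sc, n = 12, frame_size = 64, seed = 7)
    tab <- sim$truth$table
    expect_equal(nrow(tab), 12)
    expect_true(all(!is.na(tab$dy) & !is.na(tab$dx)))
    expect_true(all(tab$scene_id >= 1))
    expect_true(all(diff(tab$scene_id) >= 0))
  }
})

test_that("scenario definitions hold: corruption count, breaks, homogeneity", {
  # scenario 1: identical frames up to noise, no corruption
  s1 <- simulate_sequence(scenario = 1, n = 10, frame_size = 64, seed = 8,
                          noise_sd = 0)
  expect_true(all(s1$truth$table$dy == 0 & s1$truth$table$dx == 0))
  expect_length(s1$truth$corrupted, 0)
  expect_identical(s1$seq$frames[, , 1], s1$seq$frames[, , 10])
  # scenario 2 at the default 25% rate: exactly 5 corrupted indices in 20
  s2 <- simulate_sequence(scenario = 2, n = 20, seed = 8)
  expect_length(s2$truth$corrupted, 5)
  expect_true(all(diff(s2$truth$corrupted) > 1))  # isolated artefacts
  # scenario 3: one break; scenario 4: two
  s3 <- simulate_sequence(scenario = 3, n = 20, seed = 8)
  expect_length(s3$truth$scene_breaks, 1)
  s4 <- simulate_sequence(scenario = 4, n = 21, seed = 8)
  expect_length(s4$truth$scene_breaks, 2)
})

test_that("brick texture autocorrelation has period-spaced secondary peaks", {
  canvas <- make_texture("brick", 384, seed = 9, period = 16)
  crop <- canvas[100:227, 100:227]
  cm <- ncc_map(crop, crop)
  pk <- find_local_peaks(cm, rel_thresh = 0.5, min_sep = 8)
  offs <- pk[-1, ]  # strongest is zero lag
  near16 <- (abs(abs(offs$di) - 16) <= 2 & abs(offs$dj) <= 2) |
    (abs(abs(offs$dj) - 16) <= 2 & abs(offs$di) <= 2)
  expect_true(any(near16))
})

test_that("smooth texture has a unique dominant autocorrelation peak", {
  canvas <- make_texture("smooth", 384, seed = 10)
  crop <- canvas[100:227, 100:227]
  cm <- ncc_map(crop, crop)
  pk <- find_local_peaks(cm, rel_thresh = 0.8, min_sep = 3)
  expect_equal(nrow(pk), 1)
})

test_that("the aliasing fixture defeats the global argmax by construction", {
  fx <- alias_fixture(seed = 7)
  reg <- register_translate(fx$seq)
  err <- abs(reg$offsets$dj - fx$truth$table$dx)
  expect_true(any(err >= 15))
  expect_true(max(fx$truth$table$dx) > 16)  # drift crosses one period
})

test_that("blob textures record a usable signal mask", {
  sim <- simulate_sequence(scenario = 2, n = 4, seed = 11, texture = "blobs",
                           corruption_rate = 0)
  expect_false(is.null(sim$truth$signal_mask))
  expect_gt(sum(sim$truth$signal_mask), 0)
  # bright pixels in frame 1 coincide with the mask
  f1 <- sim$seq$frames[, , 1]
  expect_gt(mean(f1[sim$truth$signal_mask]), mean(f1) + 0.5)
})

test_that("two-gate synthesis is reproducible and consistent", {
  tau <- matrix(2, 16, 16)
  tb1 <- make_two_bin(matrix(100, 16, 16), tau, delta_t = 2,
                      poisson = TRUE, seed = 12)
  tb2 <- make_two_bin(matrix(100, 16, 16), tau, delta_t = 2,
                      poisson = TRUE, seed = 12)
  expect_identical(tb1$bin1, tb2$bin1)
  # tau = delta_t: exact ratio e^-1 without noise
  tb <- make_two_bin(matrix(100, 16, 16), tau, delta_t = 2)
  expect_equal(tb$bin1 / tb$bin0, matrix(exp(-1), 16, 16), tolerance = 1e-12)
})
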