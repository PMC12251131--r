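test_that("mean fusion averages over valid frames only", {
  a <- matrix(0, 8, 8); b <- matrix(2, 8, 8)
  fs <- frame_seq(list(a, b))
  fused <- fuse_mean(fs)
  expect_equal(fused$pixels, matrix(1, 8, 8))
  expect_true(all(fused$support == 2L))
  # single frame: identity
  f1 <- fuse_mean(frame_seq(list(b)))
  expect_equal(f1$pixels, b)
  expect_true(all(f1$support == 1L))
  # idempotence on duplicated frames
  f2 <- fuse_mean(frame_seq(list(b, b)))
  expect_equal(f2$pixels, b)
  # masked-out pixels do not contribute
  m <- array(TRUE, dim = c(8, 8, 2)); m[1, 1, 2] <- FALSE
  fs3 <- frame_seq(list(a, b), masks = m)
  f3 <- fuse_mean(fs3)
  expect_equal(f3$pixels[1, 1], 0)
  expect_equal(f3$support[1, 1], 1L)
})

test_that("fusion suppresses i.i.d. noise like 1/n", {
  set.seed(20)
  base <- make_texture("smooth", 96, seed = 2)[1:32, 1:32]
  n <- 20; sigma <- 0.2
  fr <- lapply(seq_len(n), function(k) base + rnorm(length(base), 0, sigma))
  fused <- fuse_mean(frame_seq(fr))
  resid_var <- var(as.vector(fused$pixels - base))
  expect_lt(abs(resid_var - sigma^2 / n) / (sigma^2 / n), 0.2)
})

test_that("threshold detection counts the constructed blobs", {
  px <- matrix(1, 32, 32)
  px[4:6, 4:6] <- 10
  px[20:22, 25:27] <- 10
  px[15, 15] <- 10  # single-pixel speck, below min_area
  fused <- structure(list(pixels = px,
                          support = matrix(1L, 32, 32)),
                     class = "fused_image")
  mask <- nap_detect(fused, thresh = 5, min_area = 4L)
  expect_equal(sum(mask), 18)
  expect_equal(max(EBImage::bwlabel(mask * 1L)), 2)
  # min_area = 1 keeps the speck (pure thresholding)
  expect_equal(sum(nap_detect(fused, 5, min_area = 1L)), 19)
  # threshold above the global maximum: empty mask allowed
  expect_equal(sum(nap_detect(fused, 100)), 0)
})

test_that("detection metrics match hand-counted confusion tables", {
  # TP = 7, FP = 1, FN = 3 by construction
  tr <- matrix(FALSE, 8, 8); tr[1, 1:8] <- TRUE; tr[2, 1:2] <- TRUE  # 10 truth
  p <- matrix(FALSE, 8, 8); p[1, 1:7] <- TRUE; p[5, 5] <- TRUE
  m <- detection_metrics(p, tr)
  expect_equal(m$tp, 7L); expect_equal(m$fp, 1L); expect_equal(m$fn, 3L)
  expect_equal(m$precision, 0.875)
  expect_equal(m$recall, 0.7)
  expect_equal(m$f1, 2 * 0.875 * 0.7 / 1.575, tolerance = 1e-12)
  # exact match
  ok <- detection_metrics(tr, tr)
  expect_equal(c(ok$precision, ok$recall, ok$f1), c(1, 1, 1))
  # empty prediction against non-empty truth
  none <- detection_metrics(matrix(FALSE, 8, 8), tr)
  expect_equal(c(none$precision, none$recall, none$f1), c(0, 0, 0))
  # both empty: 1 by convention
  empty <- detection_metrics(matrix(FALSE, 8, 8), matrix(FALSE, 8, 8))
  expect_equal(empty$f1, 1)
  expect_error(detection_metrics(p, matrix(FALSE, 4, 4)), "shape")
})

test_that("registration improves detection on a drifting blob scene", {
  sim <- simulate_sequence(scenario = 2, n = 12, seed = 2, texture = "blobs",
                           corruption_rate = 0)
  thresh <- 1.6
  f1 <- function(x) detection_metrics(nap_detect(fuse_mean(x), thresh),
                                      sim$truth$signal_mask)$f1
  expect_gte(f1(register_tracked(sim$seq)), f1(sim$seq))
  expect_gt(f1(register_tracked(sim$seq)), 0.7)
})
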