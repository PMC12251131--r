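test_that("FFT correlation map equals the spatial-domain oracle", {
  set.seed(10)
  for (i in 1:8) {
    h <- sample(8:24, 1); w <- sample(8:24, 1)
    a <- matrix(rnorm(h * w), h, w)
    b <- matrix(rnorm(h * w), h, w)
    cm <- ncc_map(a, b)
    expect_lt(max(abs(cm$surface - oracle_ncc_map(a, b))), 1e-8)
    expect_equal(dim(cm$surface), c(2 * h - 1, 2 * w - 1))
    expect_equal(cm$origin, c(h, w))
  }
})

test_that("self-correlation peaks at the origin with value 1", {
  set.seed(11)
  a <- matrix(rnorm(256), 16, 16)
  cm <- ncc_map(a, a)
  p <- find_global_peak(cm)
  expect_equal(c(p$i, p$j), cm$origin)
  expect_equal(p$value, 1, tolerance = 1e-8)
  expect_error(ncc_map(a, matrix(2, 16, 16)), "sigma")
})

test_that("translation equivariance: a planted shift moves the argmax exactly", {
  canvas <- make_texture("smooth", 160, seed = 12)
  for (t in list(c(2, 3), c(-4, 1), c(0, -5))) {
    pr <- shifted_pair(canvas, 48, t[1], t[2])
    cm <- ncc_map(pr$ref, pr$mov)
    expect_equal(peak_to_offset(find_global_peak(cm), cm), as.integer(t))
  }
})

test_that("exact peak ties break towards the smaller displacement", {
  cm <- bump_map(c(16, 16), list(list(di = 0, dj = 2, value = 0.9),
                                 list(di = 5, dj = 5, value = 0.9)))
  # make the two candidate cells exactly equal
  cm$surface[16, 18] <- 1
  cm$surface[21, 21] <- 1
  p <- find_global_peak(cm)
  expect_equal(peak_to_offset(p, cm), c(0L, 2L))
})

test_that("repetitive texture produces competing correlation peaks", {
  canvas <- make_texture("brick", 384, seed = 13, period = 16)
  pr <- shifted_pair(canvas, 128, 0, 10)
  cm <- ncc_map(pr$ref, pr$mov)
  pk <- find_local_peaks(cm)
  expect_gt(nrow(pk), 1)
  # the competing maxima sit one texture period apart
  expect_true(any(abs(abs(pk$dj[-1] - pk$dj[1]) - 16) <= 2 |
                  abs(abs(pk$di[-1] - pk$di[1]) - 16) <= 2))
  # a smooth pair at the same shift stays single-peaked
  sm <- shifted_pair(make_texture("smooth", 384, seed = 13), 128, 0, 10)
  expect_equal(nrow(find_local_peaks(ncc_map(sm$ref, sm$mov))), 1)
})

test_that("warp_translate shifts content without interpolation", {
  set.seed(14)
  f <- matrix(rnorm(16 * 16), 16, 16)
  w0 <- warp_translate(f, 0, 0)
  expect_identical(w0$pixels, f)
  expect_true(all(w0$mask))
  # (2, 0) on a small frame invalidates exactly two border rows
  w2 <- warp_translate(matrix(1:16, 4, 4) + diag(4), 2, 0)
  expect_equal(sum(!w2$mask), 8)
  expect_true(all(!w2$mask[3:4, ]))
  # shift then unshift restores the original on the doubly-valid region
  fwd <- warp_translate(f, 3, -2)
  back <- warp_translate(fwd$pixels, -3, 2, fwd$mask)
  expect_equal(back$pixels[back$mask], f[back$mask])
  # every valid output pixel equals some input pixel (no interpolation)
  expect_true(all(fwd$pixels[fwd$mask] %in% f))
  expect_error(warp_translate(f, 16, 0), "out of range")
})

test_that("argmax registration recovers planted shifts on smooth scenes", {
  sim <- simulate_sequence(scenario = 2, n = 8, seed = 15, corruption_rate = 0)
  reg <- register_translate(sim$seq)
  expect_equal(reg$offsets$di, sim$truth$table$dy)
  expect_equal(reg$offsets$dj, sim$truth$table$dx)
  expect_equal(reg$method, "ncc-translate")
  # registered frames agree with the reference over the valid overlap
  sc <- score_pairs(reg)
  expect_true(all(sc$qa > 0.95))
  # identical frames -> all offsets zero
  same <- frame_seq(lapply(1:4, function(k) sim$seq$frames[, , 1]))
  reg0 <- register_translate(same)
  expect_true(all(reg0$offsets$di == 0L & reg0$offsets$dj == 0L))
})

test_that("tidy and glance summarise registration results", {
  sim <- simulate_sequence(scenario = 2, n = 5, seed = 16, corruption_rate = 0)
  reg <- register_translate(sim$seq)
  td <- tidy(reg)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("frame", "di", "dj", "peak_value") %in% names(td)))
  gl <- glance(reg)
  expect_equal(gl$n_frames, 5)
  expect_equal(gl$method, "ncc-translate")
})

test_that("iterative NCC optimisation finds small shifts but aliases on periodic scenes", {
  # small planted shift on a smooth scene: exact
  path <- cbind(dy = c(0, 2), dx = c(0, 1))
  sim <- simulate_sequence(2, n = 2, seed = 5, shift_path = path,
                           corruption_rate = 0)
  rp <- register_powell(sim$seq)
  expect_equal(rp$offsets$di[2], 2L)
  expect_equal(rp$offsets$dj[2], 1L)
  expect_equal(rp$method, "ncc-general")
  # shift of 18 px on a period-16 texture: the optimiser started at zero
  # converges to the alias near (0, 2), one period short of the truth
  path2 <- cbind(dy = c(0, 0), dx = c(0, 18))
  sim2 <- simulate_sequence(2, n = 2, seed = 5, texture = "brick",
                            shift_path = path2, corruption_rate = 0,
                            noise_sd = 0.005)
  rp2 <- register_powell(sim2$seq)
  expect_lt(abs(rp2$offsets$dj[2] - 2), 3)
  expect_true(abs(rp2$offsets$dj[2] - 18) >= 13)
})
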