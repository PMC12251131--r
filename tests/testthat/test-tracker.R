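cfg_small <- tracker_config(roi_size = 31L, search_size = 15L)

test_that("tracker configuration validates its parameters", {
  expect_error(tracker_config(roi_size = 10L), "roi_size")
  expect_error(tracker_config(lambda = -1))
  expect_equal(tracker_config()$channels, c("raw", "gradmag", "smooth"))
})

test_that("feature channels standardise and drop degenerate ones", {
  cm <- bump_map(c(32, 32), list(list(di = 0, dj = 0, value = 1)))
  ext <- extract_channels(cm, cm$origin, cfg_small)
  expect_length(ext$channels, 3)
  for (ch in ext$channels) {
    expect_lt(abs(mean(ch)), 1e-10)
    expect_equal(sum(ch^2), 1, tolerance = 1e-8)
  }
  # raw channel peaks at the centre; gradient magnitude dips there (ring)
  ctr <- ext$centre_in_roi
  expect_equal(which.max(ext$channels$raw),
               (ctr[2] - 1) * 31 + ctr[1])
  expect_lt(ext$channels$gradmag[ctr[1], ctr[2]],
            max(ext$channels$gradmag))
  # constant map: all channels dropped -> error
  flat <- cm; flat$surface[] <- 0.5
  expect_error(suppressWarnings(extract_channels(flat, flat$origin, cfg_small)),
               "degenerate")
})

test_that("initialisation centres the spatial reliability on the peak", {
  cm <- bump_map(c(32, 32), list(list(di = 2, dj = -1, value = 1)))
  st <- init_tracker(cm, cfg_small)
  expect_equal(st$peak, c(cm$origin[1] + 2, cm$origin[2] - 1))
  s <- st$spatial_reliability
  ctr <- c(16L, 16L)  # roi centre for an interior peak
  expect_equal(s[ctr[1], ctr[2]], 1)
  expect_equal(s[ctr[1] + cfg_small$sigma_s, ctr[2]], exp(-0.5),
               tolerance = 1e-12)
  expect_true(all(st$channel_reliability == 1))
  # operator seeding overrides the argmax
  seed_peak <- structure(list(i = cm$origin[1], j = cm$origin[2], value = 0),
                         class = "peak_loc")
  st2 <- init_tracker(cm, cfg_small, peak0 = seed_peak)
  expect_equal(st2$peak, cm$origin)
})

test_that("freshly learned filters respond maximally at the training peak", {
  cm <- bump_map(c(32, 32), list(list(di = 0, dj = 0, value = 1)))
  st <- init_tracker(cm, cfg_small)
  up <- update_and_localise(st, cm)
  expect_equal(up$peak$i, cm$origin[1])
  expect_equal(up$peak$j, cm$origin[2])
  # re-presenting the same map leaves the channel reliabilities at 1
  expect_true(all(abs(unlist(up$state$channel_reliability) - 1) < 1e-8))
  expect_false(up$low_confidence)
})

test_that("closed-form frequency-domain ridge filter matches a dense solve", {
  set.seed(4)
  n <- 9
  xi <- matrix(rnorm(n * n), n, n)
  xi <- (xi - mean(xi)) / sqrt(sum((xi - mean(xi))^2))
  rho <- flimreg:::gaussian_bump(n, n, c(5, 5), 1.5)
  lambda <- 0.01
  h_freq <- Re(stats::fft(flimreg:::solve_filter(xi, rho, lambda, 1),
                          inverse = TRUE)) / (n * n)
  # dense equivalent: circulant convolution matrix, ridge normal equations
  N <- n * n
  A <- matrix(0, N, N)
  for (col in seq_len(N)) {
    e <- matrix(0, n, n); e[col] <- 1
    A[, col] <- as.vector(Re(stats::fft(stats::fft(xi) * stats::fft(e),
                                        inverse = TRUE)) / N)
  }
  h_dense <- solve(t(A) %*% A + lambda * diag(N), t(A) %*% as.vector(rho))
  expect_lt(max(abs(as.vector(h_freq) - h_dense)), 1e-6)
})

test_that("the tracker keeps to the near peak when a far alias is higher", {
  c0 <- bump_map(c(64, 64), list(list(di = 0, dj = 0, value = 1)))
  st <- init_tracker(c0, tracker_config())
  # next map: true peak drifted to (2, 0); period-16 alias at (18, 0) is 2% higher
  ck <- bump_map(c(64, 64), list(list(di = 2, dj = 0, value = 0.90),
                                 list(di = 18, dj = 0, value = 0.92)))
  naive <- peak_to_offset(find_global_peak(ck), ck)
  expect_equal(naive, c(18L, 0L))
  up <- update_and_localise(st, ck)
  expect_equal(c(up$peak$i - ck$origin[1], up$peak$j - ck$origin[2]), c(2, 0))
})

test_that("reliabilities stay in (0, 1] and responses finite while tracking", {
  sim <- simulate_sequence(scenario = 2, n = 8, seed = 17, corruption_rate = 0)
  ref <- sim$seq$frames[, , 1]
  st <- init_tracker(ncc_map(ref, ref), tracker_config())
  for (k in 2:8) {
    up <- update_and_localise(st, ncc_map(ref, sim$seq$frames[, , k]))
    st <- up$state
    r <- unlist(st$channel_reliability)
    expect_true(all(r > 0 & r <= 1))
    expect_true(all(is.finite(st$spatial_reliability)))
    expect_true(all(st$spatial_reliability > 0 &
                    st$spatial_reliability <= 1))
  }
})

test_that("tracked registration recovers planted shifts exactly", {
  sim <- simulate_sequence(scenario = 2, n = 10, seed = 18, corruption_rate = 0)
  reg <- register_tracked(sim$seq)
  expect_equal(reg$offsets$di, sim$truth$table$dy)
  expect_equal(reg$offsets$dj, sim$truth$table$dx)
  expect_equal(reg$method, "tracked-ncc")
  expect_equal(reg$offsets$di[1], 0L)  # reference frame
  # identical frames: all offsets zero, registered stack identical
  same <- frame_seq(lapply(1:4, function(k) sim$seq$frames[, , 1]))
  reg0 <- register_tracked(same)
  expect_true(all(reg0$offsets$di == 0L & reg0$offsets$dj == 0L))
  expect_equal(reg0$registered$frames, same$frames)
})

test_that("tracked registration beats the global argmax on aliasing sequences", {
  fx <- alias_fixture(seed = 3)
  tr <- fx$truth$table
  naive <- register_translate(fx$seq)
  tracked <- register_tracked(fx$seq)
  err_naive <- abs(naive$offsets$di - tr$dy) + abs(naive$offsets$dj - tr$dx)
  err_tracked <- abs(tracked$offsets$di - tr$dy) + abs(tracked$offsets$dj - tr$dx)
  expect_true(any(err_naive >= 15))      # the argmax jumps a texture period
  expect_equal(mean(err_tracked), 0)     # the tracker stays on the true peak
})

test_that("tracked registration is deterministic across reruns", {
  sim <- simulate_sequence(scenario = 2, n = 8, seed = 19, corruption_rate = 0)
  r1 <- register_tracked(sim$seq)
  r2 <- register_tracked(sim$seq)
  expect_identical(r1$offsets, r2$offsets)
})
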