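#' Dense two-frame optical flow
#'
#' Pyramidal, iteratively re-warped Lucas-Kanade dense flow: at each pyramid
#' level the moving frame is warped by the current flow estimate, local
#' brightness-constancy systems are solved per pixel over a square window, and
#' the increment is accumulated. Only summary statistics of the field feed
#' downstream decisions (the pipeline registers with integer translations),
#' so the estimator's job is to recover translations accurately and expose
#' non-translational motion as an inconsistent field.
#'
#' @param ref,mov numeric matrices of the same shape
#' @param levels pyramid levels (default 3; level `l` handles displacements up
#'   to roughly `window * 2^(l-1) / 2` pixels)
#' @param window odd window side for the local least-squares (default 15)
#' @param iters warp-and-solve iterations per level
#' @param presmooth Gaussian sigma applied to both frames before
#'   differentiation
#' @return a `flow_field`: list with `dy`, `dx` (matrices, pixels,
#'   reference-to-moving displacement)
#' @export
dense_flow <- function(ref, mov, levels = 3L, window = 15L, iters = 3L,
                       presmooth = 1) {
  if (!identical(dim(ref), dim(mov))) stop("frames differ in shape")
  if (stats::sd(ref) < .eps_sigma || stats::sd(mov) < .eps_sigma)
    stop("degenerate frame: no image structure for flow estimation")
  ref <- gauss_blur(ref, presmooth)
  mov <- gauss_blur(mov, presmooth)
  pyr_r <- build_pyramid(ref, levels)
  pyr_m <- build_pyramid(mov, levels)
  lvl <- length(pyr_r)
  u <- matrix(0, nrow(pyr_r[[lvl]]), ncol(pyr_r[[lvl]]))  # dy
  v <- matrix(0, nrow(pyr_r[[lvl]]), ncol(pyr_r[[lvl]]))  # dx
  for (l in lvl:1) {
    r <- pyr_r[[l]]; m <- pyr_m[[l]]
    if (l < lvl) {
      u <- resize_x2(u, dim(r)) * 2
      v <- resize_x2(v, dim(r)) * 2
    }
    for (it in seq_len(iters)) {
      inc <- lk_increment(r, m, u, v, window)
      u <- u + inc$du
      v <- v + inc$dv
    }
  }
  structure(list(dy = u, dx = v), class = "flow_field")
}

build_pyramid <- function(m, levels) {
  pyr <- list(m)
  for (l in seq_len(levels - 1L)) {
    prev <- pyr[[l]]
    if (min(dim(prev)) < 16L) break
    sm <- gauss_blur(prev, 1)
    h2 <- nrow(sm) %/% 2L; w2 <- ncol(sm) %/% 2L
    pyr[[l + 1L]] <- 0.25 * (sm[2 * seq_len(h2) - 1L, 2 * seq_len(w2) - 1L] +
                             sm[2 * seq_len(h2), 2 * seq_len(w2) - 1L] +
                             sm[2 * seq_len(h2) - 1L, 2 * seq_len(w2)] +
                             sm[2 * seq_len(h2), 2 * seq_len(w2)])
  }
  pyr
}

# nearest-neighbour upsample of a flow component to a target shape
resize_x2 <- function(m, target) {
  ri <- pmin(nrow(m), ceiling(seq_len(target[1]) / target[1] * nrow(m)))
  ci <- pmin(ncol(m), ceiling(seq_len(target[2]) / target[2] * ncol(m)))
  m[ri, ci, drop = FALSE]
}

# warp mov by the current flow and solve windowed least squares for the
# flow increment (regularised 2x2 solve per pixel)
lk_increment <- function(ref, mov, u, v, window) {
  h <- nrow(ref); w <- ncol(ref)
  yy <- matrix(seq_len(h), h, w) + u
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) + v
  yy <- pmin(pmax(yy, 1), h); xx <- pmin(pmax(xx, 1), w)
  y0 <- pmin(floor(yy), h - 1); x0 <- pmin(floor(xx), w - 1)
  fy <- yy - y0; fx <- xx - x0
  idx <- function(r, c) (c - 1L) * h + r
  warped <- (1 - fy) * (1 - fx) * mov[idx(y0, x0)] +
    (1 - fy) * fx * mov[idx(y0, x0 + 1)] +
    fy * (1 - fx) * mov[idx(y0 + 1, x0)] +
    fy * fx * mov[idx(y0 + 1, x0 + 1)]
  gy <- (warped[c(2:h, h), ] - warped[c(1, 1:(h - 1)), ]) / 2
  gx <- (warped[, c(2:w, w)] - warped[, c(1, 1:(w - 1))]) / 2
  gt <- warped - ref
  bs <- function(m) box_sum(m, window)
  a11 <- bs(gy * gy); a12 <- bs(gy * gx); a22 <- bs(gx * gx)
  b1 <- -bs(gy * gt); b2 <- -bs(gx * gt)
  eps <- 1e-4 * mean(a11 + a22)
  det <- (a11 + eps) * (a22 + eps) - a12^2
  du <- ((a22 + eps) * b1 - a12 * b2) / det
  dv <- ((a11 + eps) * b2 - a12 * b1) / det
  du[!is.finite(du)] <- 0; dv[!is.finite(dv)] <- 0
  # clamp the per-iteration step to the window radius for stability
  r <- (window - 1) / 2
  list(du = pmin(pmax(du, -r), r), dv = pmin(pmax(dv, -r), r))
}

# windowed box sum with replicate padding (separable)
box_sum <- function(m, window) {
  r <- (window - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  pr <- m[c(rep(1L, r), seq_len(h), rep(h, r)), , drop = FALSE]
  cs <- apply(pr, 2, cumsum)
  rows <- cs[(window):(window + h - 1L), , drop = FALSE] -
    rbind(0, cs[seq_len(h - 1L), , drop = FALSE])
  pc <- rows[, c(rep(1L, r), seq_len(w), rep(w, r)), drop = FALSE]
  cs2 <- t(apply(pc, 1, cumsum))
  cs2[, (window):(window + w - 1L), drop = FALSE] -
    cbind(0, cs2[, seq_len(w - 1L), drop = FALSE])
}

#' Motion report for a frame pair
#'
#' Summarises a dense flow field into the statistics that decide the motion
#' model: the median displacement vector, displacement-magnitude percentiles,
#' and the translation-consistency score — the fraction of pixels whose vector
#' lies within `tol` pixels (Euclidean) of the median vector. A pair is
#' recommended for translation-only registration when the score reaches
#' `consistency_cut`.
#'
#' @param flow a `flow_field`
#' @param tol translation tolerance in pixels (default 1, matching the
#'   integer-offset registration downstream)
#' @param consistency_cut score at or above which translation is recommended
#' @return one-row tibble: `median_dy`, `median_dx`, `mag_p50`, `mag_p90`,
#'   `mag_p99`, `consistency`, `recommended`
#' @export
motion_report <- function(flow, tol = 1.0, consistency_cut = 0.8) {
  md <- stats::median(flow$dy); mx <- stats::median(flow$dx)
  mag <- sqrt(flow$dy^2 + flow$dx^2)
  dist <- sqrt((flow$dy - md)^2 + (flow$dx - mx)^2)
  score <- mean(dist <= tol)
  tibble::tibble(median_dy = md, median_dx = mx,
                 mag_p50 = stats::quantile(mag, 0.5, names = FALSE),
                 mag_p90 = stats::quantile(mag, 0.9, names = FALSE),
                 mag_p99 = stats::quantile(mag, 0.99, names = FALSE),
                 consistency = score,
                 recommended = if (score >= consistency_cut) "translation"
                               else "non-rigid")
}

#' Characterise the motion of a scene-consistent sequence
#'
#' Runs [dense_flow()] on every consecutive pair and reports the motion model
#' statistics per pair. Used to validate that translation-only registration is
#' adequate before the registration stage.
#'
#' @param seq a scene-consistent `frame_seq` (n >= 2)
#' @param tol,consistency_cut passed to [motion_report()]
#' @param ... passed to [dense_flow()]
#' @return tibble with one row per consecutive pair (`k` = leading frame)
#' @export
characterise_motion <- function(seq, tol = 1.0, consistency_cut = 0.8, ...) {
  n <- n_frames(seq)
  if (n < 2L) stop("need at least two frames to characterise motion")
  purrr::map_dfr(seq_len(n - 1L), function(k) {
    fl <- dense_flow(seq$frames[, , k], seq$frames[, , k + 1L], ...)
    dplyr::bind_cols(tibble::tibble(k = k), motion_report(fl, tol, consistency_cut))
  })
}
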