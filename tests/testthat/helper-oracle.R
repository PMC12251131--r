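# brute-force spatial-domain NCC map: direct evaluation of the zero-shift
# correlation formula at every integer displacement; independent of the FFT path
oracle_ncc_map <- function(ref, mov) {
  h <- nrow(ref); w <- ncol(ref)
  rc <- ref - mean(ref); mc <- mov - mean(mov)
  s <- sqrt(sum(rc^2)) * sqrt(sum(mc^2))
  out <- matrix(0, 2 * h - 1, 2 * w - 1)
  for (di in -(h - 1):(h - 1)) {
    ys <- max(1, 1 - di):min(h, h - di)
    for (dj in -(w - 1):(w - 1)) {
      xs <- max(1, 1 - dj):min(w, w - dj)
      out[di + h, dj + w] <- sum(rc[ys, xs] * mc[ys + di, xs + dj]) / s
    }
  }
  out
}

# crop a pair of frames from one canvas with a known content displacement:
# mov's content is ref's moved down-right by (dy, dx)
shifted_pair <- function(canvas, frame, dy, dx, y0 = NULL, x0 = NULL) {
  if (is.null(y0)) y0 <- (nrow(canvas) - frame) %/% 2
  if (is.null(x0)) x0 <- (ncol(canvas) - frame) %/% 2
  list(ref = canvas[y0 + seq_len(frame), x0 + seq_len(frame)],
       mov = canvas[y0 - dy + seq_len(frame), x0 - dx + seq_len(frame)])
}

# synthetic correlation map with Gaussian bumps at given offsets (di, dj)
# relative to the zero-shift origin
bump_map <- function(frame_dim, bumps, sigma = 2) {
  h <- frame_dim[1]; w <- frame_dim[2]
  s <- matrix(0, 2 * h - 1, 2 * w - 1)
  ii <- matrix(seq_len(2 * h - 1), 2 * h - 1, 2 * w - 1)
  jj <- matrix(seq_len(2 * w - 1), 2 * h - 1, 2 * w - 1, byrow = TRUE)
  for (b in bumps) {
    s <- s + b$value * exp(-((ii - h - b$di)^2 + (jj - w - b$dj)^2) / (2 * sigma^2))
  }
  structure(list(surface = s, origin = c(h, w), frame_dim = c(h, w)),
            class = "corr_map")
}
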