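#' Grey-level co-occurrence texture features
#'
#' Quantises a frame to `levels` grey levels (equal-width bins over the valid
#' intensity range) and accumulates a symmetric, normalised co-occurrence
#' table for each pixel offset, averaging the classical Haralick scalars
#' (contrast, correlation, energy, homogeneity) over offsets. Global mean and
#' variance of intensity are appended, giving a fixed-length descriptor used
#' by the uninformative-frame detector.
#'
#' @param pixels numeric matrix
#' @param levels number of grey levels (>= 2)
#' @param offsets list of `(dy, dx)` integer pixel offsets
#' @param mask optional logical matrix of valid pixels
#' @return named numeric vector: `contrast`, `correlation`, `energy`,
#'   `homogeneity`, `mean`, `var`
#' @export
glcm_features <- function(pixels, levels = 32L,
                          offsets = list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L)),
                          mask = NULL) {
  stopifnot(levels >= 2L)
  if (is.null(mask)) mask <- array(TRUE, dim = dim(pixels))
  v <- pixels[mask]
  rng <- range(v)
  if (rng[1] == rng[2]) stop("degenerate frame: constant image has no texture")
  # quantise to 1..levels
  q <- matrix(NA_integer_, nrow(pixels), ncol(pixels))
  q[mask] <- pmin(levels, 1L + floor((pixels[mask] - rng[1]) / (rng[2] - rng[1]) * levels))
  feats <- vapply(offsets, function(off) {
    p <- glcm_table(q, off[1], off[2], levels)
    haralick_scalars(p)
  }, numeric(4))
  out <- rowMeans(feats)
  c(out, mean = mean(v), var = stats::var(v))
}

# symmetric normalised co-occurrence table for one offset
glcm_table <- function(q, dy, dx, levels) {
  h <- nrow(q); w <- ncol(q)
  ys <- seq_len(h); xs <- seq_len(w)
  ys1 <- ys[ys + dy >= 1 & ys + dy <= h]
  xs1 <- xs[xs + dx >= 1 & xs + dx <= w]
  a <- q[ys1, xs1, drop = FALSE]
  b <- q[ys1 + dy, xs1 + dx, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(matrix(0, levels, levels))
  counts <- table(factor(a[ok], levels = seq_len(levels)),
                  factor(b[ok], levels = seq_len(levels)))
  p <- matrix(as.numeric(counts), levels, levels)
  p <- p + t(p)
  p / sum(p)
}

haralick_scalars <- function(p) {
  levels <- nrow(p)
  i <- row(p); j <- col(p)
  pi_m <- rowSums(p)
  mu <- sum(seq_len(levels) * pi_m)
  sig2 <- sum((seq_len(levels) - mu)^2 * pi_m)
  contrast <- sum(p * (i - j)^2)
  correlation <- if (sig2 > 0) sum(p * (i - mu) * (j - mu)) / sig2 else 0
  energy <- sum(p^2)
  homogeneity <- sum(p / (1 + abs(i - j)))
  c(contrast = contrast, correlation = correlation,
    energy = energy, homogeneity = homogeneity)
}

#' Texture feature table for a sequence
#'
#' @param seq a `frame_seq`
#' @inheritParams glcm_features
#' @return tibble with one row per frame (`index` plus the six features)
#' @export
texture_features <- function(seq, levels = 32L,
                             offsets = list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
  stopifnot(inherits(seq, "frame_seq"))
  rows <- purrr::map(seq_len(n_frames(seq)), function(k) {
    f <- glcm_features(seq$frames[, , k], levels, offsets, seq$masks[, , k])
    tibble::tibble(index = seq$meta$index[k], !!!as.list(f))
  })
  dplyr::bind_rows(rows)
}
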