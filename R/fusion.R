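#' Fuse a registered sequence by per-pixel averaging
#'
#' Averages the registered frames over the frames whose validity mask covers
#' each pixel; the per-pixel count of contributing frames is kept as the
#' support map. Averaging suppresses uncorrelated noise (variance falls as
#' `1/n`), which is what makes threshold detection on the fused image viable.
#'
#' @param reg a `flim_registration` or a `frame_seq`
#' @return a `fused_image`: list with `pixels` (NA where no frame contributes)
#'   and `support`
#' @export
fuse_mean <- function(reg) {
  seq <- if (inherits(reg, "flim_registration")) reg$registered else reg
  stopifnot(inherits(seq, "frame_seq"))
  n <- n_frames(seq)
  acc <- matrix(0, dim(seq$frames)[1], dim(seq$frames)[2])
  support <- matrix(0L, nrow(acc), ncol(acc))
  for (k in seq_len(n)) {
    m <- seq$masks[, , k]
    acc[m] <- acc[m] + seq$frames[, , k][m]
    support <- support + m
  }
  if (all(support == 0L)) stop("zero support everywhere: nothing to fuse")
  px <- acc / support
  px[support == 0L] <- NA_real_
  structure(list(pixels = px, support = support), class = "fused_image")
}

#' @export
print.fused_image <- function(x, ...) {
  cat(sprintf("<fused_image> %d x %d, support %d..%d\n",
              nrow(x$pixels), ncol(x$pixels), min(x$support), max(x$support)))
  invisible(x)
}

#' Threshold detection of bright signal in a fused image
#'
#' Marks supported pixels at or above `thresh`, then removes connected
#' components (8-connectivity) smaller than `min_area` pixels to suppress
#' residual single-pixel noise. `min_area = 1` disables the component filter.
#'
#' @param fused a `fused_image`
#' @param thresh intensity threshold (same units as the fused pixels)
#' @param min_area minimum component area in pixels (default 4)
#' @return logical matrix (the detection mask; may be empty)
#' @export
nap_detect <- function(fused, thresh, min_area = 4L) {
  stopifnot(inherits(fused, "fused_image"))
  if (all(fused$support == 0L)) stop("fused image has no supported pixels")
  mask <- !is.na(fused$pixels) & fused$pixels >= thresh & fused$support >= 1L
  if (min_area > 1L && any(mask)) {
    lab <- EBImage::bwlabel(mask * 1L)
    sizes <- tabulate(lab[lab > 0])
    small <- which(sizes < min_area)
    if (length(small)) mask[lab %in% small] <- FALSE
  }
  mask
}

#' Pixel-wise detection metrics against a ground-truth mask
#'
#' Precision, recall and F1 (equivalently the Dice coefficient) from
#' pixel-wise true/false positives and false negatives. When both masks are
#' empty the score is 1 by convention (nothing to find, nothing found).
#'
#' @param pred,truth logical matrices of the same shape
#' @return one-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`, `f1`
#' @export
detection_metrics <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) stop("masks differ in shape")
  pred <- as.logical(pred); truth <- as.logical(truth)
  tp <- sum(pred & truth); fp <- sum(pred & !truth); fn <- sum(!pred & truth)
  if (tp + fp + fn == 0L) {
    return(tibble::tibble(tp = 0L, fp = 0L, fn = 0L,
                          precision = 1, recall = 1, f1 = 1))
  }
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  tibble::tibble(tp = tp, fp = fp, fn = fn,
                 precision = precision, recall = recall, f1 = f1)
}
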