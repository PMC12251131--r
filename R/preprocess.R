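#' Quality of alignment between two frames
#'
#' Normalised cross-correlation at zero shift between two frames:
#' `sum((A - mu_A) * (B - mu_B)) / (sigma_A * sigma_B)`, where `sigma` is the
#' root sum of squared deviations (no `1/N`), so `qa(A, A) = 1` exactly.
#' Computed over the mutually valid pixels.
#'
#' @param a,b numeric matrices of the same shape
#' @param mask_a,mask_b optional logical validity masks
#' @return scalar in `[-1, 1]`
#' @export
qa <- function(a, b, mask_a = NULL, mask_b = NULL) {
  if (!identical(dim(a), dim(b))) stop("frames differ in shape")
  if (is.null(mask_a)) mask_a <- array(TRUE, dim = dim(a))
  if (is.null(mask_b)) mask_b <- array(TRUE, dim = dim(b))
  m <- mask_a & mask_b
  if (sum(m) < 2L) stop("degenerate frame pair: no mutual valid overlap")
  av <- a[m]; bv <- b[m]
  ac <- av - mean(av); bc <- bv - mean(bv)
  sa <- sqrt(sum(ac^2)); sb <- sqrt(sum(bc^2))
  if (sa < .eps_sigma || sb < .eps_sigma)
    stop("degenerate frame: sigma = 0")
  val <- sum(ac * bc) / (sa * sb)
  # clamp numerical overshoot from floating point
  max(-1, min(1, val))
}

#' Consecutive-pair alignment quality series
#'
#' `QA[k]` compares frame `k` with frame `k + 1`; the series has `n - 1`
#' entries aligned to the leading frame of each pair.
#'
#' @param seq a `frame_seq`
#' @return tibble with columns `k` (leading frame position), `index`
#'   (its original frame index) and `qa`
#' @export
qa_series <- function(seq) {
  stopifnot(inherits(seq, "frame_seq"))
  n <- n_frames(seq)
  if (n < 2L) stop("need at least two frames for a QA series")
  vals <- vapply(seq_len(n - 1L), function(k) {
    qa(seq$frames[, , k], seq$frames[, , k + 1L],
       seq$masks[, , k], seq$masks[, , k + 1L])
  }, numeric(1))
  tibble::tibble(k = seq_len(n - 1L), index = seq$meta$index[seq_len(n - 1L)],
                 qa = vals)
}

#' Rate of change of the QA series
#'
#' `RoC[k] = |QA[k] - QA[k-1]| / QA[k-1] * 100` for `k = 2..n-1`, where
#' `QA[k]` is the alignment quality of pair `(k, k+1)`. The denominator is the
#' preceding pair's QA by default (the previous single-valued QA available at
#' `k`); `denominator = "current"` uses `QA[k]` instead. Entries whose
#' denominator is at or below `tol` are flagged unusable rather than thrown.
#'
#' @param qa_tbl tibble from [qa_series()]
#' @param denominator `"prev"` (default) or `"current"`
#' @param tol positive tolerance below which the denominator is unusable
#' @return tibble with columns `k` (pair position, `2..n-1`), `roc` (percent,
#'   `NA` where unusable), `usable`, and `qa_drop` (signed change
#'   `QA[k] - QA[k-1]`)
#' @export
roc_series <- function(qa_tbl, denominator = c("prev", "current"), tol = 1e-6) {
  denominator <- match.arg(denominator)
  q <- qa_tbl$qa
  if (length(q) < 2L) stop("need at least two QA values for a RoC series")
  ks <- 2:length(q)
  den <- if (denominator == "prev") q[ks - 1L] else q[ks]
  usable <- den > tol
  roc <- ifelse(usable, abs(q[ks] - q[ks - 1L]) / den * 100, NA_real_)
  tibble::tibble(k = ks, roc = roc, usable = usable,
                 qa_drop = q[ks] - q[ks - 1L])
}

#' Detect uninformative frames from texture features
#'
#' Frames corrupted by motion, noise or signal dropout carry no usable scene
#' content and are removed before registration. In `"unsupervised"` mode a
#' 2-component Gaussian mixture is fitted to standardised corruption-sensitive
#' texture features of the sequence; the minority cluster is labelled
#' uninformative (corrupted frames are a minority by the method's premise;
#' ties fall back to the cluster with lower mean GLCM correlation), and flags
#' are raised only when the two clusters are genuinely separated (standardised
#' distance between cluster centres at least `min_separation`), so clean
#' homogeneous sequences produce no flags. In `"fit"` mode a supervised
#' Gaussian classifier trained with [fit_frame_classifier()] is applied.
#'
#' @param seq a `frame_seq` (at least 4 frames for unsupervised mode)
#' @param mode `"unsupervised"` or `"fit"`
#' @param model classifier from [fit_frame_classifier()] (for `mode = "fit"`)
#' @param min_separation minimum distance between standardised cluster means
#'   for the mixture split to be believed
#' @param levels,offsets passed to [glcm_features()]
#' @return logical vector, `TRUE` for frames flagged uninformative
#' @export
detect_uninformative <- function(seq, mode = c("unsupervised", "fit"),
                                 model = NULL, min_separation = 1.5,
                                 levels = 32L,
                                 offsets = list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
  mode <- match.arg(mode)
  feats <- texture_features(seq, levels, offsets)
  # cluster on corruption-sensitive features: contrast, correlation and
  # homogeneity are invariant to the scene's intensity scale (quantisation is
  # per-frame) and variance enters on a log scale; the raw mean and the GLCM
  # energy are excluded because both track scene identity more than
  # informativeness and would make multi-scene sequences cluster by scene
  x <- as.matrix(tibble::tibble(
    contrast = feats$contrast, correlation = feats$correlation,
    homogeneity = feats$homogeneity,
    log_var = log(pmax(feats$var, 1e-12))))
  if (mode == "fit") {
    if (is.null(model)) stop("mode = 'fit' requires a model")
    z <- scale(x, center = model$center, scale = model$scale)
    pred <- stats::predict(model$fit, newdata = z)
    return(pred$classification == "uninformative")
  }
  n <- nrow(x)
  if (n < 4L) stop("unsupervised mode needs at least 4 frames")
  sds <- apply(x, 2, stats::sd)
  keep <- sds > 1e-12
  z <- scale(x[, keep, drop = FALSE])
  fit <- Mclust(z, G = 2, verbose = FALSE)
  if (is.null(fit)) return(rep(FALSE, n))
  cls <- fit$classification
  if (length(unique(cls)) < 2L) return(rep(FALSE, n))
  m1 <- colMeans(z[cls == 1L, , drop = FALSE])
  m2 <- colMeans(z[cls == 2L, , drop = FALSE])
  if (sqrt(sum((m1 - m2)^2)) < min_separation) return(rep(FALSE, n))
  # effect-size guard on the raw feature scale: a corruption-vs-clean split
  # moves at least one feature by a texturally meaningful amount, whereas a
  # mixture fitted to jitter on near-identical clean frames does not (the
  # standardised separation alone cannot tell the two apart)
  dm <- function(col) abs(diff(tapply(x[, col], cls, mean)))
  meaningful <- dm("correlation") > 0.1 || dm("log_var") > 0.5 ||
    dm("homogeneity") > 0.05 ||
    dm("contrast") / max(mean(x[, "contrast"]), 1e-12) > 0.5
  if (!meaningful) return(rep(FALSE, n))
  # corrupted frames are a minority by the method's premise; label the smaller
  # cluster uninformative, breaking ties by lower mean GLCM correlation
  # (heavy blur *raises* GLCM correlation, so the low-correlation rule alone
  # would invert for blur artefacts)
  sizes <- table(cls)
  bad <- if (sizes[["1"]] != sizes[["2"]]) {
    as.integer(names(which.min(sizes)))
  } else {
    corr_means <- tapply(x[, "correlation"], cls, mean)
    as.integer(names(which.min(corr_means)))
  }
  flags <- cls == bad
  if (all(flags)) {
    warning("all frames flagged uninformative; returning no flags")
    return(rep(FALSE, n))
  }
  flags
}

#' Train a supervised uninformative-frame classifier
#'
#' Fits class-conditional Gaussians (mclust's `MclustDA` with a single
#' component per class) on standardised texture features of a labelled
#' sequence.
#'
#' @param seq a labelled `frame_seq`
#' @param uninformative logical vector of true labels
#' @inheritParams detect_uninformative
#' @return a model usable as `detect_uninformative(seq, "fit", model = .)`
#' @export
fit_frame_classifier <- function(seq, uninformative, levels = 32L,
                                 offsets = list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
  feats <- texture_features(seq, levels, offsets)
  x <- as.matrix(tibble::tibble(
    contrast = feats$contrast, correlation = feats$correlation,
    homogeneity = feats$homogeneity,
    log_var = log(pmax(feats$var, 1e-12))))
  z <- scale(x)
  labels <- ifelse(uninformative, "uninformative", "informative")
  fit <- MclustDA(z, labels, modelType = "EDDA", verbose = FALSE)
  list(fit = fit, center = attr(z, "scaled:center"),
       scale = attr(z, "scaled:scale"))
}

#' Apply uninformative-frame removal to a sequence
#'
#' Updates the `informative` metadata column and returns the sequence with
#' flagged frames dropped. The original sequence is untouched.
#'
#' @param seq a `frame_seq`
#' @param flags logical vector from [detect_uninformative()]
#' @return a `frame_seq` of the informative frames only
#' @export
remove_uninformative <- function(seq, flags) {
  stopifnot(length(flags) == n_frames(seq))
  if (all(flags)) stop("empty sequence: all frames flagged uninformative")
  seq$meta$informative <- !flags
  subset_frames(seq, !flags)
}

#' Split a sequence into scene-consistent segments
#'
#' Scans the consecutive-pair QA series and places a scene break before frame
#' `k + 1` whenever the rate of change of QA at `k` meets `thresh_pct`
#' (percent). Uninformative frames must already be removed: corrupted frames
#' produce QA dips that mask genuine transitions. After a break fires, the
#' cross-scene QA value is discarded and the RoC baseline restarts inside the
#' new segment (otherwise the recovery of QA after a genuine transition would
#' always fire a second, spurious break against the near-zero cross-scene
#' denominator). Entries with an unusable denominator fire only when the raw
#' QA change also exceeds `abs_drop` in absolute value. Segments shorter than
#' `min_len` frames are merged into their neighbour, since a one-frame scene
#' cannot be registered.
#'
#' @param seq a `frame_seq` of informative frames
#' @param thresh_pct RoC threshold in percent (default 30, the level that
#'   empirically corresponds to a scene transition)
#' @param min_len minimum segment length (default 2)
#' @param abs_drop absolute QA-change fallback for unusable denominators
#' @param tol denominator tolerance
#' @return an object of class `scene_split`: list with `segments` (tibble
#'   `scene_id`, `start`, `end`, `start_index`, `end_index`), `break_points`
#'   (original indices of frames that open a new scene), `qa` (the QA series)
#'   and `seq` (the input with `scene_id` metadata assigned)
#' @export
split_scenes <- function(seq, thresh_pct = 30, min_len = 2L, abs_drop = 0.3,
                         tol = 1e-6) {
  stopifnot(inherits(seq, "frame_seq"))
  n <- n_frames(seq)
  if (n < 2L) stop("need at least two frames to split scenes")
  qt <- qa_series(seq)
  q <- qt$qa
  breaks <- integer(0)  # positions (in seq) of frames starting a new segment
  k <- 2L
  prev <- q[1]
  while (k <= n - 1L) {
    fired <- if (prev > tol) {
      abs(q[k] - prev) / prev * 100 >= thresh_pct
    } else {
      abs(q[k] - prev) > abs_drop
    }
    if (fired) {
      breaks <- c(breaks, k + 1L)
      # restart the baseline inside the new segment, skipping the
      # cross-scene pair (k, k+1)
      if (k + 1L <= n - 1L) prev <- q[k + 1L]
      k <- k + 2L
    } else {
      prev <- q[k]
      k <- k + 1L
    }
  }
  starts <- c(1L, breaks)
  ends <- c(breaks - 1L, n)
  segs <- tibble::tibble(start = starts, end = ends)
  # merge segments shorter than min_len into the previous (or next) one
  i <- 1L
  while (i <= nrow(segs)) {
    if (segs$end[i] - segs$start[i] + 1L < min_len && nrow(segs) > 1L) {
      if (i > 1L) {
        segs$end[i - 1L] <- segs$end[i]
        segs <- segs[-i, ]
      } else {
        segs$start[i + 1L] <- segs$start[i]
        segs <- segs[-i, ]
      }
    } else i <- i + 1L
  }
  segs$scene_id <- seq_len(nrow(segs))
  segs$start_index <- seq$meta$index[segs$start]
  segs$end_index <- seq$meta$index[segs$end]
  segs <- segs[, c("scene_id", "start", "end", "start_index", "end_index")]
  scene_id <- integer(n)
  for (i in seq_len(nrow(segs))) scene_id[segs$start[i]:segs$end[i]] <- i
  seq$meta$scene_id <- scene_id
  structure(list(segments = segs,
                 break_points = segs$start_index[-1L],
                 qa = qt, seq = seq),
            class = "scene_split")
}

#' @export
print.scene_split <- function(x, ...) {
  cat(sprintf("<scene_split> %d segment(s); breaks at frame index: %s\n",
              nrow(x$segments),
              if (length(x$break_points)) paste(x$break_points, collapse = ", ")
              else "none"))
  print(x$segments)
  invisible(x)
}

#' @export
tidy.scene_split <- function(x, ...) x$segments

#' Extract the scene segments of a split as separate sequences
#'
#' @param split a `scene_split`
#' @return list of `frame_seq`, one per scene segment
#' @export
scene_segments <- function(split) {
  stopifnot(inherits(split, "scene_split"))
  purrr::map(seq_len(nrow(split$segments)), function(i) {
    subset_frames(split$seq, split$segments$start[i]:split$segments$end[i])
  })
}
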