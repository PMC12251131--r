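#' Structural similarity index between two frames
#'
#' Mean local SSIM with the standard constants (`k1 = 0.01`, `k2 = 0.03`) and
#' a Gaussian weighting window (`sigma = 1.5`, 11 x 11). Local statistics are
#' computed with replicate padding and the map is averaged over the full
#' frame.
#'
#' @param a,b numeric matrices of the same shape
#' @param dynamic_range value range `L` of the data; defaults to the range of
#'   the two images combined
#' @param sigma Gaussian window sigma in pixels
#' @param k1,k2 stabilisation constants
#' @return scalar SSIM in `[-1, 1]`
#' @export
ssim <- function(a, b, dynamic_range = NULL, sigma = 1.5, k1 = 0.01, k2 = 0.03) {
  if (!identical(dim(a), dim(b))) stop("frames differ in shape")
  if (is.null(dynamic_range)) dynamic_range <- diff(range(c(a, b)))
  if (dynamic_range <= 0) stop("degenerate dynamic range")
  c1 <- (k1 * dynamic_range)^2
  c2 <- (k2 * dynamic_range)^2
  g <- function(m) gauss_blur(m, sigma)
  mu_a <- g(a); mu_b <- g(b)
  va <- g(a * a) - mu_a^2
  vb <- g(b * b) - mu_b^2
  vab <- g(a * b) - mu_a * mu_b
  va <- pmax(va, 0); vb <- pmax(vb, 0)
  num <- (2 * mu_a * mu_b + c1) * (2 * vab + c2)
  den <- (mu_a^2 + mu_b^2 + c1) * (va + vb + c2)
  mean(num / den)
}

#' Normalised root-mean-square error
#'
#' RMSE between the two frames divided by the intensity range
#' (`max - min`) of the reference, over the mutually valid pixels.
#'
#' @param a reference frame (numeric matrix)
#' @param b comparison frame, same shape
#' @param mask optional logical matrix restricting the evaluation
#' @return non-negative scalar
#' @export
nrmse <- function(a, b, mask = NULL) {
  if (!identical(dim(a), dim(b))) stop("frames differ in shape")
  if (is.null(mask)) mask <- array(TRUE, dim = dim(a))
  av <- a[mask]; bv <- b[mask]
  rng <- diff(range(av))
  if (rng <= 0) stop("degenerate frame: zero intensity range")
  sqrt(mean((av - bv)^2)) / rng
}

# largest rectangle of mutual validity between two masks (exact for the
# rectangular masks produced by integer translation)
mutual_rect <- function(ma, mb) {
  m <- ma & mb
  rows <- which(rowSums(m) > 0)
  cols <- which(colSums(m) > 0)
  if (length(rows) == 0L || length(cols) == 0L) return(NULL)
  list(rows = rows, cols = cols, full = all(m[rows, cols]))
}

#' Score consecutive pairs of a registered (or raw) sequence
#'
#' QA, SSIM and NRMSE for every consecutive frame pair, computed over the
#' mutually valid region (for translation-registered stacks this is a
#' rectangle). The overlap pixel count is reported alongside so that shrinking
#' support is visible rather than silently inflating scores.
#'
#' @param seq_or_reg a `frame_seq` or `flim_registration`
#' @param dynamic_range optional fixed SSIM dynamic range
#' @return tibble with columns `k`, `qa`, `ssim`, `nrmse`, `overlap`
#' @export
score_pairs <- function(seq_or_reg, dynamic_range = NULL) {
  seq <- if (inherits(seq_or_reg, "flim_registration")) seq_or_reg$registered
         else seq_or_reg
  n <- n_frames(seq)
  if (n < 2L) stop("need at least two frames to score")
  purrr::map_dfr(seq_len(n - 1L), function(k) {
    a <- seq$frames[, , k]; b <- seq$frames[, , k + 1L]
    rect <- mutual_rect(seq$masks[, , k], seq$masks[, , k + 1L])
    if (is.null(rect))
      return(tibble::tibble(k = k, qa = NA_real_, ssim = NA_real_,
                            nrmse = NA_real_, overlap = 0L))
    av <- a[rect$rows, rect$cols]; bv <- b[rect$rows, rect$cols]
    mm <- (seq$masks[, , k] & seq$masks[, , k + 1L])[rect$rows, rect$cols]
    tibble::tibble(
      k = k,
      qa = qa(av, bv, mm, mm),
      ssim = ssim(av, bv, dynamic_range),
      nrmse = nrmse(av, bv, mm),
      overlap = sum(mm))
  })
}

#' Ablation harness over pre-processing stages and registration methods
#'
#' Reproduces the structure of the staged evaluation: for every dataset,
#' pre-processing stage (`unprocessed`, `step1` = uninformative-frame removal,
#' `step1+2` = removal plus scene splitting) and registration method, the
#' partial pipeline is run and consecutive registered pairs are scored with
#' QA, SSIM and NRMSE over their valid overlap. For `step1+2`, pairs are
#' scored within scene segments only (cross-scene pairs are not comparable by
#' construction). Method failures are recorded as NA rows, not raised.
#'
#' @param datasets named list of `frame_seq` objects
#' @param methods character subset of
#'   `c("tracked-ncc", "ncc-translate", "ncc-general")`
#' @param stages character subset of `c("unprocessed", "step1", "step1+2")`
#' @param thresh_roc scene-split RoC threshold (percent)
#' @param tracker a [tracker_config()]
#' @return an object of class `flim_ablation`: list with `records` (tibble:
#'   dataset, stage, method, mean/sd of each metric, pair count) and `pairs`
#'   (per-pair scores)
#' @export
run_ablation <- function(datasets,
                         methods = c("tracked-ncc", "ncc-translate", "ncc-general"),
                         stages = c("unprocessed", "step1", "step1+2"),
                         thresh_roc = 30, tracker = tracker_config()) {
  if (is.null(names(datasets)))
    names(datasets) <- paste0("dataset", seq_along(datasets))
  register_with <- function(seq, method) {
    switch(method,
           "tracked-ncc" = register_tracked(seq, tracker),
           "ncc-translate" = register_translate(seq),
           "ncc-general" = register_powell(seq),
           stop("unknown method: ", method))
  }
  pair_rows <- list(); rec_rows <- list()
  for (ds in names(datasets)) {
    seq0 <- datasets[[ds]]
    flags <- tryCatch(detect_uninformative(seq0),
                      error = function(e) rep(FALSE, n_frames(seq0)))
    for (stage in stages) {
      segs <- switch(stage,
        "unprocessed" = list(seq0),
        "step1" = list(remove_uninformative(seq0, flags)),
        "step1+2" = {
          s1 <- remove_uninformative(seq0, flags)
          scene_segments(split_scenes(s1, thresh_pct = thresh_roc))
        },
        stop("unknown stage: ", stage))
      for (method in methods) {
        scored <- tryCatch({
          purrr::map_dfr(segs, function(sg) {
            if (n_frames(sg) < 2L) return(NULL)
            score_pairs(register_with(sg, method))
          })
        }, error = function(e) NULL)
        if (is.null(scored) || nrow(scored) == 0L) {
          rec_rows[[length(rec_rows) + 1L]] <- tibble::tibble(
            dataset = ds, stage = stage, method = method,
            qa_mean = NA_real_, qa_sd = NA_real_, ssim_mean = NA_real_,
            ssim_sd = NA_real_, nrmse_mean = NA_real_, nrmse_sd = NA_real_,
            n_pairs = 0L)
          next
        }
        pair_rows[[length(pair_rows) + 1L]] <-
          dplyr::mutate(scored, dataset = ds, stage = stage, method = method)
        rec_rows[[length(rec_rows) + 1L]] <- tibble::tibble(
          dataset = ds, stage = stage, method = method,
          qa_mean = mean(scored$qa), qa_sd = stats::sd(scored$qa),
          ssim_mean = mean(scored$ssim), ssim_sd = stats::sd(scored$ssim),
          nrmse_mean = mean(scored$nrmse), nrmse_sd = stats::sd(scored$nrmse),
          n_pairs = nrow(scored))
      }
    }
  }
  structure(list(records = dplyr::bind_rows(rec_rows),
                 pairs = dplyr::bind_rows(pair_rows)),
            class = "flim_ablation")
}

#' @export
print.flim_ablation <- function(x, ...) {
  cat("<flim_ablation>\n")
  print(x$records)
  invisible(x)
}

#' @export
tidy.flim_ablation <- function(x, ...) x$records

#' Stage-over-stage improvement summary of an ablation run
#'
#' Percentage change of the mean metrics between consecutive stages, averaged
#' over datasets, per method. QA and SSIM improvements are
#' `(after - before) / before * 100`; NRMSE improvement is
#' `(before - after) / before * 100` (lower is better), so positive numbers
#' always mean improvement.
#'
#' @param ablation a `flim_ablation`
#' @return tibble: `method`, `transition`, `qa_improvement_pct`,
#'   `ssim_improvement_pct`, `nrmse_improvement_pct`
#' @export
ablation_improvements <- function(ablation) {
  rec <- ablation$records
  stages <- c("unprocessed", "step1", "step1+2")
  out <- list()
  for (method in unique(rec$method)) {
    for (t in 1:2) {
      before <- dplyr::filter(rec, .data$method == !!method,
                              .data$stage == stages[t])
      after <- dplyr::filter(rec, .data$method == !!method,
                             .data$stage == stages[t + 1L])
      both <- dplyr::inner_join(before, after, by = "dataset",
                                suffix = c("_b", "_a"))
      if (nrow(both) == 0L) next
      out[[length(out) + 1L]] <- tibble::tibble(
        method = method,
        transition = paste(stages[t], "->", stages[t + 1L]),
        qa_improvement_pct =
          mean((both$qa_mean_a - both$qa_mean_b) / abs(both$qa_mean_b)) * 100,
        ssim_improvement_pct =
          mean((both$ssim_mean_a - both$ssim_mean_b) / abs(both$ssim_mean_b)) * 100,
        nrmse_improvement_pct =
          mean((both$nrmse_mean_b - both$nrmse_mean_a) / both$nrmse_mean_b) * 100)
    }
  }
  dplyr::bind_rows(out)
}
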