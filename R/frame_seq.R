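#' Frame sequence container
#'
#' An ordered stack of equally sized 2-D frames with per-frame metadata and
#' per-pixel validity masks. This is the common currency of the pipeline:
#' every stage takes and returns a `frame_seq`. The coordinate convention is
#' `(row, col) = (y, x)`, origin at the top-left; all displacement offsets are
#' reported as `(dy, dx)` in that order.
#'
#' @param frames either an `H x W x n` numeric array or a list of `H x W`
#'   numeric matrices (all the same shape).
#' @param meta optional tibble with one row per frame and columns `index`,
#'   `informative` (logical) and `scene_id` (integer). Defaults to
#'   `index = 1..n`, all informative, one scene.
#' @param masks optional logical array/list matching `frames`; `TRUE` marks
#'   valid pixels. Defaults to all valid.
#'
#' @return An object of class `frame_seq`: a list with elements `frames`
#'   (array `H x W x n`, doubles), `masks` (logical array) and `meta` (tibble).
#' @export
frame_seq <- function(frames, meta = NULL, masks = NULL) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L)
      stop("ragged frame shapes: all frames must share (H, W)")
    frames <- array(unlist(frames), dim = c(dims[[1]], length(frames)))
  }
  if (length(dim(frames)) == 2L) frames <- array(frames, dim = c(dim(frames), 1L))
  stopifnot(length(dim(frames)) == 3L)
  storage.mode(frames) <- "double"
  h <- dim(frames)[1]; w <- dim(frames)[2]; n <- dim(frames)[3]
  if (h < 8 || w < 8) stop("frames must be at least 8 x 8")
  if (is.null(masks)) {
    masks <- array(TRUE, dim = dim(frames))
  } else {
    if (is.list(masks)) masks <- array(unlist(masks), dim = dim(frames))
    if (length(dim(masks)) == 2L) masks <- array(masks, dim = c(dim(masks), 1L))
    storage.mode(masks) <- "logical"
    stopifnot(identical(dim(masks), dim(frames)))
  }
  if (any(!is.finite(frames[masks])))
    stop("non-finite pixel values inside the valid mask")
  if (is.null(meta)) {
    meta <- tibble::tibble(index = seq_len(n), informative = TRUE,
                           scene_id = 1L)
  } else {
    meta <- tibble::as_tibble(meta)
    stopifnot(nrow(meta) == n, all(c("index", "informative", "scene_id") %in% names(meta)))
    if (is.unsorted(meta$scene_id[meta$informative], strictly = FALSE))
      stop("scene_id must be non-decreasing in frame order")
  }
  structure(list(frames = frames, masks = masks, meta = meta),
            class = "frame_seq")
}

#' @export
print.frame_seq <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_seq> %d frame(s) of %d x %d, %d informative, %d scene(s)\n",
              d[3], d[1], d[2], sum(x$meta$informative),
              length(unique(x$meta$scene_id[x$meta$informative]))))
  invisible(x)
}

#' @export
length.frame_seq <- function(x) dim(x$frames)[3]

#' Number of frames and frame shape
#' @param seq a `frame_seq`
#' @return `n_frames`: integer count; `frame_dim`: integer `(H, W)`.
#' @export
n_frames <- function(seq) dim(seq$frames)[3]

#' @rdname n_frames
#' @export
frame_dim <- function(seq) dim(seq$frames)[1:2]

#' Subset a frame sequence by frame position
#'
#' Keeps metadata rows (including the original `index` column) aligned with
#' the retained frames.
#'
#' @param seq a `frame_seq`
#' @param keep integer positions or logical vector over frames
#' @return a `frame_seq`
#' @export
subset_frames <- function(seq, keep) {
  if (is.logical(keep)) keep <- which(keep)
  if (length(keep) == 0L) stop("empty sequence: no frames retained")
  frame_seq(seq$frames[, , keep, drop = FALSE],
            meta = seq$meta[keep, , drop = FALSE],
            masks = seq$masks[, , keep, drop = FALSE])
}

#' Read an image stack into a frame sequence
#'
#' Supports multi-page TIFF stacks (grayscale; 8/16-bit integer or 32-bit
#' float) and a portable array archive (`.rds` holding a list with elements
#' `frames`, optional `masks` and `meta`). For `layout = "two_bin"` the stack
#' is interpreted as interleaved gate pages (bin0, bin1, bin0, bin1, ...) and
#' a list of two sequences is returned.
#'
#' @param path file path to a `.tif`/`.tiff` stack or `.rds` archive
#' @param layout `"stack"` (one frame per page) or `"two_bin"`
#' @return a `frame_seq`, or `list(bin0 =, bin1 =)` for `layout = "two_bin"`
#' @export
read_frame_seq <- function(path, layout = c("stack", "two_bin")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    obj <- readRDS(path)
    seq <- frame_seq(obj$frames, meta = obj$meta, masks = obj$masks)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) == 0L) stop("format error: stack has zero pages")
    pages <- lapply(seq_along(pages), function(i) {
      p <- pages[[i]]
      if (length(dim(p)) == 3L) p <- p[, , 1]  # collapse grayscale-as-RGB
      if (is.null(dim(p))) stop("format error: page ", i, " is not 2-D")
      p
    })
    dims <- lapply(pages, dim)
    if (length(unique(dims)) != 1L) {
      bad <- which(!vapply(dims, identical, logical(1), dims[[1]]))[1]
      stop("format error: ragged page shapes (page ", bad, ")")
    }
    seq <- frame_seq(pages)
  }
  if (layout == "stack") return(seq)
  n <- n_frames(seq)
  if (n %% 2L != 0L) stop("two_bin layout needs an even page count, got ", n)
  list(bin0 = subset_frames(seq, seq(1L, n, by = 2L)),
       bin1 = subset_frames(seq, seq(2L, n, by = 2L)))
}

#' Write a frame sequence to disk
#'
#' TIFF output stores 32-bit float pages and requires pixel values in
#' `[0, 1]` (the TIFF writer's storage contract); use the `.rds` archive for
#' arbitrary-range data, which round-trips exactly.
#'
#' @param seq a `frame_seq`
#' @param path destination ending in `.tif`/`.tiff` or `.rds`
#' @param bits bits per sample for TIFF output (8, 16 or 32)
#' @return `path`, invisibly
#' @export
write_frame_seq <- function(seq, path, bits = 32L) {
  stopifnot(inherits(seq, "frame_seq"))
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    saveRDS(list(frames = seq$frames, masks = seq$masks, meta = seq$meta), path)
    return(invisible(path))
  }
  rng <- range(seq$frames)
  if (rng[1] < 0 || rng[2] > 1)
    stop("TIFF output requires pixels in [0, 1]; rescale or use an .rds archive")
  pages <- lapply(seq_len(n_frames(seq)), function(k) seq$frames[, , k])
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits)),
            silent = TRUE)
  if (inherits(ok, "try-error")) stop("I/O error writing ", path)
  invisible(path)
}

#' Normalise a frame to zero mean and unit energy
#'
#' Subtracts the mean and divides by the root sum of squared deviations over
#' valid pixels (the sigma convention used throughout the correlation code,
#' with no 1/N factor), so that the normalised cross-correlation of a frame
#' with itself is exactly 1.
#'
#' @param pixels numeric matrix
#' @param mask optional logical matrix of valid pixels
#' @return numeric matrix with zero mean and unit root-sum-of-squares over
#'   valid pixels; invalid pixels are set to 0.
#' @export
normalise_frame <- function(pixels, mask = NULL) {
  if (is.null(mask)) mask <- array(TRUE, dim = dim(pixels))
  v <- pixels[mask]
  if (length(unique(v)) < 2L)
    stop("degenerate frame: fewer than 2 distinct valid pixel values")
  mu <- mean(v)
  sig <- sqrt(sum((v - mu)^2))
  if (sig < .eps_sigma) stop("degenerate frame: sigma = 0")
  out <- (pixels - mu) / sig
  out[!mask] <- 0
  out
}

#' Read or write a ground-truth sidecar table
#'
#' Plain TSV with one record per frame: `index`, `dy`, `dx`, `corrupted`,
#' `scene_id`. Shifts are the content displacement of each frame relative to
#' its scene's reference frame, in pixels.
#'
#' @param truth a `seq_truth` object (see [simulate_sequence()])
#' @param path file path for the `.tsv` sidecar
#' @return `read_ground_truth` returns a `seq_truth`; the writer returns
#'   `path` invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.table(truth$table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  tab <- tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE))
  seq_truth(tab)
}

#' Ground truth record for a generated sequence
#'
#' @param table tibble with columns `index`, `dy`, `dx`, `corrupted`,
#'   `scene_id`
#' @param signal_mask optional logical matrix marking true signal pixels in
#'   the reference frame of the first scene
#' @return an object of class `seq_truth` with fields `table`, `corrupted`
#'   (frame indices), `scene_breaks` (indices starting a new scene) and
#'   `signal_mask`.
#' @export
seq_truth <- function(table, signal_mask = NULL) {
  table <- tibble::as_tibble(table)
  stopifnot(all(c("index", "dy", "dx", "corrupted", "scene_id") %in% names(table)))
  sid <- table$scene_id
  breaks <- table$index[which(diff(sid) != 0) + 1L]
  structure(list(table = table,
                 corrupted = table$index[as.logical(table$corrupted)],
                 scene_breaks = as.integer(breaks),
                 signal_mask = signal_mask),
            class = "seq_truth")
}
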