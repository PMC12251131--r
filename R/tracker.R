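#' Peak-tracker configuration
#'
#' Parameters of the reliability-weighted discriminative-correlation-filter
#' tracker that follows the dominant correlation peak across the sequence of
#' NCC maps.
#'
#' @param lambda ridge regularisation weight of the filter objective
#' @param sigma_s spatial-reliability width in pixels: the Gaussian weight
#'   centred on the tracked peak that suppresses distant competing maxima
#' @param sigma_c channel-reliability width on unit-normalised descriptors:
#'   how fast a channel's vote decays as its local appearance changes
#' @param sigma_rho width (px) of the Gaussian desired response the filters
#'   are regressed onto
#' @param eta exponential learning rate for the filter update
#' @param roi_size odd side length of the square map region fed to the filters
#' @param search_size odd side of the window around the previous peak within
#'   which the next peak is accepted
#' @param patch_w half-width of the descriptor patch used for channel
#'   reliability
#' @param channels feature channels computed from the correlation map; any of
#'   `"raw"`, `"gradmag"`, `"smooth"`
#' @param smooth_sigma Gaussian sigma (px) of the smoothed-map channel
#' @param conf_floor fraction of the running median response below which a
#'   frame is flagged low-confidence and its offset carried over
#' @return a `tracker_config` list
#' @export
tracker_config <- function(lambda = 0.01, sigma_s = 10, sigma_c = 0.5,
                           sigma_rho = 2, eta = 0.2, roi_size = 63L,
                           search_size = 31L, patch_w = 5L,
                           channels = c("raw", "gradmag", "smooth"),
                           smooth_sigma = 2, conf_floor = 0.2) {
  stopifnot(lambda > 0, sigma_s > 0, sigma_c > 0, sigma_rho > 0,
            eta > 0, eta <= 1, roi_size %% 2L == 1L, search_size %% 2L == 1L)
  structure(list(lambda = lambda, sigma_s = sigma_s, sigma_c = sigma_c,
                 sigma_rho = sigma_rho, eta = eta,
                 roi_size = as.integer(roi_size),
                 search_size = as.integer(search_size),
                 patch_w = as.integer(patch_w),
                 channels = channels, smooth_sigma = smooth_sigma,
                 conf_floor = conf_floor),
            class = "tracker_config")
}

# --- small image helpers -----------------------------------------------------

gauss_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r):r / sigma)^2)
  k / sum(k)
}

# separable Gaussian blur with replicate padding
gauss_blur <- function(m, sigma) {
  k <- gauss_kernel1d(sigma)
  r <- (length(k) - 1L) / 2L
  h <- nrow(m); w <- ncol(m)
  pad_rows <- m[c(rep(1L, r), seq_len(h), rep(h, r)), , drop = FALSE]
  out <- matrix(0, h, w)
  for (t in seq_along(k)) out <- out + k[t] * pad_rows[(t - 1L) + seq_len(h), , drop = FALSE]
  pad_cols <- out[, c(rep(1L, r), seq_len(w), rep(w, r)), drop = FALSE]
  out2 <- matrix(0, h, w)
  for (t in seq_along(k)) out2 <- out2 + k[t] * pad_cols[, (t - 1L) + seq_len(w), drop = FALSE]
  out2
}

# gradient magnitude by central differences (replicated edges)
grad_mag <- function(m) {
  h <- nrow(m); w <- ncol(m)
  gy <- (m[c(2:h, h), ] - m[c(1, 1:(h - 1)), ]) / 2
  gx <- (m[, c(2:w, w)] - m[, c(1, 1:(w - 1))]) / 2
  sqrt(gy^2 + gx^2)
}

# clamp a roi centre so that a roi_size window fits inside the surface;
# returns 1-based top-left corner
clamp_roi <- function(centre, roi_size, dims) {
  r <- (roi_size - 1L) %/% 2L
  ci <- min(max(centre[1], r + 1L), dims[1] - r)
  cj <- min(max(centre[2], r + 1L), dims[2] - r)
  c(ci - r, cj - r)
}

gaussian_bump <- function(nr, nc, centre, sigma) {
  ii <- matrix(seq_len(nr), nr, nc)
  jj <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  exp(-((ii - centre[1])^2 + (jj - centre[2])^2) / (2 * sigma^2))
}

# --- feature channels --------------------------------------------------------

#' Feature channels of a correlation-map region
#'
#' Cuts a `roi_size` square region centred on (or clamped around) a peak and
#' derives the configured feature channels: the raw map values, the gradient
#' magnitude (which rings around a point peak), and a Gaussian-smoothed copy.
#' Each channel is standardised to zero mean and unit Frobenius norm over the
#' region; channels that are constant over the region are dropped.
#'
#' @param cm a `corr_map`
#' @param centre integer `(i, j)` map location to centre the region on
#' @param cfg a [tracker_config()]
#' @return list with `channels` (named list of matrices), `roi_origin`
#'   (top-left corner, 1-based) and `centre_in_roi`
#' @export
extract_channels <- function(cm, centre, cfg = tracker_config()) {
  dims <- dim(cm$surface)
  if (cfg$roi_size > min(dims)) stop("roi_size exceeds the correlation map")
  tl <- clamp_roi(centre, cfg$roi_size, dims)
  rows <- tl[1]:(tl[1] + cfg$roi_size - 1L)
  cols <- tl[2]:(tl[2] + cfg$roi_size - 1L)
  roi <- cm$surface[rows, cols]
  chans <- list()
  for (nm in cfg$channels) {
    x <- switch(nm,
                raw = roi,
                gradmag = grad_mag(roi),
                smooth = gauss_blur(roi, cfg$smooth_sigma),
                stop("unknown channel: ", nm))
    x <- x - mean(x)
    nrm <- sqrt(sum(x^2))
    if (nrm < 1e-10) {
      warning("constant channel '", nm, "' dropped")
      next
    }
    chans[[nm]] <- x / nrm
  }
  if (length(chans) == 0L) stop("degenerate region: all feature channels constant")
  list(channels = chans, roi_origin = tl,
       centre_in_roi = c(centre[1] - tl[1] + 1L, centre[2] - tl[2] + 1L))
}

# unit-normalised descriptor patch around a roi-local position
descriptor_patch <- function(chan, pos, w) {
  nr <- nrow(chan); nc <- ncol(chan)
  ci <- min(max(pos[1], w + 1L), nr - w)
  cj <- min(max(pos[2], w + 1L), nc - w)
  p <- chan[(ci - w):(ci + w), (cj - w):(cj + w)]
  nrm <- sqrt(sum(p^2))
  if (nrm < 1e-12) p else p / nrm
}

# closed-form frequency-domain ridge filter for one channel:
# minimises ||rho - xi (*) h||^2 + lambda R ||h||^2 under circular convolution
solve_filter <- function(xi, rho, lambda, r_c) {
  Xi <- stats::fft(xi)
  P <- stats::fft(rho)
  Conj(Xi) * P / (Conj(Xi) * Xi + lambda * r_c)
}

# response of one channel's filter (circular convolution via FFT)
filter_response <- function(x, H) {
  Re(stats::fft(stats::fft(x) * H, inverse = TRUE)) / length(x)
}

# hill-climb from a start location to the nearest local maximum of the raw
# surface: the tracker decides WHICH peak is being followed, but the
# translation itself is decoded at the correlation peak, undoing the small
# bias the spatial-reliability weighting exerts on broad peaks
snap_to_local_max <- function(surface, start, max_steps = 10L) {
  h <- nrow(surface); w <- ncol(surface)
  pos <- start
  for (s in seq_len(max_steps)) {
    ri <- max(1L, pos[1] - 1L):min(h, pos[1] + 1L)
    rj <- max(1L, pos[2] - 1L):min(w, pos[2] + 1L)
    nb <- surface[ri, rj, drop = FALSE]
    idx <- which.max(nb)
    nxt <- c(ri[((idx - 1L) %% nrow(nb)) + 1L],
             rj[((idx - 1L) %/% nrow(nb)) + 1L])
    if (all(nxt == pos)) break
    pos <- nxt
  }
  pos
}

#' Initialise the peak tracker on the first correlation map
#'
#' The first map determines the location of the true dominant peak (by global
#' argmax unless `peak0` seeds it). A Gaussian spatial-reliability map `S`
#' centred on that peak (value 1 at its centre) masks the feature channels,
#' and one discriminative correlation filter per channel is solved in closed
#' form by ridge regression onto a Gaussian desired response centred on the
#' peak. Channel reliabilities start at 1.
#'
#' @param c0 a `corr_map` (typically reference vs reference)
#' @param cfg a [tracker_config()]
#' @param peak0 optional `peak_loc` overriding the argmax (operator seeding)
#' @return a `tracker_state`
#' @export
init_tracker <- function(c0, cfg = tracker_config(), peak0 = NULL) {
  p <- if (is.null(peak0)) find_global_peak(c0) else peak0
  ext <- extract_channels(c0, c(p$i, p$j), cfg)
  s_map <- gaussian_bump(cfg$roi_size, cfg$roi_size, ext$centre_in_roi, cfg$sigma_s)
  rho <- gaussian_bump(cfg$roi_size, cfg$roi_size, ext$centre_in_roi, cfg$sigma_rho)
  r_c <- setNames(rep(1, length(ext$channels)), names(ext$channels))
  filters <- purrr::imap(ext$channels, function(x, nm)
    solve_filter(s_map * x, rho, cfg$lambda, r_c[[nm]]))
  ref_desc <- purrr::map(ext$channels, descriptor_patch,
                         pos = ext$centre_in_roi, w = cfg$patch_w)
  structure(list(filters = filters, spatial_reliability = s_map,
                 channel_reliability = r_c, ref_descriptors = ref_desc,
                 peak = c(p$i, p$j), initial_peak = c(p$i, p$j),
                 cfg = cfg, resp_history = numeric(0)),
            class = "tracker_state")
}

#' @export
print.tracker_state <- function(x, ...) {
  cat(sprintf("<tracker_state> peak (%d, %d), channels: %s\n",
              x$peak[1], x$peak[2],
              paste(sprintf("%s=%.3f", names(x$channel_reliability),
                            x$channel_reliability), collapse = ", ")))
  invisible(x)
}

#' Track the dominant peak into the next correlation map
#'
#' Extracts the feature region around the previously tracked peak, computes
#' the reliability-weighted filter response `S * sum_c R_c (x_c (*) DCF_c)`,
#' and takes its argmax within the search window as the new peak. Channel
#' reliabilities are refreshed from the descriptor change at the new peak
#' (`R_c = exp(-||d_c||^2 / (2 sigma_c^2))`), and the filters are updated by
#' an exponential moving average towards filters re-solved on the new region.
#' If the response maximum falls below `conf_floor` times the running median
#' of previous maxima the frame is flagged low-confidence and the previous
#' peak is kept.
#'
#' @param state a `tracker_state`
#' @param ck the next `corr_map` (same shape as the initial map)
#' @param cfg optional config override (defaults to the state's)
#' @return list with `peak` (`peak_loc`), `state` (updated), and
#'   `low_confidence` flag
#' @export
update_and_localise <- function(state, ck, cfg = NULL) {
  cfg <- cfg %||% state$cfg
  ext <- extract_channels(ck, state$peak, cfg)
  use <- intersect(names(state$filters), names(ext$channels))
  if (length(use) == 0L) stop("all feature channels dropped")
  s_map <- state$spatial_reliability
  resp <- matrix(0, cfg$roi_size, cfg$roi_size)
  for (nm in use) {
    resp <- resp + state$channel_reliability[[nm]] *
      filter_response(s_map * ext$channels[[nm]], state$filters[[nm]])
  }
  resp <- s_map * resp
  # previous peak's position inside this (possibly clamped) roi
  prev_in_roi <- c(state$peak[1] - ext$roi_origin[1] + 1L,
                   state$peak[2] - ext$roi_origin[2] + 1L)
  half <- (cfg$search_size - 1L) %/% 2L
  ri <- max(1L, prev_in_roi[1] - half):min(cfg$roi_size, prev_in_roi[1] + half)
  rj <- max(1L, prev_in_roi[2] - half):min(cfg$roi_size, prev_in_roi[2] + half)
  win <- resp[ri, rj, drop = FALSE]
  mx <- max(win)
  med <- if (length(state$resp_history)) stats::median(state$resp_history) else mx
  low_conf <- mx < cfg$conf_floor * med
  if (low_conf) {
    new_peak <- state$peak
  } else {
    idx <- which.max(win)
    wi <- ((idx - 1L) %% nrow(win)) + 1L
    wj <- ((idx - 1L) %/% nrow(win)) + 1L
    new_peak <- c(ext$roi_origin[1] + ri[wi] - 1L, ext$roi_origin[2] + rj[wj] - 1L)
    new_peak <- snap_to_local_max(ck$surface, new_peak)
    state$resp_history <- c(state$resp_history, mx)
  }
  # channel reliability from descriptor drift at the tracked peak
  new_in_roi <- c(new_peak[1] - ext$roi_origin[1] + 1L,
                  new_peak[2] - ext$roi_origin[2] + 1L)
  for (nm in use) {
    d <- descriptor_patch(ext$channels[[nm]], new_in_roi, cfg$patch_w) -
      state$ref_descriptors[[nm]]
    state$channel_reliability[[nm]] <-
      exp(-sum(d^2) / (2 * cfg$sigma_c^2))
  }
  if (!low_conf) {
    # re-solve filters on a region centred at the new peak; EMA blend
    ext2 <- extract_channels(ck, new_peak, cfg)
    rho <- gaussian_bump(cfg$roi_size, cfg$roi_size, ext2$centre_in_roi,
                         cfg$sigma_rho)
    for (nm in intersect(use, names(ext2$channels))) {
      hnew <- solve_filter(s_map * ext2$channels[[nm]], rho, cfg$lambda,
                           state$channel_reliability[[nm]])
      state$filters[[nm]] <- (1 - cfg$eta) * state$filters[[nm]] + cfg$eta * hnew
      state$ref_descriptors[[nm]] <-
        descriptor_patch(ext2$channels[[nm]], ext2$centre_in_roi, cfg$patch_w)
    }
  }
  state$peak <- new_peak
  list(peak = structure(list(i = new_peak[1], j = new_peak[2],
                             value = ck$surface[new_peak[1], new_peak[2]]),
                        class = "peak_loc"),
       state = state, low_confidence = low_conf)
}

#' Peak-tracked NCC registration
#'
#' The pipeline's registration core. The first frame of the scene-consistent
#' segment is the reference; the tracker is initialised on the reference's
#' auto-correlation map, whose dominant peak sits at the zero-shift origin,
#' and then follows the true displacement peak through the sequence of NCC
#' maps between the reference and each moving frame. Because the search stays
#' local to the previous track and the spatial-reliability map down-weights
#' distant maxima, the tracker keeps to the true peak even when repetitive
#' texture raises a periodic alias above it in absolute value — the failure
#' mode of the global argmax. Offsets are decoded relative to the map's
#' zero-shift origin (which coincides with the initial peak when frame 1 is
#' the reference). Low-confidence frames carry the previous offset forward.
#'
#' @param seq a scene-consistent `frame_seq` of informative frames (n >= 2)
#' @param cfg a [tracker_config()]
#' @return a `flim_registration` with method `"tracked-ncc"`; diagnostics
#'   include the map value at the tracked peak, the number of competing local
#'   maxima, and the low-confidence flag
#' @export
register_tracked <- function(seq, cfg = tracker_config()) {
  n <- n_frames(seq)
  if (n < 2L) stop("need at least two frames to register")
  ref <- seq$frames[, , 1]
  c0 <- ncc_map(ref, ref)
  if (cfg$roi_size > min(dim(c0$surface)))
    cfg$roi_size <- as.integer(2L * (min(dim(c0$surface)) %/% 2L) - 1L)
  state <- init_tracker(c0, cfg)
  offsets <- matrix(0L, n, 2)
  pk <- numeric(n); npk <- integer(n); lowc <- logical(n)
  pk[1] <- 1; npk[1] <- 1L
  for (k in seq_len(n)[-1]) {
    cm <- ncc_map(ref, seq$frames[, , k])
    up <- update_and_localise(state, cm)
    state <- up$state
    offsets[k, ] <- c(up$peak$i - cm$origin[1], up$peak$j - cm$origin[2])
    pk[k] <- up$peak$value
    npk[k] <- nrow(find_local_peaks(cm))
    lowc[k] <- up$low_confidence
    if (up$low_confidence) offsets[k, ] <- offsets[k - 1L, ]
  }
  build_registration(seq, offsets, "tracked-ncc",
                     tibble::tibble(peak_value = pk, n_competing_peaks = npk,
                                    low_confidence = lowc))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
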