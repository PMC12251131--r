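#' Full normalised cross-correlation map between two frames
#'
#' Computes the zero-padded full linear cross-correlation of the
#' mean-subtracted frames via the FFT, divided by the product of the frames'
#' root-sum-of-squared-deviation sigmas (global normalisation), giving a
#' `(2H - 1) x (2W - 1)` surface whose centre entry is the zero-shift NCC.
#' The peak location encodes the content displacement of the moving frame
#' relative to the reference: if `mov` equals `ref` with its content moved
#' down-right by `(dy, dx)`, the surface attains its maximum at
#' `origin + (dy, dx)`.
#'
#' @param ref,mov numeric matrices of the same shape (reference, moving)
#' @return an object of class `corr_map`: list with `surface`
#'   (`(2H-1) x (2W-1)`), `origin` (1-based `(row, col)` of zero shift,
#'   i.e. `(H, W)`), and `frame_dim`
#' @export
ncc_map <- function(ref, mov) {
  if (!identical(dim(ref), dim(mov))) stop("frames differ in shape")
  h <- nrow(ref); w <- ncol(ref)
  refc <- ref - mean(ref)
  movc <- mov - mean(mov)
  sr <- sqrt(sum(refc^2)); sm <- sqrt(sum(movc^2))
  if (sr < .eps_sigma || sm < .eps_sigma) stop("degenerate frame: sigma = 0")
  ph <- 2L * h - 1L; pw <- 2L * w - 1L
  rp <- matrix(0, ph, pw); rp[1:h, 1:w] <- refc
  mp <- matrix(0, ph, pw); mp[1:h, 1:w] <- movc
  # cross-correlation r(d) = sum_p ref(p) mov(p + d) = IFFT(conj(F(ref)) F(mov))
  cc <- Re(stats::fft(Conj(stats::fft(rp)) * stats::fft(mp), inverse = TRUE)) /
    (ph * pw)
  # reorder circular lags into a full map with zero shift at (H, W)
  rows <- c((h + 1L):ph, 1:h)
  cols <- c((w + 1L):pw, 1:w)
  surface <- cc[rows, cols] / (sr * sm)
  structure(list(surface = surface, origin = c(h, w), frame_dim = c(h, w)),
            class = "corr_map")
}

#' @export
print.corr_map <- function(x, ...) {
  p <- find_global_peak(x)
  off <- peak_to_offset(p, x)
  cat(sprintf("<corr_map> %d x %d surface, peak %.4f at offset (%d, %d)\n",
              nrow(x$surface), ncol(x$surface), p$value, off[1], off[2]))
  invisible(x)
}

#' Global peak of a correlation map
#'
#' Argmax over the surface; exact ties are broken by the smallest displacement
#' magnitude from the zero-shift origin, then row-major order.
#'
#' @param cm a `corr_map`
#' @return a `peak_loc`: list with 1-based indices `i`, `j` and `value`
#' @export
find_global_peak <- function(cm) {
  s <- cm$surface
  mx <- max(s)
  idx <- which(s == mx)
  if (length(idx) > 1L) {
    ii <- ((idx - 1L) %% nrow(s)) + 1L
    jj <- ((idx - 1L) %/% nrow(s)) + 1L
    mag <- (ii - cm$origin[1])^2 + (jj - cm$origin[2])^2
    idx <- idx[order(mag, ii, jj)][1L]
  }
  i <- ((idx - 1L) %% nrow(s)) + 1L
  j <- ((idx - 1L) %/% nrow(s)) + 1L
  structure(list(i = as.integer(i), j = as.integer(j), value = s[i, j]),
            class = "peak_loc")
}

#' Competing local maxima of a correlation map
#'
#' Local maxima (3 x 3 neighbourhood non-max suppression) whose value is at
#' least `rel_thresh` of the global maximum, thinned to a minimum mutual
#' separation. More than one surviving peak signals the multi-peak ambiguity
#' produced by repetitive texture or large displacement.
#'
#' @param cm a `corr_map`
#' @param rel_thresh fraction of the global maximum (default 0.95)
#' @param min_sep minimum peak separation in pixels (default 3)
#' @return tibble with columns `i`, `j`, `di`, `dj`, `value`, ordered by
#'   decreasing value
#' @export
find_local_peaks <- function(cm, rel_thresh = 0.95, min_sep = 3) {
  s <- cm$surface
  h <- nrow(s); w <- ncol(s)
  mx <- max(s)
  # 3x3 neighbourhood maximum via shift-compare
  nbr_max <- matrix(-Inf, h, w)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    ys <- max(1, 1 + dy):min(h, h + dy)
    xs <- max(1, 1 + dx):min(w, w + dx)
    sub <- s[ys - dy, xs - dx, drop = FALSE]
    nbr_max[ys, xs] <- pmax(nbr_max[ys, xs], sub)
  }
  cand <- which(s >= nbr_max & s >= rel_thresh * mx)
  if (length(cand) == 0L) cand <- which.max(s)
  ii <- ((cand - 1L) %% h) + 1L
  jj <- ((cand - 1L) %/% h) + 1L
  ord <- order(s[cand], decreasing = TRUE)
  ii <- ii[ord]; jj <- jj[ord]; vv <- s[cand][ord]
  keep <- logical(length(ii))
  for (t in seq_along(ii)) {
    if (!any(keep)) { keep[t] <- TRUE; next }
    d <- sqrt((ii[t] - ii[keep])^2 + (jj[t] - jj[keep])^2)
    if (all(d >= min_sep)) keep[t] <- TRUE
  }
  tibble::tibble(i = ii[keep], j = jj[keep],
                 di = ii[keep] - cm$origin[1], dj = jj[keep] - cm$origin[2],
                 value = vv[keep])
}

#' Convert a peak location to a translation offset
#'
#' @param p a `peak_loc`
#' @param cm the `corr_map` it indexes
#' @return integer `(di, dj)` relative to the zero-shift origin
#' @export
peak_to_offset <- function(p, cm) {
  as.integer(c(p$i - cm$origin[1], p$j - cm$origin[2]))
}

#' Translate a frame by an integer offset
#'
#' Shifts the pixel content by `(-di, -dj)` so that a moving frame whose
#' content is displaced by `(di, dj)` relative to the reference aligns back to
#' it: `out[y, x] = f[y + di, x + dj]`. Vacated borders are marked invalid; no
#' wraparound and no interpolation, so every valid output pixel equals some
#' input pixel.
#'
#' @param pixels numeric matrix
#' @param di,dj integer offset (`|di| < H`, `|dj| < W`)
#' @param mask optional logical input validity mask
#' @return list with `pixels` and `mask`
#' @export
warp_translate <- function(pixels, di, dj, mask = NULL) {
  h <- nrow(pixels); w <- ncol(pixels)
  if (abs(di) >= h || abs(dj) >= w)
    stop("offset out of range for frame size")
  if (is.null(mask)) mask <- matrix(TRUE, h, w)
  out <- matrix(0, h, w)
  outm <- matrix(FALSE, h, w)
  ys <- max(1, 1 - di):min(h, h - di)   # output rows with a source pixel
  xs <- max(1, 1 - dj):min(w, w - dj)
  out[ys, xs] <- pixels[ys + di, xs + dj]
  outm[ys, xs] <- mask[ys + di, xs + dj]
  list(pixels = out, mask = outm)
}

# shared assembly of a registration result from per-frame offsets
build_registration <- function(seq, offsets, method, diagnostics = NULL) {
  n <- n_frames(seq)
  frames <- vector("list", n); masks <- vector("list", n)
  for (k in seq_len(n)) {
    wp <- warp_translate(seq$frames[, , k], offsets[k, 1], offsets[k, 2],
                         seq$masks[, , k])
    frames[[k]] <- wp$pixels; masks[[k]] <- wp$mask
  }
  reg <- frame_seq(frames, meta = seq$meta, masks = masks)
  tab <- tibble::tibble(frame = seq_len(n), index = seq$meta$index,
                        di = as.integer(offsets[, 1]),
                        dj = as.integer(offsets[, 2]))
  if (!is.null(diagnostics)) tab <- dplyr::bind_cols(tab, diagnostics)
  structure(list(offsets = tab, registered = reg, method = method,
                 reference = 1L),
            class = "flim_registration")
}

#' @export
print.flim_registration <- function(x, ...) {
  cat(sprintf("<flim_registration> method '%s', %d frame(s), reference frame %d\n",
              x$method, nrow(x$offsets), x$reference))
  print(x$offsets, n = 6)
  invisible(x)
}

#' @export
tidy.flim_registration <- function(x, ...) x$offsets

#' @export
glance.flim_registration <- function(x, ...) {
  tibble::tibble(method = x$method, n_frames = nrow(x$offsets),
                 mean_abs_di = mean(abs(x$offsets$di)),
                 mean_abs_dj = mean(abs(x$offsets$dj)),
                 max_abs_offset = max(abs(c(x$offsets$di, x$offsets$dj))))
}

#' Translation registration by global correlation argmax
#'
#' The direct baseline: each frame's offset is the global argmax of its NCC
#' map against the segment's reference frame (the first frame). Fast and exact
#' on unambiguous scenes, but the global argmax is fooled by repetitive
#' texture, where a periodic alias with larger overlap can outscore the true
#' displacement peak.
#'
#' @param seq a scene-consistent `frame_seq` of informative frames
#' @return a `flim_registration` with method `"ncc-translate"`; diagnostics
#'   include the peak value and the number of competing local maxima
#' @export
register_translate <- function(seq) {
  n <- n_frames(seq)
  ref <- seq$frames[, , 1]
  offsets <- matrix(0L, n, 2)
  pk <- numeric(n); npk <- integer(n)
  pk[1] <- 1; npk[1] <- 1L
  for (k in seq_len(n)[-1]) {
    cm <- ncc_map(ref, seq$frames[, , k])
    p <- find_global_peak(cm)
    offsets[k, ] <- peak_to_offset(p, cm)
    pk[k] <- p$value
    npk[k] <- nrow(find_local_peaks(cm))
  }
  build_registration(seq, offsets, "ncc-translate",
                     tibble::tibble(peak_value = pk, n_competing_peaks = npk))
}

# continuous sub-pixel translation of a frame by bilinear sampling; returns
# the shifted image and the validity mask of fully interior samples
shift_bilinear <- function(pixels, di, dj) {
  h <- nrow(pixels); w <- ncol(pixels)
  yy <- matrix(seq_len(h), h, w) + di
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) + dj
  y0 <- floor(yy); x0 <- floor(xx)
  fy <- yy - y0; fx <- xx - x0
  ok <- y0 >= 1 & y0 + 1 <= h & x0 >= 1 & x0 + 1 <= w
  out <- matrix(0, h, w)
  idx <- function(r, c) (c - 1L) * h + r
  r0 <- pmin(pmax(y0, 1), h - 1); c0 <- pmin(pmax(x0, 1), w - 1)
  v <- (1 - fy) * (1 - fx) * pixels[idx(r0, c0)] +
    (1 - fy) * fx * pixels[idx(r0, c0 + 1)] +
    fy * (1 - fx) * pixels[idx(r0 + 1, c0)] +
    fy * fx * pixels[idx(r0 + 1, c0 + 1)]
  out[ok] <- v[ok]
  list(pixels = out, mask = ok)
}

#' Translation registration by iterative NCC optimisation
#'
#' The iterative-optimisation baseline: maximises the NCC between the
#' reference frame and a continuously translated moving frame with a
#' derivative-free local optimiser (Nelder-Mead) started at zero shift, then
#' rounds to integer pixels. Inherits the classical local-optimum failure on
#' periodic scenes: a displacement beyond half the texture period converges to
#' the alias inside the starting basin.
#'
#' @param seq a scene-consistent `frame_seq`
#' @param maxit optimiser iteration budget per frame
#' @return a `flim_registration` with method `"ncc-general"`
#' @export
register_powell <- function(seq, maxit = 200) {
  n <- n_frames(seq)
  ref <- seq$frames[, , 1]
  offsets <- matrix(0L, n, 2)
  conv <- logical(n); conv[1] <- TRUE
  val <- numeric(n); val[1] <- 1
  neg_ncc <- function(par, mov) {
    sh <- shift_bilinear(mov, par[1], par[2])
    if (sum(sh$mask) < 16) return(1)
    -qa(ref, sh$pixels, mask_b = sh$mask)
  }
  for (k in seq_len(n)[-1]) {
    mov <- seq$frames[, , k]
    opt <- stats::optim(c(0, 0), neg_ncc, mov = mov, method = "Nelder-Mead",
                        control = list(maxit = maxit))
    if (opt$convergence != 0) {
      warning("optimiser did not converge on frame ", k,
              "; falling back to global argmax")
      cm <- ncc_map(ref, mov)
      offsets[k, ] <- peak_to_offset(find_global_peak(cm), cm)
      conv[k] <- FALSE
      val[k] <- NA_real_
    } else {
      offsets[k, ] <- as.integer(round(opt$par))
      conv[k] <- TRUE
      val[k] <- -opt$value
    }
  }
  build_registration(seq, offsets, "ncc-general",
                     tibble::tibble(ncc_value = val, converged = conv))
}
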