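#' Plot per-frame registration offsets
#'
#' @param object a `flim_registration`
#' @param ... ignored
#' @return a ggplot object
#' @export
autoplot.flim_registration <- function(object, ...) {
  df <- tidyr_longer_offsets(object$offsets)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$offset,
                                   colour = .data$axis)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(title = paste("Registration offsets:", object$method),
                  x = "frame", y = "offset (px)", colour = NULL) +
    ggplot2::theme_minimal()
}

tidyr_longer_offsets <- function(offsets) {
  dplyr::bind_rows(
    tibble::tibble(frame = offsets$frame, offset = offsets$di, axis = "dy"),
    tibble::tibble(frame = offsets$frame, offset = offsets$dj, axis = "dx"))
}

#' Plot the QA series and scene breaks of a split
#'
#' @param object a `scene_split`
#' @param ... ignored
#' @return a ggplot object
#' @export
autoplot.scene_split <- function(object, ...) {
  p <- ggplot2::ggplot(object$qa, ggplot2::aes(x = .data$k, y = .data$qa)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "frame pair (leading frame)",
                  y = "alignment quality (NCC)") +
    ggplot2::theme_minimal()
  if (length(object$break_points)) {
    brk <- match(object$break_points, object$seq$meta$index)
    p <- p + ggplot2::geom_vline(xintercept = brk - 0.5, linetype = "dashed",
                                 colour = "red")
  }
  p
}

#' Plot ablation records by stage and method
#'
#' @param object a `flim_ablation`
#' @param metric one of `"qa"`, `"ssim"`, `"nrmse"`
#' @param ... ignored
#' @return a ggplot object
#' @export
autoplot.flim_ablation <- function(object, metric = c("qa", "ssim", "nrmse"),
                                   ...) {
  metric <- match.arg(metric)
  mcol <- paste0(metric, "_mean"); scol <- paste0(metric, "_sd")
  rec <- object$records
  rec$stage <- factor(rec$stage, levels = c("unprocessed", "step1", "step1+2"))
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$stage, y = .data[[mcol]],
                                    colour = .data$method,
                                    group = .data$method)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data[[mcol]] - .data[[scol]],
                   ymax = .data[[mcol]] + .data[[scol]]),
      width = 0.15, position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 0.3),
                       alpha = 0.5) +
    ggplot2::labs(x = NULL, y = toupper(metric)) +
    ggplot2::theme_minimal()
}

#' Raster plot of a correlation map
#'
#' @param cm a `corr_map`
#' @param peaks optionally overlay the competing local maxima
#' @return a ggplot object
#' @export
plot_corr_map <- function(cm, peaks = TRUE) {
  s <- cm$surface
  df <- tibble::tibble(di = as.vector(row(s)) - cm$origin[1],
                       dj = as.vector(col(s)) - cm$origin[2],
                       ncc = as.vector(s))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dj, y = .data$di,
                                        fill = .data$ncc)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "dx (px)", y = "dy (px)") +
    ggplot2::theme_minimal()
  if (peaks) {
    pk <- find_local_peaks(cm)
    p <- p + ggplot2::geom_point(data = pk,
                                 ggplot2::aes(x = .data$dj, y = .data$di),
                                 inherit.aes = FALSE, colour = "red",
                                 shape = 0, size = 3)
  }
  p
}
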