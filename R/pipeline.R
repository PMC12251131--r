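#' Pipeline configuration
#'
#' Bundles the tunables of the end-to-end run: the scene-split threshold, the
#' registration method, tracker parameters, detection settings and stage
#' toggles.
#'
#' @param thresh_roc RoC scene-split threshold in percent (default 30)
#' @param method `"tracked-ncc"`, `"ncc-translate"` or `"ncc-general"`
#' @param tracker a [tracker_config()]
#' @param detect_thresh optional intensity threshold enabling the detection
#'   stage on each fused image
#' @param min_area minimum detected-component area (px)
#' @param step1,step2 stage toggles: uninformative-frame removal and scene
#'   splitting
#' @param delta_t optional gate separation (ns) when the input is two-gate
#'   data needing lifetime reconstruction
#' @param characterise run the dense-flow motion characterisation stage
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(thresh_roc = 30, method = "tracked-ncc",
                            tracker = tracker_config(), detect_thresh = NULL,
                            min_area = 4L, step1 = TRUE, step2 = TRUE,
                            delta_t = NULL, characterise = FALSE) {
  stopifnot(thresh_roc > 0,
            method %in% c("tracked-ncc", "ncc-translate", "ncc-general"))
  structure(list(thresh_roc = thresh_roc, method = method, tracker = tracker,
                 detect_thresh = detect_thresh, min_area = as.integer(min_area),
                 step1 = step1, step2 = step2, delta_t = delta_t,
                 characterise = characterise),
            class = "pipeline_config")
}

#' Run the full motion-compensation pipeline
#'
#' Executes the stages in order: optional lifetime reconstruction, removal of
#' uninformative frames (step 1), scene-consistency splitting (step 2),
#' optional motion characterisation, per-segment registration, per-segment
#' fusion, and optional threshold detection. Scene segments are processed
#' independently and never fused across breaks. The run is deterministic for
#' a given input and configuration.
#'
#' @param input a `frame_seq`, a file path readable by [read_frame_seq()], or
#'   a two-gate list when `cfg$delta_t` is set
#' @param cfg a [pipeline_config()]
#' @param out_dir optional directory for artifacts (offset CSVs, QA/RoC
#'   report, fused stacks, config snapshot)
#' @return a `flim_pipeline` result: list with `seq` (post step-1 frames),
#'   `flags`, `split`, `registrations`, `fused`, `detections`, `motion`,
#'   `scores`, `offsets` (combined tibble) and `config`
#' @export
run_pipeline <- function(input, cfg = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.character(input)) {
    input <- read_frame_seq(input,
                            layout = if (is.null(cfg$delta_t)) "stack" else "two_bin")
  }
  if (!is.null(cfg$delta_t) && is.list(input) && !inherits(input, "frame_seq")) {
    input <- reconstruct_sequence(input, cfg$delta_t)
  }
  stopifnot(inherits(input, "frame_seq"))
  log_stage <- function(name, n_in, n_out)
    message(sprintf("[%s] frames in: %d, out: %d", name, n_in, n_out))
  n0 <- n_frames(input)
  flags <- rep(FALSE, n0)
  seq <- input
  if (cfg$step1) {
    flags <- detect_uninformative(input)
    seq <- remove_uninformative(input, flags)
    log_stage("step1", n0, n_frames(seq))
  }
  if (cfg$step2) {
    split <- split_scenes(seq, thresh_pct = cfg$thresh_roc)
  } else {
    seq2 <- seq; seq2$meta$scene_id <- 1L
    split <- structure(list(
      segments = tibble::tibble(scene_id = 1L, start = 1L,
                                end = n_frames(seq2),
                                start_index = seq2$meta$index[1],
                                end_index = seq2$meta$index[n_frames(seq2)]),
      break_points = integer(0), qa = qa_series(seq2), seq = seq2),
      class = "scene_split")
  }
  segments <- scene_segments(split)
  log_stage("step2", n_frames(seq), length(segments))
  motion <- NULL
  if (cfg$characterise) {
    motion <- purrr::imap_dfr(segments, function(sg, i) {
      if (n_frames(sg) < 2L) return(NULL)
      dplyr::mutate(characterise_motion(sg), scene_id = i)
    })
  }
  register_with <- function(sg) {
    switch(cfg$method,
           "tracked-ncc" = register_tracked(sg, cfg$tracker),
           "ncc-translate" = register_translate(sg),
           "ncc-general" = register_powell(sg))
  }
  registrations <- list(); fused <- list(); detections <- list()
  for (i in seq_along(segments)) {
    sg <- segments[[i]]
    if (n_frames(sg) < 2L) {
      registrations[[i]] <- NULL
      fused[[i]] <- fuse_mean(sg)
      next
    }
    reg <- tryCatch(register_with(sg), error = function(e) {
      message(sprintf("[register] scene %d failed: %s", i, conditionMessage(e)))
      NULL
    })
    registrations[[i]] <- reg
    fused[[i]] <- if (is.null(reg)) fuse_mean(sg) else fuse_mean(reg)
    if (!is.null(cfg$detect_thresh)) {
      detections[[i]] <- nap_detect(fused[[i]], cfg$detect_thresh, cfg$min_area)
    }
  }
  offsets <- purrr::imap_dfr(registrations, function(r, i) {
    if (is.null(r)) return(NULL)
    dplyr::mutate(tidy(r), scene_id = i, method = r$method)
  })
  scores <- purrr::imap_dfr(registrations, function(r, i) {
    if (is.null(r) || nrow(r$offsets) < 2L) return(NULL)
    dplyr::mutate(score_pairs(r), scene_id = i)
  })
  res <- structure(list(seq = seq, flags = flags, split = split,
                        registrations = registrations, fused = fused,
                        detections = detections, motion = motion,
                        scores = scores, offsets = offsets, config = cfg),
                   class = "flim_pipeline")
  if (!is.null(out_dir)) write_pipeline_artifacts(res, out_dir)
  res
}

#' @export
print.flim_pipeline <- function(x, ...) {
  cat(sprintf("<flim_pipeline> method '%s': %d scene(s), %d/%d informative frame(s)\n",
              x$config$method, nrow(x$split$segments),
              n_frames(x$seq), length(x$flags)))
  invisible(x)
}

#' @export
glance.flim_pipeline <- function(x, ...) {
  tibble::tibble(method = x$config$method,
                 n_frames_in = length(x$flags),
                 n_uninformative = sum(x$flags),
                 n_scenes = nrow(x$split$segments),
                 mean_qa = mean(x$scores$qa),
                 mean_ssim = mean(x$scores$ssim),
                 mean_nrmse = mean(x$scores$nrmse))
}

write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$offsets, file.path(out_dir, "offsets.csv"),
                   row.names = FALSE)
  qa_roc <- res$split$qa
  roc <- roc_series(qa_roc)
  report <- dplyr::left_join(qa_roc, roc, by = "k")
  utils::write.csv(report, file.path(out_dir, "qa_roc.csv"), row.names = FALSE)
  utils::write.csv(res$scores, file.path(out_dir, "scores.csv"),
                   row.names = FALSE)
  if (!is.null(res$motion))
    utils::write.csv(res$motion, file.path(out_dir, "motion.csv"),
                     row.names = FALSE)
  for (i in seq_along(res$fused)) {
    f <- res$fused[[i]]$pixels
    f[is.na(f)] <- 0
    saveRDS(res$fused[[i]], file.path(out_dir, sprintf("fused_scene%02d.rds", i)))
  }
  cfg <- res$config
  snap <- list(thresh_roc = cfg$thresh_roc, method = cfg$method,
               step1 = cfg$step1, step2 = cfg$step2,
               detect_thresh = cfg$detect_thresh, min_area = cfg$min_area,
               tracker = unclass(cfg$tracker))
  if (requireNamespace("yaml", quietly = TRUE)) {
    writeLines(yaml::as.yaml(snap), file.path(out_dir, "config.yaml"))
  } else {
    dput(snap, file.path(out_dir, "config.R"))
  }
  invisible(out_dir)
}
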