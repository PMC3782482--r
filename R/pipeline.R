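#' Score chaining behavior in a recording
#'
#' The full detection pipeline: down-sample to 1 fps, build the mean-of-40
#' background, split chambers, segment and pose every fly, build the
#' per-frame directed chasing graph and score its chain index.
#'
#' @param source input for [load_frame_sequence] (frame directory, list of
#'   matrices, or a `frame_sequence`).
#' @param layout a [chamber_layout]; defaults to one chamber covering the
#'   whole frame.
#' @param params a [chain_params].
#' @param source_fps frame rate of the source (default 30).
#' @param n_background frames averaged into the background (default 40).
#' @param seed seed for background sampling and blob splitting.
#' @return list of class `chain_result`: `scores` (data.frame `frame`,
#'   `chamber`, `chain_index`, `edges`), `poses` (the pose table, full-frame
#'   coordinates), `series` (list of [chain_series], one per chamber),
#'   `params`, `layout`.
#' @export
detect_chains <- function(source, layout = NULL, params = chain_params(),
                          source_fps = 30, n_background = 40, seed = 1L) {
  seq <- if (inherits(source, "frame_sequence") && source$fps == 1) source
         else load_frame_sequence(source, source_fps = source_fps)
  d <- dim(seq$frames[[1L]])
  if (is.null(layout))
    layout <- chamber_layout(list(c(1, d[2L], 1, d[1L])))
  bg <- build_background(seq, n = n_background, seed = seed)

  all_scores <- list(); all_poses <- list(); series <- list()
  for (ci in seq_along(layout$chambers)) {
    r <- layout$chambers[[ci]]
    sub_frames <- lapply(seq$frames, function(f)
      f[r[3L]:r[4L], r[1L]:r[2L], drop = FALSE])
    sub_seq <- frame_sequence(sub_frames, fps = 1)
    sub_bg <- bg$image[r[3L]:r[4L], r[1L]:r[2L], drop = FALSE]

    poses_tab <- track_poses(sub_seq, sub_bg,
                             expected_flies = layout$expected_flies,
                             chamber_id = ci)
    ci_values <- integer(length(sub_frames))
    edge_str <- character(length(sub_frames))
    for (fi in seq_along(sub_frames)) {
      rows <- poses_tab[poses_tab$frame == fi, , drop = FALSE]
      if (nrow(rows) == 0L) { edge_str[fi] <- ""; next }
      poses <- lapply(seq_len(nrow(rows)), function(j) {
        p <- pose_from_points(c(rows$hx[j], rows$hy[j]),
                              c(rows$tx[j], rows$ty[j]),
                              minor_axis_len = rows$minor[j])
        p$major_axis_len <- rows$major[j]
        p$centroid <- c(rows$x[j], rows$y[j])
        fl <- strsplit(rows$flags[j], ";", fixed = TRUE)[[1L]]
        p$degenerate <- "degenerate" %in% fl
        p$ht_unreliable <- "ht_unreliable" %in% fl
        p
      })
      g <- detect_chain_edges(poses, silhouettes = NULL, params = params,
                              frame_index = fi)
      ci_values[fi] <- g$chain_index
      edge_str[fi] <- format_edges(g)
    }
    # map poses back to full-frame coordinates
    if (nrow(poses_tab) > 0L) {
      poses_tab$x <- poses_tab$x + r[1L] - 1; poses_tab$y <- poses_tab$y + r[3L] - 1
      poses_tab$hx <- poses_tab$hx + r[1L] - 1; poses_tab$hy <- poses_tab$hy + r[3L] - 1
      poses_tab$tx <- poses_tab$tx + r[1L] - 1; poses_tab$ty <- poses_tab$ty + r[3L] - 1
    }
    all_poses[[ci]] <- poses_tab
    all_scores[[ci]] <- data.frame(frame = seq_along(sub_frames), chamber = ci,
                                   chain_index = ci_values, edges = edge_str)
    series[[ci]] <- chain_series(ci_values, fps = 1)
  }
  structure(list(scores = do.call(rbind, all_scores),
                 poses = do.call(rbind, all_poses),
                 series = series, params = params, layout = layout),
            class = "chain_result")
}

#' @export
print.chain_result <- function(x, ...) {
  cat(sprintf("<chain_result> %d frames x %d chambers (L = %g, k = %g)\n",
              max(x$scores$frame), length(x$series), x$params$L, x$params$k))
  for (ci in seq_along(x$series))
    cat(sprintf("  chamber %d: mean chain index %.2f\n", ci,
                mean(x$series[[ci]]$values)))
  invisible(x)
}

#' Write detection scores to CSV
#' @param result a `chain_result`.
#' @param path output CSV (columns frame, chamber, chain_index, edges).
#' @param poses_path optional second CSV for the pose table.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(result, path, poses_path = NULL) {
  utils::write.csv(result$scores, path, row.names = FALSE)
  if (!is.null(poses_path))
    utils::write.csv(result$poses, poses_path, row.names = FALSE)
  invisible(path)
}

#' Read a detection-score CSV back as chain series
#' @param path CSV written by [write_scores_csv].
#' @param t0_playback playback onset in seconds for the series.
#' @return list of [chain_series], one per chamber.
#' @export
read_scores_csv <- function(path, t0_playback = 300) {
  tab <- utils::read.csv(path)
  lapply(split(tab, tab$chamber), function(d)
    chain_series(d$chain_index[order(d$frame)], fps = 1,
                 t0_playback = t0_playback))
}
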