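#' Frame sequence container
#'
#' A time-ordered stack of single-channel intensity frames at a fixed frame
#' rate. Frames are numeric matrices in `[0, 1]`, indexed `[y, x]` (row =
#' vertical pixel coordinate), all of identical dimensions.
#'
#' @param frames list of numeric matrices, all the same dimensions.
#' @param fps frames per second (> 0).
#' @param timestamps optional numeric vector of seconds from recording start;
#'   defaults to `(seq_along(frames) - 1) / fps`. Must be strictly increasing.
#' @return An object of class `frame_sequence` with elements `frames`, `fps`
#'   and `timestamps`.
#' @export
frame_sequence <- function(frames, fps = 1, timestamps = NULL) {
  if (!is.list(frames) || length(frames) == 0L)
    stop("`frames` must be a non-empty list of matrices", call. = FALSE)
  if (!all(vapply(frames, is.matrix, logical(1))))
    stop("all frames must be matrices", call. = FALSE)
  d <- dim(frames[[1L]])
  if (!all(vapply(frames, function(f) identical(dim(f), d), logical(1))))
    stop("all frames must share the same dimensions", call. = FALSE)
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0)
    stop("`fps` must be a single positive number", call. = FALSE)
  if (is.null(timestamps)) timestamps <- (seq_along(frames) - 1) / fps
  if (length(timestamps) != length(frames) || any(diff(timestamps) <= 0))
    stop("`timestamps` must be strictly increasing, one per frame",
         call. = FALSE)
  structure(list(frames = frames, fps = fps, timestamps = timestamps),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames[[1L]])
  cat(sprintf("<frame_sequence> %d frames, %dx%d px, %.3g fps, %.1f s\n",
              length(x$frames), d[2L], d[1L], x$fps,
              utils::tail(x$timestamps, 1L) - x$timestamps[1L]))
  invisible(x)
}

#' @export
length.frame_sequence <- function(x) length(x$frames)

#' Load a frame sequence, down-sampling to the analysis rate
#'
#' Reads a recording and down-samples it to `target_fps` (1 Hz by default,
#' the rate at which all chain-index scoring is done) by keeping the first
#' frame of each `1/target_fps`-second bin. Accepts either a directory of
#' numbered PNG/TIFF frames or an in-memory list of matrices; video
#' containers must be exported to numbered frames first.
#'
#' @param source directory containing numbered `.png`/`.tif`/`.tiff` frames,
#'   a list of numeric matrices, or a `frame_sequence`.
#' @param source_fps frame rate of `source` (e.g. 30 for typical recordings).
#' @param target_fps desired output rate; must not exceed `source_fps`.
#' @return A [frame_sequence] at `target_fps`. The output frame count is
#'   `floor(duration * target_fps)` where duration is `n_source / source_fps`.
#' @export
load_frame_sequence <- function(source, source_fps = 30, target_fps = 1) {
  if (target_fps > source_fps)
    stop("`target_fps` exceeds the source frame rate", call. = FALSE)
  frames <- if (inherits(source, "frame_sequence")) {
    source_fps <- source$fps
    source$frames
  } else if (is.character(source)) {
    read_frame_dir(source)
  } else if (is.list(source)) {
    source
  } else stop("unreadable source: need a directory, list or frame_sequence",
              call. = FALSE)
  if (length(frames) == 0L)
    stop("source contains no frames", call. = FALSE)
  step <- source_fps / target_fps
  n_out <- floor(length(frames) / step)
  if (n_out < 1L)
    stop("source shorter than one output frame interval", call. = FALSE)
  idx <- floor((seq_len(n_out) - 1) * step) + 1L
  frame_sequence(frames[idx], fps = target_fps)
}

read_frame_dir <- function(path) {
  if (!dir.exists(path)) stop("no such directory: ", path, call. = FALSE)
  files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) == 0L)
    stop("no PNG/TIFF frames found in ", path, call. = FALSE)
  files <- files[order(files)]
  lapply(files, function(f) {
    img <- EBImage::readImage(f)
    a <- as.array(img)
    if (length(dim(a)) == 3L) a <- a[, , 1L]          # keep one channel
    t(a)                                              # EBImage is [x, y]
  })
}

#' Static background model
#'
#' Pixel-wise mean of `n` frames sampled uniformly without replacement. Under
#' backlit imaging the flies are small, dark and mobile, so the mean of a
#' random sample approximates the empty chamber; per-pixel contamination is
#' bounded by contrast times (occupied samples)/n.
#'
#' @param seq a [frame_sequence].
#' @param n number of frames to average (default 40).
#' @param seed integer seed for the frame sample, for reproducible runs.
#' @return Object of class `background`: list with `image` (matrix),
#'   `n_samples`, `seed`.
#' @export
build_background <- function(seq, n = 40, seed = 1L) {
  stopifnot(inherits(seq, "frame_sequence"))
  nf <- length(seq$frames)
  if (nf == 0L) stop("empty frame sequence", call. = FALSE)
  if (n > nf) {
    warning(sprintf("requested %d frames but sequence has %d; using all", n, nf))
    n <- nf
  }
  idx <- if (n == nf) seq_len(nf) else {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(seed)
    sample.int(nf, n)
  }
  acc <- Reduce(`+`, seq$frames[idx]) / length(idx)
  structure(list(image = acc, n_samples = n, seed = seed),
            class = "background")
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.background <- function(x, ...) {
  cat(sprintf("<background> %dx%d px, mean of %d frames (seed %d)\n",
              ncol(x$image), nrow(x$image), x$n_samples, x$seed))
  invisible(x)
}

#' Chamber layout
#'
#' Rectangular regions of interest for up to four behavioral chambers in one
#' camera frame, plus the pixel scale and expected fly count per chamber.
#' The default scale, 0.12 mm/px, matches a 50 x 10 mm chamber imaged at
#' about 417 x 83 px.
#'
#' @param chambers list of ROIs, each `c(xmin, xmax, ymin, ymax)` in pixel
#'   coordinates (inclusive).
#' @param pixel_scale mm per pixel (> 0, default 0.12).
#' @param expected_flies flies per chamber (default 6).
#' @return Object of class `chamber_layout`.
#' @export
chamber_layout <- function(chambers, pixel_scale = 0.12, expected_flies = 6) {
  if (!is.list(chambers) || length(chambers) < 1L)
    stop("`chambers` must be a non-empty list of c(xmin,xmax,ymin,ymax)",
         call. = FALSE)
  if (length(chambers) > 4L)
    stop("at most 4 chambers are supported per frame", call. = FALSE)
  for (r in chambers) {
    if (length(r) != 4L || r[1L] > r[2L] || r[3L] > r[4L] || any(r < 1))
      stop("each ROI must be c(xmin, xmax, ymin, ymax) with min <= max, >= 1",
           call. = FALSE)
  }
  if (length(chambers) > 1L) {
    for (i in seq_along(chambers)) for (j in seq_along(chambers)) {
      if (i >= j) next
      a <- chambers[[i]]; b <- chambers[[j]]
      if (a[1L] <= b[2L] && b[1L] <= a[2L] && a[3L] <= b[4L] && b[3L] <= a[4L])
        stop("chamber ROIs must not overlap", call. = FALSE)
    }
  }
  if (pixel_scale <= 0) stop("`pixel_scale` must be > 0", call. = FALSE)
  structure(list(chambers = chambers, pixel_scale = pixel_scale,
                 expected_flies = expected_flies),
            class = "chamber_layout")
}

#' Split a frame into per-chamber views
#'
#' Crops each chamber ROI out of a full frame. Each returned view carries its
#' origin so that poses measured in chamber coordinates can be mapped back to
#' full-frame coordinates exactly (`x_full = x_chamber + origin[1] - 1`).
#'
#' @param frame numeric matrix `[y, x]`.
#' @param layout a [chamber_layout] whose ROIs lie within the frame.
#' @return List with one element per chamber: `list(image, origin = c(x0, y0),
#'   chamber_id)`.
#' @export
split_chambers <- function(frame, layout) {
  stopifnot(is.matrix(frame), inherits(layout, "chamber_layout"))
  lapply(seq_along(layout$chambers), function(i) {
    r <- layout$chambers[[i]]
    if (r[2L] > ncol(frame) || r[4L] > nrow(frame))
      stop(sprintf("chamber %d ROI exceeds frame bounds", i), call. = FALSE)
    list(image = frame[r[3L]:r[4L], r[1L]:r[2L], drop = FALSE],
         origin = c(r[1L], r[3L]), chamber_id = i)
  })
}

#' Read an analysis configuration file
#'
#' YAML or JSON with fields `chambers` (list of 4-vectors), `pixel_scale`,
#' `expected_flies`, `seed`, and optionally `L`, `k`, `q_offset`.
#'
#' @param path config file path.
#' @return list with a `layout` ([chamber_layout]), `seed` and
#'   a `params` ([chain_params]).
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  chambers <- lapply(seq_len(NROW(cfg$chambers)), function(i)
    as.numeric(if (is.matrix(cfg$chambers)) cfg$chambers[i, ]
               else cfg$chambers[[i]]))
  layout <- chamber_layout(
    chambers,
    pixel_scale = cfg$pixel_scale %||% 0.12,
    expected_flies = cfg$expected_flies %||% 6)
  params <- chain_params(L = cfg$L %||% 13, k = cfg$k %||% 0.66,
                         q_offset = cfg$q_offset %||% 5)
  list(layout = layout, seed = as.integer(cfg$seed %||% 1L), params = params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
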