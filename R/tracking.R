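#' Segment fly silhouettes from a background-subtracted frame
#'
#' Flies are darker than the backlit background, so the foreground signal is
#' `background - frame` clipped at zero. That difference image is binarized
#' with Otsu's threshold and 8-connected components within the area band are
#' returned as silhouettes. Components above `max_area` are returned flagged
#' as merged blobs (touching flies) for [split_merged].
#'
#' @param frame,background numeric matrices of identical size, values in
#'   `[0, 1]`.
#' @param chamber_id integer label carried into the silhouettes.
#' @param frame_index integer label carried into the silhouettes.
#' @param min_area,max_area area band in px^2. Defaults follow the body-size
#'   statistics of *D. melanogaster* at 0.12 mm/px (a single fly silhouette
#'   is roughly 19 px long, ~120 px^2): `min_area = 40`, `max_area = 180`
#'   (1.5x the nominal single-fly area, low enough that even two heavily
#'   overlapping flies exceed it and get flagged).
#' @return list of `silhouette` objects: `pixels` (n x 2 matrix of x, y),
#'   `area`, `chamber_id`, `frame_index`, `merged` flag.
#' @export
segment_flies <- function(frame, background, chamber_id = 1L,
                          frame_index = 1L, min_area = 40, max_area = 180) {
  stopifnot(is.matrix(frame), identical(dim(frame), dim(background)))
  diffimg <- pmax(background - frame, 0)
  if (max(diffimg) - min(diffimg) < 1e-8) return(list())   # no foreground
  thr <- EBImage::otsu(diffimg, range = range(0, max(diffimg)))
  bw <- diffimg > thr
  lab <- EBImage::bwlabel(bw)
  nlab <- max(lab)
  if (nlab == 0L) return(list())
  out <- list()
  for (l in seq_len(nlab)) {
    idx <- which(lab == l, arr.ind = TRUE)       # rows = y, cols = x
    area <- nrow(idx)
    if (area < min_area) next
    px <- cbind(x = idx[, 2L], y = idx[, 1L])
    out[[length(out) + 1L]] <- new_silhouette(
      px, chamber_id, frame_index, merged = area > max_area)
  }
  out
}

new_silhouette <- function(pixels, chamber_id = 1L, frame_index = 1L,
                           merged = FALSE) {
  structure(list(pixels = pixels, area = nrow(pixels),
                 chamber_id = as.integer(chamber_id),
                 frame_index = as.integer(frame_index), merged = merged),
            class = "silhouette")
}

#' @export
print.silhouette <- function(x, ...) {
  cat(sprintf("<silhouette> %d px, chamber %d, frame %d%s\n", x$area,
              x$chamber_id, x$frame_index, if (x$merged) " [merged]" else ""))
  invisible(x)
}

#' Split a merged blob into the expected number of silhouettes
#'
#' Touching flies segment as one over-sized component. The blob's pixel
#' coordinates are partitioned into `expected` clusters by k-means; each
#' cluster becomes a silhouette. The union of the parts is exactly the blob.
#'
#' @param blob a merged `silhouette`.
#' @param expected number of flies in the blob (>= 2).
#' @param seed seed for the k-means initialization.
#' @return list of `expected` silhouettes.
#' @export
split_merged <- function(blob, expected, seed = 1L) {
  stopifnot(inherits(blob, "silhouette"))
  if (expected < 2L) stop("`expected` must be >= 2", call. = FALSE)
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  km <- stats::kmeans(blob$pixels, centers = expected, nstart = 5L,
                      iter.max = 50L)
  lapply(seq_len(expected), function(i)
    new_silhouette(blob$pixels[km$cluster == i, , drop = FALSE],
                   blob$chamber_id, blob$frame_index, merged = FALSE))
}

#' Fit a body ellipse to a silhouette
#'
#' Centroid and axes from the second-order moments of the pixel coordinates:
#' the orientation is the principal eigenvector of the coordinate covariance
#' matrix, and each full axis length is `4 * sqrt(eigenvalue)` — the axes of
#' the uniform solid ellipse with the same second moments. A near-isotropic
#' blob (eigenvalue ratio < 1.2) is flagged degenerate: its axis direction is
#' unreliable and no chain region is built from it.
#'
#' @param s a `silhouette` with area >= 3 px.
#' @return A `fly_pose`: `centroid` (x, y), `major_axis_len`,
#'   `minor_axis_len`, `orientation` (radians, unoriented axis in
#'   `[0, pi)`), `H`, `T` (NA until [assign_head_tail]), `degenerate`,
#'   `ht_unreliable` flags.
#' @export
fit_body_ellipse <- function(s) {
  stopifnot(inherits(s, "silhouette"))
  if (s$area < 3L) stop("silhouette too small to fit an ellipse (< 3 px)",
                        call. = FALSE)
  ctr <- colMeans(s$pixels)
  cc <- sweep(s$pixels, 2L, ctr)
  # population covariance of pixel centers
  C <- crossprod(cc) / s$area
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 1e-12)
  v <- e$vectors[, 1L]
  theta <- atan2(v[2L], v[1L]) %% pi
  structure(list(centroid = unname(ctr),
                 major_axis_len = 4 * sqrt(ev[1L]),
                 minor_axis_len = 4 * sqrt(ev[2L]),
                 orientation = theta,
                 H = c(NA_real_, NA_real_), T = c(NA_real_, NA_real_),
                 degenerate = (ev[1L] / ev[2L]) < 1.2,
                 ht_unreliable = FALSE),
            class = "fly_pose")
}

#' @export
print.fly_pose <- function(x, ...) {
  cat(sprintf(
    "<fly_pose> centroid (%.1f, %.1f), axes %.1f x %.1f px, theta %.1f deg%s\n",
    x$centroid[1L], x$centroid[2L], x$major_axis_len, x$minor_axis_len,
    x$orientation * 180 / pi,
    if (x$degenerate) " [degenerate]" else ""))
  if (!anyNA(x$H))
    cat(sprintf("  H (%.1f, %.1f)  T (%.1f, %.1f)%s\n", x$H[1L], x$H[2L],
                x$T[1L], x$T[2L],
                if (x$ht_unreliable) " [unreliable]" else ""))
  invisible(x)
}

#' Harris corner response of a binary silhouette
#'
#' Structure-tensor corner measure on the lightly smoothed mask: image
#' gradients by central differences, tensor entries smoothed with a Gaussian,
#' response `det(M) - 0.04 * trace(M)^2`. The abdominal tip of a fly is
#' sharper than the head, so its maximal response is larger.
#'
#' @param mask logical or 0/1 numeric matrix `[y, x]`.
#' @param sigma Gaussian smoothing in px applied both to the mask before
#'   differentiation and to the tensor entries (default 1).
#' @return numeric matrix of the same size.
#' @export
harris_response <- function(mask, sigma = 1) {
  m <- EBImage::gblur(mask + 0, sigma = sigma)
  ix <- m; iy <- m
  ix[] <- 0; iy[] <- 0
  nr <- nrow(m); nc <- ncol(m)
  ix[, 2:(nc - 1)] <- (m[, 3:nc] - m[, 1:(nc - 2)]) / 2
  iy[2:(nr - 1), ] <- (m[3:nr, ] - m[1:(nr - 2), ]) / 2
  sxx <- EBImage::gblur(ix * ix, sigma = sigma)
  syy <- EBImage::gblur(iy * iy, sigma = sigma)
  sxy <- EBImage::gblur(ix * iy, sigma = sigma)
  (sxx * syy - sxy^2) - 0.04 * (sxx + syy)^2
}

#' Assign head and tail to a fitted pose
#'
#' The two candidate endpoints are the major-axis extremes of the fitted
#' ellipse. The Harris corner response is evaluated on the silhouette mask;
#' the endpoint with the larger maximal response within a 3-px radius is the
#' tail T (the abdominal tip is sharper), the other is the head H. When the
#' two responses differ by less than 10% the corner cue is ambiguous and, if
#' a previous pose is supplied, the assignment minimizing the angular change
#' of the head direction from `prev` wins; without `prev` the corner rule
#' decides. A degenerate pose with no previous pose gets `ht_unreliable =
#' TRUE` (its chain region is skipped for the frame).
#'
#' @param s the `silhouette` the pose was fitted to.
#' @param pose a `fly_pose` from [fit_body_ellipse].
#' @param prev previous-frame `fly_pose` for the same fly, or `NULL`.
#' @return the pose with `H`, `T` and `ht_unreliable` filled in.
#' @export
assign_head_tail <- function(s, pose, prev = NULL) {
  stopifnot(inherits(s, "silhouette"), inherits(pose, "fly_pose"))
  u <- c(cos(pose$orientation), sin(pose$orientation))
  e1 <- pose$centroid + u * pose$major_axis_len / 2
  e2 <- pose$centroid - u * pose$major_axis_len / 2

  if (pose$degenerate && is.null(prev)) {
    pose$H <- e1; pose$T <- e2; pose$ht_unreliable <- TRUE
    return(pose)
  }

  # Harris response on a local mask patch
  px <- s$pixels
  pad <- 4L
  x0 <- min(px[, 1L]) - pad; y0 <- min(px[, 2L]) - pad
  mask <- matrix(0, nrow = max(px[, 2L]) - y0 + 1L + pad,
                 ncol = max(px[, 1L]) - x0 + 1L + pad)
  mask[cbind(px[, 2L] - y0 + 1L, px[, 1L] - x0 + 1L)] <- 1
  R <- harris_response(mask)

  peak_near <- function(p, radius = 3) {
    cx <- p[1L] - x0 + 1; cy <- p[2L] - y0 + 1
    xs <- pmax(1L, floor(cx - radius)):pmin(ncol(R), ceiling(cx + radius))
    ys <- pmax(1L, floor(cy - radius)):pmin(nrow(R), ceiling(cy + radius))
    sub <- R[ys, xs, drop = FALSE]
    d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
    max(sub[d2 <= radius^2], -Inf)
  }
  r1 <- peak_near(e1); r2 <- peak_near(e2)

  gap <- abs(r1 - r2) / max(abs(r1), abs(r2), 1e-12)
  if (gap < 0.10 && !is.null(prev) && !anyNA(prev$H)) {
    prev_dir <- prev$H - prev$T
    # keep the head assignment closer in angle to the previous heading
    if (sum((e1 - e2) * prev_dir) >= 0) { pose$H <- e1; pose$T <- e2 }
    else                                { pose$H <- e2; pose$T <- e1 }
  } else if (r1 > r2) { pose$T <- e1; pose$H <- e2 }
  else                { pose$T <- e2; pose$H <- e1 }
  pose$ht_unreliable <- FALSE
  pose
}

#' Track poses through a chamber's frame sequence
#'
#' Runs segmentation, merged-blob splitting, ellipse fitting and head/tail
#' assignment on every frame of one chamber view. Fly identity across frames
#' is positional (greedy nearest-centroid linking) and is used only to carry
#' the previous pose into the head/tail tie-break.
#'
#' @param seq a [frame_sequence] of chamber-cropped frames.
#' @param background a `background` built from `seq` (or compatible).
#' @param expected_flies flies per chamber, used to split merged blobs.
#' @param chamber_id chamber label for the output table.
#' @param min_area,max_area passed to [segment_flies].
#' @return A `data.frame` pose table: columns `frame`, `chamber`, `fly_id`,
#'   `x`, `y`, `major`, `minor`, `theta`, `hx`, `hy`, `tx`, `ty`, `flags`
#'   (";"-separated out of `degenerate`, `ht_unreliable`, `split`).
#' @export
track_poses <- function(seq, background, expected_flies = 6, chamber_id = 1L,
                        min_area = 40, max_area = 180) {
  stopifnot(inherits(seq, "frame_sequence"))
  bg <- if (inherits(background, "background")) background$image else background
  rows <- list()
  prev_poses <- list()    # by fly_id
  for (fi in seq_along(seq$frames)) {
    sils <- segment_flies(seq$frames[[fi]], bg, chamber_id, fi,
                          min_area, max_area)
    split_flag <- logical(0)
    out <- list()
    for (s in sils) {
      if (s$merged) {
        k <- max(2L, min(expected_flies,
                         round(s$area / ((min_area + max_area) / 2 * 0.8))))
        parts <- split_merged(s, k)
        out <- c(out, parts)
        split_flag <- c(split_flag, rep(TRUE, length(parts)))
      } else {
        out <- c(out, list(s))
        split_flag <- c(split_flag, FALSE)
      }
    }
    poses <- lapply(out, fit_body_ellipse)
    ids <- link_ids(lapply(poses, `[[`, "centroid"), prev_poses)
    for (j in seq_along(poses)) {
      prev <- prev_poses[[as.character(ids[j])]]
      poses[[j]] <- assign_head_tail(out[[j]], poses[[j]], prev)
      p <- poses[[j]]
      flags <- c(if (p$degenerate) "degenerate",
                 if (p$ht_unreliable) "ht_unreliable",
                 if (split_flag[j]) "split")
      rows[[length(rows) + 1L]] <- data.frame(
        frame = fi, chamber = chamber_id, fly_id = ids[j],
        x = p$centroid[1L], y = p$centroid[2L],
        major = p$major_axis_len, minor = p$minor_axis_len,
        theta = p$orientation,
        hx = p$H[1L], hy = p$H[2L], tx = p$T[1L], ty = p$T[2L],
        flags = paste(flags, collapse = ";"))
    }
    prev_poses <- stats::setNames(poses, as.character(ids))
  }
  if (length(rows) == 0L)
    return(data.frame(frame = integer(), chamber = integer(),
                      fly_id = integer(), x = double(), y = double(),
                      major = double(), minor = double(), theta = double(),
                      hx = double(), hy = double(), tx = double(),
                      ty = double(), flags = character()))
  do.call(rbind, rows)
}

# Greedy nearest-centroid identity linking; new ids for unmatched detections.
link_ids <- function(centroids, prev_poses) {
  n <- length(centroids)
  if (n == 0L) return(integer(0))
  if (length(prev_poses) == 0L) return(seq_len(n))
  prev_ids <- as.integer(names(prev_poses))
  pc <- do.call(rbind, lapply(prev_poses, `[[`, "centroid"))
  cc <- do.call(rbind, centroids)
  D <- outer(seq_len(n), seq_along(prev_ids),
             Vectorize(function(i, j) sqrt(sum((cc[i, ] - pc[j, ])^2))))
  ids <- rep(NA_integer_, n)
  used <- logical(length(prev_ids))
  ord <- order(D)
  for (k in ord) {
    i <- (k - 1L) %% n + 1L
    j <- (k - 1L) %/% n + 1L
    if (is.na(ids[i]) && !used[j]) { ids[i] <- prev_ids[j]; used[j] <- TRUE }
  }
  nxt <- max(prev_ids) + 1L
  for (i in which(is.na(ids))) { ids[i] <- nxt; nxt <- nxt + 1L }
  ids
}
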