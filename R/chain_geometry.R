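#' Chain-region parameters
#'
#' The chain region of a fly is a fan-shaped sector projected in front of its
#' head: anchored at the head base Q (on segment TH, `q_offset` px behind the
#' head H), with radius `q_offset + L` (so it reaches exactly `L` px beyond
#' the head along the body axis) and half-angle `k * pi/2` radians about the
#' heading `H - T`. The defaults, `L = 13` px (1.56 mm at 0.12 mm/px) and
#' `k = 0.66` (half-angle ~59 deg), are the constants at which automated
#' scores match manual inspection.
#'
#' @param L length constant in px (> 0).
#' @param k angle constant in (0, 1]; half-angle is `k * pi/2`.
#' @param q_offset distance from H to the head base Q along TH, px.
#' @return Object of class `chain_params`.
#' @export
chain_params <- function(L = 13, k = 0.66, q_offset = 5) {
  if (L <= 0) stop("`L` must be > 0", call. = FALSE)
  if (k <= 0 || k > 1) stop("`k` must be in (0, 1]", call. = FALSE)
  if (q_offset < 0) stop("`q_offset` must be >= 0", call. = FALSE)
  structure(list(L = L, k = k, q_offset = q_offset), class = "chain_params")
}

#' @export
print.chain_params <- function(x, ...) {
  cat(sprintf("<chain_params> L = %g px, k = %g (half-angle %.1f deg), Q-offset = %g px\n",
              x$L, x$k, x$k * 90, x$q_offset))
  invisible(x)
}

#' Construct a fly pose from head and tail points
#'
#' Builds a `fly_pose` directly from known geometry — scripted scenes, worked
#' examples — without fitting a silhouette.
#'
#' @param H,T head and tail points, `c(x, y)`.
#' @param minor_axis_len body width in px (default 8).
#' @return a `fly_pose` with valid `H`, `T`.
#' @export
pose_from_points <- function(H, T, minor_axis_len = 8) {
  d <- H - T
  len <- sqrt(sum(d^2))
  if (len == 0) stop("H and T coincide", call. = FALSE)
  structure(list(centroid = (H + T) / 2,
                 major_axis_len = len, minor_axis_len = minor_axis_len,
                 orientation = atan2(d[2L], d[1L]) %% pi,
                 H = H, T = T, degenerate = FALSE, ht_unreliable = FALSE),
            class = "fly_pose")
}

#' Head base point Q
#'
#' Q, the rear end of the head area, lies on segment TH at `q_offset` px from
#' the head H (toward the tail).
#'
#' @param H,T head and tail points, `c(x, y)`.
#' @param q_offset px from H toward T (default 5; must be < `|H - T|`).
#' @return point `c(x, y)`.
#' @export
head_base <- function(H, T, q_offset = 5) {
  d <- sqrt(sum((H - T)^2))
  if (d <= q_offset)
    stop("body axis |H-T| must exceed `q_offset`", call. = FALSE)
  if (q_offset == 0) return(H)
  H + (T - H) * (q_offset / d)
}

#' Chain-region membership test
#'
#' A point p lies in the fly's chain region iff `0 < |p - Q| <= q_offset + L`
#' and the angle between `p - Q` and the heading `H - T` is at most
#' `k * pi/2`. Boundary points count as inside. A degenerate pose (or one
#' with unreliable head/tail) has an empty region.
#'
#' @param pose a `fly_pose` with valid `H`, `T`.
#' @param params a [chain_params].
#' @param p query point `c(x, y)`, or an n x 2 matrix of points.
#' @return logical, one per query point.
#' @export
chain_region_contains <- function(pose, params, p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 2L)
  if (isTRUE(pose$degenerate) || isTRUE(pose$ht_unreliable) || anyNA(pose$H))
    return(rep(FALSE, nrow(p)))
  Q <- head_base(pose$H, pose$T, params$q_offset)
  v <- cbind(p[, 1L] - Q[1L], p[, 2L] - Q[2L])
  r <- sqrt(v[, 1L]^2 + v[, 2L]^2)
  dir <- pose$H - pose$T
  dir <- dir / sqrt(sum(dir^2))
  cosang <- (v[, 1L] * dir[1L] + v[, 2L] * dir[2L]) / pmax(r, 1e-300)
  r > 0 & r <= params$q_offset + params$L &
    cosang >= cos(params$k * pi / 2) - 1e-12
}

#' Detect chasing edges between flies in one frame
#'
#' Edge i -> j is drawn when any pixel of fly j's body lies inside fly i's
#' chain region. The body of fly j is its silhouette pixel set when
#' available; otherwise the fitted-ellipse interior is rasterized at pixel
#' resolution. A fly's own body never triggers an edge, and flies with
#' unreliable head/tail produce no outgoing edges (they can still receive).
#'
#' @param poses list of `fly_pose`, index-aligned with `silhouettes`.
#' @param silhouettes list of `silhouette` or `NULL` entries (same length as
#'   `poses`), or `NULL` to rasterize all ellipses.
#' @param params a [chain_params].
#' @param frame_index integer label for the output graph.
#' @return A `chain_graph`: `frame_index`, `edges` (m x 2 integer matrix,
#'   chaser -> recipient), `n_flies`, `chain_index`.
#' @export
detect_chain_edges <- function(poses, silhouettes = NULL, params = chain_params(),
                               frame_index = 1L) {
  n <- length(poses)
  if (!is.null(silhouettes) && length(silhouettes) != n)
    stop("`poses` and `silhouettes` must be index-aligned", call. = FALSE)
  bodies <- lapply(seq_len(n), function(j) {
    s <- if (is.null(silhouettes)) NULL else silhouettes[[j]]
    if (is.matrix(s)) s
    else if (!is.null(s)) s$pixels
    else rasterize_ellipse(poses[[j]])
  })
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n)) {
    p <- poses[[i]]
    if (isTRUE(p$degenerate) || isTRUE(p$ht_unreliable) || anyNA(p$H)) next
    for (j in seq_len(n)) {
      if (i == j) next
      if (any(chain_region_contains(p, params, bodies[[j]]))) {
        from <- c(from, i); to <- c(to, j)
      }
    }
  }
  g <- structure(list(frame_index = as.integer(frame_index),
                      edges = cbind(from = from, to = to),
                      n_flies = n, chain_index = NA_integer_),
                 class = "chain_graph")
  g$chain_index <- chain_index(g)
  g
}

# Pixel-center rasterization of the fitted-ellipse interior.
rasterize_ellipse <- function(pose) {
  a <- pose$major_axis_len / 2
  b <- pose$minor_axis_len / 2
  th <- pose$orientation
  c0 <- pose$centroid
  xr <- floor(c0[1L] - a):ceiling(c0[1L] + a)
  yr <- floor(c0[2L] - a):ceiling(c0[2L] + a)
  g <- expand.grid(x = xr, y = yr)
  dx <- g$x - c0[1L]; dy <- g$y - c0[2L]
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  keep <- (u / a)^2 + (v / b)^2 <= 1
  as.matrix(g[keep, , drop = FALSE])
}

#' Chain index of a frame
#'
#' The number of flies participating in chains: distinct flies incident to at
#' least one chasing edge, as chaser or as recipient. Passive recipients (the
#' leader of a train) are included, so a single chaser-recipient pair scores
#' 2 and a three-fly train scores 3.
#'
#' @param graph a `chain_graph`.
#' @return integer count.
#' @export
chain_index <- function(graph) {
  stopifnot(inherits(graph, "chain_graph"))
  length(unique(c(graph$edges[, 1L], graph$edges[, 2L])))
}

#' @export
print.chain_graph <- function(x, ...) {
  es <- if (nrow(x$edges) == 0L) "none"
  else paste(sprintf("%d>%d", x$edges[, 1L], x$edges[, 2L]), collapse = ";")
  cat(sprintf("<chain_graph> frame %d: %d flies, chain index %d, edges %s\n",
              x$frame_index, x$n_flies, x$chain_index, es))
  invisible(x)
}

#' Format chain-graph edges for CSV output
#' @param graph a `chain_graph`.
#' @return a string like `"1>2;3>2"` (empty when no edges).
#' @export
format_edges <- function(graph) {
  if (nrow(graph$edges) == 0L) return("")
  paste(sprintf("%d>%d", graph$edges[, 1L], graph$edges[, 2L]),
        collapse = ";")
}
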