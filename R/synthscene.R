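#' Synthetic chamber scene specification
#'
#' Describes a rendered test scene: a backlit chamber (default 417 x 83 px,
#' i.e. 50 x 10 mm at 0.12 mm/px) with dark teardrop fly silhouettes (~19 px
#' long, ~8 px wide — the observed ~2.3 mm body length) on a light
#' background. Flies are rendered darker than the background by
#' `bg_intensity - fly_intensity` (default 0.7, the strong contrast of
#' backlit silhouettes).
#'
#' @param chamber `c(width, height)` in px.
#' @param n_flies flies in the chamber (default 6).
#' @param fly_len,fly_wid body length and width in px.
#' @param sharpness taper exponent of the abdominal point (default 1, a
#'   linear wedge tapering to a point).
#' @param head_bluntness superellipse exponent of the anterior outline
#'   (default 3). Values above 2 round the head off flatter than an ellipse,
#'   as in a real fly, keeping the abdominal tip the dominant corner: with
#'   the defaults the maximal Harris response at the tail exceeds the head's
#'   by >= 1.5x at every orientation.
#' @param bg_intensity,fly_intensity intensities in `[0, 1]`.
#' @param noise_sd Gaussian intensity noise s.d. (0 = noiseless).
#' @param seed RNG seed for noise and randomized scenarios.
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(chamber = c(417, 83), n_flies = 6, fly_len = 19,
                       fly_wid = 8, sharpness = 1, head_bluntness = 3,
                       bg_intensity = 0.9, fly_intensity = 0.2, noise_sd = 0,
                       seed = 1L) {
  if (fly_len <= 5) stop("body length must exceed the 5-px head offset",
                         call. = FALSE)
  structure(list(chamber = chamber, n_flies = n_flies, fly_len = fly_len,
                 fly_wid = fly_wid, sharpness = sharpness,
                 head_bluntness = head_bluntness,
                 bg_intensity = bg_intensity, fly_intensity = fly_intensity,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scene_spec")
}

#' Render one fly silhouette mask
#'
#' A filled teardrop: the anterior half (toward the heading) is a half
#' ellipse; the posterior half tapers to a point at the abdominal tip, which
#' is therefore the sharpest boundary feature — the cue the head/tail
#' assignment relies on. Pixel centers falling inside the shape are set.
#'
#' @param position `c(x, y)` body center in chamber px.
#' @param heading radians; the head tip lies at
#'   `position + (fly_len/2) * c(cos, sin)(heading)`.
#' @param spec a [scene_spec] (shape parameters are read from it).
#' @return n x 2 integer matrix of occupied pixel coordinates (x, y).
#' @export
render_fly <- function(position, heading, spec) {
  a <- spec$fly_len / 2
  b <- spec$fly_wid / 2
  xr <- floor(position[1L] - a):ceiling(position[1L] + a)
  yr <- floor(position[2L] - a):ceiling(position[2L] + a)
  g <- expand.grid(x = xr, y = yr)
  dx <- g$x - position[1L]; dy <- g$y - position[2L]
  u <- dx * cos(heading) + dy * sin(heading)      # + toward head
  v <- -dx * sin(heading) + dy * cos(heading)
  p <- spec$head_bluntness
  half_w <- ifelse(u >= 0,
                   b * pmax(0, 1 - (u / a)^p)^(1 / p),
                   b * pmax(0, 1 - (-u / a))^spec$sharpness)
  keep <- abs(u) <= a & abs(v) <= half_w & half_w > 0
  as.matrix(g[keep, c("x", "y"), drop = FALSE])
}

#' Scripted fly trajectories for named scenarios
#'
#' \describe{
#'   \item{idle}{flies parked at dispersed positions, pairwise far outside
#'     chain range; chain index 0 throughout.}
#'   \item{chain_train}{`train_n` flies head-to-tail along the chamber with a
#'     `gap`-px tip-to-tip spacing, translating and wrapping; remaining flies
#'     parked far away. Optional heading/lateral jitter.}
#'   \item{dispersed}{positions and headings re-randomized every frame with a
#'     minimum separation — unconstrained chain indices for oracle
#'     comparisons.}
#'   \item{patrol}{a single fly visiting a grid of disjoint footprints, one
#'     per frame (background-model stress case).}
#' }
#'
#' @param scenario scenario name.
#' @param spec a [scene_spec].
#' @param n_frames frames to script.
#' @param train_n flies in the chain train (default `min(3, n_flies)`).
#' @param gap tip-to-tip spacing in px between consecutive train flies
#'   (default 6 px, 0.72 mm — chaining flies follow at near contact).
#' @param speed train translation in px per 1-fps frame (default 20 px,
#'   2.4 mm/s; consecutive footprints do not overlap, as for walking flies
#'   filmed at 1 fps).
#' @param jitter_sd s.d. of per-frame heading jitter (radians) applied to
#'   train flies (`chain_train` only).
#' @param seed RNG seed (defaults to the spec's).
#' @return list of per-frame matrices with columns `x`, `y`, `heading`, one
#'   row per fly.
#' @export
scenario_script <- function(scenario = c("idle", "chain_train", "dispersed",
                                         "patrol"),
                            spec, n_frames, train_n = NULL, gap = 6,
                            speed = 20, jitter_sd = 0, seed = NULL) {
  scenario <- match.arg(scenario)
  W <- spec$chamber[1L]; Hh <- spec$chamber[2L]
  margin <- spec$fly_len / 2 + 2
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(if (is.null(seed)) spec$seed else seed)

  park_positions <- function(n) {
    # fixed dispersed anchors, far outside chain range of one another
    xs <- seq(margin + 10, W - margin - 10, length.out = max(n, 2L))[seq_len(n)]
    ys <- rep(c(Hh * 0.3, Hh * 0.7), length.out = n)
    cbind(x = xs, y = ys, heading = seq(0, 2 * pi, length.out = n + 1L)[-1L])
  }

  if (scenario == "idle") {
    base <- park_positions(spec$n_flies)
    return(replicate(n_frames, base, simplify = FALSE))
  }

  if (scenario == "patrol") {
    step <- spec$fly_len + 6
    xs <- seq(margin, W - margin, by = step)
    ys <- seq(margin, Hh - margin, by = spec$fly_wid + 6)
    sites <- expand.grid(x = xs, y = ys)
    return(lapply(seq_len(n_frames), function(i) {
      s <- sites[((i - 1L) %% nrow(sites)) + 1L, ]
      cbind(x = s$x, y = s$y, heading = 0)
    }))
  }

  if (scenario == "chain_train") {
    tn <- if (is.null(train_n)) min(3L, spec$n_flies) else train_n
    pitch <- spec$fly_len + gap          # center-to-center spacing
    y0 <- Hh * 0.75                      # train lane
    others <- NULL
    if (spec$n_flies > tn) {
      # parked flies on the far lane, heading away along it: outside every
      # chain region of the train and of one another
      np <- spec$n_flies - tn
      others <- cbind(x = seq(margin + 10, W - margin - 10,
                              length.out = max(np, 2L))[seq_len(np)],
                      y = rep(margin, np), heading = rep(pi, np))
    }
    span <- pitch * (tn - 1)
    return(lapply(seq_len(n_frames), function(i) {
      head_x <- margin + span + ((i - 1L) * speed) %% (W - 2 * margin - span)
      xs <- head_x - (seq_len(tn) - 1L) * pitch   # leader first
      hd <- rep(0, tn)
      yy <- rep(y0, tn)
      if (jitter_sd > 0) {
        hd <- stats::rnorm(tn, 0, jitter_sd)
        yy <- y0 + stats::rnorm(tn, 0, 1)
      }
      tr <- cbind(x = xs, y = yy, heading = hd)
      if (spec$n_flies > tn) rbind(tr, others) else tr
    }))
  }

  # dispersed: rejection-sample positions with minimum separation
  min_sep <- spec$fly_len * 0.9
  lapply(seq_len(n_frames), function(i) {
    pos <- matrix(NA_real_, spec$n_flies, 2L)
    for (f in seq_len(spec$n_flies)) {
      repeat {
        cand <- c(stats::runif(1, margin, W - margin),
                  stats::runif(1, margin, Hh - margin))
        if (f == 1L || all(sqrt(rowSums(sweep(pos[seq_len(f - 1L), , drop = FALSE],
                                              2L, cand)^2)) >= min_sep)) break
      }
      pos[f, ] <- cand
    }
    cbind(x = pos[, 1L], y = pos[, 2L],
          heading = stats::runif(spec$n_flies, 0, 2 * pi))
  })
}

#' Render a scripted scene with ground truth
#'
#' Composites the teardrop silhouettes onto the constant background at 1 fps,
#' adds seeded Gaussian noise if requested, and records per-frame ground
#' truth: exact tip positions H and T, mask centroids, and the true chain
#' index computed by the brute-force pixel oracle ([oracle_chain_index]) —
#' independent of the detection pipeline under test.
#'
#' @param spec a [scene_spec].
#' @param script per-frame pose matrices from [scenario_script] (or any list
#'   of `x, y, heading` matrices).
#' @param params [chain_params] under which the true chain index is scored.
#' @return list with `seq` (a [frame_sequence]) and `truth` (a `data.frame`:
#'   `frame, fly_id, x, y, hx, hy, tx, ty, heading, true_chain_index`).
#' @export
render_scene <- function(spec, script, params = chain_params()) {
  stopifnot(inherits(spec, "scene_spec"), is.list(script))
  W <- spec$chamber[1L]; Hh <- spec$chamber[2L]
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(spec$seed)
  frames <- vector("list", length(script))
  truth <- list()
  for (fi in seq_along(script)) {
    sc <- script[[fi]]
    img <- matrix(spec$bg_intensity, nrow = Hh, ncol = W)
    masks <- vector("list", nrow(sc))
    tips <- matrix(NA_real_, nrow(sc), 4L)
    cents <- matrix(NA_real_, nrow(sc), 2L)
    for (f in seq_len(nrow(sc))) {
      px <- render_fly(c(sc[f, "x"], sc[f, "y"]), sc[f, "heading"], spec)
      px <- px[px[, 1L] >= 1 & px[, 1L] <= W & px[, 2L] >= 1 & px[, 2L] <= Hh,
               , drop = FALSE]
      img[cbind(px[, 2L], px[, 1L])] <- spec$fly_intensity
      masks[[f]] <- px
      a <- spec$fly_len / 2
      d <- c(cos(sc[f, "heading"]), sin(sc[f, "heading"]))
      tips[f, ] <- c(sc[f, "x"] + a * d[1L], sc[f, "y"] + a * d[2L],
                     sc[f, "x"] - a * d[1L], sc[f, "y"] - a * d[2L])
      cents[f, ] <- colMeans(px)
    }
    if (spec$noise_sd > 0)
      img <- pmin(pmax(img + matrix(stats::rnorm(length(img), 0,
                                                 spec$noise_sd),
                                    nrow = Hh), 0), 1)
    frames[[fi]] <- img
    ci <- oracle_chain_index(tips, masks, params, spec$chamber)
    truth[[fi]] <- data.frame(
      frame = fi, fly_id = seq_len(nrow(sc)),
      x = cents[, 1L], y = cents[, 2L],
      hx = tips[, 1L], hy = tips[, 2L], tx = tips[, 3L], ty = tips[, 4L],
      heading = sc[, "heading"], true_chain_index = ci)
  }
  list(seq = frame_sequence(frames, fps = 1), truth = do.call(rbind, truth))
}

#' Brute-force chain-index oracle
#'
#' Independent re-scoring of a configuration by exhaustive rasterization:
#' every fly's fan-shaped chain region is painted into a full-chamber mask
#' (per-pixel distance and angle test on the whole grid), every body mask is
#' painted likewise, and an edge is declared whenever a region mask and a
#' different fly's body mask share a pixel. The count of flies incident to
#' any overlap is returned. This shares no code with the detection pipeline's
#' containment predicate and exists to cross-check it.
#'
#' @param tips n x 4 matrix `(hx, hy, tx, ty)` of exact head/tail positions.
#' @param body_masks list of n pixel matrices (x, y), one per fly.
#' @param params a [chain_params].
#' @param chamber `c(width, height)` in px.
#' @return the chain index (single frame count).
#' @export
oracle_chain_index <- function(tips, body_masks, params, chamber) {
  n <- nrow(tips)
  W <- chamber[1L]; Hh <- chamber[2L]
  xs <- matrix(rep(seq_len(W), each = Hh), nrow = Hh)
  ys <- matrix(rep(seq_len(Hh), times = W), nrow = Hh)
  half_angle <- params$k * pi / 2
  radius <- params$q_offset + params$L

  region_mask <- function(f) {
    hx <- tips[f, 1L]; hy <- tips[f, 2L]
    tx <- tips[f, 3L]; ty <- tips[f, 4L]
    blen <- sqrt((hx - tx)^2 + (hy - ty)^2)
    if (blen <= params$q_offset) return(matrix(FALSE, Hh, W))
    qx <- hx + (tx - hx) * params$q_offset / blen
    qy <- hy + (ty - hy) * params$q_offset / blen
    dxm <- xs - qx; dym <- ys - qy
    rm <- sqrt(dxm^2 + dym^2)
    ang <- abs(atan2(dxm * (ty - hy) - dym * (tx - hx),   # heading = H - T
                     dxm * (hx - tx) + dym * (hy - ty)))
    rm > 0 & rm <= radius & ang <= half_angle + 1e-12
  }

  bmask <- lapply(body_masks, function(px) {
    m <- matrix(FALSE, Hh, W)
    keep <- px[, 1L] >= 1 & px[, 1L] <= W & px[, 2L] >= 1 & px[, 2L] <= Hh
    m[cbind(px[keep, 2L], px[keep, 1L])] <- TRUE
    m
  })
  in_chain <- logical(n)
  for (i in seq_len(n)) {
    reg <- region_mask(i)
    for (j in seq_len(n)) {
      if (i == j) next
      if (any(reg & bmask[[j]])) { in_chain[i] <- TRUE; in_chain[j] <- TRUE }
    }
  }
  sum(in_chain)
}
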