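# Shared fixtures, all built in code.

default_scene <- function(...) scene_spec(...)

# silhouette from raw pixel matrix
sil <- function(px) flychain:::new_silhouette(px)

# pixel raster of a solid ellipse (analytic reference shape)
ellipse_pixels <- function(center, a, b, theta) {
  xr <- floor(center[1] - a):ceiling(center[1] + a)
  yr <- floor(center[2] - a):ceiling(center[2] + a)
  g <- expand.grid(x = xr, y = yr)
  dx <- g$x - center[1]; dy <- g$y - center[2]
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  as.matrix(g[(u / a)^2 + (v / b)^2 <= 1, c("x", "y")])
}

# exact head/tail tips for a scripted fly
fly_tips <- function(x, y, heading, fly_len = 19) {
  a <- fly_len / 2
  c(hx = x + a * cos(heading), hy = y + a * sin(heading),
    tx = x - a * cos(heading), ty = y - a * sin(heading))
}

# true poses + rendered body masks for one scripted frame
frame_truth <- function(sc, spec) {
  n <- nrow(sc)
  bodies <- lapply(seq_len(n), function(f)
    render_fly(c(sc[f, "x"], sc[f, "y"]), sc[f, "heading"], spec))
  tips <- t(vapply(seq_len(n), function(f)
    fly_tips(sc[f, "x"], sc[f, "y"], sc[f, "heading"], spec$fly_len),
    numeric(4)))
  poses <- lapply(seq_len(n), function(f)
    pose_from_points(tips[f, 1:2], tips[f, 3:4],
                     minor_axis_len = spec$fly_wid))
  list(bodies = bodies, tips = tips, poses = poses)
}
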