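test_that("an empty chamber yields no silhouettes", {
  bg <- matrix(0.9, 60, 120)
  expect_length(segment_flies(bg, bg), 0L)
  # pure noise with no real foreground either
  noisy <- bg + matrix(rnorm(60 * 120, 0, 0.005), 60)
  expect_length(segment_flies(noisy, bg, min_area = 40), 0L)
})

test_that("well-separated rendered flies segment one-to-one", {
  spec <- scene_spec(n_flies = 6)
  script <- scenario_script("idle", spec, n_frames = 1)
  scn <- render_scene(spec, script)
  bg <- matrix(spec$bg_intensity, spec$chamber[2], spec$chamber[1])
  sils <- segment_flies(scn$seq$frames[[1]], bg)
  expect_length(sils, 6L)
  expect_false(any(vapply(sils, `[[`, logical(1), "merged")))
  # each recovered centroid within 1 px of the rendered mask centroid
  truth <- scn$truth[scn$truth$frame == 1, ]
  for (s in sils) {
    ctr <- colMeans(s$pixels)
    d <- sqrt((truth$x - ctr[1])^2 + (truth$y - ctr[2])^2)
    expect_lt(min(d), 1)
  }
})

test_that("touching flies merge into one flagged blob and split back", {
  spec <- scene_spec(n_flies = 2)
  # two flies overlapping ~30% along a shared axis
  b1 <- render_fly(c(60, 40), 0, spec)
  b2 <- render_fly(c(73, 40), 0, spec)
  frame <- matrix(spec$bg_intensity, 83, 417)
  frame[rbind(b1[, 2:1], b2[, 2:1])] <- spec$fly_intensity
  bg <- matrix(spec$bg_intensity, 83, 417)
  sils <- segment_flies(frame, bg)
  expect_length(sils, 1L)
  expect_true(sils[[1]]$merged)

  parts <- split_merged(sils[[1]], expected = 2)
  expect_length(parts, 2L)
  # union of parts is exactly the blob
  u <- do.call(rbind, lapply(parts, `[[`, "pixels"))
  expect_setequal(paste(u[, 1], u[, 2]),
                  paste(sils[[1]]$pixels[, 1], sils[[1]]$pixels[, 2]))
  # each part centroid within 3 px of a true fly center's mask centroid
  cents <- t(vapply(parts, function(p) colMeans(p$pixels), numeric(2)))
  for (truth_c in list(colMeans(b1), colMeans(b2))) {
    d <- sqrt((cents[, 1] - truth_c[1])^2 + (cents[, 2] - truth_c[2])^2)
    expect_lt(min(d), 3)
  }

  expect_error(split_merged(sils[[1]], expected = 1), ">= 2")
})

test_that("ellipse fitting recovers analytic moments", {
  # solid 19 x 8 ellipse at 30 degrees
  px <- ellipse_pixels(c(50, 40), 9.5, 4, pi / 6)
  pose <- fit_body_ellipse(sil(px))
  expect_lt(abs(pose$orientation - pi / 6) * 180 / pi, 2)
  expect_lt(abs(pose$major_axis_len - 19) / 19, 0.1)
  expect_lt(abs(pose$minor_axis_len - 8) / 8, 0.1)
  expect_false(pose$degenerate)

  # unoriented axis: 30 vs 210 degrees give the same orientation mod pi
  px2 <- ellipse_pixels(c(50, 40), 9.5, 4, pi / 6 + pi)
  pose2 <- fit_body_ellipse(sil(px2))
  expect_equal(pose$orientation, pose2$orientation, tolerance = 1e-6)

  # a disc has no axis
  disc <- ellipse_pixels(c(30, 30), 6, 6, 0)
  expect_true(fit_body_ellipse(sil(disc))$degenerate)

  expect_error(fit_body_ellipse(sil(matrix(c(1, 1), 1))), "too small")
})

test_that("the sharper abdominal tip is assigned as tail", {
  spec <- scene_spec()
  # heading east: head tip east, sharp tail tip west
  px <- render_fly(c(50, 40), 0, spec)
  pose <- assign_head_tail(sil(px), fit_body_ellipse(sil(px)))
  expect_gt(pose$H[1], pose$T[1])
  expect_false(pose$ht_unreliable)

  # corner rule overrides a contradictory previous pose (response gap > 10%)
  prev <- pose_from_points(H = c(40, 40), T = c(60, 40))   # claims west head
  pose2 <- assign_head_tail(sil(px), fit_body_ellipse(sil(px)), prev)
  expect_gt(pose2$H[1], pose2$T[1])
})

test_that("ambiguous symmetric bodies fall back on temporal coherence", {
  # a symmetric ellipse has equal corner responses at both ends
  px <- ellipse_pixels(c(50, 40), 9.5, 4, pi / 2)
  s <- sil(px)
  prev_north <- pose_from_points(H = c(50, 30), T = c(50, 50))
  pose <- assign_head_tail(s, fit_body_ellipse(s), prev_north)
  expect_lt(pose$H[2], pose$T[2])          # head stays on the north side
  prev_south <- pose_from_points(H = c(50, 50), T = c(50, 30))
  pose2 <- assign_head_tail(s, fit_body_ellipse(s), prev_south)
  expect_gt(pose2$H[2], pose2$T[2])
})

test_that("pose recovery is accurate over random renderings", {
  spec <- scene_spec()
  set.seed(101)
  n <- 100
  cent_err <- ang_err <- numeric(n); ht_ok <- logical(n)
  bg <- matrix(spec$bg_intensity, spec$chamber[2], spec$chamber[1])
  for (i in seq_len(n)) {
    x <- runif(1, 12, spec$chamber[1] - 12)
    y <- runif(1, 12, spec$chamber[2] - 12)
    th <- runif(1, 0, 2 * pi)
    px <- render_fly(c(x, y), th, spec)
    frame <- bg
    frame[px[, 2:1]] <- spec$fly_intensity
    s <- segment_flies(frame, bg)[[1]]
    pose <- assign_head_tail(s, fit_body_ellipse(s))
    cent_err[i] <- sqrt(sum((pose$centroid - colMeans(px))^2))
    ang_err[i] <- abs(((pose$orientation - th) + pi / 2) %% pi - pi / 2) * 180 / pi
    ht_ok[i] <- sum((pose$H - pose$T) * c(cos(th), sin(th))) > 0
  }
  expect_lt(median(cent_err), 1)
  expect_lt(median(ang_err), 3)
  expect_gte(mean(ht_ok), 0.95)
})

test_that("recovered orientations rotate with the frame", {
  spec <- scene_spec()
  bg <- matrix(spec$bg_intensity, 83, 417)
  set.seed(7)
  for (th in runif(5, 0, pi)) {
    px <- render_fly(c(60, 40), th, spec)
    frame <- bg
    frame[px[, 2:1]] <- spec$fly_intensity
    pose <- fit_body_ellipse(segment_flies(frame, bg)[[1]])
    # rotate the frame by 90 degrees (transpose + flip = CCW in x,y)
    frame90 <- t(frame)[ncol(frame):1, ]
    bg90 <- t(bg)[ncol(bg):1, ]
    pose90 <- fit_body_ellipse(segment_flies(frame90, bg90)[[1]])
    d <- abs(((pose90$orientation - pose$orientation - pi / 2) + pi / 2) %% pi - pi / 2)
    expect_lt(d * 180 / pi, 2)
  }
})

test_that("pose tables link identities across frames", {
  spec <- scene_spec(n_flies = 3)
  # slow train: displacement per frame well below the inter-fly spacing,
  # so nearest-centroid linking is unambiguous
  script <- scenario_script("chain_train", spec, n_frames = 8, train_n = 3,
                            speed = 5)
  scn <- render_scene(spec, script)
  bg <- matrix(spec$bg_intensity, spec$chamber[2], spec$chamber[1])
  tab <- track_poses(scn$seq, bg, expected_flies = 3)
  expect_equal(sort(unique(tab$fly_id)), 1:3)
  expect_equal(nrow(tab), 8 * 3)
  # linked tracks follow the 5 px/frame translation
  for (id in 1:3) {
    tr <- tab[tab$fly_id == id, ]
    expect_true(all(abs(diff(tr$x) - 5) < 2))
  }
})
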