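test_that("head base Q lies on TH at the stated offset", {
  expect_equal(head_base(H = c(10, 0), T = c(-9, 0), q_offset = 5), c(5, 0))
  expect_equal(head_base(H = c(10, 0), T = c(-9, 0), q_offset = 0), c(10, 0))
  # off-axis body
  Q <- head_base(H = c(6, 8), T = c(0, 0), q_offset = 5)
  expect_equal(Q, c(3, 4))
  expect_error(head_base(H = c(4, 0), T = c(0, 0), q_offset = 5), "exceed")
})

test_that("the chain region is a sector of radius q_offset + L about the heading", {
  pose <- pose_from_points(H = c(10, 0), T = c(-9, 0))   # heading +x, Q = (5, 0)
  par <- chain_params(L = 13, k = 0.66, q_offset = 5)
  # boundary point on the axis, exactly q_offset + L from Q
  expect_true(chain_region_contains(pose, par, c(5 + 18, 0)))
  expect_false(chain_region_contains(pose, par, c(5 + 18.01, 0)))
  # directly behind Q: outside the cone for any k <= 1
  expect_false(chain_region_contains(pose, par, c(-5, 0)))
  expect_false(chain_region_contains(pose, chain_params(k = 1), c(-5, 0)))
  # monotone in k: a point just past the half-angle enters when k grows
  ang <- 0.66 * pi / 2 + 0.01
  p <- c(5 + 10 * cos(ang), 10 * sin(ang))
  expect_false(chain_region_contains(pose, par, p))
  expect_true(chain_region_contains(pose, chain_params(k = 0.75), p))
  # Q itself is excluded (strictly positive distance)
  expect_false(chain_region_contains(pose, par, c(5, 0)))
})

test_that("region membership is monotone in L and k", {
  pose <- pose_from_points(H = c(4.75, 0), T = c(-4.75, 0), 4)
  set.seed(20)
  pts <- cbind(runif(500, -25, 30), runif(500, -25, 25))
  inner <- chain_region_contains(pose, chain_params(L = 12, k = 0.5), pts)
  outer <- chain_region_contains(pose, chain_params(L = 14, k = 0.75), pts)
  expect_true(all(outer[inner]))
})

test_that("degenerate or unreliable poses have empty regions and no out-edges", {
  pose <- pose_from_points(H = c(10, 0), T = c(-9, 0))
  pose$degenerate <- TRUE
  expect_false(any(chain_region_contains(pose, chain_params(),
                                         cbind(runif(50, 0, 25), runif(50, -5, 5)))))
  # as chaser: no edges; as recipient: still reachable
  good <- pose_from_points(H = c(22, 0), T = c(41, 0))  # heading -x toward it
  bad <- pose; bad$centroid <- c(0.5, 0)
  g <- detect_chain_edges(list(bad, good),
                          list(ellipse_pixels(c(0.5, 0), 9.5, 4, 0),
                               ellipse_pixels(c(31.5, 0), 9.5, 4, 0)),
                          chain_params())
  expect_equal(unname(g$edges), matrix(c(2L, 1L), 1))   # only good -> bad
})

test_that("chasing edges and chain index reproduce the worked examples", {
  spec <- scene_spec()
  par <- chain_params()
  # follower 10 px directly behind leader, aligned: one directed edge
  leader <- c(x = 150, y = 40, heading = 0)
  follower <- c(x = 150 - 29, y = 40, heading = 0)   # 10-px tip gap
  ft <- frame_truth(rbind(leader, follower), spec)
  g <- detect_chain_edges(ft$poses, ft$bodies, par)
  expect_equal(unname(g$edges), matrix(c(2L, 1L), 1))  # follower -> leader
  expect_equal(chain_index(g), 2L)                     # recipient included

  # empty graph
  g0 <- detect_chain_edges(list(), list(), par)
  expect_equal(chain_index(g0), 0L)

  # three-fly train scores 3
  tr <- rbind(c(150, 40, 0), c(125, 40, 0), c(100, 40, 0))
  colnames(tr) <- c("x", "y", "heading")
  ft3 <- frame_truth(tr, spec)
  g3 <- detect_chain_edges(ft3$poses, ft3$bodies, par)
  expect_equal(chain_index(g3), 3L)

  # far apart: no edges
  far <- rbind(c(50, 40, 0), c(150, 40, pi))
  colnames(far) <- c("x", "y", "heading")
  ftf <- frame_truth(far, spec)
  expect_equal(chain_index(detect_chain_edges(ftf$poses, ftf$bodies, par)), 0L)

  # side-by-side parallel flies outside both cones
  side <- rbind(c(100, 30, 0), c(100, 55, 0))
  colnames(side) <- c("x", "y", "heading")
  fts <- frame_truth(side, spec)
  expect_equal(chain_index(detect_chain_edges(fts$poses, fts$bodies, par)), 0L)
})

test_that("chain index is invariant under rigid motion of the configuration", {
  spec <- scene_spec()
  par <- chain_params()
  base <- rbind(c(150, 40, 0.3), c(127, 32, 0.1), c(105, 28, -0.2),
                c(260, 60, 2), c(320, 20, 4), c(210, 70, 1))
  colnames(base) <- c("x", "y", "heading")
  ft <- frame_truth(base, spec)
  ref <- chain_index(detect_chain_edges(ft$poses, ft$bodies, par))
  for (rot in c(pi / 7, pi / 2, 1.9)) {
    Rm <- matrix(c(cos(rot), sin(rot), -sin(rot), cos(rot)), 2)
    shift <- c(40, 25)
    moved <- base
    xy <- t(Rm %*% t(base[, 1:2])) ; xy <- sweep(xy, 2, -shift)
    moved[, 1] <- xy[, 1]; moved[, 2] <- xy[, 2]
    moved[, 3] <- base[, 3] + rot
    ftm <- frame_truth(moved, spec)
    expect_equal(chain_index(detect_chain_edges(ftm$poses, ftm$bodies, par)),
                 ref)
  }
})

test_that("ellipse rasterization stands in when silhouettes are missing", {
  spec <- scene_spec()
  tr <- rbind(c(150, 40, 0), c(121, 40, 0))
  colnames(tr) <- c("x", "y", "heading")
  ft <- frame_truth(tr, spec)
  g <- detect_chain_edges(ft$poses, silhouettes = NULL, params = chain_params())
  expect_equal(chain_index(g), 2L)
  expect_equal(format_edges(g), "2>1")
})
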