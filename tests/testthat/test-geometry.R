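test_that("three-sphere intersection reproduces closed-form cases", {
  # tangency forced by radii: unit spheres at mutual distance 2
  got <- intersect_three_spheres(sphere(c(0, 0, 0), 1), sphere(c(2, 0, 0), 1),
                                 sphere(c(1, 1, 0), 1))
  expect_length(got, 1L)
  expect_equal(got[[1L]], c(1, 0, 0), tolerance = 1e-9)
  # symmetric two-point case
  got <- intersect_three_spheres(sphere(c(0, 0, 0), 2), sphere(c(2, 0, 0), 2),
                                 sphere(c(0, 2, 0), 2))
  expect_length(got, 2L)
  expect_equal(got[[1L]], c(1, 1, sqrt(2)), tolerance = 1e-9)
  expect_equal(got[[2L]], c(1, 1, -sqrt(2)), tolerance = 1e-9)
})

test_that("random sphere triples: residuals, mirror symmetry, rigid invariance", {
  set.seed(42)
  for (rep in 1:50) {
    tri <- random_sphere_triple()
    got <- intersect_three_spheres(tri$spheres[[1L]], tri$spheres[[2L]],
                                   tri$spheres[[3L]])
    expect_gte(length(got), 1L)
    for (p in got)
      for (s in tri$spheres)
        expect_lt(abs(sqrt(sum((p - s$center)^2)) - s$radius), 1e-9)
    # the constructed point must be recovered
    expect_lt(min(vapply(got, function(p) sqrt(sum((p - tri$point)^2)),
                         numeric(1L))), 1e-7)
    if (length(got) == 2L) {
      # midpoint of the two points lies in the center plane
      mid <- (got[[1L]] + got[[2L]]) / 2
      nrm <- loopBP:::vcross(tri$centers[2L, ] - tri$centers[1L, ],
                             tri$centers[3L, ] - tri$centers[1L, ])
      nrm <- nrm / sqrt(sum(nrm^2))
      expect_lt(abs(sum((mid - tri$centers[1L, ]) * nrm)), 1e-9)
    }
    # count agrees with a dense angular search on the intersection circle
    expect_equal(length(got),
                 grid_count_three_spheres(tri$spheres[[1L]], tri$spheres[[2L]],
                                          tri$spheres[[3L]], 20000L))
    # invariance under a random rigid transform
    th <- stats::runif(3L, 0, 2 * pi)
    Rz <- rbind(c(cos(th[1L]), -sin(th[1L]), 0),
                c(sin(th[1L]), cos(th[1L]), 0), c(0, 0, 1))
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[2L]), -sin(th[2L])),
                c(0, sin(th[2L]), cos(th[2L])))
    R <- Rz %*% Rx
    tr <- stats::runif(3L, -3, 3)
    moved <- lapply(tri$spheres, function(s)
      sphere(drop(R %*% s$center) + tr, s$radius))
    got2 <- intersect_three_spheres(moved[[1L]], moved[[2L]], moved[[3L]])
    expect_equal(length(got2), length(got))
    back <- lapply(got, function(p) drop(R %*% p) + tr)
    for (p in back)
      expect_lt(min(vapply(got2, function(q) sqrt(sum((p - q)^2)),
                           numeric(1L))), 1e-8)
  }
})

test_that("degenerate sphere configurations raise the specified errors", {
  expect_error(intersect_three_spheres(sphere(c(0, 0, 0), 1),
                                       sphere(c(1, 0, 0), 1),
                                       sphere(c(2, 0, 0), 1)),
               "degenerate-centers")
  expect_error(sphere(c(0, 0, 0), 0), "radius")
  expect_error(strict_triangle_ok(1, -1, 2), "non-positive")
  expect_false(strict_triangle_ok(1, 1, 2))
  expect_true(strict_triangle_ok(1, 1, 1.5))
  expect_true(strict_triangle_ok(3, 4, 5))
})

test_that("fourth-sphere refinement keeps exactly the consistent candidates", {
  cands <- list(c(1, 1, sqrt(2)), c(1, 1, -sqrt(2)))
  s4 <- sphere(c(1, 1, 2), 2 - sqrt(2))
  expect_equal(refine_with_fourth(cands, s4, tol = 1e-6),
               list(c(1, 1, sqrt(2))))
  expect_equal(refine_with_fourth(cands, sphere(c(9, 9, 9), 1), tol = 1e-6),
               list())
  # a fourth sphere violated by only tol/2 keeps both mirror candidates:
  # center on the plane of the three centers is equidistant from both
  set.seed(7)
  for (rep in 1:20) {
    tri <- random_sphere_triple()
    got <- intersect_three_spheres(tri$spheres[[1L]], tri$spheres[[2L]],
                                   tri$spheres[[3L]])
    if (length(got) < 2L) next
    ab <- stats::runif(2L, -1, 1)
    c4 <- tri$centers[1L, ] + ab[1L] * (tri$centers[2L, ] - tri$centers[1L, ]) +
      ab[2L] * (tri$centers[3L, ] - tri$centers[1L, ])
    tol <- 0.01
    r4 <- sqrt(sum((got[[1L]] - c4)^2)) + tol / 2
    if (r4 <= tol) next
    kept <- refine_with_fourth(got, sphere(c4, r4), tol = tol)
    expect_length(kept, 2L)
  }
})

test_that("four-sphere point solves the consistent system and rejects others", {
  cs <- list(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  p0 <- c(0.3, 0.4, 0.5)
  rads <- vapply(cs, function(cc) sqrt(sum((p0 - cc)^2)), numeric(1L))
  got <- four_sphere_point(sphere(cs[[1L]], rads[1L]), sphere(cs[[2L]], rads[2L]),
                           sphere(cs[[3L]], rads[3L]), sphere(cs[[4L]], rads[4L]))
  expect_equal(as.numeric(got), p0, tolerance = 1e-9)
  expect_error(four_sphere_point(sphere(cs[[1L]], 10), sphere(cs[[2L]], 10),
                                 sphere(cs[[3L]], 10), sphere(cs[[4L]], 10)),
               "inconsistent-radii")
  # coplanar centers
  expect_error(four_sphere_point(sphere(c(0, 0, 0), 1), sphere(c(1, 0, 0), 1),
                                 sphere(c(0, 1, 0), 1), sphere(c(1, 1, 0), 1)),
               "coplanar-centers")
  # 50 random construct-then-recover cases
  set.seed(11)
  for (rep in 1:50) {
    cs <- matrix(stats::runif(12L, -4, 4), 4L, 3L)
    if (abs(det(cs[2:4, ] - matrix(cs[1L, ], 3L, 3L, byrow = TRUE))) < 0.5) next
    p0 <- stats::runif(3L, -4, 4)
    rads <- sqrt(rowSums((cs - matrix(p0, 4L, 3L, byrow = TRUE))^2))
    if (min(rads) < 0.3) next
    got <- four_sphere_point(sphere(cs[1L, ], rads[1L]), sphere(cs[2L, ], rads[2L]),
                             sphere(cs[3L, ], rads[3L]), sphere(cs[4L, ], rads[4L]))
    expect_lt(sqrt(sum((as.numeric(got) - p0)^2)), 1e-9)
  }
})
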