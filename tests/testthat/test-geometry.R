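test_that("snapshots average the stated 20 s window", {
  sch <- schedule_profile("ci")
  tp <- seq(0, sch$total_duration, by = 1)
  # constant parameters: snapshot equals the constant
  const_p <- matrix(3.5, length(tp), 2)
  snaps <- extract_snapshots(tp, const_p, sch)
  expect_equal(dim(snaps), c(7L, 2L))
  expect_true(all(snaps == 3.5))
  # linear ramp g(t) = t: window [t-30, t-10) has mean t-20.5 on the
  # 1-second sample grid
  ramp <- matrix(tp, ncol = 1)
  snaps <- extract_snapshots(tp, ramp, sch)
  ev <- c(120, 420, 720, 1020, 1320, 1620, 2040)
  expect_equal(unname(snaps[, 1]), ev - 20.5)
})

test_that("displacements subtract successive snapshot points", {
  pts <- matrix(c(0, 1, 3, 6, 10, 15, 21), ncol = 1)
  v <- displacements(pts)
  expect_equal(unname(v[, 1]), 1:6)
  expect_equal(rownames(v)[1], "after_pert1")
  expect_equal(rownames(v)[6], "after_wash3")
  expect_true(all(displacements(matrix(2, 7, 3)) == 0))
  expect_error(displacements(matrix(0, 6, 2)), "7")
})

test_that("norm, sphere, outside distance, angle: worked examples", {
  expect_equal(vector_norm(c(3, 4)), 5)
  expect_equal(vector_norm(rep(0, 11)), 0)
  pts <- matrix(rep(c(0, 2), each = 3), ncol = 1)
  sph <- bounding_sphere(pts)
  expect_equal(unname(sph$center), 1)
  expect_equal(sph$radius, 1)
  expect_equal(bounding_sphere(matrix(5, 6, 4))$radius, 0)
  expect_equal(signed_outside_distance(c(0, 3), list(center = c(0, 0), radius = 1)), 2)
  expect_equal(signed_outside_distance(c(0, 0), list(center = c(0, 0), radius = 1)), -1)
  expect_equal(signed_outside_distance(c(1, 0), list(center = c(0, 0), radius = 1)), 0)
  u <- c(1, 2, -3)
  expect_equal(angle_between(u, -u), 180)
  expect_equal(angle_between(c(1, 0), c(0, 5)), 90)
  expect_equal(angle_between(u, 2 * u), 0)
  expect_error(angle_between(u, rep(0, 3)), "zero")
})

test_that("geometry is rotation invariant and scale equivariant", {
  set.seed(11)
  for (i in 1:20) {
    d <- sample(c(7, 11), 1)
    pts <- matrix(rnorm(7 * d), 7, d)
    q <- qr.Q(qr(matrix(rnorm(d * d), d)))
    s <- runif(1, 0.1, 8)
    rot <- pts %*% q
    v <- displacements(pts); vr <- displacements(rot)
    expect_equal(apply(v, 1, vector_norm), apply(vr, 1, vector_norm),
                 tolerance = 1e-12)
    expect_equal(bounding_sphere(pts[2:7, ])$radius,
                 bounding_sphere(rot[2:7, ])$radius, tolerance = 1e-12)
    expect_equal(
      signed_outside_distance(pts[1, ], bounding_sphere(pts[2:7, ])),
      signed_outside_distance(rot[1, ], bounding_sphere(rot[2:7, ])),
      tolerance = 1e-12)
    expect_equal(angle_between(v[4, ], v[5, ]), angle_between(vr[4, ], vr[5, ]),
                 tolerance = 1e-9)
    # scaling
    expect_equal(bounding_sphere(s * pts[2:7, ])$radius,
                 s * bounding_sphere(pts[2:7, ])$radius, tolerance = 1e-12)
    expect_equal(angle_between(s * v[1, ], s * v[2, ]),
                 angle_between(v[1, ], v[2, ]), tolerance = 1e-9)
  }
})

test_that("angles above 90 degrees correspond to negative dot products", {
  set.seed(3)
  for (i in 1:200) {
    u <- rnorm(11); v <- rnorm(11)
    expect_identical(angle_between(u, v) > 90, sum(u * v) < 0)
  }
})

test_that("trajectory summary carries both spaces and the two angles", {
  s <- trajectory_summary(ci_full_run())
  expect_length(s$conductance$norms, 6)
  expect_length(s$halfshift$norms, 6)
  expect_gte(s$conductance$radius, 0)
  expect_true(all(s$angles >= 0 & s$angles <= 180, na.rm = TRUE))
})
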