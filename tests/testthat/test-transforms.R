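test_that("rigid_transform validates rotations", {
  expect_error(rigid_transform(diag(3) * 2, c(0, 0, 0)), "proper rotation")
  expect_error(rigid_transform(diag(c(1, 1, -1)), c(0, 0, 0)),
               "proper rotation")
  expect_error(rigid_transform(diag(3), c(0, 0)), "length-3")
})

test_that("compose and invert are consistent", {
  a <- rigid_transform(rotation_about(c(1, 2, 3), 33), c(1, -2, 3))
  b <- rigid_transform(rotation_about(c(-1, 0, 2), 71), c(-4, 0, 9))
  p <- matrix(rnorm(30), ncol = 3)
  expect_equal(apply_rigid(apply_rigid(p, a), b),
               apply_rigid(p, compose_rigid(b, a)), tolerance = 1e-12)
  expect_equal(apply_rigid(apply_rigid(p, a), invert_rigid(a)), p,
               tolerance = 1e-12)
})

test_that("rotation_about produces the requested geodesic angle", {
  for (ang in c(0.5, 10, 90, 179)) {
    R <- rotation_about(c(2, -1, 0.5), ang)
    expect_equal(det(R), 1, tolerance = 1e-12)
    expect_equal(rotation_angle_between(R, diag(3)), ang, tolerance = 1e-9)
  }
  # angles compose along a shared axis
  R1 <- rotation_about(c(0, 0, 1), 20)
  R2 <- rotation_about(c(0, 0, 1), 50)
  expect_equal(rotation_angle_between(R1, R2), 30, tolerance = 1e-9)
})

test_that("apply_rigid works identically on matrices and meshes", {
  m <- unit_sphere(2L)
  tf <- rigid_transform(rotation_about(c(1, 1, 1), 40), c(3, 2, 1))
  expect_equal(apply_rigid(m, tf)$vertices, apply_rigid(m$vertices, tf))
})
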