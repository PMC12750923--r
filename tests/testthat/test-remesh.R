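test_that("isotropic remeshing reaches the target edge length on a sphere", {
  s <- unit_sphere(3L)
  s$vertices <- s$vertices * 20          # radius 20 mm, edges ~4.4 mm
  r <- remesh_isotropic(s, target_edge = 2.0, iterations = 5L)
  st <- mesh_stats(r)
  expect_gt(st$median_edge, 2.0 * 0.7)
  expect_lt(st$median_edge, 2.0 * 1.3)
  expect_true(st$watertight)
  expect_equal(st$n_components, 1)
  # surface preserved: remeshed vertices lie on the sphere
  radii <- sqrt(rowSums(r$vertices^2))
  expect_lt(max(abs(radii - 20)), 0.25)
  expect_lt(abs(surface_area(r) - surface_area(s)) / surface_area(s), 0.03)
})

test_that("remeshing also coarsens an over-refined surface", {
  s <- unit_sphere(4L)
  s$vertices <- s$vertices * 10          # edges ~1.1 mm
  r <- remesh_isotropic(s, target_edge = 2.5, iterations = 5L)
  expect_lt(nrow(r$vertices), nrow(s$vertices) / 2)
  st <- mesh_stats(r)
  expect_gt(st$median_edge, 2.5 * 0.7)
  expect_lt(st$median_edge, 2.5 * 1.3)
  expect_true(st$watertight)
})

test_that("remeshing rejects non-manifold input", {
  # three faces sharing one edge
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1))
  f <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 2, 5))
  m <- triangle_mesh(v, f)
  expect_error(remesh_isotropic(m, 0.5), "non-manifold")
})

test_that("remeshing validates its arguments", {
  s <- unit_sphere(2L)
  expect_error(remesh_isotropic(s, target_edge = 0), "target_edge")
  expect_error(remesh_isotropic(s, target_edge = -1), "target_edge")
})
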