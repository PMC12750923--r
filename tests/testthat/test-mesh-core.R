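test_that("triangle_mesh merges duplicate vertices and drops degenerate faces", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
             c(1, 0, 0),              # exact duplicate of vertex 2
             c(0, 0, 1))
  f <- rbind(c(1, 2, 3), c(1, 4, 5),  # face 2 references the duplicate
             c(1, 1, 3),              # repeated index
             c(1, 2, 4))              # zero area after merging 2 and 4
  m <- triangle_mesh(v, f)
  expect_equal(nrow(m$vertices), 4L)
  expect_equal(nrow(m$faces), 2L)
  expect_true(all(m$faces <= nrow(m$vertices)))
})

test_that("triangle_mesh validates inputs", {
  expect_error(triangle_mesh(matrix(0, 1, 2), matrix(1L, 1, 3)), "3 columns")
  expect_error(triangle_mesh(matrix(0, 0, 3), matrix(1L, 0, 3)), "no vertices")
  v <- diag(3)
  expect_error(triangle_mesh(v, rbind(c(1, 2, 4))), "out of range")
  expect_error(triangle_mesh(v, rbind(c(1, 2, 3)), scalars = 1:2),
               "one value per vertex")
  v[1, 1] <- NA
  expect_error(triangle_mesh(v, rbind(c(1, 2, 3))), "NA")
})

test_that("surface area and volume match closed-form sphere values", {
  s <- unit_sphere(4L)
  # icosphere inscribes the unit sphere, so slightly below 4*pi and 4/3*pi
  expect_lt(abs(surface_area(s) - 4 * pi) / (4 * pi), 0.01)
  expect_lt(abs(mesh_volume(s) - 4 / 3 * pi) / (4 / 3 * pi), 0.01)
  expect_lt(mesh_volume(s), 4 / 3 * pi)
})

test_that("mesh_stats reports watertightness and components", {
  s <- unit_sphere(2L)
  st <- mesh_stats(s)
  expect_true(st$watertight)
  expect_equal(st$n_components, 1)
  # two disjoint spheres -> 2 components
  s2 <- triangle_mesh(rbind(s$vertices, s$vertices + 5),
                      rbind(s$faces, s$faces + nrow(s$vertices)))
  expect_equal(mesh_stats(s2)$n_components, 2)
})

test_that("largest_component keeps the larger-area shell", {
  s <- unit_sphere(2L)
  small <- s
  small$vertices <- small$vertices * 0.3 + 5
  both <- triangle_mesh(rbind(s$vertices, small$vertices),
                        rbind(s$faces, small$faces + nrow(s$vertices)))
  suppressMessages(kept <- largest_component(both))
  expect_equal(nrow(kept$vertices), nrow(s$vertices))
  expect_lt(max(abs(colMeans(kept$vertices))), 0.2)
})

test_that("mirror_sagittal negates one coordinate and preserves orientation", {
  s <- unit_sphere(2L)
  s$vertices <- sweep(s$vertices, 2, c(3, 1, 2), "*")
  m <- mirror_sagittal(s, axis = "x")
  expect_equal(m$vertices[, 1], -s$vertices[, 1])
  expect_equal(m$vertices[, 2:3], s$vertices[, 2:3])
  # volume stays positive => face orientation was re-fixed after reflection
  expect_gt(mesh_volume(m), 0)
  expect_equal(mesh_volume(m), mesh_volume(s), tolerance = 1e-12)
  # mirroring twice restores the original exactly
  mm <- mirror_sagittal(m, axis = "x")
  expect_equal(mm$vertices, s$vertices)
})

test_that("hausdorff distance between offset spheres equals the offset", {
  s <- unit_sphere(3L)
  t <- s
  t$vertices <- sweep(t$vertices, 2, c(0.5, 0, 0), "+")
  h <- hausdorff_distance(s, t)
  expect_lt(abs(h - 0.5), 0.02)
})

test_that("project_to_mesh lands on the surface with correct distance", {
  s <- unit_sphere(3L)
  p <- rbind(c(2, 0, 0), c(0, 0, -3))
  pr <- project_to_mesh(p, s)
  expect_equal(pr$distance, c(1, 2), tolerance = 0.01)
  expect_equal(sqrt(rowSums(pr$point^2)), c(1, 1), tolerance = 0.01)
})
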