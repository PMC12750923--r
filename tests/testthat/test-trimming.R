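# a simple elongated closed surface with exactly known extents: a box mesh
box_mesh <- function(dx, dy, dz, n = 9L) {
  g <- seq(0, 1, length.out = n)
  quads <- function(u, v, fixed, axis, flip) {
    vv <- expand.grid(u = u, v = v)
    nvert <- nrow(vv)
    idx <- matrix(seq_len(nvert), length(u), length(v))
    f <- NULL
    for (i in seq_len(length(u) - 1)) {
      for (j in seq_len(length(v) - 1)) {
        a <- idx[i, j]; b <- idx[i + 1, j]; c <- idx[i + 1, j + 1]
        d <- idx[i, j + 1]
        f <- rbind(f, c(a, b, c), c(a, c, d))
      }
    }
    if (flip) f <- f[, c(1, 3, 2)]
    coords <- switch(axis,
                     x = cbind(fixed, vv$u, vv$v),
                     y = cbind(vv$u, fixed, vv$v),
                     z = cbind(vv$u, vv$v, fixed))
    list(v = coords, f = f)
  }
  parts <- list(
    quads(g * dy, g * dz, 0, "x", TRUE), quads(g * dy, g * dz, dx, "x", FALSE),
    quads(g * dx, g * dz, 0, "y", FALSE), quads(g * dx, g * dz, dy, "y", TRUE),
    quads(g * dx, g * dy, 0, "z", TRUE), quads(g * dx, g * dy, dz, "z", FALSE))
  v <- NULL; f <- NULL
  for (p in parts) {
    f <- rbind(f, p$f + if (is.null(v)) 0L else nrow(v))
    v <- rbind(v, p$v)
  }
  m <- triangle_mesh(v, f)
  m$vertices <- sweep(m$vertices, 2, c(dx, dy, dz) / 2)  # centre at origin
  m
}

test_that("trim height equals the medial-lateral extent when available", {
  m <- box_mesh(40, 30, 100)
  spec <- compute_trim_spec(m, "femur")
  expect_equal(spec$target_height, 40)
  expect_false(spec$short_bone)
  expect_equal(spec$keep_end, "distal")
  expect_equal(spec$cut_plane_z, -50 + 40)   # femur keeps the low-z end
  spec_t <- compute_trim_spec(m, "tibia")
  expect_equal(spec_t$keep_end, "proximal")
  expect_equal(spec_t$cut_plane_z, 50 - 40)
})

test_that("short bones fall back to available height minus 5 mm, exactly", {
  m <- box_mesh(60, 30, 50)   # X extent 60 > Z extent 50
  spec <- compute_trim_spec(m, "femur")
  expect_true(spec$short_bone)
  expect_equal(spec$target_height, 45)
  expect_equal(spec$cut_plane_z, -25 + 45)
})

test_that("patellae get a no-trim spec and an all-true exclusion mask", {
  m <- surrogate_of("patella")
  spec <- compute_trim_spec(m, "patella")
  expect_equal(spec$keep_end, "none")
  mask <- exclusion_mask(m, spec)
  expect_true(all(mask$include))
})

test_that("clip_mesh cuts exactly at the plane and preserves closedness below", {
  s <- unit_sphere(3L)
  s$vertices <- s$vertices * 30
  cut <- clip_mesh(s, 10, keep = "below")
  expect_lte(max(cut$vertices[, 3]), 10 + 1e-9)
  # new boundary vertices lie exactly on the plane
  boundary <- abs(sqrt(rowSums(cut$vertices^2)) - 30) > 0.5
  expect_true(any(abs(cut$vertices[, 3] - 10) < 1e-9))
  # area approximates the spherical cap area 2*pi*r*h, h = r + z
  expect_lt(abs(surface_area(cut) - 2 * pi * 30 * 40) / (2 * pi * 30 * 40),
            0.02)
})

test_that("exclusion mask uses an inclusive >= 2 mm rule", {
  v <- rbind(c(0, 0, 1.999), c(0, 0, 2.0), c(0, 0, 2.001), c(0, 0, 10),
             c(1, 0, 5), c(0, 1, 5))
  m <- triangle_mesh(v, rbind(c(4, 5, 6), c(1, 2, 3)))
  spec <- structure(list(bone = "femur", keep_end = "distal",
                         target_height = 10, cut_plane_z = 0,
                         short_bone = FALSE), class = "trim_spec")
  mask <- exclusion_mask(m, spec, margin = 2.0)
  expect_identical(mask$include, c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE))
})

test_that("exclusion mask refuses to discard most of the mesh", {
  s <- unit_sphere(2L)
  spec <- structure(list(bone = "femur", keep_end = "distal",
                         target_height = 2, cut_plane_z = 0,
                         short_bone = FALSE), class = "trim_spec")
  expect_error(exclusion_mask(s, spec, margin = 2.0), "fewer than 50%")
})

test_that("trimming away more than 75% of a mesh is an error", {
  s <- unit_sphere(3L)
  s$vertices <- s$vertices * 30
  # keep only a thin 5 mm cap: ~8% of the surface
  trimmed <- clip_mesh(s, -25, keep = "below")
  expect_error(osteosym:::check_trim_fraction(s, trimmed, "left"),
               "more than 75%")
})

test_that("principal-axes alignment puts the long axis on Z with joint end placement", {
  f <- surrogate_of("femur")
  tf <- rigid_transform(rotation_about(c(1, 2, 0.5), 55), c(10, -20, 5))
  rotated <- apply_rigid(f, tf)
  al <- align_to_global(rotated, "femur", params = cpd_params())
  ext <- apply(al$mesh$vertices, 2, function(p) diff(range(p)))
  expect_equal(which.max(ext), 3L)
  expect_equal(al$method, "principal-axes")
  # femur joint end (wider) must sit at low z
  v <- al$mesh$vertices
  zr <- range(v[, 3])
  lo <- v[v[, 3] < zr[1] + 0.25 * diff(zr), 1:2]
  hi <- v[v[, 3] > zr[2] - 0.25 * diff(zr), 1:2]
  spread <- function(p) mean(sqrt(rowSums(sweep(p, 2, colMeans(p))^2)))
  expect_gt(spread(lo), spread(hi))
})

test_that("compact meshes require a reference for alignment", {
  p <- surrogate_of("patella")
  expect_error(align_to_global(p, "patella", params = cpd_params()),
               "reference")
  ref <- p
  al <- align_to_global(p, "patella", reference = ref,
                        params = cpd_params())
  expect_equal(al$method, "reference-model")
  expect_lt(max(abs(al$mesh$vertices - ref$vertices)), 0.5)
})

test_that("iterative trim-and-register stabilises the cut plane", {
  run <- noisy_femur_run()
  hist <- run$cs$artifacts$trim_history
  expect_equal(nrow(hist), 2L)
  expect_lt(hist$plane_shift[2], hist$plane_shift[1] + 1e-9)
})

test_that("trim reports serialise to JSON", {
  m <- box_mesh(40, 30, 100)
  spec <- compute_trim_spec(m, "femur")
  path <- tempfile(fileext = ".json")
  write_trim_report(spec, path)
  j <- jsonlite::read_json(path)
  expect_equal(j$target_height, 40)
  unlink(path)
})
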