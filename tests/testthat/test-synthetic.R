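test_that("surrogates are watertight single components at the target edge", {
  for (kind in c("femur", "tibia", "patella")) {
    m <- surrogate_of(kind)
    st <- mesh_stats(m)
    expect_true(st$watertight)
    expect_equal(st$n_components, 1)
    expect_gt(st$median_edge, 2.0 * 0.7)
    expect_lt(st$median_edge, 2.0 * 1.3)
  }
  # long bones are elongated, the patella compact
  ext <- function(m) sort(apply(m$vertices, 2,
                                function(p) diff(range(p))), decreasing = TRUE)
  expect_gt(ext(surrogate_of("femur"))[1] / ext(surrogate_of("femur"))[2], 1.4)
  expect_gt(ext(surrogate_of("tibia"))[1] / ext(surrogate_of("tibia"))[2], 1.4)
  expect_lt(ext(surrogate_of("patella"))[1] / ext(surrogate_of("patella"))[2],
            1.3)
})

test_that("surrogate generation is deterministic", {
  a <- make_surrogate(surrogate_spec("patella", seed = 1))
  b <- make_surrogate(surrogate_spec("patella", seed = 1))
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$faces, b$faces)
})

test_that("surrogate_spec validates its inputs", {
  expect_error(surrogate_spec("femur", scale = 20), "scale")
  expect_error(surrogate_spec("femur", scale = 200), "scale")
  expect_error(surrogate_spec("humerus"), "arg")
})

test_that("asymmetry_spec validates bump tables", {
  bad_amp <- data.frame(x = 0, y = 0, z = 0, amplitude = 9, radius = 8,
                        sign = 1)
  expect_error(asymmetry_spec(bumps = bad_amp), "amplitudes")
  bad_rad <- data.frame(x = 0, y = 0, z = 0, amplitude = 2, radius = 1,
                        sign = 1)
  expect_error(asymmetry_spec(bumps = bad_rad), "radii")
  expect_error(asymmetry_spec(bumps = data.frame(x = 0)), "columns")
})

test_that("make_pair is deterministic and mirrors the base", {
  base <- surrogate_of("patella")
  asym <- asymmetry_spec(noise_sd = 0.2, misalign_rot_deg = 5,
                         misalign_trans_mm = 3)
  a <- make_pair(base, asym, seed = 11)
  b <- make_pair(base, asym, seed = 11)
  expect_identical(a$left$vertices, b$left$vertices)
  expect_identical(a$right$vertices, b$right$vertices)
  d <- make_pair(base, asym, seed = 12)
  expect_false(identical(a$left$vertices, d$left$vertices))
  # without noise/misalignment, left is the exact mirror
  clean <- make_pair(base, asymmetry_spec(), seed = 1)
  expect_equal(clean$left$vertices,
               mirror_sagittal(base, "x")$vertices)
})

test_that("make_pair does not disturb the global RNG state", {
  set.seed(123)
  before <- .Random.seed
  invisible(make_pair(surrogate_of("patella"),
                      asymmetry_spec(noise_sd = 0.1), seed = 3))
  expect_identical(.Random.seed, before)
})

test_that("bump anchors far from the surface are rejected", {
  base <- surrogate_of("patella")
  far <- data.frame(x = 500, y = 0, z = 0, amplitude = 2, radius = 8,
                    sign = 1)
  expect_error(make_pair(base, asymmetry_spec(bumps = far), seed = 1),
               "farther than 5 mm")
})

test_that("injected truth matches the analytic bump profile", {
  base <- surrogate_of("patella")
  anchor <- base$vertices[1, ]
  bumps <- data.frame(x = anchor[1], y = anchor[2], z = anchor[3],
                      amplitude = 3, radius = 8, sign = 1)
  pr <- make_pair(base, asymmetry_spec(bumps = bumps), seed = 2)
  # the right mesh moved by the truth displacement along normals
  moved <- sqrt(rowSums((pr$right$vertices - base$vertices)^2))
  expect_equal(moved, pr$truth$displacement, tolerance = 1e-8)
  expect_equal(max(pr$truth$displacement), 3, tolerance = 0.05)
  # re-evaluating the truth on the same mesh reproduces it
  again <- truth_on_mesh(pr$truth, base)
  expect_equal(again$displacement, pr$truth$displacement, tolerance = 1e-8)
  # and transforms consistently
  tf <- rigid_transform(rotation_about(c(1, 0, 1), 25), c(5, 5, -2))
  m2 <- apply_rigid(base, tf)
  t2 <- truth_on_mesh(pr$truth, m2, tf)
  expect_equal(t2$displacement, pr$truth$displacement, tolerance = 1e-8)
})

test_that("loose fragments appear as a second component on the right side", {
  base <- surrogate_of("patella")
  pr <- make_pair(base, asymmetry_spec(loose_fragment = TRUE), seed = 5)
  expect_equal(mesh_stats(pr$right)$n_components, 2)
  expect_equal(mesh_stats(pr$left)$n_components, 1)
  # the pipeline's fragment filter removes it again
  kept <- suppressMessages(largest_component(pr$right))
  expect_equal(mesh_stats(kept)$n_components, 1)
})

test_that("fixture cohorts are written with a complete manifest", {
  dir <- file.path(tempdir(), "fixture_cohort_test")
  unlink(dir, recursive = TRUE)
  man <- write_fixture_cohort(dir, n_per_group = 1L, seed = 1L,
                              bones = "patella")
  tab <- read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(tab), 3L)
  expect_setequal(tab$group, c("none", "low", "high"))
  for (i in seq_len(nrow(tab))) {
    expect_true(file.exists(file.path(dir, tab$left_path[i])))
    expect_true(file.exists(file.path(dir, tab$right_path[i])))
  }
  m <- read_mesh(file.path(dir, tab$left_path[1]))
  expect_gt(nrow(m$vertices), 100)
  unlink(dir, recursive = TRUE)
})

test_that("score_recovery flags mismatched meshes", {
  base <- surrogate_of("patella")
  anchor <- base$vertices[1, ]
  bumps <- data.frame(x = anchor[1], y = anchor[2], z = anchor[3],
                      amplitude = 2, radius = 8, sign = 1)
  pr <- make_pair(base, asymmetry_spec(bumps = bumps), seed = 2)
  expect_error(score_recovery(rep(0.1, 10), pr$truth), "different meshes")
})
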