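test_that("rigid CPD recovers an exact transform on corresponding clouds", {
  set.seed(31)
  Y <- matrix(rnorm(600), ncol = 3) * c(25, 18, 45)
  R <- rotation_about(c(2, -1, 1), 17)
  tt <- c(4, -6, 2)
  X <- sweep(Y %*% t(R), 2, tt, "+")
  fit <- rigid_cpd(Y, X, cpd_params(w = 0))
  expect_lt(rotation_angle_between(fit$transform$R, R), 1e-4)
  expect_lt(sqrt(sum((fit$transform$t - tt)^2)), 1e-5)
  expect_true(fit$trace$converged)
})

test_that("rigid CPD objective is monotone non-increasing", {
  set.seed(5)
  Y <- matrix(rnorm(450), ncol = 3) * c(20, 20, 50)
  X <- sweep(Y %*% t(rotation_about(c(1, 0, 0), 12)), 2, c(2, 1, -3), "+")
  X <- X + matrix(rnorm(length(X), sd = 0.4), ncol = 3)
  fit <- rigid_cpd(Y, X, cpd_params())
  expect_true(all(diff(fit$trace$objective) <= 1e-8))
  expect_equal(length(fit$trace$objective), fit$trace$iterations)
  expect_true(all(fit$trace$sigma2 > 0))
})

test_that("outlier weight makes rigid CPD robust to spurious points", {
  set.seed(8)
  Y <- matrix(rnorm(900), ncol = 3) * c(25, 20, 45)
  R <- rotation_about(c(0, 1, 2), 14)
  tt <- c(3, 3, -5)
  X <- sweep(Y %*% t(R), 2, tt, "+")
  X <- rbind(X, matrix(runif(90, -120, 120), ncol = 3))  # 10% junk
  fit <- rigid_cpd(Y, X, cpd_params(w = 0.2))
  expect_lt(rotation_angle_between(fit$transform$R, R), 0.5)
  expect_lt(sqrt(sum((fit$transform$t - tt)^2)), 0.5)
})

test_that("rigid CPD never estimates scale", {
  set.seed(12)
  Y <- matrix(rnorm(600), ncol = 3) * c(20, 20, 40)
  X <- Y * 1.2   # pure size difference
  fit <- rigid_cpd(Y, X, cpd_params())
  # returned transform is rigid by construction: R orthonormal, det +1
  expect_equal(crossprod(fit$transform$R), diag(3), tolerance = 1e-10)
  expect_equal(det(fit$transform$R), 1, tolerance = 1e-10)
})

test_that("nonrigid CPD on identical sets yields a null deformation", {
  m <- surrogate_of("patella")
  fit <- nonrigid_cpd(m$vertices, m$vertices, cpd_params())
  moved <- apply_deformation(m$vertices, fit$field)
  expect_lt(max(sqrt(rowSums((moved - m$vertices)^2))), 0.05)
})

test_that("nonrigid CPD recovers a smooth synthetic field", {
  m <- surrogate_of("patella")
  Y <- m$vertices
  n <- vertex_normals(m)
  anchor <- Y[which.max(Y[, 3]), ]
  d2 <- colSums((t(Y) - anchor)^2)
  X <- Y + n * (3 * exp(-d2 / (2 * 10^2)))   # 3 mm bump, radius 10 mm
  fit <- nonrigid_cpd(Y, X, cpd_params())
  moved <- apply_deformation(Y, fit$field)
  resid <- .Machine$double.xmax
  # nearest-point residual of deformed moving points to the fixed surface
  fixed_mesh <- triangle_mesh(X, m$faces, merge_duplicates = FALSE)
  resid <- project_to_mesh(moved, fixed_mesh)$distance
  expect_lt(median(resid), 0.2)
  # penalised objective is monotone non-increasing
  expect_true(all(diff(fit$trace$objective) <= 1e-6))
})

test_that("deformation fields evaluate at arbitrary points and decay far away", {
  m <- surrogate_of("patella")
  Y <- m$vertices
  X <- Y + 1.5
  fit <- nonrigid_cpd(Y, X, cpd_params())
  far <- matrix(c(1e4, 1e4, 1e4), 1, 3)
  expect_lt(max(abs(apply_deformation(far, fit$field) - far)), 1e-8)
})

test_that("degenerate point sets are rejected", {
  line <- cbind(1:50, 2 * (1:50), 3 * (1:50))
  good <- matrix(rnorm(300), ncol = 3)
  expect_error(rigid_cpd(line, good, cpd_params()), "degenerate")
  expect_error(rigid_cpd(good, line, cpd_params()), "degenerate")
  expect_error(nonrigid_cpd(matrix(0, 0, 3), good, cpd_params()), "empty")
})

test_that("cpd_params validates hyperparameters", {
  expect_error(cpd_params(w = 1), "w must lie")
  expect_error(cpd_params(w = -0.1), "w must lie")
  expect_error(cpd_params(beta = 0), "positive")
  expect_error(cpd_params(lambda = -1), "positive")
  expect_error(cpd_params(tolerance = 0), "positive")
})

test_that("cpd traces serialise to delimited text", {
  set.seed(2)
  Y <- matrix(rnorm(300), ncol = 3) * 10
  fit <- rigid_cpd(Y, Y + 1, cpd_params())
  path <- tempfile(fileext = ".tsv")
  write_cpd_trace(fit$trace, path)
  tab <- read.delim(path)
  expect_equal(names(tab), c("iteration", "sigma2", "objective", "entropy"))
  expect_equal(nrow(tab), fit$trace$iterations)
  unlink(path)
})

test_that("voxel-grid subsampling is deterministic and near the cap", {
  set.seed(77)
  P <- matrix(rnorm(30000), ncol = 3)
  a <- osteosym:::subsample_points(P, 1500L)
  b <- osteosym:::subsample_points(P, 1500L)
  expect_identical(a, b)
  expect_lte(nrow(a), 1500L)
  expect_gt(nrow(a), 1000L)
  small <- P[1:100, ]
  expect_identical(osteosym:::subsample_points(small, 1500L), small)
})
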