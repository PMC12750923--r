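#' CPD hyperparameters
#'
#' Settings for the Coherent Point Drift registrations. Both variants treat
#' the moving set as Gaussian-mixture centroids fitted to the fixed set by
#' EM, with a uniform outlier component of weight `w`. The nonrigid variant
#' regularises the displacement field through a Gaussian kernel of width
#' `beta` (mm, spatial coherence scale) weighted by `lambda`.
#'
#' @param w outlier weight in `[0, 1)`.
#' @param beta Gaussian kernel width in mm (nonrigid motion coherence).
#' @param lambda regularisation weight of the coherence prior.
#' @param tolerance relative change in the objective that stops EM.
#' @param max_iterations EM iteration cap.
#' @param subsample_cap maximum number of points per set for the nonrigid
#'   fit, whose M-step solve is cubic in the moving-set size; larger sets are
#'   downsampled to a uniform-density voxel-grid subset (deterministic), and
#'   the fitted field is then evaluated at full resolution.
#' @param rigid_subsample_cap like `subsample_cap` but for the rigid variant,
#'   whose per-iteration cost is only quadratic; kept high so rigid fits
#'   normally run at full resolution.
#' @param sigma2_floor lower bound on the mixture variance (mm^2), guarding
#'   against division blow-up near perfect fits.
#' @param n_starts number of deterministic initialisations for the rigid
#'   variant (identity plus up to four principal-axes alignments); compact,
#'   nearly ellipsoidal bones (patella) can trap a single-start EM in a
#'   rotational local optimum. Extra starts are screened for
#'   `screen_iterations` EM steps on a coarse subsample and only the best
#'   start is run to convergence.
#' @param screen_iterations EM steps used to rank the extra starts.
#' @param seed integer seed recorded with the fit; the current subsampling
#'   (voxel grid) and initialisation (principal axes) are fully
#'   deterministic, so the seed does not change results, but it is kept so
#'   future stochastic options stay reproducible and logged.
#' @export
cpd_params <- function(w = 0.1, beta = 10, lambda = 2, tolerance = 1e-6,
                       max_iterations = 150L, subsample_cap = 1800L,
                       rigid_subsample_cap = 6000L,
                       sigma2_floor = 1e-8, n_starts = 5L,
                       screen_iterations = 30L, seed = 1L) {
  if (w < 0 || w >= 1) stop("w must lie in [0, 1)")
  if (beta <= 0 || lambda <= 0 || tolerance <= 0) {
    stop("beta, lambda and tolerance must be positive")
  }
  if (n_starts < 1L) stop("n_starts must be at least 1")
  structure(list(w = w, beta = beta, lambda = lambda, tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 subsample_cap = as.integer(subsample_cap),
                 rigid_subsample_cap = as.integer(rigid_subsample_cap),
                 sigma2_floor = sigma2_floor, n_starts = as.integer(n_starts),
                 screen_iterations = as.integer(screen_iterations),
                 seed = as.integer(seed)),
            class = "cpd_params")
}

# Deterministic rigid initialisations: the identity, plus principal-axes
# alignments of the two clouds under the four proper-rotation sign
# combinations (PCA leaves each axis direction ambiguous). Compact, nearly
# ellipsoidal bones have narrow EM capture basins, and principal-axes
# alignment starts within a few degrees of the optimum.
rigid_start_transforms <- function(Y, X, n) {
  starts <- list(rigid_transform())
  if (n > 1L) {
    cy <- colMeans(Y)
    cx <- colMeans(X)
    Vy <- eigen(stats::cov(Y), symmetric = TRUE)$vectors
    Vx <- eigen(stats::cov(X), symmetric = TRUE)$vectors
    if (det(Vy) < 0) Vy[, 3] <- -Vy[, 3]
    if (det(Vx) < 0) Vx[, 3] <- -Vx[, 3]
    signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
    for (s in signs) {
      R0 <- Vx %*% diag(s) %*% t(Vy)
      starts[[length(starts) + 1L]] <-
        rigid_transform(R0, cx - as.numeric(R0 %*% cy))
    }
  }
  starts[seq_len(min(n, length(starts)))]
}

# Run code with a local RNG state; leaves the caller's RNG untouched.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Uniform-density downsampling on a voxel grid: one representative point per
# occupied cell, cell size chosen by bisection so the count approaches `cap`
# from below. Deterministic. Random subsampling is deliberately avoided: its
# density fluctuations measurably bias the GMM registration optimum (the
# mixture fits sampling density as well as geometry), whereas grid-uniform
# subsets keep the optimum on the surface geometry.
subsample_points <- function(points, cap, seed = NULL) {
  n <- nrow(points)
  if (n <= cap) return(points)
  mins <- apply(points, 2, min)
  span <- max(apply(points, 2, max) - mins) + 1e-9
  cell_pick <- function(h) {
    k <- floor(sweep(points, 2, mins, "-") / h)
    nx <- max(k[, 1]) + 1
    ny <- max(k[, 2]) + 1
    id <- k[, 1] + nx * (k[, 2] + ny * k[, 3])
    which(!duplicated(id))
  }
  # bracket: lo fine (count > cap), hi coarse (count <= cap), then bisect
  lo <- span / ceiling(2 * cap^(1 / 3))
  for (it in 1:40) {
    if (length(cell_pick(lo)) > cap) break
    lo <- lo / 2
  }
  hi <- span
  pick <- cell_pick(hi)
  for (it in 1:30) {
    mid <- 0.5 * (lo + hi)
    p <- cell_pick(mid)
    if (length(p) > cap) {
      lo <- mid
    } else {
      pick <- p
      hi <- mid
    }
  }
  points[sort(pick), , drop = FALSE]
}

check_point_geometry <- function(points, label) {
  if (is.null(points) || nrow(points) == 0L) stop(label, " point set is empty")
  if (nrow(points) >= 3L) {
    ev <- eigen(stats::cov(points), symmetric = TRUE, only.values = TRUE)$values
    if (ev[1] <= 0 || ev[2] / ev[1] < 1e-10) {
      stop(label, " point set is degenerate (coincident or collinear points)")
    }
  }
}

as_points <- function(x) {
  if (is_triangle_mesh(x)) x$vertices else as.matrix(x)
}

cpd_trace <- function(core) {
  structure(list(sigma2 = as.numeric(core$sigma2),
                 objective = as.numeric(core$objective),
                 entropy = as.numeric(core$entropy),
                 converged = isTRUE(core$converged),
                 iterations = as.integer(core$iterations)),
            class = "cpd_trace")
}

#' Rigid Coherent Point Drift registration
#'
#' Estimates the rotation and translation (no scale) aligning `moving` to
#' `fixed` by EM over a Gaussian mixture whose centroids are the transformed
#' moving points, with closed-form SVD updates for the rotation and a uniform
#' outlier component of weight `w`. Size differences are deliberately not
#' absorbed: a scale factor would hide genuine left-right asymmetry.
#'
#' @param moving,fixed `n x 3` point matrices or `triangle_mesh` objects.
#' @param params a [cpd_params()] object.
#' @return list with `transform` (a `rigid_transform`) and `trace` (a
#'   `cpd_trace` with per-iteration sigma^2, objective and correspondence
#'   entropy).
#' @export
rigid_cpd <- function(moving, fixed, params = cpd_params()) {
  Y <- as_points(moving)
  X <- as_points(fixed)
  check_point_geometry(Y, "moving")
  check_point_geometry(X, "fixed")
  Ys <- subsample_points(Y, params$rigid_subsample_cap)
  Xs <- subsample_points(X, params$rigid_subsample_cap)
  starts <- rigid_start_transforms(Ys, Xs, params$n_starts)
  finalists <- 1L
  if (length(starts) > 1L) {
    # screen the starts on a coarser subsample: sigma2 after a few EM steps
    # ranks basins, but nearby basins can swap order before convergence, so
    # the two best-screened starts are both run to convergence below
    Ysc <- subsample_points(Ys, 600L)
    Xsc <- subsample_points(Xs, 600L)
    score <- vapply(starts, function(tf) {
      core <- .rigid_cpd_core(Xsc, apply_rigid(Ysc, tf), params$w,
                              params$tolerance, params$screen_iterations,
                              params$sigma2_floor)
      tail(core$sigma2, 1L)
    }, numeric(1))
    finalists <- order(score)[1:2]
  }
  best <- NULL
  best_pre <- NULL
  for (j in finalists) {
    core <- .rigid_cpd_core(Xs, apply_rigid(Ys, starts[[j]]), params$w,
                            params$tolerance, params$max_iterations,
                            params$sigma2_floor)
    if (is.null(best) ||
          tail(core$sigma2, 1L) < tail(best$sigma2, 1L)) {
      best <- core
      best_pre <- starts[[j]]
    }
  }
  if (!isTRUE(best$converged)) {
    warning("rigid CPD did not converge within ", params$max_iterations,
            " iterations")
  }
  list(transform = compose_rigid(rigid_transform(best$R, best$t), best_pre),
       trace = cpd_trace(best))
}

#' Nonrigid Coherent Point Drift registration
#'
#' Fits a smooth displacement field `T(Y) = Y + G W` where
#' `G(i, j) = exp(-||y_i - y_j||^2 / (2 beta^2))`, by EM with the
#' kernel-regularised M-step linear solve. When the moving set exceeds
#' `subsample_cap` the fit runs on a seeded uniform subsample and the
#' returned field (control points + coefficients) is evaluated at arbitrary
#' points, so full-resolution meshes can be deformed after a subsampled fit.
#'
#' @inheritParams rigid_cpd
#' @return list with `field` (a `deformation_field`) and `trace` (a
#'   `cpd_trace`).
#' @export
nonrigid_cpd <- function(moving, fixed, params = cpd_params()) {
  Y <- as_points(moving)
  X <- as_points(fixed)
  check_point_geometry(Y, "moving")
  check_point_geometry(X, "fixed")
  Ys <- subsample_points(Y, params$subsample_cap)
  Xs <- subsample_points(X, params$subsample_cap)
  core <- .nonrigid_cpd_core(Xs, Ys, params$beta, params$lambda, params$w,
                             params$tolerance, params$max_iterations,
                             params$sigma2_floor)
  if (isTRUE(core$solve_failed)) {
    stop("nonrigid CPD M-step solve is ill-conditioned; ",
         "increase lambda or beta")
  }
  if (!isTRUE(core$converged)) {
    warning("nonrigid CPD did not converge within ", params$max_iterations,
            " iterations")
  }
  field <- structure(list(source_points = Ys, W = core$W, beta = params$beta),
                     class = "deformation_field")
  list(field = field, trace = cpd_trace(core))
}

#' Evaluate a deformation field at arbitrary points
#'
#' Adds the kernel-weighted displacement
#' `v(p) = sum_j exp(-||p - y_j||^2 / (2 beta^2)) W_j` to each point. At the
#' control points this reproduces the converged deformed positions; far from
#' all control points the displacement decays to zero.
#'
#' @param points `n x 3` matrix or `triangle_mesh`.
#' @param field a `deformation_field` from [nonrigid_cpd()].
#' @return object of the same kind as `points`, deformed.
#' @export
apply_deformation <- function(points, field) {
  stopifnot(inherits(field, "deformation_field"))
  if (is_triangle_mesh(points)) {
    points$vertices <- apply_deformation(points$vertices, field)
    return(points)
  }
  points <- as.matrix(points)
  G <- .gauss_affinity(points, field$source_points, field$beta)
  points + G %*% field$W
}

#' @export
print.cpd_trace <- function(x, ...) {
  cat(sprintf(
    "cpd_trace: %d iterations, converged: %s, final sigma2 %.3g mm^2\n",
    x$iterations, x$converged, x$sigma2[length(x$sigma2)]))
  invisible(x)
}

#' Write a CPD trace as delimited text (iteration, sigma2, objective, entropy)
#' @param trace a `cpd_trace`.
#' @param path output TSV path.
#' @export
write_cpd_trace <- function(trace, path) {
  utils::write.table(
    data.frame(iteration = seq_along(trace$sigma2), sigma2 = trace$sigma2,
               objective = trace$objective, entropy = trace$entropy),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
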