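# Synthetic paired-bone surrogates with known injected asymmetry. These stand
# in for CT-derived surface models: parametric, fully deterministic, and
# labelled synthetic throughout. They emulate bone-scale closed surfaces
# (~40-100 mm) remeshed at ~2 mm, not anatomically realistic bones.

#' Area-weighted per-vertex normals
#' @param mesh a `triangle_mesh`.
#' @return `n x 3` matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  stopifnot_mesh(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  u <- v[f[, 2], , drop = FALSE] - a
  w <- v[f[, 3], , drop = FALSE] - a
  fn <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  n <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    for (d in 1:3) n[, d] <- n[, d] + rowsum_vec(fn[, d], f[, k], nrow(v))
  }
  nl <- sqrt(rowSums(n^2))
  nl[nl == 0] <- 1
  n / nl
}

# icosahedron subdivided `level` times, projected to the unit sphere
icosphere <- function(level = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (l in seq_len(level)) {
    nv <- nrow(v)
    et <- edge_table(f, nv)
    mid <- (v[et$a, , drop = FALSE] + v[et$b, , drop = FALSE]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    mid_idx <- nv + seq_along(et$a)
    v <- rbind(v, mid)
    lookup <- function(p, q) {
      cd <- as.numeric(pmin(p, q)) * (nv + 1) + pmax(p, q)
      mid_idx[match(cd, et$code)]
    }
    m12 <- lookup(f[, 1], f[, 2])
    m23 <- lookup(f[, 2], f[, 3])
    m31 <- lookup(f[, 3], f[, 1])
    f <- rbind(cbind(f[, 1], m12, m31), cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23), cbind(m12, m23, m31))
    storage.mode(f) <- "integer"
  }
  triangle_mesh(v, f, merge_duplicates = FALSE)
}

# Displace vertices along their normals with Gaussian falloff around anchors.
# Returns the mesh plus the signed per-vertex displacement actually applied.
apply_bumps <- function(mesh, anchors, amplitudes, radii, signs) {
  n <- vertex_normals(mesh)
  disp <- numeric(nrow(mesh$vertices))
  for (b in seq_len(nrow(anchors))) {
    d2 <- colSums((t(mesh$vertices) - anchors[b, ])^2)
    disp <- disp + signs[b] * amplitudes[b] * exp(-d2 / (2 * radii[b]^2))
  }
  mesh$vertices <- mesh$vertices + n * disp
  list(mesh = mesh, displacement = disp)
}

#' Specification of a synthetic bone surrogate
#'
#' Parametric stand-ins for CT-derived bone surfaces: smoothly deformed
#' ellipsoids with bone-like features (condyles and a trochlea-like anterior
#' boss for the femur, plateau flare and a tubercle for the tibia, an
#' articular ridge for the patella). Femur and tibia surrogates are elongated
#' (long-axis extent at least 1.4x the width) to exercise principal-axes
#' alignment; the patella is compact (extent ratio below 1.3) to exercise the
#' reference-model alignment path.
#'
#' @param kind `"femur"`, `"patella"` or `"tibia"`.
#' @param scale overall long-axis size in mm (30-120).
#' @param target_edge remeshing element size in mm.
#' @param seed integer seed (kept for provenance; generation is analytic).
#' @export
surrogate_spec <- function(kind = c("femur", "tibia", "patella"),
                           scale = NULL, target_edge = 2.0, seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(scale)) {
    scale <- switch(kind, femur = 80, tibia = 75, patella = 40)
  }
  if (scale < 30 || scale > 120) stop("scale must lie in [30, 120] mm")
  structure(list(kind = kind, scale = scale, target_edge = target_edge,
                 seed = as.integer(seed)), class = "surrogate_spec")
}

#' Generate a synthetic bone surrogate mesh
#'
#' @param spec a [surrogate_spec()].
#' @return a watertight single-component `triangle_mesh` at the requested
#'   element size.
#' @export
make_surrogate <- function(spec) {
  stopifnot(inherits(spec, "surrogate_spec"))
  s <- spec$scale
  semi <- switch(spec$kind,
                 femur = c(0.28, 0.24, 0.50) * s,
                 tibia = c(0.26, 0.22, 0.50) * s,
                 patella = c(0.50, 0.40, 0.33) * s)
  level <- max(2L, min(5L, ceiling(log2(1.05 * max(semi) /
                                          (1.5 * spec$target_edge)))))
  base <- icosphere(level)
  base$vertices <- sweep(base$vertices, 2, semi, "*")
  feats <- switch(spec$kind,
    femur = list(
      anchors = rbind(c(0.15, -0.05, -0.45), c(-0.15, -0.05, -0.45),
                      c(0.04, 0.22, -0.30)) * s,
      amplitudes = c(0.060, 0.055, 0.035) * s,
      radii = c(0.12, 0.12, 0.10) * s,
      signs = c(1, 1, 1)),
    tibia = list(
      anchors = rbind(c(0.13, 0, 0.45), c(-0.13, 0.02, 0.45),
                      c(0.03, 0.20, 0.28)) * s,
      amplitudes = c(0.050, 0.045, 0.040) * s,
      radii = c(0.12, 0.12, 0.08) * s,
      signs = c(1, 1, 1)),
    patella = list(
      anchors = rbind(c(0.10, -0.38, 0.05), c(-0.15, 0.32, -0.10)) * s,
      amplitudes = c(0.050, 0.030) * s,
      radii = c(0.22, 0.15) * s,
      signs = c(1, -1)))
  # project anchors onto the ellipsoid surface before bumping
  feats$anchors <- project_to_mesh(feats$anchors, base)$point
  shaped <- apply_bumps(base, feats$anchors, feats$amplitudes, feats$radii,
                        feats$signs)$mesh
  out <- remesh_isotropic(shaped, target_edge = spec$target_edge,
                          iterations = 4L)
  st <- mesh_stats(out)
  if (!st$watertight || st$n_components != 1L) {
    stop("surrogate generation produced a non-watertight or fragmented mesh")
  }
  out
}

#' Specification of injected asymmetry for a synthetic pair
#'
#' @param bumps data frame (or NULL) with columns `x`, `y`, `z` (anchor in
#'   the base mesh frame, mm; projected onto the surface, must be within
#'   5 mm), `amplitude` (mm, in `[0, 5]`), `radius` (mm, > 2 so bumps stay
#'   resolvable at 2 mm meshing) and `sign` (+1 outward / -1 inward).
#' @param noise_sd per-coordinate Gaussian vertex noise in mm (0.3 mm
#'   emulates CT voxel-scale segmentation uncertainty).
#' @param misalign_rot_deg,misalign_trans_mm initial left-vs-right rigid
#'   misalignment magnitudes (random direction, seeded).
#' @param loose_fragment add a small detached component near the right
#'   surface, emulating a loose patellar fragment.
#' @export
asymmetry_spec <- function(bumps = NULL, noise_sd = 0,
                           misalign_rot_deg = 0, misalign_trans_mm = 0,
                           loose_fragment = FALSE) {
  if (!is.null(bumps)) {
    bumps <- as.data.frame(bumps)
    need <- c("x", "y", "z", "amplitude", "radius", "sign")
    if (!all(need %in% names(bumps))) {
      stop("bumps needs columns ", paste(need, collapse = ", "))
    }
    if (any(bumps$amplitude < 0 | bumps$amplitude > 5)) {
      stop("bump amplitudes must lie in [0, 5] mm")
    }
    if (any(bumps$radius <= 2)) {
      stop("bump radii must exceed 2 mm to stay resolvable")
    }
  }
  structure(list(bumps = bumps, noise_sd = noise_sd,
                 misalign_rot_deg = misalign_rot_deg,
                 misalign_trans_mm = misalign_trans_mm,
                 loose_fragment = loose_fragment),
            class = "asymmetry_spec")
}

#' Build a synthetic left/right pair with known asymmetry
#'
#' The right mesh is the base with bumps applied as normal-direction
#' displacements with Gaussian falloff (ground truth recorded before noise);
#' the left mesh is the mirrored unmodified base under the specified rigid
#' misalignment. Independent vertex noise is then added to both sides.
#'
#' @param base a base `triangle_mesh` (the "true" right-side bone).
#' @param asym an [asymmetry_spec()].
#' @param seed integer seed driving noise, misalignment direction and the
#'   fragment placement.
#' @return list with `left`, `right` (`triangle_mesh`) and `truth` (an
#'   `asymmetry_truth`: per-vertex true displacement magnitude on the right
#'   mesh, bump region index sets, and the analytic bump parameters).
#' @export
make_pair <- function(base, asym = asymmetry_spec(), seed = 1L) {
  stopifnot_mesh(base)
  stopifnot(inherits(asym, "asymmetry_spec"))
  right <- base
  disp <- numeric(nrow(base$vertices))
  regions <- list()
  bumps <- asym$bumps
  if (!is.null(bumps) && nrow(bumps) > 0L) {
    anchors <- as.matrix(bumps[, c("x", "y", "z")])
    pr <- project_to_mesh(anchors, base)
    if (any(pr$distance > 5)) {
      stop("bump anchor farther than 5 mm from the surface")
    }
    anchors <- pr$point
    res <- apply_bumps(base, anchors, bumps$amplitude, bumps$radius,
                       bumps$sign)
    right <- res$mesh
    disp <- res$displacement
    for (b in seq_len(nrow(bumps))) {
      d2 <- colSums((t(base$vertices) - anchors[b, ])^2)
      regions[[b]] <- which(d2 <= (2 * bumps$radius[b])^2)
    }
    bumps$x <- anchors[, 1]; bumps$y <- anchors[, 2]; bumps$z <- anchors[, 3]
  }
  truth <- structure(list(displacement = abs(disp), regions = regions,
                          bumps = bumps), class = "asymmetry_truth")
  left <- mirror_sagittal(base, axis = "x")
  res <- with_local_seed(seed, {
    if (asym$misalign_rot_deg != 0 || asym$misalign_trans_mm != 0) {
      axis <- stats::rnorm(3)
      R <- rotation_about(axis, asym$misalign_rot_deg)
      tdir <- stats::rnorm(3)
      tdir <- tdir / sqrt(sum(tdir^2))
      ctr <- colMeans(left$vertices)
      tf <- rigid_transform(R, ctr - as.numeric(R %*% ctr) +
                              asym$misalign_trans_mm * tdir)
      left <- apply_rigid(left, tf)
    }
    if (asym$noise_sd > 0) {
      right$vertices <- right$vertices +
        matrix(stats::rnorm(length(right$vertices), sd = asym$noise_sd),
               ncol = 3L)
      left$vertices <- left$vertices +
        matrix(stats::rnorm(length(left$vertices), sd = asym$noise_sd),
               ncol = 3L)
    }
    if (isTRUE(asym$loose_fragment)) {
      n <- vertex_normals(right)
      k <- sample.int(nrow(right$vertices), 1L)
      frag <- icosphere(1L)
      nvr <- nrow(right$vertices)
      frag$vertices <- frag$vertices * 4 +
        rep(right$vertices[k, ] + 8 * n[k, ], each = nrow(frag$vertices))
      right <- structure(list(
        vertices = rbind(right$vertices, frag$vertices),
        faces = rbind(right$faces, frag$faces + nvr),
        scalars = NULL), class = "triangle_mesh")
    }
    list(left = left, right = right)
  })
  list(left = res$left, right = res$right, truth = truth)
}

#' Evaluate an asymmetry truth on another mesh
#'
#' Recomputes the analytic injected-displacement magnitude at the vertices of
#' `mesh`, optionally mapping the stored bump anchors through the rigid
#' transform that carried the right mesh into the analysis frame. Used to
#' compare pipeline output (which lives on the remeshed, aligned, trimmed
#' right mesh) against the ground truth.
#'
#' @param truth an `asymmetry_truth` from [make_pair()].
#' @param mesh the target `triangle_mesh`.
#' @param transform optional `rigid_transform` mapping the original right
#'   frame into `mesh`'s frame.
#' @return an `asymmetry_truth` on `mesh`'s vertices.
#' @export
truth_on_mesh <- function(truth, mesh, transform = NULL) {
  stopifnot(inherits(truth, "asymmetry_truth"))
  stopifnot_mesh(mesh)
  disp <- numeric(nrow(mesh$vertices))
  regions <- list()
  bumps <- truth$bumps
  if (!is.null(bumps) && nrow(bumps) > 0L) {
    anchors <- as.matrix(bumps[, c("x", "y", "z")])
    if (!is.null(transform)) anchors <- apply_rigid(anchors, transform)
    for (b in seq_len(nrow(bumps))) {
      d2 <- colSums((t(mesh$vertices) - anchors[b, ])^2)
      disp <- disp + bumps$sign[b] * bumps$amplitude[b] *
        exp(-d2 / (2 * bumps$radius[b]^2))
      regions[[b]] <- which(d2 <= (2 * bumps$radius[b])^2)
    }
    bumps$x <- anchors[, 1]; bumps$y <- anchors[, 2]; bumps$z <- anchors[, 3]
  }
  structure(list(displacement = abs(disp), regions = regions, bumps = bumps),
            class = "asymmetry_truth")
}

#' Score recovery of injected asymmetry
#'
#' Compares measured correspondence-point distances against the analytic
#' ground truth on the same mesh: per bump, the maximum measured CP distance
#' inside the bump region versus the injected amplitude, and the median CP
#' distance over included vertices outside all bump regions.
#'
#' @param cs a `correspondence_set` (or plain numeric vector of distances).
#' @param truth an `asymmetry_truth` on the same mesh.
#' @return a `recovery_report` list: per-bump data frame (`amplitude`,
#'   `measured_max`, `relative_error`) and `off_region_median` (mm).
#' @export
score_recovery <- function(cs, truth) {
  stopifnot(inherits(truth, "asymmetry_truth"))
  if (inherits(cs, "correspondence_set")) {
    d <- cs$distances
    inc <- cs$included
  } else {
    d <- as.numeric(cs)
    inc <- rep(TRUE, length(d))
  }
  if (length(d) != length(truth$displacement)) {
    stop("correspondence set and truth are on different meshes (",
         length(d), " vs ", length(truth$displacement), " vertices)")
  }
  bumps <- truth$bumps
  per_bump <- NULL
  in_region <- rep(FALSE, length(d))
  if (!is.null(bumps) && nrow(bumps) > 0L) {
    per_bump <- data.frame(amplitude = bumps$amplitude,
                           measured_max = NA_real_,
                           relative_error = NA_real_)
    for (b in seq_len(nrow(bumps))) {
      idx <- intersect(truth$regions[[b]], which(inc))
      in_region[truth$regions[[b]]] <- TRUE
      if (length(idx)) {
        mx <- max(d[idx])
        per_bump$measured_max[b] <- mx
        per_bump$relative_error[b] <-
          (mx - bumps$amplitude[b]) / bumps$amplitude[b]
      }
    }
  }
  off <- d[inc & !in_region]
  structure(list(per_bump = per_bump,
                 off_region_median = if (length(off)) stats::median(off)
                                     else NA_real_),
            class = "recovery_report")
}

#' Write a ready-to-run synthetic cohort
#'
#' Emits left/right STL meshes and a manifest compatible with [run_cohort()],
#' organised as three groups of increasing injected asymmetry that mirror a
#' no / low-grade / high-grade structure: `none` (no bumps), `low` (1-2 mm
#' bumps) and `high` (2-4 mm bumps, plus a loose fragment near the patella).
#' Fully deterministic for a given seed.
#'
#' @param out_dir output directory (created if needed).
#' @param n_per_group subjects per group.
#' @param seed integer master seed.
#' @param bones which bone types to generate per subject.
#' @param noise_sd vertex noise (mm) applied to every pair.
#' @return the manifest path, invisibly; the manifest has one row per
#'   subject-bone pair: `subject_id`, `bone`, `left_path`, `right_path`,
#'   `group`.
#' @export
write_fixture_cohort <- function(out_dir, n_per_group = 2L, seed = 1L,
                                 bones = c("femur", "patella", "tibia"),
                                 noise_sd = 0.3) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  groups <- c("none", "low", "high")
  rows <- list()
  subject <- 0L
  for (gi in seq_along(groups)) {
    for (si in seq_len(n_per_group)) {
      subject <- subject + 1L
      sid <- sprintf("S%03d", subject)
      for (bone in bones) {
        pair_seed <- (seed * 1009L + subject * 17L +
                        match(bone, c("femur", "patella", "tibia"))) %%
          2147483647L
        base <- make_surrogate(surrogate_spec(bone, seed = pair_seed))
        asym <- fixture_asymmetry(groups[gi], bone, base, noise_sd, pair_seed)
        pr <- make_pair(base, asym, seed = pair_seed)
        lp <- file.path(out_dir, sprintf("%s_%s_left.stl", sid, bone))
        rp <- file.path(out_dir, sprintf("%s_%s_right.stl", sid, bone))
        write_mesh(pr$left, lp, format = "stl")
        write_mesh(pr$right, rp, format = "stl")
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, bone = bone, left_path = basename(lp),
          right_path = basename(rp), group = groups[gi])
      }
    }
  }
  manifest <- do.call(rbind, rows)
  mpath <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  invisible(mpath)
}

# group-specific injected asymmetry used by the fixture cohort
fixture_asymmetry <- function(group, bone, base, noise_sd, seed) {
  mis_rot <- 10
  mis_trans <- 6
  if (group == "none") {
    return(asymmetry_spec(noise_sd = noise_sd, misalign_rot_deg = mis_rot,
                          misalign_trans_mm = mis_trans))
  }
  amp_range <- if (group == "low") c(1, 2) else c(2, 4)
  nb <- 2L
  bumps <- with_local_seed(seed + 7L, {
    cand <- joint_side_vertices(base, bone)
    idx <- sample(cand, nb)
    data.frame(
      x = base$vertices[idx, 1], y = base$vertices[idx, 2],
      z = base$vertices[idx, 3],
      amplitude = stats::runif(nb, amp_range[1], amp_range[2]),
      radius = stats::runif(nb, 6, 10),
      sign = sample(c(-1, 1), nb, replace = TRUE))
  })
  asymmetry_spec(bumps = bumps, noise_sd = noise_sd,
                 misalign_rot_deg = mis_rot, misalign_trans_mm = mis_trans,
                 loose_fragment = group == "high" && bone == "patella")
}

# vertices on the joint-side 35% of the long axis (any vertex for patellae)
joint_side_vertices <- function(base, bone) {
  z <- base$vertices[, 3]
  zr <- range(z)
  cut <- 0.35 * diff(zr)
  sel <- switch(bone,
                femur = which(z <= zr[1] + cut),
                tibia = which(z >= zr[2] - cut),
                patella = seq_along(z))
  if (length(sel) < 5L) seq_along(z) else sel
}
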