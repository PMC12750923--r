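#' Align a bone mesh to the global coordinate frame
#'
#' The global frame puts the proximal-distal direction on +Z and the
#' medial-lateral direction on +X. Sufficiently elongated meshes (first to
#' second principal-extent ratio >= 1.3) are aligned by principal axes, with
#' the Z sign disambiguated so the joint end — identified as the wider end by
#' radial cross-sectional spread — points to the joint side of the bone
#' convention (femur joint end distal at -Z, tibia joint end proximal at +Z).
#' Compact meshes (patella, very short fragments) are aligned by rigid CPD
#' onto a pre-aligned reference model.
#'
#' @param mesh a `triangle_mesh`.
#' @param bone `"femur"`, `"patella"` or `"tibia"`.
#' @param reference optional pre-aligned reference `triangle_mesh`, required
#'   when the principal axes are ambiguous.
#' @param params CPD settings for the reference registration path.
#' @return list with `mesh` (aligned), `transform` (the `rigid_transform`
#'   that was applied) and `method` (`"principal-axes"` or
#'   `"reference-model"`).
#' @export
align_to_global <- function(mesh, bone = c("femur", "tibia", "patella"),
                            reference = NULL, params = cpd_params()) {
  stopifnot_mesh(mesh)
  bone <- match.arg(bone)
  v <- mesh$vertices
  ctr <- colMeans(v)
  vc <- sweep(v, 2, ctr)
  eg <- eigen(stats::cov(vc), symmetric = TRUE)
  ax <- eg$vectors
  extents <- apply(vc %*% ax, 2, function(p) diff(range(p)))
  ratio <- extents[1] / extents[2]
  if (ratio < 1.3) {
    if (is.null(reference)) {
      stop("principal axes are ambiguous (extent ratio ",
           sprintf("%.2f", ratio), " < 1.3); supply a pre-aligned ",
           "reference mesh for registration-based alignment")
    }
    reg <- rigid_cpd(mesh, reference, params)
    return(list(mesh = apply_rigid(mesh, reg$transform),
                transform = reg$transform, method = "reference-model"))
  }
  zdir <- ax[, 1]
  xdir <- ax[, 2]
  R <- rbind(xdir, cross3(zdir, xdir), zdir)  # right-handed by construction
  rownames(R) <- NULL
  aligned <- vc %*% t(R)
  # joint end = wider end by RMS radial spread of the outer 25% z-slabs
  z <- aligned[, 3]
  zr <- range(z)
  slab <- 0.25 * diff(zr)
  lo <- z <= zr[1] + slab
  hi <- z >= zr[2] - slab
  spread <- function(sel) {
    sqrt(mean(aligned[sel, 1]^2 + aligned[sel, 2]^2))
  }
  joint_at_top <- spread(hi) > spread(lo)
  want_top <- bone == "tibia"   # tibia joint end proximal (+Z), femur distal (-Z)
  if (joint_at_top != want_top) {
    flip <- diag(c(1, -1, -1))  # rotate 180 degrees about X
    R <- flip %*% R
    aligned <- aligned %*% t(flip)
  }
  # fix the medial-lateral sign deterministically: positive third moment in X
  if (sum(aligned[, 1]^3) < 0) {
    flip <- diag(c(-1, -1, 1))  # rotate 180 degrees about Z
    R <- flip %*% R
    aligned <- aligned %*% t(flip)
  }
  tf <- rigid_transform(R, -as.numeric(R %*% ctr))
  out <- mesh
  out$vertices <- aligned
  list(mesh = out, transform = tf, method = "principal-axes")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Compute the trim specification for an aligned bone
#'
#' The kept model height equals the medial-lateral (X) range of the surface;
#' when the available proximal-distal extent is shorter than that, the height
#' falls back to the available extent minus 5 mm (short-bone rule). The femur
#' keeps its distal portion, the tibia its proximal portion; the patella is
#' never trimmed.
#'
#' @param aligned_mesh a `triangle_mesh` in the global frame.
#' @param bone `"femur"`, `"patella"` or `"tibia"`.
#' @return a `trim_spec`: bone, `keep_end` (`"distal"`, `"proximal"` or
#'   `"none"`), `target_height` (mm), `cut_plane_z` (mm, global frame) and a
#'   `short_bone` flag.
#' @export
compute_trim_spec <- function(aligned_mesh, bone = c("femur", "tibia",
                                                     "patella")) {
  stopifnot_mesh(aligned_mesh)
  bone <- match.arg(bone)
  if (bone == "patella") {
    return(structure(list(bone = bone, keep_end = "none",
                          target_height = NA_real_, cut_plane_z = NA_real_,
                          short_bone = FALSE), class = "trim_spec"))
  }
  v <- aligned_mesh$vertices
  ml <- diff(range(v[, 1]))
  zr <- range(v[, 3])
  avail <- diff(zr)
  short <- avail < ml
  target <- if (short) avail - 5 else ml
  if (target <= 0) {
    stop("available proximal-distal extent (", sprintf("%.1f", avail),
         " mm) too small to trim")
  }
  keep_end <- if (bone == "femur") "distal" else "proximal"
  cut_z <- if (keep_end == "distal") zr[1] + target else zr[2] - target
  structure(list(bone = bone, keep_end = keep_end, target_height = target,
                 cut_plane_z = cut_z, short_bone = short),
            class = "trim_spec")
}

#' Cut a mesh at a global z-plane
#'
#' Triangles crossing the plane are clipped by edge-plane intersection so the
#' cut is exactly planar; vertices beyond the plane are removed.
#'
#' @param mesh a `triangle_mesh`.
#' @param z cut-plane height (mm, global frame).
#' @param keep `"below"` keeps vertices with `z_v <= z`, `"above"` the rest.
#' @return the clipped `triangle_mesh`.
#' @export
clip_mesh <- function(mesh, z, keep = c("below", "above")) {
  stopifnot_mesh(mesh)
  keep <- match.arg(keep)
  v <- mesh$vertices
  s <- if (keep == "below") z - v[, 3] else v[, 3] - z
  inside <- s >= 0
  f <- mesh$faces
  nin <- inside[f[, 1]] + inside[f[, 2]] + inside[f[, 3]]
  keep_f <- f[nin == 3L, , drop = FALSE]
  cross_f <- f[nin == 1L | nin == 2L, , drop = FALSE]
  cross_n <- nin[nin == 1L | nin == 2L]
  if (nrow(cross_f) == 0L) {
    out <- triangle_mesh(v, keep_f, merge_duplicates = FALSE)
    return(drop_unreferenced(out))
  }
  # unique crossing edges -> intersection vertices
  ea <- c(cross_f[, 1], cross_f[, 2], cross_f[, 3])
  eb <- c(cross_f[, 2], cross_f[, 3], cross_f[, 1])
  crossing <- inside[ea] != inside[eb]
  lo <- pmin(ea, eb)[crossing]
  hi <- pmax(ea, eb)[crossing]
  code <- as.numeric(lo) * (nrow(v) + 1) + hi
  uc <- !duplicated(code)
  ulo <- lo[uc]; uhi <- hi[uc]; ucode <- code[uc]
  tpar <- s[ulo] / (s[ulo] - s[uhi])
  ipts <- v[ulo, , drop = FALSE] +
    tpar * (v[uhi, , drop = FALSE] - v[ulo, , drop = FALSE])
  ipts[, 3] <- z   # exact by construction
  new_idx <- nrow(v) + seq_len(nrow(ipts))
  v2 <- rbind(v, ipts)
  edge_vertex <- function(p, q) {
    cd <- as.numeric(pmin(p, q)) * (nrow(v) + 1) + pmax(p, q)
    new_idx[match(cd, ucode)]
  }
  new_faces <- NULL
  # rotate each crossing face so pattern is canonical
  rot <- function(fc, k) {
    if (k == 0) fc else if (k == 1) fc[, c(2, 3, 1), drop = FALSE] else
      fc[, c(3, 1, 2), drop = FALSE]
  }
  fc2 <- cross_f[cross_n == 2L, , drop = FALSE]
  if (nrow(fc2)) {
    # rotate so the dropped vertex is third: (p, q, d)
    dpos <- max.col(matrix(!inside[fc2], ncol = 3L), ties.method = "first")
    fr <- fc2
    for (k in 1:2) {
      sel <- dpos == k
      fr[sel, ] <- rot(fc2[sel, , drop = FALSE], k)
    }
    p <- fr[, 1]; q <- fr[, 2]; d <- fr[, 3]
    i1 <- edge_vertex(q, d)
    i2 <- edge_vertex(d, p)
    new_faces <- rbind(new_faces, cbind(p, q, i1), cbind(p, i1, i2))
  }
  fc1 <- cross_f[cross_n == 1L, , drop = FALSE]
  if (nrow(fc1)) {
    kpos <- max.col(matrix(inside[fc1], ncol = 3L), ties.method = "first")
    fr <- fc1
    for (k in 1:2) {
      sel <- kpos == (k + 1L)
      fr[sel, ] <- rot(fc1[sel, , drop = FALSE], k)
    }
    p <- fr[, 1]; d1 <- fr[, 2]; d2 <- fr[, 3]
    i1 <- edge_vertex(p, d1)
    i2 <- edge_vertex(d2, p)
    new_faces <- rbind(new_faces, cbind(p, i1, i2))
  }
  all_f <- rbind(keep_f, new_faces)
  storage.mode(all_f) <- "integer"
  drop_unreferenced(triangle_mesh(v2, all_f))
}

drop_unreferenced <- function(mesh) {
  used <- sort(unique(as.vector(mesh$faces)))
  if (length(used) == nrow(mesh$vertices)) return(mesh)
  subset_mesh(mesh, used)
}

#' Iterative trim-and-register of a mirrored pair
#'
#' Two iterations (by default) of: trim both meshes at the cut plane derived
#' from the fixed right-side mesh, then refine the rigid registration of the
#' trimmed mirrored-left mesh onto the trimmed right mesh. The trim height is
#' computed once from the right mesh (medial-lateral range, or available
#' height minus 5 mm for short bones) so the plane is stable across
#' iterations; each iteration re-cuts the pristine left mesh under its
#' refined pose, which is what makes the final cuts straight and symmetrical.
#' Patellae pass through untrimmed.
#'
#' @param left_mirrored mirrored, globally aligned, rigidly pre-registered
#'   left `triangle_mesh`.
#' @param right globally aligned right `triangle_mesh` (the fixed side).
#' @param bone `"femur"`, `"patella"` or `"tibia"`.
#' @param params CPD settings for the rigid refinements.
#' @param n_iterations trim/register iterations.
#' @return list with `left` and `right` trimmed meshes, `spec` (the
#'   `trim_spec`), `transform` (total rigid refinement applied to the left
#'   mesh), and `history`: one row per iteration with the refinement rotation
#'   angle (degrees), translation norm (mm) and `plane_shift` -- the maximum
#'   over left-mesh vertices of the change in perpendicular distance to the
#'   cut plane relative to the previous iteration (mm), i.e. how far the cut
#'   plane moved across the bone between successive iterations.
#' @export
iterative_trim_register <- function(left_mirrored, right,
                                    bone = c("femur", "tibia", "patella"),
                                    params = cpd_params(),
                                    n_iterations = 2L) {
  stopifnot_mesh(left_mirrored)
  stopifnot_mesh(right)
  bone <- match.arg(bone)
  spec <- compute_trim_spec(right, bone)
  if (bone == "patella") {
    return(list(left = left_mirrored, right = right, spec = spec,
                transform = rigid_transform(),
                history = data.frame(iteration = integer(0),
                                     rotation_deg = numeric(0),
                                     translation_mm = numeric(0),
                                     plane_shift = numeric(0))))
  }
  keep <- if (spec$keep_end == "distal") "below" else "above"
  right_trim <- clip_mesh(right, spec$cut_plane_z, keep = keep)
  check_trim_fraction(right, right_trim, "right")
  total <- rigid_transform()
  left_trim <- NULL
  # perpendicular distance of each (untransformed) left vertex to the cut
  # plane under pose `total`: z-component of the transformed vertex minus the
  # plane height
  plane_dist <- function(total) {
    apply_rigid(left_mirrored$vertices, total)[, 3] - spec$cut_plane_z
  }
  prev_dist <- plane_dist(total)
  history <- data.frame(iteration = seq_len(n_iterations),
                        rotation_deg = NA_real_, translation_mm = NA_real_,
                        plane_shift = NA_real_)
  for (it in seq_len(n_iterations)) {
    left_cur <- apply_rigid(left_mirrored, total)
    left_trim <- clip_mesh(left_cur, spec$cut_plane_z, keep = keep)
    check_trim_fraction(left_mirrored, left_trim, "left")
    reg <- rigid_cpd(left_trim, right_trim, params)
    total <- compose_rigid(reg$transform, total)
    cur_dist <- plane_dist(total)
    history$rotation_deg[it] <-
      rotation_angle_between(reg$transform$R, diag(3))
    history$translation_mm[it] <- sqrt(sum(reg$transform$t^2))
    history$plane_shift[it] <- max(abs(cur_dist - prev_dist))
    prev_dist <- cur_dist
  }
  left_trim <- clip_mesh(apply_rigid(left_mirrored, total),
                         spec$cut_plane_z, keep = keep)
  list(left = left_trim, right = right_trim, spec = spec, transform = total,
       history = history)
}

check_trim_fraction <- function(full, trimmed, label) {
  frac <- nrow(trimmed$vertices) / nrow(full$vertices)
  if (frac < 0.25) {
    stop("trimming removed more than 75% of the ", label,
         " mesh; registration or alignment is suspect")
  }
  invisible(frac)
}

#' Cut-plane exclusion mask
#'
#' Marks the vertices that enter the symmetry statistics: a vertex is
#' included iff its perpendicular distance to every cut plane is at least
#' `margin` (inclusive comparison, so a vertex exactly at the margin is
#' kept). This absorbs artificial asymmetries from residual trimming
#' differences. Patellae have no cut plane, so all vertices are included.
#'
#' @param mesh the trimmed `triangle_mesh` (global frame).
#' @param spec the `trim_spec` used for trimming.
#' @param margin exclusion margin in mm.
#' @return an `exclusion_mask`: logical `include` per vertex, `margin`, and
#'   the cut-plane z values.
#' @export
exclusion_mask <- function(mesh, spec, margin = 2.0) {
  stopifnot_mesh(mesh)
  stopifnot(inherits(spec, "trim_spec"))
  planes <- if (spec$keep_end == "none") numeric(0) else spec$cut_plane_z
  include <- rep(TRUE, nrow(mesh$vertices))
  for (p in planes) {
    include <- include & abs(mesh$vertices[, 3] - p) >= margin
  }
  if (mean(include) < 0.5) {
    stop("exclusion mask would retain fewer than 50% of vertices")
  }
  structure(list(include = include, margin = margin, cut_planes = planes),
            class = "exclusion_mask")
}

#' Serialise trim and alignment results to JSON
#' @param x a `trim_spec` or a list containing one plus transforms.
#' @param path output JSON path.
#' @export
write_trim_report <- function(x, path) {
  jsonlite::write_json(unclass_recursive(x), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

unclass_recursive <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), unclass_recursive)
  } else if (is.matrix(x)) {
    apply(x, 1, function(r) as.numeric(r), simplify = FALSE)
  } else {
    x
  }
}
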