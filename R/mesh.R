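#' Construct a triangle mesh
#'
#' The package's universal surface representation: an `n x 3` matrix of vertex
#' coordinates in millimetres plus an `m x 3` integer matrix of 1-based vertex
#' indices. On construction duplicate vertices are merged (coordinates equal
#' within 1e-6 mm) and degenerate (zero-area) faces are dropped, so downstream
#' code can rely on a clean index set.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param scalars optional numeric vector with one value per vertex (mm), used
#'   for correspondence-distance heatmaps.
#' @param merge_duplicates merge vertices whose coordinates agree within
#'   1e-6 mm (default `TRUE`).
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, scalars = NULL,
                          merge_duplicates = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  if (nrow(vertices) == 0L) stop("mesh has no vertices")
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (anyNA(vertices) || anyNA(faces)) stop("mesh contains NA values")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range")
  }
  if (!is.null(scalars)) {
    scalars <- as.numeric(scalars)
    if (length(scalars) != nrow(vertices)) {
      stop("scalars must have one value per vertex")
    }
  }
  if (merge_duplicates) {
    key <- paste(round(vertices[, 1] * 1e6), round(vertices[, 2] * 1e6),
                 round(vertices[, 3] * 1e6))
    first <- !duplicated(key)
    if (!all(first)) {
      map <- match(key, key[first])
      vertices <- vertices[first, , drop = FALSE]
      if (!is.null(scalars)) scalars <- scalars[first]
      if (nrow(faces) > 0L) {
        faces <- matrix(map[faces], ncol = 3L)
        storage.mode(faces) <- "integer"
      }
    }
  }
  if (nrow(faces) > 0L) {
    areas <- face_areas(vertices, faces)
    distinct <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] &
      faces[, 1] != faces[, 3]
    keep <- distinct & areas > 1e-12
    faces <- faces[keep, , drop = FALSE]
  }
  structure(list(vertices = vertices, faces = faces, scalars = scalars),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  ext <- apply(x$vertices, 2, function(v) diff(range(v)))
  cat(sprintf(
    "triangle_mesh: %d vertices, %d faces, extent %.1f x %.1f x %.1f mm%s\n",
    nrow(x$vertices), nrow(x$faces), ext[1], ext[2], ext[3],
    if (!is.null(x$scalars)) ", with per-vertex scalars" else ""))
  invisible(x)
}

is_triangle_mesh <- function(x) inherits(x, "triangle_mesh")

stopifnot_mesh <- function(mesh) {
  if (!is_triangle_mesh(mesh)) stop("expected a triangle_mesh")
  invisible(mesh)
}

face_areas <- function(vertices, faces) {
  if (nrow(faces) == 0L) return(numeric(0))
  a <- vertices[faces[, 1], , drop = FALSE]
  u <- vertices[faces[, 2], , drop = FALSE] - a
  v <- vertices[faces[, 3], , drop = FALSE] - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Total surface area of a mesh (mm^2)
#' @param mesh a `triangle_mesh`.
#' @export
surface_area <- function(mesh) {
  stopifnot_mesh(mesh)
  sum(face_areas(mesh$vertices, mesh$faces))
}

#' Signed enclosed volume of a closed mesh (mm^3)
#'
#' Divergence-theorem sum of signed tetrahedron volumes; positive for
#' consistently outward-wound closed surfaces.
#' @param mesh a `triangle_mesh`.
#' @export
mesh_volume <- function(mesh) {
  stopifnot_mesh(mesh)
  f <- mesh$faces
  if (nrow(f) == 0L) return(0)
  a <- mesh$vertices[f[, 1], , drop = FALSE]
  b <- mesh$vertices[f[, 2], , drop = FALSE]
  c <- mesh$vertices[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) +
      a[, 2] * (b[, 3] * c[, 1] - b[, 1] * c[, 3]) +
      a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
}

# Undirected edge table with the (up to two) adjacent faces of every edge.
# Columns: a, b (a < b), fa/ca = face containing the directed edge a->b and
# its opposite vertex, fb/cb = same for b->a (NA on boundaries), count.
edge_table <- function(faces, nv) {
  nf <- nrow(faces)
  va <- c(faces[, 1], faces[, 2], faces[, 3])
  vb <- c(faces[, 2], faces[, 3], faces[, 1])
  opp <- c(faces[, 3], faces[, 1], faces[, 2])
  fid <- rep.int(seq_len(nf), 3L)
  lo <- pmin(va, vb)
  hi <- pmax(va, vb)
  code <- as.numeric(lo) * (nv + 1) + hi
  ord <- order(code)
  code_o <- code[ord]
  runs <- rle(code_o)
  n_edges <- length(runs$values)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  first <- ord[starts]
  second <- rep(NA_integer_, n_edges)
  second[runs$lengths >= 2L] <- ord[starts[runs$lengths >= 2L] + 1L]
  forward <- va[first] < vb[first]   # does the first entry carry a->b?
  a <- lo[first]
  b <- hi[first]
  fa <- ifelse(forward, fid[first], NA_integer_)
  ca <- ifelse(forward, opp[first], NA_integer_)
  fb <- ifelse(forward, NA_integer_, fid[first])
  cb <- ifelse(forward, NA_integer_, opp[first])
  has2 <- !is.na(second)
  fwd2 <- rep(NA, n_edges)
  fwd2[has2] <- va[second[has2]] < vb[second[has2]]
  idx <- which(has2 & fwd2)
  fa[idx] <- fid[second[idx]]
  ca[idx] <- opp[second[idx]]
  idx <- which(has2 & !fwd2)
  fb[idx] <- fid[second[idx]]
  cb[idx] <- opp[second[idx]]
  list(a = a, b = b, fa = fa, ca = ca, fb = fb, cb = cb,
       count = runs$lengths, code = runs$values)
}

edge_lengths_of <- function(vertices, a, b) {
  d <- vertices[a, , drop = FALSE] - vertices[b, , drop = FALSE]
  sqrt(rowSums(d^2))
}

#' Summary statistics of a mesh
#'
#' @param mesh a `triangle_mesh`.
#' @return a `mesh_stats` list: vertex/face counts, mean and median edge
#'   length (mm), axis-aligned bounding-box extents (mm), connected-component
#'   count, and a watertight flag (every edge shared by exactly two faces).
#' @export
mesh_stats <- function(mesh) {
  stopifnot_mesh(mesh)
  nv <- nrow(mesh$vertices)
  et <- edge_table(mesh$faces, nv)
  len <- edge_lengths_of(mesh$vertices, et$a, et$b)
  comp <- vertex_components(mesh)
  structure(list(
    n_vertices = nv,
    n_faces = nrow(mesh$faces),
    mean_edge = if (length(len)) mean(len) else NA_real_,
    median_edge = if (length(len)) stats::median(len) else NA_real_,
    extent = apply(mesh$vertices, 2, function(v) diff(range(v))),
    n_components = max(comp),
    watertight = length(et$count) > 0 && all(et$count == 2L)
  ), class = "mesh_stats")
}

#' @export
print.mesh_stats <- function(x, ...) {
  cat(sprintf(paste0(
    "mesh_stats: %d vertices, %d faces, median edge %.2f mm,\n",
    "  extent %.1f x %.1f x %.1f mm, %d component(s), watertight: %s\n"),
    x$n_vertices, x$n_faces, x$median_edge, x$extent[1], x$extent[2],
    x$extent[3], x$n_components, x$watertight))
  invisible(x)
}

# Connected-component label per vertex (isolated vertices get their own).
vertex_components <- function(mesh) {
  nv <- nrow(mesh$vertices)
  f <- mesh$faces
  if (nrow(f) == 0L) return(seq_len(nv))
  g <- igraph::graph_from_edgelist(
    cbind(c(f[, 1], f[, 2], f[, 3]), c(f[, 2], f[, 3], f[, 1])),
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nv - igraph::vcount(g)))
  igraph::components(g)$membership[seq_len(nv)]
}

#' Keep only the largest connected component
#'
#' Removes loose fragments (detached ossific bodies, segmentation debris),
#' keeping the component with the largest total surface area. Ties are broken
#' deterministically in favour of the component containing the lowest vertex
#' index. The number and total area of removed components is reported via
#' [message()].
#'
#' @param mesh a `triangle_mesh`.
#' @return the largest-area component as a `triangle_mesh`.
#' @export
largest_component <- function(mesh) {
  stopifnot_mesh(mesh)
  if (nrow(mesh$vertices) == 0L) stop("empty mesh")
  comp <- vertex_components(mesh)
  ncomp <- max(comp)
  if (ncomp == 1L) return(mesh)
  fcomp <- comp[mesh$faces[, 1]]
  areas <- face_areas(mesh$vertices, mesh$faces)
  comp_area <- vapply(seq_len(ncomp), function(k) sum(areas[fcomp == k]), 0)
  best <- comp_area >= max(comp_area) - 1e-9
  if (sum(best) > 1L) {
    lowest <- vapply(which(best), function(k) min(which(comp == k)), 0L)
    keep_comp <- which(best)[which.min(lowest)]
  } else {
    keep_comp <- which.max(comp_area)
  }
  message(sprintf(
    "largest_component: removed %d component(s), total area %.1f mm^2",
    ncomp - 1L, sum(comp_area[-keep_comp])))
  subset_mesh(mesh, comp == keep_comp)
}

# Keep the given vertices (logical or index) and all faces entirely inside.
subset_mesh <- function(mesh, keep) {
  if (is.logical(keep)) keep <- which(keep)
  map <- rep(NA_integer_, nrow(mesh$vertices))
  map[keep] <- seq_along(keep)
  f <- mesh$faces
  fkeep <- !is.na(map[f[, 1]]) & !is.na(map[f[, 2]]) & !is.na(map[f[, 3]])
  faces <- matrix(map[f[fkeep, , drop = FALSE]], ncol = 3L)
  triangle_mesh(mesh$vertices[keep, , drop = FALSE], faces,
                scalars = mesh$scalars[keep], merge_duplicates = FALSE)
}

#' Mirror a mesh in the sagittal plane
#'
#' Negates one coordinate for every vertex (default the first, the
#' medial-lateral axis in LPS/RAS-style patient frames) and flips face winding
#' so outward normal orientation is preserved. Applying the mirror twice
#' returns the original mesh exactly.
#'
#' @param mesh a `triangle_mesh`.
#' @param axis which coordinate to negate: `"x"`, `"y"` or `"z"`.
#' @return the mirrored `triangle_mesh`.
#' @export
mirror_sagittal <- function(mesh, axis = c("x", "y", "z")) {
  stopifnot_mesh(mesh)
  axis <- match.arg(axis)
  k <- match(axis, c("x", "y", "z"))
  v <- mesh$vertices
  v[, k] <- -v[, k]
  f <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  structure(list(vertices = v, faces = f, scalars = mesh$scalars),
            class = "triangle_mesh")
}

#' Symmetric vertex-to-surface Hausdorff distance (mm)
#'
#' Maximum over both directions of the distance from each vertex of one mesh
#' to the closest point on the other mesh's surface. A dense-sampling proxy
#' for the true surface Hausdorff distance.
#'
#' @param mesh_a,mesh_b `triangle_mesh` objects.
#' @export
hausdorff_distance <- function(mesh_a, mesh_b) {
  stopifnot_mesh(mesh_a)
  stopifnot_mesh(mesh_b)
  d_ab <- .closest_on_mesh(mesh_a$vertices, mesh_b$vertices,
                           mesh_b$faces - 1L)$distance
  d_ba <- .closest_on_mesh(mesh_b$vertices, mesh_a$vertices,
                           mesh_a$faces - 1L)$distance
  max(max(d_ab), max(d_ba))
}

#' Distance from points to a mesh surface, with footpoints
#'
#' @param points `n x 3` matrix of query points (mm).
#' @param mesh a `triangle_mesh`.
#' @return list with `distance` (n) and `point` (`n x 3` closest surface
#'   points).
#' @export
project_to_mesh <- function(points, mesh) {
  stopifnot_mesh(mesh)
  points <- as.matrix(points)
  res <- .closest_on_mesh(points, mesh$vertices, mesh$faces - 1L)
  res$distance <- as.numeric(res$distance)
  res
}
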