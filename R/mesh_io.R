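#' Read a triangle mesh from STL or PLY
#'
#' Supports binary and ASCII STL, and ASCII / binary little-endian PLY with
#' triangular faces. Coordinates are taken as millimetres; no unit metadata is
#' read. Duplicate vertices (within 1e-6 mm) are merged and degenerate faces
#' dropped on load. A PLY per-vertex property named `cp_distance` is loaded
#' into the mesh's scalar channel.
#'
#' @param path file path.
#' @param format `"stl"`, `"ply"`, or `"auto"` (from the file extension).
#' @return a `triangle_mesh`.
#' @export
read_mesh <- function(path, format = c("auto", "stl", "ply")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read mesh: no such file: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     stl = "stl", ply = "ply",
                     stop("cannot infer mesh format from extension: ", path))
  }
  mesh <- tryCatch(
    if (format == "stl") read_stl(path) else read_ply(path),
    error = function(e) {
      stop("failed to read ", format, " file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    })
  if (nrow(mesh$vertices) == 0L || nrow(mesh$faces) == 0L) {
    stop("mesh in '", path, "' is empty")
  }
  mesh
}

#' Write a triangle mesh to STL or PLY
#'
#' STL is written binary by default (`ascii = TRUE` for the text dialect); it
#' cannot carry per-vertex values, so a supplied scalar channel is dropped
#' with a warning. PLY stores scalars as a per-vertex float property named
#' `cp_distance`.
#'
#' @param mesh a `triangle_mesh`.
#' @param path output file path.
#' @param format `"stl"`, `"ply"`, or `"auto"` (from the file extension).
#' @param scalars optional per-vertex values (mm); defaults to the mesh's own
#'   scalar channel.
#' @param ascii write the ASCII dialect of the chosen format.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "stl", "ply"),
                       scalars = NULL, ascii = FALSE) {
  stopifnot_mesh(mesh)
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     stl = "stl", ply = "ply",
                     stop("cannot infer mesh format from extension: ", path))
  }
  if (is.null(scalars)) scalars <- mesh$scalars
  if (!is.null(scalars) && length(scalars) != nrow(mesh$vertices)) {
    stop("scalars must have one value per vertex")
  }
  ok <- tryCatch({
    if (format == "stl") {
      if (!is.null(scalars)) {
        warning("STL cannot store per-vertex scalars; channel dropped")
      }
      write_stl(mesh, path, ascii = ascii)
    } else {
      write_ply(mesh, path, scalars = scalars, ascii = ascii)
    }
    TRUE
  }, error = function(e) {
    stop("failed to write '", path, "': ", conditionMessage(e), call. = FALSE)
  })
  invisible(path)
}

# ---- STL ----------------------------------------------------------------

read_stl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = 80L)
  # ASCII files start with "solid" and contain no NUL in the head; binary
  # files may also start with "solid", so verify the declared triangle count.
  is_ascii <- identical(rawToChar(head[1:5]), "solid")
  ntri <- NULL
  if (is_ascii) {
    sz <- file.size(path)
    cand <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    if (length(cand) == 1L && !is.na(cand) && cand >= 0 &&
        sz == 84 + 50 * cand) {
      is_ascii <- FALSE
      ntri <- cand   # count already consumed; stream now sits at the body
    }
  }
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (length(vl) == 0L || length(vl) %% 3L != 0L) {
      stop("malformed ASCII STL")
    }
    nums <- t(vapply(strsplit(trimws(vl), "\\s+"),
                     function(x) as.numeric(x[2:4]), numeric(3)))
    v <- nums
  } else {
    if (is.null(ntri)) {
      seek(con, 80)
      ntri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    }
    raw <- readBin(con, "raw", n = 50L * ntri)
    if (length(raw) < 50L * ntri) stop("truncated binary STL")
    m <- matrix(raw, nrow = 50L)
    floats <- readBin(as.vector(m[1:48, ]), "numeric", size = 4L,
                      n = 12L * ntri, endian = "little")
    fm <- matrix(floats, nrow = 12L)   # normal xyz, v1, v2, v3
    v <- cbind(as.vector(fm[c(4, 7, 10), ]), as.vector(fm[c(5, 8, 11), ]),
               as.vector(fm[c(6, 9, 12), ]))
  }
  nv <- nrow(v)
  faces <- matrix(seq_len(nv), ncol = 3L, byrow = TRUE)
  triangle_mesh(v, faces)
}

write_stl <- function(mesh, path, ascii = FALSE) {
  f <- mesh$faces
  a <- mesh$vertices[f[, 1], , drop = FALSE]
  b <- mesh$vertices[f[, 2], , drop = FALSE]
  c_ <- mesh$vertices[f[, 3], , drop = FALSE]
  u <- b - a
  w <- c_ - a
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  nn <- sqrt(rowSums(n^2))
  nn[nn == 0] <- 1
  n <- n / nn
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid osteosym", con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(
        sprintf("  facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]),
        "    outer loop",
        sprintf("      vertex %.9g %.9g %.9g", a[i, 1], a[i, 2], a[i, 3]),
        sprintf("      vertex %.9g %.9g %.9g", b[i, 1], b[i, 2], b[i, 3]),
        sprintf("      vertex %.9g %.9g %.9g", c_[i, 1], c_[i, 2], c_[i, 3]),
        "    endloop",
        "  endfacet"), con)
    }
    writeLines("endsolid osteosym", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.raw(rep(0L, 80L)), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    tri <- rbind(t(n), t(a), t(b), t(c_))   # 12 x ntri
    for (i in seq_len(nrow(f))) {
      writeBin(tri[, i], con, size = 4L, endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  }
  invisible(path)
}

# ---- PLY ----------------------------------------------------------------

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_scalar <- function(raw, off, type) {
  sz <- ply_type_size[[type]]
  bytes <- raw[off + seq_len(sz)]
  if (type %in% c("float", "float32", "double", "float64")) {
    readBin(bytes, "numeric", size = sz, endian = "little")
  } else {
    readBin(bytes, "integer", size = sz, endian = "little",
            signed = !(sz <= 2 && grepl("^u", type)))
  }
}

read_ply <- function(path) {
  raw_all <- readBin(path, "raw", n = file.size(path))
  hdr_end <- grepRaw("end_header\r?\n", raw_all)
  if (length(hdr_end) == 0L) stop("unterminated PLY header")
  # header ends at the newline byte that terminates the end_header line
  nl <- which(raw_all[hdr_end:min(hdr_end + 12L, length(raw_all))] ==
                as.raw(0x0a))[1]
  if (is.na(nl)) stop("unterminated PLY header")
  hdr_len <- hdr_end + nl - 1L
  header <- strsplit(rawToChar(raw_all[seq_len(hdr_len)]), "\r?\n")[[1]]
  body_raw <- raw_all[(hdr_len + 1L):length(raw_all)]
  if (header[1] != "ply") stop("not a PLY file")
  fmt_line <- grep("^format ", header, value = TRUE)[1]
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian")) {
    stop("unsupported PLY format: ", fmt)
  }
  elements <- list()
  cur <- NULL
  for (line in header) {
    toks <- strsplit(trimws(line), "\\s+")[[1]]
    if (toks[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = toks[2], count = as.integer(toks[3]),
                  props = list())
    } else if (toks[1] == "property" && !is.null(cur)) {
      if (toks[2] == "list") {
        cur$props[[toks[5]]] <- list(list = TRUE, count_type = toks[3],
                                     type = toks[4])
      } else {
        cur$props[[toks[3]]] <- list(list = FALSE, type = toks[2])
      }
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  ve <- elements[["vertex"]]
  fe <- elements[["face"]]
  if (is.null(ve) || is.null(fe)) stop("PLY lacks vertex or face element")
  vprops <- names(ve$props)
  if (!all(c("x", "y", "z") %in% vprops)) stop("PLY vertex lacks x/y/z")
  if (fmt == "ascii") {
    body <- strsplit(rawToChar(body_raw), "\r?\n")[[1]]
    body <- body[nzchar(trimws(body))]
    vtok <- strsplit(trimws(body[seq_len(ve$count)]), "\\s+")
    vm <- t(vapply(vtok, function(x) as.numeric(x[seq_along(vprops)]),
                   numeric(length(vprops))))
    if (length(vprops) == 1L) vm <- matrix(vm, ncol = 1L)
    colnames(vm) <- vprops
    ftok <- strsplit(trimws(body[ve$count + seq_len(fe$count)]), "\\s+")
    faces <- t(vapply(ftok, function(x) {
      n <- as.integer(x[1])
      if (n != 3L) stop("only triangular PLY faces are supported")
      as.integer(x[2:4])
    }, integer(3)))
  } else {
    raw <- body_raw
    # vertex block: fixed stride
    sizes <- vapply(ve$props, function(p) ply_type_size[[p$type]], 0L)
    stride <- sum(sizes)
    offs <- c(0L, cumsum(sizes))[seq_along(sizes)]
    names(offs) <- vprops
    vm <- matrix(NA_real_, ve$count, length(vprops),
                 dimnames = list(NULL, vprops))
    base <- (seq_len(ve$count) - 1L) * stride
    for (p in vprops) {
      type <- ve$props[[p]]$type
      sz <- ply_type_size[[type]]
      idx <- as.vector(outer(seq_len(sz), base + offs[[p]], "+"))
      if (type %in% c("float", "float32", "double", "float64")) {
        vm[, p] <- readBin(raw[idx], "numeric", size = sz, n = ve$count,
                           endian = "little")
      } else {
        vm[, p] <- readBin(raw[idx], "integer", size = sz, n = ve$count,
                           endian = "little")
      }
    }
    fp <- fe$props[[1]]
    if (!fp$list) stop("PLY face element must be a list property")
    csz <- ply_type_size[[fp$count_type]]
    isz <- ply_type_size[[fp$type]]
    off <- as.integer(ve$count * stride)
    n0 <- ply_read_scalar(raw, off, fp$count_type)
    if (n0 != 3L) stop("only triangular PLY faces are supported")
    fstride <- csz + 3L * isz
    fbase <- off + (seq_len(fe$count) - 1L) * fstride
    counts <- vapply(fbase, function(o) ply_read_scalar(raw, o, fp$count_type),
                     0)
    if (any(counts != 3)) stop("only triangular PLY faces are supported")
    idx <- as.vector(outer(seq_len(3L * isz), fbase + csz, "+"))
    faces <- matrix(readBin(raw[idx], "integer", size = isz,
                            n = 3L * fe$count, endian = "little"),
                    ncol = 3L, byrow = TRUE)
  }
  scal <- if ("cp_distance" %in% vprops) unname(vm[, "cp_distance"]) else NULL
  triangle_mesh(unname(vm[, c("x", "y", "z"), drop = FALSE]), faces + 1L,
                scalars = scal)
}

write_ply <- function(mesh, path, scalars = NULL, ascii = FALSE) {
  v <- mesh$vertices
  f <- mesh$faces - 1L
  con <- file(path, if (ascii) "w" else "wb")
  on.exit(close(con))
  header <- c(
    "ply",
    sprintf("format %s 1.0",
            if (ascii) "ascii" else "binary_little_endian"),
    "comment osteosym bilateral symmetry pipeline",
    sprintf("element vertex %d", nrow(v)),
    "property double x", "property double y", "property double z",
    if (!is.null(scalars)) "property double cp_distance",
    sprintf("element face %d", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header")
  if (ascii) {
    writeLines(header, con)
    vm <- if (is.null(scalars)) v else cbind(v, scalars)
    writeLines(apply(vm, 1, function(r) paste(sprintf("%.17g", r),
                                              collapse = " ")), con)
    writeLines(paste(3L, f[, 1], f[, 2], f[, 3]), con)
  } else {
    writeLines(header, con, sep = "\n")
    vm <- if (is.null(scalars)) v else cbind(v, scalars)
    writeBin(as.vector(t(vm)), con, size = 8L, endian = "little")
    fr <- t(f)
    for (i in seq_len(ncol(fr))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(fr[, i]), con, size = 4L, endian = "little")
    }
  }
  invisible(path)
}
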