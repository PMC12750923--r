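test_that("binary and ascii STL round-trip geometry", {
  m <- surrogate_of("patella")
  for (ascii in c(FALSE, TRUE)) {
    path <- tempfile(fileext = ".stl")
    write_mesh(m, path, ascii = ascii)
    m2 <- read_mesh(path)
    expect_equal(nrow(m2$vertices), nrow(m$vertices))
    expect_equal(nrow(m2$faces), nrow(m$faces))
    expect_equal(surface_area(m2), surface_area(m),
                 tolerance = if (ascii) 1e-7 else 1e-6) # binary STL is float32
    unlink(path)
  }
})

test_that("binary and ascii PLY round-trip geometry and scalars exactly", {
  m <- surrogate_of("patella")
  sc <- seq_len(nrow(m$vertices)) * 0.01
  for (ascii in c(FALSE, TRUE)) {
    path <- tempfile(fileext = ".ply")
    write_mesh(m, path, scalars = sc, ascii = ascii)
    m2 <- read_mesh(path)
    expect_identical(m2$faces, m$faces)
    expect_equal(m2$vertices, m$vertices, tolerance = 1e-15)
    expect_equal(m2$scalars, sc, tolerance = 1e-15)
    unlink(path)
  }
})

test_that("write_mesh warns when STL would drop a scalar channel", {
  m <- surrogate_of("patella")
  path <- tempfile(fileext = ".stl")
  expect_warning(write_mesh(m, path, scalars = rep(1, nrow(m$vertices))),
                 "cannot store per-vertex scalars")
  unlink(path)
})

test_that("read_mesh rejects missing files, bad extensions and junk content", {
  expect_error(read_mesh(tempfile(fileext = ".stl")), "no such file")
  junk <- tempfile(fileext = ".xyz")
  writeLines("hello", junk)
  expect_error(read_mesh(junk), "cannot infer mesh format")
  bad <- tempfile(fileext = ".ply")
  writeLines(c("not", "a", "ply"), bad)
  expect_error(read_mesh(bad), "failed to read ply")
  unlink(c(junk, bad))
})

test_that("format sniffing handles binary STL that starts with 'solid'", {
  m <- surrogate_of("patella")
  path <- tempfile(fileext = ".stl")
  write_mesh(m, path)                 # binary
  raw <- readBin(path, "raw", n = file.size(path))
  raw[1:5] <- charToRaw("solid")      # adversarial header
  writeBin(raw, path)
  m2 <- read_mesh(path)
  expect_equal(nrow(m2$faces), nrow(m$faces))
  unlink(path)
})
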