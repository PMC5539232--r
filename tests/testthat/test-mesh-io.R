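# Round-trip and error behavior of the OFF / PLY / legacy-VTK readers.

test_that("write -> read round-trips preserve geometry and topology", {
  m <- make_icosphere(1)
  for (fmt in c("off", "ply", "vtk")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_mesh(m, path)
    m2 <- read_mesh(path)
    expect_identical(m2$faces, m$faces)
    expect_lt(max(abs(m2$vertices - m$vertices)), 1e-6)
    expect_true(m2$closed)
  }
})

test_that("format is inferred from the extension and can be forced", {
  m <- make_icosphere(0)
  path <- withr::local_tempfile(fileext = ".ply")
  write_mesh(m, path)
  expect_identical(read_mesh(path, format = "ply")$faces, m$faces)
  expect_error(read_mesh(path, format = "off"), "OFF header")
})

test_that("malformed files fail with a line-numbered message", {
  path <- withr::local_tempfile(fileext = ".off")
  writeLines(character(0), path)
  expect_error(read_mesh(path), ":1: empty file")

  # a quad face in an OFF file
  writeLines(c("OFF", "4 1 4",
               "0 0 0", "1 0 0", "1 1 0", "0 1 0",
               "4 0 1 2 3"), path)
  expect_error(read_mesh(path), "triangular")

  writeLines(c("OFF", "3 1 3", "0 0 0", "1 0 0"), path)
  expect_error(read_mesh(path), "truncated")

  writeLines(c("not a mesh"), path)
  expect_error(read_mesh(path), "OFF header")
})

test_that("on-disk indices are 0-based", {
  m <- make_patch(0.5)$mesh
  path <- withr::local_tempfile(fileext = ".off")
  write_mesh(m, path)
  lines <- readLines(path)
  face_lines <- utils::tail(lines, nrow(m$faces))
  idx <- as.integer(unlist(strsplit(face_lines, " "))[-seq(1, 24, by = 4)])
  expect_identical(min(idx), 0L)
})
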