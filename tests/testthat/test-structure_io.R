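test_that("read_pdb parses ATOM records and rejects malformed input", {
  path <- write_minimal_pdb(withr::local_tempfile(fileext = ".pdb"))
  s <- read_pdb(path)
  expect_s3_class(s, "allatom_structure")
  expect_equal(nrow(s$atoms), 5L)
  expect_equal(sum(s$atoms$elety == "CA"), 2L)
  expect_equal(s$atoms$x[2], 0)

  expect_error(read_pdb(file.path(tempdir(), "nope.pdb")), "not found")

  het <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00",
    "END"), het)
  expect_error(read_pdb(het), "no ATOM records")

  bad <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  ALA A   2       abc..   0.000   0.000  1.00  0.00",
    "END"), bad)
  expect_error(read_pdb(bad), "line\\(s\\) 2")
})

test_that("extract_calpha keeps one CA per amino-acid residue", {
  path <- write_minimal_pdb(withr::local_tempfile(fileext = ".pdb"))
  cg <- extract_calpha(read_pdb(path))
  expect_s3_class(cg, "cg_structure")
  expect_equal(nrow(cg$coords), 2L)
  expect_equal(unname(cg$coords[2, 1]), 3.8)
  expect_equal(cg$residue_ids, c(1L, 2L))
})

test_that("extract_calpha resolves altlocs by occupancy and flags missing CA", {
  alt <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  0.40  0.00",
    "ATOM      2  CA  ALA A   1       9.000   0.000   0.000  0.60  0.00",
    "ATOM      3  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00",
    "END"), alt)
  expect_warning(cg <- extract_calpha(read_pdb(alt)), "altloc")
  expect_equal(unname(cg$coords[1, 1]), 9)  # higher occupancy wins

  noca <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  N   GLY A   2       3.800   0.000   0.000  1.00  0.00",
    "ATOM      3  CA  ALA A   3       7.600   0.000   0.000  1.00  0.00",
    "END"), noca)
  expect_error(extract_calpha(read_pdb(noca)), "missing a CA.*2")

  # a CA-less non-amino residue is skipped, not fatal
  lig <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00",
    "ATOM      3  C1  LIG A   3       9.000   9.000   9.000  1.00  0.00",
    "END"), lig)
  expect_equal(nrow(extract_calpha(read_pdb(lig))$coords), 2L)
})

test_that("superpose recovers rigid transforms and the collinear optimum", {
  # identical structures
  a <- make_helix(12)
  expect_equal(superpose(a, a)$rmsd, 0)

  # rigidly transformed copy: rmsd 0 within 1e-8, for several transforms
  for (seed in 1:5) {
    b <- a
    b$coords <- rigid_transform(a$coords, seed)
    expect_lt(superpose(b, a)$rmsd, 1e-8)
  }

  # collinear 2-point case with a known optimum: segments centred, residual 1
  ref <- cg_structure(rbind(c(0, 0, 0), c(2, 0, 0)))
  mob <- cg_structure(rbind(c(0, 0, 0), c(4, 0, 0)))
  expect_equal(superpose(mob, ref)$rmsd, 1.0, tolerance = 1e-10)

  # symmetry after superposition
  x <- random_cloud(10, 1); y <- random_cloud(10, 2)
  expect_equal(rmsd_ca(x, y), rmsd_ca(y, x), tolerance = 1e-8)

  expect_error(superpose(make_extended(3), make_extended(4)), "mismatch")
})

test_that("rmsd is invariant under proper rigid transforms of mobile", {
  a <- random_cloud(15, 3)
  b <- random_cloud(15, 4)
  base <- rmsd_ca(a, b)
  for (seed in 11:15) {
    a2 <- a
    a2$coords <- rigid_transform(a$coords, seed)
    expect_equal(rmsd_ca(a2, b), base, tolerance = 1e-8)
  }
})

test_that("radius_of_gyration matches closed forms and is rigid-invariant", {
  two <- cg_structure(rbind(c(0, 0, 0), c(5, 0, 0)))
  expect_equal(radius_of_gyration(two), 2.5)

  sq <- cg_structure(rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(0, 2, 0)))
  expect_equal(radius_of_gyration(sq), sqrt(2))

  coincident <- cg_structure(matrix(1, 3, 3))
  expect_equal(radius_of_gyration(coincident), 0)

  s <- random_cloud(20, 5)
  s2 <- s
  s2$coords <- rigid_transform(s$coords, 6)
  expect_equal(radius_of_gyration(s2), radius_of_gyration(s),
               tolerance = 1e-10)
})

test_that("write_trajectory emits one MODEL per frame and round-trips", {
  frames <- list(make_extended(5), make_helix(5), random_cloud(5, 7))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory(frames, path)
  expect_equal(sum(grepl("^MODEL", readLines(path))), 3L)

  back <- read_trajectory(path)
  expect_length(back, 3L)
  for (k in 1:3)
    expect_equal(back[[k]]$coords, frames[[k]]$coords, tolerance = 2e-3,
                 ignore_attr = TRUE)

  expect_error(write_trajectory(list(), path), "empty")
  expect_error(write_trajectory(list(make_extended(3), make_extended(4)), path),
               "inconsistent")
})

test_that("cg_structure enforces its invariants", {
  expect_error(cg_structure(matrix(0, 1, 3)), "at least 2")
  expect_error(cg_structure(matrix(c(0, 0, 0, NA, 0, 0), 2, 3, byrow = TRUE)),
               "finite")
  expect_error(cg_structure(matrix(0, 3, 3), residue_ids = c(3, 2, 1)),
               "increasing")
})
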