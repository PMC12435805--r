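test_that("PDB and mmCIF parses of the same content agree field by field", {
  pdb <- read_structure(write_gly_pdb(tempfile(fileext = ".pdb")))
  cif <- read_structure(write_gly_cif(tempfile(fileext = ".cif")))
  expect_equal(nrow(pdb), 3)
  expect_equal(coords(pdb), gly_fixture_coords, ignore_attr = TRUE)
  ident <- c("chain", "resno", "insert", "resid", "elety", "element", "is_h")
  expect_identical(as.data.frame(pdb)[, ident], as.data.frame(cif)[, ident])
  expect_equal(coords(cif), coords(pdb), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("files without atoms raise the empty-structure error", {
  bad <- tempfile(fileext = ".pdb")
  writeLines(c("HEADER    TRUNCATED", "END"), bad)
  expect_error(read_structure(bad), "no atoms")
  expect_error(read_structure(tempfile(fileext = ".pdb")), "no such file")
})

test_that("alternate locations resolve to highest occupancy, first on tie", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CB ALYS A   2       1.000   2.000   3.000  0.40  0.00           C",
    "ATOM      2  CB BLYS A   2       1.100   2.100   3.100  0.60  0.00           C",
    "ATOM      3  CG ALYS A   2       5.000   5.000   5.000  0.50  0.00           C",
    "ATOM      4  CG BLYS A   2       6.000   6.000   6.000  0.50  0.00           C",
    "END"), f)
  a <- read_structure(f)
  expect_equal(nrow(a), 2)
  expect_equal(a$x[a$elety == "CB"], 1.1)   # higher occupancy wins
  expect_equal(a$x[a$elety == "CG"], 5.0)   # first listed wins the tie
  expect_true(all(a$alt == ""))
})

test_that("selection filters are conjunctive and tolerate empty results", {
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0), c(4, 0, 0))
  a <- atom_set(data.frame(chain = c("A", "A", "A", "B", "B"),
                           resno = c(1, 1, 2, 7, 8),
                           resid = c("GLY", "GLY", "HOH", "ALA", "ALA"),
                           elety = c("CA", "H", "O", "CA", "CA"),
                           element = c("C", "H", "O", "C", "C"),
                           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
  expect_equal(select_atoms(a, chain = "A")$resno, c(1, 1, 2))
  expect_equal(nrow(select_atoms(a, chain = "A", heavy_only = TRUE)), 2)
  # one water dropped by polymer_only (hand count: 4 polymer atoms)
  expect_equal(nrow(select_atoms(a, polymer_only = TRUE)), 4)
  expect_equal(nrow(select_atoms(a, chain = "B", residue_range = c(8, 8))), 1)
  expect_equal(nrow(select_atoms(a, chain = "Z")), 0)
  expect_error(select_atoms(a, residue_range = c(5, 1)), "interval")
})

test_that("centre of mass weights heavy atoms as documented", {
  a <- points_atom_set(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(center_of_mass(a), c(1, 0, 0))
  expect_equal(center_of_mass(a, "uniform"), c(1, 0, 0))
  # C at origin, O at (1,0,0): hand-computed mass-weighted mean
  co <- points_atom_set(rbind(c(0, 0, 0), c(1, 0, 0)), element = c("C", "O"))
  expect_equal(center_of_mass(co)[1], 15.999 / (12.011 + 15.999), tolerance = 1e-12)
  expect_equal(center_of_mass(co, "uniform")[1], 0.5)
  # hydrogens never contribute, under either weighting
  ch <- points_atom_set(rbind(c(0, 0, 0), c(9, 0, 0)), element = c("C", "H"))
  expect_equal(center_of_mass(ch, "uniform"), c(0, 0, 0))
  expect_error(center_of_mass(select_atoms(ch, heavy_only = TRUE)[0, ]), "heavy")
})

test_that("centre of mass is rigid-motion equivariant", {
  set.seed(42)
  for (rep in 1:5) {
    a <- points_atom_set(matrix(rnorm(30, sd = 5), ncol = 3),
                         element = sample(c("C", "N", "O", "S"), 10, TRUE))
    R <- random_rotation(); tr <- rnorm(3, sd = 10)
    tf <- rigid_transform(R, tr)
    lhs <- as.numeric(R %*% center_of_mass(a)) + tr
    rhs <- center_of_mass(apply_transform(a, tf))
    expect_equal(lhs, rhs, tolerance = 1e-9)
    expect_equal(center_of_mass(apply_transform(a, rigid_transform(diag(3), c(5, 5, 5)))),
                 center_of_mass(a) + 5, tolerance = 1e-12)
  }
})

test_that("write/read round trips preserve identity and coordinates", {
  gb <- make_toy_gb(11, n_res = 32)
  f_pdb <- tempfile(fileext = ".pdb"); f_cif <- tempfile(fileext = ".cif")
  write_structure(gb$atoms, f_pdb)
  write_structure(gb$atoms, f_cif)
  back_pdb <- read_structure(f_pdb)
  back_cif <- read_structure(f_cif)
  expect_equal(nrow(back_pdb), nrow(gb$atoms))
  expect_equal(coords(back_pdb), coords(gb$atoms), tolerance = 5e-4,
               ignore_attr = TRUE)  # PDB prints 3 decimals
  expect_equal(coords(back_cif), coords(gb$atoms), tolerance = 1e-6,
               ignore_attr = TRUE)
  ident <- c("chain", "resno", "resid", "elety")
  expect_identical(as.data.frame(back_pdb)[, ident],
                   as.data.frame(gb$atoms)[, ident])
  # transformed coordinates survive the round trip at format precision
  moved <- apply_transform(gb$atoms, rigid_transform(random_rotation(), c(1, 2, 3)))
  write_structure(moved, f_pdb)
  expect_equal(coords(read_structure(f_pdb)), coords(moved), tolerance = 5e-4,
               ignore_attr = TRUE)
})

test_that("wide chain ids are rejected for PDB but allowed in mmCIF", {
  a <- points_atom_set(rbind(c(0, 0, 0), c(1, 1, 1)), chain = "AB")
  expect_error(write_structure(a, tempfile(fileext = ".pdb")), "one character")
  f <- tempfile(fileext = ".cif")
  write_structure(a, f)
  expect_equal(unique(read_structure(f)$chain), "AB")
})

test_that("multi-model files use model 1 with a notice", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA  GLY A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  GLY A   1       9.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL", "END"), f)
  expect_message(a <- read_structure(f), "model 1")
  expect_equal(nrow(a), 1)
  expect_equal(a$x, 1)
})
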