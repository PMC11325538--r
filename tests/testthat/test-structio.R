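test_that("minimal PDB records parse to atoms and CONECT bonds", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1       2.500   2.000   3.000  1.00  0.00           C",
    "END"), path)
  s <- read_pdb(path)
  expect_equal(nrow(s), 2)
  expect_equal(s$serial, 1:2)
  expect_equal(s$x, c(1, 2.5))
  expect_equal(nrow(structure_bonds(s)), 0)

  writeLines(c(
    "HETATM    1  C1  LIG L   1       0.000   0.000   0.000  1.00  0.00           C",
    "HETATM    2  C2  LIG L   1       1.500   0.000   0.000  1.00  0.00           C",
    "CONECT    1    2",
    "END"), path)
  s2 <- read_pdb(path)
  expect_equal(unname(structure_bonds(s2)[1, ]), c(1L, 2L))
  expect_true(all(s2$role == "ligand"))
})

test_that("toy complex round-trips through PDB within format precision", {
  s <- make_toy_complex(seed = 4)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(s, path)
  s2 <- read_pdb(path, role_hints = c(LIG = "ligand"))
  expect_equal(nrow(s2), nrow(s))
  expect_equal(s2$serial, s$serial)
  expect_equal(s2$name, s$name)
  expect_equal(s2$x, s$x, tolerance = 1e-3)
  expect_equal(s2$y, s$y, tolerance = 1e-3)
  expect_equal(s2$z, s$z, tolerance = 1e-3)
  expect_equal(structure_bonds(s2), structure_bonds(s))
  expect_equal(s2$role, s$role)
})

test_that("read_pdb rejects missing and empty files", {
  expect_error(read_pdb(tempfile()), "no such file")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", path)
  expect_error(read_pdb(path))
})

test_that("bond perception follows covalent radii with tolerance", {
  s <- as_structure(atoms_at(c(0, 0, 0, 1.5, 0, 0)))
  expect_equal(nrow(structure_bonds(perceive_bonds(s, 0.4))), 1)
  far <- as_structure(atoms_at(c(0, 0, 0, 3.0, 0, 0)))
  expect_equal(nrow(structure_bonds(perceive_bonds(far, 0.4))), 0)

  unknown <- as_structure(atoms_at(c(0, 0, 0, 1.5, 0, 0),
                                   element = c("C", "XX")))
  expect_error(perceive_bonds(unknown), "XX")
})

test_that("perceived bonds match the exhaustive pairwise reference", {
  # ethane-like heavy+hydrogen toy: 7 bonds expected
  eth <- as_structure(atoms_at(rbind(
    c(0, 0, 0), c(1.54, 0, 0),
    c(-0.5, 0.9, 0), c(-0.5, -0.9, 0.3), c(-0.4, -0.3, -0.95),
    c(2.0, 0.9, 0), c(2.0, -0.9, 0.3), c(1.95, -0.3, -0.95)),
    element = c("C", "C", rep("H", 6))))
  got <- structure_bonds(perceive_bonds(eth))
  expect_equal(nrow(got), 7)
  expect_equal(got, abfekit:::normalize_bonds(brute_force_bonds(eth),
                                              eth$serial))

  for (seed in c(2, 9)) {
    s <- make_toy_complex(seed)
    attr(s, "bonds") <- abfekit:::normalize_bonds(NULL, s$serial)
    got <- structure_bonds(perceive_bonds(s, 0.4))
    expect_equal(got, abfekit:::normalize_bonds(brute_force_bonds(s),
                                                s$serial))
  }
})

test_that("superposition recovers identity and known rotations", {
  s <- make_toy_complex(seed = 1)
  sp <- superpose(s, s)
  expect_equal(sp$rotation, diag(3), tolerance = 1e-9)
  expect_equal(sp$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(sp$rmsd, 0, tolerance = 1e-9)

  rot90 <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)
  moved <- transform_structure(s, rot90, c(3, -2, 1))
  sp2 <- superpose(moved, s)
  expect_equal(sp2$rotation, t(rot90), tolerance = 1e-8)
  expect_lt(sp2$rmsd, 1e-6)
  back <- apply_superposition(moved, sp2)
  expect_equal(back$x, s$x, tolerance = 1e-8)
})

test_that("rmsd is self-consistent and refitting is idempotent under noise", {
  withr::with_seed(42, {
    ref_xyz <- matrix(stats::runif(60, -10, 10), ncol = 3)
    rig <- random_rigid(7)
    noise <- matrix(stats::rnorm(60, 0, 0.1), ncol = 3)
  })
  mob_xyz <- sweep(ref_xyz %*% t(rig$rotation), 2, rig$translation, "+") +
    noise
  # name as alpha-carbons so the default mapping pairs them
  ref <- as_structure(dplyr::mutate(
    atoms_at(as.vector(t(ref_xyz)), role = "protein", name = rep("CA", 20)),
    residue_number = dplyr::row_number()))
  mob <- as_structure(dplyr::mutate(
    atoms_at(as.vector(t(mob_xyz)), role = "protein", name = rep("CA", 20)),
    residue_number = dplyr::row_number()))
  sp <- superpose(mob, ref)
  fitted <- apply_superposition(mob, sp)
  direct_rmsd <- sqrt(mean((fitted$x - ref$x)^2 + (fitted$y - ref$y)^2 +
                             (fitted$z - ref$z)^2))
  expect_equal(sp$rmsd, direct_rmsd, tolerance = 1e-9)
  # refit after applying: identity within 1e-9
  sp2 <- superpose(fitted, ref)
  expect_equal(sp2$rotation, diag(3), tolerance = 1e-6)
  expect_equal(sp2$translation, c(0, 0, 0), tolerance = 1e-6)
  # dual route: bio3d's least-squares fit reaches the same minimum rmsd
  # (bio3d::rmsd prints rounded to 3 decimals)
  fit <- suppressWarnings(bio3d::fit.xyz(fixed = as.vector(t(ref_xyz)),
                                         mobile = as.vector(t(mob_xyz))))
  expect_lt(abs(sp$rmsd - bio3d::rmsd(as.vector(t(ref_xyz)), fit)), 1e-3)
})

test_that("degenerate superposition inputs error", {
  a <- as_structure(dplyr::mutate(
    atoms_at(c(0, 0, 0, 1, 0, 0, 2, 0, 0), role = "protein",
             name = rep("CA", 3)),
    residue_number = dplyr::row_number()))
  expect_error(superpose(a, a), "collinear")
  two <- a[1:2, ]
  attr(two, "bonds") <- abfekit:::normalize_bonds(NULL, two$serial)
  class(two) <- class(a)
  expect_error(superpose(two, two), "3 mapped atom pairs")
})
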