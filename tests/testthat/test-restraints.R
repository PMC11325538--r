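# six-point complex with known TR geometry, built from raw coordinates
tr_fixture <- function(xyz) {
  at <- atoms_at(as.vector(t(xyz)),
                 role = c("protein", "protein", "protein",
                          "ligand", "ligand", "ligand"),
                 residue_name = c(rep("ALA", 3), rep("LIG", 3)),
                 chain_id = c(rep("A", 3), rep("L", 3)),
                 name = c("CA", "CA", "CA", "C1", "C2", "C3"))
  at$residue_number <- c(1L, 2L, 3L, 1L, 1L, 1L)
  s <- as_structure(at)
  a <- anchor_set(s, p1 = 1, p2 = 2, p3 = 3, l1 = 4, l2 = 5, l3 = 6)
  list(s = s, a = a)
}

test_that("TR coordinates reproduce known geometries", {
  # P3, P2, P1, L1, L2, L3 laid out with simple right angles
  fx <- tr_fixture(rbind(
    c(0, 0, 1),    # P1
    c(0, 1, 1),    # P2
    c(-1, 1, 1),   # P3
    c(5, 0, 1),    # L1: r = 5 along x, theta(P2,P1,L1) = 90
    c(5, 3, 1),    # L2
    c(8, 3, 1)))   # L3
  v <- measure_tr_coordinates(fx$s, fx$a)
  expect_equal(unname(v["r"]), 5)
  expect_equal(unname(v["theta"]), 90)
  expect_equal(unname(v["Theta"]), 90)
  # coplanar trans arrangement: P3-P2-P1-L1 all in z = 1 plane, trans
  expect_equal(abs(unname(v["phi"])), 180)

  degenerate <- tr_fixture(rbind(
    c(0, 0, 0), c(0, 1, 0), c(1, 1, 0),
    c(0, 0, 0), c(3, 3, 0), c(6, 3, 0)))
  expect_error(measure_tr_coordinates(degenerate$s, degenerate$a),
               "coincide")
})

test_that("ligand dihedral enumeration excludes hydrogens and matches brute force", {
  # butane-like 4-heavy chain -> exactly one dihedral
  chain <- as_structure(
    atoms_at(c(0, 0, 0, 1.5, 0, 0, 2.2, 1.3, 0, 3.7, 1.4, 0.4)),
    bonds = rbind(c(1, 2), c(2, 3), c(3, 4)))
  zone_anchor <- abfekit:::enumerate_heavy_dihedrals(chain)
  expect_equal(nrow(zone_anchor), 1)

  # same chain with terminal hydrogens: still one
  withH <- as_structure(
    atoms_at(c(0, 0, 0, 1.5, 0, 0, 2.2, 1.3, 0, 3.7, 1.4, 0.4,
               -0.6, 0.9, 0, 4.3, 0.6, 0.9),
             element = c("C", "C", "C", "C", "H", "H")),
    bonds = rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 5), c(4, 6)))
  expect_equal(nrow(abfekit:::enumerate_heavy_dihedrals(withH)), 1)

  # branched toys: count equals the exhaustive path enumeration
  for (seed in c(3, 7)) {
    s <- make_toy_complex(seed)
    lig <- s$serial[s$role == "ligand"]
    got <- abfekit:::enumerate_heavy_dihedrals(s, lig)
    expect_equal(nrow(got), brute_force_dihedrals(
      local({
        keep <- s$role == "ligand"
        sub <- s[keep, ]
        b <- structure_bonds(s)
        attr(sub, "bonds") <- b[b[, 1] %in% sub$serial &
                                  b[, 2] %in% sub$serial, , drop = FALSE]
        class(sub) <- class(s)
        sub
      })))
  }
})

test_that("build_restraints measures references from the input pose", {
  s <- make_toy_complex(seed = 2)
  zone <- ligand_centroid_zone(s, 4)
  ca <- s$serial[s$name == "CA"]
  a <- select_anchors(s, zone, ca[1], ca[2], ca[3])
  rs <- build_restraints(s, a, protein_residue_ranges = list(c(1, 3)))
  expect_s3_class(rs, "restraint_set")
  expect_equal(rs$tr$reference, measure_tr_coordinates(s, a))
  # references measured from the same pose give exactly zero energy
  expect_identical(
    restraint_energy(measure_tr_coordinates(s, a), rs$tr, scale = 1), 0)
  vals <- abfekit:::measure_dihedrals(s, rs$ligand_conf$dihedrals)
  expect_equal(restraint_energy(vals, rs$ligand_conf), 0)
  # protein phi/psi: 3 residues in a chain give 2 phi + 2 psi
  expect_equal(nrow(rs$protein_conf$dihedrals), 4)
  # no hydrogens in the ligand dihedral list
  hy <- s$serial[s$is_hydrogen]
  expect_false(any(unlist(rs$ligand_conf$dihedrals[, c("i", "j", "k", "l")])
                   %in% hy))
})

test_that("restraint energy is harmonic with wrapped dihedral differences", {
  fx <- tr_fixture(rbind(
    c(0, 0, 1), c(0, 1, 1), c(-1, 1, 1),
    c(5, 0, 1), c(5, 3, 1), c(8, 3, 2)))
  ref <- measure_tr_coordinates(fx$s, fx$a)
  tr <- tr_restraint(fx$a, ref, k_r = 10, k_angle = 100, k_dihedral = 100)
  expect_equal(restraint_energy(ref, tr, scale = 0.3), 0)
  off <- ref
  off["r"] <- ref["r"] + 1
  expect_equal(restraint_energy(off, tr, scale = 1), 5.0)
  expect_equal(restraint_energy(off, tr, scale = 0.5), 2.5)

  # wrap: 179 vs -179 is a 2-degree difference, not 358
  ref2 <- ref
  ref2["Psi"] <- -179
  tr2 <- tr_restraint(fx$a, ref2, k_r = 10, k_angle = 100, k_dihedral = 100)
  probe <- ref2
  probe["Psi"] <- 179
  expect_equal(restraint_energy(probe, tr2),
               0.5 * 100 * (2 * pi / 180)^2)
})

test_that("dihedral wrap symmetry: energy(x0 + d) == energy(x0 - d)", {
  fx <- tr_fixture(rbind(
    c(0, 0, 1), c(0, 1, 1), c(-1, 1, 1),
    c(5, 0, 1), c(5, 3, 1), c(8, 3, 2)))
  ref <- measure_tr_coordinates(fx$s, fx$a)
  tr <- tr_restraint(fx$a, ref)
  for (delta in c(1, 45, 170, 200, 359)) {
    up <- ref; dn <- ref
    up["Phi"] <- ref["Phi"] + delta
    dn["Phi"] <- ref["Phi"] - delta
    expect_equal(restraint_energy(up, tr), restraint_energy(dn, tr))
  }
})

test_that("restraint energy is invariant under global rigid transforms", {
  s <- make_toy_complex(seed = 5)
  zone <- ligand_centroid_zone(s, 4)
  ca <- s$serial[s$name == "CA"]
  a <- select_anchors(s, zone, ca[1], ca[2], ca[3])
  tr <- tr_restraint(a, measure_tr_coordinates(s, a))
  # perturb the pose so the energy is nonzero, then transform rigidly
  bumped <- transform_structure(s, diag(3), c(0, 0, 0))
  lig <- bumped$role == "ligand"
  bumped$x[lig] <- bumped$x[lig] + 0.4
  e0 <- restraint_energy(measure_tr_coordinates(bumped, a), tr)
  expect_gt(e0, 0)
  for (seed in c(2, 4)) {
    rig <- random_rigid(seed)
    moved <- transform_structure(bumped, rig$rotation, rig$translation)
    e1 <- restraint_energy(measure_tr_coordinates(moved, a), tr)
    expect_equal(e1, e0, tolerance = 1e-8)
  }
})

test_that("schedules enforce monotone scaling factors", {
  expect_s3_class(restraint_schedule(c(0, 0.5, 1), "attach"),
                  "restraint_schedule")
  expect_error(restraint_schedule(c(0, 0.7, 0.5), "attach"), "nondecreasing")
  expect_error(restraint_schedule(c(0.5, 0.7), "release"), "nonincreasing")
  expect_error(restraint_schedule(c(0, 1.2), "attach"))
})

test_that("restraint manifest writes JSON and DISANG text", {
  s <- make_toy_complex(seed = 2)
  zone <- ligand_centroid_zone(s, 4)
  ca <- s$serial[s$name == "CA"]
  a <- select_anchors(s, zone, ca[1], ca[2], ca[3])
  rs <- build_restraints(s, a)
  json <- withr::local_tempfile(fileext = ".json")
  disang <- withr::local_tempfile(fileext = ".rst")
  write_restraint_manifest(rs, json, disang = disang)
  back <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(back$anchors$L1, a$L1)
  expect_equal(unlist(back$tr$reference),
               c(rs$tr$reference), tolerance = 1e-9)
  rst <- readLines(disang)
  expect_equal(sum(grepl("&rst", rst, fixed = TRUE)), 6)
})
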