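protein_points <- function(xyz) {
  as_structure(dplyr::mutate(
    atoms_at(xyz, role = "protein", name = rep("CA", length(xyz) / 3),
             residue_name = "ALA", chain_id = "A"),
    residue_number = dplyr::row_number()))
}

test_that("protein anchor validation applies distance and angle rules", {
  collinear <- protein_points(c(0, 0, 0, 10, 0, 0, 20, 0, 0))
  rep1 <- validate_protein_anchors(collinear, 1, 2, 3)
  expect_false(rep1$pass[rep1$rule == "angle_window"])

  good <- protein_points(c(0, 0, 0, 10, 0, 0, 10, 10, 0))
  rep2 <- validate_protein_anchors(good, 1, 2, 3)
  expect_true(all(rep2$pass))

  close_ <- protein_points(c(0, 0, 0, 1, 0, 0, 1, 10, 0))
  rep3 <- validate_protein_anchors(close_, 1, 2, 3, min_dist = 5)
  expect_false(rep3$pass[rep3$rule == "pairwise_distance"])

  notbb <- protein_points(c(0, 0, 0, 10, 0, 0, 10, 10, 0))
  notbb$name[1] <- "CB"
  rep4 <- validate_protein_anchors(notbb, 1, 2, 3)
  expect_false(rep4$pass[rep4$rule == "backbone_atoms"])

  expect_error(validate_protein_anchors(good, 1, 2, 99))
})

test_that("L1 is the closest in-zone ligand heavy atom, else unstable pose", {
  s <- as_structure(atoms_at(c(1.7, 0, 0, 3.5, 0, 0)))
  zone <- search_zone(c(0, 0, 0), 3)
  expect_identical(find_l1(s, zone), 1L)

  far_zone <- search_zone(c(100, 0, 0), 3)
  out <- find_l1(s, far_zone)
  expect_true(is_unstable_pose(out))

  noligand <- as_structure(atoms_at(c(0, 0, 0), role = "protein",
                                    residue_name = "ALA"))
  expect_error(find_l1(noligand, zone), "no ligand")
})

test_that("L1 equals the brute-force argmin on random ligands", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      xyz <- matrix(stats::runif(150, -6, 6), ncol = 3)
    })
    s <- as_structure(atoms_at(as.vector(t(xyz))))
    zone <- search_zone(c(0.5, -0.5, 0.2), 5)
    d <- sqrt(colSums((t(xyz) - zone$center)^2))
    inside <- which(d <= zone$radius)
    expected <- if (length(inside) == 0) NA else
      inside[which.min(d[inside])]
    got <- find_l1(s, zone)
    if (is.na(expected)) {
      expect_true(is_unstable_pose(got))
    } else {
      expect_identical(got, s$serial[expected])
    }
  }
})

test_that("chain selection picks the angle closest to 90 deg within range", {
  # prev_a at origin-up, prev_b at origin; candidates at 90 and 180 deg
  s <- as_structure(atoms_at(rbind(
    c(0, 1, 0),        # prev_a
    c(0, 0, 0),        # prev_b
    c(3, 0, 0),        # 90 deg
    c(0, -3, 0))))     # 180 deg
  expect_identical(select_anchor_chain(s, 1, 2, c(2.5, 5)), 3L)

  lone <- as_structure(atoms_at(rbind(
    c(0, 1, 0), c(0, 0, 0), c(2.5, 2.5, 0))))   # single candidate at 45 deg
  expect_identical(select_anchor_chain(lone, 1, 2, c(2.5, 5)), 3L)

  expect_error(select_anchor_chain(lone, 1, 2, c(10, 11)), "widen")
})

test_that("chain selection equals exhaustive argmin with serial tie-break", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      xyz <- rbind(c(0, 4, 0), c(0, 0, 0),
                   matrix(stats::runif(90, -5, 5), ncol = 3))
    })
    s <- as_structure(atoms_at(as.vector(t(xyz))))
    rng <- c(2.5, 5.0)
    d <- sqrt(rowSums(sweep(xyz, 2, xyz[2, ])^2))
    ang_dev <- vapply(seq_len(nrow(xyz)), function(i) {
      u <- xyz[1, ] - xyz[2, ]; v <- xyz[i, ] - xyz[2, ]
      abs(acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi - 90)
    }, numeric(1))
    ok <- which(d >= rng[1] & d <= rng[2] & seq_len(nrow(xyz)) > 2)
    if (length(ok) == 0) next
    expected <- ok[order(ang_dev[ok], ok)][1]
    expect_identical(select_anchor_chain(s, 1, 2, rng), s$serial[expected])
  }
  # exact tie: two candidates both exactly at 90 deg -> smaller serial
  tie <- as_structure(atoms_at(rbind(
    c(0, 4, 0), c(0, 0, 0), c(3, 0, 0), c(0, 0, 3))))
  expect_identical(select_anchor_chain(tie, 1, 2, c(2.5, 5)), 3L)
})

test_that("anchor selection is frame-covariant", {
  s <- make_toy_complex(seed = 6)
  zone <- ligand_centroid_zone(s, radius = 4)
  ca <- s$serial[s$name == "CA"]
  a0 <- select_anchors(s, zone, ca[1], ca[2], ca[3])
  expect_s3_class(a0, "anchor_set")
  for (seed in c(3, 8)) {
    rig <- random_rigid(seed)
    moved <- transform_structure(s, rig$rotation, rig$translation)
    zone_moved <- search_zone(
      as.numeric(rig$rotation %*% zone$center + rig$translation),
      zone$radius)
    a1 <- select_anchors(moved, zone_moved, ca[1], ca[2], ca[3])
    expect_identical(unclass(a1)[c("L1", "L2", "L3")],
                     unclass(a0)[c("L1", "L2", "L3")])
  }
})

test_that("selected anchors satisfy the anchor-set invariants", {
  for (seed in c(1, 5, 9)) {
    s <- make_toy_complex(seed)
    zone <- ligand_centroid_zone(s, radius = 4)
    ca <- s$serial[s$name == "CA"]
    a <- select_anchors(s, zone, ca[1], ca[2], ca[3])
    serials <- c(a$P1, a$P2, a$P3, a$L1, a$L2, a$L3)
    expect_equal(length(unique(serials)), 6)
    idx <- match(c(a$L1, a$L2, a$L3), s$serial)
    expect_true(all(s$role[idx] == "ligand"))
    expect_false(any(s$is_hydrogen[idx]))
    p <- function(k) c(s$x[s$serial == k], s$y[s$serial == k],
                       s$z[s$serial == k])
    d12 <- sqrt(sum((p(a$L1) - p(a$L2))^2))
    d23 <- sqrt(sum((p(a$L2) - p(a$L3))^2))
    expect_true(d12 >= 2.5 && d12 <= 5.0)
    expect_true(d23 >= 2.5 && d23 <= 5.0)
  }
})
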