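## Anchor-atom selection: the three protein (P1-P3) and three ligand
## (L1-L3) atoms that define the translational/rotational restraints, and
## the spherical ligand search zone that decides pose stability.

#' Spherical ligand search zone
#'
#' The zone is defined in the reference frame (after superposing the complex
#' onto the reference structure), with its center given in extrinsic
#' Cartesian coordinates.
#'
#' @param center Length-3 numeric, Angstrom.
#' @param radius Positive radius, Angstrom.
#' @return A `search_zone` object.
#' @export
search_zone <- function(center, radius) {
  center <- as.numeric(center)
  stopifnot(length(center) == 3, all(is.finite(center)),
            is.numeric(radius), radius > 0)
  structure(list(center = center, radius = radius), class = "search_zone")
}

#' Validate user-chosen protein anchor atoms
#'
#' Protein anchors should be backbone atoms in rigid regions, mutually well
#' separated, and far from collinear, to avoid gimbal locking of the
#' orientational restraints. Each rule is reported as pass/fail.
#'
#' @param s An `abfe_structure`.
#' @param p1,p2,p3 Atom serials of the candidate anchors.
#' @param min_dist Minimum allowed pairwise anchor distance, Angstrom.
#' @param angle_window Exclusion window, degrees: the P1-P2-P3 angle must lie
#'   in `[angle_window, 180 - angle_window]`.
#' @return A tibble with columns `rule`, `pass`, `detail`.
#' @export
validate_protein_anchors <- function(s, p1, p2, p3,
                                     min_dist = 5, angle_window = 25) {
  stopifnot(is_structure(s))
  serials <- c(p1, p2, p3)
  if (anyDuplicated(serials)) abort("anchor serials must be distinct")
  pos <- lapply(serials, function(k) atom_position(s, k))
  idx <- match(serials, s$serial)
  backbone_ok <- s$role[idx] == "protein" & s$name[idx] %in% c("N", "CA", "C", "O")
  d12 <- dist_points(pos[[1]], pos[[2]])
  d13 <- dist_points(pos[[1]], pos[[3]])
  d23 <- dist_points(pos[[2]], pos[[3]])
  ang <- angle_points(pos[[1]], pos[[2]], pos[[3]])
  tibble::tibble(
    rule = c("backbone_atoms", "pairwise_distance", "angle_window"),
    pass = c(all(backbone_ok),
             min(d12, d13, d23) >= min_dist,
             ang >= angle_window && ang <= 180 - angle_window),
    detail = c(
      if (all(backbone_ok)) "all anchors are protein backbone atoms" else
        paste0("non-backbone/non-protein anchor(s): ",
               paste(serials[!backbone_ok], collapse = ", ")),
      sprintf("min pairwise distance %.2f A (threshold %.2f)",
              min(d12, d13, d23), min_dist),
      sprintf("P1-P2-P3 angle %.1f deg (window [%g, %g])",
              ang, angle_window, 180 - angle_window)
    )
  )
}

#' Find the L1 ligand anchor inside the search zone
#'
#' L1 is the non-hydrogen ligand atom closest to the zone center among those
#' within the zone radius. If no ligand atom lies inside the zone the ligand
#' has left the binding site: the pose is unstable, a defined workflow
#' outcome returned as an `unstable_pose` object, not an error.
#'
#' @param s An `abfe_structure`, already in the reference frame.
#' @param zone A [search_zone()].
#' @return The serial (integer) of L1, or an `unstable_pose` object.
#' @export
find_l1 <- function(s, zone) {
  stopifnot(is_structure(s), inherits(zone, "search_zone"))
  lig <- s[s$role == "ligand" & !s$is_hydrogen, ]
  if (nrow(lig) == 0) abort("structure has no ligand heavy atoms")
  d <- sqrt((lig$x - zone$center[1])^2 +
            (lig$y - zone$center[2])^2 +
            (lig$z - zone$center[3])^2)
  inside <- d <= zone$radius
  if (!any(inside)) {
    return(structure(list(min_distance = min(d), radius = zone$radius),
                     class = "unstable_pose"))
  }
  cand <- lig$serial[inside]
  # stable tie-break: smallest serial among minimal distances
  dmin <- d[inside]
  cand[order(dmin, cand)][1]
}

#' @export
print.unstable_pose <- function(x, ...) {
  cat(sprintf(paste0("Unstable pose: no ligand atom inside the search zone ",
                     "(closest %.2f A, radius %.2f A)\n"),
              x$min_distance, x$radius))
  invisible(x)
}

#' @export
#' @rdname find_l1
#' @param x Object to test.
is_unstable_pose <- function(x) inherits(x, "unstable_pose")

#' Select the next ligand anchor along the chain
#'
#' Among non-hydrogen ligand atoms whose distance to `prev_b` lies in
#' `dist_range`, returns the one whose angle `prev_a`-`prev_b`-candidate is
#' closest to 90 degrees (ties broken by smallest serial). With
#' `(prev_a, prev_b) = (P1, L1)` this selects L2; with `(L1, L2)` it
#' selects L3.
#'
#' @param s An `abfe_structure`.
#' @param prev_a,prev_b Serials of the two previously fixed anchors.
#' @param dist_range Length-2 numeric `(min, max)` distance window, Angstrom.
#' @return The serial of the selected anchor.
#' @export
select_anchor_chain <- function(s, prev_a, prev_b, dist_range = c(2.5, 5.0)) {
  stopifnot(is_structure(s), length(dist_range) == 2,
            dist_range[1] > 0, dist_range[2] >= dist_range[1])
  a <- atom_position(s, prev_a)
  b <- atom_position(s, prev_b)
  lig <- s[s$role == "ligand" & !s$is_hydrogen &
             !(s$serial %in% c(prev_a, prev_b)), ]
  if (nrow(lig) == 0) abort("no candidate ligand heavy atoms")
  d <- sqrt((lig$x - b[1])^2 + (lig$y - b[2])^2 + (lig$z - b[3])^2)
  ok <- d >= dist_range[1] & d <= dist_range[2]
  if (!any(ok)) {
    abort(sprintf(paste0("no ligand anchor candidate with distance in ",
                         "[%.2f, %.2f] A; widen the range"),
                  dist_range[1], dist_range[2]))
  }
  cand <- lig[ok, ]
  dev <- vapply(seq_len(nrow(cand)), function(i) {
    abs(angle_points(a, b, c(cand$x[i], cand$y[i], cand$z[i])) - 90)
  }, numeric(1))
  cand$serial[order(dev, cand$serial)][1]
}

#' Select the full ligand anchor set
#'
#' Runs the L1 search then the L2/L3 chain selection, returning the six
#' anchors plus the zone and ranges that produced them.
#'
#' @param s An `abfe_structure` in the reference frame.
#' @param zone A [search_zone()].
#' @param p1,p2,p3 Protein anchor serials (user-chosen).
#' @param l1l2_range,l2l3_range Distance windows for the chain selection,
#'   Angstrom.
#' @return An `anchor_set` object, or an `unstable_pose` object when L1 is
#'   not found.
#' @export
select_anchors <- function(s, zone, p1, p2, p3,
                           l1l2_range = c(2.5, 5.0),
                           l2l3_range = c(2.5, 5.0)) {
  l1 <- find_l1(s, zone)
  if (is_unstable_pose(l1)) return(l1)
  l2 <- select_anchor_chain(s, p1, l1, l1l2_range)
  l3 <- select_anchor_chain(s, l1, l2, l2l3_range)
  anchor_set(s, p1, p2, p3, l1, l2, l3, zone = zone,
             l1l2_range = l1l2_range, l2l3_range = l2l3_range)
}

#' Construct and validate an anchor set
#'
#' @param s An `abfe_structure` (for role checking).
#' @param p1,p2,p3,l1,l2,l3 Atom serials.
#' @param zone Optional [search_zone()] that produced L1.
#' @param l1l2_range,l2l3_range Distance windows used for selection.
#' @return An `anchor_set` object.
#' @export
anchor_set <- function(s, p1, p2, p3, l1, l2, l3, zone = NULL,
                       l1l2_range = c(2.5, 5.0), l2l3_range = c(2.5, 5.0)) {
  serials <- c(P1 = p1, P2 = p2, P3 = p3, L1 = l1, L2 = l2, L3 = l3)
  if (anyDuplicated(serials)) abort("anchor serials must be distinct")
  idx <- match(serials, s$serial)
  if (anyNA(idx)) abort("anchor serial not present in structure")
  if (!all(s$role[idx[1:3]] == "protein")) abort("P anchors must be protein atoms")
  if (!all(s$role[idx[4:6]] == "ligand")) abort("L anchors must be ligand atoms")
  if (any(s$is_hydrogen[idx[4:6]])) abort("L anchors must be heavy atoms")
  structure(list(P1 = as.integer(p1), P2 = as.integer(p2), P3 = as.integer(p3),
                 L1 = as.integer(l1), L2 = as.integer(l2), L3 = as.integer(l3),
                 zone = zone, l1l2_range = l1l2_range, l2l3_range = l2l3_range),
            class = "anchor_set")
}

#' @export
print.anchor_set <- function(x, ...) {
  cat("Anchor set: P1-P3 =", x$P1, x$P2, x$P3,
      "| L1-L3 =", x$L1, x$L2, x$L3, "\n")
  invisible(x)
}
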