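## Restraint construction and evaluation: translational/rotational (TR,
## Boresch-style), conformational (dihedral), and center-of-mass classes.
## All restraints are harmonic. Force-constant units follow the AMBER
## convention: kcal mol^-1 A^-2 for distances, kcal mol^-1 rad^-2 for
## angles and dihedrals. Reference angles are stored in degrees.

TR_COORDS <- c("r", "theta", "Theta", "phi", "Phi", "Psi")

#' Measure the six TR coordinates of an anchor set
#'
#' The Boresch construction: distance `r = |P1-L1|`; angles
#' `theta = angle(P2,P1,L1)` and `Theta = angle(P1,L1,L2)`; dihedrals
#' `phi = dih(P3,P2,P1,L1)`, `Phi = dih(P2,P1,L1,L2)`,
#' `Psi = dih(P1,L1,L2,L3)`. Angles and dihedrals in degrees, dihedrals in
#' (-180, 180].
#'
#' @param s An `abfe_structure`.
#' @param a An `anchor_set`.
#' @return Named numeric vector `r, theta, Theta, phi, Phi, Psi`.
#' @export
measure_tr_coordinates <- function(s, a) {
  stopifnot(is_structure(s), inherits(a, "anchor_set"))
  p1 <- atom_position(s, a$P1); p2 <- atom_position(s, a$P2)
  p3 <- atom_position(s, a$P3)
  l1 <- atom_position(s, a$L1); l2 <- atom_position(s, a$L2)
  l3 <- atom_position(s, a$L3)
  if (dist_points(p1, l1) < 1e-8) abort("undefined geometry: P1 and L1 coincide")
  c(r = dist_points(p1, l1),
    theta = angle_points(p2, p1, l1),
    Theta = angle_points(p1, l1, l2),
    phi = dihedral_points(p3, p2, p1, l1),
    Phi = dihedral_points(p2, p1, l1, l2),
    Psi = dihedral_points(p1, l1, l2, l3))
}

#' Translational/rotational (Boresch) restraint
#'
#' @param anchors An `anchor_set`.
#' @param reference Named numeric vector of the six reference coordinates
#'   (`r` in Angstrom, the rest in degrees), typically from
#'   [measure_tr_coordinates()].
#' @param k_r Distance force constant, kcal mol^-1 A^-2.
#' @param k_angle Force constant for both angles, kcal mol^-1 rad^-2, or a
#'   length-2 vector `(k_theta, k_Theta)`.
#' @param k_dihedral Force constant for the three dihedrals,
#'   kcal mol^-1 rad^-2, or a length-3 vector.
#' @return A `tr_restraint` object.
#' @export
tr_restraint <- function(anchors, reference, k_r = 10,
                         k_angle = 100, k_dihedral = 100) {
  stopifnot(inherits(anchors, "anchor_set"))
  reference <- reference[TR_COORDS]
  if (anyNA(reference)) abort("reference must name all of r, theta, Theta, phi, Phi, Psi")
  if (reference["r"] <= 0) abort("reference r must be positive")
  if (reference["theta"] <= 0 || reference["theta"] >= 180 ||
      reference["Theta"] <= 0 || reference["Theta"] >= 180) {
    abort("reference polar angles must lie strictly inside (0, 180) degrees")
  }
  k_angle <- rep(unname(k_angle), length.out = 2)
  k_dihedral <- rep(unname(k_dihedral), length.out = 3)
  k_r <- unname(k_r)
  k <- c(r = k_r, theta = k_angle[1], Theta = k_angle[2],
         phi = k_dihedral[1], Phi = k_dihedral[2], Psi = k_dihedral[3])
  if (any(k < 0)) abort("force constants must be nonnegative")
  ref <- as.numeric(reference)
  names(ref) <- TR_COORDS
  ref[4:6] <- wrap_deg(ref[4:6])
  structure(list(anchors = anchors, reference = ref, k = k),
            class = "tr_restraint")
}

#' @export
print.tr_restraint <- function(x, ...) {
  cat("TR restraint on anchors", x$anchors$P1, x$anchors$P2, x$anchors$P3,
      "/", x$anchors$L1, x$anchors$L2, x$anchors$L3, "\n")
  print(round(x$reference, 2))
  invisible(x)
}

#' Conformational (dihedral) restraints
#'
#' @param dihedrals Tibble with columns `i, j, k, l` (atom serials),
#'   `reference` (degrees) and `force_constant` (kcal mol^-1 rad^-2).
#' @param target `"ligand"` or `"protein_backbone"`.
#' @return A `conformational_restraints` object.
#' @export
conformational_restraints <- function(dihedrals,
                                      target = c("ligand", "protein_backbone")) {
  target <- match.arg(target)
  dihedrals <- tibble::as_tibble(dihedrals)
  need <- c("i", "j", "k", "l", "reference", "force_constant")
  if (!all(need %in% names(dihedrals))) {
    abort(paste0("dihedral table needs columns: ", paste(need, collapse = ", ")))
  }
  if (any(dihedrals$force_constant < 0)) abort("force constants must be nonnegative")
  dihedrals$reference <- wrap_deg(dihedrals$reference)
  structure(list(dihedrals = dihedrals, target = target),
            class = "conformational_restraints")
}

#' Center-of-mass restraint
#'
#' COM restraints pin a selection's center of mass to maintain the reference
#' frame (complex in the box; bulk ligand away from the protein). They
#' contribute no free-energy component.
#'
#' @param selection Integer vector of atom serials.
#' @param reference_center Length-3 numeric, Angstrom.
#' @param force_constant kcal mol^-1 A^-2.
#' @return A `com_restraint` object.
#' @export
com_restraint <- function(selection, reference_center, force_constant = 10) {
  selection <- as.integer(selection)
  if (length(selection) == 0) abort("COM restraint selection is empty")
  stopifnot(length(reference_center) == 3, force_constant >= 0)
  structure(list(selection = selection,
                 reference_center = as.numeric(reference_center),
                 force_constant = force_constant),
            class = "com_restraint")
}

## ---- dihedral enumeration -------------------------------------------------

adjacency_list <- function(bonds, serials) {
  adj <- setNames(vector("list", length(serials)), as.character(serials))
  for (r in seq_len(nrow(bonds))) {
    i <- as.character(bonds[r, 1]); j <- as.character(bonds[r, 2])
    adj[[i]] <- c(adj[[i]], bonds[r, 2])
    adj[[j]] <- c(adj[[j]], bonds[r, 1])
  }
  adj
}

# every distinct bonded quadruple i-j-k-l with all four atoms heavy,
# one orientation per quadruple (canonical: j < k, or i < l when j == k
# cannot happen since j != k by construction)
enumerate_heavy_dihedrals <- function(s, serials_subset = NULL) {
  bonds <- structure_bonds(s)
  heavy <- s$serial[!s$is_hydrogen]
  if (!is.null(serials_subset)) heavy <- intersect(heavy, serials_subset)
  bonds <- bonds[bonds[, 1] %in% heavy & bonds[, 2] %in% heavy, , drop = FALSE]
  if (nrow(bonds) == 0) {
    return(tibble::tibble(i = integer(), j = integer(),
                          k = integer(), l = integer()))
  }
  adj <- adjacency_list(bonds, heavy)
  quads <- list()
  for (r in seq_len(nrow(bonds))) {
    j <- bonds[r, 1]; k <- bonds[r, 2]   # central bond, j < k canonical
    nbr_j <- setdiff(adj[[as.character(j)]], k)
    nbr_k <- setdiff(adj[[as.character(k)]], j)
    for (i in nbr_j) for (l in nbr_k) {
      if (i != l) quads[[length(quads) + 1]] <- c(i, j, k, l)
    }
  }
  if (length(quads) == 0) {
    return(tibble::tibble(i = integer(), j = integer(),
                          k = integer(), l = integer()))
  }
  q <- do.call(rbind, quads)
  # canonicalize orientation: keep (i,j,k,l) with (j,k) ascending
  flip <- q[, 2] > q[, 3]
  q[flip, ] <- q[flip, c(4, 3, 2, 1)]
  q <- unique(q)
  tibble::tibble(i = q[, 1], j = q[, 2], k = q[, 3], l = q[, 4])
}

protein_backbone_dihedrals <- function(s, residue_ranges) {
  prot <- s[s$role == "protein", ]
  out <- list()
  for (ch in unique(prot$chain_id)) {
    pc <- prot[prot$chain_id == ch, ]
    for (rng in residue_ranges) {
      for (res in seq(rng[1], rng[2])) {
        get_at <- function(resno, nm) {
          hit <- pc$serial[pc$residue_number == resno & pc$name == nm]
          if (length(hit) >= 1) hit[1] else NA_integer_
        }
        # phi: C(i-1)-N(i)-CA(i)-C(i);  psi: N(i)-CA(i)-C(i)-N(i+1)
        phi <- c(get_at(res - 1, "C"), get_at(res, "N"),
                 get_at(res, "CA"), get_at(res, "C"))
        psi <- c(get_at(res, "N"), get_at(res, "CA"),
                 get_at(res, "C"), get_at(res + 1, "N"))
        if (!anyNA(phi)) out[[length(out) + 1]] <- c(phi, 1)
        if (!anyNA(psi)) out[[length(out) + 1]] <- c(psi, 2)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(i = integer(), j = integer(),
                          k = integer(), l = integer()))
  }
  m <- unique(do.call(rbind, out))
  tibble::tibble(i = m[, 1], j = m[, 2], k = m[, 3], l = m[, 4])
}

measure_dihedrals <- function(s, quads) {
  vapply(seq_len(nrow(quads)), function(n) {
    dihedral_points(atom_position(s, quads$i[n]), atom_position(s, quads$j[n]),
                    atom_position(s, quads$k[n]), atom_position(s, quads$l[n]))
  }, numeric(1))
}

#' Build the full restraint set for a pose
#'
#' TR references are measured from the input conformation; ligand
#' conformational restraints enumerate every bonded heavy-atom quadruple
#' (one per distinct i-j-k-l path along bonds); protein phi/psi backbone
#' dihedrals are enumerated over the declared residue ranges; COM restraints
#' tether the protein backbone (and, if requested, the bulk-ligand copy).
#'
#' @param s An `abfe_structure` with ligand bonds perceived.
#' @param a An `anchor_set`.
#' @param k_r,k_angle,k_dihedral TR force constants, see [tr_restraint()].
#' @param k_conf Conformational dihedral force constant,
#'   kcal mol^-1 rad^-2.
#' @param k_com COM force constant, kcal mol^-1 A^-2.
#' @param protein_residue_ranges List of `c(first, last)` residue-number
#'   ranges for protein backbone restraints; `NULL` for none.
#' @return A list of class `restraint_set` with elements `tr`,
#'   `ligand_conf`, `protein_conf` (or `NULL`) and `com`.
#' @export
build_restraints <- function(s, a, k_r = 10, k_angle = 100, k_dihedral = 100,
                             k_conf = 10, k_com = 10,
                             protein_residue_ranges = NULL) {
  stopifnot(is_structure(s), inherits(a, "anchor_set"))
  tr <- tr_restraint(a, measure_tr_coordinates(s, a),
                     k_r = k_r, k_angle = k_angle, k_dihedral = k_dihedral)
  lig_serials <- s$serial[s$role == "ligand"]
  quads <- enumerate_heavy_dihedrals(s, lig_serials)
  if (nrow(quads) == 0) {
    warn("ligand has no heavy-atom dihedrals (rigid ligand); conformational restraint list is empty")
    lig_conf <- conformational_restraints(
      tibble::tibble(i = integer(), j = integer(), k = integer(), l = integer(),
                     reference = numeric(), force_constant = numeric()),
      target = "ligand")
  } else {
    quads$reference <- measure_dihedrals(s, quads)
    quads$force_constant <- k_conf
    lig_conf <- conformational_restraints(quads, target = "ligand")
  }
  prot_conf <- NULL
  if (!is.null(protein_residue_ranges)) {
    pq <- protein_backbone_dihedrals(s, protein_residue_ranges)
    if (nrow(pq) == 0) abort("no phi/psi dihedrals found in the declared residue ranges")
    pq$reference <- measure_dihedrals(s, pq)
    pq$force_constant <- k_conf
    prot_conf <- conformational_restraints(pq, target = "protein_backbone")
  }
  backbone <- s$serial[s$role == "protein" & s$name %in% c("N", "CA", "C", "O")]
  com <- com_restraint(backbone,
                       colMeans(coords_matrix(s, backbone)),
                       force_constant = k_com)
  structure(list(tr = tr, ligand_conf = lig_conf,
                 protein_conf = prot_conf, com = com),
            class = "restraint_set")
}

## ---- energies -------------------------------------------------------------

#' Harmonic restraint energy
#'
#' Evaluates `scale * sum(0.5 k (x - x0)^2)` with angular terms converted to
#' radians and dihedral differences wrapped into (-180, 180] degrees before
#' squaring.
#'
#' @param values For a `tr_restraint`: named vector of the six coordinates
#'   as from [measure_tr_coordinates()]. For `conformational_restraints`:
#'   numeric vector of dihedral values (degrees), in table order.
#' @param restraint A `tr_restraint` or `conformational_restraints` object.
#' @param scale Multiplicative force-constant scaling, in `[0, 1]`.
#' @return Energy in kcal/mol (nonnegative).
#' @export
restraint_energy <- function(values, restraint, scale = 1) {
  stopifnot(scale >= 0, scale <= 1)
  if (inherits(restraint, "tr_restraint")) {
    v <- values[TR_COORDS]
    if (anyNA(v)) abort("values must name all six TR coordinates")
    dr <- v["r"] - restraint$reference["r"]
    dang <- deg2rad(v[c("theta", "Theta")] -
                      restraint$reference[c("theta", "Theta")])
    ddih <- deg2rad(wrap_deg(v[c("phi", "Phi", "Psi")] -
                               restraint$reference[c("phi", "Phi", "Psi")]))
    dx2 <- c(dr^2, dang^2, ddih^2)
    return(scale * sum(0.5 * restraint$k * dx2))
  }
  if (inherits(restraint, "conformational_restraints")) {
    tab <- restraint$dihedrals
    if (length(values) != nrow(tab)) {
      abort("values length must match the dihedral table")
    }
    dd <- deg2rad(wrap_deg(values - tab$reference))
    return(scale * sum(0.5 * tab$force_constant * dd^2))
  }
  abort("unsupported restraint type")
}

#' Restraint attach/release schedule
#'
#' An ordered list of multiplicative force-constant scaling factors, one per
#' simulation window.
#'
#' @param factors Numeric vector in `[0, 1]`, nondecreasing for
#'   `direction = "attach"`, nonincreasing for `"release"`.
#' @param direction `"attach"` or `"release"`.
#' @return A `restraint_schedule` object.
#' @export
restraint_schedule <- function(factors, direction = c("attach", "release")) {
  direction <- match.arg(direction)
  stopifnot(all(factors >= 0), all(factors <= 1))
  dfs <- diff(factors)
  if (direction == "attach" && any(dfs < 0)) {
    abort("attach schedule factors must be nondecreasing")
  }
  if (direction == "release" && any(dfs > 0)) {
    abort("release schedule factors must be nonincreasing")
  }
  structure(list(factors = factors, direction = direction),
            class = "restraint_schedule")
}

## ---- manifests ------------------------------------------------------------

#' Write a restraint manifest
#'
#' JSON manifest of anchors, references and force constants; optionally an
#' AMBER NMR (DISANG-style) text file with `&rst` blocks for the six TR
#' coordinates, for interoperability with MD engines.
#'
#' @param rs A `restraint_set` from [build_restraints()].
#' @param path Output JSON path.
#' @param disang Optional path for the AMBER restraint text.
#' @return `path`, invisibly.
#' @export
write_restraint_manifest <- function(rs, path, disang = NULL) {
  stopifnot(inherits(rs, "restraint_set"))
  a <- rs$tr$anchors
  obj <- list(
    anchors = list(P1 = a$P1, P2 = a$P2, P3 = a$P3,
                   L1 = a$L1, L2 = a$L2, L3 = a$L3),
    tr = list(reference = as.list(rs$tr$reference),
              force_constants = as.list(rs$tr$k)),
    ligand_conformational = rs$ligand_conf$dihedrals,
    protein_conformational = if (is.null(rs$protein_conf)) NULL else
      rs$protein_conf$dihedrals,
    com = list(selection = rs$com$selection,
               reference_center = rs$com$reference_center,
               force_constant = rs$com$force_constant)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(disang)) write_disang(rs, disang)
  invisible(path)
}

# AMBER force constants appear as k_amber = k/2 convention-free here: we
# emit rk2 = k/2 so that rk2*(x-x0)^2 equals our 0.5*k*(x-x0)^2.
write_disang <- function(rs, path) {
  a <- rs$tr$anchors
  ref <- rs$tr$reference
  k2 <- rs$tr$k / 2
  quad <- list(
    r = c(a$P1, a$L1), theta = c(a$P2, a$P1, a$L1),
    Theta = c(a$P1, a$L1, a$L2), phi = c(a$P3, a$P2, a$P1, a$L1),
    Phi = c(a$P2, a$P1, a$L1, a$L2), Psi = c(a$P1, a$L1, a$L2, a$L3))
  lines <- unlist(lapply(TR_COORDS, function(nm) {
    at <- quad[[nm]]
    r0 <- ref[nm]
    span <- if (nm == "r") 10 else 180
    c(sprintf(" &rst iat=%s,", paste(at, collapse = ",")),
      sprintf("  r1=%.3f, r2=%.3f, r3=%.3f, r4=%.3f,",
              r0 - span, r0, r0, r0 + span),
      sprintf("  rk2=%.3f, rk3=%.3f,", k2[nm], k2[nm]),
      " &end")
  }))
  writeLines(lines, path)
  invisible(path)
}
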