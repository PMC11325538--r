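## Structure I/O: PDB reading/writing, bond perception, rigid superposition.
##
## A structure is a tibble of atoms (one row per atom) carrying bond and
## role information in attributes, so it pipes through dplyr verbs while
## staying a single object for the geometry code.

# covalent radii in Angstrom (Cordero-style single-bond values)
COVALENT_RADII <- c(
  H = 0.31, D = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  NA. = 1.66, MG = 1.41, P = 1.07, S = 1.05, CL = 1.02, K = 2.03,
  CA = 1.76, MN = 1.39, FE = 1.32, CO = 1.26, NI = 1.24, CU = 1.32,
  ZN = 1.22, SE = 1.20, BR = 1.20, I = 1.39
)

WATER_RESNAMES <- c("HOH", "WAT", "TIP3", "TIP4", "SPC", "SOL", "DOD")
ION_RESNAMES <- c("NA", "CL", "K", "MG", "CA", "ZN", "BR", "CS", "LI", "IOD")

#' Build a structure from an atom table
#'
#' Constructs the atom-table container used throughout the package. The
#' result is a tibble (one row per atom) of class `abfe_structure`, with
#' covalent bonds and molecule roles stored as attributes.
#'
#' @param atoms Data frame with columns `serial`, `name`, `element`,
#'   `residue_name`, `residue_number`, `chain_id`, `x`, `y`, `z`. A `role`
#'   column (`protein`, `ligand`, `cobinder`, `water`, `ion`) is kept if
#'   present, otherwise inferred from residue names (waters and common ions
#'   recognised; other HETATM-style residues default to `ligand` only when
#'   read from PDB).
#' @param bonds Two-column matrix (or data frame) of atom serial pairs, or
#'   `NULL` for no bonds.
#' @return An `abfe_structure` tibble.
#' @export
as_structure <- function(atoms, bonds = NULL) {
  atoms <- tibble::as_tibble(atoms)
  needed <- c("serial", "name", "element", "residue_name", "residue_number",
              "chain_id", "x", "y", "z")
  missing <- setdiff(needed, names(atoms))
  if (length(missing) > 0) {
    abort(paste0("atom table lacks columns: ", paste(missing, collapse = ", ")))
  }
  atoms$serial <- as.integer(atoms$serial)
  atoms$x <- unname(as.numeric(atoms$x))
  atoms$y <- unname(as.numeric(atoms$y))
  atoms$z <- unname(as.numeric(atoms$z))
  if (anyDuplicated(atoms$serial)) abort("atom serials must be unique")
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    abort("atom positions must be finite")
  }
  if (!"is_hydrogen" %in% names(atoms)) {
    atoms$is_hydrogen <- toupper(atoms$element) %in% c("H", "D")
  }
  if (!"role" %in% names(atoms)) {
    atoms$role <- dplyr::case_when(
      toupper(atoms$residue_name) %in% WATER_RESNAMES ~ "water",
      toupper(atoms$residue_name) %in% ION_RESNAMES ~ "ion",
      TRUE ~ "protein"
    )
  }
  bonds <- normalize_bonds(bonds, atoms$serial)
  structure(atoms,
            bonds = bonds,
            class = c("abfe_structure", class(tibble::tibble())))
}

normalize_bonds <- function(bonds, serials) {
  if (is.null(bonds) || NROW(bonds) == 0) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  }
  bonds <- as.matrix(bonds)[, 1:2, drop = FALSE]
  storage.mode(bonds) <- "integer"
  bad <- !(bonds %in% serials)
  if (any(bad)) {
    abort(paste0("bond references unknown serial(s): ",
                 paste(unique(bonds[bad]), collapse = ", ")))
  }
  ij <- cbind(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
  ij <- unique(ij[ij[, 1] != ij[, 2], , drop = FALSE])
  colnames(ij) <- c("i", "j")
  ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
}

#' @export
#' @rdname as_structure
#' @param x Object to test.
is_structure <- function(x) inherits(x, "abfe_structure")

#' Bonds of a structure
#'
#' @param s An `abfe_structure`.
#' @return Integer matrix of serial pairs (columns `i`, `j`, i < j).
#' @export
structure_bonds <- function(s) {
  stopifnot(is_structure(s))
  attr(s, "bonds")
}

coords_matrix <- function(s, serials = NULL) {
  if (!is.null(serials)) {
    s <- s[match(serials, s$serial), , drop = FALSE]
    if (anyNA(s$serial)) abort("serial not present in structure")
  }
  m <- cbind(s$x, s$y, s$z)
  rownames(m) <- s$serial
  m
}

atom_position <- function(s, serial) {
  i <- match(serial, s$serial)
  if (is.na(i)) abort(paste0("no atom with serial ", serial))
  c(s$x[i], s$y[i], s$z[i])
}

#' Read a PDB file into a structure
#'
#' ATOM/HETATM records are parsed with [bio3d::read.pdb()]; CONECT records
#' are parsed here (bio3d discards them). Only the first alternate-location
#' conformer is kept; insertion codes are ignored with a warning.
#'
#' @param path Path to a PDB file.
#' @param role_hints Optional named character vector mapping residue names to
#'   roles, e.g. `c(LIG = "ligand", NAD = "cobinder")`. Hints win over the
#'   defaults (ATOM records are `protein`, HETATM water/ion residues are
#'   recognised, any other HETATM residue defaults to `ligand`).
#' @param ligand_resname Convenience shortcut: residue name(s) to assign the
#'   `ligand` role, as set in a run-configuration file.
#' @return An `abfe_structure` tibble.
#' @export
read_pdb <- function(path, role_hints = NULL, ligand_resname = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) abort(paste0("failed to parse PDB ", path, ": ",
                                     conditionMessage(e)))
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) abort(paste0("no atoms in ", path))
  # first altloc conformer only
  alt <- at$alt
  alt[is.na(alt)] <- ""
  keep_alt <- alt %in% c("", "A", "1")
  if (!all(keep_alt)) at <- at[keep_alt, , drop = FALSE]
  ins <- at$insert
  if (!is.null(ins) && any(!is.na(ins) & ins != "")) {
    warn("insertion codes present; they are ignored")
  }
  if (any(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))) {
    bad <- which(!is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z))[1]
    abort(paste0("malformed coordinates at atom serial ", at$eleno[bad]))
  }
  element <- toupper(trimws(at$elesy))
  noel <- is.na(element) | element == ""
  element[noel] <- guess_element(at$elety[noel])
  atoms <- tibble::tibble(
    serial = as.integer(at$eleno),
    name = trimws(at$elety),
    element = element,
    residue_name = trimws(at$resid),
    residue_number = as.integer(at$resno),
    chain_id = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    x = at$x, y = at$y, z = at$z,
    is_hydrogen = element %in% c("H", "D"),
    record = at$type
  )
  atoms$role <- default_roles(atoms, role_hints, ligand_resname)
  atoms$record <- NULL
  s <- as_structure(atoms, bonds = read_conect(path, atoms$serial))
  s
}

default_roles <- function(atoms, role_hints, ligand_resname) {
  resup <- toupper(atoms$residue_name)
  role <- ifelse(atoms$record == "HETATM",
    dplyr::case_when(
      resup %in% WATER_RESNAMES ~ "water",
      resup %in% ION_RESNAMES ~ "ion",
      TRUE ~ "ligand"
    ),
    dplyr::case_when(
      resup %in% WATER_RESNAMES ~ "water",
      TRUE ~ "protein"
    )
  )
  if (!is.null(ligand_resname)) {
    role[resup %in% toupper(ligand_resname)] <- "ligand"
  }
  if (!is.null(role_hints)) {
    hit <- match(resup, toupper(names(role_hints)))
    role[!is.na(hit)] <- unname(role_hints[hit[!is.na(hit)]])
  }
  role
}

guess_element <- function(name) {
  nm <- toupper(trimws(name))
  two <- substr(nm, 1, 2)
  el <- ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "SE", "NA"),
               two, substr(sub("^[0-9]+", "", nm), 1, 1))
  el
}

read_conect <- function(path, serials) {
  lines <- readLines(path, warn = FALSE)
  cl <- lines[startsWith(lines, "CONECT")]
  if (length(cl) == 0) return(NULL)
  pairs <- lapply(cl, function(l) {
    f <- suppressWarnings(as.integer(strsplit(trimws(substring(l, 7)),
                                              "\\s+")[[1]]))
    f <- f[!is.na(f)]
    if (length(f) < 2) return(NULL)
    cbind(f[1], f[-1])
  })
  b <- do.call(rbind, pairs)
  # drop references to atoms we dropped (altlocs) or never had
  b[b[, 1] %in% serials & b[, 2] %in% serials, , drop = FALSE]
}

#' Write a structure to a PDB file
#'
#' Fixed-column ATOM/HETATM records plus CONECT lines for every stored bond;
#' sufficient for fixtures and restraint visualisation.
#'
#' @param s An `abfe_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  stopifnot(is_structure(s))
  rec <- ifelse(s$role %in% c("protein", "water"), "ATOM  ", "HETATM")
  name4 <- vapply(s$name, function(n) {
    if (nchar(n) >= 4) substr(n, 1, 4) else sprintf(" %-3s", n)
  }, character(1))
  lines <- sprintf("%s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   rec, s$serial, name4, substr(s$residue_name, 1, 3),
                   substr(s$chain_id, 1, 1), s$residue_number,
                   s$x, s$y, s$z, 1.00, 0.00, substr(s$element, 1, 2))
  b <- structure_bonds(s)
  if (nrow(b) > 0) {
    conect <- c(sprintf("CONECT%5d%5d", b[, 1], b[, 2]),
                sprintf("CONECT%5d%5d", b[, 2], b[, 1]))
    lines <- c(lines, sort(conect))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Perceive covalent bonds from interatomic distances
#'
#' Adds a bond wherever the distance between two atoms does not exceed the
#' sum of their covalent radii plus `tolerance`. Bonds already present (e.g.
#' from CONECT records) are preserved.
#'
#' @param s An `abfe_structure`.
#' @param tolerance Slack added to the radius sum, in Angstrom.
#' @param within_role Restrict perception to atoms of one role (e.g.
#'   `"ligand"`); `NULL` perceives across the whole structure.
#' @return The structure with its bond set augmented.
#' @export
perceive_bonds <- function(s, tolerance = 0.4, within_role = NULL) {
  stopifnot(is_structure(s), tolerance >= 0)
  idx <- seq_len(nrow(s))
  if (!is.null(within_role)) idx <- which(s$role %in% within_role)
  if (length(idx) < 2) return(s)
  el <- toupper(s$element[idx])
  el[el == "NA"] <- "NA."   # sodium; avoid clash with missing
  radii <- COVALENT_RADII[el]
  if (anyNA(radii)) {
    unk <- unique(s$element[idx][is.na(radii)])
    abort(paste0("no covalent radius for element(s): ",
                 paste(unk, collapse = ", ")))
  }
  xyz <- coords_matrix(s)[idx, , drop = FALSE]
  d <- as.matrix(stats::dist(xyz))
  cutoff <- outer(radii, radii, "+") + tolerance
  hit <- which(d <= cutoff & upper.tri(d) & d > 1e-6, arr.ind = TRUE)
  new_bonds <- cbind(s$serial[idx[hit[, 1]]], s$serial[idx[hit[, 2]]])
  all_bonds <- rbind(structure_bonds(s), normalize_bonds(new_bonds, s$serial))
  attr(s, "bonds") <- normalize_bonds(all_bonds, s$serial)
  s
}

#' Rigid least-squares superposition (Kabsch)
#'
#' Fits the rotation + translation minimising the RMSD of mapped atom pairs.
#' The default mapping pairs alpha-carbons by chain and residue number;
#' `selection` restricts it to other atom names.
#'
#' @param mobile,reference `abfe_structure` objects.
#' @param selection Character vector of atom names to map (default `"CA"`).
#' @return An `abfe_superposition` list: `rotation` (3x3, det +1),
#'   `translation` (length-3, Angstrom), `rmsd`, and the `atom_mapping`
#'   tibble of serial pairs used.
#' @export
superpose <- function(mobile, reference, selection = "CA") {
  stopifnot(is_structure(mobile), is_structure(reference))
  msel <- mobile[mobile$name %in% selection, ]
  rsel <- reference[reference$name %in% selection, ]
  key <- function(d) paste(d$chain_id, d$residue_number, d$name)
  hit <- match(key(msel), key(rsel))
  msel <- msel[!is.na(hit), ]
  rsel <- rsel[hit[!is.na(hit)], ]
  if (nrow(msel) < 3) abort("need at least 3 mapped atom pairs to superpose")
  P <- cbind(msel$x, msel$y, msel$z)
  Q <- cbind(rsel$x, rsel$y, rsel$z)
  qc <- colMeans(Q)
  sv_ref <- svd(sweep(Q, 2, qc))$d
  if (sv_ref[2] < 1e-8 * max(sv_ref[1], 1)) {
    abort("mapped atoms are collinear; superposition is underdetermined")
  }
  fit <- kabsch(P, Q)
  moved <- sweep(P %*% t(fit$rotation), 2, fit$translation, "+")
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  structure(list(rotation = fit$rotation, translation = fit$translation,
                 rmsd = rmsd,
                 atom_mapping = tibble::tibble(mobile = msel$serial,
                                               reference = rsel$serial)),
            class = "abfe_superposition")
}

# P, Q: n x 3; returns rotation R (applied as x %*% t(R)) and translation t
# such that R x + t maps mobile onto reference in least squares.
kabsch <- function(P, Q) {
  pc <- colMeans(P)
  qc <- colMeans(Q)
  H <- t(sweep(P, 2, pc)) %*% sweep(Q, 2, qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(rotation = R, translation = as.numeric(qc - R %*% pc))
}

#' @export
print.abfe_superposition <- function(x, ...) {
  cat("Rigid superposition:", nrow(x$atom_mapping), "atom pairs, rmsd",
      sprintf("%.4f", x$rmsd), "Angstrom\n")
  invisible(x)
}

#' Apply a superposition to a structure
#'
#' @param s An `abfe_structure`.
#' @param sp An `abfe_superposition` from [superpose()].
#' @return The transformed structure.
#' @export
apply_superposition <- function(s, sp) {
  stopifnot(is_structure(s), inherits(sp, "abfe_superposition"))
  xyz <- coords_matrix(s) %*% t(sp$rotation)
  xyz <- sweep(xyz, 2, sp$translation, "+")
  s$x <- unname(xyz[, 1]); s$y <- unname(xyz[, 2]); s$z <- unname(xyz[, 3])
  s
}

#' Rigidly transform a structure
#'
#' @param s An `abfe_structure`.
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 translation, Angstrom.
#' @return The transformed structure.
#' @export
transform_structure <- function(s, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(is_structure(s))
  xyz <- coords_matrix(s) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  s$x <- unname(xyz[, 1]); s$y <- unname(xyz[, 2]); s$z <- unname(xyz[, 3])
  s
}
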