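# Shared in-code fixtures and independent oracles for the test suite.

RT298 <- abfekit::rt_kcal(298.15)

# bare atom-table builder for geometric tests
atoms_at <- function(xyz, element = "C", name = NULL, role = "ligand",
                     residue_name = "LIG", chain_id = "L") {
  if (!is.matrix(xyz)) xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  n <- nrow(xyz)
  element <- rep(element, length.out = n)
  tibble::tibble(
    serial = seq_len(n),
    name = name %||% paste0(element, seq_len(n)),
    element = element,
    residue_name = rep(residue_name, length.out = n),
    residue_number = 1L,
    chain_id = rep(chain_id, length.out = n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    role = rep(role, length.out = n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exact (i.i.d.) harmonic window table: window k has U = 0.5 k_k (x-c_k)^2;
# independent of the package's Metropolis sampler
exact_harmonic_table <- function(k, centers = 0, n_per = 1000, seed = 1,
                                 temperature = 298.15) {
  rt <- abfekit::rt_kcal(temperature)
  centers <- rep(centers, length.out = length(k))
  withr::with_seed(seed, {
    xs <- unlist(lapply(seq_along(k), function(i) {
      stats::rnorm(n_per, centers[i], sqrt(rt / k[i]))
    }))
  })
  u <- t(vapply(seq_along(k), function(i) {
    0.5 * k[i] * (xs - centers[i])^2 / rt
  }, numeric(length(xs))))
  abfekit::window_table(u, rep(n_per, length(k)))
}

# brute-force free-energy difference of two 1-D potentials by numerical
# integration of the configuration integrals
quadrature_dg <- function(u_from, u_to, temperature = 298.15,
                          lower = -30, upper = 30) {
  rt <- abfekit::rt_kcal(temperature)
  z <- function(u) {
    stats::integrate(function(x) exp(-u(x) / rt), lower, upper,
                     rel.tol = 1e-10)$value
  }
  -rt * log(z(u_to) / z(u_from))
}

# random rigid transform (uniform-ish rotation via QR, bounded translation)
random_rigid <- function(seed) {
  withr::with_seed(seed, {
    q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    list(rotation = q, translation = stats::runif(3, -8, 8))
  })
}

# independent O(N^2) bond reference: all pairs within radius sum + tol
brute_force_bonds <- function(s, tolerance = 0.4) {
  radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05)
  n <- nrow(s)
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt((s$x[i] - s$x[j])^2 + (s$y[i] - s$y[j])^2 +
                  (s$z[i] - s$z[j])^2)
      if (d <= radii[[s$element[i]]] + radii[[s$element[j]]] + tolerance) {
        out <- rbind(out, c(s$serial[i], s$serial[j]))
      }
    }
  }
  out
}

# independent dihedral enumeration: all ordered heavy 4-tuples that form a
# bonded path, deduplicated by reversal
brute_force_dihedrals <- function(s) {
  b <- abfekit::structure_bonds(s)
  bonded <- function(a, z) {
    any((b[, 1] == a & b[, 2] == z) | (b[, 1] == z & b[, 2] == a))
  }
  heavy <- s$serial[!s$is_hydrogen]
  seen <- character(0)
  count <- 0L
  for (i in heavy) for (j in heavy) for (k in heavy) for (l in heavy) {
    if (length(unique(c(i, j, k, l))) == 4 &&
        bonded(i, j) && bonded(j, k) && bonded(k, l)) {
      key <- paste(min(paste(i, j, k, l), paste(l, k, j, i)))
      if (!key %in% seen) {
        seen <- c(seen, key)
        count <- count + 1L
      }
    }
  }
  count
}
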