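## Synthetic-data generator: one-dimensional toy potentials with closed-form
## free energies, Metropolis Monte-Carlo window sampling, toy protein-ligand
## PDB fixtures, and a Monte-Carlo oracle for the standard-state release.
## These stand in for molecular dynamics so the estimators and cycle logic
## run at desk scale; they are not molecular models.

#' Analytic toy potential
#'
#' Three forms, all quadratic in a single coordinate so every window free
#' energy is a Gaussian integral with a closed form:
#' * `harmonic_ladder`: window `k` has `U_k(x) = 0.5 k_k (x - c_k)^2`.
#' * `lambda_coupled`: linear alchemical mixing
#'   `U(x, lambda) = (1-lambda) (0.5 kA (x-cA)^2 + offsetA) +
#'    lambda (0.5 kB (x-cB)^2 + offsetB)`.
#' * `restraint_field`: a base well plus lambda-scaled harmonic restraints,
#'   `U(x, lambda) = 0.5 k_base (x-c_base)^2 +
#'    lambda sum_j 0.5 k_j (x - c_j)^2`.
#'
#' @param form Potential form.
#' @param k,centers Ladder force constants and centers (ladder form).
#' @param kA,cA,offsetA,kB,cB,offsetB End-state parameters (lambda_coupled
#'   form).
#' @param k_base,c_base,restraints Base well and a list of `c(k, c)`
#'   restraint terms (restraint_field form).
#' @return A `toy_potential` object with closed-form free energies
#'   available through [toy_analytic_dg()] and [toy_analytic_dudl()].
#' @export
toy_potential <- function(form = c("harmonic_ladder", "lambda_coupled",
                                   "restraint_field"),
                          k = NULL, centers = NULL,
                          kA = NULL, cA = 0, offsetA = 0,
                          kB = NULL, cB = 0, offsetB = 0,
                          k_base = NULL, c_base = 0, restraints = NULL) {
  form <- match.arg(form)
  p <- switch(form,
    harmonic_ladder = {
      stopifnot(!is.null(k), all(k > 0))
      centers <- rep(centers %||% 0, length.out = length(k))
      list(form = form, k = k, centers = centers)
    },
    lambda_coupled = {
      stopifnot(!is.null(kA), !is.null(kB), kA > 0, kB > 0)
      list(form = form, kA = kA, cA = cA, offsetA = offsetA,
           kB = kB, cB = cB, offsetB = offsetB)
    },
    restraint_field = {
      stopifnot(!is.null(k_base), k_base > 0, is.list(restraints),
                length(restraints) > 0)
      list(form = form, k_base = k_base, c_base = c_base,
           restraints = restraints)
    })
  structure(p, class = "toy_potential")
}

# quadratic coefficients of U(x, lambda) = 0.5*K x^2 - B x + C
toy_coeffs <- function(p, lambda) {
  terms <- toy_terms(p, lambda)
  K <- sum(terms$w * terms$k)
  B <- sum(terms$w * terms$k * terms$c)
  C <- sum(terms$w * (0.5 * terms$k * terms$c^2 + terms$off))
  list(K = K, B = B, C = C, mu = B / K)
}

# weighted harmonic terms at a given lambda, with d(weight)/d(lambda)
toy_terms <- function(p, lambda) {
  switch(p$form,
    lambda_coupled = list(
      k = c(p$kA, p$kB), c = c(p$cA, p$cB), off = c(p$offsetA, p$offsetB),
      w = c(1 - lambda, lambda), wprime = c(-1, 1)),
    restraint_field = {
      kr <- vapply(p$restraints, `[`, numeric(1), 1)
      cr <- vapply(p$restraints, `[`, numeric(1), 2)
      list(k = c(p$k_base, kr), c = c(p$c_base, cr),
           off = rep(0, 1 + length(kr)),
           w = c(1, rep(lambda, length(kr))),
           wprime = c(0, rep(1, length(kr))))
    },
    abort("lambda-dependent coefficients are undefined for a harmonic ladder"))
}

toy_energy <- function(p, x, window = NULL, lambda = NULL) {
  if (p$form == "harmonic_ladder") {
    stopifnot(!is.null(window))
    return(0.5 * p$k[window] * (x - p$centers[window])^2)
  }
  q <- toy_coeffs(p, lambda)
  0.5 * q$K * x^2 - q$B * x + q$C
}

toy_dudl <- function(p, x, lambda) {
  t <- toy_terms(p, lambda)
  out <- numeric(length(x))
  for (j in seq_along(t$k)) {
    out <- out + t$wprime[j] * (0.5 * t$k[j] * (x - t$c[j])^2 + t$off[j])
  }
  out
}

# -RT ln Z for the Gaussian integral of a quadratic potential
toy_state_free_energy <- function(p, window = NULL, lambda = NULL,
                                  temperature = DEFAULT_TEMPERATURE) {
  rt <- rt_kcal(temperature)
  if (p$form == "harmonic_ladder") {
    return(-rt * 0.5 * log(2 * pi * rt / p$k[window]))
  }
  q <- toy_coeffs(p, lambda)
  cmin <- q$C - q$B^2 / (2 * q$K)
  cmin - rt * 0.5 * log(2 * pi * rt / q$K)
}

#' Closed-form free-energy difference of a toy potential
#'
#' @param p A [toy_potential()].
#' @param from,to Window indices (ladder form) or lambda values (the
#'   lambda-dependent forms); defaults are the declared end states.
#' @param temperature Kelvin.
#' @return Exact free-energy difference, kcal/mol.
#' @export
toy_analytic_dg <- function(p, from = NULL, to = NULL,
                            temperature = DEFAULT_TEMPERATURE) {
  stopifnot(inherits(p, "toy_potential"))
  if (p$form == "harmonic_ladder") {
    from <- from %||% 1
    to <- to %||% length(p$k)
    return(toy_state_free_energy(p, window = to, temperature = temperature) -
           toy_state_free_energy(p, window = from, temperature = temperature))
  }
  from <- from %||% 0
  to <- to %||% 1
  toy_state_free_energy(p, lambda = to, temperature = temperature) -
    toy_state_free_energy(p, lambda = from, temperature = temperature)
}

#' Closed-form mean dU/dlambda of a toy potential
#'
#' The exact thermodynamic-integration integrand
#' `<dU/dlambda>_lambda` under the Boltzmann distribution at `lambda`.
#'
#' @param p A lambda-dependent [toy_potential()].
#' @param lambda Coupling value(s).
#' @param temperature Kelvin.
#' @return Numeric vector, kcal/mol.
#' @export
toy_analytic_dudl <- function(p, lambda,
                              temperature = DEFAULT_TEMPERATURE) {
  stopifnot(inherits(p, "toy_potential"))
  rt <- rt_kcal(temperature)
  vapply(lambda, function(l) {
    q <- toy_coeffs(p, l)
    t <- toy_terms(p, l)
    s2 <- rt / q$K
    sum(t$wprime * (0.5 * t$k * (s2 + (q$mu - t$c)^2) + t$off))
  }, numeric(1))
}

## ---- Metropolis window sampling -------------------------------------------

metropolis_1d <- function(energy_fn, x0, sd_target, n_samples,
                          temperature, rng_ready = TRUE) {
  rt <- rt_kcal(temperature)
  burn <- ceiling(0.1 * n_samples)
  step <- 2.4 * sd_target
  for (attempt in 1:5) {
    n_tot <- burn + n_samples
    xs <- numeric(n_tot)
    x <- x0
    ux <- energy_fn(x)
    prop <- stats::rnorm(n_tot, 0, step)
    uu <- stats::runif(n_tot)
    acc <- 0L
    for (i in seq_len(n_tot)) {
      xn <- x + prop[i]
      un <- energy_fn(xn)
      if (uu[i] < exp((ux - un) / rt)) {
        x <- xn; ux <- un; acc <- acc + 1L
      }
      xs[i] <- x
    }
    rate <- acc / n_tot
    if (rate >= 0.2) return(list(x = tail(xs, n_samples), acceptance = rate))
    if (rate < 0.01 && attempt == 5) {
      abort(sprintf("Metropolis acceptance %.3f below 0.01; adjust the step size", rate))
    }
    step <- step / 3
  }
  list(x = tail(xs, n_samples), acceptance = rate)
}

#' Sample window energy tables from a toy potential
#'
#' Runs an independent Metropolis chain in every window (10% burn-in,
#' proposal scaled to the window width, acceptance kept above 0.2), then
#' fills the reduced-potential matrix by re-evaluating every sample in
#' every window. For lambda-dependent forms the per-window dU/dlambda
#' samples are included.
#'
#' @param p A [toy_potential()].
#' @param schedule A [lambda_schedule()] giving the window lambdas
#'   (ignored for the ladder form, whose windows are its `k` vector).
#' @param n_samples Samples per window (>= 10).
#' @param seed Integer RNG seed; identical seed and parameters give
#'   identical tables.
#' @param temperature Kelvin.
#' @return A [window_table()].
#' @export
sample_windows <- function(p, schedule = NULL, n_samples = 1000, seed = 1,
                           temperature = DEFAULT_TEMPERATURE) {
  stopifnot(inherits(p, "toy_potential"), n_samples >= 10)
  rt <- rt_kcal(temperature)
  if (p$form == "harmonic_ladder") {
    K <- length(p$k)
    enfns <- lapply(seq_len(K), function(k) function(x) toy_energy(p, x, window = k))
    sds <- sqrt(rt / p$k)
    inits <- p$centers
    lambdas <- NULL
  } else {
    stopifnot(inherits(schedule, "lambda_schedule"))
    lambdas <- schedule$lambdas
    K <- length(lambdas)
    enfns <- lapply(lambdas, function(l) function(x) toy_energy(p, x, lambda = l))
    qs <- lapply(lambdas, function(l) toy_coeffs(p, l))
    sds <- vapply(qs, function(q) sqrt(rt / q$K), numeric(1))
    inits <- vapply(qs, function(q) q$mu, numeric(1))
  }
  withr::with_seed(seed, {
    chains <- lapply(seq_len(K), function(k) {
      metropolis_1d(enfns[[k]], inits[k], sds[k], n_samples, temperature)$x
    })
  })
  xall <- unlist(chains)
  u <- t(vapply(seq_len(K), function(k) enfns[[k]](xall) / rt,
                numeric(length(xall))))
  dudl <- NULL
  if (!is.null(lambdas)) {
    dudl <- lapply(seq_len(K), function(k) toy_dudl(p, chains[[k]], lambdas[k]))
  }
  window_table(u, rep(n_samples, K), schedule = schedule, dudl = dudl)
}

#' Two-window sampler for finite-difference derivatives
#'
#' Adapter turning a lambda-dependent toy potential into the `sampler`
#' argument of [fd_dudl()].
#'
#' @param p A lambda-dependent [toy_potential()].
#' @param n_samples Samples per window.
#' @param seed RNG seed.
#' @param temperature Kelvin.
#' @return A function `(lambdas) -> window_table`.
#' @export
toy_fd_sampler <- function(p, n_samples = 2000, seed = 1,
                           temperature = DEFAULT_TEMPERATURE) {
  force(p); force(n_samples); force(seed); force(temperature)
  function(lambdas, ...) {
    # bracketing windows may sit a hair outside [0, 1]; allow that here
    sched <- structure(list(mode = "explicit", lambdas = lambdas,
                            weights = NULL, n = length(lambdas)),
                       class = "lambda_schedule")
    sample_windows(p, sched, n_samples = n_samples, seed = seed,
                   temperature = temperature)
  }
}

## ---- toy protein-ligand complex -------------------------------------------

#' Generate a toy protein-ligand complex
#'
#' A rigid 3-residue helical peptide fragment (backbone N/CA/C/O, protein
#' role) with a branched 8-15 heavy-atom ligand grown in a pocket-like
#' position next to it, plus two ligand hydrogens and CONECT bonds. The
#' geometry guarantees valid protein-anchor candidates and a nonempty
#' search zone at the ligand centroid.
#'
#' @param seed Integer RNG seed.
#' @param path Optional path; if given the complex is also written as PDB.
#' @return An `abfe_structure`.
#' @export
make_toy_complex <- function(seed = 1, path = NULL) {
  withr::with_seed(seed, {
    prot <- toy_peptide()
    n_heavy <- sample(8:15, 1)
    lig <- toy_ligand(n_heavy, origin = c(6.5, 0.5, 1.0),
                      serial0 = max(prot$atoms$serial),
                      avoid = cbind(prot$atoms$x, prot$atoms$y,
                                    prot$atoms$z))
  })
  atoms <- dplyr::bind_rows(prot$atoms, lig$atoms)
  s <- as_structure(atoms, bonds = rbind(prot$bonds, lig$bonds))
  if (!is.null(path)) write_pdb(s, path)
  s
}

# idealised alpha-helical backbone, 3 residues
toy_peptide <- function() {
  res <- list()
  serial <- 0L
  bonds <- list()
  prev_c <- NULL
  for (i in 1:3) {
    t <- (i - 1) * deg2rad(100)
    ca <- c(2.3 * cos(t), 2.3 * sin(t), 1.5 * (i - 1))
    tn <- t - deg2rad(35)
    n <- c(1.9 * cos(tn), 1.9 * sin(tn), 1.5 * (i - 1) - 0.9)
    tc <- t + deg2rad(35)
    cc <- c(2.0 * cos(tc), 2.0 * sin(tc), 1.5 * (i - 1) + 0.9)
    o <- cc + c(0.65, 0.65, 0.75)
    at <- tibble::tibble(
      serial = serial + 1:4,
      name = c("N", "CA", "C", "O"),
      element = c("N", "C", "C", "O"),
      residue_name = "ALA", residue_number = i, chain_id = "A",
      x = c(n[1], ca[1], cc[1], o[1]),
      y = c(n[2], ca[2], cc[2], o[2]),
      z = c(n[3], ca[3], cc[3], o[3]),
      role = "protein")
    bonds[[length(bonds) + 1]] <- rbind(
      c(serial + 1, serial + 2), c(serial + 2, serial + 3),
      c(serial + 3, serial + 4))
    if (!is.null(prev_c)) {
      bonds[[length(bonds) + 1]] <- rbind(c(prev_c, serial + 1))
    }
    prev_c <- serial + 3L
    serial <- serial + 4L
    res[[i]] <- at
  }
  list(atoms = dplyr::bind_rows(res), bonds = do.call(rbind, bonds))
}

# branched ligand grown as a tree with 1.5 A bonds, intra-ligand clash
# distance 1.2 A, and at least 2.5 A from every protein atom
toy_ligand <- function(n_heavy, origin, serial0, avoid) {
  pos <- matrix(origin, nrow = 1)
  parent <- integer(0)
  elements <- "C"
  while (nrow(pos) < n_heavy) {
    for (try in 1:200) {
      anchor <- sample(nrow(pos), 1)
      dir <- stats::rnorm(3)
      dir <- dir / vnorm(dir)
      cand <- pos[anchor, ] + 1.5 * dir
      d <- sqrt(rowSums(sweep(pos, 2, cand)^2))
      d_prot <- sqrt(rowSums(sweep(avoid, 2, cand)^2))
      if (all(d[-anchor] > 1.2) && all(d_prot > 2.5)) {
        pos <- rbind(pos, cand)
        parent <- c(parent, anchor)
        elements <- c(elements, sample(c("C", "C", "C", "N", "O"), 1))
        break
      }
    }
    if (try == 200) abort("toy ligand growth failed to place an atom")
  }
  serials <- serial0 + seq_len(nrow(pos))
  heavy <- tibble::tibble(
    serial = as.integer(serials),
    name = paste0(elements, seq_along(serials)),
    element = elements,
    residue_name = "LIG", residue_number = 1L, chain_id = "L",
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    role = "ligand")
  bonds <- cbind(serials[parent], serials[-1])
  # two hydrogens on the first heavy atom, to exercise H exclusion
  hdir <- rbind(c(0, 0, 1), c(0, 1, 0))
  hs <- tibble::tibble(
    serial = as.integer(max(serials) + 1:2),
    name = paste0("H", 1:2),
    element = "H",
    residue_name = "LIG", residue_number = 1L, chain_id = "L",
    x = pos[1, 1] + hdir[, 1], y = pos[1, 2] + hdir[, 2],
    z = pos[1, 3] + hdir[, 3],
    role = "ligand")
  bonds <- rbind(bonds, cbind(serials[1], hs$serial))
  list(atoms = dplyr::bind_rows(heavy, hs), bonds = bonds)
}

#' Ligand-centroid search zone of a structure
#'
#' Convenience for toy fixtures: a [search_zone()] centred on the ligand
#' heavy-atom centroid.
#'
#' @param s An `abfe_structure`.
#' @param radius Zone radius, Angstrom.
#' @return A `search_zone`.
#' @export
ligand_centroid_zone <- function(s, radius = 4) {
  lig <- s[s$role == "ligand" & !s$is_hydrogen, ]
  if (nrow(lig) == 0) abort("structure has no ligand heavy atoms")
  search_zone(c(mean(lig$x), mean(lig$y), mean(lig$z)), radius)
}

## ---- Monte-Carlo oracle for the standard-state release --------------------

#' Monte-Carlo oracle for the TR release free energy
#'
#' Estimates the restrained configurational integral by free-energy
#' perturbation from the restrained Boltzmann distribution over the six TR
#' coordinates (each sampled with its Jacobian by Metropolis) to a
#' normalised Gaussian reference measure, then converts to the 1 M
#' standard state exactly as [tr_release_free_energy()] does. Unbiased for
#' any force constants; used to cross-check the quadrature route.
#'
#' @param tr A [tr_restraint()].
#' @param temperature Kelvin.
#' @param n_steps Metropolis samples per coordinate.
#' @param seed Integer RNG seed.
#' @return One-row tibble: `dg` estimate and standard error `se`
#'   (kcal/mol).
#' @export
mc_release_oracle <- function(tr, temperature = DEFAULT_TEMPERATURE,
                              n_steps = 20000, seed = 1) {
  stopifnot(inherits(tr, "tr_restraint"))
  rt <- rt_kcal(temperature)
  k <- tr$k
  if (any(k <= 0)) abort("all force constants must be positive")
  r0 <- tr$reference["r"]
  th0 <- deg2rad(tr$reference["theta"])
  Th0 <- deg2rad(tr$reference["Theta"])
  dims <- list(
    list(x0 = r0, k = k[["r"]], jac = function(x) x^2,
         lower = max(0, r0 - 12 * sqrt(rt / k[["r"]])), upper = Inf),
    list(x0 = th0, k = k[["theta"]], jac = sin, lower = 0, upper = pi),
    list(x0 = Th0, k = k[["Theta"]], jac = sin, lower = 0, upper = pi),
    list(x0 = 0, k = k[["phi"]], jac = function(x) rep(1, length(x)),
         lower = -pi, upper = pi),
    list(x0 = 0, k = k[["Phi"]], jac = function(x) rep(1, length(x)),
         lower = -pi, upper = pi),
    list(x0 = 0, k = k[["Psi"]], jac = function(x) rep(1, length(x)),
         lower = -pi, upper = pi))
  logz <- numeric(6)
  varlog <- numeric(6)
  withr::with_seed(seed, {
    for (d in seq_along(dims)) {
      dd <- dims[[d]]
      sig <- sqrt(rt / dd$k)
      en <- function(x) {
        ifelse(x <= dd$lower | x >= dd$upper, Inf,
               0.5 * dd$k * (x - dd$x0)^2 - rt * log(dd$jac(x)))
      }
      xs <- metropolis_1d(en, dd$x0, sig, n_steps, temperature)$x
      # reverse FEP: 1/Z = E_p[ phi(x) / (J(x) exp(-u/RT)) ], with phi a
      # normal reference truncated to the coordinate's domain
      coverage <- stats::pnorm(dd$upper, dd$x0, sig) -
        stats::pnorm(dd$lower, dd$x0, sig)
      w <- stats::dnorm(xs, dd$x0, sig) / coverage /
        (dd$jac(xs) * exp(-0.5 * dd$k * (xs - dd$x0)^2 / rt))
      logz[d] <- -log(mean(w))
      varlog[d] <- (block_uncertainty(w, n_blocks = 10) / mean(w))^2
    }
  })
  dg <- -rt * (log(8 * pi^2 * STANDARD_VOLUME_A3) - sum(logz))
  tibble::tibble(dg = dg, se = rt * sqrt(sum(varlog)))
}

## ---- end-to-end toy cycles ------------------------------------------------

# fixed toy "study conditions": base wells and restraint terms shared by
# the split and merged routes so their end states coincide exactly
toy_cycle_spec <- function() {
  list(
    k_site = 2, k_bulk = 1.5,
    rest = list(t = c(5, 0.4), l = c(4, 0.1), a = c(3, -0.2)),
    # transfer end/mid states (combined site well is k_site + sum k_rest = 14)
    e = list(kA = 14, cA = 0.25, kmid = 12, cmid = 0.1, offmid = 1.4,
             kB = 10, cB = 0.0, offB = 2.5),
    v = list(kA = 10, cA = 0.0, kmid = 6, cmid = -0.2, offmid = -3.0,
             kB = 3, cB = -0.4, offB = -6.0))
}

toy_attach_potential <- function(k_base, c_base, rest_names, scaled_names,
                                 spec) {
  fixed <- spec$rest[setdiff(rest_names, scaled_names)]
  scaled <- spec$rest[scaled_names]
  # fold fully attached restraints into an effective base well
  ks <- c(k_base, vapply(fixed, `[`, numeric(1), 1))
  cs <- c(c_base, vapply(fixed, `[`, numeric(1), 2))
  keff <- sum(ks)
  ceff <- sum(ks * cs) / keff
  toy_potential("restraint_field", k_base = keff, c_base = ceff,
                restraints = scaled)
}

toy_transfer_potential <- function(par, leg = c("full", "first", "second")) {
  leg <- match.arg(leg)
  # state offsets are absolute so split legs chain through the mid state
  # and first + second telescopes exactly to the full A -> B difference
  switch(leg,
    full = toy_potential("lambda_coupled", kA = par$kA, cA = par$cA,
                         kB = par$kB, cB = par$cB, offsetB = par$offB),
    first = toy_potential("lambda_coupled", kA = par$kA, cA = par$cA,
                          kB = par$kmid, cB = par$cmid,
                          offsetB = par$offmid),
    second = toy_potential("lambda_coupled", kA = par$kmid, cA = par$cmid,
                           offsetA = par$offmid,
                           kB = par$kB, cB = par$cB, offsetB = par$offB))
}

#' Run a full toy binding cycle
#'
#' Builds every simulated component of a scheme from toy potentials with
#' closed-form free energies, samples them with the Metropolis sampler,
#' estimates each leg with MBAR + block uncertainties, takes the analytic
#' TR release from [tr_release_free_energy()] on a fixed toy restraint, and
#' assembles the cycle. The split and merged routes share end states, so
#' their analytic totals are identical — the desk-scale analogue of the
#' merged-vs-split closure of production workflows.
#'
#' @param scheme `"merged_sdr"` or `"split_ddm"`.
#' @param seed Integer RNG seed.
#' @param n_windows Windows per simulated leg.
#' @param n_samples Samples per window.
#' @param temperature Kelvin.
#' @return A list: `result` (the assembled `abfe_cycle`), `ledger`,
#'   `analytic` (tibble of per-component closed-form values), and
#'   `analytic_dg_bind`.
#' @export
toy_cycle <- function(scheme = c("merged_sdr", "split_ddm"), seed = 1,
                      n_windows = 5, n_samples = 1500,
                      temperature = DEFAULT_TEMPERATURE) {
  scheme <- match.arg(scheme)
  spec <- toy_cycle_spec()
  sched <- explicit_schedule(seq(0, 1, length.out = n_windows))
  # analytic TR release on the reference toy-complex restraint; a fixed
  # condition of the toy study, shared by both routes and all seeds
  b_tr <- toy_reference_tr()
  b_val <- tr_release_free_energy(b_tr, temperature = temperature)

  attach_leg <- function(k_base, c_base, rest_names, scaled, sd_seed) {
    p <- toy_attach_potential(k_base, c_base, rest_names, scaled, spec)
    tab <- sample_windows(p, sched, n_samples = n_samples, seed = sd_seed,
                          temperature = temperature)
    est <- free_energy_estimate(tab, "mbar", temperature = temperature)
    list(est = est, analytic = toy_analytic_dg(p, temperature = temperature))
  }
  transfer_leg <- function(p, sd_seed) {
    tab <- sample_windows(p, sched, n_samples = n_samples, seed = sd_seed,
                          temperature = temperature)
    est <- free_energy_estimate(tab, "mbar", temperature = temperature)
    list(est = est, analytic = toy_analytic_dg(p, temperature = temperature))
  }
  mk <- function(letter, leg, sign = 1) {
    list(comp = component(letter, sign * leg$est$value,
                          leg$est$uncertainty),
         analytic = sign * leg$analytic)
  }

  if (scheme == "merged_sdr") {
    m <- attach_leg(spec$k_site, 0, character(0), c("t", "l", "a"), seed + 11)
    e <- transfer_leg(toy_transfer_potential(spec$e, "full"), seed + 12)
    v <- transfer_leg(toy_transfer_potential(spec$v, "full"), seed + 13)
    # n: release both conformational restraints in bulk + analytic TR term
    nrel <- attach_leg(spec$k_bulk, 0, character(0), c("l", "a"), seed + 14)
    parts <- list(
      mk("m", m), mk("e", e), mk("v", v),
      list(comp = component("n", -nrel$est$value + b_val,
                            nrel$est$uncertainty),
           analytic = -nrel$analytic + b_val))
  } else {
    t_ <- attach_leg(spec$k_site, 0, c("t"), "t", seed + 21)
    l_ <- attach_leg(spec$k_site, 0, c("t", "l"), "l", seed + 22)
    a_ <- attach_leg(spec$k_site, 0, c("t", "l", "a"), "a", seed + 23)
    e_ <- transfer_leg(toy_transfer_potential(spec$e, "first"), seed + 24)
    f_ <- transfer_leg(toy_transfer_potential(spec$e, "second"), seed + 25)
    v_ <- transfer_leg(toy_transfer_potential(spec$v, "first"), seed + 26)
    w_ <- transfer_leg(toy_transfer_potential(spec$v, "second"), seed + 27)
    c_ <- attach_leg(spec$k_bulk, 0, c("l"), "l", seed + 28)
    r_ <- attach_leg(spec$k_bulk, 0, c("l", "a"), "a", seed + 29)
    parts <- list(
      mk("a", a_), mk("l", l_), mk("t", t_),
      mk("e", e_), mk("f", f_), mk("v", v_), mk("w", w_),
      list(comp = component("b", b_val), analytic = b_val),
      mk("c", c_, sign = -1), mk("r", r_, sign = -1))
  }
  ledger <- component_ledger(lapply(parts, `[[`, "comp"))
  analytic <- tibble::tibble(
    letter = ledger$letter,
    analytic = vapply(parts, `[[`, numeric(1), "analytic"))
  list(result = assemble(ledger, scheme, temperature = temperature),
       ledger = ledger, analytic = analytic,
       analytic_dg_bind = -sum(analytic$analytic))
}

# a fixed, moderately stiff TR restraint measured on the toy complex
toy_reference_tr <- function(seed = 20) {
  s <- make_toy_complex(seed)
  zone <- ligand_centroid_zone(s, radius = 4)
  ca <- s$serial[s$name == "CA"]
  a <- select_anchors(s, zone, p1 = ca[1], p2 = ca[2], p3 = ca[3])
  if (is_unstable_pose(a)) abort("toy complex unexpectedly unstable")
  tr_restraint(a, measure_tr_coordinates(s, a),
               k_r = 10, k_angle = 100, k_dihedral = 100)
}
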