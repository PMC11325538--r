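## Analytic release of the TR restraints to the 1 M standard state.
##
## The restrained configurational integral over the six TR coordinates,
##   Z_TR = Int r^2 sin(theta) sin(Theta) exp(-u/RT) dr dtheta dTheta
##          dphi dPhi dPsi,
## is compared with the unrestrained standard-state volume 8*pi^2 * V0
## (V0 = 1/(C0*N_A) ~ 1660.54 A^3 at 1 M):
##   dG_release = -RT * ln(8*pi^2 * V0 / Z_TR).
## Releasing tight restraints into 1 M bulk is favorable (dG < 0).
## The separable harmonic potential factorises the integral into six
## one-dimensional integrals, evaluated by composite Gauss-Legendre
## quadrature with interval doubling; the stiff-spring (Boresch) closed
## form replaces each Gaussian integral with its infinite-stiffness limit.

# composite Gauss-Legendre integral of f on [a, b]; panels doubled until
# the relative change drops below rtol
gl_integral <- function(f, a, b, rtol = 1e-8, nodes = 16, max_panels = 512) {
  if (b <= a) return(0)
  g <- pracma::gaussLegendre(nodes, 0, 1)
  panels <- 1
  prev <- NA_real_
  repeat {
    edges <- seq(a, b, length.out = panels + 1)
    total <- 0
    for (p in seq_len(panels)) {
      h <- edges[p + 1] - edges[p]
      x <- edges[p] + g$x * h
      total <- total + h * sum(g$w * f(x))
    }
    if (!is.finite(total)) abort("quadrature produced a non-finite value")
    change <- if (is.na(prev)) Inf else abs(total - prev)
    if (change <= rtol * max(abs(total), .Machine$double.eps)) {
      return(total)
    }
    prev <- total
    panels <- panels * 2
    if (panels > max_panels) {
      abort(sprintf("quadrature did not converge (last change %.3e)", change))
    }
  }
}

#' Analytic TR-restraint release free energy to 1 M
#'
#' Evaluates the standard-state correction for releasing the six harmonic
#' translational/rotational restraints into unrestrained bulk at 1 M
#' (component letter `b` of the cycle ledger).
#'
#' @param tr A [tr_restraint()]. All six force constants must be positive
#'   (the configurational integral diverges otherwise).
#' @param temperature Kelvin.
#' @param method `"quadrature"` (default): direct one-dimensional
#'   integration of each factor of the separable configurational integral.
#'   `"stiff_spring"`: the Boresch closed form
#'   `Z_TR = r0^2 sin(theta0) sin(Theta0) (2 pi RT)^3 (prod k)^(-1/2)`,
#'   valid when every well is many sigma away from its domain boundary.
#' @return Release free energy in kcal/mol (negative for tight restraints).
#' @export
tr_release_free_energy <- function(tr, temperature = DEFAULT_TEMPERATURE,
                                   method = c("quadrature", "stiff_spring")) {
  method <- match.arg(method)
  stopifnot(inherits(tr, "tr_restraint"))
  k <- tr$k
  if (any(k <= 0)) {
    abort("all six force constants must be positive: the release integral diverges")
  }
  rt <- rt_kcal(temperature)
  r0 <- tr$reference["r"]
  th0 <- deg2rad(tr$reference["theta"])
  Th0 <- deg2rad(tr$reference["Theta"])
  if (method == "stiff_spring") {
    sig_th <- sqrt(rt / k["theta"]); sig_Th <- sqrt(rt / k["Theta"])
    if (min(th0, pi - th0) < 5 * sig_th || min(Th0, pi - Th0) < 5 * sig_Th) {
      warn("polar reference angle within 5 sigma of 0/180 deg; stiff-spring form is inaccurate")
    }
    z <- r0^2 * sin(th0) * sin(Th0) * (2 * pi * rt)^3 / sqrt(prod(k))
    return(unname(-rt * log(8 * pi^2 * STANDARD_VOLUME_A3 / z)))
  }
  sig_r <- sqrt(rt / k["r"])
  z_r <- gl_integral(function(r) r^2 * exp(-k["r"] * (r - r0)^2 / (2 * rt)),
                     max(0, r0 - 10 * sig_r), r0 + 10 * sig_r, rtol = 1e-10)
  z_ang <- function(k_a, a0) {
    gl_integral(function(a) sin(a) * exp(-k_a * (a - a0)^2 / (2 * rt)),
                0, pi, rtol = 1e-10)
  }
  # full-period dihedral integral; independent of the reference value
  z_dih <- function(k_d) {
    gl_integral(function(d) exp(-k_d * d^2 / (2 * rt)), -pi, pi, rtol = 1e-10)
  }
  z <- z_r * z_ang(k["theta"], th0) * z_ang(k["Theta"], Th0) *
    z_dih(k["phi"]) * z_dih(k["Phi"]) * z_dih(k["Psi"])
  unname(-rt * log(8 * pi^2 * STANDARD_VOLUME_A3 / z))
}
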