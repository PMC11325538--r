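## Letter-coded component ledger and thermodynamic-cycle assembly.
##
## Components carry the per-leg free energies in the site -> bulk
## (unbinding) direction as tabulated by BAT-style workflows: attach terms
## positive, release terms negative. The binding free energy is the
## negative of their sum; uncertainties combine in quadrature; Kd follows
## from dG at the 1 M standard state.

COMPONENT_LETTERS <- c("m", "m*", "a", "l", "t", "e", "f", "v", "w",
                       "n", "b", "c", "r")

COMPONENT_DESCRIPTIONS <- c(
  m = "attachment of all restraints (merged)",
  `m*` = "attachment of ligand TR + conformational restraints (merged)",
  a = "attachment of protein conformational restraints",
  l = "attachment of ligand conformational restraints",
  t = "attachment of ligand TR restraints",
  e = "ligand charge decoupling in site (SDR: + recoupling in bulk)",
  f = "ligand charge recoupling in bulk",
  v = "ligand LJ decoupling in site (SDR: + recoupling in bulk)",
  w = "ligand LJ recoupling in bulk",
  n = "release of all restraints (merged; includes analytic TR release)",
  b = "release of ligand TR restraints (analytic)",
  c = "release of ligand conformational restraints",
  r = "release of protein conformational restraints"
)

COMPONENT_METHODS <- list(
  m = "MBAR", `m*` = "MBAR", a = "MBAR", l = "MBAR", t = "MBAR",
  e = c("MBAR", "TI-GQ"), f = c("MBAR", "TI-GQ"),
  v = c("MBAR", "TI-GQ"), w = c("MBAR", "TI-GQ"),
  n = "MBAR", b = "analytical", c = "MBAR", r = "MBAR"
)

SCHEME_LETTERS <- list(
  split_ddm = c("a", "l", "t", "e", "f", "v", "w", "b", "c", "r"),
  merged_sdr = c("m", "e", "v", "n"),
  tevb = c("t", "e", "v", "b"),
  m_star_evbc = c("m*", "e", "v", "b", "c"),
  mevn = c("m", "e", "v", "n")
)

#' Letter-coded free-energy component
#'
#' One per-leg contribution of the cycle, identified by its letter code.
#' The `n` component folds the analytic TR release into its value, so
#' merged schemes do not add `b` separately; `tevb` and `m*evbc` do.
#'
#' @param letter One of `m, m*, a, l, t, e, f, v, w, n, b, c, r`.
#' @param value Free energy in kcal/mol, site -> bulk direction.
#' @param uncertainty Nonnegative, kcal/mol.
#' @param method `"MBAR"`, `"TI-GQ"` or `"analytical"`; defaults to the
#'   letter's canonical method. Letter/method compatibility is enforced.
#' @param pose Optional pose label.
#' @return One-row component tibble.
#' @export
component <- function(letter, value, uncertainty = 0, method = NULL,
                      pose = NA_character_) {
  if (!letter %in% COMPONENT_LETTERS) {
    abort(paste0("unknown component letter: ", letter))
  }
  allowed <- COMPONENT_METHODS[[letter]]
  method <- method %||% allowed[1]
  if (!method %in% allowed) {
    abort(sprintf("component '%s' cannot use method %s (allowed: %s)",
                  letter, method, paste(allowed, collapse = ", ")))
  }
  if (uncertainty < 0) abort("uncertainty must be nonnegative")
  tibble::tibble(letter = letter, value = as.numeric(value),
                 uncertainty = as.numeric(uncertainty),
                 method = method,
                 description = unname(COMPONENT_DESCRIPTIONS[letter]),
                 pose = as.character(pose))
}

#' Bind components into a ledger
#'
#' @param ... Component rows from [component()] (or tibbles thereof).
#' @return A component ledger tibble.
#' @export
component_ledger <- function(...) {
  led <- dplyr::bind_rows(...)
  if (nrow(led) == 0) {
    led <- component("m", 0)[0, ]
  }
  if (anyDuplicated(paste(led$letter, led$pose))) {
    abort("duplicate component letter within a pose")
  }
  led
}

#' Assemble a binding free energy from a component ledger
#'
#' Checks that every letter the scheme requires is present, sums the
#' component values (tabulated site -> bulk), and reports
#' `dG_bind = -sum`, the root-sum-square uncertainty, and the dissociation
#' constant `Kd = C0 exp(dG_bind / RT)`.
#'
#' @param components A component ledger tibble (single pose).
#' @param scheme One of `split_ddm`, `merged_sdr`, `tevb`, `m_star_evbc`,
#'   `mevn`.
#' @param temperature Kelvin.
#' @param total_planned_time_ns Optional simulation-time total from
#'   [plan_protocol()], carried into reports.
#' @return An `abfe_cycle` object; see [tidy.abfe_cycle()] and
#'   [glance.abfe_cycle()].
#' @export
assemble <- function(components, scheme = names(SCHEME_LETTERS),
                     temperature = DEFAULT_TEMPERATURE,
                     total_planned_time_ns = NA_real_) {
  scheme <- match.arg(scheme)
  need <- SCHEME_LETTERS[[scheme]]
  components <- tibble::as_tibble(components)
  missing <- setdiff(need, components$letter)
  if (length(missing) > 0) {
    abort(paste0("scheme ", scheme, " is missing component(s): ",
                 paste(missing, collapse = ", ")))
  }
  used <- components[match(need, components$letter), ]
  for (i in seq_len(nrow(used))) {
    allowed <- COMPONENT_METHODS[[used$letter[i]]]
    if (!used$method[i] %in% allowed) {
      abort(sprintf("component '%s' carries incompatible method %s",
                    used$letter[i], used$method[i]))
    }
  }
  dg <- -sum(used$value)
  unc <- sqrt(sum(used$uncertainty^2))
  structure(list(components = used, scheme = scheme,
                 dg_bind = dg, uncertainty = unc,
                 kd = kd_from_dg(dg, temperature),
                 temperature = temperature,
                 total_planned_time_ns = total_planned_time_ns),
            class = "abfe_cycle")
}

#' @export
print.abfe_cycle <- function(x, ...) {
  cat(sprintf("ABFE cycle (%s): dG_bind = %.1f (%.1f) kcal/mol, Kd = %.3g M\n",
              x$scheme, round_half_away(x$dg_bind, 1),
              round_half_away(x$uncertainty, 1), x$kd))
  invisible(x)
}

#' Tidy and glance methods for assembled cycles
#'
#' @param x An `abfe_cycle`.
#' @param ... Unused.
#' @return `tidy()`: the component table; `glance()`: one-row summary with
#'   `dg_bind`, `uncertainty`, `kd`, `scheme`, `temperature`.
#' @export
tidy.abfe_cycle <- function(x, ...) x$components

#' @rdname tidy.abfe_cycle
#' @export
glance.abfe_cycle <- function(x, ...) {
  tibble::tibble(scheme = x$scheme, dg_bind = x$dg_bind,
                 uncertainty = x$uncertainty, kd = x$kd,
                 temperature = x$temperature,
                 n_components = nrow(x$components),
                 total_planned_time_ns = x$total_planned_time_ns)
}

#' Merged-vs-split consistency report
#'
#' When initial and reference states match, the merged attach component m
#' should equal a+l+t, the merged release n should equal b+c+r, and each
#' SDR transfer component should equal the corresponding pair of
#' double-decoupling components (e ~ e+f, v ~ v+w). Reports the absolute
#' discrepancy of every supplied pair, per pose.
#'
#' @param merged Tibble with columns `pose`, `letter` (among m, e, v, n) and
#'   `value`.
#' @param split Tibble with columns `pose`, `letter`, `value`; letters may
#'   be granular (`a,l,t,b,c,r,e,f,v,w`) or pre-summed groups
#'   (`alt`, `bcr`, `ef`, `vw`) as printed in summary tables.
#' @return Tibble with one row per (pose, pair): `pose`, `pair`,
#'   `merged_value`, `split_value`, `discrepancy`; the maximum is in
#'   attribute `max_discrepancy` and in [glance()]-style column on the
#'   last row print.
#' @export
consistency_report <- function(merged, split) {
  merged <- tibble::as_tibble(merged)
  split <- tibble::as_tibble(split)
  if (!setequal(unique(merged$pose), unique(split$pose))) {
    abort("merged and split ledgers carry different pose labels")
  }
  groups <- list(m = c("a", "l", "t"), n = c("b", "c", "r"),
                 e = c("e", "f"), v = c("v", "w"))
  agg_names <- c(m = "alt", n = "bcr", e = "ef", v = "vw")
  rows <- list()
  for (p in unique(merged$pose)) {
    ms <- merged[merged$pose == p, ]
    ss <- split[split$pose == p, ]
    for (letter in intersect(names(groups), ms$letter)) {
      split_sum <- if (agg_names[[letter]] %in% ss$letter) {
        ss$value[ss$letter == agg_names[[letter]]]
      } else if (all(groups[[letter]] %in% ss$letter)) {
        sum(ss$value[ss$letter %in% groups[[letter]]])
      } else {
        next
      }
      mv <- ms$value[ms$letter == letter]
      rows[[length(rows) + 1]] <- tibble::tibble(
        pose = p,
        pair = paste0(letter, " vs ", paste(groups[[letter]], collapse = "+")),
        merged_value = mv, split_value = split_sum,
        discrepancy = abs(mv - split_sum))
    }
  }
  if (length(rows) == 0) abort("no comparable component pairs supplied")
  out <- dplyr::bind_rows(rows)
  attr(out, "max_discrepancy") <- max(out$discrepancy)
  out
}

#' Boltzmann combination of per-pose binding free energies
#'
#' For non-interconverting poses, the total standard binding free energy is
#' `-RT ln sum_i exp(-dG_i / RT)`, evaluated with an overflow-safe
#' log-sum-exp. The lowest pose dominates as the gaps grow.
#'
#' @param dg_poses Numeric vector of per-pose standard binding free
#'   energies, kcal/mol.
#' @param temperature Kelvin.
#' @return Combined binding free energy, kcal/mol.
#' @export
combine_poses <- function(dg_poses, temperature = DEFAULT_TEMPERATURE) {
  dg_poses <- as.numeric(dg_poses)
  if (length(dg_poses) == 0) abort("need at least one pose")
  rt <- rt_kcal(temperature)
  -rt * logsumexp(-dg_poses / rt)
}

#' Dissociation constant from a binding free energy (and back)
#'
#' `Kd = C0 exp(dG / RT)` with `C0 = 1 M`.
#'
#' @param dg Standard binding free energy, kcal/mol.
#' @param temperature Kelvin.
#' @return `kd_from_dg()`: Kd in molar; `dg_from_kd()`: kcal/mol.
#' @export
kd_from_dg <- function(dg, temperature = DEFAULT_TEMPERATURE) {
  exp(dg / rt_kcal(temperature))
}

#' @rdname kd_from_dg
#' @param kd Dissociation constant, molar.
#' @export
dg_from_kd <- function(kd, temperature = DEFAULT_TEMPERATURE) {
  stopifnot(all(kd > 0))
  rt_kcal(temperature) * log(kd)
}
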