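## Bundled reference tables for the BRD4(2) bromodomain fragment system
## (ligand from the 5uf0 crystal docked to the 5uez receptor), computed
## with the BAT2 workflow's published MD protocols. They are inputs for
## cycle arithmetic, closure checks, and replica statistics at desk scale;
## the package does not rerun the underlying MD.

brd4_file <- function(name) {
  system.file("extdata", name, package = "abfekit", mustWork = TRUE)
}

read_ref_tsv <- function(name) {
  tibble::as_tibble(utils::read.table(brd4_file(name), sep = "\t",
                                      header = TRUE))
}

#' Reference merged-vs-split component comparison (BRD4(2))
#'
#' Per-pose free-energy components (kcal/mol) for the five docked poses:
#' merged letters `m, e, v, n` against the pre-summed split groups
#' `alt = a+l+t`, `ef = e+f`, `vw = v+w`, `bcr = b+c+r`, as produced by
#' the OpenMM engine at the 100.8 ns (merged) and 148 ns (split)
#' protocols.
#'
#' @return Tibble with columns `pose`, `letter`, `value`, `uncertainty`,
#'   `scheme`.
#' @export
brd4_component_comparison <- function() {
  read_ref_tsv("brd4_merged_split.tsv")
}

#' Reference binding free energies (BRD4(2))
#'
#' Assembled standard binding free energies (kcal/mol) for the crystal
#' structure and five docked poses under each protocol (first-generation
#' split at 1.16 us; split/merged at 148/100.8 ns with AMBER or OpenMM).
#'
#' @return Tibble with columns `protocol`, `system`, `value`,
#'   `uncertainty`.
#' @export
brd4_binding_summary <- function() {
  read_ref_tsv("brd4_binding.tsv")
}

#' Reference short-protocol replica free energies (BRD4(2))
#'
#' Six independent replicas per pose for the short `tevb` (17.4 ns) and
#' `m*evbc` (20.4 ns) protocols.
#'
#' @return Tibble with columns `protocol`, `pose`, `replica`, `value`,
#'   `uncertainty`.
#' @export
brd4_short_replicas <- function() {
  read_ref_tsv("brd4_short_replicas.tsv")
}

#' Reference protocol configuration files
#'
#' Paths to the bundled run configurations reproducing the published
#' simulation-time accounting: the first-generation split protocol
#' (1160 ns total) and the merged/SDR protocol (100.8 ns total).
#'
#' @return Named character vector of file paths.
#' @export
brd4_plan_configs <- function() {
  c(bat1_split = brd4_file("bat1_split_plan.cfg"),
    merged = brd4_file("brd4_merged_plan.cfg"))
}
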