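# Packaged reference measurements for the anti-S-gatifloxacin monoclonal
# antibody / fluoroquinolone panel: competitive-ELISA IC50 and
# cross-reactivity values, rigid-body docking energies, and MD-derived
# quinolone-ring betweenness sums. These are experimental/simulation results
# for that antibody system, shipped as inputs for the classifier and the
# cross-reactivity arithmetic (the underlying 200 ns trajectories and assay
# plates are not reproducible at package scale).

ref_path <- function(file) {
  system.file("extdata", file, package = "fqcross", mustWork = TRUE)
}

#' Reference ELISA activity table
#'
#' IC50 (ng/mL) and cross-reactivity (percent, relative to gatifloxacin) of
#' the anti-S-GAT monoclonal antibody against a 26-compound fluoroquinolone
#' panel. Compounds without measurable inhibition up to 10,000 ng/mL are
#' censored (`censored = 1`; IC50 `> 10000`, CR `< 0.01`). The derived
#' `label` column calls a compound cross-reactive iff it has a finite IC50
#' with CR at or above 0.01% (the censoring convention of the assay).
#'
#' @return Tibble with `compound`, `ic50_ng_ml`, `ic50_sd`, `cr_percent`,
#'   `cr_sd`, `censored`, `label`.
#' @export
reference_activity <- function() {
  d <- readr::read_tsv(ref_path("reference_activity.tsv"),
                       show_col_types = FALSE)
  d$label <- ifelse(d$censored == 0 & !is.na(d$cr_percent) &
                      d$cr_percent >= 0.01,
                    "cross_reactive", "non_cross_reactive")
  d
}

#' Reference docking-energy table
#'
#' Rigid-body docking binding energies (kcal/mol) for every hapten variant
#' (stereoisomers listed separately), with the experimental cross-reactivity
#' class. `lowest_energy_kcal` is the minimum over docking clusters;
#' `mean_energy_kcal` the mean of the top cluster.
#'
#' @return Tibble with `hapten`, `label`, `lowest_energy_kcal`,
#'   `mean_energy_kcal`.
#' @export
reference_docking <- function() {
  readr::read_tsv(ref_path("reference_docking.tsv"), show_col_types = FALSE)
}

#' Reference quinolone-ring betweenness sums
#'
#' MD-derived quinolone-ring betweenness sums (rounded to integers) for every
#' hapten variant, with the experimental cross-reactivity class. This is the
#' input table for the cut-off classifier; zero entries correspond to ligands
#' that completely left the binding site during simulation.
#'
#' @return Tibble with `hapten`, `label`, `ring_sum`.
#' @export
reference_betweenness <- function() {
  readr::read_tsv(ref_path("reference_betweenness.tsv"),
                  show_col_types = FALSE)
}
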