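extdata <- function(file) {
  p <- system.file("extdata", file, package = "tyrlie")
  if (!nzchar(p)) stop("packaged fixture not found: ", file)
  p
}

read_fixture_csv <- function(file) {
  utils::read.csv(extdata(file), comment.char = "#",
                  stringsAsFactors = FALSE)
}

#' Packaged tyrosinase ligand descriptor table
#'
#' Nine ligands (the natural substrates l-DOPA and l-Tyr, the inhibitors
#' tropolone and kojic acid, and five kojic-acid analogs KA1--KA5) with
#' hydroxyl counts, charge class, per-ligand beta overrides and the
#' experimental inhibition/dissociation constants reported in the
#' enzymology literature. l-DOPA has no measured constant.
#'
#' @return Data frame, one row per ligand.
#' @export
ligand_table <- function() read_fixture_csv("ligands.csv")

#' Reference interaction-energy differences and binding free energies
#'
#' The packaged per-ligand bound-minus-free mean interaction-energy
#' differences (Delta V_vdw, Delta V_ele, kcal/mol, with their published
#' uncertainties) together with the reference LIE model-1/model-2
#' estimates, the experimental binding free energies, and the ligand
#' descriptors of [ligand_table()].
#'
#' @return Data frame, one row per ligand (9 rows), in fixture order.
#' @export
table4_fixture <- function() {
  d <- read_fixture_csv("energy_deltas.csv")
  merge(d, ligand_table(), by = "ligand_id", sort = FALSE)
}

#' Reference Cu coordination distances
#'
#' Crystallographic and mean simulated distances (with spreads) between
#' the two active-site copper ions and their His/water partners in the
#' kojic-acid complex, including the axial (Jahn--Teller elongated)
#' partner flags.
#'
#' @return Data frame, one row per metal--partner pair (12 rows).
#' @export
coordination_reference <- function() {
  read_fixture_csv("coordination_reference.csv")
}

#' Reference per-ion electrostatic contributions
#'
#' Mean electrostatic contribution of each Cu2+ ion to the
#' ligand--surrounding interaction energy, with mean ligand--ion
#' distances, for every complex.
#'
#' @return Data frame `ligand_id`, `ion_label`, `mean_distance`, `V_ele`.
#' @export
ion_contribution_reference <- function() {
  read_fixture_csv("ion_contributions.csv")
}

#' Reference per-residue interaction energies
#'
#' The per-residue mean interaction energies quoted for the decomposition
#' fixtures (Glu195 electrostatics in the kojic-acid complex; active-site
#' van der Waals contacts of the natural substrates).
#'
#' @return Data frame `ligand_id`, `residue`, `component`, `mean_energy`.
#' @export
residue_energy_reference <- function() {
  read_fixture_csv("residue_energies.csv")
}
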