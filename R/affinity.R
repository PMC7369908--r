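#' Gas constant in kcal/(mol K)
#' @export
R_KCAL <- 1.987204e-3

#' Convert a concentration to molar
#'
#' @param value Numeric value(s).
#' @param units One of `"M"`, `"mM"`, `"uM"` (micromolar; `"µM"` also
#'   accepted), `"nM"`.
#' @return Value in molar.
#' @export
convert_units <- function(value, units) {
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, "µM" = 1e-6, nM = 1e-9)
  if (length(units) != 1L || !units %in% names(scale))
    stop("unit error: unrecognized concentration unit '", units, "'")
  value * scale[[units]]
}

#' Experimental binding free energy from an inhibition constant
#'
#' Converts an inhibition (Ki) or dissociation (Kd) constant into a binding
#' free energy via `dG = R T ln K`, with K in molar. Dissociation
#' constants are treated identically to inhibition constants. The default
#' temperature is 298.15 K.
#'
#' @param Ki Constant in molar (> 0).
#' @param temperature Temperature in K (> 0).
#' @return Binding free energy in kcal/mol (negative for sub-molar K).
#' @export
delta_g_from_ki <- function(Ki, temperature = 298.15) {
  stopifnot(is.numeric(Ki), is.numeric(temperature))
  if (any(temperature <= 0)) stop("temperature must be > 0")
  if (any(is.na(Ki)) || any(Ki <= 0))
    stop("domain error: Ki must be a positive concentration (molar)")
  R_KCAL * temperature * log(Ki)
}

#' Experimental affinities for a ligand descriptor table
#'
#' Applies [delta_g_from_ki()] to every ligand with a measured constant
#' (`Ki_kind` of `"Ki"` or `"Kd"`); ligands with `Ki_kind = "none"` are
#' excluded from the result.
#'
#' @param ligands Descriptor table with `ligand_id`, `Ki_value`,
#'   `Ki_units`, `Ki_kind`.
#' @param temperature Temperature in K.
#' @return Data frame `ligand_id`, `dG_exp`, `temperature`.
#' @export
experimental_affinities <- function(ligands, temperature = 298.15) {
  stopifnot(is.data.frame(ligands),
            all(c("ligand_id", "Ki_value", "Ki_units") %in% names(ligands)))
  kind <- if ("Ki_kind" %in% names(ligands)) ligands$Ki_kind else
    ifelse(is.na(ligands$Ki_value), "none", "Ki")
  keep <- which(kind != "none" & !is.na(ligands$Ki_value))
  dg <- vapply(keep, function(i) {
    delta_g_from_ki(convert_units(ligands$Ki_value[i], ligands$Ki_units[i]),
                    temperature)
  }, numeric(1))
  data.frame(ligand_id = ligands$ligand_id[keep], dG_exp = dg,
             temperature = temperature, stringsAsFactors = FALSE)
}
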