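#' LIE scaling parameters
#'
#' The linear interaction energy estimator scales the bound-minus-free
#' change in average van der Waals energy by `alpha` and the electrostatic
#' change by `beta`. The standard literature parameterization uses
#' `alpha = 0.181` with `beta` in 0.33--0.50 depending on ligand chemistry;
#' alternatively both may be calibrated against experimental affinities
#' (see [fit_lie_parameters()]).
#'
#' @param alpha Non-polar (van der Waals) scaling factor, >= 0.
#' @param beta Polar (electrostatic) scaling factor, >= 0.
#' @param source One of `"literature"`, `"fitted"`, `"user"`.
#' @return An object of class `lie_parameters`.
#' @export
lie_parameters <- function(alpha, beta, source = "user") {
  source <- match.arg(source, c("literature", "fitted", "user"))
  stopifnot(is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
            is.numeric(beta), length(beta) == 1L, is.finite(beta))
  if (alpha < 0 || beta < 0)
    stop("'alpha' and 'beta' must be non-negative")
  structure(list(alpha = alpha, beta = beta, source = source),
            class = "lie_parameters")
}

#' Literature value of the LIE van der Waals scaling factor
#' @export
LIE_ALPHA_LITERATURE <- 0.181

#' Chemistry-dependent electrostatic scaling factor
#'
#' Resolves the LIE `beta` for one ligand. A per-ligand override (the
#' `beta_override` column of the shipped descriptor table, back-derived
#' from the reference LIE estimates) takes precedence; otherwise the
#' conventional chemistry rule applies: charged ligands 0.50; neutral with
#' no hydroxyl group 0.43; one hydroxyl 0.37; two or more hydroxyls 0.33.
#'
#' @param ligand One row of a ligand descriptor table (list or data.frame
#'   row) with `hydroxyl_count` and `charge_class`, optionally
#'   `beta_override`.
#' @param use_override Apply the override column when present (default
#'   `TRUE`).
#' @return Scalar beta.
#' @export
assign_beta <- function(ligand, use_override = TRUE) {
  if (is.data.frame(ligand)) {
    stopifnot(nrow(ligand) == 1L)
    ligand <- as.list(ligand)
  }
  ov <- ligand$beta_override
  if (use_override && !is.null(ov) && length(ov) == 1L && is.finite(ov))
    return(as.numeric(ov))
  oh <- ligand$hydroxyl_count
  cc <- ligand$charge_class
  if (is.null(oh) || is.null(cc) || is.na(oh) || is.na(cc))
    stop("descriptor error: ligand lacks hydroxyl_count/charge_class ",
         "and has no beta override")
  if (identical(cc, "charged")) return(0.50)
  if (oh == 0) 0.43 else if (oh == 1) 0.37 else 0.33
}

#' Bound-minus-free interaction-energy difference
#'
#' Combines the four block-averaged summaries of one ligand (bound/free x
#' electrostatic/vdw) into the Delta-V terms of the LIE estimator, with
#' uncertainties propagated in quadrature assuming independent states.
#'
#' @param bound_ele,bound_vdw,free_ele,free_vdw `energy_summary` objects
#'   from [block_average()], all for the same ligand.
#' @return An `energy_delta`: list with `ligand_id`, `dV_vdw`, `dV_ele`,
#'   `dV_vdw_sem`, `dV_ele_sem`.
#' @export
compute_delta <- function(bound_ele, bound_vdw, free_ele, free_vdw) {
  parts <- list(bound_ele, bound_vdw, free_ele, free_vdw)
  stopifnot(all(vapply(parts, inherits, logical(1), "energy_summary")))
  ids <- unique(vapply(parts, `[[`, character(1), "ligand_id"))
  if (length(ids) != 1L)
    stop("consistency error: mixed ligand_ids ",
         paste(ids, collapse = ", "))
  energy_delta(
    ligand_id = ids,
    dV_vdw = bound_vdw$mean - free_vdw$mean,
    dV_ele = bound_ele$mean - free_ele$mean,
    dV_vdw_sem = sqrt(bound_vdw$sem^2 + free_vdw$sem^2),
    dV_ele_sem = sqrt(bound_ele$sem^2 + free_ele$sem^2)
  )
}

#' Construct an energy delta directly
#'
#' @param ligand_id Ligand identifier.
#' @param dV_vdw,dV_ele Bound-minus-free mean interaction energies
#'   (kcal/mol).
#' @param dV_vdw_sem,dV_ele_sem Standard errors (kcal/mol), >= 0.
#' @return An object of class `energy_delta`.
#' @export
energy_delta <- function(ligand_id, dV_vdw, dV_ele, dV_vdw_sem = 0,
                         dV_ele_sem = 0) {
  stopifnot(is.finite(dV_vdw), is.finite(dV_ele),
            dV_vdw_sem >= 0, dV_ele_sem >= 0)
  structure(list(ligand_id = ligand_id, dV_vdw = dV_vdw, dV_ele = dV_ele,
                 dV_vdw_sem = dV_vdw_sem, dV_ele_sem = dV_ele_sem),
            class = "energy_delta")
}

#' LIE binding free energy
#'
#' The linear interaction energy estimate of the binding free energy:
#'
#'   dG = alpha * dV_vdw + beta * dV_ele
#'
#' where the Delta-V terms are the bound-minus-free changes in average
#' ligand--surrounding van der Waals and electrostatic interaction
#' energies. Uncertainty is propagated in quadrature:
#' `dG_sem = sqrt((alpha * dV_vdw_sem)^2 + (beta * dV_ele_sem)^2)`.
#'
#' @param delta An [energy_delta()].
#' @param params A [lie_parameters()].
#' @return A `lie_result`: list with `ligand_id`, `dG`, `dG_sem`,
#'   `parameters`.
#' @export
lie_binding_energy <- function(delta, params) {
  stopifnot(inherits(delta, "energy_delta"),
            inherits(params, "lie_parameters"))
  dG <- params$alpha * delta$dV_vdw + params$beta * delta$dV_ele
  dG_sem <- sqrt((params$alpha * delta$dV_vdw_sem)^2 +
                 (params$beta * delta$dV_ele_sem)^2)
  structure(list(ligand_id = delta$ligand_id, dG = dG, dG_sem = dG_sem,
                 parameters = params),
            class = "lie_result")
}

#' @export
print.lie_result <- function(x, ...) {
  cat(sprintf("<lie_result> %s: dG = %.3f +/- %.3f kcal/mol (alpha=%.3f, beta=%.3f, %s)\n",
              x$ligand_id, x$dG, x$dG_sem, x$parameters$alpha,
              x$parameters$beta, x$parameters$source))
  invisible(x)
}

#' LIE estimates for a table of ligands
#'
#' Applies [lie_binding_energy()] to every row of a delta table under
#' either the literature scheme (`alpha = 0.181`, per-ligand beta from
#' [assign_beta()]) or one fixed parameter pair.
#'
#' @param deltas Data frame with `ligand_id`, `dV_vdw`, `dV_ele` and
#'   optionally the `*_sem` columns.
#' @param ligands Ligand descriptor table (needed for the literature
#'   scheme's beta rule); matched by `ligand_id`.
#' @param params `NULL` (default) for the literature scheme, or a
#'   [lie_parameters()] applied uniformly.
#' @return Data frame with `ligand_id`, `alpha`, `beta`, `dG`, `dG_sem`.
#' @export
lie_table <- function(deltas, ligands = NULL, params = NULL) {
  stopifnot(is.data.frame(deltas),
            all(c("ligand_id", "dV_vdw", "dV_ele") %in% names(deltas)))
  n <- nrow(deltas)
  vsem <- rep(if ("dV_vdw_sem" %in% names(deltas)) deltas$dV_vdw_sem else 0,
              length.out = n)
  esem <- rep(if ("dV_ele_sem" %in% names(deltas)) deltas$dV_ele_sem else 0,
              length.out = n)
  res <- data.frame(ligand_id = deltas$ligand_id, alpha = numeric(n),
                    beta = numeric(n), dG = numeric(n), dG_sem = numeric(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    p <- if (is.null(params)) {
      if (is.null(ligands))
        stop("a ligand descriptor table is required for the literature scheme")
      row <- ligands[ligands$ligand_id == deltas$ligand_id[i], , drop = FALSE]
      if (nrow(row) != 1L)
        stop("descriptor error: ligand ", deltas$ligand_id[i],
             " not found (or duplicated) in descriptor table")
      lie_parameters(LIE_ALPHA_LITERATURE, assign_beta(row), "literature")
    } else params
    d <- energy_delta(deltas$ligand_id[i], deltas$dV_vdw[i],
                      deltas$dV_ele[i], vsem[i], esem[i])
    r <- lie_binding_energy(d, p)
    res$alpha[i] <- p$alpha; res$beta[i] <- p$beta
    res$dG[i] <- r$dG; res$dG_sem[i] <- r$dG_sem
  }
  res
}
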