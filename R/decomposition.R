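#' Per-residue interaction-energy profile
#'
#' Time-averages a set of per-group (residue or ion) bound-state energy
#' series for one ligand into a decomposition profile. Per-residue average
#' interaction energies highlight binding determinants; they are not a
#' rigorous free-energy partition (there is no exact decomposition of a
#' free energy into residue terms), and the package treats them as
#' presentation-level quantities only.
#'
#' @param series_list List of [energy_series()], all `state = "bound"` and
#'   sharing one `ligand_id`, with `group` set to residue/ion labels.
#' @param n_blocks Blocks for [block_average()] uncertainties.
#' @param t_start,t_end Optional analysis window (ps).
#' @return A `residue_profile`: list with `ligand_id` and `entries`, a data
#'   frame `residue`, `mean_ele`, `mean_vdw`, `sem_ele`, `sem_vdw` (NA for
#'   a component with no series).
#' @export
residue_profile <- function(series_list, n_blocks = 5L, t_start = NULL,
                            t_end = NULL) {
  stopifnot(length(series_list) >= 1L,
            all(vapply(series_list, inherits, logical(1), "energy_series")))
  ids <- unique(vapply(series_list, `[[`, character(1), "ligand_id"))
  if (length(ids) != 1L)
    stop("profile requires a single ligand_id, got: ",
         paste(ids, collapse = ", "))
  if (!all(vapply(series_list, `[[`, character(1), "state") == "bound"))
    stop("profile requires bound-state series only")
  groups <- unique(vapply(series_list, `[[`, character(1), "group"))
  groups <- sort(groups)
  get <- function(g, comp) {
    hit <- Filter(function(s) s$group == g && s$component == comp,
                  series_list)
    if (!length(hit)) return(c(NA_real_, NA_real_))
    s <- block_average(hit[[1L]], n_blocks = min(n_blocks, length(hit[[1L]])),
                       t_start = t_start, t_end = t_end)
    c(s$mean, s$sem)
  }
  ele <- vapply(groups, get, numeric(2), comp = "electrostatic")
  vdw <- vapply(groups, get, numeric(2), comp = "vdw")
  structure(
    list(ligand_id = ids,
         entries = data.frame(residue = groups, mean_ele = ele[1L, ],
                              mean_vdw = vdw[1L, ], sem_ele = ele[2L, ],
                              sem_vdw = vdw[2L, ], stringsAsFactors = FALSE,
                              row.names = NULL)),
    class = "residue_profile"
  )
}

#' Leading interaction partners of a profile
#'
#' Ranks groups by the chosen component's mean energy, most negative
#' (strongest attraction) first; ties break lexicographically by residue
#' label. Importance is read as most-attractive, not largest-magnitude.
#'
#' @param profile A [residue_profile()].
#' @param n Number of entries requested.
#' @param component `"electrostatic"` or `"vdw"`.
#' @return Data frame of the top `n` entries (`residue`, `mean`), with
#'   attribute `truncated = TRUE` when fewer than `n` groups exist.
#' @export
top_contributors <- function(profile, n = 5L,
                             component = c("electrostatic", "vdw")) {
  stopifnot(inherits(profile, "residue_profile"), n >= 1L)
  component <- match.arg(component)
  col <- if (component == "electrostatic") "mean_ele" else "mean_vdw"
  e <- profile$entries[is.finite(profile$entries[[col]]), ]
  ord <- order(e[[col]], e$residue)
  out <- data.frame(residue = e$residue[ord], mean = e[[col]][ord],
                    stringsAsFactors = FALSE)
  truncated <- n > nrow(out)
  out <- utils::head(out, n)
  attr(out, "truncated") <- truncated
  out
}

#' Copper-ion electrostatic contributions
#'
#' Pairs each active-site Cu2+ ion's mean electrostatic interaction energy
#' (from the decomposition profile) with its mean ligand--ion distance.
#'
#' @param profile A [residue_profile()] containing `Cu_A` and `Cu_B`
#'   groups.
#' @param distances Named numeric vector or data frame
#'   (`ion_label`, `mean_distance`) of mean ligand--ion distances
#'   (Angstrom).
#' @return Data frame `ligand_id`, `ion_label`, `mean_distance`, `V_ele`.
#' @export
ion_contributions <- function(profile, distances) {
  stopifnot(inherits(profile, "residue_profile"))
  ions <- c("Cu_A", "Cu_B")
  missing_ions <- setdiff(ions, profile$entries$residue)
  if (length(missing_ions))
    stop("structure error: profile lacks ion group(s) ",
         paste(missing_ions, collapse = ", "))
  if (is.data.frame(distances)) {
    d <- stats::setNames(distances$mean_distance, distances$ion_label)
  } else d <- distances
  if (!all(ions %in% names(d)))
    stop("structure error: distances must name both Cu_A and Cu_B")
  if (any(d[ions] <= 0)) stop("mean_distance must be > 0")
  v <- profile$entries$mean_ele[match(ions, profile$entries$residue)]
  data.frame(ligand_id = profile$ligand_id, ion_label = ions,
             mean_distance = as.numeric(d[ions]), V_ele = v,
             stringsAsFactors = FALSE)
}

#' Write a residue profile as delimited text
#'
#' Columns `residue,mean_ele,mean_vdw,sem_ele,sem_vdw`; a header comment
#' records the ligand and flags the averages as presentation-level
#' interaction energies, not free-energy components.
#'
#' @param profile A [residue_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "residue_profile"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    paste0("# per-residue mean interaction energies (kcal/mol), ligand ",
           profile$ligand_id),
    "# averages of interaction-energy terms; not a free-energy decomposition"),
    con)
  utils::write.csv(profile$entries, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
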