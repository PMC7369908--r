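# Run code under a fixed seed without disturbing the caller's RNG stream.
# All generators route their randomness through this (R's default
# Mersenne-Twister), so a (seed, generator version) pair is reproducible.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a stationary AR(1) interaction-energy series
#'
#' Emulates an MD ligand--surrounding interaction-energy trace: a
#' stationary Gaussian AR(1) process
#' `v_t = mean + phi * (v_{t-1} - mean) + eps_t`,
#' `eps_t ~ N(0, sd^2 * (1 - phi^2))`, so the marginal distribution is
#' `N(mean, sd^2)` at every frame and the lag-1 autocorrelation is `phi`.
#' Energies written every few dozen MD steps are strongly autocorrelated,
#' which is what makes block averaging (rather than the naive i.i.d.
#' standard error) the appropriate uncertainty estimate.
#'
#' @param mean,sd Marginal mean and standard deviation (kcal/mol),
#'   `sd >= 0`.
#' @param phi Lag-1 autocorrelation, in `[0, 1)`.
#' @param n_frames Number of frames.
#' @param seed Integer seed (determinism contract: same seed, same
#'   series).
#' @param dt Frame spacing in ps (default 0.05, i.e. every 25 steps of a
#'   2 fs integrator).
#' @param ligand_id,state,component,group Series identity, see
#'   [energy_series()].
#' @return An [energy_series()].
#' @export
gen_energy_series <- function(mean, sd, phi = 0.9, n_frames = 2000L,
                              seed = 1L, dt = 0.05, ligand_id = "LIG",
                              state = "bound", component = "electrostatic",
                              group = "surroundings") {
  stopifnot(sd >= 0, n_frames >= 1L)
  if (phi < 0 || phi >= 1)
    stop("stationarity error: 'phi' must lie in [0, 1)")
  v <- with_seed(seed, {
    if (sd == 0) rep(mean, n_frames) else {
      e <- stats::rnorm(n_frames)
      v <- numeric(n_frames)
      v[1L] <- mean + sd * e[1L]
      innov_sd <- sd * sqrt(1 - phi^2)
      for (t in seq_len(n_frames - 1L))
        v[t + 1L] <- mean + phi * (v[t] - mean) + innov_sd * e[t + 1L]
      v
    }
  })
  energy_series(ligand_id, state, component, dt * seq_len(n_frames), v,
                group)
}

#' Generate matched bound/free series for one ligand
#'
#' Produces the four series (bound/free x electrostatic/vdw) whose
#' population means differ by exactly the requested Delta V, so the full
#' pipeline ([block_average()] -> [compute_delta()] ->
#' [lie_binding_energy()]) recovers the target binding free energy up to
#' sampling noise. Free-state means are not observable quantities of the
#' analysis (only the difference enters the estimator); they default to
#' fixed fractions of the bound means (`free = frac * bound`, i.e.
#' `bound = dV / (1 - frac)`).
#'
#' @param ligand_id Ligand identifier.
#' @param dV_vdw,dV_ele Target bound-minus-free mean differences
#'   (kcal/mol).
#' @param sd,phi,n_frames,dt Noise model passed to [gen_energy_series()]
#'   (one common marginal `sd`).
#' @param free_frac_ele,free_frac_vdw Free-state mean as a fraction of the
#'   bound mean, per component.
#' @param seed Base seed; the four series use `seed`, `seed + 1`,
#'   `seed + 2`, `seed + 3`.
#' @return Named list of four [energy_series()]: `bound_ele`, `bound_vdw`,
#'   `free_ele`, `free_vdw`.
#' @export
gen_bound_free_pair <- function(ligand_id, dV_vdw, dV_ele, sd = 0.5,
                                phi = 0.9, n_frames = 2000L, dt = 0.05,
                                free_frac_ele = 0.27, free_frac_vdw = 0.5,
                                seed = 1L) {
  bound_ele <- dV_ele / (1 - free_frac_ele)
  bound_vdw <- dV_vdw / (1 - free_frac_vdw)
  mk <- function(mean, state, component, off)
    gen_energy_series(mean, sd, phi, n_frames, seed + off, dt,
                      ligand_id = ligand_id, state = state,
                      component = component)
  list(bound_ele = mk(bound_ele, "bound", "electrostatic", 0L),
       bound_vdw = mk(bound_vdw, "bound", "vdw", 1L),
       free_ele = mk(bound_ele - dV_ele, "free", "electrostatic", 2L),
       free_vdw = mk(bound_vdw - dV_vdw, "free", "vdw", 3L))
}

#' Run the LIE pipeline on generated bound/free series
#'
#' Convenience closure of the estimator over [gen_bound_free_pair()]
#' output: block-averages the four series, forms the delta, and applies
#' the parameters.
#'
#' @param pair Output of [gen_bound_free_pair()].
#' @param params A [lie_parameters()].
#' @param n_blocks Blocks for [block_average()].
#' @return A `lie_result` (see [lie_binding_energy()]).
#' @export
lie_from_series <- function(pair, params, n_blocks = 5L) {
  s <- lapply(pair, block_average, n_blocks = n_blocks)
  delta <- compute_delta(s$bound_ele, s$bound_vdw, s$free_ele, s$free_vdw)
  lie_binding_energy(delta, params)
}

#' Generate per-residue decomposition series for one ligand
#'
#' Builds bound-state electrostatic (and small vdw) series for the
#' interaction partners of the kojic-acid complex fixture: the two copper
#' ions at their reference mean contributions, Glu195 at its reference
#' electrostatic mean, plus weaker background residues. A
#' `"surroundings"` series equal to the frame-wise sum of all group series
#' is included, so per-group means sum to the total mean by construction.
#'
#' @param ligand_id Ligand (default `"KA"`; must appear in the packaged
#'   ion-contribution table).
#' @param sd,phi,n_frames Noise model per group series.
#' @param seed Base seed.
#' @return Named list of [energy_series()] (groups plus `surroundings`,
#'   electrostatic and vdw components).
#' @export
gen_decomposition_series <- function(ligand_id = "KA", sd = 0.3, phi = 0.9,
                                     n_frames = 2000L, seed = 1L) {
  ions <- ion_contribution_reference()
  ions <- ions[ions$ligand_id == ligand_id, ]
  if (!nrow(ions)) stop("no ion reference for ligand ", ligand_id)
  res <- residue_energy_reference()
  res <- res[res$ligand_id == ligand_id & res$component == "electrostatic", ]
  groups <- c(stats::setNames(ions$V_ele, ions$ion_label),
              stats::setNames(res$mean_energy, res$residue),
              His61 = -2.4, Asn205 = -1.6, Val218 = -0.8)
  vdw_means <- stats::setNames(rep(-1.0, length(groups)), names(groups))
  out <- list()
  off <- 0L
  sum_ele <- NULL; sum_vdw <- NULL
  for (g in names(groups)) {
    e <- gen_energy_series(groups[[g]], sd, phi, n_frames, seed + off,
                           ligand_id = ligand_id, state = "bound",
                           component = "electrostatic", group = g)
    v <- gen_energy_series(vdw_means[[g]], sd / 2, phi, n_frames,
                           seed + off + 1L, ligand_id = ligand_id,
                           state = "bound", component = "vdw", group = g)
    off <- off + 2L
    out[[paste0(g, "_ele")]] <- e
    out[[paste0(g, "_vdw")]] <- v
    sum_ele <- if (is.null(sum_ele)) e$values else sum_ele + e$values
    sum_vdw <- if (is.null(sum_vdw)) v$values else sum_vdw + v$values
  }
  out$surroundings_ele <- energy_series(ligand_id, "bound", "electrostatic",
                                        out[[1L]]$times, sum_ele)
  out$surroundings_vdw <- energy_series(ligand_id, "bound", "vdw",
                                        out[[1L]]$times, sum_vdw,
                                        "surroundings")
  out
}

octahedral_directions <- function(n) {
  base <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  if (n > 6L) stop("geometry error: at most 6 partners per site")
  base[seq_len(n), , drop = FALSE]
}

#' Generate a metal-site coordinate trajectory
#'
#' Emulates the fluctuating first coordination shell of a Cu2+ site: each
#' partner sits on a fixed (octahedral) direction from the metal and its
#' radial distance is drawn i.i.d. from `N(target_mean, target_sd)` per
#' frame, so [coordination_distances()] recovers the targets
#' asymptotically. The metal atom is static at the origin. Axial partners
#' (rows flagged `axial = 1`, if present) are placed on the +/-z
#' directions.
#'
#' @param partners Data frame with `partner`, `sim_mean`, `sim_sd` and
#'   optionally `axial` (0/1).
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @param metal_label Metal atom label (default `"Cu"`).
#' @return Trajectory data frame `frame`, `atom_label`, `x`, `y`, `z`.
#' @export
gen_site_trajectory <- function(partners, n_frames = 2000L, seed = 1L,
                                metal_label = "Cu") {
  stopifnot(is.data.frame(partners),
            all(c("partner", "sim_mean", "sim_sd") %in% names(partners)))
  if (any(partners$sim_mean <= 0))
    stop("geometry error: target mean distances must be > 0")
  np <- nrow(partners)
  base <- octahedral_directions(np)
  # axial-flagged partners take the +/-z directions (rows 5-6)
  assign_dirs <- seq_len(np)
  if ("axial" %in% names(partners) && np == 6L &&
      sum(partners$axial) %in% 1:2) {
    z_rows <- which(partners$axial == 1)
    other <- setdiff(seq_len(np), z_rows)
    assign_dirs[z_rows] <- c(5L, 6L)[seq_along(z_rows)]
    assign_dirs[other] <- setdiff(seq_len(np), c(5L, 6L)[seq_along(z_rows)])
  }
  dirs <- base[assign_dirs, , drop = FALSE]
  d <- with_seed(seed, {
    matrix(stats::rnorm(n_frames * np,
                        mean = rep(partners$sim_mean, each = n_frames),
                        sd = rep(partners$sim_sd, each = n_frames)),
           nrow = n_frames, ncol = np)
  })
  d[d <= 0] <- 1e-3  # distances are radial magnitudes
  frames <- rep(seq_len(n_frames), times = np + 1L)
  labels <- rep(c(metal_label, partners$partner), each = n_frames)
  xyz <- rbind(matrix(0, n_frames, 3L),
               do.call(rbind, lapply(seq_len(np), function(j)
                 d[, j] %o% dirs[j, ])))
  out <- data.frame(frame = frames, atom_label = labels, x = xyz[, 1],
                    y = xyz[, 2], z = xyz[, 3], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$frame,
            match(out$atom_label, c(metal_label, partners$partner))), ]
}

#' Write the packaged synthetic toy Cu site
#'
#' A deterministic, synthetic Cu2+ site (not derived from any deposited
#' structure): a copper ion coordinated by three histidine NE2 nitrogens
#' (one at an elongated axial distance, 2.30 Angstrom) and three water
#' oxygens, in near-octahedral geometry. With `two_sites = TRUE` a second
#' ion 4.2 Angstrom away is added, mimicking a binuclear active site (its
#' inner partners then bridge between the ions, as waters do in real
#' binuclear sites). The single-site version is shipped as
#' `extdata/cu_site_synthetic.pdb`.
#'
#' @param path Output PDB path.
#' @param two_sites Write a second ion as well (default `FALSE`).
#' @return `path`, invisibly.
#' @export
gen_toy_site <- function(path, two_sites = FALSE) {
  mk_site <- function(center, his_labels, wat_labels, resno0, serial0,
                      flip = 1) {
    # equatorial partners on x/y, axial (elongated, 2.30 A) on +z
    dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, flip),     # His NE2
                  c(-1, 0, 0), c(0, -1, 0), c(0, 0, -flip))  # water O
    dist <- c(2.05, 2.10, 2.30, 2.10, 2.12, 2.28)
    lines <- character(0)
    serial <- serial0
    for (i in 1:3) {
      xyz <- center + dist[i] * dirs[i, ]
      lines <- c(lines, sprintf(
        "ATOM  %5d  NE2 HIS A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           N",
        serial, resno0 + i, xyz[1], xyz[2], xyz[3], 1.00, 0.00))
      serial <- serial + 1L
    }
    for (i in 4:6) {
      xyz <- center + dist[i] * dirs[i, ]
      lines <- c(lines, sprintf(
        "HETATM%5d  O   HOH A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           O",
        serial, resno0 + i, xyz[1], xyz[2], xyz[3], 1.00, 0.00))
      serial <- serial + 1L
    }
    lines <- c(lines, sprintf(
      "HETATM%5d CU    CU A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          CU",
      serial, resno0 + 7L, center[1], center[2], center[3], 1.00, 0.00))
    lines
  }
  lines <- c("REMARK   1 SYNTHETIC TOY CU SITE, NOT A DEPOSITED STRUCTURE",
             mk_site(c(0, 0, 0), resno0 = 100L, serial0 = 1L))
  if (two_sites)
    lines <- c(lines, mk_site(c(4.2, 0, 0), resno0 = 200L, serial0 = 8L,
                              flip = -1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}
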