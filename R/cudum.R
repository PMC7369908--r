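#' Read a protein structure in PDB format
#'
#' Thin wrapper over [bio3d::read.pdb()] so all structure input flows
#' through one point.
#'
#' @param path PDB file path.
#' @return A `bio3d` `pdb` object.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  bio3d::read.pdb(path)
}

is_water_resid <- function(resid) {
  toupper(resid) %in% c("HOH", "WAT", "SPC", "TIP3", "H2O", "SOL", "WT")
}

#' Detect Cu2+ coordination sites in a structure
#'
#' Finds every copper atom and collects its coordinating partners: side
#' chain nitrogen atoms of histidine residues (ND1/NE2) and water oxygen
#' atoms within `cutoff` of the metal, sorted by distance. Tyrosinase-type
#' sites are binuclear (Cu_A, Cu_B), each ion His3-coordinated with
#' additional waters completing a distorted octahedron.
#'
#' @param pdb A `pdb` object from [read_structure()], or a file path.
#' @param cutoff Detection cutoff in Angstrom (default 3.0).
#' @return List of `metal_site` objects (possibly empty): each has
#'   `metal_label`, `metal_position` (length-3 numeric), and
#'   `coordinating`, a data frame `residue_label`, `atom_name`, `x`, `y`,
#'   `z`, `class` (`"protein"`/`"water"`), `distance`.
#' @export
detect_metal_sites <- function(pdb, cutoff = 3.0) {
  if (is.character(pdb)) pdb <- read_structure(pdb)
  a <- pdb$atom
  elesy <- toupper(trimws(ifelse(is.na(a$elesy), "", a$elesy)))
  elety <- toupper(trimws(a$elety))
  cu <- which(elesy == "CU" | (elesy == "" & elety == "CU"))
  if (!length(cu)) return(list())
  his_n <- toupper(a$resid) == "HIS" & elety %in% c("ND1", "NE2")
  wat_o <- is_water_resid(a$resid) & startsWith(elety, "O")
  cand <- which(his_n | wat_o)
  lapply(seq_along(cu), function(k) {
    i <- cu[k]
    pos <- c(a$x[i], a$y[i], a$z[i])
    d <- sqrt((a$x[cand] - pos[1])^2 + (a$y[cand] - pos[2])^2 +
              (a$z[cand] - pos[3])^2)
    sel <- cand[d <= cutoff]
    dsel <- d[d <= cutoff]
    ord <- order(dsel)
    structure(
      list(metal_label = paste0("Cu_", LETTERS[k]),
           metal_position = pos,
           coordinating = data.frame(
             residue_label = paste0(a$resid[sel], a$resno[sel])[ord],
             atom_name = elety[sel][ord],
             x = a$x[sel][ord], y = a$y[sel][ord], z = a$z[sel][ord],
             class = ifelse(is_water_resid(a$resid[sel]), "water",
                            "protein")[ord],
             distance = dsel[ord], stringsAsFactors = FALSE)),
      class = "metal_site")
  })
}

#' Default dummy-site parameters
#'
#' Reads a flat `key = value` config (default: the file shipped with the
#' package). The shipped charges and dummy bond lengths are placeholders
#' -- the published force-field values live in the original dummy-model
#' literature -- and every invariant the builder enforces (charge
#' conservation,
#' class distances, octahedral geometry) holds for any admissible values.
#'
#' @param path Config path; `NULL` for the packaged default.
#' @return List with `core_charge`, `eq_charge`, `ax_charge`,
#'   `eq_distance`, `ax_distance`.
#' @export
cudum_default_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cudum_params.cfg", package = "tyrlie")
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & grepl("=", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- stats::setNames(
    lapply(kv, function(p) as.numeric(trimws(p[2L]))),
    vapply(kv, function(p) trimws(p[1L]), character(1)))
  needed <- c("core_charge", "eq_charge", "ax_charge", "eq_distance",
              "ax_distance")
  if (!all(needed %in% names(out)))
    stop("config error: missing parameter(s) ",
         paste(setdiff(needed, names(out)), collapse = ", "))
  out[needed]
}

unit <- function(v) v / sqrt(sum(v^2))

# deterministic vector not parallel to the axis, for basis construction
perp_basis <- function(axis) {
  e <- diag(3)[, which.min(abs(axis))]
  u <- unit(e - sum(e * axis) * axis)
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  list(u = u, v = unit(v))
}

#' Build an octahedral dummy-atom model at a metal site
#'
#' Places a +2e Cu site as a core particle surrounded by six charged dummy
#' particles in a distorted (Jahn--Teller) octahedron: two axial dummies at
#' `ax_distance` along the elongation axis and four equatorial dummies at
#' `eq_distance` in the orthogonal plane. The axial direction points at
#' the coordinating partner farthest from the metal (the Jahn--Teller
#' elongated contact, e.g. His208 for Cu_A, His60 for Cu_B in tyrosinase),
#' unless `axial_partner` names one explicitly. The equatorial quartet is
#' rotated about the axis to minimize the summed angular deviation to the
#' remaining coordinating atoms. Total charge is checked to sum to exactly
#' +2.0 e.
#'
#' @param site A `metal_site` from [detect_metal_sites()].
#' @param params Parameter list, see [cudum_default_params()].
#' @param axial_partner Optional `residue_label` overriding the
#'   farthest-partner axis rule.
#' @return A `dummy_model`: list with the charges/distances, `axis` (unit
#'   vector), `core_position` and `dummy_positions` (6 x 3 matrix, rows
#'   DE1--DE4, DA1--DA2).
#' @export
build_dummy_model <- function(site, params = cudum_default_params(),
                              axial_partner = NULL) {
  stopifnot(inherits(site, "metal_site"))
  co <- site$coordinating
  if (nrow(co) < 3L)
    stop("geometry error: need >= 3 coordinating atoms to orient the site")
  total <- params$core_charge + 4 * params$eq_charge + 2 * params$ax_charge
  if (abs(total - 2.0) > 1e-12)
    stop("charge error: core + 4*eq + 2*ax must equal +2.0 e, got ", total)
  if (params$ax_distance < params$eq_distance)
    stop("geometry error: axial distance must be >= equatorial ",
         "(Jahn-Teller elongation)")

  pos <- as.matrix(co[, c("x", "y", "z")])
  rel <- sweep(pos, 2, site$metal_position)
  dist <- sqrt(rowSums(rel^2))
  ax_idx <- if (is.null(axial_partner)) which.max(dist) else {
    i <- which(co$residue_label == axial_partner)
    if (!length(i)) stop("geometry error: axial partner '", axial_partner,
                         "' not among coordinating atoms")
    i[1L]
  }
  axis <- unit(rel[ax_idx, ])

  others <- rel[-ax_idx, , drop = FALSE]
  odir <- others / dist[-ax_idx]
  if (all(abs(odir %*% axis) > 0.99))
    stop("orientation error: coordination is collinear with the axis")
  b <- perp_basis(axis)

  # rotate the equatorial quartet to face the non-axial partners
  ang_dev <- function(theta) {
    dirs <- vapply(theta + (0:3) * pi / 2, function(t)
      cos(t) * b$u + sin(t) * b$v, numeric(3))
    sum(apply(odir, 1L, function(p)
      min(acos(pmin(pmax(p %*% dirs, -1), 1)))))
  }
  grid <- seq(0, pi / 2, length.out = 181L)[-181L]
  f <- vapply(grid, ang_dev, numeric(1))
  best <- grid[which.min(f)]
  opt <- stats::optimize(ang_dev, interval = best + c(-1, 1) * pi / 180,
                         tol = 1e-10)
  theta <- if (opt$objective < min(f)) opt$minimum else best

  eq_dirs <- t(vapply(theta + (0:3) * pi / 2, function(t)
    cos(t) * b$u + sin(t) * b$v, numeric(3)))
  dummy <- rbind(eq_dirs * params$eq_distance,
                 rbind(axis, -axis) * params$ax_distance)
  dummy <- sweep(dummy, 2, site$metal_position, "+")
  rownames(dummy) <- c("DE1", "DE2", "DE3", "DE4", "DA1", "DA2")
  colnames(dummy) <- c("x", "y", "z")
  structure(
    list(metal_label = site$metal_label,
         core_position = site$metal_position,
         core_charge = params$core_charge, eq_charge = params$eq_charge,
         ax_charge = params$ax_charge, eq_distance = params$eq_distance,
         ax_distance = params$ax_distance, axis = axis,
         axial_partner = co$residue_label[ax_idx],
         dummy_positions = dummy,
         total_charge = total),
    class = "dummy_model")
}

#' @export
print.dummy_model <- function(x, ...) {
  cat(sprintf("<dummy_model> %s: core %+0.2fe + 4 eq %+0.2fe (%.2f A) + 2 ax %+0.2fe (%.2f A) = %+0.1fe\n",
              x$metal_label, x$core_charge, x$eq_charge, x$eq_distance,
              x$ax_charge, x$ax_distance, x$total_charge))
  cat(sprintf("  axis toward %s\n", x$axial_partner))
  invisible(x)
}

pdb_hetatm <- function(serial, name, resname, chain, resno, xyz, elesy) {
  sprintf("HETATM%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, resname, chain, resno, xyz[1], xyz[2], xyz[3],
          1.00, 0.00, elesy)
}

#' Write a structure augmented with dummy-site records
#'
#' Appends, per built model, seven HETATM records (core `CU` plus dummies
#' `DE1`--`DE4`, `DA1`--`DA2`, residue name `DUM`, element `D` for the
#' dummies) after the original records, which are preserved verbatim.
#'
#' @param path_in Input PDB path.
#' @param models List of `dummy_model` objects.
#' @param path_out Output PDB path.
#' @return `path_out`, invisibly.
#' @export
write_structure_with_dummies <- function(path_in, models, path_out) {
  stopifnot(length(models) >= 1L,
            all(vapply(models, inherits, logical(1), "dummy_model")))
  lines <- readLines(path_in)
  atoms <- grepl("^(ATOM  |HETATM)", lines)
  if (any(grepl("DUM", substr(lines[atoms], 18, 20))))
    stop("naming error: structure already contains DUM residues")
  serials <- suppressWarnings(as.integer(substr(lines[atoms], 7, 11)))
  resnos <- suppressWarnings(as.integer(substr(lines[atoms], 23, 26)))
  serial <- max(serials, na.rm = TRUE)
  resno <- max(resnos, na.rm = TRUE)
  new <- character(0)
  for (m in models) {
    resno <- resno + 1L
    serial <- serial + 1L
    new <- c(new, pdb_hetatm(serial, "CU", "DUM", "X", resno,
                             m$core_position, "CU"))
    for (nm in rownames(m$dummy_positions)) {
      serial <- serial + 1L
      new <- c(new, pdb_hetatm(serial, nm, "DUM", "X", resno,
                               m$dummy_positions[nm, ], "D"))
    }
  }
  last_atom <- max(which(atoms))
  out <- append(lines, new, after = last_atom)
  writeLines(out, path_out)
  invisible(path_out)
}

#' Read a coordinate trajectory
#'
#' Accepts either the delimited frame-table dialect
#' (`frame,atom_label,x,y,z`, `#` comments) or a multi-model PDB (frames
#' as MODEL blocks; labels formed as `<resid><resno>_<atom name>`).
#'
#' @param path Trajectory file.
#' @return Data frame `frame`, `atom_label`, `x`, `y`, `z`.
#' @export
read_trajectory <- function(path) {
  first <- readLines(path, n = 50L)
  if (any(grepl("^(MODEL|ATOM  |HETATM)", first))) {
    pdb <- bio3d::read.pdb(path, multi = TRUE)
    labels <- paste0(pdb$atom$resid, pdb$atom$resno, "_",
                     trimws(pdb$atom$elety))
    nf <- nrow(pdb$xyz)
    do.call(rbind, lapply(seq_len(nf), function(f) {
      m <- matrix(pdb$xyz[f, ], ncol = 3L, byrow = TRUE)
      data.frame(frame = f, atom_label = labels, x = m[, 1], y = m[, 2],
                 z = m[, 3], stringsAsFactors = FALSE)
    }))
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
    delim <- if (grepl("\t", lines[1L])) "\t" else ","
    tab <- utils::read.table(text = lines, header = TRUE, sep = delim,
                             stringsAsFactors = FALSE)
    needed <- c("frame", "atom_label", "x", "y", "z")
    if (!all(needed %in% names(tab)))
      stop("format error: trajectory table needs columns ",
           paste(needed, collapse = ", "))
    tab[, needed]
  }
}

#' Write a frame-table trajectory
#' @param traj Data frame `frame`, `atom_label`, `x`, `y`, `z`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(traj[, c("frame", "atom_label", "x", "y", "z")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Metal--partner coordination-distance statistics over a trajectory
#'
#' Per-partner mean and standard deviation of the metal--partner Euclidean
#' distance over all frames.
#'
#' @param traj Trajectory data frame (see [read_trajectory()]).
#' @param metal_label Label of the metal atom (default `"Cu"`).
#' @param partners Character vector of partner labels; default all
#'   non-metal labels.
#' @return A `coordination_stats` data frame: `partner`, `mean`, `sd`,
#'   `n_frames`.
#' @export
coordination_distances <- function(traj, metal_label = "Cu",
                                   partners = NULL) {
  stopifnot(all(c("frame", "atom_label", "x", "y", "z") %in% names(traj)))
  if (is.null(partners))
    partners <- setdiff(unique(traj$atom_label), metal_label)
  frames <- sort(unique(traj$frame))
  dists <- matrix(NA_real_, length(frames), length(partners),
                  dimnames = list(NULL, partners))
  for (fi in seq_along(frames)) {
    fr <- traj[traj$frame == frames[fi], ]
    mi <- match(metal_label, fr$atom_label)
    idx <- match(partners, fr$atom_label)
    if (is.na(mi) || anyNA(idx))
      stop("frame error: frame ", frames[fi], " lacks atom(s) ",
           paste(c(metal_label, partners)[is.na(c(mi, idx))], collapse = ", "))
    dists[fi, ] <- sqrt((fr$x[idx] - fr$x[mi])^2 + (fr$y[idx] - fr$y[mi])^2 +
                        (fr$z[idx] - fr$z[mi])^2)
  }
  out <- data.frame(partner = partners,
                    mean = colMeans(dists),
                    sd = apply(dists, 2L, stats::sd),
                    n_frames = length(frames), stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("coordination_stats", "data.frame")
  out
}

#' Jahn--Teller axial-elongation score
#'
#' Ratio of the mean axial coordination distance to the mean of the
#' equatorial distances. A d9 Cu2+ octahedron distorts by elongating its
#' axial contacts, so a ratio > 1 is the geometric signature of the
#' Jahn--Teller effect; a perfect octahedron scores exactly 1.
#'
#' @param stats A `coordination_stats` data frame (or any data frame with
#'   `partner` and `mean`).
#' @param axial_partners,equatorial_partners Partner labels.
#' @return Scalar ratio.
#' @export
jahn_teller_score <- function(stats, axial_partners, equatorial_partners) {
  if (!length(axial_partners) || !length(equatorial_partners))
    stop("argument error: need at least one axial and one equatorial partner")
  pick <- function(p) {
    i <- match(p, stats$partner)
    if (anyNA(i)) stop("argument error: unknown partner(s) ",
                       paste(p[is.na(i)], collapse = ", "))
    stats$mean[i]
  }
  mean(pick(axial_partners)) / mean(pick(equatorial_partners))
}

#' Radial distribution function around a center atom
#'
#' Histogram of center--species distances over all frames, normalized per
#' bin by the spherical-shell volume and by the mean number density of the
#' selected species within the `r_max` sphere (local-density convention
#' appropriate for a non-periodic spherical droplet). `g(r) = 1` then
#' corresponds to the selected species spread uniformly through the
#' analysis sphere.
#'
#' @param traj Trajectory data frame.
#' @param center_label Center atom label.
#' @param species_labels Labels of the surrounding species.
#' @param r_max Histogram range (Angstrom).
#' @param n_bins Number of uniform bins (>= 10).
#' @return An `rdf_result`: list with `r_centers`, `g`, `n_frames`,
#'   `first_peak` (center of the maximal bin).
#' @export
radial_distribution <- function(traj, center_label, species_labels,
                                r_max = 6.0, n_bins = 60L) {
  stopifnot(r_max > 0, n_bins >= 10L)
  species_labels <- setdiff(species_labels, center_label)
  if (!length(species_labels)) stop("selection error: no species selected")
  if (!any(traj$atom_label %in% species_labels))
    stop("selection error: selected species absent from trajectory")
  frames <- sort(unique(traj$frame))
  edges <- seq(0, r_max, length.out = n_bins + 1L)
  counts <- numeric(n_bins)
  n_in_sphere <- 0
  for (f in frames) {
    fr <- traj[traj$frame == f, ]
    ci <- match(center_label, fr$atom_label)
    if (is.na(ci)) stop("frame error: frame ", f, " lacks ", center_label)
    si <- which(fr$atom_label %in% species_labels)
    d <- sqrt((fr$x[si] - fr$x[ci])^2 + (fr$y[si] - fr$y[ci])^2 +
              (fr$z[si] - fr$z[ci])^2)
    d <- d[d <= r_max]
    n_in_sphere <- n_in_sphere + length(d)
    h <- findInterval(d, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
    counts <- counts + tabulate(h, nbins = n_bins)
  }
  nf <- length(frames)
  rho <- (n_in_sphere / nf) / (4 / 3 * pi * r_max^3)
  shell <- 4 / 3 * pi * diff(edges^3)
  g <- counts / (nf * shell * rho)
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  structure(list(r_centers = centers, g = g, n_frames = nf,
                 first_peak = centers[which.max(g)]),
            class = "rdf_result")
}
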