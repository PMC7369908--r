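toy_path <- function(two_sites = FALSE) {
  f <- tempfile(fileext = ".pdb")
  gen_toy_site(f, two_sites = two_sites)
  f
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(qr_q) < 0) qr_q[, 1] <- -qr_q[, 1]
  qr_q
}

test_that("metal-site detection finds the toy site and its shell", {
  sites <- detect_metal_sites(toy_path())
  expect_length(sites, 1L)
  co <- sites[[1]]$coordinating
  expect_equal(nrow(co), 6L)
  expect_setequal(unique(co$class), c("protein", "water"))
  expect_false(is.unsorted(co$distance))       # sorted by distance
  expect_equal(sum(co$class == "protein"), 3L) # His3 coordination

  two <- detect_metal_sites(toy_path(two_sites = TRUE))
  expect_length(two, 2L)
  expect_setequal(vapply(two, `[[`, character(1), "metal_label"),
                  c("Cu_A", "Cu_B"))
})

test_that("metal-free structures yield an empty site list", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  NE2 HIS A 101       2.050   0.000   0.000  1.00  0.00           N",
    "END"), f)
  expect_length(detect_metal_sites(f), 0L)
})

test_that("dummy models conserve charge and class distances exactly", {
  site <- detect_metal_sites(toy_path())[[1]]
  m <- build_dummy_model(site)
  expect_identical(m$total_charge, 2.0)
  rel <- sweep(m$dummy_positions, 2, m$core_position)
  d <- sqrt(rowSums(rel^2))
  expect_lt(max(abs(d[1:4] - m$eq_distance)), 1e-9)
  expect_lt(max(abs(d[5:6] - m$ax_distance)), 1e-9)
  expect_gte(m$ax_distance, m$eq_distance)
  # equatorial dummies are pairwise orthogonal about the axis
  eq <- rel[1:4, ] / m$eq_distance
  expect_lt(abs(sum(eq[1, ] * eq[2, ])), 1e-9)
  # axis points at the farthest (Jahn-Teller elongated) partner
  expect_equal(m$axial_partner,
               site$coordinating$residue_label[which.max(site$coordinating$distance)])
})

test_that("dummy construction is equivariant under rigid motions", {
  site <- detect_metal_sites(toy_path())[[1]]
  m0 <- build_dummy_model(site)
  for (seed in 1:5) {
    rot <- random_rotation(seed)
    shift <- c(3, -2, 5)
    rsite <- site
    rsite$metal_position <- drop(rot %*% site$metal_position) + shift
    xyz <- as.matrix(site$coordinating[, c("x", "y", "z")]) %*% t(rot)
    rsite$coordinating[, c("x", "y", "z")] <-
      sweep(xyz, 2, shift, "+")
    m1 <- build_dummy_model(rsite)
    expected <- sweep(m0$dummy_positions %*% t(rot), 2, shift, "+")
    # compare as point sets (the pi/2 equatorial symmetry can relabel)
    cost <- as.matrix(stats::dist(rbind(expected, m1$dummy_positions)))
    cost <- cost[1:6, 7:12]
    expect_lt(max(apply(cost, 1, min)), 1e-6)
  }
})

test_that("dummy construction rejects ill-posed sites and parameters", {
  site <- detect_metal_sites(toy_path())[[1]]
  small <- site
  small$coordinating <- small$coordinating[1:2, ]
  expect_error(build_dummy_model(small), "geometry error")

  lin <- site
  lin$coordinating <- data.frame(
    residue_label = c("A1", "A2", "A3"), atom_name = "NE2",
    x = c(2, -2, 2.3), y = 0, z = 0, class = "protein",
    distance = c(2, 2, 2.3), stringsAsFactors = FALSE)
  expect_error(build_dummy_model(lin), "orientation error")

  bad <- cudum_default_params()
  bad$eq_charge <- 0.5
  expect_error(build_dummy_model(site, bad), "charge error")
  swapped <- cudum_default_params()
  swapped$ax_distance <- 0.5
  expect_error(build_dummy_model(site, swapped), "Jahn-Teller")
})

test_that("augmented structures carry 7 new records per site and round-trip", {
  f <- toy_path()
  sites <- detect_metal_sites(f)
  models <- lapply(sites, build_dummy_model)
  out <- tempfile(fileext = ".pdb")
  write_structure_with_dummies(f, models, out)
  orig_n <- sum(grepl("^(ATOM  |HETATM)", readLines(f)))
  lines <- readLines(out)
  atoms <- lines[grepl("^(ATOM  |HETATM)", lines)]
  expect_equal(length(atoms), orig_n + 7L)
  dum <- atoms[substr(atoms, 18, 20) == "DUM"]
  expect_equal(length(dum), 7L)
  expect_setequal(trimws(substr(dum, 13, 16)),
                  c("CU", "DE1", "DE2", "DE3", "DE4", "DA1", "DA2"))
  # re-read: dummy coordinates survive at PDB (3-decimal) precision
  pdb <- read_structure(out)
  da1 <- pdb$atom[trimws(pdb$atom$elety) == "DA1", ]
  expect_equal(unlist(da1[, c("x", "y", "z")], use.names = FALSE),
               unname(models[[1]]$dummy_positions["DA1", ]),
               tolerance = 5e-4)
  # appending to an already-augmented file is a naming collision
  expect_error(write_structure_with_dummies(out, models,
                                            tempfile(fileext = ".pdb")),
               "naming error")
})

test_that("a two-site structure gains 14 records with unique serials", {
  f <- toy_path(two_sites = TRUE)
  sites <- detect_metal_sites(f)
  models <- lapply(sites, build_dummy_model)
  out <- tempfile(fileext = ".pdb")
  write_structure_with_dummies(f, models, out)
  lines <- readLines(out)
  atoms <- lines[grepl("^(ATOM  |HETATM)", lines)]
  dum <- atoms[substr(atoms, 18, 20) == "DUM"]
  expect_equal(length(dum), 14L)
  serials <- as.integer(substr(atoms, 7, 11))
  expect_false(anyDuplicated(serials) > 0)
})

test_that("coordination statistics are exact on a static trajectory", {
  cr <- coordination_reference()
  cua <- cr[cr$ion == "Cu_A", ]
  cua$sim_sd <- 0
  traj <- gen_site_trajectory(cua, n_frames = 10L, seed = 1L)
  st <- coordination_distances(traj)
  expect_equal(st$mean[match(cua$partner, st$partner)], cua$sim_mean,
               tolerance = 1e-9)
  expect_true(all(st$sd < 1e-12))

  broken <- traj[!(traj$frame == 5L & traj$atom_label == "His204"), ]
  expect_error(coordination_distances(broken), "frame error: frame 5")
})

test_that("coordination statistics recover generator targets", {
  cr <- coordination_reference()
  for (ion in c("Cu_A", "Cu_B")) {
    spec <- cr[cr$ion == ion, ]
    traj <- gen_site_trajectory(spec, n_frames = 2000L,
                                seed = if (ion == "Cu_A") 21L else 22L)
    st <- coordination_distances(traj)
    i <- match(spec$partner, st$partner)
    expect_lt(max(abs(st$mean[i] - spec$sim_mean)), 0.02)
    expect_lt(max(abs(st$sd[i] - spec$sim_sd)), 0.02)
  }
})

test_that("the Jahn-Teller score flags axial elongation", {
  cr <- coordination_reference()
  # reference-mean fixtures: ratios from the printed coordination table
  stats_b <- data.frame(partner = c("His60", "His42", "His69"),
                        mean = c(2.33, 2.00, 2.01))
  expect_equal(jahn_teller_score(stats_b, "His60", c("His42", "His69")),
               2.33 / mean(c(2.00, 2.01)), tolerance = 1e-12)
  expect_lt(abs(jahn_teller_score(stats_b, "His60", c("His42", "His69")) -
                1.162), 0.001)
  stats_a <- data.frame(partner = c("His208", "His204", "His231"),
                        mean = c(2.30, 2.15, 2.02))
  expect_lt(abs(jahn_teller_score(stats_a, "His208", c("His204", "His231")) -
                1.103), 0.001)
  perfect <- data.frame(partner = c("ax", "eq1", "eq2"), mean = c(2, 2, 2))
  expect_equal(jahn_teller_score(perfect, "ax", c("eq1", "eq2")), 1)
  expect_error(jahn_teller_score(perfect, character(0), "eq1"),
               "argument error")
  expect_error(jahn_teller_score(perfect, "nope", "eq1"), "unknown")
})

test_that("the RDF first peak sits at the coordination-shell distance", {
  spec <- data.frame(partner = paste0("P", 1:6), sim_mean = 2.1,
                     sim_sd = 0.05)
  traj <- gen_site_trajectory(spec, n_frames = 300L, seed = 8L)
  rdf <- radial_distribution(traj, "Cu", spec$partner, r_max = 5,
                             n_bins = 50L)
  expect_lt(abs(rdf$first_peak - 2.1), 0.1 / 2 + 1e-9)  # within the peak bin
  expect_true(all(rdf$g >= 0))

  static <- data.frame(partner = "P1", sim_mean = 2.0, sim_sd = 0)
  straj <- gen_site_trajectory(static, n_frames = 1L, seed = 1L)
  r1 <- radial_distribution(straj, "Cu", "P1", r_max = 4, n_bins = 40L)
  expect_equal(sum(r1$g > 0), 1L)
  expect_error(radial_distribution(straj, "Cu", "missing"),
               "selection error")
})

test_that("the RDF of uniform points in the sphere is flat at 1", {
  set.seed(123)
  n <- 4000L
  # rejection-sample uniform points in a sphere of radius 10
  pts <- matrix(stats::runif(3 * 3 * n, -10, 10), ncol = 3)
  pts <- pts[rowSums(pts^2) <= 100, , drop = FALSE][seq_len(n), ]
  traj <- rbind(
    data.frame(frame = 1L, atom_label = "Cu", x = 0, y = 0, z = 0),
    data.frame(frame = 1L, atom_label = paste0("S", seq_len(n)),
               x = pts[, 1], y = pts[, 2], z = pts[, 3]))
  rdf <- radial_distribution(traj, "Cu", paste0("S", seq_len(n)),
                             r_max = 10, n_bins = 20L)
  inner <- rdf$g[rdf$r_centers > 2 & rdf$r_centers < 8]
  expect_lt(max(abs(inner - 1)), 0.3)  # ~3 sigma of Poisson bin counts
})

test_that("trajectories round-trip through the frame table and PDB dialects", {
  spec <- data.frame(partner = c("A", "B"), sim_mean = c(2, 3),
                     sim_sd = c(0.1, 0.1))
  traj <- gen_site_trajectory(spec, n_frames = 5L, seed = 2L)
  f <- tempfile(fileext = ".csv")
  write_trajectory(traj, f)
  back <- read_trajectory(f)
  expect_equal(back$x, traj$x, tolerance = 1e-9)
  expect_equal(back$atom_label, traj$atom_label)

  # multi-model PDB branch
  fpdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "HETATM    1 CU    CU A 100       0.000   0.000   0.000  1.00  0.00          CU",
    "ATOM      2  NE2 HIS A 101       2.000   0.000   0.000  1.00  0.00           N",
    "ENDMDL",
    "MODEL        2",
    "HETATM    1 CU    CU A 100       0.000   0.000   0.000  1.00  0.00          CU",
    "ATOM      2  NE2 HIS A 101       2.100   0.000   0.000  1.00  0.00           N",
    "ENDMDL",
    "END"), fpdb)
  tp <- read_trajectory(fpdb)
  expect_equal(sort(unique(tp$frame)), c(1L, 2L))
  st <- coordination_distances(tp, metal_label = "CU100_CU",
                               partners = "HIS101_NE2")
  expect_equal(st$mean, 2.05, tolerance = 1e-9)
})
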