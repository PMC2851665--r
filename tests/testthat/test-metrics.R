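# Hydrogen bonds, DSSP strings, contact maps, Q, Rg, SASA, RMSD, quintiles.

test_that("ideal alpha-helix forms i+4 -> i hydrogen bonds and reads H", {
  s <- make_helix(12)
  hb <- kabsch_sander_hbonds(s)
  expect_true(all(hb$donor - hb$acceptor == 4))
  expect_setequal(hb$acceptor, 1:8)
  expect_true(all(hb$energy < -0.5))
  expect_equal(dssp_string(s), paste(rep("H", 10), collapse = ""))
})

test_that("separated strands share no hydrogen bonds; extended chain is coil", {
  s <- make_strand(10)
  far <- transform_structure(s, list(R = diag(3), t = c(0, 0, 20)))
  hb_s <- kabsch_sander_hbonds(s)
  expect_equal(nrow(hb_s), 0)
  expect_equal(dssp_string(s), paste(rep("~", 8), collapse = ""))
  # distance gate: the Kabsch-Sander energy of a 20 A separated pair is ~ 0
  Nd <- atom_coord(far, 5, "N")
  Oa <- atom_coord(s, 5, "O")
  expect_gt(sqrt(sum((Nd - Oa)^2)), 15)
})

test_that("native sheet template shows inter-strand bonds and bridge ladders", {
  s <- make_beta3s_conformers(1)$Native
  hb <- kabsch_sander_hbonds(s)
  # long-range (|i-j| >= 6) cross-strand bonds on both sheet interfaces
  sep <- abs(hb$donor - hb$acceptor)
  expect_gte(sum(sep >= 6), 6)
  d <- dssp_string(s)
  expect_equal(nchar(d), 18)
  expect_gte(lengths(regmatches(d, gregexpr("E", d))), 12)
})

test_that("conformation matching follows Hamming distance with tie errors", {
  refs <- beta3s_reference_dssp()
  expect_equal(match_conformation("EEEESSEEEEEESSEEEE", refs, 0), "Native")
  expect_equal(match_conformation("~HHHHHHHHHHHS~~~~~", refs), "Helix612")
  expect_true(is.na(match_conformation(strrep("~", 18), refs, 0)))
  ties <- c(A = "HHHH", B = "HHHH")
  expect_error(match_conformation("HHHT", ties, 2), "ambiguous")
  expect_error(match_conformation("EEE", refs), "same length")
})

test_that("contact maps respect cutoff, separation, and symmetry", {
  ext <- make_strand(12)
  cm <- contact_map(ext)
  expect_false(any(cm$map))
  nat <- make_beta3s_conformers(1)$Native
  cmn <- contact_map(nat)
  expect_true(isSymmetric(cmn$map))
  expect_true(all(diag(cmn$map) == FALSE))
  sep <- abs(outer(1:20, 1:20, "-"))
  expect_false(any(cmn$map[sep < 3]))
  expect_gt(sum(cmn$map) / 2, 10)   # cross-strand band of the folded sheet
  expect_error(contact_map(nat, cutoff = -1), "positive")
})

test_that("Q-score is 1 for native self, 0 for extended, k/K for partial", {
  nat <- make_beta3s_conformers(1)$Native
  nm <- contact_map(nat)
  expect_equal(q_score(nat, nm), 1.0)
  ext <- build_backbone(motif_spec(beta3s_sequence(), rep(-139, 20),
                                   rep(135, 20)))
  expect_equal(q_score(ext, nm), 0.0)
  # displace the C-terminal strand: expected Q = retained / total, counted
  # directly from the contact maps
  moved <- nat
  sel <- moved$atoms$residue >= 14
  moved$atoms$x[sel] <- moved$atoms$x[sel] + 50
  k <- sum(contact_map(moved)$map & nm$map) / 2
  K <- sum(nm$map) / 2
  expect_lt(k, K)
  expect_equal(q_score(moved, nm), k / K)
  # removing contacts never raises Q
  expect_lte(q_score(moved, nm), q_score(nat, nm))
})

test_that("radius of gyration matches closed forms", {
  sq <- square_structure()
  expect_equal(radius_of_gyration(sq), sqrt(2) / 2, tolerance = 1e-12)
  two <- sq
  two$atoms <- two$atoms[1:2, ]
  two$atoms$x <- c(0, 3); two$atoms$y <- 0; two$atoms$z <- 0
  expect_equal(radius_of_gyration(two, atoms = c("N", "CA")), 1.5)
})

test_that("Shrake-Rupley SASA matches sphere and two-sphere closed forms", {
  # four atoms far apart: additivity of full spheres within sampling error
  s <- square_structure()
  s$atoms$x <- c(0, 100, 200, 300)
  s$atoms$y <- 0; s$atoms$z <- 0
  radii <- c(N = 1.55, CA = 1.70, C = 1.70, O = 1.52) + 1.4
  expect_equal(sasa(s), sum(4 * pi * radii^2), tolerance = 0.01)
  # two overlapping equal spheres: spherical-cap formula
  d <- 2.0
  s2 <- square_structure()
  s2$atoms <- s2$atoms[c(2, 3), ]        # two carbons, R = 3.1
  s2$atoms$x <- c(0, d); s2$atoms$y <- 0; s2$atoms$z <- 0
  R <- 1.7 + 1.4
  cap <- 2 * pi * R * (R - d / 2)
  analytic <- 2 * (4 * pi * R^2 - cap)
  expect_equal(sasa(s2), analytic, tolerance = 0.02)
  bad <- square_structure()
  bad$atoms$element[1] <- "Zz"
  expect_error(sasa(bad), "Zz")
})

test_that("backbone RMSD removes rigid motion and matches bio3d", {
  s <- make_helix(8)
  expect_equal(backbone_rmsd(s, s), 0)
  t <- transform_structure(s, random_rigid_motion())
  expect_lt(backbone_rmsd(s, t), 1e-8)
  set.seed(5)
  j <- s
  j$atoms$x <- j$atoms$x + rnorm(nrow(j$atoms), sd = 0.3)
  v <- backbone_rmsd(s, j)
  expect_gt(v, 0)
  expect_equal(v, backbone_rmsd(j, s), tolerance = 1e-10)
  skip_if_not_installed("bio3d")
  xa <- t(matrix(t(as.matrix(s$atoms[s$atoms$atom %in% c("N","CA","C","O"),
                                     c("x","y","z")])), nrow = 3))
  xb <- t(matrix(t(as.matrix(j$atoms[j$atoms$atom %in% c("N","CA","C","O"),
                                     c("x","y","z")])), nrow = 3))
  ref <- bio3d::rmsd(as.numeric(t(xa)), as.numeric(t(xb)), fit = TRUE)
  expect_equal(v, ref, tolerance = 5e-3)   # bio3d rounds internally
})

test_that("quintile representatives pick floor-medians of RMSD quintiles", {
  base <- make_helix(6)
  set.seed(9)
  mk <- function(sd) {
    s <- base
    s$atoms$x <- s$atoms$x + rnorm(nrow(s$atoms), sd = sd)
    s
  }
  # exactly five members: all returned
  e5 <- new_ensemble(lapply(c(0, .1, .2, .3, .4), mk))
  q5 <- quintile_representatives(e5)
  expect_setequal(q5$indices, 1:5)
  # ten members with distinct distances: sorted positions 1,3,5,7,9
  e10 <- new_ensemble(lapply(seq(0, 0.9, by = 0.1), mk))
  D <- sapply(e10$structures, function(a)
    sapply(e10$structures, function(b) backbone_rmsd(a, b)))
  centroid <- which.min(rowSums(D))
  ord <- order(D[centroid, ], seq_len(10))
  q10 <- quintile_representatives(e10)
  expect_equal(q10$centroid, centroid)
  expect_equal(q10$indices, ord[c(1, 3, 5, 7, 9)])
  # degenerate ensemble: deterministic index tie-break
  same <- new_ensemble(rep(list(base), 7))
  expect_equal(quintile_representatives(same)$indices,
               quintile_representatives(same)$indices)
  expect_error(quintile_representatives(new_ensemble(list(base))), "at least 5")
})

test_that("conformational metrics are invariant under rigid motion", {
  nat <- make_beta3s_conformers(1)$Native
  nm <- contact_map(nat)
  d0 <- dssp_string(nat); q0 <- q_score(nat, nm)
  r0 <- radius_of_gyration(nat); a0 <- sasa(nat)
  set.seed(31)
  for (k in 1:3) {
    t <- transform_structure(nat, random_rigid_motion())
    expect_equal(dssp_string(t), d0)
    expect_equal(q_score(t, nm), q0)
    expect_equal(radius_of_gyration(t), r0, tolerance = 1e-9)
    expect_equal(sasa(t), a0, tolerance = 0.01)  # point-sampling resolution
  }
})
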