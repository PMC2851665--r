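# Site energies, transition dipoles, couplings, Hamiltonian assembly and
# the two-exciton block.

fake_unit <- function(C, O, N, CA = C + c(-1.4, 0, 0)) {
  structure(list(index = 1L, label_residue = 2L, C = C, O = O, N = N,
                 H = N + c(0, -1, 0), CA = CA, CA_next = N + c(1.4, 0, 0)),
            class = "AmideUnit")
}

test_that("site energies: base value, isotope shift, disorder statistics", {
  units <- extract_amide_units(make_helix(6))
  p0 <- hamiltonian_params()
  expect_equal(site_energies(units, p0), rep(1660, 5))
  # 13C/18O labelling of residue 4 red-shifts its site by 65 cm-1
  pl <- hamiltonian_params(labeled_residues = 4)
  eps <- site_energies(units, pl)
  expect_equal(eps[3], 1660 - 65)     # unit labelled by residue 4
  expect_equal(eps[-3], rep(1660, 4))
  expect_error(site_energies(units, hamiltonian_params(labeled_residues = 9)),
               "outside")
  # disorder: ~10k draws across seeds, sample sd within 5 % of sigma
  draws <- unlist(lapply(1:530, function(sd) {
    site_energies(units, hamiltonian_params(sigma_eps = 5,
                                            disorder_seed = sd)) - 1660
  }))
  expect_gt(length(draws), 2000)
  expect_lt(abs(sd(draws) - 5) / 5, 0.05)
  # determinism per seed
  p1 <- hamiltonian_params(sigma_eps = 5, disorder_seed = 42)
  expect_identical(site_energies(units, p1), site_energies(units, p1))
})

test_that("transition dipole geometry: tilt, placement, covariance", {
  u <- fake_unit(C = c(0, 0, 0), O = c(1.231, 0, 0), N = c(-0.5, -1.2, 0))
  p0 <- hamiltonian_params(dipole_tilt = 0)
  d0 <- transition_dipole(u, p0)
  co <- (u$O - u$C) / sqrt(sum((u$O - u$C)^2))
  expect_lt(acos(sum(d0$mu * co) / sqrt(sum(d0$mu^2))), 1e-8)
  expect_equal(sqrt(sum(d0$mu^2)), 0.37)
  expect_equal(d0$origin, u$C + 0.868 * co)
  p20 <- hamiltonian_params(dipole_tilt = 20)
  d20 <- transition_dipole(u, p20)
  ang <- acos(sum(d20$mu * co) / sqrt(sum(d20$mu^2))) * 180 / pi
  expect_equal(ang, 20, tolerance = 1e-6)
  # covariance under rotation
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  ur <- fake_unit(C = as.numeric(R %*% u$C), O = as.numeric(R %*% u$O),
                  N = as.numeric(R %*% u$N))
  dr <- transition_dipole(ur, p20)
  expect_lt(max(abs(dr$mu - as.numeric(R %*% d20$mu))), 1e-10)
  degen <- fake_unit(C = c(0, 0, 0), O = c(1.231, 0, 0), N = c(-1.3, 0, 0))
  expect_error(transition_dipole(degen, p0), "degenerate|collinear")
})

test_that("transition-dipole coupling closed forms", {
  p <- hamiltonian_params(dipole_tilt = 0, dipole_offset = 0)
  mkpair <- function(shift, rot = diag(3)) {
    a <- fake_unit(C = c(0, 0, 0), O = c(1.231, 0, 0), N = c(-0.5, -1.2, 0))
    b <- fake_unit(C = shift,
                   O = shift + as.numeric(rot %*% c(1.231, 0, 0)),
                   N = shift + as.numeric(rot %*% c(-0.5, -1.2, 0)))
    list(a, b)
  }
  # parallel head-to-tail along r: orientation factor -2
  r <- 5
  pr <- mkpair(c(r, 0, 0))
  expect_equal(tdc_coupling(pr[[1]], pr[[2]], p),
               -2 * p$tdc_prefactor * 0.37^2 / r^3, tolerance = 1e-10)
  # perpendicular dipoles, both perpendicular to r: zero
  Rz <- matrix(c(0, 0, 1, 0, 1, 0, -1, 0, 0), 3, 3)  # x -> z
  pp <- mkpair(c(0, 5, 0), rot = Rz)
  expect_lt(abs(tdc_coupling(pp[[1]], pp[[2]], p)), 1e-12)
  # inverse-cube decay: doubling r divides |J| by 8
  p2 <- mkpair(c(2 * r, 0, 0))
  expect_equal(tdc_coupling(pr[[1]], pr[[2]], p) /
                 tdc_coupling(p2[[1]], p2[[2]], p), 8, tolerance = 1e-10)
  # symmetry in arguments
  expect_equal(tdc_coupling(pr[[1]], pr[[2]], p),
               tdc_coupling(pr[[2]], pr[[1]], p))
})

test_that("nearest-neighbor map interpolation: nodes, midpoints, wrap", {
  mp <- nn_coupling_map()
  tb <- utils::read.delim(system.file("extdata",
                                      "nn_coupling_map_synthetic.tsv",
                                      package = "amide2d"))
  i <- 40
  expect_equal(nn_coupling(tb$phi[i], tb$psi[i], mp), tb$J[i])
  # midpoint of four nodes = mean of the four
  four <- tb[tb$phi %in% c(-60, -30) & tb$psi %in% c(0, 30), ]
  expect_equal(nn_coupling(-45, 15, mp), mean(four$J))
  # periodic seam: approaching +180 from below meets -180
  expect_equal(nn_coupling(179.999, 40, mp), nn_coupling(-180, 40, mp),
               tolerance = 1e-3)
  bad <- mp
  bad$J <- bad$J[-1, ]
  expect_error(nn_coupling(0, 0, bad), NA)  # matrix subsetting keeps shape
  expect_error(nn_coupling_map(tempfile()), "")
})

test_that("Hamiltonian assembly: dimensions, neighbor rule, symmetry", {
  mp <- nn_coupling_map()
  tri <- build_backbone(motif_spec(rep("A", 3), phi = c(NA, -60, -120),
                                   psi = c(140, -40, NA)))
  H <- build_hamiltonian(tri, map_table = mp)
  expect_equal(dim(H$H), c(2, 2))
  # adjacent units couple through the map at the shared residue (residue 2)
  expect_equal(H$H[1, 2], nn_coupling(-60, -40, mp))
  expect_equal(H$H, t(H$H))
  nat <- make_beta3s_conformers(1)$Native
  H19 <- build_hamiltonian(nat)
  expect_equal(dim(H19$H), c(19, 19))
  expect_lt(max(abs(H19$H - t(H19$H))), 1e-12)
  expect_true(all(diag(H19$H) > 1500 & diag(H19$H) < 1800))
  # round trip through the plain-text export
  path <- tempfile(fileext = ".tsv")
  write_hamiltonian(H19, path)
  expect_equal(read_hamiltonian(path), H19$H, tolerance = 1e-10)
})

test_that("Hamiltonian is invariant under rigid motion of the structure", {
  nat <- make_beta3s_conformers(1)$Native
  H0 <- build_hamiltonian(nat)$H
  set.seed(13)
  for (k in 1:3) {
    Ht <- build_hamiltonian(transform_structure(nat, random_rigid_motion()))$H
    expect_lt(max(abs(Ht - H0)), 1e-8)
  }
})

test_that("transition-dipole coupling decays below 1 cm-1 past 15 A", {
  ext <- build_backbone(motif_spec(rep("A", 20), rep(-139, 20), rep(135, 20)))
  H <- build_hamiltonian(ext)
  units <- extract_amide_units(ext)
  org <- t(vapply(units, function(u)
    transition_dipole(u, hamiltonian_params())$origin, numeric(3)))
  D <- as.matrix(dist(org))
  far <- D > 15 & upper.tri(D)
  expect_gt(sum(far), 0)
  expect_lt(max(abs(H$H[far])), 1)
})

test_that("two-exciton block: definition cases and harmonic sum rule", {
  # single site
  b1 <- two_exciton_block(matrix(1650, 1, 1), anharmonicity = 16)
  expect_equal(b1$H2, matrix(2 * 1650 - 16, 1, 1))
  # two uncoupled sites
  b2 <- two_exciton_block(diag(c(1650, 1662)), anharmonicity = 16)
  expect_equal(sort(diag(b2$H2)), sort(c(2 * 1650 - 16, 1650 + 1662,
                                         2 * 1662 - 16)))
  expect_true(all(b2$H2[upper.tri(b2$H2)] == 0))
  expect_error(two_exciton_block(diag(2) * 1650, anharmonicity = -1), ">= 0")
  # harmonic limit: two-exciton eigenvalues = all pairwise sums of
  # one-exciton eigenvalues, for arbitrary couplings (brute-force oracle)
  set.seed(21)
  for (n in 2:5) {
    M <- random_h1(n)
    e1 <- eigen(M, symmetric = TRUE)$values
    pairsums <- sort(outer(e1, e1, "+")[upper.tri(diag(n), diag = TRUE)])
    e2 <- sort(eigen(two_exciton_block(M, 0)$H2, symmetric = TRUE)$values)
    expect_lt(max(abs(e2 - pairsums)), 1e-8)
    # trace identity for the anharmonic block
    bA <- two_exciton_block(M, 16)
    expect_equal(sum(diag(bA$H2)),
                 sum(eigen(bA$H2, symmetric = TRUE)$values),
                 tolerance = 1e-8)
  }
})
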