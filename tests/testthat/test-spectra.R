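# Linear absorption and kI 2D spectra: closed forms, harmonic cancellation,
# oracle equivalence, ensemble averaging.

test_that("one-exciton states: diagonal case, dimer closed form, trace", {
  mu <- random_dipoles(3)
  st <- one_exciton_states(diag(c(1650, 1660, 1670)), mu)
  expect_equal(st$energies, c(1650, 1660, 1670))
  expect_equal(abs(st$vectors), diag(3), tolerance = 1e-12)
  expect_equal(st$dipoles, st$vectors %*% mu, tolerance = 1e-12)
  d <- one_exciton_states(matrix(c(1650, 7, 7, 1650), 2, 2),
                          matrix(1, 2, 3))
  expect_equal(d$energies, c(1643, 1657))
  expect_equal(abs(d$vectors), matrix(1 / sqrt(2), 2, 2), tolerance = 1e-12)
  set.seed(2)
  M <- random_h1(3)
  st3 <- one_exciton_states(M, random_dipoles(3))
  expect_equal(sum(st3$energies), sum(diag(M)), tolerance = 1e-9)
  expect_error(one_exciton_states(matrix(c(1, 2, 3, 4), 2, 2),
                                  matrix(1, 2, 3)), "symmetric")
})

test_that("linear absorption: position, FWHM, dark-state selection", {
  grid <- spectral_grid(1600, 1700, 0.25)
  st <- one_exciton_states(matrix(1650, 1, 1), matrix(c(1, 0, 0), 1, 3))
  for (g in c(1, 5, 10)) {
    sp <- linear_absorption(st, grid, g)
    pk <- grid$omega[which.max(sp$intensity)]
    expect_equal(pk, 1650)
    half <- max(sp$intensity) / 2
    above <- range(grid$omega[sp$intensity >= half])
    expect_lt(abs(diff(above) - g), grid$step + 1e-9)
  }
  # two uncoupled sites, orthogonal dipoles of equal magnitude: equal peaks
  st2 <- one_exciton_states(diag(c(1640, 1670)),
                            rbind(c(1, 0, 0), c(0, 1, 0)))
  sp2 <- linear_absorption(st2, grid, 5)
  h1 <- sp2$intensity[grid$omega == 1640]
  h2 <- sp2$intensity[grid$omega == 1670]
  expect_equal(h1, h2, tolerance = 1e-2)
  # coupled symmetric dimer with parallel dipoles: antisymmetric state dark
  stp <- one_exciton_states(matrix(c(1650, 10, 10, 1650), 2, 2),
                            rbind(c(1, 0, 0), c(1, 0, 0)))
  spp <- linear_absorption(stp, grid, 5)
  expect_equal(grid$omega[which.max(spp$intensity)], 1660)
  # only Lorentzian tail leakage from the bright state remains at 1640
  expect_lt(spp$intensity[grid$omega == 1640] / max(spp$intensity), 0.02)
})

test_that("harmonic systems produce no kI signal (ESA cancels GSB+SE)", {
  set.seed(3)
  grid <- spectral_grid(1620, 1700, 2)
  st <- response_settings(5)
  for (n in 1:3) {
    for (rep in 1:5) {
      M <- random_h1(n)
      mu <- random_dipoles(n)
      sp <- kI_2d_spectrum(M, two_exciton_block(M, 0), mu, grid, st)
      scale <- max(1, max(abs(sp$complex_amplitude)))
      gsb <- max(Mod(outer(rowSums(mu^2), rowSums(mu^2)))) / st$gamma^2
      expect_lt(max(abs(sp$complex_amplitude)) / gsb, 1e-10)
    }
  }
})

test_that("single anharmonic site shows a fundamental and a shifted ESA", {
  grid <- spectral_grid(1600, 1700, 1)
  st <- response_settings(5)
  M <- matrix(1660, 1, 1)
  sp <- kI_2d_spectrum(M, two_exciton_block(M, 16),
                       matrix(c(0.37, 0, 0), 1, 3), grid, st)
  pk <- pick_peaks_2d(sp, threshold_frac = 0.05, diag_tol = 2)
  expect_equal(nrow(pk), 2)
  expect_equal(sort(pk$omega1), c(1660, 1660))
  expect_setequal(round(sort(pk$omega3)), c(1644, 1660))
  amp_fund <- pk$amplitude[pk$omega3 == 1660]
  amp_esa <- pk$amplitude[pk$omega3 != 1660]
  expect_gt(amp_fund, 0)
  expect_lt(amp_esa, 0)
})

test_that("sum-over-states equals the time-domain oracle", {
  set.seed(8)
  grid <- spectral_grid(1625, 1695, 2.5)
  st <- response_settings(5)
  for (n in 1:3) {
    M <- random_h1(n)
    mu <- random_dipoles(n)
    H2 <- two_exciton_block(M, 16)
    a <- kI_2d_spectrum(M, H2, mu, grid, st)
    b <- brute_force_response(M, H2, mu, grid, st)
    expect_lt(rel_diff_2d(a, b), 1e-6)
  }
  # zero dipoles: zero spectrum from the oracle too
  z <- brute_force_response(diag(c(1650, 1660)),
                            two_exciton_block(diag(c(1650, 1660)), 16),
                            matrix(0, 2, 3), grid, st)
  expect_equal(max(abs(z$complex_amplitude)), 0)
  expect_error(brute_force_response(random_h1(5), mu = random_dipoles(5),
                                    grid = grid, settings = st), "4 sites")
})

test_that("spectra are invariant under rigid motion of the structure", {
  hel <- make_helix(8)
  grid <- spectral_grid(1620, 1700, 1)
  st <- response_settings(5)
  H0 <- build_hamiltonian(hel)
  a0 <- kI_2d_spectrum(H0, grid = grid, settings = st)
  l0 <- linear_absorption(one_exciton_states(H0), grid, 5)
  set.seed(17)
  tr <- transform_structure(hel, random_rigid_motion())
  Ht <- build_hamiltonian(tr)
  at <- kI_2d_spectrum(Ht, grid = grid, settings = st)
  lt <- linear_absorption(one_exciton_states(Ht), grid, 5)
  expect_lt(max(abs(at$amplitude - a0$amplitude)) / max(abs(a0$amplitude)),
            1e-8)
  expect_lt(max(abs(lt$intensity - l0$intensity)) / max(l0$intensity), 1e-8)
})

test_that("ensemble averaging: degenerate mean, pairwise mean, linearity", {
  hel <- make_helix(6)
  grid <- spectral_grid(1630, 1690, 2)
  st <- response_settings(5)
  ens1 <- perturb_ensemble(hel, ensemble_noise(0, 0, 4, seed = 1))
  m1 <- ensemble_spectrum(ens1, grid = grid, settings = st, kind = "1d")
  single <- linear_absorption(one_exciton_states(build_hamiltonian(hel)),
                              grid, 5)
  expect_equal(m1$intensity, single$intensity, tolerance = 1e-12)
  # two distinct members: cell-wise mean
  ens2 <- perturb_ensemble(hel, ensemble_noise(0.08, 0, 2, seed = 2))
  s_a <- kI_2d_spectrum(build_hamiltonian(ens2$structures[[1]]),
                        grid = grid, settings = st)
  s_b <- kI_2d_spectrum(build_hamiltonian(ens2$structures[[2]]),
                        grid = grid, settings = st)
  m2 <- ensemble_spectrum(ens2, grid = grid, settings = st, kind = "2d")
  expect_equal(m2$amplitude, (s_a$amplitude + s_b$amplitude) / 2,
               tolerance = 1e-10)
  # concatenation linearity (size-weighted mean)
  ens3 <- new_ensemble(c(ens1$structures, ens2$structures), "joint")
  m3 <- ensemble_spectrum(ens3, grid = grid, settings = st, kind = "1d")
  m1b <- ensemble_spectrum(ens1, grid = grid, settings = st, kind = "1d")
  m2b <- ensemble_spectrum(ens2, grid = grid, settings = st, kind = "1d")
  expect_equal(m3$intensity,
               (4 * m1b$intensity + 2 * m2b$intensity) / 6,
               tolerance = 1e-10)
})

test_that("spectrum TSV export writes axes and data", {
  hel <- make_helix(5)
  grid <- spectral_grid(1640, 1680, 5)
  sp <- linear_absorption(one_exciton_states(build_hamiltonian(hel)),
                          grid, 5)
  p <- tempfile(fileext = ".tsv")
  write_spectrum(sp, p)
  lines <- readLines(p)
  expect_true(startsWith(lines[1], "#"))
  tab <- utils::read.table(p, sep = "\t")
  expect_equal(tab[[1]], grid$omega)
  expect_equal(tab[[2]], sp$intensity, tolerance = 1e-10)
})

test_that("ensemble means converge with ensemble size (Monte Carlo)", {
  hel <- build_backbone(motif_spec(rep("A", 8), rep(-57, 8), rep(-47, 8)))
  grid <- spectral_grid(1630, 1690, 1)
  mean_spec <- function(n, seed) {
    ens <- perturb_ensemble(hel, ensemble_noise(0.06, 0, n, seed))
    ensemble_spectrum(ens, grid = grid, settings = response_settings(10),
                      kind = "1d")$intensity
  }
  ref <- mean_spec(400, 99)
  d_small <- mean(abs(mean_spec(30, 1) - ref))
  d_large <- mean(abs(mean_spec(120, 2) - ref))
  expect_lt(d_large, d_small)
})
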