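# Linear absorption and rephasing (kI = -k1+k2+k3) two-dimensional
# photon-echo spectra by sum over states with Lorentzian lineshapes,
# isotropic all-parallel polarization, waiting time t2 = 0.

#' Frequency grid
#'
#' @param start,stop axis limits (cm^-1), start < stop.
#' @param step grid step (cm^-1). Default axis 1580-1720 at 0.5 cm^-1.
#' @return object of class `SpectralGrid` with vector `omega`.
#' @export
spectral_grid <- function(start = 1580, stop = 1720, step = 0.5) {
  stopifnot(start < stop, step > 0)
  structure(list(start = start, stop = stop, step = step,
                 omega = seq(start, stop, by = step)),
            class = "SpectralGrid")
}

#' Response settings
#'
#' Homogeneous Lorentzian broadening Gamma is a full width at half maximum;
#' the internal complex half-width is gamma = Gamma/2. The waiting time t2
#' is fixed at zero. The displayed component of the complex 2D response is
#' configurable ("re", "im", "abs"); the default "re" shows 0->1 features
#' positive and 1->2 (excited-state absorption) features negative.
#'
#' @param gamma_fwhm Lorentzian FWHM Gamma (cm^-1), > 0.
#' @param component displayed component of the complex kI response.
#' @return object of class `ResponseSettings`.
#' @export
response_settings <- function(gamma_fwhm = 5, component = c("re", "im", "abs")) {
  stopifnot(gamma_fwhm > 0)
  component <- match.arg(component)
  structure(list(gamma_fwhm = gamma_fwhm, gamma = gamma_fwhm / 2,
                 t2 = 0, polarization = "isotropic_all_parallel",
                 component = component),
            class = "ResponseSettings")
}

#' One-exciton eigenstates and transition dipoles
#'
#' Diagonalizes the symmetric one-exciton Hamiltonian; eigenvalues ascending,
#' eigenvectors orthonormal; state dipole M_k = sum_m v_k(m) mu_m.
#'
#' @param H an [build_hamiltonian()] result, or a plain symmetric matrix (in
#'   which case `mu` must be supplied).
#' @param mu n x 3 site dipole matrix (Debye), when `H` is a plain matrix.
#' @return list with `energies`, `vectors` (columns = states), `dipoles`
#'   (n_states x 3), `site_mu`.
#' @export
one_exciton_states <- function(H, mu = NULL) {
  M <- if (inherits(H, "ExcitonHamiltonian")) H$H else H
  if (is.null(mu)) {
    if (!inherits(H, "ExcitonHamiltonian")) stop("site dipoles mu required")
    mu <- H$mu
  }
  if (max(abs(M - t(M))) > 1e-9 * max(1, max(abs(M)))) {
    stop("Hamiltonian must be symmetric")
  }
  eig <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ord <- order(eig$values)
  E <- eig$values[ord]
  V <- eig$vectors[, ord, drop = FALSE]
  list(energies = E, vectors = V, dipoles = t(V) %*% mu, site_mu = mu)
}

#' Linear absorption spectrum
#'
#' A(omega) = sum_k |M_k|^2 (Gamma/2) / ((omega - E_k)^2 + (Gamma/2)^2).
#'
#' @param states from [one_exciton_states()].
#' @param grid a [spectral_grid()].
#' @param gamma_fwhm Lorentzian FWHM (cm^-1).
#' @return object of class `Spectrum1D`: list with `omega`, `intensity`,
#'   `gamma_fwhm`, `n_ensemble`.
#' @export
linear_absorption <- function(states, grid = spectral_grid(),
                              gamma_fwhm = 5) {
  stopifnot(gamma_fwhm > 0)
  if (length(states$energies) == 0) stop("no states")
  g <- gamma_fwhm / 2
  w <- grid$omega
  A <- numeric(length(w))
  amp <- rowSums(states$dipoles^2)
  for (k in seq_along(states$energies)) {
    A <- A + amp[k] * g / ((w - states$energies[k])^2 + g^2)
  }
  structure(list(omega = w, intensity = A, gamma_fwhm = gamma_fwhm,
                 n_ensemble = 1L), class = "Spectrum1D")
}

# one- to two-exciton transition dipoles: mu2[f, e, 1:3]
# |f> = sum_{m<=n} c_f(mn)|mn>, mu_{ef} = sum_{m<n} c_f(mn)[v_e(m) mu_n +
# v_e(n) mu_m] + sum_m c_f(mm) sqrt(2) v_e(m) mu_m
two_exciton_dipoles <- function(states, H2) {
  V1 <- states$vectors
  mu <- states$site_mu
  n <- nrow(V1)
  pairs <- H2$pairs
  eig2 <- eigen((H2$H2 + t(H2$H2)) / 2, symmetric = TRUE)
  ord <- order(eig2$values)
  E2 <- eig2$values[ord]
  V2 <- eig2$vectors[, ord, drop = FALSE]
  np <- nrow(pairs)
  ne <- ncol(V1)
  # site-basis transition matrix T[p, m, xyz]: <pair p| dipole |site m>
  mu2 <- array(0, c(np, ne, 3))
  for (x in 1:3) {
    Tx <- matrix(0, np, n)
    for (p in seq_len(np)) {
      m <- pairs[p, 1]; k <- pairs[p, 2]
      if (m == k) {
        Tx[p, m] <- sqrt(2) * mu[m, x]
      } else {
        Tx[p, m] <- mu[k, x]
        Tx[p, k] <- mu[m, x]
      }
    }
    mu2[, , x] <- Tx %*% V1
  }
  # rotate pair index into the two-exciton eigenbasis
  out <- array(0, c(np, ne, 3))
  for (x in 1:3) out[, , x] <- t(V2) %*% mu2[, , x]
  list(energies = E2, dipoles = out)
}

# isotropic all-parallel orientational average of four dipole vectors
iso4 <- function(a, b, c, d) {
  (sum(a * b) * sum(c * d) + sum(a * c) * sum(b * d) +
   sum(a * d) * sum(b * c)) / 15
}

#' Rephasing (kI) two-dimensional spectrum by sum over states
#'
#' Sum over Liouville pathways at t2 = 0 with complex Lorentzian lines of
#' half-width gamma = Gamma/2: stimulated emission and ground-state bleach
#' over one-exciton pairs (e, e'), excited-state absorption over
#' (e, e', f) with opposite sign detected at E_f - E_e. Amplitudes carry
#' the isotropic all-parallel fourth-rank orientational average. Both
#' display axes are positive (the (omega_1, -omega_3) labelling convention);
#' peaks appear at (E_e, E_e') and (E_e, E_f - E_e).
#'
#' @param H1 an [build_hamiltonian()] result or symmetric matrix.
#' @param H2 a [two_exciton_block()]; built from `H1` when NULL.
#' @param mu site dipoles when `H1` is a plain matrix.
#' @param grid a [spectral_grid()] (used for both axes).
#' @param settings a [response_settings()].
#' @return object of class `Spectrum2D`: list with `omega1`, `omega3`,
#'   `amplitude` (matrix omega1 x omega3, displayed component),
#'   `complex_amplitude`, `gamma_fwhm`, `component`, `n_ensemble`.
#' @export
kI_2d_spectrum <- function(H1, H2 = NULL, mu = NULL, grid = spectral_grid(),
                           settings = response_settings()) {
  states <- one_exciton_states(H1, mu)
  if (is.null(H2)) H2 <- two_exciton_block(H1)
  if (nrow(H2$pairs) != length(states$energies) *
      (length(states$energies) + 1) / 2) {
    stop("two-exciton block dimension inconsistent with H1")
  }
  ing <- kI_ingredients(states, H2)
  assemble_kI(ing, grid, settings)
}

# frequency-independent pathway ingredients: eigenstates, one->two dipoles,
# orientationally averaged GSB/SE and ESA amplitude tables
kI_ingredients <- function(states, H2) {
  E1 <- states$energies
  M1 <- states$dipoles
  tx <- two_exciton_dipoles(states, H2)
  ne <- length(E1); nf <- length(tx$energies)
  # GSB + SE: iso4(a,b,b,a) + iso4(a,a,b,b) = 2(2(a.b)^2 + |a|^2|b|^2)/15
  P <- M1 %*% t(M1)
  A_gse <- 2 * (2 * P^2 + outer(diag(P), diag(P))) / 15
  # ESA: G[e, f] = sum_e' iso4(M_e, M_e', mu_e'f, mu_ef), fully tensorized.
  # B_x[f, e] = x-component of mu_ef; three pairing terms of the isotropic
  # average are contracted with matrix products.
  Bx <- lapply(1:3, function(x) matrix(tx$dipoles[, , x], nf, ne))
  T1 <- matrix(0, nf, ne)
  for (x in 1:3) T1 <- T1 + (Bx[[x]] %*% P) * Bx[[x]]
  T2 <- matrix(0, nf, ne)
  for (y in 1:3) {
    Cy <- matrix(0, nf, 3)
    for (x in 1:3) Cy[, x] <- Bx[[x]] %*% M1[, y]
    T2 <- T2 + Bx[[y]] * (Cy %*% t(M1))
  }
  DA <- matrix(0, nf, ne)
  for (x in 1:3) DA <- DA + Bx[[x]] * rep(M1[, x], each = nf)
  T3 <- DA * rowSums(DA)
  G <- t(T1 + T2 + T3) / 15
  list(E1 = E1, E2 = tx$energies, A_gse = A_gse, G = G)
}

# Lorentzian line assembly of the kI spectrum on a grid; detection-axis
# lines use the conjugate convention (emitted field), so the displayed
# real part is positive at (E_e, E_e')
assemble_kI <- function(ing, grid, settings) {
  g <- settings$gamma
  w <- grid$omega
  L1 <- 1 / (g + 1i * outer(w, ing$E1, "-"))   # nw x ne, peak at w = E_e
  L3_1 <- 1 / (g - 1i * outer(w, ing$E1, "-")) # detection at E_e'
  S <- L1 %*% ing$A_gse %*% t(L3_1)
  # ESA lines; for large systems, lines with negligible orientational
  # amplitude (< 1e-9 of the strongest) are skipped
  thr <- if (length(ing$E1) > 6) 1e-9 * max(abs(ing$G)) else 0
  for (e in seq_along(ing$E1)) {
    keep <- which(abs(ing$G[e, ]) > thr)
    if (length(keep) == 0) next
    Ldet <- 1 / (g - 1i * outer(w, ing$E2[keep] - ing$E1[e], "-"))
    S <- S - L1[, e, drop = FALSE] %*% t(Ldet %*% ing$G[e, keep])
  }
  amp <- switch(settings$component,
                re = Re(S), im = Im(S), abs = abs(S))
  structure(list(omega1 = w, omega3 = w, amplitude = amp,
                 complex_amplitude = S, gamma_fwhm = settings$gamma_fwhm,
                 component = settings$component, n_ensemble = 1L),
            class = "Spectrum2D")
}

#' Ensemble-averaged spectrum
#'
#' Unweighted mean of per-member spectra on the shared grid. Member
#' Hamiltonians are built independently; when the parameter set carries
#' site-energy disorder, each member gets a fresh seeded draw
#' (disorder_seed + member index).
#'
#' @param ensemble a [StructureEnsemble].
#' @param params a [hamiltonian_params()].
#' @param grid a [spectral_grid()].
#' @param settings a [response_settings()].
#' @param kind "1d" for linear absorption, "2d" for the kI spectrum.
#' @param map_table an [nn_coupling_map()].
#' @return a `Spectrum1D` or `Spectrum2D` with `n_ensemble` set.
#' @export
ensemble_spectrum <- function(ensemble, params = hamiltonian_params(),
                              grid = spectral_grid(),
                              settings = response_settings(),
                              kind = c("1d", "2d"),
                              map_table = nn_coupling_map()) {
  kind <- match.arg(kind)
  nm <- length(ensemble$structures)
  if (nm == 0) stop("empty ensemble")
  acc <- NULL
  for (k in seq_len(nm)) {
    pk <- params
    pk$disorder_seed <- params$disorder_seed + k
    H <- build_hamiltonian(ensemble$structures[[k]], pk, map_table)
    sp <- if (kind == "1d") {
      linear_absorption(one_exciton_states(H), grid, settings$gamma_fwhm)
    } else {
      kI_2d_spectrum(H, grid = grid, settings = settings)
    }
    if (is.null(acc)) {
      acc <- sp
    } else if (kind == "1d") {
      acc$intensity <- acc$intensity + sp$intensity
    } else {
      acc$amplitude <- acc$amplitude + sp$amplitude
      acc$complex_amplitude <- acc$complex_amplitude + sp$complex_amplitude
    }
  }
  if (kind == "1d") {
    acc$intensity <- acc$intensity / nm
  } else {
    acc$amplitude <- acc$amplitude / nm
    acc$complex_amplitude <- acc$complex_amplitude / nm
  }
  acc$n_ensemble <- nm
  acc
}

# ensemble averaging over several Gamma values with shared per-member
# eigen-decompositions (the pipeline's fast path; equivalent to calling
# ensemble_spectrum per Gamma)
ensemble_spectra_all_gamma <- function(ensemble, params, grid, gammas,
                                       component = "re",
                                       map_table = nn_coupling_map()) {
  nm <- length(ensemble$structures)
  one_d <- vector("list", length(gammas))
  two_d <- vector("list", length(gammas))
  for (k in seq_len(nm)) {
    pk <- params
    pk$disorder_seed <- params$disorder_seed + k
    H <- build_hamiltonian(ensemble$structures[[k]], pk, map_table)
    states <- one_exciton_states(H)
    H2 <- two_exciton_block(H)
    ing <- kI_ingredients(states, H2)
    for (gi in seq_along(gammas)) {
      st <- response_settings(gammas[gi], component)
      s1 <- linear_absorption(states, grid, gammas[gi])
      s2 <- assemble_kI(ing, grid, st)
      if (k == 1) {
        one_d[[gi]] <- s1
        two_d[[gi]] <- s2
      } else {
        one_d[[gi]]$intensity <- one_d[[gi]]$intensity + s1$intensity
        two_d[[gi]]$amplitude <- two_d[[gi]]$amplitude + s2$amplitude
        two_d[[gi]]$complex_amplitude <-
          two_d[[gi]]$complex_amplitude + s2$complex_amplitude
      }
    }
  }
  for (gi in seq_along(gammas)) {
    one_d[[gi]]$intensity <- one_d[[gi]]$intensity / nm
    one_d[[gi]]$n_ensemble <- nm
    two_d[[gi]]$amplitude <- two_d[[gi]]$amplitude / nm
    two_d[[gi]]$complex_amplitude <- two_d[[gi]]$complex_amplitude / nm
    two_d[[gi]]$n_ensemble <- nm
  }
  list(one_d = one_d, two_d = two_d)
}

#' Write spectra as TSV
#'
#' 1D spectra: two columns (omega, intensity) after `#` header lines.
#' 2D spectra: matrix block with axis headers.
#'
#' @param spectrum a `Spectrum1D` or `Spectrum2D`.
#' @param path output path.
#' @return invisibly the path.
#' @export
write_spectrum <- function(spectrum, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(spectrum, "Spectrum1D")) {
    writeLines(c(sprintf("# 1D amide-I spectrum, gamma_fwhm %g cm-1, ensemble %d",
                         spectrum$gamma_fwhm, spectrum$n_ensemble),
                 "# omega_cm-1\tintensity"), con)
    utils::write.table(data.frame(spectrum$omega, spectrum$intensity), con,
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  } else if (inherits(spectrum, "Spectrum2D")) {
    writeLines(c(sprintf("# kI 2D spectrum (%s part), gamma_fwhm %g cm-1, ensemble %d",
                         spectrum$component, spectrum$gamma_fwhm,
                         spectrum$n_ensemble),
                 sprintf("# omega1: %g..%g; omega3 (displayed -omega3): %g..%g; rows = omega1",
                         min(spectrum$omega1), max(spectrum$omega1),
                         min(spectrum$omega3), max(spectrum$omega3))), con)
    utils::write.table(spectrum$amplitude, con, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
  } else stop("not a spectrum object")
  invisible(path)
}
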