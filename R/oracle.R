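# Brute-force time-domain oracle for the kI (rephasing) response: numerical
# propagation over the 0/1/2-exciton manifolds with per-coherence damping,
# then numerical half-Fourier transforms t1 -> omega1 and t3 -> omega3.
# Deliberately independent of the sum-over-states route: no Hamiltonian
# diagonalization anywhere; single-step propagators come from a
# scaling-and-squaring complex matrix exponential and the time grid is
# marched step by step.

# complex matrix exponential, scaling and squaring + Taylor series
cexpm <- function(A) {
  n <- nrow(A)
  nrm <- max(rowSums(abs(A)))
  k <- max(0, ceiling(log2(max(nrm, 1e-300) / 0.5)))
  As <- A / 2^k
  E <- diag(1 + 0i, n)
  term <- diag(1 + 0i, n)
  for (j in 1:20) {
    term <- term %*% As / j
    E <- E + term
  }
  if (k > 0) for (j in seq_len(k)) E <- E %*% E
  E
}

#' Brute-force time-domain kI response (oracle)
#'
#' Propagates the three-pulse rephasing response at t2 = 0 in the time
#' domain over the ground, one- and two-exciton manifolds (stimulated
#' emission, ground-state bleach, excited-state absorption pathways), with
#' exponential damping gamma = Gamma/2 per coherence, and transforms
#' t1 -> omega1, t3 -> omega3 by high-order numerical quadrature in a
#' rotating frame. Scope-limited to systems of at most 4 sites.
#'
#' @param H1 one-exciton Hamiltonian ([build_hamiltonian()] result or
#'   symmetric matrix).
#' @param H2 a [two_exciton_block()]; built from `H1` when NULL.
#' @param mu site dipoles (n x 3) when `H1` is a plain matrix.
#' @param grid a [spectral_grid()].
#' @param settings a [response_settings()].
#' @return a `Spectrum2D` with the same display convention as
#'   [kI_2d_spectrum()].
#' @export
brute_force_response <- function(H1, H2 = NULL, mu = NULL,
                                 grid = spectral_grid(),
                                 settings = response_settings()) {
  M <- if (inherits(H1, "ExcitonHamiltonian")) H1$H else H1
  if (is.null(mu)) {
    if (!inherits(H1, "ExcitonHamiltonian")) stop("site dipoles mu required")
    mu <- H1$mu
  }
  n <- nrow(M)
  if (n > 4) stop("oracle limited to <= 4 sites")
  if (is.null(H2)) H2 <- two_exciton_block(H1)
  A2 <- H2$H2
  pairs <- H2$pairs
  np <- nrow(pairs)
  g <- settings$gamma
  w <- grid$omega
  w0 <- mean(range(w))

  # site-basis 1->2 transition matrices per Cartesian component
  Tx <- lapply(1:3, function(x) {
    Tm <- matrix(0, np, n)
    for (p in seq_len(np)) {
      m <- pairs[p, 1]; k <- pairs[p, 2]
      if (m == k) Tm[p, m] <- sqrt(2) * mu[m, x]
      else { Tm[p, m] <- mu[k, x]; Tm[p, k] <- mu[m, x] }
    }
    Tm
  })

  # rotating frame; Gershgorin bound on detunings sets the step
  S1 <- M - diag(w0, n)
  S2 <- A2 - diag(2 * w0, np)
  b1 <- max(rowSums(abs(S1)))
  b2 <- max(rowSums(abs(S2)))
  half <- max(abs(w - w0))
  dmax <- max(b1 + half, b1 + b2 + half, 1)
  Tmax <- 16 / g
  dt <- min(0.02 / dmax, Tmax / 400)
  nt <- ceiling(Tmax / dt)
  if (nt %% 2 == 1) nt <- nt + 1       # even interval count for Simpson
  nt <- nt + 1
  dt <- Tmax / (nt - 1)
  tt <- (seq_len(nt) - 1) * dt

  P1 <- cexpm(-1i * S1 * dt)
  P2 <- cexpm(-1i * S2 * dt)

  # march U1(t) and phi_{b,c}(t) = U2(t) T_c psi_b; record needed signals
  psi <- lapply(1:3, function(x) mu[, x])
  U1 <- diag(1 + 0i, n)
  phi <- vector("list", 9)   # index (b-1)*3 + c
  for (b in 1:3) for (cc in 1:3) {
    phi[[(b - 1) * 3 + cc]] <- (Tx[[cc]] %*% psi[[b]])[, 1]
  }
  u <- array(0i, c(nt, n, 3))        # u[t, , a] = U1(t) psi_a
  wsig <- array(0i, c(nt, n, 27))    # w_{b,c,d}(t) = U1(t)^H T_d^H phi_bc(t)
  for (it in seq_len(nt)) {
    if (it > 1) {
      U1 <- P1 %*% U1
      for (q in 1:9) phi[[q]] <- (P2 %*% phi[[q]])[, 1]
    }
    U1H <- Conj(t(U1))
    for (a in 1:3) u[it, , a] <- (U1 %*% psi[[a]])[, 1]
    for (b in 1:3) for (cc in 1:3) for (d in 1:3) {
      wsig[it, , (b - 1) * 9 + (cc - 1) * 3 + d] <-
        (U1H %*% (Conj(t(Tx[[d]])) %*% phi[[(b - 1) * 3 + cc]]))[, 1]
    }
  }

  # quadrature kernels (Simpson weights, damping, rotating frame)
  simp <- c(1, rep(c(4, 2), length.out = nt - 2), 1)
  wq <- simp * dt / 3 * exp(-g * tt)
  K1 <- exp(-1i * outer(w - w0, tt)) * rep(wq, each = length(w))
  K3 <- exp(+1i * outer(w - w0, tt)) * rep(wq, each = length(w))

  # t1 signals: s1_{a,c}(t) = conj(u_a(t)) . psi_c  (9 columns)
  uslice <- function(a) matrix(u[, , a], nt, n)
  s1 <- matrix(0i, nt, 9)
  for (a in 1:3) for (cc in 1:3) {
    s1[, (a - 1) * 3 + cc] <- Conj(uslice(a)) %*% psi[[cc]]
  }
  # t3 signals for SE/GSB: h_{d,b}(t) = psi_d . u_b(t)
  h <- matrix(0i, nt, 9)
  for (d in 1:3) for (b in 1:3) {
    h[, (d - 1) * 3 + b] <- uslice(b) %*% psi[[d]]
  }
  F1s <- K1 %*% s1
  F3h <- K3 %*% h
  # conj(u_a)[, m] transforms for the ESA t1 factor
  F1u <- array(0i, c(length(w), n, 3))
  for (a in 1:3) F1u[, , a] <- K1 %*% Conj(uslice(a))
  F3w <- K3 %*% matrix(wsig, nt, n * 27)
  dim(F3w) <- c(length(w), n, 27)

  # Orientational average (1/15)[(ab)(cd)+(ac)(bd)+(ad)(bc)] over the
  # lab-frame components of interactions a,b,c,d = pulses 1,2,3, signal:
  # enumerate the pairings explicitly, assigning component i to one pair
  # and j to the other.
  Sp <- matrix(0i, length(w), length(w))
  pairings <- list(c(1, 1, 2, 2), c(1, 2, 1, 2), c(1, 2, 2, 1))
  for (pg in pairings) {
    for (i in 1:3) for (j in 1:3) {
      comp <- c(i, j)[pg]   # components of (a, b, c, d)
      a <- comp[1]; b <- comp[2]; cc <- comp[3]; d <- comp[4]
      # SE: s1_{a,c} x h_{d,b}
      Sp <- Sp + outer(F1s[, (a - 1) * 3 + cc], F3h[, (d - 1) * 3 + b])
      # GSB: s1_{a,b} x h_{d,c}
      Sp <- Sp + outer(F1s[, (a - 1) * 3 + b], F3h[, (d - 1) * 3 + cc])
      # ESA: -sum_m conj(u_a)_m x w_{b,c,d,m}
      q <- (b - 1) * 9 + (cc - 1) * 3 + d
      for (m in seq_len(n)) {
        Sp <- Sp - outer(F1u[, m, a], F3w[, m, q])
      }
    }
  }
  Sp <- Sp / 15
  amp <- switch(settings$component, re = Re(Sp), im = Im(Sp), abs = abs(Sp))
  structure(list(omega1 = w, omega3 = w, amplitude = amp,
                 complex_amplitude = Sp, gamma_fwhm = settings$gamma_fwhm,
                 component = settings$component, n_ensemble = 1L),
            class = "Spectrum2D")
}
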