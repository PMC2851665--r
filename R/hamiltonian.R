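# Local amide-I exciton Hamiltonian: site energies (isotope shifts, diagonal
# disorder), transition-dipole coupling, nearest-neighbor dihedral-map
# couplings, and the two-exciton extension.

#' Hamiltonian parameter set
#'
#' Parameters of the local amide Hamiltonian. The defaults are standard
#' amide-I conventions (configurable, not fitted): unperturbed site energy
#' 1660 cm^-1, diagonal anharmonicity 16 cm^-1, transition dipole 0.37 D
#' placed 0.868 Angstrom from the carbonyl C along C=O and tilted 20 degrees
#' from C=O toward N in the amide plane, dipole-dipole prefactor 5034
#' cm^-1 A^3 D^-2 (Gaussian-units conversion), isotope-label red shift
#' -65 cm^-1 (the 13C/18O amide-I shift).
#'
#' @param epsilon0 base site energy (cm^-1).
#' @param anharmonicity diagonal anharmonicity Delta (cm^-1).
#' @param dipole_magnitude transition-dipole magnitude (Debye).
#' @param dipole_offset placement along C=O from the carbonyl C (Angstrom).
#' @param dipole_tilt in-plane tilt from C=O toward N (degrees).
#' @param tdc_prefactor dipole-dipole prefactor (cm^-1 A^3 / D^2).
#' @param sigma_eps site-energy disorder standard deviation (cm^-1).
#' @param disorder_seed integer seed for disorder draws.
#' @param labeled_residues integer vector of isotope-labelled residues
#'   (label-residue convention: unit i is labelled by residue i+1).
#' @param label_shift isotope shift added to labelled sites (cm^-1).
#' @return object of class `HamiltonianParams`.
#' @export
hamiltonian_params <- function(epsilon0 = 1660, anharmonicity = 16,
                               dipole_magnitude = 0.37,
                               dipole_offset = 0.868, dipole_tilt = 20,
                               tdc_prefactor = 5034,
                               sigma_eps = 0, disorder_seed = 1,
                               labeled_residues = integer(0),
                               label_shift = -65) {
  stopifnot(epsilon0 > 0, anharmonicity >= 0, dipole_magnitude > 0,
            sigma_eps >= 0)
  structure(list(epsilon0 = epsilon0, anharmonicity = anharmonicity,
                 dipole_magnitude = dipole_magnitude,
                 dipole_offset = dipole_offset, dipole_tilt = dipole_tilt,
                 tdc_prefactor = tdc_prefactor, sigma_eps = sigma_eps,
                 disorder_seed = as.integer(disorder_seed),
                 labeled_residues = as.integer(labeled_residues),
                 label_shift = label_shift),
            class = "HamiltonianParams")
}

#' Site energies of the amide units
#'
#' epsilon_m = epsilon0 + isotope shift (when the unit's label residue is in
#' the labelled set) + a Gaussian(0, sigma_eps) disorder draw (seeded,
#' deterministic per seed).
#'
#' @param units list of amide units from [extract_amide_units()].
#' @param params a [hamiltonian_params()].
#' @return numeric vector of site energies (cm^-1).
#' @export
site_energies <- function(units, params) {
  labels <- vapply(units, function(u) u$label_residue, 0L)
  bad <- setdiff(params$labeled_residues, labels)
  if (length(bad) > 0) {
    stop("labeled residue(s) outside the amide-unit range: ",
         paste(bad, collapse = ", "))
  }
  eps <- rep(params$epsilon0, length(units))
  eps[labels %in% params$labeled_residues] <-
    eps[labels %in% params$labeled_residues] + params$label_shift
  if (params$sigma_eps > 0) {
    old <- local_seed(params$disorder_seed)
    on.exit(restore_seed(old))
    eps <- eps + stats::rnorm(length(units), sd = params$sigma_eps)
  }
  eps
}

#' Transition dipole of one amide unit
#'
#' Dipole of the configured magnitude with origin on the C=O axis at
#' `dipole_offset` from C, direction rotated from C=O toward N by
#' `dipole_tilt` degrees within the O=C-N plane. Covariant under rigid
#' motion of the unit.
#'
#' @param unit an amide unit.
#' @param params a [hamiltonian_params()].
#' @return list with `mu` (Debye 3-vector) and `origin` (Angstrom 3-vector).
#' @export
transition_dipole <- function(unit, params) {
  co <- unit$O - unit$C
  cn <- unit$N - unit$C
  axis <- pracma_cross(co, cn)
  if (vnorm(axis) < 1e-8) stop("degenerate amide geometry: O=C-N collinear")
  e_co <- unit_vec(co)
  # in-plane unit vector perpendicular to C=O, pointing toward N
  perp <- unit_vec(cn - sum(cn * e_co) * e_co)
  th <- deg2rad(params$dipole_tilt)
  dir <- cos(th) * e_co + sin(th) * perp
  list(mu = params$dipole_magnitude * dir,
       origin = unit$C + params$dipole_offset * e_co)
}

#' Transition-dipole coupling between two amide units
#'
#' J = prefactor * [mu_m . mu_n - 3 (mu_m . r)(mu_n . r)] / r^3 with unit
#' separation vector r between dipole origins; symmetric in its arguments.
#'
#' @param unit_m,unit_n two amide units.
#' @param params a [hamiltonian_params()].
#' @return coupling in cm^-1.
#' @export
tdc_coupling <- function(unit_m, unit_n, params) {
  dm <- transition_dipole(unit_m, params)
  dn <- transition_dipole(unit_n, params)
  r <- dn$origin - dm$origin
  rr <- vnorm(r)
  if (rr < 1e-6) stop("coincident dipole origins")
  rh <- r / rr
  um <- unit_vec(dm$mu); un <- unit_vec(dn$mu)
  kappa <- sum(um * un) - 3 * sum(um * rh) * sum(un * rh)
  params$tdc_prefactor * kappa * vnorm(dm$mu) * vnorm(dn$mu) / rr^3
}

#' Load a nearest-neighbor coupling map
#'
#' Reads a TSV with columns `phi`, `psi`, `J` on a regular periodic grid.
#' The packaged default is a synthetic analytic surface with the qualitative
#' features of published ab initio nearest-neighbor maps (positive coupling
#' in the right-handed helical basin, negative in the extended basin); it
#' is a stand-in, replaceable via this loader.
#'
#' @param path TSV path; default the packaged synthetic map.
#' @return object of class `NNCouplingMap`: list with sorted grid vectors
#'   `phi`, `psi` and value matrix `J` (phi x psi).
#' @export
nn_coupling_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "nn_coupling_map_synthetic.tsv",
                        package = "amide2d")
  }
  if (!file.exists(path)) stop("coupling map not found: ", path)
  tb <- utils::read.delim(path)
  if (!all(c("phi", "psi", "J") %in% names(tb))) {
    stop("map table must have columns phi, psi, J")
  }
  gp <- sort(unique(tb$phi)); gs <- sort(unique(tb$psi))
  if (nrow(tb) != length(gp) * length(gs)) {
    stop("malformed map table: not a rectangular phi x psi grid")
  }
  J <- matrix(NA_real_, length(gp), length(gs))
  J[cbind(match(tb$phi, gp), match(tb$psi, gs))] <- tb$J
  if (any(is.na(J))) stop("malformed map table: duplicated/missing nodes")
  structure(list(phi = gp, psi = gs, J = J), class = "NNCouplingMap")
}

#' Nearest-neighbor coupling from the dihedral map
#'
#' Bilinear interpolation of the coupling surface at (phi, psi), periodic in
#' both angles.
#'
#' @param phi,psi backbone dihedrals in degrees.
#' @param map_table an [nn_coupling_map()].
#' @return coupling in cm^-1.
#' @export
nn_coupling <- function(phi, psi, map_table) {
  stopifnot(inherits(map_table, "NNCouplingMap"))
  interp_axis <- function(x, grid) {
    period <- 360
    step <- diff(grid)
    if (length(unique(round(step, 6))) != 1) {
      stop("malformed map table: irregular grid spacing")
    }
    h <- step[1]
    x0 <- grid[1]
    u <- ((x - x0) %% period) / h
    i <- floor(u)
    list(i = (i %% length(grid)) + 1,
         j = ((i + 1) %% length(grid)) + 1,
         w = u - i)
  }
  a <- interp_axis(phi, map_table$phi)
  b <- interp_axis(psi, map_table$psi)
  J <- map_table$J
  (1 - a$w) * (1 - b$w) * J[a$i, b$i] +
    a$w * (1 - b$w) * J[a$j, b$i] +
    (1 - a$w) * b$w * J[a$i, b$j] +
    a$w * b$w * J[a$j, b$j]
}

#' Build the one-exciton (local amide) Hamiltonian
#'
#' Diagonal from [site_energies()]; adjacent units (sharing a residue)
#' coupled through the nearest-neighbor map at the shared residue's
#' (phi, psi); all non-adjacent pairs coupled by transition-dipole coupling.
#' Nearest neighbors use the map only (no TDC), the standard local-amide-
#' Hamiltonian convention avoiding double counting.
#'
#' @param structure a [Structure] with >= 2 residues.
#' @param params a [hamiltonian_params()].
#' @param map_table an [nn_coupling_map()] (default: packaged map).
#' @return object of class `ExcitonHamiltonian`: list with symmetric matrix
#'   `H` (cm^-1), dipole matrix `mu` (n x 3, Debye), dipole origins
#'   `origin` (n x 3, Angstrom), `labels` (label residues), `params`.
#' @export
build_hamiltonian <- function(structure, params = hamiltonian_params(),
                              map_table = nn_coupling_map()) {
  units <- extract_amide_units(structure)
  n <- length(units)
  eps <- site_energies(units, params)
  dip <- lapply(units, transition_dipole, params = params)
  mu <- t(vapply(dip, function(d) d$mu, numeric(3)))
  org <- t(vapply(dip, function(d) d$origin, numeric(3)))
  dh <- backbone_dihedrals(structure)
  H <- diag(eps, n)
  if (n > 1) {
    muhat <- mu / sqrt(rowSums(mu^2))
    mag <- sqrt(rowSums(mu^2))
    for (m in seq_len(n - 1)) {
      # nearest neighbors: dihedral map at the shared residue
      shared <- units[[m]]$label_residue
      H[m, m + 1] <- H[m + 1, m] <-
        nn_coupling(dh$phi[shared], dh$psi[shared], map_table)
      if (m + 2 <= n) {
        for (k in (m + 2):n) {
          r <- org[k, ] - org[m, ]
          rr <- vnorm(r)
          if (rr < 1e-6) stop("coincident dipole origins")
          rh <- r / rr
          kappa <- sum(muhat[m, ] * muhat[k, ]) -
            3 * sum(muhat[m, ] * rh) * sum(muhat[k, ] * rh)
          H[m, k] <- H[k, m] <-
            params$tdc_prefactor * kappa * mag[m] * mag[k] / rr^3
        }
      }
    }
  }
  structure(list(H = H, mu = mu, origin = org,
                 labels = vapply(units, function(u) u$label_residue, 0L),
                 params = params),
            class = "ExcitonHamiltonian")
}

#' Two-exciton Hamiltonian block
#'
#' Pair basis |m <= n> of dimension N(N+1)/2: |mm> has energy
#' 2 eps_m - Delta, |mn> (m < n) energy eps_m + eps_n; couplings
#' <mm|H|mn> = sqrt(2) J_mn and <mn|H|mk> = J_nk (one shared index);
#' disjoint pairs uncoupled. With Delta = 0 the eigenvalues are exactly all
#' pairwise sums of one-exciton eigenvalues (harmonic limit).
#'
#' @param H1 an [build_hamiltonian()] result or plain symmetric matrix.
#' @param anharmonicity Delta >= 0 (cm^-1); default taken from `H1$params`.
#' @return object of class `TwoExcitonHamiltonian`: list with matrix `H2`,
#'   `pairs` (basis index matrix, columns m, n), `anharmonicity`.
#' @export
two_exciton_block <- function(H1, anharmonicity = NULL) {
  M <- if (inherits(H1, "ExcitonHamiltonian")) H1$H else H1
  if (is.null(anharmonicity)) {
    anharmonicity <- if (inherits(H1, "ExcitonHamiltonian")) {
      H1$params$anharmonicity
    } else 0
  }
  if (anharmonicity < 0) stop("anharmonicity must be >= 0")
  n <- nrow(M)
  pairs <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, "row"], pairs[, "col"]), , drop = FALSE]
  np <- nrow(pairs)
  IDX <- matrix(0L, n, n)
  IDX[pairs] <- seq_len(np)
  IDX[pairs[, c(2, 1), drop = FALSE]] <- seq_len(np)
  H2 <- matrix(0, np, np)
  eps <- diag(M)
  diag(H2) <- eps[pairs[, 1]] + eps[pairs[, 2]] -
    ifelse(pairs[, 1] == pairs[, 2], anharmonicity, 0)
  for (a in seq_len(n)) {
    others <- setdiff(seq_len(n), a)
    if (length(others) == 0) next
    # |aa> <-> |ab>: sqrt(2) J_ab
    qd <- IDX[a, a]
    qo <- IDX[cbind(a, others)]
    H2[cbind(qd, qo)] <- H2[cbind(qo, qd)] <- sqrt(2) * M[a, others]
    # |ab> <-> |ac>: J_bc (shared index a, b != c)
    if (length(others) >= 2) {
      cmb <- t(utils::combn(others, 2))
      q1 <- IDX[cbind(a, cmb[, 1])]
      q2 <- IDX[cbind(a, cmb[, 2])]
      H2[cbind(q1, q2)] <- H2[cbind(q2, q1)] <- M[cmb]
    }
  }
  structure(list(H2 = H2, pairs = unname(pairs),
                 anharmonicity = anharmonicity),
            class = "TwoExcitonHamiltonian")
}

#' Write / read a Hamiltonian as plain text
#'
#' Symmetric matrix with a one-line header `# N <n> units cm-1`.
#'
#' @param H an [build_hamiltonian()] result or plain matrix.
#' @param path file path.
#' @return `write_hamiltonian`: invisibly the path; `read_hamiltonian`: the
#'   numeric matrix.
#' @export
write_hamiltonian <- function(H, path) {
  M <- if (inherits(H, "ExcitonHamiltonian")) H$H else H
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# N %d units cm-1", nrow(M)), con)
  utils::write.table(M, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_hamiltonian
#' @export
read_hamiltonian <- function(path) {
  hdr <- readLines(path, n = 1)
  n <- as.integer(strsplit(hdr, " ")[[1]][3])
  M <- as.matrix(utils::read.table(path, skip = 1, sep = "\t"))
  dimnames(M) <- NULL
  if (nrow(M) != n || ncol(M) != n) stop("matrix dimensions disagree with header")
  M
}
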