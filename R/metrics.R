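# Conformational fingerprinting: contact maps, Q-scores, radius of gyration,
# Shrake-Rupley SASA, Kabsch-superposed RMSD, centroid clustering and
# quintile representative selection.

#' Residue contact map
#'
#' Boolean CA-CA contact matrix: residues i, j are in contact iff their CA
#' distance is at most `cutoff` and |i - j| >= `min_sep`.
#'
#' @param structure a [Structure].
#' @param cutoff contact distance cutoff in Angstrom (default 6.7, the
#'   value used for the published contact maps).
#' @param min_sep minimum sequence separation (default 3).
#' @return object of class `ContactMap`: list with logical matrix `map`,
#'   `cutoff`, `min_sep`.
#' @export
contact_map <- function(structure, cutoff = 6.7, min_sep = 3) {
  if (cutoff <= 0) stop("cutoff must be positive")
  ca <- atom_matrix(structure, "CA")
  d <- as.matrix(stats::dist(ca))
  m <- d <= cutoff
  n <- nrow(m)
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  m[sep < min_sep] <- FALSE
  diag(m) <- FALSE
  structure(list(map = m, cutoff = cutoff, min_sep = min_sep),
            class = "ContactMap")
}

#' Fraction of native contacts (Q-score)
#'
#' Number of native contacts also present in the query structure's contact
#' map (same cutoff and separation), divided by the number of native
#' contacts. 1.0 means fully native; the folding criterion in the source
#' study was Q > 0.95.
#'
#' @param structure query [Structure].
#' @param native_map a [contact_map()] of the native reference.
#' @return Q in [0, 1].
#' @export
q_score <- function(structure, native_map) {
  stopifnot(inherits(native_map, "ContactMap"))
  K <- sum(native_map$map) / 2
  if (K == 0) stop("native contact map is empty; Q undefined")
  qm <- contact_map(structure, cutoff = native_map$cutoff,
                    min_sep = native_map$min_sep)
  if (!all(dim(qm$map) == dim(native_map$map))) {
    stop("structure and native map have different residue counts")
  }
  k <- sum(qm$map & native_map$map) / 2
  k / K
}

#' Radius of gyration
#'
#' Mass-unweighted RMS distance of the backbone atoms from their centroid.
#'
#' @param structure a [Structure].
#' @param atoms which atom names to include (default backbone N, CA, C, O).
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(structure, atoms = BACKBONE_ATOMS) {
  xyz <- as.matrix(structure$atoms[structure$atoms$atom %in% atoms,
                                   c("x", "y", "z")])
  if (nrow(xyz) == 0) stop("no atoms selected")
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
}

# van der Waals radii by element (Angstrom)
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, H = 1.20, S = 1.80)

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Sphere-point sampling: each atom's sphere of radius (vdW + probe) is
#' covered with a deterministic golden-spiral point set; the exposed point
#' fraction times the sphere area is summed over atoms.
#'
#' @param structure a [Structure].
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param n_points sphere sample points per atom (default 960).
#' @param include_h include hydrogens (default FALSE; backbone heavy atoms).
#' @return total SASA in Angstrom^2.
#' @export
sasa <- function(structure, probe = 1.4, n_points = 960, include_h = FALSE) {
  at <- structure$atoms
  if (!include_h) at <- at[at$element != "H", ]
  elems <- at$element
  unknown <- setdiff(unique(elems), names(VDW_RADII))
  if (length(unknown) > 0) {
    stop("no van der Waals radius for element(s): ",
         paste(unknown, collapse = ", "))
  }
  xyz <- as.matrix(at[, c("x", "y", "z")])
  radii <- VDW_RADII[elems] + probe
  pts <- golden_spiral_points(n_points)
  total <- 0
  na <- nrow(xyz)
  for (i in seq_len(na)) {
    sph <- sweep(pts * radii[i], 2, xyz[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in seq_len(na)) {
      if (j == i) next
      dij <- xyz[j, ] - xyz[i, ]
      if (vnorm(dij) >= radii[i] + radii[j]) next
      d2 <- (sph[, 1] - xyz[j, 1])^2 + (sph[, 2] - xyz[j, 2])^2 +
            (sph[, 3] - xyz[j, 3])^2
      exposed <- exposed & d2 > radii[j]^2
    }
    total <- total + 4 * pi * radii[i]^2 * mean(exposed)
  }
  unname(total)
}

# deterministic quasi-uniform points on the unit sphere
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Backbone RMSD after optimal superposition
#'
#' Root-mean-square deviation over N, CA, C, O atoms after least-squares
#' (Kabsch) superposition; symmetric in its arguments and zero for rigidly
#' transformed copies.
#'
#' @param a,b two [Structure]s with the same residue count.
#' @return RMSD in Angstrom.
#' @export
backbone_rmsd <- function(a, b) {
  if (n_residues(a) != n_residues(b)) {
    stop("structures differ in residue count")
  }
  xa <- backbone_xyz(a)
  xb <- backbone_xyz(b)
  xa <- sweep(xa, 2, colMeans(xa))
  xb <- sweep(xb, 2, colMeans(xb))
  # Kabsch: rotation minimizing |xa R - xb|
  s <- svd(t(xa) %*% xb)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((xa %*% R - xb)^2)))
}

backbone_xyz <- function(s) {
  rows <- s$atoms[s$atoms$atom %in% BACKBONE_ATOMS, ]
  rows <- rows[order(rows$residue, match(rows$atom, BACKBONE_ATOMS)), ]
  as.matrix(rows[, c("x", "y", "z")])
}

#' Quintile representative structures of an ensemble
#'
#' The centroid is the member minimizing summed RMSD to all others; members
#' are sorted by RMSD to the centroid (ties broken by member index), split
#' into five index-contiguous quintiles (sizes differing by at most one),
#' and the floor-median member of each quintile is returned. This mirrors
#' picking "the middle structure of each quintile" of an RMSD distribution.
#'
#' @param ensemble a [StructureEnsemble] with at least 5 members.
#' @return list with `structures` (5 members), `indices` (original member
#'   indices), `centroid` (centroid member index), `rmsd` (sorted RMSD of
#'   the 5 picks to the centroid).
#' @export
quintile_representatives <- function(ensemble) {
  m <- length(ensemble$structures)
  if (m < 5) stop("ensemble must have at least 5 members")
  D <- matrix(0, m, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      D[i, j] <- D[j, i] <- backbone_rmsd(ensemble$structures[[i]],
                                          ensemble$structures[[j]])
    }
  }
  centroid <- which.min(rowSums(D))
  r <- D[centroid, ]
  ord <- order(r, seq_len(m))   # ascending; ties by lowest index
  sizes <- rep(m %/% 5, 5) + c(rep(1, m %% 5), rep(0, 5 - m %% 5))
  starts <- cumsum(c(1, sizes[-5]))
  picks <- integer(5)
  for (q in 1:5) {
    block <- ord[starts[q]:(starts[q] + sizes[q] - 1)]
    picks[q] <- block[(length(block) + 1) %/% 2]   # floor median
  }
  list(structures = ensemble$structures[picks], indices = picks,
       centroid = centroid, rmsd = r[picks])
}

#' Fingerprint an ensemble (Table-1-style conformation record)
#'
#' Per-member DSSP string, Q-score against a native contact map, radius of
#' gyration and SASA, plus the matched conformation label.
#'
#' @param ensemble a [StructureEnsemble].
#' @param native_map [contact_map()] of the native reference (for Q).
#' @param references named DSSP reference strings (for matching); NULL to
#'   skip matching.
#' @param max_mismatch Hamming tolerance for [match_conformation()].
#' @return data frame with columns `member`, `label`, `Q`, `Rg`, `SASA`,
#'   `dssp`, `match`.
#' @export
conformation_record <- function(ensemble, native_map = NULL,
                                references = NULL, max_mismatch = 3) {
  rows <- lapply(seq_along(ensemble$structures), function(k) {
    s <- ensemble$structures[[k]]
    d <- dssp_string(s)
    mt <- if (!is.null(references)) {
      tryCatch(match_conformation(d, references, max_mismatch),
               error = function(e) NA_character_)
    } else NA_character_
    data.frame(member = k, label = ensemble$label,
               Q = if (!is.null(native_map)) q_score(s, native_map) else NA,
               Rg = radius_of_gyration(s), SASA = sasa(s),
               dssp = d, match = mt, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
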