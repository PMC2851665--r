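# Structure data model: a single-chain peptide backbone and ensembles thereof.

AA1TO3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
            E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
            M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
            Y = "TYR", V = "VAL", X = "UNK")
AA3TO1 <- stats::setNames(names(AA1TO3), AA1TO3)

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Peptide backbone structure
#'
#' A single-chain peptide backbone: a residue sequence plus per-atom records.
#' Every residue must carry the backbone atoms N, CA, C and O; the amide
#' hydrogen H is optional (it is reconstructed geometrically where needed).
#'
#' @param sequence character vector of one-letter residue codes.
#' @param atoms data frame with columns `residue` (integer, 1-based,
#'   strictly increasing blocks), `atom` (name, e.g. "CA"), `element`
#'   and Cartesian coordinates `x`, `y`, `z` in Angstrom.
#' @return An object of class `Structure`.
#' @export
new_structure <- function(sequence, atoms) {
  stopifnot(is.character(sequence), is.data.frame(atoms))
  need <- c("residue", "atom", "element", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  }
  atoms$residue <- as.integer(atoms$residue)
  s <- structure(list(sequence = sequence, atoms = atoms), class = "Structure")
  validate_structure(s)
  s
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("Structure: %d residues, %d atoms\n",
              n_residues(x), nrow(x$atoms)))
  cat("  sequence:", paste(x$sequence, collapse = ""), "\n")
  invisible(x)
}

#' Number of residues in a structure
#' @param structure a [Structure].
#' @return integer residue count.
#' @export
n_residues <- function(structure) length(structure$sequence)

validate_structure <- function(s) {
  n <- n_residues(s)
  if (n < 1) stop("structure has no residues")
  if (!all(is.finite(as.matrix(s$atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in structure")
  }
  res <- unique(s$atoms$residue)
  if (any(diff(res) <= 0)) stop("residue indices must be strictly increasing")
  if (!identical(res, seq_len(n))) {
    stop("atom records must cover residues 1..", n)
  }
  for (i in seq_len(n)) {
    here <- s$atoms$atom[s$atoms$residue == i]
    missing <- setdiff(BACKBONE_ATOMS, here)
    if (length(missing) > 0) {
      stop(sprintf("residue %d is missing backbone atom(s): %s",
                   i, paste(missing, collapse = ", ")))
    }
  }
  invisible(s)
}

#' Coordinates of one named atom of one residue
#' @param structure a [Structure].
#' @param residue residue index (1-based).
#' @param atom atom name, e.g. "CA".
#' @return length-3 numeric vector, or NULL if absent.
#' @export
atom_coord <- function(structure, residue, atom) {
  sel <- structure$atoms$residue == residue & structure$atoms$atom == atom
  if (!any(sel)) return(NULL)
  as.numeric(structure$atoms[which(sel)[1], c("x", "y", "z")])
}

# n x 3 matrix of a named backbone atom across all residues (NA rows if absent)
atom_matrix <- function(structure, atom) {
  n <- n_residues(structure)
  m <- matrix(NA_real_, n, 3)
  sel <- structure$atoms$atom == atom
  sub <- structure$atoms[sel, ]
  m[sub$residue, ] <- as.matrix(sub[, c("x", "y", "z")])
  m
}

#' Ensemble of conformers of one peptide
#'
#' An ordered list of [Structure] objects sharing the same sequence.
#'
#' @param structures list of [Structure] objects.
#' @param label character ensemble label.
#' @return An object of class `StructureEnsemble`.
#' @export
new_ensemble <- function(structures, label = "ensemble") {
  if (length(structures) < 1) stop("ensemble must be non-empty")
  seqs <- vapply(structures, function(s) paste(s$sequence, collapse = ""), "")
  if (length(unique(seqs)) != 1) {
    stop("all ensemble members must share the same sequence")
  }
  structure(list(structures = structures, label = label),
            class = "StructureEnsemble")
}

#' @export
print.StructureEnsemble <- function(x, ...) {
  cat(sprintf("StructureEnsemble '%s': %d members x %d residues\n",
              x$label, length(x$structures), n_residues(x$structures[[1]])))
  invisible(x)
}

#' @export
length.StructureEnsemble <- function(x) length(x$structures)

#' Extract amide units (peptide bonds) from a backbone
#'
#' One unit per peptide bond: atoms C_i, O_i, N_(i+1), H_(i+1) and CA_i /
#' CA_(i+1). A chain of n residues yields exactly n-1 units. When the amide
#' hydrogen is absent it is reconstructed in the C_i - N_(i+1) - CA_(i+1)
#' plane, opposite C, at N-H = 1.02 Angstrom. By convention unit i is
#' labelled by its N-side residue i+1 (so a 20-mer gives units Thr2..Thr20).
#'
#' @param structure a [Structure] with at least 2 residues.
#' @return list of `AmideUnit` objects, each a list with fields `index`,
#'   `label_residue`, and coordinates `C`, `O`, `N`, `H`, `CA`, `CA_next`.
#' @export
extract_amide_units <- function(structure) {
  n <- n_residues(structure)
  if (n < 2) stop("need at least 2 residues to form an amide unit")
  Nm <- atom_matrix(structure, "N")
  CAm <- atom_matrix(structure, "CA")
  Cm <- atom_matrix(structure, "C")
  Om <- atom_matrix(structure, "O")
  Hm <- atom_matrix(structure, "H")
  units <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    C <- Cm[i, ]
    O <- Om[i, ]
    N <- Nm[i + 1, ]
    CA <- CAm[i, ]
    CA2 <- CAm[i + 1, ]
    H <- Hm[i + 1, ]
    if (any(is.na(H))) H <- reconstruct_amide_h(C, N, CA2)
    dCO <- vnorm(C - O)
    dCN <- vnorm(C - N)
    if (dCO < 0.9 || dCO > 1.6) {
      stop(sprintf("unit %d: C-O distance %.2f A outside 0.9-1.6 A", i, dCO))
    }
    if (dCN < 1.1 || dCN > 1.6) {
      stop(sprintf("unit %d: C-N distance %.2f A outside 1.1-1.6 A", i, dCN))
    }
    units[[i]] <- structure(
      list(index = i, label_residue = as.integer(i + 1),
           C = C, O = O, N = N, H = H, CA = CA, CA_next = CA2),
      class = "AmideUnit")
  }
  units
}

# H in the C-N-CA2 plane, opposite C, N-H = 1.02 A
reconstruct_amide_h <- function(C, N, CA2) {
  u <- unit_vec(C - N)
  v <- unit_vec(CA2 - N)
  N + 1.02 * unit_vec(-(u + v))
}

#' Backbone phi/psi dihedrals
#'
#' phi_i from C_(i-1), N_i, CA_i, C_i and psi_i from N_i, CA_i, C_i, N_(i+1),
#' IUPAC sign convention, degrees in (-180, 180]. phi of the first residue
#' and psi of the last are undefined (NA).
#'
#' @param structure a [Structure].
#' @return data frame with columns `residue`, `phi`, `psi` (degrees).
#' @export
backbone_dihedrals <- function(structure) {
  n <- n_residues(structure)
  Nm <- atom_matrix(structure, "N")
  CAm <- atom_matrix(structure, "CA")
  Cm <- atom_matrix(structure, "C")
  phi <- rep(NA_real_, n)
  psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1) {
      phi[i] <- dihedral_angle(Cm[i - 1, ], Nm[i, ], CAm[i, ], Cm[i, ])
    }
    if (i < n) {
      psi[i] <- dihedral_angle(Nm[i, ], CAm[i, ], Cm[i, ], Nm[i + 1, ])
    }
  }
  data.frame(residue = seq_len(n), phi = phi, psi = psi)
}
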