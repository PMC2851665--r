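# Kabsch-Sander backbone hydrogen bonds and DSSP-style secondary structure.

#' Kabsch-Sander backbone hydrogen bonds
#'
#' Electrostatic H-bond energy between the N-H of a donor residue and the
#' C=O of an acceptor residue:
#' E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) kcal/mol,
#' distances in Angstrom; a bond is assigned when E < -0.5 kcal/mol.
#' Residue 1 cannot donate (no preceding carbonyl to define its amide H).
#'
#' @param structure a [Structure]; amide H is reconstructed when absent.
#' @param cutoff energy cutoff in kcal/mol (default -0.5).
#' @return data frame with columns `donor`, `acceptor`, `energy`.
#' @export
kabsch_sander_hbonds <- function(structure, cutoff = -0.5) {
  n <- n_residues(structure)
  Nm <- atom_matrix(structure, "N")
  Cm <- atom_matrix(structure, "C")
  Om <- atom_matrix(structure, "O")
  CAm <- atom_matrix(structure, "CA")
  Hm <- atom_matrix(structure, "H")
  for (i in 2:n) {
    if (any(is.na(Hm[i, ]))) {
      Hm[i, ] <- reconstruct_amide_h(Cm[i - 1, ], Nm[i, ], CAm[i, ])
    }
  }
  q <- 0.084 * 332
  cross_dist <- function(A, B) {
    sqrt(pmax(outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B), 0))
  }
  E <- q * (1 / cross_dist(Nm, Om) + 1 / cross_dist(Hm, Cm) -
            1 / cross_dist(Hm, Om) - 1 / cross_dist(Nm, Cm))  # [donor, acc]
  E[1, ] <- NA                      # residue 1 has no amide H
  excl <- outer(seq_len(n), seq_len(n), function(d, a) a == d | a == d - 1)
  E[excl] <- NA                     # the donor H belongs to bond a -> d
  hit <- which(!is.na(E) & E < cutoff, arr.ind = TRUE)
  hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
  data.frame(donor = as.integer(hit[, 1]), acceptor = as.integer(hit[, 2]),
             energy = E[hit])
}

#' DSSP-style secondary structure string
#'
#' Reduced DSSP assignment from Kabsch-Sander hydrogen bonds with priority
#' H > G > E > T > S > '~':
#' H from two consecutive i+4 turns, G from two consecutive i+3 turns,
#' E from parallel/antiparallel bridges (isolated bridges folded into E),
#' T from remaining turn interiors (n = 3, 4, 5), S from bends (CA
#' pentapeptide kink angle > 70 degrees). The two terminal residues are
#' excluded, so a 20-mer yields an 18-character string.
#'
#' @param structure a [Structure] with >= 5 residues.
#' @return single string over the alphabet H, G, E, T, S, ~ of length
#'   `n_residues - 2`.
#' @export
dssp_string <- function(structure) {
  n <- n_residues(structure)
  if (n < 5) stop("DSSP assignment needs at least 5 residues")
  hb <- kabsch_sander_hbonds(structure)
  # hbond(acceptor, donor) lookup: CO of i accepts NH of j
  hbond <- matrix(FALSE, n, n)
  if (nrow(hb) > 0) hbond[cbind(hb$acceptor, hb$donor)] <- TRUE

  turn <- function(nn) {
    t <- rep(FALSE, n)
    idx <- seq_len(max(0, n - nn))
    t[idx] <- hbond[cbind(idx, idx + nn)]
    t
  }
  t3 <- turn(3); t4 <- turn(4); t5 <- turn(5)

  ss <- rep("~", n)
  mark <- function(ss, pos, letter) {
    pr <- c("H" = 6, "G" = 5, "E" = 4, "T" = 3, "S" = 2, "~" = 1)
    for (p in pos) if (pr[letter] > pr[ss[p]]) ss[p] <- letter
    ss
  }

  # bends first (lowest priority; overwritten by anything stronger)
  CAm <- atom_matrix(structure, "CA")
  for (i in 3:(n - 2)) {
    kink <- angle_between(CAm[i, ] - CAm[i - 2, ], CAm[i + 2, ] - CAm[i, ])
    if (kink > 70) ss <- mark(ss, i, "S")
  }
  # turns: interiors of any isolated n-turn
  for (i in which(t3)) ss <- mark(ss, (i + 1):(i + 2), "T")
  for (i in which(t4)) ss <- mark(ss, (i + 1):(i + 3), "T")
  for (i in which(t5)) ss <- mark(ss, (i + 1):(i + 4), "T")
  # bridges / ladders -> E
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j < i + 3) next
      par <- (i > 1 && hbond[i - 1, j] && j < n && hbond[j, i + 1]) ||
             (j > 1 && hbond[j - 1, i] && i + 1 <= n && j < n && hbond[i, j + 1])
      anti <- (hbond[i, j] && hbond[j, i]) ||
              (i > 1 && j < n && hbond[i - 1, j + 1] &&
               i + 1 <= n && hbond[j - 1, i + 1])
      if (par || anti) ss <- mark(ss, c(i, j), "E")
    }
  }
  # 3-10 helix: two consecutive 3-turns
  for (i in which(t3[seq_len(n - 1)] & t3[2:n])) {
    ss <- mark(ss, (i + 1):(i + 3), "G")
  }
  # alpha helix: two consecutive 4-turns
  for (i in which(t4[seq_len(n - 1)] & t4[2:n])) {
    ss <- mark(ss, (i + 1):(i + 4), "H")
  }
  paste(ss[2:(n - 1)], collapse = "")
}

#' Match a DSSP string against reference conformation strings
#'
#' Returns the label of the unique reference within `max_mismatch` Hamming
#' distance of `dssp`; `NA` when none qualifies; an error when two references
#' tie at the minimal qualifying distance.
#'
#' @param dssp a DSSP string.
#' @param references named character vector (label -> DSSP string), all the
#'   same nchar as `dssp`.
#' @param max_mismatch maximum Hamming distance accepted (default 3,
#'   approximately 80 percent identity for an 18-character string).
#' @return matching label, or `NA_character_`.
#' @export
match_conformation <- function(dssp, references, max_mismatch = 3) {
  stopifnot(length(references) >= 1, !is.null(names(references)))
  if (any(nchar(references) != nchar(dssp))) {
    stop("reference strings must have the same length as the query")
  }
  d <- vapply(references, function(r) hamming_distance(dssp, r), 0)
  ok <- which(d <= max_mismatch)
  if (length(ok) == 0) return(NA_character_)
  dmin <- min(d[ok])
  best <- names(references)[which(d == dmin)]
  if (length(best) > 1) {
    stop("ambiguous conformation match: ",
         paste(best, collapse = ", "), " at distance ", dmin)
  }
  best
}

hamming_distance <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Reference DSSP strings of the five Beta3s conformations
#'
#' The published backbone secondary-structure strings used to identify the
#' folding intermediates (18 characters, residues 2-19 of the 20-mer).
#'
#' @return named character vector with entries Native, Ns, Cs, Ch, Helix612.
#' @export
beta3s_reference_dssp <- function() {
  c(Native = "EEEESSEEEEEESSEEEE",
    Ns = "EEEESTTEEEEESSEEEE",
    Cs = "EEEESSEEEEESSSEEEE",
    Ch = "~~SSGGG~~~EESSEETT",
    Helix612 = "~HHHHHHHHHHHS~~~~~")
}
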