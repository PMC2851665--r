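# Frozen dihedral templates for the five Beta3s conformations.
#
# The motif targets were calibrated once, against the published per-
# conformation DSSP strings, by optimizing loop/bulge dihedrals so that the
# required cross-strand hydrogen-bond registers form under ideal-geometry
# construction; they are fixed package constants, not runtime parameters.
# The sheet templates use beta-bulge registers (bulges at residues 8 and 13)
# because a tight two-residue hairpin loop always carries an i->i+3 turn
# bond and would read TT rather than the published SS at the turns.

beta3s_templates <- function() {
  n <- 20
  # native: three-stranded antiparallel sheet, bulged hairpins
  sp <- -114.16; ss <- 119.95
  nat_phi <- rep(sp, n); nat_psi <- rep(ss, n)
  nat_phi[6] <- 159.74; nat_psi[6] <- 106.81
  nat_phi[7] <- 94.25;  nat_psi[7] <- 17.93
  nat_phi[8] <- 131.01; nat_psi[8] <- -156.08
  nat_psi[5] <- 87.97
  nat_phi[13] <- 159.74; nat_psi[13] <- 106.27
  nat_phi[14] <- 93.68;  nat_psi[14] <- 15.02
  nat_phi[15] <- 127.69; nat_psi[15] <- -159.56
  nat_psi[12] <- 87.97

  # 6-12 helix: helical segment residues 3-13, polyproline-II coil elsewhere
  hel_phi <- rep(-75, n); hel_psi <- rep(145, n)
  hel_phi[3:13] <- -57; hel_psi[3:13] <- -47

  list(Native = list(phi = nat_phi, psi = nat_psi, kind = "three_stranded_sheet"),
       Ns = beta3s_template_ns(nat_phi, nat_psi),
       Cs = beta3s_template_cs(nat_phi, nat_psi),
       Ch = beta3s_template_ch(),
       Helix612 = list(phi = hel_phi, psi = hel_psi, kind = "helix"))
}

# Ns: N-terminal strand out of register (hydrogen-bonded turn at residue 6)
beta3s_template_ns <- function(nat_phi, nat_psi) {
  phi <- nat_phi; psi <- nat_psi
  phi[6] <- 115.91; psi[6] <- 125.40
  phi[7] <- -22.32; psi[7] <- 3.52
  phi[8] <- -175.55; psi[8] <- 29.72
  psi[5] <- 160.55
  list(phi = phi, psi = psi, kind = "hairpin")
}

# Cs: C-terminal strand register shifted by two residues
beta3s_template_cs <- function(nat_phi, nat_psi) {
  phi <- nat_phi; psi <- nat_psi
  psi[12] <- 123.32
  phi[13] <- -144.47; psi[13] <- 128.19
  phi[14] <- 119.12;  psi[14] <- 109.79
  phi[15] <- 63.77;   psi[15] <- -18.75
  phi[16] <- -155.96; psi[16] <- -132.11
  list(phi = phi, psi = psi, kind = "hairpin")
}

# Ch: curled N-terminus with a short 3-10 segment, inverted C hairpin
beta3s_template_ch <- function() {
  n <- 20
  phi <- rep(-75, n); psi <- rep(145, n)   # polyproline-II baseline
  phi[4] <- -85.72;  psi[4] <- -88.24
  phi[5:8] <- -74.20; psi[5:8] <- 3.40     # 3-10-like segment
  phi[9] <- -80.54;  psi[9] <- 102.03
  phi[10] <- -83.96; psi[10] <- 120.67
  phi[11] <- -102.12; psi[11] <- 144.26
  phi[c(12, 13, 16, 17)] <- -125.60
  psi[c(12, 13, 16, 17)] <- 102.02         # short C-terminal strands
  phi[14] <- 48.15;  psi[14] <- -17.35
  phi[15] <- -142.07; psi[15] <- -172.34
  phi[18] <- -52.60; psi[18] <- 6.98
  phi[19] <- -94.87; psi[19] <- 15.33
  list(phi = phi, psi = psi, kind = "coil")
}

#' Build the five Beta3s conformer structures
#'
#' Ideal-geometry backbones for the five conformational states of the
#' folding pathway: the native three-stranded antiparallel sheet, the N- and
#' C-terminal out-of-register variants (Ns, Cs), the curled conformation
#' (Ch) and the 6-12 helix. Templates are fixed dihedral tables calibrated
#' against the published per-conformation DSSP strings; construction is
#' deterministic (the seed argument is accepted for interface uniformity
#' and reserved for future stochastic motifs).
#'
#' @param seed integer seed (construction is deterministic).
#' @return named list of 20-residue [Structure]s: Native, Ns, Cs, Ch,
#'   Helix612.
#' @export
make_beta3s_conformers <- function(seed = 1) {
  tmpl <- beta3s_templates()
  sq <- beta3s_sequence()
  out <- lapply(tmpl, function(tm) {
    build_backbone(motif_spec(sq, tm$phi, tm$psi, kind = tm$kind))
  })
  out
}
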