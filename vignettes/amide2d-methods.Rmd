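---
title: "Simulating amide-I 1D and 2D IR spectra of peptide folding intermediates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating amide-I 1D and 2D IR spectra of peptide folding intermediates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amide2d)
```

## The problem

Two-dimensional infrared correlation spectroscopy spreads the amide-I band
(the backbone carbonyl stretch, 1600–1700 cm⁻¹) over two frequency axes and
thereby resolves vibrational couplings between specific residues. Because
those couplings are set by three-dimensional backbone geometry, the 2D map
is a structural fingerprint fast enough to follow folding. This package
implements the full simulation chain for short peptides — backbone
structures in, spectra and per-residue peak assignments out — organized
around the five conformational states of the three-stranded β-sheet
mini-protein Beta3s: the native sheet, two out-of-register variants (Ns,
Cs), a curled state (Ch) and the 6-12 helix.

## The exciton model

Every peptide bond is one amide-I site, so a 20-residue chain has 19 sites;
unit *i* (between residues *i* and *i*+1) is labelled by residue *i*+1, so
tables run Thr2..Thr20. The one-exciton Hamiltonian has:

* **Site energies** `eps0` (default 1660 cm⁻¹, placing the computed bands in
  the experimental amide-I window), plus an isotope shift (default −65
  cm⁻¹, the ¹³C/¹⁸O red shift) for labelled residues, plus optional
  Gaussian diagonal disorder `sigma_eps` standing in for solvent
  heterogeneity.
* **Nearest-neighbor couplings** from a (φ, ψ) map evaluated at the residue
  shared by two consecutive units. The packaged surface
  (`nn_coupling_map()`) is a smooth synthetic analytic stand-in with the
  qualitative features of published ab initio maps — positive coupling in
  the right-handed helical basin, negative in the extended basin, a few
  cm⁻¹ in magnitude — tabulated on a 30° grid and interpolated bilinearly
  with periodic wrap-around. Any map with the same TSV layout can be
  substituted; quantitative peak positions inherit whatever map is used.
* **Through-space couplings** for all non-adjacent pairs by transition
  dipole coupling. The dipole (0.37 D) sits 0.868 Å from the carbonyl C
  along C=O, tilted 20° toward N in the amide plane; the prefactor 5034
  cm⁻¹·Å³·D⁻² is the Gaussian-units conversion. Nearest neighbors use the
  map only, never TDC, to avoid double counting. These are community
  conventions, configurable in `hamiltonian_params()`; no published
  parameter set is being fitted.

The two-exciton block lives in the pair basis |m≤n⟩ (dimension N(N+1)/2):
|mm⟩ at 2ε_m − Δ with anharmonicity Δ = 16 cm⁻¹ by default, |mn⟩ at
ε_m + ε_n, couplings √2·J on |mm⟩↔|mn⟩ and J on pairs sharing one site,
disjoint pairs uncoupled. With Δ = 0 this is exactly the harmonic
two-boson model: its spectrum equals all pairwise sums of one-exciton
energies, and the third-order signal cancels identically — both facts are
enforced by tests.

## Spectra

Linear absorption is a Lorentzian stick-sum over exciton states; Γ is
always the full width at half maximum (the internal complex half-width is
Γ/2), with Γ ∈ {1, 5, 10} cm⁻¹ as the standard settings. The rephasing
photon-echo signal (kI = −k1+k2+k3) is computed at waiting time t2 = 0 by
sum over states: ground-state bleach and stimulated emission on (e, e′)
pairs, excited-state absorption on (e, e′, f) with opposite sign and
detection at E_f − E_e, each pathway a product of complex Lorentzians on
the two axes, amplitudes carrying the isotropic all-parallel fourth-rank
orientational average (1/15)[(ab)(cd)+(ac)(bd)+(ad)(bc)]. Both display
axes are positive (the (ω₁, −ω₃) labelling convention) and the default
displayed component is the real part, which puts 0→1 features positive and
ESA negative. Rephasing-only lineshapes are phase-twisted, so 2D peak
*detection* runs on the modulus of the complex response while the signed
displayed amplitude is reported per peak.

Whether to display the real, imaginary or absolute part is not dictated by
the physics alone; it is configurable (`response_settings(component=)`) and
recorded in the spectrum metadata and TSV headers.

The independent check on all of this is `brute_force_response()`: a
time-domain propagation over the 0/1/2-exciton manifolds using
scaling-and-squaring matrix exponentials (never an eigendecomposition),
exponential damping Γ/2 per coherence, Simpson-rule half-Fourier transforms
in a rotating frame, with the step chosen from a Gershgorin bound so the
quadrature error sits below 10⁻⁶ of the signal. Sum-over-states and oracle
agree to better than 10⁻⁶ (relative to the spectrum maximum) on randomized
three-site systems; the oracle is limited to four sites by design.

## Synthetic conformers

No structural data accompany the study conditions, so the generator builds
ideal-geometry backbones (NeRF chain construction; N–CA 1.458 Å, CA–C
1.525 Å, C–N 1.329 Å, C=O 1.231 Å, standard angles, ω = 180°) from fixed
per-residue (φ, ψ) templates. Construction reproduces requested dihedrals
to 10⁻⁴ degrees, and amide hydrogens are placed in the peptide plane
(N–H 1.02 Å), matching the reconstruction used when input files lack them.

The five templates were calibrated once against the published
per-conformation DSSP strings and then frozen as package constants. Two
design points deserve explanation:

* **β-bulge registers.** In the reduced DSSP used here (as in the
  reference algorithm), any tight two-residue hairpin loop carries an i→i+3 hydrogen
  bond, which marks the loop as turn (T). The published strings instead
  show bend (S) at the native turns with strand (E) immediately adjacent.
  The only hydrogen-bond topology that reproduces this has bulged
  registers in which every short-range bond runs from an *upstream* donor
  (which never creates turn marks) and the cross-strand ladder is carried
  by mutual pairs at sequence separation ≥ 6 plus inter-bridge patterns.
  The native template therefore places β-bulges at residues 8 and 13; its
  computed string matches the published one at 16 of 18 positions, the two
  bulge residues reading S where the published string has E.
* **Helix extent.** The published helix-state string has H at residues
  3–13 (eleven H letters), so the template uses helical dihedrals over
  residues 3–13 — the computed string then matches the published one
  exactly — with polyproline-II dihedrals elsewhere, which produce neither
  hydrogen bonds nor bends.

Ensemble heterogeneity that in MD-based studies comes from trajectory
sampling and explicit re-solvation is emulated statistically:
`perturb_ensemble()` adds i.i.d. Gaussian coordinate jitter (default
σ = 0.05 Å, default 500 members per conformation), and site-energy
disorder σ_ε enters the Hamiltonian diagonal. Jitter draws that would
break a peptide bond (C–N outside 1.1–1.6 Å or C=O outside 0.9–1.6 Å) are
redrawn, so the ensemble is Gaussian conditioned on intact backbone
geometry; at the default σ this affects well under one percent of draws
and is undetectable in the displacement statistics. What this generator
does *not* emulate: anharmonic backbone relaxation, correlated
solvent-induced site shifts, side chains, and a five-structure ×
hundred-solvent-environment ensemble composition. Passing tests therefore
demonstrate correctness of the spectroscopy given the structures, not
reproduction of previously reported numerical tables (whose underlying
conformers and Hamiltonian parameter set are not publicly available).

## Fingerprinting

Kabsch–Sander hydrogen bonds use the electrostatic energy
E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) kcal/mol with the −0.5
cutoff; residue 1 cannot donate. The DSSP reduction assigns
H > G > E > T > S > ~ (priority order), with E from parallel/antiparallel
bridge patterns (isolated bridges folded into E), T from turn interiors,
S from CA pentapeptide kinks > 70°, and the two terminal residues excluded
(φ and ψ are undefined there), giving 18 characters for the 20-mer.
π-helix and isolated-bridge letters are not assigned; they do not occur in
the reference strings. Conformation matching is Hamming distance with a
default tolerance of 3 mismatches (~80 % identity); ties raise an error
rather than guessing.

Q-scores use CA–CA contact maps at 6.7 Å with |i−j| ≥ 3 — the published
cutoff; the atom choice is the minimal-information one consistent with a
backbone-only model, and contacts rather than unpublished NOE constraint
lists define nativeness. SASA is Shrake–Rupley with a deterministic
golden-spiral point set (960 points, probe 1.4 Å); its point-sampling
resolution is about 1 %, which is the tolerance used in invariance tests.
RMSD superposes N, CA, C, O by the Kabsch SVD. Quintile representatives
sort members by RMSD to the centroid (the member minimizing summed RMSD),
split into five index-contiguous blocks differing by at most one in size,
and take each block's floor-median, with ties broken by member index —
every ordering in the package is ascending with lowest-index tie-breaks.

## NMD and peaks

The coupling-contribution matrix is C_mn = Σ_k v_k(m)²v_k(n)²; eigenvector
orthonormality makes every row sum to one, and C → I as couplings vanish.
(The alternative reading (Σ_k v_k(m)v_k(n))² collapses to the identity by
orthogonality and is therefore rejected.) Per-residue frequencies are
assigned by maximum-weight bipartite matching between sites and modes with
weights v_k(m)², guaranteeing one frequency per residue — a per-site argmax
can assign one mode twice. Peak picking takes 8-neighborhood local maxima
above 5 % of the global maximum, classifies |ω₁−ω₃| ≤ 2 cm⁻¹ as diagonal,
and assignment accepts residue pairs within 3 cm⁻¹ on both axes; peak-list
comparison matches greedily by ascending distance (ties by lower ω₁), each
peak at most once. These defaults resolve the two-site fixtures cleanly and
are all configurable.

## Pipeline, sizes and determinism

`run_pipeline()` chains generate → fingerprint → Hamiltonian → spectra →
NMD → peaks → comparison with a master seed fanned out per stage
(generation uses the seed itself; conformation *i*'s disorder stream uses
seed + 1000·i + member), so stages are independently reproducible and a
rerun is bit-identical. The default configuration uses 50-member ensembles,
Γ ∈ {1, 5, 10} cm⁻¹ on a 1580–1720 cm⁻¹ grid at 0.5 cm⁻¹, and completes in
a few minutes on one CPU; tests use 2-member ensembles and coarser grids
where the full size adds nothing to the property under test. The
acceptance checks run the heavier sizes (100-member ensembles for the band
contrast; 50 randomized systems for cancellation; 25 for oracle
equivalence). ESA line assembly skips lines below 10⁻⁹ of the strongest
orientational amplitude for systems larger than six sites — below every
tolerance used anywhere — and keeps small systems exact.

## Known limitations

* Quantitative peak positions depend on the synthetic coupling surface and
  conventional Hamiltonian defaults; the published per-residue frequency
  tables and specific cross-peak lists derive from undeposited structures
  and an unpublished parameter set and are not reproduced numerically.
* The generator's bulged sheet registers reproduce the published DSSP
  strings at ≥ 80 % but not letter-perfectly; the native and Cs reference
  strings differ at a single position, so Hamming-based self-identification
  between those two states is not guaranteed for synthetic ensembles.
* Only the rephasing signal at t2 = 0 with all-parallel polarization is
  modelled: no non-rephasing or double-quantum signals, no waiting-time
  dynamics or population transfer, no Kubo/inhomogeneous lineshapes beyond
  static diagonal disorder, no explicit solvent electrostatics.
* Single chains only; no side chains beyond CA; no mmCIF input.
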