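# amide2d

Simulation of amide-I vibrational spectra — linear absorption and rephasing
(kI) two-dimensional infrared photon-echo maps — for short peptide
conformational ensembles, with structure-side fingerprinting and
normal-mode-decomposition (NMD) peak assignment. The package targets the
folding intermediates of the 20-residue three-stranded β-sheet mini-protein
Beta3s (sequence `TWIQNGSTKWYQNGSTKIYT`) and ships a synthetic backbone
generator for its five conformational states (native sheet, N- and
C-out-of-register variants, curl, 6-12 helix), so the whole analysis runs
without external structure data.

## Who it is for

Researchers exploring how 2D IR correlation spectroscopy reports on peptide
folding: which cross peaks a given backbone topology produces, how
out-of-register or helical intermediates differ spectrally from the native
state, and which residues carry each peak.

## The model

Each backbone peptide bond contributes one amide-I oscillator. The
one-exciton (local amide) Hamiltonian is

    H_mn = delta_mn (eps0 + isotope shift + disorder)
         + (1 - delta_mn) J_mn

with nearest-neighbor couplings taken from a (phi, psi) dihedral map at the
shared residue and all other pairs coupled through-space by transition
dipole coupling, J = kappa mu^2 / r^3 with the standard orientation factor
kappa = m̂·n̂ − 3(m̂·r̂)(n̂·r̂). Doubly excited states live in the pair basis
|mn⟩ with diagonal anharmonicity Δ on |mm⟩ and harmonic √2 couplings.

Linear absorption is a sum of Lorentzians (FWHM Γ) weighted by exciton
transition dipoles. The kI = −k1+k2+k3 photon-echo signal at waiting time
t2 = 0 is computed by sum over states over the ground-state-bleach,
stimulated-emission and excited-state-absorption pathways with the
isotropic all-parallel orientational average; a brute-force time-domain
propagation (`brute_force_response`) provides an independent oracle for
systems of up to four sites.

NMD diagonalizes the one-exciton Hamiltonian, assigns one eigenvalue per
residue (maximum-weight matching on squared eigenvector weights) and forms
the residue-residue coupling-contribution map C_mn = Σ_k v_k(m)² v_k(n)²,
whose rows sum to one.

Structure fingerprinting: Kabsch–Sander hydrogen bonds, a reduced DSSP
string (H/G/E/T/S/~, termini excluded), fraction-of-native-contacts
Q-scores on 6.7 Å CA contact maps, radius of gyration, Shrake–Rupley SASA
and Kabsch-superposed backbone RMSD with quintile representative selection.

## Worked example

```r
library(amide2d)

conf <- make_beta3s_conformers(seed = 1)
dssp_string(conf$Native)
#> [1] "EEEESSSEEEESSSEEEE"
q_score(conf$Native, contact_map(conf$Native))
#> [1] 1

ens <- perturb_ensemble(conf$Native, ensemble_noise(sigma_coord = 0.05, n = 50, seed = 2))
s1 <- ensemble_spectrum(ens, grid = spectral_grid(), settings = response_settings(10), kind = "1d")
s1$omega[which.max(s1$intensity)]
#> [1] 1658

H <- build_hamiltonian(conf$Native)
dim(H$H)
#> [1] 19 19
head(residue_frequency_table(nmd_decompose(H)), 3)
#>   residue frequency
#> 1       2      1633
#> 2       3      1630
#> 3       4      1658
```

The native DSSP string matches the published conformation string at 16 of
18 positions (the two β-bulge residues of the synthetic register read S);
the native structure scores Q = 1 against its own 24-contact map; the
ensemble amide-I maximum falls in the β/coil crossover region, and the
19×19 Hamiltonian yields one NMD frequency per residue Thr2..Thr20.

Running the full pipeline (`run_pipeline(pipeline_config(out_dir = "out"))`)
writes, per conformation, the jittered ensemble (PDB), a metrics table
(label, Q, Rg, SASA, DSSP string, matched conformation), 1D and 2D spectra
at Γ = 1, 5, 10 cm⁻¹, NMD tables, peak/assignment tables, and a
cross-conformation cross-peak comparison against the native reference.

A thin CLI wrapping these functions is installed at
`inst/scripts/amide2d` (subcommands `generate`, `fingerprint`,
`hamiltonian`, `spectra`, `nmd`, `peaks`, `pipeline`).

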