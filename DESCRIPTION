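Package: amide2d
Title: Amide-I Exciton Hamiltonians and Simulated 2D IR Spectra of Peptide Conformers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds local amide-I vibrational exciton Hamiltonians from peptide
    backbone structures and simulates linear absorption and rephasing (kI)
    two-dimensional infrared photon-echo spectra by sum over states, with a
    brute-force time-domain oracle for validation. Includes a synthetic
    backbone generator for the five Beta3s folding conformers (three-stranded
    antiparallel sheet, out-of-register variants, curl, 6-12 helix),
    conformational fingerprinting (Kabsch-Sander hydrogen bonds, DSSP-style
    secondary structure strings, fraction-of-native-contacts Q-scores, radius
    of gyration, Shrake-Rupley solvent-accessible surface area, contact maps,
    RMSD clustering), normal-mode-decomposition peak assignment, and an
    end-to-end seeded analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
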