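# Shared fixtures: ideal motifs and small exciton systems built in code.

make_helix <- function(n = 12, seq1 = rep("A", n)) {
  build_backbone(motif_spec(seq1, phi = rep(-57, n), psi = rep(-47, n),
                            kind = "helix"))
}

make_strand <- function(n = 10, seq1 = rep("A", n)) {
  build_backbone(motif_spec(seq1, phi = rep(-139, n), psi = rep(135, n),
                            kind = "strand"))
}

# random symmetric one-exciton Hamiltonian around a band center
random_h1 <- function(n, jscale = 8, center = 1660, spread = 15) {
  M <- matrix(stats::rnorm(n * n, sd = jscale), n, n)
  M <- (M + t(M)) / 2
  diag(M) <- center + stats::runif(n, -spread, spread)
  M
}

random_dipoles <- function(n, scale = 0.37) {
  matrix(stats::rnorm(3 * n, sd = scale), n, 3)
}

rel_diff_2d <- function(a, b) {
  max(abs(a$complex_amplitude - b$complex_amplitude)) /
    max(abs(a$complex_amplitude))
}

# structure with atoms at explicit coordinates (one residue, four backbone
# atoms) for closed-form geometry checks
square_structure <- function() {
  atoms <- data.frame(residue = 1L,
                      atom = c("N", "CA", "C", "O"),
                      element = c("N", "C", "C", "O"),
                      x = c(0, 1, 1, 0), y = c(0, 0, 1, 1), z = 0)
  new_structure("A", atoms)
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
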