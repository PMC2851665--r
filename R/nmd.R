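# Normal-mode decomposition: per-residue frequencies, residue-residue
# coupling-contribution maps, 2D peak picking, and peak -> residue-pair
# assignment.

#' Normal-mode decomposition of a one-exciton Hamiltonian
#'
#' Diagonalizes the Hamiltonian; the coupling-contribution matrix is
#' C_mn = sum_k v_k(m)^2 v_k(n)^2 (symmetric, rows summing to 1 by
#' eigenvector orthonormality; identity in the uncoupled limit). Each
#' residue is assigned one eigenvalue by maximum-weight bipartite matching
#' with weights v_k(m)^2, so assigned frequencies are a permutation of the
#' eigenvalues.
#'
#' @param H1 an [build_hamiltonian()] result or symmetric matrix.
#' @return object of class `NMDResult`: list with `eigenvalues`,
#'   `eigenvectors`, `C`, `site_frequency` (per-site assigned eigenvalue),
#'   `labels` (label residues, when available).
#' @export
nmd_decompose <- function(H1) {
  M <- if (inherits(H1, "ExcitonHamiltonian")) H1$H else H1
  if (max(abs(M - t(M))) > 1e-9 * max(1, max(abs(M)))) {
    stop("Hamiltonian must be symmetric")
  }
  eig <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ord <- order(eig$values)
  E <- eig$values[ord]
  V <- eig$vectors[, ord, drop = FALSE]
  W <- V^2                       # W[m, k] = weight of site m in mode k
  C <- W %*% t(W)
  perm <- max_weight_matching(W)
  labels <- if (inherits(H1, "ExcitonHamiltonian")) H1$labels else
    seq_len(nrow(M))
  structure(list(eigenvalues = E, eigenvectors = V, C = C,
                 site_frequency = E[perm], assignment = perm,
                 labels = labels),
            class = "NMDResult")
}

# exact maximum-weight bipartite matching (sites x modes) by
# branch-and-bound over permutations with greedy bound; n <= ~20
max_weight_matching <- function(W) {
  n <- nrow(W)
  if (n == 1) return(1L)
  # greedy initial solution for the bound
  perm <- integer(n)
  used <- rep(FALSE, n)
  ord <- order(-apply(W, 1, max))
  for (m in ord) {
    k <- which.max(ifelse(used, -Inf, W[m, ]))
    perm[m] <- k
    used[k] <- TRUE
  }
  best <- sum(W[cbind(seq_len(n), perm)])
  best_perm <- perm
  colmax <- apply(W, 2, max)
  rec <- function(m, used, acc, cur) {
    if (m > n) {
      if (acc > best) {
        best <<- acc
        best_perm <<- cur
      }
      return(invisible())
    }
    # optimistic bound: remaining rows take their best free column value
    ub <- acc + sum(vapply(m:n, function(r) max(W[r, !used]), 0))
    if (ub <= best) return(invisible())
    cols <- which(!used)
    cols <- cols[order(-W[m, cols])]
    for (k in cols) {
      used[k] <- TRUE
      cur[m] <- k
      rec(m + 1, used, acc + W[m, k], cur)
      used[k] <- FALSE
    }
  }
  rec(1L, rep(FALSE, n), 0, integer(n))
  best_perm
}

#' Per-residue NMD frequency table
#'
#' One row per amide unit, labelled by its N-side residue (so a 20-mer
#' yields rows for residues 2..20), with the matched eigenvalue in cm^-1.
#'
#' @param nmd an [nmd_decompose()] result.
#' @param labels residue labels (character or integer), one per site;
#'   defaults to the stored label residues.
#' @param digits rounding for the reported frequency (default 0, matching
#'   integer-cm^-1 reporting).
#' @return data frame with columns `residue`, `frequency`.
#' @export
residue_frequency_table <- function(nmd, labels = NULL, digits = 0) {
  n <- length(nmd$site_frequency)
  if (is.null(labels)) labels <- nmd$labels
  if (length(labels) != n) stop("labels length must equal matrix dimension")
  data.frame(residue = labels,
             frequency = round(nmd$site_frequency, digits))
}

#' Pick peaks in a 2D spectrum
#'
#' Local maxima of the response magnitude over 8-neighborhoods exceeding
#' `threshold_frac` of the global maximum. Detection runs on the modulus of
#' the complex response when available (the phase-twisted displayed
#' component has side lobes that are not physical peaks); the reported
#' `amplitude` is the signed displayed component at the peak. A peak is
#' diagonal iff |omega1 - omega3| <= `diag_tol`, else a cross peak.
#'
#' @param spectrum a `Spectrum2D`.
#' @param threshold_frac fraction of the global |amplitude| maximum
#'   (default 0.05).
#' @param diag_tol diagonal classification tolerance in cm^-1 (default 2).
#' @return object of class `PeakList`: data frame with columns `omega1`,
#'   `omega3`, `amplitude`, `kind`; attributes `threshold_frac`, `diag_tol`.
#' @export
pick_peaks_2d <- function(spectrum, threshold_frac = 0.05, diag_tol = 2) {
  stopifnot(threshold_frac > 0, threshold_frac < 1, diag_tol > 0)
  A <- if (!is.null(spectrum$complex_amplitude)) {
    Mod(spectrum$complex_amplitude)
  } else {
    abs(spectrum$amplitude)
  }
  gmax <- max(A)
  out <- data.frame(omega1 = numeric(0), omega3 = numeric(0),
                    amplitude = numeric(0), kind = character(0))
  if (gmax > 0) {
    n1 <- nrow(A); n3 <- ncol(A)
    thr <- threshold_frac * gmax
    for (i in 2:(n1 - 1)) {
      for (j in 2:(n3 - 1)) {
        v <- A[i, j]
        if (v < thr) next
        nb <- A[(i - 1):(i + 1), (j - 1):(j + 1)]
        if (v >= max(nb) && sum(nb == v) == 1) {
          w1 <- spectrum$omega1[i]; w3 <- spectrum$omega3[j]
          out <- rbind(out, data.frame(
            omega1 = w1, omega3 = w3,
            amplitude = spectrum$amplitude[i, j],
            kind = if (abs(w1 - w3) <= diag_tol) "diagonal" else "cross"))
        }
      }
    }
    out <- out[order(-abs(out$amplitude)), ]
    rownames(out) <- NULL
  }
  attr(out, "threshold_frac") <- threshold_frac
  attr(out, "diag_tol") <- diag_tol
  class(out) <- c("PeakList", "data.frame")
  out
}

#' Assign 2D peaks to residue pairs by NMD frequencies
#'
#' Each peak (omega1, omega3) gets the residue pair whose NMD frequencies
#' are nearest omega1 and omega3 respectively, accepted only when both are
#' within `tol`; otherwise the peak is reported unassigned (NA labels).
#'
#' @param peaks a [pick_peaks_2d()] result.
#' @param frequency_table a [residue_frequency_table()] result.
#' @param tol assignment tolerance in cm^-1 (default 3).
#' @return data frame with columns `omega1`, `omega3`, `kind`,
#'   `residue_a`, `residue_b`.
#' @export
assign_peaks <- function(peaks, frequency_table, tol = 3) {
  stopifnot(tol > 0)
  freq <- frequency_table$frequency
  lab <- frequency_table$residue
  nearest <- function(w) {
    i <- which.min(abs(freq - w))
    if (abs(freq[i] - w) <= tol) i else NA_integer_
  }
  rows <- lapply(seq_len(nrow(peaks)), function(r) {
    ia <- nearest(peaks$omega1[r])
    ib <- nearest(peaks$omega3[r])
    data.frame(omega1 = peaks$omega1[r], omega3 = peaks$omega3[r],
               kind = peaks$kind[r],
               residue_a = if (is.na(ia)) NA else lab[ia],
               residue_b = if (is.na(ib)) NA else lab[ib])
  })
  if (length(rows) == 0) {
    return(data.frame(omega1 = numeric(0), omega3 = numeric(0),
                      kind = character(0), residue_a = lab[0],
                      residue_b = lab[0]))
  }
  do.call(rbind, rows)
}

#' Compare two peak lists
#'
#' Greedy nearest matching within `tol` on both coordinates (ascending match
#' distance, ties by lower omega1); each peak matches at most once. Counts
#' partition both lists into shared, reference-only and other-only peaks.
#'
#' @param reference,other peak data frames with `omega1`, `omega3`.
#' @param tol matching tolerance in cm^-1.
#' @return list with data frames `shared` (columns from the reference),
#'   `reference_only`, `other_only` and integer `counts`.
#' @export
compare_peak_lists <- function(reference, other, tol = 3) {
  stopifnot(tol > 0)
  nr <- nrow(reference); no <- nrow(other)
  cand <- expand.grid(i = seq_len(nr), j = seq_len(no))
  if (nrow(cand) > 0) {
    cand$d <- pmax(abs(reference$omega1[cand$i] - other$omega1[cand$j]),
                   abs(reference$omega3[cand$i] - other$omega3[cand$j]))
    cand <- cand[cand$d <= tol, ]
    cand <- cand[order(cand$d, reference$omega1[cand$i]), ]
  }
  used_i <- rep(FALSE, nr); used_j <- rep(FALSE, no)
  keep <- integer(0)
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (!used_i[i] && !used_j[j]) {
      used_i[i] <- TRUE; used_j[j] <- TRUE
      keep <- c(keep, i)
    }
  }
  list(shared = reference[sort(keep), , drop = FALSE],
       reference_only = reference[!used_i, , drop = FALSE],
       other_only = other[!used_j, , drop = FALSE],
       counts = c(shared = sum(used_i), reference_only = sum(!used_i),
                  other_only = sum(!used_j)))
}
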