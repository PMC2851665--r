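# Minimal fixed-column PDB reading/writing for backbone ensembles.
# Supports ATOM / MODEL / ENDMDL / TER / END records, single chain.

#' Read a PDB file into a structure ensemble
#'
#' Parses ATOM records (fixed columns). MODEL/ENDMDL blocks become ensemble
#' members; a file without MODEL records yields a single-member ensemble.
#' Alternate locations are resolved to the highest-occupancy record. Only a
#' single chain is accepted.
#'
#' @param path path to a PDB file.
#' @param label ensemble label (defaults to the file name).
#' @return a [StructureEnsemble].
#' @export
read_pdb <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (is.null(label)) label <- basename(path)
  rec <- substr(lines, 1, 6)
  model_breaks <- which(trimws(rec) == "MODEL")
  atom_idx <- which(rec == "ATOM  ")
  if (length(atom_idx) == 0) stop("no ATOM records in ", path)

  parse_block <- function(idx) {
    fields <- lapply(idx, function(ln) {
      l <- lines[ln]
      if (nchar(l) < 54) {
        stop(sprintf("line %d: ATOM record too short to parse", ln))
      }
      xyz <- suppressWarnings(as.numeric(c(substr(l, 31, 38),
                                           substr(l, 39, 46),
                                           substr(l, 47, 54))))
      if (any(is.na(xyz))) {
        stop(sprintf("line %d: unparseable coordinates", ln))
      }
      occ <- suppressWarnings(as.numeric(substr(l, 55, 60)))
      if (is.na(occ)) occ <- 1
      elem <- trimws(substr(l, 77, 78))
      name <- trimws(substr(l, 13, 16))
      if (elem == "") elem <- substr(name, 1, 1)
      list(atom = name,
           alt = trimws(substr(l, 17, 17)),
           resname = trimws(substr(l, 18, 20)),
           chain = substr(l, 22, 22),
           resseq = suppressWarnings(as.integer(substr(l, 23, 26))),
           x = xyz[1], y = xyz[2], z = xyz[3],
           occ = occ, element = elem, line = ln)
    })
    df <- do.call(rbind, lapply(fields, function(f) as.data.frame(f)))
    if (any(is.na(df$resseq))) {
      stop(sprintf("line %d: unparseable residue number",
                   df$line[which(is.na(df$resseq))[1]]))
    }
    if (length(unique(df$chain)) > 1) {
      stop("multi-chain PDB files are not supported (single 20-mer scope)")
    }
    # altloc: keep the highest-occupancy record per (residue, atom)
    key <- paste(df$resseq, df$atom)
    keep <- unlist(lapply(split(seq_len(nrow(df)), key), function(ii) {
      ii[which.max(df$occ[ii])]
    }))
    df <- df[sort(keep), ]
    res_ids <- unique(df$resseq)
    res_map <- stats::setNames(seq_along(res_ids), res_ids)
    seq1 <- vapply(res_ids, function(r) {
      nm <- df$resname[df$resseq == r][1]
      if (nm %in% names(AA3TO1)) unname(AA3TO1[nm]) else "X"
    }, "")
    atoms <- data.frame(residue = as.integer(res_map[as.character(df$resseq)]),
                        atom = df$atom, element = df$element,
                        x = df$x, y = df$y, z = df$z,
                        stringsAsFactors = FALSE)
    new_structure(seq1, atoms)
  }

  if (length(model_breaks) == 0) {
    members <- list(parse_block(atom_idx))
  } else {
    ends <- c(model_breaks[-1] - 1, length(lines))
    members <- lapply(seq_along(model_breaks), function(k) {
      idx <- atom_idx[atom_idx > model_breaks[k] & atom_idx <= ends[k]]
      if (length(idx) == 0) stop("MODEL block without ATOM records")
      parse_block(idx)
    })
  }
  new_ensemble(members, label = label)
}

#' Write a structure ensemble as a PDB file
#'
#' Writes standard fixed-column ATOM records, one MODEL/ENDMDL block per
#' ensemble member (coordinates at the format's 0.001 Angstrom precision).
#'
#' @param ensemble a [StructureEnsemble] or single [Structure].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_pdb <- function(ensemble, path) {
  if (inherits(ensemble, "Structure")) {
    ensemble <- new_ensemble(list(ensemble))
  }
  stopifnot(inherits(ensemble, "StructureEnsemble"))
  con <- file(path, "w")
  on.exit(close(con))
  nm <- length(ensemble$structures)
  for (k in seq_len(nm)) {
    s <- ensemble$structures[[k]]
    if (nm > 1) writeLines(sprintf("MODEL     %4d", k), con)
    serial <- 0L
    out <- character(nrow(s$atoms))
    for (j in seq_len(nrow(s$atoms))) {
      serial <- serial + 1L
      a <- s$atoms[j, ]
      res3 <- AA1TO3[[s$sequence[a$residue]]]
      name <- if (nchar(a$atom) < 4) sprintf(" %-3s", a$atom) else a$atom
      out[j] <- sprintf("ATOM  %5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                        serial, name, "", res3, "A", a$residue, "",
                        a$x, a$y, a$z, 1, 0, a$element)
    }
    writeLines(out, con)
    if (nm > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
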