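# PDB structure handling: read, select one polymer chain, resolve altlocs.

#' Read a protein structure from a PDB file
#'
#' Reads the first model, keeps polymer (`ATOM`) records only (waters and
#' hetero ligands are excluded), selects a single chain, and resolves
#' alternate locations to the highest-occupancy conformer per atom.
#'
#' @param path PDB file path.
#' @param chain Chain identifier; default is the first polymer chain in the
#'   file.
#' @return A `varvote_structure`: list with `atoms` (data frame `resno`,
#'   `resid`, `elety`, `x`, `y`, `z`), `chain` and `path`.
#' @export
read_structure <- function(path, chain = NULL) {
  if (!file.exists(path)) {
    vv_stop("varvote_io_error", "PDB file not found: %s", path)
  }
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
                  error = function(e) {
                    vv_stop("varvote_io_error", "cannot read PDB %s: %s",
                            path, conditionMessage(e))
                  })
  a <- pdb$atom
  a <- a[a$type == "ATOM" & !(a$resid %in% c("HOH", "WAT", "DOD")), ,
         drop = FALSE]
  if (nrow(a) == 0L) {
    vv_stop("varvote_validation_error", "no polymer atoms in %s", path)
  }
  if (is.null(chain)) chain <- a$chain[1]
  a <- a[a$chain == chain, , drop = FALSE]
  if (nrow(a) == 0L) {
    vv_stop("varvote_validation_error", "no atoms in chain '%s' of %s",
            chain, path)
  }
  # alternate locations: keep the highest-occupancy conformer per atom
  alt <- a$alt
  alt[is.na(alt)] <- ""
  if (any(nzchar(alt))) {
    occ <- a$o
    occ[is.na(occ)] <- 1
    key <- paste(a$resno, a$elety)
    keep <- unlist(lapply(split(seq_len(nrow(a)), key), function(idx) {
      idx[which.max(occ[idx])]
    }), use.names = FALSE)
    a <- a[sort(keep), , drop = FALSE]
  }
  atoms <- data.frame(resno = as.integer(a$resno), resid = a$resid,
                      elety = a$elety, x = a$x, y = a$y, z = a$z,
                      stringsAsFactors = FALSE)
  structure(list(atoms = atoms, chain = chain, path = path),
            class = "varvote_structure")
}

#' @export
print.varvote_structure <- function(x, ...) {
  cat(sprintf("structure %s chain %s: %d atoms, %d residues\n",
              basename(x$path %||% "<memory>"), x$chain, nrow(x$atoms),
              length(unique(x$atoms$resno))))
  invisible(x)
}

# Normalize the accepted structure representations to an atom data frame.
structure_atoms <- function(structure) {
  atoms <- if (inherits(structure, "varvote_structure")) structure$atoms
  else if (is.data.frame(structure)) structure
  else vv_stop("varvote_validation_error",
               "structure must be a varvote_structure or an atom data frame")
  need <- c("resno", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) {
    vv_stop("varvote_validation_error",
            "atom table lacks column(s): %s", paste(miss, collapse = ", "))
  }
  atoms
}

#' Write a toy structure to PDB format
#'
#' Serializes an atom table (as produced by [gen_toy_structure()]) to a
#' minimal single-chain PDB file readable by [read_structure()].
#' @param atoms Data frame with `resno`, `x`, `y`, `z` (optional `elety`,
#'   `resid`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(atoms, path) {
  atoms <- structure_atoms(atoms)
  elety <- if ("elety" %in% names(atoms)) atoms$elety else
    ave_names(nrow(atoms), atoms$resno)
  resid <- if ("resid" %in% names(atoms)) atoms$resid else
    rep("ALA", nrow(atoms))
  lines <- vapply(seq_len(nrow(atoms)), function(i) {
    sprintf("ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, substr(elety[i], 1, 4), resid[i], atoms$resno[i],
            atoms$x[i], atoms$y[i], atoms$z[i])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(path)
}

ave_names <- function(n, resno) {
  idx <- stats::ave(seq_len(n), resno, FUN = seq_along)
  paste0("C", idx)
}
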