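# Protein-level variant parsing, validation and numbering conversion.
#
# Positions are 1-based throughout. Two numbering schemes are supported for
# secreted proteins such as alpha-1 antitrypsin: "mature" (signal peptide
# removed, the conventional clinical numbering) and "precursor" (including
# the signal peptide). For AAT the signal peptide is 24 residues, so
# precursor position = mature position + 24.

AA_ONE <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Default signal peptide length (residues)
#'
#' The alpha-1 antitrypsin precursor carries a 24-residue signal peptide
#' that is cleaved from the mature protein; mature and precursor residue
#' numbering differ by this offset. Override per call for other proteins.
#' @export
SIGNAL_PEPTIDE_LEN <- 24L

#' Construct a protein missense variant
#'
#' @param ref_aa One-letter code of the reference residue.
#' @param position 1-based residue index (positive integer).
#' @param alt_aa One-letter code of the substituted residue, or `"X"` for a
#'   stop gain. Stop-gain variants are representable but are excluded from
#'   score-based classification.
#' @param scheme Residue numbering scheme, `"mature"` (default) or
#'   `"precursor"`.
#' @return An object of class `varvote_variant`.
#' @examples
#' variant("E", 342, "K")      # the AAT Z allele
#' @export
variant <- function(ref_aa, position, alt_aa,
                    scheme = c("mature", "precursor")) {
  scheme <- match.arg(scheme)
  if (!is.character(ref_aa) || length(ref_aa) != 1L || !(ref_aa %in% AA_ONE)) {
    vv_stop("varvote_validation_error",
            "ref_aa must be a standard one-letter amino-acid code, got '%s'",
            paste(ref_aa, collapse = ","))
  }
  if (!is.character(alt_aa) || length(alt_aa) != 1L ||
      !(alt_aa %in% c(AA_ONE, "X"))) {
    vv_stop("varvote_validation_error",
            "alt_aa must be a standard amino acid or 'X' (stop), got '%s'",
            paste(alt_aa, collapse = ","))
  }
  if (identical(ref_aa, alt_aa)) {
    vv_stop("varvote_validation_error",
            "reference and alternate residues are identical (%s%s%s)",
            ref_aa, position, alt_aa)
  }
  position <- as.integer(position)
  if (is.na(position) || position < 1L) {
    vv_stop("varvote_validation_error", "position must be a positive integer")
  }
  structure(
    list(ref_aa = ref_aa, position = position, alt_aa = alt_aa,
         scheme = scheme),
    class = "varvote_variant"
  )
}

#' Parse a variant string such as "E342K"
#'
#' Accepts the compact `<ref><pos><alt>` protein notation, tolerating
#' surrounding and internal whitespace (published tables print forms like
#' `"M385 T"`). An annotation of the form `"[includes precursor]"` (or the
#' `scheme` argument) marks the position as precursor-numbered. Nucleotide,
#' splice, frameshift and other non-missense notations (e.g. `"A347fs"`,
#' `"917 + 1G > A"`) are rejected with a classed condition
#' (`varvote_parse_error`) rather than an unstructured crash, so callers can
#' skip them row-wise.
#'
#' @param text Variant string.
#' @param scheme Default numbering scheme when the string carries no
#'   annotation.
#' @return A `varvote_variant`.
#' @examples
#' parse_variant("E342K")
#' parse_variant("M385 T")
#' parse_variant("I9N [includes precursor]")
#' @export
parse_variant <- function(text, scheme = c("mature", "precursor")) {
  scheme <- match.arg(scheme)
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    vv_stop("varvote_parse_error", "variant must be a single string")
  }
  s <- trimws(text)
  if (grepl("\\[\\s*includes\\s+precursor\\s*\\]", s, ignore.case = TRUE)) {
    scheme <- "precursor"
    s <- trimws(sub("\\[\\s*includes\\s+precursor\\s*\\]", "", s,
                    ignore.case = TRUE))
  }
  m <- regmatches(s, regexec("^([A-Za-z])\\s*([0-9]+)\\s*([A-Za-z])$", s))[[1]]
  if (length(m) != 4L) {
    vv_stop("varvote_parse_error",
            "not a missense variant string: '%s'", text)
  }
  ref <- toupper(m[2]); alt <- toupper(m[4])
  if (!(ref %in% AA_ONE) || !(alt %in% c(AA_ONE, "X"))) {
    vv_stop("varvote_parse_error",
            "unknown amino-acid code in '%s'", text)
  }
  if (ref == alt) {
    vv_stop("varvote_parse_error",
            "reference equals alternate residue in '%s'", text)
  }
  variant(ref, as.integer(m[3]), alt, scheme = scheme)
}

#' @method format varvote_variant
#' @export
format.varvote_variant <- function(x, ...) {
  paste0(x$ref_aa, x$position, x$alt_aa)
}

#' @export
print.varvote_variant <- function(x, ...) {
  cat(format(x), " (", x$scheme, " numbering)\n", sep = "")
  invisible(x)
}

#' Test whether a string parses as a missense variant
#' @param text Variant string.
#' @return `TRUE` or `FALSE`; never throws.
#' @export
is_missense_string <- function(text) {
  !inherits(tryCatch(parse_variant(text), error = identity), "error")
}

#' Convert a variant between mature and precursor numbering
#'
#' Mature-to-precursor adds the signal peptide length to the position;
#' the reverse subtracts it. A precursor position at or below the signal
#' peptide length has no mature-scheme equivalent (it lies within the
#' cleaved signal peptide) and conversion raises a
#' `varvote_signal_peptide_error` instead of guessing.
#'
#' @param v A `varvote_variant`.
#' @param to Target scheme.
#' @param signal_peptide_len Signal peptide length in residues; defaults to
#'   the AAT value of 24.
#' @return A `varvote_variant` in the target scheme.
#' @examples
#' convert_numbering(variant("E", 342, "K"), "precursor")  # position 366
#' @export
convert_numbering <- function(v, to = c("mature", "precursor"),
                              signal_peptide_len = SIGNAL_PEPTIDE_LEN) {
  to <- match.arg(to)
  stopifnot(inherits(v, "varvote_variant"))
  if (v$scheme == to) return(v)
  if (to == "precursor") {
    variant(v$ref_aa, v$position + signal_peptide_len, v$alt_aa,
            scheme = "precursor")
  } else {
    if (v$position <= signal_peptide_len) {
      vv_stop("varvote_signal_peptide_error",
              paste0("precursor position %d lies within the %d-residue ",
                     "signal peptide and has no mature-scheme equivalent"),
              v$position, signal_peptide_len)
    }
    variant(v$ref_aa, v$position - signal_peptide_len, v$alt_aa,
            scheme = "mature")
  }
}

#' Construct a reference protein sequence
#'
#' @param id Sequence identifier.
#' @param residues Amino-acid string (standard one-letter codes).
#' @param scheme Numbering scheme the sequence is stated in.
#' @return An object of class `varvote_refseq`.
#' @export
reference_sequence <- function(id, residues,
                               scheme = c("mature", "precursor")) {
  scheme <- match.arg(scheme)
  residues <- toupper(as.character(residues))
  if (!nzchar(residues)) {
    vv_stop("varvote_validation_error", "reference sequence is empty")
  }
  chars <- strsplit(residues, "")[[1]]
  bad <- setdiff(unique(chars), AA_ONE)
  if (length(bad)) {
    vv_stop("varvote_validation_error",
            "non-standard residue code(s) in reference sequence: %s",
            paste(bad, collapse = ", "))
  }
  structure(list(id = as.character(id), residues = residues, scheme = scheme),
            class = "varvote_refseq")
}

#' @export
print.varvote_refseq <- function(x, ...) {
  cat(sprintf("<%s> %d aa (%s numbering)\n", x$id, nchar(x$residues),
              x$scheme))
  invisible(x)
}

#' Read a reference sequence from a FASTA file
#'
#' Uses the first record unless `id` selects another.
#' @param path FASTA file path.
#' @param id Optional record identifier (matched against the first
#'   whitespace-delimited token of each header).
#' @param scheme Numbering scheme to annotate the sequence with.
#' @return A `varvote_refseq`.
#' @export
read_fasta <- function(path, id = NULL, scheme = c("mature", "precursor")) {
  scheme <- match.arg(scheme)
  if (!file.exists(path)) {
    vv_stop("varvote_io_error", "FASTA file not found: %s", path)
  }
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) {
    vv_stop("varvote_io_error", "no FASTA records in %s", path)
  }
  keys <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)
  idx <- 1L
  if (!is.null(id)) {
    idx <- match(id, keys)
    if (is.na(idx)) {
      vv_stop("varvote_io_error", "no FASTA record with id '%s' in %s",
              id, path)
    }
  }
  reference_sequence(keys[idx], as.character(seqs[[idx]]), scheme = scheme)
}

#' Check a variant's reference residue against a reference sequence
#'
#' @param v A `varvote_variant`.
#' @param ref A `varvote_refseq` in the same numbering scheme (convert the
#'   variant first otherwise).
#' @param signal_peptide_len Used when the schemes differ and the variant
#'   must be converted.
#' @return `TRUE` iff the residue at the variant position equals the
#'   variant's reference residue. A position beyond the sequence raises a
#'   `varvote_range_error`, distinct from a residue mismatch (`FALSE`).
#' @export
validate_against_reference <- function(v, ref,
                                       signal_peptide_len =
                                         SIGNAL_PEPTIDE_LEN) {
  stopifnot(inherits(v, "varvote_variant"), inherits(ref, "varvote_refseq"))
  if (v$scheme != ref$scheme) {
    v <- convert_numbering(v, ref$scheme,
                           signal_peptide_len = signal_peptide_len)
  }
  if (v$position > nchar(ref$residues)) {
    vv_stop("varvote_range_error",
            "position %d beyond reference sequence '%s' (%d aa)",
            v$position, ref$id, nchar(ref$residues))
  }
  substr(ref$residues, v$position, v$position) == v$ref_aa
}
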