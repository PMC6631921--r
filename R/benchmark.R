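# Ortholog-derived neutral-variant benchmark construction.
#
# A candidate neutral variant is a position where a close homolog carries a
# different residue than the query protein. Candidates survive only if the
# local alignment context is trustworthy (conserved flanks, no nearby gaps),
# the structural micro-environment is unchanged (every 3D contact residue
# conserved), and the homolog is close (> identity threshold). The rationale:
# a substitution tolerated in an otherwise identical sequence and structural
# context in a close ortholog is very likely neutral in the query protein.

GAP_CHARS <- c("-", ".")

pair_chars <- function(row) {
  chartr(".", "-", strsplit(toupper(row), "")[[1]])
}

#' Construct an aligned query/subject sequence pair
#'
#' Rows must be equal length; columns gapped in both rows are not allowed.
#' Percent identity is computed over ungapped columns (columns holding a
#' residue in both rows); gap columns are excluded from the denominator.
#'
#' @param query_id,subject_id Sequence identifiers.
#' @param query_row,subject_row Gapped (aligned) sequence strings; `-` (or
#'   `.`) marks a gap.
#' @return An object of class `varvote_aligned_pair` with a
#'   `percent_identity` field.
#' @export
aligned_pair <- function(query_id, subject_id, query_row, subject_row) {
  q <- pair_chars(query_row); s <- pair_chars(subject_row)
  if (length(q) != length(s) || length(q) == 0L) {
    vv_stop("varvote_validation_error",
            "aligned rows must be non-empty and of equal length")
  }
  if (any(q == "-" & s == "-")) {
    vv_stop("varvote_validation_error",
            "column gapped in both rows is not a valid alignment column")
  }
  obj <- structure(
    list(query_id = as.character(query_id),
         subject_id = as.character(subject_id),
         query_row = paste(q, collapse = ""),
         subject_row = paste(s, collapse = "")),
    class = "varvote_aligned_pair"
  )
  obj$percent_identity <- percent_identity(obj)
  obj
}

#' @export
print.varvote_aligned_pair <- function(x, ...) {
  cat(sprintf("aligned pair %s / %s: %d columns, %.1f%% identity\n",
              x$query_id, x$subject_id, nchar(x$query_row),
              x$percent_identity))
  invisible(x)
}

#' Percent identity of an aligned pair
#'
#' 100 x (identical residue columns) / (columns where both rows hold a
#' residue). Gap columns do not enter the denominator.
#' @param pair A `varvote_aligned_pair`.
#' @return Percent in [0, 100].
#' @export
percent_identity <- function(pair) {
  stopifnot(inherits(pair, "varvote_aligned_pair"))
  q <- pair_chars(pair$query_row); s <- pair_chars(pair$subject_row)
  both <- q != "-" & s != "-"
  if (!any(both)) {
    vv_stop("varvote_validation_error",
            "no ungapped columns; identity undefined")
  }
  100 * sum(q[both] == s[both]) / sum(both)
}

#' Globally align an unaligned homolog to the query
#'
#' Needleman-Wunsch global alignment with BLOSUM62 scoring and affine gap
#' penalties, producing the aligned pair the filters operate on.
#' @param query,subject `varvote_refseq` objects (or plain sequences with
#'   ids supplied).
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return A `varvote_aligned_pair`.
#' @export
align_homolog <- function(query, subject, gap_opening = 10,
                          gap_extension = 0.5) {
  stopifnot(inherits(query, "varvote_refseq"),
            inherits(subject, "varvote_refseq"))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query$residues),
    Biostrings::AAString(subject$residues),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension)
  aligned_pair(query$id, subject$id,
               as.character(Biostrings::alignedPattern(aln)),
               as.character(Biostrings::alignedSubject(aln)))
}

# 1-based ungapped query position for each alignment column (NA at query gaps)
query_positions <- function(pair) {
  q <- pair_chars(pair$query_row)
  pos <- cumsum(q != "-")
  pos[q == "-"] <- NA_integer_
  pos
}

#' Extract substitution candidates from an aligned pair
#'
#' One candidate per column where both rows hold residues and they differ;
#' insertions and deletions are not substitutions. Positions are reported in
#' ungapped 1-based query coordinates.
#' @param pair A `varvote_aligned_pair`.
#' @return Data frame with columns `column`, `position`, `ref_aa`, `alt_aa`.
#' @export
extract_substitutions <- function(pair) {
  stopifnot(inherits(pair, "varvote_aligned_pair"))
  q <- pair_chars(pair$query_row); s <- pair_chars(pair$subject_row)
  idx <- which(q != "-" & s != "-" & q != s)
  data.frame(column = idx,
             position = query_positions(pair)[idx],
             ref_aa = q[idx], alt_aa = s[idx],
             stringsAsFactors = FALSE)
}

#' Conserved-flank filter
#'
#' A substitution column passes when the `k` alignment columns on each side
#' all exist and hold identical residues in both rows. Gaps or differing
#' residues in the window, or a window running off either end, fail the
#' filter.
#' @param pair A `varvote_aligned_pair`.
#' @param column Alignment column index holding the substitution.
#' @param k Flank width in columns (default 2).
#' @return Logical.
#' @export
flank_conserved <- function(pair, column, k = 2) {
  q <- pair_chars(pair$query_row); s <- pair_chars(pair$subject_row)
  n <- length(q)
  win <- c(column - seq_len(k), column + seq_len(k))
  if (any(win < 1L | win > n)) return(FALSE)
  all(q[win] != "-" & s[win] != "-" & q[win] == s[win])
}

#' Gap-proximity filter
#'
#' A substitution column passes when no gap character occurs in either row
#' within `window` columns on either side.
#' @param pair A `varvote_aligned_pair`.
#' @param column Alignment column index holding the substitution.
#' @param window Window half-width in columns (default 3).
#' @return Logical.
#' @export
gap_ok <- function(pair, column, window = 3) {
  q <- pair_chars(pair$query_row); s <- pair_chars(pair$subject_row)
  n <- length(q)
  win <- max(1L, column - window):min(n, column + window)
  !any(q[win] == "-" | s[win] == "-")
}

#' Residue contact map from atomic coordinates
#'
#' Two residues are in contact when any pair of their atoms lies strictly
#' closer than `cutoff` Angstrom. Sequence neighbours are not excluded. The
#' map is symmetric and irreflexive.
#'
#' @param structure Either a `varvote_structure` (see [read_structure()]) or
#'   a data frame of atoms with columns `resno`, `x`, `y`, `z`.
#' @param cutoff Distance cutoff in Angstrom (default 5.0, strict `<`).
#' @return A `varvote_contact_map`: list with `cutoff`, `resnos` and
#'   `contacts`, the latter a list mapping residue number (as character
#'   name) to the sorted integer vector of contacting residue numbers.
#' @export
contact_map <- function(structure, cutoff = 5.0) {
  atoms <- structure_atoms(structure)
  if (nrow(atoms) == 0L) {
    vv_stop("varvote_validation_error", "structure contains no atoms")
  }
  resnos <- sort(unique(atoms$resno))
  if (length(resnos) < 2L) {
    vv_stop("varvote_validation_error",
            "contact map needs at least 2 residues")
  }
  d <- as.matrix(stats::dist(as.matrix(atoms[, c("x", "y", "z")])))
  groups <- split(seq_len(nrow(atoms)), atoms$resno)
  groups <- groups[as.character(resnos)]
  n <- length(resnos)
  contacts <- stats::setNames(vector("list", n), as.character(resnos))
  for (i in seq_len(n)) contacts[[i]] <- integer(0)
  for (i in seq_len(n - 1L)) {
    ri <- groups[[i]]
    for (j in (i + 1L):n) {
      if (min(d[ri, groups[[j]]]) < cutoff) {
        contacts[[i]] <- c(contacts[[i]], resnos[j])
        contacts[[j]] <- c(contacts[[j]], resnos[i])
      }
    }
  }
  structure(list(cutoff = cutoff, resnos = resnos,
                 contacts = lapply(contacts, sort)),
            class = "varvote_contact_map")
}

#' Contacting residues of one residue
#' @param cmap A `varvote_contact_map`.
#' @param resno Residue number.
#' @return Sorted integer vector (empty if the residue has no contacts).
#'   Raises `varvote_unresolved_error` if the residue is absent from the
#'   structure the map was built on.
#' @export
contacts_of <- function(cmap, resno) {
  stopifnot(inherits(cmap, "varvote_contact_map"))
  if (!(resno %in% cmap$resnos)) {
    vv_stop("varvote_unresolved_error",
            "residue %s not present in the structure", format(resno))
  }
  cmap$contacts[[as.character(resno)]]
}

#' @export
print.varvote_contact_map <- function(x, ...) {
  npair <- sum(lengths(x$contacts)) / 2
  cat(sprintf("contact map: %d residues, %d contact pairs (cutoff %.1f A)\n",
              length(x$resnos), npair, x$cutoff))
  invisible(x)
}

#' Contact-conservation filter
#'
#' A substitution passes when every 3D contact residue of its query position
#' is aligned to an identical residue in the subject row. A contact residue
#' aligned to a gap, to a different residue, or falling outside the aligned
#' query range counts as different. A variant position absent from the
#' structure raises `varvote_unresolved_error` so callers can record the
#' candidate as not resolvable.
#'
#' @param pair A `varvote_aligned_pair`.
#' @param variant_position Ungapped 1-based query position of the
#'   substitution.
#' @param cmap A `varvote_contact_map` built on the query's structure.
#' @param resno_map Optional function mapping query position to structure
#'   residue number (default: identity, i.e. author numbering matches query
#'   numbering). Must be invertible over the structure residues via
#'   `inverse_resno_map` when supplied.
#' @param inverse_resno_map Optional function mapping structure residue
#'   number back to query position.
#' @return Logical.
#' @export
contacts_conserved <- function(pair, variant_position, cmap,
                               resno_map = identity,
                               inverse_resno_map = identity) {
  stopifnot(inherits(pair, "varvote_aligned_pair"))
  resno <- resno_map(variant_position)
  partners <- contacts_of(cmap, resno)  # may raise unresolved
  if (length(partners) == 0L) return(TRUE)
  qpos <- query_positions(pair)
  q <- pair_chars(pair$query_row); s <- pair_chars(pair$subject_row)
  for (p in partners) {
    cpos <- inverse_resno_map(p)
    col <- match(cpos, qpos)
    if (is.na(col)) return(FALSE)           # contact outside aligned range
    if (s[col] == "-" || s[col] != q[col]) return(FALSE)
  }
  TRUE
}

#' Build a neutral-variant benchmark set
#'
#' Runs the full candidate pipeline over a set of aligned (or alignable)
#' homolog pairs: extract substitutions, apply the conserved-flank,
#' gap-proximity and contact-conservation filters, drop candidates from
#' pairs at or below the identity threshold, and keep for each distinct
#' substitution the surviving candidate from the highest-identity pair
#' (ties broken toward the lexicographically smaller subject id).
#'
#' @param query A `varvote_refseq` (used to align unaligned homologs and to
#'   sanity-check pair rows).
#' @param pairs List of `varvote_aligned_pair` and/or `varvote_refseq`
#'   homologs (the latter are aligned internally via [align_homolog()]).
#' @param structure Optional structure (see [contact_map()]); when `NULL`
#'   the contact filter is skipped and `contacts_ok` is `NA`.
#' @param config A [run_config()]; fields `flank_k`, `gap_window`,
#'   `contact_cutoff`, `identity_min` are used.
#' @param resno_map,inverse_resno_map Query-position/structure-residue
#'   mapping passed to [contacts_conserved()].
#' @return A `varvote_neutral_set`: list with `accepted` (one row per
#'   distinct accepted substitution, sorted by position then alternate
#'   residue) and `candidates` (every evaluated candidate with its filter
#'   booleans, identity, acceptance flag and rejection reason).
#' @export
build_neutral_set <- function(query, pairs, structure = NULL,
                              config = run_config(),
                              resno_map = identity,
                              inverse_resno_map = identity) {
  stopifnot(inherits(query, "varvote_refseq"))
  if (!length(pairs)) {
    vv_stop("varvote_validation_error", "no homolog pairs supplied")
  }
  pairs <- lapply(pairs, function(p) {
    if (inherits(p, "varvote_aligned_pair")) p
    else if (inherits(p, "varvote_refseq")) align_homolog(query, p)
    else vv_stop("varvote_validation_error",
                 "pairs must be aligned pairs or reference sequences")
  })
  cmap <- if (!is.null(structure)) {
    if (inherits(structure, "varvote_contact_map")) structure
    else contact_map(structure, cutoff = config$contact_cutoff)
  }

  rows <- list()
  for (pr in pairs) {
    subs <- extract_substitutions(pr)
    if (nrow(subs) == 0L) next
    for (i in seq_len(nrow(subs))) {
      fl <- flank_conserved(pr, subs$column[i], k = config$flank_k)
      gp <- gap_ok(pr, subs$column[i], window = config$gap_window)
      reason <- NA_character_
      ct <- NA
      if (!is.null(cmap)) {
        ct <- tryCatch(
          contacts_conserved(pr, subs$position[i], cmap,
                             resno_map = resno_map,
                             inverse_resno_map = inverse_resno_map),
          varvote_unresolved_error = function(e) {
            NA
          })
        if (is.na(ct)) reason <- "position_not_in_structure"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        ref_aa = subs$ref_aa[i], position = subs$position[i],
        alt_aa = subs$alt_aa[i], subject_id = pr$subject_id,
        source_identity = pr$percent_identity,
        flank_ok = fl, gap_ok = gp, contacts_ok = ct,
        identity_ok = pr$percent_identity > config$identity_min,
        reason = reason, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    cand <- data.frame(ref_aa = character(0), position = integer(0),
                       alt_aa = character(0), subject_id = character(0),
                       source_identity = numeric(0), flank_ok = logical(0),
                       gap_ok = logical(0), contacts_ok = logical(0),
                       identity_ok = logical(0), reason = character(0),
                       accepted = logical(0), stringsAsFactors = FALSE)
    return(structure(list(accepted = cand, candidates = cand),
                     class = "varvote_neutral_set"))
  }
  cand <- do.call(rbind, rows)
  # contacts filter: NA means either "no structure" (pass-through) or
  # "position not resolvable" (reject, reason recorded)
  contact_pass <- if (is.null(cmap)) rep(TRUE, nrow(cand)) else
    !is.na(cand$contacts_ok) & cand$contacts_ok
  cand$accepted <- cand$flank_ok & cand$gap_ok & contact_pass &
    cand$identity_ok
  cand$reason <- ifelse(cand$accepted, NA_character_, ifelse(
    !is.na(cand$reason), cand$reason, ifelse(
      !cand$identity_ok, "identity_at_or_below_threshold", ifelse(
        !cand$flank_ok, "flank_not_conserved", ifelse(
          !cand$gap_ok, "gap_within_window", "contact_residue_differs")))))

  acc <- cand[cand$accepted, , drop = FALSE]
  if (nrow(acc) > 1L) {
    # highest identity first, then lexicographic subject id, per variant
    ord <- order(acc$position, acc$alt_aa, -acc$source_identity,
                 acc$subject_id)
    acc <- acc[ord, , drop = FALSE]
    key <- paste(acc$ref_aa, acc$position, acc$alt_aa)
    acc <- acc[!duplicated(key), , drop = FALSE]
  }
  acc <- acc[order(acc$position, acc$alt_aa), , drop = FALSE]
  rownames(acc) <- rownames(cand) <- NULL
  structure(list(accepted = acc, candidates = cand),
            class = "varvote_neutral_set")
}

#' @export
print.varvote_neutral_set <- function(x, ...) {
  cat(sprintf("neutral benchmark set: %d accepted of %d candidate(s)\n",
              nrow(x$accepted), nrow(x$candidates)))
  if (nrow(x$accepted)) {
    print.data.frame(x$accepted[, c("ref_aa", "position", "alt_aa",
                                    "subject_id", "source_identity")],
                     row.names = FALSE)
  }
  invisible(x)
}
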