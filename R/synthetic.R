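# Seeded synthetic-data generators with known ground truth.
#
# Each generator plants its outcome by construction and returns the exact
# expected result alongside the data, so every pipeline stage can be tested
# for ground-truth recovery without external downloads. All generators are
# deterministic functions of (spec, seed).

#' Specification for a synthetic homolog alignment
#'
#' Describes a query/homolog pair with planted substitutions whose filter
#' outcomes are known by construction: `"pass"` (survives all filters),
#' `"fail_flank"` (planted as two adjacent substitutions, so both fail the
#' conserved-flank filter), `"fail_gap"` (a subject gap planted exactly
#' `gap_window` columns away), `"fail_contacts"` (a subject gap planted at a
#' sequence-distant 3D contact partner of the substitution). Extra isolated
#' filler substitutions tune the realized identity to `target_identity`
#' (within one percentage point, validated at generation).
#'
#' @param query_length Query length in residues.
#' @param target_identity Target percent identity of the pair.
#' @param outcomes Character vector of planted outcomes (one site each).
#' @param seed Integer seed.
#' @return A `varvote_homolog_spec`.
#' @export
homolog_spec <- function(query_length = 200, target_identity = 95,
                         outcomes = c("pass", "fail_flank", "fail_gap"),
                         seed = 1) {
  ok <- c("pass", "fail_flank", "fail_gap", "fail_contacts")
  if (!length(outcomes) || !all(outcomes %in% ok)) {
    vv_stop("varvote_generation_error",
            "outcomes must be drawn from %s", paste(ok, collapse = "/"))
  }
  if (!is_scalar_number(target_identity) || target_identity <= 0 ||
      target_identity > 100) {
    vv_stop("varvote_generation_error",
            "target_identity must lie in (0, 100]")
  }
  n <- length(outcomes)
  # sites from the left, contact partners from the right, both 12 apart
  needed <- 2 * (6 + (n - 1) * 12 + 6) + 12
  if (query_length < needed) {
    vv_stop("varvote_generation_error",
            "query_length %d too short for %d planted site(s) (need >= %d)",
            query_length, n, needed)
  }
  structure(list(query_length = as.integer(query_length),
                 target_identity = target_identity,
                 outcomes = outcomes, seed = as.integer(seed)),
            class = "varvote_homolog_spec")
}

#' Generate a synthetic homolog pair with planted filter outcomes
#'
#' The query is ungapped (alignment columns equal query positions) and all
#' gaps are subject-side. A toy single-atom-per-residue structure is
#' generated alongside: residues sit 10 apart on a line, and each planted
#' site gets one sequence-distant contact partner placed 4 Angstrom away,
#' so the contact-conservation filter is exercised with analytic geometry.
#'
#' @param spec A [homolog_spec()].
#' @return List with `pair` (a `varvote_aligned_pair`), `structure` (atom
#'   data frame), `truth` (data frame of every planted substitution with
#'   its `flank_ok`, `gap_ok`, `contacts_ok` ground truth), `query` (a
#'   `varvote_refseq`), `realized_identity` and `spec`.
#' @seealso [expected_accepted()] for the accepted set implied by `truth`.
#' @export
gen_homolog_pair <- function(spec) {
  stopifnot(inherits(spec, "varvote_homolog_spec"))
  with_seed(spec$seed, {
    L <- spec$query_length
    n <- length(spec$outcomes)
    q <- sample(AA_ONE, L, replace = TRUE)
    s <- q
    gap <- rep(FALSE, L)

    sites <- 6L + (seq_len(n) - 1L) * 12L
    partners <- (L - 5L) - (seq_len(n) - 1L) * 12L
    truth <- list()
    sub_at <- function(p) {
      alt <- sample(setdiff(AA_ONE, q[p]), 1L)
      s[p] <<- alt
      alt
    }
    diff_cols <- integer(0)
    for (k in seq_len(n)) {
      p <- sites[k]; pq <- partners[k]
      out <- spec$outcomes[k]
      alt <- sub_at(p)
      diff_cols <- c(diff_cols, p)
      fl <- TRUE; gp <- TRUE; ct <- TRUE
      if (out == "fail_flank") {
        alt2 <- sub_at(p + 1L)
        diff_cols <- c(diff_cols, p + 1L)
        fl <- FALSE
        truth[[length(truth) + 1L]] <- data.frame(
          position = p + 1L, ref_aa = q[p + 1L], alt_aa = alt2,
          flank_ok = FALSE, gap_ok = TRUE, contacts_ok = TRUE,
          planted = "fail_flank_twin", stringsAsFactors = FALSE)
      } else if (out == "fail_gap") {
        gap[p + 3L] <- TRUE
        gp <- FALSE
      } else if (out == "fail_contacts") {
        gap[pq] <- TRUE
        ct <- FALSE
      }
      truth[[length(truth) + 1L]] <- data.frame(
        position = p, ref_aa = q[p], alt_aa = alt,
        flank_ok = fl, gap_ok = gp, contacts_ok = ct, planted = out,
        stringsAsFactors = FALSE)
    }

    # filler substitutions to hit the target identity
    U <- L - sum(gap)
    n_diff_target <- round(U * (1 - spec$target_identity / 100))
    n_fillers <- n_diff_target - length(diff_cols)
    if (n_fillers < 0) {
      vv_stop("varvote_generation_error",
              "planted sites alone push identity below the target")
    }
    blocked <- rep(FALSE, L)
    blocked[1:6] <- TRUE; blocked[(L - 5L):L] <- TRUE
    block <- function(cols, w) {
      for (cc in cols) {
        blocked[max(1L, cc - w):min(L, cc + w)] <<- TRUE
      }
    }
    # a filler needs: no other difference within the flank window (2), no
    # gap within the gap window (3), and must not sit on a contact partner
    block(diff_cols, 2L)
    block(which(gap), 3L)
    block(partners, 1L)
    if (n_fillers > 0) {
      for (f in seq_len(n_fillers)) {
        free <- which(!blocked)
        if (!length(free)) {
          vv_stop("varvote_generation_error",
                  "no room for %d filler substitution(s)", n_fillers)
        }
        p <- if (length(free) == 1L) free else sample(free, 1L)
        alt <- sub_at(p)
        diff_cols <- c(diff_cols, p)
        block(p, 2L)
        truth[[length(truth) + 1L]] <- data.frame(
          position = p, ref_aa = q[p], alt_aa = alt,
          flank_ok = TRUE, gap_ok = TRUE, contacts_ok = TRUE,
          planted = "filler", stringsAsFactors = FALSE)
      }
    }

    srow <- s
    srow[gap] <- "-"
    pair <- aligned_pair("synthetic_query", "synthetic_homolog",
                         paste(q, collapse = ""),
                         paste(srow, collapse = ""))
    if (abs(pair$percent_identity - spec$target_identity) > 1) {
      vv_stop("varvote_generation_error",
              "realized identity %.2f missed target %.2f by more than 1",
              pair$percent_identity, spec$target_identity)
    }

    atoms <- data.frame(resno = seq_len(L), x = 10 * seq_len(L), y = 0,
                        z = 0)
    # each planted site's contact partner moves next to its site
    atoms$x[partners] <- 10 * sites
    atoms$y[partners] <- 4

    truth <- do.call(rbind, truth)
    truth <- truth[order(truth$position, truth$alt_aa), , drop = FALSE]
    rownames(truth) <- NULL
    list(pair = pair, structure = atoms, truth = truth,
         query = reference_sequence("synthetic_query",
                                    paste(q, collapse = "")),
         realized_identity = pair$percent_identity, spec = spec)
  })
}

#' Accepted set implied by a synthetic homolog's ground truth
#' @param gen Output of [gen_homolog_pair()].
#' @param identity_min Identity threshold (strict `>`), default 90.
#' @return The planted substitutions expected to survive
#'   [build_neutral_set()], sorted by position then alternate residue.
#' @export
expected_accepted <- function(gen, identity_min = 90) {
  tr <- gen$truth
  keep <- tr$flank_ok & tr$gap_ok & tr$contacts_ok &
    gen$realized_identity > identity_min
  out <- tr[keep, c("ref_aa", "position", "alt_aa"), drop = FALSE]
  out <- out[order(out$position, out$alt_aa), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate a toy structure with an analytically known contact map
#'
#' Residues named in `contact_spec` paths are laid out along lines at 4
#' Angstrom consecutive spacing (each path on its own line), all remaining
#' residues on a wide grid, with bounded coordinate jitter, so the expected
#' contact set at the default 5 Angstrom cutoff is exactly the consecutive
#' pairs of each path. A multi-atom mode (`atoms_per_residue > 1`)
#' exercises the min-over-atom-pairs rule.
#'
#' @param n_residues Number of residues.
#' @param contact_spec List of integer vectors; each is a path of residue
#'   indices whose consecutive pairs are planted contacts. A residue may
#'   appear in at most one path (others are geometrically unrealizable with
#'   this layout and raise a generation error).
#' @param seed Integer seed for the jitter.
#' @param atoms_per_residue Atoms per residue (default 1).
#' @param jitter Half-width of the uniform coordinate jitter, Angstrom.
#' @return List with `atoms` (data frame), `expected_pairs` (two-column
#'   matrix of residue pairs, i < j, sorted) and `cutoff`.
#' @export
gen_toy_structure <- function(n_residues, contact_spec = list(), seed = 1,
                              atoms_per_residue = 1, jitter = 0.25) {
  n <- as.integer(n_residues)
  if (n < 2L) {
    vv_stop("varvote_generation_error", "need at least 2 residues")
  }
  if (jitter < 0 || jitter > 0.3) {
    vv_stop("varvote_generation_error",
            "jitter must lie in [0, 0.3] to keep contacts analytic")
  }
  idx <- unlist(contact_spec)
  if (length(idx)) {
    if (any(idx < 1L | idx > n)) {
      vv_stop("varvote_generation_error",
              "contact_spec index outside 1..%d", n)
    }
    if (anyDuplicated(idx)) {
      vv_stop("varvote_generation_error",
              "residue repeated across contact paths: unrealizable layout")
    }
    if (any(lengths(contact_spec) < 2L)) {
      vv_stop("varvote_generation_error",
              "each contact path needs at least 2 residues")
    }
  }
  with_seed(seed, {
    x <- y <- z <- numeric(n)
    grid <- setdiff(seq_len(n), idx)
    if (length(grid)) {
      ncol_grid <- max(1L, ceiling(sqrt(length(grid))))
      gi <- seq_along(grid) - 1L
      x[grid] <- 12 * (gi %% ncol_grid)
      y[grid] <- 12 * (gi %/% ncol_grid)
      z[grid] <- 0
    }
    for (t in seq_along(contact_spec)) {
      path <- contact_spec[[t]]
      x[path] <- 4 * (seq_along(path) - 1L)
      y[path] <- -40 * t
      z[path] <- 0
    }
    k <- as.integer(atoms_per_residue)
    resno <- rep(seq_len(n), each = k)
    atoms <- data.frame(
      resno = resno,
      x = rep(x, each = k) + stats::runif(n * k, -jitter, jitter),
      y = rep(y, each = k) + stats::runif(n * k, -jitter, jitter),
      z = rep(z, each = k) + stats::runif(n * k, -jitter, jitter))
    pairs <- do.call(rbind, lapply(contact_spec, function(path) {
      cbind(pmin(path[-length(path)], path[-1]),
            pmax(path[-length(path)], path[-1]))
    }))
    if (is.null(pairs)) pairs <- matrix(integer(0), ncol = 2)
    pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
    dimnames(pairs) <- NULL
    list(atoms = atoms, expected_pairs = pairs, cutoff = 5.0)
  })
}

#' Flatten a contact map to sorted residue pairs
#' @param cmap A `varvote_contact_map`.
#' @return Two-column integer matrix of contacting residue pairs (i < j),
#'   sorted.
#' @export
contact_pairs <- function(cmap) {
  stopifnot(inherits(cmap, "varvote_contact_map"))
  rows <- list()
  for (r in cmap$resnos) {
    for (p in cmap$contacts[[as.character(r)]]) {
      if (r < p) rows[[length(rows) + 1L]] <- c(r, p)
    }
  }
  if (!length(rows)) return(matrix(integer(0), ncol = 2))
  m <- do.call(rbind, rows)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

#' Generate a labelled score table with a planted confusion matrix
#'
#' Each row's truth label and intended call are fixed by the planted
#' counts; all three predictor scores for a row are drawn from
#' class-conditional ranges strictly clear of the default decision
#' boundaries, so every predictor realizes the same confusion matrix
#' exactly under default thresholds.
#'
#' @param planted Named counts `tp`, `fp`, `tn`, `fn` (total >= 1).
#' @param seed Integer seed.
#' @return List with `scores` (data frame with `variant`, `set`, `label`
#'   and the three score columns, row order shuffled), `expected_confusion`
#'   and `expected_metrics` (derived arithmetically from the planted
#'   counts).
#' @export
gen_score_table <- function(planted = c(tp = 3, fp = 1, tn = 5, fn = 1),
                            seed = 1) {
  cts <- unlist(planted)[c("tp", "fp", "tn", "fn")]
  if (anyNA(cts) || any(cts < 0) || sum(cts) < 1) {
    vv_stop("varvote_generation_error",
            "planted counts must be non-negative with total >= 1")
  }
  with_seed(seed, {
    truth <- c(rep("pathogenic", cts[["tp"]]), rep("benign", cts[["fp"]]),
               rep("benign", cts[["tn"]]), rep("pathogenic", cts[["fn"]]))
    del <- c(rep(TRUE, cts[["tp"]]), rep(TRUE, cts[["fp"]]),
             rep(FALSE, cts[["tn"]]), rep(FALSE, cts[["fn"]]))
    m <- length(truth)
    ref <- sample(AA_ONE, m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(AA_ONE, r), 1L),
                  character(1))
    pos <- sample(seq_len(max(400L, m)), m)
    svm <- ifelse(del, stats::runif(m, 0.55, 0.99),
                  stats::runif(m, 0.01, 0.45))
    pp2 <- ifelse(del, stats::runif(m, 0.55, 0.99),
                  stats::runif(m, 0.01, 0.45))
    ddg <- ifelse(del, stats::runif(m, 1.05, 6), stats::runif(m, -2, 0.85))
    ord <- sample.int(m)
    scores <- data.frame(variant = paste0(ref, pos, alt), set = "synthetic",
                         label = truth, svm = svm, foldx_ddg = ddg,
                         polyphen2 = pp2,
                         stringsAsFactors = FALSE)[ord, , drop = FALSE]
    rownames(scores) <- NULL
    tp <- cts[["tp"]]; fp <- cts[["fp"]]; tn <- cts[["tn"]]; fn <- cts[["fn"]]
    sdiv <- function(a, b) if (b == 0) NA_real_ else a / b
    tpr <- sdiv(tp, tp + fn); tnr <- sdiv(tn, tn + fp)
    expected <- c(tpr = tpr, tnr = tnr, ppv = sdiv(tp, tp + fp),
                  npv = sdiv(tn, tn + fn),
                  acc = (tp + tn) / sum(cts),
                  bacc = if (is.na(tpr) || is.na(tnr)) NA_real_ else
                    (tpr + tnr) / 2)
    list(scores = scores,
         expected_confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
         expected_metrics = expected)
  })
}
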