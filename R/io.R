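# Score-table I/O, run configuration, packaged fixtures, report writers.

#' Pipeline run configuration
#'
#' Defaults reproduce the published analysis settings: SVM cut 0.5, FoldX
#' ddG cut 1.0 kcal/mol after one-decimal rounding, PolyPhen-2 vote cut 0.5,
#' contact cutoff 5.0 Angstrom, conserved flank of 2 residues, gap window of
#' 3 columns, homolog identity strictly above 90%, and a 24-residue signal
#' peptide.
#'
#' @param thresholds A [thresholds()] object.
#' @param contact_cutoff Contact distance cutoff, Angstrom.
#' @param flank_k Conserved-flank width, residues.
#' @param gap_window Gap-proximity window, columns.
#' @param identity_min Homolog identity threshold, percent (strict `>`).
#' @param signal_peptide_len Signal peptide length, residues.
#' @param chain PDB chain selector (`NULL` = first polymer chain).
#' @param seed Integer seed for RNG-bearing stages.
#' @param log_level One of `"quiet"`, `"info"`, `"debug"`.
#' @return An object of class `varvote_config`.
#' @export
run_config <- function(thresholds = varvote::thresholds(),
                       contact_cutoff = 5.0, flank_k = 2, gap_window = 3,
                       identity_min = 90,
                       signal_peptide_len = SIGNAL_PEPTIDE_LEN,
                       chain = NULL, seed = NULL,
                       log_level = c("info", "quiet", "debug")) {
  log_level <- match.arg(log_level)
  for (nm in c("contact_cutoff", "flank_k", "gap_window", "identity_min",
               "signal_peptide_len")) {
    v <- get(nm)
    if (!is_scalar_number(v) || v <= 0) {
      vv_stop("varvote_config_error", "%s must be a positive number", nm)
    }
  }
  structure(list(thresholds = thresholds, contact_cutoff = contact_cutoff,
                 flank_k = as.integer(flank_k),
                 gap_window = as.integer(gap_window),
                 identity_min = identity_min,
                 signal_peptide_len = as.integer(signal_peptide_len),
                 chain = chain, seed = seed, log_level = log_level),
            class = "varvote_config")
}

#' Read a run configuration from a YAML file
#'
#' Flat keys mirroring the [run_config()] arguments, with threshold fields
#' (`svm_cut`, `foldx_cut`, `foldx_digits`, `pp2_vote_cut`) at top level.
#' `overrides` (e.g. from CLI flags) win over file values.
#' @param path YAML file path, or `NULL` for defaults only.
#' @param overrides Named list of values taking precedence.
#' @return A `varvote_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      vv_stop("varvote_config_error", "config file not found: %s", path)
    }
    vals <- yaml::read_yaml(path) %||% list()
  }
  vals[names(overrides)] <- overrides
  th_args <- intersect(names(vals),
                       c("svm_cut", "foldx_cut", "foldx_digits",
                         "pp2_vote_cut", "pp2_ternary"))
  th <- do.call(thresholds, vals[th_args])
  cfg_args <- intersect(names(vals),
                        c("contact_cutoff", "flank_k", "gap_window",
                          "identity_min", "signal_peptide_len", "chain",
                          "seed", "log_level"))
  do.call(run_config, c(list(thresholds = th), vals[cfg_args]))
}

MISSING_TOKENS <- c("", "NA", "N/A", "na", "n/a", ".")

numify <- function(x) {
  x <- as.character(x)
  x[trimws(x) %in% MISSING_TOKENS] <- NA_character_
  suppressWarnings(as.numeric(x))
}

#' Read a variant score table (TSV or CSV)
#'
#' Required columns: `variant`, `svm`, `foldx_ddg`, `polyphen2`. Optional:
#' `scheme`, `label`, `set`, `species`, `identity`. Empty cells, `NA` and
#' `N/A` denote missing scores. Rows whose variant string is not a missense
#' substitution (frameshifts, splice notation, ...) abort in strict mode
#' and are skipped with a warning (reporting line numbers) otherwise.
#'
#' @param path File path.
#' @param dialect `"auto"` (by extension; default), `"tsv"` or `"csv"`.
#' @param strict Abort on malformed rows instead of skipping them.
#' @return Data frame of validated rows (class `varvote_score_table`);
#'   skipped rows are recorded in the `skipped` attribute.
#' @export
read_score_table <- function(path, dialect = c("auto", "tsv", "csv"),
                             strict = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    vv_stop("varvote_io_error", "score table not found: %s", path)
  }
  if (dialect == "auto") {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else
      "tsv"
  }
  sep <- if (dialect == "csv") "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           comment.char = "#", quote = "\"",
                           stringsAsFactors = FALSE,
                           check.names = TRUE, fill = TRUE,
                           colClasses = "character")
  need <- c("variant", "svm", "foldx_ddg", "polyphen2")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    vv_stop("varvote_config_error",
            "score table %s lacks required column(s): %s", path,
            paste(miss, collapse = ", "))
  }
  out <- raw
  out$svm <- numify(raw$svm)
  out$foldx_ddg <- numify(raw$foldx_ddg)
  out$polyphen2 <- numify(raw$polyphen2)
  if ("identity" %in% names(raw)) out$identity <- numify(raw$identity)
  if (!("scheme" %in% names(out))) out$scheme <- "mature"
  out$scheme[is.na(out$scheme) | !nzchar(out$scheme)] <- "mature"
  if ("label" %in% names(out)) {
    out$label[!is.na(out$label) & !nzchar(trimws(out$label))] <- NA
  }

  bad <- integer(0); msgs <- character(0)
  for (i in seq_len(nrow(out))) {
    err <- tryCatch({
      v <- parse_variant(out$variant[i], scheme = out$scheme[i])
      out$variant[i] <- format(v)
      out$scheme[i] <- v$scheme
      chk <- c(out$svm[i], out$polyphen2[i])
      if (any(!is.na(chk) & (chk < 0 | chk > 1))) {
        vv_stop("varvote_validation_error",
                "probability score outside [0,1]")
      }
      if (is.na(out$svm[i]) && is.na(out$foldx_ddg[i]) &&
          is.na(out$polyphen2[i])) {
        vv_stop("varvote_validation_error", "all three scores missing")
      }
      NULL
    }, varvote_error = function(e) conditionMessage(e))
    if (!is.null(err)) {
      bad <- c(bad, i)
      # +1 for the header line
      msgs <- c(msgs, sprintf("line %d ('%s'): %s", i + 1L,
                              raw$variant[i], err))
    }
  }
  if (length(bad)) {
    if (strict) {
      vv_stop("varvote_validation_error",
              "malformed row(s) in %s:\n  %s", path,
              paste(msgs, collapse = "\n  "))
    }
    warning(sprintf("skipped %d malformed row(s) in %s:\n  %s",
                    length(bad), path, paste(msgs, collapse = "\n  ")),
            call. = FALSE)
    skipped <- out[bad, , drop = FALSE]
    out <- out[-bad, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "skipped") <- skipped
  }
  class(out) <- c("varvote_score_table", "data.frame")
  out
}

# md5 checksums of the packaged fixture tables, frozen at packaging time.
FIXTURE_MD5 <- c(
  table2_scores.tsv = "e04c4394598ca83a9f5eb0ca5e2e73b2",
  table3_scores.tsv = "794469f5d8486e27d75882a3c31bedb1"
)

#' Path to a packaged example/fixture file
#' @param file File name under the package's `extdata/`; with no argument,
#'   lists the available files.
#' @return File path (or a character vector of names).
#' @export
varvote_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "varvote")))
  }
  p <- system.file("extdata", file, package = "varvote")
  if (!nzchar(p)) {
    vv_stop("varvote_io_error", "no packaged file '%s'", file)
  }
  p
}

verify_fixture <- function(file) {
  p <- varvote_example(file)
  expect <- FIXTURE_MD5[[file]]
  got <- unname(tools::md5sum(p))
  if (!identical(got, expect)) {
    vv_stop("varvote_io_error",
            "packaged fixture %s failed its checksum (%s != %s)",
            file, got, expect)
  }
  p
}

#' Packaged score table of the 16 novel SERPINA1 SNVs
#'
#' The published per-variant SVM probability, FoldX ddG and PolyPhen-2
#' score for the 16 rare/novel missense SNVs (the consensus-classification
#' worked example). The file integrity is checksum-verified at load.
#' @return A `varvote_score_table` (16 rows).
#' @export
aat_novel_scores <- function() {
  read_score_table(verify_fixture("table2_scores.tsv"), strict = TRUE)
}

#' Packaged SERPINA1 benchmarking score table
#'
#' The published 57-variant benchmark: 17 ClinVar pathogenic, 5 ClinVar
#' benign, and 35 primate-derived neutral variants, each with SVM, FoldX
#' and PolyPhen-2 scores, truth labels and subset membership. Checksum
#' verified at load.
#' @return A `varvote_score_table` (57 rows).
#' @export
aat_benchmark_scores <- function() {
  read_score_table(verify_fixture("table3_scores.tsv"), strict = TRUE)
}

config_as_list <- function(config) {
  th <- config$thresholds
  list(svm_cut = th$svm_cut, foldx_cut = th$foldx_cut,
       foldx_digits = th$foldx_digits, pp2_vote_cut = th$pp2_vote_cut,
       pp2_ternary = th$pp2_ternary,
       contact_cutoff = config$contact_cutoff, flank_k = config$flank_k,
       gap_window = config$gap_window, identity_min = config$identity_min,
       signal_peptide_len = config$signal_peptide_len,
       chain = config$chain, seed = config$seed,
       log_level = config$log_level)
}

#' Write classification or benchmark results to disk
#'
#' Writes a TSV (flat rows) and/or JSON (rows plus summaries plus the full
#' run configuration for provenance). Output is deterministic: stable row
#' order and fixed number formatting.
#'
#' @param results A `varvote_classification`, `varvote_benchmark_report` or
#'   `varvote_neutral_set`.
#' @param out_dir Output directory (created if needed).
#' @param formats Subset of `c("tsv", "json")`.
#' @param config A [run_config()] recorded in the JSON output.
#' @param stem Base file name (default derived from the result class).
#' @return Character vector of written paths, invisibly.
#' @export
write_reports <- function(results, out_dir, formats = c("tsv", "json"),
                          config = run_config(), stem = NULL) {
  formats <- match.arg(formats, several.ok = TRUE)
  empty <- (is.data.frame(results) && nrow(results) == 0L) ||
    (inherits(results, "varvote_neutral_set") &&
       nrow(results$candidates) == 0L && nrow(results$accepted) == 0L) ||
    is.null(results)
  if (empty) {
    vv_stop("varvote_validation_error", "refusing to write empty results")
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) vv_stop("varvote_io_error", "cannot create %s", out_dir)
  }
  if (inherits(results, "varvote_classification")) {
    stem <- stem %||% "classification"
    tab <- as.data.frame(results)
    payload <- list(rows = tab,
                    summary_counts = as.list(category_counts(results)),
                    config = config_as_list(config))
  } else if (inherits(results, "varvote_benchmark_report")) {
    stem <- stem %||% "benchmark"
    tab <- do.call(rbind, lapply(names(results$per_predictor), function(p) {
      pp <- results$per_predictor[[p]]
      m <- unclass(pp$metrics)
      data.frame(predictor = p, n = pp$n, n_missing = pp$n_missing,
                 tp = pp$confusion[["tp"]], fp = pp$confusion[["fp"]],
                 tn = pp$confusion[["tn"]], fn = pp$confusion[["fn"]],
                 t(m), stringsAsFactors = FALSE)
    }))
    payload <- list(
      per_predictor = lapply(results$per_predictor, function(pp) {
        list(confusion = as.list(unclass(pp$confusion)),
             metrics = as.list(unclass(pp$metrics)),
             n = pp$n, n_missing = pp$n_missing)
      }),
      subset_fractions = results$subset_fractions,
      foldx_stability = results$foldx_stability,
      config = config_as_list(config))
  } else if (inherits(results, "varvote_neutral_set")) {
    stem <- stem %||% "neutral_set"
    tab <- results$candidates
    payload <- list(accepted = results$accepted,
                    candidates = results$candidates,
                    config = config_as_list(config))
  } else {
    vv_stop("varvote_validation_error",
            "unsupported results object of class %s",
            paste(class(results), collapse = "/"))
  }
  paths <- character(0)
  if ("tsv" %in% formats) {
    p <- file.path(out_dir, paste0(stem, ".tsv"))
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    paths <- c(paths, p)
  }
  if ("json" %in% formats) {
    p <- file.path(out_dir, paste0(stem, ".json"))
    jsonlite::write_json(payload, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", na = "null")
    paths <- c(paths, p)
  }
  invisible(paths)
}
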