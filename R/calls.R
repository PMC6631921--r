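# Per-predictor deleterious/neutral calls and the four-way consensus vote.
#
# Three predictors are supported: an SVM pathogenicity probability in [0,1],
# a FoldX folding free-energy change (ddG, kcal/mol; positive destabilizes),
# and a PolyPhen-2 damage probability in [0,1]. Each score is thresholded
# into deleterious/neutral; the number of deleterious votes among the
# available predictors maps onto a four-level consensus category.

CALL_LEVELS <- c("deleterious", "neutral", "missing")
CATEGORY_LEVELS <- c("probably_deleterious", "possibly_deleterious",
                     "possibly_neutral", "probably_neutral")

#' Predictor decision thresholds
#'
#' Defaults reproduce the published calling scheme: SVM deleterious at
#' probability 0.5 and above; FoldX deleterious when ddG, rounded
#' half-away-from-zero to one decimal, reaches 1.0 kcal/mol (so a printed
#' 0.99 votes deleterious while 0.72 does not); PolyPhen-2 votes deleterious
#' at 0.5 and above, with the conventional 0.15/0.85 bounds retained only
#' for the descriptive benign / possibly damaging / probably damaging label.
#' All comparisons at the cut points are inclusive.
#'
#' @param svm_cut SVM probability cut (default 0.5).
#' @param foldx_cut ddG cut in kcal/mol applied after rounding (default 1.0).
#' @param foldx_digits Decimals ddG is rounded to before comparison
#'   (default 1; set to `Inf` for a strict unrounded `>=` comparison).
#' @param pp2_vote_cut PolyPhen-2 binary vote cut (default 0.5).
#' @param pp2_ternary Lower/upper bounds of the descriptive ternary coding
#'   (default `c(0.15, 0.85)`).
#' @return An object of class `varvote_thresholds`.
#' @export
thresholds <- function(svm_cut = 0.5, foldx_cut = 1.0, foldx_digits = 1,
                       pp2_vote_cut = 0.5, pp2_ternary = c(0.15, 0.85)) {
  if (!is_scalar_number(svm_cut) || svm_cut < 0 || svm_cut > 1) {
    vv_stop("varvote_validation_error", "svm_cut must lie in [0,1]")
  }
  if (!is_scalar_number(pp2_vote_cut) || pp2_vote_cut < 0 ||
      pp2_vote_cut > 1) {
    vv_stop("varvote_validation_error", "pp2_vote_cut must lie in [0,1]")
  }
  if (!is.numeric(foldx_cut) || length(foldx_cut) != 1L) {
    vv_stop("varvote_validation_error", "foldx_cut must be a number")
  }
  if (length(pp2_ternary) != 2L || pp2_ternary[1] >= pp2_ternary[2]) {
    vv_stop("varvote_validation_error",
            "pp2_ternary must be (lower, upper) with lower < upper")
  }
  structure(
    list(svm_cut = svm_cut, foldx_cut = foldx_cut,
         foldx_digits = foldx_digits, pp2_vote_cut = pp2_vote_cut,
         pp2_ternary = as.numeric(pp2_ternary)),
    class = "varvote_thresholds"
  )
}

#' @export
print.varvote_thresholds <- function(x, ...) {
  cat(sprintf(
    "varvote thresholds: SVM >= %g; FoldX ddG >= %g (after %s-decimal rounding); PolyPhen-2 >= %g\n",
    x$svm_cut, x$foldx_cut, format(x$foldx_digits), x$pp2_vote_cut))
  invisible(x)
}

check_unit_scores <- function(x, what) {
  bad <- !is.na(x) & (x < 0 | x > 1)
  if (any(bad)) {
    vv_stop("varvote_validation_error",
            "%s score(s) outside [0,1]: %s", what,
            paste(x[bad], collapse = ", "))
  }
  invisible(x)
}

#' Call the SVM predictor
#'
#' Deleterious at `svm_cut` and above (inclusive). Vectorized; `NA` scores
#' yield `"missing"` calls.
#' @param p SVM probabilities in [0,1].
#' @param t A `varvote_thresholds`.
#' @return Character vector over deleterious/neutral/missing.
#' @export
call_svm <- function(p, t = thresholds()) {
  check_unit_scores(p, "SVM")
  ifelse(is.na(p), "missing", ifelse(p >= t$svm_cut, "deleterious", "neutral"))
}

#' Call the FoldX stability predictor
#'
#' ddG is rounded half-away-from-zero to `foldx_digits` decimals before the
#' inclusive comparison against `foldx_cut`, mirroring how one-decimal
#' published tables were called (a printed 0.99 rounds to 1.0 and votes
#' deleterious).
#' @param ddg Free-energy changes in kcal/mol (any real).
#' @param t A `varvote_thresholds`.
#' @return Character vector over deleterious/neutral/missing.
#' @export
call_foldx <- function(ddg, t = thresholds()) {
  if (!is.numeric(ddg) && !all(is.na(ddg))) {
    vv_stop("varvote_validation_error", "ddg must be numeric")
  }
  r <- if (is.finite(t$foldx_digits)) {
    round_half_away(as.numeric(ddg), t$foldx_digits)
  } else {
    as.numeric(ddg)
  }
  ifelse(is.na(r), "missing",
         ifelse(r >= t$foldx_cut, "deleterious", "neutral"))
}

#' Call the PolyPhen-2 predictor
#'
#' Binary vote at `pp2_vote_cut` and above (inclusive).
#' @param s PolyPhen-2 scores in [0,1].
#' @param t A `varvote_thresholds`.
#' @return Character vector over deleterious/neutral/missing.
#' @seealso [pp2_ternary_label()] for the descriptive three-way coding.
#' @export
call_polyphen2 <- function(s, t = thresholds()) {
  check_unit_scores(s, "PolyPhen-2")
  ifelse(is.na(s), "missing",
         ifelse(s >= t$pp2_vote_cut, "deleterious", "neutral"))
}

#' Descriptive PolyPhen-2 ternary label
#'
#' The conventional coding: scores at or above the upper bound are
#' "probably_damaging", at or below the lower bound "benign", in between
#' "possibly_damaging". Descriptive only — the consensus vote uses the
#' binary cut of [call_polyphen2()].
#' @param s PolyPhen-2 scores in [0,1].
#' @param t A `varvote_thresholds`.
#' @return Character vector (NA for missing scores).
#' @export
pp2_ternary_label <- function(s, t = thresholds()) {
  check_unit_scores(s, "PolyPhen-2")
  lo <- t$pp2_ternary[1]; hi <- t$pp2_ternary[2]
  ifelse(is.na(s), NA_character_,
         ifelse(s >= hi, "probably_damaging",
                ifelse(s <= lo, "benign", "possibly_damaging")))
}

#' Aggregate per-predictor calls into a consensus category
#'
#' Counts deleterious votes over the non-missing calls: 3 votes is
#' "probably_deleterious", 2 "possibly_deleterious", 1 "possibly_neutral",
#' 0 "probably_neutral". Missing predictors shrink the denominator without
#' changing the count-to-label map; a category decided on fewer than three
#' available predictors is flagged as reduced evidence.
#'
#' @param calls Character vector (length <= 3) of
#'   deleterious/neutral/missing calls.
#' @return A list with `label`, `n_deleterious`, `n_available` and
#'   `reduced_evidence`.
#' @examples
#' consensus_category(c("deleterious", "deleterious", "deleterious"))
#' consensus_category(c("neutral", "missing", "deleterious"))
#' @export
consensus_category <- function(calls) {
  calls <- as.character(calls)
  if (length(calls) < 1L || length(calls) > 3L ||
      !all(calls %in% CALL_LEVELS)) {
    vv_stop("varvote_validation_error",
            "calls must be 1-3 values among %s",
            paste(CALL_LEVELS, collapse = "/"))
  }
  avail <- calls != "missing"
  if (!any(avail)) {
    vv_stop("varvote_validation_error",
            "no available predictor call (all missing)")
  }
  n_del <- sum(calls[avail] == "deleterious")
  list(
    label = c("probably_neutral", "possibly_neutral",
              "possibly_deleterious", "probably_deleterious")[n_del + 1L],
    n_deleterious = n_del,
    n_available = sum(avail),
    reduced_evidence = sum(avail) < 3L
  )
}

#' Classify a table of scored variants
#'
#' Applies the three per-predictor calls and the consensus vote row-wise.
#'
#' @param scores A data frame with columns `variant` (strings or already
#'   parsed), `svm`, `foldx_ddg`, `polyphen2`; optionally `scheme`. `NA`
#'   means the predictor could not be run for that variant.
#' @param t A `varvote_thresholds`.
#' @return A `varvote_classification`: the input rows plus per-predictor
#'   calls, vote counts, the consensus `category`, the descriptive
#'   PolyPhen-2 ternary label and a reduced-evidence flag; the four-level
#'   category count summary is available via [category_counts()].
#' @export
classify_table <- function(scores, t = thresholds()) {
  if (!is.data.frame(scores) || nrow(scores) == 0L) {
    vv_stop("varvote_validation_error",
            "scores must be a non-empty data frame")
  }
  need <- c("variant", "svm", "foldx_ddg", "polyphen2")
  miss <- setdiff(need, names(scores))
  if (length(miss)) {
    vv_stop("varvote_config_error",
            "score table lacks required column(s): %s",
            paste(miss, collapse = ", "))
  }
  out <- as.data.frame(scores, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  schemes <- if ("scheme" %in% names(out)) as.character(out$scheme) else
    rep("mature", nrow(out))
  parsed <- lapply(seq_len(nrow(out)), function(i) {
    tryCatch(
      parse_variant(as.character(out$variant[i]),
                    scheme = ifelse(is.na(schemes[i]) | !nzchar(schemes[i]),
                                    "mature", schemes[i])),
      varvote_parse_error = function(e) {
        vv_stop("varvote_validation_error",
                "row %d: %s", i, conditionMessage(e))
      })
  })
  out$variant <- vapply(parsed, format, character(1))
  out$scheme <- vapply(parsed, function(v) v$scheme, character(1))

  out$call_svm <- call_svm(as.numeric(out$svm), t)
  out$call_foldx <- call_foldx(as.numeric(out$foldx_ddg), t)
  out$call_polyphen2 <- call_polyphen2(as.numeric(out$polyphen2), t)
  out$pp2_ternary <- pp2_ternary_label(as.numeric(out$polyphen2), t)

  cons <- lapply(seq_len(nrow(out)), function(i) {
    tryCatch(
      consensus_category(c(out$call_svm[i], out$call_foldx[i],
                           out$call_polyphen2[i])),
      varvote_validation_error = function(e) {
        vv_stop("varvote_validation_error",
                "row %d (%s): %s", i, out$variant[i], conditionMessage(e))
      })
  })
  out$n_deleterious <- vapply(cons, `[[`, integer(1), "n_deleterious")
  out$n_available <- vapply(cons, `[[`, integer(1), "n_available")
  out$reduced_evidence <- vapply(cons, `[[`, logical(1), "reduced_evidence")
  out$category <- vapply(cons, `[[`, character(1), "label")

  counts <- table(factor(out$category, levels = CATEGORY_LEVELS))
  structure(out,
            summary_counts = stats::setNames(as.integer(counts),
                                             CATEGORY_LEVELS),
            thresholds = t,
            class = c("varvote_classification", "data.frame"))
}

#' Consensus category counts of a classification
#' @param x A `varvote_classification` from [classify_table()].
#' @return Named integer vector over the four category levels.
#' @export
category_counts <- function(x) {
  stopifnot(inherits(x, "varvote_classification"))
  attr(x, "summary_counts")
}

#' @export
print.varvote_classification <- function(x, ...) {
  cat(sprintf("varvote classification: %d variant(s)\n", nrow(x)))
  print.data.frame(x[, c("variant", "call_svm", "call_foldx",
                         "call_polyphen2", "n_deleterious", "n_available",
                         "category")], row.names = FALSE)
  cat("\nCategory counts:\n")
  print(category_counts(x))
  invisible(x)
}
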