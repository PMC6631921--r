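# Confusion matrix and the six binary-classification statistics.
#
# Convention: pathogenic is the positive truth class, deleterious the
# positive prediction. Statistics with a zero denominator are reported as
# NA (an explicit per-statistic undefined marker) rather than raising, so
# reports over small benchmark subsets stay usable.

TRUTH_LEVELS <- c("pathogenic", "benign")
PRED_LEVELS <- c("deleterious", "neutral")

#' Confusion counts from labelled calls
#'
#' @param truth Character vector over pathogenic/benign.
#' @param predicted Character vector over deleterious/neutral, same length.
#' @return A `varvote_confusion`: named integer vector `tp`, `fp`, `tn`,
#'   `fn`.
#' @export
confusion <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) == 0L) {
    vv_stop("varvote_validation_error", "no labelled calls")
  }
  if (length(truth) != length(predicted)) {
    vv_stop("varvote_validation_error",
            "truth and predicted differ in length")
  }
  if (!all(truth %in% TRUTH_LEVELS)) {
    vv_stop("varvote_validation_error",
            "truth values must be pathogenic/benign")
  }
  if (!all(predicted %in% PRED_LEVELS)) {
    vv_stop("varvote_validation_error",
            "predictions must be deleterious/neutral")
  }
  structure(c(
    tp = sum(truth == "pathogenic" & predicted == "deleterious"),
    fp = sum(truth == "benign" & predicted == "deleterious"),
    tn = sum(truth == "benign" & predicted == "neutral"),
    fn = sum(truth == "pathogenic" & predicted == "neutral")
  ), class = "varvote_confusion")
}

#' The six binary-classification statistics
#'
#' tpr = tp/(tp+fn) (sensitivity); tnr = tn/(tn+fp) (specificity);
#' ppv = tp/(tp+fp); npv = tn/(tn+fn); acc = (tp+tn)/total;
#' bacc = (tpr+tnr)/2. Any statistic whose denominator is zero is `NA`;
#' all four counts zero is an error.
#'
#' @param counts A `varvote_confusion` or named vector/list with `tp`,
#'   `fp`, `tn`, `fn`.
#' @return Named numeric vector `tpr`, `tnr`, `ppv`, `npv`, `acc`, `bacc`
#'   of class `varvote_metrics`.
#' @export
metric_set <- function(counts) {
  cts <- unlist(counts)[c("tp", "fp", "tn", "fn")]
  if (anyNA(cts) || any(cts < 0)) {
    vv_stop("varvote_validation_error",
            "counts must be non-negative tp/fp/tn/fn")
  }
  tp <- cts[["tp"]]; fp <- cts[["fp"]]; tn <- cts[["tn"]]; fn <- cts[["fn"]]
  total <- tp + fp + tn + fn
  if (total == 0) {
    vv_stop("varvote_validation_error", "all confusion counts are zero")
  }
  sdiv <- function(num, den) if (den == 0) NA_real_ else num / den
  tpr <- sdiv(tp, tp + fn)
  tnr <- sdiv(tn, tn + fp)
  out <- c(tpr = tpr, tnr = tnr,
           ppv = sdiv(tp, tp + fp), npv = sdiv(tn, tn + fn),
           acc = (tp + tn) / total,
           bacc = if (is.na(tpr) || is.na(tnr)) NA_real_ else (tpr + tnr) / 2)
  structure(out, counts = cts, class = "varvote_metrics")
}

#' @export
print.varvote_metrics <- function(x, digits = 3, ...) {
  cts <- attr(x, "counts")
  if (!is.null(cts)) {
    cat(sprintf("tp=%d fp=%d tn=%d fn=%d\n", cts[["tp"]], cts[["fp"]],
                cts[["tn"]], cts[["fn"]]))
  }
  vals <- round_half_away(unclass(x), digits)
  print(vals)
  invisible(x)
}

predictor_caller <- function(pred) {
  switch(pred,
         svm = function(x, t) call_svm(x, t),
         foldx = function(x, t) call_foldx(x, t),
         polyphen2 = function(x, t) call_polyphen2(x, t))
}

PREDICTOR_COLS <- c(svm = "svm", foldx = "foldx_ddg",
                    polyphen2 = "polyphen2")

#' Benchmark predictors on a labelled score table
#'
#' For each predictor, rows carrying a score are thresholded into calls and
#' scored against the truth labels (confusion counts plus the six
#' statistics). When a `set` column partitions the table into benchmark
#' subsets, per-subset call fractions are reported, along with a separate
#' FoldX stability summary using the sign of ddG (fraction of each subset
#' with ddG > 0, i.e. predicted destabilizing) — deliberately distinct from
#' the classification vote cut.
#'
#' @param scores Data frame with `variant`, `label`
#'   (pathogenic/benign), the score columns `svm`, `foldx_ddg`,
#'   `polyphen2`, and optionally `set`.
#' @param t A `varvote_thresholds`.
#' @return A `varvote_benchmark_report`: list with `per_predictor`
#'   (confusion, metrics, n and n_missing per predictor), `subset_fractions`
#'   (data frame), `foldx_stability` (data frame) and `thresholds`.
#' @export
benchmark_report <- function(scores, t = thresholds()) {
  if (!is.data.frame(scores) || nrow(scores) == 0L) {
    vv_stop("varvote_validation_error",
            "scores must be a non-empty data frame")
  }
  need <- c("variant", "label")
  miss <- setdiff(need, names(scores))
  if (length(miss)) {
    vv_stop("varvote_config_error",
            "benchmark table lacks column(s): %s",
            paste(miss, collapse = ", "))
  }
  label <- as.character(scores$label)
  if (!all(label %in% TRUTH_LEVELS, na.rm = TRUE)) {
    vv_stop("varvote_validation_error",
            "labels must be pathogenic/benign")
  }

  per_pred <- list()
  for (pred in names(PREDICTOR_COLS)) {
    col <- PREDICTOR_COLS[[pred]]
    if (!col %in% names(scores)) next
    x <- as.numeric(scores[[col]])
    keep <- !is.na(x) & !is.na(label)
    if (!any(keep)) {
      warning(sprintf("predictor '%s' has no scored labelled rows; omitted",
                      pred), call. = FALSE)
      next
    }
    calls <- predictor_caller(pred)(x[keep], t)
    conf <- confusion(label[keep], calls)
    per_pred[[pred]] <- list(confusion = conf, metrics = metric_set(conf),
                             n = sum(keep), n_missing = sum(!keep))
  }
  if (!length(per_pred)) {
    vv_stop("varvote_validation_error", "no predictor column present")
  }

  subset_fractions <- NULL
  foldx_stability <- NULL
  if ("set" %in% names(scores)) {
    sets <- as.character(scores$set)
    rows <- list()
    for (ss in unique(sets)) {
      sel <- sets == ss
      for (pred in names(per_pred)) {
        col <- PREDICTOR_COLS[[pred]]
        x <- as.numeric(scores[[col]])[sel]
        ok <- !is.na(x)
        if (!any(ok)) next
        calls <- predictor_caller(pred)(x[ok], t)
        rows[[length(rows) + 1L]] <- data.frame(
          set = ss, predictor = pred, n = sum(ok),
          n_deleterious = sum(calls == "deleterious"),
          frac_deleterious = mean(calls == "deleterious"),
          frac_neutral = mean(calls == "neutral"),
          stringsAsFactors = FALSE)
      }
    }
    subset_fractions <- do.call(rbind, rows)
    if ("foldx_ddg" %in% names(scores)) {
      rows <- lapply(unique(sets), function(ss) {
        x <- as.numeric(scores$foldx_ddg)[sets == ss]
        x <- x[!is.na(x)]
        if (!length(x)) return(NULL)
        data.frame(set = ss, n = length(x),
                   n_destabilizing = sum(x > 0),
                   frac_destabilizing = mean(x > 0),
                   n_stabilizing = sum(x < 0),
                   frac_stabilizing = mean(x < 0),
                   stringsAsFactors = FALSE)
      })
      foldx_stability <- do.call(rbind, rows)
    }
  }

  structure(list(per_predictor = per_pred,
                 subset_fractions = subset_fractions,
                 foldx_stability = foldx_stability,
                 thresholds = t),
            class = "varvote_benchmark_report")
}

#' @export
print.varvote_benchmark_report <- function(x, digits = 3, ...) {
  cat("varvote benchmark report\n")
  for (pred in names(x$per_predictor)) {
    pp <- x$per_predictor[[pred]]
    cat(sprintf("\n%s (n=%d, missing=%d):\n", pred, pp$n, pp$n_missing))
    print(pp$metrics, digits = digits)
  }
  if (!is.null(x$subset_fractions)) {
    cat("\nPer-subset call fractions:\n")
    print.data.frame(x$subset_fractions, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$foldx_stability)) {
    cat("\nFoldX stability sign summary (ddG > 0 destabilizing):\n")
    print.data.frame(x$foldx_stability, row.names = FALSE, digits = 3)
  }
  invisible(x)
}
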