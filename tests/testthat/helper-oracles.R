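# Independent brute-force oracles. Deliberately naive: plain loops and
# direct re-evaluation of the defining formulas, sharing no code with the
# package implementations they check.

oracle_confusion <- function(truth, predicted) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(truth)) {
    if (truth[i] == "pathogenic") {
      if (predicted[i] == "deleterious") tp <- tp + 1L else fn <- fn + 1L
    } else {
      if (predicted[i] == "deleterious") fp <- fp + 1L else tn <- tn + 1L
    }
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

oracle_metrics <- function(cts) {
  tp <- cts[["tp"]]; fp <- cts[["fp"]]; tn <- cts[["tn"]]; fn <- cts[["fn"]]
  f <- function(num, den) if (den == 0) NA_real_ else num / den
  tpr <- f(tp, tp + fn); tnr <- f(tn, tn + fp)
  c(tpr = tpr, tnr = tnr, ppv = f(tp, tp + fp), npv = f(tn, tn + fn),
    acc = (tp + tn) / (tp + fp + tn + fn),
    bacc = if (is.na(tpr) || is.na(tnr)) NA_real_ else 0.5 * (tpr + tnr))
}

# all-pairs atom-distance scan; returns sorted two-column matrix (i < j)
oracle_contact_pairs <- function(atoms, cutoff) {
  res <- sort(unique(atoms$resno))
  out <- list()
  for (a in seq_along(res)) {
    A <- atoms[atoms$resno == res[a], , drop = FALSE]
    for (b in seq_along(res)) {
      if (b <= a) next
      B <- atoms[atoms$resno == res[b], , drop = FALSE]
      hit <- FALSE
      for (i in seq_len(nrow(A))) {
        for (j in seq_len(nrow(B))) {
          dd <- sqrt((A$x[i] - B$x[j])^2 + (A$y[i] - B$y[j])^2 +
                       (A$z[i] - B$z[j])^2)
          if (dd < cutoff) hit <- TRUE
        }
      }
      if (hit) out[[length(out) + 1L]] <- c(res[a], res[b])
    }
  }
  if (!length(out)) return(matrix(integer(0), ncol = 2))
  m <- do.call(rbind, out)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# enumerate all 2^k deleterious/neutral assignments over the available
# calls, find the one matching, and read the category off an explicit table
oracle_consensus_label <- function(calls) {
  avail <- calls[calls != "missing"]
  k <- length(avail)
  stopifnot(k >= 1)
  labels <- c("probably_neutral", "possibly_neutral",
              "possibly_deleterious", "probably_deleterious")
  for (mask in 0:(2^k - 1)) {
    combo <- ifelse(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0,
                    "deleterious", "neutral")
    if (all(combo == avail)) {
      return(labels[sum(combo == "deleterious") + 1L])
    }
  }
  stop("no matching combination")  # unreachable for valid calls
}

random_toy_atoms <- function(n_res, seed) {
  set.seed(seed)
  k <- sample(1:3, 1)
  data.frame(resno = rep(seq_len(n_res), each = k),
             x = runif(n_res * k, 0, 15), y = runif(n_res * k, 0, 15),
             z = runif(n_res * k, 0, 15))
}
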