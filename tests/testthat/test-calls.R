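test_that("SVM calls are inclusive at the 0.5 cut", {
  t <- thresholds()
  expect_equal(call_svm(0.8282, t), "deleterious")
  expect_equal(call_svm(0.3387, t), "neutral")
  expect_equal(call_svm(0.5, t), "deleterious")  # "0.5 and above"
  expect_equal(call_svm(NA, t), "missing")
  expect_error(call_svm(1.2, t), class = "varvote_validation_error")
  expect_error(call_svm(-0.1, t), class = "varvote_validation_error")
})

test_that("FoldX calls round ddG to one decimal before the 1.0 cut", {
  t <- thresholds()
  expect_equal(call_foldx(0.99, t), "deleterious")  # rounds to 1.0
  expect_equal(call_foldx(0.95, t), "deleterious")  # half rounds away
  expect_equal(call_foldx(0.94, t), "neutral")
  expect_equal(call_foldx(0.72, t), "neutral")
  expect_equal(call_foldx(-0.25, t), "neutral")
  expect_equal(call_foldx(26.29, t), "deleterious")
  expect_equal(call_foldx(NA, t), "missing")
  # unrounded strict mode is available
  ts <- thresholds(foldx_digits = Inf)
  expect_equal(call_foldx(0.99, ts), "neutral")
  expect_equal(call_foldx(1.0, ts), "deleterious")
})

test_that("PolyPhen-2 votes binary at 0.5 and labels the ternary", {
  t <- thresholds()
  expect_equal(call_polyphen2(0.648, t), "deleterious")
  expect_equal(call_polyphen2(0.517, t), "deleterious")
  expect_equal(call_polyphen2(0.134, t), "neutral")
  expect_equal(call_polyphen2(0.018, t), "neutral")
  expect_equal(call_polyphen2(NA, t), "missing")
  expect_equal(pp2_ternary_label(c(0.99, 0.5, 0.1, NA), t),
               c("probably_damaging", "possibly_damaging", "benign", NA))
  expect_equal(pp2_ternary_label(c(0.15, 0.85), t),
               c("benign", "probably_damaging"))
})

test_that("consensus category is a pure function of the deleterious count", {
  del <- "deleterious"; neu <- "neutral"
  expect_equal(consensus_category(c(del, del, del))$label,
               "probably_deleterious")
  expect_equal(consensus_category(c(del, del, neu))$label,
               "possibly_deleterious")
  expect_equal(consensus_category(c(neu, neu, del))$label,
               "possibly_neutral")
  expect_equal(consensus_category(c(neu, neu, neu))$label,
               "probably_neutral")
  # which predictor voted must not matter
  expect_equal(consensus_category(c(neu, del, del))$label,
               consensus_category(c(del, del, neu))$label)

  # missing calls shrink the denominator (the I9N pattern)
  cc <- consensus_category(c(neu, "missing", del))
  expect_equal(cc$label, "possibly_neutral")
  expect_equal(cc$n_available, 2L)
  expect_true(cc$reduced_evidence)
  expect_error(consensus_category(rep("missing", 3)),
               class = "varvote_validation_error")
  expect_error(consensus_category(c("maybe", del, del)),
               class = "varvote_validation_error")
})

test_that("consensus agrees with brute-force enumeration on random triples", {
  set.seed(7)
  t <- thresholds()
  for (i in 1:500) {
    svm <- if (runif(1) < 0.1) NA else runif(1)
    ddg <- if (runif(1) < 0.1) NA else runif(1, -3, 4)
    pp2 <- if (runif(1) < 0.1) NA else runif(1)
    calls <- c(call_svm(svm, t), call_foldx(ddg, t), call_polyphen2(pp2, t))
    if (all(calls == "missing")) next
    expect_equal(consensus_category(calls)$label,
                 oracle_consensus_label(calls))
  }
})

test_that("raising any single score never moves the label toward neutral", {
  set.seed(21)
  rank <- function(lbl) match(lbl, c("probably_neutral", "possibly_neutral",
                                     "possibly_deleterious",
                                     "probably_deleterious"))
  t <- thresholds()
  lab <- function(svm, ddg, pp2) {
    consensus_category(c(call_svm(svm, t), call_foldx(ddg, t),
                         call_polyphen2(pp2, t)))$label
  }
  for (i in 1:200) {
    svm <- runif(1); ddg <- runif(1, -3, 4); pp2 <- runif(1)
    base <- rank(lab(svm, ddg, pp2))
    dsvm <- min(1, svm + runif(1, 0, 1 - svm))
    expect_gte(rank(lab(dsvm, ddg, pp2)), base)
    expect_gte(rank(lab(svm, ddg + runif(1, 0, 3), pp2)), base)
    dpp2 <- min(1, pp2 + runif(1, 0, 1 - pp2))
    expect_gte(rank(lab(svm, ddg, dpp2)), base)
  }
})

test_that("the packaged novel-SNV table reproduces every published category", {
  cls <- classify_table(aat_novel_scores())
  expected <- c(
    P289S = "probably_deleterious", I50N = "probably_deleterious",
    D341V = "probably_deleterious", M221T = "probably_deleterious",
    V210E = "probably_deleterious", P28L = "probably_deleterious",
    P369H = "probably_deleterious", A142D = "probably_deleterious",
    M385T = "possibly_deleterious", V333M = "possibly_deleterious",
    I9N = "possibly_neutral", Q40R = "possibly_neutral",
    K174E = "possibly_neutral", H262Y = "possibly_neutral",
    E204K = "probably_neutral", A325P = "probably_neutral")
  expect_equal(stats::setNames(cls$category, cls$variant), expected)
  expect_equal(unname(category_counts(cls)), c(8L, 2L, 4L, 2L))
  # I9N: FoldX missing, vote decided on two predictors
  i9n <- cls[cls$variant == "I9N", ]
  expect_equal(i9n$call_foldx, "missing")
  expect_equal(i9n$n_available, 2L)
  expect_true(i9n$reduced_evidence)
})

test_that("classify_table validates input and flags boundary votes", {
  expect_error(classify_table(data.frame()),
               class = "varvote_validation_error")
  expect_error(classify_table(data.frame(variant = "E342K", svm = 0.9)),
               class = "varvote_config_error")
  one <- classify_table(data.frame(variant = "A10V", svm = 0.5,
                                   foldx_ddg = 1.0, polyphen2 = 0.5))
  expect_equal(one$category, "probably_deleterious")  # inclusive cuts
  expect_error(
    classify_table(data.frame(variant = "A10V", svm = NA,
                              foldx_ddg = NA_real_, polyphen2 = NA)),
    class = "varvote_validation_error")
  expect_error(
    classify_table(data.frame(variant = "A347fs", svm = 0.9,
                              foldx_ddg = 1, polyphen2 = 0.9)),
    class = "varvote_validation_error")
})
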