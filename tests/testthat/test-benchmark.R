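test_that("percent identity excludes gap columns from the denominator", {
  expect_equal(aligned_pair("q", "s", "AKLM", "AKLM")$percent_identity, 100)
  expect_equal(aligned_pair("q", "s", "AKLM", "AKIM")$percent_identity, 75)
  expect_equal(aligned_pair("q", "s", "AK-LM", "AKQLM")$percent_identity,
               100)
  expect_error(aligned_pair("q", "s", "AKL", "AK"),
               class = "varvote_validation_error")
  expect_error(aligned_pair("q", "s", "A-K", "A-K"),
               class = "varvote_validation_error")
  # zero ungapped columns leaves identity undefined
  expect_error(aligned_pair("q", "s", "A---", "-AKL"),
               class = "varvote_validation_error")
  # a single ungapped column suffices
  expect_equal(aligned_pair("q", "s", "AA--", "-AKL")$percent_identity, 100)
})

test_that("substitution extraction reports ungapped query coordinates", {
  subs <- extract_substitutions(aligned_pair("q", "s", "AKLM", "AKIM"))
  expect_equal(nrow(subs), 1L)
  expect_equal(subs$position, 3L)
  expect_equal(subs$ref_aa, "L")
  expect_equal(subs$alt_aa, "I")
  expect_equal(nrow(extract_substitutions(
    aligned_pair("q", "s", "AKLM", "AKLM"))), 0L)
  # insertions are not substitutions
  expect_equal(nrow(extract_substitutions(
    aligned_pair("q", "s", "A-KL", "AQKL"))), 0L)
  # query gaps shift coordinates
  subs2 <- extract_substitutions(aligned_pair("q", "s", "A-KLM", "AQKIM"))
  expect_equal(subs2$position, 3L)  # L is query residue 3
  expect_equal(subs2$column, 4L)
})

test_that("flank filter needs k identical residue columns on each side", {
  expect_true(flank_conserved(aligned_pair("q", "s", "ABCDE", "ABXDE"), 3))
  # window runs off the left end
  expect_false(flank_conserved(aligned_pair("q", "s", "BCDE", "BXDE"), 2))
  # right flank not conserved
  expect_false(flank_conserved(aligned_pair("q", "s", "ABCDE", "ABXDF"), 3))
  # a gap inside the window fails
  expect_false(flank_conserved(aligned_pair("q", "s", "ABCDE", "AB-DE"), 1,
                               k = 2))
  expect_true(flank_conserved(aligned_pair("q", "s", "ABCDE", "ABXDE"), 3,
                              k = 1))
})

test_that("gap filter scans a symmetric column window", {
  nogap <- aligned_pair("q", "s", "ABCDEFG", "ABXDEFG")
  expect_true(gap_ok(nogap, 3))
  gap3 <- aligned_pair("q", "s", "ABCDE-G", "ABXDEFG")
  expect_false(gap_ok(gap3, 3))   # gap at distance 3
  gap4 <- aligned_pair("q", "s", "ABCDEF-HIJ", "ABXDEFGHIJ")
  expect_true(gap_ok(gap4, 3))    # gap at distance 4
  expect_false(gap_ok(gap4, 3, window = 4))
})

test_that("contact map follows strict-< geometry", {
  line <- data.frame(resno = 1:3, x = c(0, 4, 8), y = 0, z = 0)
  cm <- contact_map(line, 5)
  expect_equal(contact_pairs(cm), rbind(c(1L, 2L), c(2L, 3L)))
  expect_equal(contacts_of(cm, 2), c(1L, 3L))
  # exactly at the cutoff is no contact
  paird <- data.frame(resno = 1:2, x = c(0, 5), y = 0, z = 0)
  expect_equal(nrow(contact_pairs(contact_map(paird, 5))), 0L)
  expect_error(contact_map(data.frame(resno = 1, x = 0, y = 0, z = 0)),
               class = "varvote_validation_error")
  expect_error(contacts_of(cm, 99), class = "varvote_unresolved_error")
})

test_that("contact map equals the brute-force all-pairs oracle", {
  for (i in 1:40) {
    atoms <- random_toy_atoms(sample(3:20, 1), seed = 1000 + i)
    cm <- contact_map(atoms, 5)
    expect_equal(contact_pairs(cm), oracle_contact_pairs(atoms, 5))
  }
})

test_that("contact maps are symmetric, irreflexive and cutoff-monotone", {
  for (i in 1:20) {
    atoms <- random_toy_atoms(sample(3:15, 1), seed = 2000 + i)
    cm5 <- contact_map(atoms, 5)
    for (r in cm5$resnos) {
      partners <- contacts_of(cm5, r)
      expect_false(r %in% partners)
      for (p in partners) expect_true(r %in% contacts_of(cm5, p))
    }
    cm4 <- contact_map(atoms, 4)
    p5 <- apply(contact_pairs(cm5), 1, paste, collapse = "-")
    p4 <- apply(contact_pairs(cm4), 1, paste, collapse = "-")
    expect_true(all(p4 %in% p5))
  }
})

test_that("contact conservation checks every partner in the subject row", {
  # query of 8 residues; contacts of residue 4 are {2, 7}
  atoms <- data.frame(resno = 1:8,
                      x = c(0, 10, 20, 12, 40, 50, 14, 70),
                      y = c(0, 4, 0, 0, 0, 0, 4, 0), z = 0)
  cm <- contact_map(atoms, 5)
  expect_equal(contacts_of(cm, 4), c(2L, 7L))
  qrow <- "ABCDEFGH"
  expect_true(contacts_conserved(
    aligned_pair("q", "s", qrow, "ABCXEFGH"), 4, cm))
  # partner 7 differs
  expect_false(contacts_conserved(
    aligned_pair("q", "s", qrow, "ABCXEFYH"), 4, cm))
  # partner aligned to a gap counts as different
  expect_false(contacts_conserved(
    aligned_pair("q", "s", qrow, "ABCXEF-H"), 4, cm))
  # isolated residue passes vacuously
  expect_true(contacts_conserved(
    aligned_pair("q", "s", qrow, "ABCDEXGH"), 6, cm))
  expect_error(contacts_conserved(
    aligned_pair("q", "s", qrow, "ABCXEFGH"), 99, cm),
    class = "varvote_unresolved_error")
})

test_that("build_neutral_set keeps the highest-identity source per variant", {
  query <- reference_sequence("q", "MKTAYIAKQRQISFVKSHFSRQ")
  # both homologs carry S17A; subjB is the closer source
  hi <- aligned_pair("q", "subjB", "MKTAYIAKQRQISFVKSHFSRQ",
                     "MKTAYIAKQRQISFVKAHFSRQ")
  lo <- aligned_pair("q", "subjA", "MKTAYIAKQRQISFVKSHFSRQ",
                     "MKTAYIAKQRQISFVKAHFSRA")
  expect_true(hi$percent_identity > lo$percent_identity)
  ns <- build_neutral_set(query, list(lo, hi))
  row <- ns$accepted[ns$accepted$position == 17, ]
  expect_equal(nrow(row), 1L)
  expect_equal(row$subject_id, "subjB")   # higher identity wins
  # equal identity: lexicographically smaller subject id wins
  twin1 <- aligned_pair("q", "zeta", "MKTAYIAKQRQISFVKSHFSRQ",
                        "MKTAYIAKQRQISFVKAHFSRQ")
  twin2 <- aligned_pair("q", "alpha", "MKTAYIAKQRQISFVKSHFSRQ",
                        "MKTAYIAKQRQISFVKAHFSRQ")
  ns2 <- build_neutral_set(query, list(twin1, twin2))
  expect_equal(ns2$accepted$subject_id, "alpha")
})

test_that("candidates from low-identity pairs are rejected with a reason", {
  query <- reference_sequence("q", "MKTAYIAKQRQISFVKSHFSRQ")
  # ~50% identity pair
  far <- aligned_pair("q", "far", "MKTAYIAKQRQISFVKSHFSRQ",
                      "MKTAYIAKQRQWWWWWWWWWWW")
  ns <- build_neutral_set(query, list(far))
  expect_equal(nrow(ns$accepted), 0L)
  expect_true(all(ns$candidates$reason == "identity_at_or_below_threshold"))
  # identity threshold is strict: identity exactly at the cut is rejected
  q10 <- reference_sequence("q", "AAAAAAAAAACCCCCCCCCC")
  s90 <- aligned_pair("q", "s", "AAAAAAAAAACCCCCCCCCC",
                      "AAAAAAAAAACCCCCCCCCW")
  expect_equal(s90$percent_identity, 95)
  ns90 <- build_neutral_set(q10, list(s90),
                            config = run_config(identity_min = 95))
  expect_equal(nrow(ns90$accepted), 0L)
})

test_that("planted synthetic homolog pairs are recovered exactly", {
  set.seed(31)
  for (i in 1:25) {
    outs <- sample(c("pass", "fail_flank", "fail_gap", "fail_contacts"),
                   sample(1:4, 1), replace = TRUE)
    gen <- gen_homolog_pair(homolog_spec(sample(250:320, 1),
                                         sample(91:97, 1), outs,
                                         seed = 5000 + i))
    ns <- build_neutral_set(gen$query, list(gen$pair),
                            structure = gen$structure)
    got <- ns$accepted[, c("ref_aa", "position", "alt_aa")]
    rownames(got) <- NULL
    expect_identical(got, expected_accepted(gen))
    # per-candidate filter booleans match the planted truth
    m <- merge(gen$truth, ns$candidates, by = "position")
    expect_equal(m$flank_ok.y, m$flank_ok.x)
    expect_equal(m$gap_ok.y, m$gap_ok.x)
    expect_equal(m$contacts_ok.y, m$contacts_ok.x)
  }
})

test_that("filters are monotone: removing one only enlarges the set", {
  gen <- gen_homolog_pair(homolog_spec(
    300, 94, c("pass", "fail_flank", "fail_gap", "fail_contacts"),
    seed = 99))
  with_struct <- build_neutral_set(gen$query, list(gen$pair),
                                   structure = gen$structure)
  no_contact_filter <- build_neutral_set(gen$query, list(gen$pair))
  key <- function(df) paste(df$ref_aa, df$position, df$alt_aa)
  expect_true(all(key(with_struct$accepted) %in%
                    key(no_contact_filter$accepted)))
  # tightening the identity threshold never adds accepted variants
  loose <- build_neutral_set(gen$query, list(gen$pair),
                             structure = gen$structure,
                             config = run_config(identity_min = 80))
  tight <- build_neutral_set(gen$query, list(gen$pair),
                             structure = gen$structure,
                             config = run_config(identity_min = 95))
  expect_true(all(key(tight$accepted) %in% key(loose$accepted)))
  # accepted implies every filter boolean
  acc <- with_struct$accepted
  expect_true(all(acc$flank_ok & acc$gap_ok & acc$contacts_ok &
                    acc$identity_ok))
})

test_that("unaligned homologs are aligned internally before filtering", {
  query <- reference_sequence("q", "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ")
  homolog <- reference_sequence("h", "MKTAYIAKQRQISFVKAHFSRQLEERLGLIEVQ")
  ns <- build_neutral_set(query, list(homolog),
                          config = run_config(identity_min = 90))
  expect_equal(nrow(ns$accepted), 1L)
  expect_equal(ns$accepted$position, 17L)
  expect_equal(ns$accepted$ref_aa, "S")
  expect_equal(ns$accepted$alt_aa, "A")
})

test_that("structures round-trip through PDB text with altloc resolution", {
  toy <- gen_toy_structure(8, contact_spec = list(c(2, 6)), seed = 4)
  pdb <- tempfile(fileext = ".pdb")
  write_pdb(toy$atoms, pdb)
  st <- read_structure(pdb)
  expect_equal(nrow(st$atoms), nrow(toy$atoms))
  cm <- contact_map(st, 5)
  expect_equal(contact_pairs(cm), toy$expected_pairs)
  expect_error(read_structure(tempfile()), class = "varvote_io_error")
})
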