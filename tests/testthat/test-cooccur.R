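test_that("dictionary matching finds enzyme and disease mentions with spans", {
  title <- "The HIV-1 protease as a therapeutic target for AIDS"
  em <- find_entities(title, tiny_enzyme_lexicon())
  dm <- find_entities(title, tiny_disease_lexicon())
  expect_equal(em$concept_id, "3.4.23.16")
  expect_equal(em$surface, "HIV-1 protease")
  expect_equal(dm$concept_id, "D000163")
  expect_equal(substr(title, dm$start + 1, dm$end), "AIDS")

  expect_equal(nrow(find_entities("nothing to see here",
                                  tiny_enzyme_lexicon())), 0L)
})

test_that("longest-leftmost wins and consumed tokens cannot restart a match", {
  # lexicon has both "protease" and "HIV-1 protease"
  m <- find_entities("HIV-1 protease inhibitors", tiny_enzyme_lexicon())
  expect_equal(m$concept_id, "3.4.23.16")   # only the longer match
  # bare "protease" elsewhere still matches
  m2 <- find_entities("a protease and the HIV-1 protease", tiny_enzyme_lexicon())
  expect_equal(m2$concept_id, c("3.4.21.1", "3.4.23.16"))
})

test_that("short acronyms match case-sensitively, longer terms do not", {
  lex <- tiny_enzyme_lexicon()
  expect_equal(nrow(find_entities("AAA was measured", lex)), 1L)
  expect_equal(nrow(find_entities("aaa was measured", lex)), 0L)
  expect_equal(nrow(find_entities("Aaa was measured", lex)), 0L)
  expect_equal(nrow(find_entities("ALPHA-GALACTOSIDASE deficiency", lex)), 1L)
})

test_that("matcher equals the brute-force window oracle on planted texts", {
  set.seed(42)
  entries <- c("kinase alpha", "kinase", "foo-bar", "ABC", "long term name",
               "beta unit", "gamma")
  ids <- sprintf("1.1.1.%d", seq_along(entries))
  lex <- lexicon(entries, ids, "enzyme")
  filler <- c("the", "of", "cells", "with", "study", "term", "name", "alpha",
              "Beta", "abc", "in", "measured")
  for (i in 1:150) {
    text <- random_planted_text(entries, filler, sample(3:30, 1))
    expect_identical(find_entities(text, lex), brute_force_entities(text, lex),
                     label = paste("text:", text))
  }
})

test_that("co-occurrence requires both entity classes in the same unit", {
  elex <- tiny_enzyme_lexicon(); dlex <- tiny_disease_lexicon()
  refs <- data.frame(
    ref_id = c("r1", "r2", "r3"),
    title = c("A study of gene expression",
              "The HIV-1 protease as a therapeutic target for AIDS",
              "Deficiency of alpha-galactosidase only"),
    abstract = c("Cells were cultured. Results are shown.",
                 "", "No disease is mentioned here."),
    stringsAsFactors = FALSE)
  recs <- find_cooccurrences(refs, elex, dlex)
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$ref_id, "r2")
  expect_equal(recs[[1]]$unit_index, 0L)
  expect_gte(nrow(recs[[1]]$enzyme_mentions), 1L)
  expect_gte(nrow(recs[[1]]$disease_mentions), 1L)

  # two enzymes, zero diseases -> no record
  refs2 <- data.frame(ref_id = "x", title = "protease and NADPH oxidase",
                      abstract = "", stringsAsFactors = FALSE)
  expect_length(find_cooccurrences(refs2, elex, dlex), 0L)
})

test_that("every co-occurrence record has non-empty mention lists", {
  lx <- generate_lexicons(40, 30, seed = 21)
  cs <- generate_corpus(corpus_spec(60, 60, 20, seed = 22), lx)
  recs <- find_cooccurrences(cs$references, lx$enzyme, lx$disease)
  for (r in recs) {
    expect_gt(nrow(r$enzyme_mentions), 0L)
    expect_gt(nrow(r$disease_mentions), 0L)
    expect_true(all(r$enzyme_mentions$end <= nchar(r$text)))
    expect_true(all(r$disease_mentions$end <= nchar(r$text)))
  }
  expect_error(cooccurrence_record("r", 0, "t",
                                   data.frame(start = integer(0), end = integer(0)),
                                   data.frame(start = 0L, end = 1L)),
               "at least one mention")
})

test_that("recognition scoring follows the unit-level confusion definitions", {
  units <- data.frame(ref_id = "r", unit_index = 0:9,
                      cooccur = rep(c(TRUE, FALSE), c(4, 6)))
  cm <- evaluate_recognition(units, units)
  expect_equal(unclass(cm)[c("tp", "tn", "fp", "fn")],
               list(tp = 4, tn = 6, fp = 0, fn = 0))

  allneg <- units; allneg$cooccur <- FALSE
  cm2 <- evaluate_recognition(allneg, units)
  expect_equal(cm2$fn, 4); expect_equal(cm2$tn, 6)

  # one entity present but flagged as co-occurring counts as a false positive
  gold1 <- data.frame(ref_id = "r", unit_index = 0L, cooccur = FALSE)
  pred1 <- data.frame(ref_id = "r", unit_index = 0L, cooccur = TRUE)
  expect_equal(evaluate_recognition(pred1, gold1)$fp, 1)

  bad <- data.frame(ref_id = "r", unit_index = 10L, cooccur = TRUE)
  expect_error(evaluate_recognition(bad, units), "differ")
})
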