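test_that("synthetic lexicons have the requested composition and are seeded", {
  lx <- generate_lexicons(10, 8, seed = 71, homonym_fraction = 0)
  expect_equal(length(unique(lx$enzyme$entries$concept_id)), 10L)
  expect_equal(length(unique(lx$disease$entries$concept_id)), 8L)
  expect_true(all(grepl("^[0-9]+\\.[0-9]+\\.[0-9]+\\.[0-9]+$",
                        lx$enzyme$entries$concept_id)))
  expect_true(all(table(lx$enzyme$entries$concept_id) <= 3))

  lx2 <- generate_lexicons(10, 8, seed = 71, homonym_fraction = 0)
  expect_identical(lx$enzyme$entries, lx2$enzyme$entries)
  expect_identical(lx$disease$entries, lx2$disease$entries)

  hom <- generate_lexicons(100, 20, seed = 72, homonym_fraction = 0.1)
  manifest <- attr(hom, "manifest")
  expect_length(manifest$homonyms, 10L)
  expect_true(all(manifest$homonyms %in% hom$enzyme$entries$surface))
  expect_true(all(grepl("^[A-Z]{3}$", manifest$homonyms)))
})

test_that("generated corpora honour the stratum counts and label prevalences", {
  lx <- generate_lexicons(60, 40, seed = 81)
  sp <- corpus_spec(120, 300, 60, seed = 82)
  cs <- generate_corpus(sp, lx)
  strata <- table(cs$gold$units$stratum)
  expect_equal(as.integer(strata[c("enzyme_only", "both", "random")]),
               c(120L, 300L, 60L))
  # labels only on co-occurrence units, at roughly the requested prevalence
  labs <- relenz:::.gold_label_matrix(cs$gold)
  expect_true(all(cs$gold$units$cooccur[rowSums(labs) > 0]))
  p_hat <- sum(labs[, "causal_interaction"]) / 300
  expect_lt(abs(p_hat - sp$prevalences[["causal_interaction"]]), 0.08)
  expect_error(corpus_spec(10, 10, 10), "seed")
})

test_that("the same spec and seed give a byte-identical corpus", {
  lx <- generate_lexicons(30, 20, seed = 91)
  a <- generate_corpus(corpus_spec(40, 40, 20, seed = 92), lx)
  b <- generate_corpus(corpus_spec(40, 40, 20, seed = 92), lx)
  expect_identical(a$references, b$references)
  expect_identical(a$gold$units, b$gold$units)
  expect_identical(a$gold$mentions, b$gold$mentions)
  expect_identical(a$gold$labels, b$gold$labels)

  d1 <- tempfile(); d2 <- tempfile()
  write_synthetic_corpus(a, d1); write_synthetic_corpus(b, d2)
  expect_identical(readLines(file.path(d1, "corpus.tsv")),
                   readLines(file.path(d2, "corpus.tsv")))
  expect_identical(readLines(file.path(d1, "gold.tsv")),
                   readLines(file.path(d2, "gold.tsv")))
})

test_that("gold spans point at the planted surface forms", {
  lx <- generate_lexicons(30, 20, seed = 101)
  cs <- generate_corpus(corpus_spec(30, 60, 10, seed = 102), lx)
  g <- cs$gold
  key <- paste(g$units$ref_id, g$units$unit_index)
  for (i in seq_len(nrow(g$mentions))) {
    m <- g$mentions[i, ]
    text <- g$units$text[match(paste(m$ref_id, m$unit_index), key)]
    expect_equal(tolower(substr(text, m$start + 1, m$end)),
                 tolower(m$surface))
  }
})

test_that("gold annotations survive a TSV round trip", {
  lx <- generate_lexicons(20, 15, seed = 111)
  cs <- generate_corpus(corpus_spec(15, 30, 5, seed = 112), lx)
  path <- tempfile()
  write_gold(cs$gold, path)
  back <- read_gold(path)
  expect_equal(back$units[, c("ref_id", "unit_index", "text", "cooccur")],
               cs$gold$units[, c("ref_id", "unit_index", "text", "cooccur")])
  expect_equal(back$mentions[, c("ref_id", "unit_index", "entity_class",
                                 "concept_id", "start", "end")],
               cs$gold$mentions[, c("ref_id", "unit_index", "entity_class",
                                    "concept_id", "start", "end")])
  expect_equal(back$labels, cs$gold$labels)
})

test_that("matching a generated corpus recovers the planted co-occurrences", {
  lx <- generate_lexicons(50, 40, seed = 121, homonym_fraction = 0.1)
  cs <- generate_corpus(corpus_spec(150, 150, 150, seed = 122), lx)
  homonyms <- cs$manifest$homonyms
  recs <- find_cooccurrences(cs$references, lx$enzyme, lx$disease)
  got <- vapply(recs, function(r) paste(r$ref_id, r$unit_index), "")
  planted <- with(cs$gold$units[cs$gold$units$cooccur, ],
                  paste(ref_id, unit_index))
  expect_true(all(planted %in% got))
  # any extra unit must be explained by a planted homonym acronym
  extra <- setdiff(got, planted)
  for (k in extra) {
    r <- recs[[match(k, got)]]
    expect_true(any(r$enzyme_mentions$surface %in% homonyms),
                label = paste("unexplained unit", k))
  }
  # after blacklisting the manifest homonyms, recovery is exact
  clean <- apply_blacklist(lx$enzyme, homonyms)
  recs2 <- find_cooccurrences(cs$references, clean, lx$disease)
  got2 <- vapply(recs2, function(r) paste(r$ref_id, r$unit_index), "")
  expect_setequal(got2, planted)
})
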