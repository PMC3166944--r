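# Seeded synthetic lexicons and gold-annotated corpora.
#
# The generator emulates the composition of the expert-annotated train/test
# corpus: 2,500 units containing at least one enzyme entity, 2,000 units
# containing an enzyme-disease co-occurrence, and 500 unconstrained units,
# with non-exclusive category labels at prevalences proportional to
# 1,382 : 587 : 477 : 366 positives out of 5,031. Entity surface forms are
# pronounceable invented names drawn from a syllable inventory disjoint
# from the filler vocabulary, so every dictionary match in generated text
# is either planted or a deliberately planted short-acronym homonym (all
# homonyms are listed in the manifest). Class separability is controlled by
# a cue-word strength s: a category's cue phrase appears in its positives
# with probability s + (1 - s)/4 and leaks into negatives with probability
# (1 - s)/4, so s = 1 gives perfectly separable classes and s = 0 gives
# label-independent text.

.syllables_lexicon <- as.vector(outer(c("b", "d", "g", "k", "p", "t", "z"),
                                      c("a", "e", "i", "o", "u"), paste0))
.syllables_filler <- as.vector(outer(c("f", "h", "j", "l", "m", "n", "r",
                                       "s", "v", "w"),
                                     c("a", "e", "i", "o", "u"), paste0))

.make_words <- function(n, syllables, min_syl = 2L, max_syl = 4L) {
  out <- character(0)
  while (length(out) < n) {
    batch <- vapply(seq_len(2L * (n - length(out)) + 10L), function(i)
      paste(sample(syllables, sample(min_syl:max_syl, 1L), replace = TRUE),
            collapse = ""), "")
    out <- unique(c(out, batch))
  }
  out[seq_len(n)]
}

.cue_phrases <- list(
  causal_interaction = c("caused by", "deficiency of", "mutation results in",
                         "induces", "leads to"),
  ongoing_research = c("potential role", "further studies needed",
                       "under investigation", "preliminary evidence",
                       "remains unclear"),
  diagnostic_usage = c("marker", "diagnosis of", "prognostic tool",
                       "measurement of activity", "assay"),
  therapeutic_application = c("inhibitor", "treatment of", "drug target",
                              "therapy", "therapeutic strategy")
)

#' Generate paired synthetic enzyme and disease lexicons
#'
#' Pronounceable unique surface forms with 1-3 synonyms per concept, valid
#' synthetic 4-field EC numbers for enzymes and opaque `Dnnnnnn` concept
#' IDs for diseases. A configurable fraction of enzyme concepts receives an
#' extra short all-caps acronym synonym that is also injected into the
#' filler vocabulary by [generate_corpus()], planting exactly the homonym
#' ambiguity a blacklist is meant to remove; the planted acronyms are
#' reported in the `manifest` attribute.
#'
#' @param n_enzymes,n_diseases number of concepts (>= 1).
#' @param seed integer seed; identical seeds give identical lexicons.
#' @param homonym_fraction fraction of enzyme concepts given an acronym
#'   homonym synonym.
#' @return list with components `enzyme` and `disease` ([lexicon()]
#'   objects); `attr(, "manifest")` records sizes and planted homonyms.
#' @export
generate_lexicons <- function(n_enzymes = 300L, n_diseases = 200L, seed = 1L,
                              homonym_fraction = 0.02) {
  stopifnot(n_enzymes >= 1L, n_diseases >= 1L)
  set.seed(as.integer(seed))
  n_stems <- 4L * (n_enzymes + n_diseases)
  stems <- .make_words(n_stems, .syllables_lexicon)
  si <- 0L
  next_stem <- function() { si <<- si + 1L; stems[si] }

  ec <- character(0)
  while (length(ec) < n_enzymes) {
    ec <- unique(c(ec, sprintf("%d.%d.%d.%d", sample(1:6, n_enzymes, TRUE),
                               sample(1:25, n_enzymes, TRUE),
                               sample(1:30, n_enzymes, TRUE),
                               sample(1:99, n_enzymes, TRUE))))
  }
  ec <- ec[seq_len(n_enzymes)]
  esurf <- character(0); eid <- character(0)
  for (i in seq_len(n_enzymes)) {
    nsyn <- sample(1:3, 1L)
    syn <- c(paste0(next_stem(), "ase"),
             if (nsyn >= 2L) paste0(next_stem(), "in"),
             if (nsyn >= 3L) paste(next_stem(), "enzyme"))
    esurf <- c(esurf, syn); eid <- c(eid, rep(ec[i], length(syn)))
  }
  n_hom <- round(homonym_fraction * n_enzymes)
  homonyms <- character(0)
  if (n_hom > 0L) {
    pool <- apply(expand.grid(LETTERS[1:13], LETTERS[1:13], LETTERS[1:13]),
                  1L, paste, collapse = "")
    homonyms <- sample(pool, n_hom)
    esurf <- c(esurf, homonyms)
    eid <- c(eid, sample(ec, n_hom))
  }

  did <- sprintf("D%06d", sample.int(999999L, n_diseases))
  dsurf <- character(0); did_all <- character(0)
  for (i in seq_len(n_diseases)) {
    nsyn <- sample(1:3, 1L)
    syn <- c(paste0(next_stem(), sample(c("itis", "oma", "osis"), 1L)),
             if (nsyn >= 2L) paste(next_stem(), "syndrome"),
             if (nsyn >= 3L) paste(next_stem(), "disease"))
    dsurf <- c(dsurf, syn); did_all <- c(did_all, rep(did[i], length(syn)))
  }
  out <- list(enzyme = lexicon(esurf, eid, "enzyme"),
              disease = lexicon(dsurf, did_all, "disease"))
  structure(out, manifest = list(
    n_enzymes = n_enzymes, n_diseases = n_diseases, seed = seed,
    homonym_fraction = homonym_fraction, homonyms = homonyms))
}

#' Specification of a synthetic corpus
#'
#' Defaults mirror the annotated-corpus protocol: 2,500 enzyme-only units,
#' 2,000 enzyme+disease co-occurrence units, 500 unconstrained units, and
#' category label prevalences proportional to 1,382 / 587 / 477 / 366
#' positives out of 5,031 units.
#'
#' @param n_enzyme_only,n_both,n_random stratum sizes (>= 0).
#' @param prevalences named numeric vector of per-category label
#'   probabilities among co-occurrence units.
#' @param cue_strength real in `[0, 1]`; see [generate_corpus()].
#' @param n_filler filler vocabulary size (Zipf-distributed tokens).
#' @param seed mandatory integer seed.
#' @return an object of class `"corpus_spec"`.
#' @export
corpus_spec <- function(n_enzyme_only = 2500L, n_both = 2000L, n_random = 500L,
                        prevalences = c(causal_interaction = 1382,
                                        ongoing_research = 587,
                                        diagnostic_usage = 477,
                                        therapeutic_application = 366) / 5031,
                        cue_strength = 0.8, n_filler = 2000L, seed) {
  if (missing(seed)) stop("a seed is mandatory for a corpus spec")
  stopifnot(n_enzyme_only >= 0L, n_both >= 0L, n_random >= 0L,
            all(prevalences >= 0 & prevalences <= 1),
            setequal(names(prevalences), relation_categories()),
            cue_strength >= 0, cue_strength <= 1, n_filler >= 50L)
  structure(list(n_enzyme_only = as.integer(n_enzyme_only),
                 n_both = as.integer(n_both), n_random = as.integer(n_random),
                 prevalences = prevalences[relation_categories()],
                 cue_strength = cue_strength, n_filler = as.integer(n_filler),
                 seed = as.integer(seed)),
            class = "corpus_spec")
}

# sample nf filler words with Zipf(1) weights
.sample_filler <- function(vocab, probs, nf) {
  sample(vocab, nf, replace = TRUE, prob = probs)
}

#' Generate a gold-annotated synthetic corpus
#'
#' Builds the three strata of `spec`, assembles the units into references
#' (one unit becomes the title, the rest abstract sentences), and records
#' every planted mention span and category label. Category-positive units
#' draw a cue phrase of their category with probability
#' `cue_strength + (1 - cue_strength)/4`; the same phrase leaks into
#' non-positive co-occurrence units with probability
#' `(1 - cue_strength)/4`, so separability is tunable from perfect
#' (strength 1) to none (strength 0). All other tokens are filler words
#' drawn Zipf-distributed from a vocabulary disjoint from the lexicon
#' surface forms, except the planted homonym acronyms listed in the lexicon
#' manifest, which are injected into the filler vocabulary on purpose.
#'
#' @param spec a [corpus_spec()].
#' @param lexicons output of [generate_lexicons()].
#' @return a list of class `"synthetic_corpus"`: `references` (reference
#'   set), `gold` ([gold_corpus()] covering every unit), `manifest`
#'   (generation parameters, stratum counts, label counts, homonyms).
#' @export
generate_corpus <- function(spec, lexicons) {
  stopifnot(inherits(spec, "corpus_spec"))
  enz <- lexicons$enzyme$entries; dis <- lexicons$disease$entries
  if (nrow(enz) == 0L || nrow(dis) == 0L) stop("lexicons must be non-empty")
  homonyms <- attr(lexicons, "manifest")$homonyms
  set.seed(spec$seed)

  filler <- .make_words(spec$n_filler, .syllables_filler)
  # avoid (vanishingly unlikely) collisions with lexicon tokens
  lex_tokens <- unique(unlist(strsplit(c(enz$norm_key, dis$norm_key), " ")))
  filler <- setdiff(filler, lex_tokens)
  vocab <- c(filler, homonyms)
  # Zipf(1) filler weights; planted acronym homonyms get a mid-rank weight
  # (short acronyms are common tokens in real abstracts, which is exactly
  # why they are the dominant homonym source).
  probs <- c(1 / seq_along(filler), rep(1 / 30, length(homonyms)))
  # plain enzyme synonyms only (acronym homonyms are planted via filler)
  enz_plain <- enz[!(enz$surface %in% homonyms), , drop = FALSE]

  cats <- relation_categories()
  p_cue_pos <- spec$cue_strength + (1 - spec$cue_strength) / 4
  p_cue_neg <- (1 - spec$cue_strength) / 4

  n_total <- spec$n_enzyme_only + spec$n_both + spec$n_random
  stratum <- c(rep("enzyme_only", spec$n_enzyme_only),
               rep("both", spec$n_both),
               rep("random", spec$n_random))
  units <- vector("list", n_total)
  for (u in seq_len(n_total)) {
    parts <- character(0)
    ments <- list()
    add_mention <- function(entry, class_) {
      ments[[length(ments) + 1L]] <<- c(class_, entry$concept_id, entry$surface)
      entry$surface
    }
    labels <- character(0)
    if (stratum[u] == "both") {
      e <- enz_plain[sample.int(nrow(enz_plain), 1L), ]
      d <- dis[sample.int(nrow(dis), 1L), ]
      labels <- cats[stats::runif(4) < spec$prevalences]
      cues <- character(0)
      for (cat_ in cats) {
        p <- if (cat_ %in% labels) p_cue_pos else p_cue_neg
        if (stats::runif(1) < p)
          cues <- c(cues, sample(.cue_phrases[[cat_]], 1L))
      }
      parts <- c(add_mention(e, "enzyme"), "is linked with",
                 add_mention(d, "disease"), cues,
                 .sample_filler(vocab, probs, sample(3:8, 1L)))
    } else if (stratum[u] == "enzyme_only") {
      e <- enz_plain[sample.int(nrow(enz_plain), 1L), ]
      parts <- c(add_mention(e, "enzyme"), "activity in",
                 .sample_filler(vocab, probs, sample(4:9, 1L)))
    } else {
      # unconstrained stratum: entities occur only by chance, as in records
      # collected without any precondition
      parts <- c("report on", .sample_filler(vocab, probs, sample(5:10, 1L)))
      if (stats::runif(1) < 0.2) {
        e <- enz_plain[sample.int(nrow(enz_plain), 1L), ]
        parts <- append(parts, add_mention(e, "enzyme"), after = 2L)
      }
      if (stats::runif(1) < 0.3) {
        d <- dis[sample.int(nrow(dis), 1L), ]
        parts <- append(parts, add_mention(d, "disease"),
                        after = length(parts) - 1L)
      }
    }
    # char offsets of the parts when joined by single spaces
    off <- cumsum(c(0L, nchar(parts[-length(parts)]) + 1L))
    text <- paste(parts, collapse = " ")
    mdf <- NULL
    if (length(ments) > 0L) {
      mm <- do.call(rbind, ments)
      pidx <- match(mm[, 3L], parts)
      mdf <- data.frame(entity_class = mm[, 1L], concept_id = mm[, 2L],
                        surface = mm[, 3L], start = off[pidx],
                        end = off[pidx] + nchar(mm[, 3L]),
                        stringsAsFactors = FALSE)
    }
    units[[u]] <- list(text = text, stratum = stratum[u],
                       mentions = mdf, labels = labels)
  }

  units <- units[sample.int(n_total)]
  # pack shuffled units into references: 1 title + 2-4 abstract sentences
  urow <- list(); mrow <- list(); lrow <- list(); refs <- list()
  u <- 1L; r <- 0L
  while (u <= n_total) {
    r <- r + 1L
    ref_id <- sprintf("SYN%06d", r)
    nu <- min(sample(3:5, 1L), n_total - u + 1L)
    sents <- character(0)
    for (j in seq_len(nu)) {
      it <- units[[u]]
      cap <- paste0(toupper(substr(it$text, 1L, 1L)), substr(it$text, 2L, nchar(it$text)))
      txt <- if (j == 1L) cap else paste0(cap, ".")
      if (j > 1L) sents <- c(sents, txt)
      ui <- j - 1L
      urow[[length(urow) + 1L]] <- data.frame(
        ref_id = ref_id, unit_index = ui, text = txt,
        stratum = it$stratum, stringsAsFactors = FALSE)
      if (!is.null(it$mentions) && nrow(it$mentions) > 0L) {
        m <- it$mentions; m$ref_id <- ref_id; m$unit_index <- ui
        mrow[[length(mrow) + 1L]] <- m
      }
      for (l in it$labels)
        lrow[[length(lrow) + 1L]] <- data.frame(
          ref_id = ref_id, unit_index = ui, category = l,
          stringsAsFactors = FALSE)
      if (j == 1L) title <- txt
      u <- u + 1L
    }
    refs[[r]] <- data.frame(ref_id = ref_id, title = title,
                            abstract = paste(sents, collapse = " "),
                            stringsAsFactors = FALSE)
  }
  empty_m <- data.frame(ref_id = character(0), unit_index = integer(0),
                        entity_class = character(0), concept_id = character(0),
                        surface = character(0), start = integer(0),
                        end = integer(0), stringsAsFactors = FALSE)
  empty_l <- data.frame(ref_id = character(0), unit_index = integer(0),
                        category = character(0), stringsAsFactors = FALSE)
  mentions <- if (length(mrow)) do.call(rbind, mrow) else empty_m
  mentions <- mentions[, c("ref_id", "unit_index", "entity_class",
                           "concept_id", "surface", "start", "end")]
  gold <- gold_corpus(do.call(rbind, urow), mentions,
                      if (length(lrow)) do.call(rbind, lrow) else empty_l)
  labs <- .gold_label_matrix(gold)
  manifest <- list(
    spec = unclass(spec),
    n_references = r, n_units = n_total,
    strata = as.list(table(gold$units$stratum)),
    label_counts = as.list(colSums(labs)),
    homonyms = homonyms)
  structure(list(references = do.call(rbind, refs), gold = gold,
                 manifest = manifest),
            class = "synthetic_corpus")
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  cat(sprintf("<synthetic corpus: %d references, %d units (seed %d)>\n",
              nrow(x$references), nrow(x$gold$units), x$manifest$spec$seed))
  invisible(x)
}

#' Write a synthetic corpus to disk
#'
#' Emits the reference corpus in a chosen dialect, the gold annotation TSV
#' and a JSON manifest of the generation parameters.
#'
#' @param corpus a [generate_corpus()] result.
#' @param dir output directory (created if missing).
#' @param dialect corpus dialect, `"tsv"` or `"jsonl"`.
#' @return the directory path, invisibly.
#' @export
write_synthetic_corpus <- function(corpus, dir, dialect = c("tsv", "jsonl")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_references(corpus$references,
                   file.path(dir, paste0("corpus.", dialect)), dialect)
  write_gold(corpus$gold, file.path(dir, "gold.tsv"))
  jsonlite::write_json(corpus$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
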