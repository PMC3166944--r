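# Fixtures built in code and independent brute-force oracles used to
# cross-check the optimized implementations.

tiny_enzyme_lexicon <- function() {
  lexicon(c("HIV-1 protease", "protease", "alpha-galactosidase",
            "AAA", "lethal toxin", "NADPH oxidase"),
          c("3.4.23.16", "3.4.21.1", "3.2.1.22",
            "3.5.1.13", "3.4.24.83", "1.6.3.1"),
          "enzyme")
}

tiny_disease_lexicon <- function() {
  lexicon(c("AIDS", "Fabry disease", "chronic granulomatous disease",
            "prostate cancer"),
          c("D000163", "D000795", "D006105", "D011471"),
          "disease")
}

# Oracle matcher: enumerate every token window against every entry, then
# resolve left-to-right taking the longest match at each unconsumed
# position. Independent of the first-token index used by find_entities().
brute_force_entities <- function(text, lex) {
  tk <- tokenize_spans(text)
  n <- nrow(tk)
  keys <- lex$entries$norm_key
  cand <- list()
  for (i in seq_len(n)) for (j in i:n) {
    key <- paste(tk$norm[i:j], collapse = " ")
    hit <- which(keys == key)
    if (length(hit) > 0L)
      cand[[length(cand) + 1L]] <- list(i = i, j = j, rows = hit)
  }
  out <- list()
  pos <- 1L
  while (pos <= n) {
    here <- Filter(function(c) c$i == pos, cand)
    if (length(here) == 0L) { pos <- pos + 1L; next }
    lens <- vapply(here, function(c) c$j - c$i + 1L, 1L)
    best <- here[[which.max(lens)]]
    for (cid in unique(lex$entries$concept_id[best$rows]))
      out[[length(out) + 1L]] <- data.frame(
        entity_class = lex$entity_class, concept_id = cid,
        surface = substr(text, tk$start[best$i] + 1L, tk$end[best$j]),
        start = tk$start[best$i], end = tk$end[best$j],
        stringsAsFactors = FALSE)
    pos <- best$j + 1L
  }
  if (length(out) == 0L)
    return(data.frame(entity_class = character(0), concept_id = character(0),
                      surface = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end, res$concept_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Oracle metrics: recompute every measure directly from a vector of
# (prediction, truth) pairs, formula by formula.
brute_force_metrics <- function(pred, truth) {
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  tn <- sum(!pred & !truth); fn <- sum(!pred & truth)
  div <- function(a, b) if (b == 0) 0 else a / b
  precision <- div(tp, tp + fp); recall <- div(tp, tp + fn)
  c(precision = precision,
    recall = recall,
    accuracy = (tp + tn) / length(pred),
    specificity = div(tn, tn + fp),
    f1 = div(2 * precision * recall, precision + recall),
    mcc = div(tp * tn - fp * fn,
              sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)),
    fpr = div(fp, fp + tn))
}

# Build a record object directly (bypassing matching) for feature tests.
make_record <- function(text, enzyme_spans = NULL, disease_spans = NULL) {
  mk <- function(spans, class_) {
    if (is.null(spans))
      return(data.frame(entity_class = character(0), concept_id = character(0),
                        surface = character(0), start = integer(0),
                        end = integer(0), stringsAsFactors = FALSE))
    data.frame(entity_class = class_,
               concept_id = paste0("ID", seq_len(nrow(spans))),
               surface = substr(text, spans[, 1L] + 1L, spans[, 2L]),
               start = spans[, 1L], end = spans[, 2L],
               stringsAsFactors = FALSE)
  }
  structure(list(ref_id = "R1", unit_index = 0L, text = text,
                 enzyme_mentions = mk(enzyme_spans, "enzyme"),
                 disease_mentions = mk(disease_spans, "disease")),
            class = "gold_unit")
}

# Random planted-term text for matcher equivalence testing. Returns the
# text; ground truth comes from the brute-force oracle.
random_planted_text <- function(lex_entries, filler, n_tokens) {
  parts <- character(0)
  while (length(parts) < n_tokens) {
    if (stats::runif(1) < 0.3)
      parts <- c(parts, sample(lex_entries, 1L))
    else
      parts <- c(parts, sample(filler, 1L))
  }
  paste(parts, collapse = " ")
}

# Subset a gold corpus by reference IDs (used for train/test splits).
gold_subset <- function(gold, ids) {
  gold_corpus(gold$units[gold$units$ref_id %in% ids,
                         setdiff(names(gold$units), "cooccur")],
              gold$mentions[gold$mentions$ref_id %in% ids, ],
              gold$labels[gold$labels$ref_id %in% ids, ])
}
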