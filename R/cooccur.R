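# Dictionary matching of enzyme and disease mentions in text units, and the
# unit-level co-occurrence conjunction (>= 1 enzyme AND >= 1 disease in the
# same title or abstract sentence) that forms the content basis of the
# relation table.

#' Find entity mentions in a text unit
#'
#' Token-boundary-anchored dictionary matching against a lexicon's
#' normalized token sequences. Among overlapping candidates the
#' longest-leftmost match wins, and a token region consumed by one mention
#' cannot start another mention of the same entity class. An ambiguous
#' surface form mapping to several concept IDs yields one mention per
#' concept at the same span.
#'
#' @param text a single character string (the unit text).
#' @param lex a [lexicon()] object.
#' @return a data.frame with columns `entity_class`, `concept_id`,
#'   `surface` (matched text), `start`, `end` (0-based half-open character
#'   span), sorted by `start`.
#' @export
find_entities <- function(text, lex) {
  stopifnot(inherits(lex, "lexicon"))
  tk <- tokenize_spans(text)
  n <- nrow(tk)
  empty <- data.frame(entity_class = character(0), concept_id = character(0),
                      surface = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  if (n == 0L || length(lex$index) == 0L) return(empty)
  ent_toks <- strsplit(lex$entries$norm_key, " ", fixed = TRUE)
  out <- list(); k <- 0L
  i <- 1L
  while (i <= n) {
    cand <- lex$index[[tk$norm[i]]]
    best_len <- 0L; best <- integer(0)
    for (e in cand) {
      L <- lex$entries$n_tokens[e]
      if (L < best_len || i + L - 1L > n) next
      if (identical(ent_toks[[e]], tk$norm[i:(i + L - 1L)])) {
        if (L > best_len) { best_len <- L; best <- e } else best <- c(best, e)
      }
    }
    if (best_len > 0L) {
      s0 <- tk$start[i]; e0 <- tk$end[i + best_len - 1L]
      for (cid in unique(lex$entries$concept_id[best])) {
        k <- k + 1L
        out[[k]] <- data.frame(entity_class = lex$entity_class,
                               concept_id = cid,
                               surface = substr(text, s0 + 1L, e0),
                               start = s0, end = e0, stringsAsFactors = FALSE)
      }
      i <- i + best_len
    } else i <- i + 1L
  }
  if (k == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end, res$concept_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' A single co-occurrence record
#'
#' @param ref_id,unit_index,text unit identity and text.
#' @param enzyme_mentions,disease_mentions non-empty mention data.frames as
#'   returned by [find_entities()].
#' @return an object of class `"cooccurrence_record"`.
#' @export
cooccurrence_record <- function(ref_id, unit_index, text,
                                enzyme_mentions, disease_mentions) {
  if (nrow(enzyme_mentions) == 0L || nrow(disease_mentions) == 0L)
    stop("a co-occurrence record needs at least one mention of each class")
  structure(list(ref_id = as.character(ref_id),
                 unit_index = as.integer(unit_index),
                 text = as.character(text),
                 enzyme_mentions = enzyme_mentions,
                 disease_mentions = disease_mentions),
            class = "cooccurrence_record")
}

#' @export
print.cooccurrence_record <- function(x, ...) {
  cat(sprintf("<co-occurrence %s#%d: %d enzyme, %d disease mention(s)>\n  %s\n",
              x$ref_id, x$unit_index, nrow(x$enzyme_mentions),
              nrow(x$disease_mentions), x$text))
  invisible(x)
}

#' Find all sentence-level enzyme-disease co-occurrences in a corpus
#'
#' Splits every reference into units (title + abstract sentences), matches
#' both lexicons independently in each unit, and keeps the units containing
#' at least one enzyme and at least one disease mention. The conjunction is
#' strictly unit-level: no cross-sentence co-occurrence.
#'
#' @param refs a reference set (see [as_reference_set()]).
#' @param enzyme_lex,disease_lex [lexicon()] objects.
#' @param units optionally, precomputed [split_corpus()] output.
#' @return a list of [cooccurrence_record()]s ordered by (`ref_id` input
#'   order, `unit_index`), with attribute `n_units` (units scanned).
#' @export
find_cooccurrences <- function(refs, enzyme_lex, disease_lex, units = NULL) {
  if (is.null(units)) units <- split_corpus(refs)
  recs <- list(); k <- 0L
  for (i in seq_len(nrow(units))) {
    em <- find_entities(units$text[i], enzyme_lex)
    if (nrow(em) == 0L) next
    dm <- find_entities(units$text[i], disease_lex)
    if (nrow(dm) == 0L) next
    k <- k + 1L
    recs[[k]] <- cooccurrence_record(units$ref_id[i], units$unit_index[i],
                                     units$text[i], em, dm)
  }
  structure(recs, n_units = nrow(units))
}

#' Tabulate co-occurrence records
#'
#' @param records a list of [cooccurrence_record()]s.
#' @return a data.frame with one row per record: `ref_id`, `unit_index`,
#'   `text`, comma-joined `enzyme_ids` and `disease_ids`, and mention spans
#'   as `start:end` pairs.
#' @export
cooccurrences_table <- function(records) {
  if (length(records) == 0L) {
    return(data.frame(ref_id = character(0), unit_index = integer(0),
                      text = character(0), enzyme_ids = character(0),
                      disease_ids = character(0), enzyme_spans = character(0),
                      disease_spans = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(records, function(r) data.frame(
    ref_id = r$ref_id, unit_index = r$unit_index, text = r$text,
    enzyme_ids = paste(unique(r$enzyme_mentions$concept_id), collapse = ","),
    disease_ids = paste(unique(r$disease_mentions$concept_id), collapse = ","),
    enzyme_spans = paste(sprintf("%d:%d", r$enzyme_mentions$start,
                                 r$enzyme_mentions$end), collapse = ","),
    disease_spans = paste(sprintf("%d:%d", r$disease_mentions$start,
                                  r$disease_mentions$end), collapse = ","),
    stringsAsFactors = FALSE)))
}

#' Score co-occurrence recognition against gold annotation
#'
#' Unit-level confusion bookkeeping: a true positive is a correctly
#' estimated presence of both an enzyme and a disease entity in the unit; a
#' correctly estimated absence of one or both entities is a true negative;
#' flagging a unit as co-occurring when at least one entity is actually
#' missing is a false positive; missing a present co-occurrence is a false
#' negative.
#'
#' @param predicted,gold data.frames with columns `ref_id`, `unit_index`,
#'   `cooccur` (logical), covering the same unit set.
#' @return a [confusion_matrix()].
#' @export
evaluate_recognition <- function(predicted, gold) {
  key <- function(d) paste(d$ref_id, d$unit_index, sep = "\r")
  kp <- key(predicted); kg <- key(gold)
  if (anyDuplicated(kp) || anyDuplicated(kg))
    stop("duplicate units in predicted or gold set")
  if (!setequal(kp, kg)) stop("predicted and gold unit sets differ")
  p <- predicted$cooccur[match(kg, kp)]
  g <- gold$cooccur
  confusion_matrix(tp = sum(p & g), fp = sum(p & !g),
                   tn = sum(!p & !g), fn = sum(!p & g))
}
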