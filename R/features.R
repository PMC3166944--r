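# Preprocessing and tf-idf representation of co-occurrence units.
#
# Entity terms are deleted (removal) or replaced by one generic token per
# mention (replacement) before vectorization, so the classifier learns from
# the surrounding language, not from the particular enzyme or disease named.
# tf-idf weights are tf * ln(D / d_t) followed by Euclidean unit
# normalization, which neutralizes sentence-length effects and makes the
# idf log base immaterial. Deliberately absent: stop-word removal (it
# lowered classification quality in tuning for this task family) and
# stemming.

#' Preprocessing mode for entity terms
#'
#' @param mode `"removal"` (entity tokens deleted, no substitution) or
#'   `"replacement"` (each mention span replaced by exactly one generic
#'   token of its entity class).
#' @param generic_enzyme_token,generic_disease_token distinct placeholder
#'   tokens; they must not occur in the raw corpus vocabulary (the defaults
#'   cannot be produced by the tokenizer, which guarantees that).
#' @return an object of class `"preprocess_mode"`.
#' @export
preprocess_mode <- function(mode = c("removal", "replacement"),
                            generic_enzyme_token = "@ENZYME@",
                            generic_disease_token = "@DISEASE@") {
  mode <- match.arg(mode)
  if (identical(generic_enzyme_token, generic_disease_token))
    stop("generic tokens must be distinct")
  structure(list(mode = mode,
                 generic_enzyme_token = generic_enzyme_token,
                 generic_disease_token = generic_disease_token),
            class = "preprocess_mode")
}

#' Preprocess one co-occurrence unit into tokens
#'
#' Tokenizes the unit text with the lexicon token rules, then deletes every
#' token overlapping a mention span (removal) or substitutes one generic
#' token per mention, in span-start order (replacement). Overlapping
#' cross-class mentions each contribute their own generic token.
#'
#' @param record a [cooccurrence_record()] (or any list with `text`,
#'   `enzyme_mentions`, `disease_mentions`).
#' @param mode a [preprocess_mode()].
#' @return a character vector of tokens.
#' @export
preprocess_unit <- function(record, mode = preprocess_mode("removal")) {
  stopifnot(inherits(mode, "preprocess_mode"))
  tk <- tokenize_spans(record$text)
  span_frame <- function(m, generic) data.frame(
    start = m$start, end = m$end,
    generic = rep(generic, length(m$start)), stringsAsFactors = FALSE)
  spans <- rbind(span_frame(record$enzyme_mentions, mode$generic_enzyme_token),
                 span_frame(record$disease_mentions, mode$generic_disease_token))
  if (nrow(tk) == 0L && nrow(spans) == 0L) return(character(0))
  inside <- rep(FALSE, nrow(tk))
  for (j in seq_len(nrow(spans)))
    inside <- inside | (tk$start < spans$end[j] & tk$end > spans$start[j])
  pos <- tk$start[!inside]
  toks <- tk$norm[!inside]
  if (mode$mode == "replacement" && nrow(spans) > 0L) {
    spans <- spans[order(spans$start, spans$end), , drop = FALSE]
    pos <- c(pos, spans$start)
    toks <- c(toks, spans$generic)
  }
  toks[order(pos)]
}

#' Build a document-frequency vocabulary
#'
#' @param docs a list of token vectors, one per document (sentence/title).
#'   Empty documents count toward `D` but contribute no document
#'   frequencies.
#' @return an object of class `"vocabulary"`: `terms` (fixed order),
#'   `doc_freq` (number of documents containing each term), `D` (number of
#'   documents).
#' @export
build_vocabulary <- function(docs) {
  stopifnot(is.list(docs), length(docs) > 0L)
  df <- table(unlist(lapply(docs, unique), use.names = FALSE))
  terms <- sort(names(df))
  structure(list(terms = terms,
                 doc_freq = as.integer(df[terms]),
                 D = length(docs)),
            class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary: %d terms over %d documents>\n",
              length(x$terms), x$D))
  invisible(x)
}

#' Write / read a vocabulary as TSV
#'
#' Header line `#D<TAB><D>` followed by `term<TAB>doc_freq` rows.
#' @param vocab a [build_vocabulary()] object.
#' @param path file path.
#' @export
write_vocabulary <- function(vocab, path) {
  writeLines(c(sprintf("#D\t%d", vocab$D),
               paste(vocab$terms, vocab$doc_freq, sep = "\t")),
             path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  D <- as.integer(strsplit(lines[1L], "\t", fixed = TRUE)[[1]][2L])
  parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
  structure(list(terms = vapply(parts, `[`, "", 1L),
                 doc_freq = as.integer(vapply(parts, `[`, "", 2L)),
                 D = D),
            class = "vocabulary")
}

.idf <- function(vocab) log(vocab$D / vocab$doc_freq)

#' Convert a token sequence to a unit-length tf-idf vector
#'
#' Weight for term t is `tf * ln(D / d_t)`; out-of-vocabulary tokens are
#' ignored; a term present in every document gets idf 0. The raw vector is
#' divided by its Euclidean length, so every non-degenerate vector has unit
#' norm; an all-zero raw vector is returned as-is.
#'
#' @param tokens character vector of tokens.
#' @param vocab a [build_vocabulary()] object.
#' @return an object of class `"feature_vector"`: `index` (positions into
#'   `vocab$terms`), `weight` (nonzero weights), `n_terms`.
#' @export
vectorize <- function(tokens, vocab) {
  stopifnot(inherits(vocab, "vocabulary"))
  tf <- table(tokens)
  idx <- match(names(tf), vocab$terms)
  keep <- !is.na(idx)
  w <- as.numeric(tf[keep]) * .idf(vocab)[idx[keep]]
  idx <- idx[keep]
  nz <- w > 0
  idx <- idx[nz]; w <- w[nz]
  nrm <- sqrt(sum(w^2))
  if (nrm > 0) w <- w / nrm
  o <- order(idx)
  structure(list(index = as.integer(idx[o]), weight = w[o],
                 n_terms = length(vocab$terms)),
            class = "feature_vector")
}

#' Vectorize a corpus into a sparse document-term matrix
#'
#' Row i is [vectorize()] of `docs[[i]]` (rows of unit Euclidean norm,
#' all-zero rows for documents with no in-vocabulary term of positive idf).
#'
#' @param docs list of token vectors.
#' @param vocab a [build_vocabulary()] object.
#' @return a `Matrix::dgCMatrix` of size `length(docs)` x
#'   `length(vocab$terms)` with columns named by term.
#' @export
vectorize_corpus <- function(docs, vocab) {
  vs <- lapply(docs, vectorize, vocab = vocab)
  i <- rep(seq_along(vs), vapply(vs, function(v) length(v$index), 1L))
  j <- unlist(lapply(vs, `[[`, "index"), use.names = FALSE)
  x <- unlist(lapply(vs, `[[`, "weight"), use.names = FALSE)
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(length(docs), length(vocab$terms)),
                       dimnames = list(NULL, vocab$terms))
}

#' Serialize feature vectors in sparse "index:weight" text form
#' @param vecs list of `"feature_vector"` objects.
#' @param path file path.
#' @export
write_vectors <- function(vecs, path) {
  lines <- vapply(vecs, function(v)
    paste(sprintf("%d:%.10g", v$index, v$weight), collapse = " "), "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
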