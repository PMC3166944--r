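# Entity dictionaries: normalized surface forms mapped to canonical IDs
# (4-field EC numbers for enzymes, opaque concept IDs for diseases), plus a
# homonym blacklist. Matching is driven entirely by the normalized token
# sequences, so the same normalization is applied here and to running text.

.ec_pattern <- "^[0-9]+\\.[0-9]+\\.[0-9]+\\.[0-9]+$"

#' Build a lexicon from surface forms and concept IDs
#'
#' @param surface character vector of surface forms.
#' @param concept_id character vector of canonical IDs, same length. For
#'   `entity_class = "enzyme"` every ID must be a complete 4-field EC number
#'   (wildcards and partial classes are rejected with a warning).
#' @param entity_class `"enzyme"` or `"disease"`.
#' @return an object of class `"lexicon"`: a list with `entity_class`,
#'   `entries` (data.frame `surface`, `concept_id`, `norm_key`, `n_tokens`),
#'   `blacklist`, and a prebuilt first-token index used by the matcher.
#' @export
lexicon <- function(surface, concept_id, entity_class = c("enzyme", "disease")) {
  entity_class <- match.arg(entity_class)
  stopifnot(length(surface) == length(concept_id))
  surface <- as.character(surface); concept_id <- as.character(concept_id)
  if (entity_class == "enzyme") {
    bad <- !grepl(.ec_pattern, concept_id)
    if (any(bad)) {
      warning(sum(bad), " row(s) with malformed EC number rejected: ",
              paste(utils::head(unique(concept_id[bad]), 3L), collapse = ", "))
      surface <- surface[!bad]; concept_id <- concept_id[!bad]
    }
  }
  toks <- lapply(surface, normalize_term)
  keep <- lengths(toks) > 0L
  if (any(!keep)) {
    warning(sum(!keep), " row(s) with empty normalized form rejected")
    surface <- surface[keep]; concept_id <- concept_id[keep]; toks <- toks[keep]
  }
  key <- vapply(toks, paste, "", collapse = " ")
  entries <- data.frame(surface = surface, concept_id = concept_id,
                        norm_key = key, n_tokens = lengths(toks),
                        stringsAsFactors = FALSE)
  entries <- entries[!duplicated(entries[c("norm_key", "concept_id")]), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(entity_class = entity_class, entries = entries,
                 blacklist = character(0), index = .lexicon_index(entries)),
            class = "lexicon")
}

# first normalized token -> entry row indices
.lexicon_index <- function(entries) {
  if (nrow(entries) == 0L) return(list())
  first <- vapply(strsplit(entries$norm_key, " ", fixed = TRUE), `[`, "", 1L)
  split(seq_len(nrow(entries)), first)
}

#' @export
print.lexicon <- function(x, ...) {
  cat(sprintf("<lexicon: %s, %d entries, %d concepts, %d blacklisted forms>\n",
              x$entity_class, nrow(x$entries),
              length(unique(x$entries$concept_id)), length(x$blacklist)))
  invisible(x)
}

#' Load a lexicon from a TSV file
#'
#' Expects UTF-8 lines `surface<TAB>concept_id`; lines starting with `#` are
#' comments. Duplicate (normalized form, concept) pairs are deduplicated;
#' enzyme rows whose concept is not a complete 4-field EC number are
#' rejected with a warning.
#'
#' @param path path to the TSV file.
#' @param entity_class `"enzyme"` or `"disease"`.
#' @return a [lexicon()] object.
#' @export
load_lexicon <- function(path, entity_class = c("enzyme", "disease")) {
  entity_class <- match.arg(entity_class)
  if (!file.exists(path)) stop("cannot read lexicon: no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(lexicon(character(0), character(0), entity_class))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 2L
  if (any(bad)) {
    warning(sum(bad), " malformed lexicon row(s) skipped")
    parts <- parts[!bad]
  }
  lexicon(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L), entity_class)
}

#' Write a lexicon to TSV
#' @param lex a [lexicon()] object.
#' @param path output path.
#' @export
write_lexicon <- function(lex, path) {
  writeLines(paste(lex$entries$surface, lex$entries$concept_id, sep = "\t"),
             path, useBytes = TRUE)
  invisible(path)
}

#' Remove blacklisted surface forms from a lexicon
#'
#' Drops every entry whose normalized token sequence equals a normalized
#' blacklist term. Dictionary curation against homonyms (typically short
#' acronyms) is expressed declaratively through this list; removal trades
#' false-positive matches for missed entities, so the count of removed
#' entries is reported in the `removed` attribute. Idempotent and
#' order-independent over the blacklist terms.
#'
#' @param lex a [lexicon()] object.
#' @param terms character vector of surface forms to exclude.
#' @return the filtered lexicon; `attr(, "removed")` holds the number of
#'   entries removed by this call.
#' @export
apply_blacklist <- function(lex, terms) {
  stopifnot(inherits(lex, "lexicon"))
  keys <- vapply(as.character(terms),
                 function(t) paste(normalize_term(t), collapse = " "), "")
  keys <- unique(keys[nzchar(keys)])
  drop <- lex$entries$norm_key %in% keys
  lex$entries <- lex$entries[!drop, , drop = FALSE]
  rownames(lex$entries) <- NULL
  lex$blacklist <- sort(unique(c(lex$blacklist, keys)))
  lex$index <- .lexicon_index(lex$entries)
  structure(lex, removed = sum(drop))
}

#' Read a blacklist file (one surface form per line)
#' @param path path to a plain-text file; blank lines and `#` comments ignored.
#' @return character vector of terms.
#' @export
read_blacklist <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  trimws(lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")])
}
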