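# Literature records and sentence segmentation.
#
# A corpus is a plain data.frame with columns ref_id, title, abstract; the
# unit of all downstream processing is a TextUnit: the title (unit 0) or one
# abstract sentence (units 1..n, in order), each carrying its character span
# in the source field.

# Common biomedical abbreviations that must not terminate a sentence.
# Stored without the trailing period; single-letter initials ("J.") are
# handled by a separate rule.
.default_abbreviations <- c(
  "e.g", "i.e", "et al", "al", "etc", "cf", "ca", "vs", "viz", "approx",
  "dr", "prof", "mr", "mrs", "ms", "st", "fig", "figs", "eq", "eqs",
  "ref", "refs", "no", "nos", "vol", "sp", "spp", "subsp", "var", "min",
  "max", "mol", "wt"
)

#' Read literature records
#'
#' Reads PubMed-style records (identifier, title, abstract) from one of
#' three dialects: a 3-column TSV, JSON lines, or MEDLINE-flavoured XML
#' (`PMID`, `ArticleTitle`, `AbstractText`; multiple `AbstractText` blocks
#' are concatenated with a space). Records with an empty title are skipped
#' with a warning; malformed records warn but are not fatal.
#'
#' @param path path to the input file.
#' @param dialect one of `"tsv"`, `"jsonl"`, `"medline_xml"`.
#' @param header for TSV input, whether the first line is a header.
#' @return a data.frame with character columns `ref_id`, `title`, `abstract`.
#' @export
read_references <- function(path, dialect = c("tsv", "jsonl", "medline_xml"),
                            header = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read references: no such file: ", path)
  refs <- switch(dialect,
    tsv = .read_refs_tsv(path, header),
    jsonl = .read_refs_jsonl(path),
    medline_xml = .read_refs_xml(path)
  )
  as_reference_set(refs)
}

.read_refs_tsv <- function(path, header) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (header && length(lines) > 0L) lines <- lines[-1L]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(ref_id = character(0), title = character(0),
                      abstract = character(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 2L
  if (any(bad)) {
    warning(sum(bad), " malformed TSV record(s) skipped")
    parts <- parts[!bad]
  }
  data.frame(
    ref_id = vapply(parts, `[`, "", 1L),
    title = vapply(parts, `[`, "", 2L),
    abstract = vapply(parts, function(p) if (length(p) >= 3L) p[3L] else "", ""),
    stringsAsFactors = FALSE
  )
}

.read_refs_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    rec <- tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
    if (is.null(rec) || is.null(rec$ref_id) || is.null(rec$title)) {
      warning("malformed JSONL record skipped")
      return(NULL)
    }
    data.frame(ref_id = as.character(rec$ref_id),
               title = as.character(rec$title),
               abstract = if (is.null(rec$abstract)) "" else as.character(rec$abstract),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) {
    return(data.frame(ref_id = character(0), title = character(0),
                      abstract = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

.read_refs_xml <- function(path) {
  doc <- xml2::read_xml(path)
  arts <- xml2::xml_find_all(doc, ".//PubmedArticle | .//MedlineCitation[not(ancestor::PubmedArticle)]")
  if (length(arts) == 0L) arts <- xml2::xml_find_all(doc, ".//Article")
  rows <- lapply(arts, function(a) {
    pmid <- xml2::xml_text(xml2::xml_find_first(a, ".//PMID"))
    title <- xml2::xml_text(xml2::xml_find_first(a, ".//ArticleTitle"))
    abst <- xml2::xml_text(xml2::xml_find_all(a, ".//AbstractText"))
    data.frame(ref_id = pmid, title = title,
               abstract = paste(abst, collapse = " "),
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L) {
    return(data.frame(ref_id = character(0), title = character(0),
                      abstract = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Validate a reference set
#'
#' Checks the reference-set contract (non-empty unique `ref_id`, non-empty
#' `title`); rows with an empty title are dropped with a warning.
#'
#' @param refs a data.frame with columns `ref_id`, `title`, `abstract`.
#' @return the validated data.frame.
#' @export
as_reference_set <- function(refs) {
  stopifnot(is.data.frame(refs),
            all(c("ref_id", "title", "abstract") %in% names(refs)))
  refs <- refs[, c("ref_id", "title", "abstract")]
  refs[] <- lapply(refs, function(x) { x <- as.character(x); x[is.na(x)] <- ""; x })
  empty <- !nzchar(refs$title)
  if (any(empty)) {
    warning(sum(empty), " record(s) with empty title skipped")
    refs <- refs[!empty, , drop = FALSE]
  }
  if (anyDuplicated(refs$ref_id)) stop("duplicate ref_id in reference set")
  if (any(!nzchar(refs$ref_id))) stop("empty ref_id in reference set")
  rownames(refs) <- NULL
  refs
}

#' Write literature records
#'
#' @param refs a reference set (see [as_reference_set()]).
#' @param path output path.
#' @param dialect `"tsv"` or `"jsonl"`.
#' @export
write_references <- function(refs, path, dialect = c("tsv", "jsonl")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    lines <- paste(refs$ref_id, refs$title, refs$abstract, sep = "\t")
  } else {
    lines <- vapply(seq_len(nrow(refs)), function(i) {
      jsonlite::toJSON(list(ref_id = refs$ref_id[i], title = refs$title[i],
                            abstract = refs$abstract[i]), auto_unbox = TRUE)
    }, "")
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# Locate sentence boundaries in an abstract. Returns 0-based half-open spans.
# A boundary is sentence-final punctuation (. ! ?) followed by whitespace and
# an uppercase letter or digit, unless the token before the period is a known
# abbreviation or a single-letter initial.
.sentence_spans <- function(text, abbreviations = .default_abbreviations) {
  n <- nchar(text)
  if (n == 0L) return(data.frame(start = integer(0), end = integer(0)))
  m <- gregexpr("[.!?]+(?=[[:space:]]+[A-Z0-9])", text, perl = TRUE)[[1]]
  breaks <- integer(0)
  if (m[1] != -1L) {
    ends <- as.integer(m) + attr(m, "match.length") - 1L  # 1-based last punct char
    for (e in ends) {
      head <- substr(text, max(1L, e - 20L), e)
      word <- regmatches(head, regexpr("[A-Za-z.]+\\.$", head))
      if (length(word) == 1L) {
        stem <- tolower(sub("\\.$", "", word))
        if (stem %in% tolower(abbreviations)) next        # listed abbreviation
        if (grepl("^[A-Za-z]$", stem)) next               # single-letter initial
        if (grepl("\\.", stem)) next                      # internal dots: e.g., i.e.
      }
      breaks <- c(breaks, e)
    }
  }
  starts1 <- integer(0); ends1 <- integer(0)
  pos <- 1L
  for (b in c(breaks, n)) {
    # skip leading whitespace of the sentence
    while (pos <= n && grepl("^[[:space:]]$", substr(text, pos, pos))) pos <- pos + 1L
    if (pos > b) next
    starts1 <- c(starts1, pos); ends1 <- c(ends1, b)
    pos <- b + 1L
  }
  # trim trailing whitespace of the final sentence
  if (length(ends1) > 0L) {
    last <- length(ends1)
    while (ends1[last] >= starts1[last] &&
           grepl("^[[:space:]]$", substr(text, ends1[last], ends1[last])))
      ends1[last] <- ends1[last] - 1L
    if (ends1[last] < starts1[last]) { starts1 <- starts1[-last]; ends1 <- ends1[-last] }
  }
  data.frame(start = starts1 - 1L, end = ends1)
}

#' Split a reference into classification units
#'
#' Unit 0 is the whole title (regardless of internal punctuation); units
#' 1..n are the abstract sentences in order, segmented at sentence-final
#' punctuation followed by whitespace and an uppercase letter or digit, with
#' an exception list of common biomedical abbreviations. Spans are 0-based
#' half-open offsets into the source field, and every unit's text equals the
#' source substring at its span.
#'
#' @param ref a one-row reference (list or data.frame row with `ref_id`,
#'   `title`, `abstract`).
#' @param abbreviations abbreviation exception list (without trailing period).
#' @return a data.frame with columns `ref_id`, `unit_index`, `text`,
#'   `start`, `end`, `field` (`"title"` or `"abstract"`).
#' @export
split_sentences <- function(ref, abbreviations = .default_abbreviations) {
  title <- as.character(ref$title)
  abstract <- as.character(ref$abstract)
  if (is.na(abstract)) abstract <- ""
  spans <- .sentence_spans(abstract, abbreviations)
  sent <- if (nrow(spans) > 0L)
    substring(abstract, spans$start + 1L, spans$end) else character(0)
  units <- data.frame(
    ref_id = as.character(ref$ref_id),
    unit_index = c(0L, seq_len(nrow(spans))),
    text = c(title, sent),
    start = c(0L, spans$start),
    end = c(nchar(title), spans$end),
    field = c("title", rep("abstract", nrow(spans))),
    stringsAsFactors = FALSE
  )
  rownames(units) <- NULL
  units
}

#' Split every reference of a corpus into units
#'
#' @param refs a reference set.
#' @inheritParams split_sentences
#' @return row-bound [split_sentences()] output, ordered by (`ref_id` input
#'   order, `unit_index`).
#' @export
split_corpus <- function(refs, abbreviations = .default_abbreviations) {
  out <- lapply(seq_len(nrow(refs)), function(i)
    split_sentences(refs[i, ], abbreviations))
  do.call(rbind, out)
}
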