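# Gold-annotated corpora: text units with expert (or synthetic) entity
# spans and non-exclusive category labels. This is the train/test material
# for the relation classifiers and the reference for recognition scoring.

#' Construct a gold corpus
#'
#' @param units data.frame with columns `ref_id`, `unit_index`, `text` (one
#'   row per annotated unit).
#' @param mentions data.frame with columns `ref_id`, `unit_index`,
#'   `entity_class` (`"enzyme"`/`"disease"`), `concept_id`, `surface`,
#'   `start`, `end` (0-based half-open spans into the unit text).
#' @param labels data.frame with columns `ref_id`, `unit_index`, `category`
#'   (values from [relation_categories()]); a unit may appear zero, one or
#'   several times (multi-label).
#' @return an object of class `"gold_corpus"`; `units$cooccur` records
#'   whether the unit carries at least one gold mention of each class.
#' @export
gold_corpus <- function(units, mentions, labels) {
  stopifnot(all(c("ref_id", "unit_index", "text") %in% names(units)),
            all(c("ref_id", "unit_index", "entity_class", "concept_id",
                  "start", "end") %in% names(mentions)),
            all(c("ref_id", "unit_index", "category") %in% names(labels)))
  if (nrow(labels) > 0L && !all(labels$category %in% relation_categories()))
    stop("unknown category label")
  ukey <- paste(units$ref_id, units$unit_index, sep = "\r")
  if (anyDuplicated(ukey)) stop("duplicate units in gold corpus")
  mkey <- paste(mentions$ref_id, mentions$unit_index, sep = "\r")
  if (!all(mkey %in% ukey)) stop("mention for unknown unit")
  if (!all(paste(labels$ref_id, labels$unit_index, sep = "\r") %in% ukey))
    stop("label for unknown unit")
  has_e <- ukey %in% mkey[mentions$entity_class == "enzyme"]
  has_d <- ukey %in% mkey[mentions$entity_class == "disease"]
  units$cooccur <- has_e & has_d
  rownames(units) <- NULL
  structure(list(units = units, mentions = mentions, labels = labels),
            class = "gold_corpus")
}

#' @export
print.gold_corpus <- function(x, ...) {
  labs <- .gold_label_matrix(x)
  cat(sprintf("<gold corpus: %d units (%d co-occurring), %d mentions>\n",
              nrow(x$units), sum(x$units$cooccur), nrow(x$mentions)))
  for (cat_ in colnames(labs))
    cat(sprintf("  %-24s %d positive\n", cat_, sum(labs[, cat_])))
  invisible(x)
}

# units x categories logical matrix of gold labels
#' @keywords internal
.gold_label_matrix <- function(gold) {
  cats <- relation_categories()
  ukey <- paste(gold$units$ref_id, gold$units$unit_index, sep = "\r")
  lkey <- paste(gold$labels$ref_id, gold$labels$unit_index, sep = "\r")
  m <- matrix(FALSE, nrow(gold$units), length(cats),
              dimnames = list(NULL, cats))
  for (cat_ in cats)
    m[, cat_] <- ukey %in% lkey[gold$labels$category == cat_]
  m
}

#' Materialize gold units as mention-carrying records
#'
#' @param gold a [gold_corpus()].
#' @param index row indices into `gold$units` (default all).
#' @return a list of record objects compatible with [preprocess_unit()]
#'   (text plus per-class mention frames).
#' @export
gold_records <- function(gold, index = seq_len(nrow(gold$units))) {
  mkey <- paste(gold$mentions$ref_id, gold$mentions$unit_index, sep = "\r")
  lapply(index, function(i) {
    u <- gold$units[i, ]
    m <- gold$mentions[mkey == paste(u$ref_id, u$unit_index, sep = "\r"), ,
                       drop = FALSE]
    structure(list(ref_id = u$ref_id, unit_index = u$unit_index,
                   text = u$text,
                   enzyme_mentions = m[m$entity_class == "enzyme", , drop = FALSE],
                   disease_mentions = m[m$entity_class == "disease", , drop = FALSE]),
              class = "gold_unit")
  })
}

#' Write / read gold annotations as TSV
#'
#' One row per unit: `ref_id`, `unit_index`, `text`, mention spans encoded
#' as `class:concept:start:end` joined by commas, labels joined by commas.
#'
#' @param gold a [gold_corpus()].
#' @param path file path.
#' @export
write_gold <- function(gold, path) {
  mkey <- paste(gold$mentions$ref_id, gold$mentions$unit_index, sep = "\r")
  lkey <- paste(gold$labels$ref_id, gold$labels$unit_index, sep = "\r")
  lines <- vapply(seq_len(nrow(gold$units)), function(i) {
    k <- paste(gold$units$ref_id[i], gold$units$unit_index[i], sep = "\r")
    m <- gold$mentions[mkey == k, , drop = FALSE]
    spans <- paste(sprintf("%s:%s:%d:%d", m$entity_class, m$concept_id,
                           m$start, m$end), collapse = ",")
    labs <- paste(gold$labels$category[lkey == k], collapse = ",")
    paste(gold$units$ref_id[i], gold$units$unit_index[i], gold$units$text[i],
          spans, labs, sep = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_gold
#' @export
read_gold <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  units <- data.frame(
    ref_id = vapply(parts, `[`, "", 1L),
    unit_index = as.integer(vapply(parts, `[`, "", 2L)),
    text = vapply(parts, `[`, "", 3L), stringsAsFactors = FALSE)
  mrows <- list(); lrows <- list()
  for (p in parts) {
    spans <- p[4L]
    if (!is.na(spans) && nzchar(spans)) {
      for (s in strsplit(spans, ",", fixed = TRUE)[[1]]) {
        f <- strsplit(s, ":", fixed = TRUE)[[1]]
        mrows[[length(mrows) + 1L]] <- data.frame(
          ref_id = p[1L], unit_index = as.integer(p[2L]),
          entity_class = f[1L], concept_id = f[2L],
          surface = NA_character_,
          start = as.integer(f[3L]), end = as.integer(f[4L]),
          stringsAsFactors = FALSE)
      }
    }
    labs <- if (length(p) >= 5L) p[5L] else ""
    if (!is.na(labs) && nzchar(labs)) {
      for (l in strsplit(labs, ",", fixed = TRUE)[[1]])
        lrows[[length(lrows) + 1L]] <- data.frame(
          ref_id = p[1L], unit_index = as.integer(p[2L]), category = l,
          stringsAsFactors = FALSE)
    }
  }
  empty_m <- data.frame(ref_id = character(0), unit_index = integer(0),
                        entity_class = character(0), concept_id = character(0),
                        surface = character(0), start = integer(0),
                        end = integer(0), stringsAsFactors = FALSE)
  empty_l <- data.frame(ref_id = character(0), unit_index = integer(0),
                        category = character(0), stringsAsFactors = FALSE)
  gold_corpus(units,
              if (length(mrows)) do.call(rbind, mrows) else empty_m,
              if (length(lrows)) do.call(rbind, lrows) else empty_l)
}
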