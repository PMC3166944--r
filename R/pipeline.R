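# End-to-end orchestration and content summaries: read -> split -> match ->
# preprocess -> vectorize -> classify -> confidence -> relation table, plus
# the per-EC-class representation quotient and the category intersection
# counts over the final table.

#' Expand a classified unit into relation entries
#'
#' Forms the Cartesian product of the distinct enzyme concept IDs and the
#' distinct disease concept IDs mentioned in the unit. For every category
#' with an assigned confidence level (>= 1) each pair yields one
#' categorized entry; pairs of a unit with no category at all are retained
#' in the uncategorized table (a unit can be assigned to none, one or more
#' categories).
#'
#' @param record a [cooccurrence_record()].
#' @param levels named integer vector of confidence levels per category
#'   (0 = unassigned), as produced by [predict.relation_ensemble()].
#' @return list with `entries` (data.frame `ec_number`, `disease_id`,
#'   `ref_id`, `unit_index`, `category`, `confidence_level`) and `pairs`
#'   (the distinct pairs of the unit, category-independent).
#' @export
expand_pairs <- function(record, levels) {
  stopifnot(all(names(levels) %in% relation_categories()))
  ecs <- unique(record$enzyme_mentions$concept_id)
  dids <- unique(record$disease_mentions$concept_id)
  pairs <- expand.grid(ec_number = ecs, disease_id = dids,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pairs$ref_id <- record$ref_id
  pairs$unit_index <- record$unit_index
  assigned <- names(levels)[levels >= 1L]
  entries <- if (length(assigned) == 0L) {
    data.frame(ec_number = character(0), disease_id = character(0),
               ref_id = character(0), unit_index = integer(0),
               category = character(0), confidence_level = integer(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, lapply(assigned, function(cat_) {
      e <- pairs
      e$category <- cat_
      e$confidence_level <- as.integer(levels[[cat_]])
      e
    }))
  }
  list(entries = entries, pairs = pairs)
}

# keep the highest confidence level per distinct (ec, disease, ref,
# category); ties resolved toward the earliest unit
.collapse_relations <- function(entries) {
  if (nrow(entries) == 0L) return(entries)
  o <- order(entries$ec_number, entries$disease_id, entries$ref_id,
             entries$category, -entries$confidence_level, entries$unit_index)
  entries <- entries[o, , drop = FALSE]
  key <- paste(entries$ec_number, entries$disease_id, entries$ref_id,
               entries$category, sep = "\r")
  entries <- entries[!duplicated(key), , drop = FALSE]
  rownames(entries) <- NULL
  entries
}

#' Run the full processing chain
#'
#' Reads (or accepts) the reference corpus, applies the blacklist to both
#' lexicons, splits sentences, matches co-occurrences, classifies every
#' co-occurrence unit with the fitted ensemble, assigns confidence levels
#' and assembles the relation table. Every stage logs its counts;
#' everything downstream of the inputs is deterministic given the fitted
#' model.
#'
#' @param refs a reference set, or a file path.
#' @param enzyme_lex,disease_lex [lexicon()] objects.
#' @param model a fitted [relation_ensemble()], or `NULL` to stop at the
#'   uncategorized co-occurrence table.
#' @param blacklist optional character vector applied to both lexicons.
#' @param dialect corpus dialect when `refs` is a path.
#' @return an object of class `"pipeline_result"`: `relations` (categorized
#'   entries, max level per distinct combination), `pairs` (all distinct
#'   EC/disease/reference/unit combinations), `records`, `predictions`,
#'   `counts` (per-stage log).
#' @export
run_pipeline <- function(refs, enzyme_lex, disease_lex, model = NULL,
                         blacklist = NULL, dialect = "tsv") {
  if (is.character(refs) && length(refs) == 1L)
    refs <- read_references(refs, dialect)
  refs <- as_reference_set(refs)
  if (!is.null(blacklist)) {
    enzyme_lex <- apply_blacklist(enzyme_lex, blacklist)
    disease_lex <- apply_blacklist(disease_lex, blacklist)
  }
  units <- split_corpus(refs)
  records <- find_cooccurrences(refs, enzyme_lex, disease_lex, units = units)
  counts <- list(references = nrow(refs), units = nrow(units),
                 cooccurrence_units = length(records))
  preds <- NULL
  if (!is.null(model) && length(records) > 0L)
    preds <- predict(model, records)
  entries <- list(); pairs <- list()
  for (i in seq_along(records)) {
    lv <- stats::setNames(rep(0L, length(relation_categories())),
                          relation_categories())
    if (!is.null(preds)) {
      for (cat_ in relation_categories())
        lv[[cat_]] <- preds[[paste0("level_", cat_)]][i]
    }
    ex <- expand_pairs(records[[i]], lv)
    entries[[i]] <- ex$entries
    pairs[[i]] <- ex$pairs
  }
  empty_entries <- data.frame(ec_number = character(0), disease_id = character(0),
                              ref_id = character(0), unit_index = integer(0),
                              category = character(0),
                              confidence_level = integer(0),
                              stringsAsFactors = FALSE)
  relations <- if (length(entries)) do.call(rbind, entries) else empty_entries
  relations <- .collapse_relations(relations)
  all_pairs <- if (length(pairs)) do.call(rbind, pairs) else
    empty_entries[, c("ec_number", "disease_id", "ref_id", "unit_index")]
  counts$categorized_entries <- nrow(relations)
  counts$distinct_pairs <- nrow(unique(all_pairs[, c("ec_number", "disease_id",
                                                     "ref_id")]))
  structure(list(relations = relations, pairs = all_pairs, records = records,
                 predictions = preds, counts = counts),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline result>\n")
  for (nm in names(x$counts)) cat(sprintf("  %-20s %d\n", nm, x$counts[[nm]]))
  invisible(x)
}

#' Write the relation table as TSV
#' @param result a [run_pipeline()] result (or a relation data.frame).
#' @param path file path.
#' @export
write_relations <- function(result, path) {
  tab <- if (inherits(result, "pipeline_result")) result$relations else result
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-EC-class representation quotient
#'
#' An enzyme class's share of the distinct EC-disease combinations divided
#' by its share of the known EC numbers: quotient(class) =
#' (a_class / total_a) / (b_class / total_b). Values above 1 mark classes
#' over-represented in the disease literature relative to their size.
#' Totals default to the column sums but can be given explicitly when the
#' published marginals carry their own totals.
#'
#' @param class_combos named numeric vector `a` of distinct EC-disease
#'   combination counts per EC class ("1".."6").
#' @param class_totals named numeric vector `b` of known EC numbers per
#'   class.
#' @param total_a,total_b totals of `a` and `b`.
#' @return named numeric vector of quotients (unrounded; display rounds to
#'   2 decimals). Classes with `b = 0` are `NA` with a warning.
#' @export
representation_quotient <- function(class_combos, class_totals,
                                    total_a = sum(class_combos),
                                    total_b = sum(class_totals)) {
  stopifnot(length(class_combos) == length(class_totals),
            total_a > 0, total_b > 0)
  q <- (class_combos / total_a) / (class_totals / total_b)
  if (any(class_totals == 0)) {
    warning("EC class with zero known EC numbers: quotient undefined")
    q[class_totals == 0] <- NA_real_
  }
  q
}

#' Category intersection counts at a confidence level
#'
#' Counts the distinct (EC number, disease, reference) combinations falling
#' in every non-empty subset of the four categories at confidence level
#' >= `level` ("at level l" is cumulative: the level-4 set nests inside
#' level 3, and so on), plus the count of combinations unassigned at that
#' level. Subset keys are category names joined by `+`.
#'
#' @param relations categorized relation entries (data.frame with
#'   `ec_number`, `disease_id`, `ref_id`, `category`, `confidence_level`).
#' @param level minimum confidence level (1-4).
#' @param all_pairs optional data.frame of all distinct combinations (e.g.
#'   the `pairs` component of [run_pipeline()]); needed for the unassigned
#'   count.
#' @return named integer vector over the 15 non-empty category subsets plus
#'   `"unassigned"`.
#' @export
category_intersections <- function(relations, level = 1L, all_pairs = NULL) {
  stopifnot(level %in% 1:4)
  cats <- relation_categories()
  subsets <- unlist(lapply(1:4, function(k)
    utils::combn(cats, k, paste, collapse = "+", simplify = FALSE)))
  out <- stats::setNames(integer(length(subsets) + 1L), c(subsets, "unassigned"))
  sel <- relations[relations$confidence_level >= level, , drop = FALSE]
  combo <- paste(sel$ec_number, sel$disease_id, sel$ref_id, sep = "\r")
  if (nrow(sel) > 0L) {
    per <- tapply(sel$category, combo, function(cs)
      paste(cats[cats %in% cs], collapse = "+"))
    tab <- table(unlist(per))
    out[names(tab)] <- as.integer(tab)
  }
  if (!is.null(all_pairs)) {
    allc <- unique(paste(all_pairs$ec_number, all_pairs$disease_id,
                         all_pairs$ref_id, sep = "\r"))
    out[["unassigned"]] <- length(setdiff(allc, unique(combo)))
  }
  out
}
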