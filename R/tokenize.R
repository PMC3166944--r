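# Shared tokenizer: the same token and case rules are applied to dictionary
# surface forms and to running text, so both sides of a match are normalized
# identically.

#' @keywords internal
.token_regex <- "[[:alnum:]]+(?:-[[:alnum:]]+)*"

# Case policy: everything is lowercased except all-caps tokens of length <= 4
# that contain a letter (short acronyms such as "AAA"), which keep their case.
# Short acronyms are the dominant homonym source in enzyme dictionaries, and
# case-sensitive matching suppresses their false positives without deleting
# the term from the lexicon.
#' @keywords internal
.norm_tokens <- function(tokens) {
  if (length(tokens) == 0L) return(character(0))
  acro <- nchar(tokens) <= 4L & tokens == toupper(tokens) & grepl("[A-Z]", tokens)
  tokens[!acro] <- tolower(tokens[!acro])
  tokens
}

#' Tokenize text with character spans
#'
#' Splits a string into maximal runs of letters and digits (internal hyphens
#' are kept inside a token) and records, for every token, its 0-based
#' half-open character span in the input together with its normalized form.
#'
#' @param text a single character string.
#' @return a data.frame with columns `token`, `norm`, `start`, `end`
#'   (`start`/`end` 0-based half-open, counted in characters).
#' @export
tokenize_spans <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(token = character(0), norm = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  }
  m <- gregexpr(.token_regex, text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(token = character(0), norm = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  }
  len <- attr(m, "match.length")
  tok <- substring(text, m, m + len - 1L)
  data.frame(token = tok, norm = .norm_tokens(tok),
             start = as.integer(m - 1L), end = as.integer(m - 1L + len),
             stringsAsFactors = FALSE)
}

#' Normalize a term to its matching token sequence
#'
#' Lowercases all tokens except short all-caps acronyms (length <= 4), which
#' stay case-sensitive. Tokens are maximal alphanumeric runs with internal
#' hyphens preserved. The operation is idempotent.
#'
#' @param term a single character string.
#' @return a character vector of normalized tokens (empty for blank input).
#' @examples
#' normalize_term("Alpha-Galactosidase")  # "alpha-galactosidase"
#' normalize_term("AAA")                  # "AAA" (acronym, case kept)
#' @export
normalize_term <- function(term) {
  if (length(term) != 1L || is.na(term)) stop("`term` must be a single string")
  tokenize_spans(term)$norm
}
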