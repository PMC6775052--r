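# Pattern compilation and matching. Tokens are runs of letters, digits and
# apostrophes; "." and "-" break tokens except inside variant forms, which
# are matched literally. All matching is case-insensitive and anchored at
# word boundaries.
#
# Internals use plain integer vectors rather than tibbles: the matcher is
# called a dozen times per instance, so per-pattern data-frame overhead
# dominates runtime otherwise.

TOKEN_REGEX <- "[A-Za-z0-9']+"

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

compile_pattern_regex <- function(stem, match_mode) {
  if (match_mode == "prefix") {
    paste0("\\b", escape_regex(stem), "[A-Za-z0-9']*")
  } else if (match_mode == "exact") {
    paste0("\\b", escape_regex(stem), "\\b")
  } else { # phrase: tokens separated by arbitrary whitespace; internal
    # punctuation matched literally
    toks <- strsplit(stem, "\\s+")[[1]]
    paste0("\\b", paste(vapply(toks, escape_regex, ""), collapse = "\\s+"),
           "\\b")
  }
}

compile_variant_regex <- function(variant) {
  # "." and "-" are token-internal for variants (o.c.d, self-described)
  paste0("(?<![A-Za-z0-9])", escape_regex(variant), "(?![A-Za-z0-9])")
}

# Positions of all matches as integer vectors (1-based inclusive).
locate_spans <- function(text, regex) {
  m <- gregexpr(regex, text, perl = TRUE, ignore.case = TRUE)[[1]]
  if (m[1] == -1L) return(list(start = integer(), end = integer()))
  list(start = as.integer(m),
       end = as.integer(m) + attr(m, "match.length") - 1L)
}

locate_all <- function(text, regex) {
  s <- locate_spans(text, regex)
  tibble::tibble(char_start = s$start, char_end = s$end)
}

# Compiled regexes are cached on the lexicon table (computed once per
# lexicon object, reused across every call).
compiled_lexicons <- function(lexicons) {
  if (!is.null(attr(lexicons, "compiled"))) return(attr(lexicons, "compiled"))
  list(regex = mapply(compile_pattern_regex, lexicons$stem,
                      lexicons$match_mode, USE.NAMES = FALSE),
       variant_regex = lapply(lexicons$variants, function(v) {
         vapply(v, compile_variant_regex, "", USE.NAMES = FALSE)
       }))
}

#' Precompile lexicon patterns
#'
#' Attaches compiled regular expressions to a lexicon table so repeated
#' matching does not recompile them. Called automatically by the
#' pipeline entry points; only needed directly when calling
#' [match_keywords()] in a tight loop.
#'
#' @param lexicons An `ocs_lexicons` tibble.
#' @return The same tibble with a compiled-pattern cache attached.
#' @export
compile_lexicons <- function(lexicons) {
  attr(lexicons, "compiled") <- compiled_lexicons(lexicons)
  lexicons
}

match_spans <- function(text, stem, mode, exceptions, regex, variant_regex) {
  sp <- locate_spans(text, regex)
  if (mode == "prefix" && length(sp$start) && length(exceptions)) {
    tok <- tolower(substring(text, sp$start, sp$end))
    keep <- !tok %in% exceptions
    sp <- list(start = sp$start[keep], end = sp$end[keep])
  }
  for (vr in variant_regex) {
    v <- locate_spans(text, vr)
    sp <- list(start = c(sp$start, v$start), end = c(sp$end, v$end))
  }
  sp
}

#' Match lexicon patterns against text
#'
#' Finds every word-boundary occurrence of the patterns in the given
#' lexicons. This matcher is the single source of truth: the document
#' pre-filter, the context-window anchors and the exclusion engine all
#' call it, which guarantees that anything the detector can see also
#' survives the pre-filter.
#'
#' @param text A single character string.
#' @param lexicons An `ocs_lexicons` tibble (see [default_lexicons()]).
#' @param lexicon_names Optional character vector restricting which
#'   lexicons to match; default all.
#' @return A tibble of keyword hits, sorted by `char_start`: columns
#'   `lexicon`, `stem`, `match_mode`, `matched_text`, `char_start`,
#'   `char_end` (1-based, inclusive).
#' @examples
#' match_keywords("She is obsessional about cleaning", default_lexicons(),
#'                c("ocs_keywords", "ybocs_keywords"))
#' @export
match_keywords <- function(text, lexicons, lexicon_names = NULL) {
  stopifnot(length(text) == 1L, is.character(text))
  comp <- compiled_lexicons(lexicons)
  idx <- if (is.null(lexicon_names)) {
    seq_len(nrow(lexicons))
  } else {
    which(lexicons$lexicon %in% lexicon_names)
  }
  if (is.na(text) || !nzchar(text) || !length(idx)) return(empty_hits())

  out_lex <- out_stem <- out_mode <- character(0)
  out_s <- out_e <- integer(0)
  for (i in idx) {
    sp <- match_spans(text, lexicons$stem[i], lexicons$match_mode[i],
                      lexicons$exceptions[[i]], comp$regex[i],
                      comp$variant_regex[[i]])
    k <- length(sp$start)
    if (!k) next
    out_lex <- c(out_lex, rep.int(lexicons$lexicon[i], k))
    out_stem <- c(out_stem, rep.int(lexicons$stem[i], k))
    out_mode <- c(out_mode, rep.int(lexicons$match_mode[i], k))
    out_s <- c(out_s, sp$start)
    out_e <- c(out_e, sp$end)
  }
  if (!length(out_s)) return(empty_hits())
  o <- order(out_s, out_e, out_lex, out_stem)
  tibble::tibble(
    lexicon = out_lex[o], stem = out_stem[o], match_mode = out_mode[o],
    matched_text = substring(text, out_s[o], out_e[o]),
    char_start = out_s[o], char_end = out_e[o]
  )
}

empty_hits <- function() {
  tibble::tibble(
    lexicon = character(), stem = character(), match_mode = character(),
    matched_text = character(), char_start = integer(), char_end = integer()
  )
}

# Tokenize text into word tokens; plain list of vectors (hot path).
tokenize <- function(text) {
  sp <- locate_spans(text, TOKEN_REGEX)
  list(token = tolower(substring(text, sp$start, sp$end)),
       char_start = sp$start, char_end = sp$end, n = length(sp$start))
}

# Index of the token covering character position pos, or NA.
token_index_at <- function(tokens, pos) {
  i <- which(tokens$char_start <= pos & tokens$char_end >= pos)
  if (length(i)) i[1] else NA_integer_
}
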