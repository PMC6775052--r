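# Deterministic rule-based sentence splitter. A statistical model would be
# overkill here and would not be bit-reproducible across environments;
# clinical note fragments are short and terminally punctuated (or not
# punctuated at all, in which case the whole fragment is one sentence).

# Abbreviations whose trailing period never ends a sentence. Single-letter
# tokens preceded by a period are protected implicitly (e.g., i.e., o.c.d).
PROTECTED_ABBREVIATIONS <- c(
  "dr", "mr", "mrs", "ms", "prof", "st", "vs", "etc", "approx",
  "eg", "ie", "cf", "dept", "appt"
)

#' Split text into sentences
#'
#' Splits on terminal punctuation (`.`, `!`, `?`) followed by whitespace
#' and a capital letter or digit, or by end of text. Periods after
#' protected abbreviations ("Dr.", "e.g.") and after single-letter tokens
#' (which covers dotted acronyms like "o.c.d") do not end a sentence.
#' Text without terminal punctuation is a single sentence. Sentence spans
#' are trimmed of surrounding whitespace, so together they cover all
#' non-whitespace text without overlap.
#'
#' @param text A single character string.
#' @return A tibble with columns `sentence_index` (1-based), `char_start`,
#'   `char_end` (1-based inclusive, into `text`) and `sentence_text`.
#'   Empty or whitespace-only text gives zero rows.
#' @examples
#' split_sentences("He sleeps well. He eats well.")
#' split_sentences("Seen by Dr. Smith today. Reports checking.")
#' @export
split_sentences <- function(text) {
  stopifnot(length(text) == 1L, is.character(text))
  empty <- tibble::tibble(sentence_index = integer(), char_start = integer(),
                          char_end = integer(), sentence_text = character())
  if (is.na(text) || !nzchar(trimws(text))) return(empty)

  n <- nchar(text)
  runs <- locate_all(text, "[.!?]+")
  ends <- integer()
  for (k in seq_len(nrow(runs))) {
    s <- runs$char_start[k]; e <- runs$char_end[k]
    run <- substr(text, s, e)
    after <- substr(text, e + 1L, n)
    at_eot <- !nzchar(trimws(after))
    followed <- grepl("^\\s+[A-Z0-9\"'(]", after)
    if (!at_eot && !followed) next
    if (!grepl("[!?]", run)) {
      # period-only run: check the token immediately before it
      before <- substr(text, 1L, s - 1L)
      tok <- stringr::str_extract(before, "[A-Za-z]+$")
      if (!at_eot && !is.na(tok)) {
        tok_low <- tolower(tok)
        prev_char <- substr(text, s - nchar(tok) - 1L, s - nchar(tok) - 1L)
        single_dotted <- nchar(tok) == 1L && prev_char == "."
        if (tok_low %in% PROTECTED_ABBREVIATIONS || single_dotted) next
      }
    }
    ends <- c(ends, e)
  }
  if (!length(ends) || ends[length(ends)] < n) {
    ends <- c(ends, n)
  }

  starts <- c(1L, head(ends, -1L) + 1L)
  spans <- purrr::map2(starts, ends, function(s, e) {
    seg <- substr(text, s, e)
    lead <- nchar(seg) - nchar(sub("^\\s+", "", seg))
    trail <- nchar(seg) - nchar(sub("\\s+$", "", seg))
    s2 <- s + lead; e2 <- e - trail
    if (s2 > e2) return(NULL)
    tibble::tibble(char_start = as.integer(s2), char_end = as.integer(e2))
  }) %>% dplyr::bind_rows()
  if (!nrow(spans)) return(empty)
  spans %>%
    dplyr::mutate(
      sentence_index = dplyr::row_number(),
      sentence_text = substr(rep(text, dplyr::n()), .data$char_start,
                             .data$char_end)
    ) %>%
    dplyr::select("sentence_index", "char_start", "char_end", "sentence_text")
}

#' Build keyword-anchored context windows ("instances")
#'
#' Each anchor hit yields one instance: the sentence containing the
#' keyword plus up to two sentences on either side (a window of at most
#' five sentences, clipped at the document edges). The window carries the
#' contextual evidence the component detectors and the exclusion engine
#' inspect.
#'
#' @param doc_id Document identifier.
#' @param text Document text.
#' @param hits Keyword hits from [match_keywords()] on `text`; only hits
#'   from anchoring lexicons (see `config$ybocs_anchors`) create
#'   instances.
#' @param sentences Output of [split_sentences()] on `text`; recomputed
#'   when `NULL`.
#' @param config A [detection_config()].
#' @return A tibble with one row per anchor hit: instance identifier,
#'   anchor span/stem/family, anchor sentence index, window sentence range
#'   (`first_sentence`, `last_sentence`), window character span and
#'   `window_text`.
#' @export
extract_instances <- function(doc_id, text, hits, sentences = NULL,
                              config = detection_config()) {
  if (is.null(sentences)) sentences <- split_sentences(text)
  anchor_lex <- "ocs_keywords"
  if (isTRUE(config$ybocs_anchors)) anchor_lex <- c(anchor_lex, "ybocs_keywords")
  anchors <- dplyr::filter(hits, .data$lexicon %in% anchor_lex)
  if (!nrow(anchors) || !nrow(sentences)) return(empty_instances())

  sent_at <- function(pos) {
    i <- which(sentences$char_start <= pos & sentences$char_end >= pos)
    if (length(i)) i[1] else NA_integer_
  }
  anchors$anchor_sentence <- vapply(anchors$char_start, sent_at, integer(1))
  if (anyNA(anchors$anchor_sentence)) {
    stop("internal consistency error: keyword hit outside every sentence span",
         call. = FALSE)
  }
  n <- nrow(sentences)
  anchors %>%
    dplyr::mutate(
      doc_id = doc_id,
      instance_id = sprintf("%s#%03d", doc_id, dplyr::row_number()),
      anchor_family = ifelse(.data$lexicon == "ocs_keywords",
                             ocs_family(.data$stem), "ybocs"),
      first_sentence = pmax(1L, .data$anchor_sentence - 2L),
      last_sentence = pmin(n, .data$anchor_sentence + 2L),
      window_start = sentences$char_start[.data$first_sentence],
      window_end = sentences$char_end[.data$last_sentence],
      window_text = substr(rep(text, dplyr::n()), .data$window_start,
                           .data$window_end)
    ) %>%
    dplyr::select("instance_id", "doc_id",
                  anchor_lexicon = "lexicon", anchor_stem = "stem",
                  anchor_text = "matched_text",
                  anchor_start = "char_start", anchor_end = "char_end",
                  "anchor_family", "anchor_sentence",
                  "first_sentence", "last_sentence",
                  "window_start", "window_end", "window_text")
}

empty_instances <- function() {
  tibble::tibble(
    instance_id = character(), doc_id = character(),
    anchor_lexicon = character(), anchor_stem = character(),
    anchor_text = character(), anchor_start = integer(),
    anchor_end = integer(), anchor_family = character(),
    anchor_sentence = integer(), first_sentence = integer(),
    last_sentence = integer(), window_start = integer(),
    window_end = integer(), window_text = character()
  )
}
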