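#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

LEXICON_NAMES <- c(
  "ocs_keywords", "ybocs_keywords", "insight_keywords",
  "excl_form", "excl_negation", "excl_experiencer",
  "excl_self_description", "excl_hedge",
  "excl_romantic_weight", "excl_risk_selfharm"
)

#' Core OCS keyword families
#'
#' Mapping from the five core keyword stems to the symptom component each
#' one anchors.
#' @keywords internal
OCS_FAMILIES <- c(
  obses  = "obsession",
  compul = "compulsion",
  ocd    = "ocd",
  hoard  = "hoard",
  ritual = "ritual"
)

new_pattern <- function(lexicon, stem, match_mode = "prefix",
                        exceptions = character(), variants = character()) {
  tibble::tibble(
    lexicon = lexicon,
    stem = tolower(stem),
    match_mode = match_mode,
    exceptions = list(tolower(exceptions)),
    variants = list(tolower(variants))
  )
}

#' Built-in keyword and exclusion lexicons
#'
#' Returns the full default rule pack as a tibble of term patterns, one row
#' per pattern, grouped into ten named lexicons:
#'
#' * `ocs_keywords` — the five core symptom families (`obses*`, `compul*`
#'   excluding the token "compulsory", `ocd` with variants `o.c.d` and
#'   `ocs`, `hoard*`, `ritual*`).
#' * `ybocs_keywords` — Yale-Brown Obsessive Compulsive Scale item
#'   vocabulary (cleaning, washing, checking, repeating, counting,
#'   ordering, rearranging) used as supporting evidence.
#' * `insight_keywords` — patient-insight markers (distress, unwanted,
#'   repugnant, repulsive, egodystonic, intrusive thoughts, "unable to
#'   stop").
#' * `excl_form` — word/punctuation combinations characteristic of
#'   questionnaire or form text.
#' * `excl_negation` — plain negation terms (`deny*`, "no history",
#'   "no evidence"); adjacency-style negations ("no/not/than" directly
#'   before a keyword, standalone "none"/"nil") are governed by
#'   [detection_config()].
#' * `excl_experiencer` — words naming someone other than the patient
#'   (kin terms, partners, and the masking pseudonym "qqqqq").
#' * `excl_self_description` — self-diagnosis phrasing ("describes
#'   himself", "says that", "told me", "self-described").
#' * `excl_hedge` — uncertainty markers (`seem*`, `possib*`, `apparent*`,
#'   "sounds like").
#' * `excl_romantic_weight`, `excl_risk_selfharm` — small, deliberately
#'   conservative seed lists for romantic/appetitive and risk-taking
#'   modifiers of the keywords. These two categories are named by the
#'   source coding rules but have no canonical term list, so the defaults
#'   here are editable starting points, not a fixed vocabulary.
#'
#' Matching semantics per `match_mode`:
#' * `prefix` — case-insensitive token-prefix match at a word boundary
#'   ("obses*" matches "obsessive", "obsessional"), minus any tokens in
#'   `exceptions`;
#' * `exact` — whole-token match;
#' * `phrase` — a token sequence separated by arbitrary whitespace.
#'
#' `variants` are literal alternates in which "." and "-" are treated as
#' token-internal (so "o.c.d" matches as one token).
#'
#' @return A tibble of class `ocs_lexicons` with columns `lexicon`, `stem`,
#'   `match_mode`, `exceptions` (list), `variants` (list).
#' @examples
#' lex <- default_lexicons()
#' dplyr::count(lex, lexicon)
#' @export
default_lexicons <- function() {
  pats <- dplyr::bind_rows(
    # core OCS keyword families
    new_pattern("ocs_keywords", "obses"),
    new_pattern("ocs_keywords", "compul", exceptions = "compulsory"),
    new_pattern("ocs_keywords", "ocd", match_mode = "exact",
                variants = c("o.c.d", "ocs")),
    new_pattern("ocs_keywords", "hoard"),
    new_pattern("ocs_keywords", "ritual"),
    # Y-BOCS supporting vocabulary
    new_pattern("ybocs_keywords", "clean"),
    new_pattern("ybocs_keywords", "wash"),
    new_pattern("ybocs_keywords", "check"),
    new_pattern("ybocs_keywords", "repeat"),
    new_pattern("ybocs_keywords", "count"),
    new_pattern("ybocs_keywords", "counting", match_mode = "exact"),
    new_pattern("ybocs_keywords", "order"),
    new_pattern("ybocs_keywords", "rearrange"),
    # patient insight markers
    new_pattern("insight_keywords", "distres"),
    new_pattern("insight_keywords", "unwanted", match_mode = "exact"),
    new_pattern("insight_keywords", "repugnant", match_mode = "exact"),
    new_pattern("insight_keywords", "repulsive", match_mode = "exact"),
    new_pattern("insight_keywords", "egodystonic", match_mode = "exact",
                variants = "ego-dystonic"),
    new_pattern("insight_keywords", "intrusive", match_mode = "exact"),
    new_pattern("insight_keywords", "intruding", match_mode = "exact"),
    new_pattern("insight_keywords", "unable to stop", match_mode = "phrase"),
    # form / questionnaire fragments
    new_pattern("excl_form", "c - obsessive compulsive", match_mode = "phrase"),
    new_pattern("excl_form", "hoarded materials blocking passages",
                match_mode = "phrase"),
    new_pattern("excl_form", "obsessions and compulsions. none",
                match_mode = "phrase"),
    new_pattern("excl_form", "obsessive compulsive index", match_mode = "phrase"),
    new_pattern("excl_form", "oci", match_mode = "exact", variants = "o.c.i"),
    # negation (plain terms; adjacency triggers live in detection_config)
    new_pattern("excl_negation", "deny"),
    new_pattern("excl_negation", "denies", match_mode = "exact"),
    new_pattern("excl_negation", "denied", match_mode = "exact"),
    new_pattern("excl_negation", "denying", match_mode = "exact"),
    new_pattern("excl_negation", "no history", match_mode = "phrase"),
    new_pattern("excl_negation", "no evidence", match_mode = "phrase"),
    # experiencers other than the patient
    new_pattern("excl_experiencer", "mother", match_mode = "exact"),
    new_pattern("excl_experiencer", "father", match_mode = "exact"),
    new_pattern("excl_experiencer", "sister", match_mode = "exact"),
    new_pattern("excl_experiencer", "brother", match_mode = "exact"),
    new_pattern("excl_experiencer", "parent"),
    new_pattern("excl_experiencer", "son", match_mode = "exact"),
    new_pattern("excl_experiencer", "daughter", match_mode = "exact"),
    new_pattern("excl_experiencer", "sibling"),
    new_pattern("excl_experiencer", "family", match_mode = "exact"),
    new_pattern("excl_experiencer", "boyfriend", match_mode = "exact"),
    new_pattern("excl_experiencer", "girlfriend", match_mode = "exact"),
    new_pattern("excl_experiencer", "partner", match_mode = "exact"),
    new_pattern("excl_experiencer", "husband", match_mode = "exact"),
    new_pattern("excl_experiencer", "wife", match_mode = "exact"),
    new_pattern("excl_experiencer", "qqqqq", match_mode = "exact"),
    # self-diagnosis phrasing
    new_pattern("excl_self_description", "self described", match_mode = "phrase",
                variants = "self-described"),
    new_pattern("excl_self_description", "describes himself", match_mode = "phrase"),
    new_pattern("excl_self_description", "described himself", match_mode = "phrase"),
    new_pattern("excl_self_description", "describes herself", match_mode = "phrase"),
    new_pattern("excl_self_description", "described herself", match_mode = "phrase"),
    new_pattern("excl_self_description", "describe himself", match_mode = "phrase"),
    new_pattern("excl_self_description", "describe herself", match_mode = "phrase"),
    new_pattern("excl_self_description", "says that", match_mode = "phrase"),
    new_pattern("excl_self_description", "say that", match_mode = "phrase"),
    new_pattern("excl_self_description", "said that", match_mode = "phrase"),
    new_pattern("excl_self_description", "saying that", match_mode = "phrase"),
    new_pattern("excl_self_description", "told me", match_mode = "phrase"),
    new_pattern("excl_self_description", "tells me", match_mode = "phrase"),
    # hedges
    new_pattern("excl_hedge", "seem"),
    new_pattern("excl_hedge", "possib"),
    new_pattern("excl_hedge", "apparent"),
    new_pattern("excl_hedge", "sounds like", match_mode = "phrase"),
    new_pattern("excl_hedge", "sound like", match_mode = "phrase"),
    new_pattern("excl_hedge", "sounded like", match_mode = "phrase"),
    # romantic / weight modifiers (seed list, editable)
    new_pattern("excl_romantic_weight", "girlfriend", match_mode = "exact"),
    new_pattern("excl_romantic_weight", "boyfriend", match_mode = "exact"),
    new_pattern("excl_romantic_weight", "love"),
    new_pattern("excl_romantic_weight", "crush", match_mode = "exact"),
    new_pattern("excl_romantic_weight", "romantic"),
    new_pattern("excl_romantic_weight", "food", match_mode = "exact"),
    new_pattern("excl_romantic_weight", "eating", match_mode = "exact"),
    new_pattern("excl_romantic_weight", "weight", match_mode = "exact"),
    new_pattern("excl_romantic_weight", "diet"),
    # risk / self-harm modifiers (seed list, editable)
    new_pattern("excl_risk_selfharm", "gambl"),
    new_pattern("excl_risk_selfharm", "risk"),
    new_pattern("excl_risk_selfharm", "self harm", match_mode = "phrase",
                variants = "self-harm"),
    new_pattern("excl_risk_selfharm", "suicid")
  )
  validate_lexicons(pats)
}

validate_lexicons <- function(pats) {
  stopifnot(is.data.frame(pats))
  required <- c("lexicon", "stem", "match_mode", "exceptions", "variants")
  missing <- setdiff(required, names(pats))
  if (length(missing)) {
    stop("lexicon table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(pats$lexicon), LEXICON_NAMES)
  if (length(bad)) {
    stop("unknown lexicon name(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(LEXICON_NAMES, collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(pats$stem))) stop("empty stem in lexicon table", call. = FALSE)
  bad_mode <- setdiff(unique(pats$match_mode), c("prefix", "exact", "phrase"))
  if (length(bad_mode)) {
    stop("unknown match_mode: ", paste(bad_mode, collapse = ", "), call. = FALSE)
  }
  dup <- pats %>%
    dplyr::count(.data$lexicon, .data$stem) %>%
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    stop("duplicate stem(s) within a lexicon: ",
         paste(dup$lexicon, dup$stem, sep = "/", collapse = ", "), call. = FALSE)
  }
  class(pats) <- c("ocs_lexicons", class(setdiff_class(pats)))
  pats
}

setdiff_class <- function(x) {
  class(x) <- setdiff(class(x), "ocs_lexicons")
  x
}

#' Load a lexicon configuration file
#'
#' Reads a YAML or JSON rule pack and merges it over [default_lexicons()].
#' The file maps lexicon names to lists of patterns:
#' ```yaml
#' ocs_keywords:
#'   - stem: ruminat
#'     match_mode: prefix
#' ```
#' Each pattern may carry `stem` (required), `match_mode`
#' (prefix/exact/phrase, default prefix), `exceptions` and `variants`.
#' Listed patterns are appended to the named default lexicon; a lexicon
#' entry with `replace: true` at pattern-list level is not supported —
#' supply the full list under `replace_<name>` semantics is intentionally
#' out of scope to keep configs additive and auditable.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file, or `NULL` for the
#'   defaults unchanged.
#' @return An `ocs_lexicons` tibble.
#' @export
load_lexicons <- function(path = NULL) {
  base <- default_lexicons()
  if (is.null(path)) return(base)
  if (!file.exists(path)) stop("lexicon config not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg) || length(cfg) == 0) return(base)
  if (is.null(names(cfg)) || any(!nzchar(names(cfg)))) {
    stop("lexicon config must be a named map of lexicon -> pattern list",
         call. = FALSE)
  }
  bad <- setdiff(names(cfg), LEXICON_NAMES)
  if (length(bad)) {
    stop("unknown lexicon name(s) in config: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  extra <- purrr::imap(cfg, function(patterns, lex_name) {
    purrr::map(patterns, function(p) {
      if (is.null(p$stem) || !nzchar(p$stem)) {
        stop("pattern in lexicon '", lex_name, "' is missing field 'stem'",
             call. = FALSE)
      }
      new_pattern(
        lexicon = lex_name,
        stem = p$stem,
        match_mode = p$match_mode %||% "prefix",
        exceptions = as.character(unlist(p$exceptions %||% character())),
        variants = as.character(unlist(p$variants %||% character()))
      )
    }) %>% dplyr::bind_rows()
  }) %>% dplyr::bind_rows()
  validate_lexicons(dplyr::bind_rows(setdiff_class(base), extra))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map a core keyword stem to its symptom component
#'
#' @param stem Character vector of lexicon stems.
#' @return Component names ("obsession", "compulsion", "ocd", "hoard",
#'   "ritual"); stems added by the user map to themselves.
#' @keywords internal
ocs_family <- function(stem) {
  out <- unname(OCS_FAMILIES[stem])
  ifelse(is.na(out), stem, out)
}
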