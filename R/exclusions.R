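EXCLUSION_CATEGORIES <- c(
  "form", "negation", "other_experiencer", "hedge", "self_diagnosis",
  "romantic_weight", "risk_selfharm"
)

#' Detection configuration
#'
#' Tunable switches for the detector. The defaults reproduce the final
#' combined algorithm: all five positive routes enabled, all seven
#' exclusion categories enabled, and Y-BOCS keywords acting as supporting
#' evidence only (not as instance anchors).
#'
#' @param ybocs_anchors Should Y-BOCS keywords (checking, cleaning, ...)
#'   anchor instances of their own? Default `FALSE`: Y-BOCS vocabulary is
#'   ubiquitous in clinical text, so by default it corroborates a core
#'   OCS keyword rather than creating instances itself.
#' @param routes Named logical vector enabling each positive route.
#' @param exclusions Named logical vector enabling each exclusion
#'   category.
#' @param negation_adjacent Tokens that negate a keyword when they precede
#'   it with at most `negation_gap` intervening tokens in the same
#'   sentence (covers "no current obsessions", "not obsessional", "rather
#'   than an obsession").
#' @param negation_standalone Tokens ("none", "nil") that negate when
#'   sentence-initial or within `negation_gap` tokens of a keyword on
#'   either side.
#' @param negation_gap Maximum intervening tokens for adjacency negation.
#' @param hedge_precede A hedge outside the anchor sentence fires if it
#'   lies within this many tokens before the anchor keyword.
#' @param modifier_gap Romantic/weight and risk/self-harm triggers must
#'   fall within this many tokens of the anchor keyword to veto (they are
#'   modifier rules, not mere co-occurrence rules).
#' @return A list of class `ocs_config`.
#' @export
detection_config <- function(ybocs_anchors = FALSE,
                             routes = c(ocd_stated = TRUE,
                                        hoarding_any = TRUE,
                                        two_plus_keywords = TRUE,
                                        keyword_plus_ybocs = TRUE,
                                        keyword_plus_insight = TRUE),
                             exclusions = c(form = TRUE,
                                            negation = TRUE,
                                            other_experiencer = TRUE,
                                            hedge = TRUE,
                                            self_diagnosis = TRUE,
                                            romantic_weight = TRUE,
                                            risk_selfharm = TRUE),
                             negation_adjacent = c("no", "not", "than"),
                             negation_standalone = c("none", "nil"),
                             negation_gap = 2L,
                             hedge_precede = 5L,
                             modifier_gap = 3L) {
  route_names <- c("ocd_stated", "hoarding_any", "two_plus_keywords",
                   "keyword_plus_ybocs", "keyword_plus_insight")
  r <- c(ocd_stated = TRUE, hoarding_any = TRUE, two_plus_keywords = TRUE,
         keyword_plus_ybocs = TRUE, keyword_plus_insight = TRUE)
  stopifnot(all(names(routes) %in% route_names),
            all(names(exclusions) %in% EXCLUSION_CATEGORIES))
  r[names(routes)] <- routes
  e <- stats::setNames(rep(TRUE, length(EXCLUSION_CATEGORIES)),
                       EXCLUSION_CATEGORIES)
  e[names(exclusions)] <- exclusions
  structure(
    list(ybocs_anchors = isTRUE(ybocs_anchors), routes = r, exclusions = e,
         negation_adjacent = tolower(negation_adjacent),
         negation_standalone = tolower(negation_standalone),
         negation_gap = as.integer(negation_gap),
         hedge_precede = as.integer(hedge_precede),
         modifier_gap = as.integer(modifier_gap)),
    class = "ocs_config"
  )
}

excl_result <- function(category, trigger_text, char_start, char_end, scope) {
  tibble::tibble(category = category, trigger_text = trigger_text,
                 char_start = as.integer(char_start),
                 char_end = as.integer(char_end), scope = scope)
}

empty_exclusions <- function() {
  excl_result(character(), character(), integer(), integer(), character())
}

# All checks are pure functions of (window_text, anchor position within the
# window, lexicons, config). The anchor sentence is recovered by
# re-splitting the window text. The context is computed once per instance
# and shared across the seven checks.
window_context <- function(instance) {
  wt <- instance$window_text
  sents <- split_sentences(wt)
  a_start <- instance$anchor_start - instance$window_start + 1L
  a_end <- instance$anchor_end - instance$window_start + 1L
  i <- which(sents$char_start <= a_start & sents$char_end >= a_start)
  anchor_sent <- if (length(i)) sents[i[1], ] else sents[1, ]
  list(window_text = wt, sentences = sents, anchor_sentence = anchor_sent,
       anchor_start = a_start, anchor_end = a_end, tokens = tokenize(wt))
}

lex_hits_in <- function(text, lexicons, lexicon_name, offset = 0L) {
  h <- match_keywords(text, lexicons, lexicon_name)
  if (nrow(h) && offset != 0L) {
    h$char_start <- h$char_start + offset
    h$char_end <- h$char_end + offset
  }
  h
}

anchor_sentence_text <- function(ctx) ctx$anchor_sentence$sentence_text[1]
anchor_sentence_offset <- function(ctx) ctx$anchor_sentence$char_start[1] - 1L

check_form_ctx <- function(ctx, lexicons, config) {
  h <- lex_hits_in(ctx$window_text, lexicons, "excl_form")
  if (!nrow(h)) return(empty_exclusions())
  excl_result("form", h$matched_text, h$char_start, h$char_end, "window")
}

check_negation_ctx <- function(ctx, lexicons, config) {
  sent <- anchor_sentence_text(ctx)
  off <- anchor_sentence_offset(ctx)
  out <- list()

  h <- lex_hits_in(sent, lexicons, "excl_negation", offset = off)
  if (nrow(h)) {
    out <- c(out, list(excl_result("negation", h$matched_text, h$char_start,
                                   h$char_end, "keyword_sentence")))
  }

  toks <- tokenize(sent)
  kw <- match_keywords(sent, lexicons, "ocs_keywords")
  if (nrow(kw) && toks$n) {
    kw_idx <- vapply(kw$char_start, function(p) token_index_at(toks, p),
                     integer(1))
    kw_idx <- sort(unique(kw_idx[!is.na(kw_idx)]))
    gap <- config$negation_gap
    for (i in which(toks$token %in% config$negation_adjacent)) {
      near <- kw_idx[kw_idx > i & kw_idx - i <= gap + 1L]
      if (length(near)) {
        out <- c(out, list(excl_result(
          "negation", paste(toks$token[i], toks$token[near[1]]),
          toks$char_start[i] + off, toks$char_end[near[1]] + off,
          "keyword_sentence")))
      }
    }
    for (i in which(toks$token %in% config$negation_standalone)) {
      if (i == 1L || any(abs(kw_idx - i) <= gap + 1L)) {
        out <- c(out, list(excl_result(
          "negation", toks$token[i],
          toks$char_start[i] + off, toks$char_end[i] + off,
          "keyword_sentence")))
      }
    }
  }
  if (!length(out)) return(empty_exclusions())
  res <- dplyr::bind_rows(out)
  res[order(res$char_start), ]
}

check_experiencer_ctx <- function(ctx, lexicons, config) {
  h <- lex_hits_in(anchor_sentence_text(ctx), lexicons, "excl_experiencer",
                   offset = anchor_sentence_offset(ctx))
  if (!nrow(h)) return(empty_exclusions())
  excl_result("other_experiencer", h$matched_text, h$char_start, h$char_end,
              "keyword_sentence")
}

check_hedge_ctx <- function(ctx, lexicons, config) {
  h <- lex_hits_in(ctx$window_text, lexicons, "excl_hedge")
  if (!nrow(h)) return(empty_exclusions())
  sent <- ctx$anchor_sentence
  in_sentence <- h$char_start >= sent$char_start & h$char_start <= sent$char_end
  anchor_tok <- token_index_at(ctx$tokens, ctx$anchor_start)
  hedge_tok <- vapply(h$char_start, function(p) token_index_at(ctx$tokens, p),
                      integer(1))
  precedes <- !is.na(anchor_tok) & !is.na(hedge_tok) &
    hedge_tok < anchor_tok & (anchor_tok - hedge_tok) <= config$hedge_precede
  keep <- in_sentence | precedes
  if (!any(keep)) return(empty_exclusions())
  h <- h[keep, , drop = FALSE]
  excl_result("hedge", h$matched_text, h$char_start, h$char_end,
              ifelse(in_sentence[keep], "keyword_sentence", "window"))
}

check_self_diagnosis_ctx <- function(ctx, lexicons, config) {
  h <- lex_hits_in(ctx$window_text, lexicons, "excl_self_description")
  if (!nrow(h)) return(empty_exclusions())
  excl_result("self_diagnosis", h$matched_text, h$char_start, h$char_end,
              "window")
}

# Romantic/weight and risk/self-harm triggers only veto when they modify
# the anchor keyword, operationalised as token distance <= modifier_gap.
check_modifier_ctx <- function(ctx, lexicons, lexicon_name, category, config) {
  h <- lex_hits_in(ctx$window_text, lexicons, lexicon_name)
  if (!nrow(h)) return(empty_exclusions())
  anchor_tok <- token_index_at(ctx$tokens, ctx$anchor_start)
  trig_tok <- vapply(h$char_start, function(p) token_index_at(ctx$tokens, p),
                     integer(1))
  keep <- !is.na(anchor_tok) & !is.na(trig_tok) &
    abs(trig_tok - anchor_tok) <= config$modifier_gap
  if (!any(keep)) return(empty_exclusions())
  h <- h[keep, , drop = FALSE]
  excl_result(category, h$matched_text, h$char_start, h$char_end, "window")
}

EXCLUSION_CHECKS <- list(
  form = check_form_ctx,
  negation = check_negation_ctx,
  other_experiencer = check_experiencer_ctx,
  hedge = check_hedge_ctx,
  self_diagnosis = check_self_diagnosis_ctx,
  romantic_weight = function(ctx, lexicons, config) {
    check_modifier_ctx(ctx, lexicons, "excl_romantic_weight",
                       "romantic_weight", config)
  },
  risk_selfharm = function(ctx, lexicons, config) {
    check_modifier_ctx(ctx, lexicons, "excl_risk_selfharm",
                       "risk_selfharm", config)
  }
)

#' Exclusion checks
#'
#' Each check inspects one instance (a row from [extract_instances()]) and
#' returns the exclusion triggers it finds, as a tibble with columns
#' `category`, `trigger_text`, `char_start`/`char_end` (window-relative,
#' 1-based) and `scope`. Scopes follow the rule set: negation and
#' experiencer terms must share the anchor keyword's sentence; form and
#' self-diagnosis patterns may occur anywhere in the window; a hedge fires
#' in the anchor sentence or within a few tokens before the keyword
#' elsewhere in the window; romantic/weight and risk/self-harm terms must
#' sit close enough to the keyword to modify it.
#'
#' @param instance A single-row tibble from [extract_instances()].
#' @param lexicons An `ocs_lexicons` tibble.
#' @param config A [detection_config()].
#' @return A tibble of exclusion results (zero rows when clean).
#' @name exclusion-checks
NULL

#' @rdname exclusion-checks
#' @export
check_form <- function(instance, lexicons, config = detection_config()) {
  check_form_ctx(window_context(instance), lexicons, config)
}

#' @rdname exclusion-checks
#' @export
check_negation <- function(instance, lexicons, config = detection_config()) {
  check_negation_ctx(window_context(instance), lexicons, config)
}

#' @rdname exclusion-checks
#' @export
check_experiencer <- function(instance, lexicons, config = detection_config()) {
  check_experiencer_ctx(window_context(instance), lexicons, config)
}

#' @rdname exclusion-checks
#' @export
check_hedge <- function(instance, lexicons, config = detection_config()) {
  check_hedge_ctx(window_context(instance), lexicons, config)
}

#' @rdname exclusion-checks
#' @export
check_self_diagnosis <- function(instance, lexicons,
                                 config = detection_config()) {
  check_self_diagnosis_ctx(window_context(instance), lexicons, config)
}

#' @rdname exclusion-checks
#' @export
check_romantic_weight <- function(instance, lexicons,
                                  config = detection_config()) {
  check_modifier_ctx(window_context(instance), lexicons,
                     "excl_romantic_weight", "romantic_weight", config)
}

#' @rdname exclusion-checks
#' @export
check_risk_selfharm <- function(instance, lexicons,
                                config = detection_config()) {
  check_modifier_ctx(window_context(instance), lexicons,
                     "excl_risk_selfharm", "risk_selfharm", config)
}

#' Run every exclusion check on an instance
#'
#' Evaluates all enabled exclusion categories exhaustively (no
#' short-circuiting, so the audit trail lists every trigger) in fixed
#' order: form, negation, other_experiencer, hedge, self_diagnosis,
#' romantic_weight, risk_selfharm. Any non-empty result vetoes the
#' instance: exclusions always take precedence over inclusion evidence.
#'
#' @inheritParams exclusion-checks
#' @return A tibble of exclusion results in category order.
#' @examples
#' lex <- default_lexicons()
#' inst <- classify_document("His mother has OCD.", lexicons = lex)$instances
#' inst$exclusions[[1]]
#' @export
apply_exclusions <- function(instance, lexicons, config = detection_config()) {
  ctx <- window_context(instance)
  enabled <- names(EXCLUSION_CHECKS)[config$exclusions[names(EXCLUSION_CHECKS)]]
  out <- lapply(EXCLUSION_CHECKS[enabled],
                function(f) f(ctx, lexicons, config))
  dplyr::bind_rows(out)
}
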