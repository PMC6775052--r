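# Seeded generator of labelled pseudo-clinical notes. Templates are built
# from the same lexicon stock as the detector, so template gold labels are
# correct by construction under the coding rules; no real patient text (or
# anything derived from it) appears anywhere.

POSITIVE_CATEGORIES <- c("ocd_stated", "hoarding_any", "two_plus_keywords",
                         "keyword_plus_ybocs", "keyword_plus_insight")
NEGATIVE_CATEGORIES <- c("bare_keyword", "negated", "other_experiencer",
                         "hedged", "self_diagnosed", "form_fragment",
                         "lay_usage")

# Keyword-free clinical-flavoured filler bank. Nothing here matches any
# lexicon pattern or negation/hedge trigger, so fillers can sit inside any
# context window without changing a verdict.
FILLER_SENTENCES <- c(
  "Attended the outpatient appointment on time.",
  "Mood was euthymic throughout the meeting.",
  "Medication adherence was discussed at length.",
  "Sleep has improved over recent weeks.",
  "Appetite remains good.",
  "He engaged well during the session.",
  "Plan to see him again in two months.",
  "Bloods were taken at the surgery this morning.",
  "Mental state examination was unremarkable.",
  "Currently attending the community day programme.",
  "Housing situation remains stable.",
  "Speech was normal in rate and tone.",
  "Reports feeling brighter in himself.",
  "No change was made to the current care plan.",
  "Continues to collect his prescription weekly."
)

run_with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

lower_first <- function(x) {
  paste0(tolower(substr(x, 1, 1)), substr(x, 2, nchar(x)))
}

#' Generator configuration
#'
#' Study-condition knobs for the synthetic corpus. Default rates give a
#' balanced half-positive, half-negative mix across every inclusion route
#' and every exclusion category, emulating a keyword-filtered note sample
#' in which each document carries at least one keyword instance.
#'
#' @param n_docs Number of documents (>= 1).
#' @param seed Integer seed; the generator derives one sub-seed per
#'   document from it (counter-based), so regenerating with the same seed
#'   is byte-identical and adding documents does not reshuffle earlier
#'   ones.
#' @param rates Named non-negative weights over the twelve template
#'   categories (five positive routes, seven negative situations); need
#'   not sum to 1.
#' @param fillers Integer range (length 2) for the number of keyword-free
#'   filler sentences per document.
#' @param second_template_prob Probability a document carries a second,
#'   well-separated template sentence (multi-instance documents).
#' @return A list of class `ocs_generator_config`.
#' @export
generator_config <- function(n_docs = 100, seed = 1,
                             rates = NULL,
                             fillers = c(3L, 8L),
                             second_template_prob = 0.25) {
  default_rates <- c(
    ocd_stated = 0.08, hoarding_any = 0.08, two_plus_keywords = 0.12,
    keyword_plus_ybocs = 0.12, keyword_plus_insight = 0.10,
    bare_keyword = 0.10, negated = 0.10, other_experiencer = 0.08,
    hedged = 0.08, self_diagnosed = 0.06, form_fragment = 0.04,
    lay_usage = 0.04
  )
  r <- default_rates
  if (!is.null(rates)) {
    bad <- setdiff(names(rates), names(default_rates))
    if (length(bad)) stop("unknown rate category: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    r[] <- 0
    r[names(rates)] <- rates
  }
  if (any(r < 0) || sum(r) <= 0) {
    stop("rates must be non-negative with positive sum", call. = FALSE)
  }
  stopifnot(n_docs >= 1, length(fillers) == 2L, fillers[1] >= 0,
            fillers[2] >= fillers[1])
  structure(
    list(n_docs = as.integer(n_docs), seed = as.integer(seed), rates = r,
         fillers = as.integer(fillers),
         second_template_prob = second_template_prob),
    class = "ocs_generator_config"
  )
}

subject_slot <- function() sample(c("He", "She", "The patient"), 1)

template_sentence <- function(category) {
  s <- subject_slot()
  switch(
    category,
    ocd_stated = sample(c(
      paste(s, "has OCD features at present."),
      paste(s, "has clear OCD symptoms."),
      "Diagnosed with OCD by the consultant psychiatrist.",
      paste(s, "was diagnosed with OCD last year.")
    ), 1),
    hoarding_any = sample(c(
      paste(s, "has been hoarding newspapers and magazines."),
      "There is marked hoarding at the property.",
      paste(s, "continues to hoard old letters and boxes.")
    ), 1),
    two_plus_keywords = sample(c(
      paste(s, "reports both obsessions and compulsions."),
      paste(s, "describes obsessional thoughts and daily rituals."),
      paste(s, "presents with compulsions and rituals around bedtime.")
    ), 1),
    keyword_plus_ybocs = {
      ex <- sample(c("washing", "checking", "cleaning", "counting"), 1)
      sample(c(
        paste0(s, " reports compulsive ", ex, " most days."),
        paste0("Obsessional thoughts about contamination, with repeated ",
               ex, "."),
        paste0(s, " performs rituals of ", ex, " each evening.")
      ), 1)
    },
    keyword_plus_insight = sample(c(
      paste(s, "describes intrusive obsessional thoughts causing marked",
            "distress."),
      "Obsessional imagery which she finds repugnant and distressing.",
      paste(s, "feels unable to stop the rituals."),
      paste(s, "reports unwanted compulsions that cause significant",
            "distress.")
    ), 1),
    bare_keyword = sample(c(
      paste(s, "mentioned obsessions in passing."),
      "Brief mention of compulsions at review.",
      "Rituals were raised at assessment."
    ), 1),
    negated = sample(c(
      paste(s, "denies obsessions and compulsions."),
      "No evidence of compulsive behaviour at present.",
      "There is no history of rituals.",
      "Nil obsessions reported.",
      paste(s, "is not obsessional about anything.")
    ), 1),
    other_experiencer = {
      kin <- sample(c("mother", "father", "sister", "brother", "husband",
                      "wife"), 1)
      sample(c(
        paste0("His ", kin, " has obsessions and compulsions."),
        paste0("Her ", kin, " is known to have OCD."),
        "Qqqqq has been hoarding for many years."
      ), 1)
    },
    hedged = sample(c(
      "Possible OCD was considered at the meeting.",
      paste(s, "seems obsessional at times, with frequent checking."),
      "Apparently performs compulsive washing at home.",
      "It sounds like compulsive checking."
    ), 1),
    self_diagnosed = sample(c(
      paste(s, "says that she has OCD."),
      paste(s, "described himself as obsessional and ritualistic."),
      paste(s, "told me that he has OCD and compulsions.")
    ), 1),
    form_fragment = sample(c(
      paste0("Obsessive Compulsive Index (OCI): ", sample(5:30, 1), "."),
      "Obsessions and compulsions. None reported this week.",
      "C - Obsessive compulsive screening section."
    ), 1),
    lay_usage = sample(c(
      paste(s, "is obsessed with football these days."),
      paste(s, "describes a compulsion to gamble at weekends."),
      "Obsessed with video games lately.",
      paste(s, "is obsessed with her new boyfriend.")
    ), 1),
    stop("unknown template category: ", category, call. = FALSE)
  )
}

build_document_sentences <- function(doc_id, cfg) {
  cats <- names(cfg$rates)
  prob <- cfg$rates / sum(cfg$rates)
  n_templates <- 1L + stats::rbinom(1, 1, cfg$second_template_prob)
  chosen <- sample(cats, n_templates, replace = TRUE, prob = prob)
  n_fill <- sample(seq(cfg$fillers[1], cfg$fillers[2]), 1)
  n_fill <- max(n_fill, 2L * (n_templates - 1L))
  fillers <- sample(FILLER_SENTENCES, n_fill, replace = TRUE)

  # layout: fillers before / >=2 between templates / after, so that no
  # template sentence ever falls inside another template's context window
  if (n_templates == 1L) {
    cut1 <- sample(0:n_fill, 1)
    parts <- list(fillers[seq_len(cut1)], chosen[1],
                  fillers[seq_len(n_fill - cut1) + cut1])
    cats_seq <- c(rep(NA, cut1), chosen[1], rep(NA, n_fill - cut1))
  } else {
    between <- 2L
    rest <- n_fill - between
    cut1 <- sample(0:rest, 1)
    cats_seq <- c(rep(NA, cut1), chosen[1], rep(NA, between), chosen[2],
                  rep(NA, rest - cut1))
  }
  texts <- character(length(cats_seq))
  fi <- 1L
  for (i in seq_along(cats_seq)) {
    if (is.na(cats_seq[i])) {
      texts[i] <- fillers[fi]; fi <- fi + 1L
    } else {
      texts[i] <- template_sentence(cats_seq[i])
    }
  }
  tibble::tibble(
    doc_id = doc_id,
    position = seq_along(texts),
    sentence_text = texts,
    category = ifelse(is.na(cats_seq), "filler", cats_seq),
    gold_label = dplyr::case_when(
      is.na(cats_seq) ~ NA_character_,
      cats_seq %in% POSITIVE_CATEGORIES ~ "positive",
      TRUE ~ "negative"
    )
  )
}

# Assemble documents and enumerate gold instances. Anchors are located
# with the same matcher/config the detector uses, so instance identifiers
# line up with detect_ocs(); each anchor inherits the gold label of the
# generator sentence it falls in (fillers contain no anchors by
# construction).
assemble_synthetic <- function(sentences, lexicons, config) {
  docs <- sentences %>%
    dplyr::group_by(.data$doc_id) %>%
    dplyr::summarise(text = paste(.data$sentence_text, collapse = " "),
                     .groups = "drop")
  gold <- purrr::map(docs$doc_id, function(id) {
    tx <- docs$text[docs$doc_id == id]
    sent <- sentences[sentences$doc_id == id, ]
    starts <- cumsum(c(1L, utils::head(nchar(sent$sentence_text) + 1L, -1L)))
    ends <- starts + nchar(sent$sentence_text) - 1L
    hits <- match_keywords(tx, lexicons, c("ocs_keywords", "ybocs_keywords"))
    inst <- extract_instances(id, tx, hits, split_sentences(tx), config)
    if (!nrow(inst)) return(NULL)
    src <- vapply(inst$anchor_start, function(p) {
      i <- which(starts <= p & ends >= p)
      if (length(i)) i[1] else NA_integer_
    }, integer(1))
    tibble::tibble(
      doc_id = id, instance_id = inst$instance_id,
      char_start = inst$anchor_start, char_end = inst$anchor_end,
      category = sent$category[src],
      label = sent$gold_label[src]
    )
  }) %>% dplyr::bind_rows()
  if (anyNA(gold$label)) {
    stop("internal generator error: keyword anchor inside a filler sentence",
         call. = FALSE)
  }
  gold_docs <- gold %>%
    dplyr::group_by(.data$doc_id) %>%
    dplyr::summarise(label = ifelse(any(.data$label == "positive"),
                                    "positive", "negative"),
                     .groups = "drop")
  gold_docs <- docs %>%
    dplyr::select("doc_id") %>%
    dplyr::left_join(gold_docs, by = "doc_id") %>%
    dplyr::mutate(label = tidyr::replace_na(.data$label, "negative"))
  structure(
    list(corpus = docs, gold_instances = gold, gold_documents = gold_docs,
         sentences = sentences),
    class = "ocs_synthetic"
  )
}

#' Generate a labelled synthetic corpus
#'
#' Builds pseudo-clinical notes by mixing keyword-free filler sentences
#' with template sentences instantiating every inclusion route (OCD
#' statements, hoarding, two keyword families, keyword plus Y-BOCS
#' example, keyword plus insight marker) and every exclusion situation
#' (bare keywords, negation, non-patient experiencers, hedges,
#' self-diagnosis, questionnaire fragments, lay/figurative usage). Gold
#' labels at instance and document level follow from the template
#' category; the document label is the any-positive roll-up.
#'
#' @param config A [generator_config()].
#' @param lexicons Lexicons shared with the detector (defaults to
#'   [default_lexicons()]); templates and rules drawing on one lexicon
#'   source is what makes the generator's labels exact.
#' @param detection A [detection_config()] (controls anchor enumeration
#'   for the gold instance table).
#' @return An object of class `ocs_synthetic`: list with `corpus`
#'   (doc_id, text), `gold_instances` (doc_id, instance_id, span,
#'   category, label), `gold_documents` and `sentences` (per-sentence
#'   provenance).
#' @examples
#' synth <- generate_corpus(generator_config(n_docs = 5, seed = 42))
#' synth$gold_documents
#' @export
generate_corpus <- function(config = generator_config(),
                            lexicons = default_lexicons(),
                            detection = detection_config()) {
  sentences <- purrr::map(seq_len(config$n_docs), function(i) {
    doc_seed <- ((config$seed %% 65011) * 32717 + i * 7919) %% 2147483647
    run_with_seed(doc_seed, {
      build_document_sentences(sprintf("synth%04d", i), config)
    })
  }) %>% dplyr::bind_rows()
  assemble_synthetic(sentences, lexicons, detection)
}

#' @export
print.ocs_synthetic <- function(x, ...) {
  cat("<ocs_synthetic>\n")
  cat("  documents:", nrow(x$corpus), "\n")
  cat("  gold instances:", nrow(x$gold_instances),
      sprintf("(%d positive)", sum(x$gold_instances$label == "positive")),
      "\n")
  invisible(x)
}

#' Perturb gold-positive instances
#'
#' Rewrites the template sentence of every gold-positive instance to
#' insert an exclusion trigger (negation, hedge or non-patient
#' experiencer) or to swap in a lay usage, re-labels those sentences
#' gold-negative, and reassembles the corpus. Used to test the
#' monotonicity contract: adding an exclusion trigger to a positive
#' mention must flip the predicted verdict.
#'
#' @param synthetic An `ocs_synthetic` object.
#' @param perturbation One of "add_negation", "add_hedge",
#'   "add_experiencer", "swap_lay_usage".
#' @param lexicons,detection As in [generate_corpus()].
#' @return A new `ocs_synthetic` object (identity when the corpus has no
#'   gold-positive instances).
#' @export
perturb_corpus <- function(synthetic,
                           perturbation = c("add_negation", "add_hedge",
                                            "add_experiencer",
                                            "swap_lay_usage"),
                           lexicons = default_lexicons(),
                           detection = detection_config()) {
  perturbation <- match.arg(perturbation)
  sentences <- synthetic$sentences
  target <- !is.na(sentences$gold_label) & sentences$gold_label == "positive"
  if (!any(target)) return(synthetic)
  rewrite <- function(text) {
    switch(perturbation,
      add_negation = paste("Denies the following -", lower_first(text)),
      add_hedge = paste("Possibly", lower_first(text)),
      add_experiencer = paste("Regarding his mother,", lower_first(text)),
      swap_lay_usage = "He is obsessed with football."
    )
  }
  sentences$sentence_text[target] <-
    vapply(sentences$sentence_text[target], rewrite, character(1),
           USE.NAMES = FALSE)
  sentences$gold_label[target] <- "negative"
  sentences$category[target] <- paste0(sentences$category[target], ":",
                                       perturbation)
  out <- assemble_synthetic(sentences, lexicons, detection)
  out
}
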