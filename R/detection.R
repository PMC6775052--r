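COMPONENTS <- c("obsession", "compulsion", "ocd", "hoard", "ritual")
FIRED_RULES <- c("ocd_stated", "hoarding_any", "two_plus_keywords",
                 "keyword_plus_ybocs", "keyword_plus_insight",
                 "clinician_diagnosis", "none")

window_evidence <- function(instance, lexicons) {
  wt <- instance$window_text
  ocs <- match_keywords(wt, lexicons, "ocs_keywords")
  ybocs <- match_keywords(wt, lexicons, "ybocs_keywords")
  insight <- match_keywords(wt, lexicons, "insight_keywords")
  a_start <- instance$anchor_start - instance$window_start + 1L
  a_end <- instance$anchor_end - instance$window_start + 1L
  if (identical(instance$anchor_lexicon, "ybocs_keywords") && nrow(ybocs)) {
    ybocs <- dplyr::filter(ybocs, !(.data$char_start == a_start &
                                      .data$char_end == a_end))
  }
  list(ocs = ocs, ybocs = ybocs, insight = insight,
       families = unique(ocs_family(ocs$stem)),
       has_diagnosis = grepl("\\bdiagnos", wt, ignore.case = TRUE))
}

#' Component-level detection for one instance
#'
#' Applies the positive inclusion routes to an instance's context window
#' and returns the verdict for the anchored component. The routes, in
#' precedence order:
#'
#' 1. `ocd_stated` / `clinician_diagnosis` — the anchor is the OCD family
#'    (a statement that the patient has OCD features or a clinician
#'    diagnosis suffices on its own);
#' 2. `hoarding_any` — the anchor is the hoarding family (hoarding counts
#'    regardless of further examples);
#' 3. `two_plus_keywords` — at least two distinct core keyword families
#'    occur in the window (distinct families, not repeated tokens of one
#'    family, so "obsessions and obsessional" does not self-corroborate);
#' 4. `keyword_plus_ybocs` / `keyword_plus_insight` — exactly one core
#'    family (obsession/compulsion/ritual), or a Y-BOCS anchor, supported
#'    by at least one Y-BOCS example or one patient-insight marker
#'    anywhere in the window.
#'
#' Exclusions are not consulted here; see [classify_instance()].
#'
#' @param instance A single-row tibble from [extract_instances()].
#' @param lexicons An `ocs_lexicons` tibble.
#' @param config A [detection_config()].
#' @param component Component to report; defaults to the anchor's family.
#'   Must be one of obsession, compulsion, ocd, hoard, ritual.
#' @return A one-row tibble: `component`, `positive`, `fired_rule`,
#'   `n_families`, `n_ybocs_support`, `n_insight_support`.
#' @export
detect_component <- function(instance, lexicons, config = detection_config(),
                             component = NULL) {
  if (is.null(component)) {
    component <- if (identical(instance$anchor_lexicon, "ybocs_keywords")) {
      "compulsion"
    } else {
      instance$anchor_family
    }
  }
  if (!component %in% COMPONENTS) {
    stop("unknown component: ", component, call. = FALSE)
  }
  ev <- window_evidence(instance, lexicons)
  routes <- config$routes
  ybocs_anchor <- identical(instance$anchor_lexicon, "ybocs_keywords")
  fam <- instance$anchor_family
  fired <- "none"

  if (!ybocs_anchor && fam == "ocd" && routes[["ocd_stated"]]) {
    fired <- if (ev$has_diagnosis) "clinician_diagnosis" else "ocd_stated"
  } else if (!ybocs_anchor && fam == "hoard" && routes[["hoarding_any"]]) {
    fired <- "hoarding_any"
  } else if (length(ev$families) >= 2 && routes[["two_plus_keywords"]]) {
    fired <- "two_plus_keywords"
  } else if (ybocs_anchor ||
             (length(ev$families) == 1 &&
              fam %in% c("obsession", "compulsion", "ritual"))) {
    if (nrow(ev$ybocs) >= 1 && routes[["keyword_plus_ybocs"]]) {
      fired <- "keyword_plus_ybocs"
    } else if (nrow(ev$insight) >= 1 && routes[["keyword_plus_insight"]]) {
      fired <- "keyword_plus_insight"
    }
  }

  tibble::tibble(
    component = component,
    positive = fired != "none",
    fired_rule = fired,
    n_families = length(ev$families),
    n_ybocs_support = nrow(ev$ybocs),
    n_insight_support = nrow(ev$insight)
  )
}

#' Classify one instance
#'
#' Runs the component detector and the full exclusion engine on an
#' instance. The final verdict is positive if and only if an inclusion
#' route fired and no exclusion category did: exclusions veto inclusion
#' evidence unconditionally.
#'
#' @inheritParams detect_component
#' @return A one-row tibble: the instance columns plus `component`,
#'   `fired_rule`, `component_positive`, `exclusions` (list-column of
#'   trigger tibbles), `excl_categories` (comma-separated string) and
#'   `final` ("positive"/"negative").
#' @export
classify_instance <- function(instance, lexicons, config = detection_config()) {
  verdict <- detect_component(instance, lexicons, config)
  excl <- apply_exclusions(instance, lexicons, config)
  instance %>%
    dplyr::mutate(
      component = verdict$component,
      fired_rule = verdict$fired_rule,
      component_positive = verdict$positive,
      exclusions = list(excl),
      excl_categories = paste(unique(excl$category), collapse = ","),
      final = ifelse(verdict$positive & nrow(excl) == 0L,
                     "positive", "negative")
    )
}

#' Classify a single document
#'
#' The full pipeline for one note: sentence split, keyword match, context
#' windows, per-instance classification, and an any-positive document
#' roll-up. Deterministic: no randomness anywhere on the detection path.
#'
#' @param text Document text (a single string).
#' @param doc_id Document identifier.
#' @param lexicons An `ocs_lexicons` tibble; defaults to
#'   [default_lexicons()].
#' @param config A [detection_config()].
#' @return A list with `document` (one-row tibble: `doc_id`,
#'   `n_instances`, `n_positive`, `label`) and `instances` (classified
#'   instance tibble). `n_positive` counts distinct positive
#'   (sentence-range, component) verdicts, so several keyword tokens in
#'   one mention are not double-counted; `label` is positive iff any
#'   instance is.
#' @examples
#' classify_document("Diagnosed with OCD by the consultant.")$document
#' @export
classify_document <- function(text, doc_id = "doc",
                              lexicons = default_lexicons(),
                              config = detection_config()) {
  lexicons <- compile_lexicons(lexicons)
  sentences <- split_sentences(text)
  hits <- match_keywords(text, lexicons, c("ocs_keywords", "ybocs_keywords"))
  instances <- extract_instances(doc_id, text, hits, sentences, config)
  classified <- if (nrow(instances)) {
    purrr::map(seq_len(nrow(instances)),
               function(i) classify_instance(instances[i, ], lexicons, config)) %>%
      dplyr::bind_rows()
  } else {
    dplyr::mutate(empty_instances(), component = character(),
                  fired_rule = character(), component_positive = logical(),
                  exclusions = list(), excl_categories = character(),
                  final = character())
  }
  n_pos <- classified %>%
    dplyr::filter(.data$final == "positive") %>%
    dplyr::distinct(.data$first_sentence, .data$last_sentence,
                    .data$component) %>%
    nrow()
  list(
    document = tibble::tibble(
      doc_id = doc_id,
      n_instances = nrow(classified),
      n_positive = n_pos,
      label = ifelse(n_pos >= 1L, "positive", "negative")
    ),
    instances = classified
  )
}

#' Detect OCS mentions across a corpus
#'
#' Maps [classify_document()] over a corpus tibble and collects the
#' results into an `ocs_annotations` object.
#'
#' @param corpus A tibble with columns `doc_id` and `text` (see
#'   [read_corpus()]).
#' @param lexicons An `ocs_lexicons` tibble.
#' @param config A [detection_config()].
#' @return An object of class `ocs_annotations`: a list with `documents`
#'   (one row per document), `instances` (one row per keyword instance)
#'   and the `config` used. Supports [generics::tidy()] (instance table),
#'   [generics::glance()] (one-row corpus summary) and
#'   [ggplot2::autoplot()].
#' @examples
#' corpus <- tibble::tibble(
#'   doc_id = c("a", "b"),
#'   text = c("Reports compulsive checking.", "Sleeping well.")
#' )
#' ann <- detect_ocs(corpus)
#' ann$documents
#' @export
detect_ocs <- function(corpus, lexicons = default_lexicons(),
                       config = detection_config()) {
  check_corpus(corpus)
  lexicons <- compile_lexicons(lexicons)
  res <- purrr::map2(corpus$doc_id, corpus$text,
                     function(id, tx) classify_document(tx, id, lexicons, config))
  structure(
    list(
      documents = dplyr::bind_rows(purrr::map(res, "document")),
      instances = dplyr::bind_rows(purrr::map(res, "instances")),
      config = config
    ),
    class = "ocs_annotations"
  )
}

#' @export
print.ocs_annotations <- function(x, ...) {
  cat("<ocs_annotations>\n")
  cat("  documents:", nrow(x$documents),
      sprintf("(%d positive)", sum(x$documents$label == "positive")), "\n")
  cat("  instances:", nrow(x$instances),
      sprintf("(%d positive)", sum(x$instances$final == "positive")), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname detect_ocs
#' @param x An `ocs_annotations` object.
#' @param ... Unused.
#' @export
tidy.ocs_annotations <- function(x, ...) x$instances

#' @rdname detect_ocs
#' @export
glance.ocs_annotations <- function(x, ...) {
  tibble::tibble(
    n_documents = nrow(x$documents),
    n_documents_positive = sum(x$documents$label == "positive"),
    n_instances = nrow(x$instances),
    n_instances_positive = sum(x$instances$final == "positive")
  )
}
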