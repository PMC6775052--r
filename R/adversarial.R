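#' Hand-curated adversarial fixtures
#'
#' A fixed set of difficult documents, each with hand-assigned gold
#' labels and a note naming the coding rule it probes: lay/figurative
#' keyword use ("obsessed with football"), risk-taking usage ("compulsive
#' gambling"), the "compulsory" exception, questionnaire and screening
#' fragments, kin experiencers, hedges, self-diagnosis, romantic and
#' weight-related modification, plus genuinely positive mentions and a
#' mixed multi-instance document. Unlike [generate_corpus()], these
#' fixtures deliberately do not reuse the generator templates; they are
#' where imperfect behaviour would show up.
#'
#' @return A list with `corpus` (doc_id, text, note), `gold_documents`
#'   (doc_id, label) and `gold_instance_labels` (doc_id, ordinal, label —
#'   labels for each keyword anchor in document order).
#' @export
adversarial_suite <- function() {
  fx <- list(
    list(id = "adv_lay_football",
         text = "He is obsessed with football. Watches every match at the weekend.",
         doc = "negative", inst = "negative",
         note = "lay keen-interest usage: single keyword family, no support terms"),
    list(id = "adv_lay_gambling",
         text = "Compulsive gambling was discussed at length. He attends a peer support group.",
         doc = "negative", inst = "negative",
         note = "risk-taking behaviour modifying the keyword"),
    list(id = "adv_compulsory",
         text = "Attendance at the day centre is compulsory. He attends every week.",
         doc = "negative", inst = character(),
         note = "'compulsory' is an explicit exception of the compul* stem; no instance at all"),
    list(id = "adv_form_oci",
         text = "Obsessive Compulsive Index (OCI): 15. Scores have reduced since admission.",
         doc = "negative", inst = c("negative", "negative"),
         note = "questionnaire/form fragment exclusion"),
    list(id = "adv_form_screening",
         text = "C - Obsessive compulsive screening section. Nothing was endorsed.",
         doc = "negative", inst = c("negative", "negative"),
         note = "form header pattern 'c - obsessive compulsive'"),
    list(id = "adv_questionnaire_none",
         text = "Obsessions and compulsions. None recorded in the last month.",
         doc = "negative", inst = c("negative", "negative"),
         note = "prompt-plus-'none' questionnaire pattern"),
    list(id = "adv_kin",
         text = "His mother has OCD and performs rituals at home.",
         doc = "negative", inst = c("negative", "negative"),
         note = "non-patient experiencer (kin term in the keyword sentence)"),
    list(id = "adv_hedge",
         text = "Possible OCD, to be kept under review.",
         doc = "negative", inst = "negative",
         note = "hedge word referring to the keyword"),
    list(id = "adv_selfdx",
         text = "She says that she has OCD. A referral was requested.",
         doc = "negative", inst = "negative",
         note = "self-diagnosis phrasing"),
    list(id = "adv_romantic",
         text = "He is obsessed with his girlfriend and texts her constantly.",
         doc = "negative", inst = "negative",
         note = "romantic experiencer/modifier of the keyword"),
    list(id = "adv_weight",
         text = "Obsessive about food and weight since starting the diet.",
         doc = "negative", inst = "negative",
         note = "weight/food-related modification of the keyword"),
    list(id = "adv_insight_pos",
         text = "Intrusive obsessional images which he finds repugnant; unable to stop checking rituals.",
         doc = "positive", inst = c("positive", "positive"),
         note = "two keyword families plus insight markers: genuine positive"),
    list(id = "adv_hoard_pos",
         text = "Flat inspection found hoarded items in every room. Environmental services are involved.",
         doc = "positive", inst = "positive",
         note = "hoarding counts regardless of further examples"),
    list(id = "adv_mixed",
         text = paste("He denies obsessions at present. Attended on time.",
                      "Mood was settled. Compulsive checking occurs daily,",
                      "causing marked distress."),
         doc = "positive", inst = c("negative", "positive"),
         note = "multi-instance document: one negated mention, one genuine mention")
  )
  corpus <- tibble::tibble(
    doc_id = vapply(fx, `[[`, "", "id"),
    text = vapply(fx, `[[`, "", "text"),
    note = vapply(fx, `[[`, "", "note")
  )
  gold_documents <- tibble::tibble(
    doc_id = corpus$doc_id,
    label = vapply(fx, `[[`, "", "doc")
  )
  gold_instance_labels <- purrr::map(fx, function(f) {
    if (!length(f$inst)) return(NULL)
    tibble::tibble(doc_id = f$id, ordinal = seq_along(f$inst),
                   label = f$inst)
  }) %>% dplyr::bind_rows()
  list(corpus = corpus, gold_documents = gold_documents,
       gold_instance_labels = gold_instance_labels)
}
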