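lex <- default_lexicons()

one_instance <- function(text, config = detection_config()) {
  hits <- match_keywords(text, lex, "ocs_keywords")
  extract_instances("d", text, hits, split_sentences(text), config)[1, ]
}

test_that("positive routes fire per the coding rules", {
  v <- detect_component(one_instance("He has obsessions and compulsions."),
                        lex)
  expect_true(v$positive)
  expect_equal(v$fired_rule, "two_plus_keywords")

  v <- detect_component(one_instance("He is hoarding newspapers."), lex)
  expect_true(v$positive)
  expect_equal(v$fired_rule, "hoarding_any")

  # a lone keyword with no supporting evidence is not enough
  v <- detect_component(one_instance("He has obsessions."), lex)
  expect_false(v$positive)
  expect_equal(v$fired_rule, "none")

  v <- detect_component(
    one_instance("Intrusive obsessional thoughts causing distress."), lex)
  expect_true(v$positive)
  expect_equal(v$fired_rule, "keyword_plus_insight")

  v <- detect_component(one_instance("Reports compulsive washing."), lex)
  expect_equal(v$fired_rule, "keyword_plus_ybocs")

  v <- detect_component(one_instance("He has OCD features."), lex)
  expect_equal(v$fired_rule, "ocd_stated")

  v <- detect_component(one_instance("Diagnosed with OCD by the team."), lex)
  expect_equal(v$fired_rule, "clinician_diagnosis")

  expect_error(
    detect_component(one_instance("He has OCD."), lex,
                     component = "anxiety"),
    "unknown component")
})

test_that("repeated tokens of one family do not self-corroborate", {
  v <- detect_component(
    one_instance("Obsessions and obsessional thinking discussed."), lex)
  expect_equal(v$n_families, 1L)
  expect_false(v$positive)
})

test_that("route toggles invert the documented rules", {
  cfg <- detection_config(routes = c(hoarding_any = FALSE))
  d <- classify_document("He is hoarding newspapers.", config = cfg)
  expect_equal(d$document$label, "negative")
  d <- classify_document("He is hoarding newspapers.")
  expect_equal(d$document$label, "positive")
})

test_that("Y-BOCS anchoring is off by default and config-selectable", {
  text <- "Checks the locks repeatedly every night."
  expect_equal(classify_document(text)$document$n_instances, 0L)
  cfg <- detection_config(ybocs_anchors = TRUE)
  d <- classify_document(text, config = cfg)
  expect_true(d$document$n_instances >= 1)
  expect_equal(d$instances$component[1], "compulsion")
})

test_that("exclusions veto inclusion evidence in the final verdict", {
  d <- classify_document("His mother has obsessions and compulsions.")
  expect_true(all(d$instances$component_positive))
  expect_true(all(d$instances$final == "negative"))
  expect_true(all(grepl("other_experiencer", d$instances$excl_categories)))

  d <- classify_document("Diagnosed with OCD.")
  expect_equal(d$instances$final, "positive")

  d <- classify_document("Possibly obsessional, will review.")
  expect_equal(d$instances$final, "negative")
  expect_true(grepl("hedge", d$instances$excl_categories))
})

test_that("document roll-up is any-positive with mention deduplication", {
  # hand-traced two-template document: one negated, one genuine mention
  text <- paste("He denies obsessions at present. Attended on time.",
                "Mood was settled. Compulsive checking occurs daily,",
                "causing marked distress.")
  d <- classify_document(text)
  expect_equal(d$document$n_instances, 2L)
  expect_equal(d$document$n_positive, 1L)
  expect_equal(d$document$label, "positive")
  expect_equal(d$instances$final, c("negative", "positive"))

  expect_equal(classify_document("Sleeping well, appetite good.")$document$label,
               "negative")
  expect_equal(classify_document("")$document$n_instances, 0L)

  # two families in one sentence: one instance per anchor, counted once
  # per (sentence-range, component) pair
  d <- classify_document("He reports obsessions and compulsions.")
  expect_equal(d$document$n_instances, 2L)
  expect_equal(d$document$n_positive, 2L)
  # repeated tokens of the same family collapse to one counted mention
  d <- classify_document(
    "Obsessional thinking with intrusive obsessions causing distress.")
  expect_equal(d$document$n_instances, 2L)
  expect_equal(d$document$n_positive, 1L)
})

test_that("detection is deterministic and ignores filler outside windows", {
  corpus <- generate_corpus(generator_config(n_docs = 15, seed = 3))$corpus
  a <- detect_ocs(corpus, lex)
  b <- detect_ocs(corpus, lex)
  expect_identical(a$instances$final, b$instances$final)
  expect_identical(a$documents, b$documents)

  # permuting filler sentences far from every window leaves verdicts alone
  pre <- c("Seen at home today.", "Family were present.",
           "Housing discussed.")
  core <- "He reports compulsive checking causing distress."
  post <- c("Plan reviewed.", "Medication unchanged.")
  t1 <- paste(c(pre, core, post), collapse = " ")
  t2 <- paste(c(rev(pre), core, rev(post)), collapse = " ")
  d1 <- classify_document(t1)
  d2 <- classify_document(t2)
  expect_equal(d1$instances$final, d2$instances$final)
  expect_equal(d1$document$label, d2$document$label)
})

test_that("tidy and glance summarise annotations", {
  ann <- detect_ocs(tibble::tibble(
    doc_id = "a", text = "Diagnosed with OCD by the team."))
  expect_equal(nrow(tidy(ann)), 1L)
  g <- glance(ann)
  expect_equal(g$n_documents, 1L)
  expect_equal(g$n_instances_positive, 1L)
})
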