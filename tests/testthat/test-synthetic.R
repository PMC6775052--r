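test_that("same seed and config give byte-identical corpora, serialization included", {
  a <- generate_corpus(generator_config(n_docs = 30, seed = 7))
  b <- generate_corpus(generator_config(n_docs = 30, seed = 7))
  expect_identical(a$corpus, b$corpus)
  expect_identical(a$gold_instances, b$gold_instances)
  fa <- withr::local_tempfile(); fb <- withr::local_tempfile()
  write_corpus(a$corpus, fa); write_corpus(b$corpus, fb)
  expect_identical(readLines(fa), readLines(fb))
  # different seed actually changes the corpus
  c <- generate_corpus(generator_config(n_docs = 30, seed = 8))
  expect_false(identical(a$corpus$text, c$corpus$text))
})

test_that("counter-based sub-seeding: earlier documents are stable as n grows", {
  small <- generate_corpus(generator_config(n_docs = 10, seed = 7))
  big <- generate_corpus(generator_config(n_docs = 20, seed = 7))
  expect_identical(small$corpus$text, big$corpus$text[1:10])
})

test_that("rate configuration shapes the gold labels", {
  neg <- generate_corpus(generator_config(n_docs = 25, seed = 2,
                                          rates = c(negated = 1)))
  expect_true(all(neg$gold_instances$label == "negative"))
  expect_true(all(neg$gold_documents$label == "negative"))

  pos <- generate_corpus(generator_config(n_docs = 25, seed = 2,
                                          rates = c(hoarding_any = 1)))
  expect_true(all(pos$gold_instances$label == "positive"))

  expect_error(generator_config(rates = c(negated = 0)), "positive sum")
  expect_error(generator_config(rates = c(banana = 1)), "unknown rate")
})

test_that("gold document label is the any-positive roll-up of instances", {
  synth <- generate_corpus(generator_config(n_docs = 60, seed = 9))
  roll <- synth$gold_instances %>%
    dplyr::group_by(doc_id) %>%
    dplyr::summarise(lab = ifelse(any(label == "positive"),
                                  "positive", "negative"),
                     .groups = "drop")
  j <- dplyr::left_join(synth$gold_documents, roll, by = "doc_id")
  expect_true(all(j$label == j$lab))
  # every generated document carries at least one keyword instance
  expect_true(all(synth$gold_documents$doc_id %in%
                    synth$gold_instances$doc_id))
})

test_that("every inclusion route and exclusion category is instantiated", {
  synth <- generate_corpus(generator_config(n_docs = 250, seed = 4))
  cats <- unique(synth$gold_instances$category)
  expect_true(all(c("ocd_stated", "hoarding_any", "two_plus_keywords",
                    "keyword_plus_ybocs", "keyword_plus_insight",
                    "bare_keyword", "negated", "other_experiencer",
                    "hedged", "self_diagnosed", "form_fragment",
                    "lay_usage") %in% cats))
  ann <- detect_ocs(synth$corpus)
  expect_true(all(c("ocd_stated", "clinician_diagnosis", "hoarding_any",
                    "two_plus_keywords", "keyword_plus_ybocs",
                    "keyword_plus_insight", "none") %in%
                    unique(ann$instances$fired_rule)))
  fired_excl <- unique(unlist(strsplit(ann$instances$excl_categories, ",")))
  expect_true(all(c("form", "negation", "other_experiencer", "hedge",
                    "self_diagnosis") %in% fired_excl))
})

test_that("perturbations flip gold-positive instances and relabel them", {
  synth <- generate_corpus(generator_config(n_docs = 30, seed = 6))
  n_pos <- sum(synth$gold_instances$label == "positive")
  expect_gt(n_pos, 0)
  pert <- perturb_corpus(synth, "add_negation")
  expect_equal(sum(pert$gold_instances$label == "positive"), 0L)
  expect_true(any(grepl(":add_negation", pert$gold_instances$category)))

  # perturbing a corpus with no positives is the identity
  neg <- generate_corpus(generator_config(n_docs = 10, seed = 2,
                                          rates = c(negated = 1)))
  expect_identical(perturb_corpus(neg, "add_hedge"), neg)

  expect_error(perturb_corpus(synth, "add_typos"), "arg")
})

test_that("adversarial fixtures carry consistent hand labels", {
  adv <- adversarial_suite()
  expect_gt(nrow(adv$corpus), 10)
  # document labels match the any-positive roll-up of instance labels
  roll <- adv$gold_instance_labels %>%
    dplyr::group_by(doc_id) %>%
    dplyr::summarise(lab = ifelse(any(label == "positive"),
                                  "positive", "negative"),
                     .groups = "drop")
  j <- dplyr::inner_join(adv$gold_documents, roll, by = "doc_id")
  expect_true(all(j$label == j$lab))
  # fixtures without instances are document-negative
  no_inst <- setdiff(adv$corpus$doc_id, adv$gold_instance_labels$doc_id)
  expect_true(all(adv$gold_documents$label[
    adv$gold_documents$doc_id %in% no_inst] == "negative"))
})
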