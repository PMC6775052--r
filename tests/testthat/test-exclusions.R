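lex <- default_lexicons()

first_instance <- function(text, config = detection_config()) {
  hits <- match_keywords(text, lex, "ocs_keywords")
  inst <- extract_instances("d", text, hits, split_sentences(text), config)
  inst[1, ]
}

test_that("form patterns veto anywhere in the window", {
  i <- first_instance("Obsessive Compulsive Index (OCI): 12")
  r <- check_form(i, lex)
  expect_true(nrow(r) >= 1)
  expect_true(all(r$category == "form"))

  i <- first_instance("Obsessions and compulsions. none")
  expect_true(nrow(check_form(i, lex)) >= 1)

  i <- first_instance("He described intrusive obsessional thoughts.")
  expect_equal(nrow(check_form(i, lex)), 0L)
})

test_that("negation fires on terms and adjacency patterns in the anchor sentence", {
  i <- first_instance("He denies any obsessions.")
  r <- check_negation(i, lex)
  expect_true(any(r$trigger_text == "denies"))

  i <- first_instance("No evidence of compulsive checking.")
  expect_true(nrow(check_negation(i, lex)) >= 1)

  i <- first_instance("There are no current obsessions.")
  r <- check_negation(i, lex)
  expect_true(any(grepl("^no ", r$trigger_text)))

  i <- first_instance("More enthusiasm than an obsession.")
  expect_true(nrow(check_negation(i, lex)) >= 1)

  i <- first_instance("Nil obsessions reported.")
  expect_true(any(check_negation(i, lex)$trigger_text == "nil"))

  i <- first_instance("He reports compulsive checking.")
  expect_equal(nrow(check_negation(i, lex)), 0L)

  # negation in a neighbouring sentence does not touch the anchor sentence
  i <- first_instance("He denies low mood. He reports compulsive checking.")
  expect_equal(nrow(check_negation(i, lex)), 0L)
})

test_that("standalone none/nil need sentence-initial position or keyword adjacency", {
  # "none" far from the keyword and not sentence-initial: no veto
  i <- first_instance(
    "He reports obsessions but in recent months none of the strategies helped.")
  expect_equal(nrow(check_negation(i, lex)), 0L)
  # adjacent after the keyword: veto
  i <- first_instance("Obsessions: none at present.")
  expect_true(nrow(check_negation(i, lex)) >= 1)
})

test_that("experiencer terms in the anchor sentence veto; elsewhere they do not", {
  i <- first_instance("His mother has OCD.")
  r <- check_experiencer(i, lex)
  expect_equal(r$category, "other_experiencer")
  expect_equal(tolower(r$trigger_text), "mother")

  i <- first_instance("qqqqq hoards newspapers at home.")
  expect_true(nrow(check_experiencer(i, lex)) >= 1)

  i <- first_instance("Patient reports hoarding newspapers.")
  expect_equal(nrow(check_experiencer(i, lex)), 0L)

  # kin term in the previous sentence is out of scope
  i <- first_instance("His mother visited. He reports compulsive checking.")
  expect_equal(nrow(check_experiencer(i, lex)), 0L)
})

test_that("hedges fire in the anchor sentence or just before the keyword", {
  i <- first_instance("Possible OCD.")
  expect_equal(check_hedge(i, lex)$category, "hedge")

  i <- first_instance("It sounds like compulsive checking.")
  expect_true(nrow(check_hedge(i, lex)) >= 1)

  i <- first_instance("Diagnosed with OCD in 2010.")
  expect_equal(nrow(check_hedge(i, lex)), 0L)

  # hedge in the previous sentence, many tokens before the anchor: no veto
  i <- first_instance(
    "He seems well in himself generally speaking today. Compulsive checking was described at length.")
  expect_equal(nrow(check_hedge(i, lex)), 0L)
})

test_that("self-diagnosis phrasing vetoes across the window", {
  i <- first_instance("He describes himself as having OCD.")
  expect_equal(unique(check_self_diagnosis(i, lex)$category),
               "self_diagnosis")

  i <- first_instance("She says that she has OCD.")
  expect_true(nrow(check_self_diagnosis(i, lex)) >= 1)

  i <- first_instance("OCD diagnosed by Dr. Smith.")
  expect_equal(nrow(check_self_diagnosis(i, lex)), 0L)
})

test_that("romantic/weight and risk triggers must modify the keyword", {
  i <- first_instance("He is obsessed with his girlfriend.")
  expect_true(nrow(check_romantic_weight(i, lex)) >= 1)

  i <- first_instance("Compulsive gambling discussed.")
  expect_true(nrow(check_risk_selfharm(i, lex)) >= 1)

  # same trigger word but far from the keyword: not a modifier
  i <- first_instance(
    "Gambling debts were mentioned early on and then compulsive checking rituals were described.")
  expect_equal(nrow(check_risk_selfharm(i, lex)), 0L)
})

test_that("apply_exclusions unions all categories in fixed order", {
  i <- first_instance("His mother denies obsessions.")
  r <- apply_exclusions(i, lex)
  expect_equal(unique(r$category), c("negation", "other_experiencer"))

  i <- first_instance("He reports obsessions and compulsions.")
  expect_equal(nrow(apply_exclusions(i, lex)), 0L)

  # disabled categories are skipped
  cfg <- detection_config(exclusions = c(other_experiencer = FALSE))
  i <- first_instance("His mother has obsessions and compulsions.", cfg)
  expect_equal(nrow(apply_exclusions(i, lex, cfg)), 0L)
})

test_that("exclusion checks are pure functions of the window", {
  i <- first_instance("Possibly obsessional, will review.")
  a <- apply_exclusions(i, lex)
  b <- apply_exclusions(i, lex)
  expect_identical(a, b)
})
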