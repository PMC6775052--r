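# Independent oracles used across the suite. These deliberately share no
# code with the package internals they check: token scanning plus
# fixed-string comparison only, no regular-expression semantics.

oracle_tokenize <- function(text) {
  m <- gregexpr("[A-Za-z0-9']+", text)[[1]]
  if (m[1] == -1L) {
    return(data.frame(token = character(), start = integer(),
                      end = integer()))
  }
  start <- as.integer(m)
  end <- start + attr(m, "match.length") - 1L
  data.frame(token = tolower(substring(text, start, end)),
             start = start, end = end, stringsAsFactors = FALSE)
}

is_alnum_char <- function(ch) {
  nzchar(ch) && grepl("[A-Za-z0-9]", ch)
}

# all fixed-string match starts of pattern in text (both already lowercase)
fixed_starts <- function(low, pat) {
  m <- gregexpr(pat, low, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer() else as.integer(m)
}

# phrase = whitespace-separated literal chunks; match chunk1, >=1
# whitespace, chunk2, ...; word boundaries at alphanumeric pattern edges
oracle_phrase_spans <- function(text, low, stem) {
  chunks <- strsplit(stem, "[ \t\n\r]+")[[1]]
  n <- nchar(low)
  res_s <- res_e <- integer()
  for (s in fixed_starts(low, chunks[1])) {
    pos <- s + nchar(chunks[1])
    ok <- TRUE
    for (ci in seq_along(chunks)[-1]) {
      ws <- 0L
      while (pos <= n && substring(low, pos, pos) %in% c(" ", "\t", "\n", "\r")) {
        pos <- pos + 1L; ws <- ws + 1L
      }
      if (ws == 0L ||
          substring(low, pos, pos + nchar(chunks[ci]) - 1L) != chunks[ci]) {
        ok <- FALSE; break
      }
      pos <- pos + nchar(chunks[ci])
    }
    if (!ok) next
    e <- pos - 1L
    prev <- if (s == 1L) "" else substring(low, s - 1L, s - 1L)
    nxt <- if (e >= n) "" else substring(low, e + 1L, e + 1L)
    first_al <- grepl("^[a-z0-9]", chunks[1])
    last_al <- grepl("[a-z0-9]$", chunks[length(chunks)])
    if ((!first_al || !is_alnum_char(prev)) &&
        (!last_al || !is_alnum_char(nxt))) {
      res_s <- c(res_s, s); res_e <- c(res_e, e)
    }
  }
  list(start = res_s, end = res_e)
}

oracle_variant_spans <- function(text, low, variant) {
  n <- nchar(low)
  res_s <- res_e <- integer()
  for (s in fixed_starts(low, variant)) {
    e <- s + nchar(variant) - 1L
    prev <- if (s == 1L) "" else substring(low, s - 1L, s - 1L)
    nxt <- if (e >= n) "" else substring(low, e + 1L, e + 1L)
    if (!is_alnum_char(prev) && !is_alnum_char(nxt)) {
      res_s <- c(res_s, s); res_e <- c(res_e, e)
    }
  }
  list(start = res_s, end = res_e)
}

oracle_match <- function(text, lexicons, lexicon_names = NULL) {
  pats <- lexicons
  if (!is.null(lexicon_names)) pats <- pats[pats$lexicon %in% lexicon_names, ]
  toks <- oracle_tokenize(text)
  low <- tolower(text)
  out <- list()
  add <- function(lex, stem, s, e) {
    if (!length(s)) return()
    out[[length(out) + 1L]] <<- data.frame(
      lexicon = lex, stem = stem, char_start = s, char_end = e,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(pats))) {
    stem <- pats$stem[i]; mode <- pats$match_mode[i]
    exc <- pats$exceptions[[i]]; var <- pats$variants[[i]]
    if (mode == "prefix") {
      keep <- startsWith(toks$token, stem) & !(toks$token %in% exc)
      add(pats$lexicon[i], stem, toks$start[keep], toks$end[keep])
    } else if (mode == "exact") {
      keep <- toks$token == stem
      add(pats$lexicon[i], stem, toks$start[keep], toks$end[keep])
    } else {
      sp <- oracle_phrase_spans(text, low, stem)
      add(pats$lexicon[i], stem, sp$start, sp$end)
    }
    for (v in var) {
      sp <- oracle_variant_spans(text, low, v)
      add(pats$lexicon[i], stem, sp$start, sp$end)
    }
  }
  if (!length(out)) {
    return(data.frame(lexicon = character(), stem = character(),
                      char_start = integer(), char_end = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$char_start, res$char_end, res$lexicon, res$stem), ]
  rownames(res) <- NULL
  res
}

# --- Clopper-Pearson oracle via binomial tail-sum root finding ---------
# lower: the p solving P(X >= k | p) = alpha/2; upper: the p solving
# P(X <= k | p) = alpha/2. Independent of the beta-quantile closed form
# used in the implementation.
oracle_clopper_pearson <- function(k, n, level = 0.95) {
  alpha <- 1 - level
  lower <- if (k == 0) 0 else {
    stats::uniroot(function(p) stats::pbinom(k - 1, n, p,
                                             lower.tail = FALSE) - alpha / 2,
                   interval = c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  upper <- if (k == n) 1 else {
    stats::uniroot(function(p) stats::pbinom(k, n, p) - alpha / 2,
                   interval = c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  c(lower = lower, upper = upper)
}

# --- random-sentence generator for matcher fuzzing ---------------------
# Vocabulary mixes keyword variants, exception tokens, phrase fragments,
# dotted variants and neutral words so boundary conditions are hit often.
FUZZ_VOCAB <- c(
  "obsessive", "obsessional", "obsessions", "obsess", "obsessed",
  "compulsive", "compulsions", "compulsory", "compelled", "ocd", "o.c.d",
  "ocs", "hoarding", "hoarded", "ritualistic", "rituals", "clean",
  "cleaning", "cleanliness", "washing", "checked", "checking", "repeat",
  "repeatedly", "counting", "count", "account", "ordered", "disorder",
  "rearranged", "distress", "distressed", "unwanted", "repugnant",
  "intrusive", "unstoppable", "unable", "to", "stop", "none", "nil",
  "denies", "deny", "denied", "no", "not", "history", "evidence",
  "mother", "father", "qqqqq", "seems", "possible", "possibly",
  "apparently", "sounds", "like", "oci", "o.c.i", "says", "that",
  "told", "me", "the", "patient", "reports", "with", "and", "a",
  "girlfriend", "food", "weight", "gambling", "risk", "self-harm",
  "well", "today", "review", "at", "home", "Dr.", "Smith"
)

random_sentence <- function(n_words = 12) {
  words <- sample(FUZZ_VOCAB, n_words, replace = TRUE)
  txt <- paste(words, collapse = " ")
  if (stats::runif(1) < 0.5) {
    substr(txt, 1, 1) <- toupper(substr(txt, 1, 1))
  }
  paste0(txt, sample(c(".", "!", "?", ""), 1))
}

random_document <- function(max_sentences = 9) {
  n <- sample(1:max_sentences, 1)
  sents <- vapply(seq_len(n), function(i) {
    s <- random_sentence(sample(3:10, 1))
    if (!grepl("[.!?]$", s)) s <- paste0(s, ".")
    sub("^([a-z])", "\\U\\1", s, perl = TRUE)
  }, character(1))
  paste(sents, collapse = " ")
}
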