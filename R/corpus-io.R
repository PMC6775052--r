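check_corpus <- function(corpus) {
  stopifnot(is.data.frame(corpus))
  if (!all(c("doc_id", "text") %in% names(corpus))) {
    stop("a corpus needs columns 'doc_id' and 'text'", call. = FALSE)
  }
  if (any(is.na(corpus$doc_id) | !nzchar(corpus$doc_id))) {
    stop("doc_id must be non-empty", call. = FALSE)
  }
  dup <- corpus$doc_id[duplicated(corpus$doc_id)]
  if (length(dup)) {
    stop("duplicate doc_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  invisible(corpus)
}

#' Read a document corpus
#'
#' Reads clinical documents either from a JSONL file (one
#' `{"doc_id": ..., "text": ...}` record per line) or from a directory of
#' `*.txt` files (filename stem becomes the `doc_id`). Text is preserved
#' verbatim — no normalisation happens at read time, so downstream
#' character offsets always refer to the original document.
#'
#' @param path A file (JSONL) or directory (text files).
#' @param format "auto" (directory means "textdir", file means "jsonl"),
#'   "jsonl" or "textdir".
#' @return A tibble with columns `doc_id` and `text`, sorted by `doc_id`.
#' @export
read_corpus <- function(path, format = c("auto", "jsonl", "textdir")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("path does not exist: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (dir.exists(path)) "textdir" else "jsonl"
  }
  if (format == "textdir") {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    corpus <- tibble::tibble(
      doc_id = sub("\\.txt$", "", basename(files)),
      text = vapply(files, function(f) {
        paste(readLines(f, warn = FALSE), collapse = "\n")
      }, character(1), USE.NAMES = FALSE)
    )
  } else {
    lines <- readLines(path, warn = FALSE)
    lines_keep <- which(nzchar(trimws(lines)))
    recs <- purrr::map(lines_keep, function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) {
                        stop("malformed JSONL at line ", i, ": ",
                             conditionMessage(e), call. = FALSE)
                      })
      if (is.null(rec$doc_id) || is.null(rec$text)) {
        stop("JSONL record at line ", i,
             " is missing required field 'doc_id' or 'text'", call. = FALSE)
      }
      tibble::tibble(doc_id = as.character(rec$doc_id),
                     text = as.character(rec$text))
    })
    corpus <- dplyr::bind_rows(recs)
    if (!nrow(corpus)) corpus <- tibble::tibble(doc_id = character(),
                                               text = character())
  }
  check_corpus(corpus)
  dplyr::arrange(corpus, .data$doc_id)
}

#' Write a corpus as JSONL
#'
#' @param corpus A tibble with `doc_id` and `text`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  check_corpus(corpus)
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    jsonlite::toJSON(list(doc_id = corpus$doc_id[i], text = corpus$text[i]),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Keyword pre-filter for a corpus
#'
#' Keeps exactly the documents containing at least one match from the
#' core OCS, Y-BOCS or patient-insight keyword sets, mirroring the corpus
#' extraction filter used to pull candidate notes from the record system.
#' Context is ignored at this stage ("He denies obsessions." is
#' retained); the filter uses the same matcher as detection, so every
#' document in which the detector could ever find an instance survives.
#'
#' @param corpus A corpus tibble.
#' @param lexicons An `ocs_lexicons` tibble.
#' @return The retained rows of `corpus`, original order preserved.
#' @examples
#' corpus <- tibble::tibble(
#'   doc_id = c("a", "b", "c"),
#'   text = c("He denies obsessions.", "Sleeping well, appetite good.",
#'            "Attendance is compulsory.")
#' )
#' prefilter_corpus(corpus, default_lexicons())$doc_id
#' @export
prefilter_corpus <- function(corpus, lexicons = default_lexicons()) {
  check_corpus(corpus)
  keep <- vapply(corpus$text, function(tx) {
    nrow(match_keywords(tx, lexicons,
                        c("ocs_keywords", "ybocs_keywords",
                          "insight_keywords"))) > 0L
  }, logical(1), USE.NAMES = FALSE)
  corpus[keep, , drop = FALSE]
}

annotation_fields <- c("doc_id", "instance_id", "char_start", "char_end",
                       "keyword_term", "component", "verdict", "fired_rule")

#' Write and read annotation records
#'
#' Annotation records serialise the classified instances as JSONL, one
#' record per instance, with the anchor span (1-based inclusive character
#' offsets into the raw document text), the matched keyword, the
#' component, the verdict, the fired inclusion rule and the exclusion
#' triggers. `write_annotations()` followed by [read_annotations()] is
#' the identity on these fields.
#'
#' @param instances A classified instance tibble (from [detect_ocs()] or
#'   [classify_document()]).
#' @param path Output JSONL path.
#' @return `path` invisibly; `read_annotations()` returns the records as
#'   a tibble with an `exclusions` list-column.
#' @export
write_annotations <- function(instances, path) {
  lines <- vapply(seq_len(nrow(instances)), function(i) {
    r <- instances[i, ]
    excl <- r$exclusions[[1]]
    rec <- list(
      doc_id = r$doc_id, instance_id = r$instance_id,
      char_start = r$anchor_start, char_end = r$anchor_end,
      keyword_term = r$anchor_text, component = r$component,
      verdict = r$final, fired_rule = r$fired_rule,
      exclusions = if (!is.null(excl) && nrow(excl)) {
        purrr::map(seq_len(nrow(excl)), function(j) {
          list(category = excl$category[j], trigger = excl$trigger_text[j])
        })
      } else {
        list()
      }
    )
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("path does not exist: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- purrr::imap(lines, function(l, i) {
    rec <- tryCatch(jsonlite::fromJSON(l, simplifyVector = FALSE),
                    error = function(e) {
                      stop("malformed JSONL at line ", i, ": ",
                           conditionMessage(e), call. = FALSE)
                    })
    excl <- if (length(rec$exclusions)) {
      dplyr::bind_rows(purrr::map(rec$exclusions, function(x) {
        tibble::tibble(category = x$category, trigger_text = x$trigger)
      }))
    } else {
      tibble::tibble(category = character(), trigger_text = character())
    }
    tibble::tibble(
      doc_id = rec$doc_id, instance_id = rec$instance_id,
      char_start = as.integer(rec$char_start),
      char_end = as.integer(rec$char_end),
      keyword_term = rec$keyword_term, component = rec$component,
      verdict = rec$verdict, fired_rule = rec$fired_rule,
      exclusions = list(excl)
    )
  })
  out <- dplyr::bind_rows(recs)
  if (!nrow(out)) {
    out <- tibble::tibble(doc_id = character(), instance_id = character(),
                          char_start = integer(), char_end = integer(),
                          keyword_term = character(), component = character(),
                          verdict = character(), fired_rule = character(),
                          exclusions = list())
  }
  out
}

#' Read gold labels
#'
#' Gold labels are JSONL records `{"doc_id", "instance_id"?, "level",
#' "label"}` with `level` one of "instance"/"document" and `label` one of
#' "positive"/"negative". Conflicting duplicate document-level labels are
#' an error.
#'
#' @param path Gold JSONL path.
#' @return A tibble `doc_id`, `instance_id` (NA for document level),
#'   `level`, `label`.
#' @export
read_gold <- function(path) {
  if (!file.exists(path)) stop("path does not exist: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- purrr::imap(lines, function(l, i) {
    rec <- tryCatch(jsonlite::fromJSON(l),
                    error = function(e) {
                      stop("malformed JSONL at line ", i, ": ",
                           conditionMessage(e), call. = FALSE)
                    })
    if (is.null(rec$doc_id) || is.null(rec$level) || is.null(rec$label)) {
      stop("gold record at line ", i,
           " needs fields doc_id, level, label", call. = FALSE)
    }
    tibble::tibble(
      doc_id = as.character(rec$doc_id),
      instance_id = as.character(rec$instance_id %||% NA_character_),
      level = as.character(rec$level), label = as.character(rec$label)
    )
  })
  gold <- dplyr::bind_rows(recs)
  if (!nrow(gold)) {
    return(tibble::tibble(doc_id = character(), instance_id = character(),
                          level = character(), label = character()))
  }
  bad <- setdiff(unique(gold$label), c("positive", "negative"))
  if (length(bad)) stop("unknown gold label(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  doc_level <- dplyr::filter(gold, .data$level == "document")
  conflict <- doc_level %>%
    dplyr::distinct(.data$doc_id, .data$label) %>%
    dplyr::count(.data$doc_id) %>%
    dplyr::filter(.data$n > 1)
  if (nrow(conflict)) {
    stop("conflicting document-level gold labels for: ",
         paste(conflict$doc_id, collapse = ", "), call. = FALSE)
  }
  gold
}

#' @rdname read_gold
#' @param gold A gold-label tibble.
#' @export
write_gold <- function(gold, path) {
  lines <- vapply(seq_len(nrow(gold)), function(i) {
    rec <- list(doc_id = gold$doc_id[i], level = gold$level[i],
                label = gold$label[i])
    if (!is.na(gold$instance_id[i])) rec$instance_id <- gold$instance_id[i]
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a per-document summary CSV
#'
#' A spreadsheet-friendly export: one row per document with instance and
#' positive-mention counts and the document label.
#'
#' @param documents The `documents` tibble from [detect_ocs()].
#' @param path Output CSV path.
#' @export
write_summary <- function(documents, path) {
  utils::write.csv(
    documents[, c("doc_id", "n_instances", "n_positive", "label")],
    path, row.names = FALSE, quote = TRUE
  )
  invisible(path)
}
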