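#' Confusion counts between predicted and gold labels
#'
#' Aligns predicted and gold labels on a shared key — `(doc_id,
#' instance_id)` at instance level, `doc_id` at document level — and
#' tallies agreement. A predicted positive with no gold partner counts as
#' a false positive; a gold positive with no predicted partner counts as
#' a false negative; unmatched negatives on either side contribute
#' nothing.
#'
#' @param predicted,gold Tibbles with `doc_id`, `label`
#'   ("positive"/"negative") and, at instance level, `instance_id`.
#' @param level "instance" or "document".
#' @return A one-row tibble `tp`, `fp`, `fn`, `tn`.
#' @examples
#' p <- tibble::tibble(doc_id = c("a", "b"), label = c("positive", "negative"))
#' g <- tibble::tibble(doc_id = c("a", "b"), label = c("positive", "positive"))
#' confusion(p, g, level = "document")
#' @export
confusion <- function(predicted, gold, level = c("instance", "document")) {
  level <- match.arg(level)
  keys <- if (level == "instance") c("doc_id", "instance_id") else "doc_id"
  for (nm in c("predicted", "gold")) {
    x <- get(nm)
    missing <- setdiff(c(keys, "label"), names(x))
    if (length(missing)) {
      stop(nm, " is missing column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    if (anyDuplicated(x[keys])) {
      stop("duplicate keys in ", nm, call. = FALSE)
    }
  }
  j <- dplyr::full_join(
    dplyr::select(predicted, dplyr::all_of(keys), pred = "label"),
    dplyr::select(gold, dplyr::all_of(keys), gold = "label"),
    by = keys
  ) %>%
    dplyr::mutate(pred = tidyr::replace_na(.data$pred, "negative"),
                  gold = tidyr::replace_na(.data$gold, "negative"))
  tibble::tibble(
    tp = sum(j$pred == "positive" & j$gold == "positive"),
    fp = sum(j$pred == "positive" & j$gold == "negative"),
    fn = sum(j$pred == "negative" & j$gold == "positive"),
    tn = sum(j$pred == "negative" & j$gold == "negative")
  )
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' The exact interval for a binomial proportion via the beta-quantile
#' closed form: with `k` successes in `n` trials and confidence level
#' `level`, the lower bound is the `alpha/2` quantile of Beta(k, n-k+1)
#' (exactly 0 when k = 0) and the upper bound the `1-alpha/2` quantile of
#' Beta(k+1, n-k) (exactly 1 when k = n). Always contains k/n.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (>= 1).
#' @param level Confidence level, default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' clopper_pearson(8, 10)
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  stopifnot(length(k) == 1L, length(n) == 1L)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (k < 0 || k > n) stop("k must satisfy 0 <= k <= n", call. = FALSE)
  stopifnot(level > 0, level < 1)
  alpha <- 1 - level
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' Precision and recall with exact binomial confidence intervals
#'
#' Point estimates precision = tp/(tp+fp), recall = tp/(tp+fn) with
#' Clopper-Pearson intervals, and the F1 harmonic mean when both are
#' defined. A metric whose denominator is zero is reported as `NA`
#' (undefined), never silently coerced to 0.
#'
#' @param counts A one-row tibble/list with `tp`, `fp`, `fn` (from
#'   [confusion()]).
#' @param level Confidence level for the intervals, default 0.95.
#' @return An object of class `ocs_eval` with elements `counts`,
#'   `precision`, `recall`, `f1`, `ci_precision`, `ci_recall`,
#'   `conf_level`. Supports `tidy()`, `glance()` and `autoplot()`.
#' @examples
#' precision_recall(tibble::tibble(tp = 54, fp = 16, fn = 27))
#' @export
precision_recall <- function(counts, level = 0.95) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp >= 1) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn >= 1) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  ci_p <- if (!is.na(precision)) clopper_pearson(tp, tp + fp, level) else
    c(lower = NA_real_, upper = NA_real_)
  ci_r <- if (!is.na(recall)) clopper_pearson(tp, tp + fn, level) else
    c(lower = NA_real_, upper = NA_real_)
  structure(
    list(counts = tibble::as_tibble(counts), precision = precision,
         recall = recall, f1 = f1, ci_precision = ci_p, ci_recall = ci_r,
         conf_level = level),
    class = "ocs_eval"
  )
}

#' Evaluate detection output against gold labels
#'
#' Convenience wrapper: [confusion()] then [precision_recall()].
#'
#' @inheritParams confusion
#' @param level "instance" or "document".
#' @param conf_level Confidence level for the binomial intervals.
#' @return An `ocs_eval` object.
#' @export
evaluate_detection <- function(predicted, gold,
                               level = c("instance", "document"),
                               conf_level = 0.95) {
  precision_recall(confusion(predicted, gold, level), level = conf_level)
}

#' @export
print.ocs_eval <- function(x, ...) {
  fmt <- function(est, ci) {
    if (is.na(est)) return("undefined")
    sprintf("%.3f (%.3f-%.3f)", est, ci[["lower"]], ci[["upper"]])
  }
  cat("<ocs_eval>  counts: tp =", x$counts$tp, " fp =", x$counts$fp,
      " fn =", x$counts$fn, "\n")
  cat(sprintf("  precision: %s\n", fmt(x$precision, x$ci_precision)))
  cat(sprintf("  recall:    %s\n", fmt(x$recall, x$ci_recall)))
  cat(sprintf("  F1:        %s\n",
              ifelse(is.na(x$f1), "undefined", sprintf("%.3f", x$f1))))
  invisible(x)
}

#' @rdname precision_recall
#' @param x An `ocs_eval` object.
#' @param ... Unused.
#' @export
tidy.ocs_eval <- function(x, ...) {
  tibble::tibble(
    metric = c("precision", "recall", "f1"),
    estimate = c(x$precision, x$recall, x$f1),
    conf.low = c(x$ci_precision[["lower"]], x$ci_recall[["lower"]], NA_real_),
    conf.high = c(x$ci_precision[["upper"]], x$ci_recall[["upper"]], NA_real_)
  )
}

#' @rdname precision_recall
#' @export
glance.ocs_eval <- function(x, ...) {
  tibble::tibble(
    tp = x$counts$tp, fp = x$counts$fp, fn = x$counts$fn,
    precision = x$precision, recall = x$recall, f1 = x$f1,
    conf_level = x$conf_level
  )
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement from a square contingency table of joint
#' labels: observed agreement po = trace/N, expected agreement pe from
#' the row/column margins, kappa = (po - pe) / (1 - pe). When pe = 1
#' (all mass in one cell) kappa is undefined and reported as `NA`.
#'
#' @param tab A square matrix/table of joint label counts, or two equal
#'   length label vectors.
#' @param rater2 Second label vector when `tab` is a vector.
#' @return An object of class `ocs_agreement`: `observed_agreement`,
#'   `expected_agreement`, `kappa`, `n`.
#' @examples
#' cohens_kappa(matrix(c(40, 5, 10, 45), 2))
#' @export
cohens_kappa <- function(tab, rater2 = NULL) {
  if (!is.null(rater2)) {
    stopifnot(length(tab) == length(rater2))
    lev <- sort(unique(c(as.character(tab), as.character(rater2))))
    tab <- table(factor(as.character(tab), lev),
                 factor(as.character(rater2), lev))
  }
  tab <- as.matrix(tab)
  if (nrow(tab) != ncol(tab)) {
    stop("contingency table must be square", call. = FALSE)
  }
  if (any(tab < 0)) stop("negative counts", call. = FALSE)
  n <- sum(tab)
  if (n < 1) stop("empty table", call. = FALSE)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  kappa <- if (pe >= 1) NA_real_ else (po - pe) / (1 - pe)
  structure(
    list(observed_agreement = po, expected_agreement = pe, kappa = kappa,
         n = n),
    class = "ocs_agreement"
  )
}

#' @export
print.ocs_agreement <- function(x, ...) {
  cat(sprintf(
    "<ocs_agreement>  observed %.3f, expected %.3f, kappa %s (n = %d)\n",
    x$observed_agreement, x$expected_agreement,
    ifelse(is.na(x$kappa), "undefined", sprintf("%.3f", x$kappa)), x$n))
  invisible(x)
}

#' @rdname cohens_kappa
#' @param x An `ocs_agreement` object.
#' @param ... Unused.
#' @export
tidy.ocs_agreement <- function(x, ...) {
  tibble::tibble(observed_agreement = x$observed_agreement,
                 expected_agreement = x$expected_agreement,
                 kappa = x$kappa, n = x$n)
}

#' Align predicted to gold instances by anchor-span overlap
#'
#' When gold annotations carry character spans rather than shared
#' instance identifiers, predicted instances are aligned greedily
#' (leftmost first) to the first gold span they overlap within the same
#' document; each gold span is consumed at most once. The result is a
#' relabelled predicted table carrying the matched gold `instance_id`,
#' suitable for [confusion()].
#'
#' @param predicted Tibble with `doc_id`, `char_start`, `char_end`,
#'   `label`.
#' @param gold Tibble with `doc_id`, `instance_id`, `char_start`,
#'   `char_end`.
#' @return `predicted` with an added `instance_id` column (unmatched rows
#'   get a synthetic id unique to themselves).
#' @export
align_instances <- function(predicted, gold) {
  predicted <- dplyr::arrange(predicted, .data$doc_id, .data$char_start)
  used <- character()
  ids <- character(nrow(predicted))
  for (i in seq_len(nrow(predicted))) {
    p <- predicted[i, ]
    g <- gold %>%
      dplyr::filter(.data$doc_id == p$doc_id,
                    !.data$instance_id %in% used,
                    .data$char_start <= p$char_end,
                    .data$char_end >= p$char_start) %>%
      dplyr::arrange(.data$char_start)
    if (nrow(g)) {
      ids[i] <- g$instance_id[1]
      used <- c(used, g$instance_id[1])
    } else {
      ids[i] <- sprintf("unmatched_pred_%04d", i)
    }
  }
  dplyr::mutate(predicted, instance_id = ids)
}
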