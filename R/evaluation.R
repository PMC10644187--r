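#' Coding records
#'
#' A coding record is one yes/no judgement on one campaign by one coder.
#' Coders are free-form tags — in the original workflow `"term_list"` (the
#' automatic classifier), `"analytic_team"`, and `"sab"` (the community
#' study advisory board, the default gold standard). One label per
#' (campaign, coder) pair.
#'
#' @param campaign_id,coder_id,label Equal-length vectors; `label` must be
#'   `"yes"` or `"no"`.
#' @return A tibble with class `coding_tbl`.
#' @export
coding_records <- function(campaign_id, coder_id, label) {
  out <- tibble(
    campaign_id = as.character(campaign_id),
    coder_id = as.character(coder_id),
    label = as.character(label)
  )
  bad <- which(!out$label %in% c("yes", "no"))
  if (length(bad) > 0) {
    stop_crowdlex(
      paste0("label must be 'yes' or 'no'; offending row(s): ",
        paste(head(bad, 5), collapse = ", ")),
      "crowdlex_coding_error"
    )
  }
  dup <- duplicated(out[, c("campaign_id", "coder_id")])
  if (any(dup)) {
    stop_crowdlex(
      paste0("duplicate (campaign_id, coder_id) at row(s): ",
        paste(head(which(dup), 5), collapse = ", ")),
      "crowdlex_coding_error"
    )
  }
  class(out) <- c("coding_tbl", class(out))
  out
}

#' @rdname coding_records
#' @param path CSV file with columns `campaign_id,coder_id,label`.
#' @export
read_codes <- function(path) {
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      campaign_id = readr::col_character(),
      coder_id = readr::col_character(),
      label = readr::col_character()
    ),
    progress = FALSE
  )
  coding_records(out$campaign_id, out$coder_id, out$label)
}

#' @rdname coding_records
#' @param codes A `coding_tbl`.
#' @export
write_codes <- function(codes, path) {
  readr::write_csv(codes[, c("campaign_id", "coder_id", "label")], path,
    progress = FALSE)
  invisible(path)
}

#' Convert classification results to coding records
#'
#' Maps a `match_results` table for one dictionary onto yes/no codes so
#' the automatic classifier can sit on one side of an agreement
#' comparison: `positive` becomes `"yes"`; `negative` becomes `"no"`;
#' unresolved `qc_pending` follows `qc_as` (default `"no"`, the
#' conservative reading that an unverified ambiguous hit is not a
#' classification).
#'
#' @param results A `match_results` tibble.
#' @param dictionary Which dictionary's results to convert.
#' @param coder_id Coder tag for the generated codes.
#' @param qc_as `"no"` or `"yes"`.
#' @return A `coding_tbl`.
#' @export
results_to_codes <- function(results, dictionary = c("lgbtq", "cancer"),
                             coder_id = "term_list", qc_as = c("no", "yes")) {
  dictionary <- match.arg(dictionary)
  qc_as <- match.arg(qc_as)
  chunk <- results[results$dictionary == dictionary, ]
  label <- ifelse(
    chunk$classification == "positive", "yes",
    ifelse(chunk$classification == "negative", "no", qc_as)
  )
  coding_records(chunk$campaign_id, coder_id, label)
}

#' Randomly sample campaigns for manual coding
#'
#' Uniform sampling without replacement, reproducible for a fixed seed,
#' with the selected ids returned sorted. This is the step that draws the
#' batches (for example, 93 campaigns from the dictionary-positive pool)
#' sent to human coders.
#'
#' @param ids Character vector of campaign ids.
#' @param n Sample size; must not exceed `length(ids)`.
#' @param seed Integer seed.
#' @return Sorted character vector of `n` ids.
#' @export
sample_for_coding <- function(ids, n, seed) {
  if (n > length(ids)) {
    stop_crowdlex(
      sprintf("cannot sample %d ids from %d available", n, length(ids)),
      "crowdlex_sampling_error"
    )
  }
  sort(withr::with_seed(as.integer(seed), sample(ids, size = n, replace = FALSE)))
}

#' Pairwise percent agreement between two coders
#'
#' The proportion of campaigns on which two coders assign the same yes/no
#' label, as a percentage rounded half-up to one decimal;
#' `misclassification_percent` is `100 - agreement` computed before
#' rounding. Simple proportion agreement is reported (not chance-corrected
#' kappa) because that is the statistic the coding workflow is built
#' around; Cohen's kappa is included as a clearly-labelled extra field.
#' Both inputs must cover exactly the same campaigns; the comparison is
#' symmetric in its arguments.
#'
#' @param codes_a,codes_b `coding_tbl`s (or data frames with
#'   `campaign_id`, `label`) covering the same campaign ids, one label
#'   each.
#' @return An `agreement_report`: `n_items`, `n_agreements`,
#'   `percent_agreement`, `misclassification_percent`, `disagreeing_ids`
#'   (sorted), `kappa`.
#' @export
#' @examples
#' a <- coding_records(letters[1:10], "term_list", rep(c("yes", "no"), 5))
#' b <- coding_records(letters[1:10], "sab", c(rep("yes", 5), rep("no", 5)))
#' pairwise_agreement(a, b)
pairwise_agreement <- function(codes_a, codes_b) {
  a <- check_one_coder(codes_a, "codes_a")
  b <- check_one_coder(codes_b, "codes_b")
  only_a <- setdiff(a$campaign_id, b$campaign_id)
  only_b <- setdiff(b$campaign_id, a$campaign_id)
  if (length(only_a) > 0 || length(only_b) > 0) {
    stop_crowdlex(
      paste0(
        "coders cover different campaigns; only in codes_a: {",
        paste(head(sort(only_a), 10), collapse = ", "), "}, only in codes_b: {",
        paste(head(sort(only_b), 10), collapse = ", "), "}"
      ),
      "crowdlex_coding_error"
    )
  }
  b_matched <- b$label[match(a$campaign_id, b$campaign_id)]
  agree <- a$label == b_matched
  n <- length(agree)
  pct <- if (n == 0) NA_real_ else 100 * sum(agree) / n
  structure(
    list(
      n_items = n,
      n_agreements = sum(agree),
      percent_agreement = round_half_up(pct, 1),
      misclassification_percent = round_half_up(100 - pct, 1),
      disagreeing_ids = sort(a$campaign_id[!agree]),
      kappa = cohen_kappa(a$label, b_matched)
    ),
    class = "agreement_report"
  )
}

check_one_coder <- function(codes, arg) {
  stopifnot(is.data.frame(codes), all(c("campaign_id", "label") %in% names(codes)))
  if (anyDuplicated(codes$campaign_id)) {
    stop_crowdlex(paste0(arg, " has duplicate campaign ids"), "crowdlex_coding_error")
  }
  if ("coder_id" %in% names(codes) && length(unique(codes$coder_id)) > 1) {
    stop_crowdlex(paste0(arg, " mixes multiple coder_ids"), "crowdlex_coding_error")
  }
  codes
}

# Chance-corrected agreement, reported alongside (never instead of) the
# simple percent agreement.
cohen_kappa <- function(x, y) {
  n <- length(x)
  if (n == 0) return(NA_real_)
  po <- mean(x == y)
  pe <- mean(x == "yes") * mean(y == "yes") + mean(x == "no") * mean(y == "no")
  if (pe == 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "<agreement report: %d/%d items agree, %.1f%% agreement, %.1f%% misclassification>\n",
    x$n_agreements, x$n_items, x$percent_agreement, x$misclassification_percent
  ))
  invisible(x)
}

#' Attribute misclassification to dictionary terms
#'
#' For campaigns the dictionary classified `positive` but the gold
#' standard coded `"no"` (false positives), counts how often each term was
#' among the hits. A campaign whose hits involve `k` distinct terms
#' contributes to all `k` rows, so the counts sum to at least the number
#' of false-positive campaigns, with equality exactly when every false
#' positive has a single hitting term. This is the audit that surfaced
#' "trans" (medical compounds) and "gay" (legal names) as
#' misclassification drivers.
#'
#' @param results A `match_results` tibble for one dictionary.
#' @param gold A `coding_tbl` from the gold-standard coder covering every
#'   campaign in `results`.
#' @param qc_as_positive Also count unresolved `qc_pending` results as
#'   automatic positives (used when auditing a dictionary whose ambiguous
#'   terms are still active).
#' @return A tibble `term`, `false_positive_count`, `example_ids` (list
#'   column), sorted by count descending then term.
#' @export
attribute_misclassification <- function(results, gold, qc_as_positive = FALSE) {
  if (length(unique(results$dictionary)) > 1) {
    stop_crowdlex(
      "attribute_misclassification expects results for a single dictionary",
      "crowdlex_coding_error"
    )
  }
  gold <- check_one_coder(gold, "gold")
  missing <- setdiff(results$campaign_id, gold$campaign_id)
  if (length(missing) > 0) {
    stop_crowdlex(
      paste0("missing gold label(s) for: ", paste(head(sort(missing), 10), collapse = ", ")),
      "crowdlex_coding_error"
    )
  }
  pos_states <- if (qc_as_positive) c("positive", "qc_pending") else "positive"
  gold_label <- gold$label[match(results$campaign_id, gold$campaign_id)]
  fp <- results[results$classification %in% pos_states & gold_label == "no", ]
  if (nrow(fp) == 0) {
    return(tibble(
      term = character(), false_positive_count = integer(), example_ids = list()
    ))
  }
  pairs <- bind_rows(lapply(seq_len(nrow(fp)), function(i) {
    tibble(
      term = unique(str_to_lower(fp$hits[[i]]$surface)),
      campaign_id = fp$campaign_id[i]
    )
  }))
  out <- pairs |>
    group_by(.data$term) |>
    summarise(
      false_positive_count = dplyr::n(),
      example_ids = list(sort(unique(.data$campaign_id))),
      .groups = "drop"
    )
  out[order(-out$false_positive_count, out$term), ]
}

#' Summarise a refinement iteration
#'
#' Juxtaposes the agreement reports from before and after a dictionary
#' refinement with the diff that produced it. Pure formatting: every value
#' is re-derivable from the inputs, no new statistics are computed.
#'
#' @param before,after [pairwise_agreement()] reports.
#' @param diff A [diff_dictionaries()] result.
#' @return An `iteration_report` list: the two reports, the agreement
#'   change in percentage points, and the terms added / removed /
#'   status-changed.
#' @export
iteration_report <- function(before, after, diff) {
  stopifnot(
    inherits(before, "agreement_report"),
    inherits(after, "agreement_report"),
    inherits(diff, "dictionary_diff")
  )
  structure(
    list(
      before = before,
      after = after,
      agreement_change = round_half_up(
        after$percent_agreement - before$percent_agreement, 1
      ),
      terms_added = diff$added$surface,
      terms_removed = diff$removed$surface,
      terms_status_changed = diff$status_changed$surface,
      diff = diff
    ),
    class = "iteration_report"
  )
}

#' @export
print.iteration_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<refinement '%s' %s -> %s: agreement %.1f%% -> %.1f%% (%+.1f points); ",
      "+%d term(s), -%d term(s), %d status change(s)>\n"
    ),
    x$diff$name, x$diff$from_iteration, x$diff$to_iteration,
    x$before$percent_agreement, x$after$percent_agreement, x$agreement_change,
    length(x$terms_added), length(x$terms_removed), length(x$terms_status_changed)
  ))
  invisible(x)
}
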