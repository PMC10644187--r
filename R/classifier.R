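#' Classify campaigns against the cancer and LGBTQ+ dictionaries
#'
#' Each record is searched (title and description by default, concatenated
#' with a paragraph break; hit spans index into that concatenated text and
#' `boundary` records where the description begins) and receives one
#' result per dictionary with a three-state classification:
#'
#' * `positive` — at least one hit on an `active` term.
#' * `qc_pending` — at least one hit, but every hit is on a
#'   `quality_check` term ("trans-abdominal ultrasound" hits only the
#'   ambiguous "trans"); the campaign needs manual verification.
#' * `negative` — no hits.
#'
#' So a campaign mentioning "her wife" is LGBTQ+-positive outright, while
#' one whose only signal is the surname "Gay" is routed to quality check,
#' never classified positive automatically.
#'
#' @param record A one-row `campaign_tbl`.
#' @param cancer_matcher,lgbtq_matcher Compiled matchers
#'   ([compile_matcher()]).
#' @param fields Record fields searched, in order.
#' @return A `match_results` tibble with one row per dictionary and
#'   columns `campaign_id`, `dictionary`, `iteration`, `classification`,
#'   `hits` (list column of hit tables, span-ordered), `boundary`.
#' @export
classify_record <- function(record, cancer_matcher, lgbtq_matcher,
                            fields = c("title", "description")) {
  record <- campaign_records(record)
  stopifnot(nrow(record) == 1)
  classify_corpus(record, cancer_matcher, lgbtq_matcher, fields = fields)
}

classification_from_hits <- function(hits) {
  if (nrow(hits) == 0) {
    "negative"
  } else if (any(hits$status == "active")) {
    "positive"
  } else {
    "qc_pending"
  }
}

#' Classify a whole corpus, optionally resolving quality-check hits
#'
#' Runs [classify_record()] over every record. Quality-check resolutions —
#' the outcome of manual review — may be supplied as a named vector
#' (`campaign_id = "confirm"` or `"reject"`): a `qc_pending` result with a
#' `confirm` resolution becomes `positive`, with `reject` becomes
#' `negative`, and unresolved results stay `qc_pending`. A resolution for
#' a campaign that is not `qc_pending` in any dictionary is ignored with a
#' warning. A summary of final classification counts per dictionary is
#' logged.
#'
#' @inheritParams classify_record
#' @param records A `campaign_tbl`.
#' @param qc_resolutions Named character vector (names are campaign ids,
#'   values `"confirm"`/`"reject"`), or `NULL`.
#' @param quiet Suppress the summary log.
#' @return A `match_results` tibble, two rows (cancer, lgbtq) per record.
#' @export
classify_corpus <- function(records, cancer_matcher, lgbtq_matcher,
                            qc_resolutions = NULL,
                            fields = c("title", "description"),
                            quiet = FALSE) {
  records <- campaign_records(records)
  stopifnot(
    inherits(cancer_matcher, "crowdlex_matcher"),
    inherits(lgbtq_matcher, "crowdlex_matcher")
  )
  matchers <- list(cancer = cancer_matcher, lgbtq = lgbtq_matcher)
  if (!is.null(qc_resolutions)) {
    bad_ids <- setdiff(names(qc_resolutions), records$campaign_id)
    if (length(bad_ids) > 0) {
      stop_crowdlex(
        paste0(
          "qc resolution(s) for unknown campaign id(s): ",
          paste(head(bad_ids, 10), collapse = ", ")
        ),
        "crowdlex_classify_error"
      )
    }
    bad_vals <- setdiff(unique(qc_resolutions), c("confirm", "reject"))
    if (length(bad_vals) > 0) {
      stop_crowdlex(
        paste0("qc resolutions must be 'confirm' or 'reject', got: ",
          paste(bad_vals, collapse = ", ")),
        "crowdlex_classify_error"
      )
    }
  }

  rows <- vector("list", nrow(records) * 2L)
  for (i in seq_len(nrow(records))) {
    text <- search_text(records[i, ], fields)
    for (d in names(matchers)) {
      hits <- match_text(matchers[[d]], text)
      rows[[(i - 1L) * 2L + match(d, names(matchers))]] <- tibble(
        campaign_id = records$campaign_id[i],
        dictionary = d,
        iteration = matchers[[d]]$iteration,
        classification = classification_from_hits(hits),
        hits = list(hits),
        boundary = attr(text, "boundary")
      )
    }
  }
  results <- bind_rows(rows)

  if (!is.null(qc_resolutions)) {
    resolved_any <- logical(length(qc_resolutions))
    names(resolved_any) <- names(qc_resolutions)
    pending <- results$classification == "qc_pending" &
      results$campaign_id %in% names(qc_resolutions)
    res <- qc_resolutions[results$campaign_id[pending]]
    results$classification[pending] <- ifelse(res == "confirm", "positive", "negative")
    resolved_any[unique(results$campaign_id[pending])] <- TRUE
    unused <- names(resolved_any)[!resolved_any]
    if (length(unused) > 0) {
      warn(paste0(
        "ignoring qc resolution(s) for campaign(s) not pending quality check: ",
        paste(head(unused, 10), collapse = ", ")
      ))
    }
  }
  class(results) <- c("match_results", class(results))
  if (!quiet) {
    summary <- classification_summary(results)
    inform(sprintf(
      "%s: %s",
      summary$dictionary,
      map_chr(seq_len(nrow(summary)), function(i) {
        sprintf(
          "%d positive, %d qc_pending, %d negative",
          summary$positive[i], summary$qc_pending[i], summary$negative[i]
        )
      })
    ))
  }
  results
}

#' Summarise classification counts per dictionary
#'
#' @param results A `match_results` tibble.
#' @return A tibble with one row per dictionary and columns `positive`,
#'   `qc_pending`, `negative`.
#' @export
classification_summary <- function(results) {
  out <- lapply(split(results, results$dictionary), function(chunk) {
    tibble(
      dictionary = chunk$dictionary[1],
      positive = sum(chunk$classification == "positive"),
      qc_pending = sum(chunk$classification == "qc_pending"),
      negative = sum(chunk$classification == "negative")
    )
  })
  bind_rows(out)
}

#' Select the LGBTQ+ cancer study subset
#'
#' The study population is the conjunction: campaigns classified positive
#' by *both* dictionaries. Unresolved `qc_pending` classifications are
#' excluded under the default policy — mirroring a conservative
#' manual-verification workflow where an unreviewed ambiguous hit never
#' enters the study — or counted as positive under `qc_policy =
#' "include"` for sensitivity analysis. The number of campaigns excluded
#' solely by pending quality checks is logged.
#'
#' @param results A `match_results` tibble with both dictionaries.
#' @param qc_policy `"exclude"` (default) or `"include"`.
#' @param quiet Suppress the log message.
#' @return Sorted character vector of campaign ids.
#' @export
select_study_subset <- function(results, qc_policy = c("exclude", "include"),
                                quiet = FALSE) {
  qc_policy <- match.arg(qc_policy)
  ok_states <- if (qc_policy == "include") c("positive", "qc_pending") else "positive"
  wide <- split(results, results$campaign_id)
  decide <- function(chunk) {
    all(c("cancer", "lgbtq") %in% chunk$dictionary) &&
      all(chunk$classification[match(c("cancer", "lgbtq"), chunk$dictionary)] %in% ok_states)
  }
  selected <- names(wide)[vapply(wide, decide, logical(1))]
  if (!quiet && qc_policy == "exclude") {
    near_miss <- vapply(wide, function(chunk) {
      states <- chunk$classification[match(c("cancer", "lgbtq"), chunk$dictionary)]
      any(states == "qc_pending") && all(states %in% c("positive", "qc_pending"))
    }, logical(1))
    inform(sprintf(
      "study subset: %d campaign(s); %d excluded only by unresolved quality checks",
      length(selected), sum(near_miss)
    ))
  }
  sort(selected)
}

#' Read and write classification results as JSONL
#'
#' One object per campaign per dictionary: `campaign_id`, `dictionary`,
#' `iteration`, `classification`, `boundary`, and a `hits` array carrying
#' full provenance (term surface, match type, status, character span in
#' the searched text).
#'
#' @param results A `match_results` tibble.
#' @param path File path.
#' @return `write_match_results()` returns `path` invisibly;
#'   `read_match_results()` returns a `match_results` tibble.
#' @export
write_match_results <- function(results, path) {
  lines <- vapply(seq_len(nrow(results)), function(i) {
    row <- results[i, ]
    jsonlite::toJSON(
      list(
        campaign_id = row$campaign_id,
        dictionary = row$dictionary,
        iteration = row$iteration,
        classification = row$classification,
        boundary = row$boundary,
        hits = row$hits[[1]]
      ),
      auto_unbox = TRUE, dataframe = "rows", na = "null", digits = NA
    )
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' @rdname write_match_results
#' @export
read_match_results <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(str_trim(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    obj <- jsonlite::parse_json(lines[i])
    hits <- if (length(obj$hits) == 0) {
      empty_hits()
    } else {
      bind_rows(lapply(obj$hits, function(h) {
        tibble(
          surface = h$surface, match_type = h$match_type, status = h$status,
          start = as.integer(h$start), end = as.integer(h$end)
        )
      }))
    }
    tibble(
      campaign_id = obj$campaign_id,
      dictionary = obj$dictionary,
      iteration = obj$iteration,
      classification = obj$classification,
      hits = list(hits),
      boundary = as.integer(obj$boundary)
    )
  })
  out <- bind_rows(rows)
  class(out) <- c("match_results", class(out))
  out
}
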