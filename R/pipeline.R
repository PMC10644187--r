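#' Configure a full pipeline run
#'
#' Wires the stages together: ingest (fixture site directory or a
#' JSONL/CSV record file) -> language detection and English retention ->
#' active/US/medical corpus filter -> classification against both
#' dictionaries -> study-subset selection -> optional agreement
#' evaluation against manual coding files.
#'
#' @param input Path to a fixture-site directory (containing
#'   `sitemap.xml`) or to a records file.
#' @param out_dir Output directory for artifacts.
#' @param lgbtq_dict,cancer_dict Paths to dictionary files; default to
#'   the packaged final iterations.
#' @param codes_lgbtq,codes_cancer Optional coding CSVs
#'   (`campaign_id,coder_id,label`) holding manual codes for the
#'   LGBTQ+/cancer question; agreement against the automatic
#'   classification is computed for whichever are supplied.
#' @param gold_coder Coder tag treated as the gold standard in the coding
#'   files.
#' @param seed Integer seed, recorded in the outputs.
#' @param fields Record fields searched by the matchers.
#' @param qc_policy Unresolved quality-check policy for subset selection
#'   ([select_study_subset()]).
#' @param qc_resolutions Optional named vector of quality-check
#'   resolutions (see [classify_corpus()]).
#' @param record_format Format of a records-file input.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(input, out_dir,
                            lgbtq_dict = crowdlex_dictionary("lgbtq", "final"),
                            cancer_dict = crowdlex_dictionary("cancer", "final"),
                            codes_lgbtq = NULL, codes_cancer = NULL,
                            gold_coder = "sab",
                            seed = 1L,
                            fields = c("title", "description"),
                            qc_policy = c("exclude", "include"),
                            qc_resolutions = NULL,
                            record_format = "auto") {
  qc_policy <- match.arg(qc_policy)
  for (p in c(input, lgbtq_dict, cancer_dict, codes_lgbtq, codes_cancer)) {
    if (!file.exists(p)) {
      stop_crowdlex(paste0("input path does not exist: ", p), "crowdlex_config_error")
    }
  }
  structure(
    list(
      input = input, out_dir = out_dir,
      lgbtq_dict = lgbtq_dict, cancer_dict = cancer_dict,
      codes_lgbtq = codes_lgbtq, codes_cancer = codes_cancer,
      gold_coder = gold_coder, seed = as.integer(seed), fields = fields,
      qc_policy = qc_policy, qc_resolutions = qc_resolutions,
      record_format = record_format
    ),
    class = "pipeline_config"
  )
}

run_stage <- function(stage, expr) {
  tryCatch(
    expr,
    error = function(e) {
      stop_crowdlex(
        paste0("pipeline stage '", stage, "' failed: ", conditionMessage(e)),
        "crowdlex_stage_error", stage = stage, parent = e
      )
    }
  )
}

#' Run the full classification pipeline
#'
#' Executes every stage of [pipeline_config()], logging a per-stage
#' record funnel (ingested -> English -> active US medical -> positives
#' -> study subset) and writing machine-readable artifacts to `out_dir`:
#'
#' * `records_filtered.jsonl` — the corpus after language and corpus
#'   filters, with `language_codes` populated.
#' * `classifications.jsonl` — per-campaign, per-dictionary results with
#'   full term-hit provenance ([write_match_results()]).
#' * `study_subset.txt` — ids classified positive by both dictionaries.
#' * `summary.json` — funnel counts, dictionary names and iterations,
#'   seed, configuration hash, and any agreement reports.
#'
#' Runs are deterministic: the same configuration and inputs produce
#' byte-identical machine-readable outputs.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress logging.
#' @return Invisibly, a list with `records`, `results`, `subset`,
#'   `agreement` (possibly empty), and `summary`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) inform(sprintf(...))

  records <- run_stage("ingest", {
    if (dir.exists(config$input)) {
      scrape_fixture_site(config$input)
    } else {
      read_campaigns(config$input, config$record_format)
    }
  })
  say("ingest: %d record(s)", nrow(records))

  english <- run_stage("language_filter", {
    apply_english_rule(records, detect_corpus_languages(records))
  })
  say("english retention: %d record(s)", nrow(english))

  filtered <- run_stage("corpus_filter", filter_corpus(english))
  say("active US medical in English: %d record(s)", nrow(filtered))

  lgbtq_dictionary <- run_stage("dictionaries", load_dictionary(config$lgbtq_dict))
  cancer_dictionary <- run_stage("dictionaries", load_dictionary(config$cancer_dict))
  results <- run_stage("classify", {
    classify_corpus(
      filtered,
      cancer_matcher = compile_matcher(cancer_dictionary),
      lgbtq_matcher = compile_matcher(lgbtq_dictionary),
      qc_resolutions = config$qc_resolutions,
      fields = config$fields,
      quiet = quiet
    )
  })

  subset_ids <- run_stage(
    "select_subset",
    select_study_subset(results, qc_policy = config$qc_policy, quiet = quiet)
  )
  say("LGBTQ+ cancer study subset: %d campaign(s)", length(subset_ids))

  agreement <- list()
  for (d in c("lgbtq", "cancer")) {
    codes_path <- config[[paste0("codes_", d)]]
    if (is.null(codes_path)) next
    agreement[[d]] <- run_stage("evaluate", {
      codes <- read_codes(codes_path)
      gold <- codes[codes$coder_id == config$gold_coder, ]
      auto <- results_to_codes(results, dictionary = d)
      shared <- intersect(gold$campaign_id, auto$campaign_id)
      pairwise_agreement(
        auto[auto$campaign_id %in% shared, ],
        gold[gold$campaign_id %in% shared, ]
      )
    })
    say(
      "%s agreement vs %s: %.1f%% on %d item(s)", d, config$gold_coder,
      agreement[[d]]$percent_agreement, agreement[[d]]$n_items
    )
  }

  summary <- list(
    seed = config$seed,
    config_hash = unname(hash({
      # out_dir is excluded so reruns into different directories remain
      # byte-identical
      cfg <- unclass(config)
      cfg <- cfg[setdiff(names(cfg), "out_dir")]
      cfg[sort(names(cfg))]
    })),
    dictionaries = list(
      lgbtq = list(name = lgbtq_dictionary$name, iteration = lgbtq_dictionary$iteration),
      cancer = list(name = cancer_dictionary$name, iteration = cancer_dictionary$iteration)
    ),
    funnel = list(
      ingested = nrow(records),
      english = nrow(english),
      active_us_medical_english = nrow(filtered),
      cancer_positive = sum(results$dictionary == "cancer" & results$classification == "positive"),
      lgbtq_positive = sum(results$dictionary == "lgbtq" & results$classification == "positive"),
      study_subset = length(subset_ids)
    ),
    agreement = lapply(agreement, function(a) {
      list(
        n_items = a$n_items, n_agreements = a$n_agreements,
        percent_agreement = a$percent_agreement,
        misclassification_percent = a$misclassification_percent
      )
    })
  )

  run_stage("write_artifacts", {
    if (!dir.exists(config$out_dir)) {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    }
    write_campaigns(filtered, file.path(config$out_dir, "records_filtered.jsonl"), "jsonl")
    write_match_results(results, file.path(config$out_dir, "classifications.jsonl"))
    readr::write_lines(subset_ids, file.path(config$out_dir, "study_subset.txt"))
    jsonlite::write_json(
      summary, file.path(config$out_dir, "summary.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
  })

  invisible(list(
    records = filtered, results = results, subset = subset_ids,
    agreement = agreement, summary = summary
  ))
}
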