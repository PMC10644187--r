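# Small builders used across test files.

make_records <- function(n = 3, description = "A plain English description for testing.",
                         ...) {
  defaults <- list(
    title = "Help our neighbor",
    description = description,
    creation_date = as.Date("2022-11-14"),
    category = "medical",
    status = "active",
    donation_amount = 100,
    donor_count = 5L,
    organizer_location = "Salt Lake City, UT"
  )
  overrides <- list(...)
  fields <- utils::modifyList(defaults, overrides)
  df <- tibble::tibble(campaign_id = sprintf("camp-%03d", seq_len(n)))
  for (f in names(fields)) {
    v <- fields[[f]]
    df[[f]] <- if (length(v) == 1) rep(v, n) else v
  }
  campaign_records(df)
}

# randomized records (with missing values) for round-trip properties
random_records <- function(n, seed = NULL) {
  gen <- function() {
    maybe_na <- function(x, na) if (stats::runif(1) < 0.2) na else x
    tibble::tibble(
      campaign_id = paste0("id-", sprintf("%04d", sample.int(9999, n))),
      title = replicate(n, maybe_na(paste(
        sample(c("Help", "Support", "Fund", "Neighbors", "for", "our", "friend"),
          3, replace = TRUE), collapse = " "
      ), NA_character_)),
      description = replicate(n, maybe_na(paste(
        sample(c("hospital", "bills", "family", "hope", "long", "road", "thanks"),
          6, replace = TRUE), collapse = " "
      ), NA_character_)),
      creation_date = as.Date("2020-01-01") +
        ifelse(stats::runif(n) < 0.2, NA, sample.int(900, n)),
      category = sample(c("medical", "other"), n, replace = TRUE),
      status = sample(c("active", "inactive"), n, replace = TRUE),
      donation_amount = ifelse(stats::runif(n) < 0.2, NA, round(stats::runif(n, 0, 9999), 2)),
      donor_count = ifelse(stats::runif(n) < 0.2, NA, sample.int(500, n)),
      organizer_location = ifelse(
        stats::runif(n) < 0.2, NA_character_,
        sample(c("Tucson, AZ", "Berlin, Germany", "Chapel Hill, NC"), n, replace = TRUE)
      ),
      language_codes = lapply(
        seq_len(n),
        function(i) sample(c("en", "es", "de"), sample(0:2, 1))
      )
    )
  }
  out <- if (is.null(seed)) gen() else withr::with_seed(seed, gen())
  out$campaign_id <- make.unique(out$campaign_id, sep = "-")
  campaign_records(out)
}

# independent restatement of the three-state rule, for property tests
classification_from_hits_for_tests <- function(hits) {
  if (nrow(hits) == 0) {
    "negative"
  } else if (any(hits$status == "active")) {
    "positive"
  } else {
    "qc_pending"
  }
}

term_statuses_for_tests <- function() {
  c("active", "eliminated", "quality_check", "zero_hit")
}

# tiny dictionary built in code
mini_dictionary <- function(terms, name = "lgbtq", iteration = "final") {
  term_dictionary(name, iteration, terms)
}

tmp_dictionary_file <- function(lines, envir = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = envir)
  readr::write_lines(lines, path)
  path
}
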