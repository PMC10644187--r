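#' Configuration for the synthetic campaign-corpus generator
#'
#' The generator emulates a scraped medical-crowdfunding corpus with
#' planted ground truth: campaigns that truly concern cancer, true
#' LGBTQ+ identity disclosures, and the documented confounder patterns
#' that drive dictionary misclassification. Every probability can be set
#' per study; the defaults describe a desk-scale corpus in which each
#' pipeline stage sees enough of every case to be exercised (see the
#' methods vignette for the rationale behind each value).
#'
#' Confounder rates (each a probability per eligible campaign):
#'
#' * `trans_medical` — hyphenated medical "trans-" compounds
#'   ("trans-metatarsal", "trans-abdominal") in non-LGBTQ+ campaigns.
#' * `gay_name` — "Gay" as a legal first or last name.
#' * `lgbtq_eliminated` — benign uses of the later-eliminated terms
#'   ("partner", "fluid", "transitioning") in non-LGBTQ+ campaigns.
#' * `chemo_other_disease` — treatment words ("chemo", "chemotherapy",
#'   "mastectomy") used for non-cancer disease.
#' * `tangential_cancer` — a family member's cancer mentioned in a
#'   campaign that is not itself about cancer.
#' * `nonenglish` — the description is entirely in Spanish (the campaign
#'   carries no planted truth; it should leave the corpus at the language
#'   filter).
#' * `mixed_language` — a Spanish paragraph appended to an English
#'   description (the campaign must be retained).
#'
#' @param n_campaigns Number of campaigns (>= 1).
#' @param seed Integer seed; the whole corpus is a deterministic function
#'   of the configuration.
#' @param p_cancer Probability a campaign truly concerns cancer.
#' @param p_lgbtq_given_cancer Probability of a true LGBTQ+ disclosure in
#'   a cancer campaign.
#' @param confounder_rates Named list overriding any of the rates above.
#' @param field_missingness Probability that each optional field
#'   (creation date, donation amount, donor count, organizer location) is
#'   missing from a campaign page.
#' @return A `synthetic_config` object.
#' @export
synthetic_config <- function(n_campaigns = 500,
                             seed = 20221114,
                             p_cancer = 0.25,
                             p_lgbtq_given_cancer = 0.2,
                             confounder_rates = list(),
                             field_missingness = 0.05) {
  defaults <- list(
    trans_medical = 0.05, gay_name = 0.05, lgbtq_eliminated = 0.05,
    chemo_other_disease = 0.05, tangential_cancer = 0.05,
    nonenglish = 0.05, mixed_language = 0.05
  )
  unknown <- setdiff(names(confounder_rates), names(defaults))
  if (length(unknown) > 0) {
    stop_crowdlex(
      paste0("unknown confounder rate(s): ", paste(unknown, collapse = ", ")),
      "crowdlex_config_error"
    )
  }
  rates <- utils::modifyList(defaults, confounder_rates)
  probs <- c(
    p_cancer = p_cancer, p_lgbtq_given_cancer = p_lgbtq_given_cancer,
    field_missingness = field_missingness, unlist(rates)
  )
  if (any(!is.finite(probs) | probs < 0 | probs > 1)) {
    bad <- names(probs)[!is.finite(probs) | probs < 0 | probs > 1]
    stop_crowdlex(
      paste0("probabilities must lie in [0, 1]: ", paste(bad, collapse = ", ")),
      "crowdlex_config_error"
    )
  }
  if (!is.numeric(n_campaigns) || n_campaigns < 1) {
    stop_crowdlex("n_campaigns must be >= 1", "crowdlex_config_error")
  }
  structure(
    list(
      n_campaigns = as.integer(n_campaigns), seed = as.integer(seed),
      p_cancer = p_cancer, p_lgbtq_given_cancer = p_lgbtq_given_cancer,
      confounder_rates = rates, field_missingness = field_missingness
    ),
    class = "synthetic_config"
  )
}

# ---- slot-filled text banks -------------------------------------------------
# Hand-written crowdfunding-style English. Every sentence outside a plant is
# vetted to contain no term from either lexicon iteration, so planted content
# alone determines match output.

synth_first_names <- function() {
  c("Jordan", "Riley", "Marcus", "Elena", "Priya", "Miguel", "Dana",
    "Noah", "Carmen", "Ruth", "Omar", "June")
}

synth_last_names <- function() {
  c("Rivera", "Okafor", "Larsen", "Whitfield", "Nguyen", "Alvarez",
    "Booker", "Castillo", "Hart", "Mori")
}

synth_filler <- function() {
  c(
    "Thank you for taking the time to read our story.",
    "Any amount helps cover hospital bills and time away from work.",
    "Please share this page with anyone who might be able to help.",
    "We are deeply grateful for the kindness of this community.",
    "The road ahead is long, but we remain hopeful.",
    "Every message of encouragement means the world to the whole family."
  )
}

synth_spanish_paragraphs <- function() {
  c(
    paste(
      "Gracias por leer nuestra historia y por todo el apoyo que nos han dado.",
      "Cada donación ayuda a cubrir los gastos del hospital y del transporte.",
      "Estamos muy agradecidos con toda la comunidad."
    ),
    paste(
      "Queremos agradecer de corazón a todas las personas que han",
      "compartido esta página. Los gastos son muy altos y cada aporte",
      "cuenta. Con su ayuda vamos a salir adelante."
    )
  )
}

# LGBTQ+ plants: final-list active terms across all five match types.
# value = sentence containing the term surface (case-insensitively verbatim;
# prefix-type surfaces appear as the leading characters of their realization).
synth_lgbtq_plants <- function() {
  list(
    "Her wife" = "Her wife has been by her side through every appointment.",
    "His husband" = "His husband has been at every single appointment.",
    "Her girlfriend" = "Her girlfriend set up this page on her behalf.",
    "His boyfriend" = "His boyfriend is organizing meals and rides.",
    "Queer" = "Queer community members have rallied around them.",
    "Lesbian" = "Lesbian friends from her book club started this fund.",
    "Nonbinary" = "Nonbinary friends from the studio are hosting a benefit show.",
    "Non-binary" = "Non-binary folks from the collective set up this page.",
    "LGBT" = "The local LGBT center is matching donations this month.",
    "Dysphoria" = "Dysphoria has made the long hospital stays even harder.",
    "Genderqueer" = "Genderqueer artists from the co-op donated pieces for the auction.",
    "AFAB" = "AFAB patients with this condition are often diagnosed late.",
    "FTM" = "FTM support groups online have been a real lifeline.",
    "Mx." = "Mx. Alvarez has taught in our district for twenty years.",
    "Ne/" = "Ne/nem pronouns are what our friend uses, and the nurses have been wonderful about it.",
    "Bottom surg" = "Bottom surgery was already scheduled when the diagnosis came.",
    "Gender aff" = "Gender affirming care has been part of her recovery plan.",
    "Gender dysphoria" = "Gender dysphoria adds another layer to every hospital visit.",
    "Assigned female at birth" = "Assigned female at birth, he has fought for respectful care at every turn."
  )
}

# Cancer plants: final-list terms with natural inline realizations.
synth_cancer_plants <- function() {
  list(
    "leukemia" = "leukemia",
    "lymphoma" = "lymphoma",
    "melanoma" = "melanoma",
    "sarcoma" = "a soft tissue sarcoma",
    "myeloma" = "multiple myeloma",
    "glioblastoma" = "glioblastoma",
    "neuroblastoma" = "neuroblastoma",
    "adenocarcinoma" = "adenocarcinoma",
    "astrocytoma" = "an astrocytoma",
    "carcinoid" = "a carcinoid tumor",
    "malignan" = "a malignant growth",
    "ductal carcinoma" = "ductal carcinoma",
    "renal cell" = "renal cell carcinoma",
    "squamous cell" = "squamous cell carcinoma",
    "wilm's tumor" = "wilm's tumor",
    "neuroendocrine tumor" = "a neuroendocrine tumor",
    "retinoblastoma" = "retinoblastoma",
    "lumpectomy" = "a lumpectomy followed by weeks of recovery"
  )
}

synth_cancer_sentences <- function() {
  c(
    "Last month %2$s was diagnosed with %1$s and treatment starts right away.",
    "Doctors found %1$s when %2$s went in for what should have been a routine visit.",
    "%2$s has been fighting %1$s since early spring."
  )
}

synth_confounders <- function() {
  list(
    trans_medical = list(
      list(term = "Trans", text = "She underwent a trans-metatarsal amputation after a severe infection."),
      list(term = "Trans", text = "A trans-abdominal scan is scheduled for early next week.")
    ),
    gay_name = list(
      list(term = "Gay", text = "%s Gay has lived in the valley all of his life."),
      list(term = "Gay", text = "Gay %s, a beloved teacher, is facing steep bills after the accident.")
    ),
    lgbtq_eliminated = list(
      list(term = "Partner", text = "Her partner of twenty years has not left her side."),
      list(term = "Fluid", text = "Doctors drained fluid from around his lungs twice this month."),
      list(term = "Transitioning", text = "We are transitioning her care to a clinic closer to home.")
    ),
    chemo_other_disease = list(
      list(term = "chemo", text = "The infusions for her autoimmune condition felt like chemo, she says."),
      list(term = "mastectomy", text = "After a preventive mastectomy for a benign condition, she faces months of recovery."),
      list(term = "chemotherap", text = "His kidney disease requires dialysis and a drug regimen as harsh as chemotherapy.")
    ),
    tangential_cancer = list(
      list(term = "leukemia", text = "Years ago her aunt passed away from leukemia, and those memories make this heart operation even harder."),
      list(term = "lymphoma", text = "His grandfather survived lymphoma, so the family knows hospital waiting rooms well; this time it is a spinal injury.")
    )
  )
}

synth_titles <- function() {
  c(
    "Help %s with medical bills",
    "Support %s and family",
    "%s needs our help",
    "Standing with %s"
  )
}

synth_us_locations <- function() {
  c(
    "Salt Lake City, UT", "Rochester, New York", "Tucson, AZ",
    "Chapel Hill, NC", "Portland, OR", "Bloomington, Indiana",
    "Cheyenne, WY", "Tampa, Florida"
  )
}

synth_nonus_locations <- function() {
  c(
    "Toronto, Ontario, Canada", "Vancouver, British Columbia, Canada",
    "London, United Kingdom", "Guadalajara, Jalisco, Mexico",
    "Berlin, Germany", "Melbourne, Victoria, Australia"
  )
}

# ---- generator --------------------------------------------------------------

#' Generate a synthetic campaign corpus with planted ground truth
#'
#' Builds `n_campaigns` campaign records from hand-written English
#' crowdfunding-style templates (no generative model), planting:
#'
#' * in true cancer campaigns, at least one final-list cancer term;
#' * in true LGBTQ+ campaigns, at least one active final-list LGBTQ+ term,
#'   sampled across all five match types (phrases like "his husband",
#'   whole words like "queer", pronoun sets, prefix targets like "bottom
#'   surgery");
#' * in confounded campaigns, only the confounder pattern (see
#'   [synthetic_config()]).
#'
#' Category, status, and organizer location vary so the corpus filter has
#' work to do, and optional fields go missing at the configured rate. The
#' result is reproducible: the same configuration always yields the same
#' corpus.
#'
#' @param config A [synthetic_config()].
#' @return A list with `records` (a `campaign_tbl`; `language_codes`
#'   left empty for the detector to fill) and `plant_log` (a tibble with
#'   `campaign_id`, `true_cancer`, `true_lgbtq`, `planted_terms`,
#'   `planted_confounders`, `confounder_terms`, `languages` — the planted
#'   truth for every campaign).
#' @export
generate_corpus <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(config) {
  n <- config$n_campaigns
  rates <- config$confounder_rates
  lgbtq_plants <- synth_lgbtq_plants()
  cancer_plants <- synth_cancer_plants()
  confounders <- synth_confounders()

  records <- vector("list", n)
  log_rows <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("campaign-%05d", i)
    first <- sample(synth_first_names(), 1)
    last <- sample(synth_last_names(), 1)

    nonenglish <- runif(1) < rates$nonenglish
    mixed <- !nonenglish && runif(1) < rates$mixed_language
    true_cancer <- !nonenglish && runif(1) < config$p_cancer
    true_lgbtq <- true_cancer && runif(1) < config$p_lgbtq_given_cancer

    planted_terms <- character()
    planted_conf <- character()
    conf_terms <- character()
    sentences <- character()
    display_name <- first

    if (!nonenglish) {
      active_conf <- character()
      if (!true_lgbtq) {
        for (key in c("trans_medical", "gay_name", "lgbtq_eliminated")) {
          if (runif(1) < rates[[key]]) active_conf <- c(active_conf, key)
        }
      }
      if (!true_cancer) {
        for (key in c("chemo_other_disease", "tangential_cancer")) {
          if (runif(1) < rates[[key]]) active_conf <- c(active_conf, key)
        }
      }

      if ("gay_name" %in% active_conf) display_name <- paste(first, "Gay")

      sentences <- c(sentences, sample(synth_filler(), 1))
      if (true_cancer) {
        term <- sample(names(cancer_plants), 1)
        tmpl <- sample(synth_cancer_sentences(), 1)
        sentences <- c(sentences, sprintf(tmpl, cancer_plants[[term]], first))
        planted_terms <- c(planted_terms, term)
      }
      if (true_lgbtq) {
        term <- sample(names(lgbtq_plants), 1)
        sentences <- c(sentences, lgbtq_plants[[term]])
        planted_terms <- c(planted_terms, term)
      }
      for (key in active_conf) {
        option <- sample(confounders[[key]], 1)[[1]]
        text <- option$text
        if (str_detect(text, "%s")) text <- sprintf(text, first)
        sentences <- c(sentences, text)
        planted_conf <- c(planted_conf, key)
        conf_terms <- c(conf_terms, option$term)
      }
      sentences <- c(sentences, sample(synth_filler(), 2))
      description <- paste(sentences, collapse = " ")
      languages <- "en"
      if (mixed) {
        description <- paste(
          description, sample(synth_spanish_paragraphs(), 1),
          sep = "\n\n"
        )
        planted_conf <- c(planted_conf, "mixed_language")
        languages <- c("en", "es")
      }
    } else {
      description <- paste(sample(synth_spanish_paragraphs(), 2), collapse = "\n\n")
      planted_conf <- "nonenglish"
      languages <- "es"
    }

    title <- sprintf(sample(synth_titles(), 1), display_name)
    miss <- function() runif(1) < config$field_missingness
    records[[i]] <- tibble(
      campaign_id = id,
      title = title,
      description = description,
      creation_date = if (miss()) as.Date(NA) else as.Date("2020-01-01") + sample.int(1049, 1),
      category = sample(c("medical", "other"), 1, prob = c(0.8, 0.2)),
      status = sample(c("active", "inactive"), 1, prob = c(0.8, 0.2)),
      donation_amount = if (miss()) NA_real_ else round(rlnorm(1, meanlog = 7, sdlog = 1), 2),
      donor_count = if (miss()) NA_integer_ else rpois(1, 30),
      organizer_location = if (miss()) {
        NA_character_
      } else if (runif(1) < 0.85) {
        sample(synth_us_locations(), 1)
      } else {
        sample(synth_nonus_locations(), 1)
      },
      language_codes = list(character())
    )
    log_rows[[i]] <- tibble(
      campaign_id = id,
      true_cancer = true_cancer,
      true_lgbtq = true_lgbtq,
      planted_terms = list(planted_terms),
      planted_confounders = list(planted_conf),
      confounder_terms = list(conf_terms),
      languages = list(languages)
    )
  }
  list(
    records = campaign_records(bind_rows(records)),
    plant_log = bind_rows(log_rows)
  )
}

# ---- fixture site -----------------------------------------------------------

escape_html <- function(x) {
  x <- str_replace_all(x, "&", "&amp;")
  x <- str_replace_all(x, "<", "&lt;")
  str_replace_all(x, ">", "&gt;")
}

fixture_url <- function(campaign_id) {
  paste0("https://fixture.test/f/", campaign_id)
}

#' Emit a fixture site for a campaign corpus
#'
#' Writes `sitemap.xml` plus one static HTML page per record into `dir`,
#' following the fixture template whose selectors
#' [extract_campaign()] reads. Missing fields are omitted from the page
#' (no element at all), so extraction reproduces the missing markers;
#' scraping the emitted site recovers the input records exactly.
#'
#' @param records A `campaign_tbl`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
emit_fixture_site <- function(records, dir) {
  records <- campaign_records(records)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) {
      stop_crowdlex(paste0("cannot create directory ", dir), "crowdlex_io_error")
    }
  }
  if (file.access(dir, mode = 2) != 0) {
    stop_crowdlex(paste0("directory not writable: ", dir), "crowdlex_io_error")
  }
  urls <- fixture_url(records$campaign_id)
  sitemap <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<urlset xmlns=\"http://www.sitemaps.org/schemas/sitemap/0.9\">",
    sprintf("  <url><loc>%s</loc></url>", urls),
    "</urlset>"
  )
  readr::write_lines(sitemap, file.path(dir, "sitemap.xml"))
  for (i in seq_len(nrow(records))) {
    row <- records[i, ]
    field_line <- function(class, value) {
      if (length(value) == 0 || is.na(value)) {
        return(character())
      }
      sprintf("<span class=\"%s\">%s</span>", class, escape_html(as.character(value)))
    }
    page <- c(
      "<!DOCTYPE html>",
      "<html><head><meta charset=\"utf-8\">",
      sprintf("<link rel=\"canonical\" href=\"%s\">", urls[i]),
      "</head><body>",
      if (!is.na(row$title)) {
        sprintf("<h1 class=\"campaign-title\">%s</h1>", escape_html(row$title))
      },
      field_line(
        "campaign-date",
        if (is.na(row$creation_date)) NA else format(row$creation_date, "%Y-%m-%d")
      ),
      field_line("campaign-category", row$category),
      field_line("campaign-status", row$status),
      field_line(
        "donation-amount",
        if (is.na(row$donation_amount)) NA else as.character(row$donation_amount)
      ),
      field_line(
        "donor-count",
        if (is.na(row$donor_count)) NA else as.character(row$donor_count)
      ),
      field_line("organizer-location", row$organizer_location),
      if (!is.na(row$description)) {
        sprintf(
          "<div class=\"campaign-description\">%s</div>",
          escape_html(row$description)
        )
      },
      "</body></html>"
    )
    readr::write_lines(page, file.path(dir, paste0(row$campaign_id, ".html")))
  }
  invisible(dir)
}
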