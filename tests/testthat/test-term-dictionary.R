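lgbtq_final <- load_dictionary(crowdlex_dictionary("lgbtq", "final"))
lgbtq_initial <- load_dictionary(crowdlex_dictionary("lgbtq", "initial"))
cancer_final <- load_dictionary(crowdlex_dictionary("cancer", "final"))
cancer_initial <- load_dictionary(crowdlex_dictionary("cancer", "initial"))

test_that("packaged dictionaries load with expected composition", {
  expect_equal(lgbtq_initial$iteration, "initial")
  expect_equal(nrow(lgbtq_initial$terms), 78)
  expect_true(all(lgbtq_initial$terms$status == "active"))

  expect_equal(nrow(lgbtq_final$terms), 34)
  qc <- lgbtq_final$terms$surface[lgbtq_final$terms$status == "quality_check"]
  expect_setequal(qc, c("Gay", "Trans"))
  expect_true("Nonbinary" %in%
    lgbtq_final$terms$surface[lgbtq_final$terms$status == "active"])

  expect_equal(nrow(cancer_initial$terms), 48)
  expect_equal(nrow(cancer_final$terms), 43)
  expect_false("chemo" %in% stringr::str_to_lower(cancer_final$terms$surface))
})

test_that("duplicate and malformed dictionary lines are load errors", {
  dup <- tmp_dictionary_file(c(
    "#! name: lgbtq", "#! iteration: final",
    "Queer\twhole_word\tactive",
    "queer\twhole_word\tactive"
  ))
  expect_error(load_dictionary(dup), regexp = "duplicate.*line 3.*line 4",
    class = "crowdlex_dictionary_error")

  badtype <- tmp_dictionary_file(c(
    "#! name: lgbtq", "Queer\tsubstring\tactive"
  ))
  expect_error(load_dictionary(badtype), regexp = "match_type",
    class = "crowdlex_dictionary_error")

  badstatus <- tmp_dictionary_file(c(
    "#! name: lgbtq", "Queer\twhole_word\tretired"
  ))
  expect_error(load_dictionary(badstatus), regexp = "status",
    class = "crowdlex_dictionary_error")

  expect_error(
    term_dictionary("lgbtq", "final",
      tibble::tibble(surface = "They", match_type = "pronoun_slash", status = "active")
    ),
    regexp = "end in '/'", class = "crowdlex_dictionary_error"
  )
})

test_that("dictionary files round-trip through write_dictionary", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dictionary(lgbtq_final, path)
  back <- load_dictionary(path)
  expect_equal(back$terms, lgbtq_final$terms)
  expect_equal(back$iteration, "final")
})

test_that("documented confounder surfaces hit as quality-check terms", {
  m <- compile_matcher(lgbtq_final)
  h1 <- match_text(m, "she underwent a trans-metatarsal amputation")
  expect_equal(h1$surface, "Trans")
  expect_equal(h1$status, "quality_check")
  h2 <- match_text(m, "a trans-abdominal ultrasound found a cyst")
  expect_equal(h2$surface, "Trans")
  h3 <- match_text(m, "Gary Gay is raising funds for his neighbor")
  expect_equal(h3$surface, "Gay")
  expect_equal(h3$status, "quality_check")
})

test_that("phrase, prefix, pronoun, and follower semantics behave as specified", {
  m <- compile_matcher(lgbtq_final)
  # active phrase
  h <- match_text(m, "her wife has been by her side")
  expect_equal(h$surface, "Her wife")
  expect_equal(substr("her wife has been by her side", h$start, h$end - 1), "her wife")
  # phrase_prefix: final token prefix
  expect_equal(match_text(m, "bottom surgery is scheduled")$surface, "Bottom surg")
  expect_equal(nrow(match_text(m, "the bottom shelf of the surgical unit")), 0)
  # pronoun_slash needs the slash
  expect_equal(match_text(m, "ne/nem pronouns")$surface, "Ne/")
  expect_equal(nrow(match_text(m, "ne nem pronouns")), 0)
  # trailing-period surface needs the period
  expect_equal(match_text(m, "Mx. Rivera teaches here")$surface, "Mx.")
  expect_equal(nrow(match_text(m, "the mx record of the domain")), 0)
  # hyphen and space spellings of a phrase both match
  expect_equal(match_text(m, "their non-binary kid")$surface, "Non-binary")
  expect_equal(match_text(m, "their non binary kid")$surface, "Non-binary")

  mc <- compile_matcher(cancer_final)
  # prefix_stem hits inflections
  expect_equal(match_text(mc, "tests showed a malignancy")$surface, "malignan")
  expect_equal(match_text(mc, "pediatric leukemias are rare")$surface, "leukemia")
  # apostrophes are token-internal
  expect_equal(match_text(mc, "treated for wilm's tumor")$surface, "wilm's tumor")
})

test_that("matching preserves diacritics: cáncer does not match cancer", {
  mc <- compile_matcher(cancer_final)
  expect_equal(match_text(mc, "le detectaron cáncer")$surface, "cáncer")
  expect_equal(nrow(match_text(mc, "a cancer diagnosis")), 0)
})

test_that("eliminated treatment words are inert in the final cancer lexicon", {
  mc <- compile_matcher(cancer_final)
  expect_equal(nrow(match_text(mc, "she is going through chemo")), 0)
  expect_equal(nrow(match_text(mc, "chemotherapy and a mastectomy")), 0)
  mi <- compile_matcher(cancer_initial)
  expect_gt(nrow(match_text(mi, "she is going through chemo")), 0)
})

test_that("adding eliminated or zero_hit terms never changes match output", {
  base <- mini_dictionary(tibble::tibble(
    surface = c("Queer", "Her wife"),
    match_type = c("whole_word", "phrase"),
    status = "active"
  ))
  padded <- mini_dictionary(tibble::tibble(
    surface = c("Queer", "Her wife", "Fluid", "Partner", "Vaginoplasty"),
    match_type = c("whole_word", "phrase", "whole_word", "whole_word", "whole_word"),
    status = c("active", "active", "eliminated", "eliminated", "zero_hit")
  ))
  texts <- c(
    "her wife and her partner are here",
    "a fluid situation for a queer couple",
    "nothing to see"
  )
  for (txt in texts) {
    expect_same_hits(
      match_text(compile_matcher(padded), txt),
      match_text(compile_matcher(base), txt),
      info = txt
    )
  }
})

test_that("match output is invariant under case-mangling of the input", {
  m <- compile_matcher(lgbtq_final)
  mc <- compile_matcher(cancer_final)
  texts <- withr::with_seed(42, replicate(20, random_oracle_text(10)))
  mangle <- function(text) {
    chars <- strsplit(text, "")[[1]]
    up <- withr::with_seed(7, stats::runif(length(chars)) < 0.5)
    paste0(ifelse(up, stringr::str_to_upper(chars), stringr::str_to_lower(chars)),
      collapse = "")
  }
  for (txt in texts) {
    for (matcher in list(m, mc)) {
      a <- match_text(matcher, txt)
      b <- match_text(matcher, mangle(txt))
      expect_same_hits(b, a, info = txt)
    }
  }
})

test_that("compiled matcher equals the brute-force scanner on focused cases", {
  cases <- c(
    "Her wife and his husband met Mx. Lee after the trans-metatarsal operation",
    "bottom surgery; gender affirming care, they/them and ne/nem",
    "chemotherapy for a malignant neuroendocrine tumor, wilm's tumor too",
    "2-spirit elders and 2 spirit youth",
    "CÁNCER cáncer cancer chemo chemo-therapy",
    ""
  )
  for (txt in cases) {
    expect_same_hits(
      match_text(compile_matcher(lgbtq_initial), txt),
      oracle_hits(lgbtq_initial$terms, txt),
      info = txt
    )
    expect_same_hits(
      match_text(compile_matcher(cancer_initial), txt),
      oracle_hits(cancer_initial$terms, txt),
      info = txt
    )
  }
})

test_that("audit_zero_hits returns unmatched terms of any status, sorted", {
  corpus <- make_records(5, description = "We are grateful for every donation.")
  corpus$description[3] <- "Queer friends set up this page."
  audited <- audit_zero_hits(lgbtq_final, corpus)
  expect_true("Vaginoplasty" %in% audit_zero_hits(lgbtq_initial, corpus)$surface)
  expect_false("Queer" %in% audited$surface)
  expect_equal(audited$surface, sort(audited$surface))

  # empty corpus: every term is vacuously zero-hit
  empty <- campaign_records(make_records(1)[0, ])
  expect_equal(nrow(audit_zero_hits(lgbtq_final, empty)), nrow(lgbtq_final$terms))
})

test_that("audit_zero_hits equals the set difference against planted terms", {
  # plant k terms whose realizations nest no other dictionary surface, so the
  # expected zero-hit set is exactly (dictionary terms) minus (planted terms)
  plants <- c(
    "Queer" = "queer friends set up this page",
    "Her wife" = "her wife has been here daily",
    "His husband" = "his husband reads every update",
    "AFAB" = "AFAB patients are diagnosed late",
    "Lesbian" = "lesbian neighbors brought meals",
    "LGBT" = "the LGBT center helped",
    "Ne/" = "ne/nem pronouns please",
    "Mx." = "Mx. Hart teaches here",
    "Bottom surg" = "bottom surgery was scheduled",
    "Non-binary" = "non-binary folks organized a raffle"
  )
  corpus <- make_records(length(plants), description = unname(plants))
  audited <- audit_zero_hits(lgbtq_final, corpus)
  expected_zero <- lgbtq_final$terms$surface[
    !stringr::str_to_lower(lgbtq_final$terms$surface) %in%
      stringr::str_to_lower(names(plants))
  ]
  expect_setequal(audited$surface, expected_zero)
})

test_that("diffing the packaged iterations recovers the documented refinement", {
  d <- diff_dictionaries(lgbtq_initial, lgbtq_final)
  removed <- stringr::str_to_lower(d$removed$surface)
  expect_true(all(c("fluid", "transitioning", "partner") %in% removed))
  expect_equal(
    d$status_changed[order(d$status_changed$surface), ]$surface,
    c("Gay", "Trans")
  )
  expect_equal(unique(d$status_changed$old_status), "active")
  expect_equal(unique(d$status_changed$new_status), "quality_check")
  expect_equal(nrow(d$added), 0)

  dc <- diff_dictionaries(cancer_initial, cancer_final)
  expect_true(all(c("chemo", "chemotherap", "mastectomy") %in%
    stringr::str_to_lower(dc$removed$surface)))

  # identity diff
  d0 <- diff_dictionaries(lgbtq_final, lgbtq_final)
  expect_equal(nrow(d0$added) + nrow(d0$removed) + nrow(d0$status_changed), 0)

  expect_error(diff_dictionaries(lgbtq_final, cancer_final),
    class = "crowdlex_dictionary_error")
})

test_that("applying a diff to its source reproduces the target", {
  sort_terms <- function(d) {
    t <- d$terms[order(stringr::str_to_lower(d$terms$surface), d$terms$match_type), ]
    rownames(t) <- NULL
    t
  }
  pairs <- list(
    list(lgbtq_initial, lgbtq_final),
    list(cancer_initial, cancer_final),
    list(lgbtq_final, lgbtq_initial)
  )
  # randomized dictionary pairs drawn from a shared pool
  pool <- lgbtq_initial$terms
  withr::with_seed(99, {
    for (i in 1:10) {
      a_rows <- pool[sample(nrow(pool), 30), ]
      b_rows <- pool[sample(nrow(pool), 30), ]
      b_rows$status <- sample(term_statuses_for_tests(), 30, replace = TRUE)
      pairs[[length(pairs) + 1]] <- list(
        term_dictionary("lgbtq", "initial", a_rows),
        term_dictionary("lgbtq", "final", b_rows)
      )
    }
  })
  for (p in pairs) {
    rebuilt <- apply_dictionary_diff(diff_dictionaries(p[[1]], p[[2]]), p[[1]])
    expect_equal(sort_terms(rebuilt), sort_terms(p[[2]]))
    expect_equal(rebuilt$iteration, p[[2]]$iteration)
  }
})
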