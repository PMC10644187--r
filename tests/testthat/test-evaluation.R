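test_that("sample_for_coding is exhaustive, deterministic, and bounded", {
  ids <- sprintf("c%02d", 1:10)
  expect_setequal(sample_for_coding(ids, 10, seed = 1), ids)
  expect_identical(
    sample_for_coding(ids, 4, seed = 99),
    sample_for_coding(ids, 4, seed = 99)
  )
  expect_equal(sample_for_coding(ids, 4, seed = 99),
    sort(sample_for_coding(ids, 4, seed = 99)))
  expect_error(sample_for_coding(ids, 11, seed = 1),
    class = "crowdlex_sampling_error")
})

test_that("single-draw frequencies are uniform within binomial tolerance", {
  ids <- c("a", "b", "c", "d")
  draws <- vapply(
    seq_len(10000),
    function(s) sample_for_coding(ids, 1, seed = s),
    character(1)
  )
  counts <- table(factor(draws, levels = ids))
  # 3 sigma around n*p with p = 1/4
  sigma <- sqrt(10000 * 0.25 * 0.75)
  expect_true(all(abs(counts - 2500) <= 3 * sigma))
})

test_that("identical label vectors give 100.0% agreement", {
  for (n in c(1, 7, 93)) {
    labels <- rep(c("yes", "no"), length.out = n)
    ids <- sprintf("c%03d", seq_len(n))
    rep_ <- pairwise_agreement(
      coding_records(ids, "term_list", labels),
      coding_records(ids, "sab", labels)
    )
    expect_equal(rep_$percent_agreement, 100.0)
    expect_equal(rep_$misclassification_percent, 0.0)
    expect_equal(rep_$disagreeing_ids, character())
  }
})

test_that("8 of 10 matching labels is 80.0% agreement", {
  ids <- sprintf("c%02d", 1:10)
  a <- coding_records(ids, "term_list", rep("yes", 10))
  b <- coding_records(ids, "sab", c(rep("yes", 8), "no", "no"))
  rep_ <- pairwise_agreement(a, b)
  expect_equal(rep_$n_agreements, 8L)
  expect_equal(rep_$percent_agreement, 80.0)
  expect_equal(rep_$misclassification_percent, 20.0)
  expect_equal(rep_$disagreeing_ids, c("c09", "c10"))
})

test_that("agreement counts match an elementwise counting oracle on random vectors", {
  withr::with_seed(404, {
    for (trial in 1:20) {
      n <- sample(5:60, 1)
      ids <- sample(sprintf("id%04d", 1:5000), n)
      la <- sample(c("yes", "no"), n, replace = TRUE)
      lb <- sample(c("yes", "no"), n, replace = TRUE)
      a <- coding_records(ids, "term_list", la)
      b <- coding_records(sample(ids), "sab", lb[match(sample(ids), ids)])
      # realign b's labels to its shuffled ids
      b <- coding_records(ids, "sab", lb)
      rep_ <- pairwise_agreement(a, b)
      # oracle: explicit elementwise loop
      agree <- 0
      for (i in seq_len(n)) {
        if (la[i] == lb[ids == ids[i]][1]) agree <- agree + 1
      }
      expect_equal(rep_$n_agreements, agree)
      # symmetry
      rep_ba <- pairwise_agreement(b, a)
      expect_equal(rep_ba$n_agreements, rep_$n_agreements)
      expect_equal(rep_ba$percent_agreement, rep_$percent_agreement)
      expect_equal(rep_ba$disagreeing_ids, rep_$disagreeing_ids)
    }
  })
})

test_that("percentages round half-up to one decimal", {
  # 5/8 = 62.5 exactly; 11/16 = 68.75 -> 68.8 under half-up
  expect_equal(round_half_up(100 * 5 / 8, 1), 62.5)
  expect_equal(round_half_up(100 * 11 / 16, 1), 68.8)
  expect_equal(round_half_up(79.25, 1), 79.3)
  ids <- sprintf("c%02d", 1:16)
  rep_ <- pairwise_agreement(
    coding_records(ids, "a", rep("yes", 16)),
    coding_records(ids, "b", c(rep("yes", 11), rep("no", 5)))
  )
  expect_equal(rep_$percent_agreement, 68.8)
})

test_that("mismatched id sets raise an error listing the symmetric difference", {
  a <- coding_records(c("x", "y"), "a", c("yes", "no"))
  b <- coding_records(c("y", "z"), "b", c("yes", "no"))
  expect_error(pairwise_agreement(a, b), regexp = "x.*z",
    class = "crowdlex_coding_error")
})

test_that("coding files round-trip and enforce one label per coder pair", {
  codes <- coding_records(
    rep(c("c1", "c2"), 2),
    rep(c("sab", "analytic_team"), each = 2),
    c("yes", "no", "yes", "yes")
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_codes(codes, path)
  expect_equal(as.data.frame(read_codes(path)), as.data.frame(codes))
  expect_error(coding_records(c("c1", "c1"), "sab", c("yes", "no")),
    class = "crowdlex_coding_error")
  expect_error(coding_records("c1", "sab", "maybe"),
    class = "crowdlex_coding_error")
})

test_that("misclassification is attributed to the hitting terms", {
  lgbtq_m <- compile_matcher(load_dictionary(crowdlex_dictionary("lgbtq", "final")))
  cancer_m <- compile_matcher(load_dictionary(crowdlex_dictionary("cancer", "final")))
  recs <- make_records(4)
  recs$description <- c(
    "Her wife is recovering well.", # true positive
    "Queer neighbors rallied around.", # false positive (gold says no)
    "Queer friends and her wife both helped.", # false positive, two terms
    "Nothing relevant." # true negative
  )
  res <- suppressMessages(classify_corpus(recs, cancer_m, lgbtq_m))
  lg <- res[res$dictionary == "lgbtq", ]
  gold <- coding_records(recs$campaign_id, "sab", c("yes", "no", "no", "no"))
  tab <- attribute_misclassification(lg, gold)
  expect_equal(tab$term, c("queer", "her wife"))
  expect_equal(tab$false_positive_count, c(2L, 1L))
  expect_equal(tab$example_ids[[1]], c("camp-002", "camp-003"))

  # zero disagreements -> empty table
  gold_all <- coding_records(recs$campaign_id, "sab", c("yes", "yes", "yes", "no"))
  expect_equal(nrow(attribute_misclassification(lg, gold_all)), 0)

  # missing gold labels are an error naming the ids
  expect_error(
    attribute_misclassification(lg, gold[1:2, ]),
    regexp = "camp-003", class = "crowdlex_coding_error"
  )
})

test_that("per-term counts equal the generator's plant log on confounder corpora", {
  cfg <- synthetic_config(
    n_campaigns = 250, seed = 33, p_cancer = 0.4, p_lgbtq_given_cancer = 0.2,
    confounder_rates = list(
      trans_medical = 0.25, gay_name = 0.15, lgbtq_eliminated = 0.3,
      chemo_other_disease = 0, tangential_cancer = 0,
      nonenglish = 0, mixed_language = 0
    )
  )
  corpus <- generate_corpus(cfg)
  initial <- load_dictionary(crowdlex_dictionary("lgbtq", "initial"))
  cancer_m <- compile_matcher(load_dictionary(crowdlex_dictionary("cancer", "final")))
  res <- suppressMessages(
    classify_corpus(corpus$records, cancer_m, compile_matcher(initial))
  )
  lg <- res[res$dictionary == "lgbtq", ]
  log <- corpus$plant_log
  gold <- coding_records(
    log$campaign_id, "sab", ifelse(log$true_lgbtq, "yes", "no")
  )
  tab <- attribute_misclassification(lg, gold)
  # oracle: join against the plant log — every confounder term planted in a
  # non-LGBTQ+ campaign is active under the initial lexicon, so each planted
  # campaign is a false positive attributed to exactly its planted terms
  expected <- table(tolower(unlist(
    log$confounder_terms[!log$true_lgbtq &
      vapply(log$confounder_terms, length, integer(1)) > 0]
  )))
  expect_setequal(tab$term, names(expected))
  expect_equal(
    tab$false_positive_count[match(names(expected), tab$term)],
    as.integer(expected)
  )
  # the most frequently planted confounder ranks first
  expect_equal(tab$term[1], names(expected)[which.max(expected)])
})

test_that("iteration_report juxtaposes agreement change with the diff", {
  ids87 <- sprintf("c%02d", 1:87)
  before <- pairwise_agreement(
    coding_records(ids87, "term_list", rep("yes", 87)),
    coding_records(ids87, "sab", c(rep("yes", 69), rep("no", 18)))
  )
  ids100 <- sprintf("d%03d", 1:100)
  after <- pairwise_agreement(
    coding_records(ids100, "term_list", rep("yes", 100)),
    coding_records(ids100, "sab", c(rep("yes", 95), rep("no", 5)))
  )
  d <- diff_dictionaries(
    load_dictionary(crowdlex_dictionary("lgbtq", "initial")),
    load_dictionary(crowdlex_dictionary("lgbtq", "final"))
  )
  rep_ <- iteration_report(before, after, d)
  expect_equal(rep_$before$percent_agreement, 79.3)
  expect_equal(rep_$after$percent_agreement, 95.0)
  expect_equal(rep_$agreement_change, 15.7)
  expect_true("Fluid" %in% rep_$terms_removed)
  expect_true("Gay" %in% rep_$terms_status_changed)

  same <- iteration_report(after, after, diff_dictionaries(
    load_dictionary(crowdlex_dictionary("lgbtq", "final")),
    load_dictionary(crowdlex_dictionary("lgbtq", "final"))
  ))
  expect_equal(same$agreement_change, 0)
  expect_equal(length(same$terms_removed), 0)
})
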