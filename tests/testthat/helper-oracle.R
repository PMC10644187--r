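# Independent brute-force matching oracle.
#
# Deliberately implemented with different machinery from the package
# (character-walking tokenizer on PCRE character classes; per-position
# term-by-term scanning) so the compiled matcher is checked against an
# independent reading of the match semantics, not against itself.

oracle_tokenize <- function(text) {
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(
      token = character(), start = integer(), end = integer(),
      stringsAsFactors = FALSE
    ))
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  is_tok <- grepl("^[\\p{L}\\p{N}']$", chars, perl = TRUE)
  n <- length(chars)
  starts <- integer()
  ends <- integer()
  i <- 1
  while (i <= n) {
    if (is_tok[i]) {
      j <- i
      while (j < n && is_tok[j + 1]) j <- j + 1
      starts <- c(starts, i)
      ends <- c(ends, j)
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  data.frame(
    token = substring(text, starts, ends),
    start = starts,
    end = ends + 1L, # half-open, as in the package
    stringsAsFactors = FALSE
  )
}

oracle_lower <- function(x) stringr::str_to_lower(x)

# every (term x token-position) pair is tested explicitly
oracle_hits <- function(terms, text, statuses = c("active", "quality_check")) {
  terms <- terms[terms$status %in% statuses, , drop = FALSE]
  tk <- oracle_tokenize(text)
  n <- nrow(tk)
  rows <- list()
  for (t in seq_len(nrow(terms))) {
    surface <- terms$surface[t]
    type <- terms$match_type[t]
    follower <- NA_character_
    src <- surface
    if (type == "pronoun_slash") {
      follower <- "/"
      src <- sub("/$", "", surface)
    } else if (grepl("\\.$", surface)) {
      follower <- "."
      src <- sub("\\.$", "", surface)
    }
    words <- oracle_lower(oracle_tokenize(src)$token)
    k <- length(words)
    if (k == 0) next
    for (pos in seq_len(n)) {
      if (pos + k - 1 > n) break
      toks <- oracle_lower(tk$token[pos:(pos + k - 1)])
      ok <- if (type == "prefix_stem") {
        substr(toks[1], 1, nchar(words[1])) == words[1] && k == 1
      } else if (type == "phrase_prefix") {
        all(toks[-k] == words[-k]) &&
          substr(toks[k], 1, nchar(words[k])) == words[k]
      } else {
        # whole_word, phrase, pronoun_slash: exact token equality
        all(toks == words)
      }
      if (ok && !is.na(follower)) {
        after <- substring(text, tk$end[pos + k - 1], tk$end[pos + k - 1])
        ok <- identical(after, follower)
      }
      if (ok) {
        rows[[length(rows) + 1]] <- data.frame(
          surface = surface, match_type = type, status = terms$status[t],
          start = tk$start[pos], end = tk$end[pos + k - 1],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(
      surface = character(), match_type = character(), status = character(),
      start = integer(), end = integer(), stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, rows)
}

# canonical ordering so hit frames from either implementation compare equal
sort_hits <- function(h) {
  h <- as.data.frame(h)[, c("surface", "match_type", "status", "start", "end")]
  h$start <- as.integer(h$start)
  h$end <- as.integer(h$end)
  h <- h[order(h$start, h$end, oracle_lower(h$surface), h$match_type), ]
  rownames(h) <- NULL
  h
}

expect_same_hits <- function(actual, expected, info = NULL) {
  expect_equal(sort_hits(actual), sort_hits(expected), info = info)
}

# word pool mixing true terms, inflections, documented confounders, and
# near misses across all five match types
oracle_word_pool <- function() {
  c(
    "the", "road", "ahead", "hospital", "bills", "family,", "hope.", "and",
    "for", "with", "every", "amount", "helps",
    "trans-metatarsal", "trans-abdominal", "transplant", "transfer",
    "Gay", "gay,", "Gaylord", "her", "wife", "her wife", "his", "husband",
    "his husband", "queer", "Queer!", "nonbinary", "non-binary",
    "genderqueer", "gender", "affirming", "gender-affirming", "bottom",
    "surgery", "surgical", "bottom surgery", "Mx.", "mx", "Ne/nem", "ne",
    "they/them", "They", "dysphoria", "AFAB", "partner", "fluid",
    "transitioning", "2", "spirit", "2-spirit",
    "leukemia", "leukemias", "luekemia", "malignancy", "malignant",
    "chemo", "chemotherapy", "mastectomy", "radiation", "therapy",
    "immuno", "cáncer", "CÁNCER", "cancer", "wilm's", "tumor",
    "wilm's tumor", "renal", "cell", "clear", "squamous", "carcinoma",
    "lymphoma", "non-hodgkins", "sarcoma"
  )
}

random_oracle_text <- function(n_words = 12) {
  words <- sample(oracle_word_pool(), n_words, replace = TRUE)
  seps <- sample(c(" ", " ", " ", ", ", " - ", "\n", "; "), n_words - 1, replace = TRUE)
  paste0(paste0(words[-n_words], seps, collapse = ""), words[n_words])
}
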