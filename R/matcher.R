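#' Tokenize text for term matching
#'
#' Tokens are maximal runs of Unicode letters, digits, and ASCII
#' apostrophes (so "wilm's" is one token); every other character — spaces,
#' hyphens, slashes, punctuation — is a boundary. That makes "trans" a
#' token of "trans-metatarsal", which is exactly why hyphenated medical
#' compounds hit the ambiguous term "trans" and need the quality-check
#' route. Matching is case-insensitive via locale-independent lower-casing;
#' diacritics are never folded, so "cáncer" and "cancer" are distinct
#' tokens.
#'
#' @param text A single string.
#' @return A tibble with columns `token` (lower-cased), `start`, `end`
#'   (character span, half-open: the token is
#'   `substr(text, start, end - 1)`), and `next_char` (the character
#'   immediately after the token, `""` at end of text).
#' @export
tokenize_text <- function(text) {
  if (is.null(text) || length(text) == 0 || is.na(text) || !nzchar(text)) {
    return(tibble(
      token = character(), start = integer(), end = integer(),
      next_char = character()
    ))
  }
  loc <- str_locate_all(text, "[\\p{L}\\p{N}']+")[[1]]
  if (nrow(loc) == 0) {
    return(tibble(
      token = character(), start = integer(), end = integer(),
      next_char = character()
    ))
  }
  tibble(
    token = str_to_lower(str_sub(text, loc[, 1], loc[, 2])),
    start = as.integer(loc[, 1]),
    end = as.integer(loc[, 2] + 1L),
    next_char = str_sub(text, loc[, 2] + 1L, loc[, 2] + 1L)
  )
}

# Tokenize a term surface into the pattern used at match time.
# A trailing "/" (pronoun sets) or "." ("Mx.") is not a token character;
# it is recorded as a required follower: the final token must be followed
# by exactly that character in the text.
compile_term <- function(surface, match_type, status) {
  follower <- NA_character_
  pattern_src <- surface
  if (match_type == "pronoun_slash") {
    follower <- "/"
    pattern_src <- sub("/$", "", surface)
  } else if (str_detect(surface, "\\.$")) {
    follower <- "."
    pattern_src <- sub("\\.$", "", surface)
  }
  tokens <- tokenize_text(pattern_src)$token
  if (length(tokens) == 0) {
    stop_crowdlex(
      paste0("term surface '", surface, "' contains no token characters"),
      "crowdlex_dictionary_error"
    )
  }
  list(
    surface = surface, match_type = match_type, status = status,
    tokens = tokens, follower = follower
  )
}

#' Compile a term dictionary into a matcher
#'
#' Compiles the `active` and `quality_check` terms of a dictionary into a
#' matcher; `eliminated` and `zero_hit` terms contribute no patterns, so
#' their presence in a file can never change match output. Matching is
#' case-insensitive, diacritic-preserving, and operates on the token
#' stream of [tokenize_text()] under these semantics:
#'
#' * `whole_word` — the surface equals one maximal token ("trans" hits
#'   inside "trans-metatarsal" because the hyphen is a token boundary). A
#'   surface with a trailing period, such as "Mx.", additionally requires
#'   the token to be immediately followed by `"."`.
#' * `prefix_stem` — the surface is a leading substring of a token
#'   ("malignan" hits "malignancy").
#' * `phrase` — consecutive tokens equal the surface's tokens ("her wife";
#'   "non-binary" written with hyphen or space alike).
#' * `phrase_prefix` — a phrase whose final token is a prefix match
#'   ("bottom surg" hits "bottom surgery").
#' * `pronoun_slash` — a token equal to the pre-slash surface immediately
#'   followed by `"/"` ("they/" hits "they/them" but not a bare "they").
#'
#' @param dictionary A [term_dictionary()].
#' @param include_all Compile every term regardless of status (used for
#'   zero-hit audits); default `FALSE`.
#' @return A `crowdlex_matcher`.
#' @export
#' @examples
#' m <- compile_matcher(load_dictionary(crowdlex_dictionary("lgbtq", "final")))
#' match_text(m, "Her wife has been by her side.")
compile_matcher <- function(dictionary, include_all = FALSE) {
  stopifnot(inherits(dictionary, "term_dictionary"))
  terms <- dictionary$terms
  if (!include_all) {
    terms <- terms[terms$status %in% c("active", "quality_check"), ]
  }
  patterns <- pmap(
    list(terms$surface, terms$match_type, terms$status),
    compile_term
  )
  structure(
    list(
      name = dictionary$name,
      iteration = dictionary$iteration,
      patterns = patterns
    ),
    class = "crowdlex_matcher"
  )
}

#' @export
print.crowdlex_matcher <- function(x, ...) {
  cat(sprintf(
    "<compiled matcher '%s' (%s iteration): %d pattern(s)>\n",
    x$name, x$iteration, length(x$patterns)
  ))
  invisible(x)
}

empty_hits <- function() {
  tibble(
    surface = character(), match_type = character(), status = character(),
    start = integer(), end = integer()
  )
}

#' Find all term hits in a text
#'
#' @param matcher A [compile_matcher()] result.
#' @param text A single string.
#' @return A tibble of hits — `surface`, `match_type`, `status`, and the
#'   half-open character span `start`/`end` of the matched token run —
#'   ordered by position. Spans slice the matched tokens out of `text`
#'   (`substr(text, start, end - 1)`).
#' @export
match_text <- function(matcher, text) {
  stopifnot(inherits(matcher, "crowdlex_matcher"))
  toks <- tokenize_text(text)
  n <- nrow(toks)
  if (n == 0 || length(matcher$patterns) == 0) {
    return(empty_hits())
  }
  token <- toks$token
  next_char <- toks$next_char
  out <- list()
  for (p in matcher$patterns) {
    k <- length(p$tokens)
    idx <- if (p$match_type %in% c("prefix_stem")) {
      which(startsWith(token, p$tokens[1]))
    } else {
      which(token == p$tokens[1])
    }
    if (k > 1 && length(idx) > 0) {
      idx <- idx[idx + k - 1 <= n]
      for (j in seq_len(k - 1)[-(k - 1)]) { # middle tokens (exact)
        if (length(idx) == 0) break
        idx <- idx[token[idx + j] == p$tokens[j + 1]]
      }
      if (length(idx) > 0) {
        last <- p$tokens[k]
        idx <- if (p$match_type == "phrase_prefix") {
          idx[startsWith(token[idx + k - 1], last)]
        } else {
          idx[token[idx + k - 1] == last]
        }
      }
    }
    if (!is.na(p$follower) && length(idx) > 0) {
      idx <- idx[next_char[idx + k - 1] == p$follower]
    }
    if (length(idx) > 0) {
      out[[length(out) + 1]] <- tibble(
        surface = p$surface, match_type = p$match_type, status = p$status,
        start = toks$start[idx], end = toks$end[idx + k - 1]
      )
    }
  }
  if (length(out) == 0) {
    return(empty_hits())
  }
  hits <- bind_rows(out)
  hits[order(hits$start, hits$end, hits$surface), ]
}

#' Audit a dictionary for zero-hit terms
#'
#' Returns the terms (of any status) with no match anywhere in the corpus
#' — across titles and descriptions — sorted by surface. An empty corpus
#' vacuously returns every term. The curated lexicons record such terms
#' with `zero_hit` status for auditability rather than deleting them.
#'
#' @param dictionary A [term_dictionary()].
#' @param corpus A `campaign_tbl`.
#' @param fields Record fields searched.
#' @return The zero-hit subset of the dictionary's term table.
#' @export
audit_zero_hits <- function(dictionary, corpus,
                            fields = c("title", "description")) {
  stopifnot(inherits(dictionary, "term_dictionary"))
  corpus <- campaign_records(corpus)
  matcher <- compile_matcher(dictionary, include_all = TRUE)
  seen <- character()
  for (i in seq_len(nrow(corpus))) {
    hits <- match_text(matcher, search_text(corpus[i, ], fields))
    seen <- union(seen, paste(str_to_lower(hits$surface), hits$match_type, sep = "\r"))
  }
  zero <- dictionary$terms[!term_key(dictionary$terms) %in% seen, ]
  zero[order(zero$surface), ]
}

# Concatenate the searched fields with a paragraph-break separator: the
# break is a token boundary, so no term can straddle the title/description
# seam. Attribute "boundary" marks where the description begins.
search_text <- function(record, fields = c("title", "description")) {
  parts <- vapply(
    fields,
    function(f) na_or(record[[f]], ""),
    character(1)
  )
  text <- paste(parts, collapse = "\n\n")
  structure(text, boundary = nchar(parts[1]) + 3L)
}
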