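#' Language calls
#'
#' A language call records the detected language(s) of one text:
#' `primary_code` (ISO 639-1, or `"und"` for undetermined), `all_codes`
#' (every language detected across the text's paragraphs; always contains
#' `primary_code`), and `confidence` in `[0, 1]`.
#'
#' @param primary_code ISO 639-1 code or `"und"`.
#' @param all_codes Character vector of codes including `primary_code`.
#' @param confidence Number in `[0, 1]`.
#' @return A `language_call` object.
#' @export
language_call <- function(primary_code, all_codes = primary_code, confidence = 0) {
  stopifnot(is_string(primary_code), is.character(all_codes))
  if (!primary_code %in% all_codes) {
    stop_crowdlex("primary_code must be a member of all_codes", "crowdlex_language_error")
  }
  if (!is.numeric(confidence) || confidence < 0 || confidence > 1) {
    stop_crowdlex("confidence must lie in [0, 1]", "crowdlex_language_error")
  }
  structure(
    list(
      primary_code = primary_code,
      all_codes = unique(all_codes),
      confidence = as.numeric(confidence)
    ),
    class = "language_call"
  )
}

#' @export
print.language_call <- function(x, ...) {
  cat(sprintf(
    "<language call: %s (all: %s, confidence %.2f)>\n",
    x$primary_code, paste(x$all_codes, collapse = ","), x$confidence
  ))
  invisible(x)
}

und_call <- function() language_call("und", "und", 0)

# Compact stop-word profiles. Function words only; content words (including
# every dictionary term) are deliberately absent so detection and term
# matching stay independent.
language_profiles <- function() {
  list(
    en = c(
      "the", "of", "and", "to", "in", "a", "is", "that", "for", "it", "as",
      "was", "with", "be", "by", "on", "not", "he", "i", "this", "are", "or",
      "his", "from", "at", "which", "but", "have", "an", "had", "they",
      "you", "were", "her", "all", "she", "there", "would", "their", "we",
      "him", "been", "has", "when", "who", "will", "more", "no", "if",
      "out", "so", "what", "up", "about", "into", "than", "them", "can",
      "only", "other", "some", "could", "these", "two", "may", "then",
      "do", "first", "any", "my", "now", "such", "our", "over", "your"
    ),
    es = c(
      "de", "la", "que", "el", "en", "y", "a", "los", "del", "se", "las",
      "un", "por", "con", "no", "una", "su", "para", "es", "al", "lo",
      "como", "más", "pero", "sus", "le", "ya", "o", "este", "sí",
      "porque", "esta", "entre", "cuando", "muy", "sin", "sobre",
      "también", "me", "hasta", "hay", "donde", "quien", "desde",
      "todo", "nos", "durante", "todos", "uno", "les", "ni", "contra",
      "otros", "ese", "eso", "ante", "ellos", "esto", "antes", "qué",
      "unos", "yo", "otro", "otras", "otra", "él", "tanto", "esa",
      "estos", "mucho", "nada", "muchos", "cual", "poco", "ella", "estar",
      "estas", "algo", "nosotros", "gracias"
    ),
    fr = c(
      "le", "de", "un", "être", "et", "à", "il", "avoir", "ne",
      "je", "son", "que", "se", "qui", "ce", "dans", "en", "du", "elle",
      "au", "pour", "pas", "vous", "par", "sur", "faire", "plus", "dire",
      "me", "on", "mon", "lui", "nous", "comme", "mais", "pouvoir", "avec",
      "tout", "y", "aller", "voir", "bien", "où", "sans", "tu", "ou",
      "leur", "homme", "si", "deux", "mari", "moi", "vouloir", "te",
      "femme", "venir", "quand", "grand", "celui", "si", "notre", "devoir",
      "là", "jour", "prendre", "même", "votre", "merci"
    ),
    de = c(
      "der", "die", "und", "in", "den", "von", "zu", "das", "mit", "sich",
      "des", "auf", "für", "ist", "im", "dem", "nicht", "ein", "eine",
      "als", "auch", "es", "an", "werden", "aus", "er", "hat", "dass",
      "sie", "nach", "wird", "bei", "einer", "um", "am", "sind", "noch",
      "wie", "einem", "über", "einen", "so", "zum", "war", "haben",
      "nur", "oder", "aber", "vor", "zur", "bis", "mehr", "durch", "man",
      "sein", "wurde", "sei", "danke"
    )
  )
}

#' Construct a language detector
#'
#' Detection is an injectable interface: any function mapping a single
#' paragraph of text to an ISO 639-1 code (or `"und"`) with an attached
#' score can serve. The packaged `"wordlist"` detector scores each
#' candidate language by the fraction of tokens found in a curated
#' stop-word profile (English, Spanish, French, German) and is fully
#' deterministic, which keeps every downstream result reproducible without
#' seeding. [detect_language()] layers paragraph splitting and code
#' unioning on top of whichever detector is supplied.
#'
#' @param method `"wordlist"`, or a function `function(text) ->
#'   list(code =, score =)` to plug in a custom detector.
#' @param min_score Minimum stop-word fraction for a call; paragraphs
#'   scoring below it are `"und"`.
#' @return A function of class `crowdlex_detector`.
#' @export
language_detector <- function(method = "wordlist", min_score = 0.1) {
  if (is.function(method)) {
    return(structure(method, class = c("crowdlex_detector", "function")))
  }
  stopifnot(identical(method, "wordlist"))
  profiles <- language_profiles()
  f <- function(text) {
    toks <- tokenize_text(text)$token
    if (length(toks) == 0) {
      return(list(code = "und", score = 0))
    }
    scores <- vapply(profiles, function(p) mean(toks %in% p), numeric(1))
    best <- which.max(scores) # ties: first of the fixed profile order
    if (scores[best] < min_score) {
      return(list(code = "und", score = 0))
    }
    list(code = names(profiles)[best], score = unname(scores[best]))
  }
  structure(f, class = c("crowdlex_detector", "function"))
}

#' Detect the language(s) of a text
#'
#' The text is split into paragraphs (blank-line separated), each paragraph
#' is scored by the detector, and the per-paragraph codes are unioned. This
#' sub-document pass is what lets a campaign written in English plus
#' another language be recognised as containing English, which the
#' retention rule requires; a whole-document detector would report only the
#' majority language. Empty or whitespace-only text yields the designated
#' `"und"` call with confidence 0.
#'
#' @param text A single character string (may be empty or `NA`).
#' @param detector A detector from [language_detector()].
#' @return A [language_call()].
#' @export
#' @examples
#' detect_language("My husband was diagnosed with leukemia last spring.")
detect_language <- function(text, detector = language_detector()) {
  if (is.null(text) || length(text) == 0 || is.na(text) || !nzchar(str_trim(text))) {
    return(und_call())
  }
  paragraphs <- str_split(text, "\\n[ \\t]*\\n+")[[1]]
  paragraphs <- paragraphs[nzchar(str_trim(paragraphs))]
  calls <- lapply(paragraphs, detector)
  codes <- map_chr(calls, "code")
  scores <- map_dbl(calls, "score")
  real <- codes != "und"
  if (!any(real)) {
    return(und_call())
  }
  # primary: the real code with the highest total score across paragraphs;
  # deterministic tie-break on alphabetical order
  totals <- tapply(scores[real], codes[real], sum)
  totals <- totals[order(-totals, names(totals))]
  primary <- names(totals)[1]
  all_codes <- c(primary, sort(setdiff(unique(codes[real]), primary)))
  confidence <- min(1, max(scores[codes == primary]))
  language_call(primary, all_codes, confidence)
}

#' Detect languages for every record in a corpus
#'
#' @param records A `campaign_tbl`.
#' @param detector A detector from [language_detector()].
#' @param fields Record fields whose text is examined; the description is
#'   the language-bearing field on campaign pages.
#' @return A named list of [language_call()]s keyed by `campaign_id`.
#' @export
detect_corpus_languages <- function(records, detector = language_detector(),
                                    fields = "description") {
  records <- campaign_records(records)
  calls <- lapply(seq_len(nrow(records)), function(i) {
    txt <- paste(
      stats::na.omit(unlist(records[i, fields, drop = FALSE], use.names = FALSE)),
      collapse = "\n\n"
    )
    detect_language(txt, detector)
  })
  setNames(calls, records$campaign_id)
}

#' Apply the English-retention rule
#'
#' A campaign is retained if and only if English is among its detected
#' languages: campaigns without an English description are excluded, while
#' campaigns written in English *and* another language are retained. The
#' `language_codes` field is populated on the retained records. The
#' operation is idempotent: re-applying it (with calls recomputed on its
#' output) changes nothing.
#'
#' @param records A `campaign_tbl`.
#' @param calls A named list of [language_call()]s keyed by `campaign_id`
#'   (one per record), as returned by [detect_corpus_languages()]; computed
#'   with the default detector when omitted.
#' @return The retained records with `language_codes` populated.
#' @export
apply_english_rule <- function(records, calls = detect_corpus_languages(records)) {
  records <- campaign_records(records)
  missing <- setdiff(records$campaign_id, names(calls))
  if (length(missing) > 0) {
    stop_crowdlex(
      paste0(
        "no language call for record(s): ",
        paste(head(missing, 10), collapse = ", ")
      ),
      "crowdlex_language_error"
    )
  }
  calls <- calls[records$campaign_id]
  keep <- map_lgl(calls, ~ "en" %in% .x$all_codes)
  out <- records[keep, ]
  out$language_codes <- lapply(calls[keep], function(c) c$all_codes)
  out
}
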