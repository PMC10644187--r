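#' Term dictionaries
#'
#' A term dictionary is a named, versioned lexicon iteration: `name`
#' (`"lgbtq"` or `"cancer"`), `iteration` (`"initial"`, `"refined"`, or
#' `"final"`), and a table of terms. Each term has:
#'
#' * `surface` — the entry exactly as curated, case and punctuation
#'   preserved (`"Mx."`, `"cáncer"`, `"wilm's tumor"`).
#' * `match_type` — its matching semantics, one of `whole_word`,
#'   `prefix_stem`, `phrase`, `phrase_prefix`, `pronoun_slash` (see
#'   [compile_matcher()]).
#' * `status` — its lifecycle state: `active` terms classify outright;
#'   `quality_check` terms still match but route the campaign to manual
#'   verification (ambiguous entries such as "trans" in medical compounds
#'   or "Gay" as a legal name); `eliminated` terms were removed during
#'   refinement for driving misclassification; `zero_hit` terms matched
#'   nothing in the corpus and are retained for audit only. Only `active`
#'   and `quality_check` terms contribute matching patterns.
#'
#' No two terms may share the same (lower-cased surface, match_type) pair,
#' and `pronoun_slash` surfaces must end in `"/"`.
#'
#' @param name `"lgbtq"` or `"cancer"`.
#' @param iteration `"initial"`, `"refined"`, or `"final"`.
#' @param terms Data frame with columns `surface`, `match_type`, `status`.
#' @return A `term_dictionary` object.
#' @export
term_dictionary <- function(name, iteration, terms) {
  name <- match.arg(name, c("lgbtq", "cancer"))
  iteration <- match.arg(iteration, c("initial", "refined", "final"))
  terms <- as_tibble(terms)
  stopifnot(all(c("surface", "match_type", "status") %in% names(terms)))
  terms <- terms[, c("surface", "match_type", "status")]
  terms$surface <- as.character(terms$surface)
  validate_terms(terms)
  structure(
    list(name = name, iteration = iteration, terms = terms),
    class = "term_dictionary"
  )
}

term_match_types <- function() {
  c("whole_word", "prefix_stem", "phrase", "phrase_prefix", "pronoun_slash")
}

term_statuses <- function() {
  c("active", "eliminated", "quality_check", "zero_hit")
}

term_key <- function(terms) {
  paste(str_to_lower(terms$surface), terms$match_type, sep = "\r")
}

validate_terms <- function(terms, lines = NULL) {
  where <- function(i) {
    if (is.null(lines)) paste0("term ", i) else paste0("line ", lines[i])
  }
  bad <- which(is.na(terms$surface) | !nzchar(str_trim(terms$surface)))
  if (length(bad) > 0) {
    stop_crowdlex(paste0("empty term surface at ", where(bad[1])), "crowdlex_dictionary_error")
  }
  bad <- which(!terms$match_type %in% term_match_types())
  if (length(bad) > 0) {
    stop_crowdlex(
      paste0(
        "unknown match_type '", terms$match_type[bad[1]], "' at ", where(bad[1])
      ),
      "crowdlex_dictionary_error"
    )
  }
  bad <- which(!terms$status %in% term_statuses())
  if (length(bad) > 0) {
    stop_crowdlex(
      paste0("unknown status '", terms$status[bad[1]], "' at ", where(bad[1])),
      "crowdlex_dictionary_error"
    )
  }
  bad <- which(terms$match_type == "pronoun_slash" & !str_detect(terms$surface, "/$"))
  if (length(bad) > 0) {
    stop_crowdlex(
      paste0(
        "pronoun_slash surface must end in '/': '", terms$surface[bad[1]],
        "' at ", where(bad[1])
      ),
      "crowdlex_dictionary_error"
    )
  }
  keys <- term_key(terms)
  dup <- which(duplicated(keys))
  if (length(dup) > 0) {
    first <- match(keys[dup[1]], keys)
    stop_crowdlex(
      paste0(
        "duplicate term '", terms$surface[dup[1]], "' (", terms$match_type[dup[1]],
        ") at ", where(first), " and ", where(dup[1])
      ),
      "crowdlex_dictionary_error"
    )
  }
  invisible(terms)
}

#' @export
print.term_dictionary <- function(x, ...) {
  counts <- table(factor(x$terms$status, levels = term_statuses()))
  cat(sprintf(
    "<term dictionary '%s' (%s iteration): %d term(s); %s>\n",
    x$name, x$iteration, nrow(x$terms),
    paste(sprintf("%s %d", names(counts), as.integer(counts)), collapse = ", ")
  ))
  invisible(x)
}

#' Load a term dictionary from a file
#'
#' Dictionary files are UTF-8 text with one term per line as
#' `surface<TAB>match_type<TAB>status`. Lines beginning `#` are comments;
#' `#! key: value` directives carry the dictionary metadata (`name`,
#' `iteration`). Duplicate (surface, match_type) pairs and unknown
#' match_type/status tokens are load errors naming the offending line(s).
#'
#' Four curated files ship with the package — the initial and final
#' iterations of the LGBTQ+ and cancer lexicons; see
#' [crowdlex_dictionary()].
#'
#' @param path Path to a dictionary file.
#' @param name,iteration Override the file's metadata directives.
#' @return A [term_dictionary()].
#' @export
#' @examples
#' lgbtq <- load_dictionary(crowdlex_dictionary("lgbtq", "final"))
#' lgbtq
load_dictionary <- function(path, name = NULL, iteration = NULL) {
  lines <- readr::read_lines(path)
  meta <- list()
  for (ln in lines[str_detect(lines, "^#!")]) {
    kv <- str_split(sub("^#!\\s*", "", ln), ":\\s*", n = 2)[[1]]
    if (length(kv) == 2) meta[[str_trim(kv[1])]] <- str_trim(kv[2])
  }
  keep <- which(!str_detect(lines, "^\\s*#") & nzchar(str_trim(lines)))
  rows <- str_split(lines[keep], "\t")
  bad <- which(vapply(rows, length, integer(1)) != 3)
  if (length(bad) > 0) {
    stop_crowdlex(
      paste0(
        "expected 3 tab-separated columns at line ", keep[bad[1]], " of ", path
      ),
      "crowdlex_dictionary_error"
    )
  }
  terms <- tibble(
    surface = str_trim(map_chr(rows, 1)),
    match_type = str_trim(map_chr(rows, 2)),
    status = str_trim(map_chr(rows, 3))
  )
  validate_terms(terms, lines = keep)
  term_dictionary(
    name = name %||% meta$name %||% stop_crowdlex(
      paste0("dictionary file ", path, " has no '#! name:' directive"),
      "crowdlex_dictionary_error"
    ),
    iteration = iteration %||% meta$iteration %||% "final",
    terms = terms
  )
}

#' Write a term dictionary file
#'
#' Inverse of [load_dictionary()].
#'
#' @param dictionary A [term_dictionary()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(dictionary, path) {
  stopifnot(inherits(dictionary, "term_dictionary"))
  lines <- c(
    paste0("#! name: ", dictionary$name),
    paste0("#! iteration: ", dictionary$iteration),
    sprintf(
      "%s\t%s\t%s",
      dictionary$terms$surface, dictionary$terms$match_type, dictionary$terms$status
    )
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Paths to the packaged term-dictionary files
#'
#' The package ships the initial and final iterations of both lexicons,
#' transcribed entry-by-entry from their curated source lists with match
#' semantics and lifecycle status annotated. In the final LGBTQ+ file,
#' "Gay" and "Trans" carry `quality_check` status: they keep matching but
#' their hits require manual verification because of documented false
#' friends ("trans-metatarsal", "Gay" as a legal name). The final cancer
#' file excludes the seven treatment words ("chemo", "chemotherap",
#' "immuno therap", "immunotherap", "mastectomy", "radiation therap",
#' "radiotherap") eliminated for matching other-disease campaigns.
#'
#' @param name `"lgbtq"` or `"cancer"`.
#' @param iteration `"initial"` or `"final"`.
#' @return Path to the file, suitable for [load_dictionary()].
#' @export
crowdlex_dictionary <- function(name = c("lgbtq", "cancer"),
                                iteration = c("final", "initial")) {
  name <- match.arg(name)
  iteration <- match.arg(iteration)
  path <- system.file(
    "extdata", "dictionaries", paste0(name, "-", iteration, ".tsv"),
    package = "crowdlex", mustWork = TRUE
  )
  path
}

#' Diff two iterations of a dictionary
#'
#' Computes the refinement between two iterations of the same lexicon as
#' three disjoint sets keyed by (lower-cased surface, match_type):
#' `added` and `removed` term tables, and `status_changed` rows giving the
#' old and new status (for example "gay": active in the initial LGBTQ+
#' list, quality_check in the final). [apply_dictionary_diff()] replays a
#' diff onto its source, reproducing the target exactly.
#'
#' @param a,b Two [term_dictionary()]s with the same `name`.
#' @return A `dictionary_diff` object with elements `added`, `removed`,
#'   `status_changed`.
#' @export
diff_dictionaries <- function(a, b) {
  stopifnot(inherits(a, "term_dictionary"), inherits(b, "term_dictionary"))
  if (!identical(a$name, b$name)) {
    stop_crowdlex(
      paste0("cannot diff dictionaries with different names: '", a$name,
        "' vs '", b$name, "'"),
      "crowdlex_dictionary_error"
    )
  }
  ka <- term_key(a$terms)
  kb <- term_key(b$terms)
  removed <- a$terms[!ka %in% kb, ]
  added <- b$terms[!kb %in% ka, ]
  common_b <- b$terms[kb %in% ka, ]
  old_status <- a$terms$status[match(term_key(common_b), ka)]
  changed <- common_b[common_b$status != old_status, ]
  status_changed <- tibble(
    surface = changed$surface,
    match_type = changed$match_type,
    old_status = old_status[common_b$status != old_status],
    new_status = changed$status
  )
  structure(
    list(
      name = a$name,
      from_iteration = a$iteration,
      to_iteration = b$iteration,
      added = added,
      removed = removed,
      status_changed = status_changed
    ),
    class = "dictionary_diff"
  )
}

#' @export
print.dictionary_diff <- function(x, ...) {
  cat(sprintf(
    "<dictionary diff '%s' %s -> %s: +%d / -%d / %d status change(s)>\n",
    x$name, x$from_iteration, x$to_iteration,
    nrow(x$added), nrow(x$removed), nrow(x$status_changed)
  ))
  invisible(x)
}

#' @rdname diff_dictionaries
#' @param diff A `dictionary_diff`.
#' @export
apply_dictionary_diff <- function(diff, a) {
  stopifnot(inherits(diff, "dictionary_diff"), inherits(a, "term_dictionary"))
  if (!identical(diff$name, a$name)) {
    stop_crowdlex("diff and dictionary names differ", "crowdlex_dictionary_error")
  }
  terms <- a$terms
  terms <- terms[!term_key(terms) %in% term_key(diff$removed), ]
  if (nrow(diff$status_changed) > 0) {
    ch <- diff$status_changed
    idx <- match(
      paste(str_to_lower(ch$surface), ch$match_type, sep = "\r"),
      term_key(terms)
    )
    terms$status[idx] <- ch$new_status
    terms$surface[idx] <- ch$surface
  }
  terms <- bind_rows(terms, diff$added)
  term_dictionary(a$name, diff$to_iteration, terms)
}
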