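#' Campaign record tables
#'
#' A campaign corpus is a tibble with one row per crowdfunding campaign and
#' the eight fields recoverable from a campaign page's static HTML, plus the
#' detected languages:
#'
#' * `campaign_id` — opaque identifier (the final path segment of the
#'   campaign URL); non-empty and unique within a corpus.
#' * `title`, `description` — free text.
#' * `creation_date` — `Date` (ISO-8601 in all serialized forms).
#' * `category` — `"medical"` or `"other"` (self-declared by the organizer).
#' * `status` — `"active"` or `"inactive"`.
#' * `donation_amount` — non-negative currency value.
#' * `donor_count` — non-negative integer.
#' * `organizer_location` — free text, typically "City, Region(, Country)".
#' * `language_codes` — list column of ISO 639-1 codes; empty before
#'   language detection has run.
#'
#' Fields other than `campaign_id` may be `NA`, the explicit missing marker:
#' values absent from a source page are never replaced by fabricated
#' defaults. `campaign_records()` validates a data frame against this schema
#' and returns it with class `campaign_tbl`; validation failures name the
#' offending row and field.
#'
#' @param x A data frame with the columns above. `language_codes` may be
#'   omitted (initialised to empty) or given as a semicolon-joined character
#'   column.
#' @return A `campaign_tbl` tibble.
#' @export
#' @examples
#' campaign_records(data.frame(
#'   campaign_id = "help-ana", title = "Help Ana", description = "Ana needs help.",
#'   creation_date = as.Date("2022-11-14"), category = "medical",
#'   status = "active", donation_amount = 50, donor_count = 2,
#'   organizer_location = "Tucson, AZ"
#' ))
campaign_records <- function(x) {
  stopifnot(is.data.frame(x))
  x <- as_tibble(x)
  missing_cols <- setdiff(setdiff(campaign_columns(), "language_codes"), names(x))
  if (length(missing_cols) > 0) {
    stop_crowdlex(
      paste0("campaign records are missing column(s): ", paste(missing_cols, collapse = ", ")),
      "crowdlex_schema_error"
    )
  }
  extra <- setdiff(names(x), campaign_columns())
  if (length(extra) > 0) {
    stop_crowdlex(
      paste0("campaign records have unknown column(s): ", paste(extra, collapse = ", ")),
      "crowdlex_schema_error"
    )
  }
  if (!"language_codes" %in% names(x)) {
    x$language_codes <- rep(list(character()), nrow(x))
  } else if (is.character(x$language_codes)) {
    x$language_codes <- lapply(x$language_codes, split_language_codes)
  }
  x <- x[, campaign_columns()]
  x$campaign_id <- as.character(x$campaign_id)
  x$title <- as.character(x$title)
  x$description <- as.character(x$description)
  if (!inherits(x$creation_date, "Date")) {
    x$creation_date <- parse_iso_date(x$creation_date, row_context = TRUE)
  }
  x$category <- as.character(x$category)
  x$status <- as.character(x$status)
  x$donation_amount <- as.numeric(x$donation_amount)
  x$donor_count <- as.integer(x$donor_count)
  x$organizer_location <- as.character(x$organizer_location)
  validate_campaigns(x)
  class(x) <- c("campaign_tbl", class(setdiff_class(x)))
  x
}

setdiff_class <- function(x) {
  class(x) <- setdiff(class(x), "campaign_tbl")
  x
}

campaign_columns <- function() {
  c(
    "campaign_id", "title", "description", "creation_date", "category",
    "status", "donation_amount", "donor_count", "organizer_location",
    "language_codes"
  )
}

split_language_codes <- function(s) {
  if (is.na(s) || !nzchar(s)) return(character())
  str_split(s, ";")[[1]]
}

# Strict ISO-8601 date parsing: anything else is rejected, never guessed.
parse_iso_date <- function(x, row_context = FALSE) {
  x <- as.character(x)
  bad <- !is.na(x) & !str_detect(x, "^\\d{4}-\\d{2}-\\d{2}$")
  if (any(bad)) {
    rows <- which(bad)
    stop_crowdlex(
      paste0(
        "creation_date must be ISO-8601 (YYYY-MM-DD); offending ",
        if (row_context) paste0("row(s) ", paste(head(rows, 5), collapse = ", ")) else "value",
        ": ", paste(head(x[bad], 5), collapse = ", ")
      ),
      "crowdlex_schema_error"
    )
  }
  as.Date(x)
}

field_check <- function(bad, field, what) {
  if (any(bad, na.rm = TRUE)) {
    rows <- which(bad)
    stop_crowdlex(
      paste0(
        "invalid campaign record: field '", field, "' ", what,
        " at row(s) ", paste(head(rows, 5), collapse = ", ")
      ),
      "crowdlex_schema_error"
    )
  }
}

validate_campaigns <- function(x) {
  field_check(is.na(x$campaign_id) | !nzchar(x$campaign_id), "campaign_id", "is empty or NA")
  field_check(duplicated(x$campaign_id), "campaign_id", "is duplicated")
  field_check(!is.na(x$category) & !x$category %in% c("medical", "other"),
    "category", "is not one of {medical, other}")
  field_check(!is.na(x$status) & !x$status %in% c("active", "inactive"),
    "status", "is not one of {active, inactive}")
  field_check(!is.na(x$donation_amount) & x$donation_amount < 0,
    "donation_amount", "is negative")
  field_check(!is.na(x$donor_count) & x$donor_count < 0, "donor_count", "is negative")
  ok_codes <- vapply(
    x$language_codes,
    function(v) is.character(v) && !anyNA(v),
    logical(1)
  )
  field_check(!ok_codes, "language_codes", "is not a character vector without NA")
  invisible(x)
}

#' @export
print.campaign_tbl <- function(x, ...) {
  cat(sprintf("<campaign corpus: %d record(s)>\n", nrow(x)))
  NextMethod()
}

#' Read and write campaign records
#'
#' Campaign corpora serialize to JSONL (one object per line, `null` for
#' missing values, unknown keys rejected) or CSV (UTF-8, header row,
#' RFC-4180 quoting, `language_codes` semicolon-joined). Blank JSONL lines
#' are skipped with a message reporting how many. Writing then reading is
#' the identity on every field including missing markers.
#'
#' @param path File path.
#' @param format `"jsonl"` or `"csv"`; inferred from the file extension when
#'   omitted.
#' @param records A `campaign_tbl` (or data frame coercible to one).
#' @return `read_campaigns()` returns a `campaign_tbl`; `write_campaigns()`
#'   returns `path` invisibly.
#' @export
read_campaigns <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- infer_format(match.arg(format), path)
  if (format == "jsonl") read_campaigns_jsonl(path) else read_campaigns_csv(path)
}

#' @rdname read_campaigns
#' @export
write_campaigns <- function(records, path, format = c("auto", "jsonl", "csv")) {
  records <- campaign_records(records)
  format <- infer_format(match.arg(format), path)
  if (format == "jsonl") write_campaigns_jsonl(records, path) else write_campaigns_csv(records, path)
  invisible(path)
}

infer_format <- function(format, path) {
  if (format != "auto") return(format)
  ext <- str_to_lower(tools::file_ext(path))
  if (ext %in% c("jsonl", "ndjson", "json")) return("jsonl")
  if (ext %in% c("csv")) return("csv")
  stop_crowdlex(paste0("cannot infer record format from path: ", path), "crowdlex_io_error")
}

jsonl_field_spec <- function() {
  # field -> scalar type used when decoding JSONL rows
  c(
    campaign_id = "character", title = "character", description = "character",
    creation_date = "date", category = "character", status = "character",
    donation_amount = "numeric", donor_count = "integer",
    organizer_location = "character", language_codes = "codes"
  )
}

read_campaigns_jsonl <- function(path) {
  lines <- readr::read_lines(path)
  blank <- !nzchar(str_trim(lines))
  if (any(blank)) {
    inform(sprintf("skipped %d blank line(s) in %s", sum(blank), path))
    lines <- lines[!blank]
  }
  spec <- jsonl_field_spec()
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(
      jsonlite::parse_json(lines[i]),
      error = function(e) {
        stop_crowdlex(
          sprintf("malformed JSON at row %d of %s: %s", i, path, conditionMessage(e)),
          "crowdlex_io_error"
        )
      }
    )
    unknown <- setdiff(names(obj), names(spec))
    if (length(unknown) > 0) {
      stop_crowdlex(
        sprintf(
          "unknown key(s) %s at row %d of %s",
          paste(unknown, collapse = ", "), i, path
        ),
        "crowdlex_schema_error"
      )
    }
    rows[[i]] <- decode_jsonl_row(obj, i, spec)
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) out <- empty_campaign_tbl()
  tryCatch(
    campaign_records(out),
    crowdlex_schema_error = function(e) {
      stop_crowdlex(paste0("while reading ", path, ": ", conditionMessage(e)),
        "crowdlex_schema_error")
    }
  )
}

decode_jsonl_row <- function(obj, row, spec) {
  out <- list()
  for (field in names(spec)) {
    v <- obj[[field]]
    out[[field]] <- switch(spec[[field]],
      character = if (is.null(v)) NA_character_ else as.character(v),
      numeric = if (is.null(v)) NA_real_ else as.numeric(v),
      integer = if (is.null(v)) NA_integer_ else as.integer(v),
      date = if (is.null(v)) as.Date(NA) else tryCatch(
        parse_iso_date(v),
        error = function(e) {
          stop_crowdlex(
            sprintf("row %d, field 'creation_date': %s", row, conditionMessage(e)),
            "crowdlex_schema_error"
          )
        }
      ),
      codes = list(as.character(unlist(v) %||% character()))
    )
  }
  tibble::as_tibble(out)
}

write_campaigns_jsonl <- function(records, path) {
  lines <- vapply(seq_len(nrow(records)), function(i) {
    row <- records[i, ]
    obj <- list(
      campaign_id = row$campaign_id,
      title = row$title,
      description = row$description,
      creation_date = if (is.na(row$creation_date)) NA_character_ else format(row$creation_date, "%Y-%m-%d"),
      category = row$category,
      status = row$status,
      donation_amount = row$donation_amount,
      donor_count = row$donor_count,
      organizer_location = row$organizer_location,
      language_codes = I(row$language_codes[[1]])
    )
    jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null", na = "null", digits = NA)
  }, character(1))
  readr::write_lines(lines, path)
}

empty_campaign_tbl <- function() {
  tibble(
    campaign_id = character(), title = character(), description = character(),
    creation_date = as.Date(character()), category = character(),
    status = character(), donation_amount = numeric(),
    donor_count = integer(), organizer_location = character(),
    language_codes = list()
  )
}

read_campaigns_csv <- function(path) {
  out <- readr::read_csv(
    path,
    col_types = readr::cols(
      campaign_id = readr::col_character(),
      title = readr::col_character(),
      description = readr::col_character(),
      creation_date = readr::col_character(),
      category = readr::col_character(),
      status = readr::col_character(),
      donation_amount = readr::col_double(),
      donor_count = readr::col_integer(),
      organizer_location = readr::col_character(),
      language_codes = readr::col_character()
    ),
    progress = FALSE
  )
  prob <- readr::problems(out)
  if (nrow(prob) > 0) {
    stop_crowdlex(
      sprintf(
        "CSV parse problem at row %d, column %s of %s", prob$row[1],
        prob$col[1], path
      ),
      "crowdlex_io_error"
    )
  }
  out$language_codes <- lapply(out$language_codes, split_language_codes)
  tryCatch(
    campaign_records(out),
    crowdlex_schema_error = function(e) {
      stop_crowdlex(paste0("while reading ", path, ": ", conditionMessage(e)),
        "crowdlex_schema_error")
    }
  )
}

write_campaigns_csv <- function(records, path) {
  flat <- setdiff_class(records)
  flat$creation_date <- ifelse(
    is.na(flat$creation_date), NA_character_, format(flat$creation_date, "%Y-%m-%d")
  )
  flat$language_codes <- vapply(
    records$language_codes, paste, character(1), collapse = ";"
  )
  readr::write_csv(flat, path, na = "", progress = FALSE)
}
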