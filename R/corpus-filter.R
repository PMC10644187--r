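#' Decide whether an organizer location is in the United States
#'
#' The corpus filter keeps US campaigns, but campaign pages give the
#' organizer location as free text. The rule here is deterministic and
#' auditable: the location is split on commas and a record counts as US if
#' any component is a US state or territory name, the District of Columbia,
#' a two-letter USPS state abbreviation (matched in upper case only, so
#' Spanish "de" or Italian "al" never trip it), or a country token such as
#' "USA" or "United States".
#'
#' @param location Character vector of free-text locations (`NA` allowed).
#' @return Logical vector; `NA` locations give `FALSE`.
#' @export
#' @examples
#' is_us_location(c("Salt Lake City, UT", "Toronto, Ontario, Canada"))
is_us_location <- function(location) {
  vapply(location, function(loc) {
    if (is.na(loc)) return(FALSE)
    parts <- str_trim(str_split(loc, ",")[[1]])
    parts <- parts[nzchar(parts)]
    if (length(parts) == 0) return(FALSE)
    lower <- str_to_lower(parts)
    any(lower %in% us_name_tokens()) || any(parts %in% us_state_abbrevs())
  }, logical(1), USE.NAMES = FALSE)
}

us_state_names <- function() {
  c(
    "Alabama", "Alaska", "Arizona", "Arkansas", "California", "Colorado",
    "Connecticut", "Delaware", "Florida", "Georgia", "Hawaii", "Idaho",
    "Illinois", "Indiana", "Iowa", "Kansas", "Kentucky", "Louisiana",
    "Maine", "Maryland", "Massachusetts", "Michigan", "Minnesota",
    "Mississippi", "Missouri", "Montana", "Nebraska", "Nevada",
    "New Hampshire", "New Jersey", "New Mexico", "New York",
    "North Carolina", "North Dakota", "Ohio", "Oklahoma", "Oregon",
    "Pennsylvania", "Rhode Island", "South Carolina", "South Dakota",
    "Tennessee", "Texas", "Utah", "Vermont", "Virginia", "Washington",
    "West Virginia", "Wisconsin", "Wyoming", "District of Columbia",
    "Puerto Rico", "Guam", "American Samoa", "Northern Mariana Islands",
    "U.S. Virgin Islands"
  )
}

us_state_abbrevs <- function() {
  c(
    "AL", "AK", "AZ", "AR", "CA", "CO", "CT", "DE", "FL", "GA", "HI", "ID",
    "IL", "IN", "IA", "KS", "KY", "LA", "ME", "MD", "MA", "MI", "MN", "MS",
    "MO", "MT", "NE", "NV", "NH", "NJ", "NM", "NY", "NC", "ND", "OH", "OK",
    "OR", "PA", "RI", "SC", "SD", "TN", "TX", "UT", "VT", "VA", "WA", "WV",
    "WI", "WY", "DC", "PR", "GU", "AS", "MP", "VI"
  )
}

us_name_tokens <- function() {
  str_to_lower(c(
    us_state_names(), "USA", "US", "U.S.", "U.S.A.", "United States",
    "United States of America"
  ))
}

#' Filter a corpus to active US medical campaigns in English
#'
#' Retains exactly the records with `status == "active"`,
#' `category == "medical"`, a US organizer location (see
#' [is_us_location()]), and `"en"` among the detected `language_codes`
#' (campaigns written in English plus another language are therefore
#' retained). Input order is preserved; `NA` in any of the tested fields
#' fails that predicate. Language codes must have been populated first, via
#' [apply_english_rule()] or [detect_corpus_languages()].
#'
#' @param records A `campaign_tbl`.
#' @return The retained subsequence, a `campaign_tbl`.
#' @export
filter_corpus <- function(records) {
  records <- campaign_records(records)
  keep <- !is.na(records$status) & records$status == "active" &
    !is.na(records$category) & records$category == "medical" &
    is_us_location(records$organizer_location) &
    map_lgl(records$language_codes, ~ "en" %in% .x)
  records[keep, ]
}
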