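#' Parse a sitemap into a vector of campaign URLs
#'
#' Reads the standard sitemap protocol: a `urlset` document yields every
#' `url/loc` entry in document order (duplicates preserved, an empty
#' `urlset` yields an empty vector). A `sitemapindex` document is flattened
#' one level: each `sitemap/loc` is resolved as a path relative to the
#' parent sitemap's directory and must itself be a `urlset`.
#'
#' @param x Path to a sitemap XML file, or a literal XML string.
#' @return Character vector of URLs.
#' @export
parse_sitemap <- function(x) {
  doc <- tryCatch(
    xml2::read_xml(x),
    error = function(e) {
      stop_crowdlex(
        paste0("malformed sitemap XML: ", conditionMessage(e)),
        "crowdlex_parse_error"
      )
    }
  )
  xml2::xml_ns_strip(doc)
  root <- xml2::xml_name(doc)
  if (root == "urlset") {
    return(xml2::xml_text(xml2::xml_find_all(doc, "./url/loc")))
  }
  if (root == "sitemapindex") {
    base_dir <- if (is_string(x) && file.exists(x)) dirname(x) else "."
    children <- xml2::xml_text(xml2::xml_find_all(doc, "./sitemap/loc"))
    urls <- lapply(children, function(loc) {
      child_path <- if (file.exists(loc)) loc else file.path(base_dir, loc)
      if (!file.exists(child_path)) {
        stop_crowdlex(
          paste0("child sitemap not found: ", loc),
          "crowdlex_io_error"
        )
      }
      child <- tryCatch(
        xml2::read_xml(child_path),
        error = function(e) {
          stop_crowdlex(
            paste0("malformed child sitemap ", loc, ": ", conditionMessage(e)),
            "crowdlex_parse_error"
          )
        }
      )
      xml2::xml_ns_strip(child)
      if (xml2::xml_name(child) != "urlset") {
        stop_crowdlex(
          paste0("sitemap indexes are flattened one level only; ", loc,
            " is not a urlset"),
          "crowdlex_parse_error"
        )
      }
      xml2::xml_text(xml2::xml_find_all(child, "./url/loc"))
    })
    return(unlist(urls) %||% character())
  }
  stop_crowdlex(
    paste0("not a sitemap document (root element '", root, "')"),
    "crowdlex_parse_error"
  )
}

# CSS selectors of the fixture page template (defined by this package;
# real-platform markup is out of scope).
fixture_selectors <- function() {
  c(
    title = ".campaign-title",
    creation_date = ".campaign-date",
    category = ".campaign-category",
    status = ".campaign-status",
    donation_amount = ".donation-amount",
    donor_count = ".donor-count",
    organizer_location = ".organizer-location",
    description = ".campaign-description"
  )
}

#' Extract a campaign record from a static fixture HTML page
#'
#' Pulls the eight campaign fields from a page following the fixture
#' template (see [emit_fixture_site()] for the selectors). Fields absent
#' from the page become explicit `NA` missing markers — never fabricated
#' defaults. A page with no description element cannot support any
#' downstream text analysis and raises a `crowdlex_unusable_page` error;
#' [scrape_fixture_site()] catches these, logs the reason, and excludes the
#' page.
#'
#' @param html Path to an HTML file, or a literal HTML string.
#' @param url Optional campaign URL; its final path segment becomes
#'   `campaign_id`. When omitted the page's canonical link is used.
#' @return A one-row `campaign_tbl`.
#' @export
extract_campaign <- function(html, url = NULL) {
  page <- tryCatch(
    xml2::read_html(html),
    error = function(e) {
      stop_crowdlex(
        paste0("cannot parse HTML page: ", conditionMessage(e)),
        "crowdlex_parse_error"
      )
    }
  )
  if (is.null(url)) {
    canon <- xml2::xml_find_first(page, "//link[@rel='canonical']")
    if (inherits(canon, "xml_missing")) {
      stop_crowdlex(
        "page has no canonical link and no url was supplied; cannot derive campaign_id",
        "crowdlex_parse_error"
      )
    }
    url <- xml2::xml_attr(canon, "href")
  }
  campaign_id <- url_slug(url)

  sel <- fixture_selectors()
  # title/description are kept verbatim (paragraph breaks carry signal for
  # language detection); metadata fields are whitespace-squished
  grab <- function(field, squish = TRUE) {
    node <- xml2::xml_find_first(page, css_to_xpath(sel[[field]]))
    if (inherits(node, "xml_missing")) {
      NA_character_
    } else if (squish) {
      str_squish(xml2::xml_text(node))
    } else {
      xml2::xml_text(node)
    }
  }
  description <- {
    node <- xml2::xml_find_first(page, css_to_xpath(sel[["description"]]))
    if (inherits(node, "xml_missing")) {
      stop_crowdlex(
        paste0("page for '", campaign_id, "' has no description element"),
        "crowdlex_unusable_page", campaign_id = campaign_id
      )
    }
    xml2::xml_text(node)
  }
  campaign_records(tibble(
    campaign_id = campaign_id,
    title = grab("title", squish = FALSE),
    description = description,
    creation_date = parse_iso_date(grab("creation_date")),
    category = grab("category"),
    status = grab("status"),
    donation_amount = as.numeric(grab("donation_amount")),
    donor_count = as.integer(grab("donor_count")),
    organizer_location = grab("organizer_location"),
    language_codes = list(character())
  ))
}

url_slug <- function(url) {
  slug <- basename(sub("[?#].*$", "", url))
  sub("\\.html?$", "", slug)
}

# minimal class-selector translation; the fixture template only needs classes
css_to_xpath <- function(css) {
  stopifnot(str_detect(css, "^\\."))
  cls <- sub("^\\.", "", css)
  sprintf("//*[contains(concat(' ', normalize-space(@class), ' '), ' %s ')]", cls)
}

#' Scrape a fixture site directory into a campaign corpus
#'
#' Reads `sitemap.xml` in `dir`, maps each URL's final path segment to
#' `<slug>.html` in the same directory, and extracts one record per page.
#' Unusable pages (no description element) are excluded with an informative
#' message, mirroring how records lacking a description cannot enter the
#' analysis.
#'
#' @param dir Directory containing `sitemap.xml` and the HTML pages.
#' @return A `campaign_tbl`.
#' @export
scrape_fixture_site <- function(dir) {
  sitemap <- file.path(dir, "sitemap.xml")
  if (!file.exists(sitemap)) {
    stop_crowdlex(paste0("no sitemap.xml in ", dir), "crowdlex_io_error")
  }
  urls <- parse_sitemap(sitemap)
  rows <- list()
  dropped <- character()
  for (url in urls) {
    slug <- url_slug(url)
    page_path <- file.path(dir, paste0(slug, ".html"))
    if (!file.exists(page_path)) {
      stop_crowdlex(paste0("page listed in sitemap not found: ", page_path),
        "crowdlex_io_error")
    }
    rec <- tryCatch(
      extract_campaign(page_path, url = url),
      crowdlex_unusable_page = function(e) {
        dropped <<- c(dropped, paste0(slug, " (", conditionMessage(e), ")"))
        NULL
      }
    )
    if (!is.null(rec)) rows[[length(rows) + 1]] <- rec
  }
  if (length(dropped) > 0) {
    inform(c(
      sprintf("excluded %d unusable page(s):", length(dropped)),
      setNames(dropped, rep("*", length(dropped)))
    ))
  }
  out <- if (length(rows) == 0) empty_campaign_tbl() else bind_rows(rows)
  campaign_records(out)
}
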