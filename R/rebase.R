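# Restriction-enzyme table I/O.
#
# Dialect: UTF-8 tab-separated lines `name<TAB>site_spec<TAB>suppliers<TAB>price`
# with `#` comments and blank lines skipped. `site_spec` follows REBASE
# conventions: a single `^` marks the top-strand cut inside the recognition
# sequence (bottom-strand cut then falls at the complementary-symmetric
# position), while outside cutters append `(t/b)` offsets counted past the
# 3' end of the site (negative offsets allowed). Suppliers are a compact
# string of single-letter commercial codes ("-" for none); price is a
# nonnegative decimal in currency units per assay unit, empty or "-" when
# the enzyme is not commercially priced (such enzymes sort last in price
# rankings).

#' Read a restriction-enzyme table
#'
#' Parses the tab-separated REBASE-like dialect described in
#' `vignette("rflp-assay-design")`. Well-formed lines each yield one enzyme,
#' in file order; comment (`#`) and blank lines are skipped. Malformed lines
#' (unknown symbol, missing or doubled cut descriptor, duplicated name,
#' negative price) are rejected individually with a reason, available via
#' [enzyme_parse_report()].
#'
#' @param file Path to the table, or a character vector of lines.
#' @return A tibble with one row per accepted enzyme and columns `name`,
#'   `site` (recognition sequence, IUPAC alphabet), `cut_top`, `cut_bottom`
#'   (0-based offsets from the pattern start; beyond the pattern for outside
#'   cutters), `degeneracy_class`, `suppliers`, `price`. The parse report is
#'   attached as attribute `"parse_report"`.
#' @seealso [write_enzyme_table()], [default_enzymes()]
#' @export
#' @examples
#' enz <- read_enzyme_table(c("EcoRI\tG^AATTC\tN\t62", "BsaI\tGGTCTC(1/5)\tN\t75"))
#' enz
#' enzyme_parse_report(enz)$accepted
read_enzyme_table <- function(file) {
  lines <- if (length(file) == 1L && !grepl("[\t\n]", file) && file.exists(file)) {
    readLines(file, warn = FALSE, encoding = "UTF-8")
  } else {
    unlist(strsplit(file, "\n", fixed = TRUE), use.names = FALSE)
  }
  keep <- !grepl("^\\s*(#|$)", lines)
  content <- trimws(lines[keep])
  line_no <- which(keep)

  rows <- vector("list", length(content))
  rejected <- list()
  seen <- character(0)
  for (i in seq_along(content)) {
    parsed <- parse_enzyme_line(content[[i]])
    if (!is.null(parsed$reason)) {
      rejected[[length(rejected) + 1L]] <-
        tibble(line = line_no[i], text = content[[i]], reason = parsed$reason)
      next
    }
    if (parsed$name %in% seen) {
      rejected[[length(rejected) + 1L]] <-
        tibble(line = line_no[i], text = content[[i]],
               reason = paste0("duplicate enzyme name ", parsed$name))
      next
    }
    seen <- c(seen, parsed$name)
    rows[[i]] <- tibble(
      name = parsed$name, site = parsed$site,
      cut_top = parsed$cut_top, cut_bottom = parsed$cut_bottom,
      degeneracy_class = classify_enzyme(parsed$site),
      suppliers = parsed$suppliers, price = parsed$price
    )
  }
  out <- bind_rows(rows)
  rejected <- if (length(rejected)) bind_rows(rejected) else
    tibble(line = integer(), text = character(), reason = character())
  if (nrow(out) == 0L) {
    abort("empty enzyme table: no line parsed successfully")
  }
  attr(out, "parse_report") <- list(
    n_lines = length(content),
    accepted = nrow(out),
    rejected = rejected
  )
  out
}

parse_enzyme_line <- function(line) {
  fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(fields) < 2L) fields <- strsplit(line, "\\s+")[[1]]
  fields <- trimws(fields)
  fields <- fields[fields != ""]
  if (length(fields) < 2L) {
    return(list(reason = "expected at least name and recognition sequence"))
  }
  name <- fields[[1]]
  spec <- toupper(fields[[2]])
  suppliers <- if (length(fields) >= 3L) fields[[3]] else "-"
  price_raw <- if (length(fields) >= 4L) fields[[4]] else ""

  raw_site <- sub("\\((-?[0-9]+)/(-?[0-9]+)\\)$", "",
                  gsub("^", "", spec, fixed = TRUE))
  if (!is_iupac_pattern(raw_site)) {
    bad <- setdiff(strsplit(raw_site, "", fixed = TRUE)[[1]], .IUPAC_ALPHABET)
    return(list(reason = paste0("non-IUPAC symbol ",
                                if (length(bad)) bad[1] else raw_site)))
  }
  n_caret <- lengths(regmatches(spec, gregexpr("^", spec, fixed = TRUE)))
  has_paren <- grepl("(", spec, fixed = TRUE)
  if (n_caret + grepl("\\(.*\\)", spec) > 1L || (n_caret > 0L && has_paren)) {
    return(list(reason = "multiple cut descriptors"))
  }
  if (n_caret == 1L) {
    cut_top <- regexpr("^", spec, fixed = TRUE) - 1L
    site <- sub("^", "", spec, fixed = TRUE)
    cut_bottom <- nchar(site) - cut_top
  } else if (has_paren) {
    m <- regexec("^([A-Z]+)\\((-?[0-9]+)/(-?[0-9]+)\\)$", spec)
    parts <- regmatches(spec, m)[[1]]
    if (length(parts) != 4L) {
      return(list(reason = "malformed cut descriptor"))
    }
    site <- parts[[2]]
    cut_top <- nchar(site) + as.integer(parts[[3]])
    cut_bottom <- nchar(site) + as.integer(parts[[4]])
  } else {
    return(list(reason = "missing cut descriptor (`^` or `(t/b)`)"))
  }
  if (!is_iupac_pattern(site)) {
    bad <- setdiff(strsplit(site, "", fixed = TRUE)[[1]], .IUPAC_ALPHABET)
    return(list(reason = paste0("non-IUPAC symbol ", bad[1])))
  }
  sup <- gsub("[^A-Za-z]", "", suppliers)
  sup <- paste(sort(unique(strsplit(toupper(sup), "", fixed = TRUE)[[1]])),
               collapse = "")
  price <- if (price_raw %in% c("", "-", ".", "NA")) {
    NA_real_
  } else {
    suppressWarnings(as.numeric(price_raw))
  }
  if (length(price) == 1L && !is.na(price) && price < 0) {
    return(list(reason = "negative price"))
  }
  if (!(price_raw %in% c("", "-", ".", "NA")) && is.na(price)) {
    return(list(reason = paste0("unparseable price ", price_raw)))
  }
  list(name = name, site = site, cut_top = as.integer(cut_top),
       cut_bottom = as.integer(cut_bottom), suppliers = sup, price = price)
}

#' Parse report of an enzyme table
#'
#' @param enzymes A tibble returned by [read_enzyme_table()].
#' @return A list with `n_lines` (non-comment, non-blank lines), `accepted`
#'   and a `rejected` tibble (`line`, `text`, `reason`). The invariant
#'   `accepted + nrow(rejected) == n_lines` always holds.
#' @export
enzyme_parse_report <- function(enzymes) {
  rep <- attr(enzymes, "parse_report")
  rep %||% list(n_lines = nrow(enzymes), accepted = nrow(enzymes),
                rejected = tibble(line = integer(), text = character(),
                                  reason = character()))
}

#' Write an enzyme table in the package's TSV dialect
#'
#' Serializes a parsed enzyme tibble back to the dialect read by
#' [read_enzyme_table()]; re-reading the written file yields an identical
#' collection.
#'
#' @param enzymes Enzyme tibble.
#' @param file Path or connection; with `file = NULL` the lines are returned
#'   invisibly instead of written.
#' @return The written lines, invisibly.
#' @export
write_enzyme_table <- function(enzymes, file = NULL) {
  spec <- site_spec(enzymes$site, enzymes$cut_top, enzymes$cut_bottom)
  price <- ifelse(is.na(enzymes$price), "-",
                  format(enzymes$price, trim = TRUE, scientific = FALSE))
  sup <- ifelse(enzymes$suppliers == "", "-", enzymes$suppliers)
  lines <- c("# name\tsite\tsuppliers\tprice",
             paste(enzymes$name, spec, sup, price, sep = "\t"))
  if (!is.null(file)) writeLines(lines, file, useBytes = TRUE)
  invisible(lines)
}

site_spec <- function(site, cut_top, cut_bottom) {
  L <- nchar(site)
  inside <- cut_top >= 0 & cut_top <= L & cut_bottom == L - cut_top
  ifelse(inside,
         paste0(substr(site, 1, cut_top), "^",
                substr(site, cut_top + 1, L)),
         sprintf("%s(%d/%d)", site, cut_top - L, cut_bottom - L))
}

#' Bundled restriction-enzyme table
#'
#' Loads the enzyme table shipped with the package
#' (`inst/extdata/enzymes_synthetic.tsv`): a curated stand-in for a
#' commercial catalogue, listing published recognition sequences of about
#' thirty widely used enzymes with synthetic supplier codes and prices.
#'
#' @return An enzyme tibble as from [read_enzyme_table()].
#' @export
#' @examples
#' head(default_enzymes())
default_enzymes <- function() {
  read_enzyme_table(system.file("extdata", "enzymes_synthetic.tsv",
                                package = "rflpdesign", mustWork = TRUE))
}
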