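# SNP template parsing: bracket notation [dNTP1/dNTP2], IUPAC ambiguity
# codes, indels, multi-SNP sequences, and FASTA I/O.

#' Strip non-nucleotide symbols from raw sequence text
#'
#' Uppercases the input and removes whitespace, digits, commas and any other
#' symbol outside the 15-letter IUPAC nucleotide alphabet. Intended for raw
#' flanking-sequence text after variant notation has been extracted (the
#' brackets that delimit alleles are consumed by [parse_snp_sequence()]
#' first, never by this filter).
#'
#' @param text A single character string.
#' @return The cleaned string, with attribute `"n_removed"` counting the
#'   characters filtered out. Errors if nothing remains.
#' @export
#' @examples
#' clean_sequence("acg t,ac\n")
clean_sequence <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  up <- toupper(text)
  kept <- gsub("[^ACGTRYSWKMBDHVN]", "", up)
  if (nchar(kept) == 0L) abort("no nucleotides in input")
  structure(kept, n_removed = nchar(up) - nchar(kept))
}

.AMBIG_CODES <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

new_snp_template <- function(label, backbone, variants) {
  stopifnot(is.character(backbone), length(backbone) == 1L)
  if (!is_concrete_dna(backbone)) {
    abort("template backbone must contain only A, C, G, T")
  }
  n <- nrow(variants)
  if (n < 1L || n > 50L) {
    abort(sprintf("a template must carry between 1 and 50 variants, got %d (up to 50 SNPs per sequence are accepted)", n))
  }
  if (is.unsorted(variants$position, strictly = FALSE)) {
    abort("variant positions must be non-decreasing")
  }
  if (any(variants$position < 0L | variants$position > nchar(backbone))) {
    abort("variant position outside backbone")
  }
  gaps <- diff(variants$position)
  if (any(gaps <= 6L)) {
    i <- which(gaps <= 6L)[1]
    abort(sprintf(
      "variants %d and %d are separated by only %d backbone nt; flanking sequences of nearby SNPs must not overlap within a range of 6 nucleotides (gap must exceed 6)",
      i, i + 1L, gaps[i]
    ))
  }
  for (al in variants$alleles) {
    if (length(al) < 2L || length(al) > 4L) {
      abort("each variant must carry 2-4 alleles")
    }
    if (anyDuplicated(al)) abort("alleles within a variant must be distinct")
    if (sum(al == "") > 1L) abort("at most one allele may be a deletion")
    if (!all(al == "" | is_concrete_dna(al))) {
      abort("alleles must be concrete DNA strings (or '-' for a deletion)")
    }
  }
  structure(
    list(label = label, backbone = backbone, variants = variants),
    class = "snp_template"
  )
}

#' @export
print.snp_template <- function(x, ...) {
  cat(sprintf("<snp_template> %s: %d nt backbone, %d variant(s)\n",
              x$label, nchar(x$backbone), nrow(x$variants)))
  v <- x$variants
  for (i in seq_len(nrow(v))) {
    cat(sprintf("  [%d] pos %d (1-based): %s\n", i, v$position[i] + 1L,
                paste(ifelse(v$alleles[[i]] == "", "-", v$alleles[[i]]),
                      collapse = "/")))
  }
  invisible(x)
}

#' Parse a SNP-containing sequence
#'
#' Accepts the bracket grammar `[X/Y]`, `[X/Y/Z]`, `[X/Y/Z/W]` and
#' `[-/SEQ]` (2-4 alleles per site; `-` is the deletion allele; alleles may
#' be multi-base, so unequal-length alleles are handled as length
#' polymorphisms), as well as single-letter IUPAC ambiguity codes in the
#' sequence body (R, Y, S, W, K, M as bi-allelic, B, D, H, V as tri-allelic;
#' N is rejected as uninformative). Other non-nucleotide characters outside
#' brackets (whitespace, digits, commas) are filtered out and counted.
#'
#' Constraints enforced: at most 50 variants per sequence, and the backbone
#' gap between adjacent variants must exceed 6 nt so that their private
#' flanking sequences do not overlap.
#'
#' @param text Sequence text with at least one variant.
#' @param label Template label (FASTA header or generated id).
#' @return An object of class `snp_template`: a list with `label`,
#'   `backbone` (the concrete sequence with the variant sites excised) and
#'   `variants`, a tibble with `position` (0-based index into the backbone
#'   where the variant inserts), `alleles` (list of character vectors;
#'   `""` is the deletion allele) and `source` (`"bracket"` or `"iupac"`).
#' @export
#' @examples
#' parse_snp_sequence("ACGTACGT[A/G]ACGTACGT")
#' parse_snp_sequence("ACGTACGRTACGT")  # R = A/G
parse_snp_sequence <- function(text, label = "seq") {
  stopifnot(is.character(text), length(text) == 1L)
  up <- toupper(text)
  chars <- strsplit(up, "", fixed = TRUE)[[1]]
  n <- length(chars)
  bb <- character(0)
  pos <- integer(0)
  alleles <- list()
  src <- character(0)
  removed <- 0L
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) abort("unbalanced bracket: missing `]`")
      inner <- substr(up, i + 1L, j - 1L)
      alleles[[length(alleles) + 1L]] <- parse_bracket_alleles(inner)
      pos <- c(pos, length(bb))
      src <- c(src, "bracket")
      i <- j + 1L
    } else if (ch == "]") {
      abort("unbalanced bracket: `]` without `[`")
    } else if (ch %in% c("A", "C", "G", "T")) {
      bb <- c(bb, ch)
      i <- i + 1L
    } else if (ch %in% .AMBIG_CODES) {
      alleles[[length(alleles) + 1L]] <- sort(.IUPAC_SETS[[ch]])
      pos <- c(pos, length(bb))
      src <- c(src, "iupac")
      i <- i + 1L
    } else if (ch == "N") {
      abort("ambiguity code N is rejected: uninformative as a variant and unusable as an unknown base")
    } else {
      removed <- removed + 1L
      i <- i + 1L
    }
  }
  if (length(pos) == 0L) {
    abort("no variant found in sequence", class = "rflpdesign_no_variant")
  }
  t <- new_snp_template(
    label = label,
    backbone = paste(bb, collapse = ""),
    variants = tibble(position = pos, alleles = alleles, source = src)
  )
  attr(t, "n_removed") <- removed
  t
}

parse_bracket_alleles <- function(inner) {
  parts <- strsplit(inner, "/", fixed = TRUE)[[1]]
  parts <- gsub("\\s", "", parts)
  if (length(parts) < 2L || length(parts) > 4L) {
    abort(sprintf("a bracket must list 2-4 alleles, got [%s]", inner))
  }
  al <- ifelse(parts == "-", "", parts)
  ok <- al == "" | grepl("^[ACGT]+$", al)
  if (!all(ok)) {
    abort(sprintf("invalid allele '%s' in bracket [%s]", parts[!ok][1], inner))
  }
  if (anyDuplicated(al)) {
    abort(sprintf("duplicate alleles in bracket [%s]", inner))
  }
  if (sum(al == "") > 1L) {
    abort(sprintf("more than one deletion allele in bracket [%s]", inner))
  }
  unname(al)
}

# realized sequence + per-variant spans for a given allele choice vector
realize_template <- function(t, choices) {
  v <- t$variants
  k <- nrow(v)
  stopifnot(length(choices) == k)
  bb <- t$backbone
  pieces <- character(2L * k + 1L)
  spans <- matrix(0L, nrow = k, ncol = 2L)
  prev <- 0L
  acc <- 0L
  for (i in seq_len(k)) {
    flank <- substr(bb, prev + 1L, v$position[i])
    a <- v$alleles[[i]][choices[i]]
    pieces[2L * i - 1L] <- flank
    pieces[2L * i] <- a
    acc <- acc + nchar(flank)
    spans[i, 1L] <- acc
    acc <- acc + nchar(a)
    spans[i, 2L] <- acc
    prev <- v$position[i]
  }
  pieces[2L * k + 1L] <- substr(bb, prev + 1L, nchar(bb))
  list(sequence = paste(pieces, collapse = ""), spans = spans)
}

#' Realize the concrete per-allele sequences of one variant
#'
#' Produces one concrete sequence per allele of the selected variant, with
#' all other variants fixed to their first-listed (reference) allele.
#'
#' @param template A `snp_template`.
#' @param which Variant index (1-based), default the first.
#' @return A tibble with one row per allele: `allele_index`, `allele`
#'   (`""` for the deletion), `sequence`, and the realized variant span
#'   `var_start`, `var_end` (0-based half-open; empty span for a deletion).
#' @export
#' @examples
#' t <- parse_snp_sequence("ACGTACG[A/G]TACGTAC")
#' realize_alleles(t)
realize_alleles <- function(template, which = 1L) {
  stopifnot(inherits(template, "snp_template"))
  k <- nrow(template$variants)
  if (which < 1L || which > k) {
    abort(sprintf("`which` must be in 1..%d", k))
  }
  al <- template$variants$alleles[[which]]
  rows <- lapply(seq_along(al), function(a) {
    choices <- rep(1L, k)
    choices[which] <- a
    r <- realize_template(template, choices)
    tibble(
      allele_index = a, allele = al[a], sequence = r$sequence,
      var_start = r$spans[which, 1L], var_end = r$spans[which, 2L]
    )
  })
  bind_rows(rows)
}

# lossless text form: brackets for bracket-sourced variants, the ambiguity
# letter for IUPAC-sourced ones
template_to_text <- function(t) {
  v <- t$variants
  bb <- t$backbone
  out <- character(0)
  prev <- 0L
  for (i in seq_len(nrow(v))) {
    out <- c(out, substr(bb, prev + 1L, v$position[i]))
    al <- v$alleles[[i]]
    if (v$source[i] == "iupac") {
      code <- names(Filter(function(s) setequal(s, al), .IUPAC_SETS))[1]
      out <- c(out, code)
    } else {
      out <- c(out, paste0("[", paste(ifelse(al == "", "-", al),
                                      collapse = "/"), "]"))
    }
    prev <- v$position[i]
  }
  paste(c(out, substr(bb, prev + 1L, nchar(bb))), collapse = "")
}

#' Read SNP templates from a FASTA file
#'
#' Standard multi-record FASTA framing (via Biostrings); each record body is
#' parsed with [parse_snp_sequence()]. Records without any variant are
#' skipped with a warning (or rejected, with `on_empty = "error"`).
#'
#' @param file FASTA path.
#' @param on_empty `"skip"` (default) or `"error"` for records lacking a
#'   variant.
#' @return A tibble with columns `label`, `n_variants` and a `template`
#'   list-column of `snp_template` objects.
#' @export
read_snp_fasta <- function(file, on_empty = c("skip", "error")) {
  on_empty <- match.arg(on_empty)
  recs <- Biostrings::readBStringSet(file)
  labels <- names(recs)
  rows <- list()
  for (i in seq_along(recs)) {
    body <- as.character(recs[[i]])
    t <- tryCatch(
      parse_snp_sequence(body, label = labels[i]),
      rflpdesign_no_variant = function(e) {
        if (on_empty == "error") abort(conditionMessage(e))
        warn(sprintf("record '%s' has no variant; skipped", labels[i]))
        NULL
      }
    )
    if (!is.null(t)) {
      rows[[length(rows) + 1L]] <-
        tibble(label = labels[i], n_variants = nrow(t$variants),
               template = list(t))
    }
  }
  if (length(rows)) bind_rows(rows) else
    tibble(label = character(), n_variants = integer(), template = list())
}

#' Write SNP templates to FASTA
#'
#' Reconstitutes the variant notation losslessly: bracket-sourced variants
#' are written back as brackets, IUPAC-sourced ones as their ambiguity
#' letter, so `read_snp_fasta()` of the output reproduces the templates.
#'
#' @param templates A tibble as from [read_snp_fasta()] (columns `label`,
#'   `template`), or a list of `snp_template` objects.
#' @param file Output path or connection.
#' @return The written lines, invisibly.
#' @export
write_snp_fasta <- function(templates, file = NULL) {
  ts <- if (is.data.frame(templates)) templates$template else templates
  lines <- unlist(lapply(ts, function(t) {
    c(paste0(">", t$label), template_to_text(t))
  }), use.names = FALSE)
  if (!is.null(file)) writeLines(lines, file, useBytes = TRUE)
  invisible(lines)
}

variant_type <- function(alleles) {
  if (any(alleles == "") || length(unique(nchar(alleles))) > 1L) return("indel")
  c("2" = "bi", "3" = "tri", "4" = "tetra")[[as.character(length(alleles))]]
}

variant_label <- function(template, which) {
  v <- template$variants
  sprintf("%s:%d[%s]", template$label, v$position[which] + 1L,
          paste(ifelse(v$alleles[[which]] == "", "-", v$alleles[[which]]),
                collapse = "/"))
}
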