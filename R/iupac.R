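# IUPAC nucleotide-ambiguity algebra used by the enzyme table and the
# site-matching engine.

#' Base sets of the 15-letter IUPAC nucleotide alphabet
#'
#' @return Named list mapping each IUPAC symbol to its set of concrete bases
#'   (e.g. `R` -> `c("A","G")`, `N` -> all four).
#' @export
#' @examples
#' iupac_base_sets()[["R"]]
iupac_base_sets <- function() .IUPAC_SETS

.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

.IUPAC_ALPHABET <- names(.IUPAC_SETS)

# complement map: R<->Y, K<->M, B<->V, D<->H; S, W, N self-complementary
.IUPAC_FROM <- "ACGTRYSWKMBDHVN"
.IUPAC_TO   <- "TGCAYRSWMKVHDBN"

is_iupac_pattern <- function(x) {
  grepl("^[ACGTRYSWKMBDHVN]+$", x)
}

is_concrete_dna <- function(x) {
  grepl("^[ACGT]+$", x)
}

#' Reverse complement of DNA strings, IUPAC-aware
#'
#' Complements every symbol under the IUPAC ambiguity algebra
#' (R<->Y, S<->S, W<->W, K<->M, B<->V, D<->H, N<->N) and reverses.
#'
#' @param x Character vector of DNA strings (concrete or degenerate).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("GAATTC", "ACRT"))
revcomp <- function(x) {
  bad <- !is_iupac_pattern(toupper(x))
  if (any(bad)) {
    abort(paste0("non-IUPAC symbol in sequence: ", x[bad][1]))
  }
  comp <- chartr(.IUPAC_FROM, .IUPAC_TO, toupper(x))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Reverse complement of a recognition pattern with cut offsets
#'
#' Maps a recognition pattern, together with its top- and bottom-strand cut
#' offsets (nt from pattern start; offsets may lie outside the pattern for
#' outside cutters), into the mirrored coordinate frame of the opposite
#' strand. The operation is an involution.
#'
#' @param site Recognition sequence (IUPAC alphabet).
#' @param cut_top,cut_bottom Integer cut offsets relative to pattern start.
#' @return A list with elements `site`, `cut_top`, `cut_bottom`.
#' @export
#' @examples
#' reverse_complement_pattern("GGTCTC", 7, 11)  # BsaI, cuts 1/5 past the site
reverse_complement_pattern <- function(site, cut_top, cut_bottom) {
  L <- nchar(site)
  list(
    site = revcomp(site),
    cut_top = L - cut_bottom,
    cut_bottom = L - cut_top
  )
}

#' Expand a degenerate pattern to all concrete DNA strings
#'
#' Cartesian expansion of every IUPAC symbol to its base set; the number of
#' strings returned is the product of the per-symbol set sizes.
#'
#' @param site Recognition sequence over the IUPAC alphabet.
#' @param cap Maximum expansion cardinality; above it the function errors and
#'   advises matching the degenerate pattern directly. Default 65536.
#' @return Character vector of concrete sequences, sorted.
#' @export
#' @examples
#' expand_pattern("GANTC")
expand_pattern <- function(site, cap = 65536L) {
  if (length(site) != 1L || !is_iupac_pattern(toupper(site))) {
    abort("`site` must be a single string over the IUPAC alphabet")
  }
  sets <- .IUPAC_SETS[strsplit(toupper(site), "", fixed = TRUE)[[1]]]
  card <- prod(lengths(sets))
  if (card > cap) {
    abort(sprintf(
      "expansion cardinality %d exceeds cap %d; match the degenerate pattern directly",
      card, cap
    ))
  }
  out <- Reduce(function(acc, s) {
    as.vector(t(outer(acc, s, paste0)))
  }, sets, accumulate = FALSE)
  sort(out)
}

#' Expansion cardinality of a degenerate pattern
#'
#' @param site Recognition sequence(s) over the IUPAC alphabet.
#' @return Numeric vector: product of per-symbol base-set sizes.
#' @export
pattern_cardinality <- function(site) {
  vapply(strsplit(toupper(site), "", fixed = TRUE), function(ch) {
    prod(lengths(.IUPAC_SETS[ch]))
  }, numeric(1))
}

#' Classify recognition sequences as degenerate or not
#'
#' An enzyme is `non_IUPAC` when its recognition sequence contains only the
#' concrete nucleotides A, C, G, T, and `IUPAC` when it uses any ambiguity
#' symbol.
#'
#' @param site Character vector of recognition sequences.
#' @return Character vector, `"non_IUPAC"` or `"IUPAC"`.
#' @export
#' @examples
#' classify_enzyme(c("GAATTC", "GANTC"))
classify_enzyme <- function(site) {
  bad <- !is_iupac_pattern(toupper(site))
  if (any(bad)) abort(paste0("non-IUPAC symbol in site: ", site[bad][1]))
  ifelse(is_concrete_dna(toupper(site)), "non_IUPAC", "IUPAC")
}
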