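# Restriction-site scanning, allele discrimination mining, and digestion
# fragment simulation.

# --- degenerate matching engine -------------------------------------------
# Bases are encoded as bits (A=1, C=2, G=4, T=8) and each pattern symbol as
# the OR of its base set, so a window matches iff every position has a
# nonzero AND. This finds all (overlapping) matches in O(pattern length)
# vectorized passes over the sequence.

.BASE_BITS <- c(A = 1L, C = 2L, G = 4L, T = 8L)

encode_dna <- function(sequence) {
  x <- utf8ToInt(sequence)
  lut <- integer(128)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 4L; lut[utf8ToInt("T")] <- 8L
  lut[x]
}

pattern_masks <- function(site) {
  vapply(.IUPAC_SETS[strsplit(site, "", fixed = TRUE)[[1]]],
         function(s) sum(.BASE_BITS[s]), integer(1), USE.NAMES = FALSE)
}

# 0-based start positions of all matches of `masks` in encoded sequence
match_starts <- function(code, masks) {
  n <- length(code)
  L <- length(masks)
  if (L > n) return(integer(0))
  ok <- bitwAnd(code[seq_len(n - L + 1L)], masks[1L]) > 0L
  if (L > 1L) for (q in 2L:L) {
    ok <- ok & bitwAnd(code[q:(q + n - L)], masks[q]) > 0L
  }
  which(ok) - 1L
}

as_enzyme_rows <- function(enzymes) {
  if (!is.data.frame(enzymes) ||
      !all(c("name", "site", "cut_top", "cut_bottom") %in% names(enzymes))) {
    abort("`enzymes` must be an enzyme tibble from read_enzyme_table()")
  }
  enzymes
}

#' Scan a concrete sequence for restriction sites on both strands
#'
#' Every position where an enzyme's (possibly degenerate) recognition
#' pattern matches the sense strand yields a `sense` hit; every match of the
#' reverse-complement pattern yields an `antisense` hit. For
#' self-complementary (palindromic) patterns the duplicate antisense hit at
#' the same locus is suppressed, leaving a single `sense` hit. Hits whose
#' cut position falls beyond the sequence (outside cutters near the ends)
#' are discarded.
#'
#' @param sequence Concrete DNA string (A/C/G/T).
#' @param enzymes Enzyme tibble ([read_enzyme_table()]); one or more rows.
#' @return A tibble with columns `enzyme`, `strand`, `match_start`,
#'   `match_end` (0-based half-open match interval), `cut_top`, `cut_bottom`
#'   (cut indices on the sequence, top/bottom strand), ordered by
#'   `match_start`.
#' @export
#' @examples
#' enz <- read_enzyme_table("EcoRI\tG^AATTC\tN\t62")
#' scan_sites("TTGAATTCAA", enz)
scan_sites <- function(sequence, enzymes) {
  enzymes <- as_enzyme_rows(enzymes)
  sequence <- toupper(sequence)
  if (!is_concrete_dna(sequence)) {
    abort("`sequence` must be a non-empty concrete DNA string")
  }
  slen <- nchar(sequence)
  code <- encode_dna(sequence)
  out <- vector("list", nrow(enzymes))
  for (i in seq_len(nrow(enzymes))) {
    site <- enzymes$site[i]
    L <- nchar(site)
    if (L > slen) next
    ct <- enzymes$cut_top[i]
    cb <- enzymes$cut_bottom[i]
    s_starts <- match_starts(code, pattern_masks(site))
    rc <- reverse_complement_pattern(site, ct, cb)
    a_starts <- match_starts(code, pattern_masks(rc$site))
    # palindromic sites with symmetric cuts produce identical sense and
    # antisense hits; keep the sense one
    s_key <- paste(s_starts, s_starts + ct, s_starts + cb)
    a_key <- paste(a_starts, a_starts + rc$cut_top, a_starts + rc$cut_bottom)
    a_keep <- !(a_key %in% s_key)
    a_starts <- a_starts[a_keep]
    starts <- c(s_starts, a_starts)
    strand <- rep(c("sense", "antisense"),
                  c(length(s_starts), length(a_starts)))
    cut_t <- c(s_starts + ct, a_starts + rc$cut_top)
    cut_b <- c(s_starts + cb, a_starts + rc$cut_bottom)
    keep <- cut_t >= 0L & cut_t <= slen & cut_b >= 0L & cut_b <= slen
    if (!any(keep)) next
    out[[i]] <- list(enzyme = rep(enzymes$name[i], sum(keep)),
                     strand = strand[keep], match_start = starts[keep],
                     match_end = starts[keep] + L, cut_top = cut_t[keep],
                     cut_bottom = cut_b[keep])
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(tibble(enzyme = character(), strand = character(),
                  match_start = integer(), match_end = integer(),
                  cut_top = integer(), cut_bottom = integer()))
  }
  res <- tibble(
    enzyme = unlist(lapply(out, `[[`, "enzyme")),
    strand = unlist(lapply(out, `[[`, "strand")),
    match_start = unlist(lapply(out, `[[`, "match_start")),
    match_end = unlist(lapply(out, `[[`, "match_end")),
    cut_top = unlist(lapply(out, `[[`, "cut_top")),
    cut_bottom = unlist(lapply(out, `[[`, "cut_bottom"))
  )
  res[order(res$match_start, res$enzyme, res$strand), ]
}

#' Simulate digestion of an amplicon by one enzyme
#'
#' Fragments are the intervals between consecutive top-strand cut positions
#' plus the sequence ends; fragment lengths always sum to the amplicon
#' length.
#'
#' @param sequence Concrete DNA amplicon.
#' @param enzyme Single-row enzyme tibble.
#' @return A tibble with `fragment`, `start`, `end` (0-based half-open) and
#'   `length`; one row per fragment, left to right.
#' @export
#' @examples
#' enz <- read_enzyme_table("EcoRI\tG^AATTC\tN\t62")
#' digest_fragments("TTTTGAATTCTTTT", enz)
digest_fragments <- function(sequence, enzyme) {
  enzyme <- as_enzyme_rows(enzyme)
  if (nrow(enzyme) != 1L) abort("`enzyme` must be a single row")
  slen <- nchar(sequence)
  hits <- scan_sites(sequence, enzyme)
  cuts <- sort(unique(hits$cut_top))
  cuts <- cuts[cuts > 0L & cuts < slen]
  bounds <- c(0L, cuts, slen)
  tibble(
    fragment = seq_len(length(bounds) - 1L),
    start = bounds[-length(bounds)],
    end = bounds[-1L],
    length = diff(bounds)
  )
}

# anchored cut keys: cuts upstream of the variant are keyed to the variant
# start, cuts downstream to the variant end, cuts inside to the start. For
# indels this makes a pure downstream coordinate shift (same cuts relative
# to both anchors) compare equal, so the shift alone never counts as
# discrimination.
anchor_cut_keys <- function(cuts, vs, ve) {
  if (length(cuts) == 0L) return(character(0))
  ifelse(cuts <= vs, sprintf("L%d", cuts - vs),
         ifelse(cuts >= ve, sprintf("R%d", cuts - ve),
                sprintf("M%d", cuts - vs)))
}

#' Mine enzymes whose digestion discriminates the alleles of a variant
#'
#' For each enzyme, each allele realization is scanned within a
#' variant-centred window (extended by the longest recognition pattern minus
#' one on each side so matches overlapping the window edge are seen), on
#' both strands. Top-strand cut positions are normalized across alleles of
#' unequal length by anchoring upstream cuts at the variant start and
#' downstream cuts at the variant end; an enzyme is reported iff the
#' anchored cut multisets of some allele pair differ. Enzyme degeneracy
#' class and price are carried through for ranking.
#'
#' @param template A `snp_template`.
#' @param enzymes Enzyme tibble.
#' @param which Variant index (1-based).
#' @param window Half-width (nt) of the mining window around the variant
#'   span; must be at least the longest recognition pattern. Default 30,
#'   which covers all common recognition sites.
#' @return A tibble with one row per discriminating enzyme: `enzyme`,
#'   `site`, `degeneracy_class`, `suppliers`, `price`, `variant` (display
#'   label), `which`, `n_alleles`, `per_allele_cuts` (list: integer cut
#'   positions per allele, realization coordinates), `cut_keys` (list:
#'   anchored keys per allele), `discriminated_pairs` (list-tibble with
#'   `i`, `j`, `allele_i`, `allele_j`) and `n_pairs`.
#' @export
#' @examples
#' t <- parse_snp_sequence("TTTCTTTGTT[G/C]AATTCTTTGTTT", label = "ex")
#' enz <- read_enzyme_table("EcoRI\tG^AATTC\tN\t62")
#' mine_discriminating_enzymes(t, enz)
mine_discriminating_enzymes <- function(template, enzymes, which = 1L,
                                        window = 30L) {
  stopifnot(inherits(template, "snp_template"))
  enzymes <- as_enzyme_rows(enzymes)
  max_l <- max(nchar(enzymes$site))
  if (window < max_l) {
    abort(sprintf("`window` (%d) must be at least the longest recognition pattern (%d nt)",
                  window, max_l))
  }
  reals <- realize_alleles(template, which)
  n_all <- nrow(reals)

  # per allele: top-strand cuts of each enzyme inside the window
  cuts_by_allele <- vector("list", n_all)
  for (a in seq_len(n_all)) {
    seq_a <- reals$sequence[a]
    vs <- reals$var_start[a]
    ve <- reals$var_end[a]
    core_lo <- max(0L, vs - window)
    core_hi <- min(nchar(seq_a), ve + window)
    lo <- max(0L, core_lo - (max_l - 1L))
    hi <- min(nchar(seq_a), core_hi + (max_l - 1L))
    sub <- substr(seq_a, lo + 1L, hi)
    hits <- scan_sites(sub, enzymes)
    if (nrow(hits)) {
      hits$match_start <- hits$match_start + lo
      hits$match_end <- hits$match_end + lo
      hits$cut_top <- hits$cut_top + lo
      hits$cut_bottom <- hits$cut_bottom + lo
      hits <- hits[hits$match_end > core_lo & hits$match_start < core_hi, ]
    }
    cuts_by_allele[[a]] <- hits
  }

  rows <- list()
  for (i in seq_len(nrow(enzymes))) {
    nm <- enzymes$name[i]
    cuts <- lapply(seq_len(n_all), function(a) {
      h <- cuts_by_allele[[a]]
      sort(h$cut_top[h$enzyme == nm])
    })
    keys <- lapply(seq_len(n_all), function(a) {
      sort(anchor_cut_keys(cuts[[a]], reals$var_start[a], reals$var_end[a]))
    })
    pairs <- list()
    for (p in seq_len(n_all - 1L)) {
      for (q in seq((p + 1L), n_all)) {
        if (!identical(keys[[p]], keys[[q]])) {
          pairs[[length(pairs) + 1L]] <- tibble(
            i = p, j = q,
            allele_i = reals$allele[p], allele_j = reals$allele[q]
          )
        }
      }
    }
    if (length(pairs)) {
      rows[[length(rows) + 1L]] <- tibble(
        enzyme = nm, site = enzymes$site[i],
        degeneracy_class = enzymes$degeneracy_class[i],
        suppliers = enzymes$suppliers[i], price = enzymes$price[i],
        variant = variant_label(template, which), which = as.integer(which),
        n_alleles = n_all,
        per_allele_cuts = list(cuts), cut_keys = list(keys),
        discriminated_pairs = list(bind_rows(pairs)),
        n_pairs = length(pairs)
      )
    }
  }
  if (length(rows)) bind_rows(rows) else tibble(
    enzyme = character(), site = character(), degeneracy_class = character(),
    suppliers = character(), price = numeric(), variant = character(),
    which = integer(), n_alleles = integer(), per_allele_cuts = list(),
    cut_keys = list(), discriminated_pairs = list(), n_pairs = integer()
  )
}

#' Per-genotype digestion fragment table for a primer pair
#'
#' Builds each allele's amplicon from its realization between the primer
#' coordinates (applying the single mutagenic substitution when `pair` is a
#' mutagenic design), digests it with the enzyme, and tabulates fragment
#' lengths. Amplicon lengths may differ across alleles for indels. Hits of
#' outside cutters whose cut falls beyond the amplicon are dropped by the
#' scanner.
#'
#' @param pair One design row from [design_natural_pair()] or
#'   [design_mutagenic()] (the first row is used if several are passed).
#' @param template The `snp_template` the pair was designed on.
#' @param enzyme Single-row enzyme tibble.
#' @param which Variant index; defaults to the pair's own `which` column.
#' @return A tibble of class `rflp_digest_tbl`: one row per allele with
#'   `allele_index`, `allele`, `amplicon_length`, `n_fragments` and a
#'   `fragments` list-column of ordered fragment lengths.
#' @export
genotype_fragment_table <- function(pair, template, enzyme, which = NULL) {
  stopifnot(inherits(template, "snp_template"), is.data.frame(pair))
  if (nrow(pair) < 1L) abort("`pair` has no rows")
  pair <- pair[1L, ]
  enzyme <- as_enzyme_rows(enzyme)[1L, ]
  which <- which %||% pair$which %||% 1L
  reals <- realize_alleles(template, which)
  len1 <- nchar(reals$sequence[1])
  mutagenic <- "introduced_base" %in% names(pair) &&
    !is.na(pair$introduced_base)
  rows <- vector("list", nrow(reals))
  for (a in seq_len(nrow(reals))) {
    shift <- nchar(reals$allele[a]) - nchar(reals$allele[1])
    fs <- pair$f_start
    fe <- fs + pair$f_length
    rs <- pair$r_start + shift
    re <- rs + pair$r_length
    vs <- reals$var_start[a]
    ve <- reals$var_end[a]
    if (fe > vs || rs < ve) {
      abort("primers do not bracket variant")
    }
    amp <- substr(reals$sequence[a], fs + 1L, re)
    if (mutagenic) {
      if (identical(pair$mutated_primer, "reverse")) {
        # offset counted from the 5' end of the reverse primer, i.e. from
        # the right end of the amplicon; base given in primer orientation
        p_amp <- nchar(amp) - pair$mismatch_offset
        b <- revcomp(pair$introduced_base)
      } else {
        p_amp <- pair$mismatch_offset + 1L
        b <- toupper(pair$introduced_base)
      }
      substr(amp, p_amp, p_amp) <- b
    }
    fr <- digest_fragments(amp, enzyme)
    rows[[a]] <- tibble(
      allele_index = a, allele = reals$allele[a],
      amplicon_length = nchar(amp), n_fragments = nrow(fr),
      fragments = list(fr$length)
    )
  }
  out <- bind_rows(rows)
  class(out) <- c("rflp_digest_tbl", class(out))
  attr(out, "enzyme") <- enzyme$name
  out
}
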