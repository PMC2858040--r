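# Primer thermodynamics and design: natural pairs bracketing a variant, and
# mutagenic (dCAPS-style) single-mismatch primers that complete an
# allele-specific restriction site.

#' Primer design constraints
#'
#' @param primer_len Length range (nt), default 18-26.
#' @param product Product length range (nt), default 100-500.
#' @param gc GC-content range (percent), default 20-80.
#' @param max_tm_diff Maximum |Tm(forward) - Tm(reverse)| (deg C), default 5.
#' @param na_molar Monovalent salt molarity for the Tm formula, default 0.05.
#' @param mismatch_window For mutagenic designs: the introduced mismatch must
#'   lie within this many bases of the primer 3' end, never at the
#'   3'-terminal base itself. Default 5 (so offsets 1-4 from the terminus).
#' @param max_pairs Maximum number of ranked designs returned, default 10.
#' @return A list of class `rflp_constraints`.
#' @export
rflp_constraints <- function(primer_len = c(18L, 26L), product = c(100L, 500L),
                             gc = c(20, 80), max_tm_diff = 5,
                             na_molar = 0.05, mismatch_window = 5L,
                             max_pairs = 10L) {
  structure(list(primer_len = as.integer(primer_len),
                 product = as.integer(product), gc = as.numeric(gc),
                 max_tm_diff = max_tm_diff, na_molar = na_molar,
                 mismatch_window = as.integer(mismatch_window),
                 max_pairs = as.integer(max_pairs)),
            class = "rflp_constraints")
}

#' Salt-adjusted melting temperature
#'
#' The classical GC/length formula
#' `Tm = 81.5 + 16.6 log10([Na+]) + 0.41 GC% - 675/length`,
#' common PCR practice for primers in this length range.
#'
#' @param sequence Character vector of concrete primer sequences.
#' @param na_molar Monovalent cation molarity (default 0.05 M).
#' @return Numeric vector of melting temperatures (deg C).
#' @export
#' @examples
#' compute_tm(strrep("AG", 10))  # 20-mer, 10 G+C
compute_tm <- function(sequence, na_molar = 0.05) {
  s <- toupper(sequence)
  n <- nchar(s)
  if (any(n == 0L)) abort("empty primer sequence")
  gc <- stringr::str_count(s, "[GC]")
  81.5 + 16.6 * log10(na_molar) + 0.41 * (100 * gc / n) - 675 / n
}

primer_stats <- function(sequence, na_molar = 0.05) {
  s <- toupper(sequence)
  n <- nchar(s)
  gc <- stringr::str_count(s, "[GC]")
  tibble(length = n, gc_count = gc, gc_fraction = 100 * gc / n,
         tm = compute_tm(s, na_molar))
}

# enumerate forward candidates: template substrings ending at or before the
# variant start
forward_candidates <- function(seq1, vs, cons) {
  lmin <- cons$primer_len[1]; lmax <- cons$primer_len[2]
  fs_min <- max(0L, vs - cons$product[2])
  fe_max <- vs
  if (fe_max - fs_min < lmin) {
    return(tibble(start = integer(), length = integer(), end = integer(),
                  seq = character(), gc_count = integer(),
                  gc_fraction = numeric(), tm = numeric()))
  }
  grid <- expand.grid(start = fs_min:(fe_max - lmin), length = lmin:lmax)
  grid <- grid[grid$start + grid$length <= fe_max, , drop = FALSE]
  seqs <- substring(seq1, grid$start + 1L, grid$start + grid$length)
  st <- primer_stats(seqs, cons$na_molar)
  keep <- st$gc_fraction >= cons$gc[1] & st$gc_fraction <= cons$gc[2]
  tibble(start = as.integer(grid$start[keep]),
         length = as.integer(grid$length[keep]),
         end = as.integer(grid$start[keep] + grid$length[keep]),
         seq = seqs[keep], gc_count = st$gc_count[keep],
         gc_fraction = st$gc_fraction[keep], tm = st$tm[keep])
}

# reverse candidates: reverse complements of template substrings starting at
# or after the variant end (coordinates on the allele-1 realization)
reverse_candidates <- function(seq1, vs, ve, cons) {
  lmin <- cons$primer_len[1]; lmax <- cons$primer_len[2]
  len1 <- nchar(seq1)
  re_max <- min(len1, vs + cons$product[2])
  rs_min <- ve
  if (re_max - rs_min < lmin) {
    return(tibble(start = integer(), length = integer(), end = integer(),
                  seq = character(), gc_count = integer(),
                  gc_fraction = numeric(), tm = numeric()))
  }
  grid <- expand.grid(start = rs_min:(re_max - lmin), length = lmin:lmax)
  grid <- grid[grid$start + grid$length <= re_max, , drop = FALSE]
  tmpl <- substring(seq1, grid$start + 1L, grid$start + grid$length)
  seqs <- revcomp(tmpl)
  st <- primer_stats(seqs, cons$na_molar)
  keep <- st$gc_fraction >= cons$gc[1] & st$gc_fraction <= cons$gc[2]
  tibble(start = as.integer(grid$start[keep]),
         length = as.integer(grid$length[keep]),
         end = as.integer(grid$start[keep] + grid$length[keep]),
         seq = seqs[keep], gc_count = st$gc_count[keep],
         gc_fraction = st$gc_fraction[keep], tm = st$tm[keep])
}

# deterministic truncation keeping candidates closest to the variant, so the
# cross join stays small on very long templates
cap_candidates <- function(cand, near_col, decreasing, cap = 2500L) {
  if (nrow(cand) <= cap) return(cand)
  ord <- order(cand[[near_col]], decreasing = decreasing,
               cand$start, cand$length, method = "radix")
  cand[sort(ord[seq_len(cap)]), ]
}

empty_pairs <- function(reason) {
  out <- tibble(
    f_seq = character(), f_start = integer(), f_length = integer(),
    f_gc_count = integer(), f_gc_fraction = numeric(), f_tm = numeric(),
    r_seq = character(), r_start = integer(), r_length = integer(),
    r_gc_count = integer(), r_gc_fraction = numeric(), r_tm = numeric(),
    tm_diff = numeric(), product_length = integer(),
    product_lengths = list(), which = integer()
  )
  attr(out, "reason") <- reason
  out
}

#' Design natural primer pairs bracketing a variant
#'
#' Enumerates forward primers (exact template substrings ending at or before
#' the variant) and reverse primers (reverse complements of substrings
#' starting at or after the variant end), filters by the constraint block,
#' and ranks pairs by Tm difference (ascending), then closeness of the
#' product length to the midpoint of the allowed range, then leftmost
#' forward position. Neither primer ever overlaps the variant span, so the
#' product brackets the variant for every allele. Fully deterministic.
#'
#' @param template A `snp_template`.
#' @param which Variant index (1-based).
#' @param constraints An [rflp_constraints()] block.
#' @return A ranked tibble of primer pairs with per-primer annotations
#'   (sequence, 0-based template start, length, GC count, GC%, Tm), the Tm
#'   difference, `product_length` on the first-listed allele and
#'   `product_lengths` (list-column, one length per allele). When no pair is
#'   feasible the tibble is empty and carries a machine-readable
#'   attribute `"reason"` (`"flank too short"` or
#'   `"constraints infeasible"`).
#' @export
design_natural_pair <- function(template, which = 1L,
                                constraints = rflp_constraints()) {
  stopifnot(inherits(template, "snp_template"))
  cons <- constraints
  reals <- realize_alleles(template, which)
  seq1 <- reals$sequence[1]
  vs <- reals$var_start[1]; ve <- reals$var_end[1]
  len1 <- nchar(seq1)

  if (vs < cons$primer_len[1] || len1 - ve < cons$primer_len[1]) {
    return(empty_pairs("flank too short"))
  }
  f <- forward_candidates(seq1, vs, cons)
  r <- reverse_candidates(seq1, vs, ve, cons)
  if (nrow(f) == 0L || nrow(r) == 0L) {
    return(empty_pairs("constraints infeasible"))
  }
  f <- cap_candidates(f, "end", decreasing = TRUE)
  r <- cap_candidates(r, "start", decreasing = FALSE)

  D <- abs(outer(f$tm, r$tm, "-"))
  P <- outer(-f$start, r$end, "+")
  ok <- D <= cons$max_tm_diff & P >= cons$product[1] & P <= cons$product[2]
  if (!any(ok)) {
    return(empty_pairs("constraints infeasible"))
  }
  idx <- which(ok, arr.ind = TRUE)
  d <- D[ok]; p <- P[ok]
  mid <- mean(cons$product)
  fi <- idx[, 1L]; ri <- idx[, 2L]
  ord <- order(round(d, 9), abs(p - mid), f$start[fi], r$end[ri],
               f$length[fi], r$length[ri], method = "radix")
  take <- head(ord, cons$max_pairs)
  fi <- fi[take]; ri <- ri[take]
  shifts <- nchar(reals$allele) - nchar(reals$allele[1])
  out <- tibble(
    f_seq = f$seq[fi], f_start = f$start[fi], f_length = f$length[fi],
    f_gc_count = f$gc_count[fi], f_gc_fraction = f$gc_fraction[fi],
    f_tm = f$tm[fi],
    r_seq = r$seq[ri], r_start = r$start[ri], r_length = r$length[ri],
    r_gc_count = r$gc_count[ri], r_gc_fraction = r$gc_fraction[ri],
    r_tm = r$tm[ri],
    tm_diff = d[take], product_length = as.integer(p[take]),
    product_lengths = lapply(p[take], function(x) as.integer(x + shifts)),
    which = as.integer(which)
  )
  attr(out, "reason") <- NA_character_
  out
}

#' Recompute the thermodynamic annotations of a pair table
#'
#' Fills GC count, GC fraction, Tm and Tm difference from the primer
#' sequences (idempotent: annotating twice equals annotating once).
#'
#' @param pair A pair tibble with `f_seq` and `r_seq` columns.
#' @param na_molar Salt molarity for the Tm formula.
#' @return The pair tibble with annotation columns (re)computed.
#' @export
annotate_pair <- function(pair, na_molar = 0.05) {
  stopifnot(is.data.frame(pair))
  if (nrow(pair) == 0L) return(pair)
  fstats <- primer_stats(pair$f_seq, na_molar)
  rstats <- primer_stats(pair$r_seq, na_molar)
  pair$f_length <- fstats$length
  pair$f_gc_count <- fstats$gc_count
  pair$f_gc_fraction <- fstats$gc_fraction
  pair$f_tm <- fstats$tm
  pair$r_length <- rstats$length
  pair$r_gc_count <- rstats$gc_count
  pair$r_gc_fraction <- rstats$gc_fraction
  pair$r_tm <- rstats$tm
  pair$tm_diff <- abs(fstats$tm - rstats$tm)
  if (all(c("f_start", "r_start", "r_length") %in% names(pair))) {
    pair$product_length <- as.integer(pair$r_start + pair$r_length -
                                        pair$f_start)
  }
  pair
}

empty_mutagenic <- function(reason) {
  out <- tibble(
    enzyme = character(), site = character(), degeneracy_class = character(),
    price = numeric(), mutated_primer = character(),
    f_seq = character(), f_start = integer(), f_length = integer(),
    f_tm = numeric(), mismatch_offset = integer(),
    original_base = character(), introduced_base = character(),
    site_start = integer(),
    r_seq = character(), r_start = integer(), r_length = integer(),
    r_tm = numeric(), tm_diff = numeric(), product_length = integer(),
    product_lengths = list(), cutting_alleles = list(), which = integer()
  )
  attr(out, "reason") <- reason
  out
}

# reverse-complemented template: same variants in the same order of alleles,
# mirrored coordinates; used to run the forward-primer mutagenic search on
# the opposite strand
revcomp_template <- function(t) {
  B <- nchar(t$backbone)
  v <- t$variants
  k <- nrow(v)
  new_v <- tibble(
    position = rev(B - v$position),
    alleles = rev(lapply(v$alleles, function(al) {
      ifelse(al == "", "", revcomp(ifelse(al == "", "A", al)))
    })),
    source = rev(v$source)
  )
  new_snp_template(paste0(t$label, "_rc"), revcomp(t$backbone), new_v)
}

#' Design mutagenic (dCAPS-style) primers
#'
#' When no natural enzyme discriminates the alleles, a single deliberate
#' mismatch near the primer 3' end can complete a restriction site together
#' with one allele but not the other(s). The search enumerates, for every
#' enzyme (both orientations of its recognition pattern), every placement of
#' the pattern that overlaps the variant and reaches into the primer-covered
#' flank; a placement is viable when exactly one template base inside the
#' flank blocks the site for at least one allele. That base is substituted
#' (the introduced base is rendered in lowercase in the primer sequence),
#' the primer 3' end is chosen so the mismatch sits within the allowed
#' window of the 3' end but never at the terminal base, and a best-matching
#' reverse primer is attached. Each candidate is replayed through
#' [genotype_fragment_table()] and emitted only if the per-allele fragment
#' patterns actually differ (closed-loop verification) and the amplicon is
#' cut for a proper nonempty subset of alleles.
#'
#' @param template A `snp_template`.
#' @param enzymes Enzyme tibble.
#' @param which Variant index.
#' @param constraints An [rflp_constraints()] block.
#' @param strands `"forward"` (default; mismatch in the forward primer) or
#'   `"both"` (also search the reverse primer via the mirrored template).
#' @return A ranked tibble of mutagenic designs (Tm difference, then product
#'   closeness, then non-degenerate before degenerate recognition sites,
#'   then price ascending with unpriced enzymes last). Columns as for
#'   [design_natural_pair()] plus `enzyme`, `mutated_primer`,
#'   `mismatch_offset` (0-based within the primer 5'->3'),
#'   `original_base`, `introduced_base`, `site_start` and
#'   `cutting_alleles` (list of allele indices whose amplicon is cut).
#'   Empty with attribute `"reason"` when nothing is feasible.
#' @export
design_mutagenic <- function(template, enzymes, which = 1L,
                             constraints = rflp_constraints(),
                             strands = c("forward", "both")) {
  strands <- match.arg(strands)
  enzymes <- as_enzyme_rows(enzymes)
  res <- mutagenic_forward_search(template, enzymes, which, constraints)
  if (strands == "both") {
    k <- nrow(template$variants)
    rc_t <- revcomp_template(template)
    rc_res <- mutagenic_forward_search(rc_t, enzymes, k - which + 1L,
                                       constraints)
    if (nrow(rc_res)) {
      len1 <- nchar(realize_alleles(template, which)$sequence[1])
      tr <- rc_res
      tr$mutated_primer <- "reverse"
      tr$f_seq <- rc_res$r_seq
      tr$f_start <- len1 - (rc_res$r_start + rc_res$r_length)
      tr$f_length <- rc_res$r_length
      tr$f_tm <- rc_res$r_tm
      tr$r_seq <- rc_res$f_seq
      tr$r_start <- len1 - (rc_res$f_start + rc_res$f_length)
      tr$r_length <- rc_res$f_length
      tr$r_tm <- rc_res$f_tm
      tr$site_start <- len1 - (rc_res$site_start + nchar(rc_res$site))
      tr$which <- as.integer(which)
      res <- bind_rows(res, tr)
    }
  }
  if (nrow(res) == 0L) return(res)
  ord <- order(round(res$tm_diff, 9),
               abs(res$product_length - mean(constraints$product)),
               res$degeneracy_class == "IUPAC",
               ifelse(is.na(res$price), Inf, res$price),
               res$enzyme, res$site_start, res$mismatch_offset,
               method = "radix")
  out <- res[head(ord, constraints$max_pairs), ]
  attr(out, "reason") <- NA_character_
  out
}

mutagenic_forward_search <- function(template, enzymes, which, cons) {
  stopifnot(inherits(template, "snp_template"))
  reals <- realize_alleles(template, which)
  n_all <- nrow(reals)
  seq1 <- reals$sequence[1]
  vs <- reals$var_start[1]
  len1 <- nchar(seq1)
  lmin <- cons$primer_len[1]; lmax <- cons$primer_len[2]
  mw <- cons$mismatch_window

  if (vs < lmin || len1 - max(reals$var_end) < lmin) {
    return(empty_mutagenic("flank too short"))
  }
  rev_cand <- reverse_candidates(seq1, vs, reals$var_end[1], cons)
  if (nrow(rev_cand) == 0L) {
    return(empty_mutagenic("constraints infeasible"))
  }
  allele_chars <- strsplit(reals$sequence, "", fixed = TRUE)
  seen_cut_outside <- FALSE
  designs <- list()

  for (ei in seq_len(nrow(enzymes))) {
    pats <- list(list(site = enzymes$site[ei],
                      cut_top = enzymes$cut_top[ei],
                      cut_bottom = enzymes$cut_bottom[ei]))
    rc <- reverse_complement_pattern(enzymes$site[ei], enzymes$cut_top[ei],
                                     enzymes$cut_bottom[ei])
    if (!identical(rc, pats[[1]])) pats <- c(pats, list(rc))
    for (pat in pats) {
      Lp <- nchar(pat$site)
      sets <- .IUPAC_SETS[strsplit(pat$site, "", fixed = TRUE)[[1]]]
      p_lo <- max(0L, vs - Lp + 1L)
      p_hi <- vs - 1L  # site must reach into the primer-covered flank
      if (p_hi < p_lo) next
      for (p in p_lo:p_hi) {
        # per-allele mismatch positions of the placed pattern
        mism <- lapply(seq_len(n_all), function(a) {
          ch <- allele_chars[[a]]
          if (p + Lp > length(ch)) return(NULL)
          loc <- ch[(p + 1L):(p + Lp)]
          which(!mapply(function(b, s) b %in% s, loc, sets))
        })
        if (any(vapply(mism, is.null, logical(1)))) next
        # viable: some allele blocked at exactly one position, inside the
        # flank upstream of the variant (so the mismatch sits in the primer)
        cand_m <- unique(unlist(lapply(mism, function(m) {
          if (length(m) == 1L && (p + m[1] - 1L) < vs) m[1] else NULL
        })))
        for (m_rel in cand_m) {
          m <- p + m_rel - 1L            # 0-based template position
          if (m > vs - 2L) next          # need a 3' end past it, <= vs
          cutting <- which(vapply(mism, function(x) {
            identical(as.integer(x), as.integer(m_rel))
          }, logical(1)))
          if (length(cutting) == 0L || length(cutting) == n_all) next
          orig <- substr(seq1, m + 1L, m + 1L)
          for (b in setdiff(sets[[m_rel]], orig)) {
            d <- build_mutagenic_design(
              template, which, reals, rev_cand, enzymes[ei, ], pat, p,
              m, orig, b, cutting, cons)
            if (is.character(d)) {
              if (d == "cut outside product") seen_cut_outside <- TRUE
            } else if (!is.null(d)) {
              designs[[length(designs) + 1L]] <- d
            }
          }
        }
      }
    }
  }
  if (length(designs) == 0L) {
    return(empty_mutagenic(
      if (seen_cut_outside) "cut outside product" else
        "no feasible mutagenic design"))
  }
  bind_rows(designs)
}

# assemble one candidate design: choose primer 3' end and length, attach the
# best reverse primer, replay the digestion per allele, and keep the design
# only if the fragment patterns differ
build_mutagenic_design <- function(template, which, reals, rev_cand, enz,
                                   pat, p, m, orig, b, cutting, cons) {
  vs <- reals$var_start[1]
  lmin <- cons$primer_len[1]; lmax <- cons$primer_len[2]
  mw <- cons$mismatch_window
  fe_opts <- seq(m + 2L, min(vs, m + mw))
  fe_opts <- fe_opts[fe_opts >= lmin]
  if (length(fe_opts) == 0L) return(NULL)
  grid <- expand.grid(fe = fe_opts, l = lmin:lmax)
  grid <- grid[grid$fe - grid$l >= 0L, , drop = FALSE]
  if (nrow(grid) == 0L) return(NULL)
  seq1 <- reals$sequence[1]
  fseq <- substring(seq1, grid$fe - grid$l + 1L, grid$fe)
  # apply the mutation (position m within each primer)
  off <- m - (grid$fe - grid$l)       # 0-based offset within primer
  mseq <- fseq
  substr(mseq, off + 1L, off + 1L) <- b
  st <- primer_stats(mseq, cons$na_molar)
  keep <- st$gc_fraction >= cons$gc[1] & st$gc_fraction <= cons$gc[2]
  if (!any(keep)) return(NULL)
  grid <- grid[keep, , drop = FALSE]
  mseq <- mseq[keep]; off <- off[keep]; st <- st[keep, ]

  D <- abs(outer(st$tm, rev_cand$tm, "-"))
  P <- outer(-(grid$fe - grid$l), rev_cand$end, "+")
  ok <- D <= cons$max_tm_diff & P >= cons$product[1] & P <= cons$product[2]
  if (!any(ok)) return(NULL)
  idx <- which(ok, arr.ind = TRUE)
  sc <- order(round(D[ok], 9), abs(P[ok] - mean(cons$product)),
              grid$fe[idx[, 1L]], rev_cand$end[idx[, 2L]], method = "radix")
  fi <- idx[sc[1], 1L]; ri <- idx[sc[1], 2L]

  f_start <- as.integer(grid$fe[fi] - grid$l[fi])
  f_seq_display <- mseq[fi]
  substr(f_seq_display, off[fi] + 1L, off[fi] + 1L) <- tolower(b)
  shifts <- nchar(reals$allele) - nchar(reals$allele[1])
  row <- tibble(
    enzyme = enz$name, site = enz$site,
    degeneracy_class = enz$degeneracy_class, price = enz$price,
    mutated_primer = "forward",
    f_seq = f_seq_display, f_start = f_start,
    f_length = as.integer(grid$l[fi]), f_tm = st$tm[fi],
    mismatch_offset = as.integer(off[fi]),
    original_base = orig, introduced_base = b,
    site_start = as.integer(p),
    r_seq = rev_cand$seq[ri], r_start = rev_cand$start[ri],
    r_length = rev_cand$length[ri], r_tm = rev_cand$tm[ri],
    tm_diff = abs(st$tm[fi] - rev_cand$tm[ri]),
    product_length = as.integer(rev_cand$end[ri] - f_start),
    product_lengths = list(as.integer(rev_cand$end[ri] - f_start + shifts)),
    cutting_alleles = list(as.integer(cutting)),
    which = as.integer(which)
  )
  prof <- genotype_fragment_table(row, template, enz, which = which)
  frag_sets <- lapply(prof$fragments, sort)
  non_cut <- setdiff(seq_len(nrow(reals)), cutting)
  differs <- any(vapply(cutting, function(ci) {
    any(vapply(non_cut, function(nj) {
      !identical(frag_sets[[ci]], frag_sets[[nj]])
    }, logical(1)))
  }, logical(1)))
  cut_happened <- any(prof$n_fragments[cutting] > 1L)
  if (!cut_happened) return("cut outside product")
  if (!differs) return(NULL)
  row
}
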