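---
title: "Designing PCR-RFLP genotyping assays with rflpdesign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing PCR-RFLP genotyping assays with rflpdesign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rflpdesign)
```

## The problem

PCR-RFLP (restriction fragment length polymorphism) is one of the cheapest
ways to genotype a known SNP: amplify a short product spanning the variant,
digest it with a restriction enzyme whose recognition site is completed by
one allele and destroyed by the other, and read the genotype off a gel as a
fragment-size pattern. Finding a suitable enzyme by hand is tedious —
recognition sequences are often degenerate (written in the 15-letter IUPAC
alphabet), sites can sit on either strand, and when no natural site
discriminates the alleles a *mutagenic* (dCAPS-style) primer can still
rescue the assay by introducing a single deliberate mismatch near its 3'
end so that the amplicon completes a site together with one allele only.

`rflpdesign` automates the whole desk workflow offline: parse
SNP-containing sequences, mine discriminating enzymes, simulate the
per-genotype digestion patterns, and design natural and mutagenic primer
pairs with the usual thermodynamic annotations.

## Inputs and their grammars

**Templates.** A sequence carries its variants inline, either in bracket
notation — `ACGT[A/G]ACGT`, `[A/C/T]`, `[-/AGG]` for an indel, 2–4 alleles
per site — or as a single-letter IUPAC ambiguity code in the body (`R` =
A/G and so on; `N` is rejected because a four-way ambiguity with no stated
order carries no assayable information, and the matching engine needs
concrete templates). Up to 50 variants per sequence are accepted, and the
backbone gap between adjacent variants must exceed 6 nt so each variant
keeps a private flank; a gap of exactly 6 is rejected, 7 is accepted. We
read the spacing rule strictly because a shared flank would make the
per-variant analyses interfere. Multi-variant sequences are analyzed one
variant at a time with every other variant fixed to its first-listed
allele — the natural "reference" reading of bracket notation. Coordinates
are 0-based half-open internally; every report prints 1-based positions.

**Enzymes.** The enzyme table is a tab-separated REBASE-style dialect:
`name<TAB>site<TAB>suppliers<TAB>price`, with `^` marking the top-strand
cut inside the recognition sequence (the bottom-strand cut then falls at
the complementary-symmetric position) or a trailing `(t/b)` offset pair for
outside cutters such as `GGTCTC(1/5)`. Suppliers are single-letter
commercial codes; the price is one optional nonnegative decimal — absent
means "not commercially priced" and such enzymes sort last in price
rankings. Enzymes whose recognition sequence uses only A/C/G/T are classed
`non_IUPAC`, all others `IUPAC`; the two classes coincide exactly with
expansion cardinality one versus greater. Lines with unknown symbols,
missing or doubled cut descriptors, or duplicate names are rejected
individually with a reason (see `enzyme_parse_report()`); enzymes that cut
on both sides of their site are out of scope and rejected. The bundled
table (`default_enzymes()`) is a curated synthetic stand-in: real published
recognition sequences for ~30 widely used enzymes, illustrative supplier
codes and prices.

## Mining discriminating enzymes

```{r mine}
t <- parse_snp_sequence("TTTCTTTGTTCCTT[G/C]AATTCTTTGTTTCTT", label = "demo")
mine_discriminating_enzymes(t, default_enzymes())[, c("enzyme", "site",
                                                      "degeneracy_class",
                                                      "price", "n_pairs")]
```

Matching uses a vectorized bit-mask engine: bases are encoded as bits
(A=1, C=2, G=4, T=8) and every IUPAC symbol as the OR of its base set, so a
window matches when each position ANDs to a nonzero value. All overlapping
matches on both strands are found; for palindromic sites with symmetric
cuts the duplicate antisense hit is suppressed. The test suite checks the
engine against a brute-force oracle (expand the degenerate pattern to
concrete strings, substring-scan both strands) and against an independent
Biostrings-based scan.

Discrimination is decided inside a variant-centred window (default ±30 nt,
wide enough for every common recognition site; the scan region is extended
by the longest pattern minus one so edge-overlapping matches are seen).
Per allele, the top-strand cut positions are normalized by anchoring cuts
upstream of the variant at the variant start and cuts downstream at the
variant end; an enzyme discriminates an allele pair when the anchored cut
multisets differ. The two-anchor normalization matters for indels: an
enzyme whose cuts merely shift with the inserted length would otherwise
"discriminate" every indel, while the genuine length difference is already
visible in the fragment table. Outside cutters whose recognition site lies
in-window but whose cut falls past the amplicon end contribute no cut and
are dropped from fragment tables.

## Primer design

Natural pairs bracket the variant without ever overlapping it, so the same
pair amplifies every allele. Candidates are filtered by the constraint
block — defaults: primer length 18–26 nt, product 100–500 nt, GC 20–80%,
|ΔTm| ≤ 5 °C — and ranked by ΔTm, then closeness of the product to the
middle of the allowed range, then leftmost forward position, which makes
the search a pure function of (template, constraints). On very long
templates the candidate sets on each side are deterministically capped at
the 2500 candidates nearest the variant before pairing.

Melting temperatures use the salt-adjusted GC/length formula

$$T_m = 81.5 + 16.6\,\log_{10}[\mathrm{Na}^+] + 0.41\,\mathrm{GC\%} - 675/L$$

with 0.05 M Na⁺ by default. It is fully specified, testable by hand
(a 20-mer with 10 G+C gives 46.65 °C), and adequate for ranking primers of
nearly equal length; nearest-neighbor thermodynamics are deliberately out
of scope.

Mutagenic designs enumerate, for every enzyme and both orientations of its
recognition pattern, every placement of the pattern that overlaps the
variant and reaches into the primer-covered flank. A placement is viable
when exactly one shared flank base blocks the site; substituting it (the
lowercase letter in the primer, plus explicit offset fields — a portable
rendering of the highlighted base) makes the site complete for exactly the
alleles whose variant base fits the pattern. The mismatch must sit within
5 nt of the 3' end but never at the 3'-terminal base itself, preserving
extension fidelity. By default only the forward primer is mutated, which
mirrors common practice; `strands = "both"` also searches the reverse
primer via the mirrored template. Every candidate is replayed through
`genotype_fragment_table()` and emitted only if the per-allele fragment
patterns genuinely differ and the amplicon is cut for a proper nonempty
subset of alleles; ranking follows the natural criteria, then non-degenerate
recognition sites before degenerate ones, then price ascending. Because
the forward primer is pinned at the variant, mutagenic assays need roughly
`product_min` nt of downstream flank to be feasible at all.

```{r mutagenic}
set.seed(5)
fl <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
fr <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
t2 <- parse_snp_sequence(paste0(fl, "GACTT[C/T]", fr), label = "dcaps")
d <- design_mutagenic(t2, read_enzyme_table("EcoRI\tG^AATTC\tN\t62"))
d[, c("enzyme", "f_seq", "mismatch_offset", "introduced_base",
      "product_length")]
```

## The synthetic fixture generator

`generate_fixture()` emulates the tool's inputs with a recorded ground
truth: random flanks of 150 nt per side (the scale of typical SNP flanking
sequences, and long enough that the default product range stays feasible
even for variant-pinned mutagenic primers), a configurable mix of bi-, tri-
and tetra-allelic and indel variants, and a planted fraction (default 0.7)
in which the first allele completes a concrete expansion of a known
enzyme's site while every alternative allele breaks it (for indels the
deletion removes the site's interior). Each planted template is verified at
generation time against the expansion-based oracle — not against the
scanning engine — so planted-truth recovery is a real end-to-end test of
the miner. Generation is deterministic per seed and restores the caller's
RNG state.

What the fixtures do *not* emulate: real genomic base composition and
repeats, sequencing errors, paralogy, primer secondary structure, and
enzyme behaviour beyond the recognition sequence (methylation sensitivity,
star activity, buffer compatibility). Passing tests therefore demonstrate
the correctness of the combinatorial design logic, not wet-lab success
rates.

## Numerical and degenerate-input choices

* Cut positions are integers in `[0, sequence length]`; hits whose cut
  falls outside are discarded, and digestion uses the strictly interior
  unique top-strand cuts, so fragment lengths always partition the
  amplicon.
* Ties in every ranking are broken positionally (leftmost forward, then
  smallest reverse end, then shortest primers), making all design
  operations deterministic; Tm values are compared after rounding to 9
  decimals so floating-point noise cannot reorder ties.
* Degenerate patterns may in principle expand combinatorially;
  `expand_pattern()` refuses cardinalities above 65536 and advises direct
  degenerate matching (the engine itself never expands).
* Reports are serialized with fixed numeric precision and no clock or
  environment values, so identical inputs give byte-identical JSON.

## Problem sizes used in the checks

The bundled checks run the scanning engine against the brute-force oracle
on 500 random sequence/enzyme pairs up to 2 kb, recover planted enzymes on
200 fixture templates, replay every mutagenic design on 100 unplanted
templates, and verify length conservation on 10000 random digests — sizes
at which the full suite completes in a few minutes on one core while still
exercising every allele class.

## Known limitations

* Isoschizomer/prototype grouping is not modeled; each table line is an
  independent enzyme.
* No primer cross-dimer or hairpin screening, no degenerate-base primers,
  no multiplex pooling.
* Partial digestion, methylation blocking and gel mobility are not
  simulated; fragment tables are exact digest arithmetic.
* All database retrieval (dbSNP identifiers, GenBank accessions, tagSNPs,
  GO/miRNA annotation) is out of scope: inputs are local files only.
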