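# rflpdesign

Offline design of **PCR-RFLP genotyping assays** for SNPs, in R.

PCR-RFLP (restriction fragment length polymorphism) genotypes a known
variant by amplifying a short product across it and digesting the product
with a restriction enzyme whose recognition site is completed by one allele
and destroyed by the other; the genotype is read on a gel as a
fragment-size pattern. `rflpdesign` automates the desk work for any lab
doing small-scale genotyping, mutation screening, food authentication or
strain typing:

* parse SNP-containing sequences in bracket (`ACGT[A/G]ACGT`, `[-/AGG]`,
  2–4 alleles per site) or IUPAC ambiguity notation, with up to 50
  variants per sequence (adjacent variants must be more than 6 nt apart);
* read restriction-enzyme tables in a documented REBASE-style TSV dialect
  (`G^AATTC`, `GGTCTC(1/5)`), with supplier codes, per-unit price and
  IUPAC / non-IUPAC degeneracy classification;
* mine enzymes whose digestion discriminates the alleles on **either
  strand**, using a vectorized bit-mask matcher over the degenerate
  IUPAC alphabet and a two-anchor cut normalization that handles indels
  without calling every coordinate shift a discrimination;
* simulate the per-genotype digestion fragment patterns;
* design natural primer pairs (length 18–26 nt, product 100–500 nt,
  GC 20–80 %, |ΔTm| ≤ 5 °C by default) with position, length, GC no.,
  GC %, Tm (salt-adjusted formula
  `Tm = 81.5 + 16.6 log10[Na+] + 0.41 GC% − 675/L`), Tm-difference and
  per-allele product length;
* design **mutagenic (dCAPS-style) primers** when no natural enzyme
  exists: a single mismatch near the primer 3' end (never terminal,
  rendered lowercase) that completes an allele-specific restriction site,
  verified closed-loop against the digestion simulator.

Everything is a pure function of its inputs — no network, no clock — so
identical inputs give byte-identical reports.

## Worked example

```r
library(rflpdesign)

t <- parse_snp_sequence("TTTCTTTGTTCCTT[G/C]AATTCTTTGTTTCTT", label = "demo")
mine_discriminating_enzymes(t, default_enzymes())[, c("enzyme", "site",
                                                      "degeneracy_class",
                                                      "price", "n_pairs")]
#> # A tibble: 2 × 5
#>   enzyme site   degeneracy_class price n_pairs
#>   <chr>  <chr>  <chr>            <dbl>   <int>
#> 1 EcoRI  GAATTC non_IUPAC           62       1
#> 2 ApoI   RAATTY IUPAC               70       1
```

The G allele completes `GAATTC`, so EcoRI (and its degenerate relative
ApoI, `RAATTY`) cuts the G amplicon but not the C amplicon — one
discriminated allele pair each (`n_pairs`).

When no natural site exists, a mutagenic design introduces one mismatch:

```r
set.seed(5)
fl <- paste(sample(c("A","C","G","T"), 120, TRUE), collapse = "")
fr <- paste(sample(c("A","C","G","T"), 120, TRUE), collapse = "")
t2 <- parse_snp_sequence(paste0(fl, "GACTT[C/T]", fr), label = "dcaps")
ecoRI <- read_enzyme_table("EcoRI\tG^AATTC\tN\t62")
d <- design_mutagenic(t2, ecoRI)
d[, c("enzyme", "f_seq", "mismatch_offset", "introduced_base", "product_length")]
#>   enzyme                      f_seq mismatch_offset introduced_base product_length
#> 1  EcoRI TACCTATAATACACACGTCTATGAaT              24               A            135

genotype_fragment_table(d[1, ], t2, ecoRI)
#> # A tibble: 2 × 5
#>   allele_index allele amplicon_length n_fragments fragments
#>          <int> <chr>            <int>       <int> <list>
#> 1            1 C                  135           2 <int [2]>
#> 2            2 T                  135           1 <int [1]>
```

The forward primer carries a C→`a` substitution at offset 24 (lowercase;
never the 3'-terminal base), so only the C allele's 135-nt amplicon
completes `GAATTC` and is cut (two fragments); the T allele stays uncut —
a clean one-enzyme genotyping assay. `autoplot()` on the fragment table
draws the expected gel.

The whole workflow over a FASTA file and an enzyme table:

```r
fix <- generate_fixture(seed = 1, n_templates = 3)   # synthetic inputs + truth
paths <- write_fixture(fix, tempfile())
reports <- run_rflp_pipeline(fasta = paths[["fasta"]],
                             rebase = paths[["enzymes"]],
                             mutagenic = "always")
glance(reports)
#> # A tibble: 1 × 6
#>   n_reports n_templates n_with_natural_enzyme n_with_natural_pair ...
#> 1         3           3                     3                   3
write_report(reports, "assays.json", format = "json")   # or "tsv" / "text"
```

A thin command-line wrapper with `mine` / `design` / `fixture` verbs lives
in `inst/cli/rflpdesign.R`.

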