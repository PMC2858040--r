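make_centered_template <- function(seed = 2, flank = 250) {
  set.seed(seed)
  parse_snp_sequence(paste0(random_seq(flank), "[A/G]", random_seq(flank)),
                     label = "centered")
}

test_that("the salt-adjusted Tm formula matches hand computation", {
  # 20-mer with 10 G+C at 0.05 M Na+:
  # 81.5 + 16.6*log10(0.05) + 0.41*50 - 675/20
  expect_equal(compute_tm(strrep("AG", 10)), 46.65, tolerance = 0.01 / 46)
  expect_equal(compute_tm(strrep("AG", 10)),
               81.5 + 16.6 * log10(0.05) + 0.41 * 50 - 675 / 20)
  # GC bookkeeping
  st <- rflpdesign:::primer_stats("ATGC")
  expect_equal(st$gc_count, 2L)
  expect_equal(st$gc_fraction, 50)
  # identical primers have zero Tm difference
  expect_equal(abs(compute_tm("ACGTACGTACGTACGTAC") -
                     compute_tm("ACGTACGTACGTACGTAC")), 0)
  expect_error(compute_tm(""), "empty")
})

test_that("natural pairs respect the constraint block and the variant span", {
  t <- make_centered_template()
  cons <- rflp_constraints()
  pairs <- design_natural_pair(t, constraints = cons)
  expect_gt(nrow(pairs), 0L)
  reals <- realize_alleles(t)
  seq1 <- reals$sequence[1]
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    # forward is an exact template substring, reverse its reverse complement
    expect_equal(p$f_seq,
                 substr(seq1, p$f_start + 1, p$f_start + p$f_length))
    expect_equal(p$r_seq,
                 revcomp(substr(seq1, p$r_start + 1, p$r_start + p$r_length)))
    # neither primer overlaps the variant span
    expect_lte(p$f_start + p$f_length, reals$var_start[1])
    expect_gte(p$r_start, reals$var_end[1])
    expect_true(p$f_length >= cons$primer_len[1] &&
                  p$f_length <= cons$primer_len[2])
    expect_true(p$product_length >= cons$product[1] &&
                  p$product_length <= cons$product[2])
    expect_lte(p$tm_diff, cons$max_tm_diff)
    expect_true(p$f_gc_fraction >= cons$gc[1] &&
                  p$f_gc_fraction <= cons$gc[2])
  }
  # ranking is by Tm difference first
  expect_true(!is.unsorted(round(pairs$tm_diff, 9)))
})

test_that("design is deterministic and infeasible flanks give a reason", {
  t <- make_centered_template()
  a <- design_natural_pair(t)
  b <- design_natural_pair(t)
  expect_identical(as.data.frame(a), as.data.frame(b))

  short <- parse_snp_sequence(paste0(strrep("ACGT", 3), "[A/G]",
                                     strrep("ACGT", 60)))
  res <- design_natural_pair(short)
  expect_equal(nrow(res), 0L)
  expect_equal(attr(res, "reason"), "flank too short")
  # feasible but over-constrained: infeasibility is reported as such
  t <- make_centered_template()
  res2 <- design_natural_pair(t, constraints = rflp_constraints(
    max_tm_diff = 0, gc = c(79, 80)))
  expect_equal(nrow(res2), 0L)
  expect_equal(attr(res2, "reason"), "constraints infeasible")
})

test_that("annotate_pair is idempotent and recomputes from sequences", {
  t <- make_centered_template()
  p <- design_natural_pair(t)
  once <- annotate_pair(p)
  twice <- annotate_pair(once)
  expect_identical(as.data.frame(once), as.data.frame(twice))
  expect_identical(as.data.frame(once[, names(p)])[
    , setdiff(names(p), "product_lengths")],
    as.data.frame(p)[, setdiff(names(p), "product_lengths")])
  expect_equal(once$product_length,
               once$r_start + once$r_length - once$f_start)
})

test_that("mutagenic designs introduce exactly one mismatch, never 3'-terminal", {
  set.seed(5)
  fl <- random_seq(120); fr <- random_seq(120)
  t <- parse_snp_sequence(paste0(fl, "GACTT[C/T]", fr), "dcaps")
  d <- design_mutagenic(t, ecoRI())
  expect_gt(nrow(d), 0L)
  reals <- realize_alleles(t)
  for (i in seq_len(nrow(d))) {
    row <- d[i, ]
    tmpl_sub <- substr(reals$sequence[1], row$f_start + 1,
                       row$f_start + row$f_length)
    prim <- toupper(row$f_seq)
    expect_equal(nchar(prim), nchar(tmpl_sub))
    mism <- which(strsplit(prim, "")[[1]] != strsplit(tmpl_sub, "")[[1]])
    expect_equal(mism, row$mismatch_offset + 1L)   # Hamming distance 1
    expect_lt(row$mismatch_offset, row$f_length - 1L)  # not 3'-terminal
    expect_gte(row$mismatch_offset, row$f_length - 5L) # within the window
    # rendering: exactly one lowercase character, the introduced base
    low <- gregexpr("[a-z]", row$f_seq)[[1]]
    expect_length(low, 1L)
    expect_equal(toupper(substr(row$f_seq, low, low)), row$introduced_base)
  }
  # EcoRI cuts only the allele that completes GAATTC
  expect_equal(d$cutting_alleles[[1]], 1L)
  gt <- genotype_fragment_table(d[1, ], t, ecoRI())
  expect_equal(gt$n_fragments, c(2L, 1L))
})

test_that("mutagenic designs replay to allele-discriminating digests", {
  enz <- default_enzymes()
  fix <- generate_fixture(seed = 21, n_templates = 8, planted_fraction = 0)
  n_checked <- 0L
  for (i in seq_len(nrow(fix$templates))) {
    t <- fix$templates$template[[i]]
    d <- design_mutagenic(t, enz)
    for (k in seq_len(nrow(d))) {
      e <- enz[enz$name == d$enzyme[k], ]
      gt <- genotype_fragment_table(d[k, ], t, e)
      sets <- lapply(gt$fragments, sort)
      cutting <- d$cutting_alleles[[k]]
      other <- setdiff(seq_len(nrow(gt)), cutting)
      expect_true(length(cutting) >= 1L && length(other) >= 1L)
      expect_false(identical(sets[[cutting[1]]], sets[[other[1]]]))
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 0L)
})

test_that("mutagenic search on both strands can mutate the reverse primer", {
  # site completable only on the downstream/reverse side of the variant
  set.seed(9)
  fl <- random_seq(120); fr <- random_seq(120)
  t <- parse_snp_sequence(paste0(fl, "[G/A]AATCT", fr), "revside")
  d <- design_mutagenic(t, ecoRI(), strands = "both")
  if (nrow(d) > 0 && any(d$mutated_primer == "reverse")) {
    row <- d[d$mutated_primer == "reverse", ][1, ]
    gt <- genotype_fragment_table(row, t, ecoRI())
    sets <- lapply(gt$fragments, sort)
    expect_false(identical(sets[[1]], sets[[2]]))
  }
  expect_true(all(d$mutated_primer %in% c("forward", "reverse")))
})
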