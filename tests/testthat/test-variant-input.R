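flank <- function(n, base = "T") strrep(base, n)

test_that("clean_sequence filters blanks, commas, digits and junk", {
  out <- clean_sequence("acg t,ac\n")
  expect_equal(as.character(out), "ACGTAC")
  expect_equal(attr(out, "n_removed"), 3L)
  expect_equal(as.character(clean_sequence("ACGT")), "ACGT")
  expect_error(clean_sequence("123,, "), "no nucleotides")
})

test_that("bracket notation parses into backbone and variants", {
  t <- parse_snp_sequence("ACGT[A/G]ACGT")
  expect_s3_class(t, "snp_template")
  expect_equal(t$backbone, "ACGTACGT")
  expect_equal(t$variants$position, 4L)
  expect_equal(t$variants$alleles[[1]], c("A", "G"))
  expect_equal(t$variants$source, "bracket")

  tri <- parse_snp_sequence("ACGTACGT[A/G/T]CCCCCCC")
  expect_equal(tri$variants$alleles[[1]], c("A", "G", "T"))
  tet <- parse_snp_sequence("ACGTACGT[A/G/T/C]CCCCCCC")
  expect_length(tet$variants$alleles[[1]], 4L)
})

test_that("IUPAC ambiguity codes in the body become variants, N is rejected", {
  t <- parse_snp_sequence("ACGRT")
  expect_equal(t$variants$position, 3L)
  expect_equal(t$variants$alleles[[1]], c("A", "G"))  # alphabetical
  expect_equal(t$variants$source, "iupac")
  b <- parse_snp_sequence("ACGTBACGT")
  expect_equal(b$variants$alleles[[1]], c("C", "G", "T"))
  expect_error(parse_snp_sequence("ACGTNACGT"), "N")
})

test_that("indel and length-polymorphism alleles are handled", {
  t <- parse_snp_sequence("ACGT[-/AGG]AC")
  r <- realize_alleles(t)
  expect_equal(r$sequence, c("ACGTAC", "ACGTAGGAC"))
  expect_equal(r$var_start, c(4L, 4L))
  expect_equal(r$var_end, c(4L, 7L))  # deletion has an empty span
  lp <- parse_snp_sequence("ACGT[AG/TTT]AC")
  expect_equal(nchar(realize_alleles(lp)$sequence), c(8L, 9L))
})

test_that("malformed brackets are rejected", {
  expect_error(parse_snp_sequence("ACGT[A/G"), "unbalanced")
  expect_error(parse_snp_sequence("ACGT]A"), "unbalanced")
  expect_error(parse_snp_sequence("ACGT[A]GT"), "2-4 alleles")
  expect_error(parse_snp_sequence("ACGT[A/G/T/C/A]GT"), "2-4 alleles")
  expect_error(parse_snp_sequence("ACGT[A/A]GT"), "duplicate")
  expect_error(parse_snp_sequence("ACGT[-/-]GT"), "duplicate|deletion")
  expect_error(parse_snp_sequence("ACGT[A/Q]GT"), "invalid allele")
})

test_that("variant count limit is 50 inclusive", {
  unit <- paste0(flank(7), "[A/G]")
  seq50 <- paste0(strrep(unit, 50), flank(7))
  t <- parse_snp_sequence(seq50)
  expect_equal(nrow(t$variants), 50L)
  seq51 <- paste0(strrep(unit, 51), flank(7))
  expect_error(parse_snp_sequence(seq51), "50")
})

test_that("adjacent variants need a backbone gap above 6 nt", {
  expect_error(parse_snp_sequence(paste0(flank(10), "[A/G]", flank(6),
                                         "[C/T]", flank(10))),
               "6 nucleotides")
  ok <- parse_snp_sequence(paste0(flank(10), "[A/G]", flank(7),
                                  "[C/T]", flank(10)))
  expect_equal(diff(ok$variants$position), 7L)
  expect_error(parse_snp_sequence(paste0(flank(10), "[A/G][C/T]", flank(10))),
               "6 nucleotides")
})

test_that("realize_alleles fixes the other variants to their first allele", {
  t <- parse_snp_sequence(paste0("GG[A/C]", flank(8), "[TT/G]CC"))
  r2 <- realize_alleles(t, which = 2L)
  expect_equal(nrow(r2), 2L)
  # variant 1 held at allele A
  expect_true(all(substr(r2$sequence, 3, 3) == "A"))
  expect_equal(r2$sequence[1], paste0("GGA", flank(8), "TTCC"))
  expect_equal(r2$var_start, c(11L, 11L))
  r3 <- realize_alleles(parse_snp_sequence("[A/G/T]CCCCCCC"), 1L)
  expect_equal(nrow(r3), 3L)
  expect_error(realize_alleles(t, which = 3L), "1\\.\\.2")
})

test_that("re-inserting allele 1 reproduces the cleaned input", {
  txt <- paste0("acg t,ACGTAC", "[A/G]", "ggttaacc")
  t <- parse_snp_sequence(txt)
  r <- realize_alleles(t, 1L)
  manual <- gsub("\\[A/G\\]", "A", txt)
  expect_equal(r$sequence[1], as.character(clean_sequence(manual)))
})

test_that("FASTA round-trip preserves templates, variant-free records skip", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "ACGTACGT[A/G]ACG", ">plain", "ACGTACGT",
               ">y", paste0("ACGTACGRT", flank(8), "[-/AT]ACGT")), tmp)
  expect_warning(tl <- read_snp_fasta(tmp), "no variant")
  expect_equal(tl$label, c("x", "y"))
  expect_equal(tl$n_variants, c(1L, 2L))
  out <- withr::local_tempfile(fileext = ".fasta")
  write_snp_fasta(tl, out)
  back <- read_snp_fasta(out)
  expect_equal(back$label, tl$label)
  for (i in seq_len(nrow(tl))) {
    expect_equal(back$template[[i]]$backbone, tl$template[[i]]$backbone)
    expect_equal(as.data.frame(back$template[[i]]$variants),
                 as.data.frame(tl$template[[i]]$variants))
  }
  expect_error(read_snp_fasta(tmp, on_empty = "error"), "no variant")
  # empty stream -> empty collection
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_equal(nrow(read_snp_fasta(empty)), 0L)
})
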