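test_that("scan_sites finds degenerate sites with correct cuts", {
  hits <- scan_sites("TTGAATTCAA", ecoRI())
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "sense")  # palindromic: antisense duplicate suppressed
  expect_equal(hits$match_start, 2L)
  expect_equal(hits$cut_top, 3L)
  expect_equal(hits$cut_bottom, 7L)

  hinfI <- read_enzyme_table("HinfI\tG^ANTC\tN\t62")
  expect_equal(scan_sites("GACTC", hinfI)$match_start, 0L)

  expect_equal(nrow(scan_sites("ACGT", ecoRI())), 0L)
})

test_that("non-palindromic sites report both strands with mirrored cuts", {
  bsaI <- read_enzyme_table("BsaI\tGGTCTC(1/5)\tN\t75")
  s <- paste0("AAAA", "GGTCTC", "TTTTTTTTTT")    # sense site at 4
  h <- scan_sites(s, bsaI)
  expect_equal(h$strand, "sense")
  expect_equal(h$cut_top, 4L + 7L)
  a <- paste0("AAAAAAAAAA", "GAGACC", "TTTT")    # antisense site at 10
  h2 <- scan_sites(a, bsaI)
  expect_equal(h2$strand, "antisense")
  expect_equal(h2$cut_top, 10L + 6L - 11L)       # mirrored offset
  # outside cutter whose cut falls past the sequence end is discarded
  expect_equal(nrow(scan_sites(paste0("AA", "GGTCTC", "TTT"), bsaI)), 0L)
})

test_that("scan_sites agrees with the expand-and-scan oracle", {
  enz <- default_enzymes()
  enz <- enz[pattern_cardinality(enz$site) <= 1024, ]
  set.seed(42)
  for (rep in 1:60) {
    s <- random_seq(sample(50:400, 1))
    e <- enz[sample.int(nrow(enz), 1), ]
    got <- scan_sites(s, e)
    want <- oracle_scan(s, e$site, e$cut_top, e$cut_bottom)
    expect_equal(
      as.data.frame(got[, c("strand", "match_start", "cut_top",
                            "cut_bottom")]),
      want,
      info = paste(e$name, s)
    )
  }
})

test_that("scan_sites agrees with Biostrings matching on random cases", {
  enz <- default_enzymes()
  set.seed(7)
  for (rep in 1:20) {
    s <- random_seq(300)
    e <- enz[sample.int(nrow(enz), 1), ]
    got <- sort(scan_sites(s, e)$match_start)
    sense <- Biostrings::start(Biostrings::matchPattern(
      e$site, Biostrings::DNAString(s), fixed = "subject")) - 1L
    rc <- reverse_complement_pattern(e$site, e$cut_top, e$cut_bottom)
    anti <- Biostrings::start(Biostrings::matchPattern(
      rc$site, Biostrings::DNAString(s), fixed = "subject")) - 1L
    want <- if (rc$site == e$site && rc$cut_top == e$cut_top) {
      sense
    } else {
      c(sense, anti)
    }
    # compare match loci (before the cut-in-bounds filter, which only
    # affects outside cutters at the ends; none lie there in 300-nt cores)
    slen <- 300L
    keep <- want + e$cut_top >= 0 & want + e$cut_top <= slen
    expect_equal(got, sort(unique(want[keep])))
  }
})

test_that("strand closure: reverse-complementing the sequence mirrors hits", {
  enz <- default_enzymes()
  set.seed(11)
  for (rep in 1:20) {
    s <- random_seq(200)
    e <- enz[sample.int(nrow(enz), 1), ]
    h <- scan_sites(s, e)
    hrc <- scan_sites(revcomp(s), e)
    # match intervals must mirror: start' = len - end
    expect_setequal(200L - h$match_end, hrc$match_start)
    # and top-strand cuts must mirror to bottom-strand cuts
    expect_setequal(sort(200L - h$cut_top), sort(hrc$cut_bottom))
  }
})

test_that("digestion fragments partition the amplicon", {
  amp <- paste0(strrep("T", 4), "GAATTC", strrep("T", 4))
  fr <- digest_fragments(amp, ecoRI())
  expect_equal(fr$length, c(5L, 9L))
  expect_equal(sum(fr$length), nchar(amp))
  # no cut -> single fragment
  expect_equal(digest_fragments("TTTTTTTTTT", ecoRI())$length, 10L)
  # two cuts
  amp2 <- paste0(strrep("A", 10), "GAATTC", strrep("A", 10), "GAATTC",
                 strrep("A", 10))
  fr2 <- digest_fragments(amp2, ecoRI())
  expect_equal(length(fr2$length), 3L)
  expect_equal(sum(fr2$length), nchar(amp2))
})

test_that("mining reports enzymes whose cuts differ between alleles", {
  t <- parse_snp_sequence(paste0(strrep("T", 12), "TTT[G/C]AATTCTTT",
                                 strrep("T", 9)), label = "ex")
  res <- mine_discriminating_enzymes(t, ecoRI())
  expect_equal(nrow(res), 1L)
  expect_equal(res$enzyme, "EcoRI")
  dp <- res$discriminated_pairs[[1]]
  expect_equal(dp$allele_i, "G")
  expect_equal(dp$allele_j, "C")
  # allele G cut once, allele C not at all
  expect_length(res$per_allele_cuts[[1]][[1]], 1L)
  expect_length(res$per_allele_cuts[[1]][[2]], 0L)
})

test_that("tri-allelic mining reports exactly the differing pairs", {
  t <- parse_snp_sequence(paste0(strrep("T", 12), "TTT[G/C/A]AATTCTTT",
                                 strrep("T", 9)), label = "tri")
  res <- mine_discriminating_enzymes(t, ecoRI())
  dp <- res$discriminated_pairs[[1]]
  expect_equal(nrow(dp), 2L)
  expect_setequal(paste(dp$allele_i, dp$allele_j), c("G C", "G A"))
})

test_that("a template with no site of any enzyme yields no results", {
  t <- parse_snp_sequence(paste0(strrep("T", 40), "[A/C]", strrep("T", 40)))
  expect_equal(nrow(mine_discriminating_enzymes(t, ecoRI())), 0L)
})

test_that("sites outside the variant window never discriminate a substitution", {
  # EcoRI site far in the flank, identical in both alleles
  t <- parse_snp_sequence(paste0("GAATTC", strrep("T", 60), "[A/C]",
                                 strrep("T", 40)))
  res <- mine_discriminating_enzymes(t, ecoRI())
  expect_equal(nrow(res), 0L)
})

test_that("an indel's pure coordinate shift does not count as discrimination", {
  # site entirely downstream of the indel: cuts shift but anchor-normalize away
  t <- parse_snp_sequence(paste0(strrep("T", 30), "[-/ACA]", strrep("T", 10),
                                 "GAATTC", strrep("T", 20)))
  res <- mine_discriminating_enzymes(t, ecoRI())
  expect_equal(nrow(res), 0L)
  # but an indel that removes the site does discriminate
  t2 <- parse_snp_sequence(paste0(strrep("T", 30), "G[-/AATTC]",
                                  strrep("T", 30)))
  res2 <- mine_discriminating_enzymes(t2, ecoRI())
  expect_equal(nrow(res2), 1L)
})

test_that("window must cover the longest recognition pattern", {
  t <- parse_snp_sequence(paste0(strrep("T", 30), "[A/C]", strrep("T", 30)))
  expect_error(mine_discriminating_enzymes(t, ecoRI(), window = 3L),
               "window")
})

test_that("genotype fragment tables follow the digestion per allele", {
  set.seed(31)
  fl <- gsub("GAATTC", "GAATAC", random_seq(80))
  fr <- gsub("GAATTC", "GAATAC", random_seq(80))
  t <- parse_snp_sequence(paste0(fl, "CTT[G/C]AATTCT", fr))
  pairs <- design_natural_pair(t, constraints = rflp_constraints(
    product = c(80L, 160L)))
  expect_gt(nrow(pairs), 0L)
  gt <- genotype_fragment_table(pairs[1, ], t, ecoRI())
  expect_s3_class(gt, "rflp_digest_tbl")
  expect_equal(gt$n_fragments, c(2L, 1L))
  expect_equal(vapply(gt$fragments, sum, integer(1)), gt$amplicon_length)
  # indel: per-allele amplicon lengths differ by the indel length
  ti <- parse_snp_sequence(paste0(fl, "CT[-/AGG]CT", fr))
  pi <- design_natural_pair(ti, constraints = rflp_constraints(
    product = c(80L, 160L)))
  gti <- genotype_fragment_table(pi[1, ], ti, ecoRI())
  expect_equal(diff(gti$amplicon_length), 3L)
})

test_that("primers that do not bracket the variant are an error", {
  t <- parse_snp_sequence(paste0(strrep("A", 40), "C[G/T]", strrep("A", 40)))
  fake <- tibble::tibble(f_start = 50L, f_length = 18L, r_start = 70L,
                         r_length = 18L, which = 1L)
  expect_error(genotype_fragment_table(fake, t, ecoRI()),
               "do not bracket")
})

test_that("random digests conserve total length", {
  enz <- default_enzymes()
  set.seed(99)
  for (rep in 1:200) {
    s <- random_seq(sample(30:300, 1))
    e <- enz[sample.int(nrow(enz), 1), ]
    fr <- digest_fragments(s, e)
    expect_equal(sum(fr$length), nchar(s))
    expect_equal(nrow(fr), length(unique(
      fr$start)))
  }
})
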