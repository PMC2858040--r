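# Synthetic fixture generation: SNP templates with known (planted)
# allele-discriminating restriction sites, plus the enzyme table and the
# ground truth.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# expansion-based top-strand cut positions; generation-time ground-truth
# check, kept independent of the bit-mask scanning engine
oracle_top_cuts <- function(sequence, site, cut_top, cut_bottom) {
  slen <- nchar(sequence)
  cuts <- integer(0)
  scan_one <- function(pat, ct) {
    L <- nchar(pat)
    if (L > slen) return(integer(0))
    subs <- substring(sequence, 1:(slen - L + 1L), L:slen)
    starts <- which(subs %in% expand_pattern(pat, cap = 65536L)) - 1L
    starts + ct
  }
  rc <- reverse_complement_pattern(site, cut_top, cut_bottom)
  cuts <- c(scan_one(site, cut_top), scan_one(rc$site, rc$cut_top))
  cuts <- cuts[cuts >= 0L & cuts <= slen]
  sort(cuts)
}

planted_discriminates <- function(template, enzyme) {
  reals <- realize_alleles(template, 1L)
  keys <- lapply(seq_len(nrow(reals)), function(a) {
    cuts <- oracle_top_cuts(reals$sequence[a], enzyme$site,
                            enzyme$cut_top, enzyme$cut_bottom)
    sort(anchor_cut_keys(cuts, reals$var_start[a], reals$var_end[a]))
  })
  !identical(keys[[1]], keys[[2]])
}

plant_one <- function(enz_row, type, flank_len, label) {
  w <- expand_pattern(enz_row$site, cap = 256L)
  w <- w[sample.int(length(w), 1L)]
  sets <- .IUPAC_SETS[strsplit(enz_row$site, "", fixed = TRUE)[[1]]]
  L <- nchar(w)
  n_alt <- switch(type, bi = 1L, tri = 2L, tetra = 3L, indel = 0L)
  if (type == "indel") {
    # deletion allele removes the interior of the site
    core <- substr(w, 2L, L - 1L)
    fl <- random_dna(flank_len); fr <- random_dna(flank_len)
    backbone <- paste0(fl, substr(w, 1L, 1L), substr(w, L, L), fr)
    alleles <- c(core, "")
    pos <- flank_len + 1L
  } else {
    ok_j <- which(vapply(sets, function(s) 4L - length(s) >= n_alt,
                         logical(1)))
    if (length(ok_j) == 0L) return(NULL)
    j <- ok_j[sample.int(length(ok_j), 1L)]
    ref <- substr(w, j, j)
    breakers <- setdiff(c("A", "C", "G", "T"), sets[[j]])
    alts <- breakers[sample.int(length(breakers), n_alt)]
    fl <- random_dna(flank_len); fr <- random_dna(flank_len)
    backbone <- paste0(fl, substr(w, 1L, j - 1L), substr(w, j + 1L, L), fr)
    alleles <- c(ref, alts)
    pos <- flank_len + j - 1L
  }
  t <- new_snp_template(label, backbone,
                        tibble(position = as.integer(pos),
                               alleles = list(alleles),
                               source = "bracket"))
  if (!planted_discriminates(t, enz_row)) return(NULL)
  list(template = t, enzyme = enz_row$name, pair = "1/2",
       site_start = flank_len)
}

random_template <- function(type, flank_len, label) {
  bases <- c("A", "C", "G", "T")
  alleles <- switch(
    type,
    bi = sample(bases, 2L),
    tri = sample(bases, 3L),
    tetra = sample(bases, 4L),
    indel = c(random_dna(sample(1:3, 1L)), "")
  )
  new_snp_template(label, random_dna(2L * flank_len),
                   tibble(position = as.integer(flank_len),
                          alleles = list(alleles), source = "bracket"))
}

#' Generate a synthetic SNP/enzyme fixture with known ground truth
#'
#' Emulates the tool's inputs: SNP templates (bi/tri/tetra-allelic and
#' indel variants with random flanks) and a restriction-enzyme table. A
#' stated fraction of the templates is constructed to contain a planted
#' allele-discriminating site for a known enzyme — the first-listed allele
#' completes a concrete expansion of the enzyme's recognition sequence and
#' every alternative allele breaks it (for indels, the deletion removes the
#' site's interior). Each planted template is checked at generation time
#' against an expansion-based digestion oracle, and the ground truth is
#' recorded alongside. Deterministic for a fixed seed; the caller's RNG
#' state is left untouched.
#'
#' @param seed Integer seed.
#' @param n_templates Number of templates, default 10.
#' @param flank_len Flank length on each side of the variant (>= 30),
#'   default 150 — the order of magnitude of typical SNP flanking sequences,
#'   and long enough for amplicons in the default 100-500 nt product range
#'   even when a mutagenic primer is pinned at the variant.
#' @param allele_spec Named probabilities over variant types
#'   `c(bi=, tri=, tetra=, indel=)`.
#' @param planted_fraction Fraction of templates carrying a planted site,
#'   default 0.7.
#' @param enzymes Enzyme tibble; defaults to [default_enzymes()]. Planting
#'   only uses enzymes with expansion cardinality at most 16.
#' @return A list with `templates` (tibble: `label`, `planted`, `type`,
#'   `template` list-column), `enzymes` (the enzyme tibble) and `truth`
#'   (tibble: `label`, `enzyme`, `pair`, `site_start`, `type` for planted
#'   templates).
#' @export
#' @examples
#' fix <- generate_fixture(seed = 1, n_templates = 4)
#' fix$truth
generate_fixture <- function(seed, n_templates = 10L, flank_len = 150L,
                             allele_spec = c(bi = 0.55, tri = 0.15,
                                             tetra = 0.10, indel = 0.20),
                             planted_fraction = 0.7, enzymes = NULL) {
  if (flank_len < 30L) abort("`flank_len` must be at least 30")
  enzymes <- enzymes %||% default_enzymes()
  plantable <- enzymes[pattern_cardinality(enzymes$site) <= 16 &
                         nchar(enzymes$site) >= 4L, ]
  if (nrow(plantable) == 0L) abort("no plantable enzyme in the table")
  allele_spec <- allele_spec / sum(allele_spec)
  n_planted <- round(planted_fraction * n_templates)

  with_private_seed(seed, {
    types <- sample(names(allele_spec), n_templates, replace = TRUE,
                    prob = allele_spec)
    rows <- vector("list", n_templates)
    truth <- list()
    for (i in seq_len(n_templates)) {
      label <- sprintf("fix%03d", i)
      if (i <= n_planted) {
        pl <- NULL
        for (attempt in 1:60) {
          er <- plantable[sample.int(nrow(plantable), 1L), ]
          pl <- plant_one(er, types[i], flank_len, label)
          if (!is.null(pl)) break
        }
        if (is.null(pl)) {
          abort("failed to plant a discriminating site (unexpected)")
        }
        tmpl <- pl$template
        rows[[i]] <- tibble(label = label, planted = TRUE, type = types[i],
                            template = list(tmpl))
        truth[[length(truth) + 1L]] <- tibble(
          label = label, enzyme = pl$enzyme, pair = pl$pair,
          site_start = pl$site_start, type = types[i]
        )
      } else {
        rows[[i]] <- tibble(label = label, planted = FALSE, type = types[i],
                            template = list(random_template(types[i],
                                                            flank_len,
                                                            label)))
      }
    }
    list(
      templates = bind_rows(rows),
      enzymes = enzymes,
      truth = if (length(truth)) bind_rows(truth) else
        tibble(label = character(), enzyme = character(), pair = character(),
               site_start = integer(), type = character())
    )
  })
}

#' Write a fixture to disk
#'
#' Serializes a [generate_fixture()] result as FASTA (bracket notation),
#' an enzyme TSV and a ground-truth JSON file.
#'
#' @param fixture A fixture list.
#' @param dir Output directory (created if missing).
#' @return The three file paths, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "templates.fasta")
  tsv <- file.path(dir, "enzymes.tsv")
  js <- file.path(dir, "truth.json")
  write_snp_fasta(fixture$templates, fa)
  write_enzyme_table(fixture$enzymes, tsv)
  writeLines(jsonlite::toJSON(fixture$truth, dataframe = "rows",
                              auto_unbox = TRUE, digits = NA, pretty = TRUE),
             js, useBytes = TRUE)
  invisible(c(fasta = fa, enzymes = tsv, truth = js))
}
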