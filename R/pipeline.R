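# End-to-end assay pipeline and report writers.

#' Run the full PCR-RFLP assay pipeline
#'
#' For every template and every variant: mine discriminating enzymes, design
#' natural primer pairs, attach per-genotype digestion fragment tables for
#' the top pair and each discriminating enzyme, and design mutagenic primers
#' when requested (always, or only when no natural enzyme exists, or never).
#'
#' @param fasta Path to a FASTA file of SNP templates, or `NULL` when
#'   `templates` is given directly.
#' @param rebase Path to an enzyme table, or `NULL` when `enzymes` is given.
#' @param templates Optional template tibble ([read_snp_fasta()]) or list of
#'   `snp_template` objects.
#' @param enzymes Optional enzyme tibble.
#' @param constraints An [rflp_constraints()] block.
#' @param window Mining window half-width (nt), default 30.
#' @param mutagenic `"auto"` (design mutagenic primers only when the natural
#'   section is empty), `"always"`, or `"never"`.
#' @param max_profiles Cap on the number of enzymes per report for which
#'   digestion profiles are tabulated, default 5.
#' @return A tibble of class `rflp_report_set`, one row per template x
#'   variant: `label`, `which`, `variant_position` (1-based display),
#'   `alleles`, `variant_type`, counts, and list-columns `natural` (mining
#'   results), `natural_pairs`, `profiles` (per-enzyme genotype fragment
#'   tables) and `mutagenic`, plus a `notes` column explaining empty
#'   sections. Output is a pure function of the inputs (no clock or
#'   environment leakage), so identical inputs give identical reports.
#' @export
run_rflp_pipeline <- function(fasta = NULL, rebase = NULL, templates = NULL,
                              enzymes = NULL,
                              constraints = rflp_constraints(),
                              window = 30L,
                              mutagenic = c("auto", "always", "never"),
                              max_profiles = 5L) {
  mutagenic <- match.arg(mutagenic)
  if (is.null(templates)) {
    if (is.null(fasta)) abort("provide `fasta` or `templates`")
    templates <- read_snp_fasta(fasta)
  }
  if (is.null(enzymes)) {
    if (is.null(rebase)) abort("provide `rebase` or `enzymes`")
    enzymes <- read_enzyme_table(rebase)
  }
  ts <- if (is.data.frame(templates)) templates$template else templates
  if (length(ts) == 0L) abort("no parseable templates")

  reports <- list()
  for (t in ts) {
    for (w in seq_len(nrow(t$variants))) {
      al <- t$variants$alleles[[w]]
      mined <- mine_discriminating_enzymes(t, enzymes, which = w,
                                           window = window)
      # rank mined enzymes: non-degenerate first, then price (unpriced
      # last), then name
      if (nrow(mined)) {
        mined <- mined[order(mined$degeneracy_class == "IUPAC",
                             ifelse(is.na(mined$price), Inf, mined$price),
                             mined$enzyme, method = "radix"), ]
      }
      pairs <- design_natural_pair(t, which = w, constraints = constraints)
      profiles <- list()
      if (nrow(mined) && nrow(pairs)) {
        top <- head(seq_len(nrow(mined)), max_profiles)
        profiles <- lapply(top, function(i) {
          genotype_fragment_table(pairs[1L, ], t,
                                  enzymes[enzymes$name == mined$enzyme[i], ],
                                  which = w)
        })
        names(profiles) <- mined$enzyme[top]
      }
      mut <- if (mutagenic == "always" ||
                 (mutagenic == "auto" && nrow(mined) == 0L)) {
        design_mutagenic(t, enzymes, which = w, constraints = constraints)
      } else {
        empty_mutagenic("not requested")
      }
      notes <- character(0)
      if (nrow(mined) == 0L) notes <- c(notes, "no natural discriminating enzyme")
      if (nrow(pairs) == 0L) {
        notes <- c(notes, paste0("no natural primer pair: ",
                                 attr(pairs, "reason")))
      }
      if (nrow(mut) == 0L && !is.null(attr(mut, "reason")) &&
          !identical(attr(mut, "reason"), "not requested")) {
        notes <- c(notes, paste0("no mutagenic design: ", attr(mut, "reason")))
      }
      reports[[length(reports) + 1L]] <- tibble(
        label = t$label, which = as.integer(w),
        variant_position = t$variants$position[w] + 1L,
        alleles = paste(ifelse(al == "", "-", al), collapse = "/"),
        variant_type = variant_type(al),
        n_natural_enzymes = nrow(mined),
        n_natural_pairs = nrow(pairs),
        n_mutagenic = nrow(mut),
        natural = list(mined), natural_pairs = list(pairs),
        profiles = list(profiles), mutagenic = list(mut),
        notes = paste(notes, collapse = "; ")
      )
    }
  }
  out <- bind_rows(reports)
  class(out) <- c("rflp_report_set", class(out))
  out
}

report_to_list <- function(reports) {
  lapply(seq_len(nrow(reports)), function(i) {
    r <- reports[i, ]
    nat <- r$natural[[1]]
    list(
      label = r$label, which = r$which,
      variant_position = r$variant_position, alleles = r$alleles,
      variant_type = r$variant_type, notes = r$notes,
      natural_enzymes = lapply(seq_len(nrow(nat)), function(k) {
        dp <- nat$discriminated_pairs[[k]]
        list(enzyme = nat$enzyme[k], site = nat$site[k],
             degeneracy_class = nat$degeneracy_class[k],
             suppliers = nat$suppliers[k], price = nat$price[k],
             per_allele_cuts = lapply(nat$per_allele_cuts[[k]],
                                      function(x) x + 1L),
             discriminated_pairs = paste(dp$i, dp$j, sep = "/"))
      }),
      natural_pairs = pair_rows_to_list(r$natural_pairs[[1]]),
      profiles = lapply(r$profiles[[1]], function(p) {
        lapply(seq_len(nrow(p)), function(a) {
          list(allele = ifelse(p$allele[a] == "", "-", p$allele[a]),
               amplicon_length = p$amplicon_length[a],
               fragments = p$fragments[[a]])
        })
      }),
      mutagenic = pair_rows_to_list(r$mutagenic[[1]])
    )
  })
}

pair_rows_to_list <- function(p) {
  lapply(seq_len(nrow(p)), function(i) {
    row <- as.list(p[i, setdiff(names(p), c("product_lengths",
                                            "cutting_alleles"))])
    row <- lapply(row, function(x) if (is.list(x)) x[[1]] else x)
    # display coordinates: 1-based
    for (cc in intersect(names(row), c("f_start", "r_start", "site_start"))) {
      row[[cc]] <- row[[cc]] + 1L
    }
    if ("product_lengths" %in% names(p)) {
      row$product_lengths <- p$product_lengths[[i]]
    }
    if ("cutting_alleles" %in% names(p)) {
      row$cutting_alleles <- p$cutting_alleles[[i]]
    }
    row
  })
}

#' Write assay reports
#'
#' `json` is the lossless canonical form (deterministic byte-for-byte for
#' identical inputs); `tsv` flattens to one row per enzyme x allele-pair
#' (see [tidy.rflp_report_set()]); `text` renders a human-readable summary,
#' with 1-based coordinates and the mutagenic base in lowercase in the
#' primer sequence.
#'
#' @param reports An `rflp_report_set`.
#' @param file Output path or connection.
#' @param format `"json"`, `"tsv"` or `"text"`.
#' @return The output lines, invisibly.
#' @export
write_report <- function(reports, file = NULL,
                         format = c("json", "tsv", "text")) {
  format <- match.arg(format)
  lines <- switch(
    format,
    json = strsplit(as.character(jsonlite::toJSON(
      report_to_list(reports), auto_unbox = TRUE, digits = 8, null = "null",
      na = "null", pretty = TRUE)), "\n", fixed = TRUE)[[1]],
    tsv = {
      flat <- tidy(reports)
      flat <- lapply(flat, function(col) {
        if (is.list(col)) vapply(col, function(x) paste(x, collapse = ","),
                                 character(1)) else col
      })
      flat <- as_tibble(flat)
      c(paste(names(flat), collapse = "\t"),
        do.call(paste, c(as.list(flat), sep = "\t")))
    },
    text = render_text_report(reports)
  )
  if (!is.null(file)) writeLines(lines, file, useBytes = TRUE)
  invisible(lines)
}

render_text_report <- function(reports) {
  out <- character(0)
  for (i in seq_len(nrow(reports))) {
    r <- reports[i, ]
    out <- c(out, sprintf("== %s | variant %d at position %d [%s] (%s) ==",
                          r$label, r$which, r$variant_position, r$alleles,
                          r$variant_type))
    nat <- r$natural[[1]]
    out <- c(out, sprintf("Natural restriction enzymes: %d", nrow(nat)))
    for (k in seq_len(nrow(nat))) {
      dp <- nat$discriminated_pairs[[k]]
      out <- c(out, sprintf(
        "  %s (%s, %s, price %s): discriminates %s",
        nat$enzyme[k], nat$site[k], nat$degeneracy_class[k],
        ifelse(is.na(nat$price[k]), "-", format(nat$price[k])),
        paste(sprintf("%s|%s", ifelse(dp$allele_i == "", "-", dp$allele_i),
                      ifelse(dp$allele_j == "", "-", dp$allele_j)),
              collapse = ", ")))
    }
    np <- r$natural_pairs[[1]]
    if (nrow(np)) {
      out <- c(out, render_pair_lines(np[1, ], "natural"))
    }
    for (nm in names(r$profiles[[1]])) {
      p <- r$profiles[[1]][[nm]]
      out <- c(out, sprintf("  Fragments with %s:", nm))
      for (a in seq_len(nrow(p))) {
        out <- c(out, sprintf("    allele %s (%d nt): %s",
                              ifelse(p$allele[a] == "", "-", p$allele[a]),
                              p$amplicon_length[a],
                              paste(p$fragments[[a]], collapse = " + ")))
      }
    }
    mut <- r$mutagenic[[1]]
    out <- c(out, sprintf("Mutagenic designs: %d", nrow(mut)))
    for (k in seq_len(nrow(mut))) {
      out <- c(out, sprintf(
        "  %s via %s (%s): introduced %s->%s at primer offset %d",
        mut$enzyme[k], mut$site[k], mut$mutated_primer[k],
        mut$original_base[k], mut$introduced_base[k],
        mut$mismatch_offset[k] + 1L))
      out <- c(out, render_pair_lines(mut[k, ], "mutagenic"))
    }
    if (nzchar(r$notes)) out <- c(out, paste0("Notes: ", r$notes))
    out <- c(out, "")
  }
  out
}

render_pair_lines <- function(p, kind) {
  c(sprintf(
    "  %s F: %s  pos %d  len %d  Tm %.2f", kind, p$f_seq, p$f_start + 1L,
    p$f_length, p$f_tm),
    sprintf(
      "  %s R: %s  pos %d  len %d  Tm %.2f  dTm %.2f  product %d", kind,
      p$r_seq, p$r_start + 1L, p$r_length, p$r_tm, p$tm_diff,
      p$product_length))
}
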