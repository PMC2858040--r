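# broom-style tidiers and plotting for report and digest objects.

#' Tidy an assay report set
#'
#' Flattens a [run_rflp_pipeline()] result into one row per enzyme x
#' discriminated allele pair (natural section) plus one row per mutagenic
#' design, the layout used by the TSV report writer.
#'
#' @param x An `rflp_report_set`.
#' @param ... Unused.
#' @return A tibble with `label`, `variant_position` (1-based), `alleles`,
#'   `variant_type`, `section`, `enzyme`, `site`, `degeneracy_class`,
#'   `price`, `allele_pair`, primer columns of the top pair of the section
#'   and `product_length`.
#' @export
tidy.rflp_report_set <- function(x, ...) {
  rows <- list()
  for (i in seq_len(nrow(x))) {
    r <- x[i, ]
    nat <- r$natural[[1]]
    np <- r$natural_pairs[[1]]
    top <- if (nrow(np)) np[1, ] else NULL
    for (k in seq_len(nrow(nat))) {
      dp <- nat$discriminated_pairs[[k]]
      for (q in seq_len(nrow(dp))) {
        rows[[length(rows) + 1L]] <- tibble(
          label = r$label, variant_position = r$variant_position,
          alleles = r$alleles, variant_type = r$variant_type,
          section = "natural", enzyme = nat$enzyme[k], site = nat$site[k],
          degeneracy_class = nat$degeneracy_class[k], price = nat$price[k],
          allele_pair = sprintf("%s|%s",
                                ifelse(dp$allele_i[q] == "", "-",
                                       dp$allele_i[q]),
                                ifelse(dp$allele_j[q] == "", "-",
                                       dp$allele_j[q])),
          f_seq = if (is.null(top)) NA_character_ else top$f_seq,
          r_seq = if (is.null(top)) NA_character_ else top$r_seq,
          tm_diff = if (is.null(top)) NA_real_ else top$tm_diff,
          product_length = if (is.null(top)) NA_integer_ else
            top$product_length
        )
      }
    }
    mut <- r$mutagenic[[1]]
    for (k in seq_len(nrow(mut))) {
      rows[[length(rows) + 1L]] <- tibble(
        label = r$label, variant_position = r$variant_position,
        alleles = r$alleles, variant_type = r$variant_type,
        section = "mutagenic", enzyme = mut$enzyme[k], site = mut$site[k],
        degeneracy_class = mut$degeneracy_class[k], price = mut$price[k],
        allele_pair = paste(mut$cutting_alleles[[k]], collapse = ","),
        f_seq = mut$f_seq[k], r_seq = mut$r_seq[k],
        tm_diff = mut$tm_diff[k], product_length = mut$product_length[k]
      )
    }
  }
  if (length(rows)) bind_rows(rows) else tibble(
    label = character(), variant_position = integer(), alleles = character(),
    variant_type = character(), section = character(), enzyme = character(),
    site = character(), degeneracy_class = character(), price = numeric(),
    allele_pair = character(), f_seq = character(), r_seq = character(),
    tm_diff = numeric(), product_length = integer()
  )
}

#' One-row summary of an assay report set
#'
#' @param x An `rflp_report_set`.
#' @param ... Unused.
#' @return A one-row tibble: number of reports, templates, reports with at
#'   least one natural enzyme, with a natural pair, with mutagenic designs,
#'   and the number of distinct enzymes used.
#' @export
glance.rflp_report_set <- function(x, ...) {
  tibble(
    n_reports = nrow(x),
    n_templates = length(unique(x$label)),
    n_with_natural_enzyme = sum(x$n_natural_enzymes > 0L),
    n_with_natural_pair = sum(x$n_natural_pairs > 0L),
    n_with_mutagenic = sum(x$n_mutagenic > 0L),
    n_enzymes_used = length(unique(unlist(lapply(x$natural,
                                                 function(m) m$enzyme))))
  )
}

#' Gel-style plot of a genotype fragment table
#'
#' Renders each allele as a lane with one band per restriction fragment,
#' larger fragments at the top (log scale), mimicking an agarose gel.
#'
#' @param object An `rflp_digest_tbl` from [genotype_fragment_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rflp_digest_tbl <- function(object, ...) {
  df <- tidyr::unnest(
    tibble(
      lane = factor(ifelse(object$allele == "", "-", object$allele),
                    levels = unique(ifelse(object$allele == "", "-",
                                           object$allele))),
      fragment = object$fragments
    ),
    "fragment"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lane, y = .data$fragment)) +
    ggplot2::geom_tile(width = 0.6, height = 0.012, fill = "grey15") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "allele", y = "fragment size (nt)",
      title = paste0("Digestion pattern",
                     if (!is.null(attr(object, "enzyme")))
                       paste0(" with ", attr(object, "enzyme")) else "")
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.rflp_digest_tbl
#' @param profile An `rflp_digest_tbl`.
#' @export
plot_gel <- function(profile, ...) autoplot(profile, ...)

#' @importFrom rlang .data
NULL
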