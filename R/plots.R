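#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_text geom_point
#'   geom_segment scale_fill_gradient2 labs theme_minimal
NULL

#' Plot an energy matrix as a position-by-nucleotide heatmap
#'
#' Tiles show the delta-delta-G of mutating each strand-A fragment
#' position to each nucleotide; the lowest-energy (consensus) cell per
#' position is outlined by its letter.
#'
#' @param object a `dbd_energy_matrix`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.dbd_energy_matrix <- function(object, ...) {
  a <- as_tibble(object)[object$strand == "A", ]
  long <- tidyr::pivot_longer(a, cols = dplyr::all_of(NUCS),
                              names_to = "nucleotide", values_to = "ddg")
  cons <- consensus_sequence(object)
  ggplot(long, aes(x = .data$position, y = .data$nucleotide,
                   fill = .data$ddg)) +
    geom_tile() +
    geom_text(data = cons, aes(x = .data$position, y = .data$nucleotide),
              label = "*", inherit.aes = FALSE) +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                         midpoint = 0, name = "ddG\n(kcal/mol)") +
    ggplot2::facet_wrap(~domain_id, ncol = 1L) +
    labs(x = "fragment position (strand A)", y = NULL,
         title = "Mutational-scan energy matrix",
         subtitle = "* marks the lowest-energy (consensus) nucleotide") +
    theme_minimal()
}

#' Plot a gene rank table as a density lollipop chart
#'
#' @param object a `dbd_gene_rank` tibble from [count_and_rank()].
#' @param top_only plot only the top-table rows (default `TRUE`).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.dbd_gene_rank <- function(object, top_only = TRUE, ...) {
  d <- as_tibble(object)
  if (top_only) d <- d[d$top, ]
  d$gene_id <- stats::reorder(d$gene_id, d$density)
  ggplot(d, aes(x = .data$density, y = .data$gene_id)) +
    geom_segment(aes(x = 0, xend = .data$density, yend = .data$gene_id),
                 colour = "grey60") +
    geom_point(aes(size = .data$n_sites), colour = "#2166ac") +
    labs(x = "binding-site density (sites/bp)", y = NULL,
         size = "sites",
         title = "Genes ranked by binding-site density") +
    theme_minimal()
}

#' Plot a contact map
#'
#' Residue-by-base grid of contacts, faceted by domain and coloured by
#' contact class (protein backbone vs side chain).
#'
#' @param object a `dbd_contact_map`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.dbd_contact_map <- function(object, ...) {
  d <- as_tibble(object) |>
    mutate(
      residue = format_residue_token(.data$aa, .data$prot_chain,
                                     .data$prot_number),
      base = format_base_token(.data$base, .data$strand, .data$position)
    )
  ggplot(d, aes(x = .data$base, y = .data$residue,
                fill = .data$contact_class)) +
    geom_tile(colour = "white") +
    ggplot2::facet_wrap(~domain_id, scales = "free") +
    labs(x = "DNA base (strand/position)", y = "protein residue",
         fill = "contact class", title = "Protein-DNA contact map") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
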