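#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a pipeline run report
#'
#' One row per (domain, gene): the per-gene site counts, lengths,
#' densities and ranks from every retained domain.
#'
#' @param x a `dbd_run_report` from [run_pipeline()].
#' @param ... unused.
#' @return a tibble with columns `domain_id`, `gene_id`, `n_sites`,
#'   `length`, `density`, `rank`, `top`.
#' @export
tidy.dbd_run_report <- function(x, ...) {
  purrr::imap_dfr(x$domains, function(d, dom) {
    mutate(as_tibble(d$rank_table), domain_id = dom, .before = 1L)
  })
}

#' Glance at a pipeline run report
#'
#' @param x a `dbd_run_report`.
#' @param ... unused.
#' @return a one-row tibble: domains retained, genes threaded, total
#'   hits, mean consensus GC fraction, version.
#' @export
glance.dbd_run_report <- function(x, ...) {
  tibble(
    n_domains_retained = length(x$domains),
    n_genes = nrow(x$domains[[1L]]$rank_table),
    n_hits = sum(purrr::map_int(x$domains, "n_hits")),
    mean_consensus_gc = mean(purrr::map_dbl(x$domains, "gc_fraction")),
    version = x$version
  )
}

#' Glance at a binding profile
#'
#' @param x a `dbd_binding_profile` from [compile_profile()].
#' @param ... unused.
#' @return a one-row tibble: domain, fragment length, number of contact
#'   positions, number of wildcard positions, mean allowed-set size.
#' @export
glance.dbd_binding_profile <- function(x, ...) {
  set_sizes <- lengths(x$allowed)
  tibble(
    domain_id = attr(x, "domain_id"),
    length = attr(x, "length"),
    n_contact_positions = nrow(x),
    n_wildcards = attr(x, "length") - nrow(x),
    mean_allowed = mean(set_sizes)
  )
}
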