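# broom-style accessors for the fitted/derived objects.

#' Tidy an enrichment table
#'
#' @param x A `mirhost_enrichment` tibble.
#' @param ... Unused.
#' @return A plain tibble with the overlap list-column flattened to a
#'   comma-joined string.
#' @export
tidy.mirhost_enrichment <- function(x, ...) {
  x |>
    mutate(overlap = map_chr(.data$overlap, comma_join)) |>
    as_tibble()
}

#' One-row summary of an enrichment run
#'
#' @param x A `mirhost_enrichment` tibble.
#' @param alpha Significance level on the q-value.
#' @param ... Unused.
#' @return A one-row tibble: `mode`, `n_terms`, `n_query`, `n_universe`,
#'   `n_significant`, `top_term`.
#' @export
glance.mirhost_enrichment <- function(x, alpha = 0.05, ...) {
  tibble(
    mode = if (nrow(x) > 0) x$mode[1] else NA_character_,
    n_terms = nrow(x),
    n_query = if (nrow(x) > 0) x$n[1] else 0L,
    n_universe = if (nrow(x) > 0) x$N[1] else 0L,
    n_significant = sum(x$qvalue < alpha),
    top_term = if (nrow(x) > 0) x$term_id[1] else NA_character_
  )
}

#' Tidy a host-gene set (its provenance records)
#'
#' @param x A `host_gene_set`.
#' @param ... Unused.
#' @return The provenance tibble: one row per gene <- precursor <- mature
#'   contribution.
#' @export
tidy.host_gene_set <- function(x, ...) as_tibble(x$provenance)

#' One-row summary of a host-gene set
#'
#' @param x A `host_gene_set`.
#' @param ... Unused.
#' @return A one-row tibble with gene and miRNA counts.
#' @export
glance.host_gene_set <- function(x, ...) {
  tibble(
    n_genes = length(x$gene_ids),
    n_dysregulated_mirnas = x$n_dysregulated_mirnas,
    n_intragenic_dysregulated = x$n_intragenic_dysregulated,
    n_unmapped = length(x$unmapped)
  )
}

#' Tidy a co-dysregulation report (per-miRNA detail)
#'
#' @param x A `codys_report`.
#' @param ... Unused.
#' @return A tibble, one row per dysregulated intragenic miRNA: `query_id`,
#'   `hosts` (comma-joined), `codys`.
#' @export
tidy.codys_report <- function(x, ...) {
  x$detail |> mutate(hosts = map_chr(.data$hosts, comma_join))
}

#' One-row summary of a co-dysregulation report
#'
#' @param x A `codys_report`.
#' @param ... Unused.
#' @return A one-row tibble: counts, fraction, percent, overlap p-value.
#' @export
glance.codys_report <- function(x, ...) {
  tibble(
    n_intragenic = x$n_intragenic, n_codys = x$n_codys,
    fraction = x$fraction, percent = x$percent,
    n_host_genes = x$n_host_genes, n_codys_genes = x$n_codys_genes,
    overlap_pvalue = x$overlap_pvalue
  )
}
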