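#' Select dysregulated features from a DE table
#'
#' Selection uses a strict adjusted-p cutoff (`padj < padj_threshold`,
#' default 0.1) with no fold-change requirement by default: both directions
#' of change are kept and labelled. A record at exactly the threshold is not
#' selected.
#'
#' @param records DE tibble from [read_de_table()].
#' @param padj_threshold Strict upper bound on the adjusted p-value, in
#'   (0, 1]. Default 0.1.
#' @param min_abs_log2fc Minimum absolute log2 fold change (inclusive).
#'   Default 0, i.e. no fold-change filter.
#' @return A tibble `feature_id`, `log2fc`, `pvalue`, `padj`, `direction`
#'   (`"up"` for log2fc >= 0, else `"down"`). Empty selection is valid and
#'   warns.
#' @export
select_dysregulated <- function(records, padj_threshold = 0.1, min_abs_log2fc = 0) {
  stopifnot(padj_threshold > 0, padj_threshold <= 1, min_abs_log2fc >= 0)
  out <- records |>
    filter(.data$padj < padj_threshold, abs(.data$log2fc) >= min_abs_log2fc) |>
    mutate(direction = ifelse(.data$log2fc >= 0, "up", "down"))
  if (nrow(out) == 0) {
    warn(sprintf("no feature passes padj < %g (|log2FC| >= %g)",
                 padj_threshold, min_abs_log2fc))
  }
  out
}

#' Build the deduplicated host-gene set for dysregulated miRNAs
#'
#' Applies family expansion ([expand_family_hosts()]) to every selected
#' mature and unions the resulting sense-strand host genes. The union's set
#' semantics implement the cluster-once rule: a cluster of co-hosted
#' precursors contributes its shared host gene exactly once, however many of
#' its matures were selected. Per-contribution provenance (gene <- precursor
#' <- mature, with direction of dysregulation) is retained.
#'
#' @param selected Selection tibble from [select_dysregulated()] (miRNA DE).
#' @param families Family table from [group_mature_families()].
#' @param assignments Assignment table from [classify_contexts()].
#' @return An object of class `host_gene_set`: a list with `gene_ids`
#'   (sorted, deduplicated), `provenance` (tibble with `direction` joined
#'   in), `n_dysregulated_mirnas` (selected matures),
#'   `n_intragenic_dysregulated` (selected matures with at least one
#'   sense-strand host), and `unmapped`.
#' @export
build_host_gene_set <- function(selected, families, assignments) {
  prov <- expand_family_hosts(selected$feature_id, families, assignments)
  prov <- prov |>
    left_join(selected |> select("feature_id", "direction"),
              by = c(query_id = "feature_id"))
  out <- list(
    gene_ids = attr(prov, "genes"),
    provenance = prov,
    n_dysregulated_mirnas = nrow(selected),
    n_intragenic_dysregulated = dplyr::n_distinct(prov$query_id),
    unmapped = attr(prov, "unmapped")
  )
  structure(out, class = "host_gene_set")
}

#' @export
print.host_gene_set <- function(x, ...) {
  cat(sprintf("Host-gene set: %d gene(s) from %d intragenic dysregulated miRNA(s) (of %d selected)\n",
              length(x$gene_ids), x$n_intragenic_dysregulated, x$n_dysregulated_mirnas))
  if (length(x$unmapped) > 0) {
    cat(sprintf("  unmapped query ids: %s\n", comma_join(x$unmapped)))
  }
  cat("  genes:", comma_join(head(x$gene_ids, 10)),
      if (length(x$gene_ids) > 10) "..." else "", "\n")
  invisible(x)
}

#' Quantify co-dysregulation of miRNAs and their host genes
#'
#' Counts, among dysregulated intragenic miRNAs, those embedded in a host
#' gene that is itself dysregulated, and reports the fraction (the unit is
#' miRNAs: two dysregulated miRNAs sharing one dysregulated host count
#' twice). A miRNA whose family maps to several hosts is co-dysregulated if
#' any of them is in the dysregulated-gene list.
#'
#' As an audit statistic not part of the original method, an upper-tail
#' hypergeometric p-value for the overlap is computed at the *gene* level
#' (distinct co-dysregulated hosts among distinct hosts, drawn from a
#' universe of `universe_size` genes containing the dysregulated-gene list),
#' where the draws are exchangeable.
#'
#' @param host_set A `host_gene_set` from [build_host_gene_set()], or a
#'   provenance-like tibble with `query_id` and `host_gene_id` columns.
#' @param dysregulated_genes Character vector of dysregulated gene ids
#'   (e.g. from [select_dysregulated()] on a gene DE table).
#' @param universe_size Number of genes in the background universe; must be
#'   at least the number of distinct hosts plus non-host dysregulated genes.
#' @return An object of class `codys_report`: `n_intragenic`, `n_codys`,
#'   `fraction`, `percent` (rounded to 1 decimal; `NA` when `n_intragenic`
#'   is 0), `n_host_genes`, `n_codys_genes`, `overlap_pvalue`, and the
#'   per-miRNA `detail` tibble.
#' @export
co_dysregulation_report <- function(host_set, dysregulated_genes, universe_size) {
  pairs <- if (inherits(host_set, "host_gene_set")) host_set$provenance else host_set
  stopifnot(all(c("query_id", "host_gene_id") %in% names(pairs)))

  detail <- pairs |>
    group_by(.data$query_id) |>
    summarise(
      hosts = list(sort(unique(.data$host_gene_id))),
      codys = any(.data$host_gene_id %in% dysregulated_genes),
      .groups = "drop"
    )
  n_intragenic <- nrow(detail)
  n_codys <- sum(detail$codys)

  host_genes <- sort(unique(pairs$host_gene_id))
  codys_genes <- intersect(host_genes, dysregulated_genes)
  K <- length(unique(dysregulated_genes))
  if (universe_size < max(length(host_genes), K)) {
    abort("universe_size smaller than the gene lists it must contain")
  }
  overlap_p <- if (length(host_genes) == 0) 1 else {
    hypergeom_upper_tail(length(codys_genes), K, length(host_genes), universe_size)
  }

  structure(list(
    n_intragenic = n_intragenic,
    n_codys = n_codys,
    fraction = if (n_intragenic > 0) n_codys / n_intragenic else NA_real_,
    percent = if (n_intragenic > 0) round(100 * n_codys / n_intragenic, 1) else NA_real_,
    n_host_genes = length(host_genes),
    n_codys_genes = length(codys_genes),
    overlap_pvalue = overlap_p,
    detail = detail
  ), class = "codys_report")
}

#' Render a co-dysregulation report as text lines
#'
#' @param x A `codys_report`.
#' @return Character vector of markdown-ish summary lines.
#' @export
render_codys_report <- function(x) {
  pct <- if (is.na(x$percent)) "NA" else sprintf("%.1f%%", x$percent)
  c(
    "## miRNA / host-gene co-dysregulation",
    sprintf("- dysregulated intragenic miRNAs considered: %d", x$n_intragenic),
    sprintf("- with a dysregulated host gene: %d", x$n_codys),
    sprintf("- co-dysregulation: %s (%d of %d miRNAs)", pct, x$n_codys, x$n_intragenic),
    sprintf("- distinct host genes: %d, of which dysregulated: %d",
            x$n_host_genes, x$n_codys_genes),
    sprintf("- overlap p (hypergeometric upper tail, audit statistic): %.3g",
            x$overlap_pvalue)
  )
}

#' @export
print.codys_report <- function(x, ...) {
  writeLines(render_codys_report(x))
  invisible(x)
}
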