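#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability that a uniform
#' draw of `n` genes from a universe of `N`, of which `K` carry the term,
#' contains at least `k` carriers. Computed through the log-space CDF of
#' [stats::phyper()], so extreme tails do not underflow. Vectorised over
#' `k`, `K`, `n`.
#'
#' @param k Observed overlap count(s), `0 <= k <= min(K, n)`.
#' @param K Term size within the universe.
#' @param n Query size within the universe.
#' @param N Universe size.
#' @return Probability in \[0, 1\].
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  args <- vctrs_recycle(k, K, n, N)
  k <- args[[1]]; K <- args[[2]]; n <- args[[3]]; N <- args[[4]]
  if (any(k != floor(k) | K != floor(K) | n != floor(n) | N != floor(N))) {
    abort("hypergeometric arguments must be integers")
  }
  if (any(N < 1 | K < 0 | n < 0 | K > N | n > N | k < 0 | k > pmin(K, n))) {
    abort("hypergeometric arguments violate 0 <= k <= min(K, n), K <= N, n <= N")
  }
  exp(phyper(k - 1, K, N - K, n, lower.tail = FALSE, log.p = TRUE))
}

vctrs_recycle <- function(...) {
  xs <- list(...)
  len <- max(lengths(xs))
  map(xs, rep_len, length.out = len)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} (m * p_(j) / j)`, clipped at
#' 1, returned in the input order.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues) | pvalues < 0 | pvalues > 1)) {
    abort("p-values must be finite and in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Hypergeometric over-representation analysis against a gene-set collection
#'
#' One-sided (over-representation only) test of a query gene set against
#' every collection term, within an explicit background universe. Query and
#' term memberships are intersected with the universe before testing; terms
#' whose in-universe size falls outside `[min_term_size, max_term_size]` are
#' not tested (degenerate terms produce unstable p-values). Results are
#' sorted by p-value with ties broken by `term_id`, so output is
#' deterministic regardless of input ordering.
#'
#' @param query Character vector of gene ids.
#' @param collection Gene-set tibble from [read_gmt()].
#' @param universe Character vector of background gene ids (non-empty).
#' @param min_term_size,max_term_size In-universe term size bounds
#'   (defaults 3 and 2000).
#' @param adjust Multiple-testing correction: `"BH"` (default) or
#'   `"bonferroni"`.
#' @param mode Label carried into the output (`"host"` or `"target"`),
#'   for side-by-side comparison of the two interpretation modes.
#' @return A tibble of class `mirhost_enrichment`: `term_id`, `description`,
#'   `k`, `K`, `n`, `N`, `fold_enrichment`, `pvalue`, `qvalue`, `overlap`
#'   (list-column of overlapping gene ids), `mode`.
#' @export
enrich <- function(query, collection, universe,
                   min_term_size = 3, max_term_size = 2000,
                   adjust = c("BH", "bonferroni"), mode = "host") {
  adjust <- match.arg(adjust)
  universe <- unique(universe)
  if (length(universe) == 0) abort("empty universe")
  q <- intersect(unique(query), universe)

  empty <- tibble(term_id = character(0), description = character(0),
                  k = integer(0), K = integer(0), n = integer(0), N = integer(0),
                  fold_enrichment = numeric(0), pvalue = numeric(0),
                  qvalue = numeric(0), overlap = list(), mode = character(0))
  class(empty) <- c("mirhost_enrichment", class(tibble()))
  if (length(q) == 0) {
    warn("enrich: query has no gene in the universe")
    return(empty)
  }

  members <- map(collection$genes, intersect, universe)
  Ksz <- lengths(members)
  keep <- Ksz >= min_term_size & Ksz <= max_term_size
  if (!any(keep)) return(empty)

  overlap <- map(members[keep], intersect, q)
  k <- lengths(overlap)
  K <- Ksz[keep]
  n <- length(q)
  N <- length(universe)
  p <- hypergeom_upper_tail(k, K, n, N)
  qv <- if (adjust == "BH") bh_adjust(p) else pmin(1, p * length(p))

  out <- tibble(
    term_id = collection$term_id[keep],
    description = collection$description[keep],
    k = as.integer(k), K = as.integer(K), n = as.integer(n), N = as.integer(N),
    fold_enrichment = (k / n) / (K / N),
    pvalue = p, qvalue = qv,
    overlap = map(overlap, sort),
    mode = mode
  ) |>
    arrange(.data$pvalue, .data$term_id)
  class(out) <- c("mirhost_enrichment", class(tibble()))
  out
}

#' Target-gene enrichment mode
#'
#' The comparison mode: instead of host genes, the union of precomputed
#' predicted target genes of the selected miRNAs is tested against the
#' collection. Selected miRNAs absent from the target map are reported in
#' the `unmapped` attribute, not an error (prediction coverage is never
#' complete).
#'
#' @param selected_ids Character vector of selected (dysregulated) miRNA ids.
#' @param target_map Tibble `mirna_id`, `gene_id` from [read_target_map()].
#' @param collection,universe,... Passed to [enrich()].
#' @return A `mirhost_enrichment` tibble with `mode = "target"` and
#'   attributes `query` (the target-gene union) and `unmapped`.
#' @export
target_set_enrichment <- function(selected_ids, target_map, collection, universe, ...) {
  selected_ids <- unique(selected_ids)
  hit <- target_map |> filter(.data$mirna_id %in% selected_ids)
  unmapped <- setdiff(selected_ids, hit$mirna_id)
  targets <- sort(unique(hit$gene_id))
  out <- if (length(targets) == 0) {
    warn("target_set_enrichment: no target gene for the selected miRNAs")
    suppressWarnings(enrich(character(0), collection, universe,
                            mode = "target", ...))
  } else {
    enrich(targets, collection, universe, mode = "target", ...)
  }
  attr(out, "query") <- targets
  attr(out, "unmapped") <- unmapped
  out
}

#' Default background universe for host-mode enrichment
#'
#' The default background is every protein-coding gene in the annotation
#' that appears in at least one collection term (genes the test could in
#' principle have returned). The `host_capable` option restricts further to
#' genes that host at least one annotated miRNA, which controls for
#' host-selection bias: under it, the question becomes "among genes that
#' *could* host a miRNA, are the observed hosts concentrated in this term?".
#' The choice materially affects p-values, so it is explicit rather than
#' buried.
#'
#' @param genes Gene-model tibble.
#' @param collection Gene-set tibble from [read_gmt()].
#' @param assignments Optional assignment table; required for
#'   `host_capable = TRUE`.
#' @param host_capable Restrict to genes hosting at least one annotated
#'   miRNA. Default `FALSE`.
#' @param protein_coding Biotype value(s) treated as protein-coding.
#' @return Character vector of gene ids.
#' @export
default_universe <- function(genes, collection, assignments = NULL,
                             host_capable = FALSE,
                             protein_coding = "protein_coding") {
  in_terms <- unique(unlist(collection$genes))
  pc <- genes$gene_id[genes$biotype %in% protein_coding]
  u <- intersect(pc, in_terms)
  if (host_capable) {
    if (is.null(assignments)) abort("host_capable universe needs assignments")
    hosts <- unique(assignments$host_gene_id[assignments$context == "intragenic_sense"])
    u <- intersect(u, hosts)
  }
  sort(u)
}

#' Write an enrichment table to TSV
#'
#' @param results A `mirhost_enrichment` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(results, path) {
  flat <- results |>
    mutate(overlap = map_chr(.data$overlap, comma_join)) |>
    as_tibble()
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}
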