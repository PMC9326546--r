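#' Classify the genomic context of each miRNA precursor
#'
#' Implements the sense-strand host-gene rule: a miRNA is *intragenic sense*
#' if at least one protein-coding gene on the same strand fully contains its
#' precursor span, *intragenic antisense* if it is fully contained only by
#' opposite-strand protein-coding genes, and *intergenic* otherwise.
#' Containment — not mere overlap — defines "embedded": a precursor hanging
#' off a gene edge is intergenic. Classification is driven by the precursor
#' interval; mature products are sub-intervals of it, so their call could
#' differ only at boundaries.
#'
#' When several same-strand protein-coding genes contain the precursor, the
#' smallest-span (most specific) container is the host and the others are
#' reported as `alternates` (see [resolve_nested_hosts()]). Containment by
#' non-protein-coding genes never confers a host; such containers are kept in
#' the `noncoding_containers` audit column.
#'
#' Sublocation is resolved against the chosen container's transcripts:
#' *exonic* if the precursor lies fully inside an exon of at least one
#' transcript; otherwise *intronic* if fully inside an intron of at least one
#' transcript; otherwise *junction* (it straddles an exon-intron boundary in
#' every transcript). A precursor exonic in one isoform and intronic in
#' another is called exonic, with `isoform_disagreement` flagged. Containers
#' whose exon structure is a flagged pseudo-exon yield
#' `confidence_flag = "pseudo_exon_gene"`.
#'
#' @param mirnas miRNA annotation tibble ([read_mirna_annotations()]).
#' @param genes Gene-model tibble ([read_gene_models()]). May be empty, in
#'   which case every miRNA is intergenic (a warning notes it).
#' @param protein_coding Biotype value(s) treated as protein-coding.
#' @return A tibble, one row per precursor: `precursor_id`, `name`, `chrom`,
#'   `strand`, `context`, `sublocation`, `host_gene_id`, `alternates`
#'   (list-column), `confidence_flag`, `noncoding_containers` (list-column),
#'   `isoform_disagreement`.
#' @export
classify_contexts <- function(mirnas, genes, protein_coding = "protein_coding") {
  base <- mirnas |>
    select("precursor_id", "name", "chrom", "start", "end", "strand")

  empty_cols <- function(df) {
    df |>
      mutate(
        context = "intergenic", sublocation = "none",
        host_gene_id = NA_character_,
        alternates = map(seq_len(nrow(df)), \(i) character(0)),
        confidence_flag = "normal",
        noncoding_containers = map(seq_len(nrow(df)), \(i) character(0)),
        isoform_disagreement = FALSE
      ) |>
      select(-"start", -"end")
  }

  if (is.null(genes) || nrow(genes) == 0) {
    warn("classify_contexts: empty gene list, every miRNA is intergenic")
    out <- empty_cols(base)
    class(out) <- c("mirhost_assignments", class(tibble()))
    return(out)
  }

  # containment query via an interval index; the test suite holds this to an
  # exhaustive all-pairs scan
  pre_gr <- GenomicRanges::GRanges(
    base$chrom, IRanges::IRanges(base$start + 1L, base$end), strand = "*"
  )
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end), strand = "*"
  )
  # suppressed warning: disjoint seqlevels between the two objects are
  # expected (a precursor on a chromosome with no genes is just intergenic)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(pre_gr, gene_gr, type = "within",
                                ignore.strand = TRUE)
  )
  by_pre <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))

  rows <- map(seq_len(nrow(base)), function(i) {
    cont <- genes[by_pre[[as.character(i)]] %||% integer(0), , drop = FALSE]
    classify_one(base[i, ], cont, protein_coding)
  })
  out <- bind_rows(rows)
  class(out) <- c("mirhost_assignments", class(tibble()))
  out
}

classify_one <- function(pre, containers, protein_coding) {
  is_pc <- containers$biotype %in% protein_coding
  same <- containers$strand == pre$strand
  pc_sense <- containers[is_pc & same, , drop = FALSE]
  pc_anti <- containers[is_pc & !same, , drop = FALSE]
  noncoding <- containers$gene_id[!is_pc]

  res <- tibble(
    precursor_id = pre$precursor_id, name = pre$name,
    chrom = pre$chrom, strand = pre$strand,
    context = "intergenic", sublocation = "none",
    host_gene_id = NA_character_, alternates = list(character(0)),
    confidence_flag = "normal",
    noncoding_containers = list(sort(noncoding)),
    isoform_disagreement = FALSE
  )

  chosen <- NULL
  if (nrow(pc_sense) > 0) {
    picked <- resolve_nested_hosts(pc_sense)
    chosen <- pc_sense[pc_sense$gene_id == picked$primary, , drop = FALSE]
    res$context <- "intragenic_sense"
    res$host_gene_id <- picked$primary
    res$alternates <- list(picked$alternates)
  } else if (nrow(pc_anti) > 0) {
    picked <- resolve_nested_hosts(pc_anti)
    chosen <- pc_anti[pc_anti$gene_id == picked$primary, , drop = FALSE]
    res$context <- "intragenic_antisense"
    res$alternates <- list(picked$alternates)
  }

  if (!is.null(chosen)) {
    sub <- sublocation_in_gene(pre$start, pre$end, chosen)
    res$sublocation <- sub$call
    res$isoform_disagreement <- sub$disagreement
    if (isTRUE(chosen$pseudo_exon)) res$confidence_flag <- "pseudo_exon_gene"
  }
  res
}

# Per-transcript call for one precursor interval, then the any-exonic-wins
# rule across isoforms.
sublocation_in_gene <- function(p_start, p_end, gene) {
  trx <- gene$transcripts[[1]]
  calls <- map_chr(unique(trx$transcript_id), function(tid) {
    ex <- trx[trx$transcript_id == tid, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (any(contains(ex$start, ex$end, p_start, p_end))) return("exonic")
    if (nrow(ex) > 1) {
      intron_start <- ex$end[-nrow(ex)]
      intron_end <- ex$start[-1]
      if (any(contains(intron_start, intron_end, p_start, p_end))) return("intronic")
    }
    "straddle"
  })
  call <- if (any(calls == "exonic")) "exonic"
          else if (any(calls == "intronic")) "intronic"
          else "junction"
  list(call = call,
       disagreement = all(c("exonic", "intronic") %in% calls))
}

#' Resolve nested or overlapping candidate host genes
#'
#' When more than one same-strand protein-coding gene fully contains a
#' precursor, the most specific container — the gene with the smallest span —
#' is the primary host; ties break lexicographically on `gene_id` so the
#' choice is deterministic. The remaining containers are retained as
#' alternates rather than discarded.
#'
#' @param candidates Tibble of candidate genes with at least `gene_id`,
#'   `start`, `end`.
#' @return A list with `primary` (one gene id) and `alternates` (character
#'   vector, possibly empty, ordered by increasing span then id).
#' @export
resolve_nested_hosts <- function(candidates) {
  stopifnot(nrow(candidates) >= 1)
  ord <- order(candidates$end - candidates$start, candidates$gene_id)
  ids <- candidates$gene_id[ord]
  list(primary = ids[1], alternates = ids[-1])
}

#' Detect miRNA clusters by genomic proximity
#'
#' Single-linkage chaining of precursors that lie on the same chromosome and
#' strand with an inter-precursor gap of at most `max_gap` base pairs —
#' the conventional operational definition of a polycistronic miRNA cluster.
#' Singletons are not reported. Output is independent of input order.
#'
#' @param mirnas miRNA annotation tibble.
#' @param max_gap Maximum gap (bp) between consecutive precursors in a
#'   chain. Default 10000, the conventional polycistron window.
#' @return A tibble, one row per cluster: `cluster_id`, `chrom`, `strand`,
#'   `start`, `end`, `n_members`, `members` (list-column of precursor ids
#'   sorted by genomic start).
#' @export
detect_clusters <- function(mirnas, max_gap = 10000) {
  stopifnot(max_gap >= 0)
  ord <- mirnas |>
    select("precursor_id", "chrom", "start", "end", "strand") |>
    arrange(.data$chrom, .data$strand, .data$start, .data$precursor_id)

  clusters <- list()
  for (grp in split(ord, paste(ord$chrom, ord$strand))) {
    run_end <- -Inf
    members <- integer(0)
    flush <- function(members) {
      if (length(members) < 2) return(NULL)
      m <- grp[members, , drop = FALSE]
      tibble(chrom = m$chrom[1], strand = m$strand[1],
             start = min(m$start), end = max(m$end),
             n_members = nrow(m), members = list(m$precursor_id))
    }
    for (i in seq_len(nrow(grp))) {
      if (grp$start[i] - run_end > max_gap) {
        clusters <- c(clusters, list(flush(members)))
        members <- integer(0)
        run_end <- -Inf
      }
      members <- c(members, i)
      run_end <- max(run_end, grp$end[i])
    }
    clusters <- c(clusters, list(flush(members)))
  }
  out <- bind_rows(clusters)
  if (nrow(out) == 0) {
    return(tibble(cluster_id = character(0), chrom = character(0),
                  strand = character(0), start = integer(0), end = integer(0),
                  n_members = integer(0), members = list()))
  }
  out <- out |> arrange(.data$chrom, .data$start)
  out |> mutate(cluster_id = sprintf("cluster_%03d", row_number()), .before = 1)
}
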