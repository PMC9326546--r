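# GFF3 writers. Written directly (nine tab-separated columns, fixed
# attribute order) so that identical inputs always produce identical bytes
# and a write/re-read cycle is the exact inverse of parsing.

gff3_line <- function(chrom, source, type, start0, end0, strand, attrs) {
  coords <- internal_to_gff3(start0, end0)
  attr_str <- paste(sprintf("%s=%s", names(attrs), unlist(attrs)), collapse = ";")
  sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
          chrom, source, type, coords$start, coords$end, strand, attr_str)
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gene_models()]: emits `gene`, `mRNA` and `exon` features
#' with `ID`/`Parent`/`Name`/`biotype` attributes, converting the internal
#' 0-based half-open coordinates back to GFF3's 1-based inclusive ones.
#' Pseudo-exon genes (no annotated exon structure) are written as a bare
#' `gene` feature, which re-reads to the same flagged pseudo-exon model.
#'
#' @param genes A gene-model tibble from [read_gene_models()] (or the
#'   simulator).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  out <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    out <- c(out, gff3_line(
      g$chrom, "mirhost", "gene", g$start, g$end, g$strand,
      list(ID = g$gene_id, Name = g$symbol, biotype = g$biotype)
    ))
    if (isTRUE(g$pseudo_exon)) next
    trx <- g$transcripts[[1]]
    for (tid in unique(trx$transcript_id)) {
      ex <- trx[trx$transcript_id == tid, , drop = FALSE]
      out <- c(out, gff3_line(
        g$chrom, "mirhost", "mRNA", min(ex$start), max(ex$end), g$strand,
        list(ID = tid, Parent = g$gene_id)
      ))
      for (j in seq_len(nrow(ex))) {
        out <- c(out, gff3_line(
          g$chrom, "mirhost", "exon", ex$start[j], ex$end[j], g$strand,
          list(ID = sprintf("%s.exon%d", tid, j), Parent = tid)
        ))
      }
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Write miRNA annotations to miRBase-dialect GFF3
#'
#' Inverse of [read_mirna_annotations()]: `miRNA_primary_transcript`
#' features for precursors, `miRNA` features for matures linked by
#' `Derives_from`.
#'
#' @param mirnas A miRNA annotation tibble from [read_mirna_annotations()]
#'   (or the simulator).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mirna_gff3 <- function(mirnas, path) {
  out <- c("##gff-version 3")
  for (i in seq_len(nrow(mirnas))) {
    p <- mirnas[i, ]
    out <- c(out, gff3_line(
      p$chrom, "mirhost", "miRNA_primary_transcript", p$start, p$end, p$strand,
      list(ID = p$precursor_id, Name = p$name)
    ))
    m <- p$matures[[1]]
    for (j in seq_len(nrow(m))) {
      out <- c(out, gff3_line(
        p$chrom, "mirhost", "miRNA", m$start[j], m$end[j], p$strand,
        list(ID = m$mature_id[j], Name = m$mature_name[j], Derives_from = p$precursor_id)
      ))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Export precursors as BED6, labelled by genomic context
#'
#' BED is natively 0-based half-open, i.e. the internal convention verbatim.
#' The name field carries `precursor_id|context` so the track is readable in
#' a genome browser without extra columns.
#'
#' @param assignments Assignment table from [classify_contexts()].
#' @param mirnas The matching miRNA annotation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_precursor_bed <- function(assignments, mirnas, path) {
  joined <- mirnas |>
    select("precursor_id", "chrom", "start", "end", "strand") |>
    inner_join(assignments |> select("precursor_id", "context"), by = "precursor_id")
  lines <- sprintf("%s\t%d\t%d\t%s|%s\t0\t%s",
                   joined$chrom, joined$start, joined$end,
                   joined$precursor_id, joined$context, joined$strand)
  writeLines(lines, path)
  invisible(path)
}
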