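#' Read gene models from a GFF3 file
#'
#' Parses `gene` / `mRNA` (or `transcript`) / `exon` features linked by
#' `ID`/`Parent` attributes into a tidy gene-model table. GFF3 coordinates
#' (1-based, inclusive) are converted once, at this boundary, to the
#' package-internal 0-based half-open convention; all downstream interval
#' arithmetic assumes it.
#'
#' Genes without any exon (common in sparse or toy annotations) are kept and
#' given a single pseudo-exon spanning the whole gene, flagged in the
#' `pseudo_exon` column so that downstream intron/exon calls against them can
#' be marked low-confidence rather than silently trusted.
#'
#' @param path Path to a GFF3 file.
#' @param biotype_attr Attribute keys searched (in order) for the gene
#'   biotype; covers the Ensembl (`biotype`) vs GENCODE (`gene_biotype`)
#'   dialect drift. Biotype is preserved verbatim; no filtering happens here.
#' @return A tibble with one row per gene: `gene_id`, `symbol`, `biotype`,
#'   `chrom`, `start`, `end`, `strand`, `pseudo_exon`, and a `transcripts`
#'   list-column of per-transcript exon tables (`transcript_id`, `start`,
#'   `end`, exons sorted by start).
#' @export
read_gene_models <- function(path, biotype_attr = c("biotype", "gene_biotype")) {
  check_gff3_syntax(path)
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)

  feat <- tibble(
    type = type,
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    id = as.character(mc$ID %na% NA_character_),
    parent = first_parent(mc$Parent),
    name = as.character(mc$Name %na% NA_character_)
  )
  feat$biotype <- NA_character_
  for (key in biotype_attr) {
    if (key %in% names(mc)) {
      vals <- as.character(mc[[key]])
      feat$biotype <- dplyr::coalesce(feat$biotype, vals)
    }
  }

  genes <- feat |> filter(.data$type == "gene")
  if (nrow(genes) == 0) abort(sprintf("no gene features found in '%s'", path))
  if (anyNA(genes$id)) abort("gene feature without an ID attribute")
  check_interval(genes$start, genes$end, genes$strand, "gene")

  tx <- feat |> filter(.data$type %in% c("mRNA", "transcript"))
  tx_gene <- setNames(tx$parent, tx$id)

  exons <- feat |> filter(.data$type == "exon")
  # resolve each exon to a gene ancestor: via its transcript, or directly
  ex_tx <- exons$parent
  direct <- ex_tx %in% genes$id
  via_tx <- ex_tx %in% tx$id
  orphan <- !direct & !via_tx
  if (any(orphan)) {
    warn(sprintf("skipping %d exon(s) with no resolvable gene ancestor (e.g. Parent=%s)",
                 sum(orphan), ex_tx[which(orphan)[1]]))
    exons <- exons[!orphan, , drop = FALSE]
    direct <- direct[!orphan]
  }
  exons <- exons |>
    mutate(
      transcript_id = ifelse(direct, paste0(.data$parent, ".t0"), .data$parent),
      gene_id = ifelse(direct, .data$parent, unname(tx_gene[.data$parent]))
    )

  ex_by_gene <- split(exons, exons$gene_id)
  transcripts <- map(genes$id, function(gid) {
    ex <- ex_by_gene[[gid]]
    if (is.null(ex) || nrow(ex) == 0) return(NULL)
    ex |>
      arrange(.data$transcript_id, .data$start) |>
      select(transcript_id = "transcript_id", start = "start", end = "end")
  })

  out <- genes |>
    transmute(
      gene_id = .data$id,
      symbol = dplyr::coalesce(.data$name, .data$id),
      biotype = .data$biotype,
      chrom = .data$chrom, start = .data$start, end = .data$end,
      strand = .data$strand,
      pseudo_exon = map_lgl(transcripts, is.null)
    )
  out$transcripts <- pmap(
    list(transcripts, out$gene_id, out$start, out$end),
    function(trx, gid, s, e) {
      if (is.null(trx)) {
        return(tibble(transcript_id = paste0(gid, ".pseudo"), start = s, end = e))
      }
      trx
    }
  )
  validate_gene_models(out)
  out <- out |> arrange(.data$chrom, .data$start, .data$gene_id)
  class(out) <- c("mirhost_genes", class(tibble()))
  out
}

validate_gene_models <- function(genes) {
  for (i in seq_len(nrow(genes))) {
    trx <- genes$transcripts[[i]]
    if (any(trx$start < genes$start[i] | trx$end > genes$end[i])) {
      abort(sprintf("exon outside gene span for gene '%s'", genes$gene_id[i]))
    }
    for (ex in split(trx, trx$transcript_id)) {
      ex <- ex[order(ex$start), , drop = FALSE]
      if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)])) {
        abort(sprintf("overlapping exons within one transcript of gene '%s'",
                      genes$gene_id[i]))
      }
    }
  }
  invisible(TRUE)
}

#' Read miRNA annotations in the miRBase GFF3 dialect
#'
#' Expects `miRNA_primary_transcript` features (precursor hairpins) and
#' `miRNA` features (mature products) linked to their precursor by a
#' `Derives_from` attribute. Mature products are kept with their precursor,
#' ordered by genomic start; a mature pointing at an absent precursor, or
#' extending beyond its precursor's span, is an error (referential and
#' containment integrity are what the host-assignment step relies on).
#'
#' @param path Path to a GFF3 file in the miRBase dialect.
#' @return A tibble with one row per precursor: `precursor_id`, `name`,
#'   `chrom`, `start`, `end`, `strand` (0-based half-open) and a `matures`
#'   list-column (`mature_id`, `mature_name`, `start`, `end`, `sequence`;
#'   sequences are `NA` until attached from a sequence table).
#' @seealso [read_sequence_table()], [collect_matures()]
#' @export
read_mirna_annotations <- function(path) {
  check_gff3_syntax(path)
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)

  feat <- tibble(
    type = type,
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    id = as.character(mc$ID %na% NA_character_),
    name = as.character(mc$Name %na% NA_character_),
    derives_from = first_parent(mc$Derives_from)
  )

  pre <- feat |> filter(.data$type == "miRNA_primary_transcript")
  mat <- feat |> filter(.data$type == "miRNA")
  if (nrow(pre) == 0) abort(sprintf("no miRNA_primary_transcript features in '%s'", path))
  check_interval(pre$start, pre$end, pre$strand, "precursor")

  missing_ref <- is.na(mat$derives_from) | !(mat$derives_from %in% pre$id)
  if (any(missing_ref)) {
    bad <- mat[which(missing_ref)[1], ]
    abort(sprintf("mature miRNA '%s' has no resolvable precursor (Derives_from=%s)",
                  dplyr::coalesce(bad$id, bad$name, "<unnamed>"),
                  dplyr::coalesce(bad$derives_from, "<absent>")))
  }

  pre_span <- pre |> select("id", p_start = "start", p_end = "end")
  mat <- mat |> left_join(pre_span, by = c(derives_from = "id"))
  outside <- mat$start < mat$p_start | mat$end > mat$p_end
  if (any(outside)) {
    bad <- mat[which(outside)[1], ]
    abort(sprintf("mature miRNA '%s' extends beyond its precursor '%s'",
                  dplyr::coalesce(bad$id, bad$name), bad$derives_from))
  }

  mat_by_pre <- split(mat, mat$derives_from)
  out <- pre |>
    transmute(
      precursor_id = .data$id,
      name = dplyr::coalesce(.data$name, .data$id),
      chrom = .data$chrom, start = .data$start, end = .data$end,
      strand = .data$strand
    )
  out$matures <- map(out$precursor_id, function(pid) {
    m <- mat_by_pre[[pid]]
    if (is.null(m) || nrow(m) == 0) {
      abort(sprintf("precursor '%s' has no mature products", pid))
    }
    m |>
      arrange(.data$start) |>
      transmute(
        mature_id = .data$id,
        mature_name = dplyr::coalesce(.data$name, .data$id),
        start = .data$start, end = .data$end,
        sequence = NA_character_
      )
  })
  out <- out |> arrange(.data$chrom, .data$start, .data$precursor_id)
  class(out) <- c("mirhost_mirnas", class(tibble()))
  out
}

# Cheap syntactic pre-scan so format errors are reported with a line number
# (the full-featured importer does not track them).
check_gff3_syntax <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    nfield <- length(strsplit(ln, "\t", fixed = TRUE)[[1]])
    if (nfield != 9) {
      abort(sprintf("malformed GFF3 at line %d of '%s': %d field(s), expected 9",
                    i, path, nfield))
    }
  }
  invisible(TRUE)
}

# Parent / Derives_from come back from the importer as CharacterList or
# character depending on the file; normalise to one id (the first).
first_parent <- function(x) {
  if (is.null(x)) return(NA_character_)
  if (methods::is(x, "List") || is.list(x)) {
    map_chr(as.list(x), function(v) if (length(v) == 0) NA_character_ else as.character(v[[1]]))
  } else {
    out <- as.character(x)
    out[!nzchar(out)] <- NA_character_
    out
  }
}

#' Read a differential-expression results table
#'
#' Reads a tab-separated DE table with a header and maps its columns onto the
#' internal schema (`feature_id`, `log2fc`, `pvalue`, `padj`). Works directly
#' on DESeq2-style exports via `column_map`. Rows whose p-values do not parse
#' as finite numbers are dropped, with the count reported; adjusted p-values
#' are deliberately not required to be >= raw p-values (they may come from an
#' independent procedure), but both must lie in \[0, 1\].
#'
#' @param path Path to a TSV file with a header row.
#' @param column_map Named character vector mapping internal names
#'   (`id`, `log2fc`, `pvalue`, `padj`) to the file's column names.
#'   Defaults to `c(id = "id", log2fc = "log2FC", pvalue = "pvalue",
#'   padj = "padj")`; supply e.g. `c(log2fc = "log2FoldChange")` to override
#'   a subset.
#' @return A tibble `feature_id`, `log2fc`, `pvalue`, `padj` with an
#'   `n_dropped` attribute counting discarded rows.
#' @export
read_de_table <- function(path, column_map = NULL) {
  defaults <- c(id = "id", log2fc = "log2FC", pvalue = "pvalue", padj = "padj")
  cmap <- defaults
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), names(defaults))
    if (length(unknown) > 0) {
      abort(sprintf("unknown column_map key(s): %s", comma_join(unknown)))
    }
    cmap[names(column_map)] <- column_map
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(unname(cmap), names(tab))
  if (length(missing) > 0) {
    abort(sprintf("DE table '%s' lacks column(s) %s; available: %s",
                  path, comma_join(missing), comma_join(names(tab))))
  }
  out <- tibble(
    feature_id = as.character(tab[[cmap[["id"]]]]),
    log2fc = suppressWarnings(as.numeric(tab[[cmap[["log2fc"]]]])),
    pvalue = suppressWarnings(as.numeric(tab[[cmap[["pvalue"]]]])),
    padj = suppressWarnings(as.numeric(tab[[cmap[["padj"]]]]))
  )
  keep <- is.finite(out$padj) & is.finite(out$pvalue) & is.finite(out$log2fc)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf("read_de_table: dropped %d row(s) with non-numeric statistics", n_dropped))
  }
  out <- out[keep, , drop = FALSE]
  if (any(out$pvalue < 0 | out$pvalue > 1 | out$padj < 0 | out$padj > 1)) {
    abort("p-values outside [0, 1] in DE table")
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, `term<TAB>description<TAB>member...`.
#' Duplicate members within one line are counted once; duplicate term ids
#' across lines make the collection ambiguous and are an error, as is a set
#' with no members.
#'
#' @param path Path to a GMT file.
#' @return A tibble `term_id`, `description`, `genes` (list-column of unique
#'   member ids), `n_genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parsed <- map(seq_along(lines), function(i) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      abort(sprintf("GMT line %d of '%s' has %d field(s); need term, description, >=1 member",
                    i, path, length(fields)))
    }
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      abort(sprintf("GMT line %d of '%s' defines an empty set", i, path))
    }
    list(term_id = fields[1], description = fields[2], genes = members)
  })
  term_ids <- map_chr(parsed, "term_id")
  dup <- unique(term_ids[duplicated(term_ids)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate term id(s) in '%s': %s", path, comma_join(dup)))
  }
  tibble(
    term_id = term_ids,
    description = map_chr(parsed, "description"),
    genes = map(parsed, "genes"),
    n_genes = map_int(parsed, \(x) length(x$genes))
  )
}

#' Write a gene-set collection to GMT
#'
#' @param collection A tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- pmap(
    list(collection$term_id, collection$description, collection$genes),
    function(id, desc, genes) paste(c(id, desc, genes), collapse = "\t")
  )
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Read a mature-sequence table
#'
#' Two-column TSV `mature_id<TAB>sequence` (header optional). Sequences may
#' be RNA or DNA, any case; they are normalised (uppercase, U -> T) when
#' families are formed, not here.
#'
#' @param path Path to the TSV file.
#' @return A tibble `mature_id`, `sequence`.
#' @export
read_sequence_table <- function(path) {
  read_two_col(path, c("mature_id", "sequence"))
}

#' Read a miRNA-to-target-gene mapping table
#'
#' Two-column TSV `mirna_id<TAB>gene_id` (header optional), one row per
#' predicted miRNA/target pair; consumed as-is by the target-gene enrichment
#' mode. No prediction is performed here.
#'
#' @param path Path to the TSV file.
#' @return A tibble `mirna_id`, `gene_id`.
#' @export
read_target_map <- function(path) {
  read_two_col(path, c("mirna_id", "gene_id"))
}

read_two_col <- function(path, col_names) {
  first <- readLines(path, n = 1L, warn = FALSE)
  has_header <- identical(strsplit(first, "\t", fixed = TRUE)[[1]], col_names)
  tab <- readr::read_tsv(
    path,
    col_names = if (has_header) TRUE else col_names,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (ncol(tab) != 2) {
    abort(sprintf("'%s' must have exactly 2 tab-separated columns (%s)",
                  path, comma_join(col_names)))
  }
  names(tab) <- col_names
  tab
}
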