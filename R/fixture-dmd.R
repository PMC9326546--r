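#' Packaged example: the PANK / miR-103a/-107 and USMG5 / miR-1307 fixture
#'
#' A small bundle encoding host-gene relationships reported in the DMD
#' (Duchenne muscular dystrophy) circulating-miRNA literature: the paralog
#' precursors mir-103a-1, mir-103a-2 and mir-107 sit in conserved intronic
#' positions of *PANK3*, *PANK2* and *PANK1* respectively, with
#' miR-103a-1-3p and miR-103a-2-3p carrying the identical mature sequence
#' (small-RNA sequencing detects them as one species, `miR-103a-3p`); and
#' mir-1307 sits in an exon of *USMG5*, with both its arms downregulated in
#' DMD while *USMG5* itself is also downregulated. The miRNA DE table marks
#' miR-103a-3p and miR-107 up and miR-1307-5p/-3p down.
#'
#' All coordinates are SYNTHETIC placeholders: only the containment, strand,
#' intron/exon and sequence-identity relations are faithful to the
#' literature. Do not mistake them for genomic positions. A few background
#' genes (`BG1`..`BG6`) pad the universe so enrichment is well-defined.
#'
#' @return A `mirhost_bundle` (same shape as [simulate_bundle()] output,
#'   without planted-truth fields beyond `truth$contexts`).
#' @export
dmd_example_bundle <- function() {
  mk_gene <- function(gene_id, chrom, start, strand, exon_offsets, exon_lens,
                      biotype = "protein_coding") {
    ex_start <- start + exon_offsets
    trx <- tibble(transcript_id = paste0(gene_id, ".t1"),
                  start = ex_start, end = ex_start + exon_lens)
    tibble(gene_id = gene_id, symbol = gene_id, biotype = biotype,
           chrom = chrom, start = start, end = max(trx$end), strand = strand,
           pseudo_exon = FALSE, transcripts = list(trx))
  }
  # three-exon hosts; introns are the gaps between the exon blocks
  host_exons <- list(offsets = c(0L, 6000L, 14000L), lens = c(800L, 700L, 900L))
  genes <- bind_rows(
    mk_gene("PANK3", "chr5", 100000L, "+", host_exons$offsets, host_exons$lens),
    mk_gene("PANK2", "chr20", 200000L, "+", host_exons$offsets, host_exons$lens),
    mk_gene("PANK1", "chr10", 300000L, "-", host_exons$offsets, host_exons$lens),
    mk_gene("USMG5", "chr10", 500000L, "+", host_exons$offsets, host_exons$lens),
    mk_gene("BG1", "chr5", 200000L, "+", c(0L, 3000L), c(500L, 500L)),
    mk_gene("BG2", "chr5", 260000L, "-", c(0L, 3000L), c(500L, 500L)),
    mk_gene("BG3", "chr20", 300000L, "+", c(0L, 3000L), c(500L, 500L)),
    mk_gene("BG4", "chr20", 360000L, "-", c(0L, 3000L), c(500L, 500L)),
    mk_gene("BG5", "chr10", 400000L, "+", c(0L, 3000L), c(500L, 500L)),
    mk_gene("BG6", "chr10", 600000L, "+", c(0L, 3000L), c(500L, 500L))
  )
  class(genes) <- c("mirhost_genes", class(tibble()))

  # identical mature sequence for the two miR-103a paralog arms
  seq_103a3p <- "AGCAGCATTGTACAGGGCTATG"
  seqs <- c(
    "miR-103a-1-5p" = "TCATAGCCCTGTACAATGCTGC",
    "miR-103a-1-3p" = seq_103a3p,
    "miR-103a-2-5p" = "TCATAGCCCTGTACACTGCTGC",
    "miR-103a-2-3p" = seq_103a3p,
    "miR-107-5p"    = "TCTAGCTTCTTTACAGTGTTGC",
    "miR-107"       = "AGCAGCATTGTACAGGGCTATC",
    "miR-1307-5p"   = "TCGACCGGACCTCGACCGGCTC",
    "miR-1307-3p"   = "ACTCGGCGTGGCGTCGGTCGTG"
  )

  mk_mirna <- function(precursor_id, chrom, pos, strand,
                       ids5, name5, ids3, name3) {
    mat <- tibble(
      mature_id = c(ids5, ids3), mature_name = c(name5, name3),
      start = c(pos, pos + 58L), end = c(pos + 22L, pos + 80L),
      sequence = NA_character_
    )
    tibble(precursor_id = precursor_id, name = precursor_id, chrom = chrom,
           start = pos, end = pos + 80L, strand = strand,
           matures = list(mat))
  }
  # intron 1 of each PANK host; exon 3 of USMG5
  mirnas <- bind_rows(
    mk_mirna("mir-103a-1", "chr5", 100000L + 2000L, "+",
             "miR-103a-1-5p", "miR-103a-1-5p", "miR-103a-1-3p", "miR-103a-3p"),
    mk_mirna("mir-103a-2", "chr20", 200000L + 2000L, "+",
             "miR-103a-2-5p", "miR-103a-2-5p", "miR-103a-2-3p", "miR-103a-3p"),
    mk_mirna("mir-107", "chr10", 300000L + 2000L, "-",
             "miR-107-5p", "miR-107-5p", "miR-107", "miR-107"),
    mk_mirna("mir-1307", "chr10", 500000L + 14010L, "+",
             "miR-1307-5p", "miR-1307-5p", "miR-1307-3p", "miR-1307-3p")
  ) |>
    arrange(.data$chrom, .data$start)
  class(mirnas) <- c("mirhost_mirnas", class(tibble()))

  sequences <- tibble(mature_id = names(seqs), sequence = unname(seqs))

  mirna_de <- tibble(
    feature_id = c("miR-103a-3p", "miR-107", "miR-1307-5p", "miR-1307-3p",
                   "miR-null-1", "miR-null-2"),
    log2fc = c(1.5, 1.2, -1.1, -1.4, 0.1, -0.2),
    pvalue = c(0.002, 0.004, 0.009, 0.001, 0.40, 0.52),
    padj = c(0.01, 0.02, 0.03, 0.004, 0.55, 0.71)
  )
  gene_de <- tibble(
    feature_id = c("USMG5", "PANK1", "PANK2", "PANK3",
                   "BG1", "BG2", "BG3", "BG4", "BG5", "BG6"),
    log2fc = c(-1.3, 0.1, -0.2, 0.15, 0.05, -0.1, 0.2, 0.0, 0.1, -0.05),
    pvalue = c(0.001, 0.3, 0.5, 0.6, 0.4, 0.7, 0.3, 0.9, 0.6, 0.8),
    padj = c(0.02, 0.45, 0.62, 0.71, 0.55, 0.81, 0.47, 0.95, 0.72, 0.88)
  )

  gmt <- tibble(
    term_id = c("COA_BIOSYNTHESIS", "ATP_SYNTHESIS_COUPLING",
                "CHOLESTEROL_SYNTHESIS", "UNRELATED_SET"),
    description = c("pantothenate to CoA conversion",
                    "mitochondrial ATP synthase assembly",
                    "sterol biosynthetic process",
                    "background set"),
    genes = list(c("PANK1", "PANK2", "PANK3"),
                 c("USMG5", "BG1", "BG5"),
                 c("PANK1", "BG2", "BG3"),
                 c("BG4", "BG5", "BG6"))
  ) |>
    mutate(n_genes = map_int(.data$genes, length))

  target_map <- tibble(
    mirna_id = c(rep("miR-103a-3p", 3), rep("miR-107", 3),
                 rep("miR-1307-5p", 2), rep("miR-1307-3p", 2)),
    gene_id = c("BG1", "BG2", "USMG5", "BG2", "BG3", "BG6",
                "BG4", "BG5", "BG1", "BG6")
  )

  truth <- list(
    contexts = tibble(
      precursor_id = c("mir-103a-1", "mir-103a-2", "mir-107", "mir-1307"),
      context = "intragenic_sense",
      sublocation = c("intronic", "intronic", "intronic", "exonic"),
      host_gene_id = c("PANK3", "PANK2", "PANK1", "USMG5")
    ),
    families = tibble(family_name = "miR-103a-3p",
                      precursor_ids = list(c("mir-103a-1", "mir-103a-2"))),
    clusters = list(),
    dys_mirnas_intragenic = c("miR-103a-3p", "miR-107", "miR-1307-3p", "miR-1307-5p"),
    dys_mirnas_intergenic = character(0),
    dys_genes = "USMG5",
    universe = sort(genes$gene_id)
  )

  structure(list(genes = genes, mirnas = mirnas, sequences = sequences,
                 mirna_de = mirna_de, gene_de = gene_de, gmt = gmt,
                 target_map = target_map, truth = truth,
                 config = NULL),
            class = "mirhost_bundle")
}
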