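# Readers/writers for GFF3, DE tables, GMT and the two-column TSVs.

write_tmp <- function(lines, ext = ".gff3") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

gene_gff3_lines <- c(
  "##gff-version 3",
  "chr1\tsrc\tgene\t1001\t2000\t.\t+\t.\tID=G1;Name=GENE1;biotype=protein_coding",
  "chr1\tsrc\tmRNA\t1001\t2000\t.\t+\t.\tID=G1.t1;Parent=G1",
  "chr1\tsrc\texon\t1001\t1100\t.\t+\t.\tID=e1;Parent=G1.t1",
  "chr1\tsrc\texon\t1301\t1500\t.\t+\t.\tID=e2;Parent=G1.t1",
  "chr1\tsrc\texon\t1801\t2000\t.\t+\t.\tID=e3;Parent=G1.t1",
  "chr1\tsrc\tgene\t5001\t6000\t.\t-\t.\tID=L1;Name=LINC1;biotype=lincRNA"
)

test_that("gene models convert GFF3 coordinates to 0-based half-open", {
  genes <- read_gene_models(write_tmp(gene_gff3_lines))
  g1 <- genes[genes$gene_id == "G1", ]
  expect_equal(g1$start, 1000L)
  expect_equal(g1$end, 2000L)
  trx <- g1$transcripts[[1]]
  expect_equal(trx$start, c(1000L, 1300L, 1800L))
  expect_equal(trx$end, c(1100L, 1500L, 2000L))
  expect_false(g1$pseudo_exon)
})

test_that("parser preserves non-coding biotypes instead of filtering", {
  genes <- read_gene_models(write_tmp(gene_gff3_lines))
  expect_true("L1" %in% genes$gene_id)
  expect_equal(genes$biotype[genes$gene_id == "L1"], "lincRNA")
})

test_that("gene_biotype fallback attribute key is honoured", {
  lines <- c("##gff-version 3",
             "chr1\tsrc\tgene\t101\t400\t.\t+\t.\tID=G9;gene_biotype=protein_coding")
  genes <- read_gene_models(write_tmp(lines))
  expect_equal(genes$biotype, "protein_coding")
})

test_that("transcript-less genes get a flagged pseudo-exon", {
  genes <- read_gene_models(write_tmp(gene_gff3_lines))
  l1 <- genes[genes$gene_id == "L1", ]
  expect_true(l1$pseudo_exon)
  trx <- l1$transcripts[[1]]
  expect_equal(nrow(trx), 1L)
  expect_equal(trx$start, l1$start)
  expect_equal(trx$end, l1$end)
})

test_that("malformed GFF3 lines are reported with their line number", {
  lines <- c(gene_gff3_lines, "chr1\tonly\tthree")
  expect_error(read_gene_models(write_tmp(lines)),
               "line 8.*3 field")
})

test_that("exons with no resolvable gene ancestor are skipped with a warning", {
  lines <- c(gene_gff3_lines,
             "chr1\tsrc\texon\t1001\t1100\t.\t+\t.\tID=eX;Parent=NOSUCH")
  expect_warning(genes <- read_gene_models(write_tmp(lines)),
                 "no resolvable gene ancestor")
  expect_equal(nrow(genes), 2L)
})

mirna_gff3_lines <- c(
  "##gff-version 3",
  "chr10\t.\tmiRNA_primary_transcript\t5001\t5084\t.\t+\t.\tID=MI1307;Name=mir-1307",
  "chr10\t.\tmiRNA\t5060\t5084\t.\t+\t.\tID=MIMAT3p;Name=miR-1307-3p;Derives_from=MI1307",
  "chr10\t.\tmiRNA\t5001\t5022\t.\t+\t.\tID=MIMAT5p;Name=miR-1307-5p;Derives_from=MI1307"
)

test_that("precursor carries its matures, ordered by genomic start", {
  mir <- read_mirna_annotations(write_tmp(mirna_gff3_lines))
  expect_equal(nrow(mir), 1L)
  mat <- mir$matures[[1]]
  expect_equal(nrow(mat), 2L)
  # -3p listed first in the file but -5p starts first on the genome
  expect_equal(mat$mature_name, c("miR-1307-5p", "miR-1307-3p"))
  expect_equal(mat$start, c(5000L, 5059L))
})

test_that("orphan matures and containment violations are errors naming the mature", {
  orphan <- c(mirna_gff3_lines[1:3],
              "chr10\t.\tmiRNA\t7001\t7022\t.\t+\t.\tID=MIMATX;Name=miR-X;Derives_from=ABSENT")
  expect_error(read_mirna_annotations(write_tmp(orphan)), "MIMATX")

  outside <- c(mirna_gff3_lines,
               "chr10\t.\tmiRNA\t5080\t5120\t.\t+\t.\tID=MIMATY;Name=miR-Y;Derives_from=MI1307")
  expect_error(read_mirna_annotations(write_tmp(outside)),
               "MIMATY.*beyond its precursor")
})

test_that("gene models survive a GFF3 write/re-read round trip", {
  for (seed in c(101, 202, 303)) {
    ann <- random_annotation(seed)
    src <- ann$genes |> dplyr::arrange(chrom, start, gene_id)
    src$symbol <- src$gene_id
    path <- tempfile(fileext = ".gff3")
    write_gene_models_gff3(src, path)
    back <- read_gene_models(path)
    expect_equal(as.data.frame(back[, 1:8]), as.data.frame(src[, 1:8]))
    for (i in seq_len(nrow(src))) {
      expect_equal(as.data.frame(back$transcripts[[i]]),
                   as.data.frame(src$transcripts[[i]]))
    }
    expect_true(all(back$start < back$end))
  }
})

test_that("miRNA annotations survive a GFF3 write/re-read round trip", {
  b <- simulate_bundle(sim_config(seed = 5, n_genes = 30, n_mirnas = 20,
                                  n_families = 1, n_clusters = 1,
                                  n_nested_genes = 1, n_noncoding_genes = 1,
                                  n_dysregulated_intragenic = 2,
                                  n_dysregulated_intergenic = 2,
                                  universe_size = 200, n_terms = 3,
                                  planted_term_size = 10))
  path <- tempfile(fileext = ".gff3")
  write_mirna_gff3(b$mirnas, path)
  back <- read_mirna_annotations(path)
  expect_equal(as.data.frame(back[, 1:6]), as.data.frame(b$mirnas[, 1:6]))
  for (i in seq_len(nrow(back))) {
    expect_equal(as.data.frame(back$matures[[i]][, 1:4]),
                 as.data.frame(b$mirnas$matures[[i]][, 1:4]))
  }
})

test_that("DE tables map columns, drop unparseable rows, honour dialects", {
  path <- write_tmp(c("id\tlog2FC\tpvalue\tpadj",
                      "miR-107\t1.2\t0.001\t0.004",
                      "miR-bad\t0.5\t0.01\tNA",
                      "miR-null\t-0.1\t0.4\t0.62"), ext = ".tsv")
  expect_message(de <- read_de_table(path), "dropped 1")
  expect_equal(nrow(de), 2L)
  expect_equal(de$padj[de$feature_id == "miR-107"], 0.004)
  expect_equal(attr(de, "n_dropped"), 1L)

  deseq <- write_tmp(c("gene\tbaseMean\tlog2FoldChange\tpvalue\tpadj",
                       "PANK1\t100\t-1.2\t0.002\t0.01"), ext = ".tsv")
  de2 <- read_de_table(deseq, column_map = c(id = "gene",
                                             log2fc = "log2FoldChange"))
  expect_equal(de2$log2fc, -1.2)

  expect_error(read_de_table(deseq), "lacks column.*available")
})

test_that("GMT parsing deduplicates members and enforces term uniqueness", {
  path <- write_tmp(c("SREBP_TARGETS\tdesc\tA\tB\tC",
                      "DUPMEM\tdesc\tX\tX\tY"), ext = ".gmt")
  gmt <- read_gmt(path)
  expect_equal(gmt$n_genes, c(3L, 2L))

  short <- write_tmp(c("GOOD\tdesc\tA", "BAD_ONLY_TWO\tdesc"), ext = ".gmt")
  expect_error(read_gmt(short), "line 2.*2 field")

  dup <- write_tmp(c("T1\tdesc\tA", "T1\tdesc\tB"), ext = ".gmt")
  expect_error(read_gmt(dup), "duplicate term")
})

test_that("sequence and target tables read with or without header", {
  p1 <- write_tmp(c("mature_id\tsequence", "miR-1\tACGU"), ext = ".tsv")
  p2 <- write_tmp(c("miR-1\tACGU"), ext = ".tsv")
  expect_equal(read_sequence_table(p1), read_sequence_table(p2))
  t1 <- write_tmp(c("mirna_id\tgene_id", "miR-1\tPANK1"), ext = ".tsv")
  expect_equal(read_target_map(t1)$gene_id, "PANK1")
})
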