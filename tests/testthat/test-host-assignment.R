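# Sense-strand host assignment, nested-host resolution, cluster detection.

test_that("intronic precursor in a same-strand coding gene is its host", {
  b <- dmd_example_bundle()
  a <- classify_contexts(b$mirnas, b$genes)
  row <- a[a$precursor_id == "mir-103a-1", ]
  expect_equal(row$context, "intragenic_sense")
  expect_equal(row$sublocation, "intronic")
  expect_equal(row$host_gene_id, "PANK3")
})

test_that("no containment, opposite strand, and non-coding-only containment classify correctly", {
  genes <- as_genes(
    make_structured_gene("GP", "c1", 10000, "+"),
    make_gene("GL", "c1", 50000, 56000, "+", biotype = "lincRNA")
  )
  mir <- as_mirnas(
    make_mirna("m_far", "c1", 30000, "+"),     # 500+ bp past every span
    make_mirna("m_anti", "c1", 10600, "-"),    # inside GP, wrong strand
    make_mirna("m_linc", "c1", 51000, "+")     # inside lincRNA only
  )
  a <- classify_contexts(mir, genes)
  expect_equal(a$context[a$precursor_id == "m_far"], "intergenic")
  expect_equal(a$sublocation[a$precursor_id == "m_far"], "none")

  anti <- a[a$precursor_id == "m_anti", ]
  expect_equal(anti$context, "intragenic_antisense")
  expect_true(is.na(anti$host_gene_id))

  linc <- a[a$precursor_id == "m_linc", ]
  expect_equal(linc$context, "intergenic")
  expect_equal(linc$noncoding_containers[[1]], "GL")
})

test_that("partial overlap at a gene edge is not embedding", {
  genes <- as_genes(make_structured_gene("G1", "c1", 1000, "+"))
  end <- max(genes$transcripts[[1]]$end)
  mir <- as_mirnas(make_mirna("m_edge", "c1", end - 40L, "+"))
  a <- classify_contexts(mir, genes)
  expect_equal(a$context, "intergenic")
})

test_that("nested hosts resolve to the smallest span with deterministic ties", {
  picked <- resolve_nested_hosts(tibble::tibble(
    gene_id = c("BIG", "SMALL"), start = c(0, 10000), end = c(300000, 60000)
  ))
  expect_equal(picked$primary, "SMALL")
  expect_equal(picked$alternates, "BIG")

  tie <- resolve_nested_hosts(tibble::tibble(
    gene_id = c("GENEB", "GENEA"), start = c(0, 100), end = c(5000, 5100)
  ))
  expect_equal(tie$primary, "GENEA")

  three <- resolve_nested_hosts(tibble::tibble(
    gene_id = c("G1", "G2", "G3"), start = c(0, 10, 20), end = c(9000, 5000, 1000)
  ))
  expect_length(three$alternates, 2L)
})

test_that("a precursor inside nested genes is assigned to the inner one with the outer as alternate", {
  outer <- make_structured_gene("OUTER", "c1", 0, "+",
                                n_exons = 3, exon_len = 500, intron_len = 20000)
  inner_ex <- tibble::tibble(transcript_id = "INNER.t1",
                             start = c(3000, 5000), end = c(3400, 5400))
  inner <- make_gene("INNER", "c1", 3000, 5400, "+", exons = inner_ex)
  mir <- as_mirnas(make_mirna("m1", "c1", 3600, "+"))
  a <- classify_contexts(mir, as_genes(outer, inner))
  expect_equal(a$host_gene_id, "INNER")
  expect_equal(a$alternates[[1]], "OUTER")
  expect_equal(a$sublocation, "intronic")
})

test_that("any-transcript-exonic wins and isoform disagreement is flagged", {
  exons <- dplyr::bind_rows(
    tibble::tibble(transcript_id = "G.t1", start = c(0, 5000), end = c(400, 5400)),
    tibble::tibble(transcript_id = "G.t2", start = c(0, 1000, 5000),
                   end = c(400, 1400, 5400))
  )
  gene <- as_genes(make_gene("G", "c1", 0, 5400, "+", exons = exons))
  # inside t2's middle exon, inside t1's intron
  a <- classify_contexts(as_mirnas(make_mirna("m1", "c1", 1100, "+")), gene)
  expect_equal(a$sublocation, "exonic")
  expect_true(a$isoform_disagreement)
})

test_that("straddling every transcript's exon boundary is called junction", {
  gene <- as_genes(make_structured_gene("G", "c1", 0, "+"))
  # spans the first exon/intron boundary (exon1 ends at 500)
  a <- classify_contexts(as_mirnas(make_mirna("m1", "c1", 460, "+")), gene)
  expect_equal(a$sublocation, "junction")
})

test_that("pseudo-exon hosts are flagged low-confidence", {
  gene <- as_genes(make_gene("G", "c1", 0, 5000, "+"))
  a <- classify_contexts(as_mirnas(make_mirna("m1", "c1", 1000, "+")), gene)
  expect_equal(a$context, "intragenic_sense")
  expect_equal(a$confidence_flag, "pseudo_exon_gene")
})

test_that("empty or chromosome-mismatched gene sets give intergenic calls", {
  mir <- as_mirnas(make_mirna("m1", "c9", 100, "+"))
  expect_warning(a0 <- classify_contexts(mir, as_genes()), "empty gene list")
  expect_equal(a0$context, "intergenic")
  a1 <- classify_contexts(mir, as_genes(make_structured_gene("G", "c1", 0, "+")))
  expect_equal(a1$context, "intergenic")
})

test_that("every miRNA receives exactly one context (partition property)", {
  for (seed in c(11, 22, 33, 44)) {
    ann <- random_annotation(seed)
    a <- classify_contexts(ann$mirnas, ann$genes)
    expect_equal(nrow(a), nrow(ann$mirnas))
    expect_true(all(a$context %in%
                      c("intragenic_sense", "intragenic_antisense", "intergenic")))
    expect_equal(sum(table(a$context)), nrow(ann$mirnas))
    # host iff sense; sublocation none iff intergenic
    expect_equal(!is.na(a$host_gene_id), a$context == "intragenic_sense")
    expect_equal(a$sublocation == "none", a$context == "intergenic")
  }
})

test_that("flipping every strand swaps sense and antisense, fixes intergenic", {
  flip <- function(s) ifelse(s == "+", "-", "+")
  for (seed in c(7, 77)) {
    ann <- random_annotation(seed)
    a1 <- classify_contexts(ann$mirnas, ann$genes)
    g2 <- ann$genes |> dplyr::mutate(strand = flip(strand))
    m2 <- ann$mirnas |> dplyr::mutate(strand = flip(strand))
    class(g2) <- class(ann$genes); class(m2) <- class(ann$mirnas)
    a2 <- classify_contexts(m2, g2)
    # flipping BOTH genes and miRNAs preserves relative orientation: the
    # context is unchanged
    expect_equal(a2$context[match(a1$precursor_id, a2$precursor_id)],
                 a1$context)
    # flipping only the miRNAs swaps sense <-> antisense wherever the
    # containing coding genes sit on a single strand (with containers on both
    # strands the call is sense either way); intergenic is always fixed
    m3 <- ann$mirnas |> dplyr::mutate(strand = flip(strand))
    class(m3) <- class(ann$mirnas)
    a3 <- classify_contexts(m3, ann$genes)
    both_strand <- purrr::map_lgl(seq_len(nrow(ann$mirnas)), function(i) {
      p <- ann$mirnas[i, ]
      cont <- ann$genes[ann$genes$chrom == p$chrom &
                          ann$genes$start <= p$start & p$end <= ann$genes$end &
                          ann$genes$biotype == "protein_coding", , drop = FALSE]
      length(unique(cont$strand)) == 2
    })
    swap2 <- c(intragenic_sense = "intragenic_antisense",
               intragenic_antisense = "intragenic_sense",
               intergenic = "intergenic")
    sel <- !both_strand
    expect_equal(a3$context[match(a1$precursor_id, a3$precursor_id)][sel],
                 unname(swap2[a1$context])[sel])
    expect_equal(a3$context[match(a1$precursor_id, a3$precursor_id)][!sel],
                 rep("intragenic_sense", sum(!sel)))
  }
})

test_that("cluster detection: singleton, pair, and single-linkage chain", {
  # lone precursor, nearest neighbour 1 Mb away
  lone <- as_mirnas(make_mirna("mA", "c1", 0, "+"),
                    make_mirna("mB", "c1", 1e6, "+"))
  expect_equal(nrow(detect_clusters(lone, max_gap = 10000)), 0L)

  pair <- as_mirnas(make_mirna("mA", "c1", 0, "+"),
                    make_mirna("mB", "c1", 2080, "+"))  # 2 kb gap
  cl <- detect_clusters(pair, max_gap = 10000)
  expect_equal(cl$n_members, 2L)

  # A -(6kb)- B -(6kb)- C: pairwise A-C exceeds the gap, chaining links all 3
  chain <- as_mirnas(make_mirna("mA", "c1", 0, "+"),
                     make_mirna("mB", "c1", 6080, "+"),
                     make_mirna("mC", "c1", 12160, "+"))
  cl3 <- detect_clusters(chain, max_gap = 10000)
  expect_equal(cl3$n_members, 3L)
  expect_equal(cl3$members[[1]], c("mA", "mB", "mC"))
})

test_that("clusters respect strand and chromosome and match the pairwise oracle", {
  for (seed in c(5, 15, 25)) {
    ann <- withr::with_seed(seed, {
      as_mirnas(purrr::map(1:12, function(i) {
        make_mirna(sprintf("m%02d", i), sample(c("c1", "c2"), 1),
                   sample(0:40000, 1), sample(c("+", "-"), 1))
      }))
    })
    got <- detect_clusters(ann, max_gap = 5000)
    got_sets <- unname(lapply(got$members, sort))
    expect_setequal(lapply(got_sets, paste, collapse = ","),
                    lapply(naive_clusters(ann, 5000), paste, collapse = ","))
  }
})

test_that("cluster output is invariant to input ordering", {
  ann <- random_annotation(99, n_mirnas = 10)
  shuffled <- ann$mirnas[withr::with_seed(1, sample(nrow(ann$mirnas))), ]
  class(shuffled) <- class(ann$mirnas)
  expect_equal(detect_clusters(ann$mirnas, 5000), detect_clusters(shuffled, 5000))
})
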