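# Seeded generator: determinism, feasibility, closed-loop truth recovery,
# format validity, and the packaged example bundle.

small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_genes = 30, n_mirnas = 20,
             n_families = 1, n_clusters = 1, n_nested_genes = 1,
             n_noncoding_genes = 1, n_dysregulated_intragenic = 4,
             n_dysregulated_intergenic = 2, universe_size = 200,
             n_terms = 4, planted_term_size = 10, ...)
}

test_that("identical seeds give identical in-memory bundles", {
  b1 <- simulate_bundle(small_cfg(seed = 3))
  b2 <- simulate_bundle(small_cfg(seed = 3))
  expect_identical(b1$genes, b2$genes)
  expect_identical(b1$mirnas, b2$mirnas)
  expect_identical(b1$mirna_de, b2$mirna_de)
  expect_identical(b1$gmt, b2$gmt)
  expect_identical(b1$truth, b2$truth)
  # and a different seed gives a different draw
  b3 <- simulate_bundle(small_cfg(seed = 4))
  expect_false(identical(b1$mirna_de, b3$mirna_de))
})

test_that("invalid and infeasible configurations fail before generation", {
  expect_error(sim_config(frac_intronic = 0.5, frac_exonic = 0.5,
                          frac_antisense = 0.2, frac_intergenic = 0),
               "sum to 1")
  expect_error(sim_config(codysregulation_rate = 1.5), "codysregulation_rate")
  expect_error(sim_config(n_genes = -1), "non-negative")

  # more cluster/family slots than intronic capacity
  expect_error(
    simulate_bundle(sim_config(n_genes = 5, n_mirnas = 10,
                               frac_intronic = 1, frac_exonic = 0,
                               frac_antisense = 0, frac_intergenic = 0,
                               n_clusters = 4, n_families = 2,
                               n_nested_genes = 0, n_noncoding_genes = 0,
                               n_dysregulated_intragenic = 1,
                               n_dysregulated_intergenic = 0,
                               universe_size = 100, planted_term_size = 5)),
    "infeasible")
  # universe smaller than the annotation it must contain
  expect_error(simulate_bundle(small_cfg(universe_size = 20)), "universe_size")
})

test_that("an all-intronic configuration classifies every miRNA intronic", {
  cfg <- sim_config(seed = 6, n_genes = 12, n_mirnas = 8,
                    frac_intronic = 1, frac_exonic = 0,
                    frac_antisense = 0, frac_intergenic = 0,
                    n_families = 0, n_clusters = 0, n_nested_genes = 0,
                    n_noncoding_genes = 0, n_dysregulated_intragenic = 4,
                    n_dysregulated_intergenic = 0, universe_size = 100,
                    n_terms = 2, planted_term_size = 5)
  b <- simulate_bundle(cfg)
  a <- classify_contexts(b$mirnas, b$genes)
  expect_true(all(a$context == "intragenic_sense"))
  expect_true(all(a$sublocation == "intronic"))
})

test_that("the pipeline recovers the planted ground truth exactly (closed loop)", {
  b <- simulate_bundle(sim_config(seed = 11))
  res <- run_host_pipeline(b$mirna_de, b$genes, b$mirnas, b$gmt,
                           sequences = b$sequences, gene_de = b$gene_de,
                           universe = "gmt-union")
  tr <- b$truth$contexts
  a <- res$assignments[match(tr$precursor_id, res$assignments$precursor_id), ]
  expect_equal(a$context, tr$context)
  expect_equal(a$sublocation, tr$sublocation)
  expect_equal(a$host_gene_id, tr$host_gene_id)

  # families: each engineered pair is one sequence group
  for (i in seq_len(nrow(b$truth$families))) {
    pre <- sort(b$truth$families$precursor_ids[[i]])
    hit <- purrr::map_lgl(res$families$precursor_ids,
                          \(p) identical(sort(p), pre))
    expect_equal(sum(hit), 1L)
  }
  # clusters
  got <- lapply(res$clusters$members, sort)
  expect_setequal(lapply(got, paste, collapse = ","),
                  lapply(lapply(b$truth$clusters, sort), paste, collapse = ","))
  # selection and host set
  expect_setequal(res$selected$feature_id,
                  c(b$truth$dys_mirnas_intragenic, b$truth$dys_mirnas_intergenic))
  expect_equal(res$host_set$n_intragenic_dysregulated, 71L)
  expect_equal(res$host_set$gene_ids, b$truth$hosts_of_dys)
  # co-dysregulation count equals the generator's coin flips
  expect_equal(res$codys$n_codys, b$truth$n_codys)
})

test_that("co-dysregulation counts are binomial at the configured rate", {
  # host-disjoint candidates make n_codys ~ Binomial(71, 12/71) by design
  cfg <- function(seed) sim_config(
    seed = seed, n_genes = 80, n_mirnas = 90,
    frac_intronic = 0.8, frac_exonic = 0, frac_antisense = 0,
    frac_intergenic = 0.2, n_families = 0, n_clusters = 0,
    n_nested_genes = 0, n_noncoding_genes = 0,
    n_dysregulated_intragenic = 71, n_dysregulated_intergenic = 0,
    codysregulation_rate = 12 / 71, universe_size = 300,
    n_terms = 2, planted_term_size = 10
  )
  counts <- vapply(1:200, function(s) simulate_bundle(cfg(s))$truth$n_codys,
                   integer(1))
  expect_true(all(counts >= 0 & counts <= 71))
  sd_mean <- sqrt(71 * (12 / 71) * (1 - 12 / 71)) / sqrt(200)
  expect_lt(abs(mean(counts) - 12), 2.576 * sd_mean)
})

test_that("emitted files respect their formats' syntactic rules", {
  dir <- file.path(tempdir(), "fmt_bundle")
  write_bundle(simulate_bundle(small_cfg(seed = 8)), dir)
  for (gff in c("genes.gff3", "mirnas.gff3")) {
    lines <- readLines(file.path(dir, gff))
    body <- lines[!startsWith(lines, "#") & nzchar(lines)]
    expect_true(all(lengths(strsplit(body, "\t", fixed = TRUE)) == 9L))
  }
  gmt_lines <- readLines(file.path(dir, "gene_sets.gmt"))
  expect_true(all(lengths(strsplit(gmt_lines, "\t", fixed = TRUE)) >= 3L))
  expect_true(file.exists(file.path(dir, "truth.json")))
  expect_silent(jsonlite::read_json(file.path(dir, "truth.json")))
})

test_that("the packaged example bundle encodes the documented relationships", {
  b <- dmd_example_bundle()
  # both miR-1307 arms are down in the DE table
  de <- b$mirna_de
  expect_true(all(de$log2fc[de$feature_id %in% c("miR-1307-5p", "miR-1307-3p")] < 0))
  expect_true(all(de$padj[de$feature_id %in% c("miR-1307-5p", "miR-1307-3p")] < 0.1))
  # the two miR-103a paralog arms carry the identical sequence
  seqs <- b$sequences
  expect_equal(seqs$sequence[seqs$mature_id == "miR-103a-1-3p"],
               seqs$sequence[seqs$mature_id == "miR-103a-2-3p"])
  # USMG5 is dysregulated in the gene DE table, the PANK genes are not
  gd <- b$gene_de
  expect_lt(gd$padj[gd$feature_id == "USMG5"], 0.1)
  expect_true(all(gd$padj[grepl("^PANK", gd$feature_id)] > 0.1))
})

test_that("the full pipeline runs from written files through the reader stack", {
  dir <- file.path(tempdir(), "dmd_files")
  write_bundle(dmd_example_bundle(), dir)
  res <- run_host_pipeline_files(
    mirna_de = file.path(dir, "mirna_de.tsv"),
    genes = file.path(dir, "genes.gff3"),
    mirnas = file.path(dir, "mirnas.gff3"),
    gmt = file.path(dir, "gene_sets.gmt"),
    sequences = file.path(dir, "mature_sequences.tsv"),
    gene_de = file.path(dir, "gene_de.tsv"),
    target_map = file.path(dir, "target_map.tsv")
  )
  expect_setequal(res$host_set$gene_ids, c("PANK1", "PANK2", "PANK3", "USMG5"))
  expect_equal(res$enrichment_host$term_id[1], "COA_BIOSYNTHESIS")
  out <- file.path(tempdir(), "dmd_out")
  written <- write_results(res, out, mirnas = read_mirna_annotations(
    file.path(dir, "mirnas.gff3")))
  expect_true(all(file.exists(written)))
})
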