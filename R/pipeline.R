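#' Run the host-gene interpretation pipeline
#'
#' End-to-end driver: select dysregulated miRNAs from the DE table, classify
#' every precursor's genomic context, group sequence-indistinguishable
#' matures, build the deduplicated host-gene set, quantify miRNA/host-gene
#' co-dysregulation (when a gene DE table is supplied), and run host-mode —
#' and optionally target-mode — over-representation analysis.
#'
#' @param mirna_de miRNA DE tibble ([read_de_table()] schema).
#' @param genes Gene models ([read_gene_models()]).
#' @param mirnas miRNA annotation ([read_mirna_annotations()]).
#' @param gmt Gene-set collection ([read_gmt()]).
#' @param sequences Optional mature-sequence table; without it every mature
#'   is its own family (id-keyed), so family expansion degenerates to direct
#'   host lookup except where matures share ids/names.
#' @param gene_de Optional gene DE tibble; enables the co-dysregulation
#'   report.
#' @param target_map Optional miRNA-to-target map; enables target-mode
#'   enrichment.
#' @param padj_threshold,min_abs_log2fc Selection rule (strict
#'   `padj < padj_threshold`); applied to both DE tables.
#' @param max_gap Cluster window (bp) for [detect_clusters()].
#' @param universe Background for enrichment: `"annotation"` (default;
#'   protein-coding genes of the annotation present in at least one term),
#'   `"host-capable"` (additionally restricted to genes hosting an annotated
#'   miRNA), `"gmt-union"` (every gene in the collection), or an explicit
#'   character vector of gene ids.
#' @param protein_coding Biotype value(s) treated as protein-coding.
#' @return A list of class `mirhost_result`: `selected`, `assignments`,
#'   `clusters`, `families`, `host_set`, `codys` (or `NULL`),
#'   `enrichment_host`, `enrichment_target` (or `NULL`), `universe`.
#' @export
run_host_pipeline <- function(mirna_de, genes, mirnas, gmt,
                              sequences = NULL, gene_de = NULL,
                              target_map = NULL,
                              padj_threshold = 0.1, min_abs_log2fc = 0,
                              max_gap = 10000,
                              universe = c("annotation", "host-capable", "gmt-union"),
                              protein_coding = "protein_coding") {
  selected <- select_dysregulated(mirna_de, padj_threshold, min_abs_log2fc)
  assignments <- classify_contexts(mirnas, genes, protein_coding)
  clusters <- detect_clusters(mirnas, max_gap)
  matures <- collect_matures(mirnas, sequences)
  families <- group_mature_families(matures)
  host_set <- build_host_gene_set(selected, families, assignments)

  keywords <- c("annotation", "host-capable", "gmt-union")
  if (is.character(universe) && all(universe %in% keywords)) {
    universe <- match.arg(universe, keywords)
    universe <- switch(universe,
      "annotation" = default_universe(genes, gmt, protein_coding = protein_coding),
      "host-capable" = default_universe(genes, gmt, assignments,
                                        host_capable = TRUE,
                                        protein_coding = protein_coding),
      "gmt-union" = sort(unique(unlist(gmt$genes)))
    )
  }

  codys <- NULL
  if (!is.null(gene_de) && nrow(host_set$provenance) > 0) {
    dys_genes <- select_dysregulated(gene_de, padj_threshold, min_abs_log2fc)
    codys <- co_dysregulation_report(host_set, dys_genes$feature_id,
                                     universe_size = length(universe))
  }

  enr_host <- enrich(host_set$gene_ids, gmt, universe, mode = "host")
  enr_target <- NULL
  if (!is.null(target_map)) {
    enr_target <- target_set_enrichment(selected$feature_id, target_map,
                                        gmt, universe)
  }

  structure(list(
    selected = selected, assignments = assignments, clusters = clusters,
    families = families, host_set = host_set, codys = codys,
    enrichment_host = enr_host, enrichment_target = enr_target,
    universe = universe
  ), class = "mirhost_result")
}

#' Run the pipeline from files on disk
#'
#' Thin convenience wrapper over the readers and [run_host_pipeline()]; the
#' interface the command-line entry point calls.
#'
#' @param mirna_de,genes,mirnas,gmt Paths to the required inputs.
#' @param sequences,gene_de,target_map Optional input paths.
#' @param ... Passed to [run_host_pipeline()].
#' @return A `mirhost_result`.
#' @export
run_host_pipeline_files <- function(mirna_de, genes, mirnas, gmt,
                                    sequences = NULL, gene_de = NULL,
                                    target_map = NULL, ...) {
  run_host_pipeline(
    mirna_de = read_de_table(mirna_de),
    genes = read_gene_models(genes),
    mirnas = read_mirna_annotations(mirnas),
    gmt = read_gmt(gmt),
    sequences = if (!is.null(sequences)) read_sequence_table(sequences),
    gene_de = if (!is.null(gene_de)) read_de_table(gene_de),
    target_map = if (!is.null(target_map)) read_target_map(target_map),
    ...
  )
}

#' @export
print.mirhost_result <- function(x, ...) {
  ctx <- table(x$assignments$context)
  cat("mirhost pipeline result\n")
  cat(sprintf("  precursors: %d (%s)\n", nrow(x$assignments),
              paste(sprintf("%s=%d", names(ctx), as.integer(ctx)), collapse = ", ")))
  cat(sprintf("  selected dysregulated miRNAs: %d\n", nrow(x$selected)))
  cat(sprintf("  clusters: %d, families with >1 precursor: %d\n",
              nrow(x$clusters), sum(x$families$n_precursors > 1)))
  print(x$host_set)
  if (!is.null(x$codys)) print(x$codys)
  nsig <- sum(x$enrichment_host$qvalue < 0.05)
  cat(sprintf("  host-mode enrichment: %d term(s) tested, %d at q < 0.05\n",
              nrow(x$enrichment_host), nsig))
  if (!is.null(x$enrichment_target)) {
    cat(sprintf("  target-mode enrichment: %d term(s) tested, %d at q < 0.05\n",
                nrow(x$enrichment_target),
                sum(x$enrichment_target$qvalue < 0.05)))
  }
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Emits the standard report files: `assignments.tsv`, `clusters.tsv`,
#' `families.tsv` (provenance), `host_genes.tsv`, `enrichment_host.tsv`,
#' optionally `enrichment_target.tsv`, `codysregulation.md`, and
#' `precursors.bed` when the annotation is supplied. Deterministic given the
#' same result object.
#'
#' @param result A `mirhost_result`.
#' @param dir Output directory (created if needed).
#' @param mirnas Optional miRNA annotation for the BED export.
#' @return Character vector of written paths, invisibly.
#' @export
write_results <- function(result, dir, mirnas = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(path) {
    written <<- c(written, path)
    path
  }

  assign_flat <- result$assignments |>
    mutate(alternates = map_chr(.data$alternates, comma_join),
           noncoding_containers = map_chr(.data$noncoding_containers, comma_join)) |>
    as_tibble()
  readr::write_tsv(assign_flat, emit(file.path(dir, "assignments.tsv")),
                   progress = FALSE)

  cl <- result$clusters |>
    mutate(members = map_chr(.data$members, comma_join)) |>
    as_tibble()
  readr::write_tsv(cl, emit(file.path(dir, "clusters.tsv")), progress = FALSE)

  fam_prov <- result$host_set$provenance |>
    left_join(result$families |> select("family_id", "n_precursors"),
              by = "family_id") |>
    select("query_id", group_size = "n_precursors", "precursor_id",
           "host_gene_id")
  readr::write_tsv(fam_prov, emit(file.path(dir, "families.tsv")),
                   progress = FALSE)

  readr::write_tsv(tibble(gene_id = result$host_set$gene_ids),
                   emit(file.path(dir, "host_genes.tsv")), progress = FALSE)
  write_enrichment_tsv(result$enrichment_host,
                       emit(file.path(dir, "enrichment_host.tsv")))
  if (!is.null(result$enrichment_target)) {
    write_enrichment_tsv(result$enrichment_target,
                         emit(file.path(dir, "enrichment_target.tsv")))
  }
  if (!is.null(result$codys)) {
    writeLines(render_codys_report(result$codys),
               emit(file.path(dir, "codysregulation.md")))
  }
  if (!is.null(mirnas)) {
    export_precursor_bed(result$assignments, mirnas,
                         emit(file.path(dir, "precursors.bed")))
  }
  invisible(written)
}
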