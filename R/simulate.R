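#' Simulation configuration for the synthetic-data generator
#'
#' The defaults emulate the statistical structure of the motivating study: a
#' miRNA complement of which roughly half is intragenic on the sense strand,
#' 71 dysregulated intragenic miRNAs, a miRNA/host-gene co-dysregulation
#' rate of 12/71, and one planted pathway term holding half of the
#' dysregulated host genes against a 5000-gene universe. Geometry
#' (chromosome layout, exon/intron sizes) is schematic: genes are
#' non-overlapping on a regular lattice except for a configurable number of
#' deliberately nested gene pairs that exercise nested-host resolution.
#'
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param n_genes Number of protein-coding genes.
#' @param n_mirnas Number of miRNA precursors (each with -5p and -3p
#'   matures).
#' @param frac_intronic,frac_exonic,frac_antisense,frac_intergenic Context
#'   fractions; must sum to 1.
#' @param n_families Sequence-indistinguishable precursor pairs placed in
#'   distinct host genes (shared -3p sequence and detection name).
#' @param n_clusters Co-hosted precursor pairs sharing one intron (gap well
#'   under `max_gap`).
#' @param n_nested_genes Nested gene pairs (small protein-coding gene inside
#'   a larger one's intron, same strand) each hosting one miRNA.
#' @param n_noncoding_genes lincRNA genes; one intergenic miRNA is placed
#'   inside the first, exercising the non-coding-container audit path.
#' @param n_dysregulated_intragenic Dysregulated intragenic detection ids
#'   (chosen with pairwise-disjoint host sets, so the co-dysregulation count
#'   is exactly binomial).
#' @param n_dysregulated_intergenic Dysregulated intergenic detection ids.
#' @param n_dysregulated_background_genes Dysregulated genes that host no
#'   selected miRNA (realistic background in the gene DE table).
#' @param codysregulation_rate Probability that a dysregulated intragenic
#'   miRNA's host gene is placed in the dysregulated-gene list.
#' @param n_terms Gene-set terms in the GMT (including the planted one).
#' @param planted_term_size,planted_fraction Size of the planted term and
#'   the fraction of it drawn from dysregulated host genes.
#' @param universe_size Total gene-universe size (annotation genes plus
#'   filler ids).
#' @param max_gap Cluster window the layout must respect.
#' @return A validated list of class `mirhost_sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_genes = 150, n_mirnas = 240,
                       frac_intronic = 0.35, frac_exonic = 0.10,
                       frac_antisense = 0.10, frac_intergenic = 0.45,
                       n_families = 3, n_clusters = 2, n_nested_genes = 2,
                       n_noncoding_genes = 5,
                       n_dysregulated_intragenic = 71,
                       n_dysregulated_intergenic = 30,
                       n_dysregulated_background_genes = 5,
                       codysregulation_rate = 12 / 71,
                       n_terms = 40, planted_term_size = 100,
                       planted_fraction = 0.5,
                       universe_size = 5000, max_gap = 10000) {
  cfg <- as.list(environment())
  fr <- c(frac_intronic, frac_exonic, frac_antisense, frac_intergenic)
  if (abs(sum(fr) - 1) > 1e-8) abort("context fractions must sum to 1")
  if (any(fr < 0)) abort("context fractions must be non-negative")
  counts <- c(n_genes, n_mirnas, n_families, n_clusters, n_nested_genes,
              n_noncoding_genes, n_dysregulated_intragenic,
              n_dysregulated_intergenic, n_terms, planted_term_size,
              universe_size)
  if (any(counts < 0)) abort("counts must be non-negative")
  if (codysregulation_rate < 0 || codysregulation_rate > 1) {
    abort("codysregulation_rate must be in [0, 1]")
  }
  if (planted_fraction < 0 || planted_fraction > 1) {
    abort("planted_fraction must be in [0, 1]")
  }
  structure(cfg, class = "mirhost_sim_config")
}

# layout constants (bp): 4 exons of 1200 with 8 kb introns, 25 kb between
# genes; precursors are 85 bp with 22 nt mature arms
.EXON_LEN <- 1200L
.INTRON_LEN <- 8000L
.N_EXONS <- 4L
.GENE_LEN <- .N_EXONS * .EXON_LEN + (.N_EXONS - 1L) * .INTRON_LEN
.GENE_GAP <- 25000L
.PRE_LEN <- 85L
.MAT_LEN <- 22L

#' Generate a synthetic input bundle with planted ground truth
#'
#' Builds, deterministically for a fixed seed, a complete set of pipeline
#' inputs (gene models, miRNA annotation, mature sequences, miRNA and gene
#' DE tables, GMT collection, target map) together with the ground truth the
#' generator planted, so every stage of the host-gene method is testable in
#' a closed loop. Infeasible configurations (more cluster/family slots than
#' intronic capacity, a universe smaller than the annotation, ...) fail
#' before anything is produced.
#'
#' @param config A [sim_config()].
#' @return A list of class `mirhost_bundle`: `genes`, `mirnas`, `sequences`,
#'   `mirna_de`, `gene_de`, `gmt`, `target_map`, `truth`, `config`.
#' @seealso [write_bundle()] to materialise it as files.
#' @export
simulate_bundle <- function(config = sim_config()) {
  stopifnot(inherits(config, "mirhost_sim_config"))
  cfg <- config

  n_intronic <- round(cfg$frac_intronic * cfg$n_mirnas)
  n_exonic <- round(cfg$frac_exonic * cfg$n_mirnas)
  n_antisense <- round(cfg$frac_antisense * cfg$n_mirnas)
  n_intergenic <- cfg$n_mirnas - n_intronic - n_exonic - n_antisense
  if (n_intergenic < 0) abort("context fractions round to more miRNAs than n_mirnas")

  n_singles <- n_intronic - 2L * cfg$n_clusters - cfg$n_nested_genes
  if (n_singles < 2L * cfg$n_families) {
    abort("infeasible config: not enough intronic slots for the requested clusters, nested pairs and families")
  }
  n_lattice <- n_singles + cfg$n_clusters + cfg$n_nested_genes + n_exonic + n_antisense
  if (n_lattice + cfg$n_nested_genes > cfg$n_genes) {
    abort("infeasible config: n_genes too small for the requested miRNA placements")
  }
  # host-disjoint dysregulation candidates: one per single host (family pair
  # counts once), one per cluster, one per nested pair
  n_candidates <- (n_singles - cfg$n_families) + cfg$n_clusters + cfg$n_nested_genes
  if (cfg$n_dysregulated_intragenic > n_candidates) {
    abort(sprintf("infeasible config: only %d host-disjoint intragenic candidates for %d dysregulated",
                  n_candidates, cfg$n_dysregulated_intragenic))
  }
  if (cfg$n_dysregulated_intergenic > n_intergenic) {
    abort("infeasible config: more dysregulated intergenic miRNAs than intergenic miRNAs")
  }
  if (cfg$universe_size < cfg$n_genes + cfg$planted_term_size) {
    abort("infeasible config: universe_size too small")
  }

  withr::with_seed(cfg$seed, {
    build_bundle(cfg, n_intronic, n_exonic, n_antisense, n_intergenic, n_singles)
  })
}

build_bundle <- function(cfg, n_intronic, n_exonic, n_antisense, n_intergenic,
                         n_singles) {
  ## --- protein-coding genes on a two-chromosome lattice -------------------
  n_lattice_genes <- cfg$n_genes - cfg$n_nested_genes
  gene_ids <- sprintf("SGENE_%04d", seq_len(cfg$n_genes))
  lattice_ids <- gene_ids[seq_len(n_lattice_genes)]
  inner_ids <- gene_ids[setdiff(seq_len(cfg$n_genes), seq_len(n_lattice_genes))]

  chrom <- ifelse(seq_len(n_lattice_genes) <= ceiling(n_lattice_genes / 2),
                  "chr1", "chr2")
  idx_on_chrom <- stats::ave(seq_len(n_lattice_genes), chrom, FUN = seq_along)
  start <- 50000L + (idx_on_chrom - 1L) * (.GENE_LEN + .GENE_GAP)
  strand <- sample(c("+", "-"), n_lattice_genes, replace = TRUE)

  make_transcripts <- function(gid, s) {
    ex_start <- s + (seq_len(.N_EXONS) - 1L) * (.EXON_LEN + .INTRON_LEN)
    tibble(transcript_id = paste0(gid, ".t1"),
           start = ex_start, end = ex_start + .EXON_LEN)
  }
  genes <- tibble(
    gene_id = lattice_ids,
    symbol = lattice_ids,
    biotype = "protein_coding",
    chrom = chrom, start = start, end = start + .GENE_LEN, strand = strand,
    pseudo_exon = FALSE,
    transcripts = map2(lattice_ids, start, make_transcripts)
  )

  ## --- roles --------------------------------------------------------------
  pool <- sample(lattice_ids)  # shuffled role assignment
  take <- function(n) {
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  single_hosts <- take(n_singles)
  cluster_hosts <- take(cfg$n_clusters)
  outer_hosts <- take(cfg$n_nested_genes)
  exonic_hosts <- take(n_exonic)
  antisense_hosts <- take(n_antisense)

  gidx <- setNames(seq_len(nrow(genes)), genes$gene_id)
  intron1_start <- function(gid) genes$start[gidx[gid]] + .EXON_LEN
  intron2_start <- function(gid) genes$start[gidx[gid]] + 2L * .EXON_LEN + .INTRON_LEN
  exon2_start <- function(gid) genes$start[gidx[gid]] + .EXON_LEN + .INTRON_LEN

  ## --- nested inner genes -------------------------------------------------
  inner_genes <- NULL
  if (cfg$n_nested_genes > 0) {
    inner_genes <- map2(inner_ids, outer_hosts, function(iid, oid) {
      s <- intron2_start(oid) + 3000L
      trx <- tibble(transcript_id = paste0(iid, ".t1"),
                    start = c(s, s + 1300L), end = c(s + 300L, s + 1600L))
      tibble(gene_id = iid, symbol = iid, biotype = "protein_coding",
             chrom = genes$chrom[gidx[oid]], start = s, end = s + 1600L,
             strand = genes$strand[gidx[oid]], pseudo_exon = FALSE,
             transcripts = list(trx))
    }) |> bind_rows()
    genes <- bind_rows(genes, inner_genes)
    gidx <- setNames(seq_len(nrow(genes)), genes$gene_id)
  }

  ## --- lincRNA genes ------------------------------------------------------
  if (cfg$n_noncoding_genes > 0) {
    tail1 <- max(genes$end[genes$chrom == "chr1"])
    nc_start <- tail1 + 60000L + (seq_len(cfg$n_noncoding_genes) - 1L) * 45000L
    nc_ids <- sprintf("SLINC_%03d", seq_len(cfg$n_noncoding_genes))
    nc <- tibble(
      gene_id = nc_ids, symbol = nc_ids, biotype = "lincRNA",
      chrom = "chr1", start = nc_start, end = nc_start + 5000L,
      strand = sample(c("+", "-"), cfg$n_noncoding_genes, replace = TRUE),
      pseudo_exon = FALSE,
      transcripts = map2(nc_ids, nc_start, function(gid, s) {
        tibble(transcript_id = paste0(gid, ".t1"), start = s, end = s + 5000L)
      })
    )
    genes <- bind_rows(genes, nc)
    gidx <- setNames(seq_len(nrow(genes)), genes$gene_id)
  }

  ## --- miRNA placement ----------------------------------------------------
  placements <- list()
  place <- function(host, chrom, start, strand, context, sublocation,
                    truth_host) {
    placements[[length(placements) + 1L]] <<- list(
      chrom = chrom, start = start, strand = strand,
      context = context, sublocation = sublocation,
      truth_host = truth_host, role_host = host
    )
  }
  for (gid in single_hosts) {
    place(gid, genes$chrom[gidx[gid]], intron1_start(gid) + 2000L,
          genes$strand[gidx[gid]], "intragenic_sense", "intronic", gid)
  }
  cluster_members <- list()
  for (gid in cluster_hosts) {
    s1 <- intron1_start(gid) + 1000L
    s2 <- s1 + .PRE_LEN + 1500L
    place(gid, genes$chrom[gidx[gid]], s1, genes$strand[gidx[gid]],
          "intragenic_sense", "intronic", gid)
    place(gid, genes$chrom[gidx[gid]], s2, genes$strand[gidx[gid]],
          "intragenic_sense", "intronic", gid)
    cluster_members[[gid]] <- c(length(placements) - 1L, length(placements))
  }
  for (j in seq_along(inner_ids)) {
    iid <- inner_ids[j]
    place(iid, genes$chrom[gidx[iid]], genes$start[gidx[iid]] + 300L + 15L,
          genes$strand[gidx[iid]], "intragenic_sense", "intronic", iid)
  }
  for (gid in exonic_hosts) {
    place(gid, genes$chrom[gidx[gid]], exon2_start(gid) + 200L,
          genes$strand[gidx[gid]], "intragenic_sense", "exonic", gid)
  }
  for (gid in antisense_hosts) {
    other <- setdiff(c("+", "-"), genes$strand[gidx[gid]])
    place(gid, genes$chrom[gidx[gid]], intron1_start(gid) + 2000L, other,
          "intragenic_antisense", "intronic", NA_character_)
  }
  # intergenic: lattice gaps, then beyond the chromosome tails
  lat <- genes[genes$gene_id %in% lattice_ids, ]
  gap_pos <- tibble(chrom = lat$chrom, start = lat$end + 12000L)
  tails <- lat |> group_by(.data$chrom) |> summarise(mx = max(.data$end), .groups = "drop")
  extra <- tibble(
    chrom = rep(tails$chrom[1], max(0, n_intergenic - nrow(gap_pos))),
    start = max(genes$end[genes$chrom == tails$chrom[1]]) + 100000L +
      seq_len(max(0, n_intergenic - nrow(gap_pos))) * 20000L
  )
  gap_pos <- bind_rows(gap_pos, extra)
  n_in_linc <- as.integer(cfg$n_noncoding_genes > 0 && n_intergenic > 0)
  if (n_in_linc == 1L) {
    linc <- genes[genes$biotype == "lincRNA", ][1, ]
    place(NA_character_, linc$chrom, linc$start + 1000L, linc$strand,
          "intergenic", "none", NA_character_)
  }
  for (j in seq_len(n_intergenic - n_in_linc)) {
    place(NA_character_, gap_pos$chrom[j], gap_pos$start[j],
          sample(c("+", "-"), 1), "intergenic", "none", NA_character_)
  }

  pl <- tibble(
    chrom = map_chr(placements, "chrom"),
    start = as.integer(map_int(placements, \(x) as.integer(x$start))),
    strand = map_chr(placements, "strand"),
    context = map_chr(placements, "context"),
    sublocation = map_chr(placements, "sublocation"),
    truth_host = map_chr(placements, "truth_host"),
    role_host = map_chr(placements, "role_host")
  ) |>
    mutate(end = .data$start + .PRE_LEN, .after = "start")
  n_pre <- nrow(pl)
  pl$precursor_id <- sprintf("syn-mir-%03d", seq_len(n_pre))
  pl$name <- pl$precursor_id

  ## --- matures, families, sequences ---------------------------------------
  rand_seq <- function(n) {
    m <- matrix(sample(c("A", "C", "G", "T"), n * .MAT_LEN, replace = TRUE),
                nrow = n)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  }
  mat5 <- tibble(
    precursor_id = pl$precursor_id,
    mature_id = sprintf("syn-miR-%03d-5p", seq_len(n_pre)),
    mature_name = sprintf("syn-miR-%03d-5p", seq_len(n_pre)),
    start = pl$start, end = pl$start + .MAT_LEN, sequence = rand_seq(n_pre)
  )
  mat3 <- tibble(
    precursor_id = pl$precursor_id,
    mature_id = sprintf("syn-miR-%03d-3p", seq_len(n_pre)),
    mature_name = sprintf("syn-miR-%03d-3p", seq_len(n_pre)),
    start = pl$end - .MAT_LEN, end = pl$end, sequence = rand_seq(n_pre)
  )
  # family pairs: the first 2*n_families single-host precursors share the
  # -3p sequence and detection name
  single_idx <- which(pl$role_host %in% single_hosts)
  family_truth <- NULL
  if (cfg$n_families > 0) {
    fam_rows <- split(single_idx[seq_len(2L * cfg$n_families)],
                      rep(seq_len(cfg$n_families), each = 2L))
    for (f in seq_along(fam_rows)) {
      rows <- fam_rows[[f]]
      shared_name <- sprintf("syn-miR-fam%02d-3p", f)
      mat3$mature_name[rows] <- shared_name
      mat3$sequence[rows] <- mat3$sequence[rows[1]]
    }
    family_truth <- tibble(
      family_name = sprintf("syn-miR-fam%02d-3p", seq_len(cfg$n_families)),
      precursor_ids = map(fam_rows, \(rows) pl$precursor_id[rows])
    )
  }

  matures <- bind_rows(mat5, mat3) |> arrange(.data$precursor_id, .data$start)
  mat_cols <- matures[, c("mature_id", "mature_name", "start", "end", "sequence")]
  mat_by_pre <- split(mat_cols, matures$precursor_id)
  mirnas <- pl |>
    select("precursor_id", "name", "chrom", "start", "end", "strand") |>
    mutate(matures = unname(mat_by_pre[.data$precursor_id])) |>
    arrange(.data$chrom, .data$start, .data$precursor_id)
  class(mirnas) <- c("mirhost_mirnas", class(tibble()))
  class(genes) <- c("mirhost_genes", class(tibble()))

  sequences <- matures |>
    distinct(.data$mature_id, .data$sequence) |>
    select("mature_id", "sequence")

  ## --- dysregulation ------------------------------------------------------
  # host-disjoint intragenic candidates: detection name of the -3p arm, one
  # per single host (family pair counted once), one per cluster, one per
  # nested pair
  fam_first_rows <- if (cfg$n_families > 0) {
    map_int(family_truth$precursor_ids, \(p) which(pl$precursor_id == p[1]))
  } else integer(0)
  fam_all_rows <- if (cfg$n_families > 0) {
    which(pl$precursor_id %in% unlist(family_truth$precursor_ids))
  } else integer(0)
  single_nonfam <- setdiff(single_idx, fam_all_rows)
  cluster_first <- map_int(cluster_members, 1)
  nested_rows <- which(pl$role_host %in% inner_ids)
  cand_rows <- c(single_nonfam, fam_first_rows, cluster_first, nested_rows)
  cand_names <- mat3$mature_name[cand_rows]

  dys_intra <- sample(cand_names, cfg$n_dysregulated_intragenic)
  inter_names <- mat3$mature_name[pl$context == "intergenic"]
  dys_inter <- sample(inter_names, cfg$n_dysregulated_intergenic)
  dys_ids <- c(dys_intra, dys_inter)

  detection_ids <- unique(matures$mature_name)
  is_dys <- detection_ids %in% dys_ids
  mirna_de <- tibble(
    feature_id = detection_ids,
    log2fc = ifelse(is_dys,
                    sample(c(-1, 1), length(detection_ids), replace = TRUE) *
                      runif(length(detection_ids), 0.8, 3),
                    runif(length(detection_ids), -0.4, 0.4)),
    padj = ifelse(is_dys,
                  runif(length(detection_ids), 1e-4, 0.09),
                  runif(length(detection_ids), 0.15, 0.95))
  ) |>
    mutate(pvalue = .data$padj * runif(length(detection_ids), 0.3, 1)) |>
    select("feature_id", "log2fc", "pvalue", "padj")

  ## --- co-dysregulated gene list ------------------------------------------
  name_hosts <- matures |>
    left_join(pl |> select("precursor_id", "truth_host"), by = "precursor_id") |>
    filter(!is.na(.data$truth_host)) |>
    group_by(.data$mature_name) |>
    summarise(hosts = list(sort(unique(.data$truth_host))), .groups = "drop")
  dys_hosts_by_id <- name_hosts |> filter(.data$mature_name %in% dys_intra)
  flips <- runif(nrow(dys_hosts_by_id)) < cfg$codysregulation_rate
  codys_ids <- dys_hosts_by_id$mature_name[flips]
  codys_genes <- map_chr(dys_hosts_by_id$hosts[flips], 1)
  hosts_of_dys <- sort(unique(unlist(dys_hosts_by_id$hosts)))

  pc_ids <- genes$gene_id[genes$biotype == "protein_coding"]
  bg_pool <- setdiff(pc_ids, hosts_of_dys)
  bg_dys <- sample(bg_pool, min(cfg$n_dysregulated_background_genes, length(bg_pool)))
  dys_genes <- sort(unique(c(codys_genes, bg_dys)))

  gene_is_dys <- pc_ids %in% dys_genes
  gene_de <- tibble(
    feature_id = pc_ids,
    log2fc = ifelse(gene_is_dys,
                    sample(c(-1, 1), length(pc_ids), replace = TRUE) *
                      runif(length(pc_ids), 0.6, 2.5),
                    runif(length(pc_ids), -0.3, 0.3)),
    padj = ifelse(gene_is_dys,
                  runif(length(pc_ids), 1e-4, 0.09),
                  runif(length(pc_ids), 0.15, 0.95))
  ) |>
    mutate(pvalue = .data$padj * runif(length(pc_ids), 0.3, 1)) |>
    select("feature_id", "log2fc", "pvalue", "padj")

  ## --- gene sets -----------------------------------------------------------
  universe <- c(pc_ids,
                sprintf("UGENE_%05d", seq_len(cfg$universe_size - length(pc_ids))))
  n_from_hosts <- min(round(cfg$planted_fraction * cfg$planted_term_size),
                      length(hosts_of_dys))
  planted_members <- c(
    sample(hosts_of_dys, n_from_hosts),
    sample(setdiff(universe, hosts_of_dys),
           cfg$planted_term_size - n_from_hosts)
  )
  size_lo <- min(30L, length(universe))
  size_hi <- min(300L, length(universe))
  other_terms <- map(seq_len(max(0, cfg$n_terms - 1L)), function(t) {
    sample(universe, sample(size_lo:size_hi, 1))
  })
  gmt <- tibble(
    term_id = c("SYNSET_PLANTED", sprintf("SYNSET_%03d", seq_along(other_terms))),
    description = c("planted host-gene pathway",
                    rep("random synthetic set", length(other_terms))),
    genes = c(list(sort(planted_members)), map(other_terms, sort))
  ) |>
    mutate(n_genes = map_int(.data$genes, length))

  ## --- target map ----------------------------------------------------------
  target_map <- tibble(
    mirna_id = rep(detection_ids, each = 25L),
    gene_id = unlist(map(detection_ids, \(x) sample(universe, 25L)))
  )

  truth <- list(
    contexts = pl |>
      select("precursor_id", "context", "sublocation",
             host_gene_id = "truth_host"),
    families = family_truth,
    clusters = unname(map(cluster_members, \(rows) pl$precursor_id[rows])),
    dys_mirnas_intragenic = sort(dys_intra),
    dys_mirnas_intergenic = sort(dys_inter),
    dys_genes = dys_genes,
    codys_ids = sort(codys_ids),
    n_codys = length(codys_ids),
    hosts_of_dys = hosts_of_dys,
    planted_term = "SYNSET_PLANTED",
    universe = universe
  )

  structure(list(genes = genes, mirnas = mirnas, sequences = sequences,
                 mirna_de = mirna_de, gene_de = gene_de, gmt = gmt,
                 target_map = target_map, truth = truth, config = cfg),
            class = "mirhost_bundle")
}

#' Write a simulated bundle to a directory
#'
#' Materialises an in-memory bundle as the plain-text formats the pipeline
#' consumes (`genes.gff3`, `mirnas.gff3`, `mature_sequences.tsv`,
#' `mirna_de.tsv`, `gene_de.tsv`, `gene_sets.gmt`, `target_map.tsv`) plus
#' `truth.json`. Output is byte-identical across runs for the same bundle.
#'
#' @param bundle A `mirhost_bundle` from [simulate_bundle()] or
#'   [dmd_example_bundle()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genes = file.path(dir, "genes.gff3"),
    mirnas = file.path(dir, "mirnas.gff3"),
    sequences = file.path(dir, "mature_sequences.tsv"),
    mirna_de = file.path(dir, "mirna_de.tsv"),
    gene_de = file.path(dir, "gene_de.tsv"),
    gmt = file.path(dir, "gene_sets.gmt"),
    target_map = file.path(dir, "target_map.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_gene_models_gff3(bundle$genes, paths[["genes"]])
  write_mirna_gff3(bundle$mirnas, paths[["mirnas"]])
  readr::write_tsv(bundle$sequences, paths[["sequences"]], progress = FALSE)
  de_out <- function(de) {
    tibble(id = de$feature_id, log2FC = de$log2fc,
           pvalue = de$pvalue, padj = de$padj)
  }
  readr::write_tsv(de_out(bundle$mirna_de), paths[["mirna_de"]], progress = FALSE)
  readr::write_tsv(de_out(bundle$gene_de), paths[["gene_de"]], progress = FALSE)
  write_gmt(bundle$gmt, paths[["gmt"]])
  readr::write_tsv(bundle$target_map, paths[["target_map"]], progress = FALSE)

  truth <- bundle$truth
  truth$contexts <- as.data.frame(truth$contexts)
  if (!is.null(truth$families)) {
    truth$families <- list(family_name = truth$families$family_name,
                           precursor_ids = truth$families$precursor_ids)
  }
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(paths)
}
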