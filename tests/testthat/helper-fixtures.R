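# In-code fixture builders and independent oracles used across the suite.

make_gene <- function(gene_id, chrom, start, end, strand,
                      biotype = "protein_coding", exons = NULL) {
  trx <- if (is.null(exons)) {
    tibble::tibble(transcript_id = paste0(gene_id, ".pseudo"),
                   start = start, end = end)
  } else {
    exons
  }
  tibble::tibble(gene_id = gene_id, symbol = gene_id, biotype = biotype,
                 chrom = chrom, start = start, end = end, strand = strand,
                 pseudo_exon = is.null(exons), transcripts = list(trx))
}

# single-transcript gene with regular exon/intron structure
make_structured_gene <- function(gene_id, chrom, start, strand,
                                 n_exons = 3, exon_len = 500, intron_len = 3000,
                                 biotype = "protein_coding") {
  ex_start <- start + (seq_len(n_exons) - 1L) * (exon_len + intron_len)
  exons <- tibble::tibble(transcript_id = paste0(gene_id, ".t1"),
                          start = ex_start, end = ex_start + exon_len)
  make_gene(gene_id, chrom, start, max(exons$end), strand, biotype, exons)
}

as_genes <- function(...) {
  out <- dplyr::bind_rows(...)
  class(out) <- c("mirhost_genes", class(tibble::tibble()))
  out
}

make_mirna <- function(precursor_id, chrom, start, strand, len = 80,
                       matures = NULL) {
  if (is.null(matures)) {
    matures <- tibble::tibble(
      mature_id = paste0(precursor_id, "-3p"),
      mature_name = paste0(precursor_id, "-3p"),
      start = start + len - 22L, end = start + len,
      sequence = NA_character_
    )
  }
  tibble::tibble(precursor_id = precursor_id, name = precursor_id,
                 chrom = chrom, start = start, end = start + len,
                 strand = strand, matures = list(matures))
}

as_mirnas <- function(...) {
  out <- dplyr::bind_rows(...)
  class(out) <- c("mirhost_mirnas", class(tibble::tibble()))
  out
}

# random small annotation for oracle-equivalence checks: genes may overlap
# and nest freely, biotypes and strands are mixed
random_annotation <- function(seed, n_genes = NULL, n_mirnas = 8) {
  withr::with_seed(seed, {
    n_g <- n_genes %||% sample(4:10, 1)
    genes <- purrr::map(seq_len(n_g), function(i) {
      s <- sample(0:8000, 1)
      make_gene(sprintf("G%02d", i), sample(c("cA", "cB"), 1),
                s, s + sample(300:5000, 1), sample(c("+", "-"), 1),
                biotype = sample(c("protein_coding", "lincRNA"), 1,
                                 prob = c(0.7, 0.3)))
    })
    mirnas <- purrr::map(seq_len(n_mirnas), function(i) {
      make_mirna(sprintf("m%02d", i), sample(c("cA", "cB"), 1),
                 sample(0:9000, 1), sample(c("+", "-"), 1))
    })
    list(genes = as_genes(genes), mirnas = as_mirnas(mirnas))
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# exhaustive O(n * m) containment scan: the context/host oracle
naive_classify <- function(mirnas, genes) {
  purrr::map_dfr(seq_len(nrow(mirnas)), function(i) {
    p <- mirnas[i, ]
    cont <- genes[genes$chrom == p$chrom &
                    genes$start <= p$start & p$end <= genes$end, , drop = FALSE]
    pc <- cont[cont$biotype == "protein_coding", , drop = FALSE]
    sense <- pc[pc$strand == p$strand, , drop = FALSE]
    anti <- pc[pc$strand != p$strand, , drop = FALSE]
    if (nrow(sense) > 0) {
      ord <- order(sense$end - sense$start, sense$gene_id)
      tibble::tibble(precursor_id = p$precursor_id,
                     context = "intragenic_sense",
                     host_gene_id = sense$gene_id[ord[1]])
    } else if (nrow(anti) > 0) {
      tibble::tibble(precursor_id = p$precursor_id,
                     context = "intragenic_antisense",
                     host_gene_id = NA_character_)
    } else {
      tibble::tibble(precursor_id = p$precursor_id, context = "intergenic",
                     host_gene_id = NA_character_)
    }
  })
}

# brute-force pairwise single-linkage chaining: the cluster oracle
naive_clusters <- function(mirnas, max_gap) {
  n <- nrow(mirnas)
  parent <- seq_len(n)
  find <- function(i) while (TRUE) {
    if (parent[i] == i) return(i)
    i <- parent[i]
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    a <- mirnas[i, ]; b <- mirnas[j, ]
    if (a$chrom == b$chrom && a$strand == b$strand) {
      gap <- max(a$start, b$start) - min(a$end, b$end)
      if (gap <= max_gap) parent[find(i)] <- find(j)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(mirnas$precursor_id, comp)
  groups <- purrr::keep(groups, \(g) length(g) >= 2)
  unname(lapply(groups, sort))
}

# subset-enumeration oracle for the hypergeometric upper tail (N small)
enum_hyper_tail <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k == 0))
  subsets <- utils::combn(N, n)
  counts <- colSums(subsets <= K)
  mean(counts >= k)
}

# hand-executed BH step-up recursion, independent of stats::p.adjust
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, m * p[ord[i]] / i)
    q[ord[i]] <- min(1, running)
  }
  q
}
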