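#' Flatten mature miRNAs into one table, optionally attaching sequences
#'
#' @param mirnas miRNA annotation tibble ([read_mirna_annotations()]).
#' @param sequences Optional sequence table ([read_sequence_table()]);
#'   matched on `mature_id`.
#' @return A tibble `mature_id`, `mature_name`, `precursor_id`, `start`,
#'   `end`, `sequence`.
#' @export
collect_matures <- function(mirnas, sequences = NULL) {
  out <- mirnas |>
    select("precursor_id", "matures") |>
    tidyr::unnest("matures")
  if (!is.null(sequences)) {
    out <- out |>
      select(-"sequence") |>
      left_join(sequences |> distinct(.data$mature_id, .keep_all = TRUE),
                by = "mature_id")
  }
  out |> select("mature_id", "mature_name", "precursor_id", "start", "end", "sequence")
}

#' Group mature miRNAs that are indistinguishable by sequence
#'
#' Distinct precursors often produce the identical mature sequence (e.g. the
#' miR-103a-1-3p / miR-103a-2-3p pair); small-RNA sequencing cannot tell
#' these apart, so a detected dysregulation of the shared mature must be
#' credited to *all* precursors that can produce it. Grouping is by exact
#' full-length sequence identity after normalisation (uppercase, U -> T) —
#' not seed identity, which would over-merge. Matures without a sequence fall
#' back to singleton groups keyed by `mature_id` (matures *sharing* an id,
#' as identical miRBase matures do, thereby still group together).
#'
#' @param matures Mature table from [collect_matures()].
#' @return A tibble, one row per family: `family_id`, `sequence` (`NA` for
#'   id-keyed groups), `mature_ids`, `mature_names`, `precursor_ids`
#'   (list-columns), `n_matures`, `n_precursors`.
#' @export
group_mature_families <- function(matures) {
  m <- matures |>
    mutate(seq_norm = normalize_rna(.data$sequence))

  conflicts <- m |>
    filter(!is.na(.data$seq_norm)) |>
    distinct(.data$mature_id, .data$seq_norm) |>
    count(.data$mature_id) |>
    filter(.data$n > 1)
  if (nrow(conflicts) > 0) {
    abort(sprintf("mature id(s) with conflicting sequences: %s",
                  comma_join(conflicts$mature_id)))
  }

  m <- m |> mutate(key = ifelse(is.na(.data$seq_norm),
                                paste0("id:", .data$mature_id),
                                paste0("seq:", .data$seq_norm)))
  groups <- m |>
    group_by(.data$key) |>
    summarise(
      sequence = dplyr::first(.data$seq_norm),
      mature_ids = list(sort(unique(.data$mature_id))),
      mature_names = list(sort(unique(.data$mature_name))),
      precursor_ids = list(sort(unique(.data$precursor_id))),
      .groups = "drop"
    ) |>
    mutate(first_member = map_chr(.data$mature_ids, 1)) |>
    arrange(.data$first_member) |>
    mutate(
      family_id = sprintf("family_%04d", row_number()),
      n_matures = map_int(.data$mature_ids, length),
      n_precursors = map_int(.data$precursor_ids, length)
    ) |>
    select("family_id", "sequence", "mature_ids", "mature_names",
           "precursor_ids", "n_matures", "n_precursors")
  groups
}

normalize_rna <- function(x) {
  out <- toupper(x)
  gsub("U", "T", out, fixed = TRUE)
}

#' Expand dysregulated matures to all host genes their family can explain
#'
#' For each queried (dysregulated) mature, takes the union of sense-strand
#' host genes over every precursor in its sequence family — because any of
#' those precursors could be the true source of the detected mature, all of
#' their host genes are considered. Queries are matched against mature ids
#' first, then mature names (DE tables typically carry the shared detection
#' name, e.g. `miR-103a-3p`, rather than per-precursor ids). Matures from
#' precursors without a sense-strand host contribute no gene; query ids
#' matching no annotated mature are returned in the `unmapped` attribute
#' rather than raising an error.
#'
#' @param query_ids Character vector of dysregulated mature ids/names.
#' @param families Family table from [group_mature_families()].
#' @param assignments Assignment table from [classify_contexts()].
#' @return A provenance tibble `query_id`, `family_id`, `mature_id`,
#'   `precursor_id`, `host_gene_id` (one row per gene contribution, host
#'   genes only), with attributes `genes` (the deduplicated host-gene ids)
#'   and `unmapped` (query ids matching no annotated mature).
#' @export
expand_family_hosts <- function(query_ids, families, assignments) {
  query_ids <- unique(query_ids)
  fam_long <- families |>
    select("family_id", "mature_ids") |>
    tidyr::unnest_longer("mature_ids", values_to = "mature_id")
  fam_names <- families |>
    select("family_id", "mature_names") |>
    tidyr::unnest_longer("mature_names", values_to = "mature_name")

  match_family <- function(q) {
    hit <- fam_long$family_id[fam_long$mature_id == q]
    if (length(hit) == 0) hit <- fam_names$family_id[fam_names$mature_name == q]
    unique(hit)
  }
  matched <- map(query_ids, match_family)
  unmapped <- query_ids[map_int(matched, length) == 0]

  hosts <- assignments |>
    filter(.data$context == "intragenic_sense") |>
    select("precursor_id", "host_gene_id")

  rows <- map2(query_ids, matched, function(q, fids) {
    if (length(fids) == 0) return(NULL)
    fam <- families[families$family_id %in% fids, , drop = FALSE]
    contrib <- fam |>
      select("family_id", "precursor_ids") |>
      tidyr::unnest_longer("precursor_ids", values_to = "precursor_id") |>
      inner_join(hosts, by = "precursor_id")
    if (nrow(contrib) == 0) return(NULL)
    contrib |>
      mutate(query_id = q,
             mature_id = map_chr(.data$family_id,
                                 \(f) fam$mature_ids[fam$family_id == f][[1]][1])) |>
      select("query_id", "family_id", "mature_id", "precursor_id", "host_gene_id")
  })
  out <- bind_rows(rows) |> distinct()
  if (nrow(out) == 0) {
    out <- tibble(query_id = character(0), family_id = character(0),
                  mature_id = character(0), precursor_id = character(0),
                  host_gene_id = character(0))
  }
  attr(out, "genes") <- sort(unique(out$host_gene_id))
  attr(out, "unmapped") <- unmapped
  out
}
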