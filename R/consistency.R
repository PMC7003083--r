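#' Taxonomic consistency of contaminant scaffolds
#'
#' A contaminant scaffold holds at least two contaminant-candidate CDS and
#' no confident-resident CDS. All CDS of a genuine contaminant scaffold
#' derive from one organism, so they are expected to share a single
#' foreign group; a scaffold mixing groups (e.g. one eubacterial and two
#' fungal CDS) is flagged inconsistent — a likely chimera between two
#' contaminant sequences.
#'
#' @param annotations Stage-2 annotations from [classify_foreign()].
#' @param table The [build_scaffold_table()] used for classification.
#' @return A tibble with one row per contaminant scaffold: `scaffold_id`,
#'   `n_contaminant_cds`, `groups` (comma-separated multiset),
#'   `n_groups`, `consistent`.
#' @export
consistency_check <- function(annotations, table) {
  stopifnot(inherits(table, "scaffold_table"))
  contam <- annotations |>
    filter(.data$stage2 == "contaminant_candidate") |>
    select("cds_id", "foreign_group")

  placements <- table$mapped |>
    select("cds_id", "scaffold_id") |>
    distinct()

  resident_scaffolds <- unique(
    table$mapped$scaffold_id[table$mapped$stage1 == "confident_arthropod"])

  placements |>
    inner_join(contam, by = "cds_id") |>
    filter(!.data$scaffold_id %in% resident_scaffolds) |>
    group_by(.data$scaffold_id) |>
    summarise(
      n_contaminant_cds = dplyr::n_distinct(.data$cds_id),
      groups = paste(sort(.data$foreign_group), collapse = ","),
      n_groups = dplyr::n_distinct(.data$foreign_group),
      .groups = "drop"
    ) |>
    filter(.data$n_contaminant_cds >= 2L) |>
    mutate(consistent = .data$n_groups == 1L) |>
    arrange(.data$scaffold_id)
}
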