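#' Retain and rank protein-similarity hits
#'
#' Applies the three hit filters — identity strictly greater than
#' `min_hit_identity_pct`, alignment length strictly greater than
#' `min_hit_aln_len_aa` amino acids, and E-value strictly lower than
#' `max_hit_evalue` — and ranks the survivors per CDS by ascending
#' E-value, breaking ties by descending bitscore then subject id.
#'
#' @param hits A hit tibble (see [read_hits()]); may hold many CDS.
#' @param thresholds A [pipeline_thresholds()] object.
#' @return The retained hits, ranked within each `query_id` (column
#'   `hit_rank`), with a logical `in_top` marking the `top_n_hits`
#'   smallest-E-value hits used for the majority vote.
#' @examples
#' tax <- taxonomy_table(data.frame(species = "ECOLI", group = "eubacteria"))
#' h <- tibble::tibble(query_id = "c1", subject_id = "ECOLI|p1",
#'                     subject_species = "ECOLI", identity_pct = 62.5,
#'                     aln_len = 120L, evalue = 1e-40, bitscore = 200)
#' retain_hits(h)
#' @export
retain_hits <- function(hits, thresholds = pipeline_thresholds()) {
  t <- thresholds
  hits |>
    filter(.data$identity_pct > t$min_hit_identity_pct,
           .data$aln_len > t$min_hit_aln_len_aa,
           .data$evalue < t$max_hit_evalue) |>
    arrange(.data$query_id, .data$evalue, dplyr::desc(.data$bitscore),
            .data$subject_id) |>
    group_by(.data$query_id) |>
    mutate(hit_rank = row_number(),
           in_top = .data$hit_rank <= t$top_n_hits) |>
    ungroup()
}

#' Stage 1: taxonomic assignment of each CDS from its best hits
#'
#' For every CDS, the filter-passing hits are ranked by E-value and the
#' `top_n_hits` best are voted on. The decision cascade is applied in this
#' fixed order:
#'
#' 1. fewer than `min_hits` retained hits, or hits to fewer than
#'    `min_distinct_species` distinct species → `orphan`;
#' 2. any foreign-source group (eubacteria, archaea, fungi, viridiplantae,
#'    protists) holding at least `majority_fraction` of the top hits →
#'    `foreign`, with that group recorded;
#' 3. all top hits metazoan and at least `majority_fraction` of them to
#'    the resident clade → `confident_arthropod`;
#' 4. at least `majority_fraction` of the top hits to non-resident
#'    metazoans and none to the resident clade → `other_metazoa`;
#' 5. otherwise `unassigned`.
#'
#' Fractions count hits, not distinct species; the minimum-two-species
#' rule is evaluated on all retained hits. At default thresholds at most
#' one group can reach the majority, so the cascade is unambiguous.
#'
#' @param hits A hit tibble (see [read_hits()]).
#' @param taxonomy A [taxonomy_table()]; every subject species must be
#'   present.
#' @param thresholds A [pipeline_thresholds()] object.
#' @param cds_ids Optional character vector of all CDS ids screened; CDS
#'   with no hits at all are then reported as orphans too. Defaults to the
#'   ids present in `hits`.
#' @return A tibble with one row per CDS: `cds_id`, `stage1` (one of
#'   `confident_arthropod`, `other_metazoa`, `foreign`, `orphan`,
#'   `unassigned`), `foreign_group` (`NA` unless `stage1 == "foreign"`),
#'   `n_retained`, `n_distinct_species`, `n_top`,
#'   `majority_fraction_observed` (largest per-group hit fraction over the
#'   top set, `NA` for orphans).
#' @export
assign_taxonomy <- function(hits, taxonomy,
                            thresholds = pipeline_thresholds(),
                            cds_ids = NULL) {
  t <- thresholds
  if (is.null(cds_ids)) cds_ids <- unique(hits$query_id)
  cds_ids <- as.character(cds_ids)

  empty <- tibble(cds_id = character(), stage1 = character(),
                  foreign_group = character(), n_retained = integer(),
                  n_distinct_species = integer(), n_top = integer(),
                  majority_fraction_observed = double())
  if (length(cds_ids) == 0L) return(empty)

  ret <- retain_hits(hits, t)
  if (nrow(ret)) {
    ret$group <- lookup_group(ret$subject_species, taxonomy)
    ret <- left_join(ret, tax_group_info(), by = "group")
  }

  per_cds <- if (nrow(ret)) {
    ret |>
      group_by(.data$query_id) |>
      summarise(
        n_retained = dplyr::n(),
        n_distinct_species = dplyr::n_distinct(.data$subject_species),
        n_top = sum(.data$in_top),
        n_top_metazoa = sum(.data$in_top & .data$is_metazoa),
        n_top_arthropod = sum(.data$in_top & .data$is_arthropod),
        .groups = "drop"
      )
  } else {
    tibble(query_id = character(), n_retained = integer(),
           n_distinct_species = integer(), n_top = integer(),
           n_top_metazoa = integer(), n_top_arthropod = integer())
  }

  fg <- foreign_groups()
  group_counts <- if (nrow(ret)) {
    ret |>
      filter(.data$in_top) |>
      count(.data$query_id, .data$group) |>
      group_by(.data$query_id) |>
      summarise(
        best_group = .data$group[which.max(.data$n)],
        best_group_n = max(.data$n),
        best_foreign_group = if (any(.data$group %in% fg)) {
          gsub <- .data$group[.data$group %in% fg]
          gsub[which.max(.data$n[.data$group %in% fg])]
        } else NA_character_,
        best_foreign_n = max(c(0L, .data$n[.data$group %in% fg])),
        .groups = "drop"
      )
  } else {
    tibble(query_id = character(), best_group = character(),
           best_group_n = integer(), best_foreign_group = character(),
           best_foreign_n = integer())
  }

  ann <- tibble(cds_id = cds_ids) |>
    left_join(per_cds, by = c(cds_id = "query_id")) |>
    left_join(group_counts, by = c(cds_id = "query_id")) |>
    mutate(across(c("n_retained", "n_distinct_species", "n_top",
                    "n_top_metazoa", "n_top_arthropod", "best_group_n",
                    "best_foreign_n"),
                  ~ dplyr::coalesce(.x, 0L)))

  decide <- function(n_retained, n_species, n_top, n_met, n_arth,
                     best_foreign_group, best_foreign_n) {
    if (n_retained < t$min_hits || n_species < t$min_distinct_species) {
      return(c("orphan", NA))
    }
    if (!is.na(best_foreign_group) &&
        best_foreign_n / n_top >= t$majority_fraction) {
      return(c("foreign", best_foreign_group))
    }
    frac_met <- n_met / n_top
    frac_arth <- n_arth / n_top
    if (frac_met >= t$confident_metazoa_fraction &&
        frac_arth >= t$majority_fraction) {
      return(c("confident_arthropod", NA))
    }
    frac_other_met <- (n_met - n_arth) / n_top
    if (frac_other_met >= t$majority_fraction && n_arth == 0) {
      return(c("other_metazoa", NA))
    }
    c("unassigned", NA)
  }

  dec <- purrr::pmap(
    list(ann$n_retained, ann$n_distinct_species, ann$n_top,
         ann$n_top_metazoa, ann$n_top_arthropod,
         ann$best_foreign_group, ann$best_foreign_n),
    decide
  )
  ann$stage1 <- vapply(dec, `[`, character(1), 1L)
  ann$foreign_group <- vapply(dec, `[`, character(1), 2L)
  ann$majority_fraction_observed <-
    ifelse(ann$stage1 == "orphan" | ann$n_top == 0, NA_real_,
           ann$best_group_n / ann$n_top)

  ann |>
    select("cds_id", "stage1", "foreign_group", "n_retained",
           "n_distinct_species", "n_top", "majority_fraction_observed") |>
    arrange(.data$cds_id)
}
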