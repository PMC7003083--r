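#' Build the scaffold co-localization table
#'
#' Only foreign candidates and confident-resident CDS are placed on
#' scaffolds (those are the categories the synteny test needs). Mappings
#' failing the inclusive filters (`aln_len_bp >= min_map_len_bp`,
#' `identity_pct >= min_map_identity_pct`) are dropped. Chimeric
#' alignments — one CDS whose two parts map to different scaffolds — link
#' their scaffold pair. The confident-resident tag is seeded on every
#' scaffold holding at least one mapped confident-resident CDS, then
#' propagated across the connected components of the chimera-link graph.
#'
#' @param annotations Stage-1 annotations from [assign_taxonomy()].
#' @param mappings Mapping tibble from [read_mappings()].
#' @param thresholds A [pipeline_thresholds()] object.
#' @return An object of class `scaffold_table`: a list with
#'   * `mapped` — tibble (`cds_id`, `scaffold_id`, `stage1`,
#'     `foreign_group`, `part_index`) of filter-passing placements;
#'   * `chimera_links` — tibble of unordered scaffold pairs
#'     (`scaffold_a` < `scaffold_b`) linked by a chimeric alignment;
#'   * `arthropod_tagged` — character vector of scaffolds carrying the
#'     (possibly propagated) confident-resident tag.
#' @export
build_scaffold_table <- function(annotations, mappings,
                                 thresholds = pipeline_thresholds()) {
  t <- thresholds
  unknown <- setdiff(unique(mappings$cds_id), annotations$cds_id)
  if (length(unknown)) {
    warning("ignoring mappings for CDS absent from annotations: ",
            paste(utils::head(unknown, 10), collapse = ", "),
            call. = FALSE)
    mappings <- filter(mappings, !.data$cds_id %in% unknown)
  }
  mappable <- annotations |>
    filter(.data$stage1 %in% c("foreign", "confident_arthropod")) |>
    select("cds_id", "stage1", "foreign_group")

  mapped <- mappings |>
    filter(.data$aln_len_bp >= t$min_map_len_bp,
           .data$identity_pct >= t$min_map_identity_pct) |>
    inner_join(mappable, by = "cds_id") |>
    select("cds_id", "scaffold_id", "stage1", "foreign_group",
           "part_index") |>
    distinct() |>
    arrange(.data$cds_id, .data$part_index)

  two_scaffold <- mapped |>
    distinct(.data$cds_id, .data$scaffold_id) |>
    count(.data$cds_id) |>
    filter(.data$n == 2L) |>
    pull(.data$cds_id)
  links <- mapped |>
    filter(.data$cds_id %in% two_scaffold) |>
    distinct(.data$cds_id, .data$scaffold_id) |>
    group_by(.data$cds_id) |>
    summarise(scaffold_a = sort(.data$scaffold_id)[1L],
              scaffold_b = sort(.data$scaffold_id)[2L],
              .groups = "drop") |>
    select("scaffold_a", "scaffold_b") |>
    distinct() |>
    arrange(.data$scaffold_a, .data$scaffold_b)

  seeds <- unique(mapped$scaffold_id[mapped$stage1 == "confident_arthropod"])
  tagged <- propagate_tag(seeds, links)

  structure(list(mapped = mapped, chimera_links = links,
                 arthropod_tagged = tagged),
            class = "scaffold_table")
}

# closure of seed scaffolds under chimera-link connectivity
propagate_tag <- function(seeds, links) {
  if (!length(seeds) || !nrow(links)) return(sort(seeds))
  g <- igraph::graph_from_data_frame(links, directed = FALSE)
  comp <- igraph::components(g)
  memb <- comp$membership
  seed_comps <- unique(memb[intersect(seeds, names(memb))])
  tagged <- union(seeds, names(memb)[memb %in% seed_comps])
  sort(tagged)
}

#' @export
print.scaffold_table <- function(x, ...) {
  cat("<scaffold_table>\n")
  cat("  mapped CDS placements:", nrow(x$mapped), "\n")
  cat("  chimera links:        ", nrow(x$chimera_links), "\n")
  cat("  resident-tagged:      ", length(x$arthropod_tagged), "scaffolds\n")
  invisible(x)
}

#' Stage 2: classify foreign candidates by scaffold synteny
#'
#' Each foreign candidate is adjudicated by the company it keeps on its
#' scaffold(s):
#'
#' * `hgt_candidate` — some scaffold it maps to carries the
#'   confident-resident tag (directly or through chimera propagation):
#'   physically linked to a resident gene.
#' * `contaminant_candidate` — otherwise, if some scaffold it maps to also
#'   carries at least one other mapped foreign candidate (a different CDS;
#'   the second part of its own chimeric alignment does not count).
#' * `uncertain` — otherwise: unmapped, or the sole mapped CDS on all its
#'   scaffolds, so synteny cannot adjudicate.
#'
#' Non-foreign CDS receive `stage2 = "not_applicable"`.
#'
#' @param annotations Stage-1 annotations from [assign_taxonomy()].
#' @param table A [build_scaffold_table()] result.
#' @return The annotations with columns `stage2` and `scaffold_id` added
#'   (first mapped scaffold, `NA` when unmapped).
#' @export
classify_foreign <- function(annotations, table) {
  stopifnot(inherits(table, "scaffold_table"))
  mapped <- table$mapped
  foreign_mapped <- filter(mapped, .data$stage1 == "foreign")

  scaffold_of <- mapped |>
    arrange(.data$cds_id, .data$part_index) |>
    group_by(.data$cds_id) |>
    summarise(scaffold_id = first(.data$scaffold_id), .groups = "drop")

  # per scaffold: number of distinct mapped foreign CDS
  per_scaffold_foreign <- foreign_mapped |>
    group_by(.data$scaffold_id) |>
    summarise(n_foreign = dplyr::n_distinct(.data$cds_id),
              .groups = "drop")

  classify_one <- function(cds) {
    scs <- foreign_mapped$scaffold_id[foreign_mapped$cds_id == cds]
    if (!length(scs)) return("uncertain")
    if (any(scs %in% table$arthropod_tagged)) return("hgt_candidate")
    n_other <- per_scaffold_foreign$n_foreign[
      match(scs, per_scaffold_foreign$scaffold_id)] - 1L
    if (any(n_other >= 1L)) return("contaminant_candidate")
    "uncertain"
  }

  foreign_ids <- annotations$cds_id[annotations$stage1 == "foreign"]
  stage2 <- setNames(rep("not_applicable", nrow(annotations)),
                     annotations$cds_id)
  stage2[foreign_ids] <- vapply(foreign_ids, classify_one, character(1))

  annotations |>
    mutate(stage2 = unname(stage2[.data$cds_id])) |>
    left_join(scaffold_of, by = "cds_id")
}
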