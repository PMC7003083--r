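#' Taxonomic groups recognized by the screen
#'
#' The screen partitions reference species into seven groups: five
#' non-metazoan groups treated as potential sources of contamination and
#' horizontal transfer (eubacteria, archaea, fungi, viridiplantae,
#' protists), the resident clade (arthropoda by default) and the remaining
#' metazoans (other_metazoa).
#'
#' @return A tibble with columns `group`, `is_metazoa`, `is_arthropod`
#'   and `is_foreign_source`, one row per group.
#' @examples
#' tax_group_info()
#' @export
tax_group_info <- function() {
  tibble(
    group = c("eubacteria", "archaea", "fungi", "viridiplantae", "protists",
              "arthropoda", "other_metazoa"),
    is_metazoa = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
    is_arthropod = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    is_foreign_source = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  )
}

foreign_groups <- function() {
  g <- tax_group_info()
  g$group[g$is_foreign_source]
}

#' Build a species-to-group taxonomy table
#'
#' Validates a two-column mapping from reference species identifiers to
#' one of the seven recognized taxonomic groups. Every species must appear
#' exactly once; looking up an unknown species downstream is an error, not
#' a silent default.
#'
#' @param df A data frame with columns `species` and `group`.
#' @return A tibble of class `xenoscan_taxonomy` with columns `species`,
#'   `group`, plus the group flags joined from [tax_group_info()].
#' @examples
#' taxonomy_table(data.frame(
#'   species = c("ECOLI", "DROME"),
#'   group = c("eubacteria", "arthropoda")
#' ))
#' @export
taxonomy_table <- function(df) {
  df <- as_tibble(df)
  if (!all(c("species", "group") %in% names(df))) {
    stop("taxonomy needs columns 'species' and 'group'", call. = FALSE)
  }
  df$species <- as.character(df$species)
  df$group <- as.character(df$group)
  dup <- unique(df$species[duplicated(df$species)])
  if (length(dup)) {
    stop("duplicated species in taxonomy: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  known <- tax_group_info()$group
  bad <- setdiff(unique(df$group), known)
  if (length(bad)) {
    stop("unknown taxonomic group(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- left_join(df[, c("species", "group")], tax_group_info(),
                   by = "group")
  class(out) <- c("xenoscan_taxonomy", class(out))
  out
}

#' Read a taxonomy table from a TSV file
#'
#' @param path Tab-separated file with a header containing `species` and
#'   `group` columns.
#' @return See [taxonomy_table()].
#' @export
read_taxonomy <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  taxonomy_table(df)
}

# Resolve species -> group, erroring on unknowns with the offending ids.
lookup_group <- function(species, taxonomy) {
  idx <- match(species, taxonomy$species)
  if (anyNA(idx)) {
    missing <- unique(species[is.na(idx)])
    stop("species absent from taxonomy: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) " ..." else "",
         call. = FALSE)
  }
  taxonomy$group[idx]
}
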