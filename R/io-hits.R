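#' Read a 12-column tabular protein-similarity hit file
#'
#' Parses the standard 12-column tab-separated search output
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`, the BLAST/DIAMOND "outfmt 6" layout) and resolves each
#' subject to a reference species, either by taking the prefix of `sseqid`
#' before `species_delim` (default) or through an explicit
#' `sseqid -> species` lookup table. Resolved species are validated
#' against the taxonomy; unresolvable subjects are an error listing the
#' offending ids, and malformed rows are reported with their line numbers.
#'
#' @param path Hit file path.
#' @param taxonomy A [taxonomy_table()].
#' @param species_delim Delimiter separating the species token from the
#'   rest of `sseqid` (default `"|"`). Ignored when `species_lookup` is
#'   given.
#' @param species_lookup Optional named character vector mapping full
#'   `sseqid` values to species identifiers.
#' @return A tibble with columns `query_id`, `subject_id`,
#'   `subject_species`, `identity_pct`, `aln_len`, `evalue`, `bitscore`.
#'   Zero rows parse to a zero-row tibble (all CDS then become orphans
#'   downstream).
#' @export
read_hits <- function(path, taxonomy, species_delim = "|",
                      species_lookup = NULL) {
  cols <- c("query_id", "subject_id", "identity_pct", "aln_len",
            "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
            "evalue", "bitscore")
  raw <- readr::read_tsv(path, col_names = cols,
                         col_types = readr::cols(.default = readr::col_character()),
                         comment = "#", progress = FALSE)
  if (nrow(raw) == 0L) {
    return(tibble(query_id = character(), subject_id = character(),
                  subject_species = character(), identity_pct = double(),
                  aln_len = integer(), evalue = double(),
                  bitscore = double()))
  }
  numeric_cols <- c("identity_pct", "aln_len", "evalue", "bitscore")
  parsed <- raw
  for (cl in numeric_cols) {
    v <- suppressWarnings(as.numeric(raw[[cl]]))
    bad <- which(is.na(v) & !is.na(raw[[cl]]))
    if (length(bad)) {
      stop(sprintf("non-numeric '%s' at line(s) %s of %s", cl,
                   paste(utils::head(bad, 10), collapse = ", "), path),
           call. = FALSE)
    }
    parsed[[cl]] <- v
  }
  species <- resolve_subject_species(parsed$subject_id, species_delim,
                                     species_lookup)
  grp <- lookup_group(species, taxonomy)  # errors on unknown species
  stopifnot(length(grp) == nrow(parsed))
  tibble(
    query_id = parsed$query_id,
    subject_id = parsed$subject_id,
    subject_species = species,
    identity_pct = parsed$identity_pct,
    aln_len = as.integer(parsed$aln_len),
    evalue = parsed$evalue,
    bitscore = parsed$bitscore
  )
}

resolve_subject_species <- function(subject_ids, species_delim,
                                    species_lookup) {
  if (!is.null(species_lookup)) {
    sp <- unname(species_lookup[subject_ids])
    missing <- unique(subject_ids[is.na(sp)])
    if (length(missing)) {
      stop("subject id(s) absent from species lookup: ",
           paste(utils::head(missing, 10), collapse = ", "),
           call. = FALSE)
    }
    return(sp)
  }
  has_delim <- grepl(species_delim, subject_ids, fixed = TRUE)
  if (!all(has_delim)) {
    missing <- unique(subject_ids[!has_delim])
    stop("cannot resolve species (no '", species_delim,
         "' delimiter and no lookup): ",
         paste(utils::head(missing, 10), collapse = ", "),
         call. = FALSE)
  }
  vapply(strsplit(subject_ids, species_delim, fixed = TRUE),
         `[`, character(1), 1L)
}
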