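#' Read a FASTA file into a named sequence set
#'
#' Thin wrapper over [Biostrings::readBStringSet()] returning plain
#' uppercase character sequences keyed by the first whitespace-delimited
#' token of each header. Duplicate identifiers are an error; an empty file
#' yields an empty set with a warning.
#'
#' @param path FASTA file path (optionally gzip-compressed).
#' @return A named character vector (id -> sequence).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    warning("empty FASTA: ", path, call. = FALSE)
    return(stats::setNames(character(0), character(0)))
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  seqs <- toupper(gsub("[-\\s]", "", as.character(set), perl = TRUE))
  stats::setNames(unname(seqs), ids)
}

#' Write a named sequence set to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Apply the assembly input filters
#'
#' Reproduces the pre-filters applied to each assembly before screening:
#' scaffolds shorter than `min_scaffold_len_bp` (default 200 bp) are
#' discarded, only the longest CDS is kept per gene (longest-transcript
#' selection), and CDS shorter than `min_cds_len_bp` (default 150 bp) are
#' discarded. Order of the survivors is deterministic (input order).
#'
#' @param scaffolds Named character vector of scaffold sequences.
#' @param cds Named character vector of CDS sequences.
#' @param gene_of Optional named character vector mapping `cds_id` to
#'   `gene_id`; when `NULL` or missing an entry, each CDS is its own gene.
#' @param thresholds An [pipeline_thresholds()] object.
#' @return A list with elements `scaffolds` and `cds` (filtered named
#'   character vectors).
#' @examples
#' filter_inputs(
#'   scaffolds = c(s1 = strrep("A", 250), s2 = strrep("A", 199)),
#'   cds = c(c1 = strrep("A", 300), c2 = strrep("A", 450)),
#'   gene_of = c(c1 = "g1", c2 = "g1")
#' )
#' @export
filter_inputs <- function(scaffolds, cds, gene_of = NULL,
                          thresholds = pipeline_thresholds()) {
  t <- thresholds
  scaffolds <- scaffolds[nchar(scaffolds) >= t$min_scaffold_len_bp]

  if (length(cds)) {
    ids <- names(cds)
    genes <- if (is.null(gene_of)) ids else {
      g <- unname(gene_of[ids])
      ifelse(is.na(g), ids, g)
    }
    tab <- tibble(cds_id = ids, gene = genes, len = nchar(cds),
                  ord = seq_along(ids))
    keep <- tab |>
      group_by(.data$gene) |>
      filter(.data$len == max(.data$len)) |>
      slice_head(n = 1L) |>                 # ties: first occurrence wins
      ungroup() |>
      filter(.data$len >= t$min_cds_len_bp) |>
      arrange(.data$ord)
    cds <- cds[keep$cds_id]
  }
  list(scaffolds = scaffolds, cds = cds)
}
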