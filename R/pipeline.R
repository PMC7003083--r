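#' Run the full screen end to end
#'
#' Composes the pipeline stages on in-memory inputs: input filtering,
#' stage-1 taxonomic assignment, scaffold-table construction, stage-2
#' synteny classification and per-assembly summary. Each assembly is
#' evaluated independently; given identical inputs and thresholds, the
#' result is identical.
#'
#' @param scaffolds Named character vector of scaffold sequences, or
#'   `NULL` to skip sequence-level filtering (then `scaffold_lengths`
#'   must be given).
#' @param cds Named character vector of CDS sequences, or `NULL` (then
#'   `cds_ids` taken from the hit table only).
#' @param hits Hit tibble (see [read_hits()]).
#' @param taxonomy A [taxonomy_table()].
#' @param mappings Mapping tibble (see [read_mappings()]).
#' @param gene_of Optional `cds_id -> gene_id` map for longest-transcript
#'   selection.
#' @param thresholds A [pipeline_thresholds()] object.
#' @param scaffold_lengths Optional named lengths; derived from
#'   `scaffolds` when those are given.
#' @return A list of class `xenoscan_run` with elements `annotations`
#'   (stage-2 annotation tibble), `table` (the scaffold table), `report`
#'   (one-row summary tibble) and `log` (per-stage record counts).
#' @export
run_pipeline <- function(scaffolds = NULL, cds = NULL, hits, taxonomy,
                         mappings, gene_of = NULL,
                         thresholds = pipeline_thresholds(),
                         scaffold_lengths = NULL) {
  log <- list()
  if (!is.null(scaffolds) && !is.null(cds)) {
    filt <- filter_inputs(scaffolds, cds, gene_of, thresholds)
    scaffolds <- filt$scaffolds
    cds <- filt$cds
    hits <- filter(hits, .data$query_id %in% names(cds))
    mappings <- filter(mappings, .data$cds_id %in% names(cds),
                       .data$scaffold_id %in% names(scaffolds))
  }
  if (is.null(scaffold_lengths)) {
    if (is.null(scaffolds)) {
      stop("either scaffolds or scaffold_lengths must be supplied",
           call. = FALSE)
    }
    scaffold_lengths <- vapply(scaffolds, nchar, integer(1))
  }
  cds_ids <- if (!is.null(cds)) names(cds) else unique(hits$query_id)
  log$n_cds <- length(cds_ids)
  log$n_scaffolds <- length(scaffold_lengths)
  log$n_hits <- nrow(hits)

  ann1 <- assign_taxonomy(hits, taxonomy, thresholds, cds_ids = cds_ids)
  log$stage1 <- as.list(table(ann1$stage1))

  sctab <- build_scaffold_table(ann1, mappings, thresholds)
  log$n_mapped <- nrow(sctab$mapped)

  ann2 <- classify_foreign(ann1, sctab)
  log$stage2 <- as.list(table(ann2$stage2[ann2$stage2 != "not_applicable"]))

  report <- summarize_assembly(ann2, sctab, scaffold_lengths)

  structure(list(annotations = ann2, table = sctab, report = report,
                 log = log, thresholds = thresholds),
            class = "xenoscan_run")
}

#' @export
print.xenoscan_run <- function(x, ...) {
  cat("<xenoscan_run>\n")
  r <- x$report
  cat(sprintf("  CDS: %d (resident %d, foreign %d, orphan %d)\n",
              r$n_cds_total, r$n_confident_arthropod, r$n_foreign,
              r$n_orphan))
  cat(sprintf("  foreign: %d contaminant, %d HGT, %d uncertain\n",
              r$n_contaminant_cds, r$n_hgt_cds, r$n_uncertain_cds))
  cat(sprintf("  contaminant scaffolds: %d (%d bp)   N50: %d bp\n",
              r$n_contaminant_scaffolds,
              r$contaminant_scaffold_cumulative_bp, r$n50_bp))
  invisible(x)
}

#' Write a cleaned scaffold FASTA excluding contaminant scaffolds
#'
#' Convenience writer that excludes whole contaminant scaffolds
#' (at least two contaminant CDS, no confident-resident CDS) from the
#' assembly FASTA. No sequence is modified, only whole scaffolds dropped.
#'
#' @param scaffolds Named character vector of scaffold sequences.
#' @param run An [run_pipeline()] result.
#' @param path Output FASTA path.
#' @return Invisibly, the ids of the dropped scaffolds.
#' @export
drop_contaminant_scaffolds <- function(scaffolds, run, path) {
  drop <- contaminant_scaffolds(run$annotations, run$table)
  write_fasta(scaffolds[!names(scaffolds) %in% drop], path)
  invisible(drop)
}

#' Invoke an external search or mapping tool via a command template
#'
#' The pipeline consumes precomputed hit and mapping files; this optional
#' hook runs a user-declared command template (placeholders `{in}`,
#' `{out}` and `{db}` are substituted verbatim) so that a search or
#' mapping step can be launched from the same session. The output file
#' then enters the normal parsers unchanged.
#'
#' @param template Command template, e.g.
#'   `"diamond blastp --more-sensitive -q {in} -d {db} -o {out}"`.
#' @param input,output,db Paths substituted into the template.
#' @return `output`, invisibly; errors with the captured stderr if the
#'   command exits nonzero, and with a pointer to precomputed-file mode if
#'   the binary is missing.
#' @export
invoke_external <- function(template, input, output, db = "") {
  cmd <- template
  cmd <- gsub("{in}", input, cmd, fixed = TRUE)
  cmd <- gsub("{out}", output, cmd, fixed = TRUE)
  cmd <- gsub("{db}", db, cmd, fixed = TRUE)
  binary <- strsplit(trimws(cmd), "\\s+")[[1]][1]
  if (Sys.which(binary) == "") {
    stop("external tool '", binary, "' not found on PATH; ",
         "run it elsewhere and supply its output as a precomputed file",
         call. = FALSE)
  }
  res <- system(cmd, intern = TRUE, ignore.stderr = FALSE)
  status <- attr(res, "status") %||% 0L
  if (status != 0L) {
    stop("external command failed (exit ", status, "): ", cmd,
         call. = FALSE)
  }
  invisible(output)
}
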