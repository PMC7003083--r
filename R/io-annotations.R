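#' Write and read the final annotation table
#'
#' The annotation TSV holds one row per CDS with columns `cds_id`,
#' `stage1`, `foreign_group`, `stage2`, `scaffold_id`, `n_top_hits`,
#' `majority_fraction_observed`, sorted by `cds_id`. A JSON sidecar
#' (`<path>.run.json`) records the thresholds used and MD5 checksums of
#' the declared input files, so identical runs produce byte-identical
#' outputs.
#'
#' @param annotations Stage-2 annotations from [classify_foreign()].
#' @param path Output TSV path.
#' @param thresholds The [pipeline_thresholds()] used.
#' @param input_files Optional named character vector of input paths to
#'   checksum into the sidecar.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path,
                              thresholds = pipeline_thresholds(),
                              input_files = NULL) {
  out <- annotations |>
    mutate(n_top_hits = .data$n_top) |>
    select("cds_id", "stage1", "foreign_group", "stage2", "scaffold_id",
           "n_top_hits", "majority_fraction_observed") |>
    arrange(.data$cds_id)
  readr::write_tsv(out, path, progress = FALSE)

  sidecar <- list(thresholds = unclass(thresholds))
  if (!is.null(input_files)) {
    sums <- tools::md5sum(unname(input_files))
    sidecar$input_checksums <- as.list(stats::setNames(unname(sums),
                                                       names(input_files)))
  }
  jsonlite::write_json(sidecar, paste0(path, ".run.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    cds_id = readr::col_character(),
                    stage1 = readr::col_character(),
                    foreign_group = readr::col_character(),
                    stage2 = readr::col_character(),
                    scaffold_id = readr::col_character(),
                    n_top_hits = readr::col_integer(),
                    majority_fraction_observed = readr::col_double()
                  ))
}
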