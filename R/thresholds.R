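#' Pipeline thresholds
#'
#' All numeric constants of the screening pipeline live in a single
#' `xenoscan_thresholds` object. The defaults reproduce the published
#' screening protocol for arthropod assemblies.
#'
#' Inequality conventions follow the protocol's wording: the three hit
#' filters are strict (`identity > 40`%, `alignment length > 75` aa,
#' `E-value < 1e-10`), whereas the mapping filters are inclusive
#' ("minimum" denotes an attainable bound: `>= 100` bp, `>= 95`%
#' identity), as are the input-length filters (scaffolds `>= 200` bp,
#' CDS `>= 150` bp are kept).
#'
#' @param min_hit_identity_pct Exclusive lower bound on hit percent
#'   identity (default 40).
#' @param min_hit_aln_len_aa Exclusive lower bound on hit alignment length
#'   in amino acids (default 75).
#' @param max_hit_evalue Exclusive upper bound on hit E-value (default
#'   1e-10).
#' @param min_hits Minimum number of retained hits for any taxonomic
#'   assignment; fewer makes the CDS an orphan (default 2).
#' @param min_distinct_species Minimum number of distinct subject species
#'   among retained hits (default 2).
#' @param top_n_hits Number of smallest-E-value retained hits used for the
#'   majority vote (default 10).
#' @param majority_fraction Fraction of top hits a group must reach for
#'   assignment (default 0.70).
#' @param confident_metazoa_fraction Fraction of top hits that must be
#'   metazoan for the confident-resident call (default 1.00).
#' @param min_map_len_bp Inclusive minimum CDS-to-scaffold alignment length
#'   in bp (default 100).
#' @param min_map_identity_pct Inclusive minimum mapping percent identity
#'   (default 95).
#' @param min_scaffold_len_bp Inclusive minimum scaffold length kept at
#'   input filtering (default 200).
#' @param min_cds_len_bp Inclusive minimum CDS length kept at input
#'   filtering (default 150).
#' @param family_identity_fraction Inclusive minimum pairwise identity
#'   (fraction in `[0,1]`) for single-linkage family clustering
#'   (default 0.60).
#' @param logit_adjustment Proportion used to squeeze 0 and 1 away from
#'   the boundary before the logit transform (default 0.025).
#' @param resident_clade,enclosing_clade Names of the resident taxonomic
#'   group and its enclosing clade flag. The defaults (`"arthropoda"`
#'   inside metazoa) reproduce the published analysis; the screen applies
#'   to any taxon given a suitable taxonomy table.
#'
#' @return An object of class `xenoscan_thresholds` (a named list).
#' @examples
#' t <- pipeline_thresholds()
#' t$top_n_hits
#' @export
pipeline_thresholds <- function(min_hit_identity_pct = 40,
                                min_hit_aln_len_aa = 75,
                                max_hit_evalue = 1e-10,
                                min_hits = 2L,
                                min_distinct_species = 2L,
                                top_n_hits = 10L,
                                majority_fraction = 0.70,
                                confident_metazoa_fraction = 1.00,
                                min_map_len_bp = 100,
                                min_map_identity_pct = 95,
                                min_scaffold_len_bp = 200,
                                min_cds_len_bp = 150,
                                family_identity_fraction = 0.60,
                                logit_adjustment = 0.025,
                                resident_clade = "arthropoda",
                                enclosing_clade = "metazoa") {
  t <- list(
    min_hit_identity_pct = as.numeric(min_hit_identity_pct),
    min_hit_aln_len_aa = as.numeric(min_hit_aln_len_aa),
    max_hit_evalue = as.numeric(max_hit_evalue),
    min_hits = as.integer(min_hits),
    min_distinct_species = as.integer(min_distinct_species),
    top_n_hits = as.integer(top_n_hits),
    majority_fraction = as.numeric(majority_fraction),
    confident_metazoa_fraction = as.numeric(confident_metazoa_fraction),
    min_map_len_bp = as.numeric(min_map_len_bp),
    min_map_identity_pct = as.numeric(min_map_identity_pct),
    min_scaffold_len_bp = as.numeric(min_scaffold_len_bp),
    min_cds_len_bp = as.numeric(min_cds_len_bp),
    family_identity_fraction = as.numeric(family_identity_fraction),
    logit_adjustment = as.numeric(logit_adjustment),
    resident_clade = as.character(resident_clade),
    enclosing_clade = as.character(enclosing_clade)
  )
  validate_thresholds(t)
  structure(t, class = "xenoscan_thresholds")
}

validate_thresholds <- function(t) {
  fracs <- c("majority_fraction", "confident_metazoa_fraction",
             "family_identity_fraction", "logit_adjustment")
  for (f in fracs) {
    if (t[[f]] < 0 || t[[f]] > 1) {
      stop(sprintf("threshold '%s' must lie in [0,1], got %s", f, t[[f]]),
           call. = FALSE)
    }
  }
  counts <- c("min_hits", "min_distinct_species", "top_n_hits")
  for (f in counts) {
    if (t[[f]] < 1L) {
      stop(sprintf("threshold '%s' must be >= 1, got %s", f, t[[f]]),
           call. = FALSE)
    }
  }
  if (t$logit_adjustment >= 0.5) {
    stop("logit_adjustment must be < 0.5", call. = FALSE)
  }
  invisible(t)
}

#' @export
print.xenoscan_thresholds <- function(x, ...) {
  cat("<xenoscan_thresholds>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-28s %s\n", nm, format(x[[nm]], digits = 15)))
  }
  invisible(x)
}

#' Read and write a thresholds configuration file
#'
#' The configuration is a plain-text `key = value` file carrying every
#' field of [pipeline_thresholds()]. Writing then reading a configuration
#' recovers an identical object.
#'
#' @param t An `xenoscan_thresholds` object.
#' @param path File path.
#' @return `write_thresholds()` returns `path` invisibly;
#'   `read_thresholds()` returns an `xenoscan_thresholds` object.
#' @examples
#' p <- tempfile(fileext = ".conf")
#' write_thresholds(pipeline_thresholds(), p)
#' identical(read_thresholds(p), pipeline_thresholds())
#' @export
write_thresholds <- function(t, path) {
  stopifnot(inherits(t, "xenoscan_thresholds"))
  vals <- vapply(t, function(v) {
    if (is.character(v)) v else format(v, digits = 17, scientific = NA)
  }, character(1))
  writeLines(paste(names(t), "=", vals), path)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(lengths(kv) != 2L)
  if (length(bad)) {
    stop("malformed config line(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- trimws(vapply(kv, `[`, character(1), 2L))
  args <- as.list(vals)
  names(args) <- keys
  character_keys <- c("resident_clade", "enclosing_clade")
  for (k in setdiff(keys, character_keys)) args[[k]] <- as.numeric(args[[k]])
  do.call(pipeline_thresholds, args)
}
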