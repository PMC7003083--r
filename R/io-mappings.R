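#' Read CDS-to-scaffold mapping records
#'
#' Normalizes placements of CDS on assembly scaffolds from one of three
#' dialects into a single internal table with 1-based inclusive
#' coordinates:
#'
#' * `"tsv"` — the internal table: tab-separated with header columns
#'   `cds_id`, `scaffold_id`, `start`, `end`, `strand`, `aln_len_bp`,
#'   `identity_pct`, `part_index`.
#' * `"paf"` — standard PAF (12+ columns, 0-based half-open target
#'   coordinates, shifted to 1-based inclusive on read); identity is
#'   computed as residue matches / alignment block length.
#' * `"gff3"` — mapping features (type `gene` or `mRNA`) whose attribute
#'   column carries `ID=` (or `Name=`), and `Identity=`/`identity=`
#'   percent; alignment length defaults to the feature span.
#'
#' After parsing, each CDS is reduced to at most one best placement per
#' `part_index` (highest identity, then longest alignment, then
#' lexicographically smallest scaffold id). Part index 1 marks the single
#' or 5' alignment; part 2 the 3' piece of a chimeric alignment whose two
#' ends map to different scaffolds.
#'
#' @param path Mapping file.
#' @param dialect One of `"tsv"`, `"paf"`, `"gff3"`.
#' @param scaffold_lengths Optional named numeric vector; when supplied,
#'   coordinates exceeding the scaffold length are an error. When absent
#'   the check is skipped with a message.
#' @return A tibble with columns `cds_id`, `scaffold_id`, `start`, `end`,
#'   `strand`, `aln_len_bp`, `identity_pct`, `part_index`.
#' @export
read_mappings <- function(path, dialect = c("tsv", "paf", "gff3"),
                          scaffold_lengths = NULL) {
  dialect <- match.arg(dialect)
  m <- switch(dialect,
    tsv = read_mappings_tsv(path),
    paf = read_mappings_paf(path),
    gff3 = read_mappings_gff3(path)
  )
  if (nrow(m) && any(m$end < m$start)) {
    bad <- which(m$end < m$start)
    stop("mapping end < start at record(s) ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  if (!is.null(scaffold_lengths) && nrow(m)) {
    len <- unname(scaffold_lengths[m$scaffold_id])
    over <- which(!is.na(len) & (m$start < 1 | m$end > len))
    if (length(over)) {
      stop("mapping coordinates exceed scaffold length at record(s) ",
           paste(utils::head(over, 10), collapse = ", "), call. = FALSE)
    }
  } else if (is.null(scaffold_lengths)) {
    message("scaffold lengths not supplied; coordinate bounds not checked")
  }
  normalize_mappings(m)
}

# keep the best placement per (cds_id, part_index)
normalize_mappings <- function(m) {
  m |>
    arrange(.data$cds_id, .data$part_index,
            dplyr::desc(.data$identity_pct), dplyr::desc(.data$aln_len_bp),
            .data$scaffold_id) |>
    group_by(.data$cds_id, .data$part_index) |>
    slice_head(n = 1L) |>
    ungroup() |>
    arrange(.data$cds_id, .data$part_index)
}

mapping_prototype <- function() {
  tibble(cds_id = character(), scaffold_id = character(),
         start = integer(), end = integer(), strand = character(),
         aln_len_bp = integer(), identity_pct = double(),
         part_index = integer())
}

read_mappings_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0L) return(mapping_prototype())
  need <- c("cds_id", "scaffold_id", "start", "end", "strand",
            "aln_len_bp", "identity_pct", "part_index")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("mapping TSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tibble(cds_id = as.character(df$cds_id),
         scaffold_id = as.character(df$scaffold_id),
         start = as.integer(df$start), end = as.integer(df$end),
         strand = as.character(df$strand),
         aln_len_bp = as.integer(df$aln_len_bp),
         identity_pct = as.numeric(df$identity_pct),
         part_index = as.integer(df$part_index))
}

read_mappings_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(mapping_prototype())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 12L)
  if (length(short)) {
    stop("PAF row(s) with fewer than 12 columns at line(s) ",
         paste(utils::head(short, 10), collapse = ", "), call. = FALSE)
  }
  f <- function(i) vapply(fields, `[`, character(1), i)
  num <- function(i) as.numeric(f(i))
  matches <- num(10)
  block <- num(11)
  # chimeric second parts are flagged with a pt:i:2 tag; default part 1
  part <- vapply(fields, function(x) {
    tag <- grep("^pt:i:", x, value = TRUE)
    if (length(tag)) as.integer(sub("^pt:i:", "", tag[1])) else 1L
  }, integer(1))
  tibble(
    cds_id = f(1),
    scaffold_id = f(6),
    start = as.integer(num(8) + 1),    # PAF is 0-based half-open
    end = as.integer(num(9)),
    strand = f(5),
    aln_len_bp = as.integer(block),
    identity_pct = 100 * matches / block,
    part_index = part
  )
}

read_mappings_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(mapping_prototype())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad)) {
    stop("GFF3 row(s) without 9 columns at line(s) ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  f <- function(i) vapply(fields, `[`, character(1), i)
  type <- f(3)
  keep <- type %in% c("gene", "mRNA", "cDNA_match", "match")
  if (!any(keep)) return(mapping_prototype())
  fields <- fields[keep]
  f <- function(i) vapply(fields, `[`, character(1), i)
  attr_get <- function(attrs, key) {
    pat <- paste0("(?i)(?:^|;)\\s*", key, "=([^;]*)")
    vapply(attrs, function(a) {
      m <- regexpr(pat, a, perl = TRUE)
      if (m < 0) return(NA_character_)
      hit <- regmatches(a, m)
      sub(pat, "\\1", hit, perl = TRUE)
    }, character(1), USE.NAMES = FALSE)
  }
  attrs <- f(9)
  ids <- attr_get(attrs, "ID")
  nm <- attr_get(attrs, "Name")
  ids[is.na(ids)] <- nm[is.na(ids)]
  if (anyNA(ids)) {
    stop("GFF3 mapping feature without ID/Name attribute", call. = FALSE)
  }
  # strip any trailing .pathN / .partN suffix into a part index
  part <- rep(1L, length(ids))
  has_part <- grepl("\\.(path|part)([0-9]+)$", ids)
  part[has_part] <- as.integer(sub("^.*\\.(path|part)([0-9]+)$", "\\2",
                                   ids[has_part]))
  ids <- sub("\\.(path|part)[0-9]+$", "", ids)
  identity <- suppressWarnings(as.numeric(attr_get(attrs, "Identity")))
  if (anyNA(identity)) {
    stop("GFF3 mapping feature without an Identity attribute",
         call. = FALSE)
  }
  start <- as.integer(f(4)); end <- as.integer(f(5))
  alen <- suppressWarnings(as.integer(attr_get(attrs, "Aln_len")))
  alen[is.na(alen)] <- (end - start + 1L)[is.na(alen)]
  tibble(cds_id = ids, scaffold_id = f(1), start = start, end = end,
         strand = f(7), aln_len_bp = alen, identity_pct = identity,
         part_index = part)
}

#' Write mapping records in the internal TSV dialect
#'
#' @param mappings A mapping tibble (see [read_mappings()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mappings <- function(mappings, path) {
  readr::write_tsv(mappings, path, progress = FALSE)
  invisible(path)
}
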