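#' Fragment an assembly in silico
#'
#' Splits every scaffold into `split_factor` pieces to emulate a more
#' fragmented assembly: each scaffold's length is divided evenly (the
#' remainder goes to the last piece), and its mapped CDS — ordered by
#' start coordinate — are partitioned into `split_factor` contiguous
#' chunks assigned to the new pieces. `split_factor = 1` is the identity.
#' The procedure is fully deterministic; `seed` is accepted for interface
#' symmetry with the other generators.
#'
#' Coordinates of re-assigned mappings are kept in the parent-scaffold
#' frame; the synteny test only consumes scaffold membership.
#'
#' @param mappings Mapping tibble (see [read_mappings()]).
#' @param scaffold_lengths Named numeric vector of scaffold lengths in bp.
#' @param split_factor Integer >= 1.
#' @param seed Unused; present for a stable generator interface.
#' @return A list with re-scaffolded `mappings` and `scaffold_lengths`.
#' @export
fragment_assembly <- function(mappings, scaffold_lengths, split_factor,
                              seed = NULL) {
  split_factor <- as.integer(split_factor)
  if (is.na(split_factor) || split_factor < 1L) {
    stop("split_factor must be an integer >= 1", call. = FALSE)
  }
  if (split_factor == 1L) {
    return(list(mappings = mappings, scaffold_lengths = scaffold_lengths))
  }

  piece_id <- function(scaffold, k) paste0(scaffold, "_f", k)

  new_lengths <- unlist(lapply(names(scaffold_lengths), function(s) {
    L <- scaffold_lengths[[s]]
    base <- floor(L / split_factor)
    lens <- rep(base, split_factor)
    lens[split_factor] <- L - base * (split_factor - 1L)
    stats::setNames(lens, piece_id(s, seq_len(split_factor)))
  }))

  new_mappings <- mappings |>
    arrange(.data$scaffold_id, .data$start, .data$cds_id) |>
    group_by(.data$scaffold_id) |>
    mutate(.chunk = ceiling(row_number() * split_factor / dplyr::n())) |>
    ungroup() |>
    mutate(scaffold_id = piece_id(.data$scaffold_id, .data$.chunk)) |>
    select(-".chunk") |>
    arrange(.data$cds_id, .data$part_index)

  list(mappings = new_mappings, scaffold_lengths = new_lengths)
}
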