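#' Single-linkage clustering of CDS into families
#'
#' Clusters CDS into families from pairwise percent-identity records:
#' pairs at identity at least `family_identity_fraction` (default 0.60)
#' become edges, and families are the connected components of the
#' resulting graph (single linkage). CDS in `universe` without any
#' qualifying edge form singleton families. Family ids are deterministic
#' (the lexicographically smallest member id).
#'
#' @param pairs A data frame with columns `cds_a`, `cds_b`, `identity`
#'   (fraction in `[0,1]`).
#' @param universe Character vector of all CDS ids to be partitioned.
#' @param thresholds A [pipeline_thresholds()] object.
#' @return A tibble `cds_id`, `family_id`, sorted by family then member.
#' @examples
#' cluster_families(
#'   data.frame(cds_a = "A", cds_b = "B", identity = 0.65),
#'   universe = c("A", "B", "C")
#' )
#' @export
cluster_families <- function(pairs, universe,
                             thresholds = pipeline_thresholds()) {
  t <- thresholds
  pairs <- as_tibble(pairs)
  if (nrow(pairs)) {
    if (any(pairs$identity < 0 | pairs$identity > 1)) {
      stop("identities must be fractions in [0,1]", call. = FALSE)
    }
    outside <- setdiff(unique(c(pairs$cds_a, pairs$cds_b)), universe)
    if (length(outside)) {
      stop("pair(s) reference CDS outside universe: ",
           paste(utils::head(outside, 10), collapse = ", "),
           call. = FALSE)
    }
  }
  edges <- filter(pairs, .data$identity >= t$family_identity_fraction)

  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(sort(unique(as.character(universe))))
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(edges$cds_a, edges$cds_b))
  }
  comp <- igraph::components(g)
  memb <- comp$membership
  fam <- tibble(cds_id = names(memb), component = unname(memb)) |>
    group_by(.data$component) |>
    mutate(family_id = min(.data$cds_id)) |>
    ungroup() |>
    select("cds_id", "family_id") |>
    arrange(.data$family_id, .data$cds_id)
  fam
}
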