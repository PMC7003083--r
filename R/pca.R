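#' Compositional PCA with a two-group separation score
#'
#' Centers the k-mer frequency profiles (no scaling), decomposes them by
#' SVD, and reports per-CDS coordinates on the first `n_components`
#' principal axes together with a silhouette-style separation score
#' between the two labeled sets (mean silhouette width over all points in
#' PC space). Component signs are canonicalized so that the
#' largest-magnitude loading of each axis is positive, making results
#' deterministic.
#'
#' The score lies in `[-1, 1]`: about 0 for indistinguishable clouds,
#' approaching 1 for well-separated ones.
#'
#' @param profiles A [kmer_profiles()] tibble with an added `label`
#'   column holding exactly two distinct values (e.g. `"contaminant"`
#'   and `"resident"`), at least two profiles per label.
#' @param n_components Number of principal axes kept (default 3).
#' @param seed Unused (the decomposition is deterministic); accepted for
#'   interface symmetry.
#' @return A list of class `xenoscan_pca`:
#'   * `coords` — tibble `cds_id`, `label`, `PC1..PCn`;
#'   * `separation` — mean silhouette width;
#'   * `variance_explained` — proportion per kept axis.
#' @export
pca_separation <- function(profiles, n_components = 3L, seed = NULL) {
  if (!"label" %in% names(profiles)) {
    stop("profiles need a 'label' column with two groups", call. = FALSE)
  }
  labs <- unique(profiles$label)
  if (length(labs) != 2L) {
    stop("exactly two labels required, got ", length(labs), call. = FALSE)
  }
  if (any(table(profiles$label) < 2L)) {
    stop("at least two profiles per label are required", call. = FALSE)
  }
  m <- kmer_matrix(profiles)
  if (nrow(unique(m)) < 2L) {
    stop("fewer than two distinct profiles", call. = FALSE)
  }
  n_components <- min(n_components, ncol(m), nrow(m) - 1L)

  p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  rot <- p$rotation[, seq_len(n_components), drop = FALSE]
  scores <- p$x[, seq_len(n_components), drop = FALSE]
  # sign canonicalization: largest-|loading| entry positive per axis
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))

  sil <- cluster::silhouette(as.integer(factor(profiles$label)),
                             stats::dist(scores))
  sep <- mean(sil[, "sil_width"])

  ve <- (p$sdev^2 / sum(p$sdev^2))[seq_len(n_components)]
  coords <- dplyr::bind_cols(
    tibble(cds_id = profiles$cds_id, label = profiles$label),
    as_tibble(scores)
  )
  structure(list(coords = coords, separation = sep,
                 variance_explained = ve, rotation = rot),
            class = "xenoscan_pca")
}

#' @export
print.xenoscan_pca <- function(x, ...) {
  cat("<xenoscan_pca>\n")
  cat("  points:    ", nrow(x$coords), "\n")
  cat("  separation:", format(x$separation, digits = 4), "\n")
  cat("  variance:  ",
      paste(format(100 * x$variance_explained, digits = 3), collapse = " / "),
      "%\n")
  invisible(x)
}

#' Plot compositional PCA coordinates
#'
#' Scatter plots of the pairwise combinations of the first three principal
#' components, colored by label.
#'
#' @param object An [pca_separation()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot xenoscan_pca
#' @export
autoplot.xenoscan_pca <- function(object, ...) {
  co <- object$coords
  pcs <- grep("^PC", names(co), value = TRUE)
  pairs <- utils::combn(utils::head(pcs, 3L), 2L, simplify = FALSE)
  long <- purrr::map_dfr(pairs, function(pr) {
    tibble(panel = paste(pr, collapse = " vs "),
           x = co[[pr[1]]], y = co[[pr[2]]], label = co$label)
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.2) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL,
                  title = sprintf("4-mer PCA (separation = %.3f)",
                                  object$separation)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
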