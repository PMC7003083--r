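#' Tetranucleotide (k-mer) composition profiles
#'
#' Computes the sliding-window k-mer frequency profile of each sequence on
#' the given strand (CDS are stranded, so no reverse-complement
#' collapsing). Windows containing non-ACGT symbols are skipped and the
#' remaining counts renormalized; a sequence shorter than `k` yields an
#' all-zero profile with `n_windows = 0` and is flagged. Profiles of at
#' least one counted window sum to 1.
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @param k Word size (default 4, i.e. 256 tetranucleotide frequencies).
#' @param min_windows Profiles with fewer counted windows are flagged
#'   (column `flagged`), not removed (default 50).
#' @return A tibble with one row per sequence: `cds_id`, `n_windows`,
#'   `flagged`, and one column per k-mer in lexicographic order (`AAAA`,
#'   `AAAC`, ...).
#' @examples
#' kmer_profiles(c(x = "ACGTACGT"))$ACGT  # 2 of 5 windows
#' @export
kmer_profiles <- function(seqs, k = 4L, min_windows = 50L) {
  stopifnot(k >= 1L)
  ids <- names(seqs) %||% paste0("seq", seq_along(seqs))
  counts <- t(vapply(seqs, function(s) kmer_counts_one(s, k),
                     numeric(4^k)))
  n_windows <- rowSums(counts)
  freqs <- counts / ifelse(n_windows > 0, n_windows, 1)
  out <- as_tibble(freqs)
  dplyr::bind_cols(
    tibble(cds_id = ids, n_windows = as.integer(n_windows),
           flagged = n_windows < min_windows),
    out
  )
}

# counts (not frequencies) of ACGT-only windows, lexicographic k-mer order
kmer_counts_one <- function(s, k) {
  if (nchar(s) < k) {
    return(stats::setNames(numeric(4^k), all_kmers(k)))
  }
  x <- Biostrings::DNAString(gsub("[^ACGT]", "N", toupper(s)))
  cnt <- Biostrings::oligonucleotideFrequency(x, width = k)
  as.numeric(cnt)[match(all_kmers(k), names(cnt))] |>
    stats::setNames(all_kmers(k))
}

all_kmers <- function(k) {
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid,
                  c(rep(list(bases), k), stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; reverse for lexicographic
  sort(apply(grid, 1L, paste0, collapse = ""))
}

kmer_matrix <- function(profiles) {
  meta <- c("cds_id", "n_windows", "flagged", "label")
  m <- as.matrix(profiles[, setdiff(names(profiles), meta)])
  rownames(m) <- profiles$cds_id
  m
}
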