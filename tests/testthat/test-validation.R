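test_that("k-mer profiles count sliding windows correctly", {
  # homopolymer: a single word takes all windows
  p <- kmer_profiles(c(x = "AAAAAAA"))
  expect_equal(p$n_windows, 4L)
  expect_equal(p$AAAA, 1.0)

  # ACGTACGT: 5 windows, ACGT twice
  p <- kmer_profiles(c(x = "ACGTACGT"))
  expect_equal(p$n_windows, 5L)
  expect_equal(p$ACGT, 0.4)
  expect_equal(p$CGTA, 0.2)
  expect_equal(p$GTAC, 0.2)
  expect_equal(p$TACG, 0.2)

  # windows overlapping a non-ACGT symbol are skipped and the rest
  # renormalized
  p <- kmer_profiles(c(x = "ACGNACGT"))
  expect_equal(p$n_windows, 1L)  # only the final ACGT window is clean
  expect_equal(sum(as.matrix(p[, -(1:3)])), 1.0)

  # shorter than k: all-zero flagged profile
  p <- kmer_profiles(c(x = "ACG"))
  expect_equal(p$n_windows, 0L)
  expect_true(p$flagged)
  expect_equal(sum(as.matrix(p[, -(1:3)])), 0)
})

test_that("k-mer profiles match brute-force window enumeration", {
  set.seed(31)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), sample(4:60, 1),
                      replace = TRUE, prob = c(0.24, 0.24, 0.24, 0.24,
                                               0.04)),
               collapse = "")
    p <- kmer_profiles(stats::setNames(s, "x"))
    expected <- oracle_kmer_profile(s)
    expect_equal(p$n_windows, sum(expected))
    for (w in names(expected)) {
      expect_equal(p[[w]], expected[[w]] / sum(expected), info = s)
    }
    if (p$n_windows > 0) {
      expect_equal(sum(as.matrix(p[, -(1:3)])), 1, tolerance = 1e-9)
    }
  }
})

test_that("profiles merge across an overlapping split (shift property)", {
  set.seed(8)
  s <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
             collapse = "")
  k <- 4L
  cut <- 37L
  left <- substr(s, 1, cut + k - 1 - 1)      # overlap of k-1 symbols
  right <- substr(s, cut, nchar(s))
  pw <- function(x) {
    pr <- kmer_profiles(stats::setNames(x, "x"), k = k)
    list(w = pr$n_windows, f = as.numeric(as.matrix(pr[, -(1:3)])))
  }
  whole <- pw(s); l <- pw(left); r <- pw(right)
  expect_equal(whole$w, l$w + r$w)
  merged <- (l$f * l$w + r$f * r$w) / (l$w + r$w)
  expect_equal(whole$f, merged, tolerance = 1e-12)
})

test_that("PCA coordinates match a dense eigendecomposition oracle", {
  set.seed(13)
  m <- matrix(stats::runif(10 * 256), nrow = 10)
  m <- m / rowSums(m)
  profiles <- dplyr::bind_cols(
    tibble::tibble(cds_id = paste0("c", 1:10), n_windows = 100L,
                   flagged = FALSE,
                   label = rep(c("a", "b"), each = 5)),
    tibble::as_tibble(stats::setNames(as.data.frame(m), all_kmers(4)))
  )
  res <- pca_separation(profiles, n_components = 3)
  expected <- oracle_pca_coords(m, 3)
  got <- as.matrix(res$coords[, c("PC1", "PC2", "PC3")])
  expect_equal(unname(got), unname(expected), tolerance = 1e-8)
})

test_that("identical point clouds give near-zero separation", {
  set.seed(14)
  base <- matrix(stats::runif(30 * 256), nrow = 30)
  m <- rbind(base, base)  # the two labels see identical clouds
  profiles <- dplyr::bind_cols(
    tibble::tibble(cds_id = paste0("c", 1:60), n_windows = 100L,
                   flagged = FALSE,
                   label = rep(c("a", "b"), each = 30)),
    tibble::as_tibble(stats::setNames(as.data.frame(m), all_kmers(4)))
  )
  res <- pca_separation(profiles)
  expect_lt(abs(res$separation), 0.1)
})

test_that("pca_separation validates its inputs", {
  profiles <- kmer_profiles(c(a = strrep("ACGT", 30),
                              b = strrep("GGCC", 30)))
  expect_error(pca_separation(profiles), "label")
  profiles$label <- c("x", "y")
  expect_error(pca_separation(profiles), "two profiles per label")
})

test_that("family clustering is single linkage at the identity cutoff", {
  # one qualifying edge joins a pair
  fam <- cluster_families(
    data.frame(cds_a = "A", cds_b = "B", identity = 0.65),
    universe = c("A", "B", "C"))
  expect_equal(fam$family_id[fam$cds_id == "A"],
               fam$family_id[fam$cds_id == "B"])
  expect_equal(fam$family_id[fam$cds_id == "C"], "C")

  # transitive chain merges despite a weak direct pair
  fam <- cluster_families(
    data.frame(cds_a = c("A", "B", "A"), cds_b = c("B", "C", "C"),
               identity = c(0.7, 0.7, 0.3)),
    universe = c("A", "B", "C"))
  expect_equal(length(unique(fam$family_id)), 1L)
  expect_equal(unique(fam$family_id), "A")

  # sub-cutoff edges leave singletons
  fam <- cluster_families(
    data.frame(cds_a = "A", cds_b = "B", identity = 0.59),
    universe = c("A", "B"))
  expect_equal(fam$family_id, c("A", "B"))

  # boundary: exactly 0.60 joins
  fam <- cluster_families(
    data.frame(cds_a = "A", cds_b = "B", identity = 0.60),
    universe = c("A", "B"))
  expect_equal(unique(fam$family_id), "A")
})

test_that("family clustering matches a set-merging oracle and is stable", {
  set.seed(77)
  for (i in 1:15) {
    universe <- paste0("x", sprintf("%02d", 1:12))
    n_pairs <- sample(5:25, 1)
    pairs <- data.frame(
      cds_a = sample(universe, n_pairs, replace = TRUE),
      cds_b = sample(universe, n_pairs, replace = TRUE),
      identity = round(stats::runif(n_pairs), 2)
    )
    pairs <- pairs[pairs$cds_a != pairs$cds_b, ]
    got <- cluster_families(pairs, universe)
    exp <- oracle_families(pairs, universe)
    got_sets <- unname(split(got$cds_id, got$family_id))
    expect_equal(got_sets, exp)

    # order-invariance under edge permutation, idempotence of re-clustering
    got2 <- cluster_families(pairs[sample(nrow(pairs)), ], universe)
    expect_equal(got, got2)
  }
})

test_that("family clustering rejects out-of-universe and bad identities", {
  expect_error(cluster_families(
    data.frame(cds_a = "A", cds_b = "Z", identity = 0.7),
    universe = c("A", "B")), "outside universe")
  expect_error(cluster_families(
    data.frame(cds_a = "A", cds_b = "B", identity = 65),
    universe = c("A", "B")), "fractions")
})

test_that("consistency check flags mixed-origin contaminant scaffolds", {
  # scaffold with one eubacterial and two fungal contaminants: inconsistent
  ann <- tibble::tibble(
    cds_id = c("e1", "u1", "u2", "a1", "h1"),
    stage1 = c("foreign", "foreign", "foreign", "confident_arthropod",
               "foreign"),
    foreign_group = c("eubacteria", "fungi", "fungi", NA, "eubacteria")
  )
  m <- tibble::tibble(
    cds_id = c("e1", "u1", "u2", "a1", "h1"),
    scaffold_id = c("mix", "mix", "mix", "sA", "sA"),
    start = 1L, end = 500L, strand = "+", aln_len_bp = 500L,
    identity_pct = 100, part_index = 1L
  )
  tab <- build_scaffold_table(ann, m)
  out <- classify_foreign(ann, tab)
  cc <- consistency_check(out, tab)
  expect_equal(cc$scaffold_id, "mix")
  expect_false(cc$consistent)
  expect_equal(cc$groups, "eubacteria,fungi,fungi")

  # uniform scaffold is consistent
  ann2 <- tibble::tibble(
    cds_id = c("e1", "e2", "e3"), stage1 = "foreign",
    foreign_group = "eubacteria"
  )
  m2 <- dplyr::mutate(m[1:3, ], cds_id = ann2$cds_id, scaffold_id = "sB")
  tab2 <- build_scaffold_table(ann2, m2)
  cc2 <- consistency_check(classify_foreign(ann2, tab2), tab2)
  expect_true(cc2$consistent)

  # a single contaminant CDS does not make a contaminant scaffold
  ann3 <- tibble::tibble(cds_id = "e1", stage1 = "foreign",
                         foreign_group = "eubacteria")
  m3 <- m[1, ]
  tab3 <- build_scaffold_table(ann3, m3)
  cc3 <- consistency_check(classify_foreign(ann3, tab3), tab3)
  expect_equal(nrow(cc3), 0L)
})
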