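# Independent brute-force oracles and random-instance generators.
# These re-derive every decision rule literally and independently of the
# package implementation, for equivalence testing.

oracle_taxonomy <- function() {
  taxonomy_table(data.frame(
    species = c("EUB1", "EUB2", "EUB3", "ARC1", "ARC2", "FUN1", "FUN2",
                "VIR1", "VIR2", "PRO1", "PRO2", "ART1", "ART2", "ART3",
                "MET1", "MET2", "MET3"),
    group = c("eubacteria", "eubacteria", "eubacteria", "archaea",
              "archaea", "fungi", "fungi", "viridiplantae",
              "viridiplantae", "protists", "protists", "arthropoda",
              "arthropoda", "arthropoda", "other_metazoa",
              "other_metazoa", "other_metazoa")
  ))
}

# literal re-statement of the stage-1 rule cascade for ONE CDS
oracle_stage1 <- function(hits1, taxonomy, t = pipeline_thresholds()) {
  keep <- hits1[hits1$identity_pct > t$min_hit_identity_pct &
                  hits1$aln_len > t$min_hit_aln_len_aa &
                  hits1$evalue < t$max_hit_evalue, , drop = FALSE]
  if (nrow(keep) < t$min_hits ||
      length(unique(keep$subject_species)) < t$min_distinct_species) {
    return(list(stage1 = "orphan", foreign_group = NA_character_))
  }
  ord <- order(keep$evalue, -keep$bitscore, keep$subject_id)
  top <- keep[ord, , drop = FALSE]
  top <- top[seq_len(min(t$top_n_hits, nrow(top))), , drop = FALSE]
  info <- tax_group_info()
  grp <- info$group[match(taxonomy$group[match(top$subject_species,
                                               taxonomy$species)],
                          info$group)]
  n <- nrow(top)
  for (g in info$group[info$is_foreign_source]) {
    if (sum(grp == g) / n >= t$majority_fraction) {
      return(list(stage1 = "foreign", foreign_group = g))
    }
  }
  is_met <- info$is_metazoa[match(grp, info$group)]
  is_art <- info$is_arthropod[match(grp, info$group)]
  if (sum(is_met) / n >= t$confident_metazoa_fraction &&
      sum(is_art) / n >= t$majority_fraction) {
    return(list(stage1 = "confident_arthropod",
                foreign_group = NA_character_))
  }
  if (sum(is_met & !is_art) / n >= t$majority_fraction &&
      sum(is_art) == 0) {
    return(list(stage1 = "other_metazoa", foreign_group = NA_character_))
  }
  list(stage1 = "unassigned", foreign_group = NA_character_)
}

# random hit set for one CDS: mixes filter-passing and failing hits over
# random groups; species drawn so the 2-species rule is also exercised
random_hitset <- function(cds_id, taxonomy) {
  n <- sample(0:15, 1)
  if (n == 0) return(NULL)
  sp <- sample(taxonomy$species, n, replace = TRUE)
  tibble::tibble(
    query_id = cds_id,
    subject_id = paste0(sp, "|p", seq_len(n)),
    subject_species = sp,
    identity_pct = round(stats::runif(n, 20, 100), 1),
    aln_len = sample(40:200, n, replace = TRUE),
    evalue = 10^stats::runif(n, -60, -5),
    bitscore = round(stats::runif(n, 50, 400), 1)
  )
}

# literal membership-scanning stage-2 classifier for one whole instance
oracle_stage2 <- function(annotations, mappings, t = pipeline_thresholds()) {
  m <- mappings[mappings$aln_len_bp >= t$min_map_len_bp &
                  mappings$identity_pct >= t$min_map_identity_pct, ,
                drop = FALSE]
  m <- m[m$cds_id %in% annotations$cds_id, , drop = FALSE]
  st1 <- stats::setNames(annotations$stage1, annotations$cds_id)
  m <- m[st1[m$cds_id] %in% c("foreign", "confident_arthropod"), ,
         drop = FALSE]

  # chimera links: unordered scaffold pairs of two-scaffold CDS
  links <- list()
  for (cid in unique(m$cds_id)) {
    scs <- unique(m$scaffold_id[m$cds_id == cid])
    if (length(scs) == 2) links[[length(links) + 1]] <- sort(scs)
  }
  # fixed-point tag propagation
  tagged <- unique(m$scaffold_id[st1[m$cds_id] == "confident_arthropod"])
  repeat {
    added <- FALSE
    for (lk in links) {
      if (any(lk %in% tagged) && !all(lk %in% tagged)) {
        tagged <- union(tagged, lk)
        added <- TRUE
      }
    }
    if (!added) break
  }

  out <- stats::setNames(rep("not_applicable", nrow(annotations)),
                         annotations$cds_id)
  for (cid in annotations$cds_id[annotations$stage1 == "foreign"]) {
    scs <- unique(m$scaffold_id[m$cds_id == cid])
    if (length(scs) == 0) { out[cid] <- "uncertain"; next }
    if (any(scs %in% tagged)) { out[cid] <- "hgt_candidate"; next }
    contaminant <- FALSE
    for (s in scs) {
      others <- unique(m$cds_id[m$scaffold_id == s & m$cds_id != cid])
      others <- others[st1[others] == "foreign"]
      if (length(others) >= 1) contaminant <- TRUE
    }
    out[cid] <- if (contaminant) "contaminant_candidate" else "uncertain"
  }
  out
}

# random small scaffold instance with optional chimeric placements;
# `prefix` namespaces ids so instances can be pooled into one batch
random_stage2_instance <- function(prefix = "i") {
  n_cds <- sample(2:30, 1)
  n_sc <- sample(1:10, 1)
  scaffolds <- paste0(prefix, "_s", seq_len(n_sc))
  cats <- sample(c("foreign", "confident_arthropod", "other_metazoa",
                   "orphan"), n_cds, replace = TRUE,
                 prob = c(0.45, 0.3, 0.15, 0.1))
  ann <- tibble::tibble(
    cds_id = paste0(prefix, "_c", seq_len(n_cds)),
    stage1 = cats,
    foreign_group = ifelse(cats == "foreign",
                           sample(c("eubacteria", "fungi", "archaea"),
                                  n_cds, replace = TRUE), NA)
  )
  # 0, 1 or 2 placements per CDS; 2 = chimeric parts (possibly on the
  # same scaffold, which normalizes away)
  k <- sample(0:2, n_cds, replace = TRUE, prob = c(0.2, 0.6, 0.2))
  idx <- c(which(k >= 1L), which(k == 2L))
  part <- c(rep(1L, sum(k >= 1L)), rep(2L, sum(k == 2L)))
  n_rows <- length(idx)
  maps <- tibble::tibble(
    cds_id = ann$cds_id[idx],
    scaffold_id = sample(scaffolds, n_rows, replace = TRUE),
    start = 1L, end = 200L, strand = "+",
    aln_len_bp = sample(80:200, n_rows, replace = TRUE),
    identity_pct = round(stats::runif(n_rows, 90, 100), 1),
    part_index = part
  )
  list(annotations = ann, mappings = maps)
}

# brute-force N50: check every candidate cut point against the definition
oracle_n50 <- function(lengths) {
  total <- sum(lengths)
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) {
    if (sum(lengths[lengths >= L]) >= total / 2) return(L)
  }
  min(lengths)
}

# dense eigendecomposition PCA oracle with the same sign convention
oracle_pca_coords <- function(m, n_components) {
  mc <- sweep(m, 2, colMeans(m))
  ev <- eigen(stats::cov(mc), symmetric = TRUE)
  v <- ev$vectors[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(ncol(v))) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  mc %*% v
}

# brute-force sliding-window k-mer profile by direct enumeration
oracle_kmer_profile <- function(s, k = 4) {
  n <- nchar(s)
  counts <- integer(0)
  if (n >= k) {
    for (i in 1:(n - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (grepl("^[ACGT]+$", w)) {
        counts[w] <- (if (w %in% names(counts)) counts[[w]] else 0L) + 1L
      }
    }
  }
  counts
}

# single-linkage families by repeated set merging
oracle_families <- function(pairs, universe, cutoff = 0.6) {
  fams <- lapply(sort(universe), function(x) x)
  edges <- pairs[pairs$identity >= cutoff, , drop = FALSE]
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      ia <- which(vapply(fams, function(f) edges$cds_a[r] %in% f,
                         logical(1)))
      ib <- which(vapply(fams, function(f) edges$cds_b[r] %in% f,
                         logical(1)))
      if (ia != ib) {
        fams[[ia]] <- union(fams[[ia]], fams[[ib]])
        fams[[ib]] <- NULL
      }
    }
  }
  out <- lapply(fams, sort)
  out[order(vapply(out, `[`, character(1), 1))]
}

# pool many random stage-2 instances into one batch (ids are namespaced,
# so classification decomposes over instances)
pooled_stage2_batch <- function(n_instances, prefix) {
  inst <- lapply(seq_len(n_instances), function(i) {
    random_stage2_instance(paste0(prefix, i))
  })
  list(
    annotations = dplyr::bind_rows(lapply(inst, `[[`, "annotations")),
    mappings = dplyr::bind_rows(lapply(inst, `[[`, "mappings"))
  )
}
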