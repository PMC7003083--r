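#' Configuration of the synthetic-assembly generator
#'
#' The generator emulates a host genome assembly carrying planted foreign
#' material: host scaffolds with resident genes, contaminant scaffolds
#' whose genes derive from a compositionally divergent source, HGT genes
#' (foreign-composition genes sitting on host scaffolds), and chimeric
#' host genes split across scaffold pairs. Every emitted CDS is recorded
#' in a ground-truth manifest with its intended stage-1 and stage-2
#' labels under noiseless hits.
#'
#' @param n_host_scaffolds Number of host scaffolds (default 30).
#' @param host_scaffold_len_bp Length of each host scaffold (default
#'   50000).
#' @param genes_per_scaffold Resident genes per host scaffold (default 8).
#' @param n_contaminant_scaffolds Number of contaminant scaffolds
#'   (default 6); each is assigned one foreign group, cycling through
#'   eubacteria, archaea, fungi, viridiplantae, protists.
#' @param contaminant_genes_per_scaffold Genes per contaminant scaffold
#'   (default 4).
#' @param n_hgt_genes Foreign-composition genes planted on host scaffolds
#'   (default 5); eubacterial donors.
#' @param n_chimeric_host_genes Host genes whose 5' and 3' halves map to
#'   two different host scaffolds (default 3).
#' @param composition_divergence In `[0,1]`: distance between the host
#'   and contaminant nucleotide-composition models; 0 makes them
#'   identical, 1 maximally divergent (default 0.5).
#' @param hit_noise Probability that a synthesized top hit is assigned to
#'   a wrong taxonomic group (default 0).
#' @param fragmentation_split Integer >= 1; the emitted assembly is split
#'   in silico by this factor (default 1, no splitting).
#' @param plant_mixed_scaffold If `TRUE`, adds one extra contaminant
#'   scaffold carrying one eubacterial and two fungal CDS — a planted
#'   taxonomically inconsistent (chimeric) contaminant scaffold
#'   (default `FALSE`).
#' @param gene_len_bp Length of every planted gene (default 300).
#' @param seed Integer seed; identical configurations and seeds yield
#'   byte-identical fixtures.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(n_host_scaffolds = 30L,
                           host_scaffold_len_bp = 50000L,
                           genes_per_scaffold = 8L,
                           n_contaminant_scaffolds = 6L,
                           contaminant_genes_per_scaffold = 4L,
                           n_hgt_genes = 5L,
                           n_chimeric_host_genes = 3L,
                           composition_divergence = 0.5,
                           hit_noise = 0,
                           fragmentation_split = 1L,
                           plant_mixed_scaffold = FALSE,
                           gene_len_bp = 300L,
                           seed = 1L) {
  cfg <- list(
    n_host_scaffolds = as.integer(n_host_scaffolds),
    host_scaffold_len_bp = as.integer(host_scaffold_len_bp),
    genes_per_scaffold = as.integer(genes_per_scaffold),
    n_contaminant_scaffolds = as.integer(n_contaminant_scaffolds),
    contaminant_genes_per_scaffold = as.integer(contaminant_genes_per_scaffold),
    n_hgt_genes = as.integer(n_hgt_genes),
    n_chimeric_host_genes = as.integer(n_chimeric_host_genes),
    composition_divergence = as.numeric(composition_divergence),
    hit_noise = as.numeric(hit_noise),
    fragmentation_split = as.integer(fragmentation_split),
    plant_mixed_scaffold = isTRUE(plant_mixed_scaffold),
    gene_len_bp = as.integer(gene_len_bp),
    seed = as.integer(seed)
  )
  stopifnot(cfg$composition_divergence >= 0, cfg$composition_divergence <= 1,
            cfg$hit_noise >= 0, cfg$hit_noise <= 1,
            cfg$fragmentation_split >= 1L,
            all(unlist(cfg[1:7]) >= 0L))
  structure(cfg, class = "fixture_config")
}

# order-1 Markov transition matrices: host is mildly AT-rich; the
# divergent source is strongly GC-rich. Mixing toward the divergent model
# is linear in `divergence`.
host_transition <- function() {
  p <- c(A = 0.30, C = 0.20, G = 0.20, T = 0.30)
  m <- matrix(rep(p, 4), nrow = 4, byrow = TRUE,
              dimnames = list(names(p), names(p)))
  # mild neighbor preference to give the chain genuine first-order structure
  diag(m) <- diag(m) + 0.10
  sweep(m, 1, rowSums(m), "/")
}

divergent_transition <- function() {
  p <- c(A = 0.10, C = 0.40, G = 0.40, T = 0.10)
  m <- matrix(rep(p, 4), nrow = 4, byrow = TRUE,
              dimnames = list(names(p), names(p)))
  diag(m) <- diag(m) + 0.10
  sweep(m, 1, rowSums(m), "/")
}

mix_transition <- function(divergence) {
  (1 - divergence) * host_transition() + divergence * divergent_transition()
}

# sample an order-1 Markov chain of length n over ACGT
markov_seq <- function(n, trans) {
  if (n <= 0L) return("")
  bases <- c("A", "C", "G", "T")
  cum <- t(apply(trans, 1, cumsum))
  statn <- colMeans(trans)  # adequate start distribution
  s <- integer(n)
  u <- stats::runif(n)
  s[1] <- findInterval(u[1], cumsum(statn)) + 1L
  if (n > 1L) {
    c1 <- cum[, 1]; c2 <- cum[, 2]; c3 <- cum[, 3]
    for (i in 2:n) {
      p <- s[i - 1L]
      s[i] <- 1L + (u[i] > c1[p]) + (u[i] > c2[p]) + (u[i] > c3[p])
    }
  }
  paste(bases[s], collapse = "")
}

# iid background from a composition's column means (intergenic filler)
background_seq <- function(n, trans) {
  if (n <= 0L) return("")
  bases <- c("A", "C", "G", "T")
  paste(sample(bases, n, replace = TRUE, prob = colMeans(trans)),
        collapse = "")
}

fixture_taxonomy <- function() {
  sp <- function(prefix, group, n = 4L) {
    tibble(species = paste0(prefix, seq_len(n)), group = group)
  }
  taxonomy_table(dplyr::bind_rows(
    sp("EUB", "eubacteria"), sp("ARC", "archaea"), sp("FUN", "fungi"),
    sp("VIR", "viridiplantae"), sp("PRO", "protists"),
    sp("ART", "arthropoda"), sp("MET", "other_metazoa")
  ))
}

# synthesize a ranked top-10 hit block for one CDS
synth_hits_one <- function(cds_id, origin_group, taxonomy, hit_noise) {
  n <- 10L
  if (origin_group == "host") {
    groups <- c(rep("arthropoda", 8L), rep("other_metazoa", 2L))
  } else {
    groups <- rep(origin_group, n)
  }
  if (hit_noise > 0) {
    flip <- stats::runif(n) < hit_noise
    all_g <- tax_group_info()$group
    groups[flip] <- vapply(groups[flip], function(g) {
      sample(setdiff(all_g, g), 1L)
    }, character(1))
  }
  species <- vapply(seq_len(n), function(i) {
    pool <- taxonomy$species[taxonomy$group == groups[i]]
    pool[(i - 1L) %% length(pool) + 1L]
  }, character(1))
  tibble(
    query_id = cds_id,
    subject_id = paste0(species, "|p", seq_len(n)),
    subject_species = species,
    identity_pct = round(90 - 2 * (seq_len(n) - 1L) +
                           stats::runif(n, -1, 1), 1),
    aln_len = 150L,
    evalue = 10^(-50 + 2 * (seq_len(n) - 1L)),
    bitscore = 300 - 10 * (seq_len(n) - 1L)
  )
}

#' Generate a synthetic assembly with planted ground truth
#'
#' Builds all five pipeline inputs in memory: scaffold and CDS sequence
#' sets, a synthesized top-hit table whose hits reflect each CDS's true
#' origin (corrupted at rate `hit_noise`), the reference taxonomy, the
#' true mapping table, plus a manifest giving every CDS's true origin and
#' the stage-1/stage-2 labels the pipeline should produce under noiseless
#' hits. Deterministic given the configuration seed.
#'
#' @param config A [fixture_config()].
#' @return A list of class `xenoscan_fixture` with elements `scaffolds`,
#'   `cds`, `hits`, `taxonomy`, `mappings`, `scaffold_lengths`,
#'   `manifest` and `config`.
#' @export
generate_fixture <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  cfg <- config
  set.seed(cfg$seed)
  taxonomy <- fixture_taxonomy()
  gl <- cfg$gene_len_bp
  host_tr <- mix_transition(0)
  cont_tr <- mix_transition(cfg$composition_divergence)
  fg <- foreign_groups()

  L <- cfg$host_scaffold_len_bp
  if (cfg$genes_per_scaffold > 0L &&
      L < (cfg$genes_per_scaffold + 2L) * (gl + 10L)) {
    stop("host scaffolds too short for the requested gene count",
         call. = FALSE)
  }

  scaffolds <- character(0)
  cds <- character(0)
  manifest <- list()
  mappings <- list()

  add_cds <- function(id, seq, origin, group, scaffold, start,
                      stage1, stage2, part = 1L) {
    cds[[id]] <<- seq
    mappings[[length(mappings) + 1L]] <<- tibble(
      cds_id = id, scaffold_id = scaffold, start = start,
      end = start + nchar(seq) - 1L, strand = "+",
      aln_len_bp = nchar(seq), identity_pct = 100, part_index = part
    )
    manifest[[length(manifest) + 1L]] <<- tibble(
      cds_id = id, origin = origin,
      group = if (is.na(group)) NA_character_ else group,
      scaffold_id = scaffold, intended_stage1 = stage1,
      intended_stage2 = stage2
    )
  }

  # --- host scaffolds with resident genes --------------------------------
  hgt_slots <- if (cfg$n_hgt_genes > 0L) {
    # spread HGT genes over the first host scaffolds, one each
    seq_len(min(cfg$n_hgt_genes, cfg$n_host_scaffolds))
  } else integer(0)
  n_hgt_left <- cfg$n_hgt_genes

  for (si in seq_len(cfg$n_host_scaffolds)) {
    sid <- sprintf("hsc%03d", si)
    gap <- floor(L / max(1L, cfg$genes_per_scaffold + 1L))
    seq_parts <- character(0)
    pos <- 1L
    for (gi in seq_len(cfg$genes_per_scaffold)) {
      start <- (gi - 1L) * gap + 1L
      seq_parts <- c(seq_parts, background_seq(start - pos, host_tr))
      gene_seq <- markov_seq(gl, host_tr)
      gid <- sprintf("%s_g%02d", sid, gi)
      add_cds(gid, gene_seq, "host", NA, sid, start,
              "confident_arthropod", "not_applicable")
      seq_parts <- c(seq_parts, gene_seq)
      pos <- start + gl
    }
    # one planted HGT gene near the scaffold end, where slots allow
    if (si %in% hgt_slots && n_hgt_left > 0L) {
      start <- L - gl - 50L
      seq_parts <- c(seq_parts, background_seq(start - pos, host_tr))
      gene_seq <- markov_seq(gl, cont_tr)
      gid <- sprintf("%s_hgt", sid)
      add_cds(gid, gene_seq, "hgt", "eubacteria", sid, start,
              "foreign", "hgt_candidate")
      seq_parts <- c(seq_parts, gene_seq)
      pos <- start + gl
      n_hgt_left <- n_hgt_left - 1L
    }
    seq_parts <- c(seq_parts, background_seq(L - pos + 1L, host_tr))
    scaffolds[[sid]] <- paste(seq_parts, collapse = "")
  }

  # --- chimeric host genes across scaffold pairs -------------------------
  if (cfg$n_chimeric_host_genes > 0L) {
    if (cfg$n_host_scaffolds < 2L) {
      stop("chimeric genes need at least two host scaffolds", call. = FALSE)
    }
    half <- max(150L, floor(gl / 2L))
    for (ci in seq_len(cfg$n_chimeric_host_genes)) {
      sa <- sprintf("hsc%03d", (2L * ci - 2L) %% cfg$n_host_scaffolds + 1L)
      sb <- sprintf("hsc%03d", (2L * ci - 1L) %% cfg$n_host_scaffolds + 1L)
      gid <- sprintf("chim%02d", ci)
      gene_seq <- markov_seq(2L * half, host_tr)
      cds[[gid]] <- gene_seq
      mappings[[length(mappings) + 1L]] <- tibble(
        cds_id = gid, scaffold_id = c(sa, sb),
        start = c(10L, 10L), end = c(10L + half - 1L, 10L + half - 1L),
        strand = "+", aln_len_bp = half, identity_pct = 100,
        part_index = c(1L, 2L)
      )
      manifest[[length(manifest) + 1L]] <- tibble(
        cds_id = gid, origin = "host", group = NA_character_,
        scaffold_id = sa, intended_stage1 = "confident_arthropod",
        intended_stage2 = "not_applicable"
      )
    }
  }

  # --- contaminant scaffolds ---------------------------------------------
  n_cont <- cfg$n_contaminant_scaffolds
  cont_groups <- if (n_cont > 0L) fg[(seq_len(n_cont) - 1L) %% 5L + 1L]
                 else character(0)
  for (si in seq_len(n_cont)) {
    sid <- sprintf("csc%03d", si)
    grp <- cont_groups[si]
    ng <- cfg$contaminant_genes_per_scaffold
    Lc <- max(1000L, (ng + 1L) * (gl + 200L))
    gap <- floor(Lc / max(1L, ng + 1L))
    seq_parts <- character(0)
    pos <- 1L
    stage2 <- if (ng >= 2L) "contaminant_candidate" else "uncertain"
    for (gi in seq_len(ng)) {
      start <- (gi - 1L) * gap + 1L
      seq_parts <- c(seq_parts, background_seq(start - pos, cont_tr))
      gene_seq <- markov_seq(gl, cont_tr)
      gid <- sprintf("%s_g%02d", sid, gi)
      add_cds(gid, gene_seq, "contaminant", grp, sid, start,
              "foreign", stage2)
      seq_parts <- c(seq_parts, gene_seq)
      pos <- start + gl
    }
    seq_parts <- c(seq_parts, background_seq(Lc - pos + 1L, cont_tr))
    scaffolds[[sid]] <- paste(seq_parts, collapse = "")
  }

  # --- optional planted mixed-origin (chimeric contaminant) scaffold -----
  if (cfg$plant_mixed_scaffold) {
    sid <- "mixsc001"
    grps <- c("eubacteria", "fungi", "fungi")
    Lc <- 4L * (gl + 200L)
    gap <- floor(Lc / 4L)
    seq_parts <- character(0)
    pos <- 1L
    for (gi in 1:3) {
      start <- (gi - 1L) * gap + 1L
      seq_parts <- c(seq_parts, background_seq(start - pos, cont_tr))
      gene_seq <- markov_seq(gl, cont_tr)
      gid <- sprintf("%s_g%02d", sid, gi)
      add_cds(gid, gene_seq, "contaminant", grps[gi], sid, start,
              "foreign", "contaminant_candidate")
      seq_parts <- c(seq_parts, gene_seq)
      pos <- start + gl
    }
    seq_parts <- c(seq_parts, background_seq(Lc - pos + 1L, cont_tr))
    scaffolds[[sid]] <- paste(seq_parts, collapse = "")
  }

  manifest <- dplyr::bind_rows(manifest)
  mappings <- dplyr::bind_rows(mappings)

  # --- synthesized hit table ---------------------------------------------
  hit_origin <- ifelse(manifest$origin == "host", "host", manifest$group)
  hits <- dplyr::bind_rows(purrr::map2(
    manifest$cds_id, hit_origin,
    ~ synth_hits_one(.x, .y, taxonomy, cfg$hit_noise)
  ))

  scaffold_lengths <- vapply(scaffolds, nchar, integer(1))

  fix <- list(scaffolds = scaffolds, cds = cds, hits = hits,
              taxonomy = taxonomy, mappings = mappings,
              scaffold_lengths = scaffold_lengths, manifest = manifest,
              config = cfg)
  class(fix) <- "xenoscan_fixture"

  if (cfg$fragmentation_split > 1L) {
    fix <- apply_fragmentation(fix, cfg$fragmentation_split)
  }
  fix
}

# re-cut an in-memory fixture by a split factor
apply_fragmentation <- function(fix, split_factor) {
  fr <- fragment_assembly(fix$mappings, fix$scaffold_lengths, split_factor)
  pieces <- lapply(names(fix$scaffolds), function(s) {
    L <- fix$scaffold_lengths[[s]]
    base <- floor(L / split_factor)
    starts <- (seq_len(split_factor) - 1L) * base + 1L
    ends <- c(starts[-1L] - 1L, L)
    stats::setNames(substring(fix$scaffolds[[s]], starts, ends),
                    paste0(s, "_f", seq_len(split_factor)))
  })
  fix$scaffolds <- unlist(pieces)
  fix$mappings <- fr$mappings
  fix$scaffold_lengths <- fr$scaffold_lengths
  # scaffold membership in the manifest follows the re-cut mappings
  first_map <- fr$mappings |>
    filter(.data$part_index == 1L) |>
    select("cds_id", "scaffold_id")
  fix$manifest <- fix$manifest |>
    select(-"scaffold_id") |>
    left_join(first_map, by = "cds_id")
  fix
}

#' @export
print.xenoscan_fixture <- function(x, ...) {
  cat("<xenoscan_fixture>\n")
  cat("  scaffolds:", length(x$scaffolds), " CDS:", length(x$cds),
      " hits:", nrow(x$hits), "\n")
  cat("  origins:", paste(names(table(x$manifest$origin)),
                          table(x$manifest$origin), collapse = ", "), "\n")
  invisible(x)
}

#' Write a fixture to disk in the pipeline's input formats
#'
#' Emits `scaffolds.fasta`, `cds.fasta`, `hits.tsv` (12-column tabular),
#' `taxonomy.tsv`, `mappings.tsv` (internal dialect) and `manifest.tsv`
#' into `dir`.
#'
#' @param fix A [generate_fixture()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fix, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(fix$scaffolds, file.path(dir, "scaffolds.fasta"))
  write_fasta(fix$cds, file.path(dir, "cds.fasta"))
  h <- fix$hits
  out12 <- tibble(qseqid = h$query_id, sseqid = h$subject_id,
                  pident = h$identity_pct, length = h$aln_len,
                  mismatch = 0L, gapopen = 0L, qstart = 1L,
                  qend = h$aln_len, sstart = 1L, send = h$aln_len,
                  evalue = h$evalue, bitscore = h$bitscore)
  readr::write_tsv(out12, file.path(dir, "hits.tsv"), col_names = FALSE,
                   progress = FALSE)
  readr::write_tsv(fix$taxonomy[, c("species", "group")],
                   file.path(dir, "taxonomy.tsv"), progress = FALSE)
  write_mappings(fix$mappings, file.path(dir, "mappings.tsv"))
  readr::write_tsv(fix$manifest, file.path(dir, "manifest.tsv"),
                   progress = FALSE)
  invisible(dir)
}

#' Fragmentation sweep over one gene content
#'
#' Generates the base fixture once, then re-cuts it at each split factor,
#' so all members of the sweep share gene content and differ only in
#' scaffold partitioning.
#'
#' @param config A [fixture_config()] (its `fragmentation_split` is
#'   ignored).
#' @param split_factors Integer vector of split factors.
#' @return A named list of fixtures, one per factor.
#' @export
sweep_fragmentation <- function(config, split_factors) {
  stopifnot(length(split_factors) >= 1L)
  config$fragmentation_split <- 1L
  base <- generate_fixture(config)
  out <- lapply(split_factors, function(k) {
    if (k == 1L) base else apply_fragmentation(base, as.integer(k))
  })
  names(out) <- paste0("split", split_factors)
  out
}
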