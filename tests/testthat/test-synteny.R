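# minimal stage-1 annotation and mapping builders
ann_of <- function(...) {
  x <- list(...)
  tibble::tibble(
    cds_id = names(x),
    stage1 = vapply(x, `[`, character(1), 1L),
    foreign_group = vapply(x, function(v) {
      if (length(v) > 1L) v[2L] else NA_character_
    }, character(1))
  )
}

map_of <- function(df) {
  tibble::tibble(
    cds_id = df$cds, scaffold_id = df$sc, start = 1L, end = 500L,
    strand = "+",
    aln_len_bp = if ("len" %in% names(df)) df$len else 500L,
    identity_pct = if ("idy" %in% names(df)) df$idy else 100,
    part_index = if ("part" %in% names(df)) df$part else 1L
  )
}

test_that("mapping filters are inclusive at their stated minima", {
  ann <- ann_of(f1 = c("foreign", "eubacteria"))
  m99 <- map_of(data.frame(cds = "f1", sc = "sA", len = 99L))
  m100 <- map_of(data.frame(cds = "f1", sc = "sA", len = 100L))
  expect_equal(nrow(build_scaffold_table(ann, m99)$mapped), 0L)
  expect_equal(nrow(build_scaffold_table(ann, m100)$mapped), 1L)

  m94 <- map_of(data.frame(cds = "f1", sc = "sA", idy = 94.9))
  m95 <- map_of(data.frame(cds = "f1", sc = "sA", idy = 95))
  expect_equal(nrow(build_scaffold_table(ann, m94)$mapped), 0L)
  expect_equal(nrow(build_scaffold_table(ann, m95)$mapped), 1L)
})

test_that("only foreign and confident-resident CDS enter the table", {
  ann <- ann_of(f1 = c("foreign", "fungi"), a1 = "confident_arthropod",
                m1 = "other_metazoa", o1 = "orphan")
  m <- map_of(data.frame(cds = c("f1", "a1", "m1", "o1"),
                         sc = c("sA", "sA", "sA", "sA")))
  tab <- build_scaffold_table(ann, m)
  expect_setequal(unique(tab$mapped$cds_id), c("f1", "a1"))
})

test_that("mappings for unknown CDS are ignored with a warning", {
  ann <- ann_of(f1 = c("foreign", "fungi"))
  m <- map_of(data.frame(cds = c("f1", "ghost"), sc = c("sA", "sA")))
  expect_warning(tab <- build_scaffold_table(ann, m), "ghost")
  expect_equal(unique(tab$mapped$cds_id), "f1")
})

test_that("the resident tag propagates across chimera links", {
  # chimeric resident CDS across sA/sB; sB otherwise empty
  ann <- ann_of(a1 = "confident_arthropod")
  m <- map_of(data.frame(cds = c("a1", "a1"), sc = c("sA", "sB"),
                         part = c(1L, 2L)))
  tab <- build_scaffold_table(ann, m)
  expect_setequal(tab$arthropod_tagged, c("sA", "sB"))

  # chain sA-sB-sC via two chimeras, resident CDS only on sA
  ann2 <- ann_of(a1 = "confident_arthropod",
                 f1 = c("foreign", "eubacteria"),
                 f2 = c("foreign", "eubacteria"))
  m2 <- map_of(data.frame(
    cds = c("a1", "f1", "f1", "f2", "f2"),
    sc = c("sA", "sA", "sB", "sB", "sC"),
    part = c(1L, 1L, 2L, 1L, 2L)
  ))
  tab2 <- build_scaffold_table(ann2, m2)
  expect_setequal(tab2$arthropod_tagged, c("sA", "sB", "sC"))
  # closure property: every link touching a tagged scaffold is inside the tag set
  for (i in seq_len(nrow(tab2$chimera_links))) {
    lk <- unlist(tab2$chimera_links[i, ])
    if (any(lk %in% tab2$arthropod_tagged)) {
      expect_true(all(lk %in% tab2$arthropod_tagged))
    }
  }
})

test_that("stage-2 classification follows the synteny rules", {
  # foreign CDS sharing a scaffold with a resident CDS -> HGT candidate
  ann <- ann_of(f1 = c("foreign", "eubacteria"), a1 = "confident_arthropod")
  m <- map_of(data.frame(cds = c("f1", "a1"), sc = c("sA", "sA")))
  out <- classify_foreign(ann, build_scaffold_table(ann, m))
  expect_equal(out$stage2[out$cds_id == "f1"], "hgt_candidate")
  expect_equal(out$stage2[out$cds_id == "a1"], "not_applicable")

  # two eubacterial CDS alone on one scaffold -> both contaminants
  ann <- ann_of(f1 = c("foreign", "eubacteria"),
                f2 = c("foreign", "eubacteria"))
  m <- map_of(data.frame(cds = c("f1", "f2"), sc = c("sA", "sA")))
  out <- classify_foreign(ann, build_scaffold_table(ann, m))
  expect_equal(out$stage2, c("contaminant_candidate",
                             "contaminant_candidate"))

  # mixed-group company still counts as corroboration
  ann <- ann_of(f1 = c("foreign", "eubacteria"), f2 = c("foreign", "fungi"))
  m <- map_of(data.frame(cds = c("f1", "f2"), sc = c("sA", "sA")))
  out <- classify_foreign(ann, build_scaffold_table(ann, m))
  expect_equal(unique(out$stage2), "contaminant_candidate")

  # sole mapped CDS on its scaffold -> uncertain
  ann <- ann_of(f1 = c("foreign", "protists"))
  m <- map_of(data.frame(cds = "f1", sc = "sA"))
  out <- classify_foreign(ann, build_scaffold_table(ann, m))
  expect_equal(out$stage2, "uncertain")

  # no surviving mapping -> uncertain
  ann <- ann_of(f1 = c("foreign", "protists"))
  m <- map_of(data.frame(cds = "f1", sc = "sA", len = 50L))
  out <- classify_foreign(ann, build_scaffold_table(ann, m))
  expect_equal(out$stage2, "uncertain")

  # chimera-propagated resident tag makes a foreign CDS an HGT candidate
  ann <- ann_of(a1 = "confident_arthropod",
                a2 = "confident_arthropod",
                f1 = c("foreign", "eubacteria"))
  m <- map_of(data.frame(
    cds = c("a1", "a2", "a2", "f1"),
    sc = c("sA", "sA", "sB", "sB"),
    part = c(1L, 1L, 2L, 1L)
  ))
  out <- classify_foreign(ann, build_scaffold_table(ann, m))
  expect_equal(out$stage2[out$cds_id == "f1"], "hgt_candidate")

  # a chimeric CDS's own second part is not self-corroboration
  ann <- ann_of(f1 = c("foreign", "eubacteria"))
  m <- map_of(data.frame(cds = c("f1", "f1"), sc = c("sA", "sB"),
                         part = c(1L, 2L)))
  out <- classify_foreign(ann, build_scaffold_table(ann, m))
  expect_equal(out$stage2, "uncertain")
})

test_that("classification matches the brute-force membership scanner", {
  set.seed(101)
  for (b in 1:20) {
    batch <- pooled_stage2_batch(25, sprintf("b%02d", b))
    tab <- build_scaffold_table(batch$annotations, batch$mappings)
    got <- classify_foreign(batch$annotations, tab)
    exp <- oracle_stage2(batch$annotations, batch$mappings)
    expect_equal(got$stage2, unname(exp[got$cds_id]))
  }
})

test_that("every foreign candidate gets exactly one stage-2 label", {
  set.seed(55)
  batch <- pooled_stage2_batch(50, "p")
  tab <- build_scaffold_table(batch$annotations, batch$mappings)
  out <- classify_foreign(batch$annotations, tab)
  foreign <- out$stage1 == "foreign"
  expect_true(all(out$stage2[foreign] %in%
                    c("hgt_candidate", "contaminant_candidate",
                      "uncertain")))
  expect_true(all(out$stage2[!foreign] == "not_applicable"))
  # no contaminant candidate sits on a resident-tagged scaffold
  contam <- out$cds_id[out$stage2 == "contaminant_candidate"]
  scs <- tab$mapped$scaffold_id[tab$mapped$cds_id %in% contam]
  expect_length(intersect(scs, tab$arthropod_tagged), 0L)
})

test_that("fragmentation splits deterministically and monotonically", {
  fix <- generate_fixture(fixture_config(seed = 12))
  # identity at factor 1
  fr1 <- fragment_assembly(fix$mappings, fix$scaffold_lengths, 1L)
  expect_identical(fr1$mappings, fix$mappings)

  fr4a <- fragment_assembly(fix$mappings, fix$scaffold_lengths, 4L)
  fr4b <- fragment_assembly(fix$mappings, fix$scaffold_lengths, 4L)
  expect_identical(fr4a, fr4b)
  expect_error(fragment_assembly(fix$mappings, fix$scaffold_lengths, 0L),
               ">= 1")

  # total length is conserved
  expect_equal(sum(fr4a$scaffold_lengths), sum(fix$scaffold_lengths))

  # split to one CDS per scaffold: every foreign candidate uncertain
  ann <- assign_taxonomy(fix$hits, fix$taxonomy,
                         cds_ids = names(fix$cds))
  big <- fragment_assembly(fix$mappings, fix$scaffold_lengths, 64L)
  out <- classify_foreign(ann, build_scaffold_table(ann, big$mappings))
  expect_true(all(out$stage2[out$stage1 == "foreign"] == "uncertain"))
})
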