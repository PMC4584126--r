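fam_plano <- function() {
  parse_lineage(paste0("kingdom:Bacteria; phylum:Firmicutes; class:Bacilli; ",
                       "order:Bacillales; family:Planococcaceae"),
                "rank_colon")[[1]]
}

test_that("organisms pool on the lowest (rank, name) in sorted order", {
  w <- toy_world()
  fdb <- filter_genomes(w$db)
  expect_identical(pool_organisms(fam_plano(), fdb), c("G1", "G2"))
  # root-level pooling over the unfiltered database catches everything
  king <- parse_lineage("kingdom:Bacteria", "rank_colon")[[1]]
  expect_identical(pool_organisms(king, w$db), c("G1", "G2", "G4"))
  # a genus matching exactly one genome
  gen <- parse_lineage(w$organisms$lineage_string[1], "rank_colon")[[1]]
  expect_identical(pool_organisms(gen, fdb), "G1")
  # contract breach: pooling an untrimmed lineage errors
  ghost <- new_lineage(c("Bacteria", "Firmicutes", "Bacilli", "Bacillales",
                         "Planococcaceae", "Kurthia"))
  expect_error(pool_organisms(ghost, fdb), class = "panfun_contract_error")
})

test_that("the hand-enumerated toy pangenome row is reproduced exactly", {
  w <- toy_world()
  fdb <- filter_genomes(w$db)
  row <- lineage_function_row(fam_plano(), fdb)
  expect_identical(row$o_i, 2L)
  expect_identical(row$copy_median, 5)
  expect_identical(row$fq, c(K1 = 1.0, K2 = 1.0, K3 = 0.5))
})

test_that("single-genome pools return raw per-KO gene counts", {
  w <- toy_world()
  gen <- parse_lineage(w$organisms$lineage_string[1], "rank_colon")[[1]]
  row <- lineage_function_row(gen, filter_genomes(w$db))
  expect_identical(row$fq, c(K1 = 2.0, K2 = 1.0))
  # duplicating the genome leaves the profile unchanged (mean invariance)
  org2 <- w$organisms[c(1, 1), ]
  org2$organism_id <- c("G1", "G1b")
  ann2 <- w$annotations[w$annotations$organism_id == "G1", ]
  ann2 <- dplyr::bind_rows(ann2, dplyr::mutate(ann2, organism_id = "G1b"))
  db2 <- genome_db(org2, ann2)
  expect_identical(lineage_function_row(gen, db2)$fq, c(K1 = 2.0, K2 = 1.0))
})

test_that("multi-copy gene families yield frequencies above 1, unclamped", {
  db <- genome_db(
    tibble::tibble(organism_id = "A",
                   lineage_string = "kingdom:Bacteria; phylum:P1",
                   n_genes_total = 2L, n_16S_copies = 1L),
    tibble::tibble(organism_id = "A", gene_id = c("g1", "g2"),
                   ko_term = "K7"))
  lin <- parse_lineage("kingdom:Bacteria; phylum:P1", "rank_colon")[[1]]
  expect_identical(lineage_function_row(lin, db)$fq, c(K7 = 2.0))
})

test_that("duplicate lineages share a single cached table row", {
  w <- toy_world()
  fdb <- filter_genomes(w$db)
  lft <- lineage_function_table(list(fam_plano(), fam_plano()), fdb)
  expect_identical(dplyr::n_distinct(lft$lineage), 1L)
  expect_identical(nrow(lft), 3L)
  expect_identical(nrow(lineage_function_table(list(), fdb)), 0L)
})

test_that("table rows match per-row hand computation on the toy database", {
  w <- toy_world()
  prot <- parse_lineage("kingdom:Bacteria; phylum:Proteobacteria",
                        "rank_colon")[[1]]
  lft <- lineage_function_table(list(fam_plano(), prot), w$db)  # unfiltered
  expect_identical(dplyr::n_distinct(lft$lineage), 2L)
  prot_row <- lft[lft$ko_term == "K4", ]
  expect_identical(prot_row$o_i, 1L)
  expect_identical(prot_row$fq, 1.0)
})

test_that("row mass equals the integer gene-KO pair total of the pool", {
  w <- random_world(21)
  fdb <- filter_genomes(w$db)
  fams <- unique(purrr::map_chr(fdb$organisms$lineage,
                                ~ lineage_string(lineage_prefix(.x, "family"))))
  for (f in fams[1:5]) {
    lin <- parse_lineage(f, "rank_colon")[[1]]
    row <- lineage_function_row(lin, fdb)
    pool <- pool_organisms(lin, fdb)
    pairs <- sum(fdb$annotations$organism_id %in% pool)
    expect_true(all(row$fq > 0))
    expect_equal(sum(row$fq) * row$o_i, pairs, tolerance = 1e-12)
  }
})

test_that("a coarse pool is the organism-weighted mean of its genus partition", {
  for (seed in c(31, 32)) {
    w <- random_world(seed)
    fdb <- filter_genomes(w$db)
    fam_lins <- unique(purrr::map_chr(
      fdb$organisms$lineage,
      ~ lineage_string(lineage_prefix(.x, "family"))))
    fam <- parse_lineage(fam_lins[1], "rank_colon")[[1]]
    coarse <- lineage_function_row(fam, fdb)
    pool <- pool_organisms(fam, fdb)
    genus_lins <- unique(purrr::map_chr(
      fdb$organisms$lineage[fdb$organisms$organism_id %in% pool],
      lineage_string))
    fine <- purrr::map(parse_lineage(genus_lins, "rank_colon"),
                       ~ lineage_function_row(.x, fdb))
    # genus pools partition the family pool
    expect_identical(sort(unlist(purrr::map(
      parse_lineage(genus_lins, "rank_colon"),
      ~ pool_organisms(.x, fdb)))), pool)
    kos <- sort(unique(unlist(purrr::map(fine, ~ names(.x$fq)))))
    val <- function(v, k) if (k %in% names(v)) unname(v[[k]]) else 0
    lhs <- coarse$o_i * purrr::map_dbl(kos, ~ val(coarse$fq, .x))
    rhs <- purrr::map_dbl(kos, function(k) {
      sum(purrr::map_dbl(fine, ~ .x$o_i * val(.x$fq, k)))
    })
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("identical inputs serialize to bit-identical tables", {
  w <- random_world(41)
  fdb <- filter_genomes(w$db)
  lins <- parse_lineage(unique(purrr::map_chr(
    fdb$organisms$lineage[1:5], lineage_string)), "rank_colon")
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  readr::write_tsv(lineage_function_table(lins, fdb), f1, progress = FALSE)
  readr::write_tsv(lineage_function_table(lins, fdb), f2, progress = FALSE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
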