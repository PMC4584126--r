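test_that("functional coverage is annotated genes over total genes", {
  w <- toy_world()
  cov <- functional_coverage(w$db)
  expect_identical(cov$coverage[match(c("G1", "G2", "G4"), cov$organism_id)],
                   c(3 / 4, 1 / 2, 1 / 5))
  # a gene with two KO terms (G2_g1) counts once toward coverage
  expect_identical(cov$n_annotated[cov$organism_id == "G2"], 1L)
})

test_that("coverage filtering keeps exactly the genomes at or above the cutoff", {
  w <- toy_world()
  fdb <- filter_genomes(w$db, 0.30)
  expect_setequal(fdb$organisms$organism_id, c("G1", "G2"))
  expect_identical(attr(fdb, "n_removed"), 1L)
  # cutoff 0 is the identity; a cutoff above 1 with unannotated genes removes all
  expect_setequal(filter_genomes(w$db, 0)$organisms$organism_id,
                  c("G1", "G2", "G4"))
  expect_identical(nrow(filter_genomes(w$db, 1 + 1e-9)$organisms), 0L)
})

test_that("coverage filtering is monotone in the cutoff", {
  w <- random_world(3)
  cuts <- seq(0, 1, by = 0.1)
  n <- vapply(cuts, function(x) nrow(filter_genomes(w$db, x)$organisms),
              integer(1))
  expect_true(all(diff(n) <= 0))
})

test_that("median 16S copy number uses the pool median with even-pool mean", {
  w <- toy_world()
  fam <- parse_lineage(paste0("kingdom:Bacteria; phylum:Firmicutes; ",
                              "class:Bacilli; order:Bacillales; ",
                              "family:Planococcaceae"), "rank_colon")[[1]]
  expect_identical(median_copy_number(fam, w$db), 5)  # mean of {4, 6}
  # odd pool and single-organism pool
  db3 <- genome_db(
    tibble::tibble(organism_id = c("A", "B", "C"),
                   lineage_string = "kingdom:Bacteria; phylum:P1; class:C1",
                   n_genes_total = 1L, n_16S_copies = c(1L, 3L, 7L)),
    tibble::tibble(organism_id = c("A", "B", "C"),
                   gene_id = "g1", ko_term = "K1"))
  cls <- parse_lineage("kingdom:Bacteria; phylum:P1; class:C1",
                       "rank_colon")[[1]]
  expect_identical(median_copy_number(cls, db3), 3)
  db1 <- genome_db(db3$organisms[1, ], db3$annotations[1, ])
  expect_identical(median_copy_number(cls, db1), 1)
})

test_that("unknown copy counts are excluded; an all-unknown pool defaults to 1", {
  db <- genome_db(
    tibble::tibble(organism_id = c("A", "B"),
                   lineage_string = "kingdom:Bacteria; phylum:P1",
                   n_genes_total = 1L, n_16S_copies = c(NA, 4L)),
    tibble::tibble(organism_id = "A", gene_id = "g1", ko_term = "K1"))
  lin <- parse_lineage("kingdom:Bacteria; phylum:P1", "rank_colon")[[1]]
  expect_identical(median_copy_number(lin, db), 4)
  db_all_na <- genome_db(dplyr::mutate(db$organisms,
                                       n_16S_copies = NA_integer_),
                         db$annotations)
  expect_warning(m <- median_copy_number(lin, db_all_na), "defaulting to 1")
  expect_identical(m, 1)
})

test_that("median copy number is invariant to record order", {
  w <- random_world(9)
  lin <- parse_lineage(w$organisms$lineage_string[1], "rank_colon")[[1]]
  lin <- lineage_prefix(lin, "family")
  shuf <- w$organisms[rev(seq_len(nrow(w$organisms))), ]
  db2 <- genome_db(shuf, w$annotations)
  expect_identical(median_copy_number(lin, w$db),
                   median_copy_number(lin, db2))
})

test_that("database loading round-trips files and rejects malformed input", {
  w <- toy_world()
  dir <- withr::local_tempdir()
  db <- genome_db(w$organisms, w$annotations)
  write_genome_db(db, dir)
  db2 <- read_genome_db(file.path(dir, "organisms.tsv"),
                        file.path(dir, "annotations.tsv"))
  expect_identical(nrow(db2$organisms), 3L)
  expect_identical(dplyr::arrange(db2$annotations, .data$organism_id,
                                  .data$gene_id, .data$ko_term),
                   dplyr::arrange(w$annotations, .data$organism_id,
                                  .data$gene_id, .data$ko_term))
  # organism annotated but not listed
  expect_error(genome_db(w$organisms[1:2, ], w$annotations),
               class = "panfun_format_error", regexp = "G4")
  # duplicate gene-KO pair
  expect_error(genome_db(w$organisms, w$annotations[c(1, 1, 2), ]),
               class = "panfun_format_error")
  # non-positive gene totals
  bad <- dplyr::mutate(w$organisms,
                       n_genes_total = c(0L, 2L, 5L))
  expect_error(genome_db(bad, w$annotations),
               class = "panfun_format_error", regexp = "G1")
  # malformed KO id
  expect_error(genome_db(w$organisms,
                         dplyr::mutate(w$annotations, ko_term = "KO1")),
               class = "panfun_format_error")
})

test_that("an organism with no annotations has coverage zero, not an error", {
  org <- tibble::tibble(organism_id = c("A", "B"),
                        lineage_string = "kingdom:Bacteria; phylum:P1",
                        n_genes_total = 3L, n_16S_copies = 2L)
  ann <- tibble::tibble(organism_id = "B", gene_id = "g1", ko_term = "K2")
  cov <- functional_coverage(genome_db(org, ann))
  expect_identical(cov$coverage[cov$organism_id == "A"], 0)
})

test_that("the organism index is sound and complete", {
  w <- random_world(4)
  idx <- w$db$index
  lin_of <- setNames(w$db$organisms$lineage, w$db$organisms$organism_id)
  # soundness: every indexed pair is on that organism's lineage
  ok <- purrr::map2_lgl(idx$key, idx$organism_id,
                        ~ .x %in% lineage_keys(lin_of[[.y]]))
  expect_true(all(ok))
  # completeness: every lineage pair of every organism is indexed
  expect_identical(nrow(idx), sum(lengths(lin_of)))
  # rebuild-and-compare: filtering leaves the index exactly derivable
  fdb <- filter_genomes(w$db, 0.30)
  rebuilt <- genome_db(fdb$organisms[, c("organism_id", "lineage_string",
                                         "n_genes_total", "n_16S_copies")],
                       fdb$annotations)
  expect_identical(dplyr::arrange(fdb$index, .data$key, .data$organism_id),
                   dplyr::arrange(rebuilt$index, .data$key, .data$organism_id))
})
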