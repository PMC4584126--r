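toy_chain <- function() {
  w <- toy_world()
  w$fdb <- filter_genomes(w$db)
  al <- assign_lineages(w$otu, w$fdb, w$ref)
  w$otu_lin <- setNames(al$assignments$lineage, al$assignments$otu_id)
  w$lft <- lineage_function_table(
    parse_lineage(unname(w$otu_lin), "rank_colon"), w$fdb)
  w
}

test_that("copy correction divides abundances by the lineage copy median", {
  w <- toy_chain()
  corrected <- copy_correct(w$otu, w$lft, w$otu_lin)
  expect_identical(corrected$S1, 2)  # 10 / 5
  # copy median 1 everywhere is the identity; zero abundance stays zero
  lft1 <- dplyr::mutate(w$lft, copy_median = 1)
  expect_identical(copy_correct(w$otu, lft1, w$otu_lin)$S1, 10)
  z <- w$otu; z$S1 <- 0
  expect_identical(copy_correct(otu_table(z), w$lft, w$otu_lin)$S1, 0)
  # missing lineage row is a structured error
  expect_error(copy_correct(w$otu, w$lft, c(OTU_1 = NA_character_)),
               class = "panfun_contract_error")
})

test_that("sample normalization makes non-empty columns sum to one", {
  t <- otu_table(tibble::tibble(
    otu_id = c("a", "b"), S1 = c(2, 6), S2 = c(0, 0), taxonomy = ""))
  expect_warning(out <- sample_normalize(t), "zero total")
  expect_identical(out$S1, c(0.25, 0.75))
  expect_identical(out$S2, c(0, 0))
  one <- otu_table(tibble::tibble(otu_id = "a", S1 = 17, taxonomy = ""))
  expect_identical(sample_normalize(one)$S1, 1)
})

test_that("collapsing sums OTUs sharing a lineage and preserves column sums", {
  t <- otu_table(tibble::tibble(
    otu_id = c("a", "b", "c"), S1 = c(0.25, 0.75, 0), S2 = c(0.2, 0.3, 0.5),
    taxonomy = ""))
  map <- c(a = "L1", b = "L1", c = "L2")
  ls <- collapse_lineages(t, map)
  expect_identical(ls$S1[ls$lineage == "L1"], 1)
  expect_identical(colSums(ls[, c("S1", "S2")]), c(S1 = 1, S2 = 1))
  # all-distinct lineages is a relabeling
  map2 <- c(a = "L1", b = "L2", c = "L3")
  expect_identical(collapse_lineages(t, map2)$S1, t$S1)
  # empty table collapses to an empty result
  empty <- otu_table(t[0, ])
  expect_identical(nrow(collapse_lineages(empty, map)), 0L)
})

test_that("function profiles weight pangenome rows by lineage abundance", {
  w <- toy_chain()
  ls <- tibble::tibble(lineage = unique(unname(w$otu_lin)), S1 = 1)
  fs <- function_profile(ls, w$lft)
  expect_identical(fs$ko_term, c("K1", "K2", "K3"))
  expect_identical(fs$S1, c(1, 1, 0.5))
  # zero weight contributes nothing
  ls0 <- dplyr::mutate(ls, S1 = 0)
  expect_identical(nrow(function_profile(ls0, w$lft)), 0L)
  # missing pangenome row is a structured error
  expect_error(function_profile(dplyr::mutate(ls, lineage = "nope"), w$lft),
               class = "panfun_contract_error")
})

test_that("two half-weight lineages with disjoint KO sets union at half value", {
  lft <- tibble::tibble(
    lineage = c("L1", "L1", "L2"), o_i = 1L, copy_median = 1,
    ko_term = c("K1", "K2", "K9"), fq = c(1, 0.5, 2))
  ls <- tibble::tibble(lineage = c("L1", "L2"), S1 = c(0.5, 0.5))
  fs <- function_profile(ls, lft)
  expect_identical(fs$ko_term, c("K1", "K2", "K9"))
  expect_identical(fs$S1, c(0.5, 0.25, 1))
})

test_that("the full chain on the toy fixture reproduces every stage", {
  w <- toy_world()
  prof <- infer_functional_profile(w$otu, w$db, ref = w$ref)
  expect_identical(prof$function_table$ko_term, c("K1", "K2", "K3"))
  expect_identical(prof$function_table$S1, c(1, 1, 0.5))
  expect_identical(prof$lineage_table$S1, 1)
  lin <- prof$assignments$lineage[1]
  expect_match(lin, "family:Planococcaceae$")
  expect_identical(unique(prof$lineage_function$copy_median), 5)
  expect_identical(unique(prof$lineage_function$o_i), 2L)
})

test_that("an untaxonomized OTU is dropped and logged, leaving the profile unchanged", {
  w <- toy_world()
  t2 <- otu_table(dplyr::bind_rows(
    w$otu, tibble::tibble(otu_id = "OTU_2", S1 = 99, taxonomy = "")))
  prof1 <- infer_functional_profile(w$otu, w$db, ref = w$ref)
  prof2 <- infer_functional_profile(t2, w$db, ref = w$ref)
  expect_identical(prof1$function_table, prof2$function_table)
  expect_identical(prof2$assignments$status[2], "dropped")
  expect_true(any(prof2$log$event == "dropped" &
                    prof2$log$otu_id == "OTU_2"))
})

test_that("a table whose OTUs are all dropped fails loudly", {
  w <- toy_world()
  bad <- otu_table(tibble::tibble(otu_id = "x", S1 = 5, taxonomy = ""))
  expect_error(infer_functional_profile(bad, w$db, ref = w$ref),
               class = "panfun_pipeline_error")
})

test_that("pipeline output equals the direct per-OTU oracle on random fixtures", {
  for (seed in c(101, 102, 103)) {
    w <- random_world(seed, n_otus = 60)
    ot <- generate_otu_table(w, w$cfg)
    prof <- infer_functional_profile(ot$otu, w$db, ref = w$ref)
    m <- profile_as_matrix(prof$function_table)
    tr <- ot$truth$profile
    expect_setequal(rownames(m), rownames(tr))
    expect_equal(m[rownames(tr), , drop = FALSE], tr, tolerance = 1e-9)
  }
})

test_that("scaling one sample's raw counts leaves its profile unchanged", {
  w <- random_world(7, n_otus = 40)
  ot <- generate_otu_table(w, w$cfg)$otu
  prof1 <- infer_functional_profile(ot, w$db, ref = w$ref)
  scaled <- ot
  scaled$S01 <- scaled$S01 * 17
  prof2 <- infer_functional_profile(otu_table(scaled), w$db, ref = w$ref)
  expect_equal(prof1$function_table$S01, prof2$function_table$S01,
               tolerance = 1e-12)
})

test_that("lineage-table columns sum to one and KO mass is conserved", {
  w <- random_world(8, n_otus = 40)
  ot <- generate_otu_table(w, w$cfg)$otu
  prof <- infer_functional_profile(ot, w$db, ref = w$ref)
  smp <- sample_ids(prof$lineage_table)
  sums <- colSums(as.matrix(prof$lineage_table[, smp]))
  expect_equal(unname(sums), rep(1, length(smp)), tolerance = 1e-9)
  # mass conservation: sum_KO fq(KO, s) = sum_L fq(L, s) * T_L
  tot <- lineage_totals(prof$lineage_function)
  t_l <- tot$total_fq[match(prof$lineage_table$lineage, tot$lineage)]
  expected <- colSums(as.matrix(prof$lineage_table[, smp]) * t_l)
  got <- colSums(as.matrix(prof$function_table[, smp]))
  expect_equal(unname(got), unname(expected), tolerance = 1e-9)
})

test_that("running the same input twice writes bit-identical outputs", {
  dir <- withr::local_tempdir()
  make_fixture("toy", out = file.path(dir, "fx"))
  for (run in c("r1", "r2")) {
    run_pipeline(
      otu_table_path = file.path(dir, "fx", "otu_table.tsv"),
      db_dir = file.path(dir, "fx"),
      ref_taxonomy_path = file.path(dir, "fx", "taxonomy.tsv"),
      out_dir = file.path(dir, run))
  }
  for (f in c("function_sample.tsv", "lineage_sample.tsv",
              "lineage_function.tsv", "run_log.tsv")) {
    p1 <- file.path(dir, "r1", f)
    p2 <- file.path(dir, "r2", f)
    expect_identical(readBin(p1, "raw", file.size(p1)),
                     readBin(p2, "raw", file.size(p2)))
  }
})
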