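#' Configuration for synthetic fixtures
#'
#' Describes a seeded synthetic world: a rank-complete taxonomy, a
#' collection of annotated genomes hanging off its genera, and an OTU table
#' drawn against it. Defaults emulate a small but realistic amplicon
#' survey: most OTUs resolved to genus or species with a tail of
#' family/order-level calls (the mixture observed in mock-community
#' surveys), log-normal read counts, 16S copy numbers between 1 and 15,
#' and a minority of poorly annotated genomes that the coverage filter
#' removes.
#'
#' @param n_phyla Number of phyla.
#' @param taxa_branching Children per taxon at each internal rank.
#' @param n_genomes_per_genus Genomes attached to each non-ghost genus.
#' @param genes_per_genome Length-2 integer range of genes per genome.
#' @param ko_vocabulary_size Size of the KO vocabulary (`K00001...`).
#' @param annotation_coverage Length-2 range of per-genome annotation
#'   coverage for well-annotated genomes (uniform draw).
#' @param frac_low_coverage Fraction of genomes drawn with coverage in
#'   `low_coverage_range` (exercises the coverage filter).
#' @param low_coverage_range Length-2 coverage range for poor genomes.
#' @param copy_number_range Length-2 integer range for 16S copy counts
#'   (uniform draw over the integers).
#' @param n_otus,n_samples OTU-table dimensions.
#' @param abundance_meanlog,abundance_sdlog Log-normal read-count model.
#' @param rank_depth_probs Named probabilities over the deepest resolved
#'   rank of an OTU (`species`, `genus`, `family`, `order`, `class`).
#' @param frac_ghost_genus Fraction of OTUs assigned to a genus present in
#'   the taxonomy but with no genomes (exercises trimming).
#' @param frac_corrupt_upper Fraction of OTUs whose class name is replaced
#'   by a string absent from the taxonomy (exercises reconciliation; the
#'   corruption sits above the pooling rank, so the profile is unchanged).
#' @param frac_untaxonomized Fraction of OTUs with an empty taxonomy
#'   (dropped by the pipeline).
#' @param dialect Dialect used when writing OTU taxonomies.
#' @param seed Mandatory integer seed.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n_phyla = 3, taxa_branching = 2,
                           n_genomes_per_genus = 2,
                           genes_per_genome = c(60L, 120L),
                           ko_vocabulary_size = 200,
                           annotation_coverage = c(0.5, 0.95),
                           frac_low_coverage = 0.10,
                           low_coverage_range = c(0.05, 0.25),
                           copy_number_range = c(1L, 15L),
                           n_otus = 100, n_samples = 4,
                           abundance_meanlog = 4, abundance_sdlog = 1.2,
                           rank_depth_probs = c(species = 0.24,
                                                genus = 0.62,
                                                family = 0.10,
                                                order = 0.03,
                                                class = 0.01),
                           frac_ghost_genus = 0.10,
                           frac_corrupt_upper = 0.05,
                           frac_untaxonomized = 0.02,
                           dialect = "greengenes_prefix",
                           seed) {
  if (missing(seed)) abort("fixture_config() requires an explicit seed",
                           class = "panfun_config_error")
  stopifnot(n_phyla >= 1, taxa_branching >= 1, n_genomes_per_genus >= 1,
            length(genes_per_genome) == 2, ko_vocabulary_size >= 1,
            n_otus >= 0, n_samples >= 1,
            abs(sum(rank_depth_probs) - 1) < 1e-8)
  structure(as.list(environment()), class = "fixture_config")
}

#' Generate a synthetic reference database and taxonomy
#'
#' Builds a rank-complete taxonomy of `n_phyla` phyla with
#' `taxa_branching` children per rank down to genus (plus one genome-less
#' "ghost" genus per family), attaches `n_genomes_per_genus` genomes to
#' every ordinary genus, draws per-genome gene counts, annotation coverage
#' and 16S copy numbers from the configured distributions, and annotates
#' genes with KO terms (a fifth of annotated genes carry a second term).
#' When the configured coverage mass lies entirely below the 30% filter no
#' genome would survive; that configuration is rejected.
#'
#' @param cfg A [fixture_config()].
#' @param dir Optional directory; when given, `organisms.tsv`,
#'   `annotations.tsv` and `taxonomy.tsv` are written there.
#' @return A list with tibbles `organisms`, `annotations`, `taxonomy`,
#'   plus `genera` (tibble of genus names, their lineage strings and
#'   `has_genomes`).
#' @export
generate_reference_db <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "fixture_config"))
  if (cfg$frac_low_coverage >= 1 && max(cfg$low_coverage_range) < 0.30) {
    abort("configured coverage mass lies entirely below the 30% filter",
          class = "panfun_config_error")
  }
  set.seed(cfg$seed)
  b <- cfg$taxa_branching
  tax_rows <- list(tibble::tibble(taxon_name = "Bacteria", rank = "kingdom",
                                  parent_name = NA_character_,
                                  parent_rank = NA_character_))
  genera <- list()
  kos <- sprintf("K%05d", seq_len(cfg$ko_vocabulary_size))
  org_rows <- list(); ann_rows <- list()
  org_n <- 0

  for (p in seq_len(cfg$n_phyla)) {
    pn <- paste0("Phylum", p)
    tax_rows[[length(tax_rows) + 1]] <- tibble::tibble(
      taxon_name = pn, rank = "phylum", parent_name = "Bacteria",
      parent_rank = "kingdom")
    for (cl in seq_len(b)) {
      cn <- paste0(pn, "_C", cl)
      tax_rows[[length(tax_rows) + 1]] <- tibble::tibble(
        taxon_name = cn, rank = "class", parent_name = pn,
        parent_rank = "phylum")
      for (o in seq_len(b)) {
        on <- paste0(cn, "_O", o)
        tax_rows[[length(tax_rows) + 1]] <- tibble::tibble(
          taxon_name = on, rank = "order", parent_name = cn,
          parent_rank = "class")
        for (f in seq_len(b)) {
          fn <- paste0(on, "_F", f)
          tax_rows[[length(tax_rows) + 1]] <- tibble::tibble(
            taxon_name = fn, rank = "family", parent_name = on,
            parent_rank = "order")
          for (g in seq_len(b + 1)) {
            ghost <- g == b + 1
            gn <- paste0(fn, if (ghost) "_Ghost" else paste0("_G", g))
            tax_rows[[length(tax_rows) + 1]] <- tibble::tibble(
              taxon_name = gn, rank = "genus", parent_name = fn,
              parent_rank = "family")
            lin <- paste0("kingdom:Bacteria; phylum:", pn, "; class:", cn,
                          "; order:", on, "; family:", fn, "; genus:", gn)
            genera[[length(genera) + 1]] <- tibble::tibble(
              genus = gn, lineage_string = lin, has_genomes = !ghost)
            if (ghost) next
            for (k in seq_len(cfg$n_genomes_per_genus)) {
              org_n <- org_n + 1
              oid <- sprintf("ORG%04d", org_n)
              n_genes <- sample(cfg$genes_per_genome[1]:cfg$genes_per_genome[2], 1)
              low <- stats::runif(1) < cfg$frac_low_coverage
              cov_rng <- if (low) cfg$low_coverage_range
                         else cfg$annotation_coverage
              cov <- stats::runif(1, cov_rng[1], cov_rng[2])
              n_ann <- round(cov * n_genes)
              copies <- sample(cfg$copy_number_range[1]:cfg$copy_number_range[2], 1)
              org_rows[[org_n]] <- tibble::tibble(
                organism_id = oid, lineage_string = lin,
                n_genes_total = as.integer(n_genes),
                n_16S_copies = as.integer(copies))
              if (n_ann > 0) {
                gene_ids <- sprintf("%s_g%04d", oid, seq_len(n_ann))
                ko1 <- sample(kos, n_ann, replace = TRUE)
                second <- stats::runif(n_ann) < 0.2
                ann <- tibble::tibble(organism_id = oid, gene_id = gene_ids,
                                      ko_term = ko1)
                if (any(second)) {
                  ko2 <- sample(kos, sum(second), replace = TRUE)
                  # a second term must differ from the first on that gene
                  clash <- ko2 == ko1[second]
                  while (any(clash) && cfg$ko_vocabulary_size > 1) {
                    ko2[clash] <- sample(kos, sum(clash), replace = TRUE)
                    clash <- ko2 == ko1[second]
                  }
                  ok <- ko2 != ko1[second]
                  ann <- dplyr::bind_rows(ann, tibble::tibble(
                    organism_id = oid, gene_id = gene_ids[second][ok],
                    ko_term = ko2[ok]))
                }
                ann_rows[[org_n]] <- ann
              }
            }
          }
        }
      }
    }
  }

  out <- list(organisms = dplyr::bind_rows(org_rows),
              annotations = dplyr::bind_rows(ann_rows),
              taxonomy = dplyr::bind_rows(tax_rows),
              genera = dplyr::bind_rows(genera))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(out$organisms, file.path(dir, "organisms.tsv"),
                     progress = FALSE)
    readr::write_tsv(out$annotations, file.path(dir, "annotations.tsv"),
                     progress = FALSE)
    readr::write_tsv(out$taxonomy, file.path(dir, "taxonomy.tsv"),
                     progress = FALSE)
  }
  out
}

#' Generate a synthetic OTU table with exact ground truth
#'
#' Draws `n_otus` OTUs against a generated reference world: most point at
#' ordinary genera (resolved to the depth drawn from `rank_depth_probs`;
#' species-level OTUs append a binomial epithet that never has genomes), a
#' configured fraction point at ghost genera (trimming must fall back to
#' the family), a fraction carries a corrupted class name absent from the
#' taxonomy (reconciliation repairs it from the genus), and a fraction has
#' no taxonomy at all (dropped). Abundances are log-normal counts. The
#' ground-truth function profile is computed at generation time by the
#' independent per-OTU enumeration of [direct_function_profile()].
#'
#' @param world Output of [generate_reference_db()].
#' @param cfg The same [fixture_config()].
#' @param dir Optional directory; writes `otu_table.tsv` (QIIME classic)
#'   and `ground_truth.tsv` (long format `ko_term`, `sample_id`, `value`).
#' @return A list: `otu` (`otu_table` tibble), `truth` (the
#'   [direct_function_profile()] result).
#' @export
generate_otu_table <- function(world, cfg, dir = NULL) {
  stopifnot(inherits(cfg, "fixture_config"))
  set.seed(cfg$seed + 1L)
  smp <- sprintf("S%02d", seq_len(cfg$n_samples))
  ordinary <- world$genera[world$genera$has_genomes, ]
  ghosts <- world$genera[!world$genera$has_genomes, ]

  n <- cfg$n_otus
  rows <- vector("list", n)
  if (n > 0) {
    kind <- sample(c("untaxonomized", "ghost", "corrupt", "ordinary"), n,
                   replace = TRUE,
                   prob = c(cfg$frac_untaxonomized, cfg$frac_ghost_genus,
                            cfg$frac_corrupt_upper,
                            1 - cfg$frac_untaxonomized - cfg$frac_ghost_genus -
                              cfg$frac_corrupt_upper))
    depths <- sample(names(cfg$rank_depth_probs), n, replace = TRUE,
                     prob = cfg$rank_depth_probs)
    for (i in seq_len(n)) {
      if (kind[i] == "untaxonomized") {
        rows[[i]] <- list(tax = "")
        next
      }
      src <- if (kind[i] == "ghost") ghosts else ordinary
      g <- src[sample.int(nrow(src), 1), ]
      lin <- parse_lineage(g$lineage_string, "rank_colon")[[1]]
      depth_rank <- if (kind[i] == "ghost") "genus" else depths[i]
      if (depth_rank == "species") {
        lin <- new_lineage(c(unname(lin), paste(g$genus, "sp1")),
                           c(names(lin), "species"))
      } else {
        lin <- lineage_prefix(lin, depth_rank)
      }
      if (kind[i] == "corrupt" && length(lin) >= 3) {
        lin["class"] <- paste0(unname(lin["class"]), "_obsolete")
      }
      rows[[i]] <- list(tax = render_taxonomy(lin, cfg$dialect))
    }
  }
  ab <- matrix(round(stats::rlnorm(n * cfg$n_samples,
                                   cfg$abundance_meanlog,
                                   cfg$abundance_sdlog)),
               nrow = n, ncol = cfg$n_samples)
  otu <- tibble::as_tibble(as.data.frame(ab))
  names(otu) <- smp
  otu <- dplyr::bind_cols(
    tibble::tibble(otu_id = sprintf("OTU_%04d", seq_len(n))), otu,
    tibble::tibble(taxonomy = purrr::map_chr(rows, "tax")))
  otu <- otu_table(otu)
  truth <- direct_function_profile(otu, world$organisms, world$annotations)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_otu_table(otu, file.path(dir, "otu_table.tsv"))
    tr <- truth$profile
    long <- tibble::tibble(
      ko_term = rep(rownames(tr), times = ncol(tr)),
      sample_id = rep(colnames(tr), each = nrow(tr)),
      value = as.vector(tr)) |>
      dplyr::filter(.data$value != 0) |>
      dplyr::arrange(.data$ko_term, .data$sample_id)
    readr::write_tsv(long, file.path(dir, "ground_truth.tsv"),
                     progress = FALSE)
  }
  list(otu = otu, truth = truth)
}

# render a lineage in a given OTU-table dialect
render_taxonomy <- function(lin, dialect) {
  if (length(lin) == 0) return("")
  if (dialect == "greengenes_prefix") {
    pre <- setNames(names(GG_PREFIX), GG_PREFIX)
    paste(paste0(pre[names(lin)], "__", unname(lin)), collapse = "; ")
  } else if (dialect == "rank_colon") {
    lineage_string(lin)
  } else {
    paste(unname(lin), collapse = "; ")
  }
}

#' The canonical toy reference world
#'
#' A three-genome hand-checkable database used throughout the tests and
#' documentation: two Planococcaceae genomes (G1: 4 genes, 3 annotated over
#' K1/K2, 4 16S copies; G2: 2 genes, 1 gene carrying both K2 and K3, 6
#' copies) and one poorly annotated Enterobacteriaceae genome (G4: 5
#' genes, 1 annotated, coverage 0.2 — removed by the default filter), plus
#' a reference taxonomy that also contains the genome-less genus Kurthia
#' under Planococcaceae.
#'
#' @return A list of tibbles `organisms`, `annotations`, `taxonomy`, and
#'   `otu` (a one-OTU, one-sample table with abundance 10 assigned to
#'   genus Kurthia).
#' @export
toy_reference_db <- function() {
  lin_plano <- paste0("kingdom:Bacteria; phylum:Firmicutes; class:Bacilli; ",
                      "order:Bacillales; family:Planococcaceae; genus:")
  lin_entero <- paste0("kingdom:Bacteria; phylum:Proteobacteria; ",
                       "class:Gammaproteobacteria; order:Enterobacterales; ",
                       "family:Enterobacteriaceae; genus:Escherichia")
  organisms <- tibble::tibble(
    organism_id = c("G1", "G2", "G4"),
    lineage_string = c(paste0(lin_plano, "Sporosarcina"),
                       paste0(lin_plano, "Solibacillus"),
                       lin_entero),
    n_genes_total = c(4L, 2L, 5L),
    n_16S_copies = c(4L, 6L, 7L))
  annotations <- tibble::tibble(
    organism_id = c("G1", "G1", "G1", "G2", "G2", "G4"),
    gene_id = c("G1_g1", "G1_g2", "G1_g3", "G2_g1", "G2_g1", "G4_g1"),
    ko_term = c("K1", "K1", "K2", "K2", "K3", "K4"))
  taxonomy <- tibble::tibble(
    taxon_name = c("Bacteria",
                   "Firmicutes", "Bacilli", "Bacillales", "Planococcaceae",
                   "Sporosarcina", "Solibacillus", "Kurthia",
                   "Proteobacteria", "Gammaproteobacteria",
                   "Enterobacterales", "Enterobacteriaceae", "Escherichia"),
    rank = c("kingdom",
             "phylum", "class", "order", "family",
             "genus", "genus", "genus",
             "phylum", "class", "order", "family", "genus"),
    parent_name = c(NA,
                    "Bacteria", "Firmicutes", "Bacilli", "Bacillales",
                    "Planococcaceae", "Planococcaceae", "Planococcaceae",
                    "Bacteria", "Proteobacteria", "Gammaproteobacteria",
                    "Enterobacterales", "Enterobacteriaceae"),
    parent_rank = c(NA,
                    "kingdom", "phylum", "class", "order",
                    "family", "family", "family",
                    "kingdom", "phylum", "class", "order", "family"))
  otu <- otu_table(tibble::tibble(
    otu_id = "OTU_1", S1 = 10,
    taxonomy = paste0("k__Bacteria; p__Firmicutes; c__Bacilli; ",
                      "o__Bacillales; f__Planococcaceae; g__Kurthia")))
  list(organisms = organisms, annotations = annotations,
       taxonomy = taxonomy, otu = otu)
}

#' Materialize a fixture on disk
#'
#' @param preset `"toy"` (the canonical hand-checkable world) or
#'   `"random"` (a seeded [fixture_config()] world).
#' @param seed Seed for the random preset (ignored for toy).
#' @param out Output directory.
#' @param cfg Optional [fixture_config()] overriding the random default.
#' @return `out`, invisibly.
#' @export
make_fixture <- function(preset = c("toy", "random"), seed = 1, out,
                         cfg = NULL) {
  preset <- match.arg(preset)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (preset == "toy") {
    toy <- toy_reference_db()
    readr::write_tsv(toy$organisms, file.path(out, "organisms.tsv"),
                     progress = FALSE)
    readr::write_tsv(toy$annotations, file.path(out, "annotations.tsv"),
                     progress = FALSE)
    readr::write_tsv(toy$taxonomy, file.path(out, "taxonomy.tsv"),
                     progress = FALSE)
    write_otu_table(toy$otu, file.path(out, "otu_table.tsv"))
  } else {
    cfg <- cfg %||% fixture_config(seed = seed)
    world <- generate_reference_db(cfg, dir = out)
    generate_otu_table(world, cfg, dir = out)
  }
  invisible(out)
}
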