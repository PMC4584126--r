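#' Load a reference genome database
#'
#' The database models a collection of functionally annotated prokaryote
#' genomes. It is stored as two tab-delimited files with header rows:
#'
#' * `organisms.tsv`: `organism_id`, `lineage_string` (rank-colon dialect),
#'   `n_genes_total`, `n_16S_copies`. Each record is the already-merged
#'   union of an organism's chromosomes (plasmid genes excluded upstream).
#' * `annotations.tsv`: `organism_id`, `gene_id`, `ko_term` — one row per
#'   gene–KO pair. Genes without any KO annotation are simply absent and are
#'   accounted for through `n_genes_total`. A gene annotated with several KO
#'   terms appears on several rows.
#'
#' @param organisms_path Path to `organisms.tsv`.
#' @param annotations_path Path to `annotations.tsv`.
#' @return A `genome_db` object.
#' @export
read_genome_db <- function(organisms_path, annotations_path) {
  org <- readr::read_tsv(organisms_path, col_types = readr::cols(
    organism_id = "c", lineage_string = "c",
    n_genes_total = "i", n_16S_copies = "i"), progress = FALSE)
  check_cols(org, c("organism_id", "lineage_string", "n_genes_total",
                    "n_16S_copies"), organisms_path)
  ann <- readr::read_tsv(annotations_path, col_types = readr::cols(
    organism_id = "c", gene_id = "c", ko_term = "c"), progress = FALSE)
  check_cols(ann, c("organism_id", "gene_id", "ko_term"), annotations_path)
  genome_db(org, ann)
}

check_cols <- function(tbl, need, path) {
  missing <- setdiff(need, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("'", path, "' lacks column(s): ",
                 paste(missing, collapse = ", ")),
          class = "panfun_format_error")
  }
  invisible(tbl)
}

#' Construct a genome database from tibbles
#'
#' Validates referential integrity (every annotated organism is listed),
#' duplicate organism ids, non-positive total gene counts, duplicate
#' gene–KO pairs within an organism, and the `K<digits>` shape of KO ids,
#' then parses lineages and builds the (rank, name) organism index.
#'
#' @param organisms Tibble: `organism_id`, `lineage_string`,
#'   `n_genes_total`, `n_16S_copies`.
#' @param annotations Tibble: `organism_id`, `gene_id`, `ko_term`.
#' @return A `genome_db`: list with elements `organisms` (with a `lineage`
#'   list-column), `annotations`, and `index` (tibble `rank`, `name`, `key`,
#'   `organism_id`).
#' @export
genome_db <- function(organisms, annotations) {
  organisms <- tibble::as_tibble(organisms)
  annotations <- tibble::as_tibble(annotations)
  if (anyDuplicated(organisms$organism_id)) {
    dup <- organisms$organism_id[duplicated(organisms$organism_id)]
    abort(paste0("duplicate organism_id in organisms table: ",
                 paste(unique(dup), collapse = ", ")),
          class = "panfun_format_error")
  }
  if (any(is.na(organisms$n_genes_total) | organisms$n_genes_total <= 0)) {
    bad <- organisms$organism_id[is.na(organisms$n_genes_total) |
                                   organisms$n_genes_total <= 0]
    abort(paste0("non-positive n_genes_total for organism(s): ",
                 paste(bad, collapse = ", ")), class = "panfun_format_error")
  }
  orphan <- setdiff(annotations$organism_id, organisms$organism_id)
  if (length(orphan) > 0) {
    abort(paste0("annotations reference organism(s) missing from the ",
                 "organisms table: ", paste(orphan, collapse = ", ")),
          class = "panfun_format_error")
  }
  dup_pair <- duplicated(annotations[c("organism_id", "gene_id", "ko_term")])
  if (any(dup_pair)) {
    abort(paste0("duplicate gene-KO annotation row(s), first for gene '",
                 annotations$gene_id[which(dup_pair)[1]], "'"),
          class = "panfun_format_error")
  }
  bad_ko <- !grepl("^K[0-9]+$", annotations$ko_term)
  if (any(bad_ko)) {
    abort(paste0("malformed KO id(s): ",
                 paste(utils::head(unique(annotations$ko_term[bad_ko]), 5),
                       collapse = ", ")),
          class = "panfun_format_error")
  }
  # 16S copy count 0/NA means unknown; kept as NA and excluded from medians
  copies <- organisms$n_16S_copies
  copies[!is.na(copies) & copies <= 0] <- NA_integer_
  organisms$n_16S_copies <- copies
  organisms$lineage <- parse_lineage(organisms$lineage_string,
                                     dialect = "rank_colon",
                                     otu_ids = organisms$organism_id)
  db <- structure(list(organisms = organisms, annotations = annotations),
                  class = "genome_db")
  db$index <- build_index(db)
  db
}

build_index <- function(db) {
  lins <- db$organisms$lineage
  n <- lengths(lins)
  ranks <- unlist(lapply(lins, names), use.names = FALSE) %||% character()
  names_ <- as.character(unlist(lapply(lins, unclass), use.names = FALSE) %||%
                           character())
  tibble::tibble(rank = as.character(ranks), name = unname(names_),
                 key = rank_key(as.character(ranks), unname(names_)),
                 organism_id = rep(db$organisms$organism_id, n))
}

#' @export
print.genome_db <- function(x, ...) {
  cat("<genome_db> ", nrow(x$organisms), " organism(s), ",
      nrow(x$annotations), " gene-KO annotation row(s), ",
      dplyr::n_distinct(x$annotations$ko_term), " KO term(s)\n", sep = "")
  invisible(x)
}

#' Per-genome functional coverage
#'
#' Functional coverage of a genome is the number of genes carrying at least
#' one KO annotation divided by the total number of genes. A gene with
#' several KO terms counts once here (it still contributes one occurrence
#' per term to pangenome profiles).
#'
#' @param db A `genome_db`.
#' @return A tibble `organism_id`, `n_genes_total`, `n_annotated`,
#'   `coverage`, one row per organism (coverage 0 for organisms with no
#'   annotated genes).
#' @export
functional_coverage <- function(db) {
  stopifnot(inherits(db, "genome_db"))
  ann <- db$annotations |>
    dplyr::distinct(.data$organism_id, .data$gene_id) |>
    dplyr::count(.data$organism_id, name = "n_annotated")
  db$organisms |>
    dplyr::select("organism_id", "n_genes_total") |>
    dplyr::left_join(ann, by = "organism_id") |>
    dplyr::mutate(n_annotated = dplyr::coalesce(.data$n_annotated, 0L),
                  coverage = .data$n_annotated / .data$n_genes_total)
}

#' Filter a genome database by functional coverage
#'
#' Poorly annotated genomes depress pangenome KO frequencies, so genomes
#' below a functional-coverage cutoff (default 30%) are excluded before
#' pangenome construction.
#'
#' @param db A `genome_db`.
#' @param min_coverage Minimum functional coverage in `[0, 1]`; genomes with
#'   coverage `>= min_coverage` are retained.
#' @return A filtered `genome_db` (index rebuilt); the number of removed
#'   genomes is recorded in attribute `n_removed`.
#' @export
filter_genomes <- function(db, min_coverage = 0.30) {
  stopifnot(inherits(db, "genome_db"), min_coverage >= 0)
  cov <- functional_coverage(db)
  keep <- cov$organism_id[cov$coverage >= min_coverage]
  out <- db
  out$organisms <- db$organisms[db$organisms$organism_id %in% keep, ]
  out$annotations <- db$annotations[db$annotations$organism_id %in% keep, ]
  out$index <- db$index[db$index$organism_id %in% keep, ]
  attr(out, "n_removed") <- nrow(db$organisms) - length(keep)
  out
}

#' Organism counts and pools per (rank, name)
#'
#' `genome_index()` returns a named integer vector of organism counts keyed
#' by (rank, name) — the structure consulted by [trim_lineage()].
#' `genome_pools()` returns the corresponding named list of sorted organism
#' ids.
#'
#' @param db A `genome_db`.
#' @return Named integer vector (counts) or named list of character vectors
#'   (pools).
#' @export
genome_index <- function(db) {
  stopifnot(inherits(db, "genome_db"))
  tab <- dplyr::count(db$index, .data$key)
  setNames(tab$n, tab$key)
}

#' @rdname genome_index
#' @export
genome_pools <- function(db) {
  stopifnot(inherits(db, "genome_db"))
  purrr::map(split(db$index$organism_id, db$index$key), sort)
}

#' Pool organisms at a lineage
#'
#' Returns the ids of all organisms whose lineage contains the lowest
#' (rank, name) of `lin` — the pool whose merged annotations form the
#' lineage's pangenome. Upper ranks are informational: reconciliation has
#' already normalized them, and keying on the lowest rank matches the
#' genome-index semantics used during trimming, which guarantees a
#' non-empty pool for any trimmed lineage.
#'
#' @param lin A trimmed `lineage`.
#' @param db A `genome_db`.
#' @return Sorted character vector of organism ids.
#' @export
pool_organisms <- function(lin, db) {
  stopifnot(is_lineage(lin), inherits(db, "genome_db"))
  if (length(lin) == 0) {
    abort("cannot pool organisms for an empty lineage",
          class = "panfun_contract_error")
  }
  key <- rank_key(lowest_rank(lin), lowest_name(lin))
  ids <- sort(db$index$organism_id[db$index$key == key])
  if (length(ids) == 0) {
    abort(paste0("no organisms pooled at '", lineage_string(lin),
                 "' — lineage was not trimmed against this database"),
          class = "panfun_contract_error")
  }
  ids
}

#' Median 16S rRNA gene copy number of a lineage's pool
#'
#' The putative 16S copy number of an OTU is the median copy count over the
#' organisms pooled at its (trimmed) lineage; an even-sized pool takes the
#' mean of the two middle values. Organisms with unknown copy counts are
#' excluded from the median; if no pooled organism has a known count the
#' copy number defaults to 1 with a warning.
#'
#' @param lin A trimmed `lineage`.
#' @param db A `genome_db`.
#' @return A positive number.
#' @export
median_copy_number <- function(lin, db) {
  ids <- pool_organisms(lin, db)
  copies <- db$organisms$n_16S_copies[match(ids, db$organisms$organism_id)]
  copies <- copies[!is.na(copies)]
  if (length(copies) == 0) {
    warn(paste0("no known 16S copy counts in pool for '",
                lineage_string(lin), "'; defaulting to 1"))
    return(1)
  }
  median(as.numeric(copies))
}

#' Serialize a genome database
#'
#' Writes `organisms.tsv` and `annotations.tsv` (same dialects read by
#' [read_genome_db()]) in deterministic order.
#'
#' @param db A `genome_db`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_genome_db <- function(db, dir) {
  stopifnot(inherits(db, "genome_db"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  org <- db$organisms |>
    dplyr::select("organism_id", "lineage_string", "n_genes_total",
                  "n_16S_copies") |>
    dplyr::arrange(.data$organism_id)
  ann <- db$annotations |>
    dplyr::arrange(.data$organism_id, .data$gene_id, .data$ko_term)
  readr::write_tsv(org, file.path(dir, "organisms.tsv"), progress = FALSE)
  readr::write_tsv(ann, file.path(dir, "annotations.tsv"), progress = FALSE)
  invisible(dir)
}
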