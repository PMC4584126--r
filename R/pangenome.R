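#' Pangenome KO frequencies for one lineage
#'
#' The pangenome of a lineage is the multiset union of annotated genes over
#' all organisms pooled at the lineage. Its functional profile counts
#' gene–KO occurrence pairs: a gene annotated with several KO terms
#' contributes one occurrence to each term, and a multi-copy gene family
#' contributes once per gene copy (occurrences are accumulated, not reduced
#' to per-genome presence/absence). Frequencies are the occurrences divided
#' by the number of pooled organisms `O_i`, so `fq(lineage, KO)` is the mean
#' per-genome occurrence of the term — it exceeds 1 for multi-copy families
#' and is never clamped.
#'
#' @param lin A trimmed `lineage`.
#' @param db A `genome_db` (already coverage-filtered).
#' @return A list with elements `o_i` (pool size), `copy_median` (median
#'   16S copy number of the pool) and `fq` (named numeric vector of KO
#'   frequencies, zeros absent, names sorted).
#' @export
lineage_function_row <- function(lin, db) {
  ids <- pool_organisms(lin, db)
  ann <- db$annotations[db$annotations$organism_id %in% ids, ]
  occ <- table(ann$ko_term)
  fq <- setNames(as.numeric(occ) / length(ids), names(occ))
  fq <- fq[order(names(fq))]
  list(o_i = length(ids), copy_median = median_copy_number(lin, db), fq = fq)
}

#' Build the lineage-function table
#'
#' One row per distinct trimmed lineage: pooled-organism count `O_i`, median
#' 16S copy number, and the pangenome KO frequencies from
#' [lineage_function_row()]. OTUs with the same trimmed lineage share the
#' same pangenome, so rows are computed once per distinct pool (the cache is
#' keyed on the lowest (rank, name), which determines the pool).
#'
#' @param lineages A list of trimmed `lineage` objects (duplicates fine).
#' @param db A `genome_db`.
#' @return A `lineage_function_table`: long tibble with columns
#'   `lineage` (canonical string), `o_i`, `copy_median`, `ko_term`, `fq`,
#'   sorted by lineage then KO term.
#' @export
lineage_function_table <- function(lineages, db) {
  stopifnot(inherits(db, "genome_db"))
  if (length(lineages) == 0) {
    out <- tibble::tibble(lineage = character(), o_i = integer(),
                          copy_median = numeric(), ko_term = character(),
                          fq = numeric())
    class(out) <- c("lineage_function_table", class(out))
    return(out)
  }
  strs <- purrr::map_chr(lineages, lineage_string)
  uniq <- !duplicated(strs)
  cache <- new.env(parent = emptyenv())
  rows <- purrr::map2_dfr(lineages[uniq], strs[uniq], function(lin, s) {
    key <- rank_key(lowest_rank(lin), lowest_name(lin))
    row <- if (exists(key, envir = cache)) get(key, envir = cache)
           else {
             r <- lineage_function_row(lin, db)
             assign(key, r, envir = cache)
             r
           }
    tibble::tibble(lineage = s, o_i = row$o_i, copy_median = row$copy_median,
                   ko_term = names(row$fq), fq = unname(row$fq))
  })
  out <- dplyr::arrange(rows, .data$lineage, .data$ko_term)
  class(out) <- c("lineage_function_table", class(out))
  out
}

#' Per-lineage total annotation mass
#'
#' For each lineage row, the sum of its KO frequencies — the total number of
#' gene–KO pairs in the pool divided by `O_i`. Used in the mass-conservation
#' identity: the per-sample sum of the function profile equals the
#' lineage-abundance-weighted sum of these totals.
#'
#' @param lft A `lineage_function_table`.
#' @return Tibble `lineage`, `total_fq`.
#' @export
lineage_totals <- function(lft) {
  lft |>
    dplyr::group_by(.data$lineage) |>
    dplyr::summarise(total_fq = sum(.data$fq), .groups = "drop")
}
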