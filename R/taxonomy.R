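#' Read a reference taxonomy
#'
#' The reference taxonomy is a tab-delimited file with a header row and
#' columns `taxon_name`, `rank`, `parent_name`, `parent_rank`. Roots
#' (kingdom-rank taxa) leave the parent columns empty. It plays the role of
#' an authoritative taxonomic hierarchy (e.g. one exported from NCBI) against
#' which OTU lineages are reconciled; parsing NCBI taxdump files directly is
#' out of scope — this TSV dialect is the contract.
#'
#' @param path Path to the TSV file.
#' @return A `ref_taxonomy` object.
#' @export
read_ref_taxonomy <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  need <- c("taxon_name", "rank", "parent_name", "parent_rank")
  missing <- setdiff(need, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("reference taxonomy '", path, "' lacks column(s): ",
                 paste(missing, collapse = ", ")),
          class = "panfun_format_error")
  }
  ref_taxonomy(tbl[need])
}

#' Build a reference taxonomy from a tibble
#'
#' @param entries Tibble with columns `taxon_name`, `rank`, `parent_name`,
#'   `parent_rank`; parent columns `NA`/empty for roots.
#' @return A `ref_taxonomy`: the entries plus a (rank, name) lookup that
#'   tolerates homonyms (the same name at the same rank under different
#'   parents).
#' @export
ref_taxonomy <- function(entries) {
  entries <- tibble::as_tibble(entries)
  entries$rank <- tolower(entries$rank)
  bad <- !entries$rank %in% RANKS
  if (any(bad)) {
    abort(paste0("unknown rank(s) in reference taxonomy: ",
                 paste(unique(entries$rank[bad]), collapse = ", ")),
          class = "panfun_format_error")
  }
  keys <- rank_key(entries$rank, entries$taxon_name)
  structure(list(entries = entries,
                 lookup = split(seq_len(nrow(entries)), keys)),
            class = "ref_taxonomy")
}

#' @export
print.ref_taxonomy <- function(x, ...) {
  cat("<ref_taxonomy> ", nrow(x$entries), " taxa, ",
      sum(is.na(x$entries$parent_name) | x$entries$parent_name == ""),
      " root(s)\n", sep = "")
  invisible(x)
}

# Ancestor chain (self included) of entry row `i`, as a lineage. Returns
# NULL if the chain is broken, cyclic, or not a contiguous rank prefix.
ref_chain <- function(ref, i) {
  ent <- ref$entries
  ranks <- character()
  names_ <- character()
  seen <- integer()
  while (TRUE) {
    if (i %in% seen || length(seen) > length(RANKS)) return(NULL)
    seen <- c(seen, i)
    ranks <- c(ent$rank[i], ranks)
    names_ <- c(ent$taxon_name[i], names_)
    p_name <- ent$parent_name[i]
    if (is.na(p_name) || p_name == "") break
    hit <- ref$lookup[[rank_key(ent$parent_rank[i], p_name)]]
    if (is.null(hit)) return(NULL)
    i <- hit[1]
  }
  if (!identical(ranks, RANKS[seq_along(ranks)])) return(NULL)
  new_lineage(names_, ranks)
}

#' Reconcile a lineage against a reference taxonomy
#'
#' OTU-picking pipelines often carry upper ranks that disagree with the
#' current reference hierarchy (nomenclature updates, merged families).
#' Reconciliation finds the lowest rank of the lineage whose (rank, name) is
#' present in the reference taxonomy and replaces the lineage with that
#' taxon's full ancestor chain from the reference: upper ranks the OTU
#' pipeline got wrong are corrected, and unrecognized ranks below the
#' matched taxon are removed. A lineage with no recognized rank
#' is returned unchanged and flagged unreconciled. Homonyms are resolved in
#' favour of the candidate whose reference ancestry shares the most
#' (rank, name) pairs with the input; a tie flags the lineage unreconciled.
#'
#' @param lin A `lineage`.
#' @param ref A `ref_taxonomy`.
#' @return The reconciled `lineage`, carrying attributes `reconciled`
#'   (logical) and `changed` (logical).
#' @export
reconcile_lineage <- function(lin, ref) {
  stopifnot(is_lineage(lin), inherits(ref, "ref_taxonomy"))
  if (length(lin) == 0) return(flag(lin, FALSE, FALSE))
  in_keys <- lineage_keys(lin)
  for (d in rev(seq_along(lin))) {
    hits <- ref$lookup[[in_keys[d]]]
    if (is.null(hits)) next
    chains <- purrr::map(hits, ~ ref_chain(ref, .x))
    chains <- purrr::compact(chains)
    if (length(chains) == 0) next
    if (length(chains) > 1) {
      shared <- purrr::map_int(chains,
                               ~ length(intersect(lineage_keys(.x), in_keys)))
      best <- which(shared == max(shared))
      if (length(best) > 1) return(flag(lin, FALSE, FALSE))  # homonym tie
      chains <- chains[best]
    }
    rebuilt <- chains[[1]]
    return(flag(rebuilt, TRUE, !identical(unclass(rebuilt), unclass(lin))))
  }
  flag(lin, FALSE, FALSE)
}

flag <- function(lin, reconciled, changed) {
  attr(lin, "reconciled") <- reconciled
  attr(lin, "changed") <- changed
  lin
}

#' @rdname reconcile_lineage
#' @export
is_reconciled <- function(lin) isTRUE(attr(lin, "reconciled"))

#' Trim a lineage to the lowest rank with reference genomes
#'
#' Removes trailing ranks while the lowest (rank, name) has no organism in
#' the (coverage-filtered) reference database, so that every retained OTU
#' pools at least one genome for pangenome construction. OTUs whose lineage
#' would lose its phylum-level designation — the phylum itself has no
#' genomes, or the lineage never reached phylum — are dropped.
#'
#' @param lin A `lineage`.
#' @param index A named integer vector of organism counts keyed by
#'   (rank, name), as built by [genome_index()].
#' @return The trimmed `lineage`, or `NULL` if the OTU must be dropped.
#' @export
trim_lineage <- function(lin, index) {
  stopifnot(is_lineage(lin))
  cur <- new_lineage(unname(lin), names(lin))  # drop reconciliation attrs
  while (length(cur) > 0) {
    n_org <- index[rank_key(lowest_rank(cur), lowest_name(cur))]
    if (!is.na(n_org) && n_org > 0) break
    cur <- cur[-length(cur)]
    class(cur) <- "lineage"
  }
  if (length(cur) < 2) return(NULL)  # must retain at least kingdom + phylum
  cur
}
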