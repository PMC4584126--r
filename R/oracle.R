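#' Direct per-OTU functional profile (reference computation)
#'
#' Computes the function-sample table by direct summation over OTUs,
#' without the pipeline's intermediate stages: for every OTU the pooled
#' organism set, KO occurrence counts, copy-number median and normalized
#' weight are obtained by plain enumeration over the raw organism and
#' annotation tables, and the profile is accumulated as
#' `fq(KO, s) = sum over OTUs of fq(OTU, s) * fq(lineage(OTU), KO)`.
#' This is the validation oracle for [infer_functional_profile()]: an
#' independent code path over raw tibbles (no `genome_db`, no
#' lineage-function table, no collapse step). It assumes taxonomy
#' discrepancies, if any, affect only ranks above the rank the lineage
#' trims to — which the synthetic generator guarantees — so reconciliation
#' cannot change pooling and is skipped.
#'
#' @param t An OTU table tibble (`otu_id`, sample columns, `taxonomy`).
#' @param organisms Raw organisms tibble (`organism_id`, `lineage_string`,
#'   `n_genes_total`, `n_16S_copies`).
#' @param annotations Raw annotations tibble (`organism_id`, `gene_id`,
#'   `ko_term`).
#' @param min_coverage Functional-coverage cutoff.
#' @param sample_size `"corrected"` or `"raw"`.
#' @return A list: `profile` (numeric matrix KO x sample, all-zero rows
#'   dropped), `kept` (otu ids used), `dropped` (otu ids discarded).
#' @export
direct_function_profile <- function(t, organisms, annotations,
                                    min_coverage = 0.30,
                                    sample_size = "corrected") {
  smp <- setdiff(names(t), c("otu_id", "taxonomy"))

  # -- coverage filter, by hand ------------------------------------------
  keep_org <- character()
  for (i in seq_len(nrow(organisms))) {
    oid <- organisms$organism_id[i]
    genes <- unique(annotations$gene_id[annotations$organism_id == oid])
    if (length(genes) / organisms$n_genes_total[i] >= min_coverage) {
      keep_org <- c(keep_org, oid)
    }
  }

  # -- per-organism (rank, name) membership keys -------------------------
  org_keys <- list()
  for (oid in keep_org) {
    ls <- organisms$lineage_string[organisms$organism_id == oid]
    parts <- strsplit(ls, ";", fixed = TRUE)[[1]]
    keys <- character()
    for (p in parts) {
      kv <- strsplit(sub("^\\s+", "", p), ":", fixed = TRUE)[[1]]
      keys <- c(keys, paste(tolower(trimws(kv[1])),
                            tolower(trimws(paste(kv[-1], collapse = ":"))),
                            sep = "|"))
    }
    org_keys[[oid]] <- keys
  }

  # -- per-OTU: trim by enumeration, pool, fq row, copy median -----------
  ladder <- c("kingdom", "phylum", "class", "order", "family", "genus",
              "species")
  prefix_map <- c(k = "kingdom", p = "phylum", c = "class", o = "order",
                  f = "family", g = "genus", s = "species")
  parse_keys <- function(tax) {
    if (is.na(tax) || trimws(tax) == "") return(character())
    parts <- trimws(strsplit(tax, ";", fixed = TRUE)[[1]])
    ranks <- character(); names_ <- character()
    for (j in seq_along(parts)) {
      p <- parts[j]
      if (p == "") break
      if (grepl("^[a-z]__", p)) {
        r <- prefix_map[[substr(p, 1, 1)]]
        nm <- trimws(sub("^[a-z]__", "", p))
      } else if (grepl("^[A-Za-z]+\\s*:", p)) {
        r <- tolower(trimws(sub(":.*$", "", p)))
        nm <- trimws(sub("^[^:]*:", "", p))
      } else {
        r <- ladder[j]
        nm <- p
      }
      if (nm == "" || !r %in% ladder) break
      ranks <- c(ranks, r); names_ <- c(names_, nm)
    }
    # enforce a contiguous ladder prefix
    keys <- character()
    for (j in seq_along(ladder)) {
      hit <- which(ranks == ladder[j])
      if (length(hit) == 0) break
      keys <- c(keys, paste(ladder[j], tolower(names_[hit[1]]), sep = "|"))
    }
    keys
  }

  profile <- matrix(0, nrow = 0, ncol = length(smp),
                    dimnames = list(character(), smp))
  kept <- character(); dropped <- character()
  weights <- list()   # per kept OTU: corrected abundances
  fq_rows <- list()   # per kept OTU: named fq vector
  raw_tot <- setNames(rep(0, length(smp)), smp)

  for (i in seq_len(nrow(t))) {
    keys <- parse_keys(t$taxonomy[i])
    pool <- character()
    depth <- length(keys)
    while (depth >= 1) {
      pool <- names(org_keys)[vapply(org_keys,
                                     function(k) keys[depth] %in% k,
                                     logical(1))]
      if (length(pool) > 0) break
      depth <- depth - 1
    }
    if (length(pool) == 0 || depth < 2) {
      dropped <- c(dropped, t$otu_id[i])
      next
    }
    occ <- c(table(annotations$ko_term[annotations$organism_id %in% pool]))
    copies <- organisms$n_16S_copies[match(pool, organisms$organism_id)]
    copies <- copies[!is.na(copies) & copies > 0]
    cm <- if (length(copies) == 0) 1 else median(copies)
    ab <- as.numeric(t[i, smp])
    kept <- c(kept, t$otu_id[i])
    raw_tot <- raw_tot + ab
    weights[[t$otu_id[i]]] <- ab / cm
    fq_rows[[t$otu_id[i]]] <- occ / length(pool)
  }

  if (length(kept) == 0) {
    return(list(profile = profile, kept = kept, dropped = dropped))
  }
  corr_tot <- Reduce(`+`, weights)
  div <- if (identical(sample_size, "corrected")) corr_tot else raw_tot
  all_kos <- sort(unique(unlist(lapply(fq_rows, names))))
  profile <- matrix(0, nrow = length(all_kos), ncol = length(smp),
                    dimnames = list(all_kos, smp))
  for (id in kept) {
    w <- weights[[id]]
    w[div > 0] <- w[div > 0] / div[div > 0]
    fq <- fq_rows[[id]]
    for (ko in names(fq)) profile[ko, ] <- profile[ko, ] + w * fq[[ko]]
  }
  profile <- profile[rowSums(profile) > 0, , drop = FALSE]
  list(profile = profile, kept = kept, dropped = dropped)
}
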