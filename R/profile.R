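#' Construct an OTU-sample table
#'
#' @param tbl A data frame with a character `otu_id` column, a character
#'   `taxonomy` column, and one non-negative numeric column per sample
#'   (counts or relative abundances).
#' @return An `otu_table` tibble (columns reordered to `otu_id`, samples,
#'   `taxonomy`).
#' @export
otu_table <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  if (!all(c("otu_id", "taxonomy") %in% names(tbl))) {
    abort("an OTU table needs 'otu_id' and 'taxonomy' columns",
          class = "panfun_format_error")
  }
  tbl$otu_id <- as.character(tbl$otu_id)
  tbl$taxonomy <- as.character(tbl$taxonomy)
  smp <- setdiff(names(tbl), c("otu_id", "taxonomy"))
  if (anyDuplicated(tbl$otu_id)) {
    abort(paste0("duplicate otu_id(s): ",
                 paste(unique(tbl$otu_id[duplicated(tbl$otu_id)]),
                       collapse = ", ")), class = "panfun_format_error")
  }
  for (s in smp) {
    v <- tbl[[s]]
    if (!is.numeric(v)) {
      abort(paste0("sample column '", s, "' is not numeric"),
            class = "panfun_format_error")
    }
    if (any(is.na(v) | v < 0)) {
      bad <- tbl$otu_id[which(is.na(v) | v < 0)[1]]
      abort(paste0("negative or missing abundance in sample '", s,
                   "', OTU '", bad, "'"), class = "panfun_format_error")
    }
  }
  out <- tbl[c("otu_id", smp, "taxonomy")]
  class(out) <- c("otu_table", setdiff(class(out), "otu_table"))
  out
}

#' Sample ids of a table
#'
#' @param t An `otu_table`, lineage-sample or function-sample tibble.
#' @return Character vector of sample column names, in input order.
#' @export
sample_ids <- function(t) {
  setdiff(names(t), c("otu_id", "taxonomy", "lineage", "ko_term"))
}

#' Assign trimmed lineages to OTUs
#'
#' Runs the lineage-preparation stage on every OTU: parse the taxonomy
#' string, reconcile it against the reference taxonomy (if given), and trim
#' it against the genome index of the (filtered) database. OTUs whose
#' lineage cannot retain a phylum-level designation are marked dropped.
#'
#' @param t An `otu_table`.
#' @param db A coverage-filtered `genome_db`.
#' @param ref A `ref_taxonomy`, or `NULL` to skip reconciliation.
#' @param dialect Taxonomy dialect passed to [parse_lineage()].
#' @return A list with `assignments` — tibble `otu_id`, `taxonomy`,
#'   `lineage` (string, `NA` when dropped), `status`
#'   (`"kept"`/`"dropped"`), `reconciled` — and `log`, a tibble of events
#'   (`otu_id`, `event`, `before`, `after`) with events among `reconciled`,
#'   `unreconciled`, `trimmed`, `dropped`.
#' @export
assign_lineages <- function(t, db, ref = NULL, dialect = "auto") {
  stopifnot(inherits(db, "genome_db"))
  idx <- genome_index(db)
  # parse/reconcile/trim is a pure function of the taxonomy string, so it
  # runs once per distinct string (bootstrap replicates repeat strings)
  uniq_tax <- unique(t$taxonomy)
  per_tax <- purrr::map(uniq_tax, function(tax) {
    lin <- parse_lineage(tax, dialect = dialect)[[1]]
    events <- list()
    reconciled <- NA
    if (!is.null(ref) && length(lin) > 0) {
      before <- lineage_string(lin)
      lin2 <- reconcile_lineage(lin, ref)
      reconciled <- is_reconciled(lin2)
      events[[1]] <- c(event = if (reconciled) "reconciled"
                               else "unreconciled",
                       before = before, after = lineage_string(lin2))
      lin <- lin2
    }
    pre_trim <- lineage_string(lin)
    trimmed <- trim_lineage(lin, idx)
    if (is.null(trimmed)) {
      events[[length(events) + 1]] <- c(event = "dropped",
                                        before = pre_trim, after = "")
      return(list(lineage = NA_character_, status = "dropped",
                  reconciled = reconciled, events = events))
    }
    if (length(trimmed) < length(lin)) {
      events[[length(events) + 1]] <- c(event = "trimmed",
                                        before = pre_trim,
                                        after = lineage_string(trimmed))
    }
    list(lineage = lineage_string(trimmed), status = "kept",
         reconciled = reconciled, events = events)
  })
  res <- per_tax[match(t$taxonomy, uniq_tax)]
  assignments <- tibble::tibble(
    otu_id = t$otu_id,
    taxonomy = t$taxonomy,
    lineage = purrr::map_chr(res, "lineage"),
    status = purrr::map_chr(res, "status"),
    reconciled = purrr::map_lgl(res, "reconciled"))
  log <- purrr::map2_dfr(res, t$otu_id, function(r, id) {
    if (length(r$events) == 0) {
      return(tibble::tibble(otu_id = character(), event = character(),
                            before = character(), after = character()))
    }
    ev <- do.call(rbind, r$events)
    tibble::tibble(otu_id = id, event = ev[, "event"],
                   before = ev[, "before"], after = ev[, "after"])
  })
  if (nrow(log) == 0) {
    log <- tibble::tibble(otu_id = character(), event = character(),
                          before = character(), after = character())
  }
  list(assignments = assignments, log = log)
}

#' Correct OTU abundances for 16S copy number
#'
#' 16S read counts over-represent organisms carrying many rRNA operon
#' copies. Each OTU's abundances are divided by the median 16S copy number
#' of its lineage's pool (the `copy_median` of its lineage-function row), so
#' corrected abundances approximate organismal abundance.
#'
#' @param t An `otu_table` (dropped OTUs already removed).
#' @param lft A `lineage_function_table` covering every assigned lineage.
#' @param otu_lineage Named character vector mapping `otu_id` to the trimmed
#'   lineage string.
#' @return The copy-corrected `otu_table`.
#' @export
copy_correct <- function(t, lft, otu_lineage) {
  lin <- unname(otu_lineage[t$otu_id])
  if (any(is.na(lin))) {
    abort(paste0("no lineage assignment for OTU(s): ",
                 paste(t$otu_id[is.na(lin)], collapse = ", ")),
          class = "panfun_contract_error")
  }
  med <- dplyr::distinct(lft, .data$lineage, .data$copy_median)
  cm <- med$copy_median[match(lin, med$lineage)]
  if (any(is.na(cm))) {
    abort(paste0("lineage-function table lacks row(s) for lineage(s): ",
                 paste(unique(lin[is.na(cm)]), collapse = " | ")),
          class = "panfun_contract_error")
  }
  out <- t
  for (s in sample_ids(t)) out[[s]] <- out[[s]] / cm
  out
}

#' Normalize per-sample OTU frequencies
#'
#' Divides each sample column by its sample size so per-sample frequencies
#' sum to 1 and are comparable across samples. Under the default
#' `mode = "corrected"` the sample size is the copy-corrected column total;
#' `mode = "raw"` divides by totals supplied in `raw_totals` (the
#' uncorrected read totals). An all-zero sample is left untouched with a
#' warning.
#'
#' @param t A (copy-corrected) `otu_table`.
#' @param mode `"corrected"` or `"raw"`.
#' @param raw_totals Named numeric vector of per-sample raw totals
#'   (required for `mode = "raw"`).
#' @return The normalized `otu_table`.
#' @export
sample_normalize <- function(t, mode = c("corrected", "raw"),
                             raw_totals = NULL) {
  mode <- match.arg(mode)
  out <- t
  for (s in sample_ids(t)) {
    tot <- if (mode == "corrected") sum(out[[s]]) else raw_totals[[s]]
    if (is.null(tot) || is.na(tot)) {
      abort(paste0("no raw total supplied for sample '", s, "'"),
            class = "panfun_contract_error")
    }
    if (tot == 0) {
      warn(paste0("sample '", s, "' has zero total abundance; left as-is"))
      next
    }
    out[[s]] <- out[[s]] / tot
  }
  out
}

#' Collapse an OTU-sample table to a lineage-sample table
#'
#' Sums the per-sample frequencies of OTUs sharing the same trimmed
#' lineage; per-sample column sums are preserved.
#'
#' @param t A normalized `otu_table`.
#' @param otu_lineage Named character vector `otu_id` -> lineage string.
#' @return A `lineage_sample_table` tibble: `lineage` + one column per
#'   sample, sorted by lineage.
#' @export
collapse_lineages <- function(t, otu_lineage) {
  smp <- sample_ids(t)
  lin <- unname(otu_lineage[t$otu_id])
  if (any(is.na(lin))) {
    abort("every OTU needs a lineage assignment before collapsing",
          class = "panfun_contract_error")
  }
  out <- t |>
    dplyr::mutate(lineage = lin) |>
    dplyr::group_by(.data$lineage) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(smp), sum),
                     .groups = "drop") |>
    dplyr::arrange(.data$lineage)
  class(out) <- c("lineage_sample_table", class(out))
  out
}

#' Combine lineage abundances with pangenome profiles
#'
#' The function-sample table weights every lineage's pangenome KO profile
#' by the lineage's abundance in each sample:
#' `fq(KO, s) = sum over lineages of fq(lineage, s) * fq(lineage, KO)`.
#' KO terms with all-zero rows are omitted.
#'
#' @param ls A `lineage_sample_table`.
#' @param lft A `lineage_function_table` with a row set covering `ls`.
#' @return A `function_sample_table` tibble: `ko_term` + one column per
#'   sample, KO terms in lexicographic order.
#' @export
function_profile <- function(ls, lft) {
  smp <- sample_ids(ls)
  missing <- setdiff(ls$lineage, unique(lft$lineage))
  if (length(missing) > 0) {
    abort(paste0("lineage-function table lacks row(s) for lineage(s): ",
                 paste(missing, collapse = " | ")),
          class = "panfun_contract_error")
  }
  long <- ls |>
    tidyr::pivot_longer(dplyr::all_of(smp), names_to = "sample_id",
                        values_to = "weight") |>
    dplyr::inner_join(lft[c("lineage", "ko_term", "fq")], by = "lineage",
                      relationship = "many-to-many") |>
    dplyr::group_by(.data$ko_term, .data$sample_id) |>
    dplyr::summarise(value = sum(.data$weight * .data$fq), .groups = "drop")
  out <- long |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "value",
                       values_fill = 0) |>
    dplyr::arrange(.data$ko_term)
  # restore input sample order and drop all-zero KO rows
  out <- out[c("ko_term", smp)]
  nz <- rowSums(as.matrix(out[smp])) > 0
  out <- out[nz, ]
  class(out) <- c("function_sample_table", class(out))
  out
}

#' Infer a community functional profile from an OTU table
#'
#' Runs the full inference chain on in-memory objects: coverage-filter the
#' genome database, parse/reconcile/trim every OTU lineage, build the
#' lineage-function table, correct abundances for 16S copy number,
#' normalize per sample, collapse to lineages and weight pangenome profiles
#' by lineage abundance.
#'
#' @param t An `otu_table` (see [otu_table()], [read_otu_table()]).
#' @param db A `genome_db`.
#' @param ref A `ref_taxonomy` or `NULL` (skip reconciliation).
#' @param min_coverage Functional-coverage cutoff for the database.
#' @param sample_size `"corrected"` (normalize by copy-corrected totals,
#'   default) or `"raw"` (normalize by raw totals of the retained OTUs).
#' @param dialect Taxonomy dialect for [parse_lineage()].
#' @return A `panfun_profile` object: list with `function_table`,
#'   `lineage_table`, `lineage_function` (the pangenome table),
#'   `assignments`, `log`, and the effective `config`.
#' @export
infer_functional_profile <- function(t, db, ref = NULL, min_coverage = 0.30,
                                     sample_size = c("corrected", "raw"),
                                     dialect = "auto") {
  sample_size <- match.arg(sample_size)
  stopifnot(inherits(t, "otu_table") || is.data.frame(t))
  t <- otu_table(t)
  fdb <- filter_genomes(db, min_coverage)
  al <- assign_lineages(t, fdb, ref = ref, dialect = dialect)
  kept <- al$assignments[al$assignments$status == "kept", ]
  if (nrow(kept) == 0) {
    abort("every OTU was dropped during lineage trimming; no profile can be built",
          class = "panfun_pipeline_error")
  }
  tk <- otu_table(t[t$otu_id %in% kept$otu_id, ])
  otu_lin <- setNames(kept$lineage, kept$otu_id)
  lineages <- parse_lineage(unique(kept$lineage), dialect = "rank_colon")
  lft <- lineage_function_table(lineages, fdb)
  raw_totals <- purrr::map_dbl(sample_ids(tk), ~ sum(tk[[.x]]))
  names(raw_totals) <- sample_ids(tk)
  corrected <- copy_correct(tk, lft, otu_lin)
  normalized <- sample_normalize(corrected, mode = sample_size,
                                 raw_totals = raw_totals)
  ls <- collapse_lineages(normalized, otu_lin)
  fs <- function_profile(ls, lft)
  structure(list(function_table = fs,
                 lineage_table = ls,
                 lineage_function = lft,
                 assignments = al$assignments,
                 log = al$log,
                 config = list(min_coverage = min_coverage,
                               sample_size = sample_size,
                               dialect = dialect)),
            class = "panfun_profile")
}

#' @export
print.panfun_profile <- function(x, ...) {
  n_drop <- sum(x$assignments$status == "dropped")
  cat("<panfun_profile>\n",
      "  samples:  ", length(sample_ids(x$function_table)), "\n",
      "  KO terms: ", nrow(x$function_table), "\n",
      "  lineages: ", nrow(x$lineage_table), "\n",
      "  OTUs:     ", nrow(x$assignments) - n_drop, " kept, ",
      n_drop, " dropped\n", sep = "")
  invisible(x)
}

#' Run the end-to-end pipeline on files
#'
#' File-level wrapper around [infer_functional_profile()]: reads the OTU
#' table, database and reference taxonomy, runs the inference, and writes
#' `function_sample.tsv`, `lineage_sample.tsv`, `lineage_function.tsv`, the
#' event log and the effective configuration into `out_dir`.
#'
#' @param otu_table_path Path to a QIIME-classic or plain-TSV OTU table.
#' @param db_dir Directory holding `organisms.tsv` and `annotations.tsv`.
#' @param ref_taxonomy_path Path to the reference-taxonomy TSV, or `NULL`.
#' @param out_dir Output directory.
#' @param min_coverage,sample_size,dialect See [infer_functional_profile()].
#' @param layout Output layout for the function table (`"long"` canonical,
#'   or `"wide"`).
#' @param digits Significant digits used when serializing frequencies.
#' @return The `panfun_profile`, invisibly.
#' @export
run_pipeline <- function(otu_table_path, db_dir, ref_taxonomy_path = NULL,
                         out_dir, min_coverage = 0.30,
                         sample_size = "corrected", dialect = "auto",
                         layout = "long", digits = 6) {
  t <- read_otu_table(otu_table_path, dialect = dialect)
  db <- read_genome_db(file.path(db_dir, "organisms.tsv"),
                       file.path(db_dir, "annotations.tsv"))
  ref <- if (!is.null(ref_taxonomy_path)) read_ref_taxonomy(ref_taxonomy_path)
  prof <- infer_functional_profile(t, db, ref = ref,
                                   min_coverage = min_coverage,
                                   sample_size = sample_size,
                                   dialect = dialect)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_function_table(prof$function_table,
                       file.path(out_dir, "function_sample.tsv"),
                       layout = layout, digits = digits)
  write_sample_table(prof$lineage_table, "lineage",
                     file.path(out_dir, "lineage_sample.tsv"),
                     digits = digits)
  readr::write_tsv(prof$lineage_function,
                   file.path(out_dir, "lineage_function.tsv"),
                   progress = FALSE)
  readr::write_tsv(prof$log, file.path(out_dir, "run_log.tsv"),
                   progress = FALSE)
  writeLines(c(paste0("min_coverage\t", min_coverage),
               paste0("sample_size\t", sample_size),
               paste0("dialect\t", dialect),
               paste0("layout\t", layout),
               paste0("digits\t", digits)),
             file.path(out_dir, "run_config.tsv"))
  invisible(prof)
}
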