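#' Resample an OTU table with replacement
#'
#' Draws as many rows as the table has, i.i.d. uniformly with replacement —
#' each draw takes an OTU together with its full abundance vector and
#' taxonomy string. Some OTUs appear more than once, some not at all;
#' repeated draws get a `.b<k>` suffix on the OTU id so row ids stay
#' unique. The caller controls the RNG state (see [bootstrap_intervals()]).
#'
#' @param t An `otu_table`.
#' @return A resampled `otu_table` with the same number of rows.
#' @export
resample_otu_table <- function(t) {
  if (nrow(t) == 0) {
    abort("cannot resample an empty OTU table",
          class = "panfun_contract_error")
  }
  idx <- sample.int(nrow(t), nrow(t), replace = TRUE)
  out <- t[idx, ]
  dup <- stats::ave(seq_along(idx), idx, FUN = seq_along)
  out$otu_id <- ifelse(dup > 1, paste0(out$otu_id, ".b", dup - 1), out$otu_id)
  otu_table(out)
}

#' Bootstrap confidence intervals for a functional profile
#'
#' Quantifies the uncertainty of the function-sample estimates under the
#' assumption that OTU abundance profiles contribute independently: the OTU
#' table's rows are resampled with replacement `B` times, the full
#' inference chain (lineage trimming through profile construction) is rerun
#' on every replicate — resampling changes sample sizes, so normalization
#' cannot be reused — and per (KO, sample) cell the empirical
#' `alpha/2` and `1 - alpha/2` quantiles over the `B` replicate values form
#' the interval. A KO term absent from a replicate's profile contributes 0
#' (the estimate of an unobserved function is zero, not missing).
#' Quantiles use linear interpolation over the order statistics
#' (`stats::quantile` type 7); the rule is recorded in the result.
#'
#' @param t An `otu_table`.
#' @param db A `genome_db`.
#' @param ref A `ref_taxonomy` or `NULL`.
#' @param B Number of bootstrap replicates (default 100).
#' @param alpha Tail mass of the interval (default 0.05, a 95% CI).
#' @param seed Integer seed; a single seeded generator drives all
#'   replicates in order, so identical inputs and seed give bit-identical
#'   results.
#' @param min_coverage,sample_size,dialect Passed to
#'   [infer_functional_profile()].
#' @return A `panfun_boot` tibble: `ko_term`, `sample_id`, `point` (the
#'   estimate on the original table), `lower`, `upper`, `b`, `alpha`; KO
#'   terms include every term seen in the original profile or any
#'   replicate. Attribute `quantile_type` records the interpolation rule.
#' @export
bootstrap_intervals <- function(t, db, ref = NULL, B = 100, alpha = 0.05,
                                seed = 1, min_coverage = 0.30,
                                sample_size = "corrected", dialect = "auto") {
  stopifnot(B >= 1, alpha > 0, alpha < 1)
  t <- otu_table(t)
  # coverage filtering depends only on the database, not the replicate, so
  # the filtered database is shared across replicates
  fdb <- filter_genomes(db, min_coverage)
  point_prof <- infer_functional_profile(t, fdb, ref = ref,
                                         min_coverage = 0,
                                         sample_size = sample_size,
                                         dialect = dialect)
  smp <- sample_ids(point_prof$function_table)
  set.seed(seed)
  reps <- vector("list", B)
  for (b in seq_len(B)) {
    rt <- resample_otu_table(t)
    reps[[b]] <- suppressWarnings(
      infer_functional_profile(rt, fdb, ref = ref,
                               min_coverage = 0,
                               sample_size = sample_size,
                               dialect = dialect)$function_table)
  }
  kos <- sort(unique(c(point_prof$function_table$ko_term,
                       unlist(purrr::map(reps, "ko_term")))))
  # replicate value array: KO x sample x B, absent terms contribute 0
  point_m <- profile_matrix(point_prof$function_table, kos, smp)
  lower <- upper <- matrix(0, length(kos), length(smp),
                           dimnames = list(kos, smp))
  vals <- array(0, dim = c(length(kos), length(smp), B))
  for (b in seq_len(B)) vals[, , b] <- profile_matrix(reps[[b]], kos, smp)
  probs <- c(alpha / 2, 1 - alpha / 2)
  for (i in seq_along(kos)) {
    for (j in seq_along(smp)) {
      q <- quantile(vals[i, j, ], probs = probs, names = FALSE, type = 7)
      lower[i, j] <- q[1]
      upper[i, j] <- q[2]
    }
  }
  out <- tibble::tibble(
    ko_term = rep(kos, times = length(smp)),
    sample_id = rep(smp, each = length(kos)),
    point = as.vector(point_m),
    lower = as.vector(lower),
    upper = as.vector(upper),
    b = B, alpha = alpha) |>
    dplyr::arrange(.data$ko_term, .data$sample_id)
  attr(out, "quantile_type") <- 7L
  attr(out, "seed") <- seed
  class(out) <- c("panfun_boot", class(out))
  out
}

profile_matrix <- function(fs, kos, smp) {
  m <- matrix(0, length(kos), length(smp), dimnames = list(kos, smp))
  if (nrow(fs) > 0) {
    m[fs$ko_term, ] <- as.matrix(fs[, smp])
  }
  m
}

#' Spearman correlation over shared non-zero KO terms
#'
#' Functional profiles produced by different approaches cover different KO
#' vocabularies, so two profiles are compared only on the KO terms with
#' non-zero values in both: the union vocabulary is taken (absent terms
#' implicit zeros), terms positive in both are retained, and the Spearman
#' rank correlation (average ranks for ties) is computed on them. Fewer
#' than two shared non-zero terms leaves the correlation undefined
#' (`NA`, flagged), not an error.
#'
#' @param a,b Named numeric vectors (KO term -> value), e.g. one sample
#'   column of a function-sample table extracted with [profile_column()].
#' @return A tibble with `rho`, `n_shared`, `defined`.
#' @export
spearman_shared_nonzero <- function(a, b) {
  all_kos <- union(names(a), names(b))
  av <- setNames(rep(0, length(all_kos)), all_kos)
  bv <- av
  av[names(a)] <- a
  bv[names(b)] <- b
  shared <- all_kos[av > 0 & bv > 0]
  if (length(shared) < 2) {
    return(tibble::tibble(rho = NA_real_, n_shared = length(shared),
                          defined = FALSE))
  }
  rho <- suppressWarnings(cor(av[shared], bv[shared], method = "spearman"))
  tibble::tibble(rho = rho, n_shared = length(shared),
                 defined = !is.na(rho))
}

#' Extract one sample's profile as a named vector
#'
#' @param fs A `function_sample_table`.
#' @param sample Sample column name.
#' @return Named numeric vector (KO term -> value).
#' @export
profile_column <- function(fs, sample) {
  setNames(fs[[sample]], fs$ko_term)
}

#' Compare two functional profiles sample by sample
#'
#' Applies [spearman_shared_nonzero()] to every sample id present in both
#' tables.
#'
#' @param fa,fb `function_sample_table` tibbles.
#' @return Tibble `sample_id`, `rho`, `n_shared`, `defined`.
#' @export
compare_profiles <- function(fa, fb) {
  shared_samples <- intersect(sample_ids(fa), sample_ids(fb))
  purrr::map_dfr(shared_samples, function(s) {
    dplyr::bind_cols(tibble::tibble(sample_id = s),
                     spearman_shared_nonzero(profile_column(fa, s),
                                             profile_column(fb, s)))
  })
}

#' Write a bootstrap result table
#'
#' @param bt A `panfun_boot` tibble.
#' @param path Output path.
#' @param digits Significant digits.
#' @return `path`, invisibly.
#' @export
write_bootstrap <- function(bt, path, digits = 6) {
  out <- bt
  for (col in c("point", "lower", "upper")) {
    out[[col]] <- fmt_num(out[[col]], digits)
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
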