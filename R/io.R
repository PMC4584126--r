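#' Read an OTU-sample table
#'
#' Accepts the QIIME "classic" tab-delimited layout (an optional leading
#' `# Constructed from biom file` comment, a header line beginning
#' `#OTU ID`, sample columns, and a trailing `taxonomy` column), plain TSV
#' with a `taxonomy` column, and BIOM files (`.biom`, read through the
#' biomformat package when available). The taxonomy column is located by
#' header name (case-insensitive) with a final-column fallback.
#'
#' @param path Path to the OTU table.
#' @param dialect Taxonomy dialect recorded for downstream parsing (the
#'   strings themselves are kept verbatim).
#' @return An `otu_table` tibble.
#' @export
read_otu_table <- function(path, dialect = "auto") {
  if (grepl("\\.biom$", path, ignore.case = TRUE)) {
    return(read_otu_table_biom(path))
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) {
    abort(paste0("'", path, "' is empty"), class = "panfun_format_error")
  }
  hdr_i <- NA_integer_
  for (i in seq_along(lines)) {
    if (grepl("^#OTU ID\t", lines[i]) || identical(lines[i], "#OTU ID")) {
      hdr_i <- i; break
    }
    if (!startsWith(lines[i], "#")) { hdr_i <- i; break }
  }
  if (is.na(hdr_i)) {
    abort(paste0("no header line found in '", path, "'"),
          class = "panfun_format_error")
  }
  header <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  header[1] <- sub("^#", "", header[1])
  body <- lines[-seq_len(hdr_i)]
  body <- body[nzchar(body)]
  tax_col <- which(tolower(header) == "taxonomy")
  if (length(tax_col) == 0) {
    if (length(header) < 2) {
      abort(paste0("'", path, "' has no taxonomy column"),
            class = "panfun_format_error")
    }
    tax_col <- length(header)  # final-column fallback
  } else tax_col <- tax_col[1]
  n_col <- length(header)
  rows <- strsplit(body, "\t", fixed = TRUE)
  otu_id <- character(length(body))
  taxonomy <- character(length(body))
  smp_idx <- setdiff(seq_len(n_col), c(1L, tax_col))
  ab <- matrix(0, nrow = length(body), ncol = length(smp_idx))
  for (r in seq_along(rows)) {
    f <- rows[[r]]
    line_no <- hdr_i + r
    if (length(f) == n_col - 1 && tax_col == n_col) {
      f <- c(f, "")  # permit a missing trailing taxonomy field
    }
    if (length(f) != n_col) {
      abort(paste0("'", path, "' line ", line_no, ": expected ", n_col,
                   " fields, got ", length(f)),
            class = "panfun_format_error")
    }
    vals <- suppressWarnings(as.numeric(f[smp_idx]))
    if (any(is.na(vals))) {
      abort(paste0("'", path, "' line ", line_no,
                   ": non-numeric abundance value"),
            class = "panfun_format_error")
    }
    if (any(vals < 0)) {
      abort(paste0("'", path, "' line ", line_no, ": negative abundance"),
            class = "panfun_format_error")
    }
    otu_id[r] <- f[1]
    taxonomy[r] <- f[tax_col]
    ab[r, ] <- vals
  }
  out <- tibble::as_tibble(as.data.frame(ab))
  names(out) <- header[smp_idx]
  out <- dplyr::bind_cols(tibble::tibble(otu_id = otu_id), out,
                          tibble::tibble(taxonomy = taxonomy))
  attr(out, "dialect") <- dialect
  otu_table(out)
}

read_otu_table_biom <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE)) {
    abort("reading .biom files requires the 'biomformat' package",
          class = "panfun_format_error")
  }
  b <- biomformat::read_biom(path)
  m <- as.matrix(biomformat::biom_data(b))
  md <- biomformat::observation_metadata(b)
  tax <- rep("", nrow(m))
  if (!is.null(md)) {
    md <- as.data.frame(md)
    tax_cols <- grep("taxonomy", names(md), ignore.case = TRUE, value = TRUE)
    if (length(tax_cols) > 0) {
      tax <- apply(md[, tax_cols, drop = FALSE], 1, function(x)
        paste(x[!is.na(x) & x != ""], collapse = "; "))
    }
  }
  out <- tibble::as_tibble(as.data.frame(m))
  dplyr::bind_cols(tibble::tibble(otu_id = rownames(m)), out,
                   tibble::tibble(taxonomy = unname(tax))) |>
    otu_table()
}

fmt_num <- function(x, digits = 6) {
  ifelse(x == trunc(x) & abs(x) < 1e15, format(x, scientific = FALSE,
                                               trim = TRUE),
         formatC(x, digits = digits, format = "g"))
}

#' Write a function-sample table
#'
#' `layout = "long"` (canonical) writes `ko_term`, `sample_id`, `value`
#' with zero cells omitted; `layout = "wide"` writes one column per sample.
#' Ordering is deterministic: KO terms lexicographic, samples in table
#' order. [read_function_table()] reads either layout back.
#'
#' @param t A `function_sample_table` tibble (`ko_term` + sample columns).
#' @param path Output path.
#' @param layout `"long"` or `"wide"`.
#' @param digits Significant digits for serialized values.
#' @return `path`, invisibly.
#' @export
write_function_table <- function(t, path, layout = c("long", "wide"),
                                 digits = 6) {
  layout <- match.arg(layout)
  smp <- sample_ids(t)
  t <- dplyr::arrange(t, .data$ko_term)
  if (layout == "wide") {
    out <- t
    for (s in smp) out[[s]] <- fmt_num(out[[s]], digits)
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    long <- t |>
      tidyr::pivot_longer(dplyr::all_of(smp), names_to = "sample_id",
                          values_to = "value") |>
      dplyr::filter(.data$value != 0) |>
      dplyr::mutate(sample_id = factor(.data$sample_id, levels = smp)) |>
      dplyr::arrange(.data$ko_term, .data$sample_id) |>
      dplyr::mutate(sample_id = as.character(.data$sample_id),
                    value = fmt_num(.data$value, digits))
    readr::write_tsv(long, path, progress = FALSE)
  }
  invisible(path)
}

#' Read a function-sample table written by [write_function_table()]
#'
#' @param path Path to the TSV (long or wide layout, auto-detected).
#' @return A `function_sample_table` tibble.
#' @export
read_function_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (identical(names(tbl)[seq_len(min(3, ncol(tbl)))],
                c("ko_term", "sample_id", "value"))) {
    out <- tbl |>
      dplyr::mutate(sample_id = factor(.data$sample_id,
                                       levels = unique(.data$sample_id))) |>
      tidyr::pivot_wider(names_from = "sample_id", values_from = "value",
                         values_fill = 0) |>
      dplyr::arrange(.data$ko_term)
  } else {
    out <- dplyr::arrange(tbl, .data$ko_term)
  }
  out <- tibble::as_tibble(out)
  class(out) <- c("function_sample_table", class(out))
  out
}

# shared writer for lineage-sample / generic id + sample-columns tables
write_sample_table <- function(t, id_col, path, digits = 6) {
  smp <- setdiff(names(t), id_col)
  out <- dplyr::arrange(t, .data[[id_col]])
  for (s in smp) out[[s]] <- fmt_num(out[[s]], digits)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write an OTU-sample table in QIIME classic layout
#'
#' @param t An `otu_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(t, path) {
  smp <- sample_ids(t)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#OTU ID", smp, "taxonomy"), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(t)), function(i) {
    paste(c(t$otu_id[i], fmt_num(as.numeric(t[i, smp]), 12), t$taxonomy[i]),
          collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}
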