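#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted functional profile
#'
#' Returns the function-sample table in long form, one row per non-zero
#' (KO term, sample) cell.
#'
#' @param x A `panfun_profile`.
#' @param ... Unused.
#' @return Tibble `ko_term`, `sample_id`, `value`.
#' @export
tidy.panfun_profile <- function(x, ...) {
  smp <- sample_ids(x$function_table)
  x$function_table |>
    tidyr::pivot_longer(dplyr::all_of(smp), names_to = "sample_id",
                        values_to = "value") |>
    dplyr::filter(.data$value != 0) |>
    dplyr::arrange(.data$ko_term, .data$sample_id)
}

#' One-row summary of a functional profile run
#'
#' @param x A `panfun_profile`.
#' @param ... Unused.
#' @return Tibble with `n_samples`, `n_ko_terms`, `n_lineages`,
#'   `n_otus_kept`, `n_otus_dropped`, `min_coverage`, `sample_size`.
#' @export
glance.panfun_profile <- function(x, ...) {
  tibble::tibble(
    n_samples = length(sample_ids(x$function_table)),
    n_ko_terms = nrow(x$function_table),
    n_lineages = nrow(x$lineage_table),
    n_otus_kept = sum(x$assignments$status == "kept"),
    n_otus_dropped = sum(x$assignments$status == "dropped"),
    min_coverage = x$config$min_coverage,
    sample_size = x$config$sample_size)
}

#' Tidy a bootstrap result
#'
#' @param x A `panfun_boot`.
#' @param ... Unused.
#' @return The underlying tibble (`ko_term`, `sample_id`, `point`,
#'   `lower`, `upper`, `b`, `alpha`).
#' @export
tidy.panfun_boot <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a bootstrap result
#'
#' Reports, among other things, the fraction of point estimates lying
#' inside their own percentile interval.
#'
#' @param x A `panfun_boot`.
#' @param ... Unused.
#' @return Tibble with `n_cells`, `b`, `alpha`, `coverage` and
#'   `mean_width`.
#' @export
glance.panfun_boot <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x),
    b = x$b[1],
    alpha = x$alpha[1],
    coverage = mean(x$point >= x$lower & x$point <= x$upper),
    mean_width = mean(x$upper - x$lower))
}

#' Plot a functional profile
#'
#' Horizontal bars of the most abundant KO terms per sample.
#'
#' @param object A `panfun_profile`.
#' @param n_top Number of KO terms shown (ranked by mean abundance).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.panfun_profile <- function(object, n_top = 20, ...) {
  long <- tidy(object)
  top <- long |>
    dplyr::group_by(.data$ko_term) |>
    dplyr::summarise(m = mean(.data$value), .groups = "drop") |>
    dplyr::slice_max(.data$m, n = n_top)
  long |>
    dplyr::filter(.data$ko_term %in% top$ko_term) |>
    ggplot2::ggplot(ggplot2::aes(
      x = .data$value,
      y = stats::reorder(.data$ko_term, .data$value),
      fill = .data$sample_id)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "inferred functional abundance", y = "KO term",
                  fill = "sample") +
    ggplot2::theme_minimal()
}

#' Plot bootstrap intervals
#'
#' Point estimates with percentile interval bars for the widest-interval
#' KO terms of each sample.
#'
#' @param object A `panfun_boot`.
#' @param n_top Number of KO terms shown per plot (ranked by point
#'   estimate).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.panfun_boot <- function(object, n_top = 20, ...) {
  top <- object |>
    dplyr::group_by(.data$ko_term) |>
    dplyr::summarise(m = mean(.data$point), .groups = "drop") |>
    dplyr::slice_max(.data$m, n = n_top)
  object |>
    dplyr::filter(.data$ko_term %in% top$ko_term) |>
    ggplot2::ggplot(ggplot2::aes(
      x = .data$point,
      y = stats::reorder(.data$ko_term, .data$point),
      colour = .data$sample_id)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.6)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lower, xmax = .data$upper),
      position = ggplot2::position_dodge(width = 0.6), height = 0.3) +
    ggplot2::labs(x = "inferred abundance (percentile CI)", y = "KO term",
                  colour = "sample") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
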