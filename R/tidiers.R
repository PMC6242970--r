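# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy lesion calls into a class count table
#'
#' @param x A `lesion_calls` tibble.
#' @param sample_id Sample identifier (default `"sample"`).
#' @param ... Unused.
#' @return A `lesion_count_table` tibble.
#' @export
tidy.lesion_calls <- function(x, sample_id = "sample", ...) {
  lesion_count_table(x, sample_id)
}

#' One-row summary of lesion calls
#'
#' @param x A `lesion_calls` tibble.
#' @param ... Unused.
#' @return A one-row tibble with molecule counts, the total lesion rate and
#'   the precise-deletion fraction.
#' @export
glance.lesion_calls <- function(x, ...) {
  counts <- lesion_count_table(x)
  rates <- compute_rates(counts)
  tibble(
    n_molecules = nrow(x),
    n_unclassified = sum(x$lesion_class == "UNCLASSIFIED"),
    total_lesion_rate_pct = total_lesion_rate(rates),
    precise_deletion_fraction = precise_deletion_fraction(rates))
}

#' One-row summary of a rate table
#'
#' @param x A `rate_table`.
#' @param ... Unused.
#' @return A one-row tibble with the total molecule count, total lesion
#'   rate, and precise-deletion fraction.
#' @export
glance.rate_table <- function(x, ...) {
  tibble(
    sample_id = x$sample_id[1],
    total = attr(x, "total") %||% NA_integer_,
    total_lesion_rate_pct = total_lesion_rate(x),
    precise_deletion_fraction = precise_deletion_fraction(x))
}

#' Bar chart of per-class lesion rates
#'
#' @param object A `rate_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rate_table <- function(object, ...) {
  col <- if ("pct_corrected" %in% names(object)) "pct_corrected" else "pct"
  df <- mutate(as_tibble(object),
               class = factor(.data$class,
                              levels = c(LESION_CLASSES, "UNCLASSIFIED")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data[[col]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL,
                  y = if (col == "pct_corrected")
                    "background-corrected % of molecules"
                  else "% of molecules") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bar chart of lesion-call class counts
#'
#' @param object A `lesion_calls` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lesion_calls <- function(object, ...) {
  autoplot.rate_table(compute_rates(lesion_count_table(object)))
}

#' Spacing histogram of composite sites by orientation
#'
#' @param object A `composite_sites` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.composite_sites <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$spacing_x,
                               fill = .data$orientation)) +
    ggplot2::geom_histogram(binwidth = 1, position = "stack") +
    ggplot2::labs(x = "intervening spacing x (bp)", y = "composite sites") +
    ggplot2::theme_minimal()
}
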