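# broom-style tidiers for the result objects.

#' @describeIn phase_reads Per-read span calls as a tibble.
#' @param x A `phasing_result`.
#' @param ... Unused.
#' @export
tidy.phasing_result <- function(x, ...) x$calls

#' @describeIn phase_reads One-row summary of counts, ratio, CI and the
#'   1:1 equilibrium test.
#' @export
glance.phasing_result <- function(x, ...) {
  tibble(n_reads = x$n_reads, n_spanning = x$n_spanning,
         n_canonical = x$n_canonical, n_noncanonical = x$n_noncanonical,
         n_unclassified = x$n_unclassified,
         ratio_noncanonical = x$ratio_noncanonical,
         ci_lo = x$ci95[1], ci_hi = x$ci95[2], p_equal = x$p_equal)
}

#' @describeIn classify_columns SNV alleles in long form: one row per
#'   (column, sequence).
#' @param x A `variant_scan`.
#' @param ... Unused.
#' @export
tidy.variant_scan <- function(x, ...) {
  if (nrow(x$variants) == 0) {
    return(tibble(column = integer(0), id = character(0),
                  allele = character(0)))
  }
  tidyr::pivot_longer(x$variants[, c("column", x$ids)],
                      cols = dplyr::all_of(x$ids),
                      names_to = "id", values_to = "allele")
}

#' @describeIn classify_columns One-row summary: SNV count, indel event
#'   count and indel column count.
#' @export
glance.variant_scan <- function(x, ...) {
  tibble(n_columns = x$n_columns, n_snv = nrow(x$variants),
         n_indel_events = nrow(x$indels),
         n_indel_columns = x$n_indel_columns)
}

#' @describeIn intersect_markers One row per SNV reference position with
#'   membership flags.
#' @param x A `marker_intersection`.
#' @param ... Unused.
#' @export
tidy.marker_intersection <- function(x, ...) {
  tibble(ref_pos = x$snv_ref_pos,
         in_list_a = x$snv_ref_pos %in% x$shared_with_a,
         in_list_b = x$snv_ref_pos %in% x$shared_with_b,
         high_confidence = x$snv_ref_pos %in% x$high_confidence)
}

#' @describeIn intersect_markers One-row summary of the set sizes.
#' @export
glance.marker_intersection <- function(x, ...) {
  tibble(n_snv = x$n_snv, n_shared_a = x$n_shared_a,
         n_shared_b = x$n_shared_b,
         n_high_confidence = x$n_high_confidence,
         n_unmapped = x$n_unmapped)
}

#' @describeIn clade_test One row per maximal query-pure clade.
#' @param x A `monophyly_report`.
#' @param ... Unused.
#' @export
tidy.monophyly_report <- function(x, ...) {
  bind_rows(lapply(seq_along(x$clades), function(i) {
    tibble(clade = i, label = x$clades[[i]])
  }))
}

#' @describeIn clade_test One-row summary.
#' @export
glance.monophyly_report <- function(x, ...) {
  tibble(n_query = length(x$query),
         is_monophyletic = x$is_monophyletic,
         min_clades = x$min_clades)
}

#' @export
autoplot.phasing_result <- function(object, ...) {
  df <- tibble(
    conformation = factor(c("canonical", "noncanonical", "unclassified"),
                          levels = c("canonical", "noncanonical",
                                     "unclassified")),
    reads = c(object$n_canonical, object$n_noncanonical,
              object$n_unclassified)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$conformation, y = .data$reads,
                                   fill = .data$conformation)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(title = "IR-spanning reads by structural conformation",
                  subtitle = sprintf(
                    "noncanonical fraction %.2f, p(1:1) = %.3f",
                    object$ratio_noncanonical, object$p_equal),
                  x = NULL, y = "reads") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.variant_scan <- function(object, ...) {
  long <- tidy(object)
  if (nrow(long) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = "No SNV columns") +
             ggplot2::theme_void())
  }
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$column), y = .data$id,
                                     fill = .data$allele)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(A = "#66c2a5", C = "#fc8d62",
                                          G = "#8da0cb", T = "#e78ac3",
                                          N = "grey80")) +
    ggplot2::labs(x = "alignment column", y = NULL, fill = "allele",
                  title = "SNV alleles by sequence") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
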