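#' Stacked-bar plot of benchmark categories
#'
#' Compares category counts across runs (e.g. naive vs CRL+EM modes, or
#' arm lengths): one bar per run, stacked by the seven alignment-quality
#' categories.
#'
#' @param counts Named list of [categorize_reads()] tibbles, or a single
#'   tibble.
#' @return A ggplot object.
#' @export
plot_categories <- function(counts) {
  if (is.data.frame(counts)) counts <- list(run = counts)
  d <- purrr::imap_dfr(counts, ~mutate(.x, run = .y))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$run, y = .data$n,
                                  fill = .data$category)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_brewer(palette = "RdYlGn", direction = -1) +
    ggplot2::labs(x = NULL, y = "reads", fill = "category") +
    ggplot2::theme_minimal()
}

#' APSI of CRLs against the random-locus baseline
#'
#' Box plots of average pairwise sequence identity for observed CRLs and
#' size-matched random locus draws; coherent CRLs (paralog families) sit
#' well above the baseline.
#'
#' @param observed [crl_apsi()] tibble (rows with `NA` APSI are dropped).
#' @param baseline [apsi_baseline()] tibble.
#' @return A ggplot object.
#' @export
plot_apsi <- function(observed, baseline) {
  d <- bind_rows(
    observed |> filter(!is.na(.data$apsi)) |>
      mutate(set = "CRL") |> select("set", "apsi"),
    baseline |> mutate(set = "random") |> select("set", "apsi")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$set, y = .data$apsi,
                                  fill = .data$set)) +
    ggplot2::geom_boxplot(show.legend = FALSE) +
    ggplot2::scale_y_continuous(limits = c(0, 1),
                                labels = function(x) sprintf("%d%%", round(100 * x))) +
    ggplot2::labs(x = NULL, y = "average pairwise sequence identity") +
    ggplot2::theme_minimal()
}
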