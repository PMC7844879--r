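#' Collapse PCR duplicates and drop too-short reads
#'
#' Reads with identical `(sequence, umi)` pairs are treated as PCR
#' duplicates and collapsed into a single record whose `copy_count` is the
#' multiplicity; identical sequences carrying *different* UMIs are
#' independent fragments and stay separate. Reads shorter than `min_length`
#' are discarded before collapsing. The collapsed record keeps the read id
#' of the first occurrence in input order, suffixed `"|N"` with N the
#' multiplicity, so every output read is traceable without a lookup table.
#'
#' Output rows are returned in a canonical order (by sequence, then UMI), so
#' the result does not depend on input order; the operation is idempotent.
#'
#' @param reads Tibble from [read_fastx()] (UMIs already split off).
#' @param min_length Minimum sequence length kept (default 10 nt).
#' @return A list with `reads` (deduplicated tibble) and `report`, a
#'   one-row tibble with `input_reads`, `output_reads` and
#'   `discarded_short`; input copies are conserved:
#'   `sum(copy_count) + discarded_short == input_reads` (counting input
#'   `copy_count`s, so re-deduplication conserves too).
#' @examples
#' r <- tibble::tibble(
#'   read_id = c("a", "b", "c", "d"),
#'   sequence = c("ACGTACGTACGT", "ACGTACGTACGT", "ACGTACGTACGT", "ACGT"),
#'   quality = NA_character_,
#'   umi = c("AAAAA", "AAAAA", "CCCCC", NA),
#'   copy_count = 1L
#' )
#' deduplicate_reads(r)
#' @export
deduplicate_reads <- function(reads, min_length = 10L) {
  stopifnot(is.data.frame(reads), min_length >= 0L)
  n_in <- sum(reads$copy_count %||% rep(1L, nrow(reads)))
  if (!"copy_count" %in% names(reads)) reads$copy_count <- 1L
  short <- nchar(reads$sequence) < min_length
  n_short <- sum(reads$copy_count[short])
  keep <- reads[!short, ]
  out <- keep |>
    mutate(umi_key = dplyr::coalesce(.data$umi, "")) |>
    arrange(.data$sequence, .data$umi_key, .data$read_id) |>
    group_by(.data$sequence, .data$umi_key) |>
    summarise(
      base_id = sub("\\|\\d+$", "", first(.data$read_id)),
      quality = first(.data$quality),
      umi = first(.data$umi),
      copy_count = sum(.data$copy_count),
      .groups = "drop"
    ) |>
    mutate(read_id = ifelse(.data$copy_count > 1L,
                            paste0(.data$base_id, "|", .data$copy_count),
                            .data$base_id)) |>
    select("read_id", "sequence", "quality", "umi", "copy_count") |>
    arrange(.data$sequence, dplyr::coalesce(.data$umi, ""))
  list(
    reads = out,
    report = tibble(input_reads = n_in,
                    output_reads = nrow(out),
                    discarded_short = n_short)
  )
}
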