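#' Write intervals to a BED6 file
#'
#' Accepts any tibble of 0-based half-open intervals: alignment segments
#' (`ref_id`/`ref_start`/`ref_end`) or expressed loci
#' (`ref_id`/`start`/`end`). Missing `name`, `score` and `strand` columns
#' fall back to `.`, `0` and `+`.
#'
#' @param x Tibble of intervals.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  chrom <- x[["chrom"]] %||% x[["ref_id"]]
  start <- x[["start"]] %||% x[["ref_start"]]
  end <- x[["end"]] %||% x[["ref_end"]]
  stopifnot(!is.null(chrom), !is.null(start), !is.null(end))
  bed <- tibble(
    chrom = chrom,
    start = as.integer(start),
    end = as.integer(end),
    name = x[["name"]] %||% x[["locus_id"]] %||% x[["read_id"]] %||% rep(".", nrow(x)),
    score = x[["score_bed"]] %||% x[["n_segments"]] %||% rep(0L, nrow(x)),
    strand = x[["strand"]] %||% rep("+", nrow(x))
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a BED6 file
#'
#' @param path BED file path.
#' @return Tibble with `chrom`, `start`, `end`, `name`, `score`, `strand`
#'   (0-based half-open, as BED is natively).
#' @export
read_bed <- function(path) {
  readr::read_tsv(path,
    col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciiccc", progress = FALSE
  ) |>
    mutate(score = suppressWarnings(as.numeric(.data$score)))
}

# Fixed, documented column set of the final interaction table. Per arm:
# transcript/reference id, expressed locus, CRL, gene annotation, reference
# and read coordinates, CIGAR, posterior assignment probability and CRL TPM.
interaction_columns <- function() {
  per_arm <- c("ref_id", "locus_id", "crl_id", "gene_id", "gene_symbol",
               "biotype", "region", "ref_start", "ref_end", "read_start",
               "read_end", "cigar", "posterior", "tpm")
  c("read_id",
    paste0("arm1_", per_arm),
    paste0("arm2_", per_arm),
    "score", "hybrid", "energy")
}

#' Write / read the final interaction table
#'
#' A tab-separated table with one row per chimeric read: the read id, then
#' for each of the two selected arms the reference/transcript id, expressed
#' locus, CRL, gene id/symbol/biotype, transcript region (5'UTR, CDS,
#' 3'UTR, noncoding or unannotated), reference and read coordinates, CIGAR,
#' posterior probability and CRL TPM; finally the interaction score (the
#' product of the two arm posteriors), and the optional hybrid structure and
#' energy (`NA` when no hybridizer was run).
#'
#' @param records Interaction tibble (see [select_arms()]).
#' @param path Output path.
#' @return `path` invisibly for the writer; a tibble for the reader.
#' @export
write_interactions <- function(records, path) {
  cols <- interaction_columns()
  missing <- setdiff(cols, names(records))
  for (m in missing) records[[m]] <- NA
  readr::write_tsv(records[, cols], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_interactions
#' @export
read_interactions <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
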