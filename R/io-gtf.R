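#' Parse a GTF annotation into transcript models
#'
#' Reads exon (and, when present, CDS) features and assembles one transcript
#' model per `transcript_id`. GTF coordinates (1-based inclusive) are
#' converted to the package-wide 0-based half-open convention on parse; exon
#' lists are ordered 5'->3' in transcript orientation (i.e. reversed
#' relative to genomic order on the minus strand).
#'
#' @param path Path to a GTF file.
#' @return A tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `gene_symbol`, `biotype`, `chrom`, `strand`, `exons` (list column of
#'   two-column integer matrices, 0-based half-open, transcription order),
#'   `cds_start`/`cds_end` (genomic 0-based half-open bounds, NA when the
#'   transcript has no CDS) and `tx_len` (summed exon length). Transcripts
#'   without exon features are excluded with a warning.
#' @export
parse_gtf <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  g <- rtracklayer::import(path, format = "gtf")
  md <- as.data.frame(g)
  if (!nrow(md) || !any(md$type == "exon")) {
    warn(paste0("no exon features in ", path, "; empty annotation"))
    return(empty_models())
  }
  pick <- function(df, nm) if (nm %in% names(df)) df[[nm]] else NA_character_
  ex <- md[md$type == "exon", ]
  if (!"transcript_id" %in% names(ex)) {
    abort("GTF exon features carry no transcript_id attribute")
  }
  ex <- tibble(
    transcript_id = ex$transcript_id,
    gene_id = pick(ex, "gene_id"),
    gene_symbol = dplyr::coalesce(pick(ex, "gene_name"), pick(ex, "gene_id")),
    biotype = dplyr::coalesce(pick(ex, "transcript_biotype"),
                              pick(ex, "gene_biotype")),
    chrom = as.character(ex$seqnames),
    strand = as.character(ex$strand),
    start = ex$start - 1L,   # to 0-based half-open
    end = ex$end
  )
  ex <- ex[!is.na(ex$transcript_id), ]

  cds <- md[md$type == "CDS", , drop = FALSE]
  cds_tbl <- if (nrow(cds)) {
    tibble(transcript_id = cds$transcript_id,
           start = cds$start - 1L, end = cds$end) |>
      group_by(.data$transcript_id) |>
      summarise(cds_start = min(.data$start), cds_end = max(.data$end))
  } else {
    tibble(transcript_id = character(), cds_start = integer(),
           cds_end = integer())
  }

  models <- ex |>
    group_by(.data$transcript_id) |>
    summarise(
      gene_id = first(.data$gene_id),
      gene_symbol = first(.data$gene_symbol),
      biotype = first(.data$biotype),
      chrom = first(.data$chrom),
      strand = first(.data$strand),
      exons = list({
        m <- cbind(start = .data$start, end = .data$end)
        m <- m[order(m[, 1]), , drop = FALSE]
        if (first(.data$strand) == "-") m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
        m
      }),
      tx_len = sum(.data$end - .data$start)
    ) |>
    left_join(cds_tbl, by = "transcript_id")
  if (any(models$tx_len <= 0L)) {
    warn("transcript(s) with zero exon length excluded")
    models <- models[models$tx_len > 0L, ]
  }
  models
}

empty_models <- function() {
  tibble(
    transcript_id = character(), gene_id = character(),
    gene_symbol = character(), biotype = character(), chrom = character(),
    strand = character(), exons = list(), tx_len = integer(),
    cds_start = integer(), cds_end = integer()
  )
}
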