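#' Transcript-to-genome coordinate conversion
#'
#' Maps a 0-based half-open transcript interval through the exon structure
#' of a transcript model to genomic blocks. Intervals crossing splice
#' junctions become several blocks; minus-strand transcripts map with
#' reversed orientation (transcript position 0 is the 3'-most genomic base
#' of the first exon in transcription order). The summed block length
#' always equals the transcript-interval length, and
#' genome->transcript->genome round-trips are exact.
#'
#' @param model One row of a [parse_gtf()] tibble (a data frame row or
#'   list) with `exons` (transcription-ordered block matrix), `strand`.
#' @param start,end 0-based half-open transcript interval.
#' @return Integer matrix of genomic `start`/`end` blocks, sorted by
#'   genomic start.
#' @export
tx_to_genomic <- function(model, start, end) {
  exons <- model$exons
  if (is.list(exons) && !is.matrix(exons)) exons <- exons[[1]]
  strand <- if (length(model$strand) > 1) model$strand[1] else model$strand
  widths <- exons[, 2] - exons[, 1]
  cum <- c(0L, cumsum(widths))
  if (start < 0 || end > cum[length(cum)] || start >= end) {
    abort(sprintf("interval [%d,%d) outside transcript of length %d",
                  start, end, cum[length(cum)]))
  }
  blocks <- list()
  for (i in seq_len(nrow(exons))) {
    a <- max(start, cum[i]) - cum[i]
    b <- min(end, cum[i + 1]) - cum[i]
    if (a >= b) next
    blocks[[length(blocks) + 1L]] <- if (strand == "+") {
      c(exons[i, 1] + a, exons[i, 1] + b)
    } else {
      c(exons[i, 2] - b, exons[i, 2] - a)
    }
  }
  m <- do.call(rbind, blocks)
  m <- m[order(m[, 1]), , drop = FALSE]
  storage.mode(m) <- "integer"
  colnames(m) <- c("start", "end")
  m
}

#' Genome-to-transcript coordinate conversion
#'
#' Inverse of [tx_to_genomic()] for genomic intervals lying within the
#' transcript's exons.
#'
#' @inheritParams tx_to_genomic
#' @param start,end 0-based half-open genomic interval (within exons).
#' @return Integer vector `c(start, end)` in transcript coordinates.
#' @export
genomic_to_tx <- function(model, start, end) {
  exons <- model$exons
  if (is.list(exons) && !is.matrix(exons)) exons <- exons[[1]]
  strand <- if (length(model$strand) > 1) model$strand[1] else model$strand
  widths <- exons[, 2] - exons[, 1]
  cum <- c(0L, cumsum(widths))
  tx_pos <- integer(0)
  for (i in seq_len(nrow(exons))) {
    a <- max(start, exons[i, 1])
    b <- min(end, exons[i, 2])
    if (a >= b) next
    if (strand == "+") {
      tx_pos <- c(tx_pos, cum[i] + (a - exons[i, 1]), cum[i] + (b - exons[i, 1]))
    } else {
      tx_pos <- c(tx_pos, cum[i] + (exons[i, 2] - b), cum[i] + (exons[i, 2] - a))
    }
  }
  if (!length(tx_pos)) {
    abort(sprintf("genomic interval [%d,%d) overlaps no exon", start, end))
  }
  as.integer(c(min(tx_pos), max(tx_pos)))
}

#' Lift alignment segments to genomic coordinates
#'
#' With an annotation, transcriptomic alignments are converted to genomic
#' blocks so that hits on exons shared between isoforms — apparent
#' multi-mappings — collapse to a single genomic location. Without an
#' annotation the operation is the identity on transcript coordinates.
#'
#' @param segments Alignment-segment tibble.
#' @param models Transcript models from [parse_gtf()], or `NULL`.
#' @return `segments` with added columns `chrom`, `gstrand`, `gstart`,
#'   `gend` (extent) and `blocks` (list of block matrices).
#' @export
lift_alignments <- function(segments, models = NULL) {
  if (is.null(models) || !nrow(models)) {
    segments$chrom <- segments$ref_id
    segments$gstrand <- segments$strand
    segments$gstart <- segments$ref_start
    segments$gend <- segments$ref_end
    segments$blocks <- purrr::map2(segments$ref_start, segments$ref_end,
                                   ~cbind(start = .x, end = .y))
    return(segments)
  }
  mi <- match(segments$ref_id, models$transcript_id)
  if (anyNA(mi)) {
    abort(paste0("transcript(s) absent from annotation: ",
                 paste(unique(segments$ref_id[is.na(mi)]), collapse = ", ")))
  }
  too_long <- segments$ref_end > models$tx_len[mi]
  if (any(too_long)) {
    abort(paste0("alignment beyond transcript end on: ",
                 paste(unique(segments$ref_id[too_long]), collapse = ", ")))
  }
  blocks <- purrr::map(seq_len(nrow(segments)), function(i) {
    tx_to_genomic(models[mi[i], ], segments$ref_start[i], segments$ref_end[i])
  })
  segments$chrom <- models$chrom[mi]
  segments$gstrand <- models$strand[mi]
  segments$gstart <- purrr::map_int(blocks, ~as.integer(min(.x[, 1])))
  segments$gend <- purrr::map_int(blocks, ~as.integer(max(.x[, 2])))
  segments$blocks <- blocks
  segments
}

# interval-set helpers for (possibly spliced) blocks ------------------------

block_union <- function(a, b) {
  m <- rbind(a, b)
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (i in seq_len(nrow(m))[-1]) {
    j <- nrow(out)
    if (m[i, 1] <= out[j, 2]) {
      out[j, 2] <- max(out[j, 2], m[i, 2])
    } else {
      out <- rbind(out, m[i, , drop = FALSE])
    }
  }
  out
}

block_overlap <- function(a, b) {
  tot <- 0L
  for (i in seq_len(nrow(a))) {
    ov <- pmin(a[i, 2], b[, 2]) - pmax(a[i, 1], b[, 1])
    tot <- tot + sum(ov[ov > 0])
  }
  tot
}

block_len <- function(a) sum(a[, 2] - a[, 1])

#' Merge overlapping alignments into expressed loci
#'
#' Alignments on one reference (or chromosome) and strand are swept in
#' start order; an alignment joins the currently open locus iff alignment
#' and locus reciprocally overlap by more than `reciprocal_overlap` of each
#' of their lengths (strictly greater, per the published rule), extending
#' the locus extent; otherwise it opens a new locus. This separates
#' different interaction sites on the same transcript while pooling reads
#' covering different parts of one site. Spliced alignments use total block
#' length in the overlap fractions.
#'
#' @param alignments Alignment tibble carrying `segment_id` (from
#'   [merge_read_segments()]) and lifted coordinates (from
#'   [lift_alignments()]).
#' @param reciprocal_overlap Fraction in (0,1]; default 0.7.
#' @return A list: `loci` — tibble with `locus_id`, `chrom`, `strand`,
#'   `start`, `end`, `blocks`, `n_segments` and `segments` (list of
#'   supporting read-segment ids); `alignments` — the input with a
#'   `locus_id` column (every alignment in exactly one locus).
#' @export
merge_into_loci <- function(alignments, reciprocal_overlap = 0.7) {
  stopifnot(reciprocal_overlap > 0, reciprocal_overlap <= 1)
  if (!"blocks" %in% names(alignments)) {
    alignments <- lift_alignments(alignments, NULL)
  }
  al <- alignments |>
    arrange(.data$chrom, .data$gstrand, .data$gstart, .data$gend,
            .data$read_id, .data$segment_id)
  key <- paste(al$chrom, al$gstrand, sep = "\r")
  locus_of <- integer(nrow(al))
  loci <- list()
  cur_key <- ""
  cur_blocks <- NULL
  cur_idx <- 0L
  open_new <- function(i) {
    loci[[length(loci) + 1L]] <<- list(
      chrom = al$chrom[i], strand = al$gstrand[i], blocks = al$blocks[[i]]
    )
    cur_blocks <<- al$blocks[[i]]
    cur_idx <<- length(loci)
  }
  for (i in seq_len(nrow(al))) {
    if (key[i] != cur_key) {
      cur_key <- key[i]
      open_new(i)
    } else {
      b <- al$blocks[[i]]
      ov <- block_overlap(cur_blocks, b)
      if (ov > reciprocal_overlap * block_len(b) &&
          ov > reciprocal_overlap * block_len(cur_blocks)) {
        cur_blocks <- block_union(cur_blocks, b)
        loci[[cur_idx]]$blocks <- cur_blocks
      } else {
        open_new(i)
      }
    }
    locus_of[i] <- cur_idx
  }
  loci_tbl <- tibble(
    idx = seq_along(loci),
    chrom = purrr::map_chr(loci, "chrom"),
    strand = purrr::map_chr(loci, "strand"),
    start = purrr::map_int(loci, ~as.integer(min(.x$blocks[, 1]))),
    end = purrr::map_int(loci, ~as.integer(max(.x$blocks[, 2]))),
    blocks = purrr::map(loci, "blocks")
  )
  loci_tbl$locus_id <- sprintf("%s:%d-%d:%s", loci_tbl$chrom, loci_tbl$start,
                               loci_tbl$end, loci_tbl$strand)
  dup <- duplicated(loci_tbl$locus_id) | duplicated(loci_tbl$locus_id, fromLast = TRUE)
  if (any(dup)) {
    loci_tbl$locus_id[dup] <- paste0(loci_tbl$locus_id[dup], "#",
                                     stats::ave(rep(1L, sum(dup)),
                                                loci_tbl$locus_id[dup],
                                                FUN = seq_along))
  }
  al$locus_id <- loci_tbl$locus_id[locus_of]
  support <- al |>
    distinct(.data$locus_id, .data$segment_id) |>
    arrange(.data$locus_id, .data$segment_id) |>
    group_by(.data$locus_id) |>
    summarise(segments = list(.data$segment_id), n_segments = n())
  loci_tbl <- loci_tbl |>
    left_join(support, by = "locus_id") |>
    select("locus_id", "chrom", "strand", "start", "end", "blocks",
           "n_segments", "segments") |>
    arrange(.data$chrom, .data$strand, .data$start, .data$end)
  list(loci = loci_tbl, alignments = al)
}

#' Merge a read's overlapping alignments into read segments
#'
#' Each aligned portion of a read is a *read segment*; a chimeric read has
#' two or more non-overlapping segments (its arms). Because of local
#' alignment against repetitive references, multi-mapped hits of the same
#' arm can be shifted by a few bases; read intervals overlapping at least
#' `segment_overlap` of both interval lengths are therefore unioned into a
#' single multi-candidate segment rather than penalised as separate
#' segments during quantification.
#'
#' @param alignments Post-processed alignment tibble (all reads at once).
#' @param segment_overlap Fraction in (0,1]; default 0.7 (inclusive rule).
#' @return A list: `segments` — tibble with `segment_id`, `read_id`,
#'   `segment_index` (ordered by read start), `read_start`, `read_end`
#'   (union interval), `n_candidates`; `alignments` — the input with a
#'   `segment_id` column; `reads` — per-read tibble with `n_segments` and
#'   `is_chimeric`.
#' @export
merge_read_segments <- function(alignments, segment_overlap = 0.7) {
  stopifnot(segment_overlap > 0, segment_overlap <= 1)
  al <- alignments |>
    arrange(.data$read_id, .data$read_start, .data$read_end,
            .data$ref_id, .data$ref_start)
  n <- nrow(al)
  seg_of <- integer(n)
  seg_id <- 0L
  cur_read <- NA_character_
  s <- e <- 0L
  for (i in seq_len(n)) {
    a <- al$read_start[i]; b <- al$read_end[i]
    new_seg <- TRUE
    if (identical(al$read_id[i], cur_read)) {
      ov <- min(e, b) - max(s, a)
      if (ov >= segment_overlap * (b - a) && ov >= segment_overlap * (e - s)) {
        new_seg <- FALSE
      }
    }
    if (new_seg) {
      seg_id <- seg_id + 1L
      cur_read <- al$read_id[i]
      s <- a; e <- b
    } else {
      s <- min(s, a); e <- max(e, b)
    }
    seg_of[i] <- seg_id
  }
  al$.seg <- seg_of
  segs <- al |>
    group_by(.data$.seg) |>
    summarise(
      read_id = first(.data$read_id),
      read_start = min(.data$read_start),
      read_end = max(.data$read_end),
      n_candidates = n(),
      .groups = "drop"
    ) |>
    group_by(.data$read_id) |>
    mutate(segment_index = rank(.data$read_start, ties.method = "first")) |>
    ungroup() |>
    mutate(segment_id = paste0(.data$read_id, "::s", .data$segment_index))
  al$segment_id <- segs$segment_id[match(al$.seg, segs$.seg)]
  al$.seg <- NULL
  segs <- segs |>
    select("segment_id", "read_id", "segment_index", "read_start",
           "read_end", "n_candidates") |>
    arrange(.data$read_id, .data$segment_index)
  reads <- segs |>
    count(.data$read_id, name = "n_segments") |>
    mutate(is_chimeric = .data$n_segments >= 2L)
  list(segments = segs, alignments = al, reads = reads)
}
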