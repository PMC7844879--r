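#' Select the two most probable chimeric arms per read
#'
#' After quantification every read segment has a posterior distribution
#' over CRLs. Per segment the best CRL is the posterior argmax; per read,
#' among all pairs of segments that cover distinct read portions — their
#' read intervals overlap by less than `segment_overlap` of the shorter
#' interval, so truncated multi-hits of one arm are never paired with the
#' arm itself, while exact matches extending a base or two across the
#' chimeric junction still pair — the pair maximising the product of best
#' posteriors becomes the interaction (`arm1` = smaller read start); ties
#' prefer the longer-covering pair. Within the best
#' CRL the reported alignment is chosen by (1) highest read coverage — the
#' same rule the alignment post-processing applies to XA alternatives —
#' then (2) largest locus support counted over best-coverage hits only,
#' the locus-level expression signal that lets CRL+EM rescue multi-mapped
#' arms, then (3) lexicographic locus id. Reads with a single segment are
#' singletons and yield no interaction record.
#'
#' @param segmentation Result of [merge_read_segments()] *after* locus
#'   assignment (its `alignments` must carry `locus_id`).
#' @param fit `crl_quant` object from [em_quantify()].
#' @param crls CRL tibble from [build_crls()].
#' @param loci Locus tibble from [merge_into_loci()].
#' @param segment_overlap Same-portion threshold used for pair validity
#'   (default 0.7, matching the read-segment merge rule).
#' @return List with `interactions` (one row per chimeric read; includes
#'   per-arm `unique` flags used by the benchmark evaluator) and
#'   `singletons` (tibble of reads with no pairable segments).
#' @export
select_arms <- function(segmentation, fit, crls, loci,
                        segment_overlap = 0.7) {
  segs <- segmentation$segments
  al <- segmentation$alignments
  post <- fit$posterior

  locus2crl <- tibble(
    crl_id = rep(crls$crl_id, lengths(crls$member_loci)),
    locus_id = unlist(crls$member_loci)
  )
  crl_tpm_map <- setNames(fit$tpm, names(fit$rho))

  # locus support counted over best-coverage hits only: an alignment
  # truncated on a paralog does not vouch for that paralog's expression
  best_support <- al |>
    group_by(.data$segment_id) |>
    filter(.data$read_end - .data$read_start ==
             max(.data$read_end - .data$read_start)) |>
    ungroup() |>
    distinct(.data$segment_id, .data$locus_id) |>
    count(.data$locus_id, name = "support")
  locus_support <- setNames(
    best_support$support[match(loci$locus_id, best_support$locus_id)],
    loci$locus_id
  )
  locus_support[is.na(locus_support)] <- 0L

  # per-segment best CRL, posterior and uniqueness of the argmax
  seg_best <- purrr::map(segs$segment_id, function(sid) {
    row <- post[sid, , drop = TRUE]
    nz <- which(row > 0)
    mx <- max(row[nz])
    best <- nz[row[nz] >= mx - 1e-12]
    list(crl = colnames(post)[min(best)], p = mx, unique = length(best) == 1L)
  })
  segs$best_crl <- purrr::map_chr(seg_best, "crl")
  segs$best_posterior <- purrr::map_dbl(seg_best, "p")
  segs$unique_best <- purrr::map_lgl(seg_best, "unique")

  al <- al |> left_join(locus2crl, by = "locus_id")

  pick_alignment <- function(sid, crl) {
    cand <- al[al$segment_id == sid & al$crl_id == crl, ]
    if (!nrow(cand)) return(NULL)
    cand$support <- unname(locus_support[cand$locus_id])
    cand <- cand[order(-(cand$read_end - cand$read_start), -cand$support,
                       cand$locus_id, cand$ref_start, cand$ref_id), ]
    cand[1, ]
  }

  by_read <- split(seq_len(nrow(segs)), segs$read_id)
  records <- list()
  singletons <- character(0)
  for (rid in names(by_read)) {
    ii <- by_read[[rid]]
    if (length(ii) < 2L) {
      singletons <- c(singletons, rid)
      next
    }
    s <- segs[ii, ]
    pairs <- utils::combn(seq_len(nrow(s)), 2)
    ov <- pmin(s$read_end[pairs[1, ]], s$read_end[pairs[2, ]]) -
      pmax(s$read_start[pairs[1, ]], s$read_start[pairs[2, ]])
    len1 <- s$read_end[pairs[1, ]] - s$read_start[pairs[1, ]]
    len2 <- s$read_end[pairs[2, ]] - s$read_start[pairs[2, ]]
    ok <- ov < segment_overlap * pmin(len1, len2)
    if (!any(ok)) {
      singletons <- c(singletons, rid)
      next
    }
    pairs <- pairs[, ok, drop = FALSE]
    len_sum <- (len1 + len2)[ok]
    sc <- s$best_posterior[pairs[1, ]] * s$best_posterior[pairs[2, ]]
    ordp <- order(-sc, -len_sum,
                  s$read_start[pairs[1, ]], s$read_start[pairs[2, ]])
    p <- pairs[, ordp[1]]
    if (s$read_start[p[1]] > s$read_start[p[2]]) p <- rev(p)
    arms <- purrr::map(p, function(k) {
      a <- pick_alignment(s$segment_id[k], s$best_crl[k])
      if (is.null(a)) return(NULL)
      tibble(
        ref_id = a$ref_id, locus_id = a$locus_id, crl_id = a$crl_id,
        gene_id = NA_character_, gene_symbol = NA_character_,
        biotype = NA_character_, region = "unannotated",
        ref_start = a$ref_start, ref_end = a$ref_end,
        read_start = a$read_start, read_end = a$read_end,
        cigar = a$cigar,
        posterior = s$best_posterior[k],
        tpm = unname(crl_tpm_map[s$best_crl[k]]),
        unique = s$unique_best[k]
      )
    })
    if (any(purrr::map_lgl(arms, is.null))) {
      abort(paste0("no alignment in best CRL for a segment of read ", rid))
    }
    rec <- dplyr::bind_cols(
      tibble(read_id = rid),
      dplyr::rename_with(arms[[1]], ~paste0("arm1_", .x)),
      dplyr::rename_with(arms[[2]], ~paste0("arm2_", .x))
    )
    rec$score <- score_pairs(rec$arm1_posterior, rec$arm2_posterior)
    rec$hybrid <- NA_character_
    rec$energy <- NA_real_
    records[[length(records) + 1L]] <- rec
  }
  interactions <- if (length(records)) {
    bind_rows(records) |> arrange(.data$read_id)
  } else {
    empty_interactions()
  }
  list(interactions = interactions,
       singletons = tibble(read_id = sort(singletons)))
}

empty_interactions <- function() {
  per_arm <- function(p) {
    tibble(
      "{p}ref_id" := character(), "{p}locus_id" := character(),
      "{p}crl_id" := character(), "{p}gene_id" := character(),
      "{p}gene_symbol" := character(), "{p}biotype" := character(),
      "{p}region" := character(), "{p}ref_start" := integer(),
      "{p}ref_end" := integer(), "{p}read_start" := integer(),
      "{p}read_end" := integer(), "{p}cigar" := character(),
      "{p}posterior" := numeric(), "{p}tpm" := numeric(),
      "{p}unique" := logical()
    )
  }
  dplyr::bind_cols(tibble(read_id = character()),
                   per_arm("arm1_"), per_arm("arm2_")) |>
    mutate(score = numeric(0), hybrid = character(0), energy = numeric(0))
}

#' Annotate interaction arms with gene information
#'
#' Copies gene id, symbol and biotype from the transcript each arm is
#' aligned to, and classifies arms on protein-coding transcripts into
#' 5'UTR / CDS / 3'UTR by the position of the arm midpoint relative to the
#' CDS (in transcript coordinates, hence strand-aware through the exon
#' order). Arms on non-coding biotypes get region `"noncoding"`;
#' transcripts absent from the annotation stay `"unannotated"`.
#'
#' @param interactions Interaction tibble from [select_arms()].
#' @param models Transcript models from [parse_gtf()], or `NULL` (no-op).
#' @return The interaction tibble with annotation columns filled.
#' @export
annotate_interactions <- function(interactions, models = NULL) {
  if (is.null(models) || !nrow(models) || !nrow(interactions)) {
    return(interactions)
  }
  for (arm in c("arm1_", "arm2_")) {
    mi <- match(interactions[[paste0(arm, "ref_id")]], models$transcript_id)
    known <- !is.na(mi)
    interactions[[paste0(arm, "gene_id")]][known] <- models$gene_id[mi[known]]
    interactions[[paste0(arm, "gene_symbol")]][known] <- models$gene_symbol[mi[known]]
    interactions[[paste0(arm, "biotype")]][known] <- models$biotype[mi[known]]
    region <- rep("unannotated", nrow(interactions))
    for (i in which(known)) {
      m <- models[mi[i], ]
      if (!identical(m$biotype, "protein_coding") || is.na(m$cds_start)) {
        region[i] <- "noncoding"
        next
      }
      cds_tx <- genomic_to_tx(m, m$cds_start, m$cds_end)
      mid <- (interactions[[paste0(arm, "ref_start")]][i] +
                interactions[[paste0(arm, "ref_end")]][i]) %/% 2
      region[i] <- if (mid < cds_tx[1]) "5UTR"
                   else if (mid < cds_tx[2]) "CDS"
                   else "3UTR"
    }
    interactions[[paste0(arm, "region")]] <- region
  }
  interactions
}

#' Hybridize two locus sequences with an external tool
#'
#' Contract hook for an RNA-RNA hybridization predictor (e.g. IntaRNA).
#' The sequences handed over are the merged *locus* sequences, which carry
#' some context around the mapped arms — the real duplex is often in the
#' vicinity of the sequenced arms. When no tool is available the record is
#' kept with `hybrid = NA`.
#'
#' @param seq1,seq2 Nucleotide sequences (non-empty).
#' @param command Path to the hybridizer executable, or `NULL`.
#' @return List with `hybrid` (dot-bracket/hybrid string or NA) and
#'   `energy` (kcal/mol or NA).
#' @export
hybridize <- function(seq1, seq2, command = NULL) {
  if (!nzchar(seq1) || !nzchar(seq2)) abort("empty sequence for hybridization")
  if (is.null(command) || Sys.which(command) == "") {
    return(list(hybrid = NA_character_, energy = NA_real_))
  }
  out <- tryCatch(
    system2(command,
            c("-q", seq1, "-t", seq2, "--outMode=C", "--outCsvCols=hybridDP,E"),
            stdout = TRUE, stderr = FALSE),
    error = function(e) character(0)
  )
  body <- out[!startsWith(out, "hybridDP") & nzchar(out)]
  if (!length(body)) {
    warn("hybridizer produced no duplex; keeping record with hybrid NA")
    return(list(hybrid = NA_character_, energy = NA_real_))
  }
  f <- strsplit(body[1], ";", fixed = TRUE)[[1]]
  list(hybrid = f[1], energy = suppressWarnings(as.numeric(f[2])))
}

#' Filter interaction records and write the final table
#'
#' Records scoring below `score_threshold` are dropped (the published
#' analyses used 0.5 as the "final probability" cut-off; the tool default
#' keeps everything). With `require_hybrid`, records without a predicted
#' duplex are dropped too.
#'
#' @param interactions Interaction tibble.
#' @param score_threshold Minimum interaction score kept (default 0).
#' @param require_hybrid Drop records with `hybrid == NA`?
#' @param path Optional output TSV path.
#' @return The filtered tibble (written to `path` when given).
#' @export
filter_interactions <- function(interactions, score_threshold = 0,
                                require_hybrid = FALSE, path = NULL) {
  out <- interactions |> filter(.data$score >= score_threshold)
  if (require_hybrid) {
    out <- out |> filter(!is.na(.data$hybrid))
    if (!nrow(out)) warn("no records carry a hybrid; was a hybridizer run?")
  }
  if (!is.null(path)) write_interactions(out, path)
  out
}
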