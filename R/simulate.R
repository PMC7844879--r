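# Benchmark simulator: CLAN-style chimeric reads over paralogous references,
# with per-read ground truth, a built-in exact toy mapper, and the 7-category
# evaluator.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  b <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(b)) < rate)
  for (i in hit) b[i] <- sample(setdiff(DNA_BASES, b[i]), 1)
  paste(b, collapse = "")
}

#' Simulate a split reference with paralogous families
#'
#' Emulates a CLASH-style split reference: short "miRNA-like" sequences and
#' longer "target-like" sequences, each organised into families of
#' `family_size` near-identical copies that differ by point substitutions
#' at per-base rate `divergence` from the family founder (member 1). One
#' member per family, drawn at random, is flagged `expressed`: the read
#' simulators draw from expressed members only, so the other copies are
#' decoys that attract multi-mapped alignments. With `divergence > 0`
#' every copy is redrawn until it differs from all other sequences of its
#' database (the published benchmark removed duplicate references, which
#' make the true origin undecidable); `divergence = 0` is the documented
#' identity case where family members are exact copies.
#'
#' @param n_families Families per reference database.
#' @param family_size Near-identical copies per family.
#' @param divergence Per-base substitution rate in \\[0,1\\].
#' @param target_len_range,mirna_len_range Length ranges (uniform integer).
#' @param seed Integer seed; output is byte-identical for a fixed seed.
#' @return Tibble with `ref_id`, `sequence`, `ref_db` (1 = miRNA-like,
#'   2 = target-like), `family`, `member`, `expressed`.
#' @export
make_reference <- function(n_families = 20L, family_size = 3L,
                           divergence = 0.03,
                           target_len_range = c(50L, 200L),
                           mirna_len_range = c(18L, 25L),
                           seed = 1L) {
  if (divergence < 0 || divergence > 1) abort("divergence must be in [0,1]")
  stopifnot(n_families >= 1L, family_size >= 1L)
  with_seed(seed, {
    one_db <- function(prefix, len_range, db) {
      founders <- character(0)
      while (length(founders) < n_families) {
        len <- sample(seq(len_range[1], len_range[2]), 1)
        s <- random_dna(len)
        if (!s %in% founders) founders <- c(founders, s)
      }
      seen <- founders
      purrr::map_dfr(seq_len(n_families), function(f) {
        copies <- founders[f]
        while (length(copies) < family_size) {
          s <- mutate_seq(founders[f], divergence)
          # divergence 0 keeps exact copies; otherwise every reference
          # sequence in the database must be distinct
          if (divergence == 0 || !s %in% seen) {
            copies <- c(copies, s)
            seen <<- c(seen, s)
          }
        }
        expressed_member <- sample.int(family_size, 1L)
        tibble(
          ref_id = sprintf("%s%03d_c%d", prefix, f, seq_len(family_size)),
          sequence = copies,
          ref_db = db,
          family = sprintf("%s%03d", prefix, f),
          member = seq_len(family_size),
          expressed = seq_len(family_size) == expressed_member
        )
      })
    }
    bind_rows(one_db("mir", mirna_len_range, 1L),
              one_db("tgt", target_len_range, 2L))
  })
}

#' Simulate chimeric benchmark reads with ground truth
#'
#' Each read is a direct fusion of an `arm_length` substring of a random
#' expressed miRNA-like reference and an `arm_length` substring of a random
#' expressed target-like reference (the published benchmark uses arm
#' lengths 10, 12, 15, 18 and 20). When a reference is shorter than
#' `arm_length` the whole sequence is used. With `insert`, a random 5-nt
#' sequence is placed uniformly between the arms or at either end.
#'
#' @param refs Reference tibble from [make_reference()].
#' @param n_reads Number of reads (> 0).
#' @param arm_length Nominal arm length in nt.
#' @param insert Insert a random 5-nt sequence?
#' @param seed Integer seed.
#' @return List with `reads` (read tibble as from [read_fastx()]) and
#'   `truth` (per read: both true arm locations, `arm_length`,
#'   `has_insert`, `insert_pos`).
#' @export
make_chimeric_reads <- function(refs, n_reads, arm_length = 20L,
                                insert = FALSE, seed = 1L) {
  if (n_reads <= 0) abort("n_reads must be positive")
  mir <- refs |> filter(.data$ref_db == 1L, .data$expressed)
  tgt <- refs |> filter(.data$ref_db == 2L, .data$expressed)
  stopifnot(nrow(mir) > 0, nrow(tgt) > 0)
  with_seed(seed, {
    draw_arm <- function(pool) {
      i <- sample.int(nrow(pool), n_reads, replace = TRUE)
      len <- pmin(arm_length, nchar(pool$sequence[i]))
      start <- purrr::map2_int(nchar(pool$sequence[i]), len,
                               ~sample.int(.x - .y + 1L, 1) - 1L)
      tibble(ref_id = pool$ref_id[i], start = start, end = start + len,
             seq = substr(pool$sequence[i], start + 1L, start + len))
    }
    a1 <- draw_arm(mir)
    a2 <- draw_arm(tgt)
    ins_pos <- if (insert) {
      sample(c("between", "start", "end"), n_reads, replace = TRUE)
    } else rep(NA_character_, n_reads)
    ins_seq <- if (insert) purrr::map_chr(seq_len(n_reads), ~random_dna(5L))
               else rep("", n_reads)
    seqs <- dplyr::case_when(
      is.na(ins_pos) ~ paste0(a1$seq, a2$seq),
      ins_pos == "between" ~ paste0(a1$seq, ins_seq, a2$seq),
      ins_pos == "start" ~ paste0(ins_seq, a1$seq, a2$seq),
      TRUE ~ paste0(a1$seq, a2$seq, ins_seq)
    )
    ids <- sprintf("simread%06d", seq_len(n_reads))
    list(
      reads = tibble(read_id = ids, sequence = seqs,
                     quality = NA_character_, umi = NA_character_,
                     copy_count = 1L),
      truth = tibble(
        read_id = ids,
        ref_id1 = a1$ref_id, ref_start1 = a1$start, ref_end1 = a1$end,
        ref_id2 = a2$ref_id, ref_start2 = a2$start, ref_end2 = a2$end,
        arm_length = as.integer(arm_length),
        has_insert = insert, insert_pos = ins_pos
      )
    )
  })
}

#' Simulate non-chimeric (singleton) reads from expressed references
#'
#' Singletons mark which family member is actually expressed: reads long
#' enough to cover a distinguishing substitution are unique to the
#' expressed copy and anchor the expression-based rescue of multi-mapped
#' chimeric arms.
#'
#' @param refs Reference tibble from [make_reference()].
#' @param n_reads Number of reads.
#' @param read_length Nominal read length (whole reference when shorter).
#' @param ref_db Which database to draw from (1, 2, or `NULL` for both).
#' @param seed Integer seed.
#' @return Read tibble.
#' @export
make_singleton_reads <- function(refs, n_reads, read_length = 30L,
                                 ref_db = NULL, seed = 1L) {
  if (n_reads <= 0) abort("n_reads must be positive")
  pool <- refs |> filter(.data$expressed)
  if (!is.null(ref_db)) pool <- pool |> filter(.data$ref_db == !!ref_db)
  stopifnot(nrow(pool) > 0)
  with_seed(seed + 7L, {
    i <- sample.int(nrow(pool), n_reads, replace = TRUE)
    len <- pmin(read_length, nchar(pool$sequence[i]))
    start <- purrr::map2_int(nchar(pool$sequence[i]), len,
                             ~sample.int(.x - .y + 1L, 1) - 1L)
    tibble(
      read_id = sprintf("single%06d", seq_len(n_reads)),
      sequence = substr(pool$sequence[i], start + 1L, start + len),
      quality = NA_character_, umi = NA_character_, copy_count = 1L
    )
  })
}

#' Exhaustive exact toy mapper
#'
#' Deterministic seed-and-extend mapper used so that benchmark round-trips
#' need no external aligner: every maximal exact match of length at least
#' `min_match` between a read and a (sense-strand) reference becomes one
#' alignment segment. Seeds are all read k-mers (`k = min_match`) matched
#' with a preprocessed dictionary; only left-maximal seeds are kept and
#' extended to the right, so each maximal match is reported exactly once.
#'
#' Hits covering the same read portion are assigned to one alternative
#' group, emulating a primary record plus its XA alternatives: per read,
#' hits are swept in decreasing coverage order and a hit joins an existing
#' group when its read interval overlaps at least 70% of its own length
#' with the group leader's interval. [postprocess_alignments()] then keeps
#' only the best-covered alternatives per group, exactly as it would for
#' aligner output.
#'
#' @param reads Read tibble (`read_id`, `sequence`).
#' @param refs Reference tibble (`ref_id`, `sequence`, optional `ref_db`).
#' @param min_match Minimum (and seed) match length; default 10.
#' @return Alignment-segment tibble in the [parse_sam()] schema.
#' @export
toy_map_reads <- function(reads, refs, min_match = 10L) {
  stopifnot(min_match >= 4L)
  k <- as.integer(min_match)
  n_kmer <- nchar(reads$sequence) - k + 1L
  keep <- which(n_kmer >= 1L)
  if (!length(keep)) return(empty_segments())
  km <- tibble(
    read_idx = rep(keep, n_kmer[keep]),
    pos = unlist(purrr::map(n_kmer[keep], seq_len)) - 1L   # 0-based
  )
  km$kmer <- substr(reads$sequence[km$read_idx], km$pos + 1L, km$pos + k)
  ok <- !grepl("[^ACGT]", km$kmer)
  km <- km[ok, ]
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(km$kmer))
  hits <- purrr::map_dfr(seq_len(nrow(refs)), function(r) {
    mi <- Biostrings::matchPDict(pd, Biostrings::DNAString(refs$sequence[r]))
    cnt <- S4Vectors::elementNROWS(mi)
    if (!sum(cnt)) return(NULL)
    tibble(
      kmer_idx = rep(seq_along(cnt), cnt),
      ref_idx = r,
      ref_pos = unlist(Biostrings::startIndex(mi)) - 1L   # 0-based
    )
  })
  if (!nrow(hits)) return(empty_segments())
  hits$read_idx <- km$read_idx[hits$kmer_idx]
  hits$read_pos <- km$pos[hits$kmer_idx]
  # keep left-maximal seeds only: previous bases differ (or boundary)
  rs <- reads$sequence[hits$read_idx]
  fs <- refs$sequence[hits$ref_idx]
  at_edge <- hits$read_pos == 0L | hits$ref_pos == 0L
  prev_eq <- substr(rs, hits$read_pos, hits$read_pos) ==
             substr(fs, hits$ref_pos, hits$ref_pos)
  hits <- hits[at_edge | !prev_eq, ]
  if (!nrow(hits)) return(empty_segments())
  # extend right, vectorised over all hits
  len <- rep(k, nrow(hits))
  active <- seq_len(nrow(hits))
  rlen <- nchar(reads$sequence)[hits$read_idx]
  flen <- nchar(refs$sequence)[hits$ref_idx]
  rs <- reads$sequence[hits$read_idx]
  fs <- refs$sequence[hits$ref_idx]
  while (length(active)) {
    i <- active
    nr <- hits$read_pos[i] + len[i] + 1L
    nf <- hits$ref_pos[i] + len[i] + 1L
    can <- nr <= rlen[i] & nf <= flen[i] &
      substr(rs[i], nr, nr) == substr(fs[i], nf, nf)
    len[i[can]] <- len[i[can]] + 1L
    active <- i[can]
  }
  db <- refs[["ref_db"]] %||% rep(1L, nrow(refs))
  out <- tibble(
    read_id = reads$read_id[hits$read_idx],
    read_start = hits$read_pos,
    read_end = hits$read_pos + len,
    ref_id = refs$ref_id[hits$ref_idx],
    ref_start = hits$ref_pos,
    ref_end = hits$ref_pos + len,
    strand = "+",
    cigar = sprintf(
      "%s%dM%s",
      ifelse(hits$read_pos > 0L, paste0(hits$read_pos, "S"), ""),
      len,
      ifelse(rlen - (hits$read_pos + len) > 0L,
             paste0(rlen - (hits$read_pos + len), "S"), "")
    ),
    score = len,
    nm = 0L,
    pass_id = 1L,
    ref_db = db[hits$ref_idx],
    source = "toy"
  )
  out <- out |>
    distinct(.data$read_id, .data$read_start, .data$read_end, .data$ref_id,
             .data$ref_start, .data$ref_end, .keep_all = TRUE) |>
    arrange(.data$read_id,
            .data$read_start - .data$read_end,  # coverage, decreasing
            .data$read_start, .data$ref_id, .data$ref_start)
  out$group_id <- toy_groups(out)
  arrange(out, .data$read_id, .data$read_start, .data$ref_id,
          .data$ref_start)
}

# XA-like alternative groups: sweep a read's hits in decreasing coverage;
# a hit joins a group when >= 70% of its read interval lies inside the
# group leader's interval, otherwise it leads a new group.
toy_groups <- function(out) {
  grp <- character(nrow(out))
  idx <- split(seq_len(nrow(out)), out$read_id)
  for (ii in idx) {
    leaders <- integer(0)
    for (i in ii) {
      assigned <- FALSE
      for (l in leaders) {
        ov <- min(out$read_end[i], out$read_end[l]) -
          max(out$read_start[i], out$read_start[l])
        if (ov >= 0.7 * (out$read_end[i] - out$read_start[i])) {
          grp[i] <- grp[l]
          assigned <- TRUE
          break
        }
      }
      if (!assigned) {
        grp[i] <- paste0(out$read_id[i], "/t", length(leaders) + 1L)
        leaders <- c(leaders, i)
      }
    }
  }
  grp
}

category_levels <- function() {
  c("perfect", "partial_multi", "both_multi", "partial_wrong",
    "both_wrong", "partial_miss", "both_miss")
}

#' Categorize predicted arms against benchmark truth
#'
#' An arm is *agreed* iff one of its considered alignments lies on the true
#' reference and overlaps at least `agree_overlap` of the true arm
#' interval. The seven categories: `perfect` (both arms uniquely mapped and
#' agreed), `partial_multi` (one unique agreed, one multi-mapped agreed),
#' `both_multi`, `partial_wrong` (one agreed arm, one mapped-but-wrong),
#' `both_wrong`, `partial_miss` (one mapped, one unmapped arm) and
#' `both_miss`. Any mapped-but-not-agreed arm routes the read into a wrong
#' category; the counts always partition the simulated read set.
#'
#' @param predictions Tibble with one row per considered alignment of a
#'   predicted arm: `read_id`, `arm_index` (1 = smaller read start),
#'   `ref_id`, `ref_start`, `ref_end` and optionally `unique` (when
#'   absent, an arm is unique iff it has exactly one row). Unmapped arms
#'   and reads are simply absent.
#' @param truth Truth tibble from [make_chimeric_reads()].
#' @param agree_overlap Fraction of the true arm that must be covered
#'   (default 0.8).
#' @return Tibble `category` (all seven, ordered), `n`; `sum(n)` equals
#'   `nrow(truth)`.
#' @export
categorize_reads <- function(predictions, truth, agree_overlap = 0.8) {
  unknown <- setdiff(unique(predictions$read_id), truth$read_id)
  if (length(unknown)) {
    abort(paste0("predicted read(s) absent from truth: ",
                 paste(head(unknown), collapse = ", ")))
  }
  if (!"unique" %in% names(predictions)) {
    predictions <- predictions |>
      group_by(.data$read_id, .data$arm_index) |>
      mutate(unique = n() == 1L) |>
      ungroup()
  }
  arm_status <- function(arm) {
    tr <- truth |>
      select(read_id = "read_id",
             true_ref = paste0("ref_id", arm),
             true_start = paste0("ref_start", arm),
             true_end = paste0("ref_end", arm))
    pr <- predictions |> filter(.data$arm_index == arm)
    j <- pr |> inner_join(tr, by = "read_id") |>
      mutate(
        ov = pmin(.data$ref_end, .data$true_end) -
             pmax(.data$ref_start, .data$true_start),
        hit = .data$ref_id == .data$true_ref &
              .data$ov >= agree_overlap * (.data$true_end - .data$true_start)
      ) |>
      group_by(.data$read_id) |>
      summarise(mapped = TRUE, agreed = any(.data$hit),
                unique = first(.data$unique))
    tr |>
      select("read_id") |>
      left_join(j, by = "read_id") |>
      mutate(mapped = dplyr::coalesce(.data$mapped, FALSE),
             agreed = dplyr::coalesce(.data$agreed, FALSE),
             unique = dplyr::coalesce(.data$unique, FALSE))
  }
  s1 <- arm_status(1)
  s2 <- arm_status(2)
  n_mapped <- s1$mapped + s2$mapped
  n_agreed <- s1$agreed + s2$agreed
  n_unique_agreed <- (s1$agreed & s1$unique) + (s2$agreed & s2$unique)
  cat <- dplyr::case_when(
    n_mapped == 0L ~ "both_miss",
    n_mapped == 1L ~ "partial_miss",
    n_agreed == 0L ~ "both_wrong",
    n_agreed == 1L ~ "partial_wrong",
    n_unique_agreed == 2L ~ "perfect",
    n_unique_agreed == 1L ~ "partial_multi",
    TRUE ~ "both_multi"
  )
  tibble(category = factor(cat, levels = category_levels())) |>
    count(.data$category, .drop = FALSE)
}

#' Predicted arms of the final interaction table, for the evaluator
#'
#' One row per selected arm, with uniqueness taken from the EM posterior
#' (an arm is unique when its posterior row has a unique argmax).
#'
#' @param interactions Interaction tibble from [select_arms()].
#' @return Prediction tibble for [categorize_reads()].
#' @export
chira_predictions <- function(interactions) {
  one <- function(arm) {
    p <- paste0("arm", arm, "_")
    tibble(
      read_id = interactions$read_id,
      arm_index = arm,
      ref_id = interactions[[paste0(p, "ref_id")]],
      ref_start = interactions[[paste0(p, "ref_start")]],
      ref_end = interactions[[paste0(p, "ref_end")]],
      unique = interactions[[paste0(p, "unique")]] %||%
        rep(TRUE, nrow(interactions))
    )
  }
  bind_rows(one(1L), one(2L)) |> arrange(.data$read_id, .data$arm_index)
}

#' Naive longest-hit arm predictions
#'
#' The baseline the published benchmark compares against: per read segment
#' only the alignments with the longest read coverage are considered (all
#' of them, when tied); an arm is unique iff exactly one alignment remains.
#' No CRL grouping, no quantification. For reads with more than two
#' segments, the two best-covered segments (in read order) are judged.
#'
#' @param alignments Post-processed alignment tibble.
#' @param segment_overlap Read-segment merge threshold (default 0.7).
#' @return Prediction tibble for [categorize_reads()].
#' @export
naive_predictions <- function(alignments, segment_overlap = 0.7) {
  seg <- merge_read_segments(alignments, segment_overlap)
  best <- seg$alignments |>
    group_by(.data$segment_id) |>
    filter(.data$read_end - .data$read_start ==
             max(.data$read_end - .data$read_start)) |>
    ungroup()
  chosen <- seg$segments |>
    left_join(
      best |> count(.data$segment_id, name = "n_best"),
      by = "segment_id"
    ) |>
    left_join(
      best |>
        group_by(.data$segment_id) |>
        summarise(coverage = max(.data$read_end - .data$read_start)),
      by = "segment_id"
    ) |>
    group_by(.data$read_id) |>
    arrange(dplyr::desc(.data$coverage), .data$segment_index,
            .by_group = TRUE) |>
    slice(1:2) |>
    arrange(.data$segment_index, .by_group = TRUE) |>
    mutate(arm_index = row_number()) |>
    ungroup()
  best |>
    inner_join(chosen |> select("segment_id", "arm_index", "n_best"),
               by = "segment_id") |>
    mutate(unique = .data$n_best == 1L) |>
    select("read_id", "arm_index", "ref_id", "ref_start", "ref_end",
           "unique") |>
    arrange(.data$read_id, .data$arm_index, .data$ref_id, .data$ref_start)
}
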