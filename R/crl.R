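#' Group expressed loci into common read loci (CRLs)
#'
#' Paralogous loci and gene-family members attract the same multi-mapped
#' read segments. Loci sharing a large fraction of their read segments are
#' therefore grouped — without any annotation — into *common read loci* by
#' single-linkage clustering under the Jaccard index. Loci are processed in
#' decreasing read-set size (well-supported loci found the clusters); each
#' locus joins the existing CRL with the highest Jaccard index
#' `J(L, C) = |L n C| / |L u C|` against the CRL's running union read set,
#' provided `J` strictly exceeds `share_threshold`; otherwise it founds its
#' own CRL. Ties go to the larger CRL, then the lexicographically smaller
#' id.
#'
#' @param loci Expressed-locus tibble from [merge_into_loci()] (needs
#'   `locus_id` and `segments`, the list of read-segment ids).
#' @param share_threshold Jaccard threshold in (0,1]; default 0.7.
#' @return Tibble with `crl_id`, `member_loci` (list), `n_members`,
#'   `read_set` (list; union of member read sets) and `n_reads`. Every
#'   locus belongs to exactly one CRL.
#' @export
build_crls <- function(loci, share_threshold = 0.7) {
  stopifnot(share_threshold > 0, share_threshold <= 1)
  if (!nrow(loci)) {
    return(tibble(crl_id = character(), member_loci = list(),
                  n_members = integer(), read_set = list(),
                  n_reads = integer()))
  }
  ord <- order(-lengths(loci$segments), loci$locus_id)
  members <- list()
  read_sets <- list()
  for (i in ord) {
    li <- loci$segments[[i]]
    best_j <- 0
    best_k <- 0L
    for (k in seq_along(read_sets)) {
      ck <- read_sets[[k]]
      inter <- length(intersect(li, ck))
      if (inter == 0L) next
      j <- inter / (length(li) + length(ck) - inter)
      if (j > best_j + 1e-12 ||
          (abs(j - best_j) <= 1e-12 && best_k > 0L &&
           length(ck) > length(read_sets[[best_k]]))) {
        best_j <- j
        best_k <- k
      }
    }
    if (best_k > 0L && best_j > share_threshold) {
      members[[best_k]] <- c(members[[best_k]], loci$locus_id[i])
      read_sets[[best_k]] <- union(read_sets[[best_k]], li)
    } else {
      members[[length(members) + 1L]] <- loci$locus_id[i]
      read_sets[[length(read_sets) + 1L]] <- li
    }
  }
  tibble(
    crl_id = sprintf("CRL%05d", seq_along(members)),
    member_loci = purrr::map(members, sort),
    n_members = lengths(members),
    read_set = purrr::map(read_sets, sort),
    n_reads = lengths(read_sets)
  )
}

#' Average pairwise sequence identity (APSI) of a set of sequences
#'
#' Pairwise identity is the global alignment score with match = 1 and no
#' mismatch or gap penalties — i.e. the longest-common-subsequence length —
#' divided by the mean of the two sequence lengths; APSI is the mean over
#' all pairs. Used to check that CRL member loci really are near-identical
#' paralogs.
#'
#' @param sequences Character vector of nucleotide sequences (a CRL's
#'   member locus sequences).
#' @return A fraction in (0,1], or `NA_real_` for fewer than 2 sequences
#'   (APSI is undefined for singleton CRLs).
#' @export
compute_apsi <- function(sequences) {
  n <- length(sequences)
  if (n < 2L) return(NA_real_)
  pairs <- utils::combn(n, 2)
  vals <- purrr::map_dbl(seq_len(ncol(pairs)), function(p) {
    a <- sequences[pairs[1, p]]
    b <- sequences[pairs[2, p]]
    lcs <- pairwise_match_score(a, b)
    lcs / mean(c(nchar(a), nchar(b)))
  })
  mean(vals)
}

# Global alignment score, match = 1, no mismatch/gap penalties (equals the
# LCS length). Biostrings does the alignment; tests cross-check against a
# plain dynamic program.
pairwise_match_score <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 0, scoreOnly = TRUE
  )
}

#' APSI of every CRL with at least two members
#'
#' @param crls CRL tibble from [build_crls()].
#' @param locus_seqs Named character vector mapping `locus_id` to the locus
#'   nucleotide sequence (see [locus_sequences()]).
#' @return Tibble `crl_id`, `n_members`, `apsi`.
#' @export
crl_apsi <- function(crls, locus_seqs) {
  crls |>
    mutate(apsi = purrr::map_dbl(.data$member_loci, function(m) {
      if (any(!m %in% names(locus_seqs))) {
        abort("locus sequence missing for APSI computation")
      }
      compute_apsi(unname(locus_seqs[m]))
    })) |>
    select("crl_id", "n_members", "apsi")
}

#' Random-locus APSI baseline
#'
#' For each requested CRL size, draws random locus sets from the pool and
#' computes their APSI — the null expectation against which observed CRL
#' coherence is judged.
#'
#' @param pool Character vector of locus sequences to sample from.
#' @param crl_sizes Integer vector of set sizes (each >= 2).
#' @param n_draws Draws per size.
#' @param seed Integer seed; draws are reproducible.
#' @return Tibble `size`, `draw`, `apsi`.
#' @export
apsi_baseline <- function(pool, crl_sizes, n_draws = 20L, seed = 1L) {
  stopifnot(all(crl_sizes >= 2L))
  if (any(crl_sizes > length(pool))) {
    abort("draw size exceeds locus pool")
  }
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed(
    tidyr::expand_grid(size = as.integer(crl_sizes), draw = seq_len(n_draws)) |>
      mutate(apsi = purrr::map_dbl(.data$size, function(sz) {
        compute_apsi(sample(pool, sz))
      }))
  )
}

#' Extract expressed-locus sequences from reference sequences
#'
#' @param loci Locus tibble from [merge_into_loci()].
#' @param refs Tibble with `ref_id` and `sequence` (the references the
#'   loci live on; transcriptomic coordinates).
#' @return Named character vector, `locus_id` -> sequence.
#' @export
locus_sequences <- function(loci, refs) {
  mi <- match(loci$chrom, refs$ref_id)
  if (anyNA(mi)) abort("locus on unknown reference")
  setNames(substr(refs$sequence[mi], loci$start + 1L, loci$end), loci$locus_id)
}
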