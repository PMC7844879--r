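# Independent oracles and in-code fixture builders. These deliberately use
# naive algorithms (dynamic programs, exhaustive loops) so they never share
# code paths with the implementation they check.

`%||%` <- function(a, b) if (is.null(a)) b else a

# longest common subsequence length by textbook dynamic program
lcs_dp <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  prev <- integer(m + 1)
  for (i in seq_len(n)) {
    cur <- integer(m + 1)
    for (j in seq_len(m)) {
      cur[j + 1] <- if (x[i] == y[j]) prev[j] + 1L
                    else max(prev[j + 1], cur[j])
    }
    prev <- cur
  }
  prev[m + 1]
}

# per-base transcript -> genome coordinate map, built explicitly
per_base_map <- function(exons, strand) {
  g <- unlist(lapply(seq_len(nrow(exons)), function(i) {
    seq(exons[i, 1], exons[i, 2] - 1L)
  }))
  if (strand == "-") {
    g <- unlist(lapply(seq_len(nrow(exons)), function(i) {
      seq(exons[i, 2] - 1L, exons[i, 1])
    }))
  }
  g
}

# brute-force single-linkage CRL clustering: at every step recompute the
# Jaccard index of the incoming locus against EVERY existing cluster's
# union read set; join the best cluster iff J > threshold (ties: larger
# cluster, then earlier creation).
brute_force_crls <- function(read_sets, ids, threshold = 0.7) {
  ord <- order(-lengths(read_sets), ids)
  clusters <- list()
  joins <- numeric(0)
  for (i in ord) {
    li <- read_sets[[i]]
    best_j <- -1
    best_k <- 0L
    for (k in seq_along(clusters)) {
      ck <- clusters[[k]]$reads
      u <- unique(c(li, ck))
      j <- (length(li) + length(ck) - length(u)) / length(u)
      better <- j > best_j + 1e-12 ||
        (abs(j - best_j) <= 1e-12 && best_k > 0L &&
         length(ck) > length(clusters[[best_k]]$reads))
      if (better) { best_j <- j; best_k <- k }
    }
    if (best_k > 0L && best_j > threshold) {
      clusters[[best_k]]$members <- c(clusters[[best_k]]$members, ids[i])
      clusters[[best_k]]$reads <- unique(c(clusters[[best_k]]$reads, li))
      joins <- c(joins, best_j)
    } else {
      clusters[[length(clusters) + 1L]] <- list(members = ids[i], reads = li)
    }
  }
  structure(lapply(clusters, function(cl) sort(cl$members)), joins = joins)
}

# exhaustive grid search of the EM likelihood over the probability simplex
grid_max_loglik <- function(Y, step = 1e-3) {
  K <- ncol(Y)
  g <- simplex_grid(K, step)
  ll <- rowSums(log(pmax(g %*% t(Y), .Machine$double.xmin)))
  max(ll)
}

simplex_grid <- function(K, step = 1e-3) {
  n <- round(1 / step)
  if (K == 1) return(matrix(1, 1, 1))
  if (K == 2) {
    i <- 0:n
    return(cbind(i / n, 1 - i / n))
  }
  i <- rep(0:n, n + 1)
  j <- rep(0:n, each = n + 1)
  ok <- i + j <= n
  cbind(i[ok] / n, j[ok] / n, (n - i[ok] - j[ok]) / n)
}

# minimal SAM writer for fixtures
write_sam_fixture <- function(path, refs, records) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(refs), nchar(refs)))
  writeLines(c(hdr, records), path)
}

sam_line <- function(qname, flag, rname, pos, cigar, seq = NULL, tags = character(0)) {
  if (is.null(seq)) seq <- "*"
  qual <- if (seq == "*") "*" else strrep("I", nchar(seq))
  paste(c(qname, flag, rname, pos, 60, cigar, "*", 0, 0, seq, qual, tags),
        collapse = "\t")
}

# small end-to-end benchmark world shared by several tests
benchmark_world <- function(seed = 42L, n_reads = 120L, arm_length = 18L,
                            n_families = 6L, family_size = 3L,
                            divergence = 0.03) {
  refs <- make_reference(
    n_families = n_families, family_size = family_size,
    divergence = divergence, target_len_range = c(60L, 120L), seed = seed
  )
  sim <- make_chimeric_reads(refs, n_reads, arm_length = arm_length,
                             seed = seed)
  singles <- make_singleton_reads(refs, n_reads, read_length = 30L,
                                  seed = seed)
  list(refs = refs, sim = sim,
       reads = dplyr::bind_rows(sim$reads, singles))
}
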