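mk_model <- function(exons, strand = "+", chrom = "chr1", id = "tx1") {
  len <- sum(exons[, 2] - exons[, 1])
  tibble::tibble(
    transcript_id = id, gene_id = "g1", gene_symbol = "G1",
    biotype = "protein_coding", chrom = chrom, strand = strand,
    exons = list(exons), tx_len = len,
    cds_start = NA_integer_, cds_end = NA_integer_
  )
}

test_that("tx_to_genomic maps spliced and minus-strand intervals", {
  m <- mk_model(cbind(start = c(1000L, 1200L), end = c(1100L, 1300L)))
  b <- tx_to_genomic(m, 50, 150)
  expect_equal(unname(b), cbind(c(1050, 1200), c(1100, 1250)),
               ignore_attr = TRUE)
  # minus strand single exon: transcript [0,10) is the genomic 3' end
  mm <- mk_model(cbind(start = 1000L, end = 1100L), strand = "-")
  expect_equal(unname(tx_to_genomic(mm, 0, 10)), cbind(1090, 1100),
               ignore_attr = TRUE)
  expect_error(tx_to_genomic(m, 150, 250), "outside transcript")
})

test_that("coordinate lift agrees with a per-base map and round-trips", {
  set.seed(31)
  for (i in 1:25) {
    n_ex <- sample(1:4, 1)
    starts <- sort(sample(seq(0, 5000, by = 50), n_ex))
    ex <- cbind(start = starts, end = starts + sample(20:80, n_ex, replace = TRUE))
    strand <- sample(c("+", "-"), 1)
    ex_tx <- if (strand == "-") ex[rev(seq_len(n_ex)), , drop = FALSE] else ex
    m <- mk_model(ex_tx, strand = strand)
    L <- sum(ex[, 2] - ex[, 1])
    s <- sample(0:(L - 2), 1); e <- sample((s + 1):L, 1)
    blocks <- tx_to_genomic(m, s, e)
    # length preserved exactly
    expect_equal(sum(blocks[, 2] - blocks[, 1]), e - s)
    # against the explicit per-base oracle
    pb <- per_base_map(ex_tx, strand)
    expect_setequal(
      unlist(apply(blocks, 1, function(r) seq(r[1], r[2] - 1))),
      pb[(s + 1):e]
    )
    # round trip
    expect_equal(unname(genomic_to_tx(m, min(blocks[, 1]), max(blocks[, 2]))),
                 c(s, e))
  }
})

test_that("lift without an annotation is the identity", {
  al <- tibble::tibble(read_id = "r", read_start = 0L, read_end = 20L,
                       ref_id = "tx", ref_start = 5L, ref_end = 25L,
                       strand = "+", segment_id = "r::s1")
  out <- lift_alignments(al, NULL)
  expect_equal(out$chrom, "tx")
  expect_equal(out$gstart, 5L)
  expect_equal(out$gend, 25L)
})

loci_from <- function(ivals, ref = "tA") {
  al <- tibble::tibble(
    read_id = paste0("r", seq_len(nrow(ivals))),
    read_start = 0L, read_end = 20L,
    ref_id = ref, ref_start = ivals[, 1], ref_end = ivals[, 2],
    strand = "+", segment_id = paste0("r", seq_len(nrow(ivals)), "::s1")
  )
  merge_into_loci(lift_alignments(al, NULL))
}

test_that("reciprocal-overlap locus merging follows the >70% rule", {
  one <- loci_from(cbind(c(100L, 110L), c(200L, 210L)))
  expect_equal(nrow(one$loci), 1L)
  expect_equal(one$loci$start, 100L)
  expect_equal(one$loci$end, 210L)

  two <- loci_from(cbind(c(0L, 200L), c(100L, 300L)))
  expect_equal(nrow(two$loci), 2L)

  # sequential merge against the growing extent
  three <- loci_from(cbind(c(0L, 5L, 10L), c(100L, 105L, 110L)))
  expect_equal(nrow(three$loci), 1L)
  expect_equal(c(three$loci$start, three$loci$end), c(0L, 110L))

  # boundary: exactly 70% reciprocal overlap does NOT merge (strict >)
  b <- loci_from(cbind(c(0L, 30L), c(100L, 100L)))  # overlap 70 of 100/70
  expect_equal(nrow(b$loci), 2L)
})

test_that("every alignment lands in exactly one locus, as the sweep oracle says", {
  # independent oracle: plain re-statement of the published rule — sweep
  # start-sorted intervals, merge into the open locus iff the overlap
  # strictly exceeds 70% of the interval length AND of the locus extent
  sweep_oracle <- function(iv) {
    iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
    grp <- integer(nrow(iv))
    s <- e <- -1L
    g <- 0L
    for (i in seq_len(nrow(iv))) {
      ov <- min(e, iv[i, 2]) - max(s, iv[i, 1])
      if (g > 0L && ov > 0.7 * (iv[i, 2] - iv[i, 1]) && ov > 0.7 * (e - s)) {
        e <- max(e, iv[i, 2])
      } else {
        g <- g + 1L
        s <- iv[i, 1]; e <- iv[i, 2]
      }
      grp[i] <- g
    }
    unname(split(seq_len(nrow(iv)), grp))
  }
  set.seed(17)
  for (rep in 1:10) {
    n <- sample(20:80, 1)
    starts <- sample(0:400, n, replace = TRUE)
    ivals <- cbind(starts, starts + sample(15:30, n, replace = TRUE))
    res <- loci_from(ivals)
    expect_equal(nrow(res$alignments), n)
    expect_false(anyNA(res$alignments$locus_id))
    expect_true(all(res$alignments$locus_id %in% res$loci$locus_id))
    # same partition of intervals into loci as the oracle
    iv_sorted <- ivals[order(ivals[, 1], ivals[, 2]), , drop = FALSE]
    oracle <- sweep_oracle(ivals)
    al <- res$alignments[order(res$alignments$ref_start,
                               res$alignments$ref_end), ]
    got <- unname(split(seq_len(n), match(al$locus_id, unique(al$locus_id))))
    expect_identical(got, oracle)
  }
})

test_that("read segments merge by the >=70% rule and flag chimeras", {
  mk_al <- function(iv, refs = NULL) {
    tibble::tibble(
      read_id = "r1", read_start = iv[, 1], read_end = iv[, 2],
      ref_id = refs %||% paste0("t", seq_len(nrow(iv))),
      ref_start = 0L, ref_end = iv[, 2] - iv[, 1], strand = "+"
    )
  }
  s1 <- merge_read_segments(mk_al(cbind(c(0L, 18L), c(20L, 40L))))
  expect_equal(nrow(s1$segments), 2L)
  expect_true(s1$reads$is_chimeric)

  s2 <- merge_read_segments(mk_al(cbind(c(0L, 2L), c(20L, 21L))))
  expect_equal(nrow(s2$segments), 1L)
  expect_false(s2$reads$is_chimeric)
  expect_equal(s2$segments$read_start, 0L)
  expect_equal(s2$segments$read_end, 21L)
  expect_equal(s2$segments$n_candidates, 2L)

  s3 <- merge_read_segments(mk_al(cbind(c(0L, 1L, 25L), c(20L, 20L, 45L))))
  expect_equal(nrow(s3$segments), 2L)
  expect_true(s3$reads$is_chimeric)
  # every alignment in exactly one segment
  expect_false(anyNA(s3$alignments$segment_id))
  # segment indices follow read order
  expect_equal(s3$segments$segment_index, c(1L, 2L))
})
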