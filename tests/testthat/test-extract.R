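# hand-built quantification world: three CRLs, one locus each
mk_world <- function(seg_tbl, post) {
  post <- Matrix::Matrix(post, sparse = TRUE)
  crls <- tibble::tibble(
    crl_id = colnames(post),
    member_loci = as.list(sub("C", "L", colnames(post))),
    n_members = 1L,
    read_set = rep(list(rownames(post)), ncol(post)),
    n_reads = nrow(post)
  )
  loci <- tibble::tibble(
    locus_id = sub("C", "L", colnames(post)),
    chrom = sub("C", "t", colnames(post)), strand = "+",
    start = 0L, end = 100L, blocks = list(cbind(0L, 100L)),
    n_segments = 3L, segments = rep(list(rownames(post)), ncol(post))
  )
  rho <- setNames(rep(1 / ncol(post), ncol(post)), colnames(post))
  fit <- structure(list(rho = rho, posterior = post, tpm = rho * 1e6),
                   class = "crl_quant")
  al <- seg_tbl |>
    dplyr::mutate(ref_id = sub("L", "t", .data$locus_id),
                  ref_start = 10L,
                  ref_end = 10L + .data$read_end - .data$read_start,
                  cigar = paste0(.data$read_end - .data$read_start, "M"))
  list(segmentation = list(segments = seg_tbl, alignments = al),
       fit = fit, crls = crls, loci = loci)
}

test_that("the two most probable non-overlapping arms are selected", {
  post <- rbind(
    "r1::s1" = c(0.9, 0.1, 0.0),
    "r1::s2" = c(0.2, 0.8, 0.0),
    "r1::s3" = c(0.3, 0.3, 0.4)
  )
  colnames(post) <- c("C1", "C2", "C3")
  segs <- tibble::tibble(
    segment_id = rownames(post), read_id = "r1", segment_index = 1:3,
    read_start = c(0L, 25L, 50L), read_end = c(20L, 45L, 60L),
    n_candidates = 1L,
    locus_id = c("L1", "L2", "L3")
  )
  w <- mk_world(segs, post)
  res <- select_arms(w$segmentation, w$fit, w$crls, w$loci)
  expect_equal(nrow(res$interactions), 1L)
  rec <- res$interactions
  # pair (0.9, 0.8) wins over (0.9, 0.4) and (0.8, 0.4)
  expect_equal(rec$arm1_crl_id, "C1")
  expect_equal(rec$arm2_crl_id, "C2")
  expect_equal(rec$score, 0.72)
  expect_equal(rec$score, rec$arm1_posterior * rec$arm2_posterior)
  # arm1 is the smaller read start
  expect_lt(rec$arm1_read_start, rec$arm2_read_start)
  expect_equal(nrow(res$singletons), 0L)
})

test_that("two-segment reads use those arms; singletons yield no record", {
  post <- rbind("r1::s1" = c(1, 0), "r1::s2" = c(0, 1), "r2::s1" = c(1, 0))
  colnames(post) <- c("C1", "C2")
  segs <- tibble::tibble(
    segment_id = rownames(post),
    read_id = c("r1", "r1", "r2"),
    segment_index = c(1L, 2L, 1L),
    read_start = c(0L, 20L, 0L), read_end = c(18L, 40L, 30L),
    n_candidates = 1L,
    locus_id = c("L1", "L2", "L1")
  )
  w <- mk_world(segs, post)
  res <- select_arms(w$segmentation, w$fit, w$crls, w$loci)
  expect_equal(res$interactions$read_id, "r1")
  expect_equal(res$interactions$score, 1)
  expect_true(res$interactions$arm1_unique)
  expect_equal(res$singletons$read_id, "r2")
})

mk_models <- function() {
  tibble::tibble(
    transcript_id = c("mrna_plus", "mrna_minus", "mir1"),
    gene_id = c("gA", "gB", "gM"),
    gene_symbol = c("A", "B", "M"),
    biotype = c("protein_coding", "protein_coding", "miRNA"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    exons = list(cbind(start = 0L, end = 300L),
                 cbind(start = 0L, end = 300L),
                 cbind(start = 0L, end = 22L)),
    tx_len = c(300L, 300L, 22L),
    cds_start = c(100L, 100L, NA),
    cds_end = c(200L, 200L, NA)
  )
}

mk_interaction <- function(ref1, s1, e1, ref2 = "mir1", s2 = 0L, e2 = 20L) {
  tibble::tibble(
    read_id = "r1",
    arm1_ref_id = ref1, arm1_locus_id = "L1", arm1_crl_id = "C1",
    arm1_gene_id = NA_character_, arm1_gene_symbol = NA_character_,
    arm1_biotype = NA_character_, arm1_region = "unannotated",
    arm1_ref_start = s1, arm1_ref_end = e1,
    arm1_read_start = 0L, arm1_read_end = e1 - s1,
    arm1_cigar = "20M", arm1_posterior = 1, arm1_tpm = 1e6, arm1_unique = TRUE,
    arm2_ref_id = ref2, arm2_locus_id = "L2", arm2_crl_id = "C2",
    arm2_gene_id = NA_character_, arm2_gene_symbol = NA_character_,
    arm2_biotype = NA_character_, arm2_region = "unannotated",
    arm2_ref_start = s2, arm2_ref_end = e2,
    arm2_read_start = 20L, arm2_read_end = 40L,
    arm2_cigar = "20M", arm2_posterior = 1, arm2_tpm = 1e6, arm2_unique = TRUE,
    score = 1, hybrid = NA_character_, energy = NA_real_
  )
}

test_that("arms are annotated by midpoint relative to the CDS", {
  m <- mk_models()
  # + strand mRNA: midpoint 40 < CDS start 100 -> 5'UTR
  a <- annotate_interactions(mk_interaction("mrna_plus", 30L, 50L), m)
  expect_equal(a$arm1_region, "5UTR")
  expect_equal(a$arm1_gene_symbol, "A")
  expect_equal(a$arm2_region, "noncoding")  # miRNA biotype
  # midpoint inside CDS
  b <- annotate_interactions(mk_interaction("mrna_plus", 140L, 160L), m)
  expect_equal(b$arm1_region, "CDS")
  # midpoint past CDS end -> 3'UTR
  d <- annotate_interactions(mk_interaction("mrna_plus", 240L, 260L), m)
  expect_equal(d$arm1_region, "3UTR")
  # minus strand: transcript coordinates already run 5'->3', so the same
  # midpoint rule applies; genomic CDS [100,200) maps to tx [100,200)
  e <- annotate_interactions(mk_interaction("mrna_minus", 40L, 60L), m)
  expect_equal(e$arm1_region, "5UTR")
  # transcript absent from the annotation stays unannotated
  f <- annotate_interactions(mk_interaction("unknown_tx", 0L, 20L), m)
  expect_equal(f$arm1_region, "unannotated")
  expect_true(is.na(f$arm1_gene_id))
  # no models: no-op
  g <- annotate_interactions(mk_interaction("mrna_plus", 0L, 20L), NULL)
  expect_equal(g$arm1_region, "unannotated")
})

test_that("hybridize honours its external-tool contract", {
  expect_error(hybridize("", "ACGU"), "empty sequence")
  out <- hybridize("ACGUACGU", "UGCAUGCA", command = NULL)
  expect_true(is.na(out$hybrid))
  expect_true(is.na(out$energy))
  out2 <- hybridize("ACGUACGU", "UGCAUGCA", command = "no-such-hybridizer")
  expect_true(is.na(out2$hybrid))
})

test_that("score filtering is monotone and respects the threshold", {
  recs <- dplyr::bind_rows(mk_interaction("a", 0L, 20L),
                           mk_interaction("b", 0L, 20L))
  recs$score <- c(0.72, 0.4)
  expect_equal(nrow(filter_interactions(recs, 0.5)), 1L)
  expect_equal(nrow(filter_interactions(recs, 0)), 2L)
  expect_warning(out <- filter_interactions(recs, 0, require_hybrid = TRUE),
                 "hybrid")
  expect_equal(nrow(out), 0L)
  # raising the threshold never increases the record count
  ns <- purrr::map_int(seq(0, 1, by = 0.1),
                       ~nrow(filter_interactions(recs, .x)))
  expect_true(all(diff(ns) <= 0))
})
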