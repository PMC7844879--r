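test_that("make_reference builds seeded paralog families", {
  refs <- make_reference(n_families = 4L, family_size = 3L,
                         divergence = 0, seed = 3L)
  expect_equal(nrow(refs), 4L * 3L * 2L)  # both databases
  # divergence 0: family members identical
  fam <- refs[refs$family == "tgt001", ]
  expect_equal(length(unique(fam$sequence)), 1L)
  # founders distinct across families
  founders <- refs[refs$member == 1L, ]
  expect_equal(anyDuplicated(founders$sequence), 0L)
  # length regimes
  expect_true(all(nchar(refs$sequence[refs$ref_db == 1]) <= 25))
  expect_true(all(nchar(refs$sequence[refs$ref_db == 2]) >= 50))
  # determinism
  expect_identical(refs, make_reference(n_families = 4L, family_size = 3L,
                                        divergence = 0, seed = 3L))
  # family_size 1: no paralogy
  solo <- make_reference(n_families = 3L, family_size = 1L, seed = 1L)
  expect_true(all(solo$expressed))
  expect_error(make_reference(divergence = 1.5), "divergence")
})

test_that("chimeric reads fuse arms as stated, with optional 5-nt inserts", {
  refs <- make_reference(n_families = 5L, family_size = 2L,
                         divergence = 0.05, seed = 11L)
  sim <- make_chimeric_reads(refs, 40L, arm_length = 20L, seed = 11L)
  expect_equal(nrow(sim$reads), 40L)
  expect_equal(nrow(sim$truth), 40L)
  # miRNA-like refs here are 18-25 nt, so arm1 is min(20, ref len)
  ref_len <- nchar(refs$sequence[match(sim$truth$ref_id1, refs$ref_id)])
  expect_equal(sim$truth$ref_end1 - sim$truth$ref_start1,
               pmin(20L, ref_len))
  expect_equal(sim$truth$ref_end2 - sim$truth$ref_start2, rep(20L, 40L))
  # read is the direct fusion of the two true substrings
  seqs <- refs$sequence
  names(seqs) <- refs$ref_id
  arm1 <- substr(seqs[sim$truth$ref_id1], sim$truth$ref_start1 + 1L,
                 sim$truth$ref_end1)
  arm2 <- substr(seqs[sim$truth$ref_id2], sim$truth$ref_start2 + 1L,
                 sim$truth$ref_end2)
  expect_equal(unname(paste0(arm1, arm2)), sim$reads$sequence)

  ins <- make_chimeric_reads(refs, 40L, arm_length = 20L, insert = TRUE,
                             seed = 12L)
  a1 <- substr(seqs[ins$truth$ref_id1], ins$truth$ref_start1 + 1L,
               ins$truth$ref_end1)
  a2 <- substr(seqs[ins$truth$ref_id2], ins$truth$ref_start2 + 1L,
               ins$truth$ref_end2)
  expect_equal(nchar(ins$reads$sequence),
               unname(nchar(a1) + nchar(a2) + 5L))
  # insert placement: arms always remain contiguous in the stated order
  for (i in seq_len(10)) {
    expect_true(grepl(
      switch(ins$truth$insert_pos[i],
             between = paste0("^", a1[i], ".{5}", a2[i], "$"),
             start = paste0("^.{5}", a1[i], a2[i], "$"),
             end = paste0("^", a1[i], a2[i], ".{5}$")),
      ins$reads$sequence[i]
    ))
  }
  expect_error(make_chimeric_reads(refs, 0L), "positive")
})

test_that("the toy mapper reports exactly the maximal exact matches", {
  refs <- tibble::tibble(
    ref_id = c("tA", "tB"),
    sequence = c("AACCGGTTACGTACGTACGTTTTT", "GGGGACGTACGTACGTGGGGGGGG"),
    ref_db = c(1L, 2L)
  )
  # read = 16 nt from tA (positions 8..24) — also matches tB at 4..16 (12 nt)
  reads <- tibble::tibble(read_id = "r1", sequence = "ACGTACGTACGTTTTT")
  out <- toy_map_reads(reads, refs, min_match = 10L)
  hitA <- out[out$ref_id == "tA", ]
  expect_equal(nrow(hitA), 1L)
  expect_equal(c(hitA$read_start, hitA$read_end), c(0L, 16L))
  expect_equal(c(hitA$ref_start, hitA$ref_end), c(8L, 24L))
  hitB <- out[out$ref_id == "tB", ]
  expect_equal(nrow(hitB), 1L)
  expect_equal(c(hitB$read_start, hitB$read_end), c(0L, 12L))
  expect_equal(c(hitB$ref_start, hitB$ref_end), c(4L, 16L))
  expect_true(all(out$strand == "+"))
  # CIGAR soft clips agree with the read interval
  expect_equal(hitB$cigar, "12M4S")
  # sub-minimum matches are absent
  none <- toy_map_reads(tibble::tibble(read_id = "r2", sequence = "ACGTACGTA"),
                        refs, min_match = 10L)
  expect_equal(nrow(none), 0L)
})

test_that("identical paralog copies multi-map in the toy mapper", {
  refs <- make_reference(n_families = 3L, family_size = 3L, divergence = 0,
                         seed = 9L)
  sim <- make_chimeric_reads(refs, 20L, arm_length = 18L, seed = 9L)
  out <- toy_map_reads(sim$reads, refs, min_match = 10L)
  # every target arm must hit all three identical family copies
  tgt_hits <- out |>
    dplyr::filter(.data$ref_db == 2L) |>
    dplyr::count(.data$read_id, .data$read_start)
  expect_true(all(tgt_hits$n >= 3L))
})

test_that("the seven categories partition hand-built fixtures one each", {
  truth <- tibble::tibble(
    read_id = paste0("r", 1:7),
    ref_id1 = "m1", ref_start1 = 0L, ref_end1 = 20L,
    ref_id2 = "t1", ref_start2 = 10L, ref_end2 = 30L,
    arm_length = 20L, has_insert = FALSE, insert_pos = NA_character_
  )
  pred <- dplyr::bind_rows(
    # r1 perfect: both arms unique, exact
    tibble::tibble(read_id = "r1", arm_index = 1:2,
                   ref_id = c("m1", "t1"),
                   ref_start = c(0L, 10L), ref_end = c(20L, 30L),
                   unique = TRUE),
    # r2 partial_multi: arm2 multi-mapped but agreed
    tibble::tibble(read_id = "r2", arm_index = c(1L, 2L, 2L),
                   ref_id = c("m1", "t1", "tX"),
                   ref_start = c(0L, 10L, 50L), ref_end = c(20L, 30L, 70L),
                   unique = c(TRUE, FALSE, FALSE)),
    # r3 both_multi
    tibble::tibble(read_id = "r3", arm_index = c(1L, 1L, 2L, 2L),
                   ref_id = c("m1", "mX", "t1", "tX"),
                   ref_start = c(0L, 0L, 10L, 0L),
                   ref_end = c(20L, 20L, 30L, 20L),
                   unique = FALSE),
    # r4 partial_wrong: arm2 on the wrong reference
    tibble::tibble(read_id = "r4", arm_index = 1:2,
                   ref_id = c("m1", "tZ"),
                   ref_start = c(0L, 10L), ref_end = c(20L, 30L),
                   unique = TRUE),
    # r5 both_wrong: arm1 wrong ref; arm2 only 75% overlap (< 80%)
    tibble::tibble(read_id = "r5", arm_index = 1:2,
                   ref_id = c("mZ", "t1"),
                   ref_start = c(0L, 15L), ref_end = c(20L, 35L),
                   unique = TRUE),
    # r6 partial_miss: arm2 unmapped
    tibble::tibble(read_id = "r6", arm_index = 1L, ref_id = "m1",
                   ref_start = 0L, ref_end = 20L, unique = TRUE)
    # r7 both_miss: absent entirely
  )
  counts <- categorize_reads(pred, truth)
  expect_equal(sum(counts$n), 7L)
  expect_equal(counts$n, rep(1L, 7))
  expect_equal(as.character(counts$category),
               c("perfect", "partial_multi", "both_multi", "partial_wrong",
                 "both_wrong", "partial_miss", "both_miss"))
  # an arm overlapping 75% of truth is not agreed
  just_under <- categorize_reads(
    tibble::tibble(read_id = "r1", arm_index = 1:2,
                   ref_id = c("m1", "t1"),
                   ref_start = c(5L, 10L), ref_end = c(25L, 30L),
                   unique = TRUE),
    truth[1, ]
  )
  expect_equal(just_under$n[just_under$category == "partial_wrong"], 1L)
  # predictions for unknown reads are an error
  expect_error(
    categorize_reads(
      tibble::tibble(read_id = "ghost", arm_index = 1L, ref_id = "m1",
                     ref_start = 0L, ref_end = 20L, unique = TRUE),
      truth),
    "absent from truth"
  )
})

test_that("category counts always partition simulated read sets", {
  w <- benchmark_world(seed = 21L, n_reads = 60L)
  res <- chim_run(w$reads, refs = w$refs, config = chim_config(seed = 21L))
  counts <- categorize_reads(
    chira_predictions(res$interactions |>
                        dplyr::semi_join(w$sim$truth, by = "read_id")),
    w$sim$truth)
  expect_equal(sum(counts$n), nrow(w$sim$truth))
  naive <- categorize_reads(naive_predictions(res$alignments |>
                                                dplyr::semi_join(w$sim$truth, by = "read_id")),
                            w$sim$truth)
  expect_equal(sum(naive$n), nrow(w$sim$truth))
})
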