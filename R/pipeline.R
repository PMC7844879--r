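#' Pipeline configuration
#'
#' Collects every stage threshold with its published default. All fraction
#' parameters must lie in (0,1]; validation happens here, before any work.
#'
#' @param min_length Minimum read length kept at deduplication (nt).
#' @param umi_length UMI length split off read 5' ends (0 = no UMI).
#' @param min_match Minimum exact-match length of the built-in toy mapper.
#' @param reciprocal_overlap Reciprocal-overlap fraction for merging
#'   alignments into expressed loci (strict >).
#' @param segment_overlap Overlap fraction for merging a read's alignments
#'   into read segments (inclusive >=).
#' @param crl_share Jaccard threshold for CRL membership (strict >).
#' @param epsilon EM convergence tolerance (L1 change of abundances).
#' @param max_iter EM iteration cap.
#' @param max_alternatives Maximum XA alternatives expanded per record.
#' @param score_min Minimum interaction score written (0 keeps all; the
#'   published analyses used 0.5).
#' @param agree_overlap Benchmark agreement overlap fraction.
#' @param seed Integer seed for every stochastic component (the analysis
#'   path itself is deterministic; only the simulator draws).
#' @return A validated list of class `chim_config`.
#' @export
chim_config <- function(min_length = 10L, umi_length = 0L, min_match = 10L,
                        reciprocal_overlap = 0.7, segment_overlap = 0.7,
                        crl_share = 0.7, epsilon = 1e-5, max_iter = 1000L,
                        max_alternatives = 100L, score_min = 0,
                        agree_overlap = 0.8, seed = 1L) {
  cfg <- list(
    min_length = as.integer(min_length), umi_length = as.integer(umi_length),
    min_match = as.integer(min_match),
    reciprocal_overlap = reciprocal_overlap,
    segment_overlap = segment_overlap, crl_share = crl_share,
    epsilon = epsilon, max_iter = as.integer(max_iter),
    max_alternatives = as.integer(max_alternatives),
    score_min = score_min, agree_overlap = agree_overlap,
    seed = as.integer(seed)
  )
  for (nm in c("reciprocal_overlap", "segment_overlap", "crl_share",
               "agree_overlap")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v > 1) {
      abort(paste0(nm, " must be a fraction in (0,1], got ", v))
    }
  }
  if (cfg$score_min < 0 || cfg$score_min > 1) {
    abort("score_min must be in [0,1]")
  }
  if (cfg$epsilon <= 0) abort("epsilon must be positive")
  if (cfg$min_length < 0 || cfg$umi_length < 0) {
    abort("lengths must be non-negative")
  }
  if (cfg$max_iter < 1 || cfg$max_alternatives < 1) {
    abort("max_iter and max_alternatives must be at least 1")
  }
  structure(cfg, class = "chim_config")
}

#' Run the full chimeric-read workflow
#'
#' Executes the stages in order: deduplication, mapping (or ingesting
#' pre-made alignments), alignment post-processing, read-segment and
#' expressed-locus merging, CRL construction, EM quantification, arm
#' selection/annotation/scoring. Re-running with the same inputs and
#' configuration is bit-identical: every stage uses canonical sort orders
#' and the single config seed.
#'
#' @param reads A read tibble ([read_fastx()] schema) or a FASTA/FASTQ
#'   path.
#' @param alignments Optional pre-made alignment tibble (e.g. from
#'   [parse_sam()] or [toy_map_reads()]) on the *deduplicated* read ids.
#' @param sam_files Optional tibble/data frame with columns `path`,
#'   `pass_id`, `ref_db` of SAM files to parse (raw-read or deduplicated
#'   ids must match).
#' @param refs Optional reference tibble; when given and no alignments are
#'   supplied, the built-in exact toy mapper is used.
#' @param models Optional transcript models from [parse_gtf()]; lifts
#'   alignments to genomic coordinates and enables arm annotation.
#' @param config A [chim_config()].
#' @param out_dir Optional output directory; when given,
#'   `interactions.tsv`, `loci.bed`, `crls.tsv`, `quant.tsv`,
#'   `summary.json` and `run.log` are written (all but `run.log` are
#'   deterministic; timings live in the log only).
#' @return List with `reads`, `dedup_report`, `alignments`, `segmentation`,
#'   `loci`, `crls`, `fit`, `interactions`, `singletons`, `summary`.
#' @export
chim_run <- function(reads, alignments = NULL, sam_files = NULL,
                     refs = NULL, models = NULL, config = chim_config(),
                     out_dir = NULL) {
  stopifnot(inherits(config, "chim_config"))
  t0 <- Sys.time()
  timings <- list()
  tick <- function(stage) {
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    t0 <<- Sys.time()
  }

  if (is.character(reads)) {
    reads <- read_fastx(reads, umi_length = if (config$umi_length > 0)
      config$umi_length else NULL)
  }
  dd <- deduplicate_reads(reads, min_length = config$min_length)
  tick("dedup")

  if (is.null(alignments)) {
    if (!is.null(sam_files)) {
      alignments <- purrr::pmap_dfr(
        as.data.frame(sam_files),
        function(path, pass_id, ref_db, ...) {
          parse_sam(path, expand_xa = TRUE,
                    max_alternatives = config$max_alternatives,
                    pass_id = pass_id, ref_db = ref_db)
        }
      )
    } else if (!is.null(refs)) {
      alignments <- toy_map_reads(dd$reads, refs,
                                  min_match = config$min_match)
    } else {
      abort("supply alignments, sam_files or refs (for the toy mapper)")
    }
  }
  alignments <- postprocess_alignments(alignments)
  tick("map")

  if (!nrow(alignments)) {
    abort("no alignments survive post-processing; nothing to quantify")
  }
  seg <- merge_read_segments(alignments, config$segment_overlap)
  lifted <- lift_alignments(seg$alignments, models)
  ml <- merge_into_loci(lifted, config$reciprocal_overlap)
  seg$alignments <- ml$alignments
  tick("loci")

  crls <- build_crls(ml$loci, config$crl_share)
  tick("crl")

  fit <- em_quantify(build_y(ml$alignments, crls),
                     epsilon = config$epsilon, max_iter = config$max_iter)
  tick("quant")

  sel <- select_arms(seg, fit, crls, ml$loci,
                     segment_overlap = config$segment_overlap)
  interactions <- annotate_interactions(sel$interactions, models) |>
    filter_interactions(score_threshold = config$score_min)
  tick("extract")

  # copy-weighted accounting so that duplicates collapsed at dedup still
  # count: chimeric + singleton + unmapped + too-short = raw input reads
  copies <- setNames(dd$reads$copy_count, dd$reads$read_id)
  mapped_ids <- unique(alignments$read_id)
  chim_ids <- unique(interactions$read_id)
  single_ids <- setdiff(mapped_ids, chim_ids)
  summary <- list(
    input_reads = dd$report$input_reads,
    discarded_short = dd$report$discarded_short,
    deduplicated_reads = dd$report$output_reads,
    mapped_reads = sum(copies[mapped_ids]),
    unmapped_reads = sum(copies) - sum(copies[mapped_ids]),
    chimeric_reads = sum(copies[chim_ids]),
    singleton_reads = sum(copies[single_ids]),
    n_loci = nrow(ml$loci),
    n_crls = nrow(crls),
    em = as.list(glance(fit)),
    config = unclass(config)
  )

  res <- list(
    reads = dd$reads, dedup_report = dd$report, alignments = alignments,
    segmentation = seg, loci = ml$loci, crls = crls, fit = fit,
    interactions = interactions, singletons = sel$singletons,
    summary = summary
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_interactions(interactions, file.path(out_dir, "interactions.tsv"))
    write_bed(ml$loci, file.path(out_dir, "loci.bed"))
    readr::write_tsv(
      crls |> mutate(member_loci = purrr::map_chr(.data$member_loci, paste,
                                                  collapse = ",")) |>
        select("crl_id", "n_members", "n_reads", "member_loci"),
      file.path(out_dir, "crls.tsv"), progress = FALSE
    )
    readr::write_tsv(tidy(fit), file.path(out_dir, "quant.tsv"),
                     progress = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(
      c(sprintf("chimloci run %s", format(Sys.time())),
        sprintf("config: %s",
                jsonlite::toJSON(unclass(config), auto_unbox = TRUE)),
        sprintf("stage %s: %.3fs", names(timings), unlist(timings))),
      file.path(out_dir, "run.log")
    )
  }
  res
}
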