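#' Post-process chimeric alignments
#'
#' Applies the three alignment filters used after (2-pass) mapping:
#'
#' 1. only alignments on the *sense* reference strand are kept (interactome
#'    libraries are strand-specific, so antisense hits are artefacts);
#' 2. within each alternative group (a primary record plus its expanded XA
#'    hits) only the alternatives with the *highest read coverage* — the
#'    longest aligned read interval — survive; equally long alternatives are
#'    all kept for later multi-mapping resolution;
#' 3. a pass-2 segment that duplicates a pass-1 segment (same read id, read
#'    interval, reference and reference interval) is removed.
#'
#' The operation is idempotent, order-independent (output in canonical
#' order) and never fabricates segments.
#'
#' @param segments Alignment-segment tibble from [parse_sam()] (one or
#'   several files row-bound).
#' @return Filtered alignment-segment tibble.
#' @export
postprocess_alignments <- function(segments) {
  if (!nrow(segments)) return(segments)
  out <- segments |>
    filter(.data$strand == "+") |>
    group_by(.data$group_id) |>
    filter(.data$read_end - .data$read_start ==
             max(.data$read_end - .data$read_start)) |>
    ungroup() |>
    arrange(.data$pass_id, .data$read_id, .data$read_start, .data$read_end,
            .data$ref_id, .data$ref_start, .data$ref_end, .data$ref_db) |>
    distinct(.data$read_id, .data$read_start, .data$read_end, .data$ref_id,
             .data$ref_start, .data$ref_end, .data$ref_db,
             .keep_all = TRUE) |>
    arrange(.data$read_id, .data$read_start, .data$read_end, .data$ref_id,
            .data$ref_start, .data$ref_end, .data$ref_db)
  out
}

#' Two-pass alignment contract for an external aligner
#'
#' The first pass targets long, gapped chimeric segments (high score
#' threshold); the second pass rescues short segments with perfect matches
#' (low threshold, insertions/deletions forbidden via prohibitive gap
#' penalties) and requests up to `max_alternatives` suboptimal hits so that
#' true locations buried in the XA tag are not lost. The defaults are
#' configuration values, not correctness requirements.
#'
#' @param executable Aligner executable (default `"bwa"`); set to a full
#'   path or `NULL`.
#' @param pass1_params,pass2_params Parameter strings passed verbatim to
#'   `bwa mem`.
#' @param max_alternatives Maximum XA hits requested in pass 2.
#' @return A list of class `aligner_contract`.
#' @export
aligner_contract <- function(executable = "bwa",
                             pass1_params = "-k 12 -T 20",
                             pass2_params = "-k 8 -T 10 -O 100 -E 100",
                             max_alternatives = 100L) {
  structure(
    list(executable = executable, pass1_params = pass1_params,
         pass2_params = paste(pass2_params, "-h", max_alternatives),
         max_alternatives = as.integer(max_alternatives)),
    class = "aligner_contract"
  )
}

#' Run the external two-pass aligner
#'
#' Thin subprocess hook around `bwa mem`; fully bypassable by supplying
#' pre-made SAM files to the pipeline, so no test or offline run needs the
#' binary. With a split reference (two FASTA files) each pass is run against
#' each reference, yielding 2x2 SAM files.
#'
#' @param reads_fa FASTA of (deduplicated) reads.
#' @param references Character vector of 1 or 2 reference FASTA paths.
#' @param contract An [aligner_contract()].
#' @param out_dir Directory for index and SAM output.
#' @return Tibble with `pass_id`, `ref_db` and `sam` (paths).
#' @export
run_two_pass <- function(reads_fa, references, contract = aligner_contract(),
                         out_dir = tempfile("twopass")) {
  exe <- contract$executable
  if (is.null(exe) || Sys.which(exe) == "") {
    abort(paste0(
      "external aligner unavailable (", exe %||% "none",
      "); supply pre-made SAM alignments instead (sam1=/sam2= inputs)"
    ))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  runs <- tidyr::expand_grid(pass_id = 1:2, ref_db = seq_along(references))
  runs$sam <- purrr::pmap_chr(runs, function(pass_id, ref_db) {
    prefix <- file.path(out_dir, paste0("ref", ref_db))
    if (!file.exists(paste0(prefix, ".bwt"))) {
      status <- system2(exe, c("index", "-p", prefix, references[ref_db]),
                        stdout = FALSE, stderr = FALSE)
      if (status != 0L) abort(paste0("bwa index failed for ", references[ref_db]))
    }
    params <- if (pass_id == 1L) contract$pass1_params else contract$pass2_params
    sam <- file.path(out_dir, sprintf("pass%d_ref%d.sam", pass_id, ref_db))
    status <- system2(exe, c("mem", strsplit(params, "\\s+")[[1]],
                             prefix, reads_fa),
                      stdout = sam, stderr = FALSE)
    if (status != 0L) abort(paste0("bwa mem failed (pass ", pass_id, ")"))
    sam
  })
  runs
}
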