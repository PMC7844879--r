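#' Read sequencing reads from FASTA or FASTQ
#'
#' Parses a (possibly gzip-compressed) FASTA or FASTQ file into a tibble of
#' read records. If `umi_length` is given, the first `umi_length` bases of
#' every read are split off into the `umi` column and removed from
#' `sequence`, mirroring libraries where the unique molecular identifier is
#' ligated to the 5' end of the fragment.
#'
#' @param path Path to a FASTA/FASTQ file, plain or gzipped. Format is
#'   auto-detected from the first non-empty character (`>` vs `@`).
#' @param umi_length Optional integer; number of leading bases that form the
#'   UMI. Reads not longer than `umi_length` are skipped with a warning.
#' @return A tibble with columns `read_id`, `sequence`, `quality` (NA for
#'   FASTA), `umi` (NA when no UMI is configured) and `copy_count`
#'   (initialised to 1; see [deduplicate_reads()]).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">r1", "ACGTACGT", ">r2", "NNNNNACGTACGTACGT"), fa)
#' read_fastx(fa)
#' read_fastx(fa, umi_length = 5)
#' @export
read_fastx <- function(path, umi_length = NULL) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  con <- gzfile(path, "rt")
  on.exit(close(con))
  first <- ""
  while (!length(first) || first == "") {
    first <- readLines(con, n = 1L)
    if (!length(first)) abort(paste0("empty file: ", path))
  }
  close(con)
  on.exit(NULL)
  fmt <- if (startsWith(first, ">")) "fasta"
         else if (startsWith(first, "@")) "fastq"
         else abort(paste0("not FASTA/FASTQ (first line: ", substr(first, 1, 30), "): ", path))

  if (fmt == "fasta") {
    seqs <- Biostrings::readBStringSet(path, format = "fasta")
    qual <- rep(NA_character_, length(seqs))
  } else {
    # metadata columns (the FASTQ description) are dropped on purpose
    qs <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
    seqs <- Biostrings::BStringSet(qs)
    qual <- as.character(Biostrings::quality(qs))
  }
  ids <- sub("\\s.*$", "", names(seqs))
  reads <- tibble(
    read_id = unname(ids),
    sequence = unname(toupper(as.character(seqs))),
    quality = unname(qual)
  )
  bad <- nchar(reads$sequence) == 0L
  if (any(bad)) {
    abort(paste0("zero-length record(s) in ", path, ": ",
                 paste(reads$read_id[bad], collapse = ", ")))
  }
  reads$umi <- NA_character_
  if (!is.null(umi_length)) {
    umi_length <- as.integer(umi_length)
    stopifnot(umi_length >= 0L)
    if (umi_length > 0L) {
      short <- nchar(reads$sequence) <= umi_length
      if (any(short)) {
        warn(paste0(sum(short), " read(s) not longer than the UMI (",
                    umi_length, " nt) skipped"))
        reads <- reads[!short, ]
      }
      reads$umi <- substr(reads$sequence, 1L, umi_length)
      reads$sequence <- substr(reads$sequence, umi_length + 1L,
                               nchar(reads$sequence))
      if (!all(is.na(reads$quality))) {
        reads$quality <- substr(reads$quality, umi_length + 1L,
                                nchar(reads$quality) + umi_length)
      }
    }
  }
  reads$copy_count <- 1L
  reads
}

#' Write reads to FASTA
#'
#' @param reads Tibble with `read_id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reads, path) {
  x <- Biostrings::BStringSet(setNames(reads$sequence, reads$read_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
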