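#' Parse SAM alignments into alignment segments
#'
#' Converts every mapped primary/secondary/supplementary SAM record into one
#' alignment-segment row, recovering the aligned read interval from the CIGAR
#' soft/hard clips. When `expand_xa` is `TRUE`, every entry of the BWA-style
#' `XA` auxiliary tag (`"ref,±pos,CIGAR,NM;"`) becomes an additional segment
#' belonging to the same alternative group as its parent record; a negative
#' position encodes the minus strand (BWA convention).
#'
#' All coordinates in the result are 0-based half-open, both on the read and
#' on the reference.
#'
#' @param path Path to a SAM file (with a header naming all references).
#' @param expand_xa Expand `XA` alternative hits into their own rows?
#' @param max_alternatives Keep at most this many `XA` entries per record.
#' @param pass_id Which alignment pass produced this file (1 or 2); stored.
#' @param ref_db Which split reference this file was aligned against (1 or
#'   2); stored.
#' @return A tibble of alignment segments with columns `read_id`,
#'   `read_start`, `read_end`, `ref_id`, `ref_start`, `ref_end`, `strand`,
#'   `cigar`, `score` (the `AS` tag, NA when absent), `nm`, `pass_id`,
#'   `ref_db`, `group_id` (primary record and its XA alternatives share one
#'   group) and `source` (`"primary"` or `"xa"`).
#' @export
parse_sam <- function(path, expand_xa = TRUE, max_alternatives = 100L,
                      pass_id = 1L, ref_db = 1L) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam))
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "cigar", "seq"),
    tag = c("XA", "AS", "NM")
  )
  r <- Rsamtools::scanBam(bam, param = p)[[1]]

  mapped <- !bitwAnd(r$flag, 4L) & !is.na(r$pos)
  if (!any(mapped)) {
    return(empty_segments())
  }
  idx <- which(mapped)
  if (any(as.character(r$seq[idx]) == "" &
          !bitwAnd(r$flag[idx], 256L) & !bitwAnd(r$flag[idx], 2048L))) {
    warn("primary record(s) without sequence; read intervals taken from CIGAR")
  }
  cig <- r$cigar[idx]
  strand <- as.character(r$strand[idx])
  cb <- cigar_read_bounds(cig, strand)
  prim <- tibble(
    read_id = r$qname[idx],
    read_start = cb$read_start,
    read_end = cb$read_end,
    ref_id = as.character(r$rname[idx]),
    ref_start = r$pos[idx] - 1L,
    ref_end = r$pos[idx] - 1L + cb$ref_len,
    strand = strand,
    cigar = cig,
    score = as.integer(r$tag$AS[idx] %||% rep(NA_integer_, length(idx))),
    nm = as.integer(r$tag$NM[idx] %||% rep(NA_integer_, length(idx))),
    pass_id = as.integer(pass_id),
    ref_db = as.integer(ref_db),
    group_id = paste0(r$qname[idx], "/g", seq_along(idx)),
    source = "primary"
  )

  xa_str <- r$tag$XA[idx] %||% rep(NA_character_, length(idx))
  if (!expand_xa || all(is.na(xa_str))) {
    return(prim)
  }
  has_xa <- which(!is.na(xa_str) & xa_str != "")
  alts <- purrr::map(has_xa, function(i) {
    entries <- strsplit(xa_str[i], ";", fixed = TRUE)[[1]]
    entries <- head(entries[entries != ""], max_alternatives)
    if (!length(entries)) return(NULL)
    f <- strsplit(entries, ",", fixed = TRUE)
    bad <- lengths(f) != 4L
    if (any(bad)) {
      abort(paste0("malformed XA entry for read ", prim$read_id[i], ": ",
                   paste(entries[bad], collapse = " ")))
    }
    f <- do.call(rbind, f)
    astrand <- ifelse(startsWith(f[, 2], "-"), "-", "+")
    apos <- as.integer(sub("^[+-]", "", f[, 2]))
    acb <- cigar_read_bounds(f[, 3], astrand)
    tibble(
      read_id = prim$read_id[i],
      read_start = acb$read_start,
      read_end = acb$read_end,
      ref_id = f[, 1],
      ref_start = apos - 1L,
      ref_end = apos - 1L + acb$ref_len,
      strand = astrand,
      cigar = f[, 3],
      score = NA_integer_,
      nm = as.integer(f[, 4]),
      pass_id = as.integer(pass_id),
      ref_db = as.integer(ref_db),
      group_id = prim$group_id[i],
      source = "xa"
    )
  })
  bind_rows(prim, bind_rows(alts))
}

empty_segments <- function() {
  tibble(
    read_id = character(), read_start = integer(), read_end = integer(),
    ref_id = character(), ref_start = integer(), ref_end = integer(),
    strand = character(), cigar = character(), score = integer(),
    nm = integer(), pass_id = integer(), ref_db = integer(),
    group_id = character(), source = character()
  )
}

#' Aligned read interval and reference span from CIGAR strings
#'
#' For a minus-strand alignment the CIGAR is written in reference
#' orientation, so the clips are swapped to express the interval on the
#' original read.
#'
#' @param cigar Character vector of CIGAR strings.
#' @param strand Character vector of `"+"`/`"-"`, recycled if length 1.
#' @return Tibble with `read_start`, `read_end` (0-based half-open on the
#'   original read), `read_len` (full read length implied by the CIGAR,
#'   hard clips included) and `ref_len` (reference bases consumed).
#' @keywords internal
cigar_read_bounds <- function(cigar, strand = "+") {
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  strand <- rep_len(strand, length(cigar))
  out <- purrr::map2(ops, lens, function(op, ln) {
    clip <- op %in% c("S", "H")
    aligned <- op %in% c("M", "I", "=", "X")
    if (!any(aligned)) abort(paste0("CIGAR consumes no read bases"))
    read_len <- sum(ln[clip | aligned])
    lead <- if (clip[1]) {
      k <- which(!clip)[1]
      sum(ln[seq_len(k - 1L)])
    } else 0L
    trail <- if (clip[length(op)]) {
      k <- max(which(!clip))
      sum(ln[seq(k + 1L, length(op))])
    } else 0L
    c(lead = lead, trail = trail, read_len = read_len,
      ref_len = sum(ln[op %in% c("M", "D", "N", "=", "X")]))
  })
  m <- do.call(rbind, out)
  minus <- strand == "-"
  lead <- ifelse(minus, m[, "trail"], m[, "lead"])
  trail <- ifelse(minus, m[, "lead"], m[, "trail"])
  tibble(
    read_start = as.integer(lead),
    read_end = as.integer(m[, "read_len"] - trail),
    read_len = as.integer(m[, "read_len"]),
    ref_len = as.integer(m[, "ref_len"])
  )
}
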