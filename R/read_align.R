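#' Construct a set of short reads
#' @param read_id character vector of read identifiers
#' @param seq character vector of read sequences (one fixed length)
#' @return data.frame with `read_id`, `seq`
#' @export
short_reads <- function(read_id, seq) {
  stopifnot(length(read_id) == length(seq))
  data.frame(read_id = as.character(read_id), seq = toupper(as.character(seq)),
             stringsAsFactors = FALSE)
}

#' Remove duplicate reads
#'
#' Keeps exactly one representative per distinct sequence, preserving the
#' input order of first occurrence.
#'
#' @param reads data.frame with `read_id`, `seq`
#' @return deduplicated data.frame
#' @export
dedupe_reads <- function(reads) {
  out <- reads[!duplicated(reads$seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove low-complexity reads
#'
#' Drops reads whose most frequent single nucleotide makes up strictly more
#' than `max_mono_frac` of the read.
#'
#' @param reads data.frame with `read_id`, `seq`
#' @param max_mono_frac maximum tolerated mononucleotide fraction (default 0.8)
#' @return filtered data.frame
#' @export
filter_low_complexity <- function(reads, max_mono_frac = 0.8) {
  stopifnot(max_mono_frac > 0, max_mono_frac <= 1)
  if (nrow(reads) == 0) return(reads)
  n <- nchar(reads$seq)
  counts <- vapply(c("A", "C", "G", "T"), function(b) {
    n - nchar(gsub(b, "", reads$seq, fixed = TRUE))
  }, numeric(nrow(reads)))
  if (nrow(reads) == 1) counts <- matrix(counts, nrow = 1)
  frac <- apply(counts, 1, max) / n
  out <- reads[frac <= max_mono_frac, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map reads to a reference, keeping unique best placements only
#'
#' Seed-and-extend alignment over the hard-masked reference. A read is placed
#' only when it has a single strictly best placement (fewest mismatches,
#' both strands considered) genome-wide; reads tied at their best mismatch
#' count are discarded as ambiguous. Placements must lie entirely within
#' unmasked sequence.
#'
#' @param reads data.frame with `read_id`, `seq` (all the same length)
#' @param reference list of [masked_contig] objects (prepped/masked)
#' @param max_mismatches maximum mismatches tolerated (default 2)
#' @return data.frame of placements (`read_id`, `contig_id`, `start` 0-based,
#'   `strand`, `mismatches`) with a `summary` attribute counting placed,
#'   ambiguous and unplaced reads
#' @export
map_reads_unique <- function(reads, reference, max_mismatches = 2L) {
  stopifnot(max_mismatches >= 0)
  ids <- vapply(reference, `[[`, "", "id")
  if (nrow(reads) == 0) {
    out <- data.frame(read_id = character(0), contig_id = character(0),
                      start = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE)
    attr(out, "summary") <- list(n_placed = 0L, n_ambiguous = 0L, n_unplaced = 0L)
    return(out)
  }
  if (length(unique(nchar(reads$seq))) != 1)
    stop("all reads must have the same length")
  hseqs <- vapply(reference, hard_masked_seq, "")
  res <- .map_reads_cpp(reads$seq, hseqs, as.integer(max_mismatches))
  out <- data.frame(
    read_id = reads$read_id[res$read],
    contig_id = ids[res$contig],
    start = res$start,
    strand = c("+", "-")[res$strand + 1L],
    mismatches = res$mismatches,
    stringsAsFactors = FALSE)
  attr(out, "summary") <- list(n_placed = res$n_placed,
                               n_ambiguous = res$n_ambiguous,
                               n_unplaced = res$n_unplaced)
  out
}

#' Ingest placements from a SAM file
#'
#' Primary mapped records with mapping quality at or above the threshold
#' become placements; unmapped, secondary and supplementary records are
#' skipped and counted.
#'
#' @param path SAM file (text, with header)
#' @param reference list of [masked_contig] objects the SAM must refer to
#' @param min_mapping_quality minimum MAPQ retained (default 1)
#' @return placements data.frame as in [map_reads_unique()], with a
#'   `summary` attribute of per-category counts
#' @export
ingest_sam <- function(path, reference, min_mapping_quality = 1L) {
  ids <- vapply(reference, `[[`, "", "id")
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "@"))
  counts <- c(kept = 0L, unmapped = 0L, secondary = 0L, supplementary = 0L,
              low_mapq = 0L)
  rows <- vector("list", length(body_idx))
  for (j in seq_along(body_idx)) {
    ln <- lines[body_idx[j]]
    if (!nzchar(ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11)
      stop("malformed SAM record at line ", body_idx[j], ": fewer than 11 fields")
    flag <- suppressWarnings(as.integer(f[2]))
    if (is.na(flag)) stop("malformed SAM record at line ", body_idx[j], ": bad FLAG")
    if (bitwAnd(flag, 4L) != 0L) { counts["unmapped"] <- counts["unmapped"] + 1L; next }
    if (bitwAnd(flag, 256L) != 0L) { counts["secondary"] <- counts["secondary"] + 1L; next }
    if (bitwAnd(flag, 2048L) != 0L) { counts["supplementary"] <- counts["supplementary"] + 1L; next }
    mapq <- suppressWarnings(as.integer(f[5]))
    if (is.na(mapq)) stop("malformed SAM record at line ", body_idx[j], ": bad MAPQ")
    if (mapq < min_mapping_quality) { counts["low_mapq"] <- counts["low_mapq"] + 1L; next }
    if (!(f[3] %in% ids))
      stop("SAM record at line ", body_idx[j], " references contig '", f[3],
           "' absent from the reference")
    pos <- suppressWarnings(as.integer(f[4]))
    if (is.na(pos) || pos < 1)
      stop("malformed SAM record at line ", body_idx[j], ": bad POS")
    nm <- 0L
    if (length(f) > 11) {
      tag <- grep("^NM:i:", f[12:length(f)], value = TRUE)
      if (length(tag)) nm <- as.integer(sub("^NM:i:", "", tag[1]))
    }
    counts["kept"] <- counts["kept"] + 1L
    rows[[j]] <- data.frame(
      read_id = f[1], contig_id = f[3], start = pos - 1L,
      strand = if (bitwAnd(flag, 16L) != 0L) "-" else "+",
      mismatches = nm, stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read_id = character(0), contig_id = character(0),
               start = integer(0), strand = character(0),
               mismatches = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "summary") <- as.list(counts)
  out
}

#' Write placements as SAM
#'
#' Minimal single-end records (`<r>M` CIGAR); enough to round-trip through
#' [ingest_sam()] and standard tools.
#'
#' @param placements placements data.frame
#' @param reference list of [masked_contig] objects (for `@SQ` headers)
#' @param path output SAM file
#' @param reads optional reads data.frame supplying sequences
#' @param read_length read length used for the CIGAR (inferred from `reads`
#'   when given)
#' @export
write_sam <- function(placements, reference, path, reads = NULL,
                      read_length = NULL) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           vapply(reference, function(ct)
             sprintf("@SQ\tSN:%s\tLN:%d", ct$id, nchar(ct$seq)), ""))
  seqs <- rep("*", nrow(placements))
  if (!is.null(reads)) {
    m <- match(placements$read_id, reads$read_id)
    seqs <- ifelse(is.na(m), "*", reads$seq[m])
    has <- !is.na(m) & placements$strand == "-"
    if (any(has)) seqs[has] <- revcomp(seqs[has])
    if (is.null(read_length) && any(!is.na(m)))
      read_length <- nchar(reads$seq[m[!is.na(m)][1]])
  }
  if (is.null(read_length)) read_length <- 36L
  recs <- sprintf("%s\t%d\t%s\t%d\t37\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                  placements$read_id,
                  ifelse(placements$strand == "-", 16L, 0L),
                  placements$contig_id,
                  placements$start + 1L,
                  read_length,
                  seqs,
                  placements$mismatches)
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Number of possible read placements on a contig
#'
#' The normalizing constant of read depth: the number of start positions at
#' which a read of length `r` fits entirely inside unmasked sequence,
#' summed over maximal unmasked segments.
#'
#' @param contig a [masked_contig]
#' @param r read length
#' @return integer (0 when no segment can hold a read)
#' @export
possible_placements <- function(contig, r) {
  stopifnot(r >= 1)
  seg <- unmasked_segments(contig)
  if (nrow(seg) == 0) return(0L)
  sum(pmax(0L, (seg$end - seg$start) - as.integer(r) + 1L))
}

#' Coverage and read-depth features for one contig
#'
#' Coverage `x1` is the fraction of unmasked bases covered by at least one
#' read; read depth `x2` is the read count divided by
#' [possible_placements()]. Contigs with no unmasked base or no possible
#' placement are flagged ineligible.
#'
#' @param contig a [masked_contig]
#' @param placements placements data.frame for this contig (or a vector of
#'   0-based start positions)
#' @param r read length
#' @return one-row data.frame: `contig_id`, `label`, `length`, `unmasked_len`,
#'   `n_reads`, `possible_placements`, `coverage`, `read_depth`, `eligible`
#' @export
compute_features <- function(contig, placements, r) {
  starts <- if (is.data.frame(placements)) {
    if (nrow(placements) > 0 && !all(placements$contig_id == contig$id))
      stop("placements contain rows for a different contig than '", contig$id, "'")
    placements$start
  } else as.integer(placements)
  ul <- unmasked_length(contig)
  pp <- possible_placements(contig, r)
  eligible <- ul > 0L && pp > 0L
  n_reads <- length(starts)
  covered <- 0L
  if (n_reads > 0 && ul > 0) {
    red <- IRanges::reduce(IRanges::IRanges(start = starts + 1L, width = r))
    seg <- unmasked_segments(contig)
    um <- IRanges::IRanges(start = seg$start + 1L, end = seg$end)
    covered <- sum(IRanges::width(IRanges::intersect(red, um)))
  }
  data.frame(contig_id = contig$id, label = contig$label,
             length = nchar(contig$seq), unmasked_len = ul,
             n_reads = n_reads, possible_placements = pp,
             coverage = if (ul > 0) covered / ul else 0,
             read_depth = if (pp > 0) n_reads / pp else 0,
             eligible = eligible, stringsAsFactors = FALSE)
}

#' Feature table for a set of contigs
#'
#' @param contigs list of [masked_contig] objects
#' @param placements placements data.frame over all contigs
#' @param r read length
#' @return data.frame with one row per contig (see [compute_features()])
#' @export
contig_features <- function(contigs, placements, r) {
  by_contig <- split(placements$start, placements$contig_id)
  rows <- lapply(contigs, function(ct) {
    compute_features(ct, by_contig[[ct$id]] %||% integer(0), r)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
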