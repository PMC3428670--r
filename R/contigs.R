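#' Construct a masked contig
#'
#' The unit of reference sequence throughout the package: a named nucleotide
#' sequence with a per-base mask (`TRUE` = excluded from alignment and
#' feature computation) and an optional class label. `N` bases are always
#' masked; lowercase (soft-masked) bases are masked when `honor_softmask` is
#' `TRUE`.
#'
#' @param id unique contig identifier
#' @param seq nucleotide string over `A,C,G,T,N` (case-insensitive)
#' @param mask optional logical vector, one entry per base (`TRUE` = masked)
#' @param label one of `"W"`, `"NONW"`, `"UNMAPPED"`, `"UNKNOWN"`
#' @param honor_softmask treat lowercase bases as masked
#' @return an object of class `masked_contig`
#' @export
masked_contig <- function(id, seq, mask = NULL,
                          label = c("UNKNOWN", "W", "NONW", "UNMAPPED"),
                          honor_softmask = TRUE) {
  label <- match.arg(label)
  stopifnot(is.character(id), length(id) == 1, nchar(id) > 0,
            is.character(seq), length(seq) == 1)
  raw <- charToRaw(seq)
  lower <- raw >= as.raw(0x61) & raw <= as.raw(0x7a)
  squp <- toupper(seq)
  rawup <- charToRaw(squp)
  ok <- rawup %in% charToRaw("ACGTN")
  if (!all(ok)) {
    stop("contig '", id, "': sequence contains characters outside {A,C,G,T,N} at position ",
         which(!ok)[1])
  }
  n <- length(rawup)
  if (is.null(mask)) mask <- rep(FALSE, n)
  if (length(mask) != n) stop("contig '", id, "': mask length != sequence length")
  mask <- as.logical(mask)
  if (honor_softmask) mask <- mask | lower
  mask <- mask | (rawup == charToRaw("N"))
  structure(list(id = id, seq = squp, mask = mask, label = label),
            class = "masked_contig")
}

#' @export
print.masked_contig <- function(x, ...) {
  cat(sprintf("<masked_contig> %s  label=%s  length=%d  unmasked=%d\n",
              x$id, x$label, nchar(x$seq), unmasked_length(x)))
  invisible(x)
}

#' Construct mask intervals
#'
#' BED-style 0-based half-open intervals naming regions to exclude.
#'
#' @param contig_id character vector of contig identifiers
#' @param start 0-based inclusive starts
#' @param end 0-based exclusive ends
#' @return a `data.frame` with columns `contig_id`, `start`, `end`
#' @export
mask_intervals <- function(contig_id, start, end) {
  stopifnot(length(contig_id) == length(start), length(start) == length(end))
  start <- as.integer(start); end <- as.integer(end)
  bad <- start < 0L | start >= end
  if (any(bad)) stop("invalid interval (need 0 <= start < end) at row ", which(bad)[1])
  data.frame(contig_id = as.character(contig_id), start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Apply mask intervals to contigs
#'
#' Unions the given intervals into the existing per-base masks (masking is
#' monotone: already-masked bases stay masked).
#'
#' @param contigs list of [masked_contig] objects
#' @param intervals `data.frame` as from [mask_intervals()]
#' @return the contig list with updated masks
#' @export
apply_mask <- function(contigs, intervals) {
  stopifnot(is.list(contigs))
  if (is.null(intervals) || nrow(intervals) == 0) return(contigs)
  ids <- vapply(contigs, `[[`, "", "id")
  idx <- match(intervals$contig_id, ids)
  if (anyNA(idx)) {
    stop("mask interval references unknown contig '",
         intervals$contig_id[which(is.na(idx))[1]], "'")
  }
  for (r in seq_len(nrow(intervals))) {
    i <- idx[r]
    n <- nchar(contigs[[i]]$seq)
    s <- intervals$start[r]; e <- intervals$end[r]
    if (s < 0 || s >= e || e > n) {
      stop("interval [", s, ",", e, ") out of bounds for contig '",
           intervals$contig_id[r], "' (length ", n, ")")
    }
    contigs[[i]]$mask[(s + 1L):e] <- TRUE
  }
  contigs
}

#' Find exact duplicate regions
#'
#' Self-alignment stand-in for the uniqueness filter: reports every position
#' lying inside a maximal exact repeat longer than `min_len` that occurs at
#' two or more distinct locations (within or across contigs, forward strand or
#' reverse complement). Only unmasked sequence is examined; all copies of a
#' repeat are reported. Implemented by counting canonical
#' (`min_len + 1`)-mers: a position is inside such a repeat exactly when it is
#' covered by a (`min_len + 1`)-mer seen at two or more locations.
#'
#' @param contigs list of [masked_contig] objects
#' @param min_len repeats strictly longer than this are masked (default 50 bp)
#' @return mask intervals (`data.frame`) covering all duplicate copies
#' @export
find_duplicate_regions <- function(contigs, min_len = 50L) {
  stopifnot(min_len >= 1)
  k <- as.integer(min_len) + 1L
  win_id <- integer(0); win_start <- integer(0); canon <- character(0)
  per <- vector("list", length(contigs))
  for (i in seq_along(contigs)) {
    s <- hard_masked_seq(contigs[[i]])
    n <- nchar(s)
    if (n < k) next
    starts <- seq_len(n - k + 1L)
    fwd <- substring(s, starts, starts + k - 1L)
    valid <- !grepl("N", fwd, fixed = TRUE)
    if (!any(valid)) next
    rcs <- revcomp(s)
    rev_ <- substring(rcs, n - (starts + k - 1L) + 1L, n - starts + 1L)
    cn <- ifelse(fwd < rev_, fwd, rev_)
    per[[i]] <- list(start = starts[valid] - 1L, canon = cn[valid])
  }
  lens <- vapply(per, function(p) if (is.null(p)) 0L else length(p$start), 0L)
  if (sum(lens) == 0) return(mask_intervals(character(0), integer(0), integer(0)))
  canon <- unlist(lapply(per, `[[`, "canon"), use.names = FALSE)
  dupvals <- unique(canon[duplicated(canon)])
  if (length(dupvals) == 0) return(mask_intervals(character(0), integer(0), integer(0)))
  hit <- canon %in% dupvals
  hit_by_contig <- split(hit, rep(seq_along(contigs), lens))
  out <- list()
  for (i in seq_along(contigs)) {
    if (lens[i] == 0) next
    h <- hit_by_contig[[as.character(i)]]
    if (!any(h)) next
    st <- per[[i]]$start[h]
    ir <- IRanges::reduce(IRanges::IRanges(start = st + 1L, width = k))
    out[[length(out) + 1L]] <- data.frame(
      contig_id = contigs[[i]]$id,
      start = IRanges::start(ir) - 1L,
      end = IRanges::end(ir),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) return(mask_intervals(character(0), integer(0), integer(0)))
  res <- do.call(rbind, out)
  mask_intervals(res$contig_id, res$start, res$end)
}

#' Mask short unmasked segments
#'
#' Masks every maximal run of unmasked bases shorter than `min_len`; longer
#' runs are untouched. Idempotent.
#'
#' @param contig a [masked_contig]
#' @param min_len minimum surviving segment length (default 50 bp)
#' @return the contig with updated mask
#' @export
drop_short_segments <- function(contig, min_len = 50L) {
  stopifnot(inherits(contig, "masked_contig"), min_len >= 1)
  r <- rle(contig$mask)
  short <- !r$values & r$lengths < min_len
  r$values[short] <- TRUE
  contig$mask <- inverse.rle(r)
  contig
}

#' Number of unmasked bases in a contig
#'
#' @param contig a [masked_contig]
#' @return integer count of unmasked bases
#' @export
unmasked_length <- function(contig) {
  stopifnot(inherits(contig, "masked_contig"))
  sum(!contig$mask)
}

#' Hard-masked sequence of a contig
#'
#' Returns the sequence with every masked base replaced by `N` (the form the
#' mapper aligns against).
#'
#' @param contig a [masked_contig]
#' @return character string
#' @export
hard_masked_seq <- function(contig) {
  if (!any(contig$mask)) return(contig$seq)
  ch <- strsplit(contig$seq, "", fixed = TRUE)[[1]]
  ch[contig$mask] <- "N"
  paste(ch, collapse = "")
}

#' Unmasked segments of a contig as 0-based half-open intervals
#' @param contig a [masked_contig]
#' @return data.frame with `start`, `end`
#' @keywords internal
unmasked_segments <- function(contig) {
  r <- rle(!contig$mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Prepare a reference for unique-read mapping
#'
#' The standard filter chain: apply externally supplied masks, mask exact
#' duplicate regions longer than `min_dup_len`, then mask unmasked segments
#' shorter than `min_seg_len`.
#'
#' @param contigs list of [masked_contig] objects
#' @param intervals optional external mask intervals (e.g. read from BED)
#' @param min_dup_len duplicates strictly longer than this are masked
#' @param min_seg_len minimum surviving unmasked segment length
#' @return list with elements `contigs` (masked) and `funnel`
#'   (a data.frame of unmasked-bp counts after each step)
#' @export
prep_reference <- function(contigs, intervals = NULL, min_dup_len = 50L,
                           min_seg_len = 50L) {
  ub <- function(cs) sum(vapply(cs, unmasked_length, 0L))
  funnel <- data.frame(step = "input", unmasked_bp = ub(contigs),
                       stringsAsFactors = FALSE)
  if (!is.null(intervals) && nrow(intervals) > 0) {
    contigs <- apply_mask(contigs, intervals)
    funnel <- rbind(funnel, data.frame(step = "external_mask", unmasked_bp = ub(contigs)))
  }
  dup <- find_duplicate_regions(contigs, min_len = min_dup_len)
  contigs <- apply_mask(contigs, dup)
  funnel <- rbind(funnel, data.frame(step = "duplicate_mask", unmasked_bp = ub(contigs)))
  contigs <- lapply(contigs, drop_short_segments, min_len = min_seg_len)
  funnel <- rbind(funnel, data.frame(step = "drop_short_segments", unmasked_bp = ub(contigs)))
  list(contigs = contigs, duplicate_intervals = dup, funnel = funnel)
}
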