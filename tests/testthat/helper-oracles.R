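# Independent oracles used to validate the package implementations.
# Each is deliberately written with a different mechanism than the code under
# test (per-base loops, exhaustive scans, outer products).

rc_string <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, "", USE.NAMES = FALSE)
}

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Brute-force Hamming sliding-window mapper: exhaustively scans every window
# of every contig on both strands, collapses strands per position, and keeps
# the read only when exactly one position attains the minimum mismatch count.
oracle_map <- function(reads, contigs, max_mm) {
  r <- nchar(reads$seq[1])
  out <- list()
  pre <- lapply(contigs, function(ct) {
    cv <- strsplit(hard_masked_seq(ct), "", fixed = TRUE)[[1]]
    n <- length(cv)
    if (n < r) return(NULL)
    npos <- n - r + 1
    cn <- cumsum(cv == "N")
    valid <- (cn[(1:npos) + r - 1] - c(0, cn)[1:npos]) == 0
    list(cv = cv, npos = npos, valid = valid)
  })
  for (i in seq_len(nrow(reads))) {
    hits <- NULL
    for (k in seq_along(contigs)) {
      p <- pre[[k]]
      if (is.null(p)) next
      for (strand in c("+", "-")) {
        sq <- if (strand == "+") reads$seq[i] else rc_string(reads$seq[i])
        rchars <- strsplit(sq, "", fixed = TRUE)[[1]]
        mm <- integer(p$npos)
        for (j in 1:r) mm <- mm + (p$cv[j:(j + p$npos - 1)] != rchars[j])
        ok <- which(p$valid & mm <= max_mm)
        if (length(ok)) {
          hits <- rbind(hits, data.frame(
            contig_id = contigs[[k]]$id, start = ok - 1L, strand = strand,
            mismatches = mm[ok], stringsAsFactors = FALSE))
        }
      }
    }
    if (is.null(hits)) next
    # collapse strands per position: keep min mismatches, prefer "+"
    key <- paste(hits$contig_id, hits$start)
    hits <- hits[order(key, hits$mismatches, hits$strand), , drop = FALSE]
    hits <- hits[!duplicated(paste(hits$contig_id, hits$start)), , drop = FALSE]
    best <- min(hits$mismatches)
    at_best <- hits[hits$mismatches == best, , drop = FALSE]
    if (nrow(at_best) == 1) {
      at_best$read_id <- reads$read_id[i]
      out[[length(out) + 1]] <- at_best[, c("read_id", "contig_id", "start",
                                            "strand", "mismatches")]
    }
  }
  if (!length(out)) {
    return(data.frame(read_id = character(0), contig_id = character(0),
                      start = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

placements_key <- function(pl) {
  sort(paste(pl$read_id, pl$contig_id, pl$start, pl$strand, pl$mismatches))
}

# Exhaustive duplicate-region oracle: for every N-free window of k bases,
# count its occurrences over all contigs (forward and reverse complement) by
# direct string comparison; windows seen at >= 2 distinct locations are
# masked. Returns per-contig logical mask vectors.
oracle_duplicate_mask <- function(contigs, min_len) {
  k <- min_len + 1L
  win <- list()
  for (ci in seq_along(contigs)) {
    s <- hard_masked_seq(contigs[[ci]])
    n <- nchar(s)
    if (n < k) next
    starts <- seq_len(n - k + 1L)
    str <- substring(s, starts, starts + k - 1L)
    keep <- !grepl("N", str, fixed = TRUE)
    if (any(keep)) {
      win[[length(win) + 1]] <- data.frame(
        ci = ci, start0 = starts[keep] - 1L, str = str[keep],
        stringsAsFactors = FALSE)
    }
  }
  masks <- lapply(contigs, function(ct) rep(FALSE, nchar(ct$seq)))
  if (!length(win)) return(masks)
  win <- do.call(rbind, win)
  for (i in seq_len(nrow(win))) {
    w <- win$str[i]
    rcw <- rc_string(w)
    cnt <- sum(win$str == w) + if (rcw != w) sum(win$str == rcw) else 0L
    if (cnt >= 2) {
      masks[[win$ci[i]]][win$start0[i] + seq_len(k)] <- TRUE
    }
  }
  masks
}

mask_from_intervals <- function(contigs, intervals) {
  masks <- lapply(contigs, function(ct) rep(FALSE, nchar(ct$seq)))
  ids <- vapply(contigs, `[[`, "", "id")
  for (i in seq_len(nrow(intervals))) {
    ci <- match(intervals$contig_id[i], ids)
    masks[[ci]][(intervals$start[i] + 1L):intervals$end[i]] <- TRUE
  }
  masks
}

# Mann-Whitney pairwise concordance (ties counted one half)
oracle_auc <- function(scores, labels, positive = "W") {
  y <- if (is.logical(labels)) labels else labels == positive
  ps <- scores[y]; ns <- scores[!y]
  mean(outer(ps, ns, ">") + 0.5 * outer(ps, ns, "=="))
}

# Per-base coverage/read-depth oracle
oracle_features <- function(contig, starts, r) {
  n <- nchar(contig$seq)
  cov <- rep(FALSE, n)
  for (s in starts) cov[(s + 1):(s + r)] <- TRUE
  um <- !contig$mask
  seg <- rle(um)
  pp <- sum(pmax(0L, seg$lengths[seg$values] - r + 1L))
  list(coverage = if (sum(um) > 0) sum(cov & um) / sum(um) else 0,
       read_depth = if (pp > 0) length(starts) / pp else 0,
       possible_placements = pp)
}
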