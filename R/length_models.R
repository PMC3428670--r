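#' Round a contig length to its 500-bp length bin
#'
#' Nearest multiple of `bin` (ties round up), floored at the smallest bin.
#'
#' @param raw_len integer vector of contig lengths (bp)
#' @param bin bin width in bp (default 500)
#' @return integer vector of bin centers (multiples of `bin`, `>= bin`)
#' @export
length_bin <- function(raw_len, bin = 500L) {
  stopifnot(all(raw_len >= 1), bin >= 1)
  raw_len <- as.integer(raw_len)
  bin <- as.integer(bin)
  pmax(bin, ((raw_len + bin %/% 2L) %/% bin) * bin)
}

#' Fragment contigs into fixed-length windows
#'
#' Non-overlapping consecutive windows of exactly `L` bases starting at
#' position 0, inheriting mask state and label; trailing partial windows are
#' discarded. Fragment ids are `<source_id>:<offset>`.
#'
#' @param contigs list of [masked_contig] objects
#' @param L window length in bp (>= 1; the classifier uses multiples of 500)
#' @return list of [masked_contig] fragments, each carrying `source_id` and
#'   `offset` fields
#' @export
fragment_genome <- function(contigs, L) {
  stopifnot(L >= 1)
  L <- as.integer(L)
  out <- list()
  for (ct in contigs) {
    n <- nchar(ct$seq)
    nf <- n %/% L
    if (nf == 0) next
    for (w in seq_len(nf) - 1L) {
      s0 <- w * L
      fr <- masked_contig(
        id = paste0(ct$id, ":", s0),
        seq = substr(ct$seq, s0 + 1L, s0 + L),
        mask = ct$mask[(s0 + 1L):(s0 + L)],
        label = ct$label, honor_softmask = FALSE)
      fr$source_id <- ct$id
      fr$offset <- s0
      out[[length(out) + 1L]] <- fr
    }
  }
  out
}

#' Re-window placements onto genome fragments
#'
#' Reuses existing placements instead of re-running alignment: each read is
#' assigned to the window containing its start. Reads whose start and end fall
#' in different windows (boundary-spanning) and reads starting in a discarded
#' trailing tail are dropped and counted.
#'
#' @param placements placements data.frame on the unfragmented contigs
#' @param contigs the source contigs (for lengths)
#' @param L fragment length used in [fragment_genome()]
#' @param r read length
#' @return list: `placements` (re-keyed to fragment ids), `n_boundary`,
#'   `n_tail`
#' @export
fragment_placements <- function(placements, contigs, L, r) {
  L <- as.integer(L)
  lens <- stats::setNames(vapply(contigs, function(ct) nchar(ct$seq), 0L),
                          vapply(contigs, `[[`, "", "id"))
  src_len <- lens[placements$contig_id]
  win_s <- placements$start %/% L
  win_e <- (placements$start + r - 1L) %/% L
  in_tail <- (win_s + 1L) * L > src_len          # window truncated/discarded
  boundary <- win_s != win_e & !in_tail
  keep <- !boundary & !in_tail
  out <- placements[keep, , drop = FALSE]
  out$contig_id <- paste0(out$contig_id, ":", win_s[keep] * L)
  out$start <- out$start %% L
  rownames(out) <- NULL
  list(placements = out, n_boundary = sum(boundary), n_tail = sum(in_tail))
}

#' Assemble a per-length-bin training set
#'
#' Uniform, without-replacement draw of `n_w` W members and
#' `round(ratio_nonw_to_w * n_w)` non-W members among the labeled feature rows
#' whose length bin equals `L`.
#'
#' @param features labeled feature data.frame (columns `label`, `length`, plus
#'   the feature columns)
#' @param L target length bin (multiple of the bin width)
#' @param n_w number of W members to draw
#' @param ratio_nonw_to_w non-W:W ratio (default 1)
#' @param seed RNG seed for a reproducible draw
#' @param bin bin width used by [length_bin()] (default 500)
#' @return object of class `training_set`: list with `L`, `members`, `ratio`
#' @export
build_training_set <- function(features, L, n_w, ratio_nonw_to_w = 1,
                               seed = NULL, bin = 500L) {
  stopifnot(n_w >= 1, ratio_nonw_to_w >= 0)
  lb <- length_bin(features$length, bin)
  at_l <- features[lb == L, , drop = FALSE]
  w_idx <- which(at_l$label == "W")
  n_idx <- which(at_l$label == "NONW")
  n_nonw <- round(ratio_nonw_to_w * n_w)
  if (length(w_idx) < n_w || length(n_idx) < n_nonw) {
    stop("insufficient members at length bin ", L, ": have ", length(w_idx),
         " W and ", length(n_idx), " non-W, need ", n_w, " and ", n_nonw)
  }
  members <- with_seed(seed, {
    rbind(at_l[sample(w_idx, n_w), , drop = FALSE],
          at_l[sample(n_idx, n_nonw), , drop = FALSE])
  })
  rownames(members) <- NULL
  structure(list(L = L, members = members, ratio = ratio_nonw_to_w),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set> L=%d  %d W + %d non-W (ratio %.3g)\n",
              x$L, sum(x$members$label == "W"), sum(x$members$label == "NONW"),
              x$ratio))
  invisible(x)
}
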