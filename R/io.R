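#' Read a reference assembly from FASTA
#'
#' Accepts plain or soft-masked FASTA. Lowercase bases are treated as masked
#' unless `honor_softmask = FALSE`; `N` bases are always masked.
#'
#' @param path FASTA file
#' @param labels optional named character vector or data.frame
#'   (`contig_id`, `label`) assigning class labels
#' @param honor_softmask treat lowercase bases as masked
#' @return list of [masked_contig] objects
#' @export
read_reference <- function(path, labels = NULL, honor_softmask = TRUE) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  ids <- sub("\\s.*$", "", names(ss))
  if (is.data.frame(labels)) {
    labels <- stats::setNames(labels$label, labels$contig_id)
  }
  lapply(seq_along(seqs), function(i) {
    lab <- if (!is.null(labels) && ids[i] %in% names(labels))
      as.character(labels[[ids[i]]]) else "UNKNOWN"
    masked_contig(ids[i], seqs[i], label = lab, honor_softmask = honor_softmask)
  })
}

#' Write contigs as hard-masked FASTA
#'
#' Masked bases are written as `N`; set `hard_mask = FALSE` to write raw
#' sequence.
#'
#' @param contigs list of [masked_contig] objects
#' @param path output FASTA file
#' @param hard_mask replace masked bases with `N`
#' @export
write_reference <- function(contigs, path, hard_mask = TRUE) {
  seqs <- if (hard_mask) vapply(contigs, hard_masked_seq, "")
          else vapply(contigs, `[[`, "", "seq")
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- vapply(contigs, `[[`, "", "id")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read mask intervals from a 3-column BED file
#' @param path BED file (0-based half-open, no header)
#' @return mask intervals data.frame
#' @export
read_mask_bed <- function(path) {
  if (file.size(path) == 0) return(mask_intervals(character(0), integer(0), integer(0)))
  b <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  mask_intervals(b[[1]], b[[2]], b[[3]])
}

#' Write mask intervals as BED
#' @param intervals mask intervals data.frame
#' @param path output BED file
#' @export
write_mask_bed <- function(intervals, path) {
  utils::write.table(intervals[, c("contig_id", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read contig class labels from TSV
#' @param path TSV with header columns `contig_id`, `label`
#' @return data.frame
#' @export
read_contig_labels <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write contig class labels as TSV
#' @param labels data.frame with `contig_id`, `label`
#' @param path output TSV
#' @export
write_contig_labels <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read short reads from FASTQ or FASTA
#' @param path input file; format inferred from extension
#'   (`.fq`/`.fastq` vs `.fa`/`.fasta`) unless given
#' @param format `"auto"`, `"fastq"` or `"fasta"`
#' @return data.frame with `read_id`, `seq`
#' @export
read_short_reads <- function(path, format = c("auto", "fastq", "fasta")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.f(ast)?q$", path, ignore.case = TRUE)) "fastq" else "fasta"
  }
  ss <- Biostrings::readDNAStringSet(path, format = format)
  data.frame(read_id = sub("\\s.*$", "", names(ss)),
             seq = as.character(ss), stringsAsFactors = FALSE, row.names = NULL)
}

#' Write short reads as FASTQ
#'
#' Constant placeholder qualities (`I`): the pipeline is quality-agnostic.
#'
#' @param reads data.frame with `read_id`, `seq`
#' @param path output FASTQ
#' @export
write_reads_fastq <- function(reads, path) {
  qual <- vapply(nchar(reads$seq), function(n) strrep("I", n), "")
  writeLines(paste0("@", reads$read_id, "\n", reads$seq, "\n+\n", qual), path)
  invisible(path)
}

#' Write per-contig features as TSV
#' @param features feature data.frame from [contig_features()]
#' @param path output TSV
#' @export
write_features <- function(features, path) {
  utils::write.table(features, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-contig feature table from TSV
#' @param path TSV written by [write_features()]
#' @return data.frame
#' @export
read_features <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
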