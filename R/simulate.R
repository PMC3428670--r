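#' Specification for a synthetic ZW assembly and ZZ read set
#'
#' Describes the study conditions the generator emulates: a female (ZW)
#' assembly containing W-specific, Z-linked and autosomal contigs with
#' plantable exact repeats, gametolog pairs and optional male-deletion
#' contigs, plus a male (ZZ) short-read library drawn only from non-W
#' sequence.
#'
#' Defaults mirror the target use case: 36-bp reads at 0.45x of the reference,
#' 100 W and 1000 non-W contigs of 1-5 kb, a 0.2% sequencing error rate, 0.2%
#' reference-vs-read-source divergence (different breeds), 5% of the genome in
#' exact 150-300 bp repeat copies, two gametolog pairs sharing a 150-bp
#' stretch, and no male-deletion contigs (the failure mode is opt-in).
#'
#' @param n_w,n_z,n_auto contig counts per chromosome class
#' @param len_range inclusive range of contig lengths (bp)
#' @param read_length read length r in bp
#' @param depth target depth as a multiple of total reference length
#' @param error_rate per-base substitution sequencing error rate
#' @param source_divergence per-base divergence between the reference assembly
#'   and the genome the reads are drawn from
#' @param repeat_fraction fraction of reference bases inside planted exact
#'   repeats
#' @param repeat_unit_len range of repeat unit lengths (bp)
#' @param repeat_copies range of copies per repeat unit
#' @param n_gametolog number of W/Z gametolog pairs
#' @param gametolog_len length of the shared gametolog stretch (bp)
#' @param gametolog_site_spacing spacing of divergent sites inside the stretch;
#'   must be below the read length so every read window sees a site
#' @param n_male_deleted autosomal contigs present in the reference but absent
#'   from the male read source
#' @param seed master seed for the generator
#' @return object of class `genome_spec`
#' @export
genome_spec <- function(n_w = 100L, n_z = 200L, n_auto = 800L,
                        len_range = c(1000L, 5000L), read_length = 36L,
                        depth = 0.45, error_rate = 0.002,
                        source_divergence = 0.002, repeat_fraction = 0.05,
                        repeat_unit_len = c(150L, 300L),
                        repeat_copies = c(2L, 5L), n_gametolog = 2L,
                        gametolog_len = 150L, gametolog_site_spacing = 30L,
                        n_male_deleted = 0L, seed = 1L) {
  spec <- list(n_w = as.integer(n_w), n_z = as.integer(n_z),
               n_auto = as.integer(n_auto),
               len_range = as.integer(len_range),
               read_length = as.integer(read_length), depth = depth,
               error_rate = error_rate, source_divergence = source_divergence,
               repeat_fraction = repeat_fraction,
               repeat_unit_len = as.integer(repeat_unit_len),
               repeat_copies = as.integer(repeat_copies),
               n_gametolog = as.integer(n_gametolog),
               gametolog_len = as.integer(gametolog_len),
               gametolog_site_spacing = as.integer(gametolog_site_spacing),
               n_male_deleted = as.integer(n_male_deleted),
               seed = as.integer(seed))
  with(spec, {
    stopifnot(n_w >= 0, n_z >= 0, n_auto >= 0, depth > 0,
              length(len_range) == 2, len_range[1] <= len_range[2],
              len_range[1] >= read_length, read_length >= 1,
              error_rate >= 0, error_rate <= 1,
              source_divergence >= 0, source_divergence <= 1,
              repeat_fraction >= 0, repeat_fraction < 1,
              repeat_copies[1] >= 2)
    if (repeat_fraction > 0 && repeat_unit_len[2] > len_range[1])
      stop("genome_spec: repeat unit longer than the shortest contig")
    if (n_gametolog > 0) {
      if (gametolog_len > len_range[1])
        stop("genome_spec: gametolog stretch longer than the shortest contig")
      if (n_gametolog > min(n_w, n_z))
        stop("genome_spec: more gametolog pairs than W or Z contigs")
      if (gametolog_site_spacing >= read_length)
        stop("genome_spec: gametolog divergent-site spacing must be below the read length")
    }
    if (n_male_deleted > n_auto)
      stop("genome_spec: more male-deletion contigs than autosomes")
  })
  structure(spec, class = "genome_spec")
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf(paste0("<genome_spec> %d W + %d Z + %d autosomal contigs, ",
                     "%d-%d bp\n  %d bp reads at %.3gx, error %.3g, ",
                     "divergence %.3g, repeats %.3g\n  %d gametolog pair(s), ",
                     "%d male-deletion contig(s), seed %d\n"),
              x$n_w, x$n_z, x$n_auto, x$len_range[1], x$len_range[2],
              x$read_length, x$depth, x$error_rate, x$source_divergence,
              x$repeat_fraction, x$n_gametolog, x$n_male_deleted, x$seed))
  invisible(x)
}

.random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.mutate_at <- function(seq, pos1) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos1) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

#' Simulate a labeled ZW genome assembly
#'
#' Generates i.i.d. uniform-composition contigs per class, plants exact
#' repeats at the requested genome fraction, inserts gametolog pairs (a W
#' stretch plus a diverged Z copy, with at least one divergent site per read
#' window so the pair is neither an exact duplicate nor ambiguous to map),
#' and flags male-deletion contigs. Reproducible from the spec seed.
#'
#' @param spec a [genome_spec]
#' @return object of class `w_sim`: list with `contigs` (list of
#'   [masked_contig]), `truth` (data.frame: `contig_id`, `class`,
#'   `chromosome`, `is_gametolog`, `is_male_deleted`, `repeat_bases`,
#'   `length`), `gametologs` (data.frame incl. the male-genome sequence of
#'   each shared stretch), and `spec`
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(derive_seed(spec$seed, "genome"), {
    n_tot <- spec$n_w + spec$n_z + spec$n_auto
    chrom <- rep(c("W", "Z", "AUTO"), c(spec$n_w, spec$n_z, spec$n_auto))
    ids <- c(sprintf("W_%04d", seq_len(spec$n_w)),
             sprintf("Z_%04d", seq_len(spec$n_z)),
             sprintf("A_%04d", seq_len(spec$n_auto)))
    lens <- sample(seq(spec$len_range[1], spec$len_range[2]), n_tot,
                   replace = TRUE)
    seqs <- vapply(lens, .random_seq, "")
    repeat_bases <- integer(n_tot)

    # plant exact repeat units until the requested genome fraction is reached
    target <- spec$repeat_fraction * sum(lens)
    planted <- 0
    while (planted < target && n_tot >= 1) {
      ul <- sample(seq(spec$repeat_unit_len[1], spec$repeat_unit_len[2]), 1)
      nc <- sample(seq(spec$repeat_copies[1], spec$repeat_copies[2]), 1)
      unit <- .random_seq(ul)
      host <- sample(which(lens >= ul), nc, replace = TRUE)
      for (h in host) {
        p <- sample(lens[h] - ul + 1L, 1)
        substr(seqs[h], p, p + ul - 1L) <- unit
        repeat_bases[h] <- repeat_bases[h] + ul
      }
      planted <- planted + ul * nc
    }

    # gametolog pairs: W carries stretch S, Z a diverged copy; the male genome
    # carries S at the Z locus (recorded in `gametologs` for the read sampler)
    gam <- data.frame(w_id = character(0), z_id = character(0),
                      w_start = integer(0), z_start = integer(0),
                      len = integer(0), male_seq = character(0),
                      stringsAsFactors = FALSE)
    is_gam <- rep(FALSE, n_tot)
    if (spec$n_gametolog > 0) {
      w_pick <- sample(which(chrom == "W"), spec$n_gametolog)
      z_pick <- sample(which(chrom == "Z"), spec$n_gametolog)
      gl <- spec$gametolog_len
      sp <- spec$gametolog_site_spacing
      for (g in seq_len(spec$n_gametolog)) {
        wi <- w_pick[g]; zi <- z_pick[g]
        s_w <- .random_seq(gl)
        sites <- seq(sp %/% 2, gl, by = sp)
        s_z <- .mutate_at(s_w, sites)
        pw <- sample(lens[wi] - gl + 1L, 1)
        pz <- sample(lens[zi] - gl + 1L, 1)
        substr(seqs[wi], pw, pw + gl - 1L) <- s_w
        substr(seqs[zi], pz, pz + gl - 1L) <- s_z
        is_gam[wi] <- TRUE
        gam <- rbind(gam, data.frame(
          w_id = ids[wi], z_id = ids[zi], w_start = pw - 1L,
          z_start = pz - 1L, len = gl, male_seq = s_w,
          stringsAsFactors = FALSE))
      }
    }

    is_del <- rep(FALSE, n_tot)
    if (spec$n_male_deleted > 0)
      is_del[sample(which(chrom == "AUTO"), spec$n_male_deleted)] <- TRUE

    contigs <- lapply(seq_len(n_tot), function(i) {
      masked_contig(ids[i], seqs[i],
                    label = if (chrom[i] == "W") "W" else "NONW",
                    honor_softmask = FALSE)
    })
    truth <- data.frame(contig_id = ids,
                        class = ifelse(chrom == "W", "W", "NONW"),
                        chromosome = chrom, is_gametolog = is_gam,
                        is_male_deleted = is_del,
                        repeat_bases = repeat_bases, length = lens,
                        stringsAsFactors = FALSE)
    structure(list(contigs = contigs, truth = truth, gametologs = gam,
                   spec = spec), class = "w_sim")
  })
}

#' @export
print.w_sim <- function(x, ...) {
  cat(sprintf("<w_sim> %d contigs (%d W / %d non-W), %d bp total\n",
              nrow(x$truth), sum(x$truth$class == "W"),
              sum(x$truth$class == "NONW"), sum(x$truth$length)))
  invisible(x)
}

#' Simulate a male (ZZ) short-read library
#'
#' Read start positions are sampled uniformly over all read-length windows of
#' non-W, non-male-deleted contigs of the read-source genome (Z at the same
#' per-copy rate as autosomes, as in a ZZ male). The read-source genome is the
#' reference with gametolog Z stretches replaced by their W-like male sequence
#' and per-base breed divergence applied. The read count is
#' `round(depth * total reference length / read_length)`; strands are
#' random and substitution errors applied at the spec's error rate. No read
#' ever originates from a W contig.
#'
#' @param sim a `w_sim` from [simulate_genome()]
#' @param depth override the spec depth (reads scale accordingly)
#' @param n_reads override the read count directly
#' @param seed override the derived read-sampling seed
#' @return data.frame with `read_id`, `seq`, plus an `origin` attribute
#'   (`contig_id`, `start`, `strand` per read)
#' @export
simulate_male_reads <- function(sim, depth = NULL, n_reads = NULL,
                                seed = NULL) {
  stopifnot(inherits(sim, "w_sim"))
  spec <- sim$spec
  r <- spec$read_length
  depth <- depth %||% spec$depth
  seed <- seed %||% derive_seed(spec$seed, "reads")
  src_rows <- which(sim$truth$class == "NONW" & !sim$truth$is_male_deleted)
  if (!length(src_rows)) stop("simulate_male_reads: no eligible source sequence")
  total_ref <- sum(sim$truth$length)
  n_reads <- n_reads %||% round(depth * total_ref / r)

  with_seed(seed, {
    src_seq <- vapply(sim$contigs[src_rows], `[[`, "", "seq")
    src_ids <- sim$truth$contig_id[src_rows]
    # gametolog Z loci carry the W-like male sequence
    if (nrow(sim$gametologs) > 0) {
      for (g in seq_len(nrow(sim$gametologs))) {
        zi <- match(sim$gametologs$z_id[g], src_ids)
        if (is.na(zi)) next
        s0 <- sim$gametologs$z_start[g]
        substr(src_seq[zi], s0 + 1L, s0 + sim$gametologs$len[g]) <-
          sim$gametologs$male_seq[g]
      }
    }
    # breed divergence between reference and read source
    if (spec$source_divergence > 0) {
      for (i in seq_along(src_seq)) {
        n <- nchar(src_seq[i])
        k <- stats::rbinom(1, n, spec$source_divergence)
        if (k > 0) src_seq[i] <- .mutate_at(src_seq[i], sample.int(n, k))
      }
    }
    src_lens <- nchar(src_seq)
    nwin <- src_lens - r + 1L
    if (any(nwin < 1)) { src_seq <- src_seq[nwin >= 1]; src_ids <- src_ids[nwin >= 1]
                         src_lens <- src_lens[nwin >= 1]; nwin <- nwin[nwin >= 1] }
    cum <- cumsum(as.double(nwin))
    total_win <- cum[length(cum)]
    u <- ceiling(stats::runif(n_reads) * total_win)
    ci <- findInterval(u - 0.5, c(0, cum))        # source contig index
    pos0 <- as.integer(u - c(0, cum)[ci] - 1)     # 0-based window start
    seqs <- substring(src_seq[ci], pos0 + 1L, pos0 + r)
    strand <- ifelse(stats::runif(n_reads) < 0.5, "+", "-")
    rev_idx <- which(strand == "-")
    if (length(rev_idx)) seqs[rev_idx] <- revcomp(seqs[rev_idx])
    # substitution sequencing errors
    if (spec$error_rate > 0 && n_reads > 0) {
      total_bases <- as.double(n_reads) * r
      k <- stats::rbinom(1, total_bases, spec$error_rate)
      if (k > 0) {
        at <- sample(total_bases, k)
        rd <- ((at - 1) %/% r) + 1
        off <- ((at - 1) %% r) + 1
        for (j in seq_len(k)) {
          s <- seqs[rd[j]]
          b <- substr(s, off[j], off[j])
          substr(seqs[rd[j]], off[j], off[j]) <-
            sample(setdiff(c("A", "C", "G", "T"), b), 1)
        }
      }
    }
    reads <- short_reads(sprintf("read_%07d", seq_len(n_reads)), seqs)
    attr(reads, "origin") <- data.frame(contig_id = src_ids[ci], start = pos0,
                                        strand = strand,
                                        stringsAsFactors = FALSE)
    reads
  })
}

#' Closed-form probability that a contig receives zero reads
#'
#' Under uniform sampling of `n_reads` reads over `total_placements` possible
#' genome-wide start positions, the probability that none of a contig's
#' `possible_placements` windows is chosen:
#' `(1 - possible_placements / total_placements) ^ n_reads`.
#'
#' @param contig a [masked_contig], or directly the number of placements the
#'   contig offers
#' @param n_reads number of reads drawn
#' @param total_placements total placements genome-wide
#' @param r read length (needed when `contig` is a `masked_contig`)
#' @return probability in `[0, 1]`
#' @export
expected_zero_hit_probability <- function(contig, n_reads, total_placements,
                                          r = NULL) {
  pp <- if (inherits(contig, "masked_contig")) {
    if (is.null(r)) stop("expected_zero_hit_probability: r required")
    possible_placements(contig, r)
  } else as.numeric(contig)
  if (pp <= 0) stop("expected_zero_hit_probability: contig offers no placement")
  if (total_placements < pp)
    stop("expected_zero_hit_probability: total_placements < contig placements")
  stopifnot(n_reads >= 0)
  (1 - pp / total_placements)^n_reads
}

#' Write a synthetic fixture to disk
#'
#' Writes reference FASTA (raw sequence), mask BED, label TSV, truth TSV,
#' reads FASTQ, an optional SAM of placements, and a manifest JSON recording
#' the spec and seed.
#'
#' @param sim a `w_sim`
#' @param reads reads data.frame from [simulate_male_reads()]
#' @param out_dir output directory (created if missing)
#' @param placements optional placements to serialize as SAM
#' @return invisible named vector of file paths
#' @export
write_fixture <- function(sim, reads, out_dir, placements = NULL) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("write_fixture: cannot create directory ", out_dir)
  paths <- c(reference = file.path(out_dir, "reference.fasta"),
             mask = file.path(out_dir, "mask.bed"),
             labels = file.path(out_dir, "labels.tsv"),
             truth = file.path(out_dir, "truth.tsv"),
             reads = file.path(out_dir, "reads.fastq"),
             manifest = file.path(out_dir, "manifest.json"))
  write_reference(sim$contigs, paths["reference"], hard_mask = FALSE)
  masks <- do.call(rbind, lapply(sim$contigs, function(ct) {
    seg <- rle(ct$mask)
    ends <- cumsum(seg$lengths); starts <- ends - seg$lengths
    if (!any(seg$values)) return(NULL)
    data.frame(contig_id = ct$id, start = starts[seg$values],
               end = ends[seg$values], stringsAsFactors = FALSE)
  }))
  if (is.null(masks)) masks <- mask_intervals(character(0), integer(0), integer(0))
  write_mask_bed(masks, paths["mask"])
  write_contig_labels(
    data.frame(contig_id = sim$truth$contig_id, label = sim$truth$class,
               stringsAsFactors = FALSE), paths["labels"])
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_reads_fastq(reads, paths["reads"])
  if (!is.null(placements)) {
    paths <- c(paths, placements = file.path(out_dir, "placements.sam"))
    write_sam(placements, sim$contigs, paths["placements"], reads = reads,
              read_length = sim$spec$read_length)
  }
  manifest <- list(format = "wlinker-fixture", version = 1L,
                   spec = unclass(sim$spec),
                   n_contigs = nrow(sim$truth), n_reads = nrow(reads),
                   files = as.list(basename(paths[names(paths) != "manifest"])))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read a fixture written by [write_fixture()]
#' @param dir fixture directory
#' @return list with `contigs`, `truth`, `reads`, `spec` (as a plain list)
#' @export
read_fixture <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  truth <- utils::read.table(file.path(dir, "truth.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  labels <- read_contig_labels(file.path(dir, "labels.tsv"))
  contigs <- read_reference(file.path(dir, "reference.fasta"), labels = labels,
                            honor_softmask = FALSE)
  contigs <- apply_mask(contigs, read_mask_bed(file.path(dir, "mask.bed")))
  reads <- read_short_reads(file.path(dir, "reads.fastq"))
  list(contigs = contigs, truth = truth, reads = reads,
       spec = manifest$spec)
}
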