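test_that("read QC removes duplicates and low-complexity reads", {
  reads <- short_reads(c("a", "b", "c"),
                       c(strrep("A", 36), strrep("A", 36), strrep("C", 36)))
  dd <- dedupe_reads(reads)
  expect_equal(nrow(dd), 2L)
  expect_equal(dd$read_id, c("a", "c"))  # first occurrence kept, order preserved

  set.seed(41)
  distinct <- short_reads(paste0("r", 1:10),
                          vapply(1:10, function(i) rand_dna(36), ""))
  expect_identical(dedupe_reads(distinct), distinct)
  many <- distinct[rep(1:3, each = 10), ]
  expect_equal(nrow(dedupe_reads(many)), 3L)

  # mononucleotide fraction rule: strictly greater than the threshold drops
  bal <- short_reads("bal", paste(rep(c("A","C","G","T"), 9), collapse = ""))
  mono <- short_reads("mono", strrep("A", 36))
  edge <- short_reads("edge", paste0(strrep("A", 30), "CGTCGT"))  # 30/36 = 0.833
  expect_equal(nrow(filter_low_complexity(mono, 0.8)), 0L)
  expect_equal(nrow(filter_low_complexity(bal, 0.8)), 1L)
  expect_equal(nrow(filter_low_complexity(edge, 0.8)), 0L)
  expect_equal(nrow(filter_low_complexity(edge, 0.85)), 1L)
})

test_that("unique mapping places, discards ambiguity, and honors masks", {
  set.seed(42)
  ref_seq <- rand_dna(400)
  ct <- masked_contig("c1", ref_seq)
  read_at <- function(pos0) substr(ref_seq, pos0 + 1, pos0 + 36)

  # exact unique match
  pl <- map_reads_unique(short_reads("r1", read_at(100)), list(ct), 2)
  expect_equal(pl$contig_id, "c1")
  expect_equal(pl$start, 100L)
  expect_equal(pl$mismatches, 0L)
  expect_equal(pl$strand, "+")

  # reverse-complement read maps to the same locus on the minus strand
  plr <- map_reads_unique(short_reads("r1r", rc_string(read_at(100))),
                          list(ct), 2)
  expect_equal(plr$start, 100L)
  expect_equal(plr$strand, "-")

  # a read matching two loci exactly is discarded as ambiguous
  dup_ref <- masked_contig("c2", paste0(rand_dna(50), read_at(100),
                                        rand_dna(40), read_at(100),
                                        rand_dna(50)))
  pl2 <- map_reads_unique(short_reads("r2", read_at(100)), list(dup_ref), 2)
  expect_equal(nrow(pl2), 0L)
  expect_equal(attr(pl2, "summary")$n_ambiguous, 1L)

  # strictly-best placement wins: Hamming 1 at locus A, 2 at locus B
  base <- read_at(200)
  mut <- function(s, at) {
    ch <- strsplit(s, "")[[1]]
    ch[at] <- setdiff(c("A","C","G","T"), ch[at])[1]
    paste(ch, collapse = "")
  }
  two_loci <- masked_contig("c3", paste0(rand_dna(40), mut(base, 5),
                                         rand_dna(40), mut(base, c(9, 20)),
                                         rand_dna(40)))
  pl3 <- map_reads_unique(short_reads("r3", base), list(two_loci), 2)
  expect_equal(pl3$start, 40L)
  expect_equal(pl3$mismatches, 1L)

  # placements may not overlap masked bases
  masked_ct <- apply_mask(list(ct), mask_intervals("c1", 110, 112))[[1]]
  pl4 <- map_reads_unique(short_reads("r4", read_at(100)), list(masked_ct), 2)
  expect_equal(nrow(pl4), 0L)
  expect_equal(attr(pl4, "summary")$n_unplaced, 1L)
})

test_that("mapper agrees exactly with the brute-force Hamming oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    contigs <- lapply(1:2, function(i) {
      s <- rand_dna(800)
      # sprinkle masked stretches
      m <- rep(FALSE, 800)
      m[sample(750, 2) + rep(0:19, each = 2)] <- TRUE
      masked_contig(paste0("t", i), s, mask = m, honor_softmask = FALSE)
    })
    genome <- paste(vapply(contigs, `[[`, "", "seq"), collapse = "")
    reads <- short_reads(
      paste0("rd", 1:25),
      vapply(1:25, function(i) {
        p <- sample(nchar(genome) - 35, 1)
        s <- substr(genome, p, p + 35)
        ch <- strsplit(s, "")[[1]]
        k <- sample(0:3, 1)
        if (k > 0) {
          at <- sample(36, k)
          for (a in at) ch[a] <- sample(setdiff(c("A","C","G","T"), ch[a]), 1)
        }
        if (runif(1) < 0.5) paste(ch, collapse = "") else
          rc_string(paste(ch, collapse = ""))
      }, ""))
    for (mm in 0:2) {
      got <- map_reads_unique(reads, contigs, mm)
      want <- oracle_map(reads, contigs, mm)
      expect_equal(placements_key(got), placements_key(want),
                   info = paste("seed", seed, "mm", mm))
    }
  }
})

test_that("SAM ingestion filters by flag and MAPQ and validates strictly", {
  dir <- withr::local_tempdir()
  ct <- masked_contig("chrA", strrep("ACGT", 50))
  sam <- file.path(dir, "in.sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:chrA\tLN:200",
    "r1\t0\tchrA\t10\t30\t36M\t*\t0\t0\t*\t*\tNM:i:1",
    "r2\t16\tchrA\t50\t30\t36M\t*\t0\t0\t*\t*",
    "r3\t0\tchrA\t70\t30\t36M\t*\t0\t0\t*\t*\tNM:i:0",
    "r4\t0\tchrA\t90\t0\t36M\t*\t0\t0\t*\t*",
    "r5\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",
    "r6\t256\tchrA\t30\t30\t36M\t*\t0\t0\t*\t*"
  ), sam)
  pl <- ingest_sam(sam, list(ct))
  expect_equal(nrow(pl), 3L)
  expect_equal(pl$read_id, c("r1", "r2", "r3"))
  expect_equal(pl$start, c(9L, 49L, 69L))
  expect_equal(pl$strand, c("+", "-", "+"))
  expect_equal(pl$mismatches, c(1L, 0L, 0L))
  s <- attr(pl, "summary")
  expect_equal(s$unmapped, 1L)
  expect_equal(s$secondary, 1L)
  expect_equal(s$low_mapq, 1L)

  # empty body with valid header
  empty <- file.path(dir, "empty.sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:chrA\tLN:200"), empty)
  expect_equal(nrow(ingest_sam(empty, list(ct))), 0L)

  # unknown contig and malformed record are hard errors with positions
  bad1 <- file.path(dir, "bad1.sam")
  writeLines(c("@SQ\tSN:chrA\tLN:200",
               "r1\t0\tchrB\t10\t30\t36M\t*\t0\t0\t*\t*"), bad1)
  expect_error(ingest_sam(bad1, list(ct)), "chrB")
  bad2 <- file.path(dir, "bad2.sam")
  writeLines(c("@SQ\tSN:chrA\tLN:200", "r1\t0\tchrA"), bad2)
  expect_error(ingest_sam(bad2, list(ct)), "line 2")
})

test_that("built-in mapper placements round-trip through SAM", {
  set.seed(43)
  ct <- masked_contig("c1", rand_dna(500))
  reads <- short_reads(paste0("r", 1:8), vapply(1:8, function(i) {
    p <- sample(465, 1)
    s <- substr(ct$seq, p, p + 35)
    if (i %% 2 == 0) rc_string(s) else s
  }, ""))
  pl <- map_reads_unique(reads, list(ct), 2)
  dir <- withr::local_tempdir()
  sam <- file.path(dir, "out.sam")
  write_sam(pl, list(ct), sam, reads = reads)
  back <- ingest_sam(sam, list(ct))
  expect_equal(placements_key(back), placements_key(pl))
})

test_that("possible_placements sums per-segment window counts", {
  ct1 <- masked_contig("p1", strrep("A", 100))
  expect_equal(possible_placements(ct1, 36), 65L)

  mask <- c(rep(FALSE, 100), TRUE, rep(FALSE, 35))
  ct2 <- masked_contig("p2", strrep("A", length(mask)), mask = mask,
                       honor_softmask = FALSE)
  expect_equal(possible_placements(ct2, 36), 65L)  # 35-bp segment holds none

  mask3 <- c(rep(FALSE, 36), TRUE, rep(FALSE, 36))
  ct3 <- masked_contig("p3", strrep("A", length(mask3)), mask = mask3,
                       honor_softmask = FALSE)
  expect_equal(possible_placements(ct3, 36), 2L)
  expect_equal(possible_placements(masked_contig("p4", strrep("N", 50)), 36), 0L)
})

test_that("coverage and read depth match their definitions", {
  ct <- masked_contig("f1", strrep("A", 100))
  one <- compute_features(ct, 0L, 36)
  expect_equal(one$coverage, 0.36)
  expect_equal(one$read_depth, 1 / 65)
  expect_true(one$eligible)

  zero <- compute_features(ct, integer(0), 36)
  expect_equal(zero$coverage, 0)
  expect_equal(zero$read_depth, 0)
  expect_equal(zero$n_reads, 0L)

  two <- compute_features(ct, c(0L, 10L), 36)
  expect_equal(two$coverage, 0.46)
  expect_equal(two$read_depth, 2 / 65)

  # ineligible: no unmasked base at all
  blank <- compute_features(masked_contig("f2", strrep("N", 60)), integer(0), 36)
  expect_false(blank$eligible)
})

test_that("features agree with the per-base oracle and are monotone", {
  set.seed(44)
  for (i in 1:5) {
    n <- sample(150:400, 1)
    m <- runif(n) < 0.15
    ct <- masked_contig(paste0("o", i), rand_dna(n), mask = m,
                        honor_softmask = FALSE)
    pp <- possible_placements(ct, 36)
    starts <- sample(0:(n - 36), sample(0:8, 1))
    got <- compute_features(ct, starts, 36)
    want <- oracle_features(ct, starts, 36)
    expect_equal(got$coverage, want$coverage)
    expect_equal(got$read_depth, want$read_depth)
    expect_equal(got$possible_placements, want$possible_placements)

    # adding a placement never decreases either feature
    extra <- compute_features(ct, c(starts, sample(0:(n - 36), 1)), 36)
    expect_gte(extra$coverage, got$coverage)
    expect_gte(extra$read_depth, got$read_depth)
  }
})

test_that("contig_features keys placements to the right contigs", {
  set.seed(45)
  contigs <- list(masked_contig("a", rand_dna(200)),
                  masked_contig("b", rand_dna(300)))
  pl <- data.frame(read_id = c("r1", "r2", "r3"),
                   contig_id = c("a", "b", "b"),
                   start = c(0L, 10L, 50L), strand = "+", mismatches = 0L)
  fx <- contig_features(contigs, pl, 36)
  expect_equal(fx$n_reads, c(1L, 2L))
  expect_equal(fx$contig_id, c("a", "b"))
})
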