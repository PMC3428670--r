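test_that("genome specs validate their feasibility constraints", {
  expect_s3_class(genome_spec(), "genome_spec")
  expect_error(genome_spec(repeat_unit_len = c(2000, 3000),
                           len_range = c(1000, 1500)), "repeat unit")
  expect_error(genome_spec(gametolog_len = 5000, len_range = c(1000, 2000)),
               "gametolog stretch")
  expect_error(genome_spec(n_gametolog = 50, n_w = 10, n_z = 20), "gametolog pairs")
  expect_error(genome_spec(n_male_deleted = 10, n_auto = 5), "male-deletion")
  expect_error(genome_spec(gametolog_site_spacing = 40, read_length = 36),
               "spacing")
})

test_that("the generator honors counts, labels, and planted structure", {
  spec0 <- genome_spec(n_w = 0, n_z = 5, n_auto = 10,
                       len_range = c(500, 800), n_gametolog = 0,
                       repeat_fraction = 0, seed = 3)
  sim0 <- simulate_genome(spec0)
  expect_equal(sum(sim0$truth$class == "W"), 0L)
  expect_equal(nrow(sim0$truth), 15L)
  expect_equal(anyDuplicated(sim0$truth$contig_id), 0L)

  # repeat fraction 0: the duplicate finder sees nothing
  expect_equal(nrow(find_duplicate_regions(sim0$contigs, 50)), 0L)

  # planted repeats are found, at roughly the requested genome fraction
  spec1 <- genome_spec(n_w = 3, n_z = 5, n_auto = 12,
                       len_range = c(1500, 2500), repeat_fraction = 0.08,
                       n_gametolog = 0, seed = 4)
  sim1 <- simulate_genome(spec1)
  expect_gte(sum(sim1$truth$repeat_bases), 0.08 * sum(sim1$truth$length))
  dup <- find_duplicate_regions(sim1$contigs, 50)
  expect_gt(nrow(dup), 0L)
  masked_bp <- sum(dup$end - dup$start)
  expect_gte(masked_bp, 0.8 * sum(sim1$truth$repeat_bases))

  # identical seed, identical genome
  expect_identical(vapply(simulate_genome(spec1)$contigs, `[[`, "", "seq"),
                   vapply(sim1$contigs, `[[`, "", "seq"))
})

test_that("a planted three-copy repeat is reported at every copy", {
  set.seed(55)
  unit <- rand_dna(80)
  c1 <- masked_contig("h1", paste0(rand_dna(120), unit, rand_dna(90), unit,
                                   rand_dna(70)))
  c2 <- masked_contig("h2", paste0(rand_dna(60), unit, rand_dna(100)))
  iv <- find_duplicate_regions(list(c1, c2), 50)
  m <- mask_from_intervals(list(c1, c2), iv)
  expect_true(all(m[[1]][121:200]))
  expect_true(all(m[[1]][291:370]))
  expect_true(all(m[[2]][61:140]))
})

test_that("read counts follow depth x genome / r and no read comes from W", {
  spec <- genome_spec(n_w = 5, n_z = 10, n_auto = 20,
                      len_range = c(800, 1200), seed = 12)
  sim <- simulate_genome(spec)
  total <- sum(sim$truth$length)
  reads <- simulate_male_reads(sim, depth = 0.45)
  expect_equal(nrow(reads), round(0.45 * total / 36))

  w_ids <- sim$truth$contig_id[sim$truth$class == "W"]
  for (s in c(1, 2, 3)) {
    rs <- simulate_male_reads(sim, seed = s)
    expect_false(any(attr(rs, "origin")$contig_id %in% w_ids))
  }

  # rerunning with the same seed is byte-identical
  r1 <- simulate_male_reads(sim, seed = 99)
  r2 <- simulate_male_reads(sim, seed = 99)
  expect_identical(r1$seq, r2$seq)

  spec_empty <- genome_spec(n_w = 2, n_z = 0, n_auto = 0,
                            len_range = c(500, 600), n_gametolog = 0,
                            repeat_fraction = 0, seed = 1)
  expect_error(simulate_male_reads(simulate_genome(spec_empty)),
               "no eligible source")
})

test_that("per-contig read counts follow the multinomial sampling model", {
  # chi-square goodness of fit of origin counts against window proportions,
  # Bonferroni-adjusted over seeds
  n_seeds <- 5
  alpha <- 0.01 / n_seeds
  spec <- genome_spec(n_w = 0, n_z = 10, n_auto = 20,
                      len_range = c(1500, 2500), n_gametolog = 0,
                      repeat_fraction = 0, error_rate = 0,
                      source_divergence = 0, seed = 13)
  sim <- simulate_genome(spec)
  nwin <- vapply(sim$contigs, function(ct) nchar(ct$seq) - 35L, 0L)
  names(nwin) <- sim$truth$contig_id
  for (s in seq_len(n_seeds)) {
    reads <- simulate_male_reads(sim, depth = 2, seed = 100 + s)
    org <- attr(reads, "origin")
    counts <- table(factor(org$contig_id, levels = names(nwin)))
    gof <- suppressWarnings(stats::chisq.test(as.numeric(counts),
                                              p = nwin / sum(nwin)))
    expect_gt(gof$p.value, alpha)
  }
})

test_that("gametolog W contigs recruit male reads in their shared stretch", {
  spec <- genome_spec(n_w = 4, n_z = 8, n_auto = 12,
                      len_range = c(1500, 2500), n_gametolog = 2,
                      gametolog_len = 600, repeat_fraction = 0, seed = 14)
  sim <- simulate_genome(spec)
  reads <- simulate_male_reads(sim, depth = 2)
  prep <- prep_reference(sim$contigs)
  # the diverged gametolog stretch must not be masked as an exact duplicate
  g <- sim$gametologs
  for (i in seq_len(nrow(g))) {
    wct <- prep$contigs[[match(g$w_id[i], sim$truth$contig_id)]]
    expect_true(all(!wct$mask[(g$w_start[i] + 1):(g$w_start[i] + g$len[i])]))
  }
  pl <- map_reads_unique(filter_low_complexity(dedupe_reads(reads)),
                         prep$contigs, 2)
  on_w <- pl[pl$contig_id %in% g$w_id, , drop = FALSE]
  expect_gt(nrow(on_w), 0L)
  # and those reads land inside the shared stretch
  st <- stats::setNames(g$w_start, g$w_id)
  en <- st + stats::setNames(g$len, g$w_id)
  expect_true(all(on_w$start + 36 > st[on_w$contig_id] &
                  on_w$start < en[on_w$contig_id]))
  # non-gametolog W contigs receive nothing
  pure_w <- sim$truth$contig_id[sim$truth$class == "W" & !sim$truth$is_gametolog]
  expect_equal(sum(pl$contig_id %in% pure_w), 0L)
})

test_that("male-deletion contigs show the W signature and are flagged in truth", {
  spec <- genome_spec(n_w = 10, n_z = 15, n_auto = 40,
                      len_range = c(1300, 2200), n_gametolog = 0,
                      n_male_deleted = 3, seed = 15)
  sim <- simulate_genome(spec)
  del <- sim$truth$contig_id[sim$truth$is_male_deleted]
  expect_length(del, 3L)
  expect_true(all(sim$truth$class[sim$truth$is_male_deleted] == "NONW"))
  reads <- simulate_male_reads(sim)
  expect_false(any(attr(reads, "origin")$contig_id %in% del))
  prep <- prep_reference(sim$contigs)
  pl <- map_reads_unique(filter_low_complexity(dedupe_reads(reads)),
                         prep$contigs, 2)
  fx <- contig_features(prep$contigs, pl, 36)
  expect_true(all(fx$coverage[fx$contig_id %in% del] == 0))
  # a classifier trained on the labeled features calls them W: the documented
  # failure mode of read-depth subtraction
  m <- wbayes(fx[fx$eligible & !(fx$contig_id %in% del), ])
  calls <- classify(fx[fx$contig_id %in% del, ], m)
  expect_true(all(calls$call == "W"))
})

test_that("empirical zero-hit frequency matches the occupancy closed form", {
  pp <- 965L           # a fully unmasked 1-kb contig, r = 36
  total <- 20000L
  n_reads <- 60L
  p0 <- expected_zero_hit_probability(pp, n_reads, total)
  n_draws <- 10000
  hits <- with_seed(16, {
    vapply(seq_len(n_draws), function(i) {
      !any(sample.int(total, n_reads, replace = TRUE) <= pp)
    }, TRUE)
  })
  se <- sqrt(p0 * (1 - p0) / n_draws)
  expect_lt(abs(mean(hits) - p0), 3 * se)

  expect_equal(expected_zero_hit_probability(pp, 0, total), 1)
  expect_equal(expected_zero_hit_probability(total, 5, total), 0)
  expect_error(expected_zero_hit_probability(0, 5, total), "no placement")
  expect_error(expected_zero_hit_probability(100, 5, 50), "total_placements")
})

test_that("fixtures round-trip identically through disk", {
  spec <- genome_spec(n_w = 4, n_z = 6, n_auto = 10,
                      len_range = c(700, 1100), seed = 17)
  sim <- simulate_genome(spec)
  reads <- simulate_male_reads(sim)
  prep <- prep_reference(sim$contigs)
  pl <- map_reads_unique(filter_low_complexity(dedupe_reads(reads)),
                         prep$contigs, 2)
  dir <- withr::local_tempdir()
  # write the prepped (masked) contigs so masks travel through the BED file
  sim_prepped <- sim
  sim_prepped$contigs <- prep$contigs
  write_fixture(sim_prepped, reads, dir, placements = pl)

  back <- read_fixture(dir)
  expect_equal(back$truth, sim$truth)
  expect_equal(back$reads$seq, reads$seq)
  expect_equal(lapply(back$contigs, `[[`, "mask"),
               lapply(prep$contigs, `[[`, "mask"))
  fx1 <- contig_features(prep$contigs, pl, 36)
  fx2 <- contig_features(back$contigs,
                         ingest_sam(file.path(dir, "placements.sam"),
                                    back$contigs), 36)
  expect_equal(fx2, fx1)

  # same spec seed regenerates byte-identical reads
  sim_b <- simulate_genome(spec)
  reads_b <- simulate_male_reads(sim_b)
  dir2 <- withr::local_tempdir()
  write_fixture(sim_b, reads_b, dir2)
  expect_identical(readLines(file.path(dir2, "reads.fastq")),
                   readLines(file.path(dir, "reads.fastq")))
})
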