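# Shared synthetic fixtures, built once per test run and memoised.
.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# Small labeled feature set for classifier/evaluation unit tests.
small_fixture <- function() {
  memo("small", function() {
    spec <- genome_spec(n_w = 30, n_z = 40, n_auto = 80,
                        len_range = c(1000, 3000), seed = 11)
    sim <- simulate_genome(spec)
    reads <- simulate_male_reads(sim)
    prep <- prep_reference(sim$contigs)
    pl <- map_reads_unique(reads, prep$contigs, 2)
    fx <- contig_features(prep$contigs, pl, 36)
    list(sim = sim, prep = prep, reads = reads, placements = pl,
         features = fx[fx$eligible, ])
  })
}

# The default study-condition fixture (100 W + 1000 non-W contigs, 1-5 kb),
# with nested read sets at several depths: the deepest library is sampled once
# and shallower libraries are its prefixes (a prefix of a uniform sample is a
# uniform sample).
main_fixture <- function() {
  memo("main", function() {
    spec <- genome_spec(seed = 101)
    sim <- simulate_genome(spec)
    prep <- prep_reference(sim$contigs)
    reads_deep <- simulate_male_reads(sim, depth = 2)
    truth <- stats::setNames(sim$truth$class, sim$truth$contig_id)
    depths <- c(0.2, 0.45, 0.9, 2)
    feats <- list()
    placements <- list()
    for (d in depths) {
      n <- round(nrow(reads_deep) * d / 2)
      rd <- filter_low_complexity(dedupe_reads(reads_deep[seq_len(n), ,
                                                          drop = FALSE]))
      pl <- map_reads_unique(rd, prep$contigs, 2)
      fx <- contig_features(prep$contigs, pl, 36)
      fx$label <- unname(truth[fx$contig_id])
      feats[[as.character(d)]] <- fx
      placements[[as.character(d)]] <- pl
    }
    list(spec = spec, sim = sim, prep = prep, depths = depths,
         features = feats, placements = placements)
  })
}

# Longer contigs (6-12 kb) for fragment-length experiments. Half the W
# contigs carry a short gametolog stretch so the W feature distribution has
# the length-dependent spread the real known-W set shows.
length_fixture <- function() {
  memo("length", function() {
    spec <- genome_spec(n_w = 120, n_z = 80, n_auto = 220,
                        len_range = c(6000, 12000), n_gametolog = 60,
                        gametolog_len = 300, seed = 202)
    sim <- simulate_genome(spec)
    prep <- prep_reference(sim$contigs)
    reads <- simulate_male_reads(sim, depth = 0.45)
    rd <- filter_low_complexity(dedupe_reads(reads))
    pl <- map_reads_unique(rd, prep$contigs, 2)
    truth <- stats::setNames(sim$truth$class, sim$truth$contig_id)
    frag_features <- function(L) {
      fr <- fragment_genome(prep$contigs, L)
      fpl <- fragment_placements(pl, prep$contigs, L, 36)
      fx <- contig_features(fr, fpl$placements, 36)
      fx$L <- L
      fx
    }
    list(sim = sim, prep = prep, placements = pl, truth = truth,
         frag_features = frag_features)
  })
}

# Whole-contig fixture for the training-size and imbalance experiments.
# Half the W contigs are gametologs, giving the W class the coverage spread
# the real known-W training set shows (its printed coverage CI reaches 0.083):
# a point-mass W class admits no learning-curve or imbalance effect.
experiment_fixture <- function() {
  memo("experiment", function() {
    spec <- genome_spec(n_w = 250, n_z = 400, n_auto = 1200,
                        len_range = c(1000, 5000), n_gametolog = 125,
                        gametolog_len = 600, seed = 303)
    sim <- simulate_genome(spec)
    prep <- prep_reference(sim$contigs)
    reads <- simulate_male_reads(sim, depth = 0.45)
    rd <- filter_low_complexity(dedupe_reads(reads))
    pl <- map_reads_unique(rd, prep$contigs, 2)
    fx <- contig_features(prep$contigs, pl, 36)
    list(sim = sim, features = fx[fx$eligible, ])
  })
}
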