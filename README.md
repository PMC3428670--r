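# wlinker

Identification of W-linked contigs in a heterogametic (ZW) genome assembly by
male read-depth subtraction.

## The problem

In ZZ/ZW species (birds, many reptiles and fish) the female-limited W
chromosome resists whole-genome shotgun assembly: it is repeat-rich, gets
half the autosomal sequencing depth in a heterogametic individual, and most
of it ends up as short unanchored contigs. `wlinker` finds the W-linked
contigs among them by subtraction: a male (ZZ) genome contains no W-specific
sequence, so short reads from a male, uniquely aligned to the female
assembly, should cover every contig *except* the W-specific ones. The same
logic finds Y-linked contigs in XX/XY systems using female reads.

## The method

Each contig, after masking of repeats, exact duplications (> 50 bp) and
unmasked segments shorter than 50 bp, is summarized by a feature vector
X = (x1, x2):

* **x1, coverage** — the fraction of unmasked bases covered by ≥ 1 uniquely
  mapped male read;
* **x2, read depth** — the number of uniquely mapped reads divided by the
  number of positions where a read of length r fits entirely in unmasked
  sequence.

A read is "uniquely mapped" when it has a single strictly best placement
(fewest mismatches, both strands, ≤ 2 mismatches for 36-bp reads) genome-wide.
Contigs are classified with a length-conditioned naive Bayes model: features
are discretized into equal-width bins (default 0.005), the class-conditional
bin frequencies P(x_i | C, L) are estimated per 500-bp contig-length bin from
fragmented training genomes with an ε smoothing term (default 1e-6), and the
posterior

    P(W | X, L) = π P(X | W, L) / [ π P(X | W, L) + (1 − π) P(X | nonW, L) ]

with P(X | C, L) = P(x1 | C, L) P(x2 | C, L) is thresholded at τ = 0.95.
Bootstrap statistics (percentile CIs of mean coverage/read depth; a
quantile-separation test comparing the W maximum with the non-W minimum
across 1000 replicates) quantify how cleanly the two classes separate, and
ROC/AUC harnesses evaluate training-set size, class imbalance and
length-transfer behaviour. A synthetic ZW/ZZ generator produces fully
labeled assemblies and male read sets so the whole pipeline is testable
end to end.

## Worked example

```r
library(wlinker)

spec <- genome_spec(n_w = 20, n_z = 30, n_auto = 60,
                    len_range = c(1000, 2500), seed = 21)   # 36-bp reads, 0.45x
sim   <- simulate_genome(spec)
reads <- simulate_male_reads(sim)

# a third of the contigs pretend to be unanchored (chrUn-style)
labels <- data.frame(contig_id = sim$truth$contig_id, label = sim$truth$class)
set.seed(2); unk <- sample(nrow(labels), 40)
labels$label[unk] <- "UNMAPPED"

res <- run_pipeline(run_config(seed = 9), sim$contigs, reads,
                    labels = labels, out_dir = "wlinker-run")
#> prep: 110 contigs in
#> prep: 184719 unmasked bp after filtering
#> reads: 2435 in, 2425 after dedupe, 2425 after low-complexity filter
#> map: 2283 unique placements (n_placed=2283, n_ambiguous=0, n_unplaced=142)
#> train: dropped 7 training contig(s) in length bins lacking a class
#> classify: 12 contig(s) fall in length bins without a trained distribution and are not scored
#> classify: 6 W calls of 28 classified contigs at tau=0.95

head(res$calls, 3)
#>   contig_id    L coverage read_depth posterior_w call
#> 1    W_0002 1500        0          0           1    W
#> 2    W_0006 2000        0          0           1    W
#> 3    W_0008 2000        0          0           1    W

print(res$stats$separation_coverage)
#> Quantile-separation test: p < 0.001  (B=1000, mean gap 0.2354)
```

All six unanchored contigs called W (posterior > 0.95) are truly W-specific
in the generator's truth table, each with the expected signature — zero
coverage and zero read depth. The separation test reports that in none of
1000 bootstrap replicates did the lowest non-W coverage drop to the highest
W coverage (p below 1/B, the clean split the method relies on). The two
`classify` messages show the pipeline refusing to score contigs whose
500-bp length bin lacks labeled training data of both classes — on this
deliberately tiny example several bins are sparse; at realistic contig
counts none are dropped. `res$features`, `wlinker-run/calls.tsv` and
`wlinker-run/stats.json` carry the full per-contig table, the ranked calls
and the bootstrap report; `wlinker-run/manifest.json` records the config
hash and the filtering funnel.

A thin command-line wrapper with `simulate`, `prep`, `features`, `run`,
`train`, `classify` and `stats` subcommands is installed at
`system.file("exec", "wlinker", package = "wlinker")`.

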