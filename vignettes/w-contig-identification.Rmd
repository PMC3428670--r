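---
title: "Identifying W-linked contigs by male read-depth subtraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying W-linked contigs by male read-depth subtraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wlinker)
```

## The problem and the idea

In species with ZZ/ZW sex determination (birds, many reptiles and fish), the
female-limited W chromosome assembles poorly: it is repeat-rich, receives half
the sequencing depth of autosomes in a heterogametic individual, and cannot be
scaffolded with a genetic map. Much of it ends up as short, unanchored contigs.

`wlinker` implements a subtraction strategy for finding the W-linked needles
in that haystack. A male (ZZ) carries no W sequence, so short reads from a
male, aligned back to the female assembly, should recruit to every contig
*except* those that are W-specific. Contigs that attract essentially no
uniquely mapping male reads are candidate W contigs. The same logic applies
to Y-chromosome discovery in XX/XY systems with female reads.

## Features

Each contig is summarized by two statistics computed over its *unmasked*
bases only:

* **coverage** (`x1`): the fraction of unmasked bases covered by at least one
  uniquely mapped read — a breadth measure in `[0, 1]`;
* **read depth** (`x2`): the number of uniquely mapped reads divided by the
  number of start positions at which a read of length `r` fits entirely
  within unmasked sequence (`possible_placements()`), a length-normalized
  count analogous to RPKM. Cross-library normalization is deliberately not
  applied: the method uses a single read library.

W-specific contigs should sit near `(0, 0)`; autosomal and Z-linked contigs
should not.

## Reference preparation

Unique mapping is meaningful only on unique sequence, so the reference is
filtered first (`prep_reference()`):

1. external masks (RepeatMasker-style BED intervals, or soft-masked FASTA)
   are honored;
2. `find_duplicate_regions()` masks every exact repeat longer than 50 bp
   occurring at two or more locations, on either strand, within or across
   contigs — a self-alignment stand-in implemented by counting canonical
   51-mers. "Larger than 50 bp" is read strictly: a repeat of exactly 50 bp
   survives. Diverged (non-identical) duplications are out of scope; the
   exactness is what keeps the operation testable against an independent
   brute-force oracle;
3. `drop_short_segments()` masks unmasked runs shorter than 50 bp, which are
   too short to place a read reliably.

Coordinates are 0-based half-open internally and in BED I/O.

## Unique read mapping

`map_reads_unique()` is a seed-and-extend Hamming mapper (compiled code, as
is usual for alignment kernels): a read is kept only when it has a single
strictly best placement — fewest mismatches over both strands, genome-wide —
and that placement overlaps no masked base. Ties at the best mismatch count
discard the read. Defaults: 36-bp reads, up to 2 mismatches (chosen for
GA-era read lengths and within-species divergence between the read source
and the reference; both configurable). Pigeonhole seeding (`max_mismatches +
1` non-overlapping exact 12-mers) enumerates every placement within the
mismatch budget, so the mapper is exhaustive, and the test suite checks it
base-for-base against a sliding-window scan. Reads may also be supplied as
SAM from an external aligner (`ingest_sam()`: primary, mapped,
MAPQ-thresholded records).

Read QC before mapping: exact-duplicate removal and a mononucleotide-fraction
low-complexity filter (default threshold 0.8; the original QC criterion is
not specified anywhere authoritative, so a simple, testable rule was chosen).

## The classifier

`wbayes()` fits a naive Bayes model over the discretized features,

* P(X | C, L) = P(x1 | C, L) · P(x2 | C, L), with C ∈ {W, non-W},
* features discretized into equal-width bins (default width 0.005, the
  cross-validated optimum; widths from 0.0005 to 0.05 are sensible),
* every bin frequency smoothed by ε (default 1e-6) at lookup time, so no
  feature bin has zero probability,
* conditioned on contig length L rounded to the nearest 500 bp (ties round
  up, floored at 500): short contigs have noisier features purely from
  sampling, so the class-conditional distributions are estimated separately
  per length bin from fragmented training genomes (`fragment_genome()`).

Two posterior modes are provided. `standard` applies Bayes' rule with both
class priors: π·P(X|W,L) / (π·P(X|W,L) + (1−π)·P(X|nonW,L)). `as_printed`
reproduces the published formula literally, with the W prior in the numerator
only and an unweighted likelihood sum in the denominator; the two coincide at
π = 0.5 up to a factor. The default prior is the W proportion of the training
set, overridable. Likelihoods are evaluated in log space; the results agree
with direct products to 1e-12 relative (tested).

Numerical conventions: bins are half-open `[k·w, (k+1)·w)`, with coverage
exactly 1.0 closed into the top bin; a 1e-9 relative tolerance in
`discretize()` keeps exact bin boundaries from drifting across floating-point
representations. A length bin absent from the model is a hard error at
prediction time — never a silent nearest-bin fallback. `run_pipeline()`
trains only on length bins containing both classes and reports (rather than
silently drops) contigs it cannot score.

`classify()` calls a contig W when its posterior strictly exceeds τ = 0.95
(so τ = 1 calls nothing), excludes contigs with no possible placement, and
returns calls sorted by descending posterior.

## Separation statistics

`bootstrap_ci()` gives percentile bootstrap CIs (B = 1000) for mean coverage
and read depth per class. `quantile_separation_test()` resamples both groups
jointly per replicate and records `min(non-W) − max(W)`; the reported `p` is
the fraction of replicates in which the difference is not positive. The
published description orders the difference the other way while stating it
"should be positive" under separation; the implementation uses the
separation-positive orientation and retains the literal-order values
(sign-flipped) alongside. Groups are resampled as whole contigs, preserving
the coverage/read-depth dependence; a `p` of zero is printed as `< 1/B`.
`w_coverage_threshold()` (the bootstrap mean of the W coverage maximum) feeds
`fpr_by_length()`, the fraction of non-W fragments below that coverage
threshold per fragment length — the curve that motivates length conditioning,
rising steeply below ~1.5 kb in line with the closed-form occupancy law
`expected_zero_hit_probability()`.

## The synthetic data generator

`genome_spec()` + `simulate_genome()` + `simulate_male_reads()` build fully
labeled ZW/ZZ datasets so every stage is testable without downloads. The
generator emulates:

* i.i.d. uniform-composition contigs for W, Z and autosomes (defaults:
  100 W + 1000 non-W, 1–5 kb);
* male reads of 36 bp at 0.45× of total reference length (the published
  sequencing conditions), sampled uniformly over non-W windows — Z at the
  same per-copy rate as autosomes, since a ZZ male carries two Z — with
  substitution errors (0.002/base) and reference-vs-read-source divergence
  (0.002/base, a different-breed scale);
* planted exact repeats (5% of the genome in 150–300 bp units) that
  `find_duplicate_regions()` must catch;
* **gametolog pairs**: a W contig and a Z contig share a stretch, identical
  except for one divergent site per read window; the male genome carries the
  W-like sequence at the Z locus. Male reads from that locus therefore map
  uniquely *to the W contig*, reproducing the documented failure mode in
  which recent W/Z duplications leave W contigs visibly covered. (Verbatim
  identical copies would instead be masked as duplicates or discarded as
  ambiguous placements.) Defaults plant 2 pairs with 150-bp stretches —
  a curated-training-set scale;
* **male-deletion contigs** (off by default): present in the reference,
  absent from the read source; they show the W signature and are called W,
  the other documented failure mode.

What the generator does *not* emulate: GC or positional sampling bias,
indels, quality scores, paired ends, diverged repeat families, assembly
errors, or validation label noise. Passing tests therefore demonstrate the
method's statistical machinery, not robustness to the full messiness of real
assemblies.

### Fixture choices in the test suite

* The default spec *is* the study condition for separation and recovery
  checks (0.45×, 36 bp, 100 W / 1000 non-W at 1–5 kb). Depth comparisons use
  nested read sets — shallower libraries are prefixes of the deepest one — a
  coupling that reduces variance while each prefix remains a uniform sample.
* The training-size and imbalance experiments use a gametolog-rich spec
  (half of 250 W contigs carry 600-bp gametolog stretches): the real known-W
  training contigs demonstrably recruit some male reads (their mean-coverage
  CI extends to ~0.08), and a W class collapsed to a point at (0, 0) is
  learned perfectly from one example, leaving no training-size effect to
  measure. The spread scale matches that CI.
* The length-transfer experiment uses 6–12 kb contigs (so multi-kb fragments
  exist) with 300-bp gametolog stretches, making the W fragment distribution
  genuinely length-dependent. Per-length training draws keep the published
  200 W + 200 non-W composition; the fixed-length grid (500, 1000, 2500 bp)
  covers the lengths that can supply 200 W training fragments at this scale.
* The training-size experiment uses a nested, shared-validation design
  (training draws for larger sizes extend those for smaller sizes within an
  iteration) — the standard learning-curve protocol, which isolates the
  information-gain effect from draw noise.
* Problem sizes throughout (3–6 Mb genomes, tens of thousands of reads,
  10–25 harness iterations) were chosen as the smallest at which the
  qualitative phenomena are stable.

## Evaluation harnesses

`roc_curve()`/`auc()` implement the trapezoidal ROC with tie grouping, which
equals Mann–Whitney pairwise concordance (ties counted one half) — asserted
exactly in tests and cross-checked against pROC. `cross_validate()` repeats
random train/validation splits (allocating training draws proportionally
across length bins when conditioning, so no validation bin lacks a trained
distribution); `size_experiment()`, `imbalance_experiment()` and
`length_transfer_experiment()` return seeded, auditable grids with per-
iteration AUC matrices retained.

## Known limitations and observed deviations

* Only exact duplications are masked; diverged repeats must come from an
  external masker.
* Pseudoautosomal-like sequence (identical between Z and W) is invisible to
  the method by construction: reads tie and are discarded.
* On clean synthetic data the imbalance trend runs opposite to the published
  one: enlarging the non-W:W training ratio from 10 to 100 *raises* mean AUC
  slightly (more majority-class data only sharpens the non-W density toward
  the Bayes-optimal ranking, and the class prior cancels in ranking). The
  published decrease arose in independent tests against a PCR-confirmed
  validation set whose labels are themselves noisy — contigs failing to
  yield a female-specific marker may still be W-linked — and that label
  noise is intentionally outside the generator's scope. The corresponding
  acceptance check is implemented as specified and documents this outcome
  rather than being weakened.
* At very low depth, zero-coverage non-W fragments are an irreducible source
  of ties with true W contigs; accuracy recovers with depth, as the
  depth-graded cross-validation shows.

## A worked run

```{r, eval = FALSE}
spec <- genome_spec(seed = 7)
sim <- simulate_genome(spec)
reads <- simulate_male_reads(sim)
labels <- data.frame(contig_id = sim$truth$contig_id,
                     label = sim$truth$class)
res <- run_pipeline(run_config(seed = 7), sim$contigs, reads,
                    labels = labels, out_dir = "wlinker-run")
head(res$calls)
print(res$stats$separation_coverage)
```

The same flow is scriptable from a shell via the thin CLI in
`system.file("exec", "wlinker", package = "wlinker")` (subcommands
`simulate`, `prep`, `features`, `run`, `train`, `classify`, `stats`).
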