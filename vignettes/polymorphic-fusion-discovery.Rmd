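---
title: "Bottom-up discovery and genotyping of polymorphic gene fusions"
author: "polyfusion authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bottom-up discovery and genotyping of polymorphic gene fusions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyfusion)
```

## The scientific problem

Chimeric RNAs — transcripts joining sequence from two parental genes — are
classically read as markers of somatic gene fusions, but they also arise in
healthy tissue, either from germline structural variants (SVs) that rewire
two neighbouring genes, or from RNA-level intergenic splicing with no DNA
change at all.  A chimera caused by a segregating DNA variant has a
characteristic signature: it appears in a *subset of individuals* (tracking
the allele through a population) yet in *many tissues within each carrier*
(the variant is in every cell).  Tissue-restricted splicing noise shows the
opposite pattern.

`polyfusion` implements this bottom-up logic as a reusable, testable
pipeline:

1. **Catalog filtering** (`confidenceFilter()`, `polymorphicFilter()`,
   `classifyJunction()`, `predictFrame()`): ingest chimeric-RNA prediction
   tables, drop low-confidence predictions, and keep chimeras with the
   polymorphic population/tissue pattern.
2. **Alignment-free genotyping** (`fuzzyMatch()`, `remapClassify()`,
   `callGenotype()`, `genotypeCohort()`): genotype the causal SV directly
   from raw reads by approximate matching of breakpoint-spanning queries,
   followed by re-mapping validation against the reference.
3. **SV evidence** (`extractSignatures()`, `classifySv()`,
   `matchSvToChimera()`): corroborate the variant from discordant
   read-pair orientation signatures and coverage profiles.
4. **Population genetics** (`alleleFrequency()`, `hweTest()`,
   `detectionSummary()`): per-population allele frequencies,
   Hardy–Weinberg tests and occurrence tables.
5. **Phenotype association** (`filterCodes()`, `fitCodeAssociation()`,
   `phewas()`): covariate-adjusted clinical-code screens and a
   phenome-wide scan under dominant/additive models.
6. **Synthetic cohorts** (`buildGenome()`, `applySV()`, `sampleCohort()`,
   `simulateWgs()`, `simulateChimeraTable()`, `simulatePhenotypes()`):
   toy genomes with planted SV alleles and full ground truth, so every
   stage above is validated against known answers without any
   controlled-access data.

`runPipeline()` orchestrates the stages end to end from a single seeded
configuration (`demoConfig()` is a complete example); a thin command-line
wrapper is installed at `inst/scripts/polyfusion.R`.

## Models and procedures

### The polymorphic filter

For each chimera we count the unique individuals in which it is detected,
and within each expressing individual the fraction of that individual's
samples containing it and the number of distinct tissues.  A chimera is
selected when it appears in fewer than 250 individuals (strict), while the
mean per-individual sample fraction exceeds 2/3 and the mean unique-tissue
count exceeds 5 (both strict).  The population cap rejects ubiquitous
transcripts; the within-carrier breadth requirements reject
tissue-restricted splicing noise.

Two aggregation semantics are provided because the breadth requirement can
be read per individual or as a cohort mean.  The default (`"mean"`)
averages the per-individual sample fraction and tissue count over
expressing individuals, matching the way such filters are usually plotted
(mean proportion of samples per individual); `"per_individual_all"`
demands that every expressing individual clear both thresholds, which is
stricter and fragile to a single poorly-sampled carrier.  The 2/3
threshold is exact thirds by default (a 66% reading is configurable via
`minSampleFraction`).

### Junction classes and reading frames

Junction sides are labelled `E` (end-of-exon) when they fall within ±2 bp
of the appropriate annotated exon edge — donor side against exon 3′ ends,
acceptor side against exon 5′ starts, both strand-aware — and `M`
otherwise; `E_E` junctions are the hallmark of genuine splicing.  Frame
prediction declares a fusion `IN_FRAME` when the CDS length contributed by
the 5′ partner up to the junction is congruent modulo 3 with the CDS phase
of the 3′ partner at its junction, `FRAMESHIFT` otherwise, and
`NON_CODING` when either partner contributes no CDS at the junction (5′
junction in the 5′UTR, or 3′ junction beyond the CDS).  Mid-exon
junctions without resolvable phase default to `NON_CODING`: without
transcript-level modelling the phase of an `M` junction is ill-defined.

### Alignment-free breakpoint genotyping

A variant allele creates novel DNA adjacencies.  Short queries (default
70 bp) are designed over each novel junction (`JUNCTION` role), inside
each deleted interval (`DEL_INTERNAL`: present only while a reference
allele remains), and in unrearranged sequence near the locus (`CTRL`: a
positive control for data presence).  `fuzzyMatch()` returns every read
containing a substring within Levenshtein distance `maxEdits` of the query
on either strand, by semi-global dynamic programming; the default
`maxEdits = 0` is an exact substring scan, the behaviour of a plain
`agrep` call, and `N` bases always count as mismatches.

Matched reads are validated by re-mapping to the reference with an
11-mer seed + banded Smith–Waterman extension (match +1, mismatch −1,
gap −2).  Sub-threshold split pieces of one read lying at one locus
(within `chainGap`, default 20 kb) are chained into a single alignment —
the behaviour of BLAT-style chained alignments — because a
breakpoint-spanning read *by construction* aligns to the reference in two
pieces.  Chains require score ≥ 90 and identity ≥ 0.90 (identity =
matches / alignment columns, gaps counting against it), and only chains
within 1% of the read's best are kept.  A read is `TRUE_POSITIVE` when
every retained locus lies inside the 100-kb target window,
`FALSE_POSITIVE` when none does, `UNCERTAIN` when both on- and off-target
loci are retained, and reads with no retained alignment are dropped from
evidence.  Only `TRUE_POSITIVE` counts feed the genotype rule.

`callGenotype()` evaluates a boolean presence rule over query roles, a
query being present at ≥ `minReadsPresent` on-target reads (default 1).
The classical three-query rule for a complex inversion–deletion allele —
positive iff `CTRL` and the inversion junction are present and the
deleted-region query is absent — is expressible verbatim
(`"CTRL & JUNCTION & !DEL_INTERNAL"`).  Note that this rule can only be
satisfied by homozygous carriers: a heterozygote retains a reference
allele, so `DEL_INTERNAL` remains present.  The rule engine reproduces
whatever rule it is given and leaves that interpretation to the user; the
package's own carrier-recovery simulations use `"CTRL & JUNCTION"`, for
which junction presence marks carriers of either dosage.

### Discordant-pair SV classification

Paired-end fragments sequenced across a rearrangement breakpoint become
discordant when lifted to reference space.  With mates ordered by
position, `FR` is the concordant geometry; the decision rules are:

* **inversion**: `FF` and `RR` clusters both present (the two breakpoints
  produce "left–left" and "right–right" pairs);
* **complex inversion + deletion**: inversion signature plus an adjacent
  depleted interval (smoothed coverage below 0.7× baseline for at least
  200 bp);
* **tandem duplication**: outward-facing `RF` cluster plus coverage ratio
  > 1.3 inside the implied interval;
* **deletion**: long-insert `FR` cluster (insert beyond mean + 3 sd) plus
  coverage ratio < 0.7;
* **NONE** otherwise.

Every supporting cluster needs ≥ 3 pairs (`minSupport`), which suppresses
stray chimeric fragments at desk-scale coverage.  Pairs are clustered per
orientation class with a positional gap tolerance of one insert mean.
Coverage ratios compare the candidate interval's mean against the median
of the rest of the region (the interval itself, padded, is excluded from
the baseline), and the profile is smoothed with a 101-bp running mean
before run-finding so per-base sampling noise does not fragment depleted
runs.  Breakpoints are reported from cluster bounds (accurate to roughly
the read length), and matching an SV call to a chimera requires each
breakpoint within 100 kb of the respective parental gene plus a geometry
check: deletions/duplications can fuse same-strand neighbours, inversions
opposite-strand neighbours; interchromosomal pairs are never matched by
this intrachromosomal detector.

The gain/loss thresholds 1.3 and 0.7 are quantitative stand-ins for what
is normally judged by eye in a genome browser: they sit roughly halfway
between the expected ratios for two copies versus three (1.5) and two
versus one (0.5) at the simulated depths, and are configurable.

### Population genetics and association

Allele frequency is the standard genotype-count estimator
$(n_1 + 2n_2)/2N$.  The Hardy–Weinberg test is the plug-in chi-square
against $(p^2, 2pq, q^2)N$ with 1 df and no continuity correction
(the conventional default; an exact test conditioning on allele counts is
available for small samples and selectable via `exact = TRUE`).
Percentages in detection summaries are rounded half-up to one decimal to
match occurrence-table formatting.

Clinical-code screens fit covariate-adjusted logistic regressions
(IRLS, tolerance 1e-8, ≤ 100 iterations) with a Wald test on the genotype
coefficient and OR = exp(β).  Codes enter testing with ≥ 20 total donor
instances including ≥ 1 in the carrier group; Bonferroni correction uses
the number of codes tested.  The phenome-wide scan supports a dominant
model (carrier indicator, logistic) and an additive model (allele count,
ordinary linear regression on the binary outcome — the convention of
standard phenome-scan tooling, unusual but deliberate; a logistic-additive
option exists).  Perfect separation is flagged and the Wald p suppressed
rather than silently switching to a penalised estimand, which matters at
the small carrier counts where such screens are run.  Wald (not
likelihood-ratio) tests are used throughout, matching standard PheWAS
tooling.  Duplicate samples per donor are collapsed to unique donors
before counting or testing.

## The synthetic-cohort generator

The generator emulates the study design the pipeline targets: a
multi-population, multi-tissue cohort segregating an SV allele.

* **Genome**: a single contig (20–50 kb in the bundled configurations)
  with uniform random background sequence and two genes in opposing
  orientations, mirroring the geometry in which an inversion can fuse a
  gene to its opposite-strand neighbour.  Coordinates are 0-based
  half-open internally; 1-based only in SAM/BED emissions.
* **SV alleles**: `DEL`, `DUP` (tandem), `INV`, and `COMPLEX_INV_DEL`
  (inversion with adjacent deletion).  `applySV()` returns the alternate
  haplotype, a block map for coordinate liftover, and junction records
  (±70 bp) whose sequences occur verbatim on the haplotype and nowhere in
  the reference.
* **Cohorts**: genotypes drawn Binomial(2, allele frequency) per
  individual — exact Hardy–Weinberg sampling.
* **Reads**: FR-oriented pairs, Normal insert sizes (mean 350, sd 50 by
  default) truncated at the read length, uniform fragment starts,
  uniform substitution errors (default 0.1%; no indel errors, keeping the
  fuzzy-matcher tests interpretable), fragments drawn from the two
  haplotypes in proportion to dosage.  Truth alignments are computed
  through the haplotype→reference liftover, so reads crossing novel
  adjacencies become discordant/split in reference space exactly as an
  aligner would place them.
* **Chimera tables**: carrier samples express the planted fusion with
  penetrance `carrier_prob` (default 0.9 — the per-sample expression
  penetrance in carriers is not well characterised, so this optimistic
  default is exposed as configuration); all samples express it at a small
  genotype-independent background rate modelling trans-splicing (default
  0.005 per sample).  Ubiquitous decoy chimeras are pure background at a
  higher rate.  Confidence scores are Beta-distributed.
* **Phenotypes**: code presence follows
  $\mathrm{logit}(p) = \mathrm{logit}(\text{prevalence}) + \ln(\mathrm{OR})\,g$,
  with age ~ Uniform(20, 80), sex ~ Bernoulli(0.5) and five ancestry PCs
  (standard normal with population-specific mean shifts on the first
  two).  Covariate effects default to zero so a planted genotype effect
  is the only structured signal.

What the generator does **not** emulate: base-quality decay, PCR
duplicates, indel errors, repetitive reference context (beyond decoys
planted explicitly in tests), alignment-reference bias, or correlated
phenotype codes.  Passing recovery tests on these cohorts therefore
demonstrates the *logic* of each stage under its stated assumptions, not
performance on real sequencing data at real loci.

## Problem sizes and numerical choices

The validation suite exercises the pipeline at sizes chosen to make the
statistics meaningful while keeping the full run desk-scale:

* matcher–oracle equivalence on 500 random (query, read, k) triples,
  including reverse-complement and mutated plants, against a brute-force
  `adist` oracle over all substrings;
* carrier genotyping on a 200-sample cohort segregating a complex
  inversion–deletion at 30× coverage on a 20-kb locus (sensitivity ≥
  0.95, specificity ≥ 0.99);
* SV-type recovery over 100 seeded replicates per type at 30× on 50-kb
  contigs (≥ 95% per type; ≥ 99% `NONE` on non-carriers), with planted
  sizes of ~3.2–10 kb;
* polymorphic-filter recovery of 1 planted chimera (carrier frequency
  ~10%, penetrance 0.9, 30 tissues/donor, per-sample trans-splicing
  background 5×10⁻⁴) among 50 ubiquitous decoys (background 0.1/sample)
  in a 300-donor cohort, 100 replicates (≥ 95%);
* Hardy–Weinberg type-I error over 2000 null cohorts (N = 100, p = 0.3),
  expected within [0.03, 0.07];
* logistic OR against the 2×2 cross-product ratio on 50 random
  non-degenerate tables (6 significant digits), and null phenome-scan
  calibration over 500 codes (nominal p < 0.05 fraction within
  [0.03, 0.07], zero Bonferroni hits);
* recovery of a planted clinical-code effect of OR 12.1 under the
  dominant model in a large cohort, where the fitted OR should be close
  and the code top-ranked.

Numerical details worth recording: percentage rounding is half-up;
the chi-square is used without continuity correction; glm fits use
epsilon 1e-8 and maxit 100; separation is detected from extreme fitted
probabilities together with an implausible coefficient magnitude; seed
handling saves and restores the global RNG state so generators are pure
functions of configuration plus seed, with per-stage child seeds derived
from the master seed.

## A worked example

```{r demo, eval = FALSE}
library(polyfusion)
cfg <- demoConfig(outdir = tempfile("pf_"), seed = 42)
manifest <- runPipeline(cfg)

# which chimeras survive the polymorphic filter?
readProvTsv(file.path(cfg$outdir, "polymorphic_chimeras.tsv"))

# per-sample genotype calls and the population detection summary
readProvTsv(file.path(cfg$outdir, "genotype_calls.tsv"))
readProvTsv(file.path(cfg$outdir, "detection_summary.tsv"))

# discordant-pair SV calls on a carrier and a non-carrier
readProvTsv(file.path(cfg$outdir, "sv_calls.tsv"))
```

The demo plants one complex inversion–deletion allele segregating at 10%
in one of three populations, expresses the fusion in carriers across
eight tissues, and runs every stage: the planted fusion is the only
catalog entry selected, carriers genotype positive, the carrier's reads
classify as `COMPLEX_INV_DEL` while the non-carrier's classify `NONE`,
and the association stage reports no significant codes (none were
planted).

## Known limitations

* The re-mapper is a deliberately small seed-and-extend aligner; it is
  adequate for desk-scale loci (≤ a few hundred kb) but is not a
  replacement for a production aligner on genome-scale references.
* Genotype calls are presence/absence; allele-balance zygosity estimation
  is out of scope, and the verbatim three-query absence rule conflates
  heterozygotes with non-carriers by construction (see above).
* The SV classifier handles the four planted geometries; nested or
  multi-SV loci, insertions and interchromosomal events are not
  detected.
* The additive-model linear regression on binary outcomes inherits the
  usual caveats of that convention (heteroscedastic residuals,
  out-of-range fitted values).
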