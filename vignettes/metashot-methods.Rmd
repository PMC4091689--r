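---
title: "Models and methods behind metashot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metashot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metashot)
```

# Scope

metashot quantifies shotgun metagenomes against two reference catalogues at
once — a genome catalogue for taxonomic profiles and a gene catalogue for
functional and richness analyses — and carries the resulting count tables
through rarefaction, core/pan analysis, diversity, enterotyping, and
non-redundant gene-catalogue construction. This vignette explains the models
and numerical choices; the README shows a worked example.

# The streaming counting model

Reads are processed as a stream: each FASTQ chunk passes quality filtering,
host-read removal, and alignment counting against both catalogues without
intermediate files, so memory is bounded by the catalogue index plus one
chunk. Quality filtering keeps a read when at least `qc_min_fraction` of its
bases reach Phred `qc_min_quality` (defaults 80% and Q20, the classic
fastq-filter rule; the defaults are logged with every run because they are
not universal). Phred offset is 33 by default, 64 selectable.

Counting follows a per-read unit-mass rule: a read with at least one hit
contributes exactly 1 under the `best-unique` policy — the best-scoring hit
wins, ties broken by a seeded uniform choice so that runs are
bit-reproducible — or a 1/n share to each tied best hit under
`all-best-fractional`. The accounting identity
`n_input = n_fail_qc + n_host + n_unaligned + n_aligned` holds exactly per
database and is asserted by tests.

Alignment itself is a contract, not a fixed engine: anything that maps a
read to scored hits fits. Two implementations ship — a SAM-stream adapter
for outputs of external aligners (flag 4 = unmapped; `AS:i:` preferred over
MAPQ as score), and an exact k-mer-seed test aligner used on synthetic data,
which seeds on the read's first 16-mer and verifies the full read against
the reference window (0 mismatches by default). The test aligner's
exactness is deliberate: with a substitution-only simulator, error-carrying
reads simply drop out of the aligned fraction uniformly across taxa, so
composition recovery is unbiased while alignment rates stay realistic.

# Count-table algebra

Sequencing runs are summed into samples with exact integer arithmetic;
features are the union over runs. Annotation aggregation pools unmapped
features into the sentinel `unannotated` so per-sample totals are conserved.
Relative abundances are normalized over *annotated* reads by default (the
unannotated pool is excluded from table and denominator); the choice is
recorded in the `denominator_policy` attribute because the alternative —
normalizing over all counted reads — is equally defensible and some
downstream comparisons need to know which was used. Genes with several KO
assignments contribute their full count to each KO by default (documented
double counting), with an exact fractional mode available.

Rarefaction is a single seeded multivariate hypergeometric draw: each
sample with at least `depth` reads is subsampled without replacement to
exactly `depth`; shallower samples are dropped and reported. A single draw
(rather than an average over draws) keeps counts integer and matches how a
rarefied table is used downstream (presence calls, richness). The
cross-study default depth is 11 million aligned reads; desk-scale analyses
pick the minimum column total. Tests verify the per-feature mean over
thousands of seeded draws against the hypergeometric expectation and against
vegan's `rrarefy` as an independent implementation.

The differential-abundance test is a two-sided Wilcoxon rank-sum test per
feature on relative abundances with Benjamini–Hochberg adjustment — the
field's default for two-group compositional comparisons — and is calibrated
under the null to the attainable exact level (about 0.043 at n = 10 vs 10
for nominal 0.05). Constant and all-zero features get p = 1 rather than NA
so the q-value vector stays complete.

# Presence, core and pan

A gene is present in a sample when at least 2 aligned reads hit it; a
species is present when its relative abundance is strictly above 1e-4
("above" is taken literally; `strict = FALSE` gives the inclusive rule).
Core analyses are defined on individuals, so repeated visits are removed
first, keeping the visit-1 sample (lowest available visit with a warning
otherwise). The core at fraction f counts features present in at least
`ceiling(f * n)` subjects — the ceiling convention is our reading of "at
least f% of subjects" and is applied uniformly. Pan/core accumulation
curves average over 100 seeded random subject orderings by default; for six
or fewer subjects an exhaustive mode enumerates every ordering, which the
tests compare against an independent brute-force enumeration.

# Diversity and sample clustering

Shannon diversity uses the natural logarithm (H of a uniform community of S
species is ln S; observed gut profiles then span roughly 0–4). Heatmap-style
sample clustering uses complete linkage on 1 − Spearman correlation over the
top-k most abundant features, ranked by mean relative abundance across
samples; a constant profile has no rank variance and its distances are
defined as 1 with a warning rather than propagating NA.

# Enterotyping

Genus profiles are filtered to genera with mean abundance strictly above
0.01%, re-normalized, and compared with the root Jensen–Shannon distance
d(a,b) = sqrt(JSD(a,b)), natural log, after replacing zeros with a
pseudocount (default 1e-6) and re-normalizing. Root-JSD is a metric; its
disjoint-support limit sqrt(ln 2) ≈ 0.8326 is a useful test anchor.

Clustering is k-medoids by the classic BUILD + SWAP (steepest-descent
single exchanges until no exchange lowers the total distance-to-medoid
cost). The seed affects only tie-breaking, so results are deterministic;
on all 8-point instances tested the local optimum coincides with the
exhaustive-search optimum for k = 2 and 3.

Model selection maximizes the Calinski–Harabasz index over candidate k
(default 2–10). We compute CH from the distance matrix via the
pairwise-dispersion identity — total dispersion T = Σ d²/(2n), within-cluster
W = Σ_c Σ_{i,j∈c} d²/(2 n_c), B = T − W, CH = (B/(k−1))/(W/(n−k)) — which
equals the classic centroid form exactly whenever the distances embed in
Euclidean space and requires no cluster centre. An alternative we evaluated,
replacing centres by cluster medoids, systematically under-scored the true
k on planted 3-cluster cohorts (selecting k = 2 in about 40% of seeds even
when PAM at k = 3 recovered the planted labels perfectly) and was rejected;
with the pairwise form the planted k was selected in 100% of evaluation
seeds. The average silhouette width at the chosen k is reported as a
separate quality measure, with singleton clusters contributing width 0.
Agreement between two clusterings is the label-permutation-maximal fraction
of identically assigned samples (optimal assignment on the confusion
matrix, found by a bounded exhaustive search — label sets here are small).

# Gene-catalogue construction

Pairwise comparison uses an ends-free (overlap) dynamic-programming
alignment of the shorter sequence against the longer, via Biostrings.
Identity is matches over all alignment columns of the shorter's aligned
span (gap columns count against identity); coverage is the fraction of the
shorter sequence inside the aligned span. We chose the ends-free form
deliberately: under a pattern-global alignment the coverage of the shorter
sequence is identically 1, which would make a coverage threshold vacuous.
`N` never matches anything, including another `N`. Gap costs are 4 to open
and 2 to extend, on a +1/−1 match/mismatch scale.

Greedy clustering sorts sequences by decreasing length (ties by id) and
assigns each to the first existing cluster, in founding order, whose
representative it matches at ≥95% identity and ≥90% coverage, else it
founds a new cluster. Acceptance is always member-vs-representative. A
shared-8-mer prefilter restricts which representatives are aligned; at 95%
identity over ≥90% of a sequence, a pigeonhole argument guarantees an
unbroken identical stretch of at least 8 bases for all but very short
sequences, so the prefilter does not change results (tests compare against
the all-pairs path). Per-study catalogues are merged by pooling the
per-study representatives and re-clustering at the same thresholds; each
global cluster records the union of member studies, which defines the Venn
partition of study sharing and the per-region read-abundance summaries
(optionally normalized by region gene count).

# The synthetic-data generator

The generator exists so every stage can be tested against known truth at
desk scale. `make_references` builds random uniform-composition genomes
(one contig per species) and carves non-overlapping gene windows out of
them, so reads genuinely align to both catalogues; two species share each
genus. `simulate_run` draws read positions uniformly, applies independent
substitution errors (default 0.1%), assigns two-state quality strings
(good Q38 / bad Q8, bad with probability 2% — enough to exercise the QC
boundary without dominating run statistics), and replaces a Bernoulli
fraction of reads with verbatim host-contig substrings. Host reads are
error-free by design: the shipped test aligner is exact, and the host
filter contract is hit/no-hit, so verbatim copies make the planted host
fraction exactly recoverable. `make_enterotype_cohort` draws genus profiles
from k Dirichlet components with one distinct driver genus each (driver
mean abundance 0.4, concentration 30, 30 genera, n = 60 — values chosen
once to mimic strongly stratified gut cohorts where the driver spans tens
of percent and cluster overlap is moderate). `make_multistudy_genes` plants
core, pairwise-shared and private genes with sub-threshold mutation rates
so the true Venn partition is recoverable exactly.

What the generator does *not* emulate — indels and platform-specific error
profiles, realistic abundance distributions fitted to real cohorts,
strain-level variation inside species, compositional correlations between
genera — bounds what green tests mean: they demonstrate algorithmic
correctness and calibrated statistics under the stated model, not
performance claims on real gut data.

# Problem sizes and numerical notes

The shipped tests and the acceptance script use: 1 000 randomized fixtures
for conservation; 5 000–10 000 seeded rarefaction draws on a 10-feature
column; exhaustive orderings on 6-subject presence matrices; 100 random
8-point PAM instances; 1 000 random profile triples for the JSD metric
checks; 100 planted 3-cluster cohorts of 60 samples; multi-study gene sets
of a few hundred genes; and a full-pipeline cohort of 20 samples × 100 000
reads against a 10-species / 200-gene reference set. These sizes were
chosen so the entire suite runs comfortably on a single CPU while leaving
the statistical tolerances meaningful (multinomial and binomial bounds are
stated next to each test).

Numerical conventions: counts are doubles holding exact integers (exact to
2^53, far beyond any realistic read total, while avoiding 32-bit overflow);
column normalization tolerates all-zero samples by flagging rather than
dividing; JSD guards `0 log 0` via the pseudocount and clamps tiny negative
divergences from floating-point cancellation to 0; PAM tie-breaking uses an
epsilon of 1e-12 when comparing costs; seeded RNG use is always local
(caller state is saved and restored).

# Known limitations

The test aligner requires an exact seed match at the read's first k bases
and is substitution-intolerant by default — it is a fixture engine, not a
production aligner; real data should enter through SAM. Greedy clustering
is quadratic in the worst case and intended for desk-scale inputs (about
10^3–10^4 sequences in R). The Hungarian-style agreement matching is
exhaustive over label permutations and capped at 12 labels. Enterotype
results on real cohorts depend on filtering choices upstream of this
package (read depth, annotation completeness) that the synthetic cohorts do
not model.
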