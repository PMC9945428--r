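---
title: "Methods: mapping and characterizing a young sex chromosome"
author: "neosex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping and characterizing a young sex chromosome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neosex)
```

`neosex` implements the computational chain used to dissect a young
(homomorphic) sex-chromosome system: localizing the sex-determining region
(SDR) from pooled resequencing of phenotypic-sex pools, quantifying X/Y
sequence differentiation, reconstructing the chromosome-fusion origin of the
neo-sex chromosome from synteny anchors, comparing the 3D chromatin
architecture of X, X^M (sex-reversed neomale X) and Y chromosomes from Hi-C,
and testing for regional sex-biased expression. Every stage has a paired
generator that simulates its input with planted ground truth, so the whole
pipeline is testable without any external download. This vignette documents
the models, the parameters that matter, and the numerical choices; it states
no result that the package's tests and `scripts/acceptance.R` do not
themselves compute.

## Coordinates and data model

All internal coordinates are 0-based half-open; only the VCF and GFF3 readers
and writers convert (both formats are 1-based inclusive on disk). A
`genome_layout` carries chromosome names, lengths and, for binned data, a
bin size; bin `i` of a chromosome covers `[i*bin, (i+1)*bin)`. A single
convention everywhere removes the usual off-by-one drift between tracks,
windows and bins, and the unit tests assert the boundary conversions
(position 1 on disk is offset 0 in memory).

## SDR localization from two pools

The design is two pooled libraries — XX females and YY supermales, 20
individuals each, so haploid sizes `n1 = n2 = 40` — with an independent
replicate batch from different families. Pool allele frequencies are read
proportions, `p_k = alt_k / depth_k`.

**Per-site F_ST.** We use the two-population Hudson estimator with a
finite-sample correction,
$$\mathrm{num} = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} -
\frac{p_2(1-p_2)}{n_2-1}, \qquad
\mathrm{den} = p_1(1-p_2) + p_2(1-p_1),$$
and windowed values are the *ratio of sums* of numerator and denominator
over sites in the window (10-kb windows, 5-kb step by default). Per-site
values are not clamped: clamping negative estimates before summation biases
the windowed ratio upward. A fixed difference gives exactly 1; monomorphic
sites have zero denominator and drop out of the sums.

**Male-specific variants.** A site is male-specific when it is (near-)fixed
reference in the XX pool and (near-)fixed alternate in the YY pool:
`alt1/depth1 <= eps1` and `alt2/depth2 >= 1 - eps2`, with both depths at
least `min_depth = 10`. The `male_specific_filter()` defaults are exact
(`eps = 0`) — the textbook criterion. The full pipeline
(`sdr_pipeline()`) instead defaults to `eps1 = eps2 = 0.05`, about one
tolerated read at 30x: pooled read counts carry raw sequencing error that no
genotype caller has absorbed, and at a 1% per-read error rate the exact
filter rejects a genuine fixed site whenever a single errored read appears
in either pool of either batch — discarding roughly 70% of true sites over
two batches ($((1-e)^{d})^{4}$ at depth $d = 30$) — while a background site
would have to sit simultaneously below 5% and above 95% frequency to leak
through, which read-sampling noise at depth 30 essentially never produces.
Replicate batches are then intersected on (chrom, pos, ref, alt), which is
what suppresses the residual false positives (sites that fluke through one
batch rarely fluke through both).

**SDR call.** On the chromosome carrying most surviving variants we report
the *shortest* interval containing at least a fraction `q = 0.85` of that
chromosome's variants (two-pointer scan; ties to the smaller start). The
default reflects that the large majority, but not all, of genuine sex-linked
variants cluster in one region, with a tail of scattered survivors; `q = 1`
reproduces the full variant span. The interval length is monotone
nondecreasing in `q`.

The synthetic generator (`gen_pool_counts()`) plants background sites with a
shared frequency `p ~ U(0.05, 0.95)` (counts Binomial(depth, p),
independently per pool and batch) and SDR sites with `p = 0` / `p = 1`;
sequencing error flips each read with rate `error_rate`. It deliberately
ignores individual-level sampling within pools — reads are drawn from the
pool frequency directly — which matches the estimator's use of haploid pool
sizes and keeps closed-form checks available (the probability that an SDR
site passes the exact filter in one batch is $((1-e)^d)^2$). What it does
not emulate: linked selection, mapping bias, depth variation across sites,
or indel-specific error profiles; passing the recovery tests therefore shows
correctness of the statistics, not robustness to alignment artifacts.

## X/Y divergence

**Ka/Ks** uses the classical counting method with equal pathway weighting.
Synonymous site counts per codon come from the standard genetic code
(changes creating stop codons count as nonsynonymous sites); codon pairs
differing at $k > 1$ positions average the observed synonymous and
nonsynonymous differences over all $k!$ single-step mutational pathways,
excluding pathways that pass through a stop codon unless every pathway does.
Proportions are corrected for multiple hits with Jukes–Cantor,
$d = -\tfrac34\ln(1 - \tfrac43 p)$, reported `NA` with a `saturated` flag
when $p \ge 3/4$. The implementation is verified to $10^{-12}$ against an
independently written pathway-enumeration oracle, and the worked
ten-phenylalanine example (one third-position T→C change: $S = 10/3$,
$p_S = 0.3$, $K_s \approx 0.3831$, $K_a = 0$) is asserted in the tests. We
compute Ka/Ks per gene pair and scan by chromosome position rather than in
fixed windows.

**Strata scan.** Recombination suppression in steps ("evolutionary strata")
would appear as changepoints in Ks along the X. We use binary segmentation:
the candidate split maximizes the standardized mean difference
$|\bar x_L - \bar x_R|\sqrt{n_L n_R / n}$, its significance is a permutation
test (default 1,000 shuffles of Ks within the segment), and recursion stops
when $p \ge \alpha / 2^{\mathrm{depth}}$ — a per-depth Bonferroni guard
against the doubling number of tests. Segments smaller than 5 genes are not
considered. On i.i.d. Ks the scan returns no changepoint in ≥ 90% of null
runs; a planted 10-fold Ks step between 50-gene segments is located within
±3 genes.

**Repeats and centromeres.** Subfamily abundance is the bp fraction of each
chromosome covered; each subfamily row is standardized across chromosomes
(Z-score), so a subfamily expanded on one chromosome stands out against its
own genome-wide level regardless of absolute abundance. The putative
centromere is the contiguous run of 100-kb windows — containing the densest
window — whose density of the genome-wide most abundant satellite subfamily
is at least half the chromosome maximum.

## Fusion origin and the highly rearranged region

Homologous-gene anchors (`qchrom, qidx, qpos, tchrom, tidx, tpos, strand`)
are chained greedily left-to-right into collinear blocks: a block extends
while the target chromosome is unchanged, the target-rank jump is at most
`max_gap = 25`, and the direction matches the block orientation (set by the
first jump); blocks with fewer than `min_anchors = 5` anchors are dropped.
Greedy chaining (rather than full dynamic programming) is adequate for
curated anchor tables without heavy paralogy, which is the intended input.

Each junction between adjacent retained blocks on a query chromosome is one
breakpoint: `interchromosomal` if the target chromosome changes,
`inversion` if the orientation flips, otherwise `translocation` (the chain
broke with target and orientation unchanged, so a rank displacement lies
between). Classifying every junction keeps the conservation identity
*breakpoints = blocks − chromosomes with blocks*, which the tests assert
against brute-force adjacency inspection. Breakpoint positions are midpoints
of inter-block gaps — unbiased without sequence-level alignment.

A **fusion** candidate is a query chromosome whose block sequence, after
dropping at most `max_noise_blocks = 1` stray blocks, is a prefix on one
target chromosome followed by a suffix on a second; the fusion position is
the midpoint between them. The **HRR** is delimited by sliding 1-Mb windows
(200-kb step) over breakpoint counts, flagging windows at or above the
genome-wide mean + 2 SD and merging overlapping flagged windows. Because the
maximum of hundreds of Poisson-distributed window counts exceeds mean + 2 SD
in essentially every realization, a flagged *single* cluster is not evidence
of a rearranged region: any tight cluster of breakpoints flags at most the
footprint of the windows containing it. Merged intervals must therefore
exceed `min_span = 2 * window` (2 Mb); with that rule, uniform breakpoints
yield no HRR in ≥ 90% of null simulations while a planted multi-megabase
dense region is recovered with Jaccard ≥ 0.6. Note the mean + 2 SD
threshold self-limits: a "dense" region covering more than ~15% of all
windows inflates the genome-wide SD past its own signal, so HRR detection
presumes a genome-scale scan, not a single-chromosome one.

## Hi-C architecture

Matrices are binned (50-kb default in the simulations), symmetric and
sparse. Bins with no nonzero entries, or with a nonzero-entry count below
10% of their chromosome's median, are masked everywhere. **ICE balancing**
iterates bias updates from row sums until the update is below `1e-5`;
balanced counts are `raw/(b_i b_j)` and unmasked row sums end up equal to
within CV < 1e-3. Balancing is idempotent and invariant (up to a constant)
to scaling a row.

**Compartments.** Per chromosome, expected counts by bin distance (zeros
included over unmasked pairs) give the O/E matrix; PC1 of its Pearson
correlation matrix, sign-oriented to correlate positively with an activity
covariate (per-bin raw coverage by default; supply gene density when
available), labels A (> 0) and B (< 0) compartments. When PC1 explains
< 10% of the correlation-matrix variance the track is flagged unreliable —
on structure-free maps this is what happens, and the planted checkerboard
(δ = 0.3) is recovered with ≥ 95% label agreement.

**TADs.** The insulation score of bin *i* is the log2 ratio of the mean
balanced contact in the `w x w` square bridging *i* (`w = 10` bins) to the
chromosome mean of such squares. Boundary candidates are local minima of the
3-bin-smoothed score; their strength is the mean of the flanking local
maxima minus the minimum. The strength threshold is 0.25: on decay-only maps
at per-pair coverage ~50 the largest noise prominence observed across seeds
is ~0.125, while the weakest genuine 2-fold-enriched domain boundary scores
≥ 0.5, so 0.25 splits the separation; a lower threshold (e.g. 0.1) admits a
false boundary in essentially every null map. TADs are the inter-boundary
intervals (chromosome ends included) of at least 3 bins. Boundary sharing
between two TAD sets is greedy one-to-one matching within ±1 bin.

**Significant interactions** follow a distance-stratified Poisson model:
cis pairs are stratified into geometric (doubling) distance bands — bands
with under 10 unmasked pairs merge into a neighbor — and the expected
balanced count is the band mean with zeros included; trans pairs use the
chromosome-pair mean. Balanced values are mapped back to effective counts
with the global raw/balanced ratio and tested with a Poisson upper tail,
then Benjamini–Hochberg within mode at FDR 0.05. Poisson discreteness makes
the test conservative; on loop-free maps the significant fraction stays
below the nominal 5% and planted 5x loops are recovered with ≥ 80% power.
Anchor bins of significant calls are annotated against gene models with
precedence promoter > exon > intron > intergenic, the promoter being
`[TSS - 2000, TSS + 500)` oriented by strand.

**Cross-sample comparisons.** The contact score of a chromosome pair is
$10^6 \times$ (sum of balanced trans counts) / (product of unmasked bin
counts) — a size-normalized proximity proxy defined here and used
consistently for all comparisons (the choice of normalization is ours; only
internal consistency matters for ranking proximities). Matrix similarity is
the Pearson correlation of `log(1 + balanced)` over unmasked cis pairs;
because the shared distance decay dominates that number, the correlation of
the O/E-transformed matrices is always reported alongside — independent maps
correlate highly on raw log counts but near zero after decay removal, so the
O/E value is the structure-sensitive one.

Cis contacts are classed short/mid/long at 160 kb and 10 Mb by default; a
300-kb short/mid edge, used in some summaries of the same data family, is
reachable through the `short_max` argument — neither edge is privileged.

**Synthetic maps.** `gen_contact_map()` plants
$\mu_{ij} = C\,d^{-\gamma}(1+\delta v_i v_j)\,\tau^{[\text{same TAD}]}
(1 + \ell\,[\text{loop}])$ with Poisson counts (trans pairs decay-free),
$C$ set so the mean cis count equals `coverage`. Poisson rather than
negative-binomial noise is the simplest model supporting the recovery tests;
overdispersion is a knob deliberately left for later. In test
configurations the compartment sign is constant within each planted TAD —
compartment switches co-locate with domain boundaries, as in real maps;
with an arbitrary checkerboard, compartment flips create genuine insulation
minima that no caller should be penalized for finding.

## 3D reconstruction

Balanced contacts convert to target distances $d_{ij} = c_{ij}^{-\alpha}$
(α = 1), the metric is completed by all-pairs shortest paths over the
contact graph, and classical MDS (double-centering, top-3 eigenpairs) gives
coordinates — the distance-geometry approach standard for single-structure
reconstruction. Noiseless $c = 1/d$ input is recovered to machine precision.
For count-sampled matrices an optional Gaussian pre-smoothing of the map
(`smooth_r = 2` recommended, off by default) suppresses the downward bias
noisy edge weights impose on shortest paths; at mean count 50 it lifts the
distance-vector Spearman against truth from ~0.975 to > 0.99.

Structures are compared after normalizing both to unit radius of gyration:
the optimal translation + uniform scale + rotation (reflections allowed,
since chirality is not identified by contact data) minimizing the summed
squared deviation gives the RMSE, and the Spearman correlation of condensed
distance vectors is reported alignment-free. RMSE values are therefore
scale-comparable across chromosomes but not comparable to reconstruction
tools that report RMSE on their own internal scale. Distances are ranked on
10 significant digits so exactly tied distances of symmetric structures stay
tied under numerically perturbed rigid motions.

## Expression bias

Counts normalize to CPM (and TPM when lengths are supplied). A gene is
male-biased when $\log_2((\bar x_M + 1)/(\bar x_F + 1)) \ge 1$ and the male
mean CPM is ≥ 1 (female-biased symmetrically) — a transparent threshold
classifier rather than a dispersion-modeled GLM, which keeps the downstream
regional test self-contained and simulation-testable; the pseudocount
bounds fold changes for silent genes. On negative-binomial simulations with
a planted 4-fold effect the classifier reaches ≥ 80% recall at ≤ 20% FDR.

The Wilcoxon rank-sum test is implemented in the package (midranks for
ties; exact p by full enumeration of the $\binom{n+m}{n}$ assignments when
$n + m \le 12$ and tie-free, else normal approximation with tie and
continuity corrections) and is verified against enumeration and
`stats::wilcox.test`. The regional test compares log2 fold changes of
same-label genes inside vs outside a region on the same chromosome,
one-sided; its null p-values are uniform (KS-checked in the tests). Whether
a published "expression ratio" is a log2 ratio is not always stated; all
outputs here label the column `log2fc`.

## Problem sizes and determinism

Every generator is deterministic given (parameters, seed). The test suite
and the acceptance script use desk-scale configurations chosen to make the
statistical properties measurable in minutes on one core: 5 x 10-Mb
chromosomes with 20,000 background and 600 SDR variant sites for the
pool-seq pipeline; 1,000-bin (50-Mb at 50-kb bins) contact maps with 20
planted boundaries for TAD/compartment recovery; 320-bin two-chromosome
maps for caller calibration; 2,000-anchor genomes for fusion/HRR recovery;
100-bin helices for 3D recovery. These sizes are statements about the
simulations, not about the method's capacity; all operations are sparse or
per-chromosome dense and scale to real binned genomes.

## Known limitations

- Pool-seq simulation draws reads from pool frequencies, so within-pool
  individual sampling variance (and hence slight overdispersion of real
  pool counts) is not represented.
- The HRR rule presumes a genome-wide scan (see above) and delimits regions
  only down to window resolution.
- The interaction caller tests marginal enrichment per pair; it does not
  model peak clusters or merge adjacent significant pixels.
- Reconstruction returns a single consensus structure; ensemble variability
  across cells is out of scope.
- The strata scan tests mean shifts in Ks; gradual clines would be reported
  as multiple weak changepoints or none.
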