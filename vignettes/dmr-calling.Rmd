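---
title: "Calling differentially methylated regions with dmrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling differentially methylated regions with dmrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmrkit)
```

## The problem

Bisulfite sequencing reads methylation as a C-versus-T signal at cytosines:
bisulfite deaminates unmethylated cytosines, so after alignment each read
reports, base by base, whether a cytosine was methylated. In adult
mammalian cells methylation concentrates at CpG dinucleotides, and the
biologically interesting unit is rarely a single CpG but a short cluster of
neighboring sites that switches state together. The analysis task is
therefore: turn alignments into per-CpG counts, group CpGs into regions,
and test each region for a methylation difference between sample groups —
producing *differentially methylated regions* (DMRs).

`dmrkit` implements those three stages behind one package and one
command-line script, plus a seeded simulator used throughout the test
suite.

## Stage 1: extraction

The extractor consumes SAM/BAM files in the Bismark dialect: each primary
alignment carries a per-base methylation-call string (`XM`, where `z`/`Z`
mark un/methylated CpG calls) and a conversion-strand tag (`XG`, `CT` or
`GA`). File access goes through `Rsamtools`; the coordinate arithmetic is
done in the package. Each CpG call is placed on the reference by walking
the CIGAR string (`M/=/X` consume query and reference, `I/S` consume query
only, `D/N` reference only). Two consequences matter:

* **Novel CpG sites.** Coordinates come from the alignment, not from a
  reference CpG catalogue. If a sample carries a variant or deletion that
  creates a CpG absent from the reference — e.g. `C·A·G` where the `A` is
  deleted — the aligner marks the call in CpG context and the extractor
  reports it at its reference coordinate. Catalogue-driven extractors
  silently drop these sites and can misstate the methylation level of the
  surrounding region.
* **Strand merging.** A CpG is palindromic; reverse-strand evidence sits on
  the G, one base right of the forward-strand C. `GA`-strand calls are
  shifted by −1 so both strands accumulate at the forward C. One caveat,
  shared with coordinate-based tools generally: for a *deletion-created*
  CpG the forward C and the G are not adjacent in reference coordinates, so
  forward- and reverse-strand evidence cannot be reconciled at one
  coordinate; the simulator therefore exercises novel sites with
  forward-strand reads.

Calls on inserted or soft-clipped bases have no reference coordinate and
are dropped (counted in the log). For properly-paired reads the second
mate's overlap with the first is clipped by default so a fragment never
counts twice at a site; a flag disables this. No mapping-quality filter is
applied by default (`min_mapq` is available). Output is a tab-delimited
table — `chrom`, `pos` (1-based), `total`, `meth`, `unmeth` — sorted by
chromosome in alignment-header order, then position. The extractor can
also report per-read *joint* methylation patterns (`M`/`u`/`-` for
methylated/unmethylated/uncovered) over user-supplied intervals; linkage
of sites along single molecules carries subpopulation information that
per-site totals discard.

## Stage 2: clustering

Sites are first screened for coverage: a CpG is *valid* when at least
`min_samples` (default 1) samples cover it with `min_reads` (default 3)
reads. Valid sites within `max_dist` (default 100 bp) of each other join a
cluster — plain single-linkage, equivalent to cutting the sorted position
list at every gap beyond the threshold. Single linkage chains: a run of
intermediate sites can fuse sites kilobases apart. Any cluster spanning
more than `max_len` (default 500 bp) is therefore split, recursively, at
its largest internal gap (leftmost on ties) until every part satisfies the
bound. Splitting at the largest gap respects the spatial structure
(sub-clusters break where sites are sparsest) and guarantees the bound;
other partition rules would too, and this one is fixed and documented.
Finally, clusters with fewer than `min_cpg` (default 3) sites are dropped,
counts are aggregated per sample over member sites (a sample missing a
site contributes zero), and regions whose total in *any* sample is below
`min_total` (default 20) are dropped so the downstream test has power.

Two properties are worth stating because the test suite enforces them:
clustering never looks at methylation levels — redistributing methylated
versus unmethylated counts at fixed coverage yields byte-identical regions,
so region formation cannot bias DMR discovery — and with the length bound
disabled the procedure is exactly single-linkage clustering (verified
against a brute-force transitive-closure oracle). The
`cluster_params(preset = "biseq")` setting (`min_reads = 1`,
`min_total = 1`, `max_len = 1e9`, `min_cpg = 5`) reproduces the pure
single-linkage clusters of BiSeq-style 100 bp clustering.

Region coordinates are the first and last member CpG (1-based inclusive).
The `min_total` filter is applied to all samples, not only those under a
given comparison, so one region table serves every pairwise test.

## Stage 3: testing

Counts within a region are conglomerated per sample, which is the point:
several sites too noisy to test individually can carry a clear joint
signal, and testing regions instead of sites also divides the number of
hypotheses. For group $g$ with replicates $i$, methylated counts $X_{gi}$
of totals $N_{gi}$, the group methylation level is the coverage-weighted
fraction $\mu_g = \sum_i X_{gi} / \sum_i N_{gi}$. The model is
beta-binomial: replicate fractions $p_i = X_{gi}/N_{gi}$ have variance

$$\operatorname{Var}(p_i) = \mu(1-\mu)\,\frac{1 + (N_{gi}-1)\varphi}{N_{gi}},$$

where $\varphi \in [0,1)$ is the dispersion (intra-class correlation)
capturing biological variation between replicates on top of binomial
sampling noise.

**Raw dispersion.** Per region and group, $\varphi$ is estimated by the
method of moments from the coverage-weighted residual variance
$S = \sum_i w_i (p_i - \hat\mu)^2$, $w_i = N_{gi}/\sum N_{gi}$, using the
exact finite-sample identity
$E[S] = \sum_i (w_i - w_i^2)\operatorname{Var}(p_i)$ (the $w_i^2$ term
accounts for $\mu$ being estimated from the same data). The estimate is
deliberately left signed: clamping at zero before pooling would bias the
across-region mean upward.

**Shrinkage.** Region-level estimates with one or two residual degrees of
freedom are extremely noisy, so they share strength through an
empirical-Bayes prior, fitted per group across regions. The prior location
is the replication-weighted mean of the signed raw estimates on the
natural scale — where the moment estimator is unbiased — corrected once,
at the pool level, for the small bias of the plug-in $\hat\mu(1-\hat\mu)$
denominator (the correction is nonlinear and would be unstable applied
region by region). Each positive raw estimate contributes a log-scale
observation whose sampling variance comes from scaled chi-square theory
($\operatorname{trigamma}(\mathrm{df}/2)$, as in moderated-variance
analyses); the prior scale is the excess spread of the log estimates over
that sampling noise, and the shrunken log-dispersion is the
precision-weighted blend of observation and prior location. Non-positive
raw estimates carry no usable log-scale information and take the prior
location, as do single-replicate groups; with fewer than two usable
estimates everywhere, a fixed fallback prior ($\log 0.01$, scale 1) is
used. When region dispersions are homogeneous the fitted prior scale is
near zero and every region receives the pooled value — which is what makes
the test calibrated at two replicates per group. When they are truly
heterogeneous the prior scale opens up and strong per-region signal passes
through (a diffuse prior returns the raw estimates unchanged).

**Wald test.** For groups $A$, $B$:

$$W = \frac{\mu_A - \mu_B}
   {\sqrt{\widehat{\operatorname{Var}}(\mu_A) + \widehat{\operatorname{Var}}(\mu_B)}},
 \qquad
 \widehat{\operatorname{Var}}(\mu_g) = \mu_g(1-\mu_g)
   \sum_i w_i^2\,\frac{1 + (N_{gi}-1)\varphi^*_g}{N_{gi}},$$

with $p = 2\Phi(-|W|)$. At $\varphi = 0$ with single replicates this is
exactly the (unpooled) two-proportion z-test. Boundary estimates
($\mu \in \{0,1\}$) are clamped to $[1/(2\sum N),\, 1 - 1/(2\sum N)]$
inside the variance so the denominator stays positive; a comparison whose
variance is still zero is reported with $p = 1$ and a degeneracy flag.
With three or more groups every unordered pair is tested; each comparison
gets its own Benjamini–Hochberg run (pooling q-values across comparisons
with different power profiles would distort all of them). Regions
untestable for a comparison (a group with zero coverage) keep their row
with missing statistics so row sets align across comparisons.

**DMR definition.** A region is a DMR for a comparison when
$|\mu_A - \mu_B| \ge$ `min_diff` (default 0.10), $p \le$ `max_p` (default
0.05) and $q \le$ `max_q` (default 0.05). The q-gate is part of the
default because without it the p-and-effect-size gates alone admit ~5% of
null regions at desk-scale coverage (any region with $p<0.05$ at these
depths necessarily clears a 10% difference), which contradicts the
intended near-empty result when replicates of the same condition are
contrasted; set `max_q = 1` to disable it.

## The simulator

`sim_config()` fixes every generator setting; the seed fully determines
all output at each boundary.

* `make_reference()` builds a CpG-free random background, plants `CG`
  dinucleotides with mean spacing `cpg_spacing` (default 50 bp, a
  CpG-island-like density appropriate for the targeted assays this
  pipeline suits), and optionally plants `CAG` loci whose deleted `A`
  yields a novel CpG. The recorded CpG list provably equals the `CG`
  content of the sequence.
* `simulate_reads()` emits Bismark-dialect SAM (single-end and overlapping
  proper pairs; default read length 50, depth 20×) with per-site Bernoulli
  methylation at configured probabilities, deletion-carrying reads over
  the novel loci, and optional unmapped/secondary records to exercise the
  filters. The returned truth table counts exactly the calls a correct
  extractor should deliver after mate-overlap clipping, so round-trip
  tests can demand byte-exact recovery.
* `simulate_region_counts()` draws region tables directly:
  $N = 1 + \mathrm{NB}(\text{size}=10, \text{mean}=\bar N - 1)$ per
  replicate (overdispersed coverage, mean 30 by default) and
  beta-binomial $X$ via the Beta-then-Binomial composition with $\varphi$
  as the intra-class correlation, so $\varphi = 0$ degenerates to the
  binomial. A configurable fraction of regions receives an injected mean
  shift in the last group, with truth labels. Defaults describe a typical
  targeted study: 3 vs 3 replicates, baseline methylation 0.1 (an
  unmethylated CpG-island baseline), injected gain of 0.3 in 10% of
  regions; the null calibration experiments use an intermediate baseline
  of 0.5, the cleanest regime for a normal-reference test.

What the simulator does *not* model: bisulfite conversion failure and
sequencing error as separate channels (both fold into the per-site
probabilities), non-CpG methylation contexts, quality-score structure,
PCR duplicates, and RRBS fragment-end effects. Passing round-trip tests
therefore demonstrates correctness of the bookkeeping — coordinates,
strand merging, overlap clipping, novel sites — not robustness to every
artifact of real libraries.

## Numerical choices and edge cases

* Dispersion floor $10^{-4}$: the smallest dispersion distinguishable from
  zero on the log scale; estimates at or below it are treated as "no
  log-scale information".
* The $1/(2\sum N)$ clamp for boundary means: any small constant works;
  this one scales with the information available.
* BH is computed on non-missing p-values only; missing stays missing.
* Ties in the largest-gap split go to the leftmost gap; splitting is
  iterative (explicit stack), so pathological chains cannot overflow the
  recursion limit.
* Empty inputs flow through: an empty SAM yields an empty count table, an
  empty count table an empty region table, each still schema-valid.
* Chromosome order follows the alignment header (then first appearance at
  the join), never lexicographic sorting.

## What the checks show, and known limits

The test suite sizes its simulations to run in about a minute (50k-read
round-trips, 5,000-region calibration and recovery studies, 200-set
clustering oracles); these sizes are the study conditions, stated in the
tests themselves.

Measured behavior at those conditions: the null rejection rate at
$p<0.05$ is 0.05–0.06 for $\varphi \in \{0, 0.05\}$ at two replicates per
group, and contrasting null groups yields zero DMRs at defaults. Two
limits of the Wald machinery at desk scale are worth knowing. First, at
$\varphi = 0.2$ with two replicates the rate is ≈ 0.08–0.09 even when the
*true* dispersion is supplied: the plug-in $\hat\mu(1-\hat\mu)$ variance
factor is anticorrelated with the observed difference, which fattens the
tails of $W$; this is a property of the statistic itself (shared by its
relatives), not of the dispersion estimator. Second, with mean region
coverage 30 per replicate, 3 vs 3 replicates and $\varphi = 0.05$, a 0.30
methylation difference carries a noncentrality of only ≈ 3.2–3.5, so no
calling rule can simultaneously exceed 90% sensitivity and stay under 10%
false discovery at 10% prevalence — the biological-variance floor
$2\mu(1-\mu)\varphi/3$ survives any coverage. At those settings the
package delivers ≈ 60% sensitivity at ≈ 2–5% realized FDR; sensitivity
rises toward 90%+ when regions aggregate more coverage (which is exactly
what conglomeration is for) or differences reach ~0.4.

Out of scope by design: smoothing, per-site DML calling with
site-chaining, covariates and batch effects, quantitative traits, and
sets of regions. The model also assumes a common dispersion within a
region and group, and the normal reference for $W$ — both standard, both
approximations.

## A worked run

```{r example, eval = FALSE}
cfg <- sim_config(seed = 7, chrom_len = 20000, mean_depth = 12,
                  samples = c(c1 = 0.8, c2 = 0.8, t1 = 0.8, t2 = 0.8),
                  dmr_window = list(start = 7000, end = 8000,
                                    prob = c(c1 = 0.9, c2 = 0.9,
                                             t1 = 0.1, t2 = 0.1)))
sim <- simulate_reads(cfg, make_reference(cfg), dir = tempdir())
dmr <- run_all(sim$sam, groups = list(ctrl = c("c1", "c2"),
                                      trt = c("t1", "t2")),
               out_dir = tempdir())
dmr[which(dmr$ctrl_vs_trt_dmr), ]
```

The same analysis from a shell, stage by stage:

```sh
dmrkit extract --in c1.sam,c2.sam,t1.sam,t2.sam \
               --out c1.tsv,c2.tsv,t1.tsv,t2.tsv
dmrkit cluster --in c1.tsv,c2.tsv,t1.tsv,t2.tsv --out regions.tsv
dmrkit test    --in regions.tsv --groups "ctrl=c1,c2;trt=t1,t2" \
               --out dmrs.tsv --bed-out dmrs.bed
```
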