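---
title: "Calling T1/T2 lamina-associated domains with Gaussian hidden Markov models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling T1/T2 lamina-associated domains with Gaussian hidden Markov models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ladatlas)
```

## The problem

Lamina-associated domains (LADs) are kilobase-to-megabase regions of the
genome in contact with the nuclear lamina, detectable as broad enrichment of
LAMIN B1 (LB1) in ChIP-seq. LAD organization is not binary: between clearly
lamina-bound and clearly interior chromatin lies an intermediate class with
moderate LB1 contact frequency. `ladatlas` implements a segmentation and
comparison pipeline for this setting: it turns binned LB1 (or H3K9me2)
ChIP-seq into per-bin log2 ratio signal, segments each cell type's genome
into three states — T1 (strongest lamina association), T2 (intermediate) and
non (depleted) — with a Gaussian hidden Markov model (HMM), and computes the
statistics used to compare such segmentations across many cell types:
domain sizes and genome coverage, boundary metaprofiles, feature enrichment,
cross-cell-type invariance, gene state assignment and expression
integration. The same machinery applied to H3K9me2 yields K9 dimethyl
domains (T1/T2/non KDDs).

## Signal model

The genome is tiled with fixed 20-kb bins (`make_grid()`); only the final
bin of a chromosome may be shorter, and it is retained (flagged, not
dropped) so chromosome ends stay callable. Bins overlapping a blacklist
interval by at least 1 bp are masked and excluded from every statistic
downstream.

Per cell type and replicate, ChIP and input read counts per bin are combined
into `log2((chip + pc) / (f * input_eq + pc))`, where:

* `input_eq` is the input count after depth equalization to the ChIP total;
* `f` is the signal extraction scaling (SES) factor (`ses_scale_factor()`).
  Bins are ranked by ascending ChIP count (ties broken by ascending input,
  then genomic order); along this ranking the cumulative ChIP fraction
  `P(i)` and input fraction `Q(i)` are accumulated, the background extent
  `k = argmax_i Q(i) - P(i)` marks where signal starts to dominate, and
  `f = P(k)/Q(k)` matches depth-normalized input to ChIP over the
  background bins. The full-ranking formulation is used (no sub-sampling);
  it is exact and deterministic, and `ses_scale_factor` is tested against an
  exhaustive scan over all candidate ranks.
* `pc` is a pseudocount, default 1.0 — the conventional choice that keeps
  zero-count bins finite while perturbing typical counts (tens of reads per
  20-kb bin) by under 5%.

Replicates are merged by per-bin median (`merge_replicates_median()`;
a bin masked in any replicate is masked in the merge), then the per-cell-type
tracks are quantile normalized against each other
(`quantile_normalize()`, classic mean-order-statistic normalization via
limma) to damp batch effects. The merge-then-normalize-then-fit order is the
package default; both steps operate on interchangeable `binned_track`
objects, so the alternative order is a two-line change for users who want
it.

### Replicate model in the simulator

The simulator draws each replicate's bin value independently:
`N(mu_state, sigma_state^2) + N(0, noise^2)`. Replicate agreement therefore
comes only from the shared state sequence; with the default emission
parameters the expected between-replicate Pearson correlation is
`var_between / (var_between + mean(sigma^2) + noise^2) ~= 0.66`, and the
median of two replicates has per-state standard deviation
`sqrt((sigma^2 + noise^2)/2) ~= 0.22`. Real replicates share per-bin
biological signal beyond the state mean and can correlate more strongly;
tests built on this generator therefore probe the segmentation under *more*
within-state noise per replicate pair than a well-correlated real pair
would show, while the merged-track regime matches the decoding conditions.

## The hidden Markov model

Each cell type gets its own K-state HMM with Gaussian emissions over the
merged, normalized log2 ratio track: initial probabilities `pi`, transition
matrix `A`, per-state `mu_k`, `sigma_k`. The free parameter count is
`p = K^2 + 2K - 1` (`K - 1` for `pi`, `K(K-1)` for `A`, `2K` emissions).

* **Initialization** (`kmeans_init()`): 1-D k-means on the pooled values
  with k-means++ seeding under a fixed seed; ten seeded draws are made and
  the lowest within-cluster sum of squares kept, because a single draw
  occasionally seeds two centers inside one cluster and Lloyd iterations
  cannot escape that optimum. `pi` and `A` start uniform; cluster means and
  standard deviations seed the emissions, ordered by ascending mean so a
  seed maps to exactly one initialization.
* **Training** (`fit_baum_welch()`): Baum-Welch EM with log-space
  forward/backward recursions (log-sum-exp, no scaling factors — directly
  comparable to the exhaustive-enumeration oracle in the tests). Iteration
  stops when the relative log-likelihood improvement drops below `tol`
  (default `1e-6`) or at `max_iter` (default 1000). Emission standard
  deviations are floored at `sigma_min = 1e-3` to prevent variance collapse
  on near-constant stretches.
* **Observation sequences**: tracks are split at chromosome ends and masked
  bins into maximal unmasked runs (`obs_sequences()`); each run restarts
  from `pi`, so no information flows across blacklist gaps. This is the
  conservative choice for gaps whose contents are by definition
  untrustworthy.
* **Decoding** (`assign_states()`): per-bin maximum-posterior (MAP) state by
  default, Viterbi by flag; ties break toward the lower state index. In the
  domain regime (strong self-transitions, separated means) the two decoders
  agree on over 99% of bins, so the choice is not load-bearing.
* **Labeling** (`label_states()`): states are ranked by descending median
  track signal; the highest becomes T1, the middle T2, the lowest non
  (LAD or KDD scheme by prefix). Ties (which require exactly equal medians)
  break deterministically by state index with a warning.

### Model selection

`model_selection()` fits each K in a range (2–5 by default) from several
seeded restarts, keeps the best log-likelihood per K, and reports
`AIC = 2p - 2 logL` and `BIC = p ln(n) - 2 logL` along with the per-K
improvement deltas. The default choice is the BIC argmin; the deltas are
reported so the "simplest model that improves the fit most" elbow rule can
be applied by inspection rather than automated away. For model comparison
the package runs EM at `max_iter = 100, tol = 1e-5`: misspecified K values
approach their optimum in long, flat crawls that change the BIC ranking by
nothing (on the default simulation, three states win by thousands of BIC
units) while costing an order of magnitude more time at the tighter
tolerance.

## Domains and atlas statistics

Labeled calls merge into 0-based half-open BED domains
(`calls_to_domains()`); masked bins split domains (no bridging across
blacklist gaps — the reproducible choice, since bridged contents would be
a guess). `domain_stats()` reports per-label counts, median/mean sizes and
genome fractions, both per cell type and as the median of per-cell-type
medians (the "median across cell types" convention); both the pooled and
across-cell-type medians are emitted because published size summaries are
ambiguous between them.

`boundary_profile()` averages signal in bin-center offsets around oriented
adjacencies of two labels (e.g. nonLAD|T2-LAD), mirroring right-to-left
adjacencies so the lower-rank label always sits at negative offsets; the
mean is taken per offset over all boundaries with no per-boundary
renormalization, matching reference-point metaprofile conventions.

Cross-cell-type invariance (`invariance_fraction()`) is the fraction of
*assigned* bins — bins called in every member of the subset under
comparison — holding the same label across the subset. Four modes: per
subtype (T1, T2), subtype-combined (exactly the sum of the two, since the
events are disjoint), and genome-wide (any identical label).
`invariance_curve()` enumerates all subsets of each size up to a threshold
(500 by default) and samples distinct subsets beyond it, since published
"random comparisons" could be either. `pairwise_invariance_comparison()`
builds per-pair 2x2 tables (subtype x retained) with Haldane 0.5 correction
on zero cells and a paired two-sided t-test of T1 vs T2 invariant fractions
across pairs. `subset_percentile()` ranks a focal subset (e.g. related
mesoderm cell types) against all size-matched subsets by strict-inequality
percentile.

Genes are assigned a state per cell type (`assign_gene_states()`) by
majority bp overlap with assigned bins, ties resolved by the TSS bin
(a `tss`-only rule is available); the rule is recorded on the result
because no single convention is standard. Gene flows between two cell
types (`gene_state_transitions()`) and expression integration
(`proportion_expressed()` at TPM > 5;
`expression_fold_change_by_transition()` with pseudocount 1 and one-way
ANOVA across transition groups) complete the atlas layer.

## Enrichment statistics

`bin_overlap_table()` counts assigned bins by state x feature overlap
(>= 1 bp by default, with a minimum-overlap flag).
`odds_ratio_fisher()` computes `OR = ad/bc` with Haldane 0.5 on zero cells
and the two-sided Fisher exact p by hypergeometric point-probability
summation (outcomes no more probable than the observed table, with the
conventional 1e-7 relative slack); it is tested against full enumeration
and against `stats::fisher.test`. `permutation_zscore()` realizes the
z-score style enrichment display: the null applies independent uniform
circular rotations of the label vector within each chromosome, preserving
domain run-length structure — naive per-bin shuffling would destroy the
autocorrelation and overstate significance. `base_overlap_fraction()` and
`gc_content()` (G+C over unambiguous bases, per domain) cover bp-level
replication and composition checks.

## The synthetic-data generator

`sim_config()` fixes the study conditions all tests run under:

| parameter | default | rationale |
|---|---|---|
| genome | 4 x 100 Mb chromosomes | 20,000 bins: domain-scale structure at desk-scale cost |
| bin size | 20 kb | the atlas resolution |
| emission means (T1, T2, non) | 0.7, 0.2, -0.5 | ordered LB1 enrichment with a genuinely intermediate T2 |
| emission sd | 0.3, 0.3, 0.35 | substantial T2 overlap with both neighbours |
| self-transitions | 0.98 | geometric mean run of 1 Mb — realistic domain lengths |
| replicates | 2, noise sd 0.1 | the atlas design |
| counts | input Poisson(50); ChIP multipliers 2.0/1.4/0.6 | enrichment ordered T1 > T2 > 1 > non |
| blacklist | 2% of bins | realistic masked fraction |
| atlas | 3 cell types, run-switch probability 0.2 | shared domain scaffold with cell-type turnover |
| genes | 2000 x 5 kb, P(expressed) 0.1/0.4/0.7 | expression rises as lamina contact falls |

State switching between cell types happens per maximal same-state run (not
per bin), preserving domain-scale structure so invariance statistics behave
like real atlases, and moves only between adjacent ranks (T1<->T2,
T2<->non) by default — direct T1<->non exchanges are forbidden, mirroring
how gene relocalization between the extreme compartments passes through the
intermediate state. Because each bin's label then evolves as a Markov chain
with a known kernel, expected invariance fractions are available in closed
form (`expected_invariance()`) and the end-to-end tests compare the
pipeline's measured invariance against them within Monte-Carlo error
(which scales with the number of domain runs, not bins, since runs switch
as blocks).

All generators are deterministic: a master seed expands into per-stream
sub-seeds through a fixed affine rule, and regenerating with the same
configuration and seed reproduces byte-identical outputs.

### What the generator does not emulate

GC/mappability bias, count overdispersion beyond Poisson, replicate-shared
per-bin biology (see above), unbalanced state proportions per chromosome,
and copy-number artifacts. Passing tests show the machinery is correct and
well-calibrated under the stated model, not that real ChIP-seq meets that
model; on real data the blacklist, SES scaling and quantile normalization
carry the burden the generator sidesteps.

## Numerical choices and degenerate inputs

* All coordinates 0-based half-open; writers emit records sorted by layout
  order and full-precision values, so write/read round trips are exact.
* bedGraph intervals that are not bin-aligned, or overlap, are errors —
  silent averaging would mask grid mismatches.
* SES requires at least 10 unmasked bins and positive totals; ties in the
  ChIP ranking break by input then genomic order for determinism.
* Quantile normalization requires identical missing-value patterns; tied
  values receive the mean of their tied-rank reference values.
* EM errors out on non-finite log-likelihood (reporting the iteration) and
  re-seeds k-means up to ten times on degenerate clusterings.
* Fisher on an all-zero table, overlap of an empty set, and decoding a
  fully masked track are hard errors or explicit NA results, never silent
  zeros — except `bin_overlap_table` with an empty feature set, which is a
  valid all-zero-overlap table.

## Problem sizes in the test suite

Unit oracles run on 8-bin sequences (exhaustive 3^8 path enumeration),
40-bin SES fixtures and 2x2 tables with margins up to 40 (full
hypergeometric enumeration). Parameter recovery runs on 50,000-bin
simulations, model selection on ten 20,000-bin seeds, and the end-to-end
atlas on the default 20,000-bin, 3-cell-type configuration; these sizes
give Monte-Carlo error comfortably inside the asserted tolerances while
keeping the whole suite a few minutes of single-core compute.

## Known limitations

* Emissions are univariate Gaussians; multivariate or mixture emissions
  (e.g. joint LB1 + H3K9me2 segmentation) are out of scope.
* The HMM is first-order Markov: run lengths are geometric, while real LAD
  length distributions are heavier-tailed. Labeling and downstream
  statistics do not depend on this, but simulated size distributions do.
* The permutation z-score's rotation null preserves run-length structure
  within chromosomes but not inter-chromosomal composition differences.
* `read_bedgraph` requires grid-aligned intervals by design; tracks binned
  at a different resolution must be re-binned upstream.
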