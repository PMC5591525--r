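---
title: "Discovering RBP co-binding groups from CLIP-seq peak sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering RBP co-binding groups from CLIP-seq peak sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

RNA-binding proteins (RBPs) rarely act alone: they compete for overlapping
elements, bind as complexes, and co-regulate splicing and decay. Individual
CLIP-seq experiments give one protein's binding map at a time, with
substantial noise — peak callers disagree, replicates disagree, and read
coverage at a site is driven as much by transcript abundance as by binding.
`rbpcobind` integrates many per-RBP peak sets into one matrix of normalized
binding-site occupancies and soft-clusters the proteins into co-binding
groups. This vignette describes the model, the parameters that matter, and
the choices made where reasonable alternatives existed.

```{r setup}
library(rbpcobind)
```

## From peaks to a unified site set

All coordinates are handled in the BED convention (0-based, half-open) on
input and output, and as standard `GRanges` internally. Overlap queries are
strand-aware whenever both sides carry a strand and strand-blind as soon as
either side is unstranded; for the set operations (Jaccard, merging) a mixed
pair of inputs is treated strand-blind as a whole, which keeps the per-base
union well defined.

Peak integration has three stages:

1. **Method intersection** (`intersect_methods()`): when two callers were
   run on the same library, only peaks confirmed by both are kept. The
   retained peaks keep the *primary* caller's coordinates and read counts —
   the alternative (keeping only the intersected bases) discards the
   caller's peak model for no clear gain, and which caller is primary is a
   configuration choice.
2. **Replicate filtering** (`filter_replicas()`): a peak survives when it
   has at least `min_reads` reads (default 4, a strict reading of "more
   than 3") and overlaps, by at least one base, a peak with the same read
   support in at least one other replicate. This semi-overlap rule is
   deliberately permissive because even good CLIP replicates have low
   Jaccard similarity. An RBP with a single usable replicate falls back to
   the read filter alone rather than being discarded.
3. **Merging** (`merge_sites()`): surviving peaks of all RBPs are pooled
   and coalesced into disjoint binding sites; bookended intervals merge,
   following the usual merge semantics. Sites longer than `bin_len`
   (default 100 bp) are replaced by 100-bp bins advancing in 50-bp steps
   (`split_long_sites()`); when the last regular bin falls short of the
   site end, one extra bin is anchored at the end so every base remains
   covered — the remainder rule had to be fixed somewhere, and end
   anchoring keeps bin widths exact instead of emitting a short tail bin.

Sites are annotated against a GTF by a fixed priority (CDS, canonical
ncRNA, 3'-UTR, 5'-UTR, lncRNA exon, pseudogene, intron, then intergenic /
others), so a site inside both a CDS and another gene's intron is counted
once, as CDS.

## Occupancy: separating binding from abundance

Read coverage at a site confounds affinity with transcript abundance.
Treating binding as an equilibrium between free protein, free sites and
bound sites, the fraction of transcript copies bound at a site — the
occupancy — is proportional to CLIP RPM divided by background RPM (total
RNA-seq, or the size-matched input for eCLIP):

$$\Theta_{ij} \propto \frac{\mathrm{CLIP\ RPM}_{ij}}{\mathrm{RNA\text{-}seq\ RPM}_{i}}$$

`build_occupancy()` computes these ratios, drops sites with zero raw
background counts (occupancy is undefined without transcript evidence; no
epsilon threshold is applied), scales each RBP's ratios by their 95%
quantile — under the assumption that an RBP's strongest sites are close to
fully occupied — and caps at 1. Two numerical choices are worth noting: the
scaling quantile is computed over *strictly positive* ratios only, since
the many structural zeros of a sparse column would otherwise deflate it,
and the quantile estimator is the standard linear-interpolation (type 7)
one. Sites bound by fewer than two RBPs are then removed
(`filter_cobound()`); they carry no co-binding information.

A practical consequence, which the test suite verifies on noiseless
synthetic data: raw CLIP RPM correlates strongly with site expression
(Spearman rho above 0.5) while the occupancy does not (|rho| below 0.2).
Occupancy is also invariant to per-track library size by construction.

## Soft clustering by KL-NMF

The N x M occupancy matrix V is factorized as V ~ WH with W (N x R) the
basis over sites and H (R x M) the coefficients over RBPs, minimizing the
generalized Kullback–Leibler divergence

$$F(W,H)=\sum_{ij}\Big[V_{ij}\log\frac{V_{ij}}{(WH)_{ij}}-V_{ij}+(WH)_{ij}\Big],$$

with the standard multiplicative updates (implemented in C++ for the many
restarts the consensus diagnostics need). Initialization is i.i.d.
Uniform(1e-6, 1) from a per-run seed, so a run is a pure function of
`(V, R, seed)`; division denominators are floored at 1e-12, which prevents
0/0 without materially changing converged solutions; iteration stops when
the relative objective decrease drops below `tol` (default 1e-5, with
`max_iter` 2000). The objective is non-increasing along the trajectory, a
property the tests assert at every iteration.

## Choosing the number of groups

For each candidate rank, many factorizations from different seeds are
summarized by a consensus matrix: per run, each RBP is hard-assigned to its
largest coefficient (ties to the smallest index — the factorization itself
does not define a hard clustering, so the argmax convention is ours), and
the consensus C is the mean of these binary co-clustering matrices.
Two diagnostics summarize its stability:

* **CPCC** — the Pearson correlation between the consensus dissimilarities
  D = 1 - C and the cophenetic distances of an average-linkage dendrogram
  built from D. The linkage is not dictated by the definition; average
  linkage is the conventional choice for consensus matrices. A perfectly
  stable consensus makes both distance vectors constant, leaving the
  correlation undefined; we return 1 by convention since the clustering
  could not be more stable.
* **DC** — the dispersion $\frac{1}{M^2}\sum_{ij} 4\,(C_{ij}-\tfrac12)^2$,
  which is 1 exactly when all entries are 0 or 1 and 1/M for the maximally
  unstable matrix. The 1/M² normalization is required for the stated 0–1
  range of the coefficient; the unnormalized sum grows with M.

`rank_scan()` computes both over a schedule of run counts (default 10, 30,
50, 80, 100 runs per rank, ranks 5–20 by default), reports per-rank means
with min/max across schedule entries, and flags ranks that are strict local
maxima of either mean (endpoints compare against their single neighbor).
The flagged ranks are candidates; the final choice remains the analyst's,
as stability alone does not decide between a coarse and a fine grouping.
The automated pipeline defaults to the flagged rank with the highest mean
DC. The final factorization at the chosen rank keeps the lowest-KL result
of `n_runs` restarts (default 100).

## Groups and site associations

The coefficient matrix is scaled per RBP column to its maximum (zeros are
preserved, which plain min–max scaling would not guarantee for these
non-negative, near-zero-minimum columns), and an RBP joins every group
where its scaled weight exceeds 0.2 — soft membership, so promiscuous RBPs
can sit in several groups. The 0.2 default corresponds roughly to the upper
few percent of scaled coefficients in practice, but that correspondence is
data-dependent and not enforced.

Sites are tied to groups through two rules on the basis matrix: the
entropy-based specificity of the site's basis row,

$$s(w) = 1 + \frac{1}{\log_2 R}\sum_r p_r \log_2 p_r,\qquad p_r = w_r / \textstyle\sum_q w_q,$$

must exceed 0.8 (the site loads essentially one group — this is what rules
out unspecific binding at highly abundant transcripts), and the basis
coefficient itself must exceed the 80% quantile of its column (computed
over all sites of the column, positives only, same estimator as above; the
alternative of conditioning the quantile on specificity-passing sites
would couple the two rules and is not what we do). The raw basis entry
W[i, r] serves as the association's affinity score.

## Validation statistics

* `permutation_group_support()` counts network edges of one evidence type
  inside a group and compares against uniform random same-size subsets of
  the RBP universe, reporting the smoothed estimator
  (1 + #\{perm >= obs\}) / (1 + n_perm), which can never return 0. For
  very small groups the edge-count statistic is coarse and this estimator
  is conservative (p-values stochastically above uniform); calibration is
  therefore checked on groups large enough that the statistic is
  effectively continuous.
* `known_motif_fraction()` scans IUPAC literature motifs (sense strand
  only, T/U equivalent) and `motif_enrichment_group_vs_rbp()` compares a
  group's sites against an individual RBP's peaks by one-sided Fisher
  test. De novo motif discovery is out of scope.
* `halflife_enrichment()` and `splicing_enrichment()` contrast
  percentile-defined gene and exon classes (short vs long half-life below
  the 20th / above the 80th percentile; AS vs constitutive exons at PSI
  < 0.2 / > 0.8) by the fraction carrying a binding site, with one-sided
  Fisher tests and log2 fraction ratios. Exon flanks are +/-2 kb in
  genomic coordinates; gene overlap uses gene bodies (the choice between
  gene bodies and 3'-UTRs is genuinely open; gene bodies are the more
  conservative, assumption-free option). Fisher's sidedness defaults to
  "greater", the enrichment direction, and the reported odds ratio is the
  sample ad/bc, not the conditional MLE.

## The synthetic scenario generator

`generate_scenario()` creates complete, seeded datasets with known ground
truth: planted groups own disjoint blocks of sites; member RBPs receive
peaks there with log-normal binding strengths multiplied by log-normal
site expression (this product is what creates the abundance confounding
the occupancy step must remove); each RBP misses a fraction of its true
sites (dropout, default 0.3); Poisson background peaks (default 50 per
track) add noise; and side tables carry planted signal — genes hosting one
designated group's sites draw short half-lives, exons near another group's
sites draw low PSI, and the association network contains all within-group
pairs plus noise edges. The default scenario (12 RBPs, 3 groups of 4,
1500 sites in runs of 10 per toy gene, 2 replicates, ~30 expected reads
per unit strength) is the standard validation condition used throughout
the tests and the acceptance script.

What the generator does **not** emulate: read-level artifacts (crosslink
mutations, PCR duplicates), isoform structure, overlapping genes, GC or
mappability biases, and realistic genome geometry. Passing the planted
recovery tests therefore demonstrates that the statistical machinery works
under the model's own assumptions, not that any particular real dataset
will yield stable groups.

## Worked example

```{r example, eval = FALSE}
scn <- generate_scenario(scenario_config(seed = 1), "scenario")
cfg <- pipeline_config(
  manifest = scn$files[["manifest"]],
  background = scn$files[["background"]],
  out_dir = "results", gtf = scn$files[["gtf"]],
  network = scn$files[["network"]],
  ranks = 2:6, seed = 1)
res <- run_pipeline(cfg)
res$scan$summary       # consensus diagnostics per rank
res$groups             # called co-binding groups
head(res$associations) # group-specific binding sites
```

Problem sizes in the shipped tests and in `scripts/acceptance.R` are kept
at the scale of the default scenario (1500 sites, 12 RBPs, ranks 2–6 with
the 10/30/50/80/100 run schedule), which resolves three planted groups
cleanly while keeping a full run in minutes on one core.

## Known limitations

* The replicate "semi-overlap" rule and the method-intersection coordinate
  convention are reasonable fixed choices among several defensible ones;
  both are configurable.
* KL-NMF is non-convex: different seeds give different local optima, which
  is precisely why consensus diagnostics and best-of-restarts selection
  are built in, but a single factorization should never be interpreted on
  its own.
* The occupancy model assumes equilibrium binding and comparable
  crosslinking efficiency across sites of one RBP; neither holds exactly.
* Enrichment statistics treat sites independently; clustered sites on one
  transcript count once per gene/exon but are not otherwise de-correlated.
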