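# rbpcobind

Discovery of RNA-binding protein (RBP) **co-binding groups** from CLIP-seq
binding peaks.

RBPs regulate splicing, stability, and translation combinatorially —
competing for overlapping elements or binding as complexes — but each
CLIP-seq experiment maps only one protein, with caller- and
replicate-dependent noise, and with read coverage confounded by transcript
abundance. `rbpcobind` integrates many per-RBP peak sets into one
quantitative matrix and clusters the proteins into groups that share
binding sites, for anyone analyzing compendia of CLIP experiments (ENCODE
eCLIP, PAR-CLIP/HITS-CLIP collections) in one cell type.

## Method at a glance

1. **Peak integration.** Per RBP, peaks must be confirmed by a second peak
   caller (when available) and carry ≥ 4 reads with a ≥ 1 bp overlapping,
   equally supported peak in a second replicate. Surviving peaks of all
   RBPs are merged into disjoint binding sites; sites > 100 bp are split
   into 100-bp bins with 50-bp overlap, and sites are annotated by a fixed
   feature-class priority (CDS first, then canonical ncRNA, UTRs, ...).
2. **Occupancy.** For site *i* and RBP *j*,
   Θ<sub>ij</sub> ∝ CLIP RPM<sub>ij</sub> / RNA-seq RPM<sub>i</sub>,
   scaled per RBP by the 95% quantile of its positive ratios and capped at
   1 — an equilibrium-binding estimate of the fraction of transcript
   copies bound, freed from abundance effects. Sites without background
   signal or bound by < 2 RBPs are dropped, giving the N × M occupancy
   matrix **V**.
3. **Soft clustering.** **V ≈ WH** by non-negative matrix factorization
   under the generalized Kullback–Leibler divergence
   F(W,H) = Σ<sub>ij</sub> [V<sub>ij</sub> log(V<sub>ij</sub>/(WH)<sub>ij</sub>) − V<sub>ij</sub> + (WH)<sub>ij</sub>],
   via multiplicative updates (C++). The rank R (number of groups) is
   chosen from consensus clustering over many seeded runs: the cophenetic
   correlation (CPCC) and dispersion (DC) of the consensus matrix are
   scanned over ranks, and their local maxima are candidate group numbers.
   The final model is the lowest-KL result among (by default) 100
   restarts.
4. **Groups and sites.** RBPs join every group where their column-scaled
   coefficient exceeds 0.2 (soft membership). A site is associated to a
   group when its entropy-based basis-specificity score
   (1 for one-group loading, 0 for uniform) exceeds 0.8 **and** its basis
   coefficient exceeds the group's 80% column quantile.
5. **Validation statistics.** Permutation tests against protein–protein
   association networks (10,000 random same-size sets by default), IUPAC
   known-motif Fisher enrichment, and Fisher enrichment of binding among
   short-half-life genes and alternatively spliced (low-PSI) exons with
   ±2 kb exon flanks.

A seeded synthetic-scenario generator (`generate_scenario()`) plants
co-binding groups, abundance confounding, dropout, background peaks, and
matched side tables, so the whole pipeline is testable without any
download.

## Worked example

```r
library(rbpcobind)

scn <- generate_scenario(scenario_config(seed = 7), "scenario")
cfg <- pipeline_config(
  manifest   = scn$files[["manifest"]],
  background = scn$files[["background"]],
  gtf        = scn$files[["gtf"]],
  network    = scn$files[["network"]],
  out_dir    = "results",
  ranks = 2:6, runs_schedule = c(10, 30), seed = 11)
res <- run_pipeline(cfg)
res$scan$summary
```

```
  rank cpcc_mean  cpcc_min  cpcc_max   dc_mean    dc_min    dc_max cpcc_local_max dc_local_max
1    2 0.9718495 0.9487188 0.9949802 0.4568210 0.4291975 0.4844444          FALSE        FALSE
2    3 1.0000000 1.0000000 1.0000000 1.0000000 1.0000000 1.0000000           TRUE         TRUE
3    4 0.9984952 0.9979956 0.9989947 0.8709259 0.8679630 0.8738889          FALSE        FALSE
4    5 0.9952768 0.9946155 0.9959382 0.7952469 0.7843827 0.8061111          FALSE        FALSE
5    6 0.9911312 0.9908235 0.9914390 0.7706790 0.7635802 0.7777778          FALSE        FALSE
```

Rank 3 is the unique local maximum of both diagnostics — the scenario's
three planted groups — with a perfectly stable consensus (DC = 1: every
one of the runs assigns the 12 RBPs to the same three clusters). The
called groups recover the planted membership exactly:

```r
res$groups
#> <rbp_groups> 3 groups (membership threshold 0.20)
#>   group1: RBP09, RBP10, RBP11, RBP12
#>   group2: RBP05, RBP06, RBP07, RBP08
#>   group3: RBP01, RBP02, RBP03, RBP04
```

and the planted "physical" association edges support each group against
10,000-fold (here 2,000-fold) random sets, e.g. p = 0.004 per group, while
the decay-designated group's sites are enriched among short-half-life
genes (Fisher p = 8.5e-18) and the splicing-designated group's sites near
low-PSI exons (p = 1.2e-65, log2 ratio 5.0) in this scenario.

See `vignettes/cobinding-methods.Rmd` for the full model description,
parameter defaults, and design decisions.

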