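---
title: "Weighted co-expression modules and miRNA-mRNA network integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted co-expression modules and miRNA-mRNA network integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comirnet)
```

# The analysis

Transcriptional regulation (genes) and post-transcriptional regulation
(miRNAs) are usually profiled separately, yet the interesting biology
sits in their coupling: modules of co-expressed genes whose behavior is
shaped by a handful of regulator miRNAs. `comirnet` implements a
weighted co-expression workflow over *paired* mRNA and miRNA expression
matrices from the same samples — typically a tumor/normal design — and
then bridges the two layers through an externally scored
miRNA-target interaction table.

The pipeline, per layer:

1. **Filter.** Features are z-scored (denominator $n-1$) and screened
   by a two-group differential-expression test at a stated FDR. This is
   a variance filter: only features that move with the phenotype enter
   the network.
2. **Network.** Co-expression similarity is the Pearson correlation
   $S_{ij} = \mathrm{cor}(x_i, x_j)$ over samples. The unsigned
   adjacency raises it to a soft-thresholding power,
   $a_{ij} = |S_{ij}|^\beta$, chosen so that the connectivity
   distribution approximates scale-free topology.
3. **Modules.** The topological overlap
   $T_{ij} = \frac{\sum_{u \ne i,j} a_{iu}a_{uj} + a_{ij}}
   {\min(k_i, k_j) + 1 - a_{ij}}$ rewards feature pairs that are both
   directly connected and share strong neighbors; average-linkage
   clustering of $1 - T$ with a static height cut yields modules,
   labeled with a frozen color palette (largest module = turquoise) and
   a layer prefix (`G-` genes, `M-` miRNAs). Features in no module are
   `grey`.
4. **Module-trait statistics.** Each module is summarized by its
   eigengene (ME) — the first principal component of its standardized
   members. Gene significance (GS) is $|\mathrm{cor}(x_i,
   \text{trait})|$; module membership (MM) is
   $\mathrm{cor}(x_i, \mathrm{ME}_m)$; module significance (MS) is the
   mean member GS. Module-trait association uses the exact $t$
   transform $t = r\sqrt{n-2}/\sqrt{1-r^2}$.
5. **Hubs and integration.** Members with $|\mathrm{MM}| \ge 0.8$ and
   $\mathrm{GS} \ge 0.2$ are hubs. Hub miRNAs of the focus miRNA module
   are linked to the genes of the focus gene module through the
   interaction table — scores per source database are converted to
   ranks, averaged, and cut at the top 20% — and the resulting
   bipartite network is reported with per-node degree and betweenness
   centrality normalized by $(n-1)(n-2)/2$.

# Parameters that matter

| parameter | default | why |
|---|---|---|
| `alpha` | 0.05 | FDR level of the DE filter (adjusted $p < 0.05$). |
| `candidate_powers` | 1–20 | scan range for $\beta$. |
| `r2_target` | 0.8 | scale-free fit acceptance; common practice for unsigned networks. |
| `min_mean_connectivity` | 1 | a power is ineligible if the average node retains less than one unit of connection weight (see below). |
| `fallback_beta` | 6 | default unsigned power when no candidate reaches the target. |
| `cut_height` | 0.995 | static cut on TOM dissimilarity; auditable, unlike adaptive cuts. |
| `min_module_size` | 30 (genes), 5 (miRNAs) | miRNA panels are an order of magnitude smaller than gene panels. |
| `merge_cut` | 0.25 | modules with eigengene dissimilarity $1 - r < 0.25$ are iteratively merged, larger label wins. |
| `mm_min`, `gs_min` | 0.8, 0.2 | hub thresholds, configurable. |
| `top_fraction` | 0.2 | interaction rank cutoff (ceiling rule, so a non-empty table always yields a non-empty selection). |

# Design choices in the open spots

**Differential expression.** Moderated count-based linear models
(voom-style) are deliberately *not* reimplemented. The DE stage only
gates features into the network, so a per-feature Welch $t$-test on
normalized values with Benjamini-Hochberg adjustment is used; it is
FDR-controlled, assumption-light, and pluggable behind a single
function if a moderated test is preferred. Consequence: on count data
the selection will differ from a voom analysis; this package operates
on normalized continuous values throughout.

**Scale-free fit.** Connectivities are placed into 10 equal-width bins,
empty bins dropped, and $\log_{10}(\text{frequency})$ is regressed on
$\log_{10}(\bar k)$ per bin. Equal-width binning is essential:
equal-occupancy bins have equal frequencies by construction, which
flattens the regression and makes the fit index meaningless — an exact
power law must score $R^2 \approx 1$, and under equal-width binning it
does. Binning granularity changes $R^2$ values, so it is fixed and
exposed.

**Power selection.** The chosen $\beta$ is the smallest candidate with
a negative slope, $R^2 \ge$ target, *and* mean connectivity at or above
the floor. The floor exists because the apparent scale-free fit keeps
improving as $\beta$ grows long after the adjacency has decayed into a
sparse noise tail (mean connectivity $\ll 1$), where module detection
degenerates; the fit index must always be read jointly with mean
connectivity. When nothing qualifies, the scan does not chase the
maximal $R^2$ into that degenerate regime; it falls back to the
conventional default unsigned power 6 with a warning, and the full scan
report is returned for inspection.

**TOM variant.** The unsigned overlap with the $+1$ denominator
convention and connectivity excluding the diagonal; the
`dissimilarity` element is exactly $1 - T$.

**Tree cutting.** A static height cut plus minimum module size, rather
than adaptive hybrid cutting: every decision is reproducible from two
numbers. Cuts are nested (a deeper cut never splits a shallower cut's
cluster), and exact-tie merge heights are monotonized against
femto-scale floating-point inversions before cutting.

**Eigengene sign.** The first principal component's sign is arbitrary,
so each ME is oriented to correlate non-negatively with the module's
mean standardized profile. The orientation is deterministic; note that
flipping the sign of every member flips the mean profile and therefore
the oriented ME with it.

**Rank aggregation.** Source databases score on incommensurable
scales, so within-source ranks (best = 1, ties averaged, missing
scores skipped per row) are averaged into `mean_rank`; ordering ties
break lexically on (miRNA, gene), and the final 1..N position is stored
as `rank`. The percentage cutoff uses the ceiling.

**Betweenness normalization.** The general undirected normalizer
$(n-1)(n-2)/2$ with each unordered pair counted once; the
bipartite-specific variant is not used, so values are comparable across
reports regardless of side sizes. Edges are unweighted in centrality —
scores influence selection only.

# The synthetic world

`simulate_study()` and the underlying generators produce the structure
the analysis assumes, with a 20 normal / 50 tumor sample design by
default:

* planted modules are latent-factor blocks: member $=
  \sqrt{\rho}\,f + \sqrt{1-\rho}\,\varepsilon$ with a shared
  standard-normal factor per module, so the expected within-module
  correlation is exactly $\rho$ (default 0.7) and features have unit
  variance — the equicorrelation TOM clustering is built to detect;
* background features are independent noise;
* differential expression is a mean shift (default 2 residual standard
  deviations) added to tumor columns of module features;
* the quantitative trait is a chosen module's eigengene plus Gaussian
  noise (default sd 0.5), giving module-trait recovery a ground truth
  with expected correlation $1/\sqrt{1+\sigma^2}$;
* the interaction table is a uniform random subset of the miRNA × gene
  grid (default density 0.05) with uniform scores per simulated source
  (default 3), and planted regulator edges lifted to at least the 0.9
  quantile of the background scores so they survive rank selection.

What it does **not** emulate: RNA-seq count distributions, library
size, batch effects, correlated noise, or realistic miRNA target
overlap structure. A green test therefore establishes that the
machinery recovers the structure it assumes — not that any particular
biological dataset will yield comparable module purity.

One behavior of the stated world is worth knowing: with the default
tumor shift applied to all module features, the shift itself induces
correlation ($\approx 0.45$) between *all* shifted features, so after
DE filtering the layers typically collapse into a single
phenotype-driven module — mirroring the dominant tumor-signature module
seen in real two-group designs. Multi-module recovery is exercised with
the shift disabled.

# Degenerate inputs and numerical conventions

* Zero-variance features are an error in z-scoring and correlation;
  `drop_zero_variance()` removes them with a warning first.
* Features constant in both DE groups get statistic `NA`, $p = 1$, with
  a warning; zero within-group variance with distinct means gives
  $p = 0$.
* Sample standard deviations use $n - 1$ throughout.
* Correlations are clamped to $[-1, 1]$ and matrices symmetrized
  against floating-point asymmetry; TOM entries are clamped to
  $[0, 1]$.
* $|r| = 1$ module-trait correlations report $p = 0$ (below any
  representable threshold); constant trait columns are flagged `NA`.
* An empty hub-gene bipartite network is a warning plus an explicit
  empty result, not an error; betweenness of networks with fewer than
  3 nodes is zero.

# Worked example

```{r example, eval = FALSE}
study <- simulate_study(seed = 1)
paths <- write_study(study, "inputs")
config <- do.call(pipeline_config,
                  c(paths, list(out_dir = "results", seed = 1)))
manifest <- run_pipeline(config)
head(manifest$results$report)
```

The run log echoes every stage parameter (FDR level, chosen power,
module counts, cutoff fractions), and `manifest.json` records the
config snapshot plus md5 checksums of every output, so a rerun under
the same config is verifiably byte-identical.

# Limitations

* Unsigned networks only; signed and biweight-midcorrelation variants
  are out of scope.
* No adaptive tree cut or PAM-style reassignment.
* The DE stage is a Welch-$t$ approximation, not a moderated
  linear-model test.
* Interaction tables are consumed as given; no live database queries,
  and no pathway enrichment.
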