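---
title: "Consensus transcriptomic signatures of polyploidy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus transcriptomic signatures of polyploidy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ploidysig)
```

## The problem

Whole-genome duplication (polyploidy) leaves transcriptional footprints that
recur across very different cell types — cancer cell lines, mesenchymal
stem cells of several tissues, cardiac progenitors. Detecting the footprint
that is *shared* requires comparing diploid and polyploid cells in several
independent cohorts, measured on incompatible platforms (microarray
intensities, bulk and single-cell sequencing counts) and in two species
(human and mouse), and then asking which genes respond in the same
direction everywhere. `ploidysig` implements that inference chain
end-to-end:

1. per-cohort normalization and moderated differential testing,
2. sign-consistent **consensus** calling across all cohorts through a 1:1
   ortholog map,
3. **master-regulator** detection by protein-interaction enrichment
   analysis (PIEA) on a one-step interactome neighborhood,
4. gene-**signature** over-representation with observed/expected ratios,
5. **MCODE** molecular-complex extraction from the consensus-induced
   subgraph, and
6. **overlap validation** of the consensus signature in an external cohort.

Because real cohorts of this design are not redistributable, the package
ships a synthetic study generator with planted ground truth; every stage is
validated by recovery and calibration tests against that truth.

## Per-cohort differential expression

Counts matrices are transformed as `log2(count + 0.5)`; intensity matrices
are used as-is when their maximum is below 30 (the practical ceiling of
log-scale array data) and `log2(x + 1)`-transformed otherwise. All cohorts
are then quantile normalized: each column is replaced by the vector of
row-rank means, so every sample shares one empirical distribution. Ties —
frequent in low counts — receive the mean of the reference values at the
tied ranks; for tie-free input the transform is exactly idempotent.

Testing uses an empirical-Bayes moderated t. For gene $g$ with pooled
residual variance $s_g^2$ on $d$ degrees of freedom, a scaled-F prior
$(d_0, s_0^2)$ is fitted across genes by matching moments of
$\log s_g^2$ (digamma/trigamma moment equations, with a Newton inversion
of the trigamma function), and the posterior variance

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d}$$

yields $t_g = \overline{x}_{poly} - \overline{x}_{dip} \,/\,
(\tilde s_g \sqrt{1/n_1 + 1/n_2})$ on $d_0 + d$ degrees of freedom.
With $d_0 = 0$ this collapses to the ordinary pooled t (a tested limiting
case); when the variance spread is degenerate the fit returns
$d_0 = \infty$, i.e. one pooled variance for all genes. A gene that is
flat in both groups with zero fold change is assigned $t = 0$, $p = 1$.
The test suite cross-checks the full fit against the reference
empirical-Bayes implementation in `limma` on a shared fixture.

DEGs are selected at **p < 0.05 and FDR < 0.1** (Benjamini–Hochberg,
per cohort), both strict inequalities, with no fold-change cutoff. The
direction of a call is the sign of the log2 fold change.

## Consensus calling

Mouse cohorts are first translated into the human namespace. Only 1:1
ortholog pairs are used; genes in one-to-many or many-to-many relations
are dropped. This conservative reading keeps the cross-cohort
intersection well defined — a gene whose identity is ambiguous across
species cannot be said to respond consistently.

The consensus universe is the set of genes testable in *every* cohort; a
gene absent from one platform cannot be consistently regulated in all
comparisons, so it is excluded rather than scored on partial evidence.
Within the universe, the consensus up set contains the genes called up in
all cohorts (down analogously); any non-significant call or sign conflict
excludes a gene. No p-value combination (Fisher, Stouffer) is performed:
the design is a pure sign-consistent intersection, which is what makes the
consensus interpretable as "observed independently everywhere". Since the
cohorts are independent, the implied consensus-level false-positive rate
is the product of the per-cohort rates.

## PIEA master regulators

For every gene with **more than 5 interactants** in the interaction
network (restricted to the analysis background), its one-step neighborhood
— proper neighbors, excluding the gene itself — is treated as a gene
signature, and its overlap with the consensus up (down) set is scored by
the cumulative hypergeometric upper tail
$P(X \ge k)$ with population $N$ (background), class $K$ (neighborhood
size) and draw $n$ (DEG-set size), followed by BH adjustment across tested
genes. A master regulator must be significant at FDR < 0.05 **and** itself
belong to the consensus set it regulates — hub status alone is not enough;
the regulator must demonstrate consistent ploidy-dependent expression.

The background is the consensus universe intersected with the network's
nodes. Using the same universe that produced the DEG set keeps the null
hypergeometric model coherent: every gene in the draw could in principle
have been a DEG.

## Signature enrichment and reporting

Signature over-representation uses the same hypergeometric tail against an
explicit background universe supplied by the caller (for synthetic runs,
the whole simulated genome). Signature members outside the background are
dropped before sizing, otherwise the expected count is ill-defined. Each
record carries the observed overlap $k$, the expected count
$e = nK/N$, the **O/E ratio** $k/e$, the tail p and the BH FDR across all
signatures of the collection (one multiple-testing family; per-database
families are not supported). The reporting filter keeps
**FDR < 0.01 and O/E > 1.5**, both strict; the full unfiltered table is
always emitted alongside. Reports render O/E to two decimals and FDR in
scientific notation, the conventional layout of published
over-representation tables.

## MCODE complexes

Complex extraction follows the MCODE scheme: each vertex is weighted by
the core-clustering coefficient of its closed neighborhood (the density of
the neighborhood's highest k-core times that core's number); complexes
grow greedily from the highest-weight unused seed, admitting neighbors
whose weight exceeds $(1 - \mathrm{vwp})$ of the seed weight (default
vwp = 0.2); the haircut step trims each complex to its 2-core and keeps
the connected piece containing the seed; nodes are never reused across
complexes; complexes smaller than 3 nodes are discarded. The complex score
is density × size. Seed ties are broken lexicographically on gene id so
the output is deterministic and vertex-order invariant — the original
algorithm leaves tie order unspecified. Fluff expansion is not
implemented: it re-admits shared peripheral nodes and would break the
node-disjointness that downstream per-complex enrichment relies on.

## Overlap validation

The consensus signature is matched against an external cohort's own DEG
lists on the shared tested universe. Only direction-concordant overlaps
count as matches (consensus-up ∩ external-up, and likewise down);
discordant overlaps are reported informationally. Each direction's overlap
is scored by the hypergeometric upper tail on the shared universe.

## The synthetic study generator

The generator emulates the five-cohort layout of a cross-platform ploidy
study: five independent cohorts, each with 6 diploid and 6 polyploid
samples over a 2000-gene genome; two cohorts are array-style intensity
data, three are sequencing counts; two cohorts are "mouse" and emitted
under mouse identifiers resolvable only through a bundled ortholog table
(95% clean 1:1, the remainder many-to-one to exercise the mapping rules).
Fifty genes are planted up and fifty down with a mean log2 shift of 2.0 in
every cohort; each cohort additionally receives 100 cohort-specific noise
DEGs (random sign) that consensus calling must reject. One extra held-out
counts cohort with the same planted signal serves as the external
validation dataset.

Counts are drawn from a negative binomial with a dispersion trend
$\phi = 0.05 + 1/\mu$ (biological CV of roughly 22–50% over the
expression range), with baseline log2 mean counts uniform on $[4, 11]$ —
the expressed-gene range: genes callable in the same direction on every
platform are, by construction, genes that survive standard low-expression
filtering, so the generator does not plant consensus signal on genes with
single-digit counts that no cohort could measure. Intensity cohorts are
Gaussian on the log2 scale (sd 0.5) around baselines uniform on
$[5, 12]$.

The interaction network is a preferential-attachment graph (3 edges per
node) over the gene universe. Twenty planted genes (half up, half down)
are rewired as hubs: each receives a 20-gene neighborhood of which 80% are
planted genes of its own direction. A consequence worth knowing: hub
wiring makes planted genes mutual neighbors, so many planted *non-hub*
genes also acquire DEG-rich neighborhoods and are legitimately called
regulators — recovery of the planted hubs, not regulator-list size, is
the meaningful quality measure on synthetic data. The signature collection
holds 200 sets of 20–200 genes; 10 are enrichment-planted with half their
members drawn from the planted genes.

A single master seed fans out into fixed per-component child seeds, so
cohorts, network and signatures are each reproducible in isolation and
all emitted files are byte-identical across reruns of one seed.

What the generator deliberately does not model: platform-specific probe
effects, batch structure, library-size gradients, single-cell zero
inflation or dropout, correlated co-expression modules beyond the hub
wiring, and realistic pathway topology. Passing recovery tests therefore
demonstrates the pipeline's correctness and calibration under a clean
signal model, not robustness to every artifact of real cohorts.

## Calibration of discrete tests

Hypergeometric p-values are discrete. At the neighborhood and signature
sizes this study operates at, most null genes have zero overlap with the
query, which places a large probability atom at $p = 1$ and makes the
null p-value distribution markedly **super-uniform**: the fraction of
null tests with $p < \alpha$ is below $\alpha$ — for random 100-gene
queries against this signature collection the exact null expectation of
$P(p < 0.05)$ is about 0.025, not 0.05. The calibration tests therefore
compare observed exceedance fractions with the *exact* discrete-null
expectation (computable from the hypergeometric itself) rather than with
the idealized uniform, and additionally bound the Kolmogorov–Smirnov
distance to the uniform, which is dominated by the $p = 1$ atom.

Two further null subtleties are built into the tests. First, the DE null
calibration runs the full generator with the planted effect set to zero,
so the nominal 5% level is checked against the complete
normalization-plus-moderation stack, not an idealized Gaussian. Second,
the PIEA null uses a degree-preserving edge rewiring of a *signal-free*
network: on a hub-wired network the planted genes carry elevated degree,
and any degree-preserving null inherits that degree–DEG correlation,
inflating neighborhood overlaps for reasons unrelated to the scan's
correctness.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `deg_p`, `deg_fdr` | 0.05, 0.1 | strict per-cohort DEG thresholds |
| `piea_min_degree` | 5 | test only genes with more than 5 interactants |
| `piea_fdr` | 0.05 | regulator significance cut |
| `enrich_fdr`, `enrich_oe` | 0.01, 1.5 | signature reporting filter |
| `edge_min_score` | 0.4 | strict lower bound when reading scored edges |
| `mcode_vwp`, `mcode_min_size` | 0.2, 3 | MCODE expansion and size floor |
| `effect_size` | 2.0 | planted log2 shift in polyploid samples |
| `samples_per_group` | 6 | per-cohort group size |

The problem sizes used throughout the tests — a 2000-gene genome, five
12-sample cohorts, a ~6000-edge network, 200 signatures — were chosen so
that a full study simulates and analyses in about two seconds while still
giving the consensus intersection, the PIEA scan and the enrichment engine
realistic multiplicity (about 1900 jointly testable genes and 600+ PIEA
candidates).

## Numerical and degenerate-input choices

* Tail probabilities are computed in log space via the stable cumulative
  hypergeometric routine, accurate for backgrounds beyond $10^5$.
* `P(X \ge 0) = 1` always; parameter violations raise domain errors
  rather than returning clamped values.
* Strictness of every published threshold is preserved exactly as printed
  (`<` and `>`, never `≤`/`≥`); a score of exactly 0.4 is excluded by the
  edge filter, a p of exactly 0.05 is not a DEG.
* Readers reject malformed input (duplicate gene ids, missing metadata,
  negative counts, empty signatures) with classed, named errors; nothing
  is silently coerced.
* The trigamma inversion runs Newton iterations to relative tolerance
  1e-10; a degenerate variance spread falls back to a fully pooled
  variance with a logged notice.

## Known limitations

* The moderated test has no array-weight estimation, duplicate
  correlation or voom-style precision weights; single-cell data are
  treated as bulk-like matrices.
* Consensus calling is all-or-nothing across cohorts; there is no
  "4 of 5" relaxation and no effect-size meta-analysis.
* PIEA considers one-step neighborhoods only, unweighted and undirected.
* The enrichment engine treats the supplied collection as one
  multiple-testing family and does not de-redundantize related
  signatures.
* Ortholog handling is strictly 1:1; genuinely duplicated genes are
  excluded from cross-species consensus rather than aggregated.
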