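---
title: "Statistical partitioning of pangenomes with panpart"
author: "panpart authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical partitioning of pangenomes with panpart}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panpart)
```

# Overview

`panpart` partitions the gene families of a bacterial pangenome into
**persistent**, **shell** and **cloud** classes. Instead of the classical
fixed frequency thresholds (e.g. "core = present in ≥ 99% of genomes"),
the partition is estimated statistically from two sources of evidence:

1. the family-by-genome presence/absence (P/A) matrix, modeled by a
   multivariate Bernoulli Mixture Model (BMM), and
2. the pangenome graph, whose nodes are families and whose edges record
   observed genomic adjacency, used as a Markov Random Field (MRF) that
   smooths labels along conserved gene neighborhoods.

This vignette documents the model, every fixed constant, and the design
decisions behind them.

# The pangenome model

A **gene table** (one row per gene: `gene_id`, `genome_id`, `contig_id`,
`start`, `end`, `strand`, `family_id`, `circular`) is the single input
record. From it:

- `buildPAMatrix()` builds the binary matrix $X \in \{0,1\}^{F\times N}$
  with $x_{ij} = 1$ when family $i$ has at least one member in genome $j$
  (paralogs do not increase the entry). Every family row has at least one
  presence by construction.
- `buildPangenomeGraph()` counts, per genome, adjacent gene pairs along
  each contig (consecutive `start`-ordered genes; circular contigs also
  contribute the last-to-first closure). The undirected edge weight is
  `count / N`, so a pair adjacent once in every genome has weight 1, and
  repeated paralogous adjacencies can push weights above 1. Strand is
  ignored. Adjacent paralogs of one family create a *self-loop*, which is
  flagged and excluded from smoothing.

# The Bernoulli mixture (BinEM)

Each family's presence vector is drawn from one of $K$ components. With
centroid $\mu_k \in \{0,1\}^N$ and dispersion
$\varepsilon_k \in (0, 1/2]^N$:

$$
P(x_i \mid z_i = k) \;=\; \prod_{j=1}^{N}
  \varepsilon_{kj}^{\,|x_{ij}-\mu_{kj}|}
  (1-\varepsilon_{kj})^{\,1-|x_{ij}-\mu_{kj}|}.
$$

$\varepsilon$ is the probability of deviating from the centroid, clamped
to $[10^{-4}, 1/2]$. In the default **constrained** mode each component
has one pooled $\varepsilon_k$ across genomes (the mean per-genome
mismatch rate); the free mode keeps a full $K \times N$ matrix.

Fitting is plain EM with log-sum-exp stabilization. The M-step sets
$\mu_{kj} = 1$ iff the responsibility-weighted presence exceeds 1/2
(ties go to 0). Empty components are re-seeded from the initializer with
a warning. After convergence components are re-sorted by decreasing mean
presence probability so component 1 is always the most prevalent
(labelled *persistent*), component $K$ the rarest (*cloud*), and
everything between is *shell* (sub-labels `shell_k` when $K > 3$).

## Triangular initialization

The initializer spreads components between an all-present and an
all-absent centroid. With $s = 1/\lceil K/2 \rceil$:

- $\pi_k = 1/K$;
- $\mu_k = \mathbf{1}$ for $k \le K/2$, else $\mathbf{0}$;
- $\varepsilon_k = s\,k/2$ for $k \le K/2$, else
  $\varepsilon_k = s\,(K - k + 1)/2$.

For $K = 3$ this gives $\varepsilon = (0.25, 0.50, 0.25)$: a tight
persistent component, a maximally dispersed middle, a tight cloud.

**Even-$K$ tie-break.** For even $K$ the two central components get
$\mu$ differing everywhere and $\varepsilon = 1/2$ exactly — but at
$\varepsilon = 1/2$ the density is independent of $\mu$, so the pair is
exchangeable and EM provably cannot separate it (their responsibilities
stay identical forever). `triangularInit()` therefore lowers the first
lower-half central component by $s/4$
($K = 4 \Rightarrow \varepsilon = (0.25, 0.5, 0.375, 0.25)$). This is a
deliberate, deterministic departure from a perfectly symmetric ladder;
without it even-$K$ fits collapse to $K - 1$ effective components and
model selection can never return an even $\hat K$.

# Choosing K: ICL

For each $K$ in the grid (default $3..20$) a short EM run (10 steps)
scores

$$
\mathrm{BIC}(K) = \log L - \tfrac{1}{2}\,d_K \log F, \qquad
\mathrm{ICL}(K) = \mathrm{BIC}(K) - \sum_{i,k} t_{ik}\log t_{ik},
$$

with $d_K = K(N+2)$ parameters in constrained mode and $K(2N+1)$ in free
mode. ICL penalizes BIC by the classification entropy, favoring
well-separated components. $\hat K$ is the **smallest** $K$ whose ICL is
within $\delta$ of the maximum, with
$\delta = 0.05\,(\max \mathrm{ICL} - \min \mathrm{ICL})$: a parsimony
margin — near-ties resolve to fewer components.

# Neighboring EM (NEM)

The MRF prior couples the labels of adjacent families. The smoothed
(mean-field) E-step is a fixed-point iteration

$$
t_{ik} \;\propto\; \pi_k \exp\Big( \log f_k(x_i)
  + \beta\, c \sum_{i' \sim i} w_{ii'}\, t_{i'k} \Big),
$$

run synchronously for up to 10 inner rounds (tolerance $10^{-4}$), with:

- $\beta = 2.5$ (smoothing strength; $\beta = 0$ reduces the whole
  algorithm *exactly* to BinEM, which the tests verify to $10^{-10}$);
- $c = N / \sum w$, a normalizer making the coupling scale-free in the
  edge-weight mass;
- the sum restricted to **MRF-eligible** edges: no self-loops, and both
  endpoints of degree ≤ 10. High-degree hubs are typically mobile
  elements whose adjacencies carry no positional signal; they keep their
  own labels but neither give nor receive smoothing.

The penalized criterion
$\sum_{ik} t_{ik}(\log \pi_k + \log f_k(x_i)) - \sum t \log t +
\tfrac{\beta c}{2}\sum_{ii'} w_{ii'} t_i^\top t_{i'}$
is evaluated after every inner round; a synchronous round that would
decrease it is rejected (a guard against the known oscillation of
synchronous mean-field updates), so the outer criterion trace is
non-decreasing by construction.

# Partition assignment

A family is assigned to its maximum-posterior component only when that
posterior **strictly exceeds 0.5**; otherwise it is labelled shell (the
most conservative class for an ambiguous family), recording the best
shell component.

# Scaling: chunked partitioning

For large cohorts, genomes are shuffled into chunks of 500 (a trailing
chunk smaller than 250 is merged into the previous one), each chunk is
partitioned independently (with edge weights recomputed for the chunk's
own $N$), and families are labelled by **absolute majority vote**: a
label wins when it is the unique mode and reaches half of the samplings
in which the family was present. Undecided families trigger further
shuffled rounds (up to 10); any survivors fall back to shell with a
warning.

# Rarefaction and Heaps' law

`rarefactionCurves()` draws 30 random genome subsets per size
$n = 1..\min(100, N)$ and records eight component counts (pangenome,
persistent/shell/cloud, soft core at 95%, soft accessory, exact core,
exact accessory). Per-subset partitions are recomputed, re-selecting
$K$ between 3 and the full-data $\hat K$. Growth is summarized by
Heaps' law $\mathrm{count} = \kappa n^{\gamma}$, fit by
Levenberg–Marquardt on all replicate points with $n \ge 16$ — smaller
subsets are dominated by sampling noise and would bias $\gamma$.
Curve stability is reported as the trapezoidal area of the
interquartile ribbon. The soft-core curve is an intrinsic stair-step:
the allowed absence count $\lfloor (1-t)n \rfloor$ increments once
every $\lceil 1/(1-t) \rceil$ genomes (every 20 at $t = 0.95$).

# Synthetic pangenomes

`simulatePangenome()` is a first-class generator with known truth, used
as the package's study system. Its defaults are fixed conditions, chosen
once up front:

- 3-pattern truth: $\pi = (0.3, 0.2, 0.5)$,
  $\varepsilon = (0.05, 0.3, 0.05)$, shell centroid present in the first
  half of the genomes; the 4-pattern variant has two antagonistic shell
  blocks, $\pi = (0.3, 0.15, 0.15, 0.4)$,
  $\varepsilon = (0.05, 0.2, 0.2, 0.05)$.
- Accessory families are grouped into **islands** of at most 8 families
  sharing correlated presence (probability 0.8 of copying a shared
  island draw), anchored at 5 hotspot positions on a circular persistent
  backbone, rotated to a random origin per genome.
- `degradeGenomes()` emulates imperfect assemblies: independent gene
  loss and junction breaking (circular contigs become linear pieces).

The generator does **not** emulate phylogenetic correlation between
genomes, rearrangements beyond rotation, or paralog inflation; results
on it bound what the algorithms can do under the model's own
assumptions, not on arbitrary real data.

# Worked example

```{r example}
sim <- simulatePangenome(F = 300, N = 30, seed = 1)
graph <- buildPangenomeGraph(sim$genes)
ks <- selectK(sim$pa, 3:10)
ks@KHat
fit <- runNEM(sim$pa, graph, K = ks@KHat)
table(partitionLabels(fit$partitioning))
labelAccuracy(fit$partitioning, sim$labels)
```

# Limitations

- Problem sizes used in tests and the acceptance script (hundreds of
  families, tens to ~1200 genomes) are the package's own desk-scale
  choices; production pangenomes are larger and rely on the chunked
  path.
- The mean-field E-step is an approximation to the MRF posterior; the
  monotonicity guard makes it stable, not exact.
- Cohorts below ~15 genomes give unreliable partitions (the CLI warns).
- $K < 3$ is rejected: the persistent/shell/cloud reading needs at
  least three components.
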