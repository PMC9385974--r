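---
title: "Screening PCD-related ceRNA networks: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening PCD-related ceRNA networks: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceRNAscreen)
```

## What this package computes

`ceRNAscreen` screens for programmed-cell-death (PCD) related competing
endogenous RNA (ceRNA) regulation in a two-group transcriptome contrast.
The archetypal application is a rodent stroke model: brain tissue after
middle cerebral artery occlusion/reperfusion versus sham surgery, profiled
in two independent expression series (one microarray, one RNA-seq). The
pipeline has five stages:

1. moderated-t differential expression per dataset, with DEG calling at
   raw p < 0.05 and |log2FC| > 1;
2. intersection of DEG sets across datasets and against apoptosis,
   necroptosis and pyroptosis gene lists, yielding a membership table;
3. (optional) hypergeometric over-representation analysis of each
   category's genes;
4. consensus voting over several interaction-prediction sources and
   assembly of a tripartite lncRNA–miRNA–mRNA network per category;
5. seven graph-centrality algorithms, seven-way consensus hub extraction,
   and enumeration of hub-only lncRNA/miRNA/mRNA regulatory axes.

Everything runs on plain-text inputs, and a synthetic-data module
generates a complete, ground-truthed scenario so the whole chain can be
validated end to end without any external database.

## The differential expression model

For gene $g$ with group sizes $n_1, n_2$ the two-group fit gives the
log2 fold change $\hat\beta_g = \bar{x}_{g,\text{case}} -
\bar{x}_{g,\text{control}}$ and pooled residual variance $s_g^2$ on
$d_g = n_1 + n_2 - 2$ degrees of freedom. The empirical-Bayes layer
assumes the gene variances are exchangeable,

$$ s_g^2 \mid \sigma_g^2 \sim \sigma_g^2 \,\chi^2_{d_g}/d_g, \qquad
   \sigma_g^2 \sim s_0^2\, d_0 / \chi^2_{d_0}, $$

and shrinks each variance toward the prior:

$$ \tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g}, \qquad
   t_g = \frac{\hat\beta_g}{\sqrt{\tilde s_g^2 (1/n_1 + 1/n_2)}}, $$

with a two-sided p-value from a t distribution on $d_0 + d_g$ degrees of
freedom (standard normal when $d_0 = \infty$). The hyperparameters are
estimated by moment matching on the log variances: with
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$, $d_0$ solves
$\psi'(d_0/2) = \mathrm{var}(e) - \psi'(d_g/2)$ via a Newton inversion of
the trigamma function, and $s_0^2 = \exp\{\bar e + \psi(d_0/2) -
\log(d_0/2)\}$. When the empirical spread of $e_g$ does not exceed its
sampling component the prior is degenerate ($d_0 = \infty$,
$s_0^2 = e^{\bar e}$) — note this value carries the digamma offset, so it
is *not* the arithmetic mean of the $s_g^2$. Zero sample variances are
floored to the smallest positive variance before estimation, since the
log-variance moments are undefined at zero. The engine reproduces the
reference empirical-Bayes implementation to numerical precision on
simulated data (checked in the test suite against `limma`), but it is
computed here from the defining formulas so the artifact is
self-contained.

With only three samples per group — the design this pipeline targets —
the 3 vs 3 contrast has little power and the variance prior does a lot of
work; this is precisely the setting the moderated t was designed for.

### DEG calling and intersection

Calling uses *strict* inequalities (p < 0.05, |log2FC| > 1) and raw,
unadjusted p-values. The absence of multiple-testing correction mirrors
common practice in two-small-cohort screens and is a deliberate,
documented caveat, not an endorsement: at 0.05 with ~20k genes one
expects hundreds of false positives per dataset, which is exactly why the
pipeline intersects two datasets and a curated gene universe afterwards.
The cross-dataset intersection matches genes on normalized symbols and
**ignores direction concordance**: heterogeneous platforms (single-channel
microarray intensity vs RNA-seq counts, different normalizations,
different laboratories) frequently disagree on sign, and requiring
concordance would empty the published worked example, where 14 of 15
genes flip direction between the two series. Per-dataset directions are
retained in the membership table so the discordance is visible, not
hidden.

Counts are `log2(x+1)`-transformed by default before the linear model;
`log2cpm` (pseudocount 0.5) and `none` are provided because the original
analysis does not state which transform (if any) was applied to the count
series.

## Gene sets and symbol normalization

Symbols are compared after trimming and mouse-convention casing (first
letter upper, rest lower). Identifiers containing `miR-` or starting with
`lncRNA` are non-coding RNA names and are exempt from gene casing;
comparison is otherwise case-insensitive by construction. Merging gene
lists follows set-union semantics (commutative, associative, idempotent;
cardinality by inclusion–exclusion), with first-seen order preserved so
outputs are deterministic.

## Over-representation analysis

The enrichment stage is a transparent stand-in for web-service enrichment
tools: the upper hypergeometric tail

$$ p = \sum_{i=k}^{\min(K,n)} \binom{K}{i}\binom{N-K}{n-i}\Big/\binom{N}{n} $$

evaluated in log space with log-sum-exp, plus Benjamini–Hochberg step-up
adjustment. The background universe defaults to the union of all term
members; a measured-gene universe can be supplied and is usually the more
defensible choice when the annotation covers much more than the assay.
Terms need an overlap of at least 2 by default to be reported.

Two honest caveats. First, hypergeometric tail p-values are discrete and
conservative, so their null distribution is only approximately uniform;
the approximation improves with query and term size. Second,
`BH(BH(p)) = BH(p)` is **not** an identity — re-adjusting adjusted values
inflates them whenever the step-up minimum binds (the reference
`stats::p.adjust` behaves identically); the properties that do hold and
are tested are agreement with the reference implementation, monotonicity
along the sorted order, and that re-adjustment never decreases a value.

## Consensus voting and network assembly

Interaction predictions arrive as per-source tables of
(regulator, target) pairs in two class strata: miRNA→mRNA (four sources
by default) and lncRNA→miRNA (two sources). A pair survives iff reported
by at least `min_support` distinct sources — defaults 3-of-4 and 2-of-2,
matching the published voting rule. Voting trades sensitivity for
precision: false positives that are independent across sources rarely
co-occur three times, while a true interaction with per-source
sensitivity 0.9 still passes 3-of-4 with probability 0.948.

Assembly keeps miRNA–mRNA pairs whose mRNA is among the category's
differentially expressed PCD genes, then lncRNA–miRNA pairs whose miRNA
is retained on the mRNA side — the "shared miRNA" condition of the ceRNA
hypothesis. The stored network is undirected (regulatory direction is an
attribute, since the hub algorithms operate on undirected topology),
simple, and tripartite by construction: edges may only join lncRNA–miRNA
or miRNA–mRNA, and identifier namespaces are kept disjoint by class so a
host-gene symbol cannot merge a lncRNA node with a gene node.

One genuinely open design point: whether a miRNA that targets a retained
mRNA but has no surviving lncRNA sponge belongs in the network. The
published figures appear to keep such miRNAs, so the
`require_lncrna_partner` flag defaults to `FALSE` (retain); setting it
`TRUE` enforces the strict sponge invariant that every miRNA has both a
lncRNA and an mRNA neighbor. The two settings coincide on the synthetic
ground truth, where every miRNA is wired to both sides by construction.

## The seven centrality algorithms

All algorithms are implemented from their defining formulas on the
undirected simple graph, with $d(v,t)$ the BFS shortest-path length:

* **Degree** — $|N(v)|$.
* **Closeness** (harmonic) — $\sum_{t \ne v} 1/d(v,t)$, unreachable
  targets contributing 0; well defined on disconnected graphs.
* **EcCentricity** — $1 / \max_t d(v,t)$ over reachable $t$; 0 for
  isolated nodes.
* **Radiality** — within $v$'s component of size $n_c$ and diameter
  $\Delta$: $\sum_{t \ne v} (\Delta + 1 - d(v,t)) / (n_c - 1)$.
* **Betweenness** — $\sum_{s \ne v \ne t} \sigma_{st}(v)/\sigma_{st}$
  over unordered pairs, by dependency accumulation over BFS DAGs.
* **MCC** — $\sum_{C \ni v} (|C|-1)!$ over maximal cliques $C$
  (Bron–Kerbosch with pivoting); when $v$'s neighborhood spans no edge
  this degenerates to $\deg(v)$, because every maximal clique through
  $v$ is then a single edge.
* **EPC** — the expected number of nodes still connected to $v$ when
  each edge survives independently with probability $p_e$, estimated by
  Monte-Carlo.

EPC needs two parameters the unweighted setting does not supply:
retention $p_e = 0.5$ (edges carry no confidence weights, and 0.5
maximizes percolation variance, hence discrimination) and $N = 1000$
realizations with a seeded generator, giving a per-node standard error of
at most $(n-1)/(2\sqrt{1000}) \approx 0.016\,(n-1)$. The test suite
checks the estimator against the exact expectation obtained by
enumerating all $2^{|E|}$ edge subsets on small graphs; because that
check makes ~1200 node-level comparisons, it bounds the rate of 3-SE
exceedances (< 1%, chance rate 0.27%) and the worst deviation (< 4.5 SE)
rather than demanding simultaneous 3-SE coverage, which an unbiased
estimator would fail by chance alone.

Top-k lists (k = 10 by default) sort by score descending with ties broken
by node identifier; the default `include_ties` policy extends the list to
every node tied with the k-th score, since the reference hub tool's tie
behavior is unspecified and truncation would make hub membership depend
on identifier spelling. Hubs are nodes present in **all seven** top lists
(full consensus, not majority), and regulatory axes are hub-only
lncRNA–miRNA–mRNA paths whose two edges exist in the network, reported
lexicographically and deduplicated across category networks with their
provenance retained.

## The synthetic world

The generator states one fixed world rather than exposing dials to tune
tests: 1000 genes, 3 vs 3, 10% differentially expressed with planted
|log2FC| = 5, gene variances from the scaled inverse chi-square with
$d_0 = 4$, $s_0^2 = 0.05$ (so the estimator tests have a known truth in
the same family the model assumes), negative-binomial counts with
dispersion 0.1 and log-normal library factors (sdlog 0.2) on the count
platform. Prediction sources report each true interaction with
sensitivity 0.9 and add spurious pairs at 0.5 per true pair, sampled
without replacement from non-interacting combinations and never
duplicating a true pair. Each artifact (each dataset, each source, the
sponge structure) draws from its own RNG stream at a fixed offset from
the master seed, so adding a source never perturbs the expression draw
and fixed seeds give byte-identical outputs.

What the generator deliberately does **not** emulate: probe-level
microarray structure, normalization artifacts, batch and laboratory
effects, correlated genes, miRNA/lncRNA expression data (the real
analysis has none either — noncoding interactions come purely from
prediction databases), or realistic inter-database correlation of
prediction errors (sources err independently here; real databases share
training data and sequence features, so real consensus voting is less
effective than the simulation suggests). A green end-to-end test
therefore establishes that the machinery is correct and calibrated under
its stated assumptions — not that the biological conclusions of any
particular screen are right.

## Numerical and degenerate-input choices

* Trigamma inversion by Newton iteration on $\psi'(x)(1 - \psi'(x)/y)/
  \psi''(x)$, converging in a handful of steps from $x = 0.5 + 1/y$.
* Hypergeometric tails in log space; BH via reverse cumulative minimum.
* Zero variances floored to the minimum positive variance; all-zero
  variance data are rejected as degenerate.
* Empty networks are legal everywhere downstream (empty exports, empty
  top lists, empty axis sets), and `p_cut = 0` runs the whole pipeline to
  a clean, empty report.
* Ties: everywhere a ranking or set is emitted, order is made
  deterministic (score then identifier; lexicographic axes; sorted node
  tables), so fixed-seed reruns are byte-identical.

## Known limitations

* Raw p-values with strict cutoffs reproduce the published screening
  rule but have no FDR control; treat membership tables as hypotheses.
* The enrichment stage cannot reproduce web-service term lists, which
  depend on curated database snapshots; it is a stand-in with the same
  statistical skeleton.
* Centralities are exact but exponential-time in the clique enumeration
  worst case (MCC); ceRNA networks of the size handled here (tens of
  nodes) are far below any problematic regime.
* The published headline network sizes (e.g. 69 nodes / 152 edges)
  depend on specific external database versions and are not reproducible
  offline; the package validates against the published worked examples
  (membership table, axis lists, count arithmetic) and against synthetic
  ground truth instead.
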