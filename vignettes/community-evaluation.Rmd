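---
title: "Evaluating network communities against their local walk background"
author: "commwalkr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating network communities against their local walk background}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commwalkr)
```

## The problem

Community detection on a protein interaction network (PIN) proposes sets of
densely interconnected proteins; an evaluation step then decides which of
those communities deserve to be called functional modules. The standard
instrument is *functional homogeneity* (FH): the average pairwise Gene
Ontology semantic similarity of the community's members, compared against a
network-wide background such as the median similarity of interacting
protein pairs.

Functional annotation, however, is not spread evenly over a network. Heavily
studied proteins accumulate many specific annotations and their
neighbourhoods form regions where almost any group of proteins looks
functionally coherent; poorly studied regions look incoherent regardless of
the underlying biology. A single global FH threshold therefore accepts
arbitrary groupings in well-annotated regions and discards genuinely
coherent modules in sparsely annotated ones.

This package evaluates each community *in situ*. Short random walks started
from the community's own nodes generate alternative "proxy" communities from
the same local environment; the community's FH is ranked within the FH
distribution of those proxies. The resulting tail probability is insensitive
to the absolute annotation density of the region, because the background is
drawn from the same region.

## The model

**Similarity.** For two annotated proteins with ancestor-closed GO term sets
$C_p$ and $C_q$ (direct annotations plus every ancestor up to the namespace
root), the package implements three set-based measures:

* simUI: $|C_p \cap C_q| / |C_p \cup C_q|$,
* simGIC: $\sum_{t \in C_p \cap C_q} \mathrm{ic}(t) \big/
  \sum_{t \in C_p \cup C_q} \mathrm{ic}(t)$,
* the Pandey measure: $\sum_{t \in C_p \cap C_q} \mathrm{ic}(t)$,

where $\mathrm{ic}(t) = -\log\!\big(n_t / n\big)$ is the information content
of term $t$ over the $n$ annotated proteins of the loaded corpus, of which
$n_t$ carry $t$ in their closure. The Pandey measure is implemented as the
unnormalised information-content sum over the intersection of the closed
sets: all three measures are declared over the *intersection* of term sets,
and only an unbounded measure is compatible with homogeneity values and
thresholds well above 1, which is where this measure family is typically
operated. The formula is isolated behind the measure dispatcher, so a
variant is a one-function change. simGIC is defined as 0 when the union
carries no information (both proteins annotated only to the root) — the
limiting case of "sharing only the root".

**Functional homogeneity.** $FH$ of a community is the arithmetic mean of
pairwise similarity over all unordered pairs of *annotated* members.
Unannotated members are ignored, never scored as 0; with fewer than two
annotated members FH is undefined and the community is reported as such. A
root-only protein counts as annotated (it scores 0 against others); for the
research-focus diagnostics, by contrast, root-only annotation does not count
as "annotated" — the two notions are deliberately distinct.

**The walk background and the T-value.** From each member of a community of
size $N_C$, simple random walks (uniform over neighbours) run until they
have visited $N_C$ distinct nodes; revisits do not terminate a walk. Each
distinct-visit set is scored by the same FH. With $m$ walks scoring
*strictly* above the community (ties do not count) out of $M$ retained
walks,

$$T = \frac{m + 1}{M + 1} \in \Big[\tfrac{1}{M+1},\, 1\Big].$$

Walks whose proxy module has fewer than two annotated nodes have undefined
FH and are excluded from both $m$ and $M$ (counted and reported). Excluding
rather than counting them as "lower" avoids biasing $T$ downwards exactly
where annotation is sparsest.

**Walk budget.** $T$ is a binomial tail estimate, so its standard error at a
true value $t$ is $\sqrt{t(1-t)/M}$. `calibrateWalkCount()` returns the
smallest $M$ meeting a target standard error at an assumed worst case; the
defaults (target 0.005 at $t = 0.5$) give $M = 10\,000$. Walks are allocated
as $\lceil M / N_C \rceil$ per member, keeping the total sampling effort
approximately constant across community sizes. The acceptance suite verifies
empirically that 100 independently seeded evaluations of one fixed community
have a T-value standard deviation within 0.005.

**Acceptance classes.** `evaluateCommunities()` computes one network-wide FH
threshold (default: the median pairwise similarity over edges with both
endpoints annotated) and classifies each community by two booleans:
FH-accepted iff $FH$ strictly exceeds the threshold, walk-accepted iff
$T \le 0.5$. The boundary conventions make the worked tail value $0.5$
(one of three walks above) accepted, and both thresholds are "half the
reference distribution" in spirit, which is what makes the two evaluations
comparable. The four classes — `both`, `cw_only`, `fh_only`, `neither` —
partition the input. Candidate communities are conventionally restricted to
6–35 members (`filterBySize()`), inclusive at both ends.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `measure` | `"pandey"` | pairwise similarity; `simUI`/`simGIC` are bounded alternatives |
| `logBase` | $e$ | information-content units (nats; base 2 gives bits) |
| `totalWalks` | `calibrateWalkCount()` = 10000 | walk budget per community |
| `tThreshold` | 0.5 | walk acceptance bound, $T \le$ threshold |
| `fhStatistic` | `"median"` | network background statistic over annotated edges |
| `minSize`, `maxSize` | 6, 35 | community size filter, inclusive |
| `restartProb` | 0 | optional restart probability; positive values keep walks local for large communities |
| `excludedEvidence` | IPI, RCA, ND | GAF evidence codes dropped (interaction-derived and no-data codes) |
| `walkSize` (co-expression) | 6 | distinct nodes per background walk |
| `quantile` (overlap) | 0.25 | community-distribution quantile defining the overlap threshold |

Evidence filtering drops IPI and RCA because those annotations are inferred
from protein interactions or omics data — scoring interaction-network
communities with them would be circular — ND because it asserts the absence
of evidence, and `NOT`-qualified rows because they are negative assertions.

Two conventions are configurable because the field fixes neither: the IC
corpus is the loaded annotation set itself (self-contained and reproducible,
rather than an external global corpus), and "walk length six" in the
co-expression background is interpreted as six *distinct nodes*, matching
the termination rule of the evaluation walks, with the size exposed as a
parameter.

## Bias diagnostics

`nodeProfiles()` runs `walksPerNode` proxy modules of `moduleSize` (default
3) distinct nodes from every node and maps two module measurements back to
the node by averaging: mean FH, and *research focus* — the fraction of
module nodes directly annotated beyond the namespace root. Both come from
the same walk set. `biasCorrelation()` then reports the Spearman rank
correlation between the two profiles (rank-based, because the Pandey scale
is unbounded; Pearson by flag). A strong positive correlation is the
signature of annotation bias: regions score as functionally homogeneous
because they are well studied.

`functionalEnrichment()` provides the classical alternative homogeneity
measure: per term, the upper-tail hypergeometric p-value of the term's
member count against the universe, Benjamini–Hochberg adjusted (BH is the
standard choice where no correction is mandated). `enrichmentTValue()`
applies the walk background to a single term's frequency instead —
the same corrective idea transplanted onto enrichment.

## Co-expression validation

`communityCoexpression()` scores a community by the mean absolute Pearson
correlation over member pairs with both profiles present and of nonzero
variance (undefined pairs are excluded, not zero-scored).
`backgroundCoexpression()` builds the reference distribution from 1000
walks of six distinct nodes per node, and `overlapScore()` compares the two
distributions: the percentage of background scores strictly above the 25%
quantile of the community distribution. Under a shared null the statistic
sits at 75% by construction; values near 0% indicate community-specific
co-expression. Quantiles use linear interpolation between order statistics
(type 7), a stated convention exposed as a parameter.

## What the synthetic fixtures emulate — and what they do not

`fixtureSpec()` fixes the package's standing study conditions:

* a 300-node planted-partition network, 20 communities of 8–12 nodes,
  within-community edge probability 0.6 over a background of 0.01;
* a two-region geometry: half the communities (and half the unassigned
  background nodes) form a "studied" region, cross-region edges are 10×
  rarer than within-region ones. Annotation bias in real PINs is spatially
  clustered — without regional structure, walk backgrounds would mix
  regions and no evaluation could be local;
* biased annotation on a depth-4, branching-3 term tree: studied communities
  share three community-specific deep terms (each member carries each with
  probability 0.8) plus Poisson(2) random deep terms; unstudied members
  carry two community-specific mid-depth terms with probability 0.35 and are
  otherwise root-only. Every node is at least root-annotated so FH is
  defined everywhere;
* one-factor expression per module with loading
  $b = \sqrt{\rho/(1-\rho)}$ against unit noise, hitting a target
  within-module correlation of $\rho = 0.6$ in expectation over 50 samples;
  profiles are shifted by +8 and floored at 0 to keep expression levels
  nonnegative (Pearson correlation is shift-invariant; the floor sits ~5
  standard deviations below the mean).

Sizes were chosen so the full suite, including a 100-run stability check at
the default 10 000-walk budget, completes in well under a minute: the
planted effects are strong enough to be detected at these scales with the
stated test sizes (rank tests and correlations at $\alpha = 0.01$).

What passing on these fixtures does **not** show: real PINs have heavy-tailed
degree distributions (the generator is not degree-corrected), annotation
depth in real GO varies continuously rather than in two planted tiers, and
real expression has batch structure and library-size effects. The fixtures
validate the *statistical machinery* — that the walk background is local,
that the tail value ranks correctly, that bias is detected and corrected in
the planted direction — not performance on any particular organism's data.

## Numerical and degenerate-case choices

* Ties between a walk's FH and the community's FH do **not** increment $m$
  ("strictly higher"); on fixtures where every walk reproduces the
  community exactly, $T = 1/(M+1)$.
* Equal-size connected components tie-break by lexicographically smallest
  member ID, making `largestConnectedComponent()` deterministic.
* Walks have a diagnostic step budget of $10^4 \times N_C$; exhausting it
  marks the walk failed (excluded and counted) rather than looping forever
  on pathological graphs.
* The walk engine caches pairwise similarities per evaluation call, keyed on
  the unordered node pair — repeated queries are guaranteed identical, and
  consecutive walks revisit the same neighbourhood so the cache carries most
  of the load.
* All randomness (including inside the C++ walk engine) flows through R's
  RNG: `set.seed()` makes every evaluation, profile, and fixture
  reproducible, and generator functions derive fixed offsets from the spec
  seed so each artifact is independent of generation order.
* `sample()`-style size draws guard the degenerate single-value range, and
  community size draws that overshoot the node budget shrink the largest
  communities back to the lower bound rather than failing stochastically.

## Worked example

```{r example, eval = FALSE}
spec <- fixtureSpec(seed = 7)
pin  <- generatePin(spec)
onto <- generateOntology(spec@ontologyDepth, spec@ontologyBranching)
ann  <- generateAnnotations(pin, onto, spec)$annotations

ev <- evaluateCommunities(pin$graph, pin$communities, ann,
                          measure = "pandey", seed = 5)
table(ev$class)
```

On this fixture the studied communities land in `both` (coherent and
annotation-rich), most unstudied communities in `cw_only` (coherent but
annotation-poor — exactly the modules a global FH threshold loses), and
none in `fh_only`.

## Known limitations

* The Pandey measure is implemented from its set-theoretic description (IC
  sum over the closed-set intersection); no independent reference
  implementation was available for cross-checking beyond the package's own
  brute-force oracles.
* The per-member walk allocation $\lceil M / N_C \rceil$ realises "similar
  sampling effort per community"; other allocations (e.g. proportional to
  degree) are conceivable and would change $T$ slightly for very
  heterogeneous communities.
* Multi-resolution community inputs may contain duplicate communities;
  the pipeline evaluates what it is given and leaves deduplication to the
  caller.
* With `restartProb > 0` the walk distribution concentrates near the start
  node; the default keeps it at 0 because the evaluation targets small
  communities (6–35) whose walks are already local.
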