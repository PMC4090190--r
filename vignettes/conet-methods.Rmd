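---
title: "Methods: co-occurrence networks, chi-square reduction, and macroscopic topology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence networks, chi-square reduction, and macroscopic topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conet)
```

conet builds a concept co-occurrence network from a term-annotated document
collection (the motivating case is MEDLINE citations annotated with MeSH
descriptors), prunes it with a chi-square test of independence, and
characterises the macroscopic topology of what remains. This vignette is the
package's account of the statistical machinery: the models, the conventions
that were genuinely open choices, and what the bundled synthetic corpus can
and cannot tell you about real data.

## From documents to a network

The counting unit is the **document**. For a vocabulary term $t$, $df(t)$ is
the number of documents containing $t$; for an unordered pair $(u, v)$,
$w_{uv}$ is the number of documents containing both. Each document
contributes at most once per pair, so a term repeated within a document has
set semantics. The raw network connects every pair with $w_{uv} \ge 1$; its
edge weights are the counts $w_{uv}$.

Two reductions precede any analysis:

* **Check-tag removal.** Near-ubiquitous housekeeping descriptors (Humans,
  Animals, age groups, common model organisms) co-occur with everything and
  carry no discriminative content. The default list ships as an editable
  text file (`inst/extdata/check_tags.txt`); it is configuration, not code,
  because no canonical enumeration exists and curation practice drifts.
* **Chi-square filtering.** For each co-occurring pair a $2 \times 2$
  contingency table is formed over the $N$ documents: $O_{11}$ documents
  with both terms, $O_{12}$ and $O_{21}$ with exactly one, $O_{22}$ with
  neither; expected counts are $E_{ij} = R_i C_j / N$. The statistic is
  $$\chi^2 = \sum_{ij} \frac{(|O_{ij} - E_{ij}| - y)^2}{E_{ij}},$$
  with Yates continuity correction $y = 1/2$ applied to all four cells when
  any $E_{ij} < 5$ (and $|O - E| - y$ floored at zero). An edge survives if
  $\chi^2$ exceeds the critical value (default $3.84$, the $0.95$ quantile
  at 1 df) *and* the pair is over-represented ($O_{11} > E_{11}$). The
  one-sided default exists because the scientific question is whether terms
  co-occur *more* often than chance; a two-sided mode is a flag
  (`positive_only = FALSE`). Tables with a zero margin (a term in every
  document, or in none) are declared degenerate with statistic 0 rather
  than errors, so extreme terms cannot crash a run. No multiple-testing
  correction is applied: the procedure is a dimensionality-reduction
  heuristic, not simultaneous inference, and the downstream topology is
  what is interpreted.

Counting pairs at document level (rather than over co-occurrence tokens) is
a deliberate resolution of an ambiguity: the contingency-table construction
only adds up to $N$ documents if cells count documents, and it keeps
$w_{uv} \le \min(df(u), df(v))$ as an invariant.

## Topology metrics and their conventions

All metrics ignore edge weights and run on the giant component (ties on
component size are broken toward the component containing the smallest node
identifier, so runs are deterministic).

* **Clustering.** $C_i = T_i / \binom{k_i}{2}$; nodes with $k_i < 2$
  contribute $C_i = 0$ and are *included* in the average $C$. Libraries
  disagree here (some drop such nodes); the inclusive convention is the
  default and the exclusive one a flag, and tests pin the choice.
* **Path length, diameter, effective diameter.** $L$ is the mean shortest
  path over connected pairs. $D_{90}$ is reported both as the integer
  $\min\{d : h(d) \ge 0.9\}$ (with $h$ the cumulative fraction of connected
  pairs within distance $d$) and as the linear interpolation
  $(d-1) + (0.9 - h(d-1))/(h(d) - h(d-1))$. Interpolation is the convention
  of the standard effective-diameter tooling, which is why the measure can
  legitimately be non-integer (and on a complete graph evaluates to 0.9,
  while the integer form is 1).
* **Small-world index.** $\sigma = (C/C_r)/(L/L_r)$ against Erdős–Rényi
  $G(n, m)$ baselines with the observed node and edge counts; $\sigma > 1$
  is read as small-world. Note $\sigma$ is sensitive to rounding of its
  four inputs: recomputing it from printed two-decimal values will not in
  general reproduce a $\sigma$ computed from unrounded ones, so tests pin
  the formula on explicit inputs rather than any particular published
  composite value.
* **Assortativity.** Pearson correlation of endpoint degrees with both
  orientations of every edge. Regular graphs have zero endpoint-degree
  variance; the coefficient is then undefined and returned as `NA` with a
  warning, never a number. A permutation test (re-pairing the pooled
  endpoint-degree multiset) is provided for significance; it is one
  reasonable construction among several and is labelled as such. An earlier
  draft permuted only one endpoint column, which is degenerate on graphs
  whose edge list is sorted (a star's permuted pairings are all identical);
  the pooled re-pairing avoids that trap.
* **Hierarchy.** The $\bar C(k)$ curve (mean clustering per degree) with a
  least-squares log–log decay fit over points with $\bar C(k) > 0$; at
  least 3 usable points are required or the fit is refused while the curve
  is still returned.

### Sampling on large graphs

Exact all-pairs computation is used up to 2000 nodes. Above that, path
lengths are averaged over BFS trees from at least 200 uniformly sampled
sources, and clustering over at least 2000 sampled nodes whose coefficients
are themselves estimated from up to 1000 sampled neighbour pairs checked
against a hashed edge set — the per-node cost is then independent of
degree, which matters when mean degree is in the thousands. Both estimators
are unbiased for their exact counterparts, and the test suite checks that
with all sources (or exhaustive pairs) they reduce to the exact values.

## Degree-distribution fitting

The tail model is the discrete power law
$P(k) = k^{-\alpha} / \zeta(\alpha, k_{min})$, normalised by the Hurwitz
zeta function (implemented by direct summation with an Euler–Maclaurin tail
correction; accurate to below $10^{-12}$ in the relevant range).

* **Exponent.** The package estimates $\alpha$ by maximising the discrete
  zeta likelihood. The familiar closed-form approximation
  $\hat\alpha = 1 + n[\sum_i \ln(k_i/(k_{min}-\tfrac12))]^{-1}$ is also
  available; its bias is negligible for large $k_{min}$ but reaches
  several hundredths below $k_{min} \approx 10$–20, enough to distort the
  $k_{min}$ scan (the inflated KS distances at small candidates push the
  selected bound upward). The default is therefore a hybrid: exact below
  $k_{min} = 20$, approximation above.
* **Lower bound.** Every distinct sample value is a $k_{min}$ candidate
  provided it leaves a tail of at least `min_tail` observations (default
  10) with at least two distinct values; the candidate minimising the
  Kolmogorov–Smirnov distance between the empirical and fitted tail CDFs
  wins, ties going to the smallest candidate. Both CDFs are evaluated at
  the observed unique values with the inclusive ($\le k$) convention —
  KS values shift under other conventions, so this one is pinned by tests.
* **Goodness of fit.** A semi-parametric bootstrap (default 2500
  replicates): each replicate draws, per observation, from the fitted
  power law with probability $n_{tail}/n$ and otherwise resamples the
  empirical body below $k_{min}$; each replicate is re-fitted with its own
  $k_{min}$ scan and the p-value is the fraction of replicate KS distances
  at least the observed one. $p > 0.1$ is read as "power law plausible".
* **Alternatives.** Discretised log-normal and exponential (probability
  mass on $[k - \tfrac12, k + \tfrac12)$) and Poisson, truncated to
  $k \ge k_{min}$, fitted by maximum likelihood and assessed by the same
  KS-plus-bootstrap scheme with $k_{min}$ held fixed across replicates.

A caution that the test suite makes concrete: the bootstrap is well
calibrated (samples drawn from the fitted model are accepted at close to
the nominal 90% rate) but has limited power against alternatives whose
tails are *locally* power-law-like. Because the $k_{min}$ scan is free to
move into the far tail — for the observed sample and for every replicate —
an exponential-family sample at a few thousand observations usually yields
some steep, short, internally consistent "power-law" tail, and the test
cannot reject it. The unit tests therefore assert the discriminations the
method genuinely supports (KS separation at a common bulk-covering lower
bound; stochastically smaller p-values for exponential-tail data), rather
than a high rejection rate the procedure does not possess. This behaviour
is worth keeping in mind when interpreting any "plausible" verdict whose
fitted tail covers a small fraction of nodes — `is_scale_free()` attaches
exactly that caveat.

## Attacks

`attack()` is single-shot: centralities (degree, or betweenness — exact up
to 2000 nodes, source-sampled Brandes above) are computed once on the
intact graph, the top $\lceil 0.1\,n \rceil$ nodes (ties broken by
ascending node identifier) or a uniform random set are removed in one
event, and the surviving giant component is reported as a fraction of the
*initial* node count — removed nodes therefore count against the survivor,
which matches the "fraction of the initial set of nodes" reading of attack
robustness. A sequential percolation curve is deliberately out of scope.

## The synthetic corpus generator

`gen_corpus()` emulates the features of citation–descriptor data that the
pipeline's statistics actually exercise, with known ground truth:

* documents carry about 12 distinct topical terms (the MEDLINE-like
  default), drawn from one "home" topic block of a block-structured
  vocabulary;
* within-block term popularity is Zipf with exponent 1 — the conventional
  skew for vocabularies; nothing downstream depends on the exact law, only
  on some terms being much more frequent than others;
* a small set of hub terms attaches to documents independently of topic
  with probability `p_hub` (default 0.9), reproducing exactly the
  statistical profile that makes check tags uninformative;
* each drawn term is replaced with probability `p_noise` (default 0.05) by
  a uniform foreign-block term, giving cross-block pairs a chance level of
  co-occurrence. Noise replacements are drawn without replacement so the
  per-document term count is exact.

Same-block pairs are positively associated by construction and cross-block
pairs are independent-to-negatively associated, so the chi-square filter
has planted truth to discriminate: the test suite checks that at the 3.84
cutoff it retains at least 90% of planted pairs that co-occur at least 5
times and at most 10% of cross-block pairs. A single integer seed drives
per-document sub-streams, so corpora are reproducible and invariant to
generation order.

What the generator does **not** emulate: the MeSH tree structure,
qualifiers, temporal growth of the vocabulary, or the empirical shape of
MEDLINE's degree distribution. A green pipeline on synthetic corpora
demonstrates the statistical machinery end to end — counting, filtering
with controlled error behaviour, metric correctness — not that any
particular real corpus is small-world or scale-free.

Degree-sequence fixtures come from `gen_powerlaw_degrees()` (inverse-CDF
sampling against the zeta tail; the deep tail is resolved by bisection on
the survival function, so no truncation bias) and
`gen_configuration_graph()`, an *erased* configuration model: stubs are
matched uniformly and self-loops/multi-edges deleted. Erasure guarantees
termination on heavy-tailed sequences at the price of slightly reduced
high degrees, acceptable for fixtures; realised degrees never exceed the
requested ones.

## Problem sizes and numerical choices

The package's own test and reproduction runs use: exact topology up to
2000 nodes and sampling above (200–500 BFS sources, 2000 clustering nodes,
1000 neighbour pairs per node); 10 Erdős–Rényi baseline replicates by
default (the reproduction scripts use 1 at the largest sizes, where the
concentration of $G(n,m)$ statistics makes replicate variance negligible
at two-decimal resolution); bootstrap sizes of 100–200 in tests against
the 2500 default; synthetic corpora of 400–5000 documents. Diameters are
exact up to 5000 nodes and reported as flagged double-sweep lower bounds
above. All randomness flows from explicit seeds through per-purpose
sub-streams, and reports embedding the same configuration are
byte-identical across runs.

## Known limitations

* Document-level counting is the only implemented unit; a pair-token mode
  (counting co-occurrence instances rather than documents) is deliberately
  absent.
* The chi-square filter tests marginal pairwise independence only; it
  cannot distinguish direct association from association induced by a
  shared neighbour term.
* The GOF bootstrap's power limitation described above is intrinsic to
  the re-scanned $k_{min}$ design, not a tuning matter.
* Betweenness estimation quality on very large graphs depends on the
  source sample; the default (200 sources) targets ranking stability for
  attack selection, not per-node precision.
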