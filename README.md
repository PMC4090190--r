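# conet

Concept co-occurrence networks from term-annotated document corpora:
chi-square network reduction and macroscopic topology analysis.

## The problem

Large literature databases annotate each document with controlled-vocabulary
terms (the motivating case: MEDLINE citations carrying ~12 MeSH descriptors
each). Linking every pair of terms that share a document yields a network so
dense that raw co-occurrence is nearly meaningless — ubiquitous "check tag"
terms connect to everything, and most edges are chance co-occurrence. conet
implements the full analysis pipeline for such data:

1. **Ingest** MEDLINE-style citation XML or a plain `doc_id / term / major`
   TSV into a tidy corpus tibble; remove check tags; optionally restrict to
   major-topic terms.
2. **Reduce**: for each co-occurring pair (u, v) over N documents, form the
   2×2 contingency table (O₁₁ documents with both terms, margins Rᵢ, Cⱼ,
   expected Eᵢⱼ = RᵢCⱼ/N) and keep the edge only if

   χ² = Σᵢⱼ (|Oᵢⱼ − Eᵢⱼ| − y)² / Eᵢⱼ  >  3.84   (p ≤ 0.05, 1 df)

   with Yates correction y = ½ when any Eᵢⱼ < 5, and O₁₁ > E₁₁ (the pair
   co-occurs *more* often than chance).
3. **Characterise** the giant component: density ρ, mean degree c, average
   clustering C, average path length L, diameter D and interpolated
   effective diameter D₉₀; Erdős–Rényi G(n, m) baselines (L_r, C_r) and the
   small-world index σ = (C/C_r)/(L/L_r); degree assortativity; the C̄(k)
   hierarchy curve; discrete power-law tail fitting P(k) ∝ k^(−α), k ≥ kmin
   (zeta-likelihood MLE, kmin by KS minimisation, semi-parametric bootstrap
   goodness of fit with the p > 0.1 plausibility rule) plus discretised
   log-normal / Poisson / exponential alternatives; and single-shot degree,
   betweenness and random attacks removing 10% of nodes.

A synthetic corpus generator with planted block structure (`gen_corpus()`),
power-law degree sampling (`gen_powerlaw_degrees()`), G(n, m) graphs and an
erased configuration model make every stage testable with no external data.

## Worked example

```r
library(conet)

sim <- gen_corpus(corpus_config(n_docs = 2000, seed = 11))
report <- run_pipeline(conet_config(corpus = sim$corpus,
                                    replicates = 3, n_boot = 0, seed = 11))
print(report)
```

```
<conet_report>

Reduction steps:
               stage n_docs n_terms n_edges
              ingest   2000     103      NA
  check_tags_removed   2000     103      NA
        cooccurrence   2000     103    5068
 chi_square_filtered     NA     103     962
     giant_component     NA      42     386

Topology:
  n   m   density mean_degree clustering path_length diameter diameter_exact
 42 386 0.4483159    18.38095  0.9489378    2.408827        4           TRUE
      d90 d90_int
 3.734259       4

Random baseline:
      l_r       c_r replicates     seed
 1.551684 0.4424961          3 20505282

Small-world index: sigma = 1.381 (small-world)
Power-law tail: alpha = 25.000, kmin = 19, KS = 0.1597, p = NA

Attacks:
    strategy fraction_removed n_initial n_removed giant_fraction     seed
      degree              0.1        42         5      0.4285714       NA
 betweenness              0.1        42         5      0.4285714 25498857
      random              0.1        42         5      0.8809524 27163382
```

Reading the numbers: the 103-term vocabulary (5 topic blocks of 20 terms
plus 3 hub terms) produces 5,068 raw co-occurrence pairs; the chi-square
filter keeps 962 — essentially the within-block pairs, since cross-block
co-occurrence is chance-level and the near-ubiquitous hubs are statistically
uninformative. The giant component is a tightly clustered block cluster
(C = 0.95 against C_r = 0.44 at random-graph-like path lengths, hence
σ > 1), targeted attacks shatter it far more effectively than random
removal (0.43 vs 0.88 surviving), and a power-law tail is a poor model for
its degrees — the fit degenerates to a very steep slope on the top of a
bounded, dense degree distribution, exactly what `is_scale_free()` warns
about.

Individual stages compose with the pipe, e.g.:

```r
edges <- sim$corpus |> count_pairs() |> filter_network(critical_value = 3.84)
g <- giant_component(edges)
topology_summary(g)
fit <- degree_sequence(g)$degree |> fit_power_law_tail(n_boot = 200, seed = 1)
glance(fit)      # broom-style one-row summary
autoplot(fit)    # CCDF with the fitted tail overlaid
```

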