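---
title: "Methods: the Harmfulness Score pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Harmfulness Score pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(harmscore)
```

This vignette documents the model, the numerical choices, and the validation
design behind `harmscore`. It is a methods description, not a tutorial; see
the README for a worked example.

## 1. The model

For each polymer $p$ observed in a tagged abstract corpus of $N$ documents,
with $n_p$ documents mentioning $p$:

$$
H_p \;=\; B_p \,\bigl(0.7 + 0.3\,F_p\bigr)\,\sigma(n_p),
\qquad
B_p \;=\; 0.4\,S_p + 0.4\,I_p + 0.2\,C_p,
$$

with

- $F_p = \mathrm{pct}_p / \max_q \mathrm{pct}_q$, where
  $\mathrm{pct}_p = 100\,n_p/N$ (the most-studied polymer has $F = 1$);
- $\sigma(n) = 1 - 1/(1 + 0.05\,n)$, a saturating replication penalty
  ($\sigma(0)=0$, $\sigma(20)=0.5$, $\sigma \to 1$), so
  $H_p \le B_p$ always;
- $S_p, I_p, C_p \in [0,1]$, the sentiment, impact and centrality components
  defined below.

The frequency bracket $(0.7 + 0.3F)$ bounds the frequency effect: rarity can
reduce a score to at most 70% of base, while the confidence penalty $\sigma$
can reduce it arbitrarily. This separates "rarely studied" (mild, bounded
penalty) from "barely replicated" (strong penalty).

### Sentiment component $S$

Each abstract receives a compound valence in $(-1, 1)$:

1. Sum the raw valences of matched words from the shipped valence lexicon
   (83 entries, e.g. `harmful` $=-2.1$, `hazardous` $=-2.6$, `promising`
   $=+1.8$).
2. A negator within the 3 preceding tokens multiplies a word's valence by
   $-0.74$; an intensifier shifts its magnitude by $\pm 0.293$
   (`very harmful` is more negative than `harmful`; `slightly harmful` less).
3. Normalize the sum $v$ to $v/\sqrt{v^2 + 15}$.
4. Classify with inclusive thresholds: compound $\ge 0.25$ positive,
   $\le -0.25$ negative, otherwise neutral.

$S_p$ is the harm-oriented min–max across polymers of
$h_p = -\operatorname{mean}(\text{compound over } p\text{'s documents})$:
the polymer with the most negative mean discourse gets $S = 1$, the most
positive $S = 0$. If all means coincide, every polymer gets $0.5$. Because
$S$ is a min–max, it is invariant under affine rescaling of all compounds
(tested).

### Impact component $I$

$I_p$ is the fraction of $p$'s documents that co-mention at least one term of
the controlled impact vocabulary (toxicity, cytotoxicity, genotoxicity,
bioaccumulation, oxidative stress, degradation, adsorption, …),
max-normalized across polymers. It is a per-document *density*, not a raw
count, so it is not merely a second copy of frequency.

### Centrality component $C$

A co-occurrence network is built over polymer, engineered-nanoparticle and
impact terms: nodes are terms, and an edge's `link_strength` is the number of
documents mentioning both endpoints (computed as a sparse cross-product of the
document–term incidence matrix; validated against an explicit document-pair
counting oracle). `centralities()` reports degree (normalized by $n-1$),
betweenness (igraph, unweighted, normalized), and eigenvector centrality from
an authored power iteration (tolerance $10^{-8}$, max 1000 iterations,
max-normalized). When the iteration cannot converge — e.g. a disconnected
graph with no dominant eigenvector — the function falls back to normalized
degree and flags `method = "degree_fallback"` rather than failing. $C_p$ is
the chosen centrality max-normalized over the polymer subset.

## 2. Tagging design

Controlled vocabularies cover 18 polymers (with full-name synonyms, e.g.
*polystyrene* → PS), 12 nanoparticles, 14 impact descriptors, morphologies,
techniques, and countries. Matching is:

- **longest-surface-first with span masking**: matched spans are overwritten
  with a sentinel before shorter surfaces are tried, so *polyethylene
  terephthalate* yields PET and never a spurious PE;
- **word-boundary delimited** via lookarounds on letters/digits, with an
  optional plural `s`;
- **case-sensitive for short uppercase abbreviations** (≤ 4 characters):
  `PSD` or lowercase `ps` never count as polystyrene, while long surfaces
  match case-insensitively;
- hyphenated `micro-plastic` / `nano-plastic` spellings are collapsed before
  matching.

The valence lexicon is deliberately **disjoint from the impact vocabulary**.
If *toxicity* carried negative valence, the impact and sentiment components
would be partially the same measurement, and the generator's sentiment
mixture (Section 4) could not be controlled independently of impact density.

## 3. Numerical choices

- **Size distributions.** `fit_mixture()` fits a $K$-component
  amplitude-parameterized Gaussian (or lognormal) envelope on $[0,5]$ mm by
  Levenberg–Marquardt (`minpack.lm::nls.lm`, bounds $\mu \in [0,5]$,
  scale $\ge 10^{-4}$, amplitude $\ge 0$, `ftol = ptol = 1e-14`). The
  objective is multimodal, so the fit is multi-start: one start from the
  data's own local maxima plus 20 random starts; the lowest-WSSR converged
  solution wins. Modal fractions are each component's `stats::integrate`
  quadrature over the domain divided by total mass (they sum to 1);
  goodness-of-fit reports WSSR, $R^2$, and residual degrees of freedom
  $n - 3K$.
- **Topics.** TF-IDF uses the smoothed inverse document frequency
  $\ln\!\bigl((1+N)/(1+\mathrm{df})\bigr)+1$ with L2 row normalization
  (a ubiquitous term has idf exactly 1), exact truncated SVD, and seeded
  `stats::kmeans` with 10 restarts. Quality metrics: mean silhouette
  (`cluster::silhouette`) and a hand-written Davies–Bouldin index (tested for
  label-permutation invariance).
- **Bootstrap.** Tagging and sentiment are per-document deterministic, so
  per-document feature rows are computed once and only the aggregation stages
  are re-run on each of the 200 resamples — algebraically identical to
  re-running the full pipeline, at a fraction of the cost. Intervals are
  percentile CIs; identical seeds give byte-identical results, and interval
  widths shrink with corpus size (tested at 500 vs 4000 documents).
- **Skewness** of the score distribution uses the adjusted Fisher–Pearson
  estimator $G_1$ (cross-checked against `e1071::skewness(type = 2)`).

## 4. The synthetic-corpus generator as ground truth

`synthetic_corpus_spec()` / `generate_corpus()` produce corpora whose
statistical properties are exact by construction, which is what the test
suite validates against:

- **Entity frequencies** are independent Bernoulli draws per document;
  empirical rates converge to the configured probabilities at the binomial
  rate (tested over 100 seeds).
- **`cooccur_boost`** correlates two entities' mention indicators through a
  Gaussian copula ($\rho = 1 - 1/\text{boost}$), which inflates joint
  mentions while preserving the exact marginal probabilities — a naive
  "add joint mentions" scheme would silently break the frequency guarantee.
- **Sentiment mixtures** (global or per-entity) draw each document's class
  and emit template sentences built only from valence-lexicon words of that
  class; because the valence and impact vocabularies are disjoint, the
  classifier recovers the drawn classes deterministically and the recovered
  fractions match the mixture to binomial error.
- A mixture vector summing to 1 within $0.01$ (such as a 3-decimal printed
  vector summing to 1.001) is accepted and renormalized; larger deviations
  are validation errors.

## 5. Problem sizes and costs

Intended scales: corpora up to ~$10^5$ abstracts (tagging is vectorized
regex counting; the network uses sparse matrices), networks of tens to
hundreds of terms, size-distribution fits on $10^2$–$10^4$ grid points,
bootstraps of 200 replicates on $10^3$–$10^4$ documents (seconds). The
published component table for the 18 reference polymers ships in
`inst/extdata/` and is exercised by the regression tests.

## 6. Known limitations and reference-table caveats

- Four reference rows — **PTFE, EVA, PBT, PEEK** — have printed base scores
  that are *not* reproducible from their printed $S, I, C$ components under
  the published weights (deviations 0.03–0.13, far beyond rounding). The
  package reproduces final scores from the printed base column, treats those
  four rows as quarantined in base-score regression tests, and asserts that
  they genuinely deviate (so a silent fixture edit would be caught).
- Every reference row prints a centrality component of exactly 1, making the
  0.2 weight a constant offset in that table; per-polymer centrality only
  differentiates scores on real corpora.
- The valence scorer is lexicon-based and English-only; it measures the tone
  of reporting, not toxicological ground truth. $S$ is a *relative* ranking
  across polymers within one corpus and is not comparable across corpora.
- Ranking ties are broken deterministically (descending paper count, then
  polymer id) to keep outputs reproducible, but ties indicate genuinely
  indistinguishable scores.
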