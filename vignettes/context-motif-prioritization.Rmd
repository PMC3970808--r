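---
title: "Prioritizing short-linear-motif matches with network context"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing short-linear-motif matches with network context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slimrank)
```

## The model

Linear-motif scans have a precision problem: a 3–10 residue pattern
matches a whole proteome largely by chance, and the sequence itself
cannot tell a functional site from a look-alike. `slimrank` treats the
cellular context as the missing evidence channel. A motif match in
protein $s$ is scored by how strongly a confidence-weighted
protein-association network connects $s$ to any protein carrying the
motif's binding domain.

For a path $n_1 = s, n_2, \dots, n_L$ ending at a domain carrier, the
association score is the product of *step factors*, one per edge entered:

$$\prod_{i=2}^{L}
  \frac{C(n_{i-1}\!\to\! n_i)}
       {\bigl(1 + \sum_x C(n_i\!\to\! n_x)
         - C(n_{i-1}\!\to\! n_i) - C(n_i\!\to\! n_i)\bigr)^{\beta}}$$

with $C \in [0,1]$ an edge confidence. The denominator is the *hub
penalty*: entering a node is discounted by its remaining connectivity
(its strength minus the edge just used and any self-loop), raised to
$\beta$. Subtracting the incoming edge makes the denominator at least 1,
so every step factor lies in $(0, C]$ and every path score in $[0,1]$.
The substrate's association score is the **best** such path to **any**
carrier; the carrier reached is reported as the most probable interaction
partner. A substrate that itself carries the domain scores exactly 1
(the empty product).

Motif evidence and context are then fused geometrically:

$$\mathrm{Final} = \mathrm{Motif}^{\,1-\alpha} \cdot
  \mathrm{Association}^{\,\alpha}, \qquad \alpha \in [0,1].$$

When the motif scanner is binary (a regular expression), there is no
graded motif factor and hits are ranked by the association score alone.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `beta` | 0.34 | hub-penalty exponent (dimensionless); 0 disables the penalty, larger values punish promiscuous nodes harder. The default carries over from kinase-substrate context scoring, where it was calibrated on real interaction networks. |
| `maxHops` | 3 | maximum path length in edges. Step factors are $\le 1$, so long paths decay multiplicatively; three hops (direct plus two intermediates) covers scaffolding-type indirection while keeping the search linear per hop layer. |
| `alpha` | 0.5 | context weight. Conserved motifs need little context (SUMO preset 0.4); degenerate motifs lean on it (PDZ preset 0.8). Choose by how much you trust the sequence signal. |
| `pseudocountTotal` | 1 | total pseudocount mass in PSSM estimation, spread proportionally to the background. |

The fixed-FPR readout of the benchmark harness ships the matching presets
(0.3 for SUMO-style, 0.15 for PDZ-style runs).

## Design choices where the design was open

**Best path, not sum over paths.** Summing over all paths could exceed 1
and would break the $[0,1]$ geometry the fusion formula needs; the single
best path keeps the score interpretable as the most plausible chain of
associations and is what the hop-bounded dynamic program computes
exactly.

**Why the dynamic program is exact.** The step factor depends only on the
traversed edge and the entered node, so path scores factor over edges.
Every factor is in $(0,1]$; deleting a cycle from a walk therefore never
lowers its score, the best walk is attained by a simple path, and layered
relaxation over at most `maxHops` hop layers — which optimizes over walks
— returns the best simple path. The test suite verifies this against
exhaustive path enumeration on random graphs rather than taking the
argument on faith. Equal-score ties break toward fewer hops, then the
lexicographically smaller interactor id, making ranked output fully
deterministic.

**Motif-score normalization.** A PSSM window score is a base-2 log-odds
sum; the fusion formula needs a $[0,1]$ quantity. The logistic transform
$2^{raw}/(1+2^{raw})$ maps the likelihood-ratio interpretation onto the
unit interval smoothly and without tunable parameters: raw 0 (window
indistinguishable from background) maps to 0.5, $-\infty$ to 0. It is
strictly monotone, so motif-only rankings are unaffected; the choice only
shapes how motif and association magnitudes trade off inside the
geometric mean.

**Background correction.** PSSM columns are estimated against the
proteome's own residue distribution, with add-one smoothing
$f(a) = (\mathrm{count}(a)+1)/(\mathrm{total}+20)$ — this keeps every
frequency positive (an absent residue gets exactly the floor
$1/(\mathrm{total}+20)$) while the vector still sums to one.
Pseudocounts are background-proportional, so a column whose usage equals
the background scores exactly zero at any pseudocount mass.

**Degenerate and edge cases.** `0^0 := 1` in the fusion, so $\alpha = 0$
ignores a zero association entirely (and vice versa) and the reduction
identities hold exactly. Windows containing `X` are skipped, never scored
— unknown residues must not fabricate evidence. Substrates missing from
the network score 0, which zeroes the final score for $\alpha > 0$; no
floor is applied, and users wanting motif-only ranking set $\alpha = 0$.
Self-loop confidences count once in a node's strength and are subtracted
back in the denominator. Duplicate or reciprocal network rows merge
keeping the maximum confidence. All coordinates are 1-based closed
intervals.

## The benchmark harness

`rocCurve()` sweeps thresholds over *distinct* scores (tied scores form a
single ROC vertex, so ties cannot inflate the AUC); the trapezoidal AUC
then equals the Mann–Whitney statistic with half-credit for ties, which
the tests check pairwise. TPR at a fixed FPR is linearly interpolated
between adjacent vertices.

`crossValidate()` performs repeated stratified k-fold cross-validation
(defaults $k = 5$, 5 repeats) of the PSSM + context ranking: per fold, a
PSSM is trained on the remaining folds' positive peptides and all
held-out sites are scored with the combined score; per-repeat ROCs are
computed on the pooled held-out scores and the medians across repeats are
reported. Stratification is used because small motif datasets otherwise
produce folds without positives; a partition that still lacks a positive
in some fold is redrawn. Negatives must be supplied explicitly (here, by
the generator) — real benchmark negatives for SUMO/PDZ are not
reconstructible from public tables, which is why the harness is exercised
on synthetic data.

## What the synthetic generator emulates — and what it does not

`generateScenario()` builds a universe in which the method's premise is
true by construction and its strength is tunable. Proteins take four
roles: substrates with one planted true site each, decoy proteins with
one planted decoy site, domain carriers, and filler proteins carrying an
Erdős–Rényi background network (default density 0.08, confidences uniform
on [0.4, 0.95], rounded to 3 decimals so fixtures round-trip losslessly).
Decoys are *genuine motif matches* drawn from the same instance
distribution as true sites — sequence evidence alone cannot separate the
classes, mirroring the poor specificity of real motifs. With probability
`contextSignal` a substrate gains a planted path of at most two hops to a
carrier with upper-half confidences; decoys stay unconnected by default
(`decoyConnect = "random"` wires them into the filler background
instead). At `contextSignal = 0` no substrate or decoy touches the
network, so the context channel is exactly uninformative — the clean null
for paired comparisons.

Default sizes (60 proteins of 80 residues, 5 carriers, 15 + 15 sites)
keep a full generate–scan–associate–cross-validate cycle under a second
while leaving enough sites for stratified five-fold splits; the
signal-recovery analyses in `scripts/acceptance.R` use 40-protein
scenarios across 10–20 seeds for the same reason.

What the generator deliberately does **not** model: realistic proteome
composition (sequences are i.i.d. uniform over the 20 residues),
disorder context of real motifs, STRING's evidence-channel structure, or
hub-dominated degree distributions (a preferential-attachment topology is
out of scope; the hub penalty is instead stress-tested directly by edge
perturbation). Passing tests on these scenarios therefore demonstrate
the *mechanics* — exact path scoring, correct fusion, honest evaluation —
and the qualitative claim that context separates motif-tied decoys when
context carries signal; they do not predict absolute performance on real
proteomes.

## Known limitations

- Identifier mapping between sequence, network and annotation namespaces
  is the user's job; nothing is resolved automatically.
- The regex dialect is deliberately small (classes, `.`, `*`, `+`,
  `{m}`, `{m,n}`, anchors, one capture group); alternation and
  lookaround are rejected rather than silently mis-scored.
- PSSMs are fixed-length and ungapped; variable-length motifs are only
  supported through the regex path, which is binary.
- The association score uses one global network; condition-specific
  (tissue, compartment) networks must be supplied as inputs.
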