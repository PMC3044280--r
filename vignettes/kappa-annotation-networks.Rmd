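---
title: "Kappa-scored over-representation analysis and annotation networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kappa-scored over-representation analysis and annotation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

High-throughput experiments end in gene lists, and gene lists are
interpreted by asking which annotation terms — pathways, GO terms,
protein domains, disease gene sets, drug-target sets — contain more of
the list than chance would predict. Two practical difficulties dominate:
annotation collections are heterogeneous (many categories, thousands of
terms, often more terms than genes), and the enriched terms themselves
overlap heavily, so a flat result table hides the structure among them.
`oranet` addresses both: a single over-representation analysis (ORA) run
spans any number of annotation categories at once, and the enriched
terms are arranged into a kappa-weighted relationship network that makes
the redundancy explicit and exportable to Cytoscape or MCL.

## The model

Everything rests on the 2×2 cross-tabulation of gene membership over a
background universe $U$. For a query set $Q$ and an annotation term $T$
(both intersected with $U$ first):

|            | in $T$   | not in $T$ |
|------------|----------|------------|
| in $Q$     | $n_{11}$ | $n_{10}$   |
| not in $Q$ | $n_{01}$ | $n_{00}$   |

with $N = |U|$.

**Cohen's kappa** is the enrichment *score*. Membership in $Q$ and
membership in $T$ are two binary classifications of the same $N$ genes;
kappa is their chance-corrected agreement:

$$P_o = \frac{n_{11}+n_{00}}{N},\qquad
  P_e = \frac{(n_{11}+n_{10})(n_{11}+n_{01}) +
              (n_{01}+n_{00})(n_{10}+n_{00})}{N^2},\qquad
  \kappa = \frac{P_o-P_e}{1-P_e}.$$

Kappa is bounded in $[-1,1]$, symmetric in its two arguments, and —
because it corrects for the agreement expected from the marginals — far
less sensitive to raw set size than tail-probability statistics. That
makes it usable both as an effect-size column in the result table and as
an edge weight between two annotation terms (the same formula applied to
two terms instead of query-vs-term). When a marginal covers the whole
universe, $P_e = 1$ and no agreement beyond chance is measurable; we
define $\kappa = 0$ there, the conventional "nothing beyond chance"
value.

**Significance** comes from the one-sided hypergeometric tail (Fisher's
exact enrichment test): $p = P(X \ge n_{11})$ with population $N$,
$n_{11}+n_{01}$ successes, and $n_{11}+n_{10}$ draws. Kappa itself is
never converted into a p-value: a score and a test answer different
questions, and the exact tail is the standard, assumption-free choice
for set-overlap ORA. A `depletion` alternative switches to the lower
tail. **Multiple testing** is handled by Benjamini–Hochberg; one BH
family spans all terms tested in a run, pooled across the selected
categories, because a multi-category run is one joint screening (a
per-category mode exists for users who consider categories separate
questions). The default stringency is strict `q < 0.05`.

This is deliberately *set-overlap* ORA: no rank-based running-sum
statistics, no permutation nulls. Those are different methods with
different inputs, and out of scope here.

## Parameters that matter

* **Background universe.** The single most consequential choice: every
  count in the 2×2 table depends on it. The default is the union of all
  genes annotated in the selected categories — self-contained,
  reproducible, and the population about which the annotations can
  actually speak. Any user-supplied universe (e.g. all assayed genes)
  can be passed explicitly (`universe =` / `--universe`), which is the
  more rigorous choice when the assay covered a known gene panel.
* **Term-size filter** (`min_size = 2`, `max_size = Inf`): singleton
  terms make both kappa and the hypergeometric test degenerate; very
  large terms are testable but rarely interpretable. Sizes are measured
  after intersection with the universe.
* **q-value threshold** (`0.05`, strict inequality): the conventional
  FDR stringency; adjustable, or disabled entirely (`q_threshold =
  NULL`) to keep the full table.
* **Kappa edge threshold** (`0.35`): the cutoff above which two enriched
  terms are connected in the relationship network. There is no natural
  universal value; 0.35 is the established DAVID
  functional-annotation-clustering convention for "meaningful"
  kappa agreement, and it is an explicit, documented flag rather than a
  constant.
* **Expansion direction and hops** (`downstream`, `1`): gene-set
  expansion along typed molecular networks defaults to one hop following
  edge direction (regulator → target), because the typical question is
  the downstream effect of a perturbed list. PPI edges are undirected
  and always expand both ways. Deeper or reversed traversal is a flag,
  not a different function.

## Numerical and design choices

* BH is implemented as the exact suffix-minimum form of the step-up
  rule ($q_{(i)} = \min_{j\ge i} \min(1, p_{(j)} m / j)$, returned in
  input order) so that adjusted values are bit-reproducible; unit tests
  cross-check it against `stats::p.adjust(method = "BH")`.
* Hypergeometric tails are computed by `stats::phyper`, which is exact
  to machine precision via log-gamma; tests verify it against explicit
  binomial-coefficient sums on every small table.
* Result ordering is the deterministic tuple `(q, p, -kappa, term_id)`;
  all file exports sort members/edges (C-locale radix order), so a given
  input yields byte-identical output on any platform.
* ID conversion keeps *all* canonical IDs of an ambiguous token and
  flags the token, rather than dropping it: inclusive mapping cannot
  silently lose signal, and the flag preserves auditability. Gene
  symbols match case-insensitively; accessions exactly.
* Hierarchies are ingested as plain parent–child pairs (a DAG; multiple
  parents per child are fine, cycles are an error at load). Annotations
  are *not* propagated to ancestor terms: the analysis tests what the
  file states. The tree view nests enriched terms under their parent
  chains, inserting non-enriched ancestors as unscored scaffold nodes.
* Gene-set expansion across miRNA/drug networks can produce
  mixed-namespace sets (miRNA and drug IDs live outside the gene ID
  space); `restrict_to_genes()` filters back down before GSA.

## What the synthetic fixtures emulate

The generator (`fixture_config()` / `simulate_fixture()` /
`generate_fixture()`) produces a complete, self-contained analysis
environment: a gene pool, per-category GMT term collections, a GO-like
DAG hierarchy, one molecular network of each kind, an ID-mapping table
(identity rows plus aliases and two deliberately ambiguous symbols), and
a query list. Its defaults are the reference conditions used by the
test suite: 2,000 genes, 2 × 100 terms of size 10–40, three planted
terms, a 40-gene query, planted overlap fraction 0.6. The planted terms
share a common core of `round(0.6 × 40) = 24` genes that is also placed
in the query — with three planted terms each required to overlap 60 % of
the query, the terms must share members, so a shared core is the
construction that satisfies the design exactly. Term sizes 10–40 match
the mid-range of curated pathway databases, where most testable terms
live; network edge counts (300 PPI, 120 TF–target, 60 miRNA–target, 30
drug–target edges) give average degrees comparable to sparse curated
interactomes. All randomness flows from the single config seed through
one isolated RNG scope (the caller's RNG state is untouched), making
every fixture byte-reproducible.

What the fixtures do **not** emulate: real annotation collections are
strongly nested and correlated (GO terms share genes by construction),
gene coverage is biased toward well-studied genes, and real queries
carry measurement noise that is not uniform over the genome. Planted
terms here are recovered essentially always and null fixtures are
essentially always clean; on real data, correlated terms inflate the
number of significant, mutually redundant hits — which is precisely why
the kappa network view exists. Passing the recovery and calibration
tests therefore demonstrates that the statistics and machinery are
correct, not that any particular biological discovery is easy.

Test-suite problem sizes (100 fixtures per recovery/calibration check,
exhaustive 2×2 enumeration up to $N = 12$, 1,000 random p-vectors,
random networks up to 50 nodes) were chosen to exercise every code path
with comfortable margins while keeping a full run around a minute.

## Known limitations

* No OBO parsing: GO-style hierarchies must be flattened to parent–child
  TSV first (a one-line preprocessing step with any OBO tool).
* No annotation content ships with the package; all real analyses
  require user-supplied GMT/TSV files.
* ORA treats genes as exchangeable; gene-level covariates (length, GC,
  expression level) are not modeled.
* The network expansion is unweighted bounded reachability — no
  diffusion, no edge confidence weights.
* BH assumes the usual positive-dependence conditions for exact FDR
  control; heavily nested term collections are handled in the sense
  that BH remains valid under PRDS, but the effective number of
  independent hypotheses is smaller than the term count.
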