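---
title: "Validating herb-prescription disease predictions with permutation null models and dose-weighted GSEA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating herb-prescription disease predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(herbnet)
```

## The model

A multi-herb prescription is represented as a four-layer directed graph:
herbs point to their chemical ingredients, ingredients to the genes they
are statistically associated with, genes to the diseases they are linked
to. The prescription itself is an implicit root above the herb layer
(it is not exported as a node, so the four node classes stay aligned
with the herb / ingredient / target / disease layout used by graph
viewers). The set of disease-layer nodes reachable from the root is the
prescription's *predicted indication set*.

Two filters precede assembly, in this order:

1. **OB screen.** Ingredients lacking an oral-bioavailability score are
   excluded, together with every link incident to them. This is a
   presence/absence screen: no numeric threshold is applied by default,
   because the OB score's role here is to mark compounds for which
   in-vivo activity is plausible at all. A numeric cutoff
   (`filter_config(ob_numeric_cutoff = )`) exists for sensitivity
   analyses but is off by default.
2. **FDR control.** The raw association p-values of all remaining
   ingredient–gene links are Benjamini–Hochberg adjusted in one global
   pass, and only links with adjusted *q* strictly below 0.05 are kept.
   Global scope (rather than per prescription or per ingredient) is a
   deliberate choice: the adjustment is part of knowledge-base
   refinement, performed once before any prescription-specific network
   exists, so every prescription sees the same validated link set. The
   removal cascade stops at genes: genes with no surviving inbound link
   are dropped with their disease links, but the disease *universe* is
   never shrunk — it remains the sampling population of the null model
   below regardless of filtering.

Disease terms are matched by exact string comparison after
normalization (case-fold, trim, collapse internal whitespace), with an
optional user-supplied synonym table applied at load. Keyword matching
of clinical vocabularies is genuinely hard; exact normalized matching is
the reproducible floor, and it may undercount overlaps relative to
manual curation — a conservative direction for the validation statistic.

## The permutation null model

For a prescription with predicted set of size $m$, a gold-standard list
$G$ of size $n$, and a background universe of $U$ disease terms, the
observed statistic is the concordance rate

$$ c_{\mathrm{obs}} = 100 \cdot \frac{|P \cap G|}{|G|} \; [\%]. $$

Normalization is by the **gold** list size, not the predicted set size:
predicted sets run to hundreds or thousands of terms while curated gold
lists hold a handful, and the scientific question is "how much of the
clinically validated indication list does the network recover", not the
reverse. With gold-normalization a fully recovered single-term list
scores exactly 100%, which is the only reading under which perfect
recovery of a tiny list can still be non-significant (see below).

The null distribution redraws, $N$ times, a uniformly random
$m$-subset of the universe (without replacement — a disease either is
or is not predicted) and recomputes the concordance. The empirical
p-value is

$$ p = \frac{C + 1}{N + 1}, $$

with $C$ the number of null concordances **greater than or equal to**
the observed one. Ties count as exceedances and the +1 treats the
observed value as one more draw from its own null, so
$p \in [1/(N+1), 1]$ and $p$ can never be zero. Significance is strict
$p < \alpha$ with $\alpha = 0.05$. $N$ defaults to 10{,}000, putting
the p-value floor at $1/10001 \approx 0.0001$.

Two useful closed forms anchor the tests: for $n = 1$ with the gold
term inside the predicted set, the per-permutation success probability
is exactly $m/U$ (one marked ball in a hypergeometric draw), so the
Monte-Carlo p converges to $m/U$ — 100% concordance with $n = 1$ is
non-significant whenever $m/U \ge \alpha$; and by linearity of
expectation the null concordance mean is $100\,m/U$ for any $n$. The
hypergeometric shortcut is used **only** as a test oracle; the shipped
statistic is the permutation itself, which is what generalizes when the
concordance definition changes.

Reproducibility: each (prescription, category) pair seeds its own RNG
sub-stream via `derive_seed(master, "null_model", prescription,
category)` — a label hash, so adding or removing a prescription never
perturbs any other's draws. Degenerate inputs are handled explicitly:
an empty predicted set gives concordance 0 and $p = 1$ with a warning
(not an error — it is a legitimate outcome of aggressive filtering);
an empty gold list is a domain error (the statistic is undefined);
rounding of $p$ to 4 decimals happens only in output tables, never
internally.

## Dose-weighted gene ranking and pre-ranked GSEA

The GSEA ranking metric weighs evidence by dose:

$$ S_g = \sum_{h \in \mathrm{herbs}} \mathrm{dose}_g(h)
   \sum_{\substack{i \in h \\ (i,g)\ \mathrm{surviving}}} \mathrm{ev}(i, g). $$

Evidence scores live on ingredient–gene links and are summed along all
herb→ingredient→gene paths, then scaled by the herb's dose in grams and
summed across herbs into one comprehensive score per gene — the
polypharmacological reading, where several weak contributions through
different herbs add up. Summation (rather than max or mean) is isolated
in `composite_gene_scores()` so alternatives are a one-line swap. Scores
are homogeneous of degree 1 in the doses, and the ES below is invariant
to homogeneous scaling, so dose *units* do not matter — only ratios do.

Genes are ranked by descending $S_g$ (ties broken lexicographically by
gene id, so rankings are deterministic). For a gene set $S$ with $k$
members in the ranked universe of length $L$, the walk statistic
increments at hits by $|s_i|^{w}/\sum_{\mathrm{hits}}|s_j|^{w}$ and
decrements at misses by $1/(L-k)$; the enrichment score is the maximum
of the running sum floored at 0 (positive mode — the analysis asks only
which sets are concentrated at the *top* of a non-negative score list),
and the leading edge is the hits at or before the peak, so ES = 0
implies an empty leading edge. The weight exponent defaults to 1.
Degenerate cases: an all-zero score vector falls back to equal hit
weights; a set that misses the universe or covers it entirely is
rejected; peaks below $10^{-12}$ are treated as 0 to keep float dust
from fabricating leading edges.

The null is gene-label permutation — the only choice for a pre-ranked
list — drawing `n_perm` random $k$-subsets of the ranked universe and
recomputing ES ($O(k)$ per draw from sorted hit positions). $p$ uses
the same $(C+1)/(N+1)$ form; NES divides the observed ES by the mean of
the *positive* null ES (standard positive-mode normalization), and is
reported `NA` in the (practically unreachable) case of no positive null
ES rather than overriding the p-value formula. BH q-values are computed
across retained sets; effective sizes outside [10, 500] are skipped and
recorded. `n_perm` defaults to 1{,}000 for desk-scale runtime and
scales up by configuration. Leading edges of one shared set can be
intersected across prescriptions (`leading_edge_intersection()`) to
extract a common core of enrichment-driving genes.

## Network ranking and visualization extraction

The "most frequently represented" diseases of a network are ranked by
the in-degree of the disease node (distinct gene→disease edges). The
field reports such tables without a formula; in-degree is the simplest
frequency over the assembled network, the support count is emitted
alongside the rank so alternatives (e.g., path counts) can be compared,
and ties break lexicographically.

For display, each layer keeps its top
$\max(1, \lceil 0.01 \cdot \text{layer size} \rceil)$ nodes by exact
directed betweenness centrality; if that count exceeds 50 the fraction
drops to 0.5%. Selection ties break by betweenness then node id. The
rule runs per layer, the full network is never modified, and nothing
downstream consumes the selection — it exists purely for figure export
(GraphML / SIF with a `selected` flag).

## What the synthetic generator emulates

`generate_knowledge_base()` reproduces the *statistical structure* the
pipeline assumes, never real content:

* sparse bipartite layers with Bernoulli link densities
  (ingredient→gene 0.02, gene→disease 0.002 by default);
* a 20% share of ingredients lacking OB scores;
* ingredient–gene p-values from the mixture
  $\pi\,\mathrm{Beta}(a,1) + (1-\pi)\,\mathrm{Unif}(0,1)$ with
  $\pi = 0.2$, $a = 0.1$ — Beta$(a,1)$ makes the BH survival rate
  analytically tunable (its CDF is $t^a$);
* herb doses uniform on 2–12 g (the range typical of single-herb doses
  in multi-herb decoctions) and evidence scores uniform on 0.1–1;
* gold lists with a controllable planted-overlap fraction: exactly
  $\mathrm{round}(\text{overlap} \times n)$ terms inside the true
  predicted set, the rest drawn from the universe outside it;
* optionally a shared core gene set planted with strong links
  (p $= 10^{-12}$, high evidence) into every prescription, so
  leading-edge intersection has a known answer.

The desk-scale default — 3 prescriptions × 4 herbs × 10 ingredients,
500 genes, a 2,000-term universe — was chosen so that one full
validation with $N = 10{,}000$ runs in well under a second while the
filtered networks still carry a few hundred predicted diseases
($m/U \approx 0.15$, comparable to a large real knowledge base in the
sense that random draws recover a modest share of any gold list). The
test suite exercises this preset, plus a 1,000-term universe for the
closed-form checks, 2,000-gene ranked lists for planted-enrichment
recovery, and 50 replicate seeds for the power/type-I suite.

What the generator does **not** emulate: real marginal distributions of
SymMap scores, real vocabulary overlap structure between predicted and
curated disease names (everything matches exactly by construction), or
correlated link structure (links are independent given the layer
sizes). Passing tests therefore demonstrate the statistical machinery —
calibration of the empirical p-value, FDR behaviour, recovery of
planted signal — not performance on real curation noise.

One subtlety is worth making explicit: with planted overlap 0 the gold
list is drawn strictly *outside* the predicted set, which forces
concordance 0 and $p = 1$ — a stronger statement than independence.
The type-I calibration of the test under genuinely independent gold
lists is checked separately by drawing gold terms uniformly from the
whole universe, where the rejection rate must not exceed the nominal
$\alpha$ (the permutation p is valid, and slightly conservative for
coarse concordance grids: with a small gold list the statistic takes
few distinct values).

Small gold lists are underpowered by the same discreteness: with
$n = 3$ and two planted terms, 66.7% observed concordance sits within
reach of chance at $m/U \approx 0.15$, so the replicate-seed recovery
suite asserts detection on the $n = 8$ "all" category, where planting
6 of 8 terms puts the observed rate far outside the null.

## Numerical and design choices, in brief

* Strict inequalities throughout: link survival $q < 0.05$,
  significance $p < 0.05$ (matching "less than" conventions).
* BH step-up via `stats::p.adjust`; a brute-force evaluation of the
  step-up definition serves as the test oracle.
* Betweenness via igraph's exact algorithm; the test oracle recounts
  shortest paths from all-pairs BFS.
* All randomness flows from one master seed through named, label-hashed
  sub-streams (`derive_seed`); identical seed + inputs give
  byte-identical output tables.
* Duplicate (herb, ingredient) rows merge idempotently; duplicate
  (ingredient, gene) links are an error because their p-value would be
  ambiguous.
* Numeric parsing is strict at load: unparseable text is an error
  naming the table and column, never a silent `NA`; only the OB column
  may be blank.

## Limitations

* Exact normalized string matching of disease terms will miss synonym
  pairs a human curator would catch; supply a synonym table when
  vocabularies differ.
* The evidence aggregation (sum over paths, dose-weighted, summed over
  herbs) is one defensible reading of "dose-weighted evidence scores";
  the function boundary makes alternatives easy to test but the package
  does not adjudicate between them.
* Gene identifiers are opaque strings; identifier conversion
  (symbol → Entrez etc.) is out of scope beyond a user-supplied mapping.
* The GSEA null permutes gene labels, not phenotypes; as with all
  pre-ranked GSEA, inter-gene correlation is not modelled.
* Node ids must be unique across layers; colliding herb/gene/disease
  identifiers are rejected at assembly rather than silently namespaced.
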