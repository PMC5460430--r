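---
title: "Building log-odds substitution matrices from seed alignments"
author: "submat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building log-odds substitution matrices from seed alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(submat)
```

## The model

A substitution matrix assigns every pair of amino acids $(a, b)$ a score
measuring how much more (or less) often $a$ is found aligned to $b$ in
trusted alignments than independent pairing would predict:

$$S_{ab} = \log_2 p(a,b) - \log_2\big(p(a)\,p(b)\big),$$

rounded to integers for use in search and alignment tools. The joint
$p(a,b)$ is estimated by counting aligned residue pairs in a collection
of manually curated seed multiple sequence alignments ("groups", one per
protein family), and the marginals $p(a)$ follow by summing conservation
plus half of each substitution frequency. Unlike block-based estimation,
no column is discarded: gap/residue and gap/gap pairings are simply
skipped, so gap-rich but reliably aligned indel regions still contribute
every residue pair they contain.

Three complications drive the algorithm's structure.

**Redundancy.** Seed alignments contain near-identical sequences that
would otherwise dominate the counts. Sequences are clustered at a percent
identity threshold $t$: pairwise identity is
$$\phi(A,B) = \sum_{l=1}^{L} \delta(\alpha_l, \beta_l)
  \,[1 - \delta(\alpha_l, \gamma)]\,[1 - \delta(\beta_l, \gamma)],
\qquad \Phi = \frac{\phi}{\min(\lambda_A, \lambda_B)},$$
with $\gamma$ the gap symbol and $\lambda$ the residue count of a
sequence: only positions with identical non-gap symbols count, and the
fraction is taken against the shorter sequence. Two sequences join one
cluster whenever a chain of pairwise identities at or above $t\%$
connects them (single-linkage transitive closure; the comparison is
inclusive, $100\,\Phi \ge t$). A cluster then behaves like one sequence:
pairs inside a cluster are ignored, and a pair between clusters of sizes
$|c_x|$ and $|c_y|$ carries weight $1/(|c_x||c_y|)$. We define the
partition as connected components of the thresholded identity graph
rather than an incremental insertion pass because insertion order would
otherwise influence the result; components are order-independent and
match the "joins if similar to at least one member" rule exactly.

**Group size.** Each group is normalized before accumulation so that
families with thousands of members do not swamp small families. The
default divides each group's weighted counts by $N_k$, the group's total
weighted number of observed pairs; an alternative mode divides by the
group's sequence count $s_k$ instead. Both are retained (`mode = "total-pairs"`
vs `"per-sequence"`) because the two normalizations are genuinely
different conventions and reproduction studies may need either; the
$N_k$ form is the default because it is the one the correction term
below is defined against. The accumulated table is finally rescaled so
the mass on distinct unordered canonical pairs is exactly 1; since every
group enters with equal total mass, appending a copy of an existing
group (or scaling all counts) changes nothing.

**Ambiguity codes.** Modern databases contain B (= N or D), Z (= E or
Q), J (= I or L) and X (= any) often enough to matter. Each observed
pair involving such a code is counted *directly* under its own symbols
and *additionally* redistributed in equal shares over the canonical
expansions: an observed A–B pair counts $0.5$ to (A,N), $0.5$ to (A,D),
and $1.0$ to (A,B). Because this books the same observation twice, the
per-group frequency applies a correction,
$$\mu_k(\Theta_x,\Theta_y) = \frac{\sum_{a \in \Theta_x}\sum_{b \in
\Theta_y} n_k(a,b) \;-\; n_k(\Theta_x,\Theta_y)}{|\Theta_x||\Theta_y|},
\qquad
p_k(\Theta_x,\Theta_y) = \frac{\mu_k + n_k(\Theta_x,\Theta_y)}{N_k},$$
which vanishes for canonical pairs and guarantees each observation
contributes once. $N_k$ counts each observed pair's weight exactly once,
never per redistributed cell — otherwise the single A–B observation
above would not reproduce $p_k(\Theta_A,\Theta_B) = 1$.

## Numerical conventions

*Ordered-symmetric representation.* Pair tables are stored in unordered
semantics (the cell $(a,b)$ holds the full weight of the unordered pair,
mirrored). For scoring, the off-diagonal unordered mass is split in half
over the two ordered cells, which makes the marginal definition
$p(a) = p(a,a) + \tfrac12\sum_{b\neq a} p(a,b)$ and the score formula
above coincide with the conventional factor-2 off-diagonal denominator.
Totals over "distinct pairs" always mean the upper triangle including
the diagonal; only under that reading does the worked A–B example above
carry unit mass.

*Rounding.* "Round to the nearest integer" is ambiguous at `.5`; we
round half away from zero, deterministically. Scores are in whole bits
by default; a half-bit option exists for drop-in compatibility with
common matrix files (diagnostics stay in bits).

*Zero cells.* A canonical pair never observed makes its log-odds
undefined. The default is a hard error naming the offending pairs — at
very low clustering thresholds whole matrices become unusable this way
and should be discarded rather than patched — with an optional additive
pseudocount for experimentation.

*Ambiguity rows.* Scores for B/J/Z/X rows use their own accumulated
frequencies against set marginals $p(\Theta_x) = \sum_{a\in\Theta_x}
p(a)$; when a cell carries no observed mass the score falls back to
averaging the canonical pair frequencies over the expansion sets.
Relative entropy and the expected score are computed over canonical
cells only: the ambiguous cells are score outputs, not probability mass.

*Diagnostics.* Relative entropy $H = \sum_{a,b} p_{\text{ord}}(a,b)
S_{ab}$ is the KL divergence (bits) between observed and independent
pairing; the expected score $E = \sum_{a,b} p(a)p(b) S_{ab}$ must be
negative for a usable local-alignment matrix. Both are carried in the
matrix object and written into the file header.

## Benchmark statistics

The evaluation functions implement the statistics used to compare
matrices on homology-search benchmarks, without running any search tool:

- `coverageAtEPQ()` truncates an E-value-ranked hit list at an error
  budget of `epq` false positives per query (ties broken by stable input
  order, for determinism) and averages retained true-positive relations
  per superfamily with quadratic normalization
  $Q = \tfrac1S \sum_i t_i/(s_i^2 - s_i)$. "Errors per query" counts
  erroneous *relations*; superfamilies with fewer than two members
  contribute no orderable relations and are excluded.
- `bootstrapCoverage()` draws per-sequence weights from a flat Dirichlet
  prior, weights each retained true-positive relation by the product of
  its query and target weights and each superfamily denominator by the
  weighted quadratic term $(\sum_j w_j)^2 - \sum_j w_j^2$; the retained
  set stays fixed by the unweighted truncation. The exact published
  weighting expression is not reprinted in full anywhere we could follow,
  so this quadratically-normalized product form is our reading of it; the
  degenerate equal-weights limit reproduces the unweighted $Q$ exactly,
  which the tests assert.
- `zScore()` is the plain two-distribution Z statistic with the number
  of bootstrap replicates as $N$ (500 in the published protocol);
  $|Z| \ge 1.96$ is flagged significant.
- `qScore()` is the fraction of reference-aligned residue pairs
  reproduced by a test alignment, with residues identified by sequence
  id and residue ordinal.

By default every cross-superfamily hit is a false positive; benchmarks
that exclude same-fold/different-superfamily hits can pre-filter the
hit list before scoring.

## The synthetic generator

`simulateGroups()` produces seed-alignment sets with *known* ground
truth so the whole pipeline is testable without downloads. Per column an
ancestor residue is drawn from the marginal of a configurable target
joint $J$; every sequence's residue is then emitted independently
through the *half-kernel* of $J$ — the matrix square root of the
reversible Markov kernel $\mathrm{diag}(1/m)\,J$ — so that the joint
distribution of any two sequences at a column is exactly $J$. (Emitting
through the kernel itself, i.e. from the conditional $J(\cdot\mid a)$,
would interpose the ancestor and square the kernel between two leaves:
the pairwise joint would be systematically flatter than $J$ and the
recovered log-odds biased toward zero, with an exact-limit correlation
of only about 0.98 against the target. The half-kernel construction is
the standard reversible-model device of evolving both leaves from a
root at half distance.) Gap runs with geometric lengths are injected at
a configurable rate, residues are masked to their ambiguity code at a
small rate, and exact duplicates can be appended to exercise the
clustering weights.

The default target joint inverts the half-bit BLOSUM62 scores shipped
with Biostrings against standard background frequencies — a realistic,
diagonally dominant substitution structure with an expected pairwise
identity of about 34%, comfortably below the usual clustering
thresholds. `groundTruthLogOdds()` returns the recovery target
$\log_2 J_{\text{ord}} - \log_2 (m \otimes m)$.

The generator is column-independent: there is no phylogeny, no
position-specific conservation, no alignment error. Passing recovery
tests therefore demonstrates correctness of clustering, weighting,
redistribution and normalization — not robustness to tree-correlated
sampling or misalignment, which real seed alignments do contain.

## Validation scales and defaults

The package validates at 200 groups of 8 sequences by 50 columns
(10% gaps in geometric runs of mean 3, 1% ambiguity masking) — the
scale at which the recovered raw scores correlate above 0.99 with the
generator's ground truth, in about two seconds — and the bootstrap at
500 replicates, matching the published protocol. Oracle tests run the
brute-force counterparts (triple-loop counting, BFS components,
exhaustive prefix coverage, direct KL sums) on small random instances:
up to 5 sequences by 10 columns for counting, 200 records for coverage.

```{r recovery}
cfg <- simConfig(seed = 2024)
gs <- simulateGroups(cfg)
m <- buildSubstitutionMatrix(gs, t = 62, pseudocount = 1e-6)
m
cor(as.vector(rawScores(m)[1:20, 1:20]),
    as.vector(groundTruthLogOdds(cfg)))
```

## Known limitations

- Building a full-scale matrix from a complete seed database is
  supported by the same code path but takes the time the database
  demands; the package has been validated on synthetic and toy data,
  and full-database relative entropies have not been reproduced here.
- Karlin–Altschul E-value parameters and gap-penalty optimization are
  out of scope; matrices are written with enough header metadata for
  downstream tools to derive what they need.
- Clustering is quadratic in the number of sequences per group, which is
  acceptable for seed-sized alignments (tens to hundreds of sequences)
  but not for full alignments, which are out of scope.
- Exact third-party reproduction of published four-decimal entropies may
  depend on the original marginal convention (whether substitution
  events are halved); we adopt the ordered-symmetric reading, under
  which the printed score formula and the standard factor-2 convention
  agree.
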