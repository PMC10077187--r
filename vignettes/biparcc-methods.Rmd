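---
title: "Methods: inferring and analysing cross-kingdom bipartite co-occurrence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring and analysing cross-kingdom bipartite co-occurrence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biparcc)
```

`biparcc` turns paired 16S (bacteria) and 18S (microeukaryote) OTU count
tables into signed bipartite co-occurrence networks and a suite of
architecture statistics. This vignette records the models, the conventions
behind every tunable number, and the choices made where more than one
defensible definition exists.

## Input model and preprocessing

An `otu_table` is an OTU-by-sample matrix of non-negative integer counts for
one kingdom. Counts from amplicon sequencing are *compositional*: the
per-sample total is an instrument artifact, so only relative information is
meaningful. Preprocessing mirrors standard amplicon practice:

* **Rarefaction** (`rarefy`) subsamples each sample to a common depth
  without replacement (multivariate hypergeometric), the standard semantics
  of rarefying; columns sum exactly to the requested depth.
* **Prevalence filtering** (`prevalence_filter`) keeps OTUs detected
  (count > 0) in at least `ceiling(min_fraction * n_samples)` samples. The
  default `min_fraction = 0.5` encodes the "present in at least half of the
  samples" rule commonly used to stabilize correlation estimates: with 48
  samples, presence in 24 keeps an OTU and 23 drops it.
* **Sample alignment** (`align_samples`) restricts both kingdoms to their
  shared samples, in a common order, requiring at least 3.

Whether rarefaction precedes or follows the prevalence filter is not
standardized in the field; the pipeline defaults to rarefy-then-filter (the
filter then judges detectability at even depth) and exposes
`step_order = "filter_then_rarefy"` for the other convention.

## SparCC correlation inference

Let x_i be the latent absolute ("basis") abundance of OTU i and f_i its
observed fraction. The variation matrix

$$t_{ij} = \mathrm{var}\,\log(f_i/f_j) = \mathrm{var}\,\log(x_i/x_j)$$

is closure-invariant. Writing ω_i² for the basis log-variance and ρ_ij for
the basis correlation, t_ij = ω_i² + ω_j² − 2ρ_ij ω_i ω_j. Under the
sparsity assumption (most |ρ| small, so cross terms cancel in sums), summing
over partners gives the linear system

$$t_i \equiv \sum_{j \ne i} t_{ij} \approx (p-2)\,\omega_i^2 + \sum_j \omega_j^2,$$

solved in `estimate_basis_variances`; correlations follow as
ρ_ij = (ω_i² + ω_j² − t_ij) / (2 ω_i ω_j), clipped to [−1, 1]. At p = 3 the
system is exactly the classic three-variable decomposition
ω₁² = (t₁₂ + t₁₃ − t₂₃)/2, which the tests use as an oracle.

Strong pairs violate sparsity, so `estimate_correlations` iteratively
removes the single largest |ρ| pair above the **exclusion threshold**
(default 0.1) from the basis system and re-solves, up to
**max_exclusion_rounds** (default 10). Numerical guards:

* basis variances are floored at 1e−10 before taking square roots;
* an OTU is never excluded below 3 remaining pairwise equations
  (at most p − 3 exclusions per OTU), which keeps the system identifiable;
* if heavy exclusion still leaves the system singular, a minimum-norm
  least-squares solution (SVD pseudoinverse with relative tolerance 1e−10)
  replaces the direct solve.

Zeros are handled by the Dirichlet machinery of `sparcc()`: per draw, each
sample's fractions are sampled from Dirichlet(counts + 1) (pseudocount 1),
and the element-wise **median** over `n_draws = 20` draws is reported. These
defaults follow the original algorithm; all are arguments.

**P-values.** The significance procedure is a permutation null: each OTU's
counts are permuted independently across samples, destroying all between-OTU
association while preserving marginal count distributions; ρ is re-estimated
per permutation (posterior-mean fractions, no extra Dirichlet noise — the
permutation itself is the randomness source) and the two-sided p is the
plain proportion of null |ρ| ≥ observed |ρ| over `n_boot = 100` replicates.
Plain proportions (no +1 correction) were chosen to keep p-values exact
proportions of the stated null ensemble; with 100 replicates the smallest
attainable p is 0.

**Thresholding.** `significant_edges` retains pairs with |ρ| strictly
greater than `r_threshold = 0.6` **and** p strictly below
`p_threshold = 0.05`, the conventional robust-network setting; ρ = 0.60
exactly is dropped. Both kingdoms are pooled into one SparCC run —
intra-kingdom correlations are estimated (they stabilize the basis system)
but only inter-kingdom edges proceed to the bipartite stage.

## Bipartite construction

`extract_cross_kingdom` keeps edges with one endpoint per kingdom and
orients them microeukaryote → bacterium. `split_by_sign` builds one network
per sign with weight |ρ|; a taxon engaged in both signs appears in both
networks. Isolated nodes are pruned (a network node must carry a link).
Downstream metrics are quantitative (weights |ρ|) because the quantitative
indices (linkage density, interaction diversity) are more informative than
their binary counterparts; NODF, degrees, z and c binarize internally where
their definitions require it.

## Topology metrics and their conventions

* **Connectance** L/(r·c) and **links per species** L/(r+c) on the binarized
  incidence.
* **NODF** (0–100): over every ordered row pair and column pair,
  100·overlap/fill_smaller when the fills strictly decrease, else 0, averaged
  over all pairs. Computed on the binarized matrix (standard NODF is binary;
  no weighted variant is offered) via `vegan::nestednodf(order = FALSE)`,
  which matches this definition exactly; the test suite carries an
  independent brute-force pair enumeration as the oracle.
* **Interaction diversity** H = −Σ p_ij ln p_ij over nonzero cells
  (natural log), and **evenness** IE = H / ln(r·c). The evenness denominator
  is the "product" convention; `denominator = "links"` (ln L) is available
  since the literature uses both.
* **Linkage density**: LD = ½[Σ_j (w_.j/m)·2^{H_j} + Σ_i (w_i./m)·2^{H_i}]
  with H the node's base-2 entropy of interaction weights — a
  marginal-weighted mean of effective partner numbers. Unit-weight K₂,₂
  gives exactly 2, a single link gives 1.
* **Specialization d′** (per node): the Kullback–Leibler divergence
  d_i = Σ_j p′_ij ln(p′_ij/q_j) of a node's interaction shares p′ from the
  partner availability q (partner marginals / grand total), standardized by
  its attainable extremes. The bounds used are the closed forms d_min = 0
  (attained when shares match availabilities) and d_max = ln(m/A_i) (A_i =
  node total, m = grand total; attained exactly when all of a node's
  interactions fall on partners nobody else uses; no observed d can exceed
  it because c_j ≥ a_ij implies every log term is at most ln(m/A_i)). This
  replaces the discrete search heuristics used elsewhere with provable,
  deterministic bounds; weights are scaled ×100 and rounded to integer
  counts first, so results are reproducible across rescalings of |ρ|.
  A node with a single possible partner has d′ = 0 by convention.
  Perfect specialists are counted at d′ ≥ 1 − 1e−9.
* **Guild clustering coefficient**: one-mode projection onto a guild (two
  nodes adjacent iff they share ≥ 1 partner), then the mean local clustering
  coefficient with degree-<2 nodes contributing 0. Several two-mode
  clustering definitions exist; this is the most interpretable for "how
  clique-like is each guild".
* **Compartments**: connected components of the bipartite graph.

## Nestedness significance

`nodf_significance` scales weights ×100 to integer counts, draws
`n_rand = 100` Patefield tables with the observed row/column totals
(`stats::r2dtable`, the exact uniform sampler for fixed marginals),
binarizes each at > 0 (NODF is binary; the null must be scored on the same
scale as the observation), and reports p_higher and p_lower as plain
proportions of null indices at least as extreme. Degenerate inputs (a
single row/column, or an empty marginal) are errors rather than silent
zeros. Tables with a single row or column are forced by their marginals and
are constructed directly.

## Modularity and roles

Barber's bipartite modularity for partition g is

$$Q = \frac{1}{m} \sum_{i,j:\; g(\text{row } i) = g(\text{col } j)} \left( w_{ij} - \frac{k_i d_j}{m} \right),$$

zero for the one-module partition by the marginal identity. `lpawb_plus`
maximizes Q by alternating guild sweeps of weighted label propagation: each
node adopts the label maximizing its own Q contribution given the other
guild's labels. Because the objective is additive over the swept guild,
every accepted move strictly increases Q, so the propagation terminates; a
label that has lost all counterpart nodes contributes 0 and is merged away
on Q-neutral moves. Ties break to the lowest label, making a run
deterministic given its initialization. `dirt_lpawb_plus` (default
`n_restarts = 10`) repeats from random initial module counts, the first
restart being the deterministic singleton initialization, and keeps the best
Q — the restart idea behind DIRTLPAwb+.

Roles use **binary degrees** (link counts), matching the z–c framework the
thresholds come from: z is the within-module degree z-score over the
module's same-guild members (modules with zero spread assign z = 0, a
convention the framework leaves open), and c = 1 − Σ_t (k_it/k_i)². The
thresholds z = 2.5 and c = 0.62 split nodes into module hubs, network hubs,
connectors and peripherals; boundary values (z = 2.5 or c = 0.62) fall in
the non-hub / non-connector classes because the hub conditions are strict
inequalities.

## Co-extinction robustness

`simulate_extinction` removes one guild's nodes cumulatively in a given
order; after each primary removal, opposite-guild nodes with no surviving
partner suffer secondary loss. The survivor fraction y is recorded after
each step (y₀ = 1; y_N = 0 because every partner is eventually gone). The
robustness index is the trapezoidal area

$$R = \frac{1}{N} \sum_{k=1}^{N} \frac{y_{k-1} + y_k}{2} \in [0, 1];$$

a left-step rule is available (`method = "step"`) since both conventions
appear in the literature. `extinction_random` averages R over
`n_reps = 100` uniformly random orders; `extinction_generalist_first`
removes by descending *initial* degree — degrees are not recomputed after
removals, which keeps the order well-defined and deterministic up to ties,
and ties are reshuffled per replicate. Both guild directions are reported
separately rather than averaged, since their asymmetry is itself of
interest. The pipeline runs robustness on the positive ("mutualistic")
network by default (`robustness_signs`), where secondary extinction has its
ecological reading; any network is accepted.

## The synthetic generator: what it does and does not emulate

`generate_community` draws per-OTU basis log-abundances from a multivariate
normal whose covariance embeds the planted signed correlations (magnitudes
specified on the latent log-abundance scale — the scale SparCC estimates),
then turns each sample into counts by multinomial sampling at the stated
depth within each kingdom. This reproduces the two features that make naive
correlation fail and SparCC work: closure (counts are forced to a total) and
count noise at realistic depths. Defaults emulate a coastal-pond water
survey: 48 samples, 406 microeukaryotic and 1210 bacterial OTUs (post-filter
table sizes), depths 31,781 (18S) and 49,706 (16S), abundance heterogeneity
from a log-normal basis (log-mean sd 1, per-OTU log-sd 1 — typical order for
amplicon data), and phylum labels sampled from the node-percentage
distribution of a pond bipartite survey, so phylum summaries look realistic.
The default planted set is 24 positive and 16 negative disjoint pairs at
magnitude 0.9.

Planted pairs are **disjoint** by default for a structural reason: several
strong correlations sharing one node quickly violate positive-definiteness
of the embedding covariance (k edges of magnitude ρ on one node need
roughly ρ²·k < 1), and the generator refuses a non-PD covariance rather
than silently shrinking it. Two consequences matter for interpreting green
tests. First, recovered synthetic networks are near-perfect matchings —
sparse, modular in the trivial sense, with NODF ≈ 0 and R = 0.5 — so
passing the recovery test says the *inference* chain works, not that the
package reproduces realistic network architecture. Second, nestedness,
modularity and robustness are therefore validated on constructed incidence
fixtures with known answers (`generate_nested_incidence`, a prefix
staircase whose square form has NODF exactly 100;
`generate_modular_incidence`, block-diagonal complete bipartite blocks with
planted labels and Q = 1 − 1/blocks for equal blocks) rather than on
generator output. The generator also makes no attempt to simulate
sequencing error, chimeras, taxonomic misassignment, or environmental
covariates; all association in the data is pairwise and log-linear.

## Validation problem sizes

The test suite validates parameter recovery on a scaled community — 30
microeukaryotes × 60 bacteria, 200 samples, depth 50 reads per OTU per
kingdom, 12 positive and 8 negative planted edges at magnitude 0.9 —
demanding at least 80% of planted edges recovered with correct sign and at
most 5% spurious inter-kingdom edges at the |ρ| > 0.6, P < 0.05 thresholds.
These sizes keep the full suite fast while preserving the estimation
regime (depth per OTU and samples-per-parameter comparable to the
study-scale defaults). NODF is cross-checked against brute-force pair
enumeration on hundreds of random 6×6 matrices; extinction curves against a
from-scratch oracle over all 120 removal orders of a 5-node guild; the
Patefield sampler against exact enumeration of the 2×2 unit-marginal case.

## Known limitations

* Co-occurrence is not interaction: an edge is a statistical association,
  subject to environmental confounding; the package deliberately stops at
  "potential" interactions.
* SparCC's sparsity assumption biases estimates when many strong
  correlations coexist; the exclusion mechanism mitigates but does not
  remove this (visible as attenuation of planted ρ = 0.9 toward ~0.75–0.85
  in the recovery tests).
* d′ standardization uses continuous bounds; implementations using discrete
  integer searches can give slightly larger d′ for coarse matrices.
* The permutation null for p-values treats samples as exchangeable;
  longitudinal or spatially structured designs would need a restricted
  permutation scheme.
* Label propagation is a greedy Q-maximizer: restarts reduce but cannot
  eliminate local optima; reported module counts are lower bounds on
  structure, not exact optima.
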