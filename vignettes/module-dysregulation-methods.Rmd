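---
title: "Transcription modules and their dysregulation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcription modules and their dysregulation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A hemizygous microdeletion (as in Williams-Beuren syndrome) removes one
copy of a contiguous gene block. Beyond the direct ~50% dosage reduction
of the deleted genes, the deletion perturbs regulatory programs that are
hard to see gene by gene with a handful of patient samples. The modular
strategy implemented here first learns *transcription modules* — sets of
genes co-expressed across subsets of samples of a large public
compendium of the same cell type — and then asks whether each module's
summary expression differs between cases and controls. Aggregating over
a module's genes trades single-gene resolution for power: a coherent
0.5 log2 shift spread over 40 genes is invisible per gene at n = 17 but
obvious on the module average.

## Module discovery: the Iterative Signature Algorithm

Given a log2 expression matrix $E$ (genes × samples), let $E_G$ be $E$
standardized per gene and $E_C$ per sample (mean 0, sd 1, denominator
$n-1$). From a random gene seed $g$, the ISA alternates

$$ s = E_G^\top g / \textstyle\sum_g |g_g|, \qquad
   g' = E_C\, s / \textstyle\sum_c |s_c|, $$

keeping after each projection only entries that deviate from the mean of
the raw score vector by more than $t_C$ (samples) or $t_G$ (genes)
standard deviations of that vector — two-sided and signed, so a module
may contain an anti-correlated gene half. Fixed points of this map are
the modules; gene scores are rescaled to max $|w| = 1$, and the stored
sample scores are exactly the weighted average expression of the module
genes (this consistency is asserted by the tests, and is what the
dysregulation statistic reuses). A grid of thresholds (defaults: genes
2, 2.2, …, 4; samples 1, 1.2, …, 2) yields modules of graded stringency.

Numerical choices that the algorithm's description leaves open:

* **Convergence.** A seed is converged when its membership set is
  unchanged for two consecutive iterations *and* the gene-score vector
  moves by less than 1e-8 in max norm (cap: 100 iterations;
  non-converged seeds are discarded). A correlation-based criterion
  (> 0.99) proved too loose: it admitted signatures whose scores still
  drifted at the 1e-3 level, violating the fixed-point contract.
* **Deduplication.** Candidates are visited in decreasing *robustness*
  and dropped when their gene-score vector correlates (absolutely)
  above 0.9 with a kept module. Robustness is the bilinear strength per
  module cell, $|g^\top E_G s| \,/\, (\lVert g\rVert\,\lVert s\rVert
  \sqrt{n_g n_s})$. The $\sqrt{n_g n_s}$ denominator matters: without
  it the statistic grows with module size, so a module diluted with a
  second module's genes outranks its pure core and deduplication keeps
  the contaminated version. The per-cell form is size-free and favors
  purity; with it, the default synthetic world is recovered 10/10.
* **Sign canonicalization.** $(g, s) \mapsto (-g, -s)$ is a symmetry of
  the model; modules are stored with the majority of member sample
  scores positive.
* **Seeds.** 100 random binary seeds of 10 genes per threshold pair.
  Seeds are cheap (the iteration is vectorized over seeds), and any
  seed sharing even one gene with a strong module is typically captured
  by it.

## Preprocessing

Features rarely detected (Present in fewer than 10 samples for a
compendium, 6 for the 17-sample case/control set) or unmapped to a gene
are dropped; multi-feature genes keep the single most variable feature
(ties: lexicographically smallest feature id); datasets are merged on
their common features. Detection flags are applied per dataset before
merging — the flags are not recomputed afterwards.

Batch correction follows the parametric empirical-Bayes location/scale
model: per gene $g$ and batch $b$,
$y = \alpha_g + X\beta_g + \gamma_{gb} + \delta_{gb}\,\varepsilon$, with
a normal prior on $\gamma$ and inverse-gamma on $\delta^2$ whose
hyperparameters are estimated across genes by moments; posterior
estimates come from the standard iterative conditional scheme (tolerance
1e-4, max 100 iterations) and are removed while covariate effects
$X\beta$ are retained. Two degenerate situations are handled without
shrinkage: when the batch location estimates have no spread across genes
(prior variance 0) or when within-batch residual variance vanishes, the
raw estimates are removed as-is. These guards make the correction exact
for batches that differ by a literal per-gene shift with no within-batch
noise; for noisy batches, EB shrinkage deliberately leaves residuals of
the order of the shrinkage weight — that bias is the price of stabilized
scale estimates, and the balanced-contrast invariant (case/control
differences move by < 0.1 log2) is what the tests guarantee.

## Single-gene statistics

The moderated t shrinks gene-wise pooled variances toward a prior:
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$, with $(d_0, s_0^2)$
estimated by fitting a scaled F distribution to the sample variances via
the moments of their logs (inverse-trigamma by Newton iteration). When
the spread of log variances does not exceed the theoretical chi-square
component, $d_0 = \infty$ and $s_0^2$ is the plain mean of the
variances; the total df for p-values is capped at the pooled residual df
of the matrix. The implementation reproduces the established
empirical-Bayes reference implementation to 1e-10 on random data (the
reference is used in tests only). DEGs require both BH-adjusted
p ≤ 0.05 and a fold change ≥ 1.5 (|log2 FC| ≥ 0.585). Class
over-representation uses the one-sided hypergeometric tail; odds ratios
are sample cross-product ratios with a Haldane 0.5 correction only when
a cell is zero. The hemizygous-set test compares the mean moderated t of
the set against relabeled nulls with the +1 permutation convention —
p-values are never exactly zero.

## Module dysregulation

The case/control matrix is standardized per gene; each module with at
least 10 usable genes is scored per sample by
$\sum_g w_g x_{gc} / \sum_g |w_g|$ (equal weights give a plain mean, and
rescaling all weights changes nothing); cases and controls are compared
with a two-sided Welch t-test; BH runs over the *tested* modules only —
modules failing the size filter never enter the family, which changes
the adjusted p-values of the rest and is asserted as a property.
Permutation validation repeats the procedure under label permutations
preserving group sizes. Two facts shape what a green test can claim:
with ~20 modules tested at FDR 0.05, roughly 5% of *random* relabelings
will produce one BH discovery (that is what FDR control means), so the
meaningful property is that permutations reaching the observed discovery
count are only those nearly identical to the true labels — or to their
complement, which a two-sided test cannot distinguish (with an 8/9
split, the complement's attainable label agreement is 1 of 17).

Replication in a second cell type uses per-array log fold changes as
input: the weighted mean logFC of the module genes per array, then a
one-sample t against zero, BH over modules. No per-gene standardization
is applied here — a logFC is already a contrast; a config switch exposes
the alternative.

## Hierarchy, enrichment, network

Modules discovered at different thresholds nest; the hierarchy connects
two modules when the first's gene set is strictly contained in the
second's, stores the transitive reduction (unique for a DAG), collapses
identical gene sets into one node (avoiding 2-cycles), and reports
weakly connected components of size ≥ 2 ("non-trivial"; the minimum size
is a parameter).

Enrichment is the one-sided hypergeometric test of each category against
each module's gene set, with BH over the pooled (modules × categories)
family. Categories are taken exactly as given in the GMT — no ontology
propagation; the universe defaults to the genes present after filtering.

The network stage takes an evidence-weighted interaction network
(STRING-style; combined scores above 1 are divided by 1000). Genes
recurring across dysregulated modules induce a subnetwork whose total
edge evidence is compared against uniformly drawn vertex subsets of the
same size; degree and PageRank (damping 0.85, unweighted adjacency,
power iteration to L1 1e-10) of the frequent genes are compared to the
remaining vertices by a two-sided rank-sum test (exact by subset
enumeration for ≤ 16 vertices, which handles ties; exact
distribution for tie-free samples ≤ 50; normal approximation with tie
correction beyond). Hierarchical organization is tested by fitting a
hierarchical random graph — per dendrogram split $r$, cross edges are
Bernoulli with MLE $p_r = E_r/(L_r R_r)$, log-likelihood
$\sum_r E_r\log p_r + (L_rR_r - E_r)\log(1-p_r)$ — via Metropolis MCMC
over subtree-exchange moves (each step swaps a random internal node's
sibling with one of its children; acceptance $\min(1, e^{\Delta\log L})$;
best-seen model returned; default $50 n^2$ steps, intended for graphs of
up to a few hundred vertices). Significance comes from refitting on
degree-preserving rewired networks (double-edge swaps with random
orientation for ergodicity, evidence scores reassigned to the new edge
slots so evidence statistics stay comparable); the empirical p uses the
+1 convention.

## The synthetic world

The generator emulates a multi-dataset compendium plus a separate
case/control matrix: i.i.d. Gaussian log2 noise (sd 0.5), 10 gene-disjoint
planted modules of 20–60 genes shifted by ±4 log2 in a random quarter of
the compendium samples (signs per gene with probability 0.5, giving
anti-correlated halves), per-dataset batch effects (additive N(0, 0.3),
multiplicative exp(N(0, 0.1)) — exactly the location/scale model the
correction assumes), 8 cases vs 9 controls, case shifts applied along
each gene's module sign (a uniform shift would cancel in the signed
weighted average), 13 hemizygous genes at −0.5 log2 in cases (single-copy
dosage is −1; arrays compress it), and 10% detection dropout. Defaults
were chosen once for testability at desk scale: amplitude 4 at noise 0.5
makes planted modules unambiguous attractors, and the case effect of 1
log2 (2 noise sd) makes dysregulation detectable at n = 17. What the
generator does *not* emulate: correlated noise, probe-level effects,
mixed module overlap in gene space (planted modules are gene-disjoint;
discovered modules still overlap through sample sets), and realistic
effect sizes — the study's true dysregulation magnitudes are unknown, so
a green recovery test establishes correctness of the machinery, not
field performance.

## Known limitations

* Module counts are not comparable to published counts; they depend on
  seed numbers and deduplication settings that the original study does
  not report.
* The HRG MCMC is pure R and sized for desk-scale subnetworks
  (≤ ~200 vertices), not whole interactomes.
* ComBat here supports one categorical covariate set; the full
  design-matrix interface of the reference implementation is out of
  scope.
* Enrichment direction labels (induced/suppressed) require a caller-
  supplied per-gene sign table; without one the column is blank.
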