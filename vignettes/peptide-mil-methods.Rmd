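---
title: "Multiple-instance learning for MHC-II peptide binding: model and methods"
author: "PepMIL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple-instance learning for MHC-II peptide binding: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PepMIL)
```

## The prediction problem

MHC class II molecules present peptides of roughly 11–20 residues in a
binding groove that is open at both ends.  Only nine consecutive
residues — the binding core — occupy the groove's nine pockets, and the
residues immediately flanking the core still modulate affinity.  Because
the core's position within a measured peptide is unknown, supervised
learning on MHC-II affinity data faces a latent-alignment problem: the
label (an IC50 in nM) belongs to the peptide, while the physics happens
in an unobserved 9-residue window.

PepMIL treats this as multiple-instance regression.  Each peptide is a
*bag*; its candidate cores are the *instances*:

* all 9-mer substrings (candidate binding cores), and, in the
  flexible-length variants,
* all 11-mer substrings, i.e. a candidate core plus its two flanking
  residues,

so a peptide of length $L$ contributes $(L-8)$ nine-long and $(L-10)$
eleven-long instances.

## Distances, embedding and regression

Instances are compared through a substitution-matrix score restricted to
a configurable set of key positions.  For equal-length instances $x, x'$,

$$d(x, x') = \sum_{i \in KP_\ell} \mathrm{BLOSUM62}(x(i), x'(i)),$$

where $KP_9 \subseteq \{1..9\}$ and $KP_{11} \subseteq \{1..11\}$ are the
scheme's position sets.  The canonical anchor set is
$KP_9 = \{1,4,6,7,9\}$; because an 11-long instance is a 9-long core with
one residue added on each side, a core set induces
$KP_{11} = \{1\} \cup \{p+1 : p \in KP_9\} \cup \{11\}$
(`coreTo11Positions()`), giving $\{1,2,5,7,8,10,11\}$.  The raw score is
scaled into a distance in $(0, 1]$ by its sign: $1/d$ if $d > 0$, else
$1$.  Instances of different lengths never match; their distance is
defined as infinite.

A literal reading of "infinite distance" through the sign-scaling rule
would give $1/\infty = 0$, i.e. maximal *similarity* — the opposite of
the intent.  PepMIL therefore excludes cross-length pairs from every
minimum and assigns them a *sentinel* value of 1.0, the maximum of the
distance range.  The sentinel is configurable but should stay in
$(0, 1]$ so feature vectors keep a common scale.

Training bags define a *meta-space*: the deduplicated union of all
training instances, ordered deterministically (length ascending, then
lexicographic in the C locale).  Duplicated strings are kept once —
identical instances would produce identical feature columns, which add
cost but no information to a kernel regressor.  A bag $B_i$ is embedded
as

$$m(B_i) = [\,s(x^1, B_i), \ldots, s(x^n, B_i)\,], \qquad
  s(x^k, B_i) = \min_j \mathrm{dis}(x^k, B_{ij}),$$

the minimum taken over bag instances of the same length as $x^k$ (the
sentinel if there are none).  Features are distances — small means
similar — and no conversion to similarities is performed.  An
$\varepsilon$-SVR with RBF kernel maps the embedding to the transformed
affinity.

## Affinity scale and labels

IC50 values are mapped to the unit interval with
$y = 1 - \log(\mathrm{IC50}) / \log(50000)$ (the base cancels in the
ratio); predictions return to the nM scale through
$\mathrm{IC50} = 50000^{\,1-y}$.  Affinities outside $[1, 50000]$ nM
would leave $[0,1]$ and are clamped; the clamp makes the two maps exact
inverses on the calibrated range, which the tests verify on a 1000-point
log-spaced grid.  A peptide is a *binder* when its measured IC50 is
strictly below 1000 nM.

## Tunable parameters

* **Instance lengths** — `{9}`, `{11}` or `{9, 11}` (presets `mhcmir9`,
  `mhcmir11`, `fl*`).  Only 9 and 11 are supported; 11 is the smallest
  length that carries flanking information.
* **Key-position scheme** — `all`, `kp` ($\{1,4,6,7,9\}$), or `kp+n`
  for $n \in \{2,3,5,8\}$; custom sets are accepted and the 11-mer set
  is always induced from the core set, the single source of truth.
* **First-position limitation (fpl)** — drops instances whose core does
  not start with an aliphatic or aromatic residue (I, L, M, V, F, W, Y).
  For an 11-long instance the rule is applied at position 2, the
  embedded core's first position, since position 1 is a flank, not a
  pocket anchor; the position is configurable because the convention is
  genuinely ambiguous.  A bag emptied by the filter is embedded as an
  all-sentinel vector (with a message) rather than failing the run; a
  strict error policy is available.
* **SVR hyperparameters** — the libsvm defaults $C = 1$,
  $\gamma = 1/\#\mathrm{features}$, $\varepsilon = 0.1$.  The first two
  are the published configuration; $\varepsilon$ is the libsvm default
  kept explicit and overridable.  No hyperparameter search is performed
  by design.

## Cross-validation and method comparison

`crossValidate()` runs per-allele $k$-fold evaluation (default 5).  The
meta-space is rebuilt from each fold's training bags only, so held-out
instances never enter the feature space; the per-allele AUC is computed
over the pooled out-of-fold predictions against the binder labels, and
the table's average AUC is the unweighted mean across alleles.  Folds
are taken from the input's `fold` column when present, otherwise
generated stratified by binder label within allele (sizes differ by at
most one per stratum, deterministic given the seed).

Two methods are compared with the classic one-tailed sign test:
per-allele AUC wins at full floating precision, ties dropped, and the
exact binomial tail $P(X \ge w_A)$, $X \sim \mathrm{Bin}(w_A + w_B,
\tfrac12)$.  The test-suite oracle enumerates all $2^n$ outcomes for
$n \le 12$.

## The synthetic generator

Real benchmark affinities are not redistributable, so the package ships
a generator (`syntheticConfig()` / `syntheticDataset()`) that emulates
the statistical structure the method assumes: peptides drawn uniformly
over the 20 standard residues (lengths 11–20 by default), a per-position
residue weight table planted at configurable core positions (default
$\{1,4,6,7,9\}$), an optional contribution from the two residues
flanking a window, Gaussian noise, and an offset.  Each 9-mer window
scores its core motif plus its own flanks, the peptide binds through its
best window, and the resulting latent score is clipped to $[0,1]$ and
mapped to nM, so `transformAffinity()` recovers it exactly.  Clipping
(rather than a sigmoid) keeps the affinity map invertible on the
interior.  The default offset of $-0.04$ centres the default tables on a
binder fraction near 40/60, the balance typical of curated MHC-II
benchmarks.

`ablationSuite()` fixes three datasets (train 400 / test 100 each) used
by the end-to-end tests and the acceptance script:

* **A — core-only signal.**  A fixed anchor table: each of the five
  canonical positions favours two high self-score residues (e.g. W, C,
  H, P, Y, F) and penalises two others.  Favourable residues are placed
  on high BLOSUM62 self-score letters deliberately: a shared anchor then
  flips the key-position sum positive, so the planted identity is
  *visible to the distance the method actually uses*.  This choice is
  about detectability, not about imitating real pocket chemistry.
* **B — core + flank signal.**  A weak core (quarter-strength table)
  plus a strong flank term carried by the same high self-score letters.
  Only the 11-long instances span a window's two flanks (10 residues
  apart), so flexible-length bags can represent the joint structure that
  9-mer-only bags cannot.
* **C — pure noise.**  Zero weight tables, offset 0.35, noise SD 0.15:
  affinities independent of sequence with both label classes present,
  for null-behaviour checks.

The suite uses peptide lengths 11–14.  With long peptides the planted
signal becomes recoverable from overall residue composition (any
position subset sees shifted copies of the motif through the sliding
windows); short peptides keep the number of candidate cores small so
that position identity, not composition, carries the signal — which is
exactly the property the ablation contrasts need.

What the generator does *not* emulate: real pocket chemistry,
BLOSUM-correlated residue preferences, experimental assay noise
structure, shared epitopes between alleles, or length distributions of
curated datasets.  Passing the synthetic checks therefore demonstrates
that the implementation recovers the structure it models — not that the
method attains any particular accuracy on real immunological data.

## Numerical choices and degenerate inputs

* Distances and features live in $(0, 1]$; equality comparisons in the
  sign test and AUC win counting use full floating precision, while
  printed tables round half-up to 3 decimals.
* AUC uses the midrank (Mann–Whitney) formulation; tied scores
  contribute $1/2$ per binder/non-binder pair; single-class inputs are
  an error, and alleles whose training split loses a class are skipped
  with a warning.
* With constant training targets libsvm retains no support vectors; the
  decision function is then the constant $-\rho$, which `milPredict()`
  handles explicitly.
* Regressor outputs are clamped to $[0,1]$ before inverting to nM, so
  predicted affinities always lie in $[1, 50000]$.
* All randomness (fold assignment, the generator) flows through
  explicit seeds under a private RNG stream that restores the caller's
  state; command outputs contain no timestamps, making reruns
  byte-identical.

## Problem sizes in the tests

The test suite validates the embedding against a brute-force double loop
on 200 randomized small problems (up to 10 bags, peptide lengths 9–20,
every preset scheme, tolerance $10^{-12}$), and runs the full pipeline
on the 500-peptide suite datasets: null cross-validation over all nine
presets and the two ablation contrasts.  These sizes exercise every code
path at desk scale; larger experiments scale linearly in
(bags × meta-space) distance evaluations, which are computed as blocked
matrix lookups rather than per-pair loops.

## Known limitations

* Allele-specific only; no pan-specific mode, no ensembles, and no
  kernels beyond RBF.
* Instance lengths other than 9 and 11, gapped instances, and learned
  position weights are out of scope.
* Whether the self-distance $\mathrm{dis}(x,x)$ is minimal among all
  comparisons is not asserted: BLOSUM62 off-diagonal pair sums can in
  principle exceed a diagonal sum at another pair, so only the
  min-property of the bag feature is guaranteed.
* The fpl convention for 11-long instances (position 2) is an
  interpretation; it is configurable (`fplCorePos`).
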