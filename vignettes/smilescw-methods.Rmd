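---
title: "Correlation-weight QSAR from SMILES attributes: models, criteria and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation-weight QSAR from SMILES attributes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smilescw)
```

## The model

`smilescw` builds one-descriptor regressions for continuous molecular
endpoints -- the motivating application is acute aquatic toxicity expressed
as pLC50, the negative decadic logarithm of LC50 in mM/L -- directly from
SMILES strings:

$$\mathrm{endpoint} = C_0 + C_1 \cdot DCW(T, N)$$

The *optimal descriptor* $DCW$ of a molecule is the sum of **correlation
weights** over its *SMILES attributes*: every SMILES atom (one symbol or an
inseparable symbol group) contributes its single-atom weight, and every pair
of neighbouring SMILES atoms contributes its pair weight, each occurrence
counted with multiplicity.  The weights are not computed from chemistry;
they are free parameters found by a Monte Carlo hill-climb so that $DCW$
correlates with the endpoint on training data.  The appeal of the approach
is that no molecular descriptors are ever calculated: the features are read
off the SMILES text, and the learned weights are directly interpretable
per structural fragment.

### Tokenization and attribute keys

A SMILES string is split into tokens: single characters, except for
two-letter element symbols (`Cl`, `Br`, `Si`, `Se` by default,
configurable), the chirality mark `@@`, `%` ring-closure labels with two
digits, and entire bracket expressions (`[N+]`, `[C@@H]`, ...), each taken
as one token.  Attributes are serialized as 12-character dotted keys with
4-character fields (`"Cl.........."` for a single atom, `"c...1......."`
for a neighbour pair).  Pair keys are canonical: the two padded fields are
ordered by descending byte value, so the key is independent of reading
direction.  Tokens longer than four characters are hashed to their first
three characters plus `#`; distinct long bracket atoms sharing a 3-character
prefix therefore collide, a deliberate trade-off that keeps the fixed-width
key dialect.  The `.` disconnection symbol is rejected on input because it
is the key padding character; salts must be stripped upstream.

### Rare attributes and blocking

Attributes whose frequency in the active training set is strictly below a
threshold `T` are *blocked*: their weights are frozen at zero and they are
excluded from descriptor sums, the active-attribute count `N_A` and the
applicability domain.  Frequency here means the number of molecules
containing the attribute (presence), not total occurrences; an
occurrence-count mode is available via `attribute_counts(..., "occurrence")`.
The default `T = 5` balances coverage against overfitting to singleton
fragments.  `T = 0` blocks nothing.

## The four-subset protocol

Records are split into four disjoint subsets of roughly a quarter each:

* **active training** -- drives the weight optimization and the final fit;
* **passive training** -- an inspector: its correlation enters the target
  function so the weights cannot overfit the active set alone;
* **calibration** -- steers the predictive-potential criteria (below) and
  the applicability-domain statistics;
* **validation** -- untouched until the model is final.

When the record count is not divisible by four, the leftovers go to the
active and calibration sets (active first).  For 311 records this yields
sizes 79/77/78/77 (A/P/C/V).  `make_splits()` repeats the split with
derived seeds -- five repetitions is the standard protocol -- and re-draws
any split whose validation membership exactly repeats an earlier one.
Validation isolation is structural: `cw_optimize()` accepts only the
active, passive and calibration subsets, so validation data cannot leak
into training through the interface.

## Target functions and the predictive-potential criteria

The base target of the hill-climb is

$$TF_0 = r_{AT} + r_{PT} - |r_{AT} - r_{PT}| \cdot 0.1$$

where $r_{AT}$, $r_{PT}$ are Pearson correlations of endpoint versus $DCW$
on the active and passive training sets.  The absolute-difference penalty
keeps the two training correlations balanced.  Three augmented variants add
a criterion computed on the *calibration* set, using calibration predictions
from the active-set regression, refreshed after every proposal:

$$TF_1 = TF_0 + IIC \cdot 0.3, \qquad
  TF_2 = TF_0 + CII \cdot 0.3, \qquad
  TF_3 = TF_0 + CCCP \cdot 0.3$$

The criteria, for a series of observed/calculated pairs with residuals
$e_i = y_i - \hat y_i$:

* **IIC** (index of ideality of correlation):
  $r \cdot \min(MAE^-, MAE^+) / \max(MAE^-, MAE^+)$, where $MAE^-$ averages
  $|e_i|$ over negative residuals and $MAE^+$ over non-negative ones.  It
  rewards residual symmetry on top of correlation.  If either class is
  empty -- including the degenerate exact fit, whose zero residuals all land
  in the $\ge 0$ class -- the index is 0 by convention.
* **CII** (correlation intensity index):
  $1 - \sum_k \max(0, R^2_{-k} - R^2)$, with $R^2_{-k}$ the determination
  coefficient after removing point $k$.  Points whose removal raises $R^2$
  are *opponents* of the correlation; only their protests lower the index.
* **CCCP** (coefficient of conformism of correlation prediction):
  $(n_{supporters} - n_{opponents})/n$, classifying each point by whether
  its removal lowers ($R^2_{-k} < R^2$, supporter) or raises (opponent) the
  determination coefficient.  It weighs both sides where CII hears only the
  opponents.

The coefficients 0.1 and 0.3 are plain configuration values
(`tf_config()`); their selection in this methodology is empirical, and no
search over them is built in.  The leave-one-out quantities are computed by
downdating the five running sums, so a criterion evaluation is $O(n)$, and
the implementation is cross-checked in the test suite against a naive
refit-per-point oracle.

A note on expectations: steering with a calibration-set criterion is a
trade.  It can buy robustness when the calibration set is statistically
closer to future data than the training sets are; on data with no such
shift (including this package's synthetic fixtures, whose endpoint is an
exactly additive function of the attributes) the plain $TF_0$ typically
fits and validates better.  The package reports both and takes no side.

## The optimizer

A deliberately plain accept-if-not-worse Monte Carlo: weights start at 1.0
for every non-blocked attribute (so the initial descriptor is an attribute
count; uniform random initialization is available), and each of `N` epochs
visits every non-blocked attribute once in seeded-random order, proposing
`CW' = CW + step_size * u` with `u ~ U(-1, 1)`.  A proposal is kept iff the
target function does not decrease; ties are accepted so the search can
drift across plateaus.  Proposals that make a statistic undefined (constant
descriptor on a subset, degenerate criterion series) are rejected.  There
is no annealing, no temperature, no gradient -- determinism for a fixed
seed and auditability were preferred over search sophistication.

Defaults: `N = 15` epochs, `T = 5`, `step_size = 0.6`.  The step size was
chosen by a convergence study on the reference fixture below: with one
proposal per attribute per epoch, the total drift available to a weight is
bounded by `N * step_size`, so steps much below ~0.3 cannot move a weight
from its 1.0 start across the typical fitted range within 15 epochs (step
0.1 plateaued near validation $R^2 \approx 0.27$; step 0.6 reaches
0.91-0.96 on the same data).  Larger steps lower the acceptance rate
without improving the optimum materially.

## Applicability domain

For every attribute $A_k$ the *statistical defect*

$$d_k = \frac{|P - P'|}{N + N'} + \frac{|P - P''|}{N + N''} +
        \frac{|P' - P''|}{N' + N''}$$

measures prevalence disagreement between the active training ($P$, $N$),
passive training ($P'$, $N'$) and calibration ($P''$, $N''$) subsets
(prevalence = fraction of molecules containing the attribute; an addend
with zero frequency sum contributes nothing).  A molecule's defect $D_j$
sums $d_k$ over its *distinct* non-blocked attributes, and it is in the
applicability domain iff $D_j < 2\bar D$, where $\bar D$ is the mean
molecular defect of the active training set -- the only subset guaranteed
present at deployment.  The boundary is strict: $D_j = 2\bar D$ is out.
The numerators are absolute differences; without the bars the "defect"
could be negative, which contradicts its role as a penalty.

## Mechanistic interpretation

Because the optimizer is stochastic, a single run's weight signs are not
evidence.  `run_probes()` repeats the optimization with derived seeds, and
`classify_attributes()` calls an attribute a *promoter of endpoint
increase* only if its weight is positive in every probe, a *promoter of
decrease* only if negative in every probe, and *unclear* otherwise -- an
exact zero in any probe is unclear under the strict sign rule.
Interpretation tables order the increase block first, then decrease, then
unclear, by active-training frequency within each block.

## The synthetic fixture generator

No public reference dataset ships with the package, so validation runs on
synthetic token strings with a known additive ground truth
(`fixture_spec()` / `generate_dataset()`).  Each molecule is a seeded
random string over a small vocabulary, with parentheses and ring digits
emitted only in matched pairs so tokenization round-trips; each endpoint is
`c0 + c1 * sum(true attribute weights) + N(0, noise_sd)`.  The reference
conditions (`default_fixture_spec()`) are 400 molecules over the 10-token
vocabulary `C c N O Cl S = 1 ( )`, 8-20 free tokens per molecule, noise
0.2 on the endpoint scale, and fixed ground-truth weights in `[-1, 1]`
whose signs echo aquatic-toxicity chemistry (halogens, sulfur, aromatic
carbon and unsaturation raise the endpoint; nitrogen, oxygen, branching
lower it).  The endpoint scale that results (sd around 2.8) is of the
order of a pLC50 range.

What the generator *does* emulate: the attribute algebra, rare-attribute
blocking, subset prevalence imbalance (via `perturb_split()`, which
redistributes an attribute's carriers across subsets to any target
imbalance), and noisy linear structure.  What it does *not* emulate: real
chemical co-occurrence structure, nonlinearity, activity cliffs, or
measurement error correlated with structure.  Passing the recovery
experiments therefore demonstrates correctness of the machinery and
identifiability under the model's own assumptions -- not predictive power
on real pesticide data.

## Numerical and degenerate-case choices

* Residuals are `observed - calculated` everywhere.
* Correlation statistics on a constant series raise an error rather than
  return `NA`; inside the optimizer such proposals are simply rejected.
* The concordance correlation coefficient uses population (1/n) moments;
  two identical constant series score 1.
* `Q^2` is leave-one-out, via the exact hat-value identity.
* A perfect correlation makes the F-ratio infinite (flagged with a
  warning).
* Leave-one-out removals that leave a constant series contribute zero
  protest (CII) and no vote (CCCP).
* Ties in the hill-climb are accepted; ties in the supporter/opponent
  classification count to neither side.
* Model files store doubles with 17 significant digits, so a re-loaded
  model predicts bit-exactly.

## Problem sizes used in the checks

The packaged tests and the acceptance script run entirely on generated
data at modest sizes chosen to exercise every code path with comfortable
statistical margins: criterion oracles on 200 random series of length
5-15; descriptor oracles on 50 molecules; recovery and interpretation on
the 400-molecule reference fixture with five splits and three probes.  A
full acceptance run completes in well under a minute on one CPU.

## Known limitations

* The IIC/CII/CCCP formulas implemented here are the package's own
  definitions of these criteria (documented above and enforced by oracle
  tests); other software in this family may differ in detail, so
  cross-package numerical agreement should not be assumed without checking.
* The 4-character key fields truncate long bracket atoms (hash collisions
  are possible, see above).
* The optimizer is a local search; different seeds give different weight
  tables, which is why all interpretation is multi-probe.
* SMILES with disconnections (`.`) are rejected rather than handled.
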