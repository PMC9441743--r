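---
title: "Causal analysis of the brain age gap: models, assumptions, and design choices"
author: "bagnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal analysis of the brain age gap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bagnet)
```

# The problem

The brain age gap (BAG) — the difference between a machine-learning
estimate of biological brain age and chronological age — is a candidate
biomarker for accelerated brain aging. Cardiovascular risk factors
(obesity markers, blood pressure, smoking, alcohol use) correlate with the
BAG, but they also correlate with each other and with sex, so univariate
associations mix direct effects with confounded ones. `bagnet` implements
a complete causal-modelling alternative: learn a directed acyclic graph
over the variables under domain constraints, fit a discrete Bayesian
network on it, and contrast *observational* conditionals
$P(\mathrm{BAG} \mid X = x)$ with *interventional* ones
$P(\mathrm{BAG} \mid do(X = x))$.

Real cohorts of this kind are restricted-access, so the package is built
around a synthetic-cohort generator with known ground truth. Everything
downstream is therefore testable: structure recovery against the
generating graph, parameter recovery against the generating tables, and
inference against brute-force enumeration.

# The synthetic generator

`generate_scm_cohort()` samples a structural causal model ancestrally
(each node after its parents). Continuous mechanisms are linear-Gaussian;
categorical mechanisms are conditional probability tables; a categorical
node with continuous parents discretizes them on the fly with the same
clinical scheme the network later uses, so generator and analysis share
one categorization.

`default_study_scm()` encodes the study template: `sex` and `age` are
roots, waist-to-hip ratio (WHR) is an exogenous obesity marker,
`sex -> {BMI, BP, smoking, drinking}`, `WHR -> {BMI, BP}`, and
`{BMI, WHR, smoking, drinking} -> BAG`. No edge enters age or sex and none
leaves BAG. Two parameterizations exist, both fixed:

* **realistic** (the default): marginals loosely matched to published
  cohort demographics — BMI ≈ 27.4 (SD ≈ 4) kg/m², systolic BP ≈ 127
  (SD ≈ 15) mmHg, WHR ≈ 0.88 (SD 0.07), sex-specific smoking/drinking
  frequencies, age uniform on [21, 82] years (the published range; the
  uniform shape is a simplification chosen for transparency), and a BAG
  with SD ≈ 4 years centred at zero so the three BAG categories at ±3
  years are roughly balanced. Standardized causal effects are modest
  (0.15–0.45 SD), as in real epidemiology — which means, deliberately,
  that at n ≈ 2000 some true edges sit at the detection boundary.
* **strong**: the same graph with effects of ~0.8–1.2 "normal-band
  widths" and equal noise scale across mechanisms. This is the regime for
  structure-recovery experiments (see below); it trades marginal realism
  for identifiability.

The morphometric table (`generate_morphometrics()`) is 223 features, each
affine in a subject-level aging signal plus independent Gaussian noise.
Defaults (slopes spread over ±1.5/year, noise SD 5) make age recoverable
from the joint features while no single feature is a clean proxy. Real
morphometry's covariance structure, site effects and nonlinearity in age
are *not* emulated — so passing tests demonstrate the pipeline's
correctness, not transfer to real MRI. In the full pipeline the aging
signal defaults to *effective brain age* (chronological age plus the
generating model's true BAG), so the BAG computed by the regression stage
carries the simulated risk-factor signal downstream; features driven by
chronological age only are available via `morph_on_brain_age = FALSE` (in
that limit every computed BAG is "normal" and the BAG node degenerates,
which the validation stage reports as `NA` rather than failing).

Default cohort size is 2025 and the default seed 20220822; both are
recorded with every run.

# Brain-age stage

The regressor is a feed-forward network (ReLU hidden layers, linear
output) with the four candidate architectures (256), (256, 128),
(256, 128, 64), (256, 128, 64, 32); `select_architecture()` picks by
lowest cross-validated MAE with ties broken toward fewer parameters.
Training is full-batch Adam (default learning rate 0.01, at most 500
epochs) with early stopping (patience 20) on the MAE of an age-stratified
15% validation split; inputs are z-scored with training-fold statistics
only. Folds are age-stratified by decile binning followed by a seeded
round-robin deal; bin members are age-sorted before the shuffle so the
partition does not depend on input order (up to exact age ties).

Brain-age models overpredict young and underpredict old subjects
(regression toward the mean). Per CV iteration, the bias line
$\widehat{\mathrm{pred}} = \alpha\,\mathrm{age} + \beta$ is fitted on the
*validation* predictions and applied to the test fold as
$\mathrm{corrected} = \mathrm{pred} + [\mathrm{age} - (\alpha\,\mathrm{age} + \beta)]$,
so the correction never sees the data it corrects. The BAG is
corrected-minus-chronological age: positive = accelerated. The sign
convention is fixed throughout the package.

# Discretization

Fixed clinical cut-offs, not data-driven bins: BMI (25, 30), BP
(120, 140), WHR male (0.95, 1) / female (0.8, 0.85), age (35, 65), BAG
(−3, 3). Category codes are always ordered 0 = low, 1 = normal, 2 = high,
which is what makes edge-sign classification well defined. The boundary
convention is open outer bins: a value exactly at an edge falls in the
closed middle ("normal") interval. Values at an edge are a measure-zero
event for continuous data; the convention is documented rather than
empirically consequential.

# Structure discovery

`learn_weighted_adjacency()` is the continuous-optimization formulation of
DAG learning: minimize $\frac{1}{2n}\|X - XW\|_F^2 + \lambda\|W\|_1$
subject to $h(W) = \mathrm{tr}\,e^{W \circ W} - d = 0$. The augmented
Lagrangian starts at $\rho = 1$, multiplies by 10 whenever $h$ fails to
shrink to a quarter of its previous value, caps $\rho$ at $10^{16}$, runs
at most 100 dual iterations, and declares convergence at
$h \le 10^{-8}$; failure raises an explicit error carrying the final $h$.
The inner problem is solved by L-BFGS-B on the positive/negative split
$W = W^+ - W^-$, which makes the L1 term smooth on the orthant.
Domain constraints (nothing into age/sex, nothing out of BAG, no
obesity/BP edges into behaviour) are enforced by *excluding* those entries
from the parameter vector: they are exactly zero at every iterate, not
merely penalized. Default $\lambda = 0.1$; the candidate pruning grid is
{0.05, 0.1, 0.15, 0.2, 0.3}.

**Variable encoding.** Sex stays {0, 1} and smoking/drinking stay ordinal
{0, 1, 2}. Continuous variables are divided by fixed clinical constants —
the width of each variable's "normal" band (BMI/5, BP/20, WHR/0.05,
age/30, BAG/6) — rather than z-scored. This was a deliberate design
decision after measurement: with per-column empirical standardization,
every marginal variance is 1 and the least-squares score
$\sum_i (1 - R^2_i)$ of a linear-Gaussian system is invariant under edge
reversal, so orientation information is provably absent and recovery
collapses to near-chance. Fixed unit constants bring the columns to
comparable numeric ranges (a prerequisite for a meaningful common
$\lambda$) while preserving the cause-to-effect variance ordering that
least-squares discovery exploits. Empirical z-scoring remains available
(`encode_for_structure_learning(..., scaling = "unit_sd")`) for
sensitivity analyses.

The **strong** generator parameterization is designed on that clinical
scale to satisfy the equal-noise-variance condition under which the true
DAG is the least-squares optimum: all mechanism noise SDs ≈ 1 band width.
Under those conditions, constrained learning plus pruning at 0.15
recovers the generating graph with structural Hamming distance ≤ 2 (in
practice 0) at n = 2000. Under the realistic parameterization the same
procedure finds only the strongest edges — an honest reflection of
weak-signal epidemiology, not a failure mode.

The pruning threshold for the full pipeline is not fixed a priori: for
each candidate the pruned DAG is fitted and validated by cross-validated
node AUC, and the candidate maximizing the unweighted mean of (average
node AUC, BAG-node AUC) wins, ties toward the sparser graph. The
bi-objective is scalarized as a plain mean because no other weighting is
obviously better; the per-candidate report is returned so users can apply
their own criterion.

# Bayesian network

CPDs are Dirichlet posterior means with a default pseudo-count of 1 per
cell (uniform prior): $(n_{x|u} + 1)/(n_u + r)$ for a node with $r$
states. Unseen parent configurations yield the uniform row; with
pseudo-count 0 they raise an error instead of silently producing NaNs.

Inference is exact variable elimination with a greedy min-width
elimination order; correctness is order-independent and the test suite
checks it against full-joint enumeration (at 8 ternary nodes, 6561
terms). Zero-probability evidence raises an explicit error.

Validation follows the repeated cross-validation design: per repetition a
fresh k-fold split, per fold refit CPDs on the training folds and predict
every node for held-out subjects from all other variables (the Markov
blanket product, which equals the full conditional exactly and is
vectorized for speed — and is itself tested against variable
elimination). The AUC per node and repetition is macro one-vs-rest,
pooled over that repetition's test folds; means and SDs are reported over
repetitions. Macro averaging was chosen for robustness to class
imbalance; the per-state AUCs are computed with `pROC` with a fixed
comparison direction so results are deterministic.

# Causal queries

`intervene()` implements $do(X = x)$ by graph mutilation: incoming edges
of $X$ removed, its CPD replaced by a point mass, everything else
untouched. For point interventions on a fully specified discrete model
this is equivalent to symbolic do-calculus, and it is directly testable:
the suite verifies interventional distributions against the backdoor
adjustment $\sum_z P(Y \mid X = x, Z = z)\,P(z)$ and against truncated
factorization by enumeration, and verifies that for parentless nodes
observation and intervention coincide to machine precision.

Edge signs reproduce the usual network-figure annotation: for edge
$P \to C$, compute the expected child code
$m(s) = \sum_c c\,P(C = c \mid P = s)$ over ascending parent states,
marginalizing the child's other parents. Monotone increasing ⇒ positive,
monotone decreasing ⇒ negative, anything else ⇒ nonlinear (a flat profile
is additionally flagged `zero_effect`). The qualitative notion of a
"non-linear association" has no unique quantitative definition; the
monotonicity rule is this package's documented operationalization.

# Problem sizes

The shipped test suite and acceptance script use sizes chosen to make
every statistical check well-powered yet quick on a laptop: cohorts of
300–2000 for regression checks, 2000 per seed (5 seeds) for structure
recovery, 5000 for AUC sanity checks, 50,000 for CPT convergence, and the
full pipeline at the default n = 2025 in `scripts/acceptance.R`. The
brain-age stage in the acceptance run caps training at 200 epochs with
patience 20; early stopping typically ends training far earlier.

# A small end-to-end run

```{r pipeline, eval = FALSE}
st <- run_study_pipeline(n = 1500, seed = 42, k = 5,
                         scm = default_study_scm("strong"),
                         config = regressor_config(max_epochs = 150),
                         cv_select = list(repeats = 2),
                         cv_final = list(k = 10, repeats = 5))
print(st)
print(st$ovi[["BMI"]])        # observation vs intervention on BAG
plot(st$ovi[["BMI"]])         # solid = observe, dashed = intervene
export_dot(st$dag, "network.dot", signs = st$edge_signs)
```

# Known limitations

* The generator's linear-Gaussian mechanisms cannot produce genuinely
  nonlinear (V-shaped) risk-factor effects, so the `nonlinear` edge label
  is exercised on constructed tables in the tests, not on simulated
  cohorts.
* Least-squares structure discovery depends on the variance ordering of
  the data scale; conclusions about edge *orientation* between variables
  measured on arbitrary scales should be treated as a modelling choice,
  constrained by the domain knowledge edges, not as proven causal fact.
* AUC-based threshold selection evaluates the discretized network, so
  information lost to discretization also shapes the selected structure.
* No counterfactual (twin-network) queries and no identification analysis
  for partially observed graphs: the model is fully specified by
  construction, which is exactly what the synthetic setting provides.
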