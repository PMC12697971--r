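---
title: "Hybrid filter-wrapper feature selection: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid filter-wrapper feature selection: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmfw)
```

## The problem

Omics classification tasks — tumour versus normal from a microarray, disease
subtype from a proteome — typically offer 60–260 samples against 2,000–25,000
features. Most features are noise, informative features travel with correlated
redundant copies (co-regulated genes, probe duplicates), and a classifier
wants a subset that is simultaneously *accurate* and *short*. `hmfw`
implements a dual-module hybrid selector for this regime:

1. **Pre-screen (module M1).** A random forest is grown on the full
   normalized matrix and features are ranked by mean impurity decrease; the
   top $K_1$ (typically hundreds) survive. Impurity importance handles
   nonlinear feature–label relationships without distributional assumptions,
   and cuts the search space by an order of magnitude before anything
   expensive runs.

2. **Bivariate filter (mSMMI).** From the pre-screened pool a greedy
   procedure picks $K_2$ features (typically tens) maximizing
   $s \cdot MI(L, f) - y \cdot mS(f)$, where $MI$ is plug-in mutual
   information between feature and label (natural log) and $mS$ is the
   candidate's minimum Spearman coefficient against the already-selected set —
   the relevance/redundancy trade-off familiar from mRMR, but with
   iteration-dependent weights $s = \cos((i/I)\,\pi/2)$,
   $y = \sin((i/I)\,\pi/2)$: early episodes emphasize relevance, late
   episodes emphasize diversity ($s^2 + y^2 = 1$ throughout).

3. **Wrapper (HGW-CDBW).** Binary grey-wolf search over masks of the $K_2$
   candidates. Continuous positions in a box $[l, u]$ are binarized against
   the *median of their own components*, so a mask is never empty and never
   full; fitness is cross-validated SVM (RBF) accuracy with grid-searched
   $C, \gamma$, compared lexicographically (accuracy first, subset length as
   tie-break, then indices for determinism). Each iteration, a small chaotic
   dung-beetle swarm refines the three pack leaders with the logarithmic
   forager step $x' = x + \delta\,\mathrm{sign}(x_{best}-x)\log(1+|x_{best}-x|)$,
   $\delta$ drawn from a per-beetle logistic map $x \mapsto 3.9\,x(1-x)$;
   non-leaders then move to the mean of the three leader-guided grey-wolf
   candidates with convergence factor $a = 2(1 - t/T)$.

4. **Controller (POM).** The best fitness per iteration feeds an
   *average improvement rate* $AIR = \frac{1}{N-1}\sum (f_{i+1}-f_i)/f_i$
   computed over the history since the last restart. Stagnation events
   (AIR dropping, or non-positive) increment a counter (CAD); when CAD
   exceeds the active patience threshold, the filter re-runs with the
   current $s/y$ weights, the population re-initializes chaotically over the
   new candidates, and CAD resets. The thresholds come from the local extrema
   of a sum-of-sines intensity model
   $I(t) = I_0 + \sum_i A_i \sin(2\pi f_i t + \phi_i)$ with
   $A = (2.743, 1.372, 0.914)$, $f = (0.1, 0.2, 0.4)$, $\phi = 0$: the
   absolute deviations $|I - I_0|$ at the extrema over one fundamental period
   (10 time units) are affinely mapped to integers in
   $[\mathrm{patience}_{\min}, \mathrm{patience}_{\max}]$. Extremum control
   walks a cursor over these thresholds — sustained AIR increases raise the
   patience (let a productive search run), sustained non-positive AIR lowers
   it (end a stuck episode sooner). The global best mask is archived outside
   the population, so the reported result is monotone across restarts, and
   the wrapper-iteration budget $T$ is global: restarts never extend a run.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `population` | 30 | grey-wolf pack size |
| `iterations` | 100 | global wrapper budget $T$ (shared across restarts) |
| `beetle_swarm`, `beetle_steps` | 10, 5 | dung-beetle refinement effort per leader per iteration |
| `bounds` | draw | box: $l \sim U[-1,-0.3]$, $u \sim U[0.3,1]$ per run |
| `seed_param` | 3.9 | logistic-map parameter, chaotic regime of (3,4) |
| `budget` | see below | stochastic $K_1/K_2$ formula parameters |
| `cv$k` | 10 | fitness CV folds |
| `c_grid`, `gamma_grid` | $2^{-2..8}$, $2^{-8..2}$ (steps of $2^2$) | SVM grid |
| `patience_min/max` | 3, 12 | range of the extrema-derived thresholds |
| `ec_up`, `ec_down` | 3, 2 | streak lengths for extremum control |
| `rf_trees` | 500 | pre-screen forest size |

The feature budgets follow
$K = \mathrm{RandnumA} + (f \cdot \mathrm{rand}()/e)\cos(p \cdot e)$ with $f$
features, $e$ samples, $\mathrm{rand}() \in (1, 10)$, $p = 0.8$;
$\mathrm{RandnumA} \sim U[10, 20]$ for $K_2$ and ten times that for $K_1$,
rounded and clamped to $[k_{\min}, \lceil k_{\max\text{-}fraction} \cdot
\text{available}\rceil]$ (defaults 5 and 1.0). The grouping of the formula and
the baseline ranges are design choices: the cosine argument and the ranges of
$\mathrm{rand}()$ and $p$ are fixed by the method's definition, the rest is
chosen so that typical budgets land in the low hundreds for $K_1$ and the
tens for $K_2$ on datasets of this shape. Note the cosine makes the raw value
strongly negative for some sample counts (e.g. $e = 60$, where
$\cos(48) \approx -0.64$); the clamp then yields $k_{\min}$, which is
intended — budgets react to dataset geometry.

## Numerical choices and conventions

* **Logarithm bases.** Mutual information uses the *natural* log — the
  method's worked examples (1.609 on a 5-point deterministic pair, i.e.
  $\ln 5$; 0.673 on a 3/2-split pair) admit no other base. Entropy and
  information gain in the forest pre-screen context use base 2, as is
  conventional for impurity screens. Both are implemented as defined and
  pinned by tests.
* **MI estimator.** Default for scoring real expression data is equal-width
  discretization into 10 bins; the distinct-value plug-in estimator (each
  unique value its own category) is what reproduces the worked examples and
  remains available via `mi_mode = "distinct"`. Distinct-value binning
  degenerates on continuous data — every feature ties at the label entropy —
  which is why it is not the scoring default.
* **Spearman.** Average ranks for ties, then the printed formula
  $1 - 6\sum d^2/(n(n^2-1))$ *without* tie correction: only this combination
  reproduces the documented 0.384 example. On tie-free data it coincides with
  the Pearson correlation of ranks (property-tested at $10^{-12}$).
* **Binarization.** A wolf's own component median is the threshold
  (`>` strictly). The alternative literal reading — comparing fresh random
  numbers to the median — would make selection independent of position and
  cannot express the documented never-empty/never-full guarantee. Measure-zero
  tie cases are handled: if nothing strictly exceeds the median, the maximal
  components are selected; a constant vector selects the
  $\lceil J/2 \rceil$ lowest-index features.
* **Tie-breaks.** Everywhere, the lowest feature index wins (filter argmax,
  fitness comparison, grid search prefers smaller $C$ then $\gamma$). This
  makes entire runs reproducible from one master seed: the seed fans out to
  the budget draws, the forest, one CV split per run, and per-agent chaos
  streams.
* **Boundary handling.** Positions are clipped to the box after both
  grey-wolf and dung-beetle updates.
* **Beetle start scatter.** Beetles start at the leader perturbed
  componentwise by $(\delta - 0.5)(u - l)/5$ with $\delta$ one chaotic draw —
  the method fixes the existence of this perturbation but not its scale; a
  fifth of the box keeps refinement local to the leader.
* **CAD semantics.** A stagnation event is counted when AIR drops relative to
  the previous value *or* is non-positive; counting is cumulative since the
  last restart. Counting only strict AIR decreases would make a perfectly
  flat (fully stagnant) episode unable to trigger a restart.
* **Mean intensity $I_0$.** Only deviations $|I - I_0|$ enter the schedule,
  so $I_0$ is an arbitrary positive level (default 10).
* **Extrema count.** The schedule derives the number of extrema numerically
  from the configured waves (verified against a derivative sign-change
  oracle) rather than hard-coding a count; an explicit integer threshold list
  can override the whole schedule.
* **Fitness caching.** Grid search per mask is memoised, keyed by the sorted
  feature-index tuple; the cache is sound because one run uses one fold split.

## The synthetic-data generator

`generate_synthetic_omics()` emulates the target regime: $n$ samples in 2–5
near-balanced classes, informative features with class means separated by
`class_separation` $\times$ `noise_sd`, redundant copies built as
$\rho \cdot z(\mathrm{parent}) + \sqrt{1-\rho^2} \cdot \varepsilon$ (so the
parent–copy correlation is $\approx \rho$ by construction), all remaining
features i.i.d. Gaussian noise, and a seeded column permutation so planted
features carry no positional signal. Defaults (60 samples, 2,000 features, 10
informative, 2 redundant copies each, separation 2, $\rho = 0.8$) mirror the
small-cohort microarray shape.

What it does *not* emulate: heavy-tailed and heteroscedastic expression
distributions, correlated noise blocks and batch effects, class imbalance,
and probe-level artefacts. Tests passing on this generator therefore
demonstrate algorithmic correctness (recovery of planted structure,
determinism, monotonicity), not expected accuracy on any particular public
benchmark.

## Problem sizes used in the tests

The shipped tests and the reduced-budget recovery study run the pipeline at
desk scale, the package's own choice for routine verification: population 10,
$T = 20$, 5-fold CV, a $2 \times 2$ SVM grid ($C \in \{1, 16\}$,
$\gamma \in \{2^{-4}, 2^{-1}\}$), beetle swarm 5 with 2 steps, and a
300-tree pre-screen, on $60 \times 2000$ synthetic data. A single such run
takes a few seconds; the full default protocol (population 30, $T = 100$,
10-fold CV, $6 \times 6$ grid, 10 repeats) is what one would use on a real
dataset.

```{r example, eval = FALSE}
spec <- synthetic_spec(n_samples = 60, n_features = 2000, n_informative = 10,
                       n_redundant_per_informative = 2, class_separation = 2,
                       seed = 101)
ds <- generate_synthetic_omics(spec)
ctl <- hmfw_control(population = 10, iterations = 20, beetle_swarm = 5,
                    beetle_steps = 2,
                    cv = cv_config(k = 5, c_grid = c(1, 16),
                                   gamma_grid = c(2^-4, 2^-1)),
                    rf_trees = 300)
fit <- hmfw(ds, control = ctl, seed = 101)
fit
recovery_eval(fit, attr(ds, "planted"))
```

## Known limitations

* The flat CV protocol tunes the SVM on the folds it reports, as in the
  method's standard evaluation; accuracy estimates are optimistic. The
  nested protocol (`cv_config(nested = TRUE)`) is the honest alternative and
  fits normalization and tuning strictly inside training folds
  (instrumentation-tested), at `k`-fold extra cost.
* Budgets $K_1, K_2$ are stochastic by design; two seeds can search candidate
  pools of quite different sizes on the same data.
* The wrapper's cost is dominated by fitness evaluations
  ($O(\text{pop} + 3 \cdot \text{beetles} \cdot \text{steps})$ grid-searched
  CV fits per iteration, minus cache hits); with the default grids this is
  only practical because masks repeat heavily late in a run.
* With very small sample counts the budget clamp can pin $K_2$ at `k_min`,
  making the final subsets very short; raise `k_min` if longer signatures
  are wanted.
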