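---
title: "Testing origin hypotheses for butterfly eyespots and their gene network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing origin hypotheses for butterfly eyespots and their gene network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eyespots)
```

This vignette is the package's methods account: the models it fits, the
assumptions they carry, the tunable parameters and why their defaults are
what they are, what the synthetic-data generators do and do not emulate,
and the numerical choices made where the design was genuinely open.

## 1. The scientific problem

Nymphalid eyespots are a candidate evolutionary novelty: a ringed wing
pattern whose development involves a network of genes (*Antp*, *sal*,
*Notch*, *en*, *Dll*, among others) expressed in the future eyespot center
of the larval wing disc. Homology of eyespots across the family is an
empirical question with three testable components:

1. **Origins on the phylogeny.** How many independent gains of eyespots
   (and of each gene's focal expression) does a time-calibrated phylogeny
   support?
2. **Temporal conservation.** Is the order in which the genes switch on
   during wing-disc development conserved across species?
3. **Network vs trait complexity.** Do species expressing more of the
   surveyed genes build eyespots with more color rings?

Each component gets one estimator in this package, plus a molecular-clock
utility for dating species pairs absent from the reference chronogram.

## 2. The asymmetric two-rate trait model

`fit_mk2()` fits a two-state continuous-time Markov chain with distinct
gain (0→1) and loss (1→0) rates, both per million years. Asymmetry matters
here: losses of gene expression are expected to be much easier than gains,
and forcing one symmetric rate would bias reconstructions toward extra
origins. The chain's transition probabilities are closed-form
(`mk2_transition_matrix()`), so the pruning likelihood needs no numerical
exponentials.

Assumptions worth stating: rates are homogeneous across lineages and time;
the tree (topology and branch lengths in MY) is known without error;
character states are scored without error; tips with unavailable data are
missing at random (they enter as partial likelihoods (1,1)). Polytomies are
treated as hard — the likelihood simply products over all children.

**Root prior.** The likelihood at the root must be weighted by a prior on
the root state. The default is the stationary distribution of the fitted
chain, which makes the likelihood invariant to the root position (the
two-state chain is reversible); `"equal"` and fixed-state priors are
exposed because reference implementations differ in this choice and it is
the usual source of small log-likelihood discrepancies between programs.
With the asymmetric fit the stationary prior is also self-consistent: a
trait with rare gains gets a root prior concentrated on absence.

**Optimization.** The likelihood is maximized over (log gain, log loss)
with L-BFGS-B, rates bounded in [1e-8, 1e3] per MY. Surfaces for rare
gains are flat and can be multimodal, so `n_restarts = 5` starting points
are used: one data-driven heuristic (about one event per minority-state
tip over the total tree length) plus random log-normal perturbations,
deterministic under `seed`. Boundary behavior is expected and allowed for
monomorphic characters (the gain rate pins at its lower bound when no tip
shows the derived state).

**Ancestral states.** `predict()` on a fit returns marginal posteriors from
the up–down algorithm; each node's value provably equals the ratio of the
two node-fixed likelihoods, and the test suite checks that identity to
1e-9 at every node of random trees. A state is *called* at a node only
when its marginal reaches 0.5 plus a 1e-9 tie band; exact ties are
reported as ambiguous, never silently broken, and `count_origins()` then
returns an interval over the tied nodes' assignments.

## 3. Origin hypotheses as node constraints

`evaluate_origin_models()` encodes each origin-number hypothesis as a set
of ancestral nodes fixed to presence or absence. Fixing is conditioning:
the disallowed state's partial likelihood is zeroed at that node before
pruning continues — not a soft prior. Two design choices deserve note:

- **Rates are re-optimized per model** (default). The alternative —
  scoring all models at the unconstrained ML rates — is exposed as
  `shared_rates = TRUE`, because which convention the reference analyses
  used is not documented. Re-optimizing is conservative: it gives every
  hypothesis its best shot.
- **The two-log-unit rule.** Models are rejected when their lnL falls ≥ 2
  units below the best model. A χ² likelihood-ratio test would be wrong
  here: competing hypotheses differ in node constraints, not parameter
  count, so the standard asymptotics do not apply. The fixed 2-unit
  criterion (roughly a ΔAIC of 4 between equally-parameterized models) is
  implemented verbatim, with the `>=` boundary exact.

Nodes in constraint files are addressed as `"tipA|tipB"` — the MRCA of two
named tips — because figure-position node labels do not transfer between
tree ladderizations. A root reconstructed in state 1 is reported as an
origin on the root stem (the gain predates the root), separately from the
0→1 edge count.

## 4. The expression-onset δ test

For each gene within a species, focal expression (0/1) is regressed on
developmental stage (an ordered continuous covariate in arbitrary units)
by maximum-likelihood logistic regression, pooling wing compartments.
δ is the absolute difference in the areas under two genes' curves over the
pooled observed stage range; when both curves saturate inside the range, δ
is simply the onset shift in stage units. The area is analytic
(a softplus difference, `curve_auc()`), checked against adaptive
quadrature to 1e-8.

The null — both genes share one curve — is materialized by the mixed
bootstrap: pseudo-gene A\* draws ⌊n_A/2⌋ observations (with replacement)
from gene A and the remainder from gene B, and B\* conversely, preserving
each gene's sampling effort; 10,000 replicates is the reference effort.
The p-value uses the add-one estimator (r+1)/(B+1), so it is never exactly
zero and equals 1 exactly when δ_obs = 0. Odd sample sizes put the extra
observation in the second source (⌊n/2⌋ from the first), a convention the
original description leaves open. Whether δ was originally signed is also
unstated; the absolute value is used, which is what makes the one-sided
bootstrap comparison coherent.

**Perfect separation.** Sparse stage designs regularly separate, driving
the ML slope to infinity. The slope is capped at |b| = 50 with the fitted
midpoint retained: once a curve saturates within the integration range the
area is insensitive to the slope, so the cap stabilizes δ without biasing
it. Degenerate resamples (one outcome class, or one distinct stage) return
flagged boundary curves rather than failing, so bootstrap replicates stay
scoreable; genuinely unfittable replicates are redrawn and counted, and
more than 50% redraws aborts with advice to collect larger samples.

**Calibration and design.** The bootstrap resamples rows without regard to
stage. When observations arrive with random stages — the realistic case:
wing discs are dissected at whatever stage they happen to be — the scheme
is calibrated: with 60 discs per gene at stages uniform on the sampled
range, the measured type-I error is ~0.04–0.06 at α = 0.05. Under an
*exactly* stage-balanced design (identical fixed counts at every stage)
the unstratified resampling overstates the null variance and the test
becomes conservative at small n (type-I ~0.01 at n = 60, vanishing by
n ≈ 250). This is a known limitation of the method, not of the
implementation; calibration tests here therefore use the random-stage
design. Stars in reports follow the convention \*\*\* p < 0.0001,
\*\* p < 0.01, \* p < 0.05, ns.

## 5. Molecular clock

`percent_divergence()` is the uncorrected p-distance × 100 over comparable
sites (both sequences unambiguous A/C/G/T; gaps and IUPAC codes excluded
from numerator and denominator), requiring ≥ 100 comparable sites. Species
represented by several sequences are compared by the equal-weight average
over all between-species pairs. `divergence_time()` divides by a clock
rate, default 2.3% per MY — the standard arthropod mitochondrial COI rate —
and reports two decimals (5.45% → 2.37 MY; 5.71% → 2.48 MY). No
multiple-hit correction is applied: the linear rule is what reproduces the
reference conversions exactly, and at divergences of a few percent the
correction would be smaller than the clock rate's own uncertainty.

## 6. Complexity regression

`complexity_regression()` is deliberately plain OLS with an F(1, n−2)
test — the question is a simple association between gene count and ring
count across species, and with fewer than ten species anything richer
(e.g. phylogenetic GLS) would be over-modeling. Collinear records are
reported as R² = 1 with an unbounded F rather than an error.

## 7. Synthetic data: what it does and does not emulate

All generators return their ground truth and are bit-reproducible under a
seed.

- `sim_chronogram()`: pure-birth trees conditioned on the tip count,
  rescaled to a target root depth (default 110 MY, the scale of the
  among-family splits; 399 ingroup + 29 outgroup tips in the default
  bundle, the larger of the two outgroup counts reported for the source
  phylogeny). Pure birth rather than birth–death is the default because
  extinction adds nothing to likelihood-correctness testing; a death rate
  is exposed.
- `sim_character()`: evolves the trait by drawing each child's state from
  the closed-form transition matrix (`"endpoint"`, exact for tip-state
  law) or by simulating the full jump process (`"exact"`), which is the
  mode to use when within-branch double events must be counted. Both
  modes record the true node states and origin count.
- `sim_single_origin()`: the inferred eyespot history — absence
  everywhere, one forced gain on a chosen edge (in the default bundle, the
  internal node nearest 90 MY), loss-only dynamics below. Its origin count
  is exactly 1 by construction.
- `sim_onset()`: Bernoulli draws from per-gene logistic curves at given
  stages. The default bundle uses the five-gene cascade with midpoints at
  stages 3–7 and slope 2 (onset spread over the observable stage range,
  adjacent genes one stage-unit apart), 8 observations per stage over
  stages 1–9.
- `sim_sequence_pair()`: a random sequence plus a copy with
  `round(length·d/100)` substitutions at distinct sites — at the 658-bp
  COI barcode length, a 5.45% target plants 36 changes (realized 5.47%,
  the nearest achievable).

What passing tests on these data do **not** show: robustness to rate
heterogeneity across lineages, to errors in the tree or in state scoring,
to non-random missingness of expression data, or to immunostaining noise —
none of which the generators emulate.

## 8. Problem sizes and numerical choices

The verification suite uses: exhaustive-enumeration likelihood checks on
200 random trees of ≤ 6 tips (tolerance 1e-10); transition probabilities
against matrix exponentials on 10,000 random draws (1e-10); marginal
posteriors against node-fixing ratios (1e-9); rate recovery on 50
simulated 400-tip, 100-MY chronograms at gain 0.005 / loss 0.02 per MY
(within a factor of 2.5 in ≥ 80%); origin-model comparisons on 30
simulated 200-tip single-origin histories; onset calibration on 500 null
tests (60 discs per gene, 500 bootstrap replicates each) and power on 100
tests at a two-stage-unit onset shift; and a byte-for-byte determinism
check of two full pipeline runs on the seeded synthetic bundle. These
sizes were chosen to give stable Monte-Carlo estimates while keeping the
whole suite to a few minutes on one core.

Other numerical choices collected in one place: ultrametricity tolerance
1e-6 relative (published chronograms carry rounding error); partial
likelihoods rescaled during pruning to avoid underflow on deep trees;
likelihood of contradictory constraints is −Inf (probability zero), while
a constraint contradicting an *observed* tip state errors; `NA` marginals
never arise because per-node scaling factors cancel in the normalized
up–down ratio.

## 9. End-to-end run

```{r pipeline, eval = FALSE}
paths <- write_synthetic_bundle("inputs", seed = 11)
cfg <- list(tree = paths$tree, character = paths$character,
            models = paths$models, onset = paths$onset,
            fasta = paths$fasta, species_map = paths$species_map,
            complexity = paths$complexity, n_boot = 10000, seed = 11)
res <- run_eyespot_pipeline(cfg, "reports")
res$comparison          # origin-model table, best model first
res$onset_report        # starred pairwise onset comparisons
res$clock               # dated species pairs
```

Outputs are delimited text plus a JSON manifest of input/output digests;
rerunning with the same config reproduces every table byte-for-byte, since
all randomness flows from the root seed through named substreams.

## 10. Known limitations

- Rate homogeneity: one gain and one loss rate across the whole tree; no
  covarion or branch-specific rates.
- The 2-unit rule is a convention, not a calibrated test; its error rates
  depend on tree shape and rates (the simulation suite measures them under
  the emulated conditions only).
- The δ test compares curves only through their areas: two curves with
  equal areas but different shapes are invisible to it, and the mixed
  bootstrap is conservative under exactly balanced stage designs at small
  n (section 4).
- The clock conversion ignores rate variation among lineages and
  saturation; it is meant for recent splits (a few MY) only.
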