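# rhythmprior

Tools for measuring perceptual **priors over three-interval rhythms**
with the iterated-reproduction ("telephone game") tapping paradigm, and
for comparing those priors across participant groups.

A three-interval rhythm is a cycle of intervals (s1, s2, s3) with a
fixed total duration (2,000 ms by default). A participant taps along
with ten repetitions of the cycle; the averaged reproduction
(r1, r2, r3) becomes the next iteration's stimulus. Over five
iterations the chain drifts toward rhythms the listener finds natural,
so the distribution of fifth-iteration reproductions estimates the
listener's prior on the rhythm simplex — the equilateral triangle whose
barycentric coordinates are the normalized intervals. Priors measured
this way are dominated by modes at **small-integer-ratio rhythms**
(ratios over the integers 1–3: 22 unique categories in 8
cyclic-permutation classes), with weights that differ across musical
cultures.

The package implements the full path from raw tap onsets to group-level
inference:

* **Geometry** — simplex projection, the 22/25-category integer-ratio
  sets and their cyclic classes, uniform seed sampling
  (`project`, `omega22`, `cyclic_classes`, `sample_seed`).
* **Preprocessing** — onset extraction from audio, 80 ms merge rule,
  asynchrony-centred tap/click matching (±150 ms), per-position
  averaging with imputation, validity rules (≥3 of 10 taps per
  position, 285 ms interval floor).
* **Trial engine** — the seed → reproduce → feed-back protocol with the
  invalid-iteration bookkeeping (`run_trial`, `run_group`).
* **Synthetic tapper** — a Bayesian observer/motor model with a known
  ground-truth mixture prior, used as the test bed
  (`observer_params`, `simulate_dataset`).
* **Prior estimation** — one regularized Gaussian kernel per trial,
  averaged on a 0.006-unit triangular grid (`estimate_prior`).
* **Category model** — a constrained Gaussian mixture anchored at the
  integer-ratio categories (means within d_min/2 of their anchors,
  eigenvalue truncation and aspect clamping), class weights, and the
  exponent-weighted categorical-perception predictor
  (`fit_constrained_gmm`, `category_weights`, `predict_category`).
* **Inference** — Jensen–Shannon divergence, split-half bootstrap group
  comparison, peakiness, integer-ratio overlap, category bias,
  split-half reliability with Spearman–Brown correction, transmission
  error, tapping asynchrony metrics, permutation symmetry.
* **Cross-group structure** — MDS (stress majorization) on the JSD
  matrix and PCA on prior grids (`mds_embedding`, `pca_on_grids`).

The mixture density is
Q(x) = Σᵢ wᵢ/(2π√|Cᵢ|) · exp(−½ (x−μᵢ)ᵀ Cᵢ⁻¹ (x−μᵢ)),
with ‖μᵢ − μᵢ⁰‖ < d_min/2, eigenvalues λ′ = min(λ, d_min/2) and
A ≤ λ/(λ₁+λ₂) ≤ 1−A (A = 1/5), fitted by projected EM. The prior is
P(x) = (1/N) Σᵢ N(x; μᵢ, Σᵢ + γ²I) over trials, and groups are compared
with JSD(P,Q) = ½KL(P,M) + ½KL(Q,M), M = (P+Q)/2, in bits.

## Worked example

Simulate a group whose ground-truth prior puts weights 0.5 / 0.3 / 0.2
on the 1:1:2, 1:2:2 and 3:3:2 categories, then recover the prior and
its category weights:

```r
library(rhythmprior)
o22 <- omega22()
anchors <- o22[match(c("1:1:2", "1:2:2", "3:3:2"), o22$ratio), ]
truth <- mixture_prior(anchors, weights = c(0.5, 0.3, 0.2), sd = 0.02)
params <- observer_params(prior = truth, posterior = "sample")
ds <- simulate_dataset(params, n_trials = 400, seed = 1)

pts <- dataset_points(ds)                 # fifth-iteration repetitions
grid <- triangle_grid(bin = 0.006)
km <- kernel_matrix(pts, grid)
prior <- prior_from_kernels(km)
prior
#> discrete prior: 12028 bins (bin 0.006, f 0.15), 132 trials

gmm <- fit_constrained_gmm(km$means)
round(sort(category_weights(gmm), decreasing = TRUE), 3)
#>   112   122   233   123   113   223   132   111
#> 0.171 0.095 0.068 0.000 0.000 0.000 0.000 0.000
round(100 * explained_variance(gmm, prior), 1)
#> [1] 92.4
```

132 of the 400 trials survive to a valid, in-region fifth iteration
(the same validity rules applied to human data). Class weights are the
*mean* over a category's three rotations, so the recovered class means
0.171 / 0.095 / 0.068 correspond to class *sums* of roughly
0.51 / 0.29 / 0.20 — the ground-truth 0.5 / 0.3 / 0.2. The mixture
explains 92.4% of the kernel-density variance. The prior is strongly
peaked:

```r
set.seed(2)
pk <- peakiness(pts, grid, n_null = 200)
#> top-33% mass 97.7% (p = 0.005), peak ratio 15.5 (p = 0.005)
tapping_metrics(ds)[c("mean_ms", "sd_ms")]
#> asynchrony mean -57.2 ms, sd 81.6 ms
```

The negative mean asynchrony reflects anticipatory tapping
(the simulator's observer taps 50 ms ahead of the click on average).

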