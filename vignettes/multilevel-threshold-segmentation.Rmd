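---
title: "Optimization-driven multilevel thresholding: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimization-driven multilevel thresholding: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the segmentation model, the optimizers and their
parameters, the fuzzy soft-thresholding variant, the noise-robustness
protocol, and the design decisions taken where the design was genuinely
open. It states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## 1. The segmentation model

An 8-bit grayscale image is represented by its 256-bin intensity
histogram with probabilities $p_j$. A threshold vector
$T_1 < \dots < T_n$ (integers in $[1, 255]$) partitions the axis into
$L = n+1$ half-open regions $[T_{l-1}, T_l)$ with sentinels $T_0 = 0$
and $T_{L} = 256$; a pixel with intensity exactly $T_l$ therefore
belongs to region $l+1$. The fitness of a partition is the **Kapur
entropy**,

$$\mathrm{fit}(T_1..T_n) \;=\; \sum_{l=1}^{L} H_l, \qquad
H_l = -\sum_{j \in \text{region } l} \frac{p_j}{\omega_l}
      \ln \frac{p_j}{\omega_l}, \qquad
\omega_l = \sum_{j \in \text{region } l} p_j ,$$

in nats (natural logarithm). Conventions: $0 \ln 0 = 0$, and a region
with $\omega_l = 0$ contributes $H_l = 0$. Note that the fitness is a
*sum* of per-region entropies, so its ceiling is the sum of the logs of
the region bin-widths, not $\ln 256$ — the uniform histogram split at
128 already reaches $2\ln 128 \approx 9.70$.

Maximizing this sum prefers partitions whose regions each spread their
probability mass evenly — a separability criterion that needs no
assumption about class shapes, only the histogram. Its weakness, shared
by all purely histogram-based criteria, is blindness to spatial
context: two images with identical histograms get identical thresholds.

## 2. Optimizers

All five metaheuristics maximize a *batch objective*: a function from a
matrix of candidate integer vectors (one sorted, strictly increasing
vector per row) to fitness values. Candidates are evolved as unordered
real vectors and repaired at evaluation (round half-up, clip to bounds,
sort, bump duplicates upward) so the continuous dynamics stay smooth
while the objective always sees a valid threshold vector.

Shared defaults follow the standard benchmark setting of 100 iterations
and a population of 50 (`optimizer_control()`); the genetic algorithm
is conventionally also run at 500 iterations with population 200, and
both presets are used by the acceptance checks. All optimizers are
elitist (the returned best never decreases along the iteration
history), and each consumes a single seeded RNG stream, so a run is
reproducible and a longer run replays a shorter one exactly.

* **ABC** — the colony splits into food sources (half the population);
  employed bees perturb one coordinate toward a random other source,
  $v_{ij} = x_{ij} + \varphi\,(x_{ij} - x_{kj})$ with
  $\varphi \sim U(-1,1)$; onlookers re-sample sources
  fitness-proportionally; a source failing to improve for `limit = 50`
  attempts is abandoned and re-scouted uniformly. The phase structure
  is canonical; the one-coordinate uniform perturbation is the standard
  operator, chosen because the method description names the phases but
  not the perturbation.
* **PSO** — velocity update
  $v \leftarrow w v + c_1 r_1 (p_i - x) + c_2 r_2 (p_g - x)$,
  $c_1 = c_2 = 2$, velocity clamped to 20% of the range. An inertia
  weight $w$ is included (linear decay 0.9 to 0.4) even though the
  plain velocity rule is often printed without one: the fuzzy variant
  explicitly *controls* the inertia weight, so the base dynamics must
  carry it. The decay horizon is a fixed control parameter
  (`w_decay_iters = 100`), deliberately decoupled from the total
  iteration count so that runs of different lengths share their common
  prefix under the same seed — that is what makes "doubling iterations
  never hurts" a theorem rather than a hope.
* **FPSO** — PSO whose inertia is retuned each iteration by a
  two-input, one-output Mamdani controller: inputs are the normalized
  progress NCBPE (0 = the best-known optimum was just matched, 1 = far
  from it) and the current inertia, both fuzzified over triangular
  low/medium/high sets; output is an inertia change bounded by
  `fpso_step = 0.1`, with $w$ clamped to $[0.2, 1.2]$. The nine-rule
  base is a documented package choice (the concept prescribes nine
  rules but not their content): low progress-distance always shrinks
  $w$ (exploit near the optimum — in particular, a swarm sitting at
  the optimum drives $w$ monotonically to its lower clamp), high
  distance with low inertia grows $w$ (escape), high inertia is always
  pulled back, and the middle holds steady. NCBPE itself is the
  exported `ncbpe()` normalization, fed at runtime with the negated
  fitness of the iteration best against the running best and the worst
  initial fitness.
* **DPSO** — several PSO swarms under natural selection: improvement
  is rewarded with an extra particle; stagnation past the
  search-counter ceiling (`scc_max = 10` iterations) costs the worst
  particle, with the counter restarting at
  $\mathrm{SCC}_{max}(1 - 1/(N_{kill}+1))$ so repeated punishment
  accelerates; a swarm finding a new global best spawns a fresh swarm
  with probability $f/N_S$ ($f \sim U(0,1)$, $N_S$ = swarm count). The
  structural constants (4 initial swarms, 2–6 swarms, 10–50 particles
  per swarm) are package defaults chosen at the scale of the
  population default; the dynamics prescribe no constants. A swarm
  shrinking below its size floor is deleted, unless that would breach
  the swarm floor, in which case it is re-seeded — the punishment
  cannot be allowed to empty a swarm that may not be removed.
* **GA** — generational: roulette selection on min-shifted fitness,
  single-point crossover at rate 0.8 on the sorted vector, per-gene
  uniform-reset mutation at rate 0.1, elitism of one, offspring
  repaired like every other candidate. Rates are standard defaults and
  configurable.

The optimizers are validated against `exhaustive_search()`, which
enumerates every ordered combination of candidate thresholds. Because
the objective only depends on which *occupied* bins land in which
region, the candidate set is condensed to the few smallest members of
every inactive gap — enough to keep optima with several thresholds in
one gap (empty regions) reachable, and to make the returned optimum the
lexicographically smallest one (ties resolved within a $10^{-12}$
band). The combinatorial guard refuses more than 3 thresholds on
histograms with more than 64 active bins.

## 3. Soft thresholding with PTS memberships

The fuzzy variant replaces thresholds with $L$ strictly increasing
vertices $V_1 < \dots < V_L$ in $[0, 255]$, one per region, defining
piecewise-linear pseudo trapezoid-shaped membership functions: plateaus
at the outer vertices extended to 0 and 255, linear ramps between
adjacent vertices. By construction memberships sum to one everywhere,
each vertex has membership one in its own region and zero elsewhere,
and at most two adjacent functions are nonzero at any intensity.
Defuzzification labels each pixel by maximal membership, ties toward
the lower region — which is *exactly* hard thresholding at
$T_l = \lfloor (V_l + V_{l+1})/2 \rfloor + 1$, a fact the tests assert
over all 256 intensities.

The fitness of a vertex vector is the Kapur entropy of this
crisp-equivalent partition. The alternative — some fuzzy-weighted
entropy — is nowhere specified in the protocol this package
implements, and scoring all methods with one objective is what makes
them comparable; the crisp-equivalent reading is therefore a designed
decision, not an approximation. Vertex candidates are integers repaired
like thresholds, which keeps the soft search space finite and directly
comparable with the exhaustive oracle.

## 4. Noise generators and sweeps

All noise arithmetic happens on the normalized $[0,1]$ scale — the
steering parameters (variance 0.01, density 0.2, ...) only make sense
there — followed by clipping to $[0,1]$ and requantization to 8 bits
(clipping, not wrapping: sensor saturation semantics; requantization
because segmentation operates on 256-bin histograms).

* Gaussian: add $N(\mu, \sigma^2)$ per pixel; sweeps vary $\mu$ from
  0.01 to 0.2 with $\sigma^2$ fixed at 0.01.
* Speckle: $J = I + nI$ with $n$ zero-mean *uniform* of variance
  $\sigma^2$ (range $\pm\sigma\sqrt3$) — the convention of the common
  imaging toolboxes this parameterization mirrors; a Gaussian $n$ is a
  one-line change. Sweep: $\sigma^2$ 0.01–0.2. Note the variance law
  $\mathrm{Var}(nI) = \sigma^2 I^2$ only shows cleanly where clipping
  is inactive; at $I = 1$ half the noise mass saturates the ceiling.
* Salt-and-pepper: exactly $\mathrm{round}(dN)$ pixels chosen without
  replacement, each set to 0 or 255 with probability one half. The
  exact count (rather than per-pixel Bernoulli) makes the corrupted
  count deterministic and testable. Sweep: $d$ 0.17–0.33.
* Rician: $M = \sqrt{(I+n_1)^2 + n_2^2}$ with $n_1, n_2$ independent
  $N(0, \sigma^2)$ — the MR magnitude-image model, Rayleigh where the
  signal vanishes (mean $\sigma\sqrt{\pi/2}$, which the tests check to
  2%). Sweep: $\sigma^2$ 0.02–0.4.

Each sweep has 20 levels, linearly spaced, identical for every region
count; level 0 is the untouched native image.

## 5. The robustness protocol

For every image × method × region count, the method first segments the
native image — that label map is the **gold standard** for that cell.
Each noise level is then applied (seed derived deterministically from
the master seed and the cell coordinates), the corrupted image is
segmented with identical settings, and the noisy label map is scored
against the gold one. The gold standard is deliberately *per method*:
the protocol measures each method's self-stability under noise, never
cross-method agreement.

Metrics operate on integer region-index matrices, never raw
intensities. SSIM is computed globally (whole-image moments, $n-1$
variance convention, $C_1 = C_2 = (0.02\,\mathrm{range})^2$) — no local
windowing, since the protocol defines a single similarity per map pair.
SNR is implemented with its signed numerator
$\sum (g^2 - f^2)$ taken literally: identical maps give $+\infty$, a
nonpositive numerator gives an undefined flag (`NA`) that aggregation
excludes and counts. This literal form is consistent with the
protocol's reported small-to-negative averaged SNR values; a
`conventional = TRUE` switch exposes the textbook $\sum g^2$ numerator
for sensitivity analysis without changing defaults. Pearson correlation
flags (rather than throws on) constant maps.

Aggregation averages per level across images first, then across levels
into grand means — the two-stage order is stated because pooling all
records first is the other defensible reading. Significance testing
uses the one-sided Wilcoxon rank-sum test (normal approximation, tie
correction): direction *greater* for SSIM/correlation/SNR, *less* for
MSE, each optimized method against each baseline, with a chi-square
normality pre-check (equal-probability classes, $\sqrt n$ classes
capped at $n/5$, degrees of freedom classes − 3) recorded per cell.

## 6. The phantom generator

`generate_phantom()` emulates the structures the protocol cares about:
an L-class intensity layout with a background, a bone-like ellipse, a
cartilage-like ribbon (upper half-annulus — always region 3, so the
ribbon *is* exactly one region), a fluid-like band, and small discs for
any further regions. Region means are equally spaced by `contrast`
(default: fill the 8-bit range), Gaussian texture of standard deviation
`texture_sd` (default 8 intensity units, a moderate within-tissue
spread that leaves classes clearly separable) is added, and values are
clipped to $[0,255]$. The generator is a pure function of its
arguments, seed included.

The recorded truth is analytic where possible: ribbon area is the
rasterized half-annulus pixel count (within 3% of
$\pi(R^2 - r^2)/2$); the perimeter truth is the two-sided boundary band
(pixels whose 3×3 neighbourhood mixes ribbon and non-ribbon), which is
what a Sobel edge count measures on a thick region; the skeleton truth
is the Chebyshev digital length of the mid-radius arc,
$2\sqrt2 \cdot \bar r + 1$, since an 8-connected digital curve carries
one pixel per unit Chebyshev length.

What the phantom does **not** emulate: partial-volume mixing at tissue
interfaces, intensity inhomogeneity (bias fields), anatomical shape
variability, or spatially correlated texture. Passing the phantom suite
therefore demonstrates that the algorithms implement their contracts
and degrade gracefully under the four noise models — it does not
certify clinical segmentation accuracy on real MR data.

## 7. Morphology features

Region masks are extracted from label maps with an optional
largest-components filter (8-connected components — diagonal lobe
contact counts as connected, which is why the package carries its own
labeller). Features: area = pixel count; perimeter = count of nonzero
3×3 Sobel gradient magnitude pixels on the padded 0/1 mask (the mask is
padded by background first so image borders cause no artifacts);
skeleton = Zhang–Suen two-subiteration thinning to a one-pixel-wide
8-connected skeleton, length = pixel count by default with a geodesic
option weighting diagonal links by $\sqrt2$. Pixel count is the default
because the protocol says only "length"; the simplest auditable choice
wins, and the alternative stays behind a flag. Percentage differences
against gold features use the gold denominator,
$100\,|a - g|/g$ — asymmetric by design.

## 8. Problem sizes and numerical choices

The test suite and the acceptance script exercise: 20 random
histograms condensed to 64 active bins for optimizer-vs-oracle checks
(3 thresholds; ABC/PSO/FPSO/DPSO at 100 iterations / population 50, GA
also at 500/200); 100 random vertex models for the fuzzy laws;
noise statistics at $256 \times 256$ (65 536 samples); and the full
sweep protocol on ten $256\times256$ four-region phantoms under the
20-level salt-and-pepper grid with methods {multi-Otsu, K-means,
ABC-fuzzy, PSO}, plus a ten-region ABC-fuzzy sweep for the
region-count effect. These sizes were chosen as the smallest that
exercise every code path at the protocol's standard settings while
keeping a full run comfortably interactive.

Numerical conventions collected in one place: intensities are 0-based
integers, coordinates row/column 0-based with pixel-center semantics;
thresholds are integers with half-open upper-exclusive regions;
$0\ln0 = 0$; empty regions contribute zero entropy; all search
tie-breaks are lexicographic toward the smallest vector (and the
lowest region index in defuzzification and K-means assignment), chosen
for determinism; K-means initializes at seeded quantile-spread distinct
intensities, re-seeds emptied clusters at the farthest intensity, stops
when no pixel changes class, and renumbers classes by ascending
centroid; 8-bit conversion uses Rec. 709 luminance weights
(0.2126/0.7152/0.0722) with round-half-up, and 16-bit input is min-max
rescaled.

## 9. Known limitations

Histogram-only objectives ignore spatial context; the Kapur criterion
can place thresholds in low-mass valleys that carry no anatomical
meaning. The literal signed-numerator SNR is undefined whenever the
noisy map's index power exceeds the gold map's, which in practice
happens often under heavy impulse noise — the flag-and-exclude
mechanism reports this honestly but reduces the effective sample for
SNR aggregation. The exhaustive oracle is limited to small search
spaces by design. The phantom suite, as noted, bounds what robustness
results on it can claim about clinical images. Wall-clock timing is
logged nowhere and asserted nowhere: it is hardware-bound and outside
the package's contracts.
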