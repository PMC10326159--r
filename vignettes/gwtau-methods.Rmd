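---
title: "Comparing trajectories by their distance-from-start profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing trajectories by their distance-from-start profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A multivariate time series — a cell's position over time, a measured angle,
an ECG trace — is treated here as a *trajectory*: a finite ordered list of
points $x_1, \dots, x_n \in \mathbb{R}^d$. Each trajectory is turned into a
metric-measure space: the metric is the intrinsic (polygonal arc-length)
distance along the curve, and the measure is uniform over the observed
points. Comparing two such spaces with the full Gromov–Wasserstein machinery
requires a non-convex quadratic program; `gwtau` instead fixes one argument
of each intrinsic distance at the trajectory's start point. What remains of
each trajectory is its **distance-from-start profile**

$$v_k \;=\; \sum_{j < k} \lVert x_{j+1} - x_j \rVert, \qquad k = 1, \dots, n,$$

together with weights $1/n$, i.e. the pushforward of the uniform point
measure to the real line. The distance between trajectories $X$ and $Y$ is
then the $p$-Wasserstein distance between the two pushforwards:

$$GW_\tau(X, Y) \;=\; \mathcal{W}_p\!\left(v(X)_\#\mu_X,\; v(Y)_\#\mu_Y\right),$$

which, because both measures live on $\mathbb{R}$, has a closed form through
quantile functions. Three facts drive the whole package:

1. **Profiles are already sorted.** Cumulative sums of nonnegative segment
   lengths are nondecreasing, so the equal-length closed form
   $\bigl(\tfrac1N \sum_i |z_i - w_i|^p\bigr)^{1/p}$ needs no sorting — a
   single $O(N)$ pass. The package never sorts a profile; monotonicity is
   asserted, and a violation is an internal error.
2. **Unequal lengths use the quantile coupling.** For uniform measures of
   sizes $n \ne m$ the optimal coupling
   $\lambda_{ij} = \bigl(\tfrac{i}{n}\wedge\tfrac{j}{m} -
   \tfrac{i-1}{n}\vee\tfrac{j-1}{m}\bigr)_+$ has a monotone staircase
   support with at most $n+m-1$ nonzero entries; `wasserstein_1d()` walks
   exactly that staircase. For $n = m$ the staircase degenerates to the
   diagonal and the two formulas agree to machine precision (this is tested).
3. **Only arc lengths matter.** Rotations, translations and reflections of
   the ambient space leave every segment length unchanged, so $GW_\tau$ is
   exactly invariant under rigid motions — including a *different* motion
   per trajectory. The flip side is that $GW_\tau$ is a pseudo-metric on
   trajectories: a curve and its mirror image, or any two trajectories with
   the same distribution of distances from the start, are indistinguishable.
   On the space of profiles it is a true metric (symmetry, triangle
   inequality and zero self-distance are tested properties).

One convention matters for scalar series: a 1-D signal $h(t)$ is compared as
the plane curve $(t, h(t))$, so that its profile reflects both elapsed time
and movement. This embedding happens when a dataset is split into point
matrices (`trajectories()`, default `embed_time_for_1d = TRUE`); the
Euclidean and DTW baselines instead compare raw value sequences, which is
how those distances are conventionally used. The time axis is kept in its
native units; if time and signal units are wildly incommensurate, rescaling
is the user's modelling decision.

## Parameters that matter

* `p` (default 2, any value in $[1,\infty)$): the transport exponent. The
  distance is nondecreasing in `p` (tested); `p = 2` is used throughout the
  workflow functions, matching common practice.
* Repeated consecutive points give zero-length segments. The underlying
  curve model assumes an injective map, so the package warns, keeps the
  tied values, and proceeds — profiles stay nondecreasing either way.
* Single-point trajectories are legal: their profile is $\{0\}$, and the
  distance to any other trajectory is the $p$-mean of the other profile.

## Reference computations

Two independent routes validate the closed form:

* `wasserstein_1d_lp_oracle()` solves the transport linear program exactly
  (simplex method, `boot::simplex`, with the one redundant marginal
  constraint dropped). It is $O((nm)^3)$-ish and intended for $nm \lesssim
  10^4$; the test suite checks closed form against LP over hundreds of
  random weighted and unweighted instances at $10^{-8}$.
* `tlb()` computes the Third Lower Bound: matching costs are 1-D
  Wasserstein distances between *local distance distributions* (arc-length
  distances from every anchor point, which are not monotone — this
  validator sorts, unlike the fast path), and the outer problem is again an
  exact transport LP, halved after the $p$-th root. The chain
  $TLB \le GW \le GW_\tau$ motivates using $GW_\tau$ as a scalable
  surrogate; the package tests $TLB \le GW_\tau + 10^{-9}$ on random pairs.

DTW is implemented as the unconstrained dynamic program (steps $(1,0)$,
$(0,1)$, $(1,1)$, Euclidean local cost, no window) in compiled code, and is
verified against exhaustive path enumeration on tiny instances. DTW is not
a metric; no triangle inequality is asserted. Cell updates are counted
inside the DP, and profile/staircase operations are counted in the closed
form, so the linear-versus-quadratic scaling claim is checked on
instrumented operation counts rather than wall clock: between $N = 10^3$
and $N = 10^4$ the closed-form count grows by a factor of about 10 and the
DTW count by about 100.

## What the generators emulate

All generators are pure functions of their configuration (same seed, same
bytes) and return long tibbles (`trajectory_id`, `t`, `dim_*`, `label`).

**Analytic shapes** (`sim_analytic_shapes()`): a 3-D helix and a 2-D circle
on $[0, 23\pi/12]$, and 3-D/2-D lines on $[0, 2]$, all unit-speed, on
unequally spaced points (sorted uniform draws including the endpoints).
Default counts are 48 points per circular shape and 30 per line — enough to
reproduce the similarity block structure (same-shape distances a few
thousandths of the cross-shape ones). Note a sampling consideration: the
polygonal arc length of a circle sampled at 48 points undershoots the true
length by about $1.6\times10^{-2}$ (chord-versus-arc error), so the
unit-speed *verification* in tests uses a denser uniform grid (240 circle
points, 60 line points) where the polygonal error is $\sim 1.6\times10^{-4}$,
below the $10^{-3}$ tolerance asserted.

**StraightAround** (`sim_straight_around()`): two classes of 3-D series, 30
per class on a common 300-point grid, descending from $(1,1,1)$ to the
origin with per-coordinate Gaussian noise (sd 0.01) plus a 60-point window
of higher-variance excursion (sd 0.15) placed uniformly at random inside
the first third (class 1) or last third (class 2) of the path. The classes
differ only in *when* the activity burst happens — exactly the regime where
a warping distance can align the bursts away while the profile's shape (a
steep stretch early versus late) separates them cleanly.

**3-D Lotka–Volterra** (`sim_lotka_volterra()`): the competitive system
$\dot x = \mathrm{diag}(x)(r + Ax)$ with circulant interaction matrix
$A = -\,\mathrm{circ}(1, \alpha, \beta)$ and $r = -A\mathbf{1}$, which
places an interior equilibrium at $(1,1,1)$ whose Jacobian is $A$ itself.
Three shipped regimes realize three local behaviours, each verified by
Jacobian eigenvalues in the tests: a stable focus
($\alpha + \beta < 2$, complex pair with negative real part), an unstable
focus ($\alpha + \beta > 2$), and an unstable node at the origin (Jacobian
$\mathrm{diag}(r)$, $r > 0$). Custom $(r, A)$ regimes can be supplied in
the same format. Integration runs in log-coordinates, so positivity of all
populations is exact rather than approximate. Initial conditions are drawn
at a fixed radius in a uniformly random direction around each regime's
reference state; for the unstable-focus regime the perturbation is drawn in
the unstable eigenplane (orthogonal to the stable $(1,1,1)$ direction),
because a draw with a dominant stable-manifold component would spend the
whole observation window sliding toward the equilibrium and never exhibit
the spiral-out behaviour that defines the class. Fixing the radius keeps
escape and relaxation times — and therefore total arc lengths — coherent
within a class, which is what makes single-linkage clustering (fragile to
chaining) reliable here.

**Random rotations** (`random_rotate()`): Haar-uniform elements of
$SO(3)$ via the sign-corrected QR of a Gaussian matrix, either one shared
rotation or an independent one per trajectory. $GW_\tau$ matrices are
bitwise-insensitive to either; coordinate-based distances scramble under
per-trajectory rotation, which is the mechanism behind the rotation
robustness comparison.

**Wobble-like angles** (`sim_wobble()`): 1-D angle series on a shared grid
of 40 points at 5-second spacing, sized 10 / 12 / 7 (one flat control-like
class, two oscillatory perturbation-like classes) to match the real
experiment the stand-in emulates. Oscillation defaults — 15° mean amplitude
with 10 % per-trajectory spread, 0.03 Hz (the second class at 0.8× amplitude
and 1.4× frequency), uniform phase on $(-\pi, \pi)$, 1° measurement noise —
are the package's own choice of a plausible oscillation regime at this
sampling rate (roughly six cycles per record). The full phase jitter is the
point: the pointwise class mean then damps to roughly $1/\sqrt{K}$ of the
class amplitude, which is the failure mode `averaging_assessment()`
exposes — the damped mean lands nearer the flat group in mean $GW_\tau$
than any faithful class representative does.

What passing these synthetic checks does *not* show: real pronuclear-angle
data, ECGs or EEGs have autocorrelated noise, drift, and class structure
far messier than sinusoids and noisy lines. The generators reproduce the
*statistical mechanisms* the method responds to (timing shifts, phase
jitter, rotation nuisance, arc-length contrast), not the biology.

## Workflow choices

The analysis workflow is deliberately plain: distance matrix → 1-NN
classification, PAM k-medoids or agglomerative clustering on the matrix,
classical MDS embedding with seeded k-means on the coordinates, and ARI /
permutation-minimal error counts against known labels.

* **PAM without restarts.** The BUILD + SWAP algorithm in `cluster::pam` is
  deterministic given the matrix and at least as good as seeded random
  multi-restart initialization for the sizes used here, so determinism is
  obtained structurally rather than by seed bookkeeping (the `seed`
  argument remains in the interface for pipeline stability).
* **Classical MDS by default.** Torgerson's double-centred eigendecomposition
  is deterministic and exact for Euclidean-realizable matrices; negative
  eigenvalues are reported as diagnostics. A non-metric alternative
  (`flavor = "isoMDS"`) is available for heavily non-Euclidean matrices;
  classical MDS is the default because the downstream k-means step only
  needs a stable planar summary.
* **1-NN ties** break toward the lowest training index; `which.min` provides
  this and it matches the common archive-benchmark convention.
* **Error counts** are minimized over one-to-one matchings of predicted
  clusters onto true classes (exhaustive over the smaller side, which is at
  most a handful of clusters in every use here).

## Numerical notes and limitations

* Arc lengths are accumulated left-to-right in double precision; profile
  values are order-dependent floating-point sums, documented as such.
* The staircase walk advances indices using exact integer comparisons
  ($im \le jn$), so tie handling does not depend on floating-point
  rounding.
* The general-weights path merges the two CDF breakpoint sets and
  integrates the quantile difference piecewise; it is only used when
  weights are non-uniform.
* Problem sizes in the test suite are chosen to keep the whole suite at
  around a minute and a half on one core: 500 LP-oracle comparisons at
  lengths up to 30, 100–200 random pairs/triples for metric properties,
  10 trajectories per class at 200 points for the rotation study, and
  operation-count (not wall-clock) scaling at $N \in \{10^3, 10^4\}$.
* The full Gromov–Wasserstein value itself is *not* computed anywhere — the
  package ships its lower bound (TLB) and upper surrogate ($GW_\tau$) only;
  the sandwich $TLB \le GW \le GW_\tau$ is how the surrogate's fidelity is
  reasoned about.
* $GW_\tau$'s blindness to mirror symmetry and, more generally, to any
  rearrangement preserving the distance-from-start law, is inherent. If
  chirality or absolute position carries the class signal, use the
  Euclidean or DTW baselines (or both families side by side, as
  `trajectory_dist()` encourages).
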