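---
title: "Methods: delay-coupled Wilson-Cowan networks with inhibitory plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delay-coupled Wilson-Cowan networks with inhibitory plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model, the numerical choices and the design
decisions behind `wcnet`, at the level of detail a user needs to judge what
the package computes and what its tests do and do not establish.

## The model

Each cortical region is a Wilson-Cowan unit: two coupled rate equations for
the excitatory and inhibitory population activities $E_k, I_k \in [0,1]$
(fractions of the maximal firing rate),

$$\tau_e \dot E_k = -E_k + S\!\Big(c_{ee}E_k + c_{ie}^k I_k + P + \xi(t)
 + C\sum_j W_{jk}E_j(t-\tau_{jk})\Big),$$
$$\tau_i \dot I_k = -I_k + S\big(c_{ei}E_k + \xi(t)\big),$$

with the logistic response $S(x) = 1/(1+e^{-(x-\mu)/\sigma})$. Only
excitatory populations couple across regions; the connectome $W$ enters
through a global coupling scale $C$ and per-edge conduction delays
$\tau_{jk} = d_{jk}/v$ at a uniform velocity $v$. Because $S$ is bounded,
the noise-free flow leaves the unit square invariant (asserted numerically
in the tests).

Inhibitory synaptic plasticity (ISP) adapts the local, signed inhibitory
weight $c_{ie}^k \le 0$ towards a target excitatory rate $\rho$:

$$\tau_{isp}\,\dot c_{ie}^k = -I_k\,(E_k-\rho).$$

**Sign convention.** With $c_{ie}$ entering the excitatory drive additively
and initialised negative ($-2.5$), only this sign is homeostatic: activity
above target strengthens inhibition (pushes $c_{ie}$ down). The same rule
written for the inhibitory *magnitude* $|c_{ie}|$ has the textbook positive
sign. Weights are clamped at zero from above — inhibition cannot turn into
excitation — and clamp events are counted on the result object.

### Parameters

| name | meaning | default | units |
|---|---|---|---|
| `c_ee` | local E-to-E coupling | 3.5 | – |
| `c_ei` | local E-to-I coupling | 3.75 | – |
| `c_ie0` | initial local I-to-E coupling (signed) | −2.5 | – |
| `mu` | firing threshold | 1 | – |
| `sigma` | threshold spread | 0.25 | – |
| `P` | constant excitatory drive | 0.31 | – |
| `tau_e`, `tau_i` | population time constants | 0.01, 0.02 | s |
| `rho` | ISP target rate | 0.15 | – |
| `C` | global coupling | sweep variable | – |
| `noise_sd` | per-step noise sd | 0.01 | – |
| `tau_isp` | plasticity timescale | schedule-controlled | s |

These defaults place an isolated unit just below a supercritical Hopf
bifurcation: `find_hopf()` locates the critical drive at $P \approx 0.336$,
with fixed-point activity $E^* \approx 0.122$ and an emergent frequency of
$\approx 11$ Hz — an alpha-band oscillator. The threshold depends on the
ratio $\tau_e/\tau_i$ only; rescaling both time constants together moves the
frequency inversely and leaves the threshold untouched (an exact symmetry,
verified to $10^{-4}$ in the tests). `P = 0.31` keeps units sub-threshold so
that network oscillations arise from coupling, and noise ($\sigma = 0.01$,
much smaller than the nonlinear oscillations) prevents trapping in
marginally stable periodic states.

### What "the mean rate converges to the target" does and does not mean

The ISP equilibrium condition is $\langle I\,(E-\rho)\rangle = 0$, hence

$$\langle E\rangle = \rho - \mathrm{cov}(E, I)/\langle I\rangle.$$

In a steady (non-oscillatory) regime the covariance vanishes and
$\langle E\rangle \to \rho$ exactly; the package verifies this against the
closed-form equilibrium weight
$c_{ie}^* = (S^{-1}(\rho) - c_{ee}\rho - P - \text{ext})/S(c_{ei}\rho)$
(for $\rho = 0.10$, $c_{ie}^* \approx -2.76$, matched by simulation within
2%). In the oscillatory regime implied by $\rho = 0.15$, however, $E$ and
$I$ co-oscillate with a phase lag below quarter-cycle, the covariance is
positive, and the converged time-mean of $E$ settles near the Hopf-point
activity ($\approx 0.12$), below the nominal target. This is a property of
the plasticity rule itself, not of the integrator; the acceptance suite
states the nominal-target expectation and records the measured value.

## Numerical integration

* **Scheme.** Fixed-step classical RK4 at $\Delta t = 10^{-4}$ s, compiled
  (Rcpp). Fourth-order convergence is asserted on the isolated unit (log-log
  slope 4 ± 0.3 against a $\Delta t/16$ reference).
* **Delays.** Per-edge delays are rounded to integer steps (error
  $\le \Delta t/2$) and served from a circular history buffer of past $E$.
  At the RK half/full stages the delayed value is interpolated linearly
  between buffer entries. When all delays are zero (infinite-velocity
  sentinel) the coupling is evaluated from the stage states themselves,
  i.e. the scheme degenerates to plain RK4 on the coupled ODE. Edges whose
  delay rounds to zero at finite velocity hold the start-of-step value.
* **Noise.** One Gaussian sample per population per step, linearly
  interpolated at the stage times; the next-step sample is drawn ahead so
  interpolation is causal within the step. The noise is therefore a smooth
  interpolant, not white noise, and no stochastic-calculus correction is
  applied (this is deliberate). All draws go through R's RNG, so a single
  `set.seed` makes runs bit-reproducible.
* **Initial conditions.** $E, I \sim U(0.1, 0.3)$ per region from the seed
  — inside the low-activity basin, away from the saturated branch — with
  the history clamped to the initial value for $t < 0$. The discarded
  transient (15 s at full scale, shorter in desk-scale runs) absorbs both
  artifacts.
* **ISP update.** Forward Euler on $c_{ie}$ inside each RK4 macro-step,
  using start-of-step rates. With $\tau_{isp} \ge 0.1$ s
  $\gg \Delta t$, higher-order treatment of the slow variable would change
  nothing measurable; this is a stated approximation. The staged protocol
  (fast learning first, then progressively slower stages, then freezing
  $c_{ie}$ for the analysis segment) mirrors the standard
  accelerate-then-decouple practice; all stage durations and rates are
  configurable so tests can shrink the protocol. Desk-scale note: near
  equilibrium the slow variable relaxes with an effective time constant
  $\tau_{isp}/(I^*\,\partial E^*/\partial c_{ie})$, which for quiescent
  units is of order $10^3\,\tau_{isp}$ — accelerated first stages
  ($\tau_{isp} = 0.1$–0.5 s) are what make short protocols converge.
* **Output.** The analysis segment is decimated to 300 Hz behind a
  zero-phase 4th-order Butterworth low-pass at $0.4\,f_{out}$ (with
  odd-reflection end padding), then linearly resampled; $c_{ie}$ is stored
  at 10 Hz.
* **Failure handling.** Non-finite states abort with the time and region;
  per-cell failures in sweeps are recorded and do not kill the sweep.

## Signal pipeline

Processing order is band-pass → orthogonalise → analytic decomposition; the
leakage correction is applied within the analysis band, as in standard MEG
practice. The band-pass is a 4th-order Butterworth applied forward and
backward (zero net phase). Spans of $1/f_{lo}$ seconds at each end are
flagged and excluded from all downstream statistics; two-pass IIR filtering
of narrowband signals is inherently inaccurate near the ends (reflection
padding cannot phase-align an arbitrary tone), which is why the exclusion
is not optional.

The symmetric multivariate orthogonalisation finds the closest set (least
squares) of mutually orthogonal, per-channel positively rescaled
timecourses to the demeaned input, by alternating a polar-decomposition
step with an optimal-rescaling step until the relative Frobenius change
drops below $10^{-10}$ (200-iteration cap, error on non-convergence).
Because the orthonormal basis lies in the column space of the demeaned
data, outputs are exactly zero-mean and all pairwise instantaneous
correlations vanish to numerical precision. Rank-deficient input (e.g. a
duplicated channel) is rejected with the offending pair named.

Connectivity metrics follow their standard definitions: AEC as the Pearson
correlation of 1 Hz block-averaged Hilbert envelopes of orthogonalised
signals; PLV as the mean resultant length of the phase difference
(orthogonalised signals — zero-lag mixing inflates it); PLI as
$|\langle \mathrm{sign}\sin\Delta\phi\rangle|$ on raw signals (insensitive
to zero-lag mixing; $\mathrm{sign}(0) = 0$, so identical signals give PLI
0). Diagonals are set by convention (1 for AEC/PLV, 0 for PLI) and carry no
information; FC similarity correlates strict upper triangles only. The
Kuramoto order parameter uses analytic phases of band-passed activity;
synchrony and metastability are its window mean and sample standard
deviation (n − 1, appropriate for 55-subject-scale cohorts, as are the
leave-one-out Z-scores).

## Synthetic data

`generate_connectome()` emulates the gross regularities of a parcellated
tractography connectome: two mirrored hemispheres of centroids in a
brain-sized ellipsoid (semi-axes 85 × 35 × 60 mm per hemisphere), Euclidean
inter-centroid distances, log-normally dispersed weights around an
exponential distance decay, thresholding to a target edge density, and the
same log-compression/max-normalisation applied to real streamline counts
(zeros preserved, smallest nonzero mapped to the log origin, maximum exactly
1). Defaults — 68 regions, density 0.6, decay scale 40 mm, log-normal
dispersion 1.0 — are fixed once as a realistic stand-in for an averaged
cortical connectome.

What it does **not** emulate: community/modular structure, homotopic
(inter-hemispheric mirror) connections, the heavy bilateral asymmetries of
real tracts, or the specific node-strength distribution of any particular
dataset. Consequences follow for any statistic that depends on the strength
scale: the global coupling at which the whole network saturates into the
high-activity state scales roughly inversely with mean node strength, so
its numerical value on the synthetic connectome is not transferable to a
particular empirical matrix. `load_matrix_text()` accepts real weight and
distance matrices in plain whitespace/CSV text whenever an empirical
connectome is available.

`generate_subject_fc_set()` builds surrogate per-subject FC matrices as a
group template plus independent symmetric edge noise, clipped to the
metric's range. It exercises the leave-one-out Z-score machinery — the
expected leave-one-out similarity has the closed form
$v/\sqrt{(v+s^2)(v+s^2/(m-1))}$ for template edge variance $v$, noise sd
$s$ and $m$ subjects, which the tests recover — but it does not model
subject-level covariance structure, so passing tests show the machinery is
correct, not that the model matches real individual variability.

## Numerical edge cases and tie-breaks

* Fixed points are bracketed by a 10⁴-point scan of the self-consistency
  residual on [0, 1] and polished by `uniroot` to $10^{-12}$; with multiple
  roots the smallest-$E$ root is "the" operating point (the low-activity
  branch is the physiological regime), and the full root list is returned.
* Hopf bisection runs on the sign of the maximal real eigenvalue part at
  that tracked fixed point (default tolerance $10^{-4}$ in $P$, tightened
  to $10^{-5}$ where quoted).
* An all-zero weight matrix normalises to itself with a warning; a
  connectome whose nonzero weights are all equal log-compresses to a flat
  matrix, which is mapped to 1 at the nonzero positions.
* `fc_similarity` returns `NA` flagged `undefined` when either triangle has
  zero variance; `balance_correlation` flags constant $c_{ie}$ the same way
  (without ISP, inhibition is independent of node strength by construction).

## Problem sizes

Desk-scale defaults keep every test and the acceptance script on one CPU:
isolated-unit analyses are instant; ISP protocols use 30–60 s stages on
2–10 regions; the saturation scan uses 30 s runs on the 68-region synthetic
connectome over a coarse coupling grid. Full-scale protocols (1500 s of ISP
plus 500 s of analysis per grid cell) use the same code paths with larger
configuration values.

## Known limitations

* No long-range E→I connections, conductance-based synapses, or regional
  parameter gradients; one frequency band per call.
* Whether the noise is shared between the E and I equations of a region is
  not biologically settled; the package draws independent samples (the
  weaker assumption).
* Memory: analysis segments are held at full rate before decimation
  (~160 MB per state variable for 30 s × 68 regions); very long segments
  should be run as sweeps of shorter cells.
* The connectome is assumed symmetric with zero diagonal; directed
  connectomes are out of scope.
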