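---
title: "Noise, network structure, and the effects of focal stimulation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noise, network structure, and the effects of focal stimulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question

Focal stimulation of one brain region — electrically, magnetically, or as a
model of sensory input — changes activity far beyond the stimulated site,
because activity propagates along anatomical (white-matter) connections.
Two factors jointly shape that propagation: the *structural network* (who is
connected to whom, and how strongly) and the *noise amplitude* of the
ongoing dynamics. `stimnet` implements a complete in-silico version of this
question: a delay-coupled stochastic Wilson–Cowan whole-brain model driven
through a grid of noise amplitudes and stimulation sites, with regional
(spectral) and network-level (functional-connectivity) read-outs.

## The model

Each region i carries an excitatory and an inhibitory population with
firing rates $E_i(t), I_i(t) \in [0, 1]$:

$$\tau \dot E_i = -E_i + (S_E^{max} - E_i)\,
  S_E\!\big[c_{EE}E_i - c_{IE}I_i + c\textstyle\sum_j A_{ij} E_j(t - \tau_{ij}) + P_i(t)\big]
  + \sigma w_i(t)$$

$$\tau \dot I_i = -I_i + (S_I^{max} - I_i)\,
  S_I\!\big[c_{EI}E_i - c_{II}I_i\big] + \sigma v_i(t)$$

with sigmoids $S(x) = 1/(1+e^{-a(x-\theta)}) - 1/(1+e^{a\theta})$ shifted so
that $S(0)=0$ and bounded by $S^{max} = 1 - 1/(1+e^{a\theta})$. Defaults
(all dimensionless unless noted): $\tau = 8$ ms, $c_{EE},c_{IE},c_{EI},c_{II}
= 16, 12, 15, 3$, $a_E = 1.3$, $a_I = 2$, $\theta_E = 4$, $\theta_I = 3.7$
(so $S_E^{max} = 0.9945$, $S_I^{max} = 0.9994$), conduction velocity
$v = 10$ m/s, delays $\tau_{ij} = D_{ij}/v$ from the inter-center distances.
Long-range coupling links excitatory populations only, scaled by the global
coupling $c$. The stimulus is a constant $P_i = 1.25$ added inside the
excitatory sigmoid argument of one site during 2–3 s (zero before).

Only $\sigma$ (noise amplitude) and the stimulation site vary in the main
experiment; $c$ is fixed once per network (below).

### Interpretation of the noise term

$\sigma w_i(t)$ is read as white noise in the Itô sense, so the
Euler–Maruyama update adds $(\sigma/\tau)\sqrt{\Delta t}\,\xi$ with
independent standard Gaussians per population per step. This is the
standard reading; an alternative scaling would be a one-line change in the
integrator. Noise perturbs both populations with independent streams.

### Integration

Explicit Euler–Maruyama at $\Delta t = 5\times10^{-6}$ s by default. Delays
are rounded to the nearest integer step, with a floor of one step so no
algebraic loop arises for coincident centers. The delay history for
$t < 0$ equals the constant initial condition $E = I = 0.1$ (the value is
configurable; only transient behavior depends on it, and the first second
is always discarded). States are clipped to $[0,1]$ after every step —
the drift alone keeps trajectories in range only approximately once noise
is added — and the number of clipped updates is reported; at the
sub-threshold fixed point near zero the lower bound acts as a reflecting
floor for the noise. Output is plain decimation to 1 ms resolution (every
200th state at the default step), matching a literal down-sampling of the
model output; no anti-alias filter is applied.

The integrator is written in C++ with a counter-splittable xoshiro256++
generator (ziggurat normals), so every (seed, stream) pair is an
independent, exactly reproducible realization regardless of execution
order. Delayed inputs are gathered blockwise from per-node ring buffers;
the sigmoid evaluation uses a Cephes-style rational exponential accurate
to a few ulp. A plain-R reference integrator in the test suite pins the
C++ path to $10^{-10}$ on deterministic problems.

### A note on the stimulated rhythm

With these parameters an isolated stimulated node leaves its fixed point
and settles on a limit cycle of period $5\tau = 40$ ms, i.e. 25 Hz (the
24 Hz bin of the 2-Hz Welch grid). This rhythm is often quoted nominally
as "about 20 Hz"; exactly 20 Hz would correspond to $\tau = 10$ ms. The
package keeps $\tau = 8$ ms and reports the frequency the model actually
produces.

## The synthetic connectome

No empirical connectome ships with the package; the generator emulates the
statistical structure the analyses rely on:

* region centers uniform in a 150 mm box, Euclidean distance matrix
  (typical inter-center distances of tens of mm);
* edges sampled without replacement with probability $\propto
  e^{-D/60\,\mathrm{mm}}$ until the target density (default 0.3),
  then minimal-distance edges added if components remain;
* weights $\propto e^{-D/60\,\mathrm{mm}}$ with log-normal dispersion
  (sdlog 0.4), non-negative, symmetric, zero diagonal;
* a hub set (default 14 of 82) placed closest to the box center, labelled
  subcortical, with all incident weights tripled — producing the
  positively skewed weighted-degree distribution and the hub role of
  subcortical regions; remaining regions split evenly at random among the
  SA, HOC and MDM systems.

The overall weight scale is a free parameter of any synthetic network
(empirical streamline counts have no canonical units). It was calibrated
once so that the coupling threshold falls inside the standard grid
$c \in [0.01, 0.3]$: the default `weight_scale = 4` gives mean weighted
degree ≈ 60 and a detected threshold $c^* = 0.12$ for the default
82-region network (0.26 for the 40-region study network). What the
generator does *not* emulate: community structure beyond the hub set,
hemispheric symmetry, empirical edge-weight distributions, or realistic
region volumes — so quantitative correlation values obtained on synthetic
networks are not comparable to empirical ones, while the qualitative
regimes (below) are.

## Analysis metrics

**Spectra.** Each regional series (1 kHz) is demeaned as a whole and Welch
PSDs are computed with 0.5-s Hann windows at 50% overlap (three windows per
1-s segment; 2 Hz resolution). Spectra are averaged across realizations
*before* peak extraction. The peak frequency is the argmax over positive
frequencies — the DC bin is excluded so that degenerate, essentially flat
spectra have a well-defined "slow" answer — with ties broken toward the
lower frequency; all-zero spectra are flagged and given $f_{peak} = 0$.

**Functional connectivity.** For each pair, Pearson correlation of the two
1-s segments at every integer-millisecond lag within ±250 ms, each lag
normalized by the overlapping samples' own means and standard deviations
(this avoids edge bias from the shrinking overlap), maximized over lags.
The default takes the signed maximum, keeping anti-correlation visible; an
absolute mode returns the signed value at the lag maximizing $|r|$. The
matrix is symmetric with unit diagonal; pairs with no lag of nonzero
variance are flagged and set to 0.

**Effects.** With $FC_b$ (1–2 s) and $FC_d$ (2–3 s),
$fe = \overline{|FC_d - FC_b|}$ (mean over the strictly upper triangle,
$fe \in [0,2]$) and $se = \rho(FC_d, SC) - \rho(FC_b, SC)$ (Pearson over
upper-triangle entries, all pairs including unconnected ones,
$se \in [-2,2]$).

**Statistics.** Per (noise amplitude, realization): Pearson r between
per-site effects and weighted degree, the OLS adjusted
$R^2 = 1-(1-R^2)(n-1)/(n-2)$, two-sided t-based p-values, and
Benjamini–Hochberg FDR across all noise amplitudes and realizations within
each effect family. Structure–frequency similarity uses Spearman rank
correlation over all off-diagonal entries (both orderings of each pair, as
the matrices are vectorized), average ranks for ties, t-approximate
p-values. Degree is weighted strength by default (a binary mode exists);
effects are computed per realization first and averaged afterwards.

## Pipeline and chosen problem sizes

1. **Coupling sweep** (`coupling_sweep`): 2-s unstimulated runs over the
   coupling grid; the threshold $c^*$ is the grid value with the largest
   increment of network-mean activity at the reference $\sigma = 10^{-5}$,
   requiring that increment to exceed 10× the median increment (otherwise
   "no threshold"); the working coupling is one grid step below $c^*$.
   The detected threshold is checked, not assumed, to be
   noise-independent.
2. **Stimulation grid** (`stimulation_grid`): one 3-s run per (σ, site,
   realization), effects and spectra as above; checkpointed and
   resumable; sub-streams derived deterministically from the cell index.
3. **Associations, structure–frequency similarity, system summaries** as
   above.

The packaged study (analysis/ scripts and the trend tests) uses a
40-region network, the 6-point noise grid $\{10^{-9}, 10^{-7}, 10^{-5},
10^{-4}, 10^{-3}, 10^{-2}\}$, all sites, 5 realizations, at
$\Delta t = 10^{-5}$ s — sizes chosen so the full grid is an
afternoon-coffee computation on a single core while leaving the regime
structure clearly resolved. Convergence of the coarser step was checked
against $\Delta t = 5\times10^{-6}$ on a quasi-deterministic cell
(relative difference in $fe$ about 0.5%). The qualitative contract on
synthetic data comprises the regimes: strong suppression of $fe$ with
rising noise (≥4× from $10^{-9}$ to $10^{-2}$), an interior noise
amplitude maximizing r(fe, degree), and the rise of r(se, degree) toward
positive values at the largest noise before the effects collapse.

## Numerical and design choices worth knowing

* Windowed lagged correlation uses FFT cross-sums plus prefix-sum
  means/variances; window variances below $10^{-11}$ of the window energy
  are treated as zero (cancellation guard). Rows are demeaned first —
  per-lag Pearson is offset-invariant, so this only improves conditioning.
* The oscillatory-before-stimulation exclusion for the noise-averaged
  peak-frequency matrix flags entries with pre-stimulation
  $f_{peak} > 10$ Hz (the sub-threshold regime sits below 10 Hz).
* Ties in the lag maximization resolve toward the most negative lag; ties
  in peak frequency toward the lower frequency — both deterministic.
* `detect_threshold` on a strictly linear activity profile errors rather
  than returning an arbitrary grid point.
* p-values for correlations use the t approximation throughout (exact
  permutation nulls are out of scope).

## Limitations

Identical Wilson–Cowan parameters for every region; a single constant
stimulation protocol; no plasticity, no regional heterogeneity, no
empirical-data comparison. Synthetic connectomes support qualitative
regime statements only — headline correlation values measured on an
empirical connectome (e.g. structure–frequency $\rho$) are expected to
differ in magnitude on synthetic networks.
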