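---
title: "A multi-frequency Jansen-Rit whole-brain model with homeostatic inhibition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multi-frequency Jansen-Rit whole-brain model with homeostatic inhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfjr)
```

## The model

Each brain region is a cortical column made of **two Jansen-Rit
subpopulations**, one tuned to the EEG alpha band and one to the gamma band.
A subpopulation consists of pyramidal cells, excitatory and inhibitory
interneurons; membrane potentials are converted to firing rates by the
logistic sigmoid

\[ S(v) = \frac{\zeta_{max}}{1 + e^{r (v_{th} - v)}} \]

with \(\zeta_{max} = 5\) Hz, \(r = 0.56\) mV\(^{-1}\), \(v_{th} = 6\) mV, and
rates are converted back to postsynaptic potentials (PSPs) by the
alpha-function kernel \(h(t) = A\,a\,t\,e^{-at}\). Per subpopulation
\(s \in \{\alpha, \gamma\}\) of region \(i\), the second-order form is

\[
\begin{aligned}
\ddot x_0 &= A_s a_s S(x_1 - x_2) - 2 a_s \dot x_0 - a_s^2 x_0\\
\ddot x_1 &= A_s a_s \bigl(p(t) + C_2 S(C_1 x_0) + K C \textstyle\sum_{j \ne i} M_{ij} S(v_j)\bigr) - 2 a_s \dot x_1 - a_s^2 x_1\\
\ddot x_2 &= B_s b_s C_4^{(s)} S(C_3 x_0) - 2 b_s \dot x_2 - b_s^2 x_2
\end{aligned}
\]

where \(v_j\) is region \(j\)'s **combined pyramidal PSP**
\(v = r_\alpha (x_1^\alpha - x_2^\alpha) + (1 - r_\alpha)(x_1^\gamma - x_2^\gamma)\),
the EEG-like output. The mixing weight \(r_\alpha \in [0, 1]\) is the
proportion of alpha subpopulation: \(r_\alpha = 1\) is the classical
single-population column, \(r_\alpha = 0\) a purely fast column, and
intermediate values yield broadband spectra. The slow subpopulation uses
\(A = 3.9\) mV, \(a = 120\) s\(^{-1}\), \(B = 26.4\) mV, \(b = 60\)
s\(^{-1}\); the fast one \(a = 660\), \(b = 330\) s\(^{-1}\) with gains tied
to the time constants by \(A = 32.5a/1000\), \(B = 440b/1000\) (evaluating
those formulas at the slow time constants recovers the slow gains, which is
how the package validates them). Local gains are fractions of one scale
\(C = 135\): \(C_1 = C\), \(C_2 = 0.8C\), \(C_3 = 0.25C\),
\(C_4(0) = 0.25C\).

**Inhibitory synaptic plasticity (ISP).** Each subpopulation's
inhibitory-to-pyramidal gain \(C_4\) obeys a Vogels-type homeostatic rule,

\[ \tau \frac{dC_4}{dt} = \zeta_{inh} (\zeta_{pyr} - \rho)
   \left(\frac{C_4 - C_{4,min}}{C}\right)^{\beta}, \]

with \(\zeta_{pyr} = S(x_1 - x_2)\) and \(\zeta_{inh} = S(C_3 x_0)\) of the
same subpopulation, target rate \(\rho = 2.5\) Hz, \(\tau = 2\) s,
soft-bound exponent \(\beta = 1\), and \(C_{4,min} = 0\). When pyramidal
firing exceeds the target, feedback inhibition grows; below target it is
released. This makes \(\rho\) a bifurcation control: low targets put the
column below the Hopf point (slow, large-amplitude or silent dynamics),
higher targets move it through alpha-band cycles towards fast activity, and
the oscillatory range of the background input widens dramatically
(`attractor_scan()` demonstrates this numerically).

## What the integrator does, exactly

`simulate_jr()` uses an **explicit Euler–Maruyama scheme at
\(\Delta t = 1\) ms** with simultaneous updates (all derivatives evaluated
on the pre-step state), in compiled code, seeded from R's RNG so equal
seeds give bit-identical trajectories. The background drive
\(p(t)\) has mean 220 Hz and SD 31 Hz. Two noise readings are provided:

* `noise_mode = "iid"` (default): \(p\) is redrawn from
  \(N(220, 31)\) at every step, per node and subpopulation — the literal
  "values randomly sampled from a normal distribution". Its effective
  diffusion amplitude is \(\sigma_p \sqrt{\Delta t}\), i.e. step-size
  dependent, but at the model's native 1-ms step it reproduces the
  single-node phenomenology (stochastic alpha node peaks at ~11.5 Hz).
* `noise_mode = "diffusion"`: \(A_s a_s \sigma_p \sqrt{\Delta t}\,\xi\) is
  added to the \(\dot y_1\) update — the step-size-invariant SDE reading.
  At \(\sigma_p = 31\) Hz this injects a much stronger fluctuation
  (equivalent to i.i.d. SD \(\approx 980\) Hz at 1 ms) and drags the alpha
  peak down to ~7 Hz; it is kept as an option, not the default.

Outputs (combined PSP, combined pyramidal rate, \(x_0\), \(C_4\)) are
recorded after a transient `t_discard` (default 60 s) and decimated to
`out_fs` (default 200 Hz) by **block averaging** over each
\(1/(\Delta t \cdot f_{out})\) window — a boxcar low-pass applied before
subsampling, chosen over an IIR anti-aliasing filter so memory stays
proportional to the output length for large networks. Initial conditions
are the origin with \(C_4 = 0.25C\); the discard window absorbs the
transient. A divergence guard aborts with a diagnostic if the state leaves
\([-10^9, 10^9]\) (the sigmoid bounds all drives, so this only triggers on
pathological parameters).

A fidelity note that matters when comparing against continuum analysis: at
1 ms the fast subpopulation (\(a = 660\) s\(^{-1}\), \(a\Delta t = 0.66\))
is marginally resolved. Its discrete-time limit cycle runs at ~35 Hz,
whereas the continuous-time system (recovered at \(\Delta t = 0.1\) ms)
runs at ~69 Hz — an exact 5.5x time-rescaling of the slow subpopulation.
The package treats the 1-ms discretisation as part of the model definition,
since all of the reference phenomenology was produced at that step.

Another consequence of the printed ISP rule worth stating plainly: its
equilibrium balances \(E[\zeta_{inh}(\zeta_{pyr} - \rho)] = 0\). On a limit
cycle \(\zeta_{inh}\) and \(\zeta_{pyr}\) covary positively, so the
time-averaged pyramidal rate settles **below** \(\rho\) by
\(\mathrm{cov}(\zeta_{inh}, \zeta_{pyr}) / E[\zeta_{inh}]\) — about 0.5–0.9
Hz for targets in \([2, 3]\) Hz (20–35% relative). Exact clamping holds
only at fixed points. The qualitative homeostasis (mean rate increasing
with \(\rho\), \(C_4\) decreasing, tau-independent spectra) is robust and
tested; the `isp_clamping` experiment reports the measured bias.

## From rates to BOLD

`simulate_bold()` feeds the combined pyramidal rate (Hz, unscaled; an
optional gain exists because the hemodynamic formulation assumes O(1)
inputs) into the generalized Balloon–Windkessel cascade — vasodilatory
signal, inflow, volume, deoxyhemoglobin, with
\(\tau_s = 0.65\), \(\tau_f = 0.41\), \(\tau_v = \tau_q = 0.98\) s,
\(\kappa = 0.32\), \(E_0 = 0.4\) — integrated with explicit Euler at 10 ms
and read out as
\(B = V_0 (k_1(1-q) + k_2(1-q/v) + k_3(1-v))\), \(V_0 = 0.04\),
\(k_{1,2,3} = 2.77, 0.2, 0.5\), decimated to TR = 2.08 s. The neural series
is resampled to the 10-ms grid by bin means. Rest \((0,1,1,1)\) is
preserved to machine precision under zero input. Being first order, the
10-ms Euler solution differs from a 1-ms reference by ~1% of the response
amplitude on a 1-s test pulse; the refinement tests assert first-order
convergence (halving the step roughly halves the error) rather than a
tighter bound that a first-order scheme cannot meet.

## Observables

The EEG pipeline mirrors the empirical one: 3rd-order **Bessel band-pass**
in the canonical bands (delta 0.5–4, theta 4–8, alpha 8–13, beta 13–30 Hz),
Hilbert **amplitude envelopes**, 3rd-order Butterworth 0.5-Hz high-pass of
the envelopes, and Pearson correlation between all region pairs
(`envelope_fc()`). BOLD FC band-passes 0.01–0.08 Hz at TR before
correlating. Spectra use **Welch's method** with 2-s Hann windows, 50%
overlap, mean detrending (0.5-Hz resolution); relative band powers
integrate the PSD per band over the 0.5–30 Hz total (tiling bands sum to 1
by construction). Numerical choices the data do not dictate: filters are
applied zero-phase (forward–backward with odd-extension padding and
steady-state initial conditions) because FC is phase-sensitive; envelope
edges are trimmed by 1 s before correlating; PSD peak ties break to the
lower frequency. No IIR design routine ships with the available R stack,
so the Bessel/Butterworth designs are implemented in-package
(prototype poles, band transform, bilinear transform) and pinned by tests
to reference coefficients.

## Fitting

`ssim()` implements the windowed structural similarity index (Gaussian
window, sigma 1.5, 11x11 shrunk for small matrices, stability constants
from a data range pinned to the joint span of both matrices — essential for
correlation-valued input), `clarkson_goodness()` the spectral goodness
\(1 - \tfrac12 \lVert x/\lVert x\rVert - y/\lVert y\rVert \rVert\), and
`cohens_d()` the pooled-SD effect size with the usual qualitative bins.
`grid_sweep()` runs the exhaustive grid the model is fitted by (no
gradients): per cell, `n_seeds` simulations; BOLD FCs are averaged across
seeds before SSIM, EEG metrics averaged after, matching the stated
seed-averaging orders. `dual_fit_select()` applies the EEG goodness surface
as a mask (threshold 0.85) and maximises the fMRI SSIM inside it, ties
broken towards low K then low rho; an empty mask is an explicit no-fit.
FC diagonals are kept at 1 in both matrices so SSIM windows stay dense.

## Synthetic world

With the empirical datasets available only on request, the package ships a
generator rather than data. `synthetic_connectome(n)` builds a modular,
hemispherically mirrored weight matrix (homologs on the anti-diagonal, so
`add_homotopic()` applies exactly as for AAL ordering), weights in [0, 1],
deterministic per seed; defaults (2 modules per hemisphere, 0.8/0.2
intra/inter densities) give the dense-within, sparse-between structure
typical of group-averaged DTI connectomes at desk scale (8 nodes in tests).
What it does **not** emulate: realistic degree distributions, distance-
dependent weights, inter-subject variability, tract-length delays. A green
network test therefore establishes that the dynamics and fitting machinery
behave as specified on a connectome-shaped coupling, not that empirical FC
is reproduced.

The dual-fit demonstration generates its "empirical" targets by simulating
at a known \((K^*, \rho^*) = (1.5, 2.5)\) with a held-out seed (theta/
alpha/beta relative power of the region-mean EEG + BOLD FC), then recovers
the generating cell on a 5x5 grid over \(K \in [0, 3]\),
\(\rho \in [2, 3]\) with 3 seeds per cell — the paper-scale 41x41x50 sweep
reduced to desk scale; simulations are 320 s (not 660 s) so that BOLD FC
retains the >= 200 s the 0.01-Hz filter needs while staying inside the test
budget.

## Worked example

```{r example, eval = FALSE}
library(mfjr)

# an isolated classical column: alpha rhythm
p <- jr_params(r_alpha = 1, K = 0,
               plasticity = plasticity_params(enabled = FALSE),
               drive = drive_params(p_sd = 0))
sim <- simulate_jr(NULL, p, jr_protocol(t_sim = 180, t_discard = 60, seed = 1))
dominant_frequency(welch_psd(sim$eeg[, 1], sim$fs))
#> [1] 11.5

# homeostatic widening of the oscillatory input range
scan <- run_experiment("attractor_scan")
scan$summary$n_oscillating_no_isp   #> 8
scan$summary$n_oscillating_isp      #> 15

# dual-fit parameter recovery on a synthetic connectome
demo <- run_experiment("dual_fit_demo")
demo$fit$selected                   #> K = 1.5, rho = 2.5
```

## Known limitations

* No conduction delays, no region-heterogeneous parameters, no
  thalamo-cortical loop, no EEG forward model (sensor-level spectra are
  approximated by region averages).
* The 1-ms step under-resolves the gamma subpopulation (see above); treat
  gamma-band frequencies as properties of the discretised model.
* The printed ISP rule clamps rates with a covariance bias on limit cycles
  (see above); use the reported mean rates, not the nominal target, when an
  exact rate matters.
* Bifurcation structure is probed numerically (`attractor_scan()`), not by
  continuation; the oscillation flag depends on a peak-to-peak threshold
  (0.1 mV) that cleanly separates settled fixed points from limit cycles in
  this model but is not a proof of a bifurcation.
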