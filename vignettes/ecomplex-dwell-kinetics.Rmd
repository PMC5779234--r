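---
title: "Dwell-time kinetics of spliceosome E-complex formation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dwell-time kinetics of spliceosome E-complex formation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smdwell)
```

`smdwell` analyzes colocalization single-molecule spectroscopy (CoSMoS)
recordings of spliceosome E-complex assembly: fluorescent U1 snRNP and
branchpoint bridging protein (BBP) binding and releasing individual
surface-tethered pre-mRNA molecules. This vignette is the package's account
of the underlying models, the tunable parameters, and the design choices
made where the methodology was genuinely open. No number quoted here is
asserted anywhere that the test suite or the acceptance script does not
recompute.

## The observable and its censoring window

The primary observable is the *dwell time*: how long a fluorescent factor
remains colocalized with one RNA. Recordings are frame-sampled — by default
1 s exposures every 5 s for 30 min (360 frames, 1800 s) via
`frame_schedule()` — which bounds what is observable:

* no dwell shorter than one frame interval `t_m` can be measured (events
  shorter than ~0.5 s can fall entirely between exposures and are
  invisible; anything detected spans at least one frame);
* no dwell longer than the record `t_max` can be measured.

Fitted densities are therefore truncated and renormalized on
`[t_m, t_max]`, by default `[5, 1800]` s (`censor_window()`). With
amplitude $A_1$ ($A_2 = 1 - A_1$ is always derived, never stored), the
two-component density is

$$
f(t) \;=\;
\frac{\frac{A_1}{\tau_1} e^{-t/\tau_1} + \frac{A_2}{\tau_2} e^{-t/\tau_2}}
     {A_1\!\left(e^{-t_m/\tau_1} - e^{-t_{max}/\tau_1}\right)
    + A_2\!\left(e^{-t_m/\tau_2} - e^{-t_{max}/\tau_2}\right)},
\qquad t \in [t_m, t_{max}],
$$

and the one-component form is its $A_1 = 1$ special case. Each normalizer
term must carry its own time constant — with $\tau_1$ in both terms the
expression would not integrate to one, which is the prefactor's entire
purpose; `censored_pdf()` has a property test asserting unit mass to
$10^{-6}$ for random parameter draws.

**Truncation, not censoring of boundary events.** Dwells in contact with a
record boundary (already bound at the first frame, or still bound at the
last) have unknown total length. They are flagged by `extract_dwells()`
and *excluded* from fitting rather than entered as right-censored
likelihood terms: the density above is normalized on the observable
window, i.e. it models *completed* dwells, and mixing censored terms into
a truncated model would double-count the window. The same convention is
applied to conditional lifetimes and E-complex durations.

**Duration convention.** A run of $k$ consecutive present frames is
recorded as $k \times \text{interval}$ seconds: the temporal resolution is
one frame interval and `t_m` equals that interval, so durations are
quantized at the frame spacing. Two consequences, visible in
`analysis/02_dwell_fits.R` when fitting frame-sampled records end to end:
sub-frame events that happen to touch an exposure are recorded as
one-frame dwells (biasing $\hat\tau_1$ low), and completed dwells starting
late in a record face less than the full window (biasing $\hat\tau_2$ low
relative to the generator). Measured records share both conventions, so
fitted constants are comparable across conditions even though they sit
below the generator's when the truth is known. Fits of dwells drawn
directly from the window density itself (the acceptance operating point)
are unbiased.

## Maximum likelihood, bootstrap, model selection

`fit_mle()` maximizes the unbinned log-likelihood. The one-component fit
reduces to a one-dimensional search over $\log\tau$ through the sufficient
statistic $\sum_i t_i$ (in the untruncated limit the optimum is the sample
mean, which the tests assert). The two-component likelihood is multimodal,
so optimization runs in unconstrained coordinates — logit $A_1$,
$\log\tau_1$, $\log(\tau_2 - \tau_1)$, which enforces
$0 \le A_1 \le 1$ and $\tau_1 \le \tau_2$ — with Nelder-Mead from ten
starts (one moment-based, nine stratified random; deterministic given the
seed). Amplitudes driven to a boundary ($A_1 \to 0$ or $1$: no resolvable
second component) are flagged rather than hidden.

`bootstrap_fit()` resamples dwells (cases, matching how experimental
events are exchangeable), refits each of `n_boot` replicates warm-started
from the full-data optimum, and reports per-parameter standard deviations;
1000 resamples is the reporting default, and tests verify both the
$\pm 2\,\mathrm{SD}$ coverage (about 95% over repeated simulations) and
the $\sqrt{n}$ scaling of the SD. Failed replicate refits are dropped and
counted; more than 10% failures aborts.

`select_model()` compares one against two components with a likelihood
ratio whose null is non-standard: the extra parameters sit partly on the
boundary of the parameter space, so the deviance null is approximated by
the 50:50 mixture of a point mass at zero and $\chi^2_2$. At the default
$\alpha = 0.05$ this keeps the false-two-component rate near 5% while
detecting a well-separated mixture (20 s / 165 s at equal amplitude,
$n = 5000$) essentially always. A p-value exactly at $\alpha$ keeps the
simpler model.

Probability-density histograms (`density_histogram()`) divide each bin
count by bin width times total events, with per-bin counting errors from
the binomial variance, $\sqrt{n_i (1 - n_i/N)}/(N w_i)$.
`photobleach_extrapolate()` separates dissociation from photobleaching by
regressing each component's observed rate $1/\tau$ on laser power
(weighted by inverse bootstrap variances when available): the zero-power
intercept is the bleach-corrected dissociation rate, and a slope within
two standard errors of zero flags minimal photobleaching.

## The synthetic-data generator

Because raw single-molecule records of this kind are not publicly
deposited, the package generates its own under explicit kinetic schemes,
and the generator is first-class, tested code.

`kinetic_scheme()` defines a continuous-time Markov chain over named
states with strictly positive rate constants; rates are memoryless, the
dark state must be reachable from every bound state, and bound intervals
are maximal spans in bound states. Three constructors cover the schemes of
interest: `one_step_scheme()`, `two_step_scheme()` (short-lived initial
5'SS complex converting to a long-lived stabilized complex — the mechanism
favored for U1), and `independent_pathway_scheme()` (two
non-interconverting complexes). `simulate_timeline()` is an exact
Gillespie realization; `dwell_distribution_from_scheme()` gives the exact
phase-type dwell law of any scheme with at most two bound states by
eigen-decomposition of the bound sub-generator, and a goodness-of-fit test
checks it against $10^5$ brute-force draws.

`frame_sample()` imposes the acquisition: a frame reads present iff a
bound interval overlaps its exposure (this reproduces the sub-frame
detection floor), optional photobleaching truncates intervals with
constant hazard per illuminated second, and optional surface background
adds spurious single-frame presences (default rate 0 — such events are
rare on passivated surfaces). The generator emulates exponential arrivals
and phase-type dwells, frame sampling, the detection floor, bleaching and
background; it does **not** emulate 2-D images, point-spread functions,
camera noise fields, spatial diffusion/rebinding, or intensity
fluctuations beyond optional Gaussian noise around unit fluorophore
levels. Passing tests therefore validate the dwell-time and colocalization
statistics, not image-level processing, which the package deliberately
starts downstream of.

Seeds are explicit arguments everywhere; any simulation is reproducible
bit for bit given its configuration and seed. Intervals are half-open
`[start, end)` in seconds throughout.

## The coupled two-channel model and its calibration

`coupling_spec()` joins a U1 scheme and a BBP scheme into one product-state
chain in which BBP occupancy stabilizes U1: while BBP is bound, U1
dissociation rates are divided by `stabilization_factor` (and,
optionally, U1 bound-to-bound transitions multiplied by
`transition_multiplier`). Coupling is instantaneous rate switching on
partner occupancy — the simplest mechanism that produces a
conditional-lifetime effect; `stabilization_factor = 1` recovers two
independent channels, a decoupled limit the tests exercise.

**Calibration to observed conditional means.** The headline conditional
U1 lifetimes (182.3 s colocalized with BBP, 73.6 s without) are
*measured* class means inside a finite record from which truncated dwells
were excluded. For binding events starting at a stationary (uniform) rate
over a record of length $R$, a true exponential mean $\tau$ is observed
among completed dwells as

$$
m(\tau) = \tau \;-\;
\frac{\tau^2 \left(1 - e^{-R/\tau}(1 + R/\tau)\right)}
     {R - \tau\left(1 - e^{-R/\tau}\right)} \;<\; \tau ,
$$

because long events are preferentially cut off by the record end
(`windowed_complete_mean()`). `calibrate_conditional_coupling()` therefore
inverts $m$ with `uniroot` and sets the *true* conditional lifetimes to
$m^{-1}(182.3) \approx 210$ s and $m^{-1}(73.6) \approx 77$ s
(stabilization factor $\approx 2.73$). Calibrating the true means to the
printed values directly would make the recovered class means ~11% low
($m(182.3) \approx 161.8$ s at $R = 1800$ s).

For this calibration the BBP channel is made quasi-static
($k_{on} = k_{off} = 10^{-6}\,\mathrm{s^{-1}}$, equilibrium initial
occupancy of one half): each molecule is BBP-occupied or BBP-free for
essentially its whole record, so the two U1 dwell classes are clean single
exponentials and the closed-form calibration is exact (the equilibrium
start also makes dwell-start times exactly stationary, which the formula
assumes). This is a deliberate idealization of the study conditions: with
a rapidly cycling partner, classifying a dwell as "with partner" whenever
any overlap exists *length-biases* the classes — longer dwells have more
opportunity to be tagged — and conditional distributions differ even
without coupling. The decoupled-limit test uses the quasi-static regime
for exactly this reason, and `analysis/03_ecomplex_coloc.R` uses a
separate, dynamically cycling simulation for the turnover analyses.

## Colocalization, fates, assembly order

`find_coloc()` reports maximal U1xBBP interval overlaps per molecule with
entry and exit labels at frame resolution: arrivals within one frame
interval are "simultaneous"; exact departure ties (probability zero in
continuous simulations, possible in frame-quantized data) break toward
U1 loss, deterministically. Complexes reaching the record end are labeled
`record-end` and excluded from fate fractions as censored, since their
resolution was not observed.

`conditional_dwells()` partitions completed U1 dwells by whether any BBP
overlap exists during the dwell (a binary classification at any overlap
$\ge$ one frame). `randomized_control()` reassigns BBP channels across
molecules by a random derangement — no molecule keeps its own partner —
which destroys genuine coupling while preserving both marginals. When
testing that the control abolishes the conditional difference, the package
compares *molecule-level* class means: after permutation all dwells of a
molecule share a class, so dwells are not independent units and a naive
per-dwell t-test over-rejects.

`classify_fates()` resolves each complex's disassembly: the channel lost
first is identified at the complex end; if it rebinds while the partner
persists, the corresponding site was *redefined* (5'SS redefinition for
U1, branchsite redefinition for BBP); if the partner is lost before any
rebinding, the complex decayed by double loss. The rebinding lookahead
extends to the record end (no arbitrary cap). By default only each
molecule's *initial* complex is tallied, matching the convention of
reporting fates of initial colocalized complexes; `initial_only = FALSE`
classifies every episode. Fractions carry binomial counting errors and sum
to one. `assembly_order()` tallies which factor arrived first;
restricted to initial complexes it reproduces the competing-exponentials
arrival race (a 3:1 arrival-rate ratio gives 3:1 first-binder odds), which
the tests verify.

`fit_affine()` provides the least-squares affine registration between the
two camera fields of view from matched bead positions, with the RMS
residual reported; it requires at least three non-collinear pairs.

## Splice-site base pairing

`count_basepairs()` scans every ungapped antiparallel register of a 5'
splice-site region against the U1 snRNA 5' end and returns the register
maximizing paired positions. Watson-Crick pairs (A:U, G:C) count by
default; G:U wobble counts only when requested, since the headline counts
are of potential Watson-Crick pairs against the consensus. Ties between
registers break toward fewer internal mismatches, then the smaller offset;
a property test checks the scan against an independent brute-force
implementation.

The packaged U1 5' end is `AUACUUACCU` — the first ten nucleotides of the
region defined by the ablation oligo used to destroy 5'SS pairing. The
packaged consensus region is `GGUAUGU` (the terminal exonic G plus the
intronic hexamer), which forms 6 Watson-Crick pairs; the weak SUS1-derived
site `GUAUGA` forms 4; a hyperstabilized site built as the exact reverse
complement of the 10-nt U1 5' end forms 10. The published exon context of
the reporter constructs is in supplementary material that is not part of
the package, so the exact exonic extent of the consensus region is this
package's choice; including a second exonic position (`AG...`) would add a
seventh pair at the same register. `tau_to_rate()` converts fitted time
constants to rate constants (a 165 s time constant is
$0.36\,\mathrm{min^{-1}}$, ~0.4 at one significant figure — the
dissociation bound on cross-intron bridging interactions).

## Numerical choices and problem sizes

* Optimizer: Nelder-Mead, relative tolerance $10^{-10}$, at most 2000
  iterations; bootstrap refits warm-start from the full-data optimum with
  relative tolerance $10^{-9}$.
* One-component fits search $\log\tau$ over mean/100 to 100x mean with
  `optimize` at tolerance $10^{-12}$.
* Degenerate inputs: identical dwells produce a warned degenerate fit with
  $\tau$ equal to that value and zero bootstrap spread; empty bins have
  density and error zero; an all-dark trace has zero occupancy steps.
* Stationary distributions of joint chains are solved by least squares on
  $\pi Q = 0$ with the normalization row appended.
* The test suite and the analysis scripts use simulation sizes chosen as
  the package's standard operating points: 5000 dwells for parameter
  recovery, 1500-2000 molecules for two-channel analyses, $10^5$ draws for
  distributional goodness-of-fit, 200 simulated datasets for bootstrap
  coverage, and 200-1000 bootstrap resamples depending on context (1000
  remains the reporting default for final fits).

## Known limitations

* Dwell-time fits assume completed dwells drawn from the window density;
  per-event availability inside the record (see above) is a shared
  convention with measured data rather than corrected for.
* The phase-type closed form covers schemes with at most two bound states;
  three or more bound states (or mixtures with three components) are out
  of scope.
* The coupled model stabilizes U1 only while BBP is bound, with no delay
  or memory; cooperative mechanisms with history dependence are not
  representable.
* Step counting quantizes against the smallest positive plateau and will
  read a trace that only ever shows simultaneous double occupancy as one
  level.
* No three-color (cap-binding complex) analysis and no image-level
  processing.
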