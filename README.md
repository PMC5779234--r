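# smdwell

Single-molecule dwell-time kinetics of spliceosome E-complex assembly.

## What this is for

The spliceosome's earliest committed intermediate, the E complex, forms
when U1 snRNP engages a pre-mRNA 5' splice site (5'SS) and branchpoint
bridging protein (BBP) engages the branchsite. Colocalization
single-molecule spectroscopy (CoSMoS) watches these events directly: a
fluorescent factor binding a surface-tethered RNA appears as a spot whose
lifetime — the *dwell time* — reports the stability of the complex, and
two-color recordings reveal which factor arrives first, how long the
colocalized complex persists, and whether splice sites are redefined after
a factor departs.

`smdwell` is an R package plus a set of analysis scripts for this kind of
data, written for single-molecule biophysicists and RNA biochemists. It
covers both directions of the problem:

* **simulation** — exact-stochastic (Gillespie) binding timelines under
  explicit kinetic schemes (one-step, two-step with a stabilized complex,
  independent pathways, and a coupled two-channel U1/BBP model in which
  BBP occupancy stabilizes U1), frame-sampled the way a camera would
  record them (1 s exposures every 5 s for 30 min by default), with
  detection floor, photobleaching and surface background;
* **analysis** — extraction of dwell times with truncation bookkeeping,
  maximum-likelihood fitting of window-censored exponential mixtures with
  bootstrap uncertainties and likelihood-ratio model selection,
  probability-density histograms with binomial counting errors,
  photobleaching extrapolation across laser powers, two-channel
  colocalization (E-complex lifetimes, conditional U1 lifetimes with a
  randomized control, disassembly fates, assembly order), affine
  field-of-view registration, and 5'SS/U1-snRNA base-pairing register
  scans.

## The model at the core

Observed dwell times are confined to a window: nothing shorter than one
frame interval `t_m` nor longer than the record `t_max` can be measured.
Dwell distributions are therefore fit by unbinned maximum likelihood to
the truncated density

```
f(t) = [ (A1/tau1) e^(-t/tau1) + (A2/tau2) e^(-t/tau2) ]
     / [ A1 (e^(-t_m/tau1) - e^(-t_max/tau1)) + A2 (e^(-t_m/tau2) - e^(-t_max/tau2)) ]
```

on `t in [t_m, t_max]`, with `A2 = 1 - A1`; the single-exponential form is
the `A1 = 1` special case. Parameter uncertainties come from a
case-resampling bootstrap (1000 resamples by default); one vs. two
components is decided by a boundary-corrected likelihood-ratio test. The
package also provides the exact phase-type dwell law of any scheme with at
most two bound states (eigen-decomposition of the bound sub-generator), so
fitted mixtures can be compared against mechanistic schemes directly.

## Worked example

Simulate 5000 completed dwells at the E-complex operating point
(equal-amplitude 20 s / 165 s mixture in the 5-1800 s window), refit them,
and convert the slow time constant into a dissociation rate:

```r
library(smdwell)
w     <- censor_window(5, 1800)
truth <- exp_mixture_model(A1 = 0.5, tau1 = 20, tau2 = 165, window = w)
d     <- sample_mixture_dwells(truth, 5000, seed = 1)
fit   <- bootstrap_fit(d, 2, w, n_boot = 200, seed = 2)
fit
#> Censored biexponential: A1 = 0.483, tau1 = 20.86 s, tau2 = 162.5 s  [window 5-1800 s]
#>   loglik -27464.20 on 5000 dwells
#>   bootstrap SD (200 resamples): A1 0.01365, tau1 0.9205, tau2 4.056
round_rate(tau_to_rate(fit$model$tau2, "per_minute"))
#> [1] 0.4
```

The fit recovers the generating amplitudes and time constants within their
bootstrap uncertainties; a ~165 s long-lived complex dissociates at ~0.4
per minute.

A coupled two-channel simulation, calibrated so the window-censored
conditional U1 lifetimes match measured values, is recovered by the
colocalization analysis:

```r
cp  <- calibrate_conditional_coupling(mean_with = 182.3, mean_without = 73.6)
rec <- simulate_two_channel(cp, 1000, frame_schedule(), seed = 3,
                            start_at_equilibrium = TRUE)
cd  <- conditional_dwells(rec)
mean_lifetime(cd$duration_s[cd$with_bbp])   # 178.4 +/- 4.7 s (n = 1475)
mean_lifetime(cd$duration_s[!cd$with_bbp])  # 74.5 +/- 1.5 s (n = 2394)
```

U1 dwells overlapping BBP are about 2.5-fold longer than dwells without
BBP — the conditional-lifetime signature of BBP-stabilized U1 binding —
and `randomized_control()` (re-pairing channels across molecules by a
derangement) abolishes the difference. Base-pairing counts behind the
splice-site series:

```r
count_basepairs(consensus_5ss_region())$n_pairs        # 6
count_basepairs(weak_5ss_region())$n_pairs             # 4
count_basepairs(hyperstabilized_5ss_region())$n_pairs  # 10
```

## Analysis scripts

`analysis/` holds the end-to-end workflow as numbered scripts, each a thin
driver over package functions that prints what it found and writes tables
under `results/`:

1. `01_simulate_binding.R` — two-step U1 binding records, frame-sampled,
   dwells extracted;
2. `02_dwell_fits.R` — censored mixture fits with bootstrap errors, model
   selection, density histogram and overlay figure;
3. `03_ecomplex_coloc.R` — coupled two-channel analysis: conditional
   lifetimes with randomized control, E-complex lifetimes, fates,
   assembly order, rastergram;
4. `04_splice_site_pairing.R` — base-pairing table for the 5'SS variants
   and the rate-constant conversion.

`run_pipeline()` runs the same stages from a single YAML/JSON config and
writes a manifest enabling bit-exact re-runs.

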