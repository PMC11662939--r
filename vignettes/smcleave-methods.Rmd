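---
title: "Models and methods behind smcleave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smcleave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smcleave)
```

# Scope

`smcleave` models how a miniature type V-F CRISPR nuclease takes a bound
DNA target apart: an initial nick of the displaced non-target strand (NTS)
inside the protospacer, bidirectional exonucleolytic trimming outward from
that nick, unwinding of the duplex beyond the protospacer, a single
endonucleolytic cut of the target strand (TS) outside the protospacer, and
finally release of the PAM-distal DNA. The package provides (i) a kinetic
model of this sequence with magnesium-dependent rates, gel-band prediction
and rate fitting; (ii) a complete smFRET analysis chain (trace correction,
selection, Gaussian-HMM idealization, dwell/transition statistics) together
with a forward simulator of the measurement; and (iii) optical-tweezers
unzipping mechanics for detecting the protein on DNA as a mechanical
roadblock. Because no raw traces, gels or tweezers records are publicly
deposited for this system, synthetic data generated by the package's own
seeded simulators stand in for every instrument, and all quantitative tests
are against known generating truths.

# The substrate coordinate system

All positions use protospacer coordinates: +1 is the first protospacer
nucleotide next to the PAM and +20 the PAM-distal end of the 20-nt
protospacer. A cut at position $p$ severs the backbone bond on the 3' side
of nucleotide $p$ on the cut strand's own axis. With a PAM-proximal flank
of $f$ nucleotides (PAM included), the fragment carrying the PAM-proximal
duplex end has length $f + p$ and its complement $L - f - p$ on an
$L$-bp substrate. The standard 80-bp substrate uses $f = 26$, fixed by the
anchor relation that the +16 nick yields a 42-nt 5'-labelled NTS fragment;
this single choice then reproduces every other observed product length
(40 for +14; 38/36/33/31/29 for the +16..+25 ladder on the 3' label; 31 and
49 for the TS cut at +23; 39/36/35/33 for the +15/+18/+19/+21 products on
the LNA-modified substrate), which is why we treat the convention as
settled rather than tunable.

Locked-nucleic-acid (LNA) modifications spanning +21..+27 resist duplex
opening. Since unwinding is a prerequisite for cleavage, a cut at $p$ is
blocked whenever it requires opening past the first locked pair: the bond
cut at +21 lies at the region boundary and remains allowed, while +23 and
+25 (and the TS cut at +23) are blocked. This reproduces the observed
truncation: the two shortest NTS products and the TS product disappear.

# The sequential cleavage scheme

The kinetic model is a continuous-time Markov chain over lesion states
$(\text{proximal front}, \text{distal front}, \text{TS cut}, \text{released})$:

* `k_nick` — intact → nick at +16;
* `k_trim35` — proximal 3'→5' trim +16 → +14, one 2-nt step (the gel
  resolves no intermediate, so a single step is the most parsimonious
  parameterization);
* `k_trim53` — distal 5'→3' trimming +16 → +18 → +21 → +23 → +25, four
  sequential steps sharing one rate by default (per-step rates are
  accepted). Whether the enzyme removes one nucleotide at a time is not
  resolvable at gel resolution; the ladder positions are what is modelled.
  Trimming past +25 is not included — the data show accumulation at +25,
  and we treat whether the stop is steric or kinetic as open;
* `k_ts` — TS cut at +23, allowed only from states whose distal front has
  reached +21, encoding that out-of-protospacer unwinding is a
  prerequisite;
* `k_release` — PAM-distal release after the TS cut, infinite by default
  (release treated as immediate, matching the prompt dissociation seen in
  the single-molecule data); a finite rate inserts explicit pre-release
  states.

States unreachable under a given rate specification are pruned, so
degenerate schemes (e.g. nick-only) expose exactly the bands they can
produce. Occupancies solve the master equation $\dot p = p\,Q$ via the
matrix exponential; a vectorised Gillespie sampler provides the exact
stochastic counterpart and is tested against the ODE solution at
$10^5$ paths.

## Magnesium dependence

The data constrain the direction of the Mg$^{2+}$ effect (cleavage and
unwinding-coupled steps slow at low Mg; binding is essentially
insensitive) but not its functional form. We apply a Hill factor
$\theta(\mathrm{Mg}) = \mathrm{Mg}^h/(K^h + \mathrm{Mg}^h)$ with $h = 2$,
$K = 4$ mM to the nick, trimming and TS-cut edges — all of which are
unwinding-coupled — and leave release unscaled. This is a modelling choice,
exposed as parameters and fitted in applications, not asserted as
mechanism. At the two experimental anchors it gives
$\theta(10\,\mathrm{mM}) \approx 0.86$ and
$\theta(1\,\mathrm{mM}) \approx 0.06$, i.e. a roughly 15-fold slowdown,
enough to reproduce the qualitative low-Mg phenotypes (premature-state
dominance, rare out-of-protospacer excursions, attenuated release).

## Fixture rates

The study reports kinetics qualitatively, so the default rate constants
are package fixtures chosen once to reproduce the reported phenomenology
at the gel time base (first time point 10 s, reactions followed to tens of
minutes at reduced Mg): `k_nick = 0.10`, `k_trim35 = 0.05`,
`k_trim53 = 0.10`, `k_ts = 0.02` s$^{-1}$ at saturating Mg. With distal
trimming faster than the TS cut, most chains complete the ladder before
the TS cut — matching the observation that the terminal +25 product's
kinetics track the TS cut — while the transient 42-mer → 40-mer
conversion and the rise-and-fade of the intermediate ladder bands emerge
without further adjustment.

`fit_rates` recovers rate constants from band timecourses by weighted
least squares on the log scale (L-BFGS-B), with parametric-bootstrap
confidence intervals. Identifiability is probed by factor-two
perturbations of each fitted rate: a parameter whose perturbation leaves
the residual sum flat is reported in a warning. This matters in practice —
a single-band observable (e.g. the TS product) cannot constrain the
proximal trim, and the recommended protocol is two-stage: fit the nick,
distal-trimming and TS rates on 3'-NTS ladder data, then the proximal trim
on 5'-NTS data with the others held.

# The smFRET forward model

The mechanistic FRET states and their emission means are taken from the
experimental phenomenology: S1 (unbound, $E \approx 0$), pS2 (premature,
partially hybridised R-loop, $E \approx 0.3$), S2 (full R-loop with
ongoing protospacer trimming, $E$ fluctuating 0.4–0.7 around 0.55),
S2′ (stable R-loop, $E \approx 0.6$, low variance; the terminal state with
catalytically dead protein or LNA-blocked substrates), S3
(out-of-protospacer processing, $E \approx 0.9$) and RELEASED
(acceptor-dark, since the acceptor leaves with the guide RNA–bound
complex). The slow S2 fluctuation is modelled as an intra-state
Ornstein–Uhlenbeck wander of the mean (relaxation 2 s, stationary s.d.
0.08 E units) rather than as extra discrete states, because the data
attribute it to continuous trimming, not to switching between defined
levels.

The state graph has three variants mirroring the experimental conditions
(`wt`, `lna` — no S3 and no release, S2 stabilises into S2′ — and `dead` —
binding leads directly to S2′). Binding is pseudo-first-order with a free
apparent rate (the absolute rate and trace-start synchronisation are not
reported; both are simulator parameters). The premature branch fraction at
binding is $1 - \theta(\mathrm{Mg})$, the simplest law consistent with
pS2 dominating at 1 mM and being rare at 10 mM. Rewinding S3 → S2 is
Mg-independent while the competing TS-cut/release edge scales with
$\theta$, so low Mg favours rewinding — the observed behaviour at 5 mM.
Fixture rates (`k_bind = 0.05`, `k_mature = 0.2`, `k_s23 = 0.08`,
`k_rel = 0.5`, `k_rewind = 0.04` s$^{-1}$) put the mean dwells at
$t_1 = 20$ s, $t_2 \approx 15$ s, $t_3 \approx 2.3$ s at 10 mM, so that
most trajectories complete within the 1500-frame, 0.1 s-per-frame
observation window, as in the experiments.
The engineered v5.1 protein is modelled by accelerating only `k_s23`
(3-fold by default), the one step its mutations speed up.

Traces are rendered at 100 ms per frame for 1500 frames: per frame the
occupancy-weighted mean E of the states visited, state emission noise,
constant total intensity split as $I_A = TE$, $I_D = T(1-E)$, channel
backgrounds, Gaussian read noise, donor→acceptor leakage $\alpha$ (0.07
default, capped at 0.2), and single-step photobleaching with per-frame,
per-dye hazards. Acceptor-dark states return the full emission to the
donor channel. Emission noise is deliberately left unclipped in the
renderer — clipping is the analysis side's job — so that the corrected E
distribution of a constant state is an honest Gaussian; this is also why
the E histogram calibration test holds to 2%.

What the simulator does *not* emulate: camera point-spread functions and
spot detection (intensity extraction is upstream of this package),
spectral crosstalk beyond the single leakage fraction, multi-step or
reversible photophysics (blinking beyond missing frames), and any
sequence dependence of the kinetics. Tests passing on these synthetic
ensembles therefore validate the analysis chain's correctness and
statistical behaviour, not instrument-specific artefact handling.

# Trace processing and idealization

Correction follows the standard two-step
$I_D' = I_D - b_D$, $I_A' = I_A - b_A - \alpha I_D'$, and
$E = I_A'/(I_D' + I_A')$ with frames below a total-intensity threshold
set to missing; missing frames are excluded, never interpolated, to avoid
fabricating transitions. Smoothing is the adjacent-averaging mean with a
5-point centred window truncated at the edges, applied only for display
and synchronisation, never before HMM fitting. Trajectory selection is
deterministic with reason codes: active acceptor required at the start,
interior dark gaps at most 2 frames, minimum valid window. Population
contours align traces at the first binding event, defined as E > 0.15
sustained for 3 frames (the trigger is not specified experimentally;
this one is robust to single-frame noise at the fixture SNR).

Idealization uses a single Gaussian-emission HMM shared across all traces
of a condition — pooling stabilises short-dwell statistics and matches the
pooled transition-density analysis — fitted by Baum–Welch EM with scaled
forward–backward passes in compiled code. Numerical choices: emission
s.d. floor 0.01 E units (flagged when hit; clipped E series produce a
genuine point mass at 0 that would otherwise collapse a state's variance),
relative log-likelihood tolerance $10^{-6}$, 500 iteration cap, 10
jittered restarts by default, states reported in ascending-mean order so
well-separated fits are seed-stable, and flat emission likelihood for
missing frames. Model order is chosen by BIC when not fixed; heavily
overlapping states at very low SNR are deliberately under-split. For the
fixture analyses we initialise at the mechanistic levels
(0.02/0.30/0.55/0.90), as an analyst supplies initial guesses in
HaMMy-style software; quantile initialisation is the default otherwise.
Viterbi decoding breaks likelihood ties toward the lowest state index.

Fitted states map to mechanistic classes by ordered E boundaries 0.15,
0.40, 0.75, a mean exactly on a boundary going to the lower class with a
warning. S2 and S2′ share a band and are separated contextually per
trace: a terminal S2-band dwell persisting to the end of the valid window
with no later S3 visit, low fitted variance and sufficient length is
relabelled S2′.

# Dwell statistics

The three kinetic readouts are $t_1$, the S1 dwell before the first
S2-band entry; $t_2$, the *cumulative* S2-band occupancy (pS2 ↔ S2
excursions included, reading $t_2$ as the total protospacer-processing
time) before the first S3 entry; and $t_3$, the cumulative S3 occupancy
before release (the S3 → baseline drop). Dwells cut off by the trace
boundary or photobleaching are censored. Survival uses Kaplan–Meier
(reducing to the empirical survival without censoring); exponential means
use the censoring-aware MLE $\hat\tau = \sum t_i / d$ with $d$ events and
an exact $\chi^2$ interval. Censored dwells enter the MLE but are excluded
from two-group t tests (their inclusion rule is not specified in the
source analyses; exclusion is conservative). The two-group comparison
defaults to Welch's t test — the reported analyses say Student's t, but
group sizes and variances are routinely unequal in dwell data, so the
pooled-variance variant is available behind a flag rather than the
default. Transition density plots place one count per Viterbi transition
at the fitted (before, after) means, normalised to unit mass, diagonal
empty by construction. In the end-to-end recovery test the idealized $t_2$
runs ~15–17% above the generating truth: Viterbi smoothing of brief S3
entries extends the apparent S2 period. We report this bias rather than
retuning the fixture, and it is the reason the end-to-end tolerance is
20% where direct simulations are tested at 3 standard errors.

# Unzipping mechanics

Unzipped ssDNA follows an extensible freely jointed chain
(contour 0.59 nm/nt, Kuhn length 1.5 nm, stretch modulus 800 pN) and the
dsDNA handles an extensible worm-like chain (persistence 45 nm, rise
0.338 nm/bp, modulus 1200 pN) at 298 K. The experimental elastic values
"under our conditions" are not printed anywhere, so these are documented,
configurable fixture defaults typical of 100 mM-salt assays — not asserted
experimental values. Each opened base pair contributes exactly two
stretched nucleotides; `extension_to_bp` solves
$x_\text{total} = x_\text{handles}(F) + 2\,n_\text{bp}\,x_\text{nt}(F)$
per point and clamps (with a flag) points below the handle-only
prediction.

Because the pulling velocity (50 nm/s) is slow, unzipping is treated as
quasi-static: the equilibrium force at base pair $j$ satisfies
$g_j = 2\,w_\text{ss}(F)$, where $g_j$ is the nearest-neighbour unzipping
free energy (unified NN set at 37 °C with a configurable additive
ionic-strength offset) and $w_\text{ss}(F)$ the ssDNA stretching free
energy per nucleotide. No kinetic barrier-crossing model is included. The
per-bp energy profile is averaged over a 3-bp window by default: at slow
pulling the fork hops thermally over a few base pairs, and the raw
profile's bp-to-bp force jumps would otherwise be artefacts of the
discretisation. Alignment to theory maximises the normalised
cross-correlation over two user-chosen regions flanking the
protein-disruption window, on integer shifts with parabolic sub-bp
refinement. A protein roadblock is an excess-force span: excess over the
naked-DNA baseline, median-filtered (window 5) to reject conversion-noise
spikes, exceeding 2 pN over at least 5 bp *and* 5 consecutive points;
tether breakage is a force collapse below 1 pN after load, reported at
the last loaded position. The simulator realises a roadblock as an energy
barrier over a 10-bp footprint, which is what makes the round-trip
localisation test (±3 bp) meaningful.

# Problem sizes and determinism

Every stochastic component takes an explicit seed and is bit-reproducible.
The test suite uses the sizes at which its guarantees are stated: $10^5$
Gillespie paths against the master equation (3 standard errors), 100
replicates of the rate-recovery study (each rate within 20% in ≥90% of
replicates), 200 traces for the end-to-end smFRET recovery (20%), $10^4$
dwells for the exponential MLE (3 SE), $10^3$ null replicates for the
test-size check, and 40 seeds for noisy alignment (±1 bp in ≥95%). These
sizes were chosen so each criterion's sampling error is comfortably below
its tolerance.

# Known limitations

The cleavage scheme has no sequence-specificity model of cut-site choice
and no representation of the dimeric protein architecture; the second
substrate set with shifted cut positions mentioned in supplementary
material is not enumerated in the main text, so its map is not fixed
here. The HMM is maximum-likelihood, not Bayesian, and makes no claim of
equivalence to HaMMy's internal initialisation or model-order policy.
Dwell fitting is single-exponential with censoring; multi-exponential
mixtures are out of scope. The unzipping module starts from
force/extension records: trap calibration, bead tracking and raw
photodiode processing are upstream of the package.
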