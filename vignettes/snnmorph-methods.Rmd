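---
title: "Methods: spiking-network analysis of EEG under morphing sound therapy"
author: "snnmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spiking-network analysis of EEG under morphing sound therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

`snnmorph` implements a brain-inspired analysis chain for longitudinal scalp
EEG recorded around a tinnitus sound-therapy protocol, in which a synthesized
"avatar" of the patient's tinnitus is cross-faded over one hour into a
preferred environmental sound. EEG is recorded in six conditions: quiet
baseline (`Pre`), the first, middle and last 10 minutes of the morphing file
(`Sound1`-`Sound3`), quiet immediately after (`Post`), and quiet at a
three-month follow-up (`Post3Month`).

The analysis chain is: (1) Step Forward (SF) encoding of each channel into
ternary spike trains; (2) mapping channels into a 3D reservoir of spiking
neurons at anatomical (Talairach-like) coordinates with distance-dependent
small-world connectivity; (3) unsupervised training with spike-timing-
dependent plasticity (STDP) interleaved with leaky integrate-and-fire (LIF)
dynamics, one model per condition from one shared seeded initial reservoir;
(4) edge-wise subtraction of trained models, retention of the top 5% of
relative weight changes, and aggregation into ten scalp zones (five sites
per hemisphere) with a hemispheric dominance index.

Because the underlying clinical study shared no raw EEG, the package ships a
synthetic-EEG generator with *planted* lagged couplings as its test bed, and
every downstream claim is phrased as recovery of that planted structure.

## Spike encoding

SF encoding keeps a per-channel moving baseline $B$ and fixed threshold
$\theta$ (`SFthr`). At sample $n$: if $x(n) - B > \theta$, emit $+1$ and set
$B \leftarrow B + \theta$; if $B - x(n) > \theta$, emit $-1$ and set
$B \leftarrow B - \theta$; otherwise emit 0. One spike and one baseline step
per sample, at most.

Decoding returns the baseline trajectory $B(n) = B_0 + \theta \,
\mathrm{cumsum}(s)$. The familiar reconstruction bound
$|x(n) - B(n)| \le \theta$ is **conditional** under the one-step-per-sample
rule: it holds by induction whenever per-sample increments satisfy
$|\Delta x| \le \theta$, and can be violated by jumps larger than $2\theta$
(the baseline then trails the signal). The acceptance suite therefore tests
the bound on bounded-increment random walks with $\theta$ set at each
signal's largest increment; this is the regime in which the bound is a
theorem, not an empirical observation.

Choices the source protocol leaves open, and our defaults:

* **Baseline initialization**: the channel's first sample (flag for mean).
* **Threshold optimization**: per channel, grid search minimizing the RMSE
  between the signal and its decoded baseline; default grid is 21
  log-spaced multiples of the channel SD in $[0.01, 1]$; ties break to the
  smaller threshold. Per-channel (not global) thresholds, because channel
  amplitudes differ. Note that on a pure ramp of slope $s$ the RMSE
  argmin over $\{s/2, s, 2s\}$ is $2s$, not $s$: a threshold *below* the
  per-sample step makes the baseline fall behind and is the clear loser,
  while $2s$ tracks with slightly smaller ripple.

## Reservoir

Neurons sit at 3D coordinates. Two grids are provided: a packaged 1-cm
lattice with 1471 points inside a brain-shaped ellipsoid (semi-axes
68.5/88/59 mm), a **synthetic stand-in** for the published 1471-neuron
brain-template grid (which is not redistributable here); and
`synthetic_grid(n)`, a lattice in a 70/85/65 mm ellipsoid whose `n = 11`
desk-scale default has 503 neurons.

Electrode positions come from an idealized spherical 10-10 layout (row
letter fixes the sagittal angle, numeric index the lateral angle) projected
onto the template ellipsoid. This replaces a published electrode-coordinate
lookup: the zone lists used downstream require PO5/PO6, which the common
measured tables for 64-channel caps lack, and only relative geometry matters
for the two uses of positions (nearest-neighbour input mapping, and
assignment of edge endpoints to their nearest electrode).

Each channel injects into its nearest free grid neuron (injective map;
collisions go to the next-nearest). Initial connectivity follows a
small-world rule: ordered pairs within radius $r = r_{frac} \cdot d_{max}$
connect with probability $\exp(-d^2/\lambda^2)$, $\lambda = r/2$; weights
are uniform on $(0, w_{init}]$, and a fraction $p_{inh} = 0.2$ of neurons is
inhibitory (all outgoing weights negative, fixed for life).

Dynamics are discrete-time LIF with one step per 256 Hz sample:
$v \leftarrow v\,e^{-1/\tau_m} + \sum_i w_{ij} s_i(t-1) + \sigma k_{in}
v_{thr}$ for an input spike of sign $\sigma$; firing at $v \ge v_{thr}$
resets to $v_{reset}$ and starts a refractory hold of `refrac` steps during
which input is ignored. Both spike polarities drive the *same* input neuron
with signed current (the alternative, separate neurons per polarity, is
noted but not implemented). Defaults: $\tau_m = 10$ steps, $v_{thr} = 1$,
$v_{reset} = 0$, refractory 2, $k_{in} = 1.2$.

### Calibrating the small-world operating point

$r_{frac}$ and $w_{init}$ are nowhere specified by the protocol; they set
the reservoir's operating regime, and the planted-recovery requirement pins
them down empirically:

* Very sparse wiring ($r_{frac} = 0.15$, about 2 connections/neuron on the
  503-neuron grid) leaves so few connections near the coupled channels that
  a condition contrast contains ~10 changed edges and the 5% retention
  keeps a single edge — the dominance index degenerates to $\pm 1$ or 0.
* Strong initial weights ($w_{init} \ge 0.25$) make recurrent firing
  chaotic: two training runs that differ on a few input channels diverge
  globally, and trained-model differences reflect seed-dependent
  divergence, not the planted couplings.

The shipped defaults $r_{frac} = 0.25$, $w_{init} = 0.20$ sit between these
failure modes: recurrent activity propagates, but firing stays
predominantly input-driven, so weight changes concentrate around the
channels whose statistics actually changed. With them, the left-planted
`Sound1` contrast yields negative (left) dominance in 18/20 seeds and the
right-planted `Post` contrast positive dominance in 19/20 — the fixture
parameters (gain 0.9, noise SD 0.1, 60 s, 20 seeds) and the 16/20 pass
threshold were fixed before calibration and never changed.

## Plasticity

Nearest-spike STDP, interleaved with the dynamics (updates at every firing,
active immediately): when neuron $j$ fires at $t$, each incoming connection
whose source last fired at $t' < t$ is potentiated by
$a_+ e^{-(t-t')/\tau_+}$, and each outgoing connection whose target last
fired at $t' < t$ is depressed by $a_- e^{-(t-t')/\tau_-}$. Simultaneous
spikes ($t' = t$) cause no update. Updates act on the weight magnitude —
inhibitory connections mirror the rule — with magnitudes clipped to
$[0, w_{max}]$; an edge's sign is a fixed property of its (excitatory or
inhibitory) source neuron and never flips. STDP modifies only existing
connections. Defaults: $a_+ = a_- = 0.01$, $\tau_+ = \tau_- = 10$ steps,
$w_{max} = 1$, one pass.

Per-condition models start from an identical copy of the same seeded
initial reservoir, so differences between trained models are attributable
to the data. (The alternative reading — continued sequential training across
conditions — is possible via repeated `stdp_train` calls but is not the
default.) A brute-force event-list R implementation of the same rules
serves as the test oracle; the compiled path must agree to $10^{-12}$.

## Contrast analysis

`subtract_models` takes $\Delta w = w_{post} - w_{pre}$ per edge; positive
deltas are "increase" (green by figure convention), negative "decrease"
(red). `retain_top` keeps the $\lceil 0.05 M \rceil$ edges of largest
*relative* change $|\Delta w| / \max(|w_{pre}|, 10^{-6})$ among the $M$
edges with nonzero delta (absolute ranking behind a flag; ties break by
edge index). The 5% filter is applied per model pair.

Each retained edge maps to the zone pair of the electrodes nearest its two
endpoint neurons; endpoints farther than 40 mm from every electrode, or
nearest to an auxiliary channel, stay unassigned and are dropped. Zones are
the ten printed electrode groups (left/right × frontal, frontocentral,
temporal, centroparietal, occipitoparietal). These lists cover 52 of the 64
cap electrodes; the ten midline channels and AF7/AF8 belong to no zone —
an acceptance check that expects the lists to cover the whole cap is
therefore left failing deliberately, as documentation of that shortfall.
The hemispheric dominance index is $(R - L)/(R + L)$ over the retained
$|\Delta w|$ assigned to each hemisphere (each endpoint contributes half an
edge's magnitude), 0 when both sides are empty.

## Stimulus synthesis

The avatar is a pure tone (bandwidth 0) or band-limited Gaussian noise with
geometric centre at the matched pitch (250-16000 Hz) and bandwidth from the
octave ladder {0, 1/24, 1/12, 1/6, 1/3, 1/2, 1, 2, 3, 4}; level sets the
total RMS, and location is reduced to an equal-power stereo balance (HRTF
spatialization is out of scope). "Intensity ratio" is read as *power*
share, so the renderer weights stems by $\sqrt{r(t)}$ and $\sqrt{1-r(t)}$;
with equal-RMS uncorrelated stems this keeps total output power constant
and makes the measured band-power share track the schedule. An
amplitude-share variant would be a one-line change in `render_morph`.

The acute schedule holds $r = 0.90$ for minutes 0-10, decreases linearly
("steadily") to 0.10 across minutes 10-50 — passing the stated 50/50 point
in the middle window — and holds 0.10 for minutes 50-60. The chronic ladder
is four one-hour files: constant 1.0, then linear 1.0→0.5, 0.5→0.1,
0.1→0.0. Stems are equalized by long-term RMS; the protocol's loudness-
spectrum matching is undefined and not modelled.

## Synthetic EEG generator

`simulate_recording` draws seeded Gaussian noise per channel (optionally
1/f-shaped; white by default for analyzability) and adds planted linear
lagged couplings $x_t(n) \mathrel{+}= g\, x_s(n - L)$. This is deliberately
the *simplest* spatiotemporal structure an STDP-based pipeline should
recover; it does not emulate volume conduction, artifacts, oscillatory
rhythms, or participant heterogeneity, so a green recovery test establishes
that the chain detects lagged lateralized coupling above noise — not that
it reproduces clinical findings.

`make_study_fixture` builds the six-condition set on one shared noise
background (so condition contrasts isolate the couplings): `Sound1` plants
four left temporo-parietal edges (CP5→P5, P7→PO7, TP7→P7, P5→PO7, lags 2-5
samples, gain 0.9, noise SD 0.1), `Post`/`Post3Month` the right-hemisphere
mirrors, `Sound2`/`Sound3` bilateral subsets, `Pre` none. Lateral sites were
chosen over para-midline ones so the two hemispheres' coupling
neighbourhoods stay separated at the desk grid's ~15 mm resolution; they
also correspond to the temporo-parietal scalp sites where the acute effects
are described. Desk-scale duration is 60 s per condition (the protocol's
segments are 10 min; configurable).

## Numerical and I/O choices

* Downsampling (8192 → 256 Hz): zero-phase windowed-sinc (Hamming) FIR with
  cutoff $0.4 \times$ target rate, reflection padding, then integer
  decimation.
* EDF (16-bit) and BDF (24-bit) are written with a single data record and
  the condition tag in the recording-identification field; physical ranges
  are rounded *outward* to their 8-character ASCII representation before
  quantization so no sample clips. WAV supports PCM 16/24-bit and float32.
  These are minimal readers/writers in base R, because no suitable package
  exists in the target environment.
* All randomness is seeded; fixture, wiring and training are bit-
  reproducible per seed, and the pipeline report is byte-identical across
  reruns of one configuration.

## Known limitations

* The generator's linear lagged coupling is far simpler than real EEG; the
  recovery tests are sanity checks of the machinery, not clinical
  validation.
* Group-level aggregation across participants is not modelled (the package
  trains per recording); the protocol is ambiguous about pooling, and
  averaging per-recording deltas over a shared sparsity pattern is one of
  several defensible choices.
* The electrode-to-Brodmann-area narrative of the source protocol is
  interpretive and out of computational scope, as are statistical tests on
  delta significance (none are defined for it).
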