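---
title: "Models and methods behind the bacteria-on-a-bead pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the bacteria-on-a-bead pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beadcycle)
```

## The assay

*Caulobacter crescentus* divides asymmetrically: a sessile stalked mother
cell repeatedly buds off motile swarmer daughters that carry a single
flagellum and a few retractable type IV (Tad) pili at the free pole. In the
bacteria-on-a-bead assay, predivisional cells are grown attached (via stalk
and holdfast) to polystyrene microspheres. The bead then acts as a handle:
small (1 µm) beads are dragged around by the swimming cell in a quasi-2D
chamber, and large (3 µm) beads are clamped in an optical trap so that the
forces exerted by the cell's appendages read out as bead displacement. Three
recording geometries occur:

* **free swimmer** — the bead–cell assembly swims in a 10 µm chamber,
  alternating forward (push, CW flagellar motor) and backward (pull, CCW)
  runs;
* **trapped bead** — the rotating flagellum gyrates the assembly around the
  trap center; pili intermittently attach to the nearby glass, drag the bead
  out of the trap, hold, and release; just before cell separation the
  daughter spins about its long axis and the gyration slows;
* **pole track** — for cells attached directly to glass, the flagellated
  pole is tracked at high frame rate; it shows slow bending, then fast
  quadrature rotation with motor reversals, then ballistic escape after
  separation.

The package implements both sides of this experiment: a physics-based
generator that produces such recordings with known ground truth, and the
inference pipeline (tracking, calibration, force inference, behavioral
segmentation, swim/rotation statistics) whose correctness is demonstrated by
recovering what the generator planted. `paper_defaults()` is the single
fixture holding every headline value being planted and recovered.

## Units

All quantities use one coherent system: µm, s, pN, pN/µm, Hz, K. The
Boltzmann constant is then `kB = 1.380649e-5` pN µm/K, and a viscosity in
Pa·s is numerically identical in pN·s/µm² (so water-like media are `1e-3`).
This removes an entire class of silent `1e3` errors when combining
`kappa * x` forces with `6*pi*eta*a` drags.

## The trapped-bead model

The bead obeys an overdamped Langevin equation per axis,

$$ \mathrm{d}x = \frac{-\kappa (x - c) + F_\mathrm{drive}(t)}{\gamma}\,
   \mathrm{d}t + \sqrt{2D}\,\mathrm{d}W, $$

with trap stiffness $\kappa$, Stokes drag $\gamma = 6\pi\eta a$ and
diffusion $D = k_BT/\gamma$. Behavioral states differ only in
$F_\mathrm{drive}$:

* **gyration** — a rotating force vector whose phase advances at the
  gyration frequency $f$: a radial component `trans_force` and a tangential
  component `rot_force`. The defaults use the self-consistent pair
  $F_\mathrm{trans} = \kappa r_0$, $F_\mathrm{rot} = \gamma\,2\pi f\,r_0$,
  for which the noiseless steady state is exactly a circle of radius $r_0$
  traversed at $f$, and drag-balance force inference returns `rot_force`
  exactly. CCW is the positive angular direction throughout (image
  coordinates, y up); the trap center is the coordinate origin.
* **long-axis rotation** — the same driving with the tangential force and
  phase rate scaled by `slow_rotation_factor` (default 0.5): the gyration
  proceeds, slower, while the daughter cell spins about its long axis.
* **pilus cycle** — pili are modeled kinematically, as prescribed bead
  displacement, not as an elastic filament with a force–velocity relation
  (no such relation is available for planting, and only the displacement
  phenomenology matters for segmentation). A stiff tether (20 pN/µm,
  i.e. 20× the trap) pulls the bead from its position at attachment toward an
  anchor point at `hold_displacement` (0.8 µm) along a bearing within ±45° of
  the bead's current bearing, at `retract_speed` (0.15 µm/s); the tether
  point is placed so the trap+tether equilibrium tracks the prescribed path,
  hence the *bead* moves at the planted speed. At release the tether vanishes
  and the bead relaxes back under the trap with time constant
  $\gamma/\kappa \approx 28$ ms — an initial return speed of tens of µm/s,
  reproducing the observed order-of-magnitude gap between release and
  retraction speeds by construction rather than by an extra parameter.
* **brownian** — thermal motion only.

Integration is Euler–Maruyama with step
`min(1 ms, 1/(10 * frame_rate))`, subsampled to the frame grid. Because
every state has linear drift, the per-step recursion has a constant
coefficient within a segment and is evaluated with
`stats::filter(, method = "recursive")` — C speed, bit-reproducible under a
seed, no compiled code. The step is validated against the closed-form
Ornstein–Uhlenbeck stationary law in the tests; at the default stiffness the
discretization bias on the stationary variance is below 1%.

Randomness: one stream per track, seeded by stable integer hashing of
(master seed, track id) (`derive_seed()`), so multi-track experiments are
reproducible and insensitive to execution order.

## The free swimmer and the pole track

The swimmer alternates push and pull runs strictly. Dwell times are a 0.25 s
refractory minimum plus an exponential tail, with total mean equal to the
headline dwell time (2.2 s push, 1.2 s pull). A pure exponential would put
roughly a fifth of pull runs below five frames at the 20 Hz recording rate
used for 1 µm beads; no frame-rate-limited tracker — the assay's or ours —
can resolve those, and their censoring would bias every recovered mean. A
short motor-switching refractory is the generator's model of the same
physical fact. Per-run speeds are drawn per sequence (see *Planted
distributions* below); the body axis diffuses rotationally
(0.05 rad²/s) and flips by π at each reversal; translational Brownian noise
uses the drag of the whole ~3 µm bead+cell assembly, not the bare bead.

Pole tracks are built directly in the frame domain: bending is a sub-Hz
oscillation along a bending axis; rotation is a phase-continuous quadrature
pair $x = A\cos\phi$, $y = A\sin\phi$ with $\dot\phi = \pm 2\pi f$ per
motor interval; release is ballistic drift. Gaussian localization noise of
`amplitude / snr` is added. The generator refuses frequencies above
`frame_rate / 4` (its own anti-aliasing margin). Recovery experiments sample
at 250 Hz — inside the 200–300 Hz band used for surface-attached cells —
because the CW frequency distribution (29.9 ± 25.6 Hz) needs headroom up to
~59 Hz.

## Planted distributions

Reported summary values are means ± SD of *measured, range-limited* data.
Planting them as normals truncated to the stated range would therefore
overshoot every mean (a normal with mean 99.8 and SD 57.3 truncated to
[40, 180] s has mean ≈ 106; one with mean 20.4, SD 15 truncated above 1 Hz
has mean ≈ 23.3). The generator instead solves for the latent location such
that the **realized truncated mean equals the reported mean**
(`rtnorm_matched()`), keeping the latent scale at the reported SD; where a
range is stated it is used as the truncation window, otherwise quantities
are truncated at zero (or at a symmetric mean-preserving upper bound for the
pole frequencies). Sampling is inverse-CDF, hence exact and rejection-free.

## Inference methods

**Calibration.** Equipartition: $\kappa = k_BT/\mathrm{var}(x)$ per axis on
a caller-asserted quiescent segment, with a block bootstrap CI (blocks of
10 relaxation times — trapped positions are autocorrelated, so an i.i.d.
bootstrap would understate the CI). PSD: a Welch periodogram is log-binned
and fitted with the spectrum of the *sampled* process (the AR(1) form of the
Lorentzian, equal to the Lorentzian with all aliasing folds summed); fitting
a naive Lorentzian instead reads the corner frequency ~10% high at typical
frame rates. Estimates are flagged unreliable when the corner frequency
leaves the trustworthy band. Camera-blur corrections are omitted — the
synthetic frames are not motion-blurred — and this is a declared limitation
for real recordings.

**Force inference.** The trap force is $F = \kappa(c - x)$ per frame,
decomposed into radial and tangential components about the center; angular
velocity comes from the unwrapped bearing with a 5-frame Savitzky–Golay
derivative. Two summaries: $F_\mathrm{rot} = \gamma_\mathrm{eff}\,
\langle|\omega|\rangle\,\langle r\rangle$ over gyration frames (drag
balance; $\gamma_\mathrm{eff}$ defaults to the bead-only Stokes drag and is
a declared lower bound, since the attached cell adds unmodeled drag), and
$F_\mathrm{trans,max} = \kappa \cdot \max r$ on a 1 s boxcar-smoothed radial
trace, so the maximum reflects sustained driving rather than a single
thermal excursion. Force inference is validated purely by planted-force
recovery; the assay's printed force values are not comparison targets
because the trap stiffness and effective drag behind them are not reported.

**Segmentation.** A windowed rule cascade (0.5 s windows, 50% overlap)
rather than an HMM: the behavioral signatures are explicit geometric
criteria, and rules keep every decision auditable. Per window the features
are mean radial distance, radial-velocity slope, net signed angular
displacement, sign consistency, positional variance, and directedness
(net/path on a coarse-grained window). Defaults, for trap stiffness
$\kappa$ and $\sigma^2 = k_BT/\kappa$:

| threshold | default | role |
|---|---|---|
| `r_thresh` | $3\sigma$ | off-center gate (pilus and gyration) |
| `a_thresh` | $\pi/2$ rad/window | net rotation for gyration; rotation-free gate for pilus |
| `d_thresh` | 0.7 | directedness (retraction/release) |
| `rv_thresh` | 0.05 µm/s | sustained outward radial velocity |
| `var_hold` | $k_BT/\kappa_x + k_BT/\kappa_y$ (halved) | low-variance hold |
| `min_duration` | 0.4 s | hysteresis merging |
| `slow_frac` | 0.7 | long-axis rotation vs fast gyration split |

A window is **pilus-attached** when off-center *and* rotation-free *and*
(retracting, holding at low variance, or strongly directed); **gyration**
when off-center with consistent net rotation above `a_thresh`; ties go to
pilus, because pilus attachment arrests gyration. Gyration windows slower
than `slow_frac` times the track's fast-gyration reference (0.9 quantile of
angular speed) are relabeled **long-axis rotation**; this split resolves the
pre-separation rotation stage but is relative, so a track containing *only*
slow rotation reads as gyration — a known limitation. The off-center gate is
what makes the flagellum-free control clean: thermal excursions reach
$3\sigma$ with vanishing probability, so no Brownian window can masquerade
as gyration. Onset of flagellar activity is the start of the first rotation
interval; separation is the transition into the terminal Brownian interval.
Pilus sub-phases (attachment, retraction, hold, release) are resolved on the
smoothed radial trace inside each pilus interval; intervals shorter than
three windows are emitted unresolved, and intervals running into the end of
the track are flagged censored rather than counted.

**Swim statistics.** Direction is the sign of the velocity projection on
the flagellated-pole-to-bead axis (forward = push = positive, the
simulator's and the assay's color convention); the axis comes from the
generator's ground truth or from the smoothed velocity direction (labels
then defined up to one global flip, and invariant under coordinate
rotation). Per-sequence speed averages the projected speed over the
sequence interior — the frames straddling a reversal mix both directions in
a centered difference and are trimmed. Both the count fraction and the time
fraction of pushing are reported, because a "two-thirds pushing" statement
can be read either way; under strict alternation the time fraction is the
renewal value $\tau_\mathrm{push}/(\tau_\mathrm{push}+\tau_\mathrm{pull})
\approx 0.65$.

**Rotation frequency.** Per 0.5 s window, the frequency is the significant
Hann-windowed, zero-padded periodogram peak of $x(t)$ (quadratically
interpolated), and the direction is the sign of the mean cross-quadrature
$\langle x\dot y - y\dot x\rangle$ — exact on noiseless quadrature at any
frequency below the anti-aliasing margin. A spectral peak is preferred over
zero-crossing counting because it is robust to localization noise at
20–35 Hz on 200–300 Hz recordings. Adjacent windows with the same direction
and frequencies within 20% merge into intervals, refined on the full
interval; single-window orphans overlapping multi-window neighbors are
dropped (they straddle a motor reversal and blend both rotations).

## Declared physical defaults

The study does not print its trap stiffness, medium viscosity, gyration
rate or pilus kinematic parameters. The package declares (not infers):
$\kappa = 1$ pN/µm per axis (a typical single-trap value at moderate laser
power; thermal cloud $\sigma \approx 65$ nm), $\eta = 10^{-3}$ Pa·s
(aqueous growth medium), $T = 303.15$ K, gyration orbit radius 0.5 µm with
frequency 2 Hz (the rotation must exceed `a_thresh` per window to be
segmentable at all; 2 Hz leaves a factor-4 margin and keeps the slow stage
at factor 2), hold displacement 0.8 µm (a clearly visible displacement at
0.8 pN, within the reported force scale) and retraction speed 0.15 µm/s
(hold displacement over the retraction share of a typical 13 s cycle).
These are fixed in `paper_defaults()` and not revisited.

## What the generator does and does not emulate

It emulates: quasi-2D motion, the bead diameters and frame-rate bands of
the three recording geometries, Brownian noise at 30 °C in water-like
medium, run-reverse switching, gyration arrest by pilus attachment, the
stiff→soft septum transition (as the slow-rotation factor), the
flagellum-free control (gyration disabled), and camera-like image stacks
(Gaussian spot, additive or shot noise).

It does not emulate: z-motion (the chamber and near-surface hydrodynamics
justify a 2-D treatment; the associated ~10% force underestimation in the
real assay is documented, not modeled), hydrodynamic wall coupling,
flagellar filament mechanics, cell-body shape and its image, camera motion
blur, multiple simultaneously attached pili, or drift. Passing recovery
tests therefore demonstrates the *inference pipeline* is correct under the
stated noise model — not that the thresholds are optimal for any particular
microscope's recordings, where they remain configurable.

## Problem sizes and numerical choices

Recovery experiments run at the sizes the acceptance criteria state: 200
(speeds) and 500 (dwell times) sequences per direction, 100 pilus cycles
over 20 tracks (with and without flagellum), 50 pole cells, 30 stage tracks,
and 10⁵-frame calibration segments. Calibration segments are sampled at
25 Hz so the 10⁵ frames span ~7000 relaxation times — the variance estimate
is then sampling-limited at ~2%, not correlation-limited. Degenerate inputs
are handled explicitly: frames at the exact trap center get zero angular
velocity and a flag; empty categories are reported absent (`NULL`), never
zero; tracks shorter than a window, single-frame stacks, unresolvable
sub-phases and censored cycles all produce typed errors or flags rather
than silent numbers.

## A worked example

```{r example, eval = FALSE}
library(beadcycle)
d <- paper_defaults()
trap <- trap_model(d$physical$kappa_trap, temperature = d$physical$temperature)
cfg <- sim_config(trap = trap, frame_rate = 100, seed = 7)
sch <- behavior_schedule(c("gyration", "pilus_cycle", "gyration", "brownian"),
                         c(15, 12, 10, 20))
sim <- simulate_trapped_bead(cfg, sch)
ev <- classify_states(compute_features(sim$trajectory, trap$center), trap)
summarize_events(ev, extract_pilus_cycles(ev, sim$trajectory))
```

The README shows this example with the numbers it prints; the full recovery
table across all headline quantities is produced by `run_pipeline()` and by
`scripts/acceptance.R`.
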