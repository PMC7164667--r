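---
title: "In silico spheroid analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico spheroid analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spheroidbridge)
```

`spheroidbridge` turns phase-contrast time-lapse images of a multicellular
tumour spheroid growing in soft agar into a calibrated three-dimensional
particle simulation of that same spheroid, and then reads virtual inner
proliferative activity — which cells are still cycling, which have gone
quiescent — off the simulation. This vignette explains each model in the
pipeline, the parameters that matter, and the choices we made where the
design was genuinely open.

## From images to growth curves

A spheroid appears in each 8-bit frame as a single dark (or bright) blob.
`segment_spheroid()` binarizes with Otsu's threshold, applies binary opening
then closing with a small disc element (default diameter 3 px), fills holes,
and keeps the largest connected component. Otsu was chosen because it is
parameter-free and robust for high-contrast blobs; the opening removes
isolated speckles, the closing and hole fill cover the spheroid body. The
retained region is summarized as the *equivalent circle* of the same area,
radius $p\sqrt{A/\pi}$ for area $A$ px and pixel size $p$ µm/px. Pixel size
is a required configuration value (synthetic default 0.65 µm/px, a typical
10× scale).

Treating the spheroid as a sphere of the equivalent-circle diameter $D$
packed with cells of diameter $d$, the cell count is bounded by lattice
packing densities:

$$n_{\mathrm{lower}} = \left\lfloor (D/d)^3\,\pi/6 \right\rfloor
  \qquad
  n_{\mathrm{upper}} = \left\lfloor (D/d)^3\,\pi/(3\sqrt2) \right\rfloor,$$

simple cubic below, face-centred cubic above; their ratio is $2^{-1/2}$
before flooring. The FCC count is used as the point estimate $e(t)$ because
spheroids pack densely. Counts are floored and clamped to at least 1 —
counts are whole cells. A Monte-Carlo packing experiment
(`random_packing_count()`, overlap relaxation with culling) gives an
independent count between the two bounds, at random-close-packing density.

The single-cell diameter is estimated the same way from one- or two-cell
frames (`estimate_single_cell_size()`), halving the area of two-cell
regions before conversion.

## The Richards curve and the feature plane

Growth curves are summarized by the five-parameter generalized logistic
(Richards) curve

$$y(x) = A + C\left(1 + T e^{-B(x-M)}\right)^{-1/T},$$

with lower asymptote $A$ (cells), growth rate $B$ (1/day), asymptotic rise
$C$ (cells), time of maximum growth $M$ (day) and inflection-shape parameter
$T$. `fit_richards()` uses bounded Levenberg–Marquardt least squares
(positivity of $B$, $C$, $T$ via box constraints). Default initial values
are deterministic sigmoid heuristics — $A=\min y$, $C=\mathrm{range}$, $M$
at the steepest median-smoothed slope, $B = 4\,\max\text{slope}/C$ clamped
into $[0.05, 5]$, $T=1$ — with one neutral logistic fallback start; the fit
is reproducible given data and start.

A cohort of fitted $(A,B,C,M,T)$ vectors is z-scored per parameter
(*population* SD; the convention is stored in the normalization record so
projections round-trip exactly — whether to divide by $n$ or $n-1$ is a
genuinely open convention and we declare ours rather than infer it) and
eigen-decomposed. The first two eigenvectors form the feature plane;
contribution rates are eigenvalue shares. Eigenvector signs are
mathematically arbitrary, so we orient them so the loading of $C$ on the
first component and of $B$ on the second are non-negative, which makes
quadrant labels reproducible. Points on an axis go to the adjacent
lower-numbered quadrant. A perfectly collinear cohort is accepted (first
component carries 100%); only a cohort with no variance at all is an error.

## The particle simulator

A spheroid in silico is a set of cellular particles of diameter $r_0 =
10\ \mu m$ moving freely in space. Two particles at distance $r$ interact
with the force

$$F(r) = k\left(1-\frac{r}{R\,r_0}\right)\left(1-\frac{r}{G\,r_0}\right),$$

$k = 0.005$, repulsion constant $R = 1.106$, attraction constant $G = 1.5$:
repulsive below the equilibrium spacing $R r_0 = 11.06\ \mu m$, attractive
up to $G r_0 = 15\ \mu m$. The polynomial turns positive again beyond
$G r_0$, which is unphysical, so the force is cut off to zero there ($G$
bounds the interaction range). With these constants a relaxed cluster
settles into near-hexagonal-close packing, where interior particles touch
exactly 12 neighbours — the kissing number in three dimensions; the second
HCP shell at $\sqrt2 \cdot 11.06 = 15.6\ \mu m$ falls outside the attraction
range, so the neighbour count within $G r_0$ is exactly the first
coordination shell.

Motion is overdamped: each minute a particle moves $\eta \sum_j F_{ij}
\hat u_{ij}$, capped at $0.2\,r_0$, with mobility constant $\eta = 2000$
µm per unit force. No inertia — the standard regime for centre-based cell
models, stable at the 1-minute step.

**Growth sources.** The culture supplies a finite budget. With consumption
of one unit per supplied particle per minute, the *residual source index*
is $R_t = \max(0,\, 1 - \sum_k C_k / Q_0)$, where the configuration value
`capacity` is $Q_0/c$ in particle-minutes. $R_t$ is imposed at the spheroid
surface and diffuses inward along the depth coordinate $x$ with fixed
consumption:

$$\frac{\partial R}{\partial t} = D \frac{\partial^2 R}{\partial x^2} - \alpha,
  \qquad \alpha/D = 20\ \mathrm{mm}^{-2},$$

with no supply deeper than 200 µm (the distance oxygen travels from a
vessel). Depth is measured in millimetres where $\alpha/D$ enters; the
implied penetration depth $\sqrt{2 R_s D/\alpha} \le 316\ \mu m$ is
consistent with the 200 µm cap, which always applies. Because diffusion
equilibrates much faster than the 1-minute step, we solve the *quasi-steady*
profile each step on depth shells (default width 10 µm): projected
Gauss–Seidel with the surface value $R_t$, zero flux at the innermost node,
consumption in occupied shells, and the profile clamped at zero — the clamp
realizes the free boundary where the source runs out. On a 200-shell grid
the solver reproduces the closed-form parabola
$R_s - \frac{\alpha}{2D}x(2L-x)$ to better than 1%.

**Cell cycle.** Each particle's cycle time couples supply (Monod-type),
crowding, and surface proximity:

$$T_z = \frac{1}{\mu_{max}}
  \cdot \frac{1 + (K_c/N_z)^2}{1 + K_c^2}
  \cdot \left(1 + K_e \frac{D_z}{P_z}\right),$$

where $N_z \in [0,1]$ is the supply at the particle's depth, $D_z$ the
neighbour count, $P_z$ the mobility (centre-distance over the outermost
particle's centre distance, clamped at $\varepsilon = 10^{-3}$ for the
central particle), and $\mu_{max}$ the reciprocal of the minimum cycle time
(default 18 h). The supply factor equals 1 at full supply, so a fully
supplied isolated particle divides at exactly the minimum cycle; a starved
particle ($N_z = 0$) never divides. The two relaxation coefficients $K_c$
and $K_e$ are the quantities the bridge fits. The algebraic arrangement of
the published cycle formula is ambiguous in its source rendering; we fixed
the canonical reconstruction above — minimum $1/\mu_{max}$ at $N=1$, $D=0$,
environment factor $1 + K_e D/P$ — and isolated it in `cell_cycle_time()`
so alternates can be swapped; all property tests depend only on the
monotonicities and the minimum.

**Division.** When a particle's age reaches $T_z$ it is replaced by two
daughters at $\pm(r_0/4)\hat u$ for a seeded random unit direction
(separation $r_0/2$); both inherit generation $+1$ and age 0. Generation
numbers therefore count divisions since the founding cell. When a run
starts from $N_0 > 1$ particles (a relaxed HCP cluster), the founding
generation is $g_0 = \lceil \log_2 N_0 \rceil$ so generations approximate
divisions since seeding, and founding ages are desynchronized uniformly
over one minimum cycle (a deterministic auxiliary generator) to avoid
lockstep division artefacts.

Each 1-minute step: (1) update $R_t$ and the supply profile, (2) age and
divide, (3) relax positions. A `max_particles` guard (default `Inf`)
suspends divisions above a configured count; it exists to bound the cost of
exploratory simulations during bridging, and runs that hit it fit their
target badly and are rejected by the error surface.

## The bridge

Given an image-derived curve $e(t)$ and a simulated count curve $n(t)$
(linearly interpolated in time onto the estimated grid — counts are near
piecewise-linear at 3-hour resolution), the bridging error is

$$f(K_c, K_e) = \sum_t
  \left(\frac{\log_{10} e(t) - \log_{10} n(t)}{\log_{10} e(t)}\right)^2,$$

summed from day 4 (image-derived curves fluctuate earlier) over points with
$e(t) \ge 2$. The log base is not dictated by the ratio structure; base 10
is fixed and recorded. `optimize_coefficients()` minimizes $f$ over
$(\log K_c, \log K_e)$ with a hard evaluation budget (default 30; each
evaluation is a full simulation at a fixed seed, so the objective is
deterministic). Because $K_e$ varies over orders of magnitude between cell
lines and the surface has a compensation ridge ($K_c$ up, $K_e$ down), the
search first brackets $K_e$ on a coarse log grid through the start point
(4 evaluations), then runs a Nelder–Mead descent from the best bracket
point. The Nelder–Mead is implemented in the package with a right-angled
initial simplex of 0.8 log-unit edges: a stock simplex built from 10% of
the start coordinates collapses at the log-scale start $(0,0)$. The best
evaluation seen is always returned, and the best-so-far error is
non-increasing by construction.

`plateau_day()` operationalizes "day the curve reaches plateau" as the
first grid day whose forward one-day window rises by less than 1%
(configurable); on a 3-hour grid this yields fractional days.

## Virtual inner proliferative activity

Between two consecutive daily snapshots, a generation whose particle count
is exactly unchanged has stopped dividing. The cutoff $g^\*$ is the largest
generation such that *every* generation up to it is unchanged — a single
changed generation breaks the run, matching the "low up to the $N$th
generation" reading — and counts are compared as exact integers, since they
only change through division. Particles with generation $\le g^\*$ are
labelled low-activity (the quiescent zone), the rest high-activity (the
proliferating rim); `low_activity_ratio()` is the low share of the earlier
day's census (the day pairing is ambiguous in principle; we use the earlier
day and say so). Cross-sections through the centroid (slab thickness one
cell diameter by default) visualize the layering; in grown runs the most
recent generations concentrate near the surface. For histology-style
bookkeeping, `quiescent_volume_ratio()` converts two concentric diameters
to a volume fraction $(D_{in}/D_{out})^3$.

## The synthetic-data generator

No public raw data exist for this kind of acquisition, so the package
generates its own study conditions: frames every 3 h from day 2 to day 15,
0.65 µm/px, one disc per frame whose radius follows a Richards curve
(defaults $A=1$, $B=0.9$/day, $C=4000$, $M=8$ d, $T=1$ — a single cell
rising to a few thousand with maximum growth around day 8, the scale of a
two-week soft-agar culture), Gaussian background noise and optional
isolated speckles, dark-on-bright polarity. Counts are inverted to disc
diameters through the same FCC packing formula the analysis applies, so
generation and analysis are inverse maps — except at the one- and two-cell
stages, where a lone cell shows its own diameter, not a packing-equivalent
one, and the generator uses area-additive cell size instead. Cohorts draw
independent parameters per spheroid ($A \equiv 1$; $B$, $C$, $T$ lognormal;
$M$ normal; lognormal count noise $\sigma = 0.05$), emulating the spread of
an 18-spheroid panel.

What the generator does *not* emulate: phase-contrast halos, focus drift,
neighbouring spheroids, shape irregularity. Passing tests demonstrate the
pipeline's internal consistency on clean single-object frames, not
segmentation robustness on difficult real microscopy.

## Problem sizes and numerical choices

Simulation-backed tests run scaled-down conditions chosen as the smallest
that still exercise both control factors: coefficient recovery uses 5
simulated days from a 100-particle cluster with a 3×10⁶ particle-minute
budget, at most 2000 particles and a 30-evaluation budget (the supply-rich
early phase pins $K_e$, the depletion phase pins $K_c$); the
capacity-ordering comparison uses 8 days at budgets 2×10⁶ vs 5×10⁶ with
censuses at days 5 and 6. Further conventions: coordinates are row-major
with origin top-left and 0-based pixel indexing; ties on feature-plane axes
go to the lower-numbered quadrant; coincident particles are separated by a
seeded jitter; one integer seed governs every stochastic choice in a run,
and fixed seeds make runs bit-reproducible on the same platform.

## Known limitations

- No cell death or necrosis: particle counts never decrease, so the
  quiescent core is arrested, not lysed.
- One growth-source species; oxygen and glucose are not distinguished.
- The cycle-formula reconstruction is one canonical choice among the
  algebraic arrangements consistent with its source.
- The bridge is a local search; it fits exactly two coefficients and can in
  principle settle on the compensation ridge if the target curve lacks a
  depletion phase.
- Segmentation assumes one in-focus, isolated spheroid per frame; tracking,
  merging and focus selection are out of scope.

## A worked example

```{r example, eval = FALSE}
library(spheroidbridge)

# synthetic acquisition -> growth curve -> Richards fit
spec <- synthetic_spec(seed = 1)
tl <- generate_timelapse(spec)
curve <- extract_growth_curve(tl$frames, cell_diameter_um = 10)
fit <- fit_richards(curve)

# scaled simulation bridged to the curve it generated
cfg <- sim_config(total_days = 5, capacity = 3e6, n0 = 100,
                  Kc = 0.8, Ke = 0.05, max_particles = 2000, seed = 42)
target <- trajectory_growth_curve(run_simulation(cfg))
bridged <- optimize_coefficients(target, cfg, budget = 30, t_min = 1)
bridged

# activity labelling of the final state
tr <- run_simulation(cfg)
s4 <- tr$snapshots[[which.min(abs(tr$index$day - 4))]]
s5 <- tr$snapshots[[length(tr$snapshots)]]
g_star <- activity_cutoff(generation_census(s4), generation_census(s5))
low_activity_ratio(generation_census(s4), g_star)
```
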