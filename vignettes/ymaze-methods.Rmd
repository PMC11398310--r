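---
title: "Quantifying locomotor turn decisions in Y-mazes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying locomotor turn decisions in Y-mazes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

# The problem

An animal walking freely in a Y-shaped maze produces a long stream of
binary turn decisions: each traversal of an arm ends with an exit into
the arm on the left or on the right. Conventionally the decision is
scored at a single "choice point", the arm intersection. `ymaze` treats
the decision instead as a process extended over space and time: it asks,
at every location along the arm and at every moment of the traversal,
how well the animal's lateral position already predicts the upcoming
turn. The package covers the full path from raw centroid tracks to that
answer: trial segmentation, coordinate normalization, the Turn
Predictiveness Index (TPI), midline-crossing parity statistics,
wall-proximity scores, occupancy and velocity fields, resampling nulls,
and synthetic-data generators that stand in for raw tracking data.

# Coordinates and trials

A **trial** is everything the animal does from entering the bottom arm,
through the rounded dead end ("cul-de-sac"), back up the arm, and out
into the left or right arm. Segmentation is by polygon membership in a
parametric three-arm geometry (arms of length $L$ and width $w$ at
120°, closed by semicircular caps); the arm proper starts at depth
$w/\sqrt{3}$ from the centre, where neighbouring arm rectangles stop
overlapping, and shallower in-maze points count as intersection. Trials
that never reach the cul-de-sac region, contain missing samples, or
contain out-of-maze coordinates are dropped; individuals with fewer
than 80 valid trials (28 for human-style data) are excluded.

Within each individual, raw y is mapped affinely so that 1 is the upper
edge of the bottom arm and 0 the minimal location reached during the
whole session; x is scaled by the same factor, preserving aspect. Each
trial is then signed about its turning point $K_{\min}$ (the first
sample attaining the trial's minimal y): $y = -y'$ strictly before
$K_{\min}$ and $y = +y'$ after, so descent is negative, ascent positive,
and $\mathrm{sign}(y)$ flips exactly once. x is centred on the midpoint
of the individual's x-range over $-1 \le y \le 1$, putting $x = 0$ on
the arm's midline. Relative time anchors three landmarks at
$t \in \{-1, 0, 1\}$: first sample with $y \ge -1$, the turning point,
last sample with $y \le 1$.

Two normalization details are deliberate interpretations. First, the
turning-point sample itself carries $+y'(K_{\min})$, the per-trial
minimum of the session-wide map — it is near, but not re-zeroed to,
exactly 0. Second, centring subtracts the midpoint
$\tfrac12(\max x + \min x)$ of the in-arm x-range, which is the only
reading that centres a symmetric arm.

# The Turn Predictiveness Index

For a y-range (or relative-time range) $R$ and one individual's trials,
each trial is labelled by the side of its mean lateral position in $R$:
$x^b_R = \mathrm{sign}\,\langle x \mid R \rangle$. The TPI of the range
is the difference of two conditional probabilities,

$$\mathrm{TPI}_R \;=\; P(\text{turn} = \mathrm{R} \mid x^b_R = +1)\;-\;
P(\text{turn} = \mathrm{R} \mid x^b_R = -1) \in [-1, 1],$$

estimated per bin over 26 spatial bins of width 0.1 spanning
$[-1.3, 1.3]$, or 17 + 17 relative-time bins of width 0.075 per motion
phase. An equivalent counting form (ratios of trial counts) is also
implemented; the two are verified to agree on all inputs. Conventions
worth stating:

* Trials with no sample in the range are *absent*; trials whose mean is
  exactly 0 are *ties*. Both are excluded from both conditionals rather
  than assigned a side.
* A bin with either side unpopulated is *undefined* (`NA`), never 0 —
  zero would fake "no predictiveness".
* The per-bin standard error treats the two conditionals as independent
  binomial proportions,
  $\sqrt{\hat p_1(1-\hat p_1)/n_1 + \hat p_2(1-\hat p_2)/n_2}$.
* Group curves average per-individual curves unweighted over the
  individuals with a defined value in each bin, with the SEM across
  those individuals.

The curve's two tails are defined at the trial's first and last data
point. At the start the side indicator is fixed by the arm the subject
arrived from (+1 right, −1 left), so the negative tail is
$P(\mathrm{R}\mid\text{prev}=\mathrm{R}) -
P(\mathrm{R}\mid\text{prev}=\mathrm{L})$: positive for repetition,
−1 for perfect alternation. At the end the lateral position defines the
turn, so the positive tail is identically 1.

# Midline-crossings and parity

A crossing occurs where consecutive samples have opposite-signed x.
Samples exactly on the midline are skipped: a zero-run between opposite
signs is one crossing, between equal signs none — the
measure-theoretically consistent completion of the sign-product
definition. Each crossing is located at the earlier sample of its pair
(no sub-frame interpolation), which makes every downstream histogram
bit-reproducible.

Crossings are attributed to regions by their y: cul-de-sac
($|y| \le y_c$), post-cul-de-sac ($y > y_c$, through the end of the
trial), down-arm ($y < -y_c$); the three partition the whole-trial
count. The boundary $y_c = 0.34$ (in short-maze normalized units) is the
analysis constant used throughout and is configurable; for other
geometries `yc_for_geometry()` places the boundary at the same physical
height above the cap.

Because the final side defines the turn, the side at cul-de-sac exit
together with the parity of subsequent crossings determines the outcome
exactly (even = same side, odd = opposite). **PEven** is the fraction of
an individual's trials with an even post-cul-de-sac count (0 included);
each individual gets an exact two-sided binomial test against 0.5 and a
cohort gets a sign test over its individuals' PEven values. The
`exclude_zero` variant conditions on at least one crossing, separating a
genuine parity tendency from mere wall-hugging. Two null analyses probe
alternative explanations:

* `crossing_scan()` recounts crossings up to a continuously varying
  scoring position; a parity tendency keeps the even fraction above 0.5
  across positions, a characteristic crossing wavelength makes it
  oscillate.
* `resample_interval_null()` rebuilds each trial's crossing sequence by
  resampling the individual's pool of inner-crossing intervals with
  replacement from the cul-de-sac exit, truncated at the trial's own
  maximal y. This preserves interval statistics while destroying any
  dependence between consecutive crossings; PEven recomputed on the
  rebuilt sequences gives the null distribution.

# Wall proximity and fields

The MAD score is the median absolute deviation of x *from the midline*
(not from the sample median — wall proximity is relative to the arm's
axis), pooled over all of an individual's samples in a y-window:
$(y_c, 1)$ for the upward traversal, $(-1, -y_c)$ downward. Scores feed
extreme-group splits (bottom/top $k$ or quantile, stable-id
tie-breaking), strata conditioned on the post-cul-de-sac crossing
count, rank-sum comparisons (Bonferroni-corrected across a comparison
family by default, the correction method being configurable), and
Pearson correlations.

Occupancy fields normalize each individual's 2D histogram to unit mass
before averaging, so individuals contribute equally regardless of trial
count. Velocity fields use forward differences of consecutive
within-trial samples, binned by the position of the first sample, with
no smoothing; each occupied bin reports the unit mean-displacement
direction and its visit share. The default grid is 0.05-unit square
bins, chosen as roughly a tenth of the arm width.

# Synthetic data

Two generators make every stage testable without tracking data.

**Agent-based models** integrate point agents with Euler steps
(dt = 1/30 s, matching 30 fps acquisition) and specular wall
reflections: *brownian* redraws the heading uniformly each step;
*heading_rw* diffuses it, $\theta \leftarrow \theta +
\sigma\sqrt{dt}\,\xi$; *wall_following* adds a steering term that,
within sensing range of a wall, rotates the heading toward the nearest
wall tangent blended slightly toward the wall (blend angle
$\frac{\pi}{4}\,d/R$, vanishing at contact) with a dimensionless gain.
These update rules are this package's reference reconstruction of
tunable wall-following locomotion; they are fully parameterized so
alternative rules can be slotted in. Each agent runs on its own RNG
substream derived from a master seed, and simulated tracks flow through
segmentation and every analysis with no special-casing. Two emergent
properties matter for interpretation: wall attraction produces
individual handedness (within-agent turn sequences are correlated), and
wall-followers' crossing counts beyond zero are mildly *odd*-biased —
they never show an even excess.

**The parametric parity generator** samples ready-made normalized
trials on a fixed y-grid: with probability `p_zero` a trial hugs one
wall (zero post-cul-de-sac crossings); otherwise the crossing count is
$1 + \mathrm{Poisson}(\lambda)$ nudged to the parity drawn with
probability `beta` of being even, and crossing locations are placed in
the post-cul-de-sac span (distinct uniform grid positions by default,
or cumulated exponential gaps). The expected even fraction is
`p_zero + (1 - p_zero) * beta` in closed form, which the test suite
recovers. Turn labels derive from the final side, so the
exit-side/parity/turn identity holds exactly by construction. Defaults
emulate a wild-type-like short-maze cohort: 24% zero-crossing trials,
overall even fraction 0.65, ≈3.7 post-cul-de-sac and ≈6 cul-de-sac
crossings per trial, 144 trials per individual.

What the generators do *not* emulate: within-cul-de-sac side
persistence (so generated cohorts are not TPI-predictive inside the
cul-de-sac), pausing and speed modulation (agents never stop, so
temporal and spatial binning differ less than in real data), and any
coupling between consecutive trials beyond the recorded previous arm.
Passing tests on synthetic cohorts therefore validate the estimators
and their invariances, not any biological claim about real flies.

# Numerical choices and degenerate inputs

* Ties for the turning point (flat trial bottom) resolve to the first
  minimal sample; trials whose turning point is the first or last
  sample, or with a zero-length phase, are rejected as degenerate.
* Bin membership is inclusive at both edges, matching the bin
  definitions above; the 0.1/0.075 bin widths and the ±1.3/±1.275
  spans are the standard schemes and can be overridden.
* Maze geometry defaults: arm width 1, short arm length 2 (long 4,
  twice as long). The paper-scale cul-de-sac boundary 0.34 then sits
  just above the rounded cap, which starts at normalized y ≈ 0.26.
* Interval resampling caps the per-draw matrix at 500 intervals and
  extends scalar-wise beyond, so pathological pools cannot exhaust
  memory; empty pools skip the individual with a note.
* All stochastic paths take explicit seeds; cohort simulation derives
  per-agent substreams from the master seed so agents are independent
  but reproducible.

# Problem sizes used by the checks

The test suite and the analysis scripts run entirely on synthetic
cohorts sized for quick, stable statistics: parity cohorts of a few
hundred to 5,000 trials, agent cohorts of 8–20 agents at 20–40
simulated minutes each (the Brownian control, which reaches the
cul-de-sac rarely, gets 2-hour sessions), and 300–500 resamples for
null distributions. These sizes put Monte-Carlo error comfortably below
the assertion margins used in the tests.

# Known limitations

* The package analyzes centroid tracks; it does not do video I/O,
  tracking, or lens-distortion correction.
* Human-style data are handled by rotating each arm onto the bottom arm
  (the geometry is 3-fold symmetric by construction); incomplete
  traversals are dropped by segmentation.
* The agent models are point agents with reflective collisions; no
  biomechanics, and no fitting of agent parameters to real data.
* Cohort medians can be pooled over trials (default) or taken
  per-individual first; both are available because published summary
  conventions vary.
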