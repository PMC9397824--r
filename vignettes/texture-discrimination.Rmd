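---
title: "Assessing and training touch sensibility with rendered gratings: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing and training touch sensibility with rendered gratings: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(texdisc)
```

## The task and what this package simulates

Tactile discrimination of grating textures is a standard probe of touch
sensibility, and a candidate outcome measure for somatosensory retraining
after stroke. In the robotic version of the task, a force-feedback robot
renders three virtual textures as sinusoidal force gratings; on every
trial two textures share a spatial frequency and the participant hunts for
the odd one (a *triangle test*, guessing probability 1/3). The robot can
either leave the hand free (*active touch*) or drive it along the texture
with an impedance controller (*passive touch*, the clinically relevant
mode for patients who cannot move the paretic hand themselves).

`texdisc` implements the complete computational core of such a system at
desk scale: the force laws and guidance controller, the constant-stimuli
triangle-test protocol, the psychometric and kinematic analyses, and the
reliability and power statistics. Because no human or robot is attached,
the package also supplies the two simulators that close the loop — a
point-mass hand/end-effector model and a stochastic observer with known
psychometric parameters — so every analysis can be validated by parameter
recovery on data whose ground truth is known.

## Stimuli and trial structure

A grating is described by its spatial frequency $f$ (m$^{-1}$); its
spatial period is $1/f$. The default stimulus set fixes the standard at
$f_{St} = 164$ m$^{-1}$ and arranges eight comparison stimuli
symmetrically around it, four *more coarse* ($100$–$148$ m$^{-1}$) and
four *less coarse* ($180$–$228$ m$^{-1}$), spaced $16$ m$^{-1}$ apart so
that the standard equals the mean of the comparisons. The stimulus
intensity axis used throughout the analysis is the *difference ratio*
$x = |f_{Co} - f_{St}| / f_{St}$, which spans $16/164 \approx 0.098$ to
$64/164 \approx 0.390$ for this set.

An assessment block presents each comparison five times (40 trials) in a
seeded random order; each trial draws one of the six triangle position
patterns (St/St/Co … St/Co/Co) uniformly. For training, three 40-trial
blocks are built; the comparison order is randomized once and repeated in
blocks two and three. The position patterns are re-drawn per block: the
published protocol states only that the *stimulus* order repeats, and
repeating odd positions would let a participant answer from memory, so
independence is the conservative choice.

## Haptic rendering and guidance

Forces are composed from three laws, all acting at the end effector:

* grating force along the scanning axis $y$:
  $F_g = C \sin(2 \pi f \, y_{EE})$ with amplitude $C = 3$ N, applied
  only while in contact (below the virtual table height
  $z_{tbl} = 1$ mm and inside a texture rectangle);
* a PD virtual wall in $z$:
  $F_z = K_z (z_{tbl} - z_{EE}) - B_z \dot z_{EE}$ for
  $z_{EE} < z_{tbl}$, with $K_z = 1960$ N/m and $B_z = 28$ N·s/m;
* passive-mode guidance along $y$:
  $F_{hg} = m_v \ddot y_R + K_{hg} (y_R - y_{EE}) + B_{hg} (\dot y_R -
  \dot y_{EE})$, gated on contact, with $K_{hg} = 300$ N/m,
  $B_{hg} = 60$ N·s/m.

The guidance reference $y_R(t)$ follows the cycloidal motion law,
$y_R = y_0 + D\,(t/T - \sin(2\pi t/T)/(2\pi))$, which starts and ends
each sweep with zero velocity *and* zero acceleration, so concatenated
sweeps are C$^1$-continuous and the feedforward term vanishes smoothly at
the turn-arounds. The printed form of the guidance law adds the reference
acceleration (m/s$^2$) directly to force terms (N); we make the units
explicit through a virtual feedforward mass $m_v$, defaulting to 1 kg so
the numbers coincide with the bare sum.

The three textures lie side by side along $x$ (0.176 m long, 0.02 m wide,
0.01 m gaps), middle texture centred at the origin; the robot is
transparent in $x$.

### The simulated exploration loop

`simulate_exploration()` integrates a point-mass hand/end-effector,
$m_h \ddot{\mathbf p} = \mathbf F_{robot} + \mathbf F_{hand} - b_h
\dot{\mathbf p}$, with semi-implicit Euler at 1 kHz (the typical haptic
servo rate), using $m_h = 1$ kg and a viscous hand impedance
$b_h = 5$ N·s/m. The scripted hand visits the three textures in order:
it settles above a texture (0.7 s transit, 0.35 s press — long enough for
the PD approach to settle before a sweep starts), presses down with 5 N,
then sweeps along the texture. In passive mode the robot's guidance does
the sweeping and the hand stays compliant; in active mode the hand's own
PD policy tracks the same cycloidal schedule with guidance off. Sweep
duration is set so the cycloid's peak speed is 0.17 m/s, matching typical
scanning speeds in this task. Sweeps turn around 4 mm inside the texture
edge so a lagging end effector cannot slip off the texture and lose the
contact-gated guidance.

Numerical behavior is tested rather than assumed: the wall dissipates
energy in a free-drop test, tracking error decreases monotonically as
$K_{hg}$ grows through $\{100, 300, 1000\}$ N/m (maximum
$|y_R - y_{EE}| < 1$ cm at the default gain), and halving the timestep
moves the final position by less than $10^{-4}$ m. Non-finite states
abort with an error naming the parameter set.

## The simulated observer

The observer answers each triangle trial correctly with probability
$p(x)$ and otherwise picks uniformly between the two non-odd positions.
Its default response model is the same logistic family the analysis fits,
$p(x) = \mathrm{logistic}(\alpha + \beta x)$, with $\alpha = -\ln 2$ so
that $p(0) = 1/3$ exactly (the triangle-test chance level) and
$\beta = 10$. A guessing-floored variant,
$p(x) = 1/3 + \tfrac{2}{3}\,\frac{F(x) - F(0)}{1 - F(0)}$, keeps the
floor at exactly 1/3 for any finite $\alpha$; it exists for robustness
experiments because the analysis chain fits a plain logistic even though
triangle-test chance is 1/3, and the anchored form is the member of that
family that honours the floor exactly. Observers are stateless; training
effects are modelled by switching to an observer with a larger slope.

## Psychometric analysis

Task performance per phase is the mean over the eight comparisons of the
per-stimulus proportion correct $p_i$. The psychometric analysis fits, by
maximum likelihood (`stats::glm`, binomial), one logistic per coarseness
side and reads off the point of subjective equality
$PSE = -\alpha/\beta$, the difference ratio at which the fitted curve
crosses 0.5. A fit counts as *converged* only when the PSE lies inside
the baseline ratio range $[16/164,\, 64/164]$ (bounds inclusive; the
exact fractions are used, which print as 0.098 and 0.39). Perfect
separation, degenerate designs and non-positive slopes are data states
flagged as non-converged, never errors.

Phase-level PSE applies two protocol rules: a participant who answered
*every* trial of the phase correctly scores the minimum ratio $16/164$
(the ceiling edge rule, applied per phase as the protocol describes; a
per-side variant sits behind `all_correct_rule = "side"`), and otherwise
the phase PSE is the mean of the two side PSEs, missing unless both sides
converged so that paired pre/post analyses can exclude the participant
(`require_both_sides = FALSE` relaxes this).

### Adaptive training stimuli

After baseline, each converged side's four training comparisons are
re-centred on that side's PSE with the baseline spacing
$\Delta = 16/164$ retained: ratios
$PSE + \{-1.5, -0.5, 0.5, 1.5\}\Delta$, clipped below at the smallest
ratio the robot can render (one 0.02 mm change of the standard's period)
and above at $64/164$, then mapped back to frequencies as
$f_{St}(1 \mp r)$. When the PSE equals a side's central baseline ratio
the construction returns exactly that side's baseline stimuli, and a
non-converged side keeps its baseline comparisons. The exact construction
used in the original study is not published beyond its inputs; this
symmetric equal-spacing rule is our reconstruction and is deliberately
isolated in `adapt_training_set()` so it can be swapped.

## Design statistics and reliability

`triangle_power()` implements the exact one-sided binomial test of the
guessing probability: critical count
$c = \min\{k : P(X \ge k \mid n, 1/3) \le \alpha\}$, power
$P(X \ge c \mid n, p_{alt})$. `triangle_sample_size()` scans $n$ upward;
because exact power is a sawtooth in $n$, the default returns the first
crossing (what common tools report) and a `"stable"` mode requires all
larger $n$ to qualify too. With $p_{alt} = 25/40$ — the pilot rate of the
original study — $\alpha = 0.05$ and target power 0.95, the first
crossing is $n = 34$.

Test-retest reliability uses ICC(2,k): two-way random effects, absolute
agreement, average measures,
$(MS_R - MS_E)\,/\,(MS_R + (MS_C - MS_E)/n)$, with F-based confidence
bounds obtained on the single-measures coefficient and stepped up by
Spearman–Brown, and the p-value from $F = MS_R/MS_E$. No reliability
package is imported; the implementation is tested against a from-scratch
`aov()` mean-squares oracle on random matrices (agreement to $10^{-10}$).
Bland–Altman limits are the mean paired difference $\pm\, 1.96$ SD.

## The protocol simulator

`run_protocol_simulation()` executes the full three-session design:
session 1 holds a familiarization trial (twin 228 m$^{-1}$ gratings with
a 100 m$^{-1}$ odd texture — logged but excluded from analysis) and two
40-trial initial baselines, one per condition in counterbalanced order;
sessions 2 and 3 each run baseline, three training blocks with the
PSE-adapted set, and retention, with the session-2 condition randomized
over half the sample and crossed over on day 3. All randomness derives
from one master seed through deterministic sub-seed derivation, so a
study reproduces byte-identically. `analyze_study()` recomputes phase
scores, PSE outcomes, the per-condition ICC and Bland–Altman tables
(day-1 iBL vs day-2 BL, participants grouped by their day-2 condition),
and kinematics from any stored traces.

Kinematic traces are simulated for a configurable subset of trials
(default: the first trial of each assessment phase). Tracing all ~480
trials per participant is possible (`trace_policy = "all"`) but is
rarely informative, since the scripted exploration policy is identical
across trials of a condition.

## What the simulation does and does not show

The simulators reproduce the *structure* of the experiment — chance
level, psychometric family, protocol arithmetic, controller physics —
with known ground truth, which is exactly what is needed to validate the
analysis chain. They deliberately omit perceptual mechanism (vibration
coding, adaptation), learning dynamics within a session, lapses and
attention drift, 6-DOF robot dynamics and friction. A passing test suite
therefore certifies the computations, not the human findings: group-level
results from the original experiment require the human dataset and are
out of scope here.

## Problem sizes used in the tests

Monte-Carlo checks use 60,000 draws for pattern uniformity, 100,000
trials for the chance-level check, 200 simulated observers at 400
trials/side for PSE recovery, 50 random matrices for the ICC oracle and
500,000 replicates per point for binomial-power verification; controller
checks run single trials with one sweep per texture at 1 kHz. These sizes
give Monte-Carlo standard errors comfortably below the asserted
tolerances while keeping the whole suite around a minute.

## A short worked example

```{r example, eval = FALSE}
set.seed(7)
s <- default_stimulus_set()
blk <- constant_stimuli_block(s, repetitions = 5, phase = "BL", seed = 1)
obs <- observer_model(alpha = -2, beta = 12)   # true PSE = 1/6
sim <- simulate_block(blk, obs, seed = 2)
phase_score(sim, s)$score
pse_outcome(sim)$pse

dir <- tempfile("study")
cfg <- protocol_config(n_participants = 4, trace_policy = "none")
run_protocol_simulation(cfg, dir, seed = 11)
analyze_study(dir)
```
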