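---
title: "Modeling clonal dynamics and therapy response with clonedyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling clonal dynamics and therapy response with clonedyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonedyn)
```

## The model

clonedyn simulates a tumor as a set of competing cell subpopulations
(subclones) evolving in discrete time. The model is deliberately reduced:
each subclone is described by three rate attributes —

* **DR**, the division rate: the probability that a cell divides in one
  iteration;
* **AR**, the apoptosis rate: the fraction of the subclone's cells that die
  in one iteration;
* **MR**, the mutation rate: the expected number of mutations the subclone
  acquires per iteration —

plus its current size $n$, its set of driver mutations and its cumulative
tumor mutation burden (TMB). One iteration represents a fixed real-time
interval $T$ (10 days by default, calibrated for slowly cycling cells with
$AR = 0.02$).

### Growth with competition

Each iteration, a subclone of size $n$ gains

$$ B \sim \mathrm{Poisson}\!\left(n \, DR \, e^{-N \cdot DR \cdot AR / c}\right) $$

cells and loses $\lfloor n \cdot AR \rfloor$ cells, where $N$ is the total
tumor size at the start of the iteration and $c$ is the competition
constant. The single pooled Poisson draw is distributionally identical to
summing one $\mathrm{Poisson}(DR \cdot e^{-\cdot})$ draw per cell
(superposition; this equivalence is verified in the test suite). The
exponential factor throttles *births only*: damping deaths instead would
weaken mortality exactly where crowding should enforce it, and damping the
whole net change leaves the equilibrium unbounded. With births throttled,
the expected-size recursion has a stable fixed point at

$$ N^* = \frac{c \, \ln(DR / AR)}{DR \cdot AR}, $$

a Gompertz-like carrying capacity ($\approx 1.39 \times 10^6$ cells at the
defaults $DR = 0.2$, $AR = 0.05$, $c = 10^4$). The test suite checks that
long-run simulated means settle within 5% of $N^*$ when mutation processes
are switched off. The model is well-mixed: there is no spatial structure,
so it is not suited to tumors whose geometry shapes competition.

### Passenger mutations

Every iteration a subclone acquires
$k = \lfloor MR \cdot U(0, z) \rfloor$ passenger mutations ($z = 0.1$).
Each passenger perturbs the division rate additively by
$U(x_1, y_1) = U(-0.001, 0.0008)$ and the apoptosis rate *relatively* by
$U(x_2, y_2) \cdot AR = U(-0.002, 0.002) \cdot AR$. The DR perturbation is
asymmetric around zero, so passengers carry a slightly deleterious load —
heavily mutated clones slowly lose fitness (Muller's ratchet), which is
what makes very high mutation rates self-limiting in the parameter sweeps.
All $k$ passengers count toward the subclone's TMB. A configuration switch
(`passenger_model = "poisson"`) replaces the count with
$\mathrm{Poisson}(MR / 100)$, a weaker mutational load sometimes quoted
for passenger processes; the default follows the floored-uniform form.

### Driver events

With probability $\min(1, MR / 6000)$ per iteration, a subclone spawns a
new subpopulation founded by one cell carrying a new **driver event**. The
chance is per subpopulation, not per cell — a deliberate echo of Peto's
paradox (cell number does not proportionally raise the chance of a
cancer-driving hit). The driver belongs to one of three hallmark
categories, drawn uniformly:

| Category | DR change | AR change | MR change |
|---|---|---|---|
| proliferation/survival | $+U(0.10, 0.25)$ | $\times\,0.95$ | $+U(10, 20)$ |
| invasion/microenvironment | $+U(0.05, 0.15)$ | $\times\,0.60$ | $+U(10, 20)$ |
| genomic mutability | $+U(0.05, 0.15)$ | $\times\,0.95$ | $+U(50, 100)$ |

Every child therefore has strictly higher DR than its parent at spawn —
new subclones are, by construction, fitter. The child starts at size 1,
debited from the parent so cells are conserved; 1 is the most conservative
choice and any small constant behaves similarly. At most 10 subclones may
coexist; when the cap is full, driver trials are suppressed (rather than
evicting a resident clone), and extinction frees capacity. Each founder
subclone is tagged with one synthetic founding driver event so that
targeted therapy and the off-target metric are well-defined from time 0;
the founding event contributes 1 to the founder's initial TMB.

### Mutation-rate drift

MR itself drifts: with probability 0.1 per iteration the change is
size-dependent, $s \cdot (\log_{10} n - \log_{10} 10)$ with scale $s = 10$,
so clones below 10 cells tend to lose mutability and large clones gain it;
otherwise the change is symmetric noise $U(-s, s)$. The scale $s$ controls
how fast mutability wanders; 10 keeps the size-dependent gain of a
$10^6$-cell clone at a biologically plausible ~50 per event while leaving
small clones' MR roughly stationary. Because the noise is clamped at
$MR \ge 0$, MR performs a reflected random walk — a population started at
$MR = 0$ will regain mutability unless the drift scale is also set to 0
(`global_params(mr_drift_scale = 0)`), which is how the test suite builds
truly mutation-free controls.

### Sub-step order

Within one iteration every living subclone is processed in a fixed order:
(1) growth/death using the shared start-of-iteration $N$; (2) active
therapy effects; (3) passenger drift; (4) MR drift; (5) driver trials;
then extinct subclones are removed, totals recomputed and the clock
advanced. The order is a convention that must simply be fixed and
documented; therapies act directly after growth so that a course's effect
is visible in the same iteration's record. A subclone spawned at step (5)
first participates fully in the following iteration; its `origin_time`
equals the time of its first trajectory record.

## Therapies

All four operators are cytotoxic — each active course strictly shrinks at
least one targeted subclone per iteration:

* **Targeted therapy** draws one driver event, uniformly, from the driver
  set of the largest subclone at course start (ties broken by lowest
  subclone id) and keeps that target for the whole course. Every subclone
  carrying the event — descendants included — loses $U(25\%, 60\%)$ of its
  cells per iteration; non-carriers are untouched. The carriers' DR is
  halved for the duration (`targeted_dr_factor`) and restored to its exact
  pre-course value when the course ends. Subclones that arise mid-course
  inherit their parent's suppressed DR and are not separately restored.
* **General therapy** removes $U(5\%, 15\%)$ of every subclone plus an
  integer loss drawn uniformly from 0–99 — negligible for a bulky tumor but
  lethal to small subclones — and raises MR by $U(0, 10)$ per iteration as
  a mutagenic side-effect.
* **Surgery** acts at a single iteration and removes every subclone
  entirely unless it carries the metastasis-permitting hallmark (genomic
  mutability by default; `surgery_hallmark` can switch this to the
  invasion hallmark, arguably the more natural biology) *and* exceeds 100
  cells. Qualifying clones keep the saturating fraction
  $\min(0.40,\, 1 - e^{-n \cdot 10^{-9}})$ of their cells. This form rises
  with clone size and caps at 40%; in practice clones below $\sim 10^5$
  cells leave no survivors, so surgery is close to curative unless a large
  mutability-hallmark clone exists.
* **Immunotherapy** kills the TMB-dependent fraction
  $\min(0.45,\, 1 - e^{-0.02 \cdot TMB})$ of each subclone per iteration:
  highly mutated clones present more neoantigens and are hit harder, up to
  a 45% ceiling.

The surgery and immunotherapy response curves are saturating forms chosen
so that efficiencies are valid proportions that increase in clone size and
TMB respectively and respect their stated ceilings (40% and ~45%); the
exact shapes below the ceiling are modeling choices.

Durations are capped at 10 iterations for general therapy and 15 for
targeted therapy and immunotherapy; surgery ignores its duration. By
default consecutive courses must be at least 10 iterations apart;
experiment scenarios that deliberately probe shorter gaps (including
overlapping courses) disable this check with `strict_schedule = FALSE`.

## Heterogeneity metrics

Two complementary intra-tumor heterogeneity (ITH) summaries are computed
on every state:

* **Dominant clone proportion** — size of the largest living subclone over
  total size; an *absolute* heterogeneity measure (1 = clonal).
* **Off-target probability** — the fraction of extant driver mutations not
  carried by the dominant subclone; a *potential* heterogeneity measure:
  the chance that a therapy aimed at the dominant clone's biology misses a
  subclonal driver. Ties for dominance are broken by lowest subclone id
  (the proportion metric is tie-invariant; the off-target metric is not,
  so the tie-break matters and is fixed). Drivers private to extinct
  subclones are excluded.

Therapy outcomes are summarized as the base-10 log fold change of total
size across a fixed window (log base 10 is a reporting choice; the ratio
itself is also returned).

## The experiment harness

Every scenario runs `reps` independent simulations with per-replicate
seeds drawn once from the base seed, so the whole table is reproducible
and any single replicate can be re-run in isolation. The canonical study
size is 200 replicates; the packaged tests assert the same orderings at a
50-replicate tier with correspondingly conservative margins (the scenario
functions themselves default to 200).

Scenario design choices, made once:

* **Multi-founder recipes.** Founders split the initial cell count
  equally, each drawing its DR independently from $U(0.15, 0.2)$ (the
  cancer-cell range), with $AR = 0.05$, $MR = 100$. Untreated sweeps start
  from total size 30; therapy scenarios start from total size 100 so
  tumors are well grown when treatment begins at iteration 100.
* **Therapy intervals.** The interval is the gap between the *starts* of
  the targeted course (iteration 100, duration 10) and the adjuvant
  general course, so interval 5 overlaps the two courses. The alternative
  reading — a gap measured from the end of the targeted course — was
  implemented and rejected: with it, every adjuvant course finishes long
  before the outcome window closes and regrowth toward carrying capacity
  erases any ordering, whereas the start-to-start reading reproduces the
  expected pattern (earliest adjuvant course best, outcomes degrading with
  delay). Outcome: log10 fold change of N between iterations 100 and 170.
* **Adjuvant vs neoadjuvant.** Surgery and a 10-iteration general course
  at iterations 100 and 120 in the two orders; same outcome window; arms
  compared with a Wilcoxon rank-sum test whose p-value is reported, never
  asserted against a fixed value. In this parameterization the adjuvant
  arm (surgery first) tends to do *better*: the tumor is smallest at the
  earlier surgery, and the quadratic-in-size survivor curve makes delaying
  surgery costly — see "Known limitations".
* **ITH-outcome correlation.** Three founders, a single 10-iteration
  targeted course at iteration 100, outcome measured 50 iterations after
  the course ends (iteration 160 vs 100, i.e. the window starts at course
  start); both metrics recorded at iteration 100 and compared to the
  outcome by Spearman rank correlation.
* **Tumorigenesis.** Near-normal founders ($AR = 0.02$, size 30), varying
  MR over {50, 100, 500} and DR over {0.02, 0.03, 0.04} one at a time
  around the no-advantage base point $DR = AR = 0.02$, $MR = 100$. Runs
  stop at the detectable size 10,000 or a 2000-iteration cap
  (~55 years); censored runs are reported, not dropped. Iterations convert
  to years at $T = 10$ days.

## What the simulator does and does not emulate

The simulator *is* the data generator: it produces subclone size
trajectories with realistic qualitative features — Gompertz-like
saturation, selective sweeps that transiently reduce heterogeneity,
parabolic heterogeneity over tumor development, relapse from off-target
subclones after targeted therapy, and mutational meltdown at extreme
mutation rates. It does not emulate spatial structure, microenvironmental
niches, germline variation, pharmacokinetics, cytostatic (growth-arrest)
therapy, measurement noise, or sequencing-based observation of clones.
Conclusions from these simulations are statements about the model, not
about any particular patient cohort.

## Numerical conventions

* Deaths are the deterministic $\lfloor n \cdot AR \rfloor$; below
  $n = 1/AR$ cells this floor is 0, so small subclones cannot die of
  apoptosis — extinction happens through therapy or the spawn debit. This
  is a real discreteness effect of the floored form, visible as a small
  upward bias of equilibria (+0.5 cells per iteration on average).
* DR is clamped to $\ge 10^{-6}$, AR to $[0, 1)$, MR to $\ge 0$, sizes to
  non-negative integers, after every perturbation.
* All randomness flows through R's global RNG from a single
  `set.seed(seed)`; replicate seeds are drawn once by `replicate_seeds()`.
  Identical inputs and seed give bit-identical trajectories.
* Trajectory CSVs store doubles at 17 significant digits, so
  write-then-read round-trips are exact.

## Problem sizes

The packaged test suite runs scenarios at 50 replicates and the
single-trajectory checks over a handful of seeds; Monte-Carlo oracles use
$10^5$ draws (3 standard errors) and goodness-of-fit checks $10^4$
samples. These sizes keep the suite comfortably under a couple of minutes
while leaving the asserted orderings far from their noise floor; the
scenario functions default to the canonical 200 replicates.

## Known limitations

* **Detection-time calibration.** The median time for a no-advantage
  founder to reach detectable size is governed almost entirely by the
  driver-event chance $MR/6000$ and the post-driver expansion speed; with
  the default constants the median is ~3.2 years. Published estimates of
  the time to a first driver hit in normal tissue are several-fold longer;
  matching them would require a lower effective driver rate than the
  model's stated constant, so absolute detection times should be read as
  model time, not calendar predictions.
* **Surgery order-of-therapy results.** Because the metastatic survivor
  fraction grows with clone size and regrowth toward carrying capacity is
  fast, operating *earlier* (adjuvant arm) is advantageous in this
  parameterization, and the often-cited clinical benefit of neoadjuvant
  systemic therapy before surgery is not reproduced. The result is
  sensitive to the survivor curve, which is only pinned down at its 40%
  ceiling.
* General therapy barely shrinks a tumor sitting at carrying capacity
  (kill ~10% per iteration against regrowth of a similar magnitude); its
  long-run value in the model comes from its mutagenic side-effect (via
  the passenger ratchet) and from crushing small subclones with its
  absolute loss term.
* The subclone cap (10) is a visualization-motivated constraint; it
  suppresses late driver supply in large tumors.
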