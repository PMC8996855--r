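# clonedyn

Stochastic simulation of tumor subclonal evolution and therapy response.

Tumors are mixtures of genetically distinct cell subpopulations, and that
intra-tumor heterogeneity (ITH) — which subclones exist, how big they are,
and which driver mutations they carry — largely decides whether a therapy
works or a resistant minority repopulates the tumor. `clonedyn` is a
seeded, reproducible simulator of this process for anyone who wants to
study ITH dynamics and treatment timing in silico: a discrete-time
stochastic clonal-expansion model with competition, driver/passenger
mutation processes, four cytotoxic therapy operators, two ITH metrics, and
a replicated experiment harness that turns simulation studies into tidy
tables.

## The model in brief

Each subclone carries a division rate $DR$, an apoptosis rate $AR$ and a
mutation rate $MR$. Per iteration (a fixed interval, 10 days by default) a
subclone of size $n$ gains

$$B \sim \mathrm{Poisson}\left(n\,DR\,e^{-N \cdot DR \cdot AR / c}\right)$$

cells and loses $\lfloor n\,AR \rfloor$, where $N$ is the total tumor size
and $c = 10^4$ a competition constant — a Gompertz-like constraint with
carrying capacity $N^* = c\,\ln(DR/AR)/(DR \cdot AR)$. Passenger mutations
($\lfloor MR \cdot U(0, 0.1)\rfloor$ per iteration) nudge $DR$ and $AR$
with a slightly deleterious bias and accumulate into the tumor mutation
burden (TMB); with chance $MR/6000$ a driver event founds a new, strictly
fitter subclone of one of three hallmark flavors (proliferation/survival,
invasion/microenvironment, genomic mutability). Up to 10 subclones
coexist. Therapy operators — targeted (kills 25–60%/iteration of subclones
carrying a chosen driver), general (5–15% plus an absolute loss, with a
mutagenic side-effect), surgery (instant removal; only large
mutability-hallmark clones leave up to 40% metastatic survivors) and
immunotherapy (kill fraction $\min(0.45, 1 - e^{-0.02\,TMB})$) — act on
the simulated tumor on a validated schedule.

Heterogeneity is summarized by the **dominant clone proportion** (largest
subclone / total) and the **off-target probability** (fraction of extant
driver mutations absent from the dominant subclone). The methods vignette
(`vignettes/clonal-dynamics.Rmd`) derives and motivates every rule and
constant.

## Worked example

```r
library(clonedyn)

traj <- simulate_tumor(founders(size = 30), iterations = 200, seed = 1)
traj
#> <tumor_trajectory> 200 iteration(s), 10 subclone(s) ever, final N = 8,128,202

tail(ith_metrics(traj), 3)
#>    time dominant_clone_proportion off_target_probability      N living_subclones
#> 1   198                     0.894                    0.5 8.04e6               10
#> 2   199                     0.895                    0.5 8.08e6               10
#> 3   200                     0.895                    0.5 8.13e6               10

fold_change(traj, 100, 170)
#>      t0    t1      N0      N1 fold_change log10_fold_change
#> 1   100   170 3498091 7048066        2.01             0.304

autoplot(traj)   # Muller-style stream plot of subclone sizes
```

A single founder of 30 cells (DR 0.2, AR 0.05, MR 100) grows to ~8.1
million cells, saturating against the competition constraint; by the end
one subclone holds 89.5% of the tumor (dominant clone proportion 0.895)
while half of the driver mutations present are not in that clone
(off-target probability 0.5) — ten subclones coexist, so a therapy aimed
at the dominant clone's drivers could miss real targets. Between
iterations 100 and 170 the tumor doubles (log10 fold change +0.30).

Replicated scenarios return tidy objects:

```r
cc <- ith_outcome_correlation(n_founders = 3, reps = 50, base_seed = 1)
glance(cc)
#>   rho_dominant p_dominant rho_off_target p_off_target n_founders reps
#> 1      -0.0992      0.492          0.145        0.315          3   50
tidy(cc)   # one row per replicate: metrics at therapy start + outcome
```

At 50 replicates the signs already point the expected way — more clonal
tumors (higher dominant proportion) respond better to targeted therapy
(negative rank correlation with the log fold change), more subclonal
drivers predict worse response — and at the canonical 200 replicates both
correlations are significant (−0.27 and +0.25, p < 3e−4).

Other scenarios: `sweep_parameters()`, `sweep_therapy_intervals()`,
`compare_adjuvant_neoadjuvant()`, `metric_trajectory_summary()`,
`tumorigenesis_study()`. A thin command-line front end wraps them:

```sh
Rscript inst/cli/clonedyn.R simulate --config config.yaml --out-dir out/
Rscript inst/cli/clonedyn.R experiment therapy_intervals --reps 200 --seed 1 --out-dir out/
Rscript inst/cli/clonedyn.R metrics out/trajectory.csv
```

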