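# ccgrowth

Single-cell growth dynamics of asymmetrically dividing bacteria.

*Caulobacter crescentus* divides into two different daughters: a small,
motile **swarmer** cell that spends an extended G1 phase before replicating
its chromosome, and a larger **stalked** cell that starts replication almost
immediately. `ccgrowth` is for microscopists and quantitative biologists who
track such cells in timelapse movies and want cell-cycle-resolved growth
analysis from the resulting per-frame area tables and fluorescence stacks:
does the swarmer grow slower on average, and is any slowdown coupled to G1?

## What it computes

For each tracked cell with areas `A(t)` (1.5-min frames):

- **average growth rate** λ = ln(A_d / A_b) / Δt, from the areas at birth
  (A_b) and division (A_d) and the interdivision time Δt;
- **instantaneous relative growth rate**
  r_i = (A_{i+1} − A_i) / (A_i · Δt_frame) on a 12-frame (18-min)
  sliding-averaged trajectory;
- **exponential-fit residual score** — mean |A − Â|/A against a log-linear
  fit, a per-cell measure of departure from single-exponential growth;
- **G1 duration** — time from birth to the first fluorescence frame with two
  replication-marker foci, under either of two birth conventions:
  visible daughter separation, or cytokinesis completion (quantities under
  the latter carry an asterisk: G1\*, growth rate\*);
- **cell-cycle-aligned population curves** — rates mapped to normalized
  cycle time (0 = birth, 1 = division), binned, with percentile-bootstrap
  confidence bands from resampling cells, plus per-cell **tempograms**;
- rule-based **swarmer/stalked classification** (stalk flag + sister/self
  motion), the published **curation filters** (< 30 min cycles,
  < 0.61 µm² area gain, rates outside (−0.0025, 0.015) min⁻¹, incomplete
  lineages, uncertain identity) with full rejection logging, and the
  statistical primitives used throughout (Mann–Whitney U with exact
  enumeration for small tie-free samples, two-sample KS, Spearman,
  bootstrap CI of a mean).

A fully ground-truthed **synthetic generator** produces lineages with a
G1-coupled growth-rate dip, asymmetric division, cytokinesis-before-
separation event structure, measurement noise, and rendered
fluorescence/label-mask TIFF stacks — so every stage of the pipeline is
testable by parameter recovery. See `vignette("growth-analysis")` for the
model, parameter defaults and design rationale.

## Worked example

```r
library(ccgrowth)

p   <- sim_params(seed = 7)                      # study-condition defaults
sim <- simulate_lineage(p, n_generations = 3, n_founders = 60)
sim
#> Synthetic lineage: 420 cells (120 complete), 28586 tracked frames, 3 generations

tracks   <- link_generations(sim$table)          # mother/daughter/sister links
tracks   <- assign_birth_all(tracks, "cytokinesis")
tracks   <- classify_progeny_all(tracks)         # swarmer / stalked / uncertain
profiles <- growth_profiles(tracks)              # smoothing, rates, residuals
report   <- apply_filters(tracks, profiles, curation_config())
report
#> Curation: 120 retained, 300 rejected of 420 tracks
#>   incomplete_lineage: 300
#>   rate_above_upper: 1

keep <- report$retained
type <- vapply(tracks[keep], `[[`, "", "progeny_type")
avg  <- vapply(profiles[keep], `[[`, 1, "avg_rate")
mann_whitney_u(avg[type == "swarmer"], avg[type == "stalked"])
#> Two-sample test (asymptotic): statistic = 294, p = 2.748e-15 (n1 = 60, n2 = 60)
```

The 120 retained cells are the ones with a fully tracked cycle (founders and
final-generation cells have no linked mother or daughters and are dropped;
one cell additionally trips the upper rate bound). The swarmer cohort grows
about 9.6% slower on average (0.00667 vs 0.00737 min⁻¹ here), and G1\*
durations recovered from the simulated focus counts have medians of 38.2 min
(swarmer) versus 12.0 min (stalked) — the programmed asymmetry, recovered
end to end.

Aligned population curves and tempograms come from `align_cell_cycle()` +
`population_mean_curve()` + `tempogram()`, each with a `plot()` method.

## Command line

A thin Rscript front end wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "ccgrowth.R", package = "ccgrowth"))') \
    simulate --out sim/ --seed 7
# ... then: analyze --tracks sim/track_table.csv --foci sim/foci_counts.csv --out results/
```

Commands: `simulate`, `detect-foci`, `curate`, `analyze`, `report`. Every
command writes the exact configuration it used (`config_used.yaml`) next to
its outputs; identical config + seed reproduce outputs byte-for-byte.

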