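# pbodykinetics

Compartmentalized mRNA decay kinetics from single-molecule FISH imaging.

When decay of a tagged mRNA is induced synchronously (for example by
rapamycin-triggered tethering of a decay factor), the transcripts are
rapidly recruited into P-bodies, form bright RNA granules there, and
disappear over a few hours from both compartments. `pbodykinetics` is for
researchers who quantify that process: it turns smFISH-IF image stacks into
per-cell RNA counts in the cytoplasm and in P-bodies, fits a two-compartment
kinetic model to the resulting time courses, and asks which mechanistic
scenario — storage without decay, equal decay everywhere, or fast decay
inside granules — the data actually support.

## The model

RNA counts in the cytoplasm (CT) and in P-bodies (PB) follow the linear
system

    d RNA_CT / dt = -k_CT RNA_CT - k_R RNA_CT + k_L RNA_PB
    d RNA_PB / dt = -k_PB RNA_PB + k_R RNA_CT - k_L RNA_PB

with first-order decay rates k_CT and k_PB in each compartment, recruitment
k_R into P-bodies, and release k_L back to the cytoplasm (all per hour).
The package solves this system in closed form (eigen-decomposition of the
2x2 rate matrix, with the repeated-eigenvalue case handled by the
defective-matrix limit) and fits both observed curves simultaneously by
weighted nonlinear least squares under four nested variants:

| variant       | constraint      | interpretation                       |
|---------------|-----------------|--------------------------------------|
| `full`        | none            | all four rates free                  |
| `no_pb_decay` | k_PB = 0        | P-bodies are pure storage            |
| `equal_decay` | k_PB = k_CT     | granules confer no kinetic advantage |
| `no_leave`    | k_L = 0         | recruited RNA decays in place        |

Variants are ranked by reduced chi-square (weighted residual sum of squares
over degrees of freedom), with ties going to the model with fewer free
parameters. Bootstrap resampling of biological replicates gives parameter
intervals.

Because this kind of microscopy data is rarely deposited, the package ships
a first-class synthetic-data module: a count simulator with the replicate
and per-cell dispersion structure the fits assume, a renderer that builds
3D two-channel image stacks (single-RNA PSF spots plus granules on P-body
blobs, Poisson + read noise) with complete ground truth, and a live-cell
granule-intensity trace simulator. Every stage of the pipeline is tested
against those ground truths.

## Worked example

```r
library(pbodykinetics)

# ground truth: fast decay inside P-bodies, no release
p <- rate_params(k_ct = 0.2, k_pb = 3.0, k_r = 1.0, k_l = 0, n0_ct = 1500)

# a simulated experiment: 0-9 h, 4 replicates, 200 cells per timepoint
sim <- simulate_counts(p, "no_leave", experiment_design(seed = 7))

# fit all four variants and rank them
cmp <- compare_models(sim$pooled, options = fit_options(seed = 1))
cmp[, c("variant", "k_ct", "k_pb", "k_r", "k_l", "reduced_chi2", "sufficient")]
#>       variant  k_ct k_pb   k_r     k_l reduced_chi2 sufficient
#> 1    no_leave 0.220 2.98 0.987 0.00000      0.00234       TRUE
#> 2        full 0.221 2.97 0.987 0.00297      0.00255         NA
#> 3 equal_decay 1.001 1.00 0.949 1.92098      0.09156      FALSE
#> 4 no_pb_decay 1.339 0.00 0.987 3.12438      0.18500      FALSE

half_life(2.98)   # ~0.23 h inside P-bodies
half_life(0.220)  # ~3.2 h in the cytoplasm
```

The storage-only and equal-decay variants fit an order of magnitude worse
than the no-release model, which recovers the generating rates within a few
percent and is flagged `sufficient`: it matches the more complex full model
while using one parameter fewer. The rate ratio k_PB / k_CT ≈ 14 is the
kinetic advantage P-bodies confer in this simulation.

Image stacks are quantified the same way:

```r
st <- render_stack(scene_config(seed = 1))     # synthetic smFISH-IF stack
q  <- quantify_stack(st$rna, st$pbody)         # segment, detect, fit, count
q$cell                                         # n_ct, n_pb, n_pbodies, ...
```

`run_pipeline()` ties quantification, aggregation, fitting and comparison
into one provenance-stamped run from a JSON config;
`inst/scripts/pipeline.R` exposes the same stages as shell subcommands.

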