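# gaitfuse

Gait recognition from optical motion-capture marker trajectories by
decision fusion.

## What problem this solves, and for whom

An optical motion-capture system records the 3-D positions of ten
lower-body markers (thigh, shank, two ankle positions and tiptoe per
side) while a person walks a few meters at 5 Hz sampling. `gaitfuse`
identifies which of N enrolled subjects is walking from such a short
recording. It is aimed at researchers in gait biometrics and human
movement analysis who want a tested, scriptable reference implementation
of the first-classify-then-fuse approach — including when no capture
hardware is at hand: a deterministic synthetic gait simulator stands in
for the lab.

## The method

Per frame *t*, the feature vector `z^t` stacks the 45 pairwise marker
distances (strict upper triangle of the 10×10 distance matrix) with the
10 walking-axis velocities `v_i = (x_i^{t+1} − x_i^t)/τ` — 55 features.
The pipeline then:

1. **Calibrates** unreliable values: per feature, a Gaussian KDE with
   Silverman bandwidth `ρ = σ(4/(3L))^{1/5}` fitted on training data
   yields tail bounds `z_ub = Φ⁻¹(P_th)`, `z_lb = Φ⁻¹(1 − P_th)`
   (default `P_th = 0.999`); out-of-bound values are clamped to the
   bound (no frame is ever deleted).
2. **Classifies** each frame with a kernel extreme learning machine:
   RBF Gram matrix `K_ij = exp(−‖z_i − z_j‖²/h)`, one-vs-rest ±1 label
   coding `C`, closed-form weights `β = (K + I/λ)⁻¹ C`, scores
   `o^t = k(z^t, Z)β`.
3. **Softens** outputs into fuzzy memberships
   `μ_i = exp(−(o_i/(ō + γσ(o)))²)`, `γ = 0.5`.
4. **Fuses** the per-frame decisions with the reliability-weighted-sum
   rule: the consistency matrix `A_tk = ⟨μ^t, μ^k⟩` is built, its
   principal eigenvector (Perron–Frobenius orientation) is rescaled into
   `[a, a+b]` as per-frame reliabilities `r_t`, and the global decision
   is `μ_g = (1/T) Σ_t r_t μ^t`, winner by arg-max. Sum, product,
   majority-vote, belief and weighted-belief rules are included as
   baselines.

See `vignettes/gait-decision-fusion.Rmd` for the full account of
parameters, degenerate cases and design choices.

## Worked example

Ten synthetic subjects, one 121-frame training and one 61-frame test
recording each; KELM parameters chosen by validation trials; accuracy of
all six fusion rules against the fraction of fused test frames:

```r
library(gaitfuse)
pop   <- sample_population(10, seed = 11)
train <- simulate_gait_dataset(population = pop, n_frames = 121, seed = 12)
test  <- simulate_gait_dataset(population = pop, n_frames = 61,  seed = 13)

sel <- select_kelm_params(train)            # h = 4, lambda = 0.001
clf <- train_gait_classifier(train, h = sel$h, lambda = sel$lambda)
fusion_accuracy_curve(clf, test, ratios = c(0.1, 0.2, 0.5, 1.0))
#> eval_result: single-frame accuracy 0.977
#>  ratio rws sum product majority belief wbelief
#>    0.1   1   1       1        1      1       1
#>    0.2   1   1       1        1      1       1
#>    0.5   1   1       1        1      1       1
#>    1.0   1   1       1        1      1       1
```

Single frames are classified correctly 97.7% of the time; fusing even
the first 10% of a recording's frames lifts every rule to 100% subject
identification on this benchmark.

The fusion stage can be inspected on the bundled ten-frame worked
example (reliability bounds a = 0.3, b = 0.7 reproduce its tabulated
values):

```r
rws_fuse(toy_fuzzy_decisions(), a = 0.3, b = 0.7)
#> global_decision (rws rule): winner 'class2'
#> class1 class2 class3 class4 class5
#> 0.1150 0.2719 0.1565 0.1425 0.1411
```

Frames whose arg-max disagrees with the consensus get the smallest
reliabilities, and the fused decision is class 2.

## Command line

A thin CLI over the same functions lives at `inst/scripts/gaitfuse`:

```sh
Rscript inst/scripts/gaitfuse simulate --subjects 10 --frames 120 --test-frames 60 --seed 1 --out data
Rscript inst/scripts/gaitfuse train    --train-dir data/train --out model.json
Rscript inst/scripts/gaitfuse predict  --model model.json --in data/test/S03.csv --rule rws
Rscript inst/scripts/gaitfuse evaluate --train-dir data/train --test-dir data/test --out curve.csv
```

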