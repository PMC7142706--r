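# herdsample

Can the welfare level of a fattening-pig herd be judged from a sample?
Welfare assessment guides (notably the German KTBL practical guide)
recommend scoring six animal-based indicators — tail lesions, faecal
soiling, skin lesions, ear lesions, lameness, runts — on a sample of the
herd instead of a full census. `herdsample` is a finite-population
simulation framework for quantifying what that shortcut costs: it builds
synthetic herds with a rooms → pens → animals hierarchy and exact indicator
counts, draws replicate samples under five designs, and measures estimator
validity.

It is aimed at veterinary epidemiologists and welfare scientists who want
to evaluate (or redesign) sampling recommendations before taking them into
a barn.

## The model

Each indicator defines a true herd prevalence *p* = *K*/*N* (problematic
animals over herd size). A design yields replicate estimates *p̂ᵢ*, judged
by

- Bias = mean(*p̂*) − *p* and relative bias RB = Bias/*p* ∈ [−1, (1−*p*)/*p*],
- RMSE = √mean((*p̂* − *p*)²),
- NRMSE = RMSE / (max *p̂ᵢ* − min *p̂ᵢ*) — normalized by the *empirical
  range* of the replicate estimates,
- deviation proportions: the fraction of replicates strictly outside
  (1 ± *t*)·*p* for *t* = 10 %, 30 %, 50 %.

The five designs: S1 simple random sample of 167 animals; S2 the same size
allocated to rooms by largest-remainder proportionality; S3 eight whole
pens ignoring rooms; S4 two whole pens per room; S5 the guide's scheme (ten
pens — two per room plus two extras — all animals for runts/faecal
soiling/lameness, at most 15 animals per pen for the three lesion
indicators). Under simple random sampling the affected count is
hypergeometric, so the package also carries an exact oracle
(`exact_rmse()`, `exact_deviation_fraction()`, `extreme_value_cdf()`)
against which the simulator is tested.

The packaged `reference_herd()` reproduces a real 636-pig barn: rooms of
88/174/174/200 animals × 8 pens, with indicator counts (20, 28, 35, 54, 37,
7) back-computed exactly from the published census prevalences. How
affected animals were spread over pens was never published, so pen-level
clustering is an explicit parameter (`clustering = 0` places them
uniformly; larger values concentrate them by a Pólya-urn scheme). See the
vignette `vignettes/sampling-validity.Rmd` for the full account.

## Worked example

```r
library(herdsample)

h <- reference_herd(seed = 1)
round(100 * true_prevalence(h), 1)
#>   tail_lesions faecal_soiling   skin_lesions    ear_lesions       lameness
#>            3.1            4.4            5.5            8.5            5.8
#>          runts
#>            1.1

em <- simulate_strategy(h, strategy_spec("S1_simple", n_animals = 167),
                        n_replicates = 100000, master_seed = 4)
r <- validity_report(em, h)
setNames(r$aggregate$mean, r$aggregate$measure)[c("rb", "nrmse", "dev_total_30")]
#>           rb        nrmse dev_total_30
#>  -0.00049767   0.13504326   0.36873667
```

Read: simple random sampling of 167 of the 636 pigs is essentially
unbiased (indicator-averaged RB ≈ −0.0005, pure Monte-Carlo noise around
the exact value 0) and its accuracy, RMSE over the spread of the 100,000
estimates, averages 0.14 — yet 37 % of samples still miss the true
prevalence of an average indicator by more than 30 % (68 % for the rarest
indicator, runts, at 1.1 % prevalence). Precision, not bias, is what
sampling costs.

A whole study — herd, all five designs, estimate matrices, tidy per-design
reports and a cross-design summary — runs from one config:

```r
cfg <- read_run_config(system.file("extdata", "reference_study.yaml",
                                   package = "herdsample"),
                       output_dir = "results")
run_validity_study(cfg)
```

or from the shell via the thin CLI in `inst/scripts/herdsample`
(subcommands `generate-herd`, `simulate`, `report`, `oracle`,
`reference-study`).

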