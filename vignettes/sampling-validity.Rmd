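---
title: "How valid are sample-based welfare prevalence estimates? The model behind herdsample"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How valid are sample-based welfare prevalence estimates? The model behind herdsample}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdsample)
```

## The problem

Animal welfare assessment guides for fattening pigs (notably the German KTBL
practical guide) recommend scoring several animal-based indicators — tail,
ear and skin lesions, faecal soiling, lameness, runts — on a *sample* of the
herd rather than in a full census. Whether the herd-level welfare judgement
survives that shortcut is a question about finite-population survey
sampling: each indicator defines a true herd prevalence $p = K/N$ (the
proportion of "problematic" animals), and a sampling design yields replicate
estimates $\hat p_i$ whose systematic and random deviation from $p$ can be
quantified by Monte-Carlo simulation.

`herdsample` implements that study design as a reusable framework: a
synthetic-herd generator, the five sampling strategies, a replicate engine,
the validity metrics, and an exact hypergeometric oracle that pins down the
simple-random design analytically.

## The population model

A herd is a three-level hierarchy: rooms (all-in/all-out, so each room is a
single age/weight class), pens within rooms, animals within pens. The
packaged reference herd mirrors a real 636-pig barn: four rooms of 88, 174,
174 and 200 animals, eight pens per room, at most 25 animals per pen.
Individual pen occupancies were never published, so `allocate_pens()` splits
each room as evenly as possible (sizes within a room differ by at most one,
remainders go to the lowest-indexed pens). That deterministic choice
reproduces the published average of 19.9 animals per pen (636/32 = 19.875).

Each indicator's problematic-animal count in the reference herd is
back-computed from the published one-decimal census prevalences; at
$N = 636$ each printed value identifies a *unique* integer count (20, 28,
35, 54, 37, 7), so the fixture's census is exact rather than approximate.

Raw field scores are collapsed to binary by `binarize_scores()`: for the two
three-level indicators, scores 0 and 1 are "normal" and only the top score 2
is "problematic"; two-level indicators pass through.

### Within-pen clustering is a free parameter

How the affected animals were distributed over rooms and pens on the real
farm is unknown — and it is exactly what the pen-based designs are sensitive
to. `generate_herd()` therefore exposes a clustering parameter $c \ge 0$.
At $c = 0$ (the default) affected animals are a uniform random subset of the
herd. At $c > 0$ they are placed sequentially by a Pólya-urn scheme: the
next affected animal joins pen $j$ with probability proportional to
$\text{size}_j + c \cdot \text{affected}_j$, so early placements attract
later ones and the across-pen variance of affected counts grows with $c$
(an empirical invariant in the test suite). Indicators are placed
independently — no co-morbidity model, since no joint distribution was
published.

Consequences worth being explicit about:

* Results that depend only on herd **totals** (everything about the
  simple-random design S1, all sample-size facts, the census prevalences)
  are exactly reproducible and are the package's acceptance surface.
* Results of the pen-based designs S2–S5 depend on the unpublished pen-level
  placement. The package simulates them under any chosen $c$, but their
  published metric values (e.g. the strong lesion-group underestimation of
  the guide's design) cannot be matched number-for-number and are not
  claimed. They are covered instead by structural properties: clustering
  strictly degrades the clustered design's RMSE while leaving the
  simple-random benchmark untouched, and with uniform placement and equal
  pens the clustered design degenerates to near the simple-random accuracy.

## The five designs

| design | selection rule | sample size |
|---|---|---|
| S1 | simple random sample of animals | 167 fixed |
| S2 | animals allocated to rooms proportionally (largest remainder) | 167 fixed |
| S3 | 8 whole pens, rooms ignored | varies, mean 159 |
| S4 | 2 whole pens per room | varies, mean 159 |
| S5 | guide scheme: 10 pens (2 per room + 2 extras), lesion indicators capped at 15 animals/pen | varies |

All draws are without replacement; pens are drawn before animals so a fixed
seed reproduces a draw exactly. The proportional allocation uses
largest-remainder (Hamilton) apportionment because plain rounding of the
room quotas misses the total (it gives 168 for the reference herd where
largest remainder reproduces the published 23/46/46/52).

Two S5 details are underdetermined by the guide's wording and were fixed as
package design choices:

* "two additional pens from two different rooms" is read as: choose 2 of
  the 4 rooms uniformly, then one additional not-yet-chosen pen uniformly
  from each — the simplest reading that keeps at least two pens per room;
* with fewer than ten pens in total, the per-pen lesion quota is raised to
  $\lceil 150 / \text{pens} \rceil$, a generic rendering of the guide's
  "increase the animals per pen" rule (flagged experimental — the reference
  study never exercises it). Herds of at most 150 animals are censused.

S4 deliberately ignores the unequal room sizes (two pens per room
regardless): that disproportionality is a property of the design being
evaluated, not a bug to fix.

## The validity metrics

For replicate estimates $\hat p_1, \dots, \hat p_n$ and true prevalence $p$:

$$\text{Bias} = \tfrac1n \sum_i \hat p_i - p, \qquad
  \text{RB} = \text{Bias}/p \in [-1, (1-p)/p],$$

$$\text{RMSE} = \sqrt{\tfrac1n \sum_i (\hat p_i - p)^2}, \qquad
  \text{NRMSE} = \frac{\text{RMSE}}{\max_i \hat p_i - \min_i \hat p_i}.$$

The NRMSE denominator is the *empirical range* of the replicate estimates —
an unusual normalization (it makes the measure depend on the replicate
count through the extremes), but it is the one this framework is built
around, so it is kept exactly as defined; the conventional
prevalence-normalized variant is available under the separate name
`nrmse_prevalence()` and never silently substituted.

Deviation proportions count replicates falling *strictly* outside
$(1 \pm t)\,p$ for thresholds $t \in \{0.10, 0.30, 0.50\}$ (at $p = 5\%$ and
$t = 10\%$ the band is 4.5 %–5.5 %); boundary hits do not deviate, and a
$10^{-9}$ guard keeps floating-point ties on the correct side. Indicator
averaging is unweighted throughout; since the mean is linear, averaging the
under/over split before or after indicator-averaging gives the same result,
so only one ordering is reported. Reports show prevalences to 0.1
percentage points, NRMSE to two decimals and RB to four, matching the
conventions of the reference study.

Degenerate inputs: relative bias and deviation fractions are undefined at
$p = 0$ (the functions raise errors; `validity_report()` records `NA` so a
herd with an empty indicator still reports), and the NRMSE of a zero-range
(census-like) run is likewise `NA`.

## The exact oracle

Under simple random sampling the affected count in a sample of $n$ from a
herd of $N$ with $K$ affected is hypergeometric, so every metric has an
exact counterpart (`exact_estimate_pmf()`, `exact_rmse()` with the
finite-population correction $\sqrt{p(1-p)/n \cdot (N-n)/(N-1)}$,
`exact_deviation_fraction()` by pmf summation). For the range-normalized
RMSE the denominator is an extreme-value statistic; its exact distribution
follows from $P(\max \le x) = F(x)^{\text{reps}}$ and
$P(\min \ge x) = (1-F(x^-))^{\text{reps}}$ (`extreme_value_cdf()`), and
`expected_nrmse()` divides the exact RMSE by the expected range — a
first-order approximation that is tight at $10^5$ replicates because the
range concentrates. Probabilities come from `stats::dhyper()`, which is
log-gamma based and stable far beyond herd sizes in the hundreds. The test
suite holds the simulator to this oracle within three Monte-Carlo standard
errors.

```{r oracle}
exact_s1_report(reference_herd(), n_animals = 167, n_replicates = 100000)[,
  c("indicator", "true_p", "rmse", "expected_nrmse", "dev_total_50")]
```

## Randomness contract

One master seed drives a run. `simulate_strategy()` uses L'Ecuyer-CMRG
substreams: replicate $r$ always consumes substream $r$ of the master seed,
so extending a run from 10^4 to 10^5 replicates reproduces the first 10^4
draws bit-for-bit, and the caller's RNG state is never touched. Herd
generation uses its own seed in the configuration. `run_validity_study()`
gives strategy $k$ the seed `master_seed + k - 1` and logs every derived
seed and the herd digest.

## Problem sizes

The reference study size — 100,000 replicates per strategy on the 636-animal
herd — runs in a few seconds per strategy in pure R (the per-replicate work
is two or three vectorized `sample` calls and a 6-column count). The unit
tests use 5,000–20,000 replicates with tolerances widened as
$1/\sqrt{\text{reps}}$; the study-scale checks in the acceptance tests use
the full 100,000.

```{r study, eval = FALSE}
cfg <- read_run_config(system.file("extdata", "reference_study.yaml",
                                   package = "herdsample"),
                       output_dir = "results")
run_validity_study(cfg)
```

## What passing tests do and do not show

The generator emulates the hierarchy, the exact census counts, and a
*tunable* within-pen aggregation. It does not model room-level prevalence
differences (the real barn likely had elevated skin lesions in its
newly-stocked room; `herd_config()` accepts arbitrary room sizes and counts
but no room-specific rates by default), assessor observation error,
co-morbidity between indicators, or fattening-day dynamics. Passing tests
therefore demonstrate that the *designs and metrics* behave correctly on
populations with known structure — not that any particular real herd is
well characterized by a 167-animal sample. The package's own headline
result, matching the reference study, is that even the best design leaves a
large fraction of samples more than 30 % away from the true prevalence of
rare indicators; the framework exists so that conclusion can be re-examined
under other herd structures.
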