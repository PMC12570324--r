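---
title: "NRFE: control-independent plate quality control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NRFE: control-independent plate quality control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htsqc)
```

## Why control wells are not enough

Multi-dose screening plates devote a handful of edge columns to
negative (vehicle) and positive (full-kill) controls and judge plate
quality from their separation: Z′, robust Z′, SSMD and the
signal-to-background ratio. These statistics answer one question — *was
the assay window intact in the control columns?* — and are silent about
the compound wells where the actual measurements happen. A dispenser
with failing alternate tips, an evaporation ring, or a thermal gradient
can shift compound responses by tens of percentage points without
touching a single control well.

## The NRFE metric

Each compound on a plate contributes a dose series
$(x_{ij}, y_{ij})_{j=1..n_i}$ of concentrations and percent-inhibition
responses. `htsqc` fits the four-parameter log-logistic model

$$f(x) = d + \frac{a - d}{1 + (x/c)^b}, \qquad b > 0,$$

to every series and forms absolute residuals
$\varepsilon_{ij} = |y_{ij} - f(x_{ij})|$. Residuals are weighted by a
binomial-variance scaling factor

$$k_{ij} = 1 + \frac{p(1-p)}{0.25}, \qquad p = f(x_{ij})/100
\text{ clamped to } [0,1],$$

which doubles the weight of deviations near 50 % inhibition — where the
curve carries the most information — and leaves the asymptotes at unit
weight. The plate score averages over the $N$ fitted series:

$$\mathrm{NRFE} = \frac{1}{N} \sum_{i=1}^{N} \frac{1}{n_i}
\sum_{j=1}^{n_i} \varepsilon_{ij}\, k_{ij}.$$

Plates are tiered at NRFE $< 10$ (acceptable), $10$–$15$ (borderline)
and $> 15$ (poor). The cutoffs follow a mean-plus-three-standard-
deviations rule over large screening batches, available as
`deriveThreshold()` for recalibration on a new batch.

The key property is what NRFE responds to. I.i.d. well noise of
$\sigma = 5$ inflates it only to $\approx 4$–$6$, because an LL4 curve
tracks the series through the noise. A *systematic spatial* artifact
shifts specific doses of specific series and cannot be absorbed by any
single monotone curve, so residuals — and NRFE — grow several-fold.

## Fitting details

`fitLL4()` runs bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) on $(a, d, \log_{10} b, \log_{10} c)$ in
log-concentration space with a deterministic initialisation, so fits
are exactly reproducible. Degenerate inputs never throw during plate
scoring: a series with response span below 10 points takes a flat
fallback, a fitted $c$ pinned to its box edge triggers a constrained
re-fit, and series with at most three distinct doses free at most as
many parameters as they have points and are flagged low-confidence.

```{r fit}
sim <- simulatePlate(plateSimConfig(geometry = 96, seed = 42))
s <- extractDoseSeries(sim$plate)[["C004"]]
fit <- fitLL4(s)
fit
computeResponseMetrics(fit, s)[c("ic50", "ic50Reached", "auc", "dss")]
```

## Control blindness, demonstrated

Stripe five compound-only columns; the controls (columns 1 and 12)
never see the artifact:

```{r blindness}
clean <- plateQC(sim$plate)
striped <- injectArtifact(
  sim$plate,
  artifactSpec("column_striping", 40, columns = c(3, 5, 7, 9, 11))
)
degraded <- plateQC(striped)
c(nrfe_clean = nrfe(clean), nrfe_striped = nrfe(degraded))
c(z_clean = as.numeric(controlMetrics(clean)$z_prime),
  z_striped = as.numeric(controlMetrics(degraded)$z_prime))
```

NRFE inflates several-fold and crosses into the poor tier; Z′ is
bit-identical. The residual heatmap localises the damage:

```{r heatmap, fig.width = 6, fig.height = 4}
renderPlateHeatmap(striped, mode = "residual")
```

## Why plate quality matters downstream

`simulateReplicateBatch()` generates pairs of plates measuring the same
compounds (shared ground-truth curves, independent noise), degrading
one side of some pairs with a row-graded striping artifact until the
plate lands in a target NRFE tier. Replicate agreement then stratifies
cleanly by tier:

```{r replicates}
b <- simulateReplicateBatch(plateSimConfig(geometry = 96),
                            nPairs = 25, seed = 11)
pairs <- pairReplicates(b$results)
td <- tierStratifiedDeltas(pairs)
td$summary[, c("tier", "n", "medianAbsDAuc")]
td$tests
```

And filtering on joint quality thresholds (Z′ $> 0.5$ and NRFE $< 10$
on both sides, versus Z′ $< 0$ or NRFE $> 15$ on either) moves the
between-replicate Spearman correlation in the expected direction:

```{r consistency}
b2 <- simulateReplicateBatch(
  plateSimConfig(geometry = 96), nPairs = 30,
  tierMix = c(acceptable = 0.55, borderline = 0.2, poor = 0.25),
  seed = 71
)
rep_ <- consistencyReport(pairReplicates(b2$results), nBoot = 500, seed = 5)
c(good = rep_$rhoGood, all = rep_$spearmanRho, poor = rep_$rhoPoor)
```

`bootstrapReference()` and `compareToReference()` supply the reference
distribution and KS / standardized-mean-difference machinery for
judging whether a quality stratum's consistency differs from the
baseline.

## Batch usage

`qcRun()` processes a list of plates or a `plateFileSpec()` pointing at
a long-format CSV, writes `qc_table.csv`, `qc_report.json` and residual
heatmaps for flagged plates, and reports an exit status (0 / 3 / 4 for
acceptable / borderline / poor-or-failed) that the bundled
`inst/scripts/htsqc` CLI forwards to the shell.
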