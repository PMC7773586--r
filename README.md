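# cytokinetics

Event-aligned, quantitative analysis of protein accumulation kinetics at
the yeast division site, for cell biologists doing time-lapse
fluorescence microscopy of cytokinesis (and for anyone who needs a fully
ground-truthed synthetic benchmark for such pipelines).

During cytokinesis, functional modules — the actomyosin ring (AMR),
vesicle transport, primary/secondary septum (PS/SS) synthesis, septum
maturation, and the MEN/RAM timing pathways — accumulate at the bud neck
in a strict order. Because cells divide asynchronously, single-cell
intensity traces only become comparable after re-timing every cell to
the breakage of the anaphase spindle (t = 0). On that clock:

* a protein's **kinetic signature** is the peak time (and shape) of its
  mean ± SD accumulation curve, x̄(t) ± s(t) on a 1-min grid; proteins of
  one module share a signature, so Pearson correlation of mean curves
  over a common window ranks candidate proteins into modules;
* the AMR diameter follows a **biphasic constriction** model — constant
  d₀, a slow linear phase (rate r_slow), then a fast one (r_fast), i.e.
  a continuous two-segment linear decline with a breakpoint t_b fitted
  by exact least squares over grid candidates with slopes ≤ 0;
* drug/deletion effects are summarized as the peak ratio, peak-time
  shift, rising-rate ratio (max 5-min sliding-window slope) and AUC
  ratio versus control.

The package provides all stages: a ground-truth synthetic generator
(per-cell traces, constriction traces, rendered multi-channel movies
with Gaussian-PSF puncta, an elongating/breaking spindle, and
Poisson + read noise), ROI quantification with background subtraction,
ring-diameter estimation by two-punctum profile fitting,
spindle-breakage detection, clock alignment and aggregation, signature
extraction, biphasic fitting, condition comparison, and similarity
ranking / module assignment.

## Worked example

```r
library(cytokinetics)

panel <- loadSignaturePanel()          # packaged 25-protein panel
sim   <- simulatePanel(panel, proteins = c("Myo1", "Hof1", "Chs2",
                                           "Inn1", "Kre6", "Crh1"),
                       seed = 1)       # 30 cells per protein
mks   <- lapply(sim$traces, function(trs)
  aggregateTraces(lapply(trs, alignTrace)))

extractSignature(mks$Hof1)
#> KineticSignature Hof1 ( control )
#>   peaks at -5, -1, 6 min; arrival -6.81 ; departure 8.92 min
```

The F-BAR scaffold's three bursts (septin-hourglass remodeling, AMR
peak, SS-timing peak) are recovered at −5, −1 and +6 min, with arrival
and departure read off the 15%-of-peak threshold crossings.

```r
ens   <- simulateConstrictionEnsemble(30, defaultConstrictionParams(),
                                      seed = 1)
onset <- estimateConstrictionOnset(ens$traces)   # -6 min, from the mean curve
fits  <- Filter(Negate(is.null), lapply(ens$traces, function(tr)
  tryCatch(fitBiphasic(tr, onset = onset), error = function(e) NULL)))
sm <- summarizeConstriction(fits)
sm$stats
#>      quantity    mean     sd
#> 1    slowRate  0.0278 0.0481
#> 2    fastRate  0.1733 0.0519
#> 3    slowDrop  0.1136 0.0890
#> 4    fastDrop  0.9241 0.1382
#> 5 percentFast 89.1820 8.4373
```

Fast-phase rate (0.17 µm/min vs the 0.18 configured in the generator)
and the fast phase's ~90% share of the total diameter decrease are
recovered; the mean slow rate reads high (0.028 vs 0.02) because slow
phases shorter than the 1-min frame interval cannot be resolved per
cell — a documented resolution limit, discussed in the methods
vignette (`vignettes/kinetic-landscape.Rmd`).

```r
rankSimilarity(correlationMatrix(mks), "Kre6")
#>   rank protein           r peak_dt
#> 5    1    Crh1  0.94099616     Inf
#> 4    2    Inn1  0.09515844     Inf
#> 3    3    Chs2  0.08764534     Inf
#> 2    4    Hof1  0.01283007     Inf
#> 1    5    Myo1 -0.55796510     Inf
```

(`peak_dt`, the peak-time tie-break distance, is only finite when
signatures are passed to `rankSimilarity()`.)

The glucan-synthesis candidate Kre6 correlates almost exclusively with
the cell-wall maturation transglycosylase Crh1 — the signature-based
module prediction this analysis is built around.

End-to-end runs (`simulateExperiment()` → `runLandscape()`) write mean
kinetics, signature, fit and similarity tables, a summary JSON and a
landscape figure; `inst/scripts/cytokinetics-cli.R` wraps both stages
for shell use.

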