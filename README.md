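# actmap

Brain-wide IEG activation mapping and fiber-photometry response analysis.

`actmap` is for labs that (a) count immediate-early-gene (IEG)
reporter-positive cells across parcellated brain regions to ask *which
region distinguishes one treatment from another*, and (b) record
fiber-photometry calcium signals during social behaviour to ask *how that
region responds to contact*. It packages the two bespoke analyses those
questions need, plus seeded synthetic-data generators so the whole chain is
testable without any raw recordings.

## What it computes

**Count side.** Per-animal counts in M regions are z-scored per region over
the full cohort, a soft-margin linear SVM separates two treatment groups,
and the weight vector W is transformed into the forward-model activation
pattern

    A = Σx · W · Σŝ⁻¹ ,   Σŝ = Wᵀ Σx W ,

where Σx is the data covariance of the animals in that comparison and Σŝ the
(scalar, K = 1) variance of the decision value. Unlike W, A is interpretable
region by region; the region with the largest |A| is nominated as the
discriminator. Insular-cortex cells are also histogrammed along the
anteroposterior axis (10 × 0.35 mm bins over +2.50 to −1.00 mm from bregma;
the anterior subdivision is exactly (+1.45, +2.50]).

**Photometry side.** 100 Hz fluorescence traces are baseline-corrected with
airPLS (adaptive iteratively reweighted penalized least squares), z-scored
to a 5 min home-cage baseline segment, investigation bouts are filtered to
nonsequential events (onset ≥ 10 s after the previous bout's end), and each
contact's evoked response is Δz = mean z[0, 3 s) − mean z[−3 s, 0). Sessions
are summarized by a paired t test (mouse vs object contact across animals)
and a Spearman correlation between Δz and contact duration.

## Worked example

```r
library(actmap)

# --- counts: plant a 2-SD effect in the IC for the R-ket group ------------
sim <- simCellCounts(countSimConfig(effectSize = 2, effectRegions = "IC",
                                    seed = 2))
res <- classifyAndMap(sim$table)     # R-ket vs saline, R-ket vs S-ket
res$nominated
#> R-ket_vs_saline  R-ket_vs_S-ket
#>            "IC"            "IC"
head(res$comparisons[["R-ket_vs_saline"]]$ranking, 3)
#>   rank region activation absActivation nominated
#> 1    1     IC  0.8384944     0.8384944      TRUE
#> 2    2     PL  0.6774232     0.6774232     FALSE
#> 3    3     HY  0.6264477     0.6264477     FALSE
```

The planted region tops both rankings here. Note the honest caveat: at the
default scale (5 animals/group, 22 regions, 2 SD effect) top-1 nomination
succeeds in roughly half of replicates — the full ranking and |A| values are
the robust output, and the null rate for any fixed region stays at chance.

```r
# --- photometry: transients planted on mouse (2 z) and object (0.5 z) -----
ses  <- simPhotometrySession(photoSimConfig(seed = 2))
fit  <- airplsBaseline(ses$trace@signal, lambda = 1e10)
zt   <- correctAndZscore(ses$trace, fit)
resp <- evokedResponses(zt, selectNonsequentialEvents(ses$events))
resp
#> EvokedResponseSet: 20 events (+0 skipped), window +/- 3 s
#>   mean dz by label: mouse=0.932, object=0.257
```

The recovered means match the planted ground truth (amplitude × kernel
window mean = 0.935 and 0.234 for the two labels): the airPLS baseline
removed the drift without absorbing the transients.

One call runs everything — simulate, classify, map, bin, preprocess,
quantify — and writes a deterministic report bundle (CSV/TSV/JSON plus a
provenance block):

```r
runPipeline(pipelineConfig(seed = 1), "out/")
```

A thin command-line wrapper with subcommands
`run | simulate | iegmap | apdist | photom` lives at
`inst/scripts/actmap.R`.

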