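# TraceN15

Quantitative analysis of **15N leaf-disc tracer experiments** and the
accompanying **qPCR expression analysis**, as used to study nitrogen
remobilization and proline metabolism in *Brassica napus* source
leaves. Leaf discs float on a 15N tracer (15NH4Cl or [15N]proline) for
a few hours; LC-MS isotopologue intensities and amino-acid contents
become *net 15N allocation* — a proxy for net biosynthetic flux — while
qPCR tracks the proline pathway genes (*P5CS*, *ProDH*) across leaf
ranks, light/dark transitions, osmotic stress and dark-induced
senescence.

The package is aimed at plant physiologists running such leaf-disc
assays who need a tested, reproducible path from raw intensity and Cq
tables to the published quantities.

## What it computes

**Isotope labelling.** For a compound with *n* nitrogen atoms and
isotopologues M+0..M+xmax, fractional labelling is
`f(x) = [M+x] / Σ [M+y]`. The ~20 % artificial M+1 enrichment added by
AccQTag derivatization is modelled as a one-mass-unit shift of a
fraction *r* of each isotopologue's signal, estimated from 15N-free
external standards and inverted exactly
(`obs(x) = (1−r)·true(x) + r·true(x−1)`). Net labelling subtracts the
T0 (natural abundance) fractions and sums to zero; its first moment
`Σ x·net(x)` is the mean number of labelled N atoms per molecule.

**Quantification.** Peak areas are normalized to the
dl-3-aminobutyric-acid internal standard (111 µM), inverted through
per-compound OLS calibration curves, and converted to µmol g⁻¹ DW.
Net 15N allocation is `content × Σ x·net(x) × 1000` in
nmol 15N g⁻¹ DW per labelling period.

**qPCR.** Primer efficiency `E = 10^(−1/slope)` from dilution series;
relative expression `E_t^(−Cq_t) / geomean_j(E_j^(−Cq_j))` normalized
to two reference genes; GeNorm M stability ranking of reference
candidates; per-gene fold changes between consecutive time points and
`log2(FC_treatment / FC_control)`.

**Statistics.** One-way ANOVA + Tukey HSD with compact letter display
(insert-and-absorb), two-sided equal-variance t-tests, natural-log
transformation of expression values.

**Osmotic design.** Michel & Kaufman's PEG 6000 polynomial
`Ψ(bar) = −1.18e−2·C − 1.18e−4·C² + 2.67e−4·C·T + 8.39e−7·C²·T`
and its inverse for dose design.

**Synthetic data.** Because no raw data are deposited with the study
this package re-implements, a first-class generator produces
isotopologue tables, quantification tables and qPCR plates with the
statistical structure the analysis assumes (binomial MIDs, artifact
convolution, lognormal intensity noise, Gaussian Cq noise, stable
references plus an unstable decoy), with bit-for-bit seed
reproducibility.

## Worked example

```r
library(TraceN15)

pegOsmoticPotential(400, 20)
#> [1] -1.87792        # the -1.88 MPa osmotic-shock dose

sim <- simulateLabellingExperiment(seed = 42)        # study conditions
res <- suppressWarnings(analyseLabellingTable(sim$intensities))
pro <- subset(res$summary, amino_acid == "proline")
round(tapply(pro$mean_labelled_atoms, pro$group, mean)[
  c("L15", "L11", "L7", "L3")], 4)
#>    L15    L11     L7     L3
#> 0.0984 0.0712 0.0159 0.0034
```

The recovered mean labelled atoms per proline molecule reproduce the
configured sink-to-source gradient (0.10 / 0.07 / 0.02 / 0.005 per-atom
enrichment) within the 2 % noise at n = 3. Combining with contents
gives the allocation profile — ~200 nmol 15N g⁻¹ DW in the young L15
leaf collapsing to near zero in strong source leaves:

```r
cfg <- simulationConfig()
round(net15NAllocation(cfg$contents$proline,
  tapply(pro$mean_labelled_atoms, pro$group, mean)[cfg$leafRanks]), 1)
#>   L15   L11    L7    L3
#> 196.7  76.2   9.5   1.0

plate <- simulateQPCRPlate(seed = 42)
analyseQPCRExperiment(plate$cq, plate$dilution)$foldChanges
#>           gene fcTreatment fcControl log2FcRatio
#> 1   BnaA.P5CS1   0.2554681 0.9974024   -1.965032
#> 2 BnaC.ProDH1b 128.9362896 1.0539258    6.934741
#> 3     BnaDecoy   1.3802244 0.2569292    2.425460
```

The qPCR chain recovers the configured log2 FC ratios (−2 and +7; the
decoy row is a deliberately unstable gene that GeNorm ranks last).
`runPipeline(config, outDir, seed)` chains simulate → labelling →
quantification → qPCR → statistics and writes CSVs plus a JSON run
manifest; `inst/scripts/tracen15` wraps it for the shell.

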