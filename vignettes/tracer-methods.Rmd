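---
title: "Methods: 15N leaf-disc tracing, qPCR expression and the synthetic experiment"
author: "TraceN15"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 15N leaf-disc tracing, qPCR expression and the synthetic experiment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TraceN15)
```

TraceN15 implements the quantitative layer of a leaf-disc tracer study
of nitrogen remobilization: leaf discs from leaves of different
sink/source status float for a few hours on a buffer containing a 15N
tracer (15NH4Cl or [15N]proline), and the incorporation of the heavy
nitrogen into free amino acids — glutamine, glutamate, proline — is read
out by LC-MS as mass isotopologue distributions (MIDs). Combined with
absolute amino-acid quantification, the labelling becomes a net 15N
allocation, a proxy for net biosynthetic flux. In parallel, qPCR
measures the transcriptional response of the proline pathway genes
(P5CS biosynthesis, ProDH catabolism). This vignette documents the
models, the parameters that matter, the synthetic-data generator, and
the numerical choices.

## Isotope labelling

### The measurement and its artifact

For an amino acid with $n$ nitrogen atoms, the instrument records
intensities of the isotopologues $M{+}0 \dots M{+}x_{\max}$ (default
$x_{\max} = 4$, configurable per compound). The *fractional labelling*
of isotopologue $x$ is its share of the compound total:

$$f(x) = \frac{[M{+}x]}{\sum_{y} [M{+}y]}.$$

AccQTag amine derivatization introduces an artificial M+1 signal of
roughly 20 % for every amino acid. We model the artifact as a
one-mass-unit shift convolution: a fraction $r$ of each isotopologue's
signal appears one mass unit higher,

$$\mathrm{obs}(x) = (1-r)\,\mathrm{true}(x) + r\,\mathrm{true}(x-1),$$

and invert it exactly by the recursion
$\mathrm{true}(0) = \mathrm{obs}(0)/(1-r)$,
$\mathrm{true}(x) = (\mathrm{obs}(x) - r\,\mathrm{true}(x-1))/(1-r)$.
When only M+0/M+1 carry signal this reduces to subtracting the
standard's M+1 share, which is the only behaviour the original
description pins down; the convolution form extends it consistently to
higher isotopologues and is exactly invertible. A plain
`subtract_standard` mode is kept behind a switch for sensitivity
checks. The choice between the two is the main genuinely open design
point in this module; we default to the shift deconvolution because it
is self-consistent across isotopologues and reduces to the simple
subtraction in the two-isotopologue case.

$r$ is estimated per analytical batch as the mean M+1 fraction of
15N-free external standards in excess of a configurable baseline
(`estimateM1Artifact()`). The default baseline is zero: commercial
"unlabelled" standards still carry natural 15N (abundance
$p_0 = 0.003663$ per N atom), so the zero baseline folds that ~0.4 %
into $r$; the bias this causes cancels almost entirely in the T0
subtraction below, and a theoretical binomial baseline is available for
users who prefer the decomposition. Correction is applied per sample
with the batch $r$ — per-sample standards are rarely available.
Negative corrected intensities (noise at essentially empty
isotopologues) are clipped to zero with a warning reporting the clipped
magnitude, then fractions are renormalized.

### Net labelling and allocation

*Net labelling* subtracts the fractional labelling of the matched T0
samples (natural abundance at the start of the experiment):
$\mathrm{net}(x) = f_{\mathrm{sample}}(x) - f_{T0}(x)$. It sums to zero
by construction, M+0 is typically depleted, and values are never
clipped. The *mean labelled atom count* is its first moment,
$\sum_x x\,\mathrm{net}(x)$ atoms per molecule, and *net 15N
allocation* multiplies it by the compound content:

$$A = \mathrm{content}\;(\mu\mathrm{mol\,g^{-1}\,DW}) \times
      \textstyle\sum_x x\,\mathrm{net}(x) \times 1000
      \quad (\mathrm{nmol\ ^{15}N\ g^{-1}\,DW})$$

per labelling period (4 h in the emulated design; conversion to hourly
rates is left to the report layer). Protein-bound 15N is ignored — in
the emulated experiments it was below detection.

Fractions are used internally throughout; percentages appear only at
report boundaries.

## Quantification

Contents come from UV peak areas through internal-standard
normalization and external calibration. The analyte area is scaled by
(expected internal-standard response / observed IS area) — the IS is
dl-3-aminobutyric acid spiked at 111 µM into the 0.9 mL MeOH/H2O
fraction — then inverted through the per-compound ordinary
least-squares calibration line and converted with the extract volume
and the dry weight. The exact volume bookkeeping from the 0.9 mL
fraction through evaporation and resuspension is not fully specified by
the protocol; the effective extract volume is therefore a parameter
(`extractVolumeMl`, default 0.9). Areas below the lowest standard warn
about extrapolation instead of erroring, because small leaf-disc pools
legitimately fall below the calibrated range.

## qPCR expression

Primer efficiency $E$ comes from a serial dilution: the OLS slope of Cq
against $\log_{10}$ input gives $E = 10^{-1/\mathrm{slope}}$ (perfect
doubling: slope $-3.32$, $E = 2$). Relative expression normalizes the
efficiency-corrected target signal to the geometric mean of the
reference genes:

$$\mathrm{RE} = \frac{E_t^{-Cq_t}}
  {\left(\prod_j E_j^{-Cq_j}\right)^{1/m}},$$

computed in log space. Measured efficiencies are used for reference
genes as well as targets (the alternative of fixing reference $E = 2$
is not taken). Technical replicates are averaged before RE computation;
undetected targets are carried as missing, never as Cq = 40 or zero.

Reference-gene stability uses the GeNorm measure: for candidate $j$,
$M_j$ is the mean over other candidates $k$ of the standard deviation
across samples of $\log_2(a_j/a_k)$; lower is more stable, and the
iterative variant (`geNormRank()`) repeatedly discards the least stable
candidate until the best pair remains. At least three candidates are
required, per the GeNorm convention.

Treatment effects are summarized per gene as fold changes between
consecutive time points within each arm,
$FC = \mathrm{RE}_{t1}/\mathrm{RE}_{t0}$, and the cross-arm ratio
$\log_2(FC_{\mathrm{treatment}}/FC_{\mathrm{control}})$.

## Group statistics

Leaf-rank comparisons use one-way ANOVA followed by Tukey's HSD, with
the pairwise outcome at $\alpha = 0.05$ (configurable) rendered as a
compact letter display by the insert-and-absorb algorithm: groups
sharing a letter are not significantly different. The display is
guaranteed consistent with the pairwise matrix in both directions, and
the test suite cross-checks it against multcomp's display. Two-condition
comparisons use the two-sided pooled-variance Student t-test; for two
groups $t^2 = F$, which the suite asserts. Relative expression values
are log-transformed before testing (natural log; the base does not
affect decisions). Zero pooled variance returns $p = 1$ when means are
equal, and $p = 0$ flagged degenerate otherwise.

## PEG osmotic design

The osmotic shock dose uses Michel & Kaufman's empirical polynomial for
PEG 6000, evaluated in bars and reported in MPa:

$$\Psi(\mathrm{bar}) = -1.18\times10^{-2} C - 1.18\times10^{-4} C^2
 + 2.67\times10^{-4} C T + 8.39\times10^{-7} C^2 T$$

with $C$ in g PEG per kg water and $T$ in °C. The protocol's 400 g/kg
dose gives $-1.88$ MPa at $T = 20$ °C; the incubation temperature is
not stated in the protocol, and 20 °C — a standard growth-chamber
temperature that reproduces the printed dose — is the default,
configurable. The inverse design (`pegConcentrationForPotential()`)
bisects the polynomial on $C \in [0, 800]$ g/kg to $10^{-6}$ g/kg.
Outside the validity envelope ($C \le 800$, $5 \le T \le 35$) the
value is still computed, with a warning.

## The synthetic experiment

No raw LC-MS or qPCR data are deposited with the study the package
re-implements, so the generator *is* the data source for testing, and
its defaults are the study conditions, fixed once:

* leaf ranks L15/L11/L7/L3 (sink to source-to-senescent);
* proline per-atom 15N incorporation 0.10 / 0.07 / 0.02 / 0.005 across
  ranks — the reported gradient; glutamate 0.54 (reported 48–60 %,
  rank-independent); glutamine 0.68 per atom;
* derivatization artifact $r = 0.20$; natural abundance
  $p_0 = 0.003663$; multiplicative intensity noise CV 2 %; $n = 3$
  biological replicates;
* proline contents 2.0 / 1.07 / 0.6 / 0.3 µmol g$^{-1}$ DW, chosen so
  content × net labelling reproduces the reported allocation
  magnitudes (≈200 nmol 15N g$^{-1}$ DW in L15, ≈75 in L11, near zero
  in L7/L3); glutamate and glutamine contents flat at typical leaf
  pools (10 and 15 µmol g$^{-1}$ DW);
* qPCR: two stable reference genes at $E = 2$, a deliberately unstable
  decoy candidate (SD 1 on log2 expression) for GeNorm testing, and
  target genes with configured $\log_2(FC_t/FC_c)$ of +7 (the strong
  stress induction scale) and −2; Cq noise SD 0.2 cycles, two technical
  replicates, dilution series over 3 decades.

Each molecule's nitrogen positions are labelled independently with the
configured probability, so MIDs are binomial; at T0 and in standards
the probability is $p_0$. The tracer's 99 % purity is folded into the
realized per-atom probability rather than modelled separately. The
binomial truth is forward-convolved with the artifact, scaled to
intensities proportional to content, and perturbed with lognormal
multiplicative noise (Gaussian on Cq) — the simplest models consistent
with an SD-bar presentation of real data. A fixed seed makes every
table bit-for-bit reproducible.

One deliberate tension: the reported glutamine labelling (M+1 30–35 %,
M+2 50–55 %) is not jointly reachable by any independent per-atom
probability (two-site binomial with $p = 0.68$ gives M+2 ≈ 46 %,
M+1 ≈ 44 %). Real glutamine labelling is not site-independent — the
amide nitrogen turns over faster than the amino nitrogen. The generator
keeps the binomial model and honours the M+2 magnitude; tests therefore
validate the chain against the generator's own truth, not against the
correlated-site structure of real data.

What passing tests show — and do not show. The suite demonstrates that
the analysis chain is algebraically correct (deconvolution inverts the
forward model to 1e-10), that it recovers known parameters through the
full pipeline under the stated noise, and that its statistics agree
with independent references. It does not validate peak integration,
chromatographic artifacts, carryover, plate-position effects, or the
site-correlation structure just described, none of which the generator
emulates.

## Numerical choices and problem sizes

Fractional vectors must sum to 1 within $10^{-9}$ and net vectors to 0
within $10^{-9}$; the deconvolution round trip is asserted to
$10^{-10}$ on 1000 random MIDs with $r \in [0, 0.5]$. RE is computed in
log2 space. Tie-breaking in the compact letter display orders letters
by decreasing group mean. Parameter-recovery checks run at the study's
own scale ($n = 3$ replicates, 4 ranks, 3 amino acids, 2 qPCR arms × 2
time points), which keeps the whole suite under a minute while leaving
the noise envelopes non-trivial; tolerances are 3-sigma bounds derived
by error propagation from the configured CVs, not fitted numbers.

## Known limitations

* Single-element (15N) correction only; no 13C or multi-element
  correction matrices, and no natural-isotope correction beyond the
  M+1 artifact and T0 subtraction.
* The artifact is assumed mass-independent and strictly one mass unit.
* Calibration is strictly linear; response-factor drift across runs is
  not modelled.
* No melt-curve QC, absolute copy-number quantification, or
  multiple-testing control beyond per-gene tests — matching the scope
  of the emulated analyses.
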