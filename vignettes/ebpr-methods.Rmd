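---
title: "Models and methods behind ebprtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ebprtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebprtools)
```

## The system under study

Enhanced biological phosphorus removal (EBPR) relies on
polyphosphate-accumulating organisms (PAOs, canonically *Candidatus*
Accumulibacter) that cycle carbon and phosphorus across alternating
redox conditions. Anaerobically, PAOs hydrolyse stored polyphosphate to
take up volatile fatty acids — mostly acetate (HAc) — and store them as
poly-β-hydroxyalkanoates (PHA, measured as its PHB and PHV fractions),
drawing reducing equivalents from glycogen glycolysis, from anaerobic
operation of the TCA cycle, or both. Aerobically the PHA is burned to
take up phosphate (net P removal) and rebuild glycogen.
Glycogen-accumulating organisms (GAOs, e.g. *Candidatus* Competibacter,
*Defluviicoccus*) run the same carbon cycle without polyphosphate and
therefore compete without removing P.

`ebprtools` implements the quantitative toolkit such a study needs:

1. **Stoichiometry** — transformation ratios from batch-test time
   series, summarised per operating epoch.
2. **Metabolic models** — canonical PAO/GAO model predictions and a
   glycolysis + full-TCA flux-balance fit with jackknife errors.
3. **Community change-point statistics** — step-change tests on OTU
   time series with Storey–Tibshirani FDR control and simulation-based
   error-rate characterisation.
4. **In-silico FISH** — IUPAC-aware exact probe matching in shotgun
   reads, normalised to a universal probe.
5. **Synthetic data generators** that plant known structure for every
   stage, so the whole pipeline is testable without any external data.

## Transformation ratios

A batch cycle is a time series of acetate and orthophosphate in the
liquor (C-/P-mmol/L) and PHB, PHV and glycogen in the biomass (C-mmol
per g VSS), with a phase label. Deltas are taken between the first and
last sample of each phase — endpoint differencing is the standard
convention for EBPR batch tests, where single per-cycle ratios are
reported — and liquid analytes are divided by VSS so every delta shares
the per-biomass basis. The anaerobic ratios are then

P released / HAc taken up, Gly consumed / HAc, PHB formed / HAc, PHV
formed / HAc, and their sum PHA/HAc; the aerobic ratios are P taken up /
PHA consumed and Gly replenished / PHA consumed.

Conventions worth stating:

* The anaerobic endpoint is the last anaerobic sample, whether or not
  acetate is fully depleted; ratios always use the measured acetate
  delta.
* Missing analytes yield missing ratios, never zeros. In the bundled
  campaign (`ebpr_cycle_ratios()`) one aerobic glycogen measurement is
  missing and the corresponding Gly/PHA is `NA`; epoch summaries skip
  it.
* Duplicate reactors are carried through `replicate_id` and averaged at
  the ratio level (one ratio per reactor, then the mean), which
  preserves per-reactor spread for resampling-based errors.
* Ratios are dimensionless in C- or P-mol per C-mol, so they are
  invariant under any common rescaling of the concentration units — a
  property the test suite checks.
* Epoch summaries report the arithmetic mean and the sample (n−1)
  standard deviation at full precision; rounding happens only at report
  time.

## The flux-balance model

The canonical anaerobic models make fixed predictions
(`model_predictions()`): the full-TCA PAO model, the glycolysis-only
PAO model, the combined glycolysis + full-TCA model, the split-TCA
model and the GAO model, plus the parametric glyoxylate-pathway model
(`predict_yagci()`) whose ratios are closed-form in the acetate
transport energy α and the glyoxylate fraction f:

* P/HAc = α + ½(1 − 1/(2+f))
* Gly/HAc = 1/(2+f)
* PHB/HAc = 8/(6+3f)
* PHV/HAc = 2.5/(6+3f)

`fit_pereira()` goes further and estimates, from observed ratios, how a
PAO community splits its reducing-power generation between glycolysis
and the full TCA cycle. Per C-mol of acetate taken up, with glycogen
flux g and TCA fraction f:

* **Carbon**: acetate (1) plus glycogen (g) ends up as PHB + PHV + CO2.
  Glycogen is glycolysed to pyruvate; pyruvate either loses 1/3 of its
  carbon as CO2 on the way to acetyl-CoA, or is carried to propionyl-CoA
  (carbon-conserving) for PHV synthesis. A fraction f of the acetyl-CoA
  pool is fully oxidised to CO2 in the TCA cycle; the rest condenses
  into PHB (pure acetyl) and the acetyl 2/5 of PHV.
* **Reducing equivalents**: glycolysis and pyruvate decarboxylation
  produce NADH in proportion to their carbon fluxes; TCA oxidation
  produces `nadh_tca` NADH-equivalents per C-mol oxidised; PHB and PHV
  synthesis and the propionyl route consume NADH. The propionyl flux is
  the free electron sink that closes this balance, which is why PHV
  appears exactly when reducing power is in surplus.
* **ATP**: polyphosphate hydrolysis (the P/HAc ratio) makes up the
  difference between the cost of acetate uptake/activation and the ATP
  from glycolysis and TCA substrate-level phosphorylation.

Given (f, g) the three balances determine every other flux, hence a
predicted ratio vector; the fit minimises the weighted squared
discrepancy to the four observed anaerobic ratios over f ∈ [0, 1] and
g ≥ 0, using five fixed starting points and an L-BFGS-B polish
(objective tolerance near machine precision), so the result is
deterministic. The reported reducing-power share is TCA-derived NADH
over total NADH produced; it is identically zero when f = 0. Feasibility
is enforced: if no non-negative flux solution exists the fit aborts and
names the violated balance.

Two cross-checks anchor the implementation. With zero TCA flux and the
glycogen level that balances NADH without any propionyl flux, the
equations collapse to the glycolysis-only model exactly (PHB/HAc = 4/3,
PHV = 0) — the classical result. And fitting ratios generated by the
model itself recovers the generating f to 10⁻⁶ with residual below
10⁻¹⁰ across the whole f range, which the test suite asserts.

### Coefficients and calibration

The coefficient table (`balance_coefficients()`) is data, not code.
The carbon-side entries are fixed chemistry (2/3 of glycogen carbon
reaches acetyl-CoA; PHV is 3/5 propionyl + 2/5 acetyl carbon). The
NADH and ATP yields are less settled in the literature: published PAO
models differ in whether FADH2 counts at par with NADH, in the cost
assigned to the succinate–propionate route, and in the pH-dependent
acetate transport energy. The package therefore ships a default table
calibrated once against the bundled full-scale campaign — chosen so
that the epoch-mean fits reproduce the flux partition obtained by the
original spreadsheet-solver analysis of that campaign (9%/11% of
acetyl-CoA through the TCA cycle, 36%/53% of reducing power) — and
every entry, as well as the objective weights, is a plain argument the
user can override. The glycolysis yields (1/3 NADH, 1/2 ATP per C-mol
glycogen), the PHB demand (1/4 NADH per C-mol) and the pyruvate
decarboxylation yield (1/3 NADH per C-mol) are textbook values and are
left untouched by the calibration, which keeps the glycolysis-only
collapse exact.

### Jackknife errors

Uncertainty on fitted parameters uses leave-one-cycle-out jackknife
resampling (`jackknife_se()`, `fit_pereira_epochs()`): drop one cycle,
recompute the epoch mean, refit, and convert the spread of leave-one-out
estimates to a standard error. For the mean this reduces to the
classical s/√n, which the tests verify, alongside a brute-force
enumeration check for a non-smooth estimator.

## Community change-point statistics

The 16S pipeline follows the usual compositional bookkeeping: a single
random subsample to even depth per sample (one recorded draw, seeded —
not an average over draws, so a run is reproducible from its
configuration), log10(x+1) normalisation, and relative-abundance
aggregation over OTUs sharing an annotation (exact match on the rank
value; unclassified ranks never match a named query).

Only OTUs detected at every sampling event enter testing; rarer OTUs
produce runs of zeros whose step statistics are dominated by detection
artefacts rather than abundance change.

The step-change statistic at a designed split (n1, n2) — here 4
high-aeration and 6 low-aeration samples — is realised as the
two-segment one-way ANOVA F with (1, n−2) degrees of freedom on the
log-normalised series, with p from the upper F tail. The change point
is fixed by the experiment (the aeration setpoint change), not
searched, so no selection correction is needed; multi-change-point
detection is out of scope. The reported difference is the second-epoch
mean minus the first, so taxa that increase after the switch carry
positive differences. Degenerate series (zero within-segment variance
with a nonzero step) are flagged and given the numerical floor rather
than p = 0.

Multiplicity is handled with the Storey–Tibshirani estimator:
π0(λ) = #{p > λ}/(m(1−λ)) smoothed with a natural cubic spline over
λ = 0.05…0.95 and read off at λ = 0.95; below 100 p-values the single
point λ = 0.5 is used instead, since the spline is unstable on sparse
tail counts. q-values are the π0-scaled step-up quantities, monotone in
p; at π0 = 1 they reduce exactly to Benjamini–Hochberg, which the test
suite asserts against `p.adjust`.

Because n = 10 is small, the package characterises the design's error
rates by simulation rather than asymptotics
(`simulate_error_rates()`): Gaussian AR(1) series with a planted mean
shift, rejection rates per (effect, ρ) cell. Under the i.i.d. null the
type-I error sits at the nominal level (checked at 10⁴ replicates
within ±0.01); positive autocorrelation inflates it, which is the
reason the autocorrelation scan exists — a rejection under ρ > 0 cells
warns the analyst how much of the signal a correlated series could
fake. Fold changes between epochs are computed on plain relative
abundances (never the log-normalised values; the pseudo-count exists
only in the log domain), with decreases reported as factors above one
and a flagged undefined result when the baseline epoch mean is zero.

## In-silico FISH

Probe and primer sets are IUPAC nucleotide sequences; reads are
concrete A/C/G/T (with N). A read is a hit for a probe when the probe
or its reverse complement occurs as a contiguous exact substring under
IUPAC compatibility — degenerate probe positions expand, but an N in a
read matches nothing, so low-quality positions cannot create hits.
Matching is delegated to Biostrings with `fixed = "subject"`, which
implements precisely these semantics. Counts are distinct reads (a read
matching one probe twice counts once; a read matching two probes counts
for both), probe mixes count distinct reads matching any member, and
every count is normalised to the universal aggregate (e.g. the EUB338
mix) per sample. Zero universal hits flag the sample undefined rather
than silently producing zeros, and non-detection of a probe is an
explicit zero row. A ≤ k-mismatch mode exists as a sensitivity tool but
is off by default; the standard analysis is exact matching. The
normalised ratio is a relative-abundance proxy only — 16S copy-number
differences are not corrected.

## Synthetic data: what it does and does not emulate

* `sim_batch_timeseries()` plants chosen transformation ratios in
  piecewise-linear phase profiles with additive Gaussian noise scaled
  to each analyte's dynamic range. Ratios are endpoint-determined, so
  the within-phase shape is immaterial to them; the generator makes no
  attempt at Monod-style kinetics, and rate estimation is accordingly
  out of scope. Defaults (acetate dose 1.25 C-mmol/L ≈ 15 mg C/L, VSS
  2.5 g/L, 7 points per 3-h phase, 2% noise) reflect typical lab-scale
  batch tests on full-scale sludge.
* `sim_otu_counts()` draws log10-normal baselines, applies a
  multiplicative step after sample n1, optionally adds AR(1) dependence
  on the log scale, and samples reads multinomially at fixed depth —
  matching both the compositional counting and the autocorrelation
  concern the error-rate simulations probe. It does not emulate
  phylogenetic correlation between OTUs or overdispersion beyond the
  log-normal layer.
* `sim_probe_reads()` assigns reads to taxa by abundance, embeds
  concrete instantiations of each carried probe site at random
  non-overlapping offsets, embeds the universal site in a chosen
  fraction of reads, and reverse-complements half the reads. Reads are
  error-free by default; a uniform substitution rate exists to probe
  the brittleness of exact matching. No attempt is made at realistic
  error profiles or abundance-correlated fragment models.

Every generator is a pure function of its specification and seed, and
column sums of generated OTU tables equal the depth exactly. Passing
recovery tests on these generators demonstrates the statistical
machinery is correct at the planted effect sizes; it does not certify
performance on real data whose noise structure (chimeras, copy-number
variation, run effects) the generators deliberately omit.

## Numerical choices and degenerate inputs

* Fit optimiser: L-BFGS-B within bounds, five fixed starts, objective
  tolerance at machine precision, then a polish from the best start;
  penalties steer the optimiser away from infeasible (negative-flux)
  regions and feasibility is re-checked at the optimum.
* Rarefaction at depth equal to a sample's total returns that sample
  unchanged (exhaustive draw); depth 0 returns zeros; depth above any
  total is an error naming the offending samples.
* `epoch_summary()` needs one cycle for a mean and two for an s.d.;
  single-cycle epochs report `NA` spread rather than 0.
* q-values are clamped to [1/m, 1] through the π0 clamp, and ties in p
  share the maximal rank, which keeps the step-up monotone.
* Problem sizes in the shipped tests (10⁴ null replicates for the
  type-I check, 2×10⁴ reads for probe recovery, 10³–10⁴ Monte-Carlo
  draws elsewhere) were chosen so the whole suite exercises every
  stochastic claim at useful precision while remaining a desk-scale
  run.

## Known limitations

* The flux-balance fit treats the anaerobic phase only; aerobic ratios
  are compared against fixed model rows, not fitted.
* PH2MV, the third PHA fraction, is not modelled; in communities with
  substantial propionate uptake the PHV/PH2MV chemistry would need
  additional coefficients.
* Maximum specific uptake/release rates are not computed: the
  estimation window on the profiles is not standardised, and endpoint
  ratios do not constrain it.
* The step-change test assumes a single step at a known position;
  gradual drifts load onto both segments and dilute the statistic.
* eFISH abundance is probe-target abundance: it inherits probe
  coverage biases and 16S copy-number effects wholesale.
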