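---
title: "Methods: quantifying the mitotic shutdown of clathrin-mediated endocytosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the mitotic shutdown of clathrin-mediated endocytosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocme)
```

# Background

During mitosis, clathrin-mediated endocytosis (CME) shuts down: clathrin-coated
pits persist at the plasma membrane of mitotic cells but arrest in a shallow
state and internalise no cargo. One mechanistic account ties the arrest to
membrane mechanics: plasma-membrane tension rises in mitotic cells, raising the
energy needed to invaginate a coated pit, and the actin machinery that would
normally supply the extra force is unavailable because monomeric actin is
sequestered for the mitotic cortex. `mitocme` packages the quantitative assays
with which that account is tested:

1. **Tether force** from optical-trap bead-displacement traces, a proxy for
   apparent membrane tension.
2. **Comparative LFQ proteomics** of clathrin-coated-structure (CCS)
   fractions from interphase versus mitotic cells, with Gaussian-histogram
   outlier calling.
3. **Image quantification** of cortical versus cytoplasmic F-actin,
   cytoplasmic G-actin, and transferrin uptake.
4. **Flow-cytometry uptake** (forward-scatter gating, FL1 geometric means).
5. **Group statistics** shared by all modules (Welch/Student t-tests, one-way
   ANOVA with Tukey's post-hoc test, mean ± SEM).

No raw data are required: a synthetic-data module generates every input type
with recorded ground truth, so the full pipeline is exercised and validated
offline.

# Tether-force analysis

A concanavalin-A-coated bead held in an optical trap is attached to the cell
and pulled away to draw a membrane tether. The trap is Hookean over the working
range, so the tether force is

$$F = k\,\Delta x,$$

with $k$ the trap stiffness (pN/nm, typically ~0.3) and $\Delta x$ the bead's
displacement from the trap centre (nm). Tether force is proportional to the
apparent membrane tension; the pipeline deliberately stops at force and does
not estimate tension itself, which would require the membrane bending rigidity.

**Calibration.** The acquisition method states per-experiment calibration but
not the estimator, so the package implements the equipartition method: for a
tether-free bead, $\tfrac12 k \langle x^2 \rangle = \tfrac12 k_B T$, giving
$k = k_B T / \mathrm{var}(x)$ (`calibrate_stiffness()`, requiring at least
1000 samples). A directly supplied calibrated stiffness is equally acceptable
and is how `tether_trace` objects normally arrive. On synthetic no-load
segments of $10^4$ samples the estimator recovers the generating stiffness
within 5%.

**Measurement.** `measure_tether_force()` implements the acquisition
conventions:

* The **plateau** is the mean force over the 1 s immediately preceding the
  first stage manipulation after tether formation (`averaging_span = 1`).
* The **zero reference** is the window between the toward-cell stage event
  (which relaxes the tether) and the subsequent away event. A settling margin
  of 0.2 s after the toward event excludes stage-motion transients; the margin
  is a package choice, exposed as a parameter. Averaging windows are half-open
  so the sample at a stage-event instant belongs to the following regime.
* Force = plateau mean − baseline mean, so constant displacement offsets and
  slow drift common to both windows cancel exactly.
* **Stale tethers**: measurements whose plateau ends more than 30 s after
  tether formation are flagged (`stale_tether`) and excluded — actin
  polymerises into older tethers and corrupts the reading.
* **Double tethers** double the force from the same cell. The original
  experiments spotted them by DIC imaging; the pipeline approximates that
  check with a quantitative rule: a measurement within 15% of twice the
  median unflagged force of its own cell is flagged `double_tether`
  (`flag_double_tethers()`), iterated to a fixed point, with an
  `annotated_double` column as an unconditional override. The twofold
  signature is the only quantitative criterion available.
* Traces lacking a toward/away annotation get a changepoint fallback (the
  lowest-mean sliding window) and carry `no_zero_reference`; flagged
  measurements never enter summaries.

`relative_forces()` divides each force by the mean unflagged interphase force
of the same experiment, so interphase values average exactly 1 within each
experiment; this removes day-to-day trap and cell-batch variation when pooling
experiments. Whether zero references should be shared per cell when several
tethers are pulled is not specified by the source methods; the package
subtracts a zero per tether.

# CCS proteomics

Starting from a MaxQuant-style `proteinGroups.txt` (the pipeline never touches
raw spectra or the database search), `read_protein_groups()` drops
contaminant/decoy rows (`CON__`/`REV__` prefixes) and locates
`LFQ intensity <condition>_<experiment>` columns. For each protein:

* the per-condition LFQ value is the combined-analysis column when a single
  column per condition exists, otherwise the mean over experiments with
  nonzero intensity (robust to MS dropout; zeros are missing-not-small);
* the abundance ratio is interphase/mitotic, log2-transformed;
* proteins with a zero condition value are excluded from the ratio analysis
  (`excluded_zero`) because a zero may mean loss of the protein or poor
  detection — unless the nonzero side exceeds $10^6$ LFQ units, in which case
  the protein is classified condition-exclusive (`interphase_exclusive` /
  `mitotic_exclusive`), a likely genuine presence/absence difference.

`fit_gaussian_null()` builds a frequency histogram of the log2 ratios
(default bin width 0.25 log2 units, chosen to give ≥ 30 bins over a typical
±4 range; Freedman–Diaconis available) and least-squares fits
$A e^{-(x-\mu)^2/2\sigma^2}$ with free amplitude, initialised at the sample
moments (Levenberg–Marquardt). Fitting the histogram rather than taking
moments matches the published procedure and is robust to the injected
outliers in the tails; `method = "moments"` is available for comparison.
`call_outliers()` flags proteins strictly beyond $\mu \pm 2\sigma$ — the
boundary itself has measure zero, and the strict inequality is documented for
reproducibility. Under a pure Gaussian null the expected flagged fraction is
$2\Phi(-2) \approx 4.55\%$, which the synthetic null reproduces.
`per_experiment_consistency()` reruns the whole chain per experiment and
counts how many runs independently re-call each outlier, mirroring the
published observation that the same outliers appear when each experiment is
analysed individually. `annotate_ratios()` restricts results to reference
lists (bona fide CCS proteins, actin-cytoskeleton components) ordered by log2
ratio, as in the comparative bar chart.

The published anchor ratios — 46.2 for the most interphase-enriched protein
(cortactin) and 0.077 for the most mitotic-enriched (NSF) — are used as
generator parameters and fixture anchors, not as reproduction targets: they
came from live MS runs that no desk-scale computation can re-measure.

# Image quantification

The ROI geometry follows the published analysis of equatorial confocal
sections: a **24-px-wide border ring** at the cell edge and a **50 × 50-px
box** in the cytoplasm. `border_and_cytoplasm_rois()` builds the ring as the
mask minus its erosion by the border width (computed from the Euclidean
distance transform, so the ring has exact geometric width), entirely inside
the mask boundary — whether the original hand-drawn ROI straddled the edge is
unknowable, and inside is the conservative choice. The box is centred at the
distance-transform maximum of the mask, the reproducible analogue of placing
it by hand in open cytoplasm; avoiding organelle contamination in real images
is the caller's responsibility via a provided mask. With background $b$
(median intensity outside all cell masks — robust to stray cells; the original
background strategy is unstated):

$$\mathrm{F\text{-}actin\ ratio} = \frac{\bar I_\mathrm{cortex} - b}{\bar I_\mathrm{cytoplasm} - b},
\qquad \mathrm{G\text{-}actin} = \bar I^{(G)}_\mathrm{cytoplasm} - b.$$

Transferrin uptake is the integrated background-subtracted intensity over the
cell mask (negative residuals clipped): the acid wash before imaging removes
surface-bound label, so total internal signal is the meaningful quantity, and
it is normalized to the mean of a caller-designated reference group (the
published figures use different references — control RNAi interphase vs
untreated interphase — so the reference is a required argument, never a
default). Masks are derived by Otsu thresholding, largest connected
component, hole filling (`derive_mask()`); for z-stacks the equatorial plane
is the one with maximal mask area.

# Flow cytometry

Events are gated at forward scatter ≥ 200 to exclude sub-cellular particles;
the boundary is kept inclusive (the stated intent is to exclude particles
*smaller* than cells). Uptake per sample is the geometric mean of FL1 over
gated events, $\exp(\overline{\ln \mathrm{FL1}})$, the standard summary for
log-normal fluorescence; non-positive FL1 events are unmeasurable on a log
scale and are excluded with a reported count. Detector values are treated as
linear. Input is plain CSV (`FSC,SSC,FL1`); FCS containers are out of scope.

# Statistics

`two_sample_t()` accepts raw vectors or `(mean, sem, n)` summaries — the t
statistic depends on the data only through those summaries, and both entry
points agree to machine precision. Welch (Satterthwaite degrees of freedom) is
the default: the two tether-force groups have ~4-fold different variances, and
the Welch test computed from the published group summaries (19.2 ± 1.5 pN,
n = 13 vs 27 ± 2.8 pN, n = 11) gives p = 0.0263, consistent with the printed
p = 0.027 whose exact test was not named. Student's variant is a flag.
`anova_tukey()` wraps one-way `aov()` with `TukeyHSD()`; it requires raw
values because the studentized-range adjustment needs within-group spread, and
offers a convenience filter for comparisons against a designated control
group. All p-values are two-sided. No multiple-testing control beyond Tukey is
applied, matching the source analyses. `assemble_report()` bundles
per-figure-style panels (n, mean ± SEM, tests, QC exclusion counts) into a
deterministic JSON + CSV report.

# Synthetic data: what it emulates, and what it does not

Each generator reproduces the statistical structure the corresponding analysis
assumes, with ground truth recorded before noise:

* **Traces** (`gen_tether_trace()`): plateau at
  $\Delta x = F \cdot n_\mathrm{tethers} / k$ above the drift offset, a
  zero-reference dip between explicit toward/away stage events (the stage was
  computer-controlled, so events are known at acquisition time, and the
  generator encodes them rather than inferring motion), i.i.d. Gaussian
  displacement noise — the simplest stationary model of trap thermal noise.
  The source does not state its displacement noise magnitude, so the SD is an
  exposed parameter (tests use 10 nm at 5 kHz). The default schedule places a
  2-s reference window; validation harnesses use an 8-s window so the
  baseline contributes little variance to recovery checks against the 1-s
  plateau's standard error. Not modelled: full Brownian dynamics of the bead,
  low-frequency drift, camera/QPD artefacts.
* **LFQ tables** (`gen_lfq_table()`): log-normal intensities; a per-protein
  log2 ratio drawn from the Gaussian null (default over 4 experiments, as in
  the source design); a run-to-run loading factor shared by both conditions of
  a protein, so the condition ratio is exact at the protein level —
  LFQ normalisation across runs is out of scope, and making the ratio exact
  keeps the null σ interpretable as the protein-level parameter. Dropout
  zeros are injected per cell. Not modelled: peptide-level variance,
  intensity-dependent missingness, between-protein correlation.
* **Images** (`gen_cell_image()`): disc cells with annular cortices (mitotic
  cells are rounded; matches the equatorial-section geometry), uniform
  cytoplasm and background, single-pixel transferrin puncta, Gaussian noise.
  The default cortex width equals the 24-px analysis ring so the ring samples
  cortex signal, as it does in real equatorial sections. Not modelled: optics
  (PSF blur), shot noise, nuclei, irregular cell shapes — so passing recovery
  tests demonstrates correctness of the ROI arithmetic, not robustness to
  segmentation pathology.
* **Flow events** (`gen_flow_events()`): Gaussian FSC / log-normal FL1
  mixtures plus sub-gate debris (FSC uniform in [20, 180]); truth records
  per-population geometric means and the exact sub-gate count. Not modelled:
  spillover/compensation or detector voltage response.

All generators are bit-reproducible given their seed, and seeds are isolated
from the caller's RNG state.

# Validation conditions and problem sizes

The package's validation suite runs entirely on synthetic data at sizes chosen
to keep Monte-Carlo error well inside the tolerances being asserted: 50 traces
at 5 kHz (noise SD 10 nm, forces 10–40 pN, stiffness 0.3 pN/nm) for force
recovery; 20 segments of $10^4$ samples for calibration; 5000 null proteins
(log2 null $N(0.2, 0.8^2)$, 4 experiments) plus 20 injected outliers beyond
4σ for the LFQ chain; ~100 synthetic cells at truth ratios {1.5, 2.5, 4.0}
with 10% noise for imaging; 1000 three-group null simulations for the ANOVA
type-I error. The published headline numbers (tether forces 19.2 ± 1.5 vs
27 ± 2.8 pN, ratios 46.2 and 0.077, the condition-exclusive protein lists)
enter as generator parameters and fixture anchors; the pipeline is validated
by recovering known ground truth and by reproducing derived quantities (the
Welch p-value, the exclusive-list classification) exactly where they are
derivable.

# Known limitations

* Double-tether detection by the twofold rule needs ≥ 2 measurements per cell
  (or an annotation); an isolated double tether with no sibling measurement
  passes undetected.
* The changepoint fallback for missing zero references is a minimum-mean
  window, adequate for clean dips but not for drifting traces; such
  measurements are flagged and excluded from summaries regardless.
* The Gaussian-histogram fit depends mildly on bin width for small n; for
  n < ~500 the moments method is more stable.
* Image analysis assumes a single dominant cell per field and an equatorial
  section; multi-cell fields need caller-provided masks.
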