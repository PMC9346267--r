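---
title: "Methods: digital H-DAB quantification and its validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: digital H-DAB quantification and its validation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihcquant)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. It states no empirical result that the test
suite does not itself compute.

## The measurement model

Brightfield immunohistochemistry produces a transmitted-light RGB image in
which two absorbing dyes are mixed: hematoxylin (blue, nuclear) and DAB
(brown, the antibody chromogen). Absorbances add linearly in optical
density, so per pixel

$$\mathrm{OD}_c = -\log_{10}\frac{I_c + \varepsilon}{I_{0,c} + \varepsilon},
\qquad c \in \{R, G, B\},$$

and the OD vector is a nonnegative mixture of unit stain vectors. We unmix
with the Ruifrok–Johnston H-DAB matrix (the de-facto standard when stain
vectors have not been calibrated for a particular scanner), clip negative
concentrations, and map concentrations to a fixed $[0, 1]$ scale by
dividing by a **saturation OD** of 2.0 and clipping. Key consequences:

* an unstained (white) pixel is exactly 0 in both channels;
* channel value 1 is a reproducible "maximum staining" ceiling, identical
  across images. A per-image normalization (e.g. by the image maximum)
  would make intensity/area incomparable between fields, which is why a
  fixed constant is used;
* $\varepsilon = 1/I_0$ merely guards $\log 0$ and sits below quantization
  noise.

`white_point` defaults to the nominal dtype maximum (255 for 8-bit); it can
be set per image when a scanner's background is darker.

## Segmentation

Nuclei are detected on the hematoxylin channel: Gaussian smoothing
(`sigma = 2` px), Otsu threshold computed **from ROI pixels only** (the
surrounding glass/fibrosis would otherwise drag the threshold), area
filtering (`min_area = 40` px² removes debris; `max_area` unbounded by
default), and distance-transform watershed with a height tolerance of 2 px
to split touching nuclei — the standard declumping recipe. The thresholded
mask is intersected with the ROI and objects are kept only if their
centroid lies inside it, so segmentation never leaks across the analyst's
outline.

Whole cells are delimited by **distance-limited nearest-nucleus expansion**
(default `expansion_px = 10`): every pixel within 10 px (Euclidean, to the
nearest pixel of a nucleus) is assigned to its nearest nucleus, exact ties
going to the lower label id. This emulates the familiar
"secondary object by distance" construction, guarantees cell count equals
nucleus count, and is fully deterministic. Internally each label's distance
field is computed on its padded bounding box and folded into a running
arg-min in ascending label order, which is what makes the tie-break
label-ordered rather than scan-ordered.

A cell is **DAB-positive** when at least `min_frac = 10%` of its pixels
reach `threshold = 0.15` on the normalized DAB scale. No published
criterion exists for this step; these defaults are an explicit design
decision of this package, chosen as a *fixed global* rule (not a per-image
Otsu) so that a truly negative field yields zero positive cells — matching
the "no positive cells" semantics of the lowest IRS category. Both
parameters are configurable, and the whole cell (nucleus plus expansion) is
evaluated, i.e. membranous and cytoplasmic staining together; compartment
scoring is out of scope.

The denominator of %PC is the nucleus count, which by construction equals
the cell count.

## The two measures and their aggregation

* `%PC = 100 × n_positive / n_cells`. A field with zero detected cells
  reports %PC as missing, not 0 — 0/0 is not "no positive cells" — and
  missing fields are excluded from the %PC mean only.
* `intensity/area = Σ DAB / ROI pixels`, summing over **all** ROI pixels,
  stained or not. The division by ROI area (rather than by stained area)
  makes the measure sensitive to the spatial extent of staining as well as
  its strength, which is what makes it comparable to the *total* IRS.

A sample is the unweighted mean of its fields (up to four; fewer are
accepted with smaller tissue), per selector/analyzer combination; a
combination-level mean averages the available combinations (up to
S1A1, S1A2, S2A1, S2A2). No area weighting is applied at either level.

## The immunoreactivity score

`score_pct()` bins %PC as 0 (exactly 0%), 1 (<10%), 2 (10–50%), 3
(51–80%), 4 (>80%); the customary printed bins leave (50, 51) unnamed, and
we close the gap by letting category 3 cover $(50, 80]$ so the function is
total and monotone — category 2 keeps its printed closed range $[10, 50]$.
The intensity category (0 none / 1 weak / 2 moderate / 3 strong) is a human
judgment and is deliberately **an input, never derived from pixels**:
inventing a pixel-to-category mapping would manufacture a correspondence
the score does not define. The IRS is the product, range 0–12; only
{0, 1, 2, 3, 4, 6, 8, 9, 12} are achievable.

## Validation statistics

**Lin's CCC.** $\rho_c = 2 s_{xy} / (s_x^2 + s_y^2 + (\bar x - \bar y)^2)$
with 1/n moments (the original estimator; a flag switches to 1/(n−1)). The
95% CI uses the Fisher z transform with Lin's asymptotic standard error.
Agreement is categorized as none (< 0.800), acceptable (≥ 0.800), strong
(≥ 0.950), with ≥ comparisons exactly at the boundaries. Degenerate cases:
identical vectors give $\rho_c = 1$ with a collapsed CI; two constant
vectors are an error. `pairwise_ccc()` computes all pairs of observer
combinations and labels each by which index differs — with two selectors
and two analyzers that is 6 pairs, of which 2 differ in analyzer only, 2 in
selector only, and 2 in both.

**Spearman, Kruskal–Wallis, ANOVA.** These are standard steps and go
through `stats` (`cor.test(..., method = "spearman", exact = FALSE)`,
`kruskal.test`, `oneway.test(var.equal = TRUE)`); the package adds only the
tabular surface. p-values are two-sided everywhere and no multiplicity
correction is applied.

**ROC.** The empirical curve, trapezoidal AUC and DeLong CI come from pROC
behind the `roc_analysis()` surface; the test suite checks the AUC against
a brute-force concordant-pair count. The Youden optimum is selected by the
package itself from the full threshold table (thresholds are midpoints
between consecutive distinct scores) so that exact ties in J resolve to the
**lower** cut-off, reproducibly. Direction is auto-detected: if the
conventional direction yields AUC < 0.5 — as happens when staining is
*negatively* correlated with the biochemical response — the curve is
flipped and a `flipped` flag recorded. The paired AUC comparison is the
DeLong test (the natural choice for correlated curves; no alternative is
mandated anywhere); identical or rank-equivalent scores give a zero AUC
difference with degenerate variance, reported as p = 1.

## What the synthetic data emulate — and what they do not

`generate_field()` builds fields that are *geometrically* faithful to the
measurement problem: non-overlapping disk nuclei (dart-throwing placement
with a 3 px guard gap; bounded retries, so an infeasible density errors
rather than loops), hematoxylin on every nucleus, DAB on positive cells
over nucleus plus a 3 px perinuclear ring (whole-cell staining), forward
Beer–Lambert composition with the same stain matrix the pipeline inverts,
Gaussian pixel noise, clip, quantize. Defaults: 512×512 8-bit, 300 cells,
radius 8 ± 1 px, DAB at 0.6 of saturation, noise sd 4 counts — roughly a
10× field at desk-scale runtime (well under a second per field).

They are **not** histologically realistic: no texture, no chromatin
structure, no overlapping or out-of-focus cells, no fibrosis or vessels, no
scanner color profile, and the stain matrix is exactly the one the pipeline
assumes. Passing the recovery suites therefore demonstrates that the
implementation is internally correct (segmentation finds what was placed,
deconvolution inverts the forward model, statistics recover known
parameters) — not that the pipeline is robust to real-tissue artifacts,
which only real slides can show.

`generate_observer_tables()` uses additive Gaussian selector/analyzer/
residual effects, under which the population CCC between two combinations
has a closed form (`theoretical_ccc()`); truth clipping, when a valid range
is supplied, mildly attenuates agreement at extreme truths.
`generate_response_tables()` couples a staining measure to a positive
IGF-1×ULN response through a Gaussian copula with the Spearman-matched
latent correlation $2\sin(\pi\rho/6)$, and flags normalization at ≤ 1.

## Numerical choices and degenerate inputs

* Round-trip accuracy of separate-after-recombine is limited by
  quantization: at 8 bits a doubly stained pixel near saturation maps to a
  handful of counts and one count back-projects to a visible concentration
  error, so the round-trip contract (max error < 0.02 away from
  saturation) is exercised at 16-bit white point, consistent with 8/16-bit
  input support.
* Labels are consecutive integers ordered by nucleus centroid (row, then
  column): identical inputs give identical label maps.
* Empty ROI is always an error; a field with no detected nuclei is valid
  (empty label map, a warning, %PC missing).
* CSV output writes doubles at 17 significant digits and reads them back
  with the base-R parser, which is exactly round-tripping (a faster parser
  in common use is one ulp off).
* Test-suite problem sizes: property suites use 100–1000 random vectors at
  n ≤ 50; parameter recovery uses 30 fields of 250 cells at 512×512, 500
  samples for observer agreement, 1000 null ROC replicates at n = 400 and
  2000 null Kruskal–Wallis datasets — sizes chosen so the whole suite runs
  in a few minutes on one core while keeping Monte-Carlo error well inside
  the asserted tolerances.

## Known limitations

* Stain vectors are fixed, not estimated per slide (no Macenko/NMF); a
  YAML config can supply calibrated vectors.
* The DAB positivity criterion is a package decision, not a community
  standard; sensitivity of %PC to `threshold` should be examined before
  cross-study comparisons.
* Whole-slide formats are out of scope; the unit of analysis is the
  selected field with its ROI mask.
* The IRS intensity category cannot be computed from images by design, so
  fully automated IRS reproduction is impossible — only the %PC component
  is derivable from the pipeline.
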