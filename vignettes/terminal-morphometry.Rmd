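---
title: "Quantitative EM morphometry of presynaptic terminals: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative EM morphometry of presynaptic terminals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(presynmorph)
```

## The measurement problem

Presynaptic terminals of cerebellar parallel fibres release glutamate both
at the active zone (onto the postsynaptic Purkinje-cell density) and,
ectopically, at membrane sites directly apposed to Bergmann-glial
processes. Transmission-EM of single 70 nm sections, with the terminal
perimeter, the postsynaptic density (PSD), the abutting glial membranes and
every vesicle centre traced by hand, turns questions about these release
sites into morphometry:

* how are vesicle-to-membrane distances distributed, and do they resolve
  into pools (a readily-releasable pool clustered within ~50 nm of the
  active zone and a reserve pool near ~100 nm)?
* what fraction of vesicles sits within 50 nm — one typical vesicle
  diameter (~52.5 nm), so a centre that close can be touching the
  membrane — of the active zone or of glial-facing membrane, and does
  stimulation change it?
* how much of the terminal is ensheathed by glia, and how wide is the
  terminal-to-glia gap at each apposition's midpoint?

`presynmorph` implements that measurement pipeline over traced coordinates
(it does not segment images), plus the statistics used on its outputs, plus
a synthetic-annotation generator with ground truth so that the whole chain
can be validated without access to raw micrographs.

## The pipeline

**Compartment classification.** The perimeter is resampled at a fixed
arc-length step (default 1 nm). A sample is `active_zone` when within
`tau_az` (default 30 nm) of any PSD trace, else `glial_facing` when within
`tau_glial` (default 30 nm) of any glial trace, else `other`; the active
zone wins where both apply, because glial processes do not overlie the
synaptic cleft. Runs shorter than `min_run` (default 10 nm) are absorbed by
their flanks, and maximal runs become numbered regions. The thresholds are
a surrogate for the manual demarcation a microscopist would draw: observed
terminal-to-glia gaps are ~6 nm and the synaptic cleft ~20 nm, so 30 nm
separates apposed from non-apposed membrane with a wide margin on both
sides. The threshold geometry extends each region slightly past the true
apposition (by at most `sqrt(tau^2 - gap^2)` at each end, ~20-30 nm);
with realistic region counts this biases glial coverage upward by ~0.02,
which is inside the 0.05 band we validate against ground truth. Explicit
arc extents can be passed instead (`az_arcs_nm`, `glial_arcs_nm`) to
reproduce a fully manual demarcation.

**Distances.** For every vesicle centre, the distance to the perimeter is
exact point-to-segment geometry. Distances to the two compartments use the
resampled sample points — nearest-sample semantics, with discretisation
error bounded by half the resampling step — because the compartments are
defined on those samples. Halving the step from 2 nm to 0.5 nm moves pooled
compartment distances by well under 1 nm (tested), so the default 1 nm step
is immaterial at analysis scale.

**Pools.** Distances are pooled per condition and compartment across all
terminals (pooled counting, not per-terminal averaging, so contingency
totals are vesicle counts). The density is a plain Gaussian-kernel estimate
with Silverman's rule-of-thumb bandwidth
`h = 0.9 min(sd, IQR/1.34) n^(-1/5)`, evaluated on a uniform 0.5 nm grid
from 0 to `max + 3h`. No boundary reflection is applied at zero; mass
smoothed below the origin (a few percent when a pool sits near the
membrane) is a documented bias, not corrected, and the estimator itself
integrates to one over its full support (tested). Peaks are local maxima
with topographic prominence at least 5% of the maximum density — permissive
on purpose, since shallow third pools are biologically meaningful — and
each peak's probability is the trapezoidal mass over one histogram bin
width (default 10 nm) centred on the peak. A peak "%" could equally be read
as density times width; we report the integral as the probability and also
expose the raw density so either reading is recoverable.

**Near-membrane counting and statistics.** A vesicle is near-membrane when
its centre is strictly closer than 50 nm; ties at exactly 50 nm count as
outside. Pairwise condition comparisons use a two-sided Fisher's exact test
on (within, beyond) counts under the sum-of-small-p convention with a 1e-7
relative tie slack, computed from log-factorials so tables with tens of
thousands of vesicles remain exact; the implementation is checked against
exhaustive hypergeometric enumeration for every table up to n = 40.
Per-terminal metrics are compared across conditions with the tie-corrected
Kruskal-Wallis test and Dunn's pairwise z from mean midranks with
tie-corrected variance, Bonferroni-adjusted over the pairs compared
(`adjust = "none"` is available). The Bonferroni reading of "Dunn's
correction" is the common one in the ecosystem these analyses come from;
nothing downstream depends on the choice.

**Coverage and gaps.** Glial coverage is glial-facing arc length over
perimeter length. For each glial-facing region the gap is the exact
distance from the region's arc-length midpoint sample to the nearest glial
trace.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes, not
micrograph pixels:

* **Perimeter**: a Fourier-perturbed ellipse (harmonics 2-4, amplitude
  ~8% of a 450 nm mean radius), giving smooth convex-ish outlines of
  ~2.8 µm perimeter, the scale of parallel-fibre boutons.
* **Arc layout**: one active-zone arc (12% of the perimeter) with a PSD
  trace offset 20 nm outward; 2 or 3 glial arcs (13% each) flanking the
  AZ across 25-70 nm of bare membrane, since perisynaptic processes
  approach the cleft. Glial traces run parallel at a per-region gap drawn
  from N(6, 1) nm and flare away to 45 nm over the last ~20 nm of each
  apposition, the way withdrawing processes do; the flare also keeps the
  threshold classifier's region boundaries sharp.
* **Vesicles**: counts are Poisson (default mean 57 per terminal);
  each vesicle draws a target active-zone distance from a Gaussian mixture
  (defaults 30% at 32 nm sd 12, 60% at 97 nm sd 30) or is uniform
  background (10%), and is placed inside the polygon at that distance from
  the AZ arc by rejection sampling. Placement conditions on the AZ distance
  only; the glial-facing distance distribution is then emergent, and comes
  out as a single broad right-skewed peak.
* **Conditions**: `condition_presets()` defines a three-arm study
  (167/295/287 terminals; gap means 5.82/6.01/6.26 nm; pool locations
  32+97, 36+87 and 31+81+117 nm; vesicle means 57/59/56, the published
  totals divided by the terminal counts). These are synthetic study
  conditions for power and recovery checks, not measurements.
* **Reproducibility**: one dataset seed spawns a recorded per-terminal
  seed, so output is byte-identical under a fixed seed and any terminal can
  be regenerated alone.

What the generator does *not* emulate: tracing jitter, section-thickness
projection, non-convex terminal shapes, vesicle exclusion volumes, and a
realistic abundance of vesicles adjacent to glial membrane — because
placement conditions on AZ distance only, the synthetic near-glial fraction
(~0.02) is well below values measured in real terminals (~0.11-0.14).
Passing recovery tests therefore show that the *measurement chain* is
unbiased on idealised geometry, not that real tracings are this clean.

## Validation strategy and problem sizes

Every geometric primitive is tested against an independent dense-resampling
oracle (0.01 nm), every counting operation against exhaustive enumeration,
and the full pipeline against generator ground truth: active-zone extent
within `2*step + 2*tau_az`, glial region counts exactly, coverage within
0.05, midpoint gaps within 2 SE, and KDE pool peaks within 5 nm of the
configured pool locations in at least 18 of 20 replicate datasets of 10
terminals x 500 vesicles. The replicate size keeps per-pool samples near
the regime where Silverman-bandwidth KDE resolves 32 nm from 97 nm
(separation is several bandwidths) while the whole suite runs in minutes;
the analysis scripts use 30-50 terminals per condition for the same reason.

## Known limitations

* Compartment labels inherit the threshold surrogate's end-of-region
  extension; analyses of *lengths* carry a small positive bias relative to
  a manual demarcation, while distances are essentially unaffected.
* The KDE is unreflected at zero, so a pool hugging the membrane has its
  peak pulled slightly outward and its mass slightly undercounted.
* Single-section analysis: all quantities are 2-D section morphometry, not
  3-D reconstructions.
* The condition presets encode published summary differences as generator
  defaults; they are illustrative, and any real inference should come from
  real tracings read through `read_annotation_bundle()`.
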