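---
title: "Ratiometric nanoladder barcodes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ratiometric nanoladder barcodes: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoladder)
```

This vignette is the package's own account of the science it implements: the
probe and barcode model, the statistical structure of the synthetic data,
the decoding procedure, and the choices made where the design was genuinely
open. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The probe model

A circular DNAzyme probe against one target RNA consists of:

* **two recognition arms**, 20 nt each by default, exact reverse complements
  of the target windows flanking a cleavable purine–pyrimidine (R–Y)
  dinucleotide junction. Coordinates are 0-based and half-open throughout;
  the upstream window ends at the purine (inclusive), the downstream window
  starts at the pyrimidine, so a junction at position *p* is usable iff
  `p + 1 >= arm_len` and `L - p - 1 >= arm_len`;
* **a catalytic core** between the arms. Published probe sets defer core
  sequences to supplementary material, so the package defaults to the
  canonical 10–23 DNAzyme core (`GGCTAGCTACAACGA`) and accepts any core
  string; which core is used changes nothing downstream of design;
* **a reference region** (20 nt) and a **barcode anchor** (20 nt), drawn
  from an orthogonal pool generated by seeded rejection sampling: GC
  fraction 40–60%, no homopolymer longer than 4, and no 10-mer shared with
  any target (either strand) or with another pool member;
* **inert spacers** (`TT` by default) between segments. Circle positions
  are read modulo the circle length.

When several junctions are available, `design_probes()` ranks them
AU > GU > AC > GC — the standard 10–23 cleavage preference — then by
centrality in the transcript. The ranking is exposed in `probe_config()`.

Cleavage chemistry itself (the 2′,3′-cyclic phosphate on the cleaved RNA,
its removal by PNK, the one-base 3′ overhang) is outside the computational
scope; its net effect is an *efficiency*, which the simulator models as the
detection-efficiency parameter below. The arms are therefore taken symmetric
about the R|Y junction rather than offset by the overhang.

### Specificity screening and control variants

`screen_specificity()` slides the probe's intended 2×20-nt recognition
window along each background sequence and reports the longest contiguous
per-arm complementarity plus a cleavage-competence call: an alignment is
competent only if the background junction is R–Y **and** no mismatch falls
within `critical_window` (default 8 nt) of the junction on either side. The
8-nt window encodes the observation that central mismatches abolish
cleavage; it is configurable because the literature does not pin down a
single value.

Control variants mirror the wet-lab negative controls: `SNV` substitutes
the single central base of the recognition region (index `len %/% 2`,
0-based — the first base 3′ of the junction for even lengths); `MM12`
substitutes 12 bases spread evenly; `random` resamples the region with GC
within ±5% and no shared 10-mer; `core_deleted` replaces the core with an
inert spacer of equal length. Substitutions use a fixed within-class swap
(A↔C, G↔U) so variants are reproducible without a seed; only `random`
consumes one.

## 2. The coding model

A design with C detection channels and R repeat levels defines the code
space {1..R}^C, enumerated lexicographically; capacity over *m* sequential
hybridize/image/strip rounds is `m · R^C`. Levels start at 1, not 0: the
nine-code two-channel/three-level scheme equals 3^2 only when every channel
carries at least one repeat, and an all-channels-present design lets the
decoder demand colocalized signal in every channel, which is exactly how
degenerate spots are rejected. Allowing zero levels would give
(R+1)^C − 1 codes but make single-channel noise decodable; the package does
not assume it.

The theoretical ratio of a code in channel c is

$$ \rho_c = \frac{l_c \, b_c}{N_{\mathrm{norm}} \, b_{\mathrm{ref}}} $$

with level $l_c$, per-channel brightness factors $b$, and a normalization
level $N_{\mathrm{norm}}$ that defaults to the design maximum (10 for the
single-channel 1..10 ladder, giving the smallest barcode ratio 0.1).

## 3. What the synthetic-data generator emulates

The generator reproduces the statistical structure the analysis assumes, at
parameter values taken from the experimental regime the method operates in:

| Parameter | Default | Meaning / rationale |
|---|---|---|
| copy-number law | NB(mean, size = 5) per gene | overdispersed cell-to-cell variation; PFN1 mean 24 and ER mean 4 follow the printed single-cell ranges (18–30, 1–9); other panel means are package choices of the same order |
| `p_det` | 0.30 | in situ detection efficiency; copies become amplicons by binomial thinning |
| K law | round(lognormal(ln 60, 0.5)), min 1 | tandem-repeat count of each RCA amplicon; no distributional form is published, a right-skewed law is chosen and exposed |
| `h_dfp`, `h_rfp` | 0.9 | per-site hybridization efficiency of detection/reference probes |
| brightness | 20 counts/fluorophore | with Poisson shot noise on by default |
| `lambda_ns` | 0.2 (`rna_primed`) / 16 (`primer_assisted`) | Poisson nonspecific spots per cell; the two modes contrast primer-free and primer-assisted amplification |
| geometry | 500 nm z-spacing, 160 nm pixels, PSF σ 1.2 px | acquisition-like metadata; z-spacing matches the imaging protocol |

Per amplicon, bound fluorophores are `Binomial(K·l_c, h_dfp)` per detection
channel and `Binomial(K, h_rfp)` for the reference — so with noise off and
unit efficiencies the ratio is *exactly* the level for every K, which is the
normalization claim in testable form. Nonspecific amplicons carry a uniform
random level in one random detection channel with K from the same law: they
look decodable in that channel and stress the decoder's rejection path
(multi-channel designs reject them because the other channel reads 0).

Rendering places each spot as a separable 3D Gaussian whose voxel sum equals
its channel intensity, over constant background with Gaussian read noise,
quantized to 16 bits with saturation. Cells are disks on a grid with disk
nuclei (a DAPI channel and 16-bit label masks are emitted). The generator
deliberately does **not** model: optical crowding and amplicon overlap,
tissue autofluorescence, non-Gaussian PSFs, chromatic aberration, or
spatially structured expression. Tests passing on this generator therefore
demonstrate the pipeline's correctness under its stated assumptions, not
performance on real micrographs.

qPCR simulation uses `Ct = intercept − slope·log10(copies)` with slope
log2(10) ≈ 3.32 (ideal doubling per cycle), so noise-free fold changes
recovered through 2^-ddCt are exact.

## 4. Spot calling

Detection works on maximum intensity projections, matching the acquisition
protocol; full 3D detection is a possible extension. The detector is a
Laplacian-of-Gaussian band-pass at `blob_scale_px = 2`, thresholded at
`median + 5·MAD` of the filtered plane (robust to the mostly-background
pixel population), 3×3 local maxima, greedy non-maximum suppression at
`min_separation = 3` px (of two closer detections only the stronger
survives — the documented merge rule), and subpixel centroids by local
center of mass of the positive band-pass response. Photometry is aperture
sum minus annulus-median background times aperture area, clamped at zero,
with border-clipped apertures flagged.

Channel colocalization is mutual-nearest-neighbor pairing within
`radius_px = 2`, anchored on the reference channel (one matched record per
reference spot, unmatched channels contribute intensity 0); exact distance
ties are broken toward the lower spot index. These defaults are engineering
choices — the thresholds used by the original imaging software are not
published — and all are exposed as arguments.

## 5. Decoding

For each matched spot, ratios `r_c = I_De_c / I_Re` (reference ≤ 0 is an
immediate reject; detection 0 gives ratio 0). Calibration estimates one
scale per channel and per field — not per cell, since 1–30 spots per cell is
far too few: candidate scales `median(r)/l` for each level *l* are scored by
the mean level-relative distance of the rescaled ratios to their nearest
level, the best candidate (ties toward the smallest correction) is refined
once as `median(r / nearest level)`. Classification assigns the code
minimizing

$$ d(\text{code}) = \sum_c \frac{|r_c/s_c - l_c|}{l_c}, $$

level-relative because the binomial variance of bound fluorophores makes
ratio dispersion grow with level. A spot is rejected when the minimum
distance exceeds `reject_margin = 0.35`, when any scaled ratio falls below
0.5 (beneath the lowest level — the nonspecific signature), or when the top
two codes tie exactly. The margin was fixed as a design constant before any
accuracy measurement and is not tuned. The published analysis separates the
code clusters graphically without stating an estimator; nearest theoretical
level with rejection is this package's explicit choice, and a Gaussian
mixture decoder would be a natural extension, not required to reproduce the
separation property.

Two consequences are tested as invariants: decoding is unchanged under any
global intensity rescaling (ratios and calibration both cancel it), and at
zero photometric noise accuracy is 100% independently of K.

## 6. Quantification

`build_expression_matrix()` aggregates decoded spots to a genes × cells
integer table, excluding but reporting rejects. Detection efficiency is
`mean(observed)/reference` with a Wilson interval on the pooled counts.
Fold changes use the standard 2^-ddCt contrast with replicate means. Cell
typing uses a nearest-centroid classifier on log1p counts with leave-one-out
confusion reporting — chosen for determinism and zero hyperparameters, since
the published discrimination model is unspecified; the counts involved are
small (0–30), which log1p stabilizes. `predict()` supports new profiles, so
the classifier interface is pluggable.

## 7. Interfaces and problem sizes

The package is tidyverse-shaped: every user-facing function takes a data
frame first and returns a tibble, so pipelines chain with the pipe;
`tidy()`, `glance()` and `autoplot()` methods cover the result objects.
File formats go through the field's standard packages: FASTA via Biostrings,
TIFF stacks plus JSON sidecars via tiff/jsonlite, TSV sheets via readr,
codebooks as versioned JSON. These functions are the package's interface;
shell scripts wrapping them are trivial to write but not shipped, except
for `scripts/acceptance.R` which reproduces the design arithmetic.

The test suite runs the nine-plex decoding benchmark at 500 cells
(≈35,000 spots), the noise ladder at 60 cells per point, spot-calling
oracle checks on ≤64 px fields with ≤50 spots, and the rendered-field
recovery suite over 50 seeds at 6 spots per field — sizes chosen so the
whole suite completes in well under a minute per file while keeping Monte
Carlo standard errors far from the asserted bounds.

## 8. Known limitations

* Arms are modeled at the sequence level only; no melting-temperature or
  secondary-structure screening (use a thermodynamics package on the emitted
  probe sheet if needed).
* The specificity screen is exact-complementarity based; it does not score
  G·U wobbles or bulged alignments.
* Spot detection assumes resolvable spots; optically crowded cells violate
  the generator's separation assumption and would need 3D or
  super-resolution handling.
* Absolute copy-number conversion from qPCR requires a user-supplied
  standard curve (slope/intercept); none is bundled.
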