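# nanoladder

Design, simulation and decoding of ratiometric fluorescent "nanoladder"
barcodes for multiplexed single-cell RNA imaging.

## The problem

Amplified single-molecule RNA FISH visualizes each transcript as one bright
spot: a circular probe hybridizes to the RNA, rolling circle amplification
(RCA) produces a long tandem-repeat amplicon, and fluorescent probes light it
up. Two things limit the approach in practice:

1. **Nonspecific amplification.** Conventional in situ RCA needs an extra DNA
   primer, whose off-target priming produces on the order of 16 false spots
   per cell. A circular probe carrying a 10-23-style DNAzyme core instead
   cleaves the bound RNA at a purine-pyrimidine (R-Y) dinucleotide junction;
   the cleaved RNA itself primes the RCA ("RNA-primed" RCA), removing the
   primer and with it essentially all nonspecific spots — and discriminating
   even single-nucleotide variants, since a central mismatch abolishes
   cleavage.
2. **Multiplexing.** Spectral overlap caps simultaneous fluorophores at about
   four. Branched DNA barcodes assembled on each amplicon repeat carry *N*
   tandem copies of a detection fluorescent probe (DFP) binding site per
   detection channel, so *fluorescence intensity* becomes a coding dimension:
   with C detection channels and R repeat levels there are R^C "virtual
   channels" per imaging round (3^2 = 9 with two channels and three levels;
   two rounds give 18).

Because RCA efficiency is heterogeneous, raw spot intensity confounds the
repeat level N with the amplicon's tandem-repeat count K. A reference
fluorescent probe (RFP) bound once per amplicon unit normalizes this out: for
detection channel c,

    r_c = I_De_c / I_Re  ≈  N_c · h_DFP / h_RFP,

so K cancels and the ratio reads out the level directly. The theoretical
ratio of level l normalized to the largest barcode of a design is
l / N_max — 0.1 for the 1-DFP barcode of a 1..10 ladder.

The package implements the full computational pipeline for whoever wants to
design such an experiment or study its decoding behaviour: circular DNAzyme
probe design with specificity controls, virtual-channel codebooks, a
synthetic-data generator (single-cell copy numbers, amplicon photometry,
rendered multi-channel z-stacks), spot calling and colocalization,
ratiometric decoding with rejection, and per-cell quantification
(detection efficiency, 2^-ddCt fold changes, nearest-centroid cell typing).

## Worked example

A nine-plex experiment with two detection channels and three repeat levels,
simulated at the pipeline's default conditions (30% in situ detection
efficiency, lognormal amplicon lengths, RNA-primed nonspecific rate):

```r
library(nanoladder)
library(dplyr)

cfg <- channel_config(channels = 2, levels = 3)
cfg
#> <virtual-channel config> 2 detection channel(s) x 3 repeat level(s) = 9 codes/round (reference: Re)

codebook <- assign_codebook(default_gene_panel()$gene_id, cfg)
head(tibble::as_tibble(codebook), 4)
#> # A tibble: 4 × 6
#>   transcript_id code_id level_De1 level_De2 code_label round_index
#>   <chr>           <int>     <int>     <int> <chr>            <int>
#> 1 GAPDH               1         1         1 1-1                  0
#> 2 THBS1               2         1         2 1-2                  0
#> 3 HER2                3         1         3 1-3                  0
#> 4 PR                  4         2         1 2-1                  0

sim_cfg <- simulation_config(n_cells = 200)
truth   <- simulate_ground_truth(codebook, sim_cfg, seed = 7)
spots   <- simulate_spot_intensities(truth$amplicons, codebook, sim_cfg, seed = 8)
decoded <- decode_cells(spots, codebook)
decoded
#> <decoded spots> 13789 spots, 13542 decoded, 247 rejected (1.8%)
#> calibration: De1=1, De2=1
```

Each spot's (De1/Re, De2/Re) ratio pair is assigned to the nearest code in
level-relative distance or rejected (margin 0.35); the 1.8% rejects are
mostly the simulated nonspecific spots, whose single-channel signature falls
below the lowest level in the other channel. Against the simulated ground
truth, 98.3% of specific spots decode to the right transcript. Per-cell
counts and detection efficiency follow directly:

```r
expr <- build_expression_matrix(decoded)
tibble::as_tibble(expr)[1:4, 1:5]
#> # A tibble: 4 × 5
#>   gene_id cell_1 cell_2 cell_3 cell_4
#>   <chr>    <int>  <int>  <int>  <int>
#> 1 GAPDH       57     38     31     10
#> 2 THBS1       19     14     15      9
#> 3 HER2         5     10      2      5
#> 4 PR           0      5      5      5

estimate_detection_efficiency(as_count_matrix(expr)["THBS1", ], reference_mean = 40)
#> # A tibble: 1 × 4
#>   efficiency conf_low conf_high n_cells
#>        <dbl>    <dbl>     <dbl>   <int>
#> 1      0.298    0.288     0.308     200
```

The estimated efficiency recovers the generator's 30% detection rate, with
the reference mean playing the role qPCR-derived copy numbers play for real
cells. `plot_ratio_plane(decoded)` draws the two-channel ratio scatter in
which the nine code clusters separate; `autoplot()`, `tidy()` and `glance()`
methods are provided for decoding results and cell-type fits.

## Further reading

The methods vignette (`vignettes/nanoladder-methods.Rmd`) documents the
model assumptions, every tunable parameter with its default and rationale,
what the synthetic-data generator does and does not emulate, and the
package's numerical choices (calibration estimator, distance metric,
tie-breaks, rejection rules).
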