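# piRslice

Tools for asking what mouse pachytene piRNAs actually do to mRNAs: which
transcripts they cleave, how efficiently, and why most cleavage barely moves
steady-state RNA levels. The package is aimed at computational biologists
working with matched small RNA-seq, 5'-monophosphate (degradome) RNA-seq,
RNA-seq, ribosome-profiling and GRO-seq data from piRNA-pathway mutants, and
at anyone who wants a fully simulated, ground-truthed sandbox for this class
of analysis.

## What it implements

* **Absolute small-RNA quantification.** UMI-aware adapter trimming and PCR
  deduplication, grouping into 25-nt 5'-prefix species, spike-in
  calibration, and conversion between library ppm, molecules per cell and
  intracellular concentration (1 molecule per 1,800 um^3 spermatocyte
  = 0.92 pM; 1 ppm of 10^7 piRNAs per cell = 10 molecules). Detection
  filters: >= 1 ppm in every control replicate; "ablated" when mean mutant
  abundance <= 0.1 ppm.
* **Abundance-tiered target search.** A site qualifies when any clause
  holds: >= 1 ppm guides with >= 20 nt paired in g2-g25; >= 5 ppm with
  contiguous g3-g15; >= 10 ppm with contiguous g3-g16; >= 50 ppm with
  contiguous g4-g17. Slicing is predicted between the targets of g10 and
  g11, so the 3'-fragment 5' end is t1 - 9. Nearest-neighbour duplex
  free energies, miRNA-like seed matching (g2-g8), and
  ELAVL1-motif/seed/g9-g30 translation candidates are included.
* **Degradome evidence.** 5'-end collapsing, detection at >= 0.1 ppm,
  >= 8-fold loss in mutants (or detection in both genotypes for control
  guides), evaluated over all control x mutant replicate pairings
  (4 x 4 = 16) with per-target support, exclusivity filtering, the
  fraction-cleaved statistic, and the <= 1.25 / > 1.25-fold target classes.
* **Expression statistics.** An authored negative-binomial Wald test
  (median-of-ratios normalisation, trended dispersion shrinkage), strict
  two-allele intersection with minimum-magnitude fold changes, a 3 TPM
  (~10 molecules/cell) floor, translational-efficiency ratio-of-ratios
  tests, and KS / Mann-Whitney / Kruskal-Wallis comparisons.
* **Annotation.** GRO-seq PolII density in ppm/kb excluding the first
  500 bp from the TSS, PhyloP-style conservation over guide positions
  g2-g30 of piRNA genomic origins, and repeat-origin fractions.
* **Kinetics.** The burst-and-steady-state model
  `P_rel(t) = E_rel[(k2/(k2+k3))^2 (1 - e^-(k2+k3)t) + (k2k3/(k2+k3)) t]`
  with a multi-start Levenberg-Marquardt fitter returning a classed object
  (`print`, `summary`, `coef`, `predict`, `plot`, `simulate`, ...).
* **Synthetic data.** A generator that plants piRNA pools, target sites of
  every tier, near-miss decoys, genotype-structured NB counts, degradome
  signals that vanish with the guide's locus, spike-ins, genomic tracks and
  noisy kinetic time courses - with a machine-readable truth table.

## Worked example

A complete simulated study - 100 piRNA species across 10 loci (two deleted
in the mutant), 200 transcripts with 20 planted functional cleavage targets
among 190 complementarity-qualifying sites, 4 + 4 replicates per assay -
runs end to end in a few minutes:

```r
library(piRslice)
cfg <- sim_config(seed = 42)
run <- run_pipeline(cfg)
print(run)
#> piRslice pipeline run (seed 42)
#>   piRNA species kept: 100 (20 ablated in mutant)
#>   qualifying sites: 192
#>   target calls: 20 (precision 1.000, recall 1.000 vs 20 planted)
#>   permutation set size: median 20.0 (IQR 20.0-20.0 over 16 pairings)
#>   KS (log2FC, cleavage evidence required): D = 0.900, p = 1.13e-08
#>   KS (complementarity only): D = 0.193, p = 0.165
#>   kinetics fit: k2 = 0.97, k3 = 0.0505 min^-1
```

Reading the output: the quantifier recovered all 100 species from raw reads
and correctly flagged the 20 piRNAs of the two deleted loci as ablated
(mean mutant abundance <= 0.1 ppm). The scanner found 192 qualifying sites
(the 190 planted ones, none of the 20 decoys, plus two genuine chance
complements). Degradome evidence over the 16 replicate pairings called
exactly the 20 planted functional targets. The two KS lines reproduce the
central asymmetry of this analysis type: requiring a cleavage product makes
the derepression of ablated-guide targets obvious (p ~ 1e-8), while
complementarity alone does not separate target classes (p = 0.165) - most
complementary sites are biologically inert. The kinetic fit recovers the
simulated rates (k2 = 1, k3 = 0.05 min^-1) from a noisy six-point time
course.

Individual stages are ordinary functions (`trim_and_dedup()`,
`group_by_prefix()`, `scan_transcript()`, `permutation_calls()`,
`nb_differential()`, `fit_burst()`, ...) and work on user-supplied tables
in the plain-text formats documented in their help pages.

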