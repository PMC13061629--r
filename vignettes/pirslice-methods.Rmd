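---
title: "Identifying piRNA cleavage targets: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying piRNA cleavage targets: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piRslice)
```

## The problem

Pachytene piRNAs are an extraordinarily abundant class of small RNAs in
mammalian male germ cells: a mouse primary spermatocyte holds on the order of
10^7 piRNA molecules spread over tens of thousands of distinct species whose
concentrations span roughly 0.01-10 nM. PIWI-clade Argonaute proteins loaded
with these guides can slice mRNAs that pair extensively with the guide,
leaving a diagnostic 5'-monophosphorylated 3' cleavage fragment whose 5' end
sits opposite guide position g10. Yet deleting entire piRNA-producing loci
changes the steady-state abundance of remarkably few transcripts. piRslice
implements the computational machinery needed to ask why: absolute
quantification of piRNA species, an abundance-tiered complementarity search,
degradome-based cleavage evidence, negative-binomial differential
expression, transcription-rate and conservation annotation, and
pre-steady-state cleavage kinetics - together with a synthetic-data
generator that plants a known ground truth so that every stage is testable
without any external download.

## piRNA species and absolute quantification

Because 3' trimming leaves piRNA 3' ends heterogeneous, a species is defined
by its 5' 25-nt prefix. Reads carry a 9-nt unique molecular identifier (UMI)
on each side of the insert; `trim_and_dedup()` locates the 3' adapter
(`TGGAATTCTCGGGTGCCAAGG`) by an anchored 8-nt match tolerating one mismatch,
keeps one record per distinct (UMI5, insert, UMI3) triple, and discards
inserts outside 14-54 nt. Species abundances are expressed in parts per
million (ppm) of the kept library. Two filters mirror standard practice:

* a species is *expressed* when it is at >= 1 ppm in **every** control
  replicate (at ~10^7 piRNAs per cell, 1 ppm is ~10 molecules per cell, so a
  Poisson model puts a molecule in >= 99.99% of cells);
* a species is *ablated* in a mutant when its mean mutant abundance is
  <= 0.1 ppm.

All thresholds are applied inclusively, exactly as written.

Absolute quantification has two routes: a spike-in calibration (least-squares
slope through the origin of deduplicated counts versus molecules added), and
the ppm route (ppm x total piRNAs per cell / 10^6). Concentrations use the
median primary-spermatocyte volume of 1,800 um^3, so one molecule per cell
is 1/(1.8e-12 L x N_A) = 0.92 pM, i.e. "about 1 pM".

## The abundance-tiered pairing rules

Guide positions are numbered g1-g30 from the piRNA 5' end; the target
nucleotide paired to g1 is t1 and the duplex is antiparallel, so gi faces
transcript position t1 - (i - 1). A window qualifies as a potential cleavage
site when *any* of four clauses holds, each combining an abundance floor
with a pairing pattern:

| abundance floor | pattern |
|---|---|
| >= 1 ppm  | >= 20 positions paired within g2-g25 |
| >= 5 ppm  | contiguous pairing g3-g15 |
| >= 10 ppm | contiguous pairing g3-g16 |
| >= 50 ppm | contiguous pairing g4-g17 |

"Contiguous pairing between gA and gB" is read as: every position gA..gB is
a Watson-Crick pair, with positions outside the range unconstrained. G:U
wobble counts as unpaired by default (a flag turns it on; it is off in every
shipped analysis). g1 is never required, matching the fact that all four
patterns start at g2-g4; positions beyond g30 are ignored. The reported tier
is the satisfied clause with the lowest abundance floor - a consequence is
that a mask satisfying g3-g16 contiguously always also satisfies g3-g15, so
the g3-g16 clause can only ever be reported for guides between 5 and 10 ppm;
the generator's truth table records the tier the scanner will actually
report, keeping the two in exact agreement. Where several clauses tie at the
same floor the order of the table above decides; since floors are distinct
this never arises in practice.

The predicted cleavage coordinate follows the canonical PIWI/Argonaute
geometry: the scissile phosphate lies between the targets of g10 and g11, so
the 5' end of the 3' fragment is t1 - 9. Coordinates are 0-based half-open
internally (bedGraph/BED semantics) and 1-based inclusive in every
user-facing table.

Duplex stability is summarised by a nearest-neighbour free energy: standard
RNA/RNA Watson-Crick stack parameters summed over consecutive paired
positions, one duplex-initiation term, terminal A:U penalties, and a
configurable per-unpaired-position loop penalty (default 0.4 kcal/mol). This
is a ranking statistic, not an ensemble free energy; a thermodynamics
engine can be substituted where exactness matters.

## Degradome evidence and target calling

5'-monophosphate reads with the same 5' end are merged into one species
(`collapse_five_prime()`), normalised per replicate library. A predicted
site is *detected* when the control signal at the exact predicted coordinate
is >= 0.1 ppm (a +/- 1 nt tolerance is available but off by default; the
data the package targets have nucleotide-exact 5' ends). For guides from
deleted loci, evidence requires detection plus a >= 8-fold decrease in the
mutant, computed with a 0.01 ppm pseudocount; for retained ("control")
guides, detection in both genotypes. Because the study design crosses every
control replicate with every mutant replicate, evidence is evaluated over
all n_c x n_m pairings (16 for 4 + 4); a target's support is the number of
pairings it passes, and set sizes are summarised by median and IQR across
pairings. Whether the 8-fold rule is applied per pairing or on means is an
option; per-pairing is the default as it matches the permutation design.
`call_targets()` additionally enforces exclusivity - a site that a
qualifying retained-locus guide could also explain is removed from the
ablated-locus set - joins the expression results, computes the fraction
cleaved (mean control product ppm over the target's steady-state abundance,
unclipped), and classifies targets into <= 1.25-fold versus > 1.25-fold
steady-state increase (the boundary falls in the <= class).

## Differential expression and the distribution-level tests

The negative-binomial Wald test is authored here rather than delegated:
median-of-ratios size factors; per-feature method-of-moments dispersion on
normalised counts, shrunk in log space toward a 1/mean trend (trend weight
`prior_df`, default 10); delta-method standard error of the log2 ratio of
group means; standard-normal reference; Benjamini-Hochberg FDR. Features
below 3 TPM in control are excluded before testing - at ~3.4e6 transcripts
per primary spermatocyte, 3 TPM is ~10 molecules per cell, the same
detectability argument as the 1 ppm piRNA floor. The contract of this module
is calibration and power on synthetic data (null false-call rate at
FDR < 0.01 at most twice nominal; a planted 2-fold change at dispersion
0.05 with 7-8 replicates recovered), not numerical identity with any
external package; an installed NB framework is used as an independent
cross-check in the test suite.

To guard against line-specific (e.g. CRISPR off-target) artifacts, mutants
carry two alleles; only changes significant (FDR < 0.01) in both alleles
with the same sign are called, and the reported fold change is the smaller
in magnitude - the absolute minimum of the two alleles.

Translational efficiency is ribosome-footprint TPM over RNA TPM; the
differential test works on the ratio of ratios, log2 dTE = log2FC(RFP) -
log2FC(RNA), with the two Wald variances added. Features under 10 TPM of
control ribosome occupancy are excluded. The methodology beyond the
thresholds is not prescribed by the source analyses, so this ratio-of-ratios
NB approach is a documented design choice validated by null calibration.

Distribution-level comparisons use the two-sample two-tailed
Kolmogorov-Smirnov test and the two-tailed Mann-Whitney test (exact for
groups of <= 8 without ties, tie-corrected normal approximation otherwise),
plus a Kruskal-Wallis convenience wrapper with BH-corrected pairwise
follow-up.

## Genome annotation

GRO-seq PolII density is read coverage over the gene body, excluding the
first 500 bp downstream of the TSS (strand-aware) to remove paused
polymerase, normalised as reads / depth x 10^6 / kb (ppm per kb). The
unspliced gene span is used, as nascent-RNA coverage is intronic as well as
exonic. Conservation profiles take per-base scores (e.g. PhyloP) at the
genomic bases of guide positions g2-g30 of each piRNA origin, strand-aware,
summarised per piRNA by the median and per cohort by median and IQR, with a
helper to sample fixed-length background segments (for example 29-nt
segments from CDS annotation). Repeat origin is the fraction of piRNA
origins overlapping a repeat by >= 1 bp (a majority-overlap rule is
available); whether densities should use unique-mapping reads only is an
upstream alignment choice outside this package's scope.

## Cleavage kinetics

Single-turnover piRISC time courses follow the burst-and-steady-state
scheme E + S <=> ES -> EP -> E + P (rapid-equilibrium binding; k1 and k-1
are not identifiable from product curves and are not fitted):

P_rel(t) = E_rel [ (k2/(k2+k3))^2 (1 - e^-(k2+k3)t) + (k2 k3/(k2+k3)) t ]

with burst amplitude E_rel (k2/(k2+k3))^2 and steady-state slope
E_rel k2 k3/(k2+k3). A duplicated E_rel factor sometimes seen in typeset
versions of this equation is a typesetting artifact; the standard derivation
has a single factor, which is what `burst_model()` implements. `fit_burst()`
runs Levenberg-Marquardt least squares on log-rate parameters from a 5 x 5
log-spaced multi-start grid (k2, k3 in 10^-3..10^2 min^-1) to avoid local
minima, and flags non-identifiability when a 95% confidence interval of a
rate spans more than two decades (e.g. curvature-free data that never leave
the burst phase). Times are minutes throughout; hour-scale experiments are
converted on input. The fit is a classed object with the usual
`print`/`summary`/`coef`/`predict`/`residuals`/`plot`/`simulate` methods.

```{r kinetics, fig.width = 5, fig.height = 4}
tc <- gen_kinetic_timecourse(k2 = 1, k3 = 0.05, e_rel = 0.5,
                             noise_sd = 0.01, seed = 7)
fit <- fit_burst(tc)
fit
plot(fit)
```

## What the synthetic data emulates - and what it does not

The generator is first-class, tested code, and its defaults *are* the study
conditions used by the acceptance analyses: 100 piRNA species over 10 loci
(two deleted in the simulated mutant), 200 transcripts, 4 + 4 small RNA
replicates at 10^6 reads, 4 + 4 degradome replicates at 10^7 reads, RNA-seq
with 4 controls versus 2 + 2 mutant allele replicates, and seed 42 for the
demonstration run. Design choices worth knowing:

* **Abundance law.** Species means are log-normal (sdlog 1.5). With ~10^2
  species forced to sum to 10^6 ppm, absolute ppm run higher than in a real
  cell with ~8 x 10^4 species; the *span* (about three decades, matching the
  0.01-10 nM range after conversion) is what the tier rules exercise. The
  true empirical abundance distribution's shape is unknown beyond its range,
  so log-normal is a stand-in, exposed in the configuration.
* **Planted sites.** 20 functional targets (ablated-locus guides; cleavage
  efficiency uniform on 0.05-0.5), 130 ablated-locus bystander sites that
  qualify by complementarity but are sliced at a negligible rate
  (efficiency < 2e-5 - bound but not productively cleaved), 20 cleaved
  sites of retained-locus guides (the control-piRNA target set), 20
  retained-locus bystanders, 10 seed-only sites, and 20 near-miss decoys
  (one fewer paired base than their pattern requires). This makes functional
  sites a small minority of complementarity-qualifying sites, the
  scaled-down analogue of the real ~1% fraction, which is what lets the
  "complementarity without cleavage evidence" comparison come out null.
* **Derepression.** fold = 1 + 4 x efficiency, coupling slicing efficiency
  to the steady-state effect; across the planted efficiency range this spans
  ~1.2-3-fold with a median near 2-fold and induces the <= 1.25 / > 1.25
  class structure used by the fraction-cleaved and PolII comparisons.
* **Small-RNA ablation.** Deleting a locus removes its precursor, so
  ablated species drop to an absolute residual (uniform on 0-0.05 ppm)
  rather than a proportional fraction: with only ~100 species sharing the
  library, any proportional reduction would leave abundant species far above
  the 0.1 ppm "undetectable" line.
* **Degradome.** Cleavage products appear at the exact predicted coordinate
  with Poisson mean efficiency x 40 ppm; genotypes lacking the guide's locus
  keep 1/100 of the signal (deliberately not zero, so the detection and
  fold filters are exercised rather than trivialised). A uniform Poisson
  background of 5 x 10^-5 of the library is spread over all transcript
  positions; at 10^7 reads a single background read is exactly 0.1 ppm, so
  isolated background never *exceeds* the detection threshold.
* **Counts.** NB dispersion 0.02, appropriate for FACS-purified,
  developmentally homogeneous cell populations; baseline expression
  log-normal (meanlog log 400, sdlog 0.6). Translational efficiency is
  genotype-independent by construction - the translation analyses are null
  tests.
* **Problem sizes.** The demonstration study (200 transcripts, 10^6-10^7
  reads, 2,000-gene calibration simulations, 100 kinetic refits) was chosen
  so a complete run finishes in a few minutes on one CPU while every filter
  still operates away from its degenerate regime.

What passing tests on these data do **not** show: robustness to alignment
artifacts, multimapping, sequencing error, 3' non-templated tailing,
isoform ambiguity, or mis-annotated transcript models - the generator
simulates none of these (alignment itself is out of scope; the pipeline
consumes transcript-coordinate tables). Real degradome background is also
structured (exonuclease stalling, abundant decay intermediates), not
uniform; the uniform null is the simplest model that makes the 0.1 ppm
threshold meaningful.

## Numerical choices and degenerate inputs

Thresholds are inclusive as printed (>= 1 ppm, <= 0.1 ppm, >= 0.1 ppm,
>= 8-fold, FDR < 0.01 strict). Fold changes use a 0.01 ppm pseudocount.
Dispersion estimates are floored at 1e-8; size factors require at least one
feature with nonzero counts in every sample and suggest a pseudocount
otherwise. Empty inputs return empty, well-typed tables. The multi-start
kinetic fit reports the best converged start and errors only if every start
fails; ties among pairing clauses cannot occur because the abundance floors
are distinct. Seeds are mandatory in the simulator configuration, every
generator derives independent substreams from the one seed, and the
pipeline manifest records a hash of the configuration plus checksums of all
written files, so identical inputs reproduce identical outputs byte for
byte.

## Known limitations

The NB test's dispersion moderation is deliberately simple (trend +
log-space shrinkage) and is validated by calibration, not by equivalence
with heavier machinery; at 2 replicates per allele its power is limited,
which is faithful to the underlying design. The duplex free energy ignores
dangling ends and coaxial stacking. The exclusivity rule compares exact
predicted coordinates; a guide pair whose sites differ by 1 nt would both
survive. `seed_targets()` reports perfect g2-g8 7-mers only - no offset
6-mers - and the translation-candidate motif set defaults to the canonical
AU-rich element `AUUUA` alone.
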