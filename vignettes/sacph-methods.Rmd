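---
title: "Methods: pH-controlled sAC analysis in sacph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pH-controlled sAC analysis in sacph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sacph)
```

# Scientific background

Soluble adenylyl cyclase (sAC) synthesizes the second messenger cAMP. In
mammals the enzyme is activated by bicarbonate, which is coordinated in the
human enzyme by two positively charged residues, K95 and R176. In sperm of
marine invertebrates and fish, one or both of these residues are replaced by
neutral ones (sea urchin: K/N, salmon: N/R, written as the residues at the
positions homologous to K95/R176), and the enzyme responds to intracellular
pH instead: alkalization, not bicarbonate, switches on cAMP synthesis. This
package implements the computational side of that analysis chain:

1. **orthosite** — reference-anchored genotyping of the bicarbonate site
   across ortholog sequences;
2. **kinetics** — reduction of cAMP assay plates to activities, turnover
   numbers, fold-changes and rank statistics;
3. **flagellum / cascade** — the flagellar cAMP budget and a deterministic
   model of the spawning cascade (membrane potential → intracellular pH →
   cAMP → motility);
4. **motility** — frame-subtraction and tracking analysis of dark-field
   sperm movies;
5. **synth** — seeded generators that produce every input the other modules
   consume, with machine-readable truth tables.

# Sequence genotyping

Queries are aligned to a human-numbered reference by global pairwise
alignment with affine gaps (Needleman–Wunsch–Gotoh). Defaults are BLOSUM62
with gap open −11 and extend −1; a gap run of length $L$ scores
$\mathrm{open} + (L-1)\,\mathrm{extend}$, terminal gaps are penalized, and
the traceback is deterministic (diagonal preferred, then gap in the query).
Unknown residues (`X`) score zero against everything and never count as
identities. Percent identity defaults to aligned columns excluding terminal
gap runs, because published pairwise identities rarely state their
denominator; the other policies are available behind a switch.

Site mapping carries a reference position through the alignment and fails
(returns absent) when the position sits opposite a gap; genotype labels
write an unmapped site as `-`, which counts as non-positive when classifying
charge. The survey aggregates per-clade counts and fractions and can carry
presence-only rows for species whose genomes lack a sAC gene.

**Reference caveat.** The packaged reference
(`inst/extdata/hs_sac_synthetic.fasta`) is a *synthetic stand-in*: the
bicarbonate-site residues, catalytic residues and the two β2/3 loop motifs
(AGD at 97–99, FDKG at 338–341) are planted at the human coordinates, but
the remainder of the sequence is random. All coordinate conventions are
therefore exercised faithfully, while alignments to natural orthologs of the
real protein require the user to supply the real reference FASTA. For the
same reason the published cross-species residue correspondences (e.g. human
176 → sea urchin 198) are covered here by planted synthetic fixtures rather
than by the natural accessions, which are not shipped.

# Plate kinetics

Readings are converted to cAMP through a four-parameter logistic standard
curve on the log-concentration axis. Initialization uses the data quartiles
(asymptotes from the extremes, midpoint at the half-range crossing) followed
by Levenberg–Marquardt refinement; the self-starting initializer in base R
was not used because it fails on zero-residual calibrators. The inverse is
defined only between the fitted asymptotes; readings outside are flagged,
not extrapolated.

Activity is cAMP per reaction time (pmol min⁻¹); the turnover number divides
further by the enzyme amount, giving mol cAMP per mol sAC per second.
Fold-changes default to the ratio of condition means (the bar-chart
convention), with median-of-ratios as an alternative. The pH profile
descriptor orders (pH, k) points and flags interior peaks and troughs, which
is how the biphasic pH dependence (first peak near pH 7.0, trough at 7.2,
surge above 7.8) is detected programmatically.

Comparisons use the Mann–Whitney U test — exact by complete enumeration of
group assignments for combined n ≤ 12 (this handles ties, which the exact
mode of `wilcox.test` does not), tie-corrected normal approximation with
continuity correction otherwise — and the Kruskal–Wallis test with Dunn's
post hoc z tests. Multiplicity control is Benjamini–Hochberg throughout,
including for Dunn's test, chosen for consistency with the mutant-panel
analysis. Note that FDR control at q = 0.05 still admits occasional false
flags among truly unchanged mutants; the tests assert detection of planted
effects and a bounded false-flag rate, not zero false flags.

# Flagellar budget and spawning cascade

The budget arithmetic is exact: 7000 sAC molecules stepping from the
measured MgATP turnover at pH 7.2 (0.035 s⁻¹) to that at pH 8.0 (0.106 s⁻¹)
add $7000 \times 0.071 = 497$ molecules s⁻¹. In the 2 fL flagellum one
molecule is 0.830 nM exactly ($1/(N_A \cdot 2\,\mathrm{fL})$); the rounded
1 molecule ≡ 1 nM convention used in back-of-envelope prose is an explicit
opt-in flag, never the default. Steady state under hydrolysis with time
constant τ is $s\,\tau$ molecules; with τ = 0.35 s this is ≈ 144 nM, within
the sensitivity window of PKA ($K_D$ = 2–10 nM) and HCN channels
($K_{1/2}$ = 0.74 µM), whose occupancies follow a Hill curve.

The cascade model is an artifact definition — the experiments constrain the
order and rough timing of events, not a differential-equation form — so the
simplest forms consistent with the physiology were chosen and every constant
is exposed in `cascade_params()`:

* $V_m$ relaxes first-order toward the K⁺ Nernst potential. Internal K⁺ is
  not measured; 160 mM gives a resting potential near −45 mV in seminal
  fluid (27 mM K⁺) at 18 °C and ≈ −70 mV after the drop to 10 mM.
* The Na⁺/H⁺ exchanger SLC9C1 is a threshold gate, open while
  $V_m < -55$ mV (between the resting and hyperpolarized potentials).
  While open, pH$_i$ relaxes first-order from 6.84 toward 7.2.
* cAMP follows $\dot c = N\,k(\mathrm{pH}_i) - c/\tau$ with the piecewise
  linear pH–activity curve; anchors at pH 6.7/7.0 are not printed and are
  set from the narrative shape (baseline, twofold peak) relative to the
  measured pH 7.2 value.
* Motility switches on when PKA occupancy stays above a threshold (0.92)
  for a phosphorylation delay (25 s).

With the default alkalization time constant (100 s) and delay, motility
onset lands near 40 s after mixing and the event order is
hyperpolarization < alkalization < cAMP half-rise < motility onset; raising
external K⁺ to 30 mM instead of dropping it keeps the gate closed and
suppresses every downstream event, reproducing the experimental control.
The measured bulk cAMP rise (baseline 0.23, plateau
15.1 pmol per 10⁸ cells, half-time ≈ 50 s) is a population-level
biochemical measurement; it is carried by the trace generator and fitted
with `fit_halftime()`, not identified with the fast flagellar free-cAMP
kinetics of the model. The printed baseline and plateau imply a ≈ 66-fold
rise although the source text calls it fivefold; both printed numbers are
stored as-is and not reconciled.

The integrator is fixed-step explicit Euler (default dt = 10 ms, ≪ the
fastest time constant, 350 ms); halving the step changes the trace by well
under 1% (tested), and no randomness is involved. Photorelease of caged
cAMP uses a saturating form $c_{max}(1 - e^{-\alpha E})$ anchored to the
calibrated 5.3–342 nM window; latency comes from a first-order
phosphorylation variable driven by PKA occupancy of the decaying cAMP step,
which makes latency non-increasing in dose and ≈ 100 ms at saturation.

# Movie analysis

Frames are thresholded by Otsu's method on the normalized histogram (a
constant frame yields an empty mask), which makes the scores invariant to
global intensity scaling. The global motility score counts pixels that
change between consecutive binarized frames and normalizes the mean count by
the mean *raw* intensity of the stack as a sperm-density proxy. Per-cell
analysis detects connected components above a small area cutoff, links
centroids frame-to-frame by nearest neighbour within 3 cell diameters, and
calls a cell motile when its displacement from start exceeds 2 diameters
within the analysis window; displacement is evaluated along the track so a
cell that moves and is later lost is still classified. Response latency is
the first post-flash time the per-frame displacement exceeds half a cell
diameter on at least two consecutive frames; the run requirement rejects
single-frame centroid jumps that occur when a passing cell's blob briefly
merges with a static one. These thresholds are declared assumptions — the
original analysis software is unspecified — and all are arguments.

# Synthetic data

Noise families are fixed once: lognormal for plates (multiplicative assay
noise), Gaussian for traces and titrations, Poisson for images. Every
generator takes an explicit seed, restores the caller's RNG state, and
reproduces byte-identical output for the same seed and preset. Presets
encode the study conditions: activation ratios (e.g. 5.4-fold for
full-length sea urchin sAC with Mg²⁺, n = 3, 10% CV), the per-pH turnover
samples (0.035 ± 0.013 at pH 7.2, n = 17; 0.106 ± 0.041 at pH 8.0, n = 20),
the resting pH$_i$ titration (truth 6.84; ΔF noise calibrated so the
replicate-mean dispersion matches the reported ± 0.02 for n = 3), the bulk
cAMP trace, and the motility movies (740 cells at motile fraction 0.875
across three fields; 429 cells with 412 responders for photorelease,
emulated as three fields of view at realistic density because the reported
counts pool several experiments).

What the movies emulate — point-like cells, persistent random-walk
swimming, shot noise — deliberately omits flagellar shape, motion blur,
uneven illumination and focus drift. Passing tests therefore demonstrate
correctness of the estimators against a controlled ground truth, not
robustness to every artifact of real recordings. Likewise the sequence
generator plants genotypes into a mutated copy of the reference; it does not
model real evolutionary divergence, so survey recovery rates quantify
alignment robustness to indels, not ortholog-detection performance.

# Problem sizes and numerical choices

The shipped tests and the acceptance script run at the study's own sizes
wherever they are small (n = 3 plates, n = 20 turnover replicates, 3
titrations, 3 movies with 740 cells) and use reduced fields of view
(320–400 px) chosen so that blob-merging between neighbouring cells stays
rare. Degenerate inputs are defined rather than left to chance: empty masks
for constant frames, flagged out-of-range readings, `NA` for unmapped sites,
p = 1 with a flag for fully tied samples, and bracket-failure flags for
titrations without a sign change.

# Known limitations

* The natural sequences of the studied accessions are not shipped; the
  packaged reference is synthetic and labelled as such, and cross-species
  position mappings are validated on planted fixtures only.
* The cascade model's rate constants are assumptions exposed as parameters;
  only the event ordering and the controls are constrained by data.
* Mn²⁺ turnover scales and the bicarbonate-era literature values are stored
  where printed but are not modelled; Mg²⁺ is the quantitative backbone.
* The tracker is a nearest-neighbour linker adequate for sparse fields; it
  is not a multi-hypothesis tracker and will undercount in dense or
  fast-crossing scenes.
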