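---
title: "Mutational signature dynamics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutational signature dynamics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mutsigdyn` quantifies the activity, timing and chromatin context of somatic
mutational processes across the stages of oesophageal adenocarcinoma
development — from Barrett Oesophagus through primary tumour to metastasis —
and bundles a ground-truth synthetic cohort generator so that every stage of
the pipeline can be validated by parameter recovery. This vignette is the
package's own account of the underlying models: what is assumed, which knobs
matter, where the design was genuinely open and which option we took, and
what the tests do and do not demonstrate.

## 1. Signature refitting

A sample's mutation spectrum is a count vector over the 96 pyrimidine-centred
trinucleotide substitution channels (or 83 indel channels). Given a reference
matrix $S$ of per-channel signature probabilities, exposures are estimated in
four stages (`fit_exposures()`):

1. non-negative least squares of the normalized spectrum on $S$
   (Lawson–Hanson, via `pracma::lsqnonneg`);
2. normalization of the weights to sum one;
3. pruning: every weight below the threshold (default **0.05**) is set to
   exactly zero;
4. restricted NNLS refit on the surviving signatures, renormalized.

The 5% threshold reflects a practical detection limit: contributions that
small are unstable between variant callers and fitting methods, so they are
treated as absent rather than reported as noise. The same 5% rule drives the
repair-deficiency calls (`call_deficiencies()`): homologous-recombination
deficiency requires SBS3, SBS8, ID6 **and** ID8 each above 5% (the strictest
reading of the conjunction; the rule set is overridable for users who prefer
an either/or on the indel evidence), colibactin exposure requires SBS41 +
ID18, and mismatch-repair deficiency requires SBS44. The reconstruction
residual (Euclidean norm between observed and reconstructed normalized
spectra) is reported per sample for QC.

We deliberately use NNLS + threshold + restricted refit rather than a
forward-selection heuristic: it honours the same contract (non-negative
contributions, small-signature pruning) while being convex, deterministic and
checkable against a grid-search oracle over the weight simplex — which the
test suite does at 0.01 resolution.

**Bundled reference.** COSMIC signature profiles are external data that this
package does not redistribute. `synthetic_signature_reference()` builds a
deterministic *synthetic* stand-in: SBS1-like (CpG C>T), APOBEC-like (TpC),
SBS17a/b-like (T>C and T>G at NpTpT) and slippage/microhomology-style indel
profiles are hand-sketched to carry the field's qualitative character, and
the remaining signatures are sparse random profiles fixed by an internal
seed. Rules and groupings that operate on signature *names* (deficiency
calls, SBS17 dominance) are therefore exercised faithfully, but the profiles
themselves are not the COSMIC vectors — any real-data analysis should load a
real reference with `read_signature_matrix()`.

## 2. Clonality and timing

For a mutation with variant allele fraction $f$ in a segment with
allele-specific copy number $(n_{maj}, n_{min})$ in a tumour of purity
$\rho$, the locus-level expected copy number is
$N = \rho (n_{maj} + n_{min}) + 2(1 - \rho)$, the multiplicity is
$m = \mathrm{clamp}(\mathrm{round}(f N / \rho), 1, n_{maj})$, and the cancer
cell fraction is $\mathrm{CCF} = f N / (\rho m)$. CCFs are capped at 1.25
(an overflow flag is kept; the uncapped value feeds the dip test so that a
cap-induced atom cannot masquerade as a mode).

**Unimodality testing.** "Purity-corrected VAF" is interpreted as the CCF
with per-mutation multiplicity — the only correction that puts mutations
from different copy-number states on a comparable scale. Deviation from
unimodality is measured by a dip statistic built from the
greatest-convex-minorant / least-concave-majorant band construction: for
each candidate mode the empirical CDF band is approximated by a CDF convex
to the left and concave to the right of the mode (an atom is allowed at the
mode itself), and the statistic is the best achievable sup-distance,
minimized over modes. It is implemented in C++ with an incremental hull and
validated against a brute-force enumeration over mode placements. The
p-value is Monte Carlo against the uniform reference null —
$p = (1 + \#\{d_{null} \ge d\})/(1 + n_{ref})$, ties counted in favour of
the null, $n_{ref} = 2000$ by default. The uniform is the classical least
favourable unimodal null: on uniform data the test is exactly calibrated
(the suite checks a type-I error of 0.05 ± 0.03), while on peaked unimodal
data it is conservative — a deliberate property, since a false subclone is
costlier downstream than a missed one. The null distribution depends only on
the sample size, so `analyze_clonality()` can share `dip_null()` tables
across equal-sized samples.

**Subclonal decomposition.** Samples with dip $p < 0.05$ get a two-component
Gaussian mixture on CCFs (EM; k-means initialization from the quartiles;
tolerance $10^{-6}$; at most 500 iterations; variance floor $10^{-4}$). The
component with mean nearer 1 is clonal; the other's weight is the subclonal
fraction; a mutation is subclonal when its posterior exceeds 0.5, with ties
broken to clonal. A collapsing component (weight < 0.01, or coincident
means) reverts the sample to fully clonal with a flag.

**Timing.** Deterministic rules, whole-genome-doubling aware: subclonal
mutations keep their mixture label; clonal mutations in segments with
$n_{maj} \ge 2$ are *early* if $m \ge 2$ and *late* if $m = 1$; clonal
mutations at $n_{maj} = 1$ (or without copy-number information) are
*clonal-other*. WGD is called when more than half the segment-covered genome
has $n_{maj} \ge 2$ and ploidy exceeds 2.9. We use point estimates with
binomial clamping instead of bootstrapped probabilistic assignment: the
label semantics are identical, and at 50x depth the deterministic rule and a
bootstrap majority vote differ only for mutations whose multiplicity is
genuinely ambiguous.

## 3. Nucleosome periodicity

Mutations are stacked at signed offsets from nucleosome dyad centres
(±72 bp zoom-in; ±1000 bp zoom-out), each mutation contributing at every
qualifying (mutation, dyad) incidence. The null model re-places each
mutation uniformly among indexed positions sharing its canonical
*pentamer* context — conserving the pentamer multiset exactly, and with it
the sequence-composition biases that dominate raw mutation-rate profiles.
The expected profile is the mean of the randomized profiles (chosen for
unbiasedness; the aggregation is otherwise arbitrary), and the relative
increase $r(x) = (\mathrm{obs} - \mathrm{exp})/\mathrm{exp}$ is the signal.

The periodogram is an explicit oversampled DTFT,
$P(T) = |\sum_x r(x)\, e^{-2\pi i x/T}|^2$ over a 5–50 bp period grid at
0.01 bp: a plain DFT on 145 offsets cannot separate a 10.3 from a 10.15 bp
repeat, so oversampling is required, and the direct sum over ~145 offsets is
cheap enough that no FFT is needed (the suite checks it against a naive
complex-sum oracle at $10^{-9}$). $r(x)$ is mean-centred before the
transform to suppress the zero-frequency term; zoom-out profiles are
additionally detrended by subtracting a 50 bp moving average, which removes
the linker-scale trend that otherwise dominates low frequencies. The SNR is
the peak power divided by the *median* band power excluding ±0.5 bp around
the peak — median rather than mean so that harmonics and secondary peaks do
not inflate the background.

The empirical p-value re-runs the identical chain on each randomization. One
subtlety makes the null exact: each randomization's relative increase is
computed against the leave-self-out mean *including the observed profile*,
while the observed profile uses the mean of all randomizations. Observed and
randomized SNRs are then exchangeable under the null, so
$p = (1 + \#\{SNR_i \ge SNR_{obs}\})/(1 + n_{rand})$ is exactly (discretely)
uniform — the suite verifies uniformity under uniform mutagenesis with a KS
test across 200 replicates.

Strand analyses use fixed, documented conventions: a mutation is
*transcribed-strand* when its pyrimidine lies opposite the overlapping
gene's coding strand; in a right-replicating domain the reference "+" strand
is taken as the lagging-strand template. Strand bias is a log2 count ratio
(continuity-corrected when a count is zero) with a two-sided exact binomial
test.

## 4. Genome alterations

Gene-level copy-number classes use the segment with maximal overlap of the
gene (deterministic, matching the granularity of the input rather than
averaging across breakpoints): amplification when total copy number is at
least twice the sample ploidy, deletion when at most half, LOH when the
minor allele count is zero (LOH does not additionally require total loss).
SNV/indel events count when an overlapping variant's upstream consequence
annotation matches a configurable allow-list (missense, nonsense,
frameshift/in-frame indels, initiator/terminal-codon, UTR and TF-binding
variants by default); the package computes no annotation of its own.
Pathways are flagged per class when any member gene is flagged, with
per-class altered fractions ordered by deletion fraction.

The chromosomal-instability score counts segments whose total copy number
differs from the *rounded sample ploidy* and which span more than 5% of
their chromosome. Using ploidy rather than 2 as the baseline is a
considered choice: with a diploid baseline a whole-genome-doubled tumour
would score on every segment and the score would saturate. The raw counts
are Z-scaled across the cohort (zero-variance cohorts get z = 0). The
proliferation score is $1 - QS$, where $QS$ is the arithmetic mean of the
G0-arrest markers' cohort Z-scores — the mean (rather than a weighted
combination) keeps the score interpretable: a sample at the cohort mean on
every marker scores exactly 1.

## 5. Dynamics and stage classification

Per-sample subclonal shifts are $\Delta = $ subclonal $-$ clonal exposure per
signature, computed from *raw* per-compartment refits (thresholding before
differencing would censor exactly the small changes of interest; the
threshold remains available for users who want pruned compartments).
Compartments with fewer than 50 mutations are excluded — exposure estimates
below that are too unstable to difference. Group comparisons are two-sided
Wilcoxon rank-sum (unpaired) or signed-rank (paired) tests with optional
Benjamini–Hochberg correction across the tested family; all-tied strata
report p = 1 with a flag. "SBS17 dominant" means SBS17a + SBS17b exposures
strictly exceed 0.5.

Stage classifiers take either overall signature exposures (plus subclonal
and early fractions) or signature-by-compartment features. The pipeline is
a stratified 70/30 discovery/validation split, hyperparameter selection by
repeated k-fold cross-validation on the discovery set (5 folds; the
repetition count is configurable — 100 for a full run, small values for
quick checks), a final refit, one-vs-rest macro-averaged AUC on the held-out
set, and *permutation* feature importance (mean held-out AUC drop over
permutations of each feature). Permutation importance replaces Shapley-value
attribution: it is model-agnostic, dependency-light and preserves the
ranking intent. Learners (gradient boosting, random forest, multinomial
glmnet) are pluggable behind a documented `train`/`predict` contract.

## 6. The synthetic cohort generator

The generator defines the study conditions for every recovery test:

- **Genome**: i.i.d. bases at GC 0.40, 1 Mb default — synthetic rather than
  a real reference so the package is fully self-contained; every
  trinucleotide context is guaranteed to exist at moderate GC.
- **Chromatin**: dyads every 197 bp (147 bp core + 50 bp linker, textbook
  nucleosome repeat) with U(−10, 10) bp jitter; genes tile ~50% of the
  genome on alternating strands; replication domains alternate direction.
- **Mutations**: signature-first sampling (clone → compartment exposures →
  channel → uniformly among matching genomic contexts), 5000 SNVs and 200
  indels per sample, depth 50x (Poisson per site, binomial alt reads at the
  expected VAF), purity U(0.3, 0.95).
- **Clonal structure**: half the samples carry one subclone (CCF U(0.25,
  0.6), weight U(0.2, 0.45)); exactly one clone has CCF 1.
- **Periodic planting**: positions within ±73 bp of a dyad accepted with
  probability ∝ $1 + A\cos(2\pi d/T)$ — the simplest generative model whose
  periodogram peak sits exactly at the planted period. Defaults: amplitude
  0.6; periods 10.3 bp (bulk) and 10.15 bp (SBS17b-specific), the helical
  repeat values the field reports for nucleosomal mutation periodicity.
- **Indels**: channel-first sampling against engineered context sites
  (homopolymers, tandem repeats, microhomology tracts with guard bases)
  embedded at generation time, so every ID-83 channel is realizable and
  round-trips exactly through the classifier.
- **Copy number**: 1+1 background (2+2 for WGD samples, drawn with
  stage-dependent probability) with planted events overlaid; ploidy is the
  length-weighted mean total copy number.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: realistic human chromatin maps, germline variation,
sequencing-error and FFPE artefact signatures, mapping noise, kataegis,
structural variation, more than two clones, and real COSMIC profiles.
Recovery results demonstrate the *correctness* of the estimators under the
stated model, not their robustness to every failure mode of real tumours.

## 7. Problem sizes and numerical conventions

The test suite runs at deliberately desk-scale sizes chosen as the smallest
that exercise each statistical property: 1 Mb genomes with 20,000 stacked
mutations and 200 randomizations for periodicity recovery (the planted
period is recovered within ±0.2 bp); 50 samples x 5000 SNVs for exposure
recovery (MAE < 0.05); 200 x 300-value samples for dip-test calibration;
30 samples x 4000 SNVs for the planted −0.2 subclonal shift (recovered
within ±0.05 median); 200 replicates at 200 randomizations for the
empirical-p null calibration.

Conventions worth knowing: all internal coordinates are 0-based half-open
with conversion only at I/O boundaries (VCF and segment TSVs are 1-based on
disk, BED is 0-based); indels are left-aligned and minimally represented
before ID-83 classification, with repeat context taking precedence over
microhomology; ambiguous (N-containing) trinucleotides drop an SNV from the
catalogue with a counted warning, and pentamer-ambiguous sites are excluded
from periodicity; readers reject malformed input rather than coercing it.

## 8. Known limitations

- The dip test is conservative for peaked unimodal CCF distributions;
  weak subclones (CCF separation ≲ 0.3 at 50x) are routinely missed.
- Per-compartment exposure estimates shrink observed subclonal shifts
  slightly toward zero when mutation labels are imperfect; at the default
  depths this bias is well inside the ±0.05 recovery tolerance.
- The CIN score depends on the segmentation granularity of the input; it is
  comparable within a cohort processed uniformly, not across pipelines.
- `simulate_cohort()`'s clinical covariates (treatment, smoking, Mandard
  TRG, survival) are independent draws — sufficient as plumbing for
  interface tests, but carrying no planted associations.
- The stage classifiers are sanity-checked (separable → AUC 1, permuted →
  0.5, planted effect → > 0.9); no claim is made about clinically meaningful
  discrimination on real cohorts.
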