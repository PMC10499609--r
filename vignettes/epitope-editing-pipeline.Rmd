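---
title: "Models and methods behind the epitope-editing pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the epitope-editing pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models, the tunable parameters,
the synthetic-data generators and the numerical choices in `epiedit`. It
states no empirical result beyond what the package's test suite and
`scripts/acceptance.R` themselves compute.

## The problem

A therapeutic antibody recognizes a small surface patch (epitope) on a
receptor such as FLT3, KIT or CD123. If one or two amino-acid
substitutions abolish antibody binding while leaving ligand binding and
signalling intact, those substitutions can be installed in healthy donor
cells by base editing, making them invisible to the corresponding CAR T
cells or antibody-drug conjugates. The pipeline has four stages:
find candidate substitutions (library design + sort-seq screen), find
guides that install them (base-editor nomination), quantify what editing
actually did (amplicon layer), and establish safety and binding
consequences (off-target statistics, RNA editing, affinity curves).

## Library design

A `library_spec` is an in-frame reference ORF plus, per variable
position, a set of allowed codons. Two modes are supported:

* **combinatorial** — every variable position carries the reference codon
  or exactly one alternative (the built-in FLT3 ECD4 spec swaps human
  against murine codons at 16 positions, residues 354-419, giving
  2^16 = 65,536 assignments);
* **degenerate_scan** — every scanned position admits all 64 codons (the
  built-in KIT ECD4 spec scans residues 314-381).

Degenerate codons are emitted expanded — 64 concrete records per position
rather than a single IUPAC "NNN" string — so read simulation and
round-trip tests are exact. Enumeration order is lexicographic (first
position most significant, codons alphabetical) to keep outputs stable.
Stop codons arising in a scan are retained but flagged
(`has_stop()`): a truncated receptor cannot be surface-stained, so stop
variants are excluded from enrichment denominators downstream.

Protein coordinates are construct-local 1-based; each spec carries a
`numbering_offset` so outputs use the published residue numbering (e.g.
N399D rather than N46D). The built-in ORFs are synthetic stand-ins: the
variable-position residue identities and the Asp alternative at FLT3
position 399 are the published ones, but the surrounding sequence (and
the murine residues other than 399D) are representative placeholders,
because the codon-optimized construct sequences themselves are not
public. Every computation in the package depends only on the positions
and residue identities, not on the filler sequence.

## Sort-seq screen analysis

`process_reads()` requires the exact 5' anchor, then the exact 3' anchor;
the segment between them must have exactly the reference ORF length,
otherwise the read is discarded as an indel read. For a fixed-length
design this length criterion detects every 1-nt indel without alignment.
Anchor matching is exact by default so counts are reproducible; a
Hamming-1 option exists but is off. Reads are translated with the
standard genetic code and aggregated by protein sequence; the
conservation identity `aggregated + discarded = input` always holds.

Enrichment is scored at the substitution level: the reads of every
(stop-free) variant carrying a substitution are pooled, so
multi-substitution variants from the combinatorial library contribute to
each of their substitutions. With pseudocount $a$ (default 0.5 reads)
and $K$ substitutions in the table, the abundance of substitution $s$ in
a fraction with $N$ stop-free reads is $(r_s + a) / (N + aK)$, and

$$\mathrm{logFC}(s) = \log_{10}
  \frac{\mathrm{abundance}_{SP}(s)}{\mathrm{abundance}_{DP}(s)}.$$

The log base and pseudocount are configuration (`screen_config()`)
because neither is fixed by convention; the defaults make the statistic
finite, and antisymmetric under swapping the fractions. A substitution
is called when $\mathrm{logFC} > 0.5$ and its single-positive abundance
exceeds 0.0015 (both strict inequalities, matching the ">" filters the
thresholds come from). Candidates are ranked by logFC, ties broken by
single-positive abundance then position.

Two frequency filters exist at the variant level: the analysis filter
(default 0.001) and a detection floor (default 0.0001).
`analyze_screen()` applies the detection floor within each fraction
independently; `filter_by_abundance()` on a list of fractions applies
the joint rule (a variant must pass in every fraction), which is the
right behaviour for logo plots but would erase abrogating variants —
present almost exclusively in one fraction — from an enrichment
analysis. Whether the floor precedes the 0.001 filter is a free choice;
both are config stages and `analyze_screen()` uses only the floor.

## What the screen simulator emulates, and what it does not

`simulate_screen()` mirrors the generative process of a FACS screen:

1. a **clone pool** of `n_clones` variants is drawn once from the
   library — the transduction bottleneck. Real screens observe far fewer
   unique variants than theoretical complexity (thousands of clones
   against 65,536 assignments); the default of 5,000 clones reproduces
   that regime. The bottleneck matters statistically: it is what makes a
   per-sample detection floor meaningful, because genuine clones collect
   many reads while each sequencing-error derivative of a clone is
   essentially unique and stays below the floor. An optional
   `clone_bias` weight vector emulates uneven synthesis/transduction;
   it is off by default because the bias mechanism in real libraries is
   not characterized.
2. each cell stains therapeutic-positive with probability equal to the
   **minimum** binding-map value over its substitutions (one abrogating
   substitution suffices to lose the epitope); stop-carrying clones
   never stain. Positive cells sort double-positive, negative cells
   single-positive, and assignments flip with the misassignment
   probability (default 5%).
3. one read per cell carries uniform per-base substitution errors
   (default 0.3%) and, with probability 0.5% per read, a 1-nt insertion
   or deletion placed inside the synthesized insert region.

Defaults are the validated study conditions: one abrogating
substitution (N399D), 50,000 reads per fraction. Separate RNG streams
drive the pool, the cell draws, the assignment, the errors and the
indels, so changing one rate does not reshuffle the others.

Not modelled: PCR amplification bias, read-quality profiles, chimeric
reads, clonal fitness differences during expansion, and doublet
integrations. Passing recovery tests therefore demonstrate the
analysis logic under realistic error and misassignment rates, not
robustness to those additional artefacts.

## Base-editor guide nomination

An `editor_spec` is a conversion chemistry (A→G for adenine editors,
C→T for cytosine editors, applied on the protospacer strand), an
editing window in spacer coordinates (position 1 = PAM-distal end;
default 3-9, configurable per editor because windows differ between
deaminase generations), and an IUPAC PAM. `scan_guides()` slides every
placement on both strands and keeps those whose PAM matches and whose
target base is a substrate inside the window. `predict_outcomes()`
enumerates all $2^k$ conversion subsets of the $k$ editable window
positions (capped at $2^8$ with a truncation flag), re-translates, and
labels each outcome silent / intended / bystander. Conversion
probability is deliberately not modelled here — window bases are
editable or not; per-position efficiencies belong to the amplicon layer
and its simulator. `editability()` answers the inverse question: which
(editor, strand) pairs can convert a given codon into a given amino
acid, reproducing the known routes (N399D and N399G by ABE from AAC;
H378R by ABE from CAC; S59P by antisense ABE and S59F by CBE from TCC;
P→S and P→L by CBE from proline codons).

Genomic intervals are 0-based half-open internally; serialized outputs
are 1-based with a strand column.

## Amplicon quantification

Reads with `n_inserted > 0` or `n_deleted > 0` are indel reads. They are
excluded from per-position conversion denominators (their coordinates
are shifted) but retained in the totals, mirroring the separate indel
procedure used downstream. Among non-indel reads the per-position rate
is the fraction carrying the substrate→product change; an edited read
carries at least one in-window conversion. Because the denominator of
the published indel proportion is ambiguous, both `indel_of_total` and
`indel_of_edited` are reported. Raw proportions get Wilson intervals,
which behave at 0 and 1 (model-based intervals belong to the regression
layer). Antisense guides are handled by complementing the conversion
class before scanning sense-coordinate alleles.

## Bias-reduced off-target model

Per candidate locus, edited-read counts are modelled as
$y_i \sim \mathrm{Binomial}(n_i, \pi_i)$,
$\mathrm{logit}(\pi_i) = \beta_0 + \beta_{\mathrm{donor}(i)} +
\beta_t \, \mathrm{treatment}_i$. Plain maximum likelihood diverges when
all mock samples have zero edited reads (complete separation), which is
the typical case at clean loci. `firth_fit()` maximizes the
Jeffreys-prior penalized likelihood
$\ell(\beta) + \tfrac12 \log\lvert I(\beta)\rvert$ — equivalent to
mean-bias reduction for the canonical logit link — by Newton iteration
on the adjusted score
$U^*(\beta) = X^\top(y - n\pi + h(\tfrac12 - \pi))$, with step-halving
against the penalized objective. Estimates and standard errors are
finite under all configurations; for the intercept-only model the fit
reduces to the closed form $(y + \tfrac12)/(n + 1)$, which the tests
verify together with agreement (to $10^{-5}$) with direct numeric
maximization of the penalized likelihood. Different bias-reduction
flavours (mean vs median) differ in the fourth decimal; this package
implements the mean-bias/Jeffreys variant.

A locus is flagged when $\hat\beta_t > 0$ and its two-sided Wald p-value
is below $\alpha = 0.05$; loci are analysed separately without
multiplicity adjustment (an adjustment method is exposed). Under a
symmetric null this positive-sign rule flags between $\alpha/2$ and
$\alpha$ of loci, which the calibration test checks against a 99%
binomial envelope. Fitted per-sample proportions get Wald intervals on
the logit scale, inverse-transformed — the package's documented choice
for model-based proportion intervals.

GUIDE-seq site tables are filtered by dropping sites overlapping any
control (background) interval, then keeping mismatches + bulges
strictly below 6; survivors are annotated exonic > intronic >
intergenic, where overlap means at least one shared base. RNA-editing
rates restrict to reference-adenine sites at or above the per-sample
95th-percentile coverage (order-statistic quantile, ties included —
whether the cut should be global or per-chromosome is unstated upstream,
and per-sample global is implemented) and report per-site G/coverage.

## Affinity curves

Normalized MFI is
$(\mathrm{MFI}_{ther} - \mathrm{MFI}_{bg}) / (\mathrm{MFI}_{ctrl} -
\mathrm{MFI}_{bg})$. The four-parameter log-logistic mean is
$f(x) = c + (d - c)/(1 + e^{b(\ln x - \ln e)})$ with Hill slope $b$,
asymptotes $c \le d$ and midpoint $e$ (dose units, e.g. ng/ml). Fitting
is Gaussian maximum likelihood (least squares, $\hat\sigma^2 =
\mathrm{RSS}/n$) with a deterministic multi-start grid: $b \in \{\pm0.5,
\pm1, \pm2\}$, $e$ at the 25/50/75% dose quantiles, $c, d$ at the
response extremes; the best final likelihood wins and ties break to the
smallest $|b|$.

Numerical choices worth knowing:

* **Canonical orientation.** $(b, c, d, e)$ and $(-b, d, c, e)$ trace
  the identical curve; fits are reported with $c \le d$ so parameters
  are comparable across runs.
* **Parameter box.** On data without sigmoidal structure the RSS
  surface has a degenerate ridge ($b \to 0$, $e \to 0$ or $\infty$,
  $|c|, |d| \to \infty$: the log-linear limit) with no finite optimum.
  Optimization is bounded (L-BFGS-B) in a generous box around the data
  scale, which turns the ridge into a well-defined boundary optimum.
* **Zero doses.** $\ln 0$ is undefined, so zero-dose rows are anchored
  to the curve's limiting asymptote by default ($d$ for $b > 0$), or
  dropped via `zero_dose = "drop"`.

`lr_test()` compares a pooled curve (model 0) against per-group curves
(model 1), each with a single shared error variance estimated by ML, so
df counts mean-function parameters only: $4(G-1)$. The statistic is
$2(\ell_1 - \ell_0) \ge 0$. Because the likelihood is Gaussian, the LR
is a monotone function of the RSS ratio and the exact finite-sample
reference is $F(4(G-1),\, n - 4G)$; the asymptotic $\chi^2$ reference is
noticeably liberal at typical sample sizes (a few dozen points — its
analytic type-I error at $n = 48$ is about 0.09 at nominal 0.05), so the
F reference is the default and `reference = "chisq"` retains the
large-sample convention. The acceptance suite measures the type-I error
of the default test at 500 null replicates and requires it within
[0.03, 0.08].

## Problem sizes used in the test and acceptance suites

Chosen as the package's validation conditions: 20 seeded screen
replicates at 50,000 reads per fraction; 1,000 null loci and 200 shifted
loci for caller calibration and power (totals near 5,000 reads,
baseline logit −5, shift +3); 500 null and 20 shifted replicates for the
curve-comparison operating characteristics ($\sigma = 0.05$, 8 doses ×
3 replicates per group); amplicon depth 10,000 with a 7-adenine window;
10,000-site pileups at 2% background. Noisy midpoint recovery is
assessed over 200 seeds against a ±20% band (observed concentration
around 88% under these noise conditions).

## Known limitations

* The screen simulator draws one read per cell and ignores PCR
  duplication; discard accounting is exact only for fixed-length
  designs.
* Guide nomination does not score genome-wide off-target similarity
  (that is the role of the site-table layer, fed by an external
  assay/predictor) and does not model editing efficiency.
* The Firth layer assumes binomial sampling within sample; overdispersion
  between technical replicates of the same donor/arm is not modelled.
* LL.4 standard errors are Gauss-Newton approximations; confidence sets
  for the midpoint near flat fits should use profile or bootstrap
  methods, which are out of scope here.
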