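# epiedit

Epitope editing installs a small number of amino-acid substitutions into a
cell-surface receptor so that a therapeutic monoclonal antibody (or the CAR
T cells derived from it) no longer recognizes the protein, while ligand
binding and signalling are preserved. Applied to donor haematopoietic
stem/progenitor cells, this shields healthy haematopoiesis from
immunotherapies directed at antigens such as FLT3, KIT and CD123 that are
shared between leukaemia and normal cells.

`epiedit` is an R package for the computational side of that workflow. It
covers, end to end:

- **Library design** (`library_spec`, `enumerate_variants`,
  `sample_variants`, `emit_inserts`): combinatorial codon-swap libraries
  (e.g. human/mouse orthologue swaps across an extracellular domain) and
  single-position degenerate (NNN) scans, with built-in FLT3 ECD4 and KIT
  ECD4 specifications.
- **Sort-seq screen analysis** (`process_reads`, `filter_by_abundance`,
  `positional_aa_frequency`, `substitution_logfc`,
  `rank_epitope_candidates`, `analyze_screen`): translate sorted-fraction
  reads into protein-variant counts (discarding indel and unanchored
  reads), build the per-position amino-acid frequency matrices behind
  sequence logos, and score substitutions by their log10 fold change
  between the single-positive (therapeutic binding lost) and
  double-positive fractions, with the `>0.5` log-fold-change and `>0.0015`
  single-positive abundance filters.
- **Base-editor guide nomination** (`scan_guides`, `predict_outcomes`,
  `editability`): place 20-nt spacers in a 1-bp stagger so the target
  base falls in the editing window (default spacer positions 3-9), under
  NGG / NGN / NRN PAMs, and enumerate all codon outcomes including
  bystander edits.
- **Amplicon quantification** (`quantify_amplicon`, `summarize_window`):
  per-position conversion rates, edited-read proportion and indel
  proportion (`n_inserted > 0` or `n_deleted > 0`) from
  CRISPResso-style allele tables.
- **Off-target statistics** (`firth_fit`, `firth_logistic`,
  `call_offtargets`, `indel_glm`, `filter_guideseq_sites`,
  `rna_editing_rates`): per-locus bias-reduced (Jeffreys-penalized)
  binomial logistic regression of edited-read proportions on donor and
  treatment — finite estimates and standard errors even under complete
  separation — with Wald calls (positive, significant treatment effect =
  bona fide off-target activity); GUIDE-seq site filtering
  (background-peak subtraction, mismatches + bulges < 6) with
  exonic/intronic/intergenic annotation; and top-5%-coverage A>G
  transcriptome editing-rate summaries.
- **Affinity curves** (`normalize_mfi`, `fit_ll4`, `lr_test`):
  four-parameter log-logistic fits
  `f(x) = c + (d - c) / (1 + exp(b (ln x - ln e)))` to normalized MFI,
  and likelihood-ratio comparison of curves across receptor variants or
  antibodies.
- **Synthetic data** (`simulate_screen`, `simulate_amplicon`,
  `simulate_offtarget_counts`, `simulate_dose_response`,
  `simulate_pileup`): seeded generators with ground truth for every
  input above, so the whole pipeline is testable without external data.

## Worked example

Simulate the 16-position human/mouse FLT3 ECD4 combinatorial screen
(65,536 theoretical variants, 50,000 reads per sorted fraction, 0.3%
per-base error, 0.5% indels, 5% sorter misassignment, N399D abrogating)
and recover the epitope:

```r
library(epiedit)

spec <- flt3_library_spec()
spec
#> library_spec (combinatorial): 66-aa ORF, 16 variable position(s), complexity 65,536

sim <- simulate_screen(screen_truth(spec), seed = 42)
res <- analyze_screen(sim$sp, sim$dp, spec)
res$sp
#> variant_counts [single_positive]: 2354 variants, 27178 aggregated reads (229 indel, 5669 unanchored discarded)
res$candidates[, c("substitution", "abundance_sp", "abundance_dp", "logfc")]
#>   substitution abundance_sp abundance_dp    logfc
#> 9        N399D    0.9995402 0.0005667691 3.246394
```

The only substitution passing both filters is the planted N399D: it
carries essentially all single-positive reads (abundance 0.9995) and is
3.2 orders of magnitude enriched over the double-positive fraction.
Asking which editor installs it:

```r
editability("N", "D", "AAC")
#>   editor strand codon_outcome
#> 1    ABE      +           GAC
```

— an adenine base editor acting on the sense strand converts AAC (Asn)
to GAC (Asp). Downstream, the off-target layer fits one bias-reduced
logistic model per locus:

```r
tab <- simulate_offtarget_counts(n_loci = 1, baseline = -5,
                                 treatment_shift = 3, seed = 1)
firth_logistic(tab)
#> Firth-penalized binomial logistic fit
#>               estimate         se          z             p
#> (Intercept) -5.3250623 0.11908215 -44.717554  0.000000e+00
#> DonorIDD2    0.3414953 0.06261151   5.454195  4.919530e-08
#> DonorIDD3   -0.1501980 0.06906991  -2.174580  2.966161e-02
#> treatment    3.0564207 0.11566913  26.423825 7.296281e-154
```

The treatment coefficient (+3.06 log-odds, Wald p < 1e-150) recovers the
programmed +3 shift, so this locus would be flagged by
`call_offtargets()`. Affinity curves with a genuine binding loss separate
decisively:

```r
dr <- simulate_dose_response(
  params = list(WT = c(1, 0, 1, 50), N399D = c(1, 0.02, 0.35, 480)),
  sigma = 0.05, seed = 2)
lr_test(dr)
#> LL.4 likelihood-ratio test: LR = 139.6 on 4 df, p = 1.08e-24
```

See `vignettes/epitope-editing-pipeline.Rmd` for the models, their
assumptions and the numerical choices.

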