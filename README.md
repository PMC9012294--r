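# immunotraj

Paired pre/post-treatment peripheral immune trajectory analysis in R.

When a cancer therapy is suspected of activating adaptive immunity, two
complementary readouts from peripheral blood can test it: (i) the T cell
receptor (TCR) repertoire should concentrate into expanded clones after
treatment, and (ii) innate immune cells — above all plasmacytoid dendritic
cells (pDCs), the main type-1-interferon producers — should show proportional
and transcriptional activation that *co-varies* with the clonal expansion.
`immunotraj` implements this analysis for paired (pre, post) patient samples:

- **Repertoire.** From AIRR Rearrangement tables, clone proportions
  `p_i = c_i / Σc`, the Simpson diversity index family built on the
  concentration `λ = Σ p_i²` (gini-Simpson `1 − λ` by default, inverse
  `1/λ` and `λ` itself selectable), the paired diversity log fold change
  `log2((DI_post + ε)/(DI_pre + ε))` (negative = clonal expansion), and
  top-*N* clone expansion profiles (summed repertoire mass of the top
  post-treatment clones and of the same clonotypes before treatment).
- **Expression.** From sparse cell-by-gene count matrices with
  patient/timepoint/cluster metadata: counts-per-10k log normalization,
  cluster proportions and their Haldane-corrected log2 fold change,
  per-cluster pseudobulk gene log2FC, the **disturbance score** (mean
  absolute gene logFC of a cluster between paired samples — a scalar measure
  of global transcriptional activation), per-cell pathway mean-expression
  scores, and marker-panel cluster annotation.
- **Enrichment.** Preranked GSEA: the weighted running-sum enrichment score
  (hit steps `|s|^p / Σ_hits |s|^p`, miss steps `−1/(N − N_hits)`), a
  gene-permutation null with the add-one p estimator, sign-matched NES, and
  Benjamini-Hochberg FDR.
- **Linking.** Spearman correlation of per-patient DI logFC against pDC
  activation (proportion logFC or disturbance score) with **exact
  permutation inference** (full `n!` enumeration for `n ≤ 9`), and a
  DI-ordered gene-panel signature matrix.
- **Synthetic cohorts.** A fully seeded generator plants all of the above:
  Zipf-law repertoires with top-clone reweighting in responders,
  negative-binomial expression with an interferon-responsive gene module,
  a pDC-like cluster shift, and a per-patient responder-strength scalar that
  couples expansion to activation. Ground truth is returned for
  parameter-recovery testing, so no patient data are required anywhere.

## Worked example

```r
library(immunotraj)

cfg <- cohort_config(seed = 42)     # 12 patients, 9 responders
cohort <- simulate_cohort(cfg)

pat <- cohort$patients[[1]]
di_logfc(pat$repertoire$pre, pat$repertoire$post)
#>  patient_id chain    di_pre  di_post    di_logfc      variant expansion
#>         P01   TRB 0.9307431 0.876979 -0.08584069 gini_simpson      TRUE

top_clone_mass(pat$repertoire$pre, pat$repertoire$post, n_top = 200)
#> <expansion_profile> P01 TRB: top 200 clones hold 94.4% post vs 85.2% pre
```

Patient P01 is a responder: diversity drops after treatment (negative DI
logFC) and the 200 most abundant post-treatment clones gained repertoire
mass. The full pipeline ties the cohort together:

```r
bundle <- run_cohort_analysis(cfg)
bundle$tables$correlation
#>            activation          r      p_value  n          method
#>  pdc_proportion_logfc -0.8811189 0.0001526741 12 t_approximation
#>       pdc_disturbance -0.8391608 0.0006428260 12 t_approximation
```

Both pDC activation readouts correlate negatively with the DI logFC: the
patients whose repertoires concentrated the most are the ones whose pDCs
expanded and were transcriptionally disturbed — the planted coupling,
recovered. The planted interferon module is likewise enriched at the top of
the innate-cluster logFC rankings (`bundle$tables$enrichment`), while the
control set is not positively enriched.

A command-line wrapper covers the same pipeline
(`exec/immunotraj run-all --simulate --seed 42 --out bundle/`), writing one
tidy TSV per table plus a timestamp-free JSON manifest, so a repeated run is
byte-identical.

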