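# nkbias

Rule-based classification of NKG2A+/NKG2C+ immune biases and the statistics
that relate them to clinical outcomes.

NKG2A (*KLRC1*) and NKG2C (*KLRC2*) are inhibitory and stimulatory receptors
on NK cells and subsets of CD8+ T cells; both require CD94 (*KLRD1*) as a
heterodimer partner and both bind HLA-E. Whether a patient's response is
dominated by NKG2A+ or NKG2C+ cells — their *immune bias* — is a candidate
correlate of protection across infection, autoimmunity and cancer. `nkbias`
is for analysts who need to assign that bias reproducibly at every
measurement level and test its clinical associations without hand-rolled
thresholds scattered across notebooks.

## What it computes

**Bias calls.** At single-cell resolution on ln(CPM+1) data, cell *i* is
NKG2A+ iff

    CD94_i >= t  and  NKG2A_i >= t  and not NKG2C_i >= t,   t = 2.5

(NKG2C+ symmetrically; cells passing both are labelled `dual`). On Z-scored
data, NKG2A+ iff `z(NKG2A) − z(NKG2C) >= 1`. Bulk samples are scored

    s = log2( (CD94·NKG2A + ε) / (CD94·NKG2C + ε) ),   ε = 0.01

with the top and bottom pentile (floor(0.2·N)) of s called NKG2A+/NKG2C+.
Spatial spots use any non-zero expression. A patient is NKG2A-biased when
`n_A > r · n_C` in a compartment (r = 3 for NK cells, 1 for CD8+ T cells),
optionally at any acute timepoint.

**Statistics.** Covariate-adjusted logistic models (ln odds ratios, Wald 95%
CIs), Kaplan–Meier curves and log-rank tests, hypergeometric set-overlap
tails, exact/approximate Mann–Whitney, Pearson/Spearman correlations, and
the differential-protein and confident-gene selection rules.

**CMV serostatus.** A two-feature linear SVM (CMV-associated clone hits,
total distinct clones) with stratified 6-fold cross-validation, AUROC
scoring, and any-sample-positive patient calling.

**Spatial.** Lattice neighbour graphs (square/hex), positive-spot density
diffusion (`decay^distance`, nearest-source), per-spot ligand–receptor
product scores with limiting-subunit complexes, and NKG2A+ vs NKG2A− CD8
differential interaction tables.

**Synthetic data.** `sim_config()` plus four seeded generators produce
single-cell cohorts, bulk survival cohorts, TCR repertoires and spatial
lattices with planted effects and truth tables, so the whole pipeline is
testable offline.

## Worked example

```r
library(nkbias)

cfg    <- sim_config(seed = 42)                 # 120 patients x 60 cells
cohort <- gen_single_cell_cohort(cfg)

calls  <- call_cells_absolute(cohort$expression)
table(calls$label)
#>    A    C none
#>  895 1029 5276

bias   <- assign_patient_bias(calls, cohort$annotations, compartment = "NK")
design <- encode_covariates(cohort$clinical, bias, outcome = "survived")
fit_logistic(design)
#>          term estimate      se  ci_low ci_high p_value
#> 1 (Intercept) -1.24287 0.60633 -2.4313 -0.0545  0.0404
#> 2      bias_A  0.73599 0.38104 -0.0108  1.4828  0.0534
#> 3      female  0.12229 0.38020 -0.6229  0.8675  0.7477
#> 4         age  0.00823 0.00925 -0.0099  0.0264  0.3739
#> 5      severe  0.26311 0.38117 -0.4840  1.0102  0.4900
```

The 895/1029 NKG2A+/NKG2C+ cells come from the generator's two-component
marker mixture; the patient-level calls recover the planted bias for ~94%
of patients on this seed. The `bias_A` row is the covariate-adjusted
ln(odds ratio) of survival for NKG2A-biased patients — positive, consistent
with the planted protective effect of 1.0, with the wide interval a
120-patient cohort implies.

A subcommand-style driver wraps the same functions for batch runs:

```r
run_cli(c("simulate", "--seed", "7", "--out", "run1"))
run_cli(c("call-bias", "--dir", "run1"))
run_cli(c("associate", "--dir", "run1"))
run_cli(c("report",    "--dir", "run1"))
```

Outputs are TSVs with `.meta.yaml` sidecars recording the rule parameters
used; identical seeds give byte-identical runs.

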