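# sofatraj

Trajectory-based subphenotyping of sepsis from ICU organ-dysfunction
scores.

Sepsis is a heterogeneous syndrome, and subgroups defined by *how* organ
dysfunction evolves — rather than by a single baseline snapshot — separate
patients with very different outcomes. `sofatraj` implements the full
analysis as a tested, reusable R pipeline:

1. **SOFA engine** — builds 72-hour Sequential Organ Failure Assessment
   (SOFA) trajectories from raw time-stamped measurements: 6-hour windows
   `[6(k-1), 6k)`, worst value per window per variable, daily urine
   divided by 4, lowest GCS irrespective of sedation, standard organ
   bands, LOCF → NOCB → zero-fill imputation at the subscore level. Each
   patient becomes a vector of 12 total scores `s_1..s_12` (0-24) plus a
   6×12 subscore matrix.
2. **Trajectory distance** — dynamic time warping with squared local cost
   and unconstrained monotone alignment:
   `D(i,j) = (x_i − y_j)² + min(D(i−1,j), D(i,j−1), D(i−1,j−1))`,
   distance = `√D(n,m)`.
3. **Clustering** — hierarchical agglomerative clustering (average linkage
   by default) on the DTW matrix; silhouette/Dunn/C-index report for the
   choice of k; archetype labeling of four clusters as Rapidly Worsening
   (RW), Delayed Worsening (DW), Rapidly Improving (RI), Delayed
   Improving (DI) from the sign pattern of the first-48-h and last-24-h
   changes of each cluster's mean curve.
4. **GBTM sensitivity arm** — latent-class polynomial trajectory mixture
   (`y_it | g ~ N(Σ_j β_gj t^j, σ²)`) fitted by EM with multi-start,
   BIC model choice, posterior membership, and adjusted-Rand agreement
   with the clustering.
5. **Characterization** — Table-1-style group comparisons (chi-square /
   Fisher; t-test / ANOVA vs Mann-Whitney / Kruskal-Wallis after a
   normality screen), Kaplan-Meier curves to 28 days, log-rank test.
6. **Early prediction** — leakage-free feature snapshots at hours
   6/24/36/48/60, a 500-tree random forest on a fixed stratified split,
   bootstrap accuracy CIs, and Monte-Carlo permutation Shapley
   attribution.
7. **Synthetic cohorts** — a seeded generator with known latent
   archetypes, rubric-exact measurement back-generation, MCAR
   missingness and archetype-linked 28-day outcomes, so every stage is
   testable with no restricted data access.

See the methods vignette
(`vignettes/sofa-trajectory-subphenotyping.Rmd`) for the model details and
design rationale.

## Worked example

```r
library(sofatraj)

cfg    <- cohort_config(n_patients = 400, seed = 1,
                        archetypes = archetype_specs(noise_sd = 0.5),
                        missing_rate = 0, full_missing_rate = 0)
cohort <- generate_cohort(cfg)
traj   <- build_trajectories(cohort)
traj
#> SOFA trajectories: 400 patients x 12 windows (72-h horizon)
#> mean baseline SOFA (window 1): 4.92

D      <- pairwise_dtw(traj)
tree   <- hac_linkage(D)               # average linkage
assign <- cut_tree(tree, 4)
lab    <- label_archetypes(assign, traj)
lab
#> Archetype labeling (status: ok )
#>   cluster 1 -> RI  (early -1.69, late -1.13)
#>   cluster 2 -> DI  (early +0.58, late -1.13)
#>   cluster 3 -> DW  (early -1.34, late +0.74)
#>   cluster 4 -> RW  (early +1.88, late +0.80)

truth <- cohort$truth$archetype[match(assign$patient_id,
                                      cohort$truth$patient_id)]
adjusted_rand_index(assign$cluster, truth)
#> [1] 0.7423609
```

The labeling reads each cluster's mean curve: cluster 4 rises throughout
(+1.88 SOFA points over the first 48 h, +0.80 over the last 24 h), so it
is Rapidly Worsening; cluster 3 falls then rebounds, the Delayed Worsening
signature. The adjusted Rand index of 0.74 against the generator's hidden
labels says the DTW + clustering stage recovered the archetypes well at
this noise level.

The sensitivity arm and outcome comparison:

```r
gb   <- fit_gbtm(traj, G = 4, degree = 2, seed = 1)
agreement(assign,
          data.frame(patient_id = traj$patient_id,
                     cluster = posterior_assign(gb, traj)$assignment))$ari
#> [1] 0.7615435

surv <- survival_records(cohort, patient_archetypes(assign, lab))
logrank_test(surv)$p_value
#> [1] 0.09347763
```

The trajectory-mixture re-derivation agrees with the clustering (ARI
0.76). At only 400 patients the 28-day mortality gradient across the
labeled groups is visible but not yet significant (log-rank p = 0.093);
at the development-cohort scale used by `scripts/acceptance.R`
(n = 4678) the same comparison over the true archetypes gives a log-rank
chi-square of ~277 (p far below 0.001).

A single call, `run_pipeline(cfg, out_dir = "out")`, executes every stage
(including index-based k selection and early prediction) and writes
`trajectories.csv`, `assignments.csv`, `indices.json`, `gbtm.json`,
`table1.csv`, `km.csv` and `report.json`; two runs with the same
configuration are byte-identical. A thin command-line wrapper with
`simulate` / `sofa` / `cluster` / `gbtm` / `characterize` / `predict` /
`pipeline` subcommands is installed at `inst/cli/sofatraj`.

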